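#' Stoichiometric family sums of a composition
#'
#' The canonical pentamer carries two alpha, two beta-position and one
#' odd-position subunit, so compositions are summarized by Sigma-alpha (the
#' six alpha genes), Sigma-beta (beta1-3 plus theta) and Sigma-chi (the
#' gammas, delta, epsilon, pi); the rho genes are excluded and reported as
#' Sigma-rho, so the four sums partition 100%.
#'
#' @param composition a `CompositionMatrix`, or a named numeric vector (one
#'   composition column, percentages summing to 100).
#' @param panel a `GenePanel` (defaults to the panel carried by the
#'   composition).
#' @return For a vector input, a named numeric
#'   `c(sigma_alpha, sigma_beta, sigma_chi, sigma_rho)`; for a matrix, a
#'   4 x samples matrix of the same sums.
#' @export
family_sums <- function(composition, panel = NULL) {
  if (inherits(composition, "CompositionMatrix")) {
    if (is.null(panel)) panel <- composition$panel
    vals <- composition$values
  } else {
    vals <- as.matrix(composition)
    if (is.null(panel)) stop("a panel is required for plain input")
  }
  mem <- panel$sum_membership
  groups <- list(sigma_alpha = "SigmaAlpha", sigma_beta = "SigmaBeta",
                 sigma_chi = "SigmaChi", sigma_rho = "excluded")
  out <- vapply(groups, function(tag) {
    idx <- intersect(names(mem)[mem == tag], rownames(vals))
    colSums(vals[idx, , drop = FALSE])
  }, numeric(ncol(vals)))
  out <- t(matrix(out, ncol = length(groups),
                  dimnames = list(colnames(vals), names(groups))))
  if (ncol(out) == 1) out[, 1] else out
}

#' Build nucleus profiles from a composition matrix and labels
#'
#' @param composition a `CompositionMatrix` over nuclei.
#' @param labels data.frame with `nucleus`, `cell_type`, `class` matching
#'   the composition columns.
#' @return A data.frame of class `NucleusProfileTable` (nucleus, cell_type,
#'   class, sigma_alpha, sigma_beta, sigma_chi, sigma_rho) with the full
#'   composition attached as the `composition` attribute.
#' @export
nucleus_profiles <- function(composition, labels) {
  sums <- family_sums(composition)
  ids <- colnames(composition$values)
  idx <- match(ids, labels$nucleus)
  if (anyNA(idx)) stop("labels missing for some nuclei")
  out <- data.frame(nucleus = ids,
                    cell_type = labels$cell_type[idx],
                    class = labels$class[idx],
                    sigma_alpha = sums["sigma_alpha", ],
                    sigma_beta = sums["sigma_beta", ],
                    sigma_chi = sums["sigma_chi", ],
                    sigma_rho = sums["sigma_rho", ],
                    row.names = NULL)
  attr(out, "composition") <- composition
  class(out) <- c("NucleusProfileTable", "data.frame")
  out
}

#' Gate nuclei on the 2:2:1 stoichiometric windows
#'
#' Keeps nuclei whose family sums fall inside closed windows around the
#' pentamer expectation: Sigma-alpha and Sigma-beta within 40 +/- 5% and
#' Sigma-chi within 20 +/- 5% by default (boundary nuclei are kept). The
#' gate is idempotent and, with windows [0, 100], the identity.
#'
#' @param profiles a `NucleusProfileTable` (see [nucleus_profiles()]).
#' @param alpha_window,beta_window,chi_window numeric length-2 windows
#'   `c(center, halfwidth)`.
#' @return The gated subset (same class); the `gate_summary` attribute holds
#'   kept/dropped counts per cell type.
#' @export
stoichiometric_gate <- function(profiles,
                                alpha_window = c(40, 5),
                                beta_window = c(40, 5),
                                chi_window = c(20, 5)) {
  inside <- function(x, w) x >= w[1] - w[2] & x <= w[1] + w[2]
  keep <- inside(profiles$sigma_alpha, alpha_window) &
          inside(profiles$sigma_beta, beta_window) &
          inside(profiles$sigma_chi, chi_window)
  out <- profiles[keep, , drop = FALSE]
  comp <- attr(profiles, "composition")
  if (!is.null(comp)) {
    comp$values <- comp$values[, keep, drop = FALSE]
    comp$samples <- comp$samples[keep, , drop = FALSE]
    attr(out, "composition") <- comp
  }
  summ <- as.data.frame(table(cell_type = profiles$cell_type, kept = keep))
  attr(out, "gate_summary") <- summ
  class(out) <- class(profiles)
  out
}

#' Sampling-convergence of family sums within one cell type
#'
#' Repeatedly subsamples nuclei (without replacement) at each requested
#' size and reports mean and SD of the subsample means of Sigma-alpha,
#' Sigma-beta and Sigma-chi: the larger the sample, the tighter the sums
#' converge on the 40/40/20 pentamer split.
#'
#' @param profiles `NucleusProfileTable` restricted to one cell type.
#' @param sample_sizes integer sizes, each at most the number of nuclei.
#' @param n_draws subsamples per size.
#' @param seed integer seed.
#' @return data.frame (size, family, mean, sd).
#' @export
convergence_curve <- function(profiles, sample_sizes, n_draws = 100,
                              seed = 1) {
  n <- nrow(profiles)
  if (any(sample_sizes > n))
    stop(sprintf("sample size %d exceeds population %d",
                 max(sample_sizes), n))
  rng <- .local_rng(seed)
  on.exit(rng$restore())
  sums <- as.matrix(profiles[, c("sigma_alpha", "sigma_beta", "sigma_chi")])
  rows <- list()
  for (s in sample_sizes) {
    draws <- vapply(seq_len(n_draws), function(d)
      colMeans(sums[sample.int(n, s), , drop = FALSE]), numeric(3))
    rows[[length(rows) + 1]] <- data.frame(
      size = s, family = rownames(draws),
      mean = rowMeans(draws),
      sd = apply(draws, 1, stats::sd), row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Pairwise Pearson correlations of gene contributions
#'
#' Pearson r and a two-tailed p value (t distribution with n - 2 df) for
#' every unordered pair of the chosen genes, over the observation unit of
#' the analysis level: substructures (level A), samples (level B),
#' cell-type means (level C), or nuclei within one cell type (level D).
#' Zero-variance genes are skipped and recorded in the `skipped` attribute.
#'
#' @param observations genes x observations numeric matrix, or a
#'   `CompositionMatrix`.
#' @param genes gene subset (default: all rows).
#' @param tag dataset tag, e.g. `"A_microarray"`, `"D_within_celltype"`.
#' @param group optional group label (cell type or class) carried into the
#'   report.
#' @return A `CorrelationReport` data.frame (gene_a, gene_b, r, p, n, tag,
#'   group).
#' @export
pairwise_correlations <- function(observations, genes = NULL, tag = "A",
                                  group = NA_character_) {
  vals <- if (inherits(observations, "CompositionMatrix") ||
              inherits(observations, "ExpressionMatrix"))
    observations$values else as.matrix(observations)
  if (is.null(genes)) genes <- rownames(vals)
  miss <- setdiff(genes, rownames(vals))
  if (length(miss)) stop("genes absent: ", paste(miss, collapse = ", "))
  n <- ncol(vals)
  if (n < 3) stop("need at least 3 observations")
  sds <- apply(vals[genes, , drop = FALSE], 1, stats::sd)
  usable <- genes[sds > 0]
  skipped <- setdiff(genes, usable)
  pairs <- utils::combn(usable, 2)
  r <- apply(pairs, 2, function(gp)
    stats::cor(vals[gp[1], ], vals[gp[2], ]))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out <- data.frame(gene_a = pairs[1, ], gene_b = pairs[2, ],
                    r = r, p = p, n = n, tag = tag, group = group,
                    row.names = NULL)
  attr(out, "skipped") <- skipped
  class(out) <- c("CorrelationReport", "data.frame")
  out
}

#' Cross-level consensus of correlated subunit pairs
#'
#' Pools correlation reports from the different analysis levels and keeps
#' every unordered pair that is significant with the same sign in at least
#' `min_support` reports. A pair that is also significant with the opposite
#' sign in some other report is flagged `both` (subunits shared by some
#' receptors and mutually excluded in other contexts). Supporting dataset
#' tags and groups are recorded per row.
#'
#' @param reports list of `CorrelationReport` objects.
#' @param alpha two-tailed significance threshold (default 0.05, raw p; set
#'   `adjust = "BH"` for a Benjamini-Hochberg correction within each
#'   report).
#' @param min_support minimum number of supporting reports (default 2).
#' @param adjust `"none"` or `"BH"`.
#' @return A `ConsensusPairTable` data.frame (gene_a, gene_b, direction,
#'   n_support, support, groups, both).
#' @export
consensus_pairs <- function(reports, alpha = 0.05, min_support = 2,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (length(reports) < 2) stop("need at least 2 reports")
  all_sig <- do.call(rbind, lapply(reports, function(rep) {
    p <- if (adjust == "BH") stats::p.adjust(rep$p, "BH") else rep$p
    sig <- rep[p < alpha, , drop = FALSE]
    if (!nrow(sig)) return(NULL)
    key <- apply(sig[, c("gene_a", "gene_b")], 1, function(g)
      paste(sort(g), collapse = "|"))
    data.frame(key = key, sign = sign(sig$r), tag = sig$tag,
               group = sig$group)
  }))
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      direction = character(), n_support = integer(),
                      support = character(), groups = character(),
                      both = logical())
  class(empty) <- c("ConsensusPairTable", "data.frame")
  if (is.null(all_sig) || !nrow(all_sig)) return(empty)
  rows <- list()
  for (key in unique(all_sig$key)) {
    sub <- all_sig[all_sig$key == key, , drop = FALSE]
    genes <- strsplit(key, "|", fixed = TRUE)[[1]]
    for (dir_sign in c(1, -1)) {
      hit <- sub[sub$sign == dir_sign, , drop = FALSE]
      if (nrow(hit) < min_support) next
      rows[[length(rows) + 1]] <- data.frame(
        gene_a = genes[1], gene_b = genes[2],
        direction = if (dir_sign > 0) "positive" else "negative",
        n_support = nrow(hit),
        support = paste(unique(hit$tag), collapse = ","),
        groups = paste(unique(stats::na.omit(hit$group)), collapse = ","),
        both = any(sub$sign == -dir_sign))
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  class(out) <- c("ConsensusPairTable", "data.frame")
  out
}
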