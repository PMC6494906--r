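#' Canonical ordered gene pairs of a panel
#'
#' The 19-gene panel yields 171 unordered pairs, listed in fixed
#' lexicographic order; every distance vector follows this order so vectors
#' from different subjects and structures are comparable entry-wise.
#'
#' @param panel a `GenePanel` (or character vector of symbols).
#' @return A 2 x n_pairs character matrix of gene pairs.
#' @export
canonical_pairs <- function(panel = gaba_panel()) {
  symbols <- if (inherits(panel, "GenePanel")) panel$symbols else panel
  utils::combn(sort(symbols), 2)
}

.distance_vector <- function(values, pairs, kind, context) {
  structure(values,
            pairs = paste(pairs[1, ], pairs[2, ], sep = "-"),
            kind = kind, context = context,
            class = "DistanceVector")
}

#' Individual pairwise subunit distances
#'
#' For one profile (the 19 expression values of a single subject in a
#' single structure, or a whole-brain mean profile), the distance between
#' subunits x and y is sqrt((x - y)^2) = |x - y|, giving a 171-entry vector
#' in the canonical pair order.
#'
#' @param profile named numeric vector of expression values covering the
#'   panel.
#' @param panel a `GenePanel`.
#' @param context optional list (subject, structure, transform) recorded on
#'   the result.
#' @return A `DistanceVector` of kind `"individual"`.
#' @export
pair_distance_individual <- function(profile, panel = gaba_panel(),
                                     context = list()) {
  pairs <- canonical_pairs(panel)
  miss <- setdiff(unique(as.vector(pairs)), names(profile))
  if (length(miss)) stop("missing gene(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(profile))) stop("profile must be finite")
  d <- abs(profile[pairs[1, ]] - profile[pairs[2, ]])
  .distance_vector(unname(d), pairs, "individual", context)
}

#' Consensus pairwise subunit distances over subjects
#'
#' The consensus distance between subunits x and y pools all n subjects:
#' sqrt(sum_k (x_k - y_k)^2). With a single subject it reduces exactly to
#' the individual distance; no 1/n normalization is applied (the stereotypy
#' correlation is scale-invariant, so none is needed).
#'
#' @param profiles genes x subjects numeric matrix (one column per
#'   subject), rows covering the panel.
#' @param panel a `GenePanel`.
#' @param context optional context list.
#' @return A `DistanceVector` of kind `"consensus"`.
#' @export
pair_distance_consensus <- function(profiles, panel = gaba_panel(),
                                    context = list()) {
  profiles <- as.matrix(profiles)
  pairs <- canonical_pairs(panel)
  miss <- setdiff(unique(as.vector(pairs)), rownames(profiles))
  if (length(miss)) stop("missing gene(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(profiles))) stop("profiles must be finite")
  diff <- profiles[pairs[1, ], , drop = FALSE] -
          profiles[pairs[2, ], , drop = FALSE]
  d <- sqrt(rowSums(diff^2))
  .distance_vector(unname(d), pairs, "consensus", context)
}

#' Stereotypy of an individual layout against a consensus
#'
#' Pearson correlation R(d_i, d_c) over the 171 pair distances: values near
#' 1 mean the individual's collective subunit layout matches the consensus
#' organization. Invariant to a common positive rescaling of either vector.
#'
#' @param individual,consensus `DistanceVector`s in the same pair order.
#' @return The correlation R, or `NA` with a warning when either vector has
#'   zero variance.
#' @export
stereotypy <- function(individual, consensus) {
  if (length(individual) != length(consensus))
    stop("distance vectors differ in length")
  pa <- attr(individual, "pairs"); pb <- attr(consensus, "pairs")
  if (!is.null(pa) && !is.null(pb) && !identical(pa, pb))
    stop("distance vectors differ in pair order")
  if (stats::sd(individual) == 0 || stats::sd(consensus) == 0) {
    warning("zero variance; stereotypy undefined")
    return(NA_real_)
  }
  stats::cor(as.numeric(individual), as.numeric(consensus))
}

#' Stereotypy of every subject and structure against a reference
#'
#' Builds the consensus distance vector of a chosen reference substructure
#' across subjects, then correlates each subject's individual distance
#' vector in every substructure against it. Rows are ordered
#' rostro-caudally by the ontology rank, so regional gradients of layout
#' similarity read naturally.
#'
#' @param subject_mats named list of substructure-level `ExpressionMatrix`
#'   (or `CompositionMatrix`), one per subject, on a common transform.
#' @param reference substructure code used to build the reference
#'   consensus.
#' @param ontology an `OntologyMap`.
#' @param panel a `GenePanel`.
#' @param transform tag recorded in the output (`"log2"` or
#'   `"proportional"`).
#' @return A `StereotypyReport` data.frame (subject, substructure,
#'   structure, rank, transform, R).
#' @export
reference_similarity <- function(subject_mats, reference,
                                 ontology = build_default_ontology(),
                                 panel = gaba_panel(),
                                 transform = "log2") {
  vals <- lapply(subject_mats, function(m)
    if (inherits(m, "ExpressionMatrix") || inherits(m, "CompositionMatrix"))
      m$values else as.matrix(m))
  for (s in names(vals))
    if (!reference %in% colnames(vals[[s]]))
      stop("reference ", reference, " missing for subject ", s)
  ref_profiles <- vapply(vals, function(v) v[panel$symbols, reference],
                         numeric(length(panel$symbols)))
  rownames(ref_profiles) <- panel$symbols
  d_ref <- pair_distance_consensus(ref_profiles, panel,
                                   context = list(structure = reference,
                                                  transform = transform))
  common <- Reduce(intersect, lapply(vals, colnames))
  rows <- list()
  for (s in names(vals)) {
    for (st in common) {
      di <- pair_distance_individual(vals[[s]][panel$symbols, st], panel)
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, substructure = st,
        R = suppressWarnings(stereotypy(di, d_ref)))
    }
  }
  out <- do.call(rbind, rows)
  onto <- ontology_lookup(out$substructure, ontology)
  out$structure <- onto$structure
  out$rank <- onto$rank
  out$transform <- transform
  out <- out[order(out$rank, out$subject),
             c("subject", "substructure", "structure", "rank",
               "transform", "R")]
  rownames(out) <- NULL
  class(out) <- c("StereotypyReport", "data.frame")
  out
}

#' Whole-brain stereotypy of each subject
#'
#' Each subject's whole-brain profile is the across-substructure mean per
#' gene; the consensus pools all subjects' whole-brain profiles. Returns
#' R(d_i, d_c) per subject.
#'
#' @param subject_mats named list of substructure-level matrices per
#'   subject.
#' @param panel a `GenePanel`.
#' @return data.frame (subject, R) plus the consensus vector as attribute
#'   `consensus`.
#' @export
whole_brain_stereotypy <- function(subject_mats, panel = gaba_panel()) {
  profs <- vapply(subject_mats, function(m) {
    v <- if (inherits(m, "ExpressionMatrix") ||
             inherits(m, "CompositionMatrix")) m$values else as.matrix(m)
    rowMeans(v[panel$symbols, , drop = FALSE])
  }, numeric(length(panel$symbols)))
  rownames(profs) <- panel$symbols
  d_c <- pair_distance_consensus(profs, panel)
  out <- data.frame(
    subject = colnames(profs),
    R = vapply(colnames(profs), function(s)
      stereotypy(pair_distance_individual(profs[, s], panel), d_c),
      numeric(1)),
    row.names = NULL)
  attr(out, "consensus") <- d_c
  out
}

#' Ward dendrogram of subunits from a distance vector
#'
#' Uses the 171 pairwise distances directly as the dissimilarity structure
#' over the 19 subunits and applies Ward clustering, visualizing which
#' subunits sit close together in the organizational layout.
#'
#' @param d a `DistanceVector`.
#' @param panel a `GenePanel`.
#' @return An `hclust` object over the panel genes.
#' @export
layout_dendrogram <- function(d, panel = gaba_panel()) {
  symbols <- sort(panel$symbols)
  n <- length(symbols)
  mat <- matrix(0, n, n, dimnames = list(symbols, symbols))
  pairs <- canonical_pairs(panel)
  for (k in seq_len(ncol(pairs))) {
    mat[pairs[1, k], pairs[2, k]] <- d[k]
    mat[pairs[2, k], pairs[1, k]] <- d[k]
  }
  stats::hclust(stats::as.dist(mat), method = "ward.D2")
}

#' Dunnett-adjusted many-to-one comparisons after one-way ANOVA
#'
#' One-way ANOVA of the stereotypy values across structures, followed by
#' Dunnett's many-to-one comparison of every structure against the
#' reference. The adjustment simulates the null distribution of the maximum
#' absolute many-to-one t statistic (shared control, pooled variance) and
#' reports, per structure, the probability of a null maximum at least as
#' large as the observed statistic. Groups with fewer than 2 observations
#' are excluded with a warning.
#'
#' @param report a `StereotypyReport` (or data.frame with `R` and a
#'   grouping column).
#' @param reference reference structure code (the control group).
#' @param grouping name of the grouping column (default `"structure"`).
#' @param n_sim null-simulation draws (default 1e5).
#' @param seed integer seed for the simulation.
#' @param alpha significance level (default 0.05).
#' @return A list: `anova` (data.frame F, df1, df2, p), `contrasts`
#'   (data.frame structure, diff, t, p_adj, significant).
#' @export
compare_to_reference <- function(report, reference,
                                 grouping = "structure",
                                 n_sim = 1e5, seed = 1, alpha = 0.05) {
  g <- as.character(report[[grouping]])
  y <- report$R
  ok <- stats::complete.cases(g, y)
  g <- g[ok]; y <- y[ok]
  counts <- table(g)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !(g %in% small)
    g <- g[keep]; y <- y[keep]
    counts <- table(g)
  }
  if (!reference %in% names(counts))
    stop("reference group ", reference, " absent (or too small)")
  if (length(counts) < 2) stop("need at least 2 groups")

  fit <- stats::aov(y ~ factor(g))
  an <- summary(fit)[[1]]
  anova_row <- data.frame(F = an$`F value`[1], df1 = an$Df[1],
                          df2 = an$Df[2], p = an$`Pr(>F)`[1])

  mse <- an$`Mean Sq`[2]
  df_err <- an$Df[2]
  others <- setdiff(names(counts), reference)
  n0 <- counts[[reference]]
  m0 <- mean(y[g == reference])
  tstat <- vapply(others, function(gr) {
    ni <- counts[[gr]]
    (mean(y[g == gr]) - m0) / sqrt(mse * (1 / ni + 1 / n0))
  }, numeric(1))

  # simulate the max-|t| null: group means ~ N(0, 1/n_i), shared control,
  # pooled sd ~ sqrt(chi2_df / df)
  rng <- .local_rng(seed)
  on.exit(rng$restore())
  ns <- vapply(others, function(gr) counts[[gr]], numeric(1))
  zc <- stats::rnorm(n_sim, 0, sqrt(1 / n0))
  sdv <- sqrt(stats::rchisq(n_sim, df_err) / df_err)
  maxt <- rep(0, n_sim)
  absT <- matrix(0, n_sim, length(others))
  for (j in seq_along(others)) {
    zj <- stats::rnorm(n_sim, 0, sqrt(1 / ns[j]))
    absT[, j] <- abs((zj - zc) / (sdv * sqrt(1 / ns[j] + 1 / n0)))
  }
  maxt <- do.call(pmax, asplit(absT, 2))
  p_adj <- vapply(tstat, function(t0) mean(maxt >= abs(t0)), numeric(1))
  contrasts <- data.frame(structure = others,
                          diff = vapply(others, function(gr)
                            mean(y[g == gr]) - m0, numeric(1)),
                          t = tstat, p_adj = p_adj,
                          significant = p_adj < alpha,
                          row.names = NULL)
  list(anova = anova_row, contrasts = contrasts)
}
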