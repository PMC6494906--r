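#' Composition matrix container
#'
#' Per-sample percentage contribution of each panel gene to the panel total
#' (the compositional representation P of the panel): every column sums to
#' 100 and entries lie in [0, 100].
#'
#' @param values gene x sample percentage matrix.
#' @param samples sample annotation data.frame (as in [expression_matrix()]).
#' @param panel the `GenePanel` the rows cover.
#' @return An object of class `CompositionMatrix`.
#' @export
composition_matrix <- function(values, samples, panel) {
  values <- as.matrix(values)
  if (any(values < -1e-9) || any(values > 100 + 1e-9))
    stop("composition entries must lie in [0, 100]")
  sums <- colSums(values)
  if (any(abs(sums - 100) > 1e-9))
    stop("composition columns must sum to 100")
  samples <- as.data.frame(samples)
  structure(list(values = values, samples = samples, panel = panel),
            class = "CompositionMatrix")
}

#' @export
print.CompositionMatrix <- function(x, ...) {
  cat(sprintf("CompositionMatrix: %d genes x %d samples (columns sum to 100)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Select the representative probe for one gene
#'
#' Microarray panels carry several probes per gene; one is chosen to avoid
#' redundant co-linear rows downstream. The rule mirrors common array
#' summarization practice: a single probe is itself; of exactly two probes
#' the one with the higher mean expression wins; with three or more probes,
#' an unrotated principal-component (exploratory factor) analysis of the
#' probe correlation structure is run and the probe with the largest
#' absolute loading on the first component is taken, ties broken by higher
#' mean expression then by probe id.
#'
#' @param probe_matrix an `ExpressionMatrix` whose rows are the probes of a
#'   single gene.
#' @return The selected probe id (character scalar).
#' @details The loadings are taken from the first component of the
#'   covariance structure (centered but unstandardized profiles): a probe
#'   that tracks the gene's regional signal at full amplitude loads higher
#'   than an attenuated copy of the same signal, which standardization
#'   would hide (after standardizing, a faithful probe and an attenuated
#'   one are symmetric and the choice degenerates to a coin flip).
#' @export
select_probe_efa <- function(probe_matrix) {
  vals <- probe_matrix$values
  if (nrow(vals) == 0) stop("no probes supplied")
  ids <- rownames(vals)
  if (nrow(vals) == 1) return(ids)
  means <- rowMeans(vals)
  if (nrow(vals) == 2) {
    return(ids[order(-means, ids)][1])
  }
  # first principal component (no rotation) of the centered probe profiles
  x <- t(vals)                              # samples x probes
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc, nu = 0, nv = 1)
  loading <- sv$v[, 1]
  score <- abs(loading)
  ids[order(-score, -means, ids)][1]
}

#' Cross-subject probe consistency scores
#'
#' For each probe, the Pearson correlation of its regional expression
#' profile is computed between every pair of subjects and averaged over all
#' pairs (a probe that tracks a reproducible regional signal scores near 1;
#' a probe dominated by noise scores near 0).
#'
#' @param subject_mats named list of substructure-aggregated
#'   `ExpressionMatrix`, one per subject, sharing probe rows; profiles are
#'   compared on the intersection of their substructure columns.
#' @param probe_gene optional named character mapping probe id to gene,
#'   echoed into the output.
#' @return A data.frame (probe_id, gene, consistency) sorted by descending
#'   consistency; `consistency` lies in [-1, 1].
#' @export
probe_consistency <- function(subject_mats, probe_gene = NULL) {
  if (length(subject_mats) < 2)
    stop("probe consistency needs at least 2 subjects")
  common <- Reduce(intersect, lapply(subject_mats, function(m)
    colnames(m$values)))
  if (length(common) < 3) stop("fewer than 3 shared substructures")
  probes <- rownames(subject_mats[[1]]$values)
  arrs <- lapply(subject_mats, function(m)
    m$values[probes, common, drop = FALSE])
  ns <- length(arrs)
  pair_idx <- utils::combn(ns, 2)
  cons <- vapply(probes, function(p) {
    rs <- apply(pair_idx, 2, function(ij) {
      a <- arrs[[ij[1]]][p, ]; b <- arrs[[ij[2]]][p, ]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
      stats::cor(a, b)
    })
    mean(rs)
  }, numeric(1))
  out <- data.frame(probe_id = probes,
                    gene = if (is.null(probe_gene)) NA_character_
                           else unname(probe_gene[probes]),
                    consistency = unname(cons))
  out[order(-out$consistency), , drop = FALSE]
}

#' Remove age effects from expression values
#'
#' Fits, per gene, a least-squares line against age (`continuous`) or
#' one-way category means (`ordinal`), and returns residual + the gene's
#' grand mean so corrected values remain on the original scale. If age is
#' constant across samples the correction is skipped with a warning.
#'
#' @param m an `ExpressionMatrix` whose samples carry `age`.
#' @param mode `"continuous"` or `"ordinal"`.
#' @return An `ExpressionMatrix` on the same scale.
#' @export
correct_age <- function(m, mode = c("continuous", "ordinal")) {
  mode <- match.arg(mode)
  if (!"age" %in% names(m$samples)) stop("samples lack age")
  age <- m$samples$age
  if (anyNA(age)) stop("every sample needs an age")
  if (length(unique(age)) < 2) {
    warning("age constant across samples; correction skipped")
    return(m)
  }
  X <- if (mode == "continuous") stats::model.matrix(~ age)
       else stats::model.matrix(~ factor(age))
  fit <- stats::lm.fit(X, t(m$values))
  resid <- t(fit$residuals)
  m$values <- resid + rowMeans(m$values)
  m
}

#' Proportional contribution of panel genes per sample
#'
#' Converts the matrix to the linear scale and expresses each panel gene as
#' a percentage of the summed linear expression of the whole panel within
#' each sample (substructure or cell type), so columns sum to 100. Columns
#' whose panel total is zero have no defined composition; they are dropped
#' with a warning and their ids recorded in the `dropped` attribute.
#'
#' @param m an `ExpressionMatrix` containing all panel genes.
#' @param panel a `GenePanel`.
#' @return A `CompositionMatrix` over the panel genes.
#' @export
proportional_contribution <- function(m, panel) {
  miss <- setdiff(panel$symbols, rownames(m$values))
  if (length(miss))
    stop("panel genes missing from matrix: ", paste(miss, collapse = ", "))
  lin <- to_linear(m)
  vals <- lin$values[panel$symbols, , drop = FALSE]
  tot <- colSums(vals)
  bad <- tot <= 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " column(s) with zero panel total")
    vals <- vals[, !bad, drop = FALSE]
    tot <- tot[!bad]
  }
  pct <- sweep(vals, 2, tot, "/") * 100
  samples <- lin$samples[!bad, , drop = FALSE]
  out <- composition_matrix(pct, samples, panel)
  attr(out, "dropped") <- colnames(lin$values)[bad]
  out
}

#' Global proportional contribution across the whole brain
#'
#' Per gene, the linear-scale expression summed over every column of the
#' input (all substructures, and all subjects if several matrices are
#' given), divided by the panel-wide total, times 100.
#'
#' @param m an `ExpressionMatrix` at substructure level, or a list of them
#'   (one per subject).
#' @param panel a `GenePanel`.
#' @return Named numeric vector of percentages summing to 100.
#' @export
global_contribution <- function(m, panel) {
  mats <- if (inherits(m, "ExpressionMatrix")) list(m) else m
  sums <- rowSums(vapply(mats, function(mm) {
    lin <- to_linear(mm)
    rowSums(lin$values[panel$symbols, , drop = FALSE])
  }, numeric(length(panel$symbols))))
  names(sums) <- panel$symbols
  tot <- sum(sums)
  if (tot <= 0) stop("panel-wide total is zero")
  sums / tot * 100
}

#' Regional fold enrichment of each gene
#'
#' Fold enrichment is the ratio, on the linear scale, of a gene's mean
#' expression in a substructure to its average across all substructures
#' (equal region weighting), so a gene uniform across regions has fold 1
#' everywhere. The table also records the log2 region average and flags,
#' per gene, the substructure of maximal enrichment.
#'
#' @param m a substructure-level `ExpressionMatrix` averaged across
#'   subjects (genes x substructures), log2 or linear.
#' @param panel a `GenePanel`; rows restricted to the panel.
#' @param ontology optional `OntologyMap` used to annotate structure and
#'   major region.
#' @return An `EnrichmentTable` data.frame (gene, substructure, structure,
#'   major_region, mean_log2, fold, is_max).
#' @export
fold_enrichment <- function(m, panel = NULL, ontology = NULL) {
  genes <- if (is.null(panel)) rownames(m$values) else panel$symbols
  lin <- to_linear(m)$values[genes, , drop = FALSE]
  if (any(rowMeans(lin) <= 0))
    stop("zero global mean for gene(s): ",
         paste(genes[rowMeans(lin) <= 0], collapse = ", "))
  fold <- sweep(lin, 1, rowMeans(lin), "/")
  mean_log2 <- log2(lin)
  regions <- colnames(lin)
  out <- data.frame(
    gene = rep(genes, times = length(regions)),
    substructure = rep(regions, each = length(genes)),
    mean_log2 = as.vector(mean_log2),
    fold = as.vector(fold))
  argmax <- regions[apply(fold, 1, which.max)]
  out$is_max <- out$substructure == argmax[match(out$gene, genes)]
  if (!is.null(ontology)) {
    onto <- ontology_lookup(out$substructure, ontology)
    out$structure <- onto$structure
    out$major_region <- onto$major_region
  }
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}

#' Classify genes into the three expression profiles
#'
#' Genes fall into three canonical profiles: `noise` (brain-wide mean log2
#' below the noise threshold and no strong regional enrichment),
#' `region_specific` (low-to-moderate global expression but at least one
#' substructure enriched beyond `enrich_fold`), and `global_high`
#' (everything else -- high expression across the brain).
#'
#' @param m a log2 substructure-level `ExpressionMatrix`.
#' @param enrichment an `EnrichmentTable` from [fold_enrichment()] on the
#'   same genes.
#' @param noise_log2 noise threshold on the brain-wide mean log2 (default 4).
#' @param enrich_fold regional enrichment threshold (default 5); with
#'   `noise_log2 * 1.5` these bound the `region_specific` band.
#' @return Named character vector gene -> profile class.
#' @export
classify_profiles <- function(m, enrichment, noise_log2 = 4,
                              enrich_fold = 5) {
  genes <- rownames(m$values)
  brain_mean <- rowMeans(m$values)
  max_fold <- tapply(enrichment$fold, enrichment$gene, max)[genes]
  cls <- ifelse(brain_mean < noise_log2 & max_fold < enrich_fold, "noise",
         ifelse(brain_mean < noise_log2 * 1.5 & max_fold >= enrich_fold,
                "region_specific", "global_high"))
  names(cls) <- genes
  cls
}
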