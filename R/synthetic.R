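#' Ground truth for the regional expression generator
#'
#' Describes the statistical world the regional generator draws from: a log2
#' baseline per gene, planted region-specific enrichments (linear-scale fold
#' multipliers), planted co-expressed gene pairs implemented as shared latent
#' factors, and inter-subject log2 noise. Defaults mirror the study design
#' this package emulates: 6 subjects, the 111 grey-matter substructures of
#' the default ontology, the 19-gene panel, a handful of strong regional
#' enrichments (an alpha6-like cerebellar enrichment of 200-fold, a
#' theta-like dentate gyrus enrichment, ...), two planted positive and two
#' planted negative pairs at strength 0.9, and 0.3 log2 units of
#' between-subject noise.
#'
#' @param panel a `GenePanel`.
#' @param ontology an `OntologyMap`; white-matter rows are excluded.
#' @param baseline named numeric, log2 mean per gene. The default encodes
#'   the three canonical profiles: a few high-expression genes (log2 8-10),
#'   mid-range genes, and noise-level genes (log2 ~3, below the threshold 4).
#' @param enrichments data.frame (gene, substructure, fold), fold > 0 on the
#'   linear scale.
#' @param coexpression_pairs data.frame (gene_a, gene_b, sign in {-1, +1},
#'   strength in (0, 1]).
#' @param subject_sd log2 SD of per-subject noise (>= 0).
#' @param region_sd log2 SD of gene-specific regional variation shared by
#'   all subjects; gives each gene a non-degenerate regional profile so that
#'   planted pair strength governs the observable correlation.
#' @param n_subjects number of subjects.
#' @return An object of class `RegionalTruth`.
#' @export
regional_truth <- function(panel = gaba_panel(),
                           ontology = build_default_ontology(),
                           baseline = NULL,
                           enrichments = NULL,
                           coexpression_pairs = NULL,
                           subject_sd = 0.3,
                           region_sd = 0.5,
                           n_subjects = 6) {
  if (is.null(baseline)) {
    baseline <- c(GABRA1 = 10, GABRA2 = 8.5, GABRA3 = 7, GABRA4 = 7,
                  GABRA5 = 7.5, GABRA6 = 3.5, GABRB1 = 8, GABRB2 = 9.5,
                  GABRB3 = 8.5, GABRD = 8, GABRE = 3.5, GABRG1 = 7.5,
                  GABRG2 = 9.5, GABRG3 = 3.5, GABRP = 3, GABRQ = 3.5,
                  GABRR1 = 3, GABRR2 = 3, GABRR3 = 3)
    baseline <- baseline[panel$symbols]
    if (anyNA(baseline)) { baseline[] <- 7; names(baseline) <- panel$symbols }
  }
  if (is.null(enrichments))
    enrichments <- data.frame(
      gene = c("GABRA6", "GABRQ", "GABRE", "GABRG1"),
      substructure = c("CbCx.PV.V", "HiF.DG", "Hy.PrOR", "Amg.CeA"),
      fold = c(200, 31, 13, 10))
  if (is.null(coexpression_pairs))
    coexpression_pairs <- data.frame(
      gene_a = c("GABRA1", "GABRB2", "GABRA1", "GABRB1"),
      gene_b = c("GABRB2", "GABRG2", "GABRA2", "GABRB2"),
      sign = c(1, 1, -1, -1),
      strength = 0.9)
  stopifnot(all(enrichments$fold > 0),
            all(coexpression_pairs$strength > 0),
            all(coexpression_pairs$strength <= 1),
            all(coexpression_pairs$sign %in% c(-1, 1)),
            subject_sd >= 0, region_sd >= 0, n_subjects >= 1)
  missing <- setdiff(c(enrichments$gene, coexpression_pairs$gene_a,
                       coexpression_pairs$gene_b), panel$symbols)
  if (length(missing))
    stop("truth references genes outside the panel: ",
         paste(missing, collapse = ", "))
  structure(list(panel = panel, ontology = ontology, baseline = baseline,
                 enrichments = enrichments,
                 coexpression_pairs = coexpression_pairs,
                 subject_sd = subject_sd, region_sd = region_sd,
                 n_subjects = n_subjects),
            class = "RegionalTruth")
}

#' Simulate multi-subject regional expression with known ground truth
#'
#' For each subject and grey-matter substructure, the log2 value of gene g is
#' baseline_g + log2(fold) for planted enrichments + a gene-specific regional
#' term shared across subjects (SD `region_sd`) + sign * strength * z for
#' each planted pair (z a latent standard-normal factor per pair and region,
#' shared across subjects) + Normal(0, subject_sd) subject noise. The
#' generator is a pure function of (truth, seed).
#'
#' @param truth a `RegionalTruth`.
#' @param seed integer seed.
#' @return A list with `subjects` (named list of substructure-level
#'   `ExpressionMatrix`, scale log2), `ontology`, and `truth`.
#' @export
simulate_regional <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "RegionalTruth"))
  rng <- .local_rng(seed)
  on.exit(rng$restore())
  onto <- truth$ontology[!truth$ontology$white_matter, , drop = FALSE]
  regions <- onto$substructure
  genes <- truth$panel$symbols
  G <- length(genes); R <- length(regions)

  base <- matrix(truth$baseline[genes], G, R,
                 dimnames = list(genes, regions))
  for (i in seq_len(nrow(truth$enrichments))) {
    e <- truth$enrichments[i, ]
    if (e$substructure %in% regions)
      base[e$gene, e$substructure] <- base[e$gene, e$substructure] +
        log2(e$fold)
  }
  regional <- matrix(stats::rnorm(G * R, 0, truth$region_sd), G, R)
  shared <- base + regional
  pairs <- truth$coexpression_pairs
  for (i in seq_len(nrow(pairs))) {
    z <- stats::rnorm(R)
    shared[pairs$gene_a[i], ] <- shared[pairs$gene_a[i], ] +
      pairs$strength[i] * z
    shared[pairs$gene_b[i], ] <- shared[pairs$gene_b[i], ] +
      pairs$sign[i] * pairs$strength[i] * z
  }

  ages <- c(24, 31, 39, 49, 55, 57, 60, 65, 70, 75)
  subjects <- list()
  for (s in seq_len(truth$n_subjects)) {
    noise <- matrix(stats::rnorm(G * R, 0, truth$subject_sd), G, R)
    vals <- shared + noise
    sid <- sprintf("S%02d", s)
    ann <- data.frame(sample_id = regions, subject_id = sid,
                      substructure = regions, hemisphere = "none",
                      age = ages[((s - 1) %% length(ages)) + 1],
                      sex = c("M", "F")[((s - 1) %% 2) + 1])
    subjects[[sid]] <- expression_matrix(vals, ann, scale = "log2",
                                         unit = "intensity")
  }
  list(subjects = subjects, ontology = truth$ontology, truth = truth)
}

#' Simulate probe-level redundancy on top of a regional simulation
#'
#' Expands each gene row into `probes_per_gene` probe rows. Probe 1 is
#' faithful: the gene value plus Normal(0, noise_sd/10). The remaining
#' probes cycle through corrupted variants -- attenuated (halved dynamic
#' range around the gene mean), shuffled across regions, or constant at the
#' gene mean -- each plus Normal(0, noise_sd). The returned truth map names
#' the faithful probe per gene.
#'
#' @param regional result of [simulate_regional()], or a single log2
#'   `ExpressionMatrix`.
#' @param probes_per_gene integer >= 2.
#' @param noise_sd log2 SD of probe noise.
#' @param seed integer seed.
#' @return A list with `probes` (a per-subject list of probe-level
#'   `ExpressionMatrix`), `true_probe` (named character: gene -> faithful
#'   probe id), and `probe_gene` (named character: probe id -> gene).
#' @export
simulate_probes <- function(regional, probes_per_gene = 4, noise_sd = 0.2,
                            seed = 1) {
  stopifnot(probes_per_gene >= 2)
  rng <- .local_rng(seed)
  on.exit(rng$restore())
  mats <- if (inherits(regional, "ExpressionMatrix"))
    list(S01 = regional) else regional$subjects
  genes <- rownames(mats[[1]]$values)
  probe_ids <- unlist(lapply(genes, function(g)
    paste0(g, "_p", seq_len(probes_per_gene))))
  probe_gene <- rep(genes, each = probes_per_gene)
  names(probe_gene) <- probe_ids
  true_probe <- paste0(genes, "_p1")
  names(true_probe) <- genes

  variants <- c("attenuated", "shuffled", "constant")
  # fix the variant type per probe slot so it is consistent across subjects
  slot_variant <- vapply(seq_len(probes_per_gene - 1), function(j)
    variants[((j - 1) %% length(variants)) + 1], character(1))
  # one shuffle permutation per (gene, slot), shared across subjects
  R <- ncol(mats[[1]]$values)
  perms <- lapply(seq_along(genes), function(i)
    lapply(seq_len(probes_per_gene - 1), function(j) sample.int(R)))

  probes <- lapply(mats, function(m) {
    vals <- matrix(0, length(probe_ids), R,
                   dimnames = list(probe_ids, colnames(m$values)))
    for (i in seq_along(genes)) {
      g <- genes[i]
      row <- m$values[g, ]
      vals[paste0(g, "_p1"), ] <- row + stats::rnorm(R, 0, noise_sd / 10)
      for (j in seq_len(probes_per_gene - 1)) {
        corrupted <- switch(slot_variant[j],
          attenuated = mean(row) + 0.5 * (row - mean(row)),
          shuffled   = row[perms[[i]][[j]]],
          constant   = rep(mean(row), R))
        vals[paste0(g, "_p", j + 1), ] <- corrupted +
          stats::rnorm(R, 0, noise_sd)
      }
    }
    expression_matrix(vals, m$samples, scale = m$scale, unit = m$unit)
  })
  list(probes = probes, true_probe = true_probe, probe_gene = probe_gene)
}

#' Ground truth for the single-nucleus composition generator
#'
#' Cell-type mean compositions are concentrated around the 2:2:1 family
#' split: Sigma-alpha 40, Sigma-beta 40, Sigma-chi 20 (rho ~ 0), with
#' deterministic type-to-type variation in the within-family split. Defaults
#' follow the emulated study design: 76 cell types (mirroring the reference
#' single-nucleus taxonomy) across excitatory, inhibitory and non-neuronal
#' classes, a Dirichlet concentration of 200 (compositions tightly clustered
#' around the type mean), and 10% per-gene dropout (many nuclei read zero
#' for whole subunit families, as droplet data do).
#'
#' @param panel a `GenePanel`.
#' @param n_nuclei nuclei per cell type.
#' @param n_types number of cell types.
#' @param composition_concentration Dirichlet concentration parameter; the
#'   limit `Inf` collapses every nucleus onto its type mean.
#' @param dropout_rate probability in [0, 1) that a gene reads 0.
#' @param coexpression_pairs optional data.frame (gene_a, gene_b, sign,
#'   strength): within-type trade-offs applied multiplicatively on the
#'   latent abundances before closure (e.g. a beta2/beta3 anti-correlation).
#' @return An object of class `NucleiTruth`; `cell_types` is a data.frame
#'   (name, class) and `means` a genes x types matrix of mean compositions,
#'   each column summing to 100.
#' @export
nuclei_truth <- function(panel = gaba_panel(), n_nuclei = 100, n_types = 76,
                         composition_concentration = 200,
                         dropout_rate = 0.1,
                         coexpression_pairs = NULL) {
  stopifnot(n_nuclei >= 1, n_types >= 1,
            composition_concentration > 0,
            dropout_rate >= 0, dropout_rate < 1)
  genes <- panel$symbols
  mem <- panel$sum_membership
  # family-level targets of the 2:2:1 pentamer split; rho stays at noise
  fam_target <- c(SigmaAlpha = 40, SigmaBeta = 40, SigmaChi = 20,
                  excluded = 0)
  # deterministic within-family splits varied across types (fixed internal
  # stream so truth construction is reproducible independent of user seed)
  rng <- .local_rng(760813)
  on.exit(rng$restore())
  classes <- rep(c("excitatory", "inhibitory", "non_neuronal"),
                 c(ceiling(n_types * 0.32), ceiling(n_types * 0.59),
                   n_types))[seq_len(n_types)]
  means <- matrix(0, length(genes), n_types,
                  dimnames = list(genes, sprintf("type%02d", seq_len(n_types))))
  for (t in seq_len(n_types)) {
    w <- stats::rgamma(length(genes), shape = 2, rate = 1) + 0.05
    names(w) <- genes
    for (fam in names(fam_target)) {
      idx <- names(mem)[mem == fam]
      if (fam == "excluded") { means[idx, t] <- 0; next }
      means[idx, t] <- fam_target[[fam]] * w[idx] / sum(w[idx])
    }
  }
  structure(list(panel = panel, n_nuclei = n_nuclei,
                 cell_types = data.frame(name = colnames(means),
                                         class = classes),
                 means = means,
                 composition_concentration = composition_concentration,
                 dropout_rate = dropout_rate,
                 coexpression_pairs = coexpression_pairs),
            class = "NucleiTruth")
}

#' Simulate single-nucleus panel compositions
#'
#' Each nucleus draws a composition around its cell-type mean via a Gamma
#' (Dirichlet) construction at the stated concentration, applies planted
#' within-type trade-offs multiplicatively, zeroes genes at the dropout
#' rate, and scales the surviving abundances to a counts-like library size.
#'
#' @param truth a `NucleiTruth`.
#' @param seed integer seed.
#' @param library_size expected total counts per nucleus.
#' @return A list with `nuclei` (linear `ExpressionMatrix`, unit counts) and
#'   `labels` (data.frame nucleus, cell_type, class).
#' @export
simulate_nuclei <- function(truth, seed = 1, library_size = 5000) {
  stopifnot(inherits(truth, "NucleiTruth"))
  rng <- .local_rng(seed)
  on.exit(rng$restore())
  genes <- rownames(truth$means)
  G <- length(genes)
  n_types <- ncol(truth$means)
  total <- truth$n_nuclei * n_types
  vals <- matrix(0, G, total, dimnames = list(genes, NULL))
  labels <- data.frame(nucleus = character(total), cell_type = character(total),
                       class = character(total))
  conc <- truth$composition_concentration
  pairs <- truth$coexpression_pairs
  col <- 0L
  for (t in seq_len(n_types)) {
    mean_t <- truth$means[, t]
    alpha <- conc * mean_t / 100
    for (k in seq_len(truth$n_nuclei)) {
      col <- col + 1L
      w <- if (is.infinite(conc)) mean_t else
        vapply(alpha, function(a)
          if (a <= 0) 0 else stats::rgamma(1, shape = a, rate = 1),
          numeric(1))
      if (!is.null(pairs)) for (i in seq_len(nrow(pairs))) {
        z <- stats::rnorm(1)
        w[pairs$gene_a[i]] <- w[pairs$gene_a[i]] *
          2 ^ (pairs$strength[i] * z)
        w[pairs$gene_b[i]] <- w[pairs$gene_b[i]] *
          2 ^ (pairs$sign[i] * pairs$strength[i] * z)
      }
      if (truth$dropout_rate > 0)
        w[stats::runif(G) < truth$dropout_rate] <- 0
      tot <- sum(w)
      vals[, col] <- if (tot > 0) w / tot * library_size else 0
      labels$nucleus[col] <- sprintf("n%06d", col)
      labels$cell_type[col] <- colnames(truth$means)[t]
      labels$class[col] <- truth$cell_types$class[t]
    }
  }
  colnames(vals) <- labels$nucleus
  ann <- data.frame(sample_id = labels$nucleus,
                    cell_type = labels$cell_type, class = labels$class)
  list(nuclei = expression_matrix(vals, ann, scale = "linear",
                                  unit = "counts"),
       labels = labels)
}

# Seed the global RNG for the duration of a generator call and restore the
# caller's RNG state on exit, so generators are pure in (truth, seed) without
# perturbing user code.
.local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  list(restore = function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
}
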