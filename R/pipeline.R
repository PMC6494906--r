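#' Pipeline run configuration
#'
#' Collects every tunable of an end-to-end run: the synthetic truth (or
#' input file paths), panel, thresholds, sweep grids, gate windows, seed and
#' output directory.
#'
#' @param regional a `RegionalTruth` for the synthetic route, or `NULL`
#'   when `inputs` point at files.
#' @param nuclei a `NucleiTruth`, or `NULL` to skip nucleus-level stages.
#' @param inputs optional named list of file paths
#'   (`expression`, `annotation`, `dialect`) for accession-derived data.
#' @param panel a `GenePanel`.
#' @param noise_log2 noise classification threshold (default 4).
#' @param enrich_fold regional enrichment threshold (default 5).
#' @param gate list of windows `alpha`, `beta`, `chi`, each
#'   `c(center, halfwidth)`.
#' @param alpha significance level for the correlation consensus.
#' @param min_support minimum supporting analyses per consensus pair.
#' @param sweep a `ClusterSweepConfig`.
#' @param reference reference substructure for the layout comparison.
#' @param seed global seed, fanned out to per-stage substreams.
#' @param out_dir output directory (created on demand).
#' @return An object of class `RunConfig`.
#' @export
pipeline_config <- function(regional = regional_truth(),
                            nuclei = nuclei_truth(),
                            inputs = NULL,
                            panel = gaba_panel(),
                            noise_log2 = 4,
                            enrich_fold = 5,
                            gate = list(alpha = c(40, 5), beta = c(40, 5),
                                        chi = c(20, 5)),
                            alpha = 0.05,
                            min_support = 2,
                            sweep = sweep_config(),
                            reference = "FL.FrOp",
                            seed = 1,
                            out_dir = NULL) {
  structure(list(regional = regional, nuclei = nuclei, inputs = inputs,
                 panel = panel, noise_log2 = noise_log2,
                 enrich_fold = enrich_fold, gate = gate, alpha = alpha,
                 min_support = min_support, sweep = sweep,
                 reference = reference, seed = seed, out_dir = out_dir),
            class = "RunConfig")
}

#' Validate a run configuration
#'
#' Checks thresholds, windows, grids and panel integrity without mutating
#' anything; an empty character vector means the configuration is valid.
#'
#' @param config a `RunConfig`.
#' @return Character vector of violations (length 0 when ok).
#' @export
validate_config <- function(config) {
  v <- character()
  add <- function(msg) v <<- c(v, msg)
  if (!inherits(config, "RunConfig")) return("not a RunConfig")
  if (is.null(config$regional) && is.null(config$inputs))
    add("no inputs: neither synthetic truth nor input files configured")
  if (!inherits(config$panel, "GenePanel")) add("panel is not a GenePanel")
  if (!is.numeric(config$noise_log2) || config$noise_log2 <= 0)
    add("noise_log2 must be positive")
  if (!is.numeric(config$enrich_fold) || config$enrich_fold <= 1)
    add("enrich_fold must exceed 1")
  for (w in names(config$gate)) {
    win <- config$gate[[w]]
    if (length(win) != 2 || win[2] < 0 ||
        win[1] - win[2] < 0 || win[1] + win[2] > 100)
      add(sprintf("gate window '%s' exceeds [0, 100]", w))
  }
  if (config$alpha <= 0 || config$alpha >= 1)
    add("alpha must lie in (0, 1)")
  if (config$min_support < 1) add("min_support must be >= 1")
  if (!inherits(config$sweep, "ClusterSweepConfig")) {
    add("sweep is not a ClusterSweepConfig")
  } else {
    if (!length(config$sweep$sigma_grid)) add("empty sigma grid")
    if (!length(config$sweep$k_grid)) add("empty k grid")
  }
  if (!is.numeric(config$seed)) add("seed must be numeric")
  v
}

# stable (non-cryptographic) hash of a configuration for run provenance;
# the output directory is not part of the scientific configuration
.config_hash <- function(config) {
  config$out_dir <- NULL
  s <- paste(deparse(config, control = "all"), collapse = "")
  codes <- utf8ToInt(s)
  h <- 5381
  for (ch in codes) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Executes preprocess, clustering, stoichiometry and layout on synthetic
#' (or file-derived) inputs and returns the consolidated report bundle:
#' global contributions, enrichment table with profile classes, the
#' consensus clustering, the gated-nucleus correlation consensus, and the
#' stereotypy tables. The bundle is a pure function of (config, seed); if
#' `config$out_dir` is set, per-stage CSV/JSON outputs are written, each
#' stamped with run id, config hash and seed.
#'
#' @param config a `RunConfig` (see [pipeline_config()]).
#' @return A list of stage results (invisibly also written to
#'   `config$out_dir` if set).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  violations <- validate_config(config)
  if (length(violations))
    stop("invalid configuration:\n  ", paste(violations, collapse = "\n  "))
  seed <- config$seed
  meta <- list(run_id = sprintf("run-%s-%d", .config_hash(config), seed),
               config_hash = .config_hash(config), seed = seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  panel <- config$panel
  log <- list()

  # ---- inputs -------------------------------------------------------
  sim <- stage("simulate", {
    if (!is.null(config$inputs)) {
      m <- read_expression_table(config$inputs$expression,
                                 config$inputs$annotation,
                                 config$inputs$dialect)
      subjects <- split(seq_len(ncol(m$values)), m$samples$subject_id)
      list(subjects = lapply(subjects, function(idx)
        expression_matrix(m$values[, idx, drop = FALSE],
                          m$samples[idx, , drop = FALSE],
                          scale = m$scale, unit = m$unit)),
        ontology = build_default_ontology())
    } else simulate_regional(config$regional, seed = seed)
  })
  log$n_subjects <- length(sim$subjects)

  # ---- preprocess ---------------------------------------------------
  pre <- stage("preprocess", {
    mats <- lapply(sim$subjects, function(m)
      if (length(unique(m$samples$age)) > 1) correct_age(m) else m)
    common <- Reduce(intersect, lapply(mats, function(m) colnames(m$values)))
    group_vals <- Reduce(`+`, lapply(mats, function(m)
      m$values[, common, drop = FALSE])) / length(mats)
    group <- expression_matrix(
      group_vals,
      data.frame(sample_id = common, substructure = common),
      scale = mats[[1]]$scale, unit = mats[[1]]$unit)
    enr <- fold_enrichment(group, panel, sim$ontology)
    list(subjects = mats, group = group,
         global = global_contribution(mats, panel),
         composition = proportional_contribution(group, panel),
         enrichment = enr,
         profiles = classify_profiles(group, enr, config$noise_log2,
                                      config$enrich_fold))
  })
  log$n_substructures <- ncol(pre$group$values)

  # ---- clustering ---------------------------------------------------
  clus <- stage("clustering", {
    list(ward_regions = ward_cluster(pre$group, axis = "columns"),
         ward_genes = ward_cluster(pre$group, axis = "rows"),
         sweep = run_sweep(pre$group, config$sweep, panel = panel,
                           seed = seed + 1))
  })

  # ---- stoichiometry ------------------------------------------------
  stoi <- stage("stoichiometry", {
    reports <- list(pairwise_correlations(pre$composition,
                                          tag = "A_microarray"))
    gate_summary <- NULL
    if (!is.null(config$nuclei)) {
      nuc <- simulate_nuclei(config$nuclei, seed = seed + 2)
      comp <- proportional_contribution(nuc$nuclei, panel)
      keep <- comp$samples$sample_id
      labels <- nuc$labels[nuc$labels$nucleus %in% keep, , drop = FALSE]
      prof <- nucleus_profiles(comp, labels)
      gated <- stoichiometric_gate(prof, config$gate$alpha,
                                   config$gate$beta, config$gate$chi)
      gate_summary <- attr(gated, "gate_summary")
      gcomp <- attr(gated, "composition")
      type_means <- vapply(split(seq_len(nrow(gated)), gated$cell_type),
                           function(idx)
                             rowMeans(gcomp$values[, idx, drop = FALSE]),
                           numeric(nrow(gcomp$values)))
      if (is.matrix(type_means) && ncol(type_means) >= 3)
        reports$C <- pairwise_correlations(type_means,
                                           tag = "C_across_celltypes")
      for (ct in unique(gated$cell_type)) {
        idx <- which(gated$cell_type == ct)
        if (length(idx) < 20) next        # floor against spurious support
        reports[[paste0("D_", ct)]] <- pairwise_correlations(
          gcomp$values[, idx, drop = FALSE], tag = "D_within_celltype",
          group = ct)
      }
      log$n_nuclei_gated <- nrow(gated)
    }
    pairs <- if (length(reports) >= 2)
      consensus_pairs(reports, alpha = config$alpha,
                      min_support = config$min_support)
    else NULL
    list(reports = reports, pairs = pairs, gate_summary = gate_summary)
  })

  # ---- layout -------------------------------------------------------
  lay <- stage("layout", {
    wb <- whole_brain_stereotypy(pre$subjects, panel)
    ref <- reference_similarity(pre$subjects, config$reference,
                                sim$ontology, panel, transform = "log2")
    dendro <- layout_dendrogram(attr(wb, "consensus"), panel)
    cmp <- compare_to_reference(ref, ontology_lookup(
      config$reference, sim$ontology)$structure,
      n_sim = 2e4, seed = seed + 3)
    list(whole_brain = wb, reference = ref, dendrogram = dendro,
         comparison = cmp)
  })

  bundle <- list(meta = meta, log = log, preprocess = pre[-1],
                 clustering = clus, stoichiometry = stoi, layout = lay)
  if (!is.null(config$out_dir)) .write_bundle(bundle, config$out_dir)
  bundle
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    df <- as.data.frame(df)
    data.table::fwrite(df, file.path(out_dir, name))
  }
  meta <- c(bundle$meta, bundle$log)
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  w(data.frame(gene = names(bundle$preprocess$global),
               percent = as.numeric(bundle$preprocess$global)),
    "global_contribution.csv")
  w(bundle$preprocess$enrichment, "enrichment.csv")
  w(data.frame(gene = names(bundle$preprocess$profiles),
               profile = as.character(bundle$preprocess$profiles)),
    "profiles.csv")
  cons <- bundle$clustering$sweep$consensus$values
  w(data.frame(item = rownames(cons), cons, check.names = FALSE),
    "consensus_matrix.csv")
  writeLines(dendrogram_newick(bundle$clustering$ward_regions),
             file.path(out_dir, "ward_regions.nwk"))
  writeLines(dendrogram_newick(bundle$layout$dendrogram),
             file.path(out_dir, "layout_dendrogram.nwk"))
  if (!is.null(bundle$stoichiometry$pairs))
    w(bundle$stoichiometry$pairs, "consensus_pairs.csv")
  if (!is.null(bundle$stoichiometry$gate_summary))
    jsonlite::write_json(bundle$stoichiometry$gate_summary,
                         file.path(out_dir, "gate_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  w(bundle$layout$whole_brain, "whole_brain_stereotypy.csv")
  w(bundle$layout$reference, "reference_stereotypy.csv")
  invisible(out_dir)
}
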