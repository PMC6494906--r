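# Shared fixtures and independent oracles. Everything is generated in code;
# heavyweight simulations are built once per test run and cached.

toy_panel <- function(n = 3) {
  symbols <- paste0("G", seq_len(n))
  fam <- stats::setNames(rep("alpha", n), symbols)
  mem <- stats::setNames(rep("SigmaAlpha", n), symbols)
  gene_panel(symbols, fam, mem)
}

toy_ontology <- function(n_sub = 10, n_struct = 2) {
  struct <- rep(paste0("ST", seq_len(n_struct)), length.out = n_sub)
  ontology_map(data.frame(
    substructure = paste0("sub", seq_len(n_sub)),
    structure = struct,
    major_region = "region1",
    origin = "telencephalon",
    rank = seq_len(n_sub),
    white_matter = FALSE))
}

toy_expression <- function(values, scale = "log2",
                           extra = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("G", seq_len(nrow(values)))
  ann <- data.frame(sample_id = paste0("s", seq_len(ncol(values))))
  if (!is.null(extra)) ann <- cbind(ann, extra)
  expression_matrix(values, ann, scale = scale)
}

# independent brute-force Ward oracle: enumerate all cluster pairs at every
# step, merging the pair with the smallest Ward cost
# sqrt(2 |A||B|/(|A|+|B|)) * ||centroid_A - centroid_B||.
ward_oracle_heights <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), function(i) i)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, 0L, 0L)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      a <- clusters[[i]]; b <- clusters[[j]]
      ma <- colMeans(x[a, , drop = FALSE])
      mb <- colMeans(x[b, , drop = FALSE])
      cost <- sqrt(2 * length(a) * length(b) / (length(a) + length(b))) *
        sqrt(sum((ma - mb)^2))
      if (cost < best[1]) best <- c(cost, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[3]]] <- c(clusters[[best[3]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

two_blob_fixture <- function(n = 40, blob_sd = 0.5, sep_factor = 20,
                             seed = 1) {
  set.seed(seed)
  sep <- sep_factor * blob_sd
  x <- rbind(matrix(stats::rnorm(n * 2, 0, blob_sd), ncol = 2),
             matrix(stats::rnorm(n * 2, sep, blob_sd), ncol = 2))
  rownames(x) <- paste0("p", seq_len(2 * n))
  list(x = x,
       labels = stats::setNames(rep(1:2, each = n), rownames(x)))
}

# cached default regional simulation (6 subjects, 111 substructures, seed 1)
.fixture_cache <- new.env(parent = emptyenv())
fix_regional <- function() {
  if (is.null(.fixture_cache$regional))
    .fixture_cache$regional <- simulate_regional(regional_truth(), seed = 1)
  .fixture_cache$regional
}
fix_probes <- function() {
  if (is.null(.fixture_cache$probes))
    .fixture_cache$probes <- simulate_probes(fix_regional(),
                                             probes_per_gene = 4,
                                             noise_sd = 0.2, seed = 1)
  .fixture_cache$probes
}

# subject-averaged composition of a regional simulation
regional_composition <- function(sim, panel = gaba_panel()) {
  avg <- Reduce(`+`, lapply(sim$subjects, function(m) m$values)) /
    length(sim$subjects)
  em <- expression_matrix(avg, data.frame(sample_id = colnames(avg)),
                          scale = "log2")
  proportional_contribution(em, panel)
}

# 19 genes x 36 regions with 3 planted region groups (rank-2 between-group
# structure) over small iid noise
planted_groups_fixture <- function(seed = 12, noise_sd = 0.3) {
  set.seed(seed)
  sig <- matrix(stats::rnorm(19 * 3, 0, 2), 19, 3)
  cols <- lapply(1:3, function(k)
    sig[, k] + matrix(stats::rnorm(19 * 12, 0, noise_sd), 19, 12))
  x <- do.call(cbind, cols) + 8
  rownames(x) <- gaba_panel()$symbols
  colnames(x) <- paste0("r", seq_len(36))
  list(matrix = x,
       labels = stats::setNames(rep(1:3, each = 12), colnames(x)))
}

# planted pairs used by the correlation-consensus fixtures: moderate
# proportional-contribution genes, where compositional closure preserves
# the planted sign (for dominant shares closure can cancel it; see the
# methods vignette).
planted_pairs <- function() {
  data.frame(gene_a = c("GABRA3", "GABRA4", "GABRA5", "GABRD"),
             gene_b = c("GABRB1", "GABRG1", "GABRA2", "GABRE"),
             sign = c(1, 1, -1, -1), strength = 0.9)
}
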