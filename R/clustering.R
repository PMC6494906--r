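#' Ward's minimum-variance hierarchical clustering
#'
#' Agglomerative clustering in which each merge minimizes the increase in
#' within-cluster sum of squares, on Euclidean base distances (the classical
#' Ward criterion; merge heights are the Ward distances
#' sqrt(2 |A||B| / (|A|+|B|)) * ||centroid_A - centroid_B||).
#'
#' @param x numeric matrix or `ExpressionMatrix`.
#' @param axis cluster the `"rows"` or the `"columns"` of `x`.
#' @return An object of class `hclust` (merge heights nondecreasing, n-1
#'   merges for n leaves).
#' @export
ward_cluster <- function(x, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  if (inherits(x, "ExpressionMatrix") || inherits(x, "CompositionMatrix"))
    x <- x$values
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite values in clustering input")
  if (axis == "columns") x <- t(x)
  if (nrow(x) < 2) stop("need at least 2 items to cluster")
  stats::hclust(stats::dist(x), method = "ward.D2")
}

#' Export a dendrogram as Newick text
#'
#' @param hc an `hclust` object.
#' @param path optional file path; when omitted the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Project items on the top principal components and whiten
#'
#' Singular value decomposition of the centered item x feature matrix; the
#' items are projected on the top `n_components` singular directions and
#' each direction is rescaled to unit variance (whitening). If the data rank
#' is lower than requested, the embedding is truncated with a warning.
#'
#' @param x items x features numeric matrix.
#' @param n_components number of components to keep (default 5, which on
#'   the regional data accounts for >80% of the variance).
#' @return A list: `embedding` (items x k, whitened), `explained` (variance
#'   fractions per component of the full decomposition), `cumulative`
#'   (cumulative explained variance of the kept components).
#' @export
pca_whiten <- function(x, n_components = 5) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need more than one item")
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  tol <- max(dim(xc)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > max(tol, 0) & sv$d > 1e-12)
  k <- min(n_components, rank)
  if (k < n_components)
    warning(sprintf("rank %d < requested %d components; truncated",
                    rank, n_components))
  expl <- sv$d^2 / sum(sv$d^2)
  emb <- sv$u[, seq_len(k), drop = FALSE] * sqrt(n - 1)
  rownames(emb) <- rownames(x)
  list(embedding = emb, explained = expl,
       cumulative = sum(expl[seq_len(k)]))
}

# Potential landscape of the quantum clustering model. The scale-space
# wavefunction is psi(x) = sum_i exp(-||x - x_i||^2 / (2 sigma^2)); viewing
# psi as the ground state of a Schrodinger equation gives the potential
# V(x) = E - d/2 + sum_i r_i^2 e_i / (2 sigma^2 psi), with E fixed so that
# min V = 0 over the data. Gradients are analytic. The optional weight
# filter normalizes each point's kernel by its local density so cluster
# detection follows the shape, not the mass, of the data.
.qc_potential <- function(x, data, sigma, w = NULL) {
  d2 <- colSums((t(data) - x)^2)
  e <- exp(-d2 / (2 * sigma^2))
  if (!is.null(w)) e <- e * w
  psi <- sum(e)
  if (psi < 1e-300) return(list(V = Inf, grad = rep(0, length(x))))
  U <- sum(d2 * e)
  V <- U / (2 * sigma^2 * psi)
  diff <- sweep(data, 2, x, "-")            # n x d, rows x_i - x
  dU <- colSums(e * (-2 * diff + d2 * diff / sigma^2))
  dpsi <- colSums(e * diff / sigma^2)
  grad <- (dU * psi - U * dpsi) / (2 * sigma^2 * psi^2)
  list(V = V, grad = grad)
}

#' Quantum clustering
#'
#' Density-based clustering: a Parzen-window wavefunction is built from the
#' points, the associated Schrodinger potential is derived, and every point
#' descends the potential gradient to a local minimum; points whose terminal
#' positions fall within a merge radius share a cluster. The single scale
#' parameter `sigma` controls the granularity.
#'
#' @param embedding items x dims numeric matrix (typically from
#'   [pca_whiten()]).
#' @param sigma positive scale parameter.
#' @param step gradient-descent step as a multiple of `sigma` (default 0.1).
#' @param max_iter maximum descent iterations (default 200).
#' @param tol convergence when the step displacement drops below
#'   `tol * sigma` (default 1e-5).
#' @param merge_radius radius within which terminal positions are merged
#'   into one cluster (default `sigma / 4`).
#' @param weight_filter logical; normalize each kernel by its local density
#'   (shape-only variant, off by default).
#' @return A `Partition`: list with `assignments` (named integer vector),
#'   `parameters`, and `converged` (logical per item; non-converged points
#'   are attached to the nearest converged minimum).
#' @export
quantum_cluster <- function(embedding, sigma, step = 0.1, max_iter = 200,
                            tol = 1e-5, merge_radius = sigma / 4,
                            weight_filter = FALSE) {
  stopifnot(sigma > 0)
  x <- as.matrix(embedding)
  n <- nrow(x)
  items <- rownames(x)
  if (is.null(items)) items <- as.character(seq_len(n))
  if (n == 1)
    return(partition(stats::setNames(1L, items),
                     list(method = "qc", sigma = sigma)))
  w <- NULL
  if (weight_filter) {
    dens <- vapply(seq_len(n), function(i)
      sum(exp(-colSums((t(x) - x[i, ])^2) / (2 * sigma^2))), numeric(1))
    w <- 1 / dens
  }
  pos <- x
  converged <- rep(FALSE, n)
  for (i in seq_len(n)) {
    p <- x[i, ]
    Vp <- .qc_potential(p, x, sigma, w)
    for (it in seq_len(max_iter)) {
      g <- Vp$grad
      move <- -step * sigma * g
      if (sqrt(sum(move^2)) < tol * sigma) { converged[i] <- TRUE; break }
      cand <- p + move
      Vc <- .qc_potential(cand, x, sigma, w)
      # halve an uphill step so the descent cannot oscillate across a basin
      halvings <- 0
      while (Vc$V > Vp$V && halvings < 12) {
        move <- move / 2
        cand <- p + move
        Vc <- .qc_potential(cand, x, sigma, w)
        halvings <- halvings + 1
      }
      if (sqrt(sum(move^2)) < tol * sigma) { converged[i] <- TRUE; break }
      p <- cand
      Vp <- Vc
    }
    pos[i, ] <- p
  }
  # merge terminal positions within the merge radius (single linkage)
  assign <- .merge_positions(pos, merge_radius)
  if (any(!converged) && any(converged)) {
    for (i in which(!converged)) {
      d <- colSums((t(pos[converged, , drop = FALSE]) - pos[i, ])^2)
      assign[i] <- assign[converged][which.min(d)]
    }
  }
  names(assign) <- items
  out <- partition(assign, list(method = "qc", sigma = sigma,
                                weight_filter = weight_filter))
  out$converged <- converged
  out
}

.merge_positions <- function(pos, radius) {
  n <- nrow(pos)
  if (n == 1) return(1L)
  hc <- stats::hclust(stats::dist(pos), method = "single")
  as.integer(stats::cutree(hc, h = radius))
}

#' Construct a partition object
#'
#' @param assignments named integer/character vector item -> cluster.
#' @param parameters list of method parameters (method, sigma or k,
#'   transform tag).
#' @return An object of class `Partition`.
#' @export
partition <- function(assignments, parameters = list()) {
  if (is.null(names(assignments))) stop("assignments must be named")
  structure(list(assignments = assignments, parameters = parameters),
            class = "Partition")
}

#' Bipartite spectral co-clustering
#'
#' Simultaneous clustering of rows and columns: the matrix is shifted to
#' nonnegativity if needed, rows and columns are scaled by the inverse
#' square root of their sums, the leading singular vectors are computed, and
#' the stacked scaled row and column embeddings are k-means-clustered into k
#' groups, yielding paired row and column partitions (biclusters).
#'
#' @param x numeric matrix (rows x columns).
#' @param k number of biclusters (>= 2, at most `min(dim(x))`).
#' @param seed seed for the k-means initialization.
#' @return A list with `rows` and `columns`, each a `Partition`.
#' @export
spectral_cocluster <- function(x, k, seed = 1) {
  x <- as.matrix(x)
  if (k < 2) stop("k must be at least 2")
  if (k > min(dim(x)))
    stop(sprintf("k = %d exceeds min matrix dimension %d", k, min(dim(x))))
  rn <- rownames(x); if (is.null(rn)) rn <- paste0("r", seq_len(nrow(x)))
  cn <- colnames(x); if (is.null(cn)) cn <- paste0("c", seq_len(ncol(x)))
  if (min(x) < 0) x <- x - min(x)
  eps <- 1e-9
  r <- rowSums(x) + eps
  c <- colSums(x) + eps
  an <- x / sqrt(r) / rep(sqrt(c), each = nrow(x))
  l <- min(1 + ceiling(log2(k)), min(dim(x)) - 1)
  sv <- svd(an, nu = l + 1, nv = l + 1)
  keep <- 2:(l + 1)
  zr <- sv$u[, keep, drop = FALSE] / sqrt(r)
  zc <- sv$v[, keep, drop = FALSE] / sqrt(c)
  z <- rbind(zr, zc)
  if (sum(sv$d[keep]) < 1e-10 || nrow(unique(round(z, 12))) < k) {
    warning("degenerate structure; falling back to an index partition")
    cl <- rep_len(seq_len(k), nrow(z))
  } else {
    rng <- .local_rng(seed)
    on.exit(rng$restore())
    cl <- stats::kmeans(z, centers = k, nstart = 25,
                        iter.max = 100)$cluster
  }
  rows <- stats::setNames(as.integer(cl[seq_len(nrow(x))]), rn)
  cols <- stats::setNames(as.integer(cl[nrow(x) + seq_len(ncol(x))]), cn)
  list(rows = partition(rows, list(method = "scc", k = k)),
       columns = partition(cols, list(method = "scc", k = k)))
}

#' Co-occurrence consensus over a set of partitions
#'
#' Entry (i, j) is the fraction of partitions in which items i and j share a
#' cluster; the matrix is symmetric with a unit diagonal.
#'
#' @param partitions list of `Partition` objects over the same item set.
#' @return An object of class `ConsensusMatrix`: list with `values` (item x
#'   item fractions) and `n_runs`.
#' @export
consensus_cooccurrence <- function(partitions) {
  if (!length(partitions)) stop("no partitions supplied")
  items <- sort(names(partitions[[1]]$assignments))
  for (p in partitions) {
    other <- sort(names(p$assignments))
    if (!identical(items, other)) {
      diffs <- c(setdiff(items, other), setdiff(other, items))
      stop("partitions cover different items: ",
           paste(unique(diffs), collapse = ", "))
    }
  }
  n <- length(items)
  acc <- matrix(0, n, n, dimnames = list(items, items))
  for (p in partitions) {
    a <- p$assignments[items]
    same <- outer(a, a, "==") * 1
    acc <- acc + same
  }
  vals <- acc / length(partitions)
  structure(list(values = vals, n_runs = length(partitions)),
            class = "ConsensusMatrix")
}

#' Cut a consensus matrix into groups at a co-occurrence threshold
#'
#' Items are linked when their co-occurrence fraction is at least
#' `threshold`; connected components of the resulting graph are the
#' consensus groups.
#'
#' @param consensus a `ConsensusMatrix`.
#' @param threshold co-occurrence fraction (default 0.5).
#' @return Named integer vector item -> group.
#' @export
consensus_groups <- function(consensus, threshold = 0.5) {
  adj <- consensus$values >= threshold
  n <- nrow(adj)
  group <- rep(0L, n)
  g <- 0L
  for (i in seq_len(n)) {
    if (group[i] > 0) next
    g <- g + 1L
    frontier <- i
    group[i] <- g
    while (length(frontier)) {
      nb <- which(adj[frontier[1], ] & group == 0L)
      group[nb] <- g
      frontier <- c(frontier[-1], nb)
    }
  }
  stats::setNames(group, rownames(adj))
}

#' Sweep configuration for the consensus clustering
#'
#' @param sigma_grid positive scale multipliers applied to the median
#'   pairwise distance of the whitened embedding (default 10 log-spaced
#'   steps spanning 0.1-1.0: on a whitened embedding the median pairwise
#'   distance is set by the between-cluster scale, so scales at or above it
#'   smooth all structure away and the informative scan lies below it).
#' @param k_grid integer bicluster counts (default 2:10).
#' @param transforms subset of `c("log2", "proportional")`.
#' @param n_components components kept by the whitening step (default 5).
#' @return An object of class `ClusterSweepConfig`.
#' @export
sweep_config <- function(sigma_grid = exp(seq(log(0.1), log(1),
                                              length.out = 10)),
                         k_grid = 2:10,
                         transforms = c("log2", "proportional"),
                         n_components = 5) {
  stopifnot(length(sigma_grid) > 0, all(sigma_grid > 0),
            length(k_grid) > 0, all(k_grid >= 2), n_components >= 1)
  transforms <- match.arg(transforms, c("log2", "proportional"),
                          several.ok = TRUE)
  structure(list(sigma_grid = sigma_grid, k_grid = k_grid,
                 transforms = transforms, n_components = n_components),
            class = "ClusterSweepConfig")
}

#' Secondary (consensus) clustering over a parameter sweep
#'
#' For each data transform, quantum clustering is run over the sigma grid on
#' the whitened embedding (sigmas are multiples of the median pairwise
#' embedding distance, so grids transfer across datasets) and spectral
#' co-clustering over the k grid; all resulting partitions of the chosen
#' axis are pooled into one co-occurrence consensus.
#'
#' @param m an `ExpressionMatrix` (log2 scale) whose columns are the items
#'   to cluster (e.g. substructures), or a plain items-in-columns matrix.
#' @param config a `ClusterSweepConfig`.
#' @param panel `GenePanel` used to build the proportional transform; only
#'   needed when `"proportional"` is in `config$transforms`.
#' @param axis consensus over `"columns"` (regions; default) or `"rows"`
#'   (genes).
#' @param seed seed fanned out to the stochastic components.
#' @return A list with `consensus` (a `ConsensusMatrix`), `partitions`
#'   (all pooled partitions) and `config`.
#' @export
run_sweep <- function(m, config = sweep_config(), panel = NULL,
                      axis = c("columns", "rows"), seed = 1) {
  axis <- match.arg(axis)
  stopifnot(inherits(config, "ClusterSweepConfig"))
  get_values <- function(transform) {
    if (inherits(m, "ExpressionMatrix")) {
      if (transform == "log2") {
        if (m$scale != "log2") log2(pmax(m$values, 2^-20)) else m$values
      } else {
        if (is.null(panel)) stop("proportional transform needs a panel")
        proportional_contribution(m, panel)$values
      }
    } else {
      if (transform == "proportional")
        sweep(as.matrix(m), 2, colSums(as.matrix(m)), "/") * 100
      else as.matrix(m)
    }
  }
  partitions <- list()
  for (tr in config$transforms) {
    vals <- get_values(tr)
    items_x <- if (axis == "columns") t(vals) else vals
    wh <- suppressWarnings(pca_whiten(items_x, config$n_components))
    emb <- wh$embedding
    med <- stats::median(stats::dist(emb))
    for (sg in config$sigma_grid) {
      p <- quantum_cluster(emb, sigma = sg * med)
      p$parameters$transform <- tr
      partitions[[length(partitions) + 1]] <- p
    }
    for (k in config$k_grid) {
      sc <- spectral_cocluster(vals, k, seed = seed + k)
      p <- if (axis == "columns") sc$columns else sc$rows
      p$parameters$transform <- tr
      partitions[[length(partitions) + 1]] <- p
    }
  }
  list(consensus = consensus_cooccurrence(partitions),
       partitions = partitions, config = config)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1
#' means identical partitions, 0 is the expectation under independence.
#'
#' @param a,b named label vectors (or `Partition` objects) over the same
#'   items.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (inherits(a, "Partition")) a <- a$assignments
  if (inherits(b, "Partition")) b <- b$assignments
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
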