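test_that("ward clustering orders merges by separation and matches the oracle", {
  x <- matrix(c(0, 0.1, 10, 10.1), 4, 1,
              dimnames = list(paste0("p", 1:4), NULL))
  hc <- ward_cluster(x)
  expect_equal(sort(hc$height[1:2]), c(0.1, 0.1))
  first_two <- lapply(1:2, function(k) sort(-hc$merge[k, ]))
  expect_setequal(vapply(first_two, paste, collapse = ",", ""),
                  c("1,2", "3,4"))

  two <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
  expect_equal(ward_cluster(two)$height, 5)  # Euclidean distance

  # property: heights equal the brute-force enumeration oracle (<= 7 items)
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(2:7, 1); d <- sample(1:3, 1)
    x <- matrix(rnorm(n * d), n, d, dimnames = list(paste0("i", 1:n), NULL))
    expect_equal(sort(ward_cluster(x)$height), sort(ward_oracle_heights(x)),
                 tolerance = 1e-8)
  }
  expect_error(ward_cluster(matrix(c(1, NA), 1)), "non-finite")
})

test_that("pca_whiten whitens, truncates rank and explains fixture variance", {
  set.seed(4)
  x <- matrix(rnorm(400), 200, 2)
  w <- pca_whiten(x, 2)
  expect_equal(cov(w$embedding), diag(2), tolerance = 1e-8)

  r1 <- outer(rnorm(50), c(1, 2, 3))          # rank-1 data
  expect_warning(w1 <- pca_whiten(r1, 5), "truncated")
  expect_equal(ncol(w1$embedding), 1)

  # structured fixture: 5 components carry well over 80% of the variance
  fx <- planted_groups_fixture()
  wf <- pca_whiten(t(fx$matrix), 5)
  expect_gt(wf$cumulative, 0.8)
})

test_that("quantum clustering recovers planted blobs and degenerate limits", {
  fx <- two_blob_fixture()
  for (s in 0.5 * c(1, 3, 10)) {
    p <- quantum_cluster(fx$x, sigma = s)
    expect_equal(adjusted_rand_index(p$assignments, fx$labels), 1,
                 label = paste("sigma", s))
  }
  one <- quantum_cluster(matrix(c(1, 2), 1, 2,
                                dimnames = list("only", NULL)), sigma = 1)
  expect_equal(unname(one$assignments), 1L)
  big <- quantum_cluster(fx$x, sigma = 1000)   # sigma >> data diameter
  expect_equal(length(unique(big$assignments)), 1)
})

test_that("quantum clustering is translation invariant and scale equivariant", {
  fx <- two_blob_fixture(n = 25)
  p0 <- quantum_cluster(fx$x, sigma = 1)
  p_shift <- quantum_cluster(fx$x + 500, sigma = 1)
  expect_equal(adjusted_rand_index(p0, p_shift), 1)
  p_scaled <- quantum_cluster(fx$x * 3, sigma = 3)
  expect_equal(adjusted_rand_index(p0, p_scaled), 1)
})

test_that("spectral co-clustering splits planted biclusters", {
  A <- matrix(0.05, 30, 12, dimnames = list(paste0("r", 1:30),
                                            paste0("c", 1:12)))
  A[1:15, 1:6] <- 5; A[16:30, 7:12] <- 5
  sc <- spectral_cocluster(A, 2)
  expect_equal(adjusted_rand_index(
    sc$rows$assignments,
    stats::setNames(rep(1:2, each = 15), rownames(A))), 1)
  expect_equal(adjusted_rand_index(
    sc$columns$assignments,
    stats::setNames(rep(1:2, each = 6), colnames(A))), 1)

  # planted 3 biclusters
  B <- matrix(0.05, 30, 15)
  for (k in 0:2) B[k * 10 + 1:10, k * 5 + 1:5] <- 4
  rownames(B) <- paste0("r", 1:30); colnames(B) <- paste0("c", 1:15)
  sc3 <- spectral_cocluster(B, 3, seed = 1)
  expect_equal(adjusted_rand_index(
    sc3$rows$assignments, setNames(rep(1:3, each = 10), rownames(B))), 1)

  expect_warning(dg <- spectral_cocluster(matrix(1, 6, 6), 2), "degenerate")
  expect_equal(length(dg$rows$assignments), 6)  # valid partition regardless
  expect_error(spectral_cocluster(A, 13), "exceeds")
  expect_error(spectral_cocluster(A, 1), "at least 2")
})

test_that("consensus co-occurrence counts shared-cluster fractions", {
  p1 <- partition(c(a = 1L, b = 1L, c = 2L))
  p2 <- partition(c(a = 1L, b = 2L, c = 2L))
  cm <- consensus_cooccurrence(list(p1, p1))
  expect_equal(cm$values["a", "b"], 1)
  expect_equal(cm$values["a", "c"], 0)
  cm2 <- consensus_cooccurrence(list(p1, p2))
  expect_equal(cm2$values["a", "b"], 0.5)      # together in 1 of 2 runs
  expect_true(isSymmetric(cm2$values))
  expect_equal(unname(diag(cm2$values)), rep(1, 3))
  p3 <- partition(c(a = 1L, d = 1L, c = 2L))
  expect_error(consensus_cooccurrence(list(p1, p3)), "b")
})

test_that("run_sweep pools QC and SCC partitions into one consensus", {
  fx <- two_blob_fixture(n = 15, seed = 3)
  items_in_cols <- t(cbind(fx$x, fx$x[, 1] * 0.5 - fx$x[, 2]))
  rownames(items_in_cols) <- paste0("g", 1:3)
  cfg <- sweep_config(sigma_grid = 1, k_grid = 2, transforms = "log2")
  sw <- run_sweep(items_in_cols, cfg, axis = "columns")
  expect_length(sw$partitions, 2)              # one QC + one SCC run
  expect_true(isSymmetric(sw$consensus$values))
  expect_equal(unname(diag(sw$consensus$values)),
               rep(1, ncol(items_in_cols)))

  # reproducibility: identical consensus for identical (input, config, seed)
  sw2 <- run_sweep(items_in_cols, cfg, axis = "columns")
  expect_identical(sw$consensus$values, sw2$consensus$values)
})

test_that("sweep consensus recovers planted region groups", {
  fx <- planted_groups_fixture()
  m <- expression_matrix(fx$matrix,
                         data.frame(sample_id = colnames(fx$matrix)),
                         scale = "log2")
  # n_components matches the rank-2 between-group structure; whitening
  # pure-noise directions up to unit variance would bury the separation
  sw <- run_sweep(m, sweep_config(transforms = "log2", n_components = 2),
                  seed = 1)
  grp <- consensus_groups(sw$consensus, 0.5)
  expect_gte(adjusted_rand_index(grp, fx$labels), 0.9)
})
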