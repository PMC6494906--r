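test_that("individual distances are absolute differences in canonical order", {
  panel <- gaba_panel()
  prof <- setNames(seq(1, 10, length.out = 19), panel$symbols)
  prof["GABRA1"] <- 5; prof["GABRA2"] <- 3
  d <- pair_distance_individual(prof, panel)
  expect_length(d, 171)
  expect_equal(d[attr(d, "pairs") == "GABRA1-GABRA2"][[1]], 2)
  expect_true(all(d >= 0))

  # constant profile -> all-zero vector
  flat <- setNames(rep(4, 19), panel$symbols)
  expect_equal(as.numeric(pair_distance_individual(flat, panel)),
               rep(0, 171))

  # order independence: permuting the input leaves the vector unchanged
  perm <- sample(19)
  expect_equal(as.numeric(pair_distance_individual(prof[perm], panel)),
               as.numeric(d))
  expect_error(pair_distance_individual(prof[-1], panel), "GABRA1")
})

test_that("consensus distances follow the multi-subject formula", {
  panel <- gaba_panel()
  # two subjects with pair differences 2 and 3 -> sqrt(13)
  p1 <- setNames(rep(0, 19), panel$symbols); p1["GABRA1"] <- 2
  p2 <- setNames(rep(0, 19), panel$symbols); p2["GABRA1"] <- 3
  dc <- pair_distance_consensus(cbind(S1 = p1, S2 = p2), panel)
  expect_equal(dc[attr(dc, "pairs") == "GABRA1-GABRA2"][[1]], sqrt(13))

  # identical subjects: consensus = sqrt(n) * individual
  set.seed(3)
  prof <- setNames(rnorm(19, 8, 2), panel$symbols)
  di <- pair_distance_individual(prof, panel)
  dc4 <- pair_distance_consensus(matrix(prof, 19, 4,
                                        dimnames = list(panel$symbols, NULL)),
                                 panel)
  expect_equal(as.numeric(dc4), sqrt(4) * as.numeric(di))
})

test_that("single-subject consensus reduces exactly to the individual distance", {
  panel <- gaba_panel()
  set.seed(17)
  for (i in 1:50) {
    prof <- setNames(rnorm(19, 7, 3), panel$symbols)
    expect_identical(
      as.numeric(pair_distance_consensus(
        matrix(prof, dimnames = list(panel$symbols, NULL)), panel)),
      as.numeric(pair_distance_individual(prof, panel)))
  }
})

test_that("stereotypy is a scale-invariant correlation with guards", {
  panel <- gaba_panel()
  set.seed(21)
  prof <- setNames(rnorm(19, 8, 2), panel$symbols)
  di <- pair_distance_individual(prof, panel)
  dc <- pair_distance_consensus(matrix(prof, 19, 6,
                                       dimnames = list(panel$symbols, NULL)),
                                panel)
  expect_equal(stereotypy(di, dc), 1)            # consensus proportional
  di_scaled <- di; di_scaled[] <- di * 42
  expect_equal(stereotypy(di_scaled, dc), 1)     # rescaling invariance

  # a 3-gene toy whose ranking is reversed gives negative R
  p3 <- toy_panel(3)
  a <- setNames(c(0, 1, 5), p3$symbols)          # d = (1, 5, 4)
  b <- setNames(c(0, 4, 5), p3$symbols)          # d = (4, 5, 1)
  da <- pair_distance_individual(a, p3)
  db <- pair_distance_individual(b, p3)
  expect_lt(stereotypy(da, db), 0)

  flat <- pair_distance_individual(setNames(rep(1, 3), p3$symbols), p3)
  expect_warning(r0 <- stereotypy(flat, da), "zero variance")
  expect_true(is.na(r0))
})

test_that("reference similarity ranks a planted outlier region lowest", {
  sim <- fix_regional()
  subjects <- lapply(sim$subjects, function(m) {
    # invert the layout of one region for every subject
    m$values[, "DT.ILr"] <- rev(m$values[, "DT.ILr"])
    m
  })
  rep <- reference_similarity(subjects, "FL.FrOp", sim$ontology)
  by_region <- aggregate(R ~ substructure, rep, mean)
  expect_equal(by_region$substructure[which.min(by_region$R)], "DT.ILr")
  # reference vs itself: near 1 when subjects agree
  self <- rep[rep$substructure == "FL.FrOp", ]
  expect_gt(mean(self$R), 0.95)
  # rows are ordered rostro-caudally
  expect_true(!is.unsorted(rep$rank))
  expect_error(reference_similarity(subjects, "no.such", sim$ontology),
               "missing")
})

test_that("layout dendrograms join the closest subunits first", {
  p3 <- toy_panel(3)
  d <- pair_distance_individual(setNames(c(0, 0.1, 10), p3$symbols), p3)
  hc <- layout_dendrogram(d, p3)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("G1", "G2"))

  zero <- pair_distance_individual(setNames(rep(2, 3), p3$symbols), p3)
  expect_equal(layout_dendrogram(zero, p3)$height, rep(0, 2))

  # planted co-regulated trio forms one subtree on the fixture consensus
  wb <- whole_brain_stereotypy(fix_regional()$subjects)
  hc19 <- layout_dendrogram(attr(wb, "consensus"))
  # the three noise-level genes sit at nearly identical baselines
  ct <- cutree(hc19, k = 4)
  expect_equal(length(unique(ct[c("GABRR1", "GABRR2", "GABRR3")])), 1)
})

test_that("ANOVA plus Dunnett flags only genuinely shifted groups", {
  set.seed(10)
  mk_report <- function(shift) {
    g <- rep(c("ref", "same1", "same2", "shifted"), each = 6)
    data.frame(structure = g,
               R = rnorm(24, 0.9, 0.01) +
                 ifelse(g == "shifted", shift, 0))
  }
  # all groups identical: tiny F, nothing significant
  r0 <- mk_report(0)
  c0 <- compare_to_reference(r0, "ref", n_sim = 2e4, seed = 1)
  expect_false(any(c0$contrasts$significant))

  # one group shifted by 10 SDs: that contrast significant
  r1 <- mk_report(0.1)
  c1 <- compare_to_reference(r1, "ref", n_sim = 2e4, seed = 1)
  expect_true(c1$contrasts$significant[c1$contrasts$structure == "shifted"])
  expect_false(any(c1$contrasts$significant[
    c1$contrasts$structure != "shifted"]))
  expect_lt(c1$anova$p, 0.05)

  # two groups only: Dunnett p equals the ordinary two-sample contrast
  r2 <- data.frame(structure = rep(c("ref", "other"), each = 8),
                   R = rnorm(16, 0.5, 0.05) +
                     rep(c(0, 0.04), each = 8))
  c2 <- compare_to_reference(r2, "ref", n_sim = 1e5, seed = 2)
  tt <- t.test(R ~ structure, r2, var.equal = TRUE)
  expect_equal(c2$contrasts$p_adj, tt$p.value, tolerance = 0.02)

  # single-observation groups are excluded with a warning
  r3 <- rbind(r2, data.frame(structure = "singleton", R = 0.4))
  expect_warning(compare_to_reference(r3, "ref", n_sim = 1e4, seed = 1),
                 "singleton")
})
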