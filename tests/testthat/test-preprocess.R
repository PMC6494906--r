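test_that("probe selection applies the 1-, 2- and many-probe rules", {
  one <- toy_expression(matrix(1:4, 1, dimnames = list("P1", NULL)))
  expect_equal(select_probe_efa(one), "P1")

  two <- toy_expression(matrix(c(7, 5, 7, 5, 7, 5), 2,
                               dimnames = list(c("Pa", "Pb"), NULL)))
  expect_equal(select_probe_efa(two), "Pa")   # higher mean wins

  # faithful vs shuffled vs constant probes from the generator fixture
  pr <- fix_probes()
  allv <- do.call(cbind, lapply(pr$probes, function(m) m$values))
  colnames(allv) <- paste0("s", seq_len(ncol(allv)))
  hits <- vapply(gaba_panel()$symbols, function(g) {
    sub <- allv[pr$probe_gene[rownames(allv)] == g, , drop = FALSE]
    em <- expression_matrix(sub, data.frame(sample_id = colnames(sub)),
                            scale = "log2")
    select_probe_efa(em) == pr$true_probe[[g]]
  }, logical(1))
  expect_gte(sum(hits), 18)
  expect_error(select_probe_efa(list(values = matrix(numeric(0), 0, 4))),
               "no probes")
})

test_that("probe consistency ranks reproducible probes first", {
  # identical profiles across 3 subjects -> consistency exactly 1
  prof <- matrix(rnorm(20), 2, 10, dimnames = list(c("Pa", "Pb"), NULL))
  mats <- lapply(1:3, function(i)
    toy_expression(prof, extra = data.frame(substructure = paste0("r", 1:10))))
  mats <- lapply(mats, function(m) {
    colnames(m$values) <- paste0("r", 1:10); m
  })
  cons <- probe_consistency(mats)
  expect_equal(cons$consistency, c(1, 1))

  # independently shuffled profiles score near zero at 100 regions
  set.seed(5)
  base <- rnorm(100)
  mats2 <- lapply(1:4, function(i) {
    v <- rbind(Pgood = base, Pbad = sample(base))
    m <- toy_expression(v)
    colnames(m$values) <- paste0("r", 1:100)
    m
  })
  cons2 <- probe_consistency(mats2)
  expect_equal(cons2$probe_id[1], "Pgood")
  expect_equal(cons2$consistency[cons2$probe_id == "Pgood"], 1)
  expect_lt(abs(cons2$consistency[cons2$probe_id == "Pbad"]), 0.2)

  # faithful probes out-rank noisy variants on the generator fixture
  pr <- fix_probes()
  cons3 <- probe_consistency(pr$probes, pr$probe_gene)
  top <- do.call(rbind, lapply(split(cons3, cons3$gene), function(d)
    d[which.max(d$consistency), ]))
  expect_gte(sum(top$probe_id == pr$true_probe[top$gene]), 18)

  expect_error(probe_consistency(mats[1]), "at least 2 subjects")
})

test_that("age correction removes linear trends and preserves scale", {
  set.seed(2)
  age <- runif(100, 20, 80)
  # perfect linear dependence flattens to the grand mean
  g1 <- 2 + 0.1 * age
  m <- toy_expression(matrix(g1, 1, dimnames = list("G1", NULL)),
                      extra = data.frame(age = age))
  corr <- correct_age(m, "continuous")
  expect_equal(unname(corr$values[1, ]), rep(mean(g1), 100))

  # age-independent gene passes through (refit slope ~ 0)
  g2 <- rep(5, 100)
  m2 <- toy_expression(matrix(g2, 1, dimnames = list("G1", NULL)),
                       extra = data.frame(age = age))
  corr2 <- correct_age(m2, "continuous")
  expect_lt(abs(coef(lm(corr2$values[1, ] ~ age))[2]), 1e-8)

  # noisy slope: residual slope within +/- 0.02 of zero (refit oracle)
  g3 <- 3 + 0.1 * age + rnorm(100, 0, 0.1)
  m3 <- toy_expression(matrix(g3, 1, dimnames = list("G1", NULL)),
                       extra = data.frame(age = age))
  corr3 <- correct_age(m3, "continuous")
  expect_lt(abs(coef(lm(corr3$values[1, ] ~ age))[2]), 0.02)

  # ordinal mode removes category means
  cat_age <- rep(c(60, 70, 80), length.out = 99)
  g4 <- ifelse(cat_age == 60, 1, ifelse(cat_age == 70, 5, 9))
  m4 <- toy_expression(matrix(g4, 1, dimnames = list("G1", NULL)),
                       extra = data.frame(age = cat_age))
  corr4 <- correct_age(m4, "ordinal")
  expect_equal(unname(corr4$values[1, ]), rep(mean(g4), 99))

  m5 <- toy_expression(matrix(1:3, 1, dimnames = list("G1", NULL)),
                       extra = data.frame(age = 50))
  expect_warning(out <- correct_age(m5), "constant")
  expect_identical(out$values, m5$values)
})

test_that("proportional contribution normalizes columns to 100", {
  panel <- toy_panel(2)
  lin <- expression_matrix(matrix(c(25, 75), 2,
                                  dimnames = list(c("G1", "G2"), NULL)),
                           data.frame(sample_id = "s1"), scale = "linear")
  comp <- proportional_contribution(lin, panel)
  expect_equal(unname(comp$values[, 1]), c(25, 75))

  lg <- expression_matrix(matrix(c(3, 3), 2,
                                 dimnames = list(c("G1", "G2"), NULL)),
                          data.frame(sample_id = "s1"), scale = "log2")
  expect_equal(unname(proportional_contribution(lg, panel)$values[, 1]),
               c(50, 50))

  # scale invariance: multiplying a column by any positive constant
  set.seed(8)
  v <- matrix(rexp(8) + 0.1, 4, dimnames = list(paste0("G", 1:4), NULL))
  p4 <- toy_panel(4)
  c1 <- proportional_contribution(toy_expression(v, "linear"), p4)
  c2 <- proportional_contribution(toy_expression(v * 37.5, "linear"), p4)
  expect_equal(c1$values, c2$values)

  # zero-total column flagged and dropped
  vz <- matrix(c(1, 1, 0, 0), 2, dimnames = list(c("G1", "G2"), NULL))
  expect_warning(cz <- proportional_contribution(toy_expression(vz, "linear"),
                                                 panel), "zero panel total")
  expect_equal(ncol(cz$values), 1)
  expect_error(proportional_contribution(lin, toy_panel(3)), "G3")
})

test_that("global contribution sums to 100 and handles point masses", {
  panel <- toy_panel(3)
  v <- matrix(0, 3, 4, dimnames = list(panel$symbols, NULL))
  v[2, ] <- 5
  g <- global_contribution(toy_expression(v, "linear"), panel)
  expect_equal(unname(g), c(0, 100, 0))

  u <- matrix(1, 3, 4, dimnames = list(panel$symbols, NULL))
  gu <- global_contribution(toy_expression(u, "linear"), panel)
  expect_equal(unname(gu), rep(100 / 3, 3))
  expect_equal(sum(gu), 100)
})

test_that("fold enrichment is a linear-scale ratio to the region mean", {
  panel <- toy_panel(2)
  v <- matrix(1, 2, 10, dimnames = list(panel$symbols, NULL))
  v[2, 1] <- 2
  et <- fold_enrichment(toy_expression(v, "linear"))
  expect_equal(et$fold[et$gene == "G1"], rep(1, 10))      # uniform gene
  expect_equal(et$fold[et$gene == "G2" & et$substructure == "s1"],
               2 / 1.1)                                   # 2 vs mean 1.1
  expect_true(et$is_max[et$gene == "G2" & et$substructure == "s1"])
  # unweighted folds average to exactly 1 per gene
  for (g in c("G1", "G2"))
    expect_equal(mean(et$fold[et$gene == g]), 1)
  expect_error(fold_enrichment(toy_expression(matrix(0, 1, 3), "linear")),
               "zero global mean")
})

test_that("profile classification separates noise, regional and global genes", {
  v <- rbind(noise = rep(3, 10),
             regional = c(10, rep(3, 9)),
             high = rep(10, 10))
  m <- toy_expression(v, "log2")
  et <- fold_enrichment(m)
  cls <- classify_profiles(m, et)
  expect_equal(unname(cls["noise"]), "noise")
  expect_equal(unname(cls["regional"]), "region_specific")
  expect_equal(unname(cls["high"]), "global_high")
})
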