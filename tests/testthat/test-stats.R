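test_that("percent differences reproduce the reference-table arithmetic", {
  expect_equal(round(percent_difference(92, 94), 2), -2.13)
  expect_equal(round(percent_difference(27, 26), 2), 3.85)
  expect_equal(percent_difference(5, 5), 0)
  expect_error(percent_difference(1, 0), "zero reference")
})

test_that("percent difference satisfies the asymmetric-inverse identity", {
  set.seed(14)
  for (i in 1:20) {
    a <- runif(1, 50, 250)
    b <- runif(1, 50, 250)
    pd_ab <- percent_difference(a, b)
    pd_ba <- percent_difference(b, a)
    expect_equal(pd_ab, -pd_ba / (1 + pd_ba / 100), tolerance = 1e-10)
  }
})

test_that("balanced two-way ANOVA matches textbook closed-form F tests", {
  # 2x2 design with n = 2 per cell; hand-computed sums of squares
  d <- data.frame(
    condition = rep(c("wt", "dia"), each = 4),
    age_group = rep(c("12", "24"), times = 4),
    y = c(10, 12, 11, 13, 7, 9, 6, 10)
  )
  # textbook arithmetic (balanced): SS_A = 4*(mean_wt - mean)^2 * 2 ...
  gm <- mean(d$y)
  m_cond <- tapply(d$y, d$condition, mean)
  m_age <- tapply(d$y, d$age_group, mean)
  m_cell <- tapply(d$y, interaction(d$condition, d$age_group), mean)
  ss_cond <- 4 * sum((m_cond - gm)^2)
  ss_age <- 4 * sum((m_age - gm)^2)
  ss_cells <- 2 * sum((m_cell - gm)^2)
  ss_int <- ss_cells - ss_cond - ss_age
  ss_err <- sum((d$y - m_cell[interaction(d$condition, d$age_group)])^2)
  f_cond <- (ss_cond / 1) / (ss_err / 4)
  f_age <- (ss_age / 1) / (ss_err / 4)
  f_int <- (ss_int / 1) / (ss_err / 4)
  expected <- stats::pf(c(f_cond, f_age, f_int), 1, 4, lower.tail = FALSE)
  p <- two_way_anova(d, "y")
  expect_equal(unname(p), expected, tolerance = 1e-10)
})

test_that("ANOVA rejects degenerate designs", {
  d <- data.frame(condition = rep(c("wt", "dia"), each = 4),
                  age_group = rep(c("12", "24"), times = 4),
                  y = rep(5, 8))
  expect_error(two_way_anova(d, "y"), "residual variance")
  d2 <- data.frame(condition = c("wt", "wt", "wt", "wt", "dia", "dia"),
                   age_group = c("12", "12", "24", "24", "12", "12"),
                   y = rnorm(6))
  expect_error(two_way_anova(d2, "y"), "cell")
})

test_that("null condition p-values are uniform (Type II, unbalanced cells)", {
  set.seed(200)
  pvals <- replicate(200, {
    d <- data.frame(
      condition = rep(c("wt", "dia"), c(22, 21)),
      age_group = c(rep(c("12", "24"), c(12, 10)),
                    rep(c("12", "24"), c(11, 10))),
      y = rnorm(43, 100, 5)
    )
    two_way_anova(d, "y")[["condition"]]
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("a strong condition effect is detected in an unbalanced design", {
  set.seed(42)
  hits <- replicate(10, {
    y_wt <- rnorm(22, 100, 3)
    y_dia <- rnorm(21, 90, 3)
    d <- data.frame(
      condition = rep(c("wt", "dia"), c(22, 21)),
      age_group = c(rep(c("12", "24"), c(12, 10)),
                    rep(c("12", "24"), c(11, 10))),
      y = c(y_wt, y_dia)
    )
    two_way_anova(d, "y")[["condition"]] < 0.05
  })
  expect_true(all(hits))
})

test_that("exact censored rank-sum matches the permutation count", {
  # no overlap, n = 5 vs 5: two-sided p = 2 / choose(10, 5)
  res <- rank_sum_censored(c(10, 11, 12, 13, 14), c(1, 2, 3, 4, 5),
                           ceiling = Inf)
  expect_equal(res$p.value, 2 / choose(10, 5))
  # identical samples: two-sided tie-corrected p = 1
  expect_equal(rank_sum_censored(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_error(rank_sum_censored(numeric(0), 1), "non-empty")
})

test_that("exact rank-sum agrees with wilcox.test when ties are absent", {
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(6)
    y <- rnorm(7, 0.5)
    ours <- rank_sum_censored(x, y, ceiling = Inf)
    ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample rank-sum matches the tie-corrected normal form", {
  set.seed(4)
  x <- round(rnorm(15, 5, 1)) # discrete -> ties
  y <- round(rnorm(12, 6, 1))
  ours <- rank_sum_censored(x, y, ceiling = Inf)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("rank-sum is invariant to monotone transforms above the ceiling", {
  x <- c(450, 550, 700, 900, 1200) # last three censored at 600
  y <- c(120, 140, 150, 160, 170)
  p1 <- rank_sum_censored(x, y)$p.value
  p2 <- rank_sum_censored(c(450, 550, 601, 1e6, 2e6), y)$p.value
  expect_identical(p1, p2)
})

test_that("global mean averages map values", {
  segs <- list(interface_set(rep(10, 4), rep(30, 4), rep(50, 4),
                             rep(60, 4)))
  maps <- build_maps(segs, axial_pitch = 3.9)
  maps$maps$trt[1, 1:2] <- 200
  maps$maps$trt[1, 3:4] <- 210
  expect_equal(unname(global_mean(maps)["trt"]), 205)
})

test_that("pairwise within-factor t-tests run per stratum", {
  set.seed(15)
  d <- data.frame(
    condition = rep(c("wt", "dia"), each = 20),
    age_group = rep(rep(c("12", "24"), each = 10), 2),
    body_weight = c(rnorm(10, 28, 2), rnorm(10, 32, 2),
                    rnorm(10, 24, 1), rnorm(10, 24, 1))
  )
  out <- pairwise_group_t(d, "body_weight", by = "age_group",
                          within = "condition")
  expect_equal(nrow(out), 2)
  expect_lt(out$p_value[out$stratum == "wt"], 0.01)
  expect_gt(out$p_value[out$stratum == "dia"], 0.05)
})
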