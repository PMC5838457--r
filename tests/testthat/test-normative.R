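make_flat_maps <- function(value = 200, nb = 4, na = 16, jitter = 0) {
  segs <- lapply(seq_len(nb), function(b) {
    base <- 10
    r2 <- base + round(value / 3.9 / 2)
    r4 <- base + round(value / 3.9)
    interface_set(rep(base, na), rep(r2, na), rep(r4 - 3, na), rep(r4, na))
  })
  maps <- build_maps(segs, axial_pitch = 3.9)
  if (jitter != 0) {
    maps$maps <- lapply(maps$maps, function(m) m + jitter)
  }
  maps
}

test_that("two identical eyes give SD zero and mean equal to the map", {
  eyes <- list(make_flat_maps(), make_flat_maps())
  model <- build_normative(eyes)
  expect_true(all(model$sd$trt == 0))
  expect_equal(model$mean$trt, eyes[[1]]$maps$trt)
  expect_equal(model$n_eyes, 2)
  # Z undefined where SD = 0: all pixels excluded -> error
  expect_error(zscore_map(eyes[[1]], model), "no valid pixels")
})

test_that("normative requires two eyes and matching grids", {
  expect_error(build_normative(list(make_flat_maps())), "at least 2")
  expect_error(build_normative(list(make_flat_maps(na = 16),
                                    make_flat_maps(na = 20))),
               "shapes differ")
})

test_that("per-pixel SD recovers the simulated between-eye SD", {
  # all per-pixel SD estimates share the same 12 eye draws, so the pooled
  # estimate is a single chi-square realisation with n - 1 df
  spec <- small_spec(n_bscans = 3, n_ascans = 24)
  co <- generate_cohort(12, 0, spec = spec,
                        between_eye_sd = c(inner = 4, outer = 0, osl = 0),
                        seed = 31, render = FALSE, left_fraction = 0)
  maps <- lapply(co$eyes, eye_maps_from_truth)
  model <- build_normative(maps)
  s2 <- mean(model$sd$irt[model$valid]^2)
  bounds <- 16 * qchisq(c(0.005, 0.995), df = 11) / 11
  expect_gt(s2, bounds[1])
  expect_lt(s2, bounds[2])
  # mean map sits at the 94 um wild-type IRT target
  expect_lt(abs(mean(model$mean$irt[model$valid]) - 94), 4 * 3 / sqrt(12))
})

test_that("Z-scores are zero at the mean and one at mean + SD", {
  set.seed(5)
  eyes <- lapply(1:6, function(i) make_flat_maps(jitter = rnorm(1, 0, 5)))
  model <- build_normative(eyes)
  mean_eye <- eyes[[1]]
  mean_eye$maps <- model$mean
  z0 <- zscore_map(mean_eye, model)
  expect_true(all(abs(z0$z$trt[z0$valid$trt]) < 1e-12))
  up_eye <- mean_eye
  up_eye$maps <- Map(`+`, model$mean, model$sd)
  z1 <- zscore_map(up_eye, model)
  expect_true(all(abs(z1$z$trt[z1$valid$trt] - 1) < 1e-12))
})

test_that("Z-scores are invariant to a constant shift of every eye", {
  set.seed(6)
  eyes <- lapply(1:5, function(i) make_flat_maps(jitter = rnorm(1, 0, 4)))
  test_eye <- make_flat_maps(jitter = 3)
  z <- zscore_map(test_eye, build_normative(eyes))
  shifted <- lapply(eyes, function(e) {
    e$maps <- lapply(e$maps, `+`, 17)
    e
  })
  test_shift <- test_eye
  test_shift$maps <- lapply(test_eye$maps, `+`, 17)
  z2 <- zscore_map(test_shift, build_normative(shifted))
  expect_equal(z$z$trt, z2$z$trt, tolerance = 1e-9)
})

test_that("area fractions bin correctly, ties to the middle bin", {
  expect_equal(area_fractions(matrix(0, 3, 3)),
               c(below = 0, within = 100, above = 0))
  expect_equal(area_fractions(c(-2, 0, 2, 0)),
               c(below = 25, within = 50, above = 25))
  # Z exactly +/-1 falls in the closed middle bin
  expect_equal(area_fractions(c(-1, 1, -1, 1)),
               c(below = 0, within = 100, above = 0))
  expect_error(area_fractions(matrix(NA_real_, 2, 2)), "zero valid")
  # fractions always sum to 100 before rounding
  set.seed(9)
  f <- area_fractions(rnorm(257))
  expect_equal(sum(f), 100)
})

test_that("standard-normal scores give the Gaussian bin fractions", {
  set.seed(12)
  f <- area_fractions(rnorm(2e5))
  expect_lt(abs(f[["below"]] - 15.87), 0.5)
  expect_lt(abs(f[["within"]] - 68.27), 0.5)
  expect_lt(abs(f[["above"]] - 15.87), 0.5)
})

test_that("cohort summary averages fractions and differences reduced-increased", {
  one <- data.frame(eye_id = "a", measure = "trt",
                    below = 10, within = 80, above = 10)
  s <- cohort_fraction_summary(one)
  expect_equal(s$below, 10)
  expect_equal(s$reduced_minus_increased, 0)
  two <- rbind(one, data.frame(eye_id = "b", measure = "trt",
                               below = 30, within = 65, above = 5))
  s2 <- cohort_fraction_summary(two)
  expect_equal(s2$below, 20)
  expect_equal(s2$reduced_minus_increased, 20 - 7.5)
  expect_error(cohort_fraction_summary(one[0, ]), "empty")
})

test_that("mean Z recovers -thinning/SD for simulated diabetic eyes", {
  # thinning delta on a normative SD sigma gives E[Z] = -delta/sigma
  set.seed(77)
  spec <- small_spec(n_bscans = 3, n_ascans = 24)
  sds <- c(inner = 4, outer = 0.01, osl = 0.01)
  zbar <- replicate(15, {
    seed <- sample.int(1e6, 1)
    wt <- generate_cohort(12, 0, spec = spec, between_eye_sd = sds,
                          seed = seed, render = FALSE)
    dia <- generate_cohort(0, 8, spec = spec, between_eye_sd = sds,
                           seed = seed + 1, render = FALSE)
    model <- build_normative(lapply(wt$eyes, eye_maps_from_truth))
    mean(sapply(dia$eyes, function(e) {
      z <- zscore_map(eye_maps_from_truth(e), model)
      mean(z$z$irt[z$valid$irt])
    }))
  })
  # 12-week inner thinning of 2 um against sigma = 4 um -> E[Z] = -0.5
  expect_lt(abs(mean(zbar) - (-2 / 4)), 0.2)
})
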