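test_that("identical spec and seed reproduce identical volumes bit for bit", {
  spec <- small_spec(speckle_level = 0.3, seed = 42L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$bscans, b$volume$bscans)
  expect_identical(a$truth, b$truth)
  c <- generate_phantom(small_spec(speckle_level = 0.3, seed = 43L))
  expect_false(identical(a$volume$bscans, c$volume$bscans))
})

test_that("ground-truth geometry conserves TRT = IRT + ORT and OSL <= ORT", {
  ph <- generate_phantom(small_spec())
  tm <- ph$truth$true_maps
  expect_equal(tm$trt, tm$irt + tm$ort, tolerance = 0)
  expect_true(all(tm$osl <= tm$ort))
  expect_true(all(unlist(tm) > 0))
  # strict interface ordering everywhere
  z <- ph$truth$interfaces_um
  expect_true(all(z$ilm < z$inl_opl))
  expect_true(all(z$inl_opl < z$onl_ise))
  expect_true(all(z$onl_ise < z$os_rpe))
})

test_that("zero undulation and zero disk bump give flat interface planes", {
  spec <- small_spec(undulation_amplitude = 0,
                     undulation_bscan_amplitude = 0, disk_amplitude = 0)
  ph <- generate_phantom(spec)
  for (z in ph$truth$interfaces_px) {
    expect_equal(max(z) - min(z), 0)
  }
})

test_that("wild-type defaults hit the 12-week global thickness targets", {
  # away from the optic disk the noise-free TRT must sit at 208 um
  spec <- small_spec(n_ascans = 96)
  ph <- generate_phantom(spec)
  far <- col(ph$truth$true_maps$trt) > 40 # disk sits near the left edge
  expect_lt(abs(mean(ph$truth$true_maps$trt[far]) - 208), 0.5)
  expect_lt(abs(mean(ph$truth$true_maps$irt[far]) - 94), 10 * 0.4) # disk tail
  expect_lt(abs(mean(ph$truth$true_maps$osl[far]) - 26), 1e-9)
})

test_that("diabetic thinning scales the true IRT map by 1 - fraction", {
  f <- 2 / 94 # calibrated 12-week inner thinning (-2.13%)
  spec <- small_spec()
  wt <- generate_phantom(spec, "wildtype", render = FALSE)
  dia <- generate_phantom(
    small_spec(thinning_fraction = c(inner = f, outer = 0, osl = 0)),
    "diabetic", render = FALSE
  )
  # direct map averaging: disk bump scales multiplicatively, so the ratio
  # is exact at every pixel
  ratio <- mean(dia$truth$true_maps$irt) / mean(wt$truth$true_maps$irt)
  expect_equal(ratio, 1 - f, tolerance = 1e-12)
  expect_equal(dia$truth$true_maps$ort, wt$truth$true_maps$ort,
               tolerance = 1e-12)
})

test_that("noise-free images step dark-to-bright exactly at the interfaces", {
  ph <- generate_phantom(small_spec(vessel_attenuation = 1))
  img <- ph$volume$bscans[[3]]
  nr <- nrow(img)
  grad <- (img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]) / 2
  cols <- c(30, 45, 60) # away from the disk
  for (nm in names(ph$truth$interfaces_px)) {
    for (a in cols) {
      r <- floor(ph$truth$interfaces_px[[nm]][3, a] + 0.5)
      window <- grad[(r - 3):(r + 3), a]
      expect_gt(grad[r, a], 0)
      expect_equal(max(window), max(grad[r, a], grad[r - 1, a]))
    }
  }
})

test_that("cohorts reproduce the study design sizes and are deterministic", {
  spec <- small_spec(n_bscans = 3, n_ascans = 32)
  co <- generate_cohort(12, 11, spec = spec, age_group = "12", seed = 5,
                        render = FALSE)
  expect_equal(nrow(co$metadata), 23)
  expect_equal(sum(co$metadata$condition == "wildtype"), 12)
  expect_equal(sum(co$metadata$condition == "diabetic"), 11)
  co2 <- generate_cohort(12, 11, spec = spec, age_group = "12", seed = 5,
                         render = FALSE)
  expect_identical(co$metadata, co2$metadata)
  expect_identical(co$eyes[[3]]$truth, co2$eyes[[3]]$truth)
})

test_that("degenerate cohort with zero variability gives identical eyes", {
  spec <- small_spec(n_bscans = 3, n_ascans = 32,
                     thinning_fraction = c(inner = 0, outer = 0, osl = 0))
  co <- generate_cohort(3, 0, spec = spec,
                        between_eye_sd = c(inner = 0, outer = 0, osl = 0),
                        seed = 2, render = FALSE, left_fraction = 0)
  expect_identical(co$eyes[[1]]$truth$true_maps,
                   co$eyes[[2]]$truth$true_maps)
  expect_identical(co$eyes[[2]]$truth$true_maps,
                   co$eyes[[3]]$truth$true_maps)
})

test_that("diabetic glucose is censored at the 600 mg/dL meter ceiling", {
  co <- generate_cohort(10, 30, spec = small_spec(n_bscans = 3, n_ascans = 32),
                        seed = 9, render = FALSE)
  md <- co$metadata
  expect_true(all(md$glucose <= 600))
  expect_true(all(md$glucose[md$glucose_censored] == 600))
  expect_true(all(md$condition[md$glucose_censored] == "diabetic"))
  # the ceiling binds for a nontrivial share of diabetic eyes
  expect_gt(sum(md$glucose_censored), 2)
  expect_true(all(md$glucose[md$condition == "diabetic"] >= 269))
})

test_that("left eyes are mirrored at acquisition and flagged in metadata", {
  spec <- small_spec(n_bscans = 3, n_ascans = 32)
  co <- generate_cohort(6, 0, spec = spec, seed = 4, render = TRUE,
                        left_fraction = 1)
  eye <- co$eyes[[1]]
  expect_equal(eye$metadata$laterality, "left")
  expect_equal(eye$metadata$disk_ascan,
               spec$n_ascans + 1 - spec$disk_center[2])
  right <- generate_cohort(6, 0, spec = spec, seed = 4, render = TRUE,
                           left_fraction = 0)
  expect_equal(eye$truth$true_maps$irt,
               right$eyes[[1]]$truth$true_maps$irt[, 32:1])
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(depth_px = 40), "cannot contain")
  expect_error(phantom_spec(n_ascans = 0), "positive")
  lt <- c(nfl_gcl = 30, ipl = -1, inl = 24, opl = 16, onl = 56, is = 16,
          ise = 12, os = 14, rpe = 12)
  expect_error(phantom_spec(layer_thicknesses = lt), "positive")
})
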