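#' Specification of a synthetic SD-OCT phantom
#'
#' Describes the raster geometry, layer anatomy, and artefact model of a
#' synthetic mouse-retina SD-OCT volume. Defaults emulate a Spectralis-like
#' raster of 31 horizontal B-scans with 1536 A-scans per B-scan and a 3.9
#' micron axial pixel pitch, and default layer thicknesses are calibrated so
#' that the wild-type global measures are IRT 94, ORT 114, TRT 208 and OSL
#' 26 microns at 12 weeks of age.
#'
#' Layer reflectances follow the usual murine SD-OCT appearance: NFL+GCL,
#' IPL, OPL, ISe and RPE bright; INL, ONL, IS and OS dark. They are chosen
#' so that the positive (dark-to-bright) vertical gradient magnitudes rank
#' ILM > OS/RPE > INL/OPL > IS/ISe, which the fixed four-stage detection
#' order requires.
#'
#' @param n_bscans number of B-scans in the raster (rows of the map grid).
#' @param n_ascans number of A-scans per B-scan (columns). The full 1536 is
#'   supported; tests and examples typically use 256 or less.
#' @param depth_px axial image depth in pixels.
#' @param axial_pitch axial pixel pitch in microns per pixel.
#' @param layer_thicknesses named vector of layer thicknesses in microns for
#'   `nfl_gcl, ipl, inl, opl, onl, is, ise, os, rpe`.
#' @param layer_reflectances named vector of relative intensities for
#'   `vitreous, nfl_gcl, ipl, inl, opl, onl, is, ise, os, rpe, choroid`.
#' @param ilm_depth mean depth of the vitreous/ILM interface below the image
#'   top, microns.
#' @param undulation_amplitude amplitude (microns) of the smooth sinusoidal
#'   lateral undulation of all interfaces; identical in every eye (gross
#'   retinal shape), so it cancels in normative Z-scores.
#' @param undulation_wavelength undulation wavelength in A-scan units;
#'   `NULL` means `n_ascans / 1.8`.
#' @param undulation_bscan_amplitude amplitude (microns) of the slow depth
#'   variation across B-scans.
#' @param disk_center optic-disk centre as `c(bscan, ascan)` grid position.
#' @param disk_diameter optic-disk diameter in grid units (used by both the
#'   phantom bump and the downstream exclusion window).
#' @param disk_amplitude fractional thickening of the inner layers at the
#'   disk centre (Gaussian profile, sigma = 0.75 * diameter).
#' @param vessel_positions A-scan indices of vessel shadow centres; `NULL`
#'   places nine vessels at fixed fractions of the scan width.
#' @param vessel_width full width of each vessel shadow in A-scans.
#' @param vessel_attenuation multiplicative intensity factor applied below
#'   the inner retina in shadowed columns.
#' @param speckle_level multiplicative speckle coefficient of variation;
#'   speckle is gamma-distributed with unit mean and shape
#'   `1/speckle_level^2`. Zero disables noise.
#' @param thinning_fraction named vector `c(inner, outer, osl)` of
#'   fractional thinning applied to the corresponding layer groups when a
#'   phantom is generated with `condition = "diabetic"`. All-zero means
#'   "use the per-age defaults" in [generate_cohort()].
#' @param seed integer seed for the speckle noise of this volume.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_cohort()]
#' @export
phantom_spec <- function(n_bscans = 31L,
                         n_ascans = 1536L,
                         depth_px = 496L,
                         axial_pitch = 3.9,
                         layer_thicknesses = c(
                           nfl_gcl = 30, ipl = 40, inl = 24,
                           opl = 16, onl = 56, is = 16,
                           ise = 12, os = 14, rpe = 12
                         ),
                         layer_reflectances = c(
                           vitreous = 0.02, nfl_gcl = 0.92, ipl = 0.80,
                           inl = 0.25, opl = 0.88, onl = 0.32, is = 0.45,
                           ise = 0.88, os = 0.18, rpe = 0.98, choroid = 0.15
                         ),
                         ilm_depth = 150,
                         undulation_amplitude = 10,
                         undulation_wavelength = NULL,
                         undulation_bscan_amplitude = 6,
                         disk_center = c(16, max(1, round(0.05 * n_ascans))),
                         disk_diameter = 5,
                         disk_amplitude = 0.4,
                         vessel_positions = NULL,
                         vessel_width = max(1L, round(n_ascans / 85)),
                         vessel_attenuation = 0.55,
                         speckle_level = 0.30,
                         thinning_fraction = c(inner = 0, outer = 0, osl = 0),
                         seed = 1L) {
  if (is.null(undulation_wavelength)) {
    undulation_wavelength <- n_ascans / 1.8
  }
  if (is.null(vessel_positions)) {
    vessel_positions <- unique(pmax(1L, pmin(
      n_ascans,
      as.integer(round(seq(0.12, 0.94, length.out = 9) * n_ascans))
    )))
  }
  spec <- structure(list(
    n_bscans = as.integer(n_bscans),
    n_ascans = as.integer(n_ascans),
    depth_px = as.integer(depth_px),
    axial_pitch = axial_pitch,
    layer_thicknesses = layer_thicknesses,
    layer_reflectances = layer_reflectances,
    ilm_depth = ilm_depth,
    undulation_amplitude = undulation_amplitude,
    undulation_wavelength = undulation_wavelength,
    undulation_bscan_amplitude = undulation_bscan_amplitude,
    disk_center = disk_center,
    disk_diameter = disk_diameter,
    disk_amplitude = disk_amplitude,
    vessel_positions = as.integer(vessel_positions),
    vessel_width = as.integer(vessel_width),
    vessel_attenuation = vessel_attenuation,
    speckle_level = speckle_level,
    thinning_fraction = thinning_fraction,
    seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$n_bscans < 1 || spec$n_ascans < 1 || spec$depth_px < 1) {
    stop("phantom_spec: all raster dimensions must be positive",
         call. = FALSE)
  }
  if (spec$axial_pitch <= 0) {
    stop("phantom_spec: axial_pitch must be positive", call. = FALSE)
  }
  lt <- spec$layer_thicknesses
  need <- c(INNER_LAYERS, OUTER_LAYERS, OSL_LAYERS, "rpe")
  if (!all(need %in% names(lt)) || any(lt[need] <= 0)) {
    stop("phantom_spec: layer_thicknesses must name ", paste(need, collapse = ", "),
         " with positive values", call. = FALSE)
  }
  tf <- spec$thinning_fraction
  if (!all(c("inner", "outer", "osl") %in% names(tf)) || any(tf >= 1)) {
    stop("phantom_spec: thinning_fraction must name inner, outer, osl (< 1)",
         call. = FALSE)
  }
  # deepest interface (incl. RPE band, disk bump, undulation) must fit;
  # the disk bump thickens only the inner layers
  max_depth <- spec$ilm_depth +
    sum(lt[INNER_LAYERS]) * (1 + spec$disk_amplitude) +
    sum(lt[c(OUTER_LAYERS, OSL_LAYERS, "rpe")]) +
    spec$undulation_amplitude + spec$undulation_bscan_amplitude + 10
  if (max_depth >= spec$depth_px * spec$axial_pitch) {
    stop("phantom_spec: depth_px * axial_pitch (",
         spec$depth_px * spec$axial_pitch,
         " um) cannot contain the retina plus margins (", round(max_depth),
         " um)", call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  lt <- x$layer_thicknesses
  cat("<phantom_spec> ", x$n_bscans, " B-scans x ", x$n_ascans,
      " A-scans x ", x$depth_px, " px (", x$axial_pitch, " um/px)\n",
      sep = "")
  cat("  IRT/ORT/TRT/OSL targets: ",
      sum(lt[INNER_LAYERS]), "/",
      sum(lt[c(OUTER_LAYERS, OSL_LAYERS)]), "/",
      sum(lt[c(INNER_LAYERS, OUTER_LAYERS, OSL_LAYERS)]), "/",
      sum(lt[OSL_LAYERS]), " um; speckle CV ", x$speckle_level, "\n",
      sep = "")
  invisible(x)
}

# Interface depth fields (microns, n_bscans x n_ascans) and per-layer
# boundary stack for rendering. Group scales combine condition thinning,
# per-eye offsets, and the optic-disk inner-layer bump.
phantom_geometry <- function(spec, condition,
                             group_offsets = c(inner = 0, outer = 0, osl = 0)) {
  nb <- spec$n_bscans
  na <- spec$n_ascans
  lt <- spec$layer_thicknesses
  thin <- if (condition == "diabetic") spec$thinning_fraction else
    c(inner = 0, outer = 0, osl = 0)

  inner_base <- sum(lt[INNER_LAYERS])
  outer_base <- sum(lt[OUTER_LAYERS])
  osl_base <- sum(lt[OSL_LAYERS])

  s_inner <- (1 - thin[["inner"]]) * (1 + group_offsets[["inner"]] / inner_base)
  s_outer <- (1 - thin[["outer"]]) * (1 + group_offsets[["outer"]] / outer_base)
  s_osl <- (1 - thin[["osl"]]) * (1 + group_offsets[["osl"]] / osl_base)
  if (any(c(s_inner, s_outer, s_osl) <= 0)) {
    stop("phantom geometry: layer-group scale became non-positive",
         call. = FALSE)
  }

  b_idx <- matrix(seq_len(nb), nb, na)
  a_idx <- matrix(seq_len(na), nb, na, byrow = TRUE)

  # smooth surface undulation, identical across eyes
  und <- spec$undulation_amplitude *
    sin(2 * pi * (a_idx - 1) / spec$undulation_wavelength) +
    spec$undulation_bscan_amplitude *
      sin(pi * (b_idx - 1) / max(1, nb - 1))
  z_ilm <- spec$ilm_depth + und

  # optic-disk bump: Gaussian inner-layer thickening near disk_center
  sig <- 0.75 * spec$disk_diameter
  bump <- exp(-((b_idx - spec$disk_center[1])^2 +
                  (a_idx - spec$disk_center[2])^2) / (2 * sig^2))
  inner_scale <- s_inner * (1 + spec$disk_amplitude * bump)

  # cumulative layer boundaries in microns (list of nb x na matrices)
  order_layers <- c(INNER_LAYERS, OUTER_LAYERS, OSL_LAYERS, "rpe")
  scale_of <- c(
    nfl_gcl = NA, ipl = NA, inl = NA, # spatially varying, handled below
    opl = s_outer, onl = s_outer, is = s_outer,
    ise = s_osl, os = s_osl, rpe = 1
  )
  bounds <- vector("list", length(order_layers) + 1L)
  bounds[[1L]] <- z_ilm
  acc <- z_ilm
  for (i in seq_along(order_layers)) {
    layer <- order_layers[i]
    thick <- if (layer %in% INNER_LAYERS) lt[[layer]] * inner_scale else
      lt[[layer]] * scale_of[[layer]]
    acc <- acc + thick
    bounds[[i + 1L]] <- acc
  }
  names(bounds) <- c("ilm", order_layers)

  interfaces_um <- list(
    ilm = bounds$ilm,
    inl_opl = bounds$inl,
    onl_ise = bounds$is,
    os_rpe = bounds$os
  )
  irt <- interfaces_um$inl_opl - interfaces_um$ilm
  ort <- interfaces_um$os_rpe - interfaces_um$inl_opl
  true_maps <- list(
    irt = irt,
    ort = ort,
    trt = irt + ort, # exact conservation by construction
    osl = interfaces_um$os_rpe - interfaces_um$onl_ise
  )
  list(bounds = bounds, interfaces_um = interfaces_um, true_maps = true_maps)
}

#' Generate a synthetic SD-OCT volume with known ground truth
#'
#' Renders a raster stack of grayscale B-scans whose noise-free intensity
#' profile steps from dark to bright exactly at the four ground-truth
#' interfaces (vitreous/ILM, INL/OPL, ONL/ISe, OS/RPE), then applies vessel
#' shadows and multiplicative gamma speckle. The diabetic condition scales
#' the inner and outer layer groups by `1 - thinning_fraction`.
#'
#' @param spec a [phantom_spec()].
#' @param condition `"wildtype"` or `"diabetic"`.
#' @param group_offsets per-eye additive thickness offsets in microns for
#'   the `inner`, `outer` (OPL+ONL+IS) and `osl` (ISe+OS) groups, as drawn
#'   by [generate_cohort()].
#' @param render if `FALSE`, skip image rendering and return only the
#'   ground truth (fast path for statistical simulations).
#'
#' @return A list with elements `volume` (class `bscan_volume`, or `NULL`
#'   when `render = FALSE`) and `truth` (class `ground_truth` holding
#'   sub-pixel interface depths in microns and pixels and the exact
#'   IRT/ORT/TRT/OSL maps implied by the geometry).
#' @export
generate_phantom <- function(spec, condition = c("wildtype", "diabetic"),
                             group_offsets = c(inner = 0, outer = 0, osl = 0),
                             render = TRUE) {
  condition <- match.arg(condition)
  validate_phantom_spec(spec)
  geo <- phantom_geometry(spec, condition, group_offsets)

  truth <- structure(list(
    interfaces_um = geo$interfaces_um,
    interfaces_px = lapply(geo$interfaces_um, function(z) z / spec$axial_pitch),
    true_maps = geo$true_maps,
    disk = list(center = spec$disk_center, diameter = spec$disk_diameter),
    axial_pitch = spec$axial_pitch,
    condition = condition
  ), class = "ground_truth")

  volume <- NULL
  if (render) {
    volume <- render_volume(spec, geo, condition)
  }
  list(volume = volume, truth = truth)
}

render_volume <- function(spec, geo, condition) {
  nb <- spec$n_bscans
  na <- spec$n_ascans
  nr <- spec$depth_px
  refl <- spec$layer_reflectances[c(
    "vitreous", "nfl_gcl", "ipl", "inl", "opl", "onl", "is", "ise", "os",
    "rpe", "choroid"
  )]
  row_mat <- matrix(seq_len(nr), nr, na)

  # vessel shadow columns (full width)
  half_w <- (spec$vessel_width - 1L) %/% 2L
  vcols <- unique(unlist(lapply(spec$vessel_positions, function(v) {
    (v - half_w):(v + half_w + (spec$vessel_width - 1L) %% 2L)
  })))
  vcols <- vcols[vcols >= 1 & vcols <= na]

  bscans <- with_seed(spec$seed, {
    lapply(seq_len(nb), function(b) {
      # rasterise boundaries: round half-up to pixel rows; rows >= boundary
      # row belong to the layer below, so the first bright row sits at the
      # rounded interface position.
      idx <- matrix(1L, nr, na)
      for (k in seq_along(geo$bounds)) {
        rk <- floor(geo$bounds[[k]][b, ] / spec$axial_pitch + 0.5)
        idx <- idx + (row_mat >= matrix(rk, nr, na, byrow = TRUE))
      }
      img <- matrix(refl[idx], nr, na)

      if (length(vcols) && spec$vessel_attenuation < 1) {
        # shadow everything below the superficial vessels (15 um under ILM)
        rs <- floor((geo$bounds$ilm[b, vcols] + 15) / spec$axial_pitch + 0.5)
        shadow <- row_mat[, vcols, drop = FALSE] >=
          matrix(rs, nr, length(vcols), byrow = TRUE)
        img[, vcols][shadow] <- img[, vcols][shadow] * spec$vessel_attenuation
      }
      if (spec$speckle_level > 0) {
        shape <- 1 / spec$speckle_level^2
        img <- img * matrix(rgamma(nr * na, shape = shape, rate = shape),
                            nr, na)
      }
      img
    })
  })

  structure(list(
    bscans = bscans,
    n_bscans = nb, n_ascans = na, depth_px = nr,
    axial_pitch = spec$axial_pitch,
    metadata = list(
      condition = condition, laterality = "right",
      disk_center = spec$disk_center, disk_diameter = spec$disk_diameter
    )
  ), class = "bscan_volume")
}

#' @export
print.bscan_volume <- function(x, ...) {
  cat("<bscan_volume> ", x$n_bscans, " B-scans x ", x$n_ascans,
      " A-scans x ", x$depth_px, " px, ", x$axial_pitch, " um/px (",
      x$metadata$condition, ", ", x$metadata$laterality, " eye)\n", sep = "")
  invisible(x)
}

# Table-2-calibrated study conditions -------------------------------------

# Wild-type baseline group sums by age (um): IRT / non-OS outer / OSL.
# 12 wk: 94 / 88 / 26 (ORT 114, TRT 208); 24 wk: 96 / 89 / 26 (ORT 115,
# TRT 211). Diabetic thinning reproduces the printed percent differences in
# expectation; OSL thinning is zero (the OSL difference was not significant).
age_baseline_scale <- function(age_group) {
  switch(as.character(age_group),
    "12" = c(inner = 1, outer = 1, osl = 1),
    "24" = c(inner = 96 / 94, outer = 89 / 88, osl = 1),
    stop("unknown age_group: ", age_group, call. = FALSE)
  )
}

default_thinning <- function(age_group) {
  switch(as.character(age_group),
    "12" = c(inner = 2 / 94, outer = 2 / 88, osl = 0),
    "24" = c(inner = 4 / 96, outer = 3 / 89, osl = 0),
    stop("unknown age_group: ", age_group, call. = FALSE)
  )
}

#' Generate a synthetic imaging cohort
#'
#' Draws `n_wt + n_diabetic` eyes at one age group. Each eye receives an
#' independent normal perturbation of its layer-group thicknesses
#' (`between_eye_sd`, microns) on top of the condition effect, a laterality
#' (left eyes are rendered mirrored, as acquired), and simulated blood
#' glucose and body weight. Wild-type glucose is normal (151 +/- 19 mg/dL at
#' 12 weeks, 139 +/- 19 at 24 weeks); diabetic glucose sits above a
#' hyperglycemic floor and is censored at the 600 mg/dL glucometer ceiling,
#' with the censored flag recorded.
#'
#' Baseline layer thicknesses and the diabetic thinning fractions are
#' age-specific and calibrated so the expected wild-type global measures and
#' the expected diabetic percent differences match the reference cohort
#' values (IRT/ORT/TRT/OSL of 94/114/208/26 um at 12 weeks, 96/115/211/26 at
#' 24 weeks; thinning of about 2-4% of the inner and outer groups and none
#' of the outer segments). An explicit non-zero `spec$thinning_fraction`
#' overrides the per-age default.
#'
#' @param n_wt,n_diabetic number of wild-type / diabetic eyes (>= 1; 0 is
#'   allowed for single-condition cohorts).
#' @param spec baseline [phantom_spec()] shared by all eyes.
#' @param between_eye_sd named vector `c(inner, outer, osl)` of between-eye
#'   SDs in microns for the three layer-group offsets.
#' @param age_group `"12"` or `"24"` (weeks).
#' @param seed root seed; all per-eye randomness derives from it.
#' @param render render B-scan images (`FALSE` returns ground truth only).
#' @param left_fraction probability that an eye is a left eye.
#'
#' @return A list of class `phantom_cohort`: `eyes` (each with `volume`,
#'   `truth`, `metadata`), a combined `metadata` data frame, and the spec.
#' @export
generate_cohort <- function(n_wt, n_diabetic, spec = phantom_spec(),
                            between_eye_sd = c(inner = 4.4, outer = 2.5, osl = 2.0),
                            age_group = "12", seed = 1L, render = TRUE,
                            left_fraction = 14 / 44) {
  if (n_wt < 0 || n_diabetic < 0 || n_wt + n_diabetic < 1) {
    stop("generate_cohort: need at least one eye", call. = FALSE)
  }
  age_group <- as.character(age_group)
  base_scale <- age_baseline_scale(age_group)
  spec$layer_thicknesses[INNER_LAYERS] <-
    spec$layer_thicknesses[INNER_LAYERS] * base_scale[["inner"]]
  spec$layer_thicknesses[OUTER_LAYERS] <-
    spec$layer_thicknesses[OUTER_LAYERS] * base_scale[["outer"]]
  spec$layer_thicknesses[OSL_LAYERS] <-
    spec$layer_thicknesses[OSL_LAYERS] * base_scale[["osl"]]
  if (all(spec$thinning_fraction == 0)) {
    spec$thinning_fraction <- default_thinning(age_group)
  }

  conditions <- rep(c("wildtype", "diabetic"), c(n_wt, n_diabetic))
  n <- length(conditions)

  draws <- with_seed(seed, {
    list(
      offsets = matrix(rnorm(3 * n), n, 3) %*%
        diag(between_eye_sd[c("inner", "outer", "osl")]),
      left = rbinom(n, 1, left_fraction) == 1,
      glucose_wt = rnorm(n, mean = if (age_group == "12") 151 else 139, sd = 19),
      glucose_dia = (if (age_group == "12") 269 else 380) +
        rgamma(n, shape = 2, scale = 170),
      weight_wt = rnorm(n, mean = if (age_group == "12") 28 else 32, sd = 3),
      weight_dia = rnorm(n, mean = 24, sd = 2),
      eye_seeds = sample.int(.Machine$integer.max - 1L, n)
    )
  })

  eyes <- vector("list", n)
  meta_rows <- vector("list", n)
  for (i in seq_len(n)) {
    cond <- conditions[i]
    eye_spec <- spec
    eye_spec$seed <- draws$eye_seeds[i]
    off <- draws$offsets[i, ]
    names(off) <- c("inner", "outer", "osl")
    ph <- generate_phantom(eye_spec, cond, group_offsets = off,
                           render = render)
    laterality <- if (draws$left[i]) "left" else "right"
    disk_ascan <- spec$disk_center[2]
    if (laterality == "left") {
      ph <- mirror_eye(ph, spec$n_ascans)
      disk_ascan <- spec$n_ascans + 1 - disk_ascan
      if (!is.null(ph$volume)) ph$volume$metadata$laterality <- "left"
    }
    glucose_raw <- if (cond == "diabetic") draws$glucose_dia[i] else
      draws$glucose_wt[i]
    censored <- cond == "diabetic" && glucose_raw >= 600
    md <- data.frame(
      eye_id = sprintf("%s_%swk_%02d", substr(cond, 1, 2), age_group, i),
      condition = cond,
      age_group = age_group,
      laterality = laterality,
      glucose = if (censored) 600 else glucose_raw,
      glucose_censored = censored,
      body_weight = if (cond == "diabetic") draws$weight_dia[i] else
        draws$weight_wt[i],
      disk_bscan = spec$disk_center[1],
      disk_ascan = disk_ascan,
      disk_diameter = spec$disk_diameter,
      stringsAsFactors = FALSE
    )
    if (!is.null(ph$volume)) ph$volume$metadata$eye_id <- md$eye_id
    eyes[[i]] <- list(volume = ph$volume, truth = ph$truth, metadata = md)
    meta_rows[[i]] <- md
  }

  structure(list(
    eyes = eyes,
    metadata = do.call(rbind, meta_rows),
    spec = spec,
    age_group = age_group
  ), class = "phantom_cohort")
}

# Mirror an eye along the A-scan axis (left-eye acquisition geometry).
mirror_eye <- function(ph, n_ascans) {
  flip <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
  ph$truth$interfaces_um <- lapply(ph$truth$interfaces_um, flip)
  ph$truth$interfaces_px <- lapply(ph$truth$interfaces_px, flip)
  ph$truth$true_maps <- lapply(ph$truth$true_maps, flip)
  ph$truth$disk$center[2] <- n_ascans + 1 - ph$truth$disk$center[2]
  if (!is.null(ph$volume)) {
    ph$volume$bscans <- lapply(ph$volume$bscans, flip)
    ph$volume$metadata$disk_center[2] <-
      n_ascans + 1 - ph$volume$metadata$disk_center[2]
  }
  ph
}

#' @export
print.phantom_cohort <- function(x, ...) {
  tb <- table(x$metadata$condition)
  cat("<phantom_cohort> age ", x$age_group, " wk: ",
      paste(names(tb), tb, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
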