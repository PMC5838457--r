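#' Default run configuration for the synthetic end-to-end pipeline
#'
#' Returns the configuration the pipeline runs with unless overridden.
#' Cohort sizes default to the reference study design (12 weeks: 12
#' wild-type / 11 diabetic; 24 weeks: 10 / 11). The default lateral
#' sampling (256 A-scans) is a reduced raster for tractable run times; the
#' full 1536-A-scan geometry is supported by setting `n_ascans = 1536` and
#' `depth_px = 496`.
#'
#' @param n_bscans,n_ascans,depth_px raster geometry per eye.
#' @param axial_pitch axial pixel pitch, microns per pixel.
#' @param cohorts named list of `c(wt, diabetic)` eye counts per age group.
#' @param between_eye_sd between-eye layer-group SDs in microns, see
#'   [generate_cohort()].
#' @param speckle_level multiplicative speckle coefficient of variation.
#' @param sigma,w_min,guard segmentation parameters (anisotropic
#'   smoothing SDs, weight floor, guard band), see [segment_bscan()].
#' @param normative_mode `"per_age"` (default) builds one wild-type
#'   normative model per age group; `"pooled"` pools all wild-type eyes.
#' @param disk_shape optic-disk exclusion window shape, see
#'   [apply_disk_exclusion()].
#' @param seed root seed; all cohort and noise randomness derives from it.
#' @param out optional output directory.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(n_bscans = 31L, n_ascans = 256L,
                               depth_px = 160L, axial_pitch = 3.9,
                               cohorts = list(
                                 "12" = c(wt = 12L, diabetic = 11L),
                                 "24" = c(wt = 10L, diabetic = 11L)
                               ),
                               between_eye_sd = c(inner = 4.4, outer = 2.5,
                                                  osl = 2.0),
                               speckle_level = 0.30,
                               sigma = c(0.3, 1.5), w_min = 1e-5, guard = 2L,
                               normative_mode = c("per_age", "pooled"),
                               disk_shape = c("rect", "ellipse"),
                               seed = 1L, out = NULL) {
  structure(list(
    n_bscans = n_bscans, n_ascans = n_ascans, depth_px = depth_px,
    axial_pitch = axial_pitch, cohorts = cohorts,
    between_eye_sd = between_eye_sd, speckle_level = speckle_level,
    sigma = sigma, w_min = w_min, guard = guard,
    normative_mode = match.arg(normative_mode),
    disk_shape = match.arg(disk_shape),
    seed = as.integer(seed), out = out
  ), class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Executes phantom generation, four-interface segmentation, thickness
#' mapping with right-eye orientation and optic-disk exclusion, per-pixel
#' normative Z-score analysis of the diabetic eyes, and group statistics
#' (per-eye global means, percent differences, two-way condition x age
#' ANOVA, censored glucose rank-sum). Fully deterministic for a fixed
#' configuration and seed.
#'
#' @param config a [default_run_config()] (or a named list overriding it).
#' @param out_dir output directory for CSV results and a Markdown report;
#'   `NULL` (default) writes nothing.
#' @param quiet suppress progress messages.
#' @return A list of class `retlayer_run` with elements `records` (per-eye
#'   data), `fractions` (per-eye Z-score area fractions), `summary` (cohort
#'   fraction summary), `anova` (p-values per measure), `percent_diff`,
#'   `glucose`, `normative`, and `config`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = config$out,
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  ages <- names(config$cohorts)
  cohort_seeds <- derive_seeds(config$seed, length(ages))

  records <- list()
  wt_maps <- stats::setNames(vector("list", length(ages)), ages)
  dia_maps <- stats::setNames(vector("list", length(ages)), ages)
  glucose_tests <- list()

  for (ai in seq_along(ages)) {
    age <- ages[ai]
    sizes <- config$cohorts[[age]]
    say("retlayer: generating and segmenting ", age, "-week cohort (",
        sizes[["wt"]], " WT + ", sizes[["diabetic"]], " diabetic eyes)")
    spec <- phantom_spec(
      n_bscans = config$n_bscans, n_ascans = config$n_ascans,
      depth_px = config$depth_px, axial_pitch = config$axial_pitch,
      speckle_level = config$speckle_level
    )
    cohort <- generate_cohort(
      sizes[["wt"]], sizes[["diabetic"]], spec = spec,
      between_eye_sd = config$between_eye_sd, age_group = age,
      seed = cohort_seeds[ai]
    )
    for (eye in cohort$eyes) {
      segs <- segment_volume(eye$volume, sigma = config$sigma,
                             w_min = config$w_min, guard = config$guard)
      maps <- build_maps(segs, axial_pitch = config$axial_pitch,
                         laterality = eye$metadata$laterality,
                         disk_center = c(eye$metadata$disk_bscan,
                                         eye$metadata$disk_ascan),
                         disk_diameter = eye$metadata$disk_diameter)
      maps <- orient_right(maps)
      maps <- apply_disk_exclusion(maps, shape = config$disk_shape)
      gm <- global_mean(maps)
      rec <- cbind(eye$metadata,
                   as.data.frame(as.list(gm), stringsAsFactors = FALSE))
      records[[length(records) + 1L]] <- rec
      if (eye$metadata$condition == "wildtype") {
        wt_maps[[age]] <- c(wt_maps[[age]], list(maps))
      } else {
        dia_maps[[age]] <- c(dia_maps[[age]],
                             stats::setNames(list(maps),
                                             eye$metadata$eye_id))
      }
    }
    md <- cohort$metadata
    glucose_tests[[age]] <- rank_sum_censored(
      md$glucose[md$condition == "diabetic"],
      md$glucose[md$condition == "wildtype"]
    )
  }
  records <- do.call(rbind, records)

  # normative models and diabetic Z-score area fractions
  say("retlayer: building normative models (", config$normative_mode,
      ") and Z-score summaries")
  models <- if (config$normative_mode == "pooled") {
    pooled <- build_normative(unlist(wt_maps, recursive = FALSE))
    stats::setNames(rep(list(pooled), length(ages)), ages)
  } else {
    lapply(wt_maps, build_normative)
  }
  fractions <- list()
  for (age in ages) {
    for (eye_id in names(dia_maps[[age]])) {
      zm <- zscore_map(dia_maps[[age]][[eye_id]], models[[age]])
      for (m in MEASURES) {
        fr <- area_fractions(zm, measure = m)
        fractions[[length(fractions) + 1L]] <- data.frame(
          eye_id = eye_id, age_group = age, measure = m,
          below = fr[["below"]], within = fr[["within"]],
          above = fr[["above"]], stringsAsFactors = FALSE
        )
      }
    }
  }
  fractions <- do.call(rbind, fractions)
  summary <- cohort_fraction_summary(fractions)

  # group statistics
  anova_p <- t(vapply(MEASURES, function(m) two_way_anova(records, m),
                      numeric(3)))
  anova_p <- data.frame(measure = MEASURES, anova_p,
                        stringsAsFactors = FALSE, row.names = NULL)

  pd <- do.call(rbind, lapply(ages, function(age) {
    d <- records[records$age_group == age, ]
    do.call(rbind, lapply(MEASURES, function(m) {
      a <- mean(d[[m]][d$condition == "diabetic"])
      b <- mean(d[[m]][d$condition == "wildtype"])
      data.frame(age_group = age, measure = m,
                 diabetic_mean = a, wildtype_mean = b,
                 percent_difference = percent_difference(a, b),
                 stringsAsFactors = FALSE)
    }))
  }))

  run <- structure(list(
    records = records, fractions = fractions, summary = summary,
    anova = anova_p, percent_diff = pd,
    glucose = lapply(glucose_tests, function(t) t$p.value),
    normative = models, config = config
  ), class = "retlayer_run")

  if (!is.null(out_dir)) {
    write_run(run, out_dir)
    say("retlayer: results written to ", out_dir)
  }
  run
}

#' @export
print.retlayer_run <- function(x, ...) {
  cat("<retlayer_run> ", nrow(x$records), " eyes, seed ", x$config$seed,
      "\n", sep = "")
  cat("  ANOVA condition p:",
      paste(sprintf("%s=%.3g", x$anova$measure, x$anova$condition),
            collapse = ", "), "\n")
  cat("  reduced - increased area (%):",
      paste(sprintf("%s=%.1f", x$summary$measure,
                    x$summary$reduced_minus_increased), collapse = ", "),
      "\n")
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write.csv(run$records, fp("eyes.csv"), row.names = FALSE)
  write.csv(run$fractions, fp("area_fractions.csv"), row.names = FALSE)
  write.csv(run$summary, fp("cohort_summary.csv"), row.names = FALSE)
  write.csv(run$anova, fp("anova.csv"), row.names = FALSE)
  write.csv(run$percent_diff, fp("percent_differences.csv"),
            row.names = FALSE)
  cfg <- unclass(run$config)
  cfg$checksum <- config_checksum(run$config)
  jsonlite::write_json(cfg, fp("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(run_report(run), fp("report.md"))
  invisible(out_dir)
}

# polynomial rolling checksum of the serialised configuration (not
# cryptographic; identifies a run's settings in the output directory)
config_checksum <- function(config) {
  cfg <- unclass(config)
  txt <- paste(deparse(cfg[sort(names(cfg))]), collapse = "")
  h <- 17
  for (v in utf8ToInt(txt)) {
    h <- (h * 31 + v) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

run_report <- function(run) {
  fmt <- function(x, d = 2) formatC(x, format = "f", digits = d)
  lines <- c(
    "# retlayer synthetic cohort report",
    "",
    sprintf("Seed %d; %d eyes; %d x %d grid.", run$config$seed,
            nrow(run$records), run$config$n_bscans, run$config$n_ascans),
    "",
    "## Blood glucose (mg/dL)",
    "",
    "| Age (wk) | Diabetic | Wild-type | p (rank-sum) |",
    "|---|---|---|---|"
  )
  for (age in unique(run$records$age_group)) {
    d <- run$records[run$records$age_group == age, ]
    gd <- d$glucose[d$condition == "diabetic"]
    gw <- d$glucose[d$condition == "wildtype"]
    cens <- any(d$glucose_censored)
    lines <- c(lines, sprintf(
      "| %s | %s%s | %s +/- %s | %s |",
      age, if (cens) ">=" else "", fmt(stats::median(gd), 0),
      fmt(mean(gw), 0), fmt(sd(gw), 0),
      format.pval(run$glucose[[age]], digits = 2, eps = 0.001)
    ))
  }
  lines <- c(lines, "",
             "## Thickness (um)",
             "",
             "| Measure | Age (wk) | Diabetic | Wild-type | % difference | p condition | p age | p interaction |",
             "|---|---|---|---|---|---|---|---|")
  for (m in MEASURES) {
    ap <- run$anova[run$anova$measure == m, ]
    for (age in unique(run$percent_diff$age_group)) {
      pdrow <- run$percent_diff[run$percent_diff$measure == m &
                                  run$percent_diff$age_group == age, ]
      d <- run$records[run$records$age_group == age, ]
      lines <- c(lines, sprintf(
        "| %s | %s | %s +/- %s | %s +/- %s | %s | %s | %s | %s |",
        toupper(m), age,
        fmt(pdrow$diabetic_mean, 0),
        fmt(sd(d[[m]][d$condition == "diabetic"]), 0),
        fmt(pdrow$wildtype_mean, 0),
        fmt(sd(d[[m]][d$condition == "wildtype"]), 0),
        fmt(pdrow$percent_difference),
        fmt(ap$condition, 3), fmt(ap$age, 3), fmt(ap$interaction, 3)
      ))
    }
  }
  lines <- c(lines, "",
             "## Diabetic Z-score area fractions (% of retinal area)",
             "",
             "| Measure | Z < -1 | -1..1 | Z > 1 | reduced - increased |",
             "|---|---|---|---|---|")
  for (i in seq_len(nrow(run$summary))) {
    s <- run$summary[i, ]
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s | %s |", toupper(s$measure), fmt(s$below, 1),
      fmt(s$within, 1), fmt(s$above, 1), fmt(s$reduced_minus_increased, 1)
    ))
  }
  lines
}

#' Simulated per-eye global means from phantom geometry
#'
#' Fast statistical-simulation path: draws a cohort at one age group,
#' computes each eye's global thickness means directly from the exact
#' ground-truth maps (after right-eye orientation and optic-disk
#' exclusion), and returns the per-eye record table. Used for power and
#' calibration studies where the segmentation stage is not under test.
#'
#' @inheritParams generate_cohort
#' @return Data frame of per-eye records with global `irt`, `ort`, `trt`,
#'   `osl` means in microns.
#' @export
simulate_global_means <- function(n_wt, n_diabetic, spec = phantom_spec(),
                                  between_eye_sd = c(inner = 4.4,
                                                     outer = 2.5,
                                                     osl = 2.0),
                                  age_group = "12", seed = 1L) {
  cohort <- generate_cohort(n_wt, n_diabetic, spec = spec,
                            between_eye_sd = between_eye_sd,
                            age_group = age_group, seed = seed,
                            render = FALSE)
  do.call(rbind, lapply(cohort$eyes, function(eye) {
    maps <- ground_truth_maps(eye$truth,
                              laterality = eye$metadata$laterality)
    maps <- orient_right(maps)
    maps <- apply_disk_exclusion(maps)
    cbind(eye$metadata,
          as.data.frame(as.list(global_mean(maps)),
                        stringsAsFactors = FALSE))
  }))
}
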