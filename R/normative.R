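#' Per-pixel normative model from a wild-type cohort
#'
#' Computes, at every grid location and for each thickness measure, the
#' sample mean and sample standard deviation (denominator `n - 1`) across
#' the wild-type eyes, restricted to pixels valid in every contributing eye.
#' Pixels with zero SD are flagged: Z-scores are undefined there.
#'
#' @param wt_maps list of `thickness_maps` (>= 2 eyes, identical grids),
#'   typically oriented and disk-excluded.
#' @return Object of class `normative_model`: `mean` and `sd` (named lists
#'   of micron matrices per measure), `n_eyes`, and the joint validity mask
#'   `valid`.
#' @export
build_normative <- function(wt_maps) {
  n <- length(wt_maps)
  if (n < 2) {
    stop("build_normative: need at least 2 wild-type eyes", call. = FALSE)
  }
  dims <- lapply(wt_maps, function(m) c(m$n_bscans, m$n_ascans))
  if (length(unique(dims)) != 1) {
    stop("build_normative: grid shapes differ between eyes", call. = FALSE)
  }
  valid <- Reduce(`&`, lapply(wt_maps, `[[`, "valid"))
  mean_maps <- list()
  sd_maps <- list()
  for (m in MEASURES) {
    s <- 0
    s2 <- 0
    for (eye in wt_maps) {
      s <- s + eye$maps[[m]]
      s2 <- s2 + eye$maps[[m]]^2
    }
    mu <- s / n
    v <- pmax((s2 - n * mu^2) / (n - 1), 0)
    mean_maps[[m]] <- mu
    sd_maps[[m]] <- sqrt(v)
  }
  structure(list(
    mean = mean_maps, sd = sd_maps, n_eyes = n, valid = valid,
    n_bscans = wt_maps[[1]]$n_bscans, n_ascans = wt_maps[[1]]$n_ascans,
    axial_pitch = wt_maps[[1]]$axial_pitch
  ), class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat("<normative_model> ", x$n_eyes, " wild-type eyes, ",
      sum(x$valid), " jointly valid px\n", sep = "")
  for (m in MEASURES) {
    cat(sprintf("  %-3s mean %6.1f um, median SD %4.2f um\n", toupper(m),
                mean(x$mean[[m]][x$valid]),
                stats::median(x$sd[[m]][x$valid])))
  }
  invisible(x)
}

#' Per-pixel Z-score maps against a normative model
#'
#' Assigns `Z = (value - mean) / SD` at every pixel valid both in the eye
#' and in the model; pixels where the normative SD is zero are excluded
#' from the validity mask rather than given infinite scores.
#'
#' @param maps a `thickness_maps` object for the eye under test.
#' @param model a [build_normative()] model on the same grid.
#' @return Object of class `zscore_maps`: `z` (named list of matrices with
#'   `NA` at invalid pixels) and `valid` (named list of masks per measure).
#' @export
zscore_map <- function(maps, model) {
  stopifnot(inherits(maps, "thickness_maps"),
            inherits(model, "normative_model"))
  if (maps$n_bscans != model$n_bscans || maps$n_ascans != model$n_ascans) {
    stop("zscore_map: grid shapes differ", call. = FALSE)
  }
  z <- list()
  valid <- list()
  any_valid <- FALSE
  for (m in MEASURES) {
    ok <- maps$valid & model$valid & model$sd[[m]] > 0
    zm <- matrix(NA_real_, maps$n_bscans, maps$n_ascans)
    zm[ok] <- (maps$maps[[m]][ok] - model$mean[[m]][ok]) / model$sd[[m]][ok]
    z[[m]] <- zm
    valid[[m]] <- ok
    any_valid <- any_valid || any(ok)
  }
  if (!any_valid) {
    stop("zscore_map: no valid pixels for any measure", call. = FALSE)
  }
  structure(list(z = z, valid = valid), class = "zscore_maps")
}

#' Retinal area fractions by Z-score bin
#'
#' Percentage of valid retinal area with `Z < -1` (reduced thickness),
#' `-1 <= Z <= 1` (within 1 SD; boundary values fall in this closed middle
#' bin), and `Z > 1` (increased thickness). The three fractions sum to 100
#' before rounding.
#'
#' @param z numeric matrix (or vector) of Z-scores, or a `zscore_maps`
#'   object (then `measure` selects the map).
#' @param valid optional logical mask; defaults to non-`NA` entries.
#' @param measure measure name when `z` is a `zscore_maps` object.
#' @return Named vector `c(below, within, above)` in percent.
#' @export
area_fractions <- function(z, valid = NULL, measure = NULL) {
  if (inherits(z, "zscore_maps")) {
    stopifnot(!is.null(measure))
    valid <- z$valid[[measure]]
    z <- z$z[[measure]]
  }
  if (is.null(valid)) valid <- !is.na(z)
  v <- z[valid]
  v <- v[!is.na(v)]
  if (!length(v)) {
    stop("area_fractions: zero valid pixels", call. = FALSE)
  }
  below <- 100 * mean(v < -1)
  above <- 100 * mean(v > 1)
  c(below = below, within = 100 - below - above, above = above)
}

#' Cohort summary of per-eye area fractions
#'
#' Averages the per-eye below/within/above fractions over all eyes, per
#' measure, and reports the difference between the mean reduced and mean
#' increased area percentages (`reduced_minus_increased`), the headline
#' local-thinning statistic.
#'
#' @param fractions data frame with columns `eye_id`, `measure`, `below`,
#'   `within`, `above` (one row per eye and measure).
#' @return Data frame with one row per measure: mean fractions and
#'   `reduced_minus_increased = mean(below) - mean(above)`.
#' @export
cohort_fraction_summary <- function(fractions) {
  fractions <- as.data.frame(fractions)
  if (!nrow(fractions)) {
    stop("cohort_fraction_summary: empty fraction table", call. = FALSE)
  }
  need <- c("measure", "below", "within", "above")
  if (!all(need %in% names(fractions))) {
    stop("cohort_fraction_summary: need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(fractions, fractions$measure),
                               function(d) {
    data.frame(
      measure = d$measure[1],
      n_eyes = nrow(d),
      below = mean(d$below),
      within = mean(d$within),
      above = mean(d$above),
      reduced_minus_increased = mean(d$below) - mean(d$above),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  # keep canonical measure order when present
  ord <- order(match(out$measure, MEASURES, nomatch = length(MEASURES) + 1L))
  out[ord, , drop = FALSE]
}
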