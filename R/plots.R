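#' Heatmap of one thickness map
#'
#' Renders a micron-scaled heatmap of a thickness measure on the
#' B-scan x A-scan grid; excluded (invalid) pixels are blanked.
#'
#' @param maps a `thickness_maps` object.
#' @param measure one of `"irt"`, `"ort"`, `"trt"`, `"osl"`.
#' @return A ggplot object.
#' @export
plot_thickness_map <- function(maps, measure = "trt") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_thickness_map requires ggplot2", call. = FALSE)
  }
  measure <- match.arg(measure, MEASURES)
  m <- maps$maps[[measure]]
  m[!maps$valid] <- NA
  d <- expand.grid(bscan = seq_len(nrow(m)), ascan = seq_len(ncol(m)))
  d$um <- as.vector(m)
  ggplot2::ggplot(d, ggplot2::aes(x = ascan, y = bscan, fill = um)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "µm", na.value = "grey85") +
    ggplot2::labs(title = toupper(measure), x = "A-scan", y = "B-scan") +
    ggplot2::theme_minimal()
}

#' Bar plot of cohort Z-score area fractions
#'
#' Mirrors the usual presentation of the local-deviation analysis: for each
#' measure, the cohort-mean percentage of retinal area with Z below -1,
#' within 1 SD, and above 1.
#'
#' @param summary output of [cohort_fraction_summary()].
#' @return A ggplot object.
#' @export
plot_area_fractions <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_area_fractions requires ggplot2", call. = FALSE)
  }
  d <- do.call(rbind, lapply(seq_len(nrow(summary)), function(i) {
    data.frame(measure = toupper(summary$measure[i]),
               bin = factor(c("Z < -1", "-1 ≤ Z ≤ 1", "Z > 1"),
                            levels = c("Z < -1", "-1 ≤ Z ≤ 1",
                                       "Z > 1")),
               pct = c(summary$below[i], summary$within[i],
                       summary$above[i]))
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = measure, y = pct, fill = bin)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of retinal area", fill = NULL) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("ascan", "bscan", "um", "measure", "bin", "pct"))
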