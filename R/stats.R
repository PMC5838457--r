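#' Global thickness means for one eye
#'
#' Arithmetic mean of each thickness map over its valid pixels.
#'
#' @param maps a `thickness_maps` object.
#' @return Named vector of means in microns (`irt`, `ort`, `trt`, `osl`).
#' @export
global_mean <- function(maps) {
  stopifnot(inherits(maps, "thickness_maps"))
  if (!any(maps$valid)) {
    stop("global_mean: no valid pixels", call. = FALSE)
  }
  vapply(maps$maps, function(m) mean(m[maps$valid]), numeric(1))
}

#' Percent difference relative to a reference group
#'
#' `100 * (a - b) / b`, with `b` the (wild-type) reference mean. Reported
#' values are conventionally rounded to two decimals.
#'
#' @param a group mean (e.g. diabetic).
#' @param b reference group mean (non-zero).
#' @return Percent difference (full precision; round for display).
#' @export
percent_difference <- function(a, b) {
  if (any(b == 0)) {
    stop("percent_difference: zero reference mean", call. = FALSE)
  }
  100 * (a - b) / b
}

#' Two-way fixed-effects ANOVA for condition and age
#'
#' Evaluates the effects of condition (diabetic vs wild-type) and age group
#' (12 vs 24 weeks) and their interaction on a per-eye response, using Type
#' II sums of squares so unbalanced cell sizes are handled symmetrically.
#'
#' @param records data frame of per-eye records with columns `condition`,
#'   `age_group`, and the response.
#' @param response name of the response column (e.g. `"trt"` or
#'   `"body_weight"`).
#' @return Named vector of p-values: `condition`, `age`, `interaction`.
#' @export
two_way_anova <- function(records, response) {
  records <- as.data.frame(records)
  if (!all(c("condition", "age_group", response) %in% names(records))) {
    stop("two_way_anova: records must contain condition, age_group, ",
         response, call. = FALSE)
  }
  records$condition <- factor(records$condition)
  records$age_group <- factor(records$age_group)
  cells <- table(records$condition, records$age_group)
  if (length(cells) < 4 || any(cells < 2)) {
    stop("two_way_anova: every condition x age cell needs >= 2 records",
         call. = FALSE)
  }
  fml <- stats::reformulate("condition * age_group", response = response)
  fit <- stats::lm(fml, data = records)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((records[[response]] - mean(records[[response]]))^2)
  if (tss == 0 || rss < 1e-12 * max(tss, 1)) {
    stop("two_way_anova: residual variance is zero (degenerate response)",
         call. = FALSE)
  }
  tab <- car::Anova(fit, type = 2)
  p <- tab[["Pr(>F)"]]
  names(p) <- rownames(tab)
  c(condition = unname(p["condition"]),
    age = unname(p["age_group"]),
    interaction = unname(p["condition:age_group"]))
}

#' Mann-Whitney rank-sum test with ceiling censoring
#'
#' Compares two samples after recording every value at or above the
#' measurement ceiling (glucometer maximum, 600 mg/dL) as the ceiling value
#' itself. Ties are mid-ranked. For small samples (both sizes <= 8) the
#' two-sided p-value is computed by exact enumeration of all group
#' assignments of the observed (mid)ranks; otherwise the tie-corrected
#' normal approximation is used. If every observation is tied the two-sided
#' p-value is 1.
#'
#' @param x first sample (e.g. diabetic glucose), numeric.
#' @param y second sample (e.g. wild-type glucose), numeric.
#' @param ceiling measurement ceiling; values above it are censored to it.
#'   Use `Inf` for no censoring.
#' @param exact_max_n per-group size limit for exact enumeration.
#' @return List of class `htest` with `statistic` (U for sample `x`),
#'   `p.value` and `method`.
#' @export
rank_sum_censored <- function(x, y, ceiling = 600, exact_max_n = 8L) {
  if (!length(x) || !length(y)) {
    stop("rank_sum_censored: both groups must be non-empty", call. = FALSE)
  }
  x <- pmin(x, ceiling)
  y <- pmin(y, ceiling)
  n1 <- length(x)
  n2 <- length(y)
  nn <- n1 + n2
  rk <- rank(c(x, y)) # midranks
  w_obs <- sum(rk[seq_len(n1)])
  u_obs <- w_obs - n1 * (n1 + 1) / 2

  if (n1 <= exact_max_n && n2 <= exact_max_n) {
    combos <- utils::combn(nn, n1)
    w_all <- colSums(matrix(rk[combos], nrow = n1))
    eps <- 1e-8
    p <- min(1, 2 * min(mean(w_all <= w_obs + eps),
                        mean(w_all >= w_obs - eps)))
    method <- "Mann-Whitney rank-sum, exact enumeration (censored)"
  } else {
    ties <- table(rk)
    sigma2 <- n1 * n2 / 12 *
      ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - n1 * n2 / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "Mann-Whitney rank-sum, normal approximation with tie correction (censored)"
  }
  structure(list(
    statistic = c(U = u_obs), p.value = p, method = method,
    data.name = "x vs y",
    censored = c(sum(x >= ceiling), sum(y >= ceiling))
  ), class = "htest")
}

#' Pairwise two-sample t-tests within a factor
#'
#' Post-hoc style contrasts (e.g. body weight between ages within each
#' condition), reported without multiplicity correction.
#'
#' @param records per-eye data frame.
#' @param response response column name.
#' @param by factor column defining the two groups to compare.
#' @param within optional factor column; the comparison is repeated within
#'   each of its levels.
#' @return Data frame of group pairs and p-values.
#' @export
pairwise_group_t <- function(records, response, by, within = NULL) {
  records <- as.data.frame(records)
  strata <- if (is.null(within)) list(all = records) else
    split(records, records[[within]])
  out <- lapply(names(strata), function(s) {
    d <- strata[[s]]
    lv <- unique(d[[by]])
    if (length(lv) != 2) return(NULL)
    tt <- stats::t.test(d[[response]][d[[by]] == lv[1]],
                        d[[response]][d[[by]] == lv[2]])
    data.frame(stratum = s, group_a = lv[1], group_b = lv[2],
               mean_a = mean(d[[response]][d[[by]] == lv[1]]),
               mean_b = mean(d[[response]][d[[by]] == lv[2]]),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
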