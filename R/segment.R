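#' Segment the four retinal interfaces in one B-scan
#'
#' Detects the vitreous/ILM, INL/OPL, ONL/ISe and OS/RPE interfaces as
#' minimum-weight graph paths, in the fixed order that makes each stage's
#' search region well defined:
#' \enumerate{
#'   \item vitreous/ILM on the full image (the largest dark-to-bright
#'     gradient, hence the lowest-weight path);
#'   \item OS/RPE restricted to the region below the ILM path;
#'   \item INL/OPL restricted to between the ILM and OS/RPE paths;
#'   \item ONL/ISe restricted to between the INL/OPL and OS/RPE paths.
#' }
#' A guard band of `guard` pixels is excluded on the bounding side(s) of
#' each restricted region so a stage cannot re-detect the gradient ridge of
#' an already-found interface.
#'
#' @param bscan numeric matrix (depth x A-scans), at least 20 pixels deep.
#' @param sigma Gaussian pre-smoothing SDs `c(vertical, lateral)` in
#'   pixels, see [build_weight_graph()].
#' @param w_min edge-weight floor, see [build_weight_graph()].
#' @param guard guard band in pixels between a bounding path and the next
#'   stage's search region.
#' @return An object of class `interface_set` with the four
#'   `interface_path`s (`ilm`, `inl_opl`, `onl_ise`, `os_rpe`), strictly
#'   ordered in depth at every column.
#' @export
segment_bscan <- function(bscan, sigma = c(0.3, 1.5), w_min = 1e-5,
                          guard = 2L) {
  if (!is.matrix(bscan) || nrow(bscan) < 20) {
    stop("segment_bscan: image must be a matrix at least 20 px deep",
         call. = FALSE)
  }
  bad <- which(colSums(is.finite(bscan)) == 0)
  if (length(bad)) {
    stop("segment_bscan: all-NaN column(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(bscan))) {
    stop("segment_bscan: image contains non-finite values", call. = FALSE)
  }

  scores <- gradient_scores(bscan, sigma)
  nr <- nrow(scores)
  nc <- ncol(scores)
  row_mat <- matrix(seq_len(nr), nr, nc)
  stage <- function(name, region) {
    g <- tryCatch(
      weight_graph(scores, region = region, w_min = w_min),
      retlayer_infeasible_region = function(e) segmentation_error(name, e)
    )
    tryCatch(
      shortest_path(g, interface = name),
      retlayer_infeasible_region = function(e) segmentation_error(name, e)
    )
  }
  above <- function(path) {
    row_mat > matrix(path$rows + guard, nr, nc, byrow = TRUE)
  }
  below <- function(path) {
    row_mat < matrix(path$rows - guard, nr, nc, byrow = TRUE)
  }

  ilm <- stage("ilm", NULL)
  os_rpe <- stage("os_rpe", above(ilm))
  inl_opl <- stage("inl_opl", above(ilm) & below(os_rpe))
  onl_ise <- stage("onl_ise", above(inl_opl) & below(os_rpe))

  interface_set(ilm, inl_opl, onl_ise, os_rpe)
}

segmentation_error <- function(stage, parent = NULL) {
  stop(structure(class = c("retlayer_segmentation_error", "error",
                           "condition"),
                 list(message = paste0(
                   "segmentation failed at stage '", stage, "': ",
                   if (is.null(parent)) "infeasible region" else
                     conditionMessage(parent)),
                   call = NULL, stage = stage)))
}

#' Interface set for one B-scan
#'
#' Bundles the four detected interfaces and validates the strict depth
#' ordering ILM < INL/OPL < ONL/ISe < OS/RPE at every column. Inputs may be
#' `interface_path` objects or plain row vectors (coerced; the per-column
#' slope limit is only enforced for genuine paths, so synthetic ordered row
#' sets can be constructed for thickness computations).
#'
#' @param ilm,inl_opl,onl_ise,os_rpe the four interfaces, top to bottom.
#' @return An object of class `interface_set`.
#' @export
interface_set <- function(ilm, inl_opl, onl_ise, os_rpe) {
  as_rows <- function(x, name) {
    if (inherits(x, "interface_path")) x$rows else as.integer(x)
  }
  paths <- list(
    ilm = ilm, inl_opl = inl_opl, onl_ise = onl_ise, os_rpe = os_rpe
  )
  rows <- Map(as_rows, paths, names(paths))
  n <- unique(lengths(rows))
  if (length(n) != 1) {
    stop("interface_set: interfaces have differing lengths", call. = FALSE)
  }
  for (i in 1:3) {
    if (any(rows[[i]] >= rows[[i + 1]])) {
      stop(structure(class = c("retlayer_ordering_error", "error",
                               "condition"),
                     list(message = paste0(
                       "interface_set: ordering violated between ",
                       names(rows)[i], " and ", names(rows)[i + 1]),
                       call = NULL)))
    }
  }
  paths <- Map(function(p, nm) {
    if (inherits(p, "interface_path")) p else interface_path_raw(p, nm)
  }, paths, names(paths))
  structure(list(paths = paths, n_ascans = n), class = "interface_set")
}

# wrap plain row vectors without the slope check
interface_path_raw <- function(rows, interface) {
  structure(list(rows = as.integer(rows), interface = interface,
                 cost = NA_real_), class = "interface_path")
}

#' @export
print.interface_set <- function(x, ...) {
  cat("<interface_set> 4 interfaces over ", x$n_ascans, " A-scans\n",
      sep = "")
  for (p in x$paths) {
    cat(sprintf("  %-8s rows %d-%d\n", p$interface, min(p$rows),
                max(p$rows)))
  }
  invisible(x)
}

#' Rows of one interface in an interface set
#' @param ifc an `interface_set`.
#' @param which interface name (`ilm`, `inl_opl`, `onl_ise`, `os_rpe`).
#' @return Integer vector of 1-based row indices per A-scan.
#' @export
interface_rows <- function(ifc, which) {
  stopifnot(inherits(ifc, "interface_set"))
  ifc$paths[[match.arg(which, names(ifc$paths))]]$rows
}

#' Operator-style constrained re-cut of a detected interface
#'
#' Emulates manual correction: the operator draws a polyline through the
#' intended interface; the graph search region is restricted to a narrow
#' vertical band around the (linearly interpolated) correction over the
#' corrected column span, and to a band of the same half-width around the
#' current path elsewhere, then the minimum-weight path is recomputed.
#'
#' @param bscan the B-scan the interface was detected in.
#' @param path the current `interface_path` (or an `interface_set` plus
#'   `which`).
#' @param correction two-column matrix or data frame of `(column, row)`
#'   polyline points spanning at least two distinct columns.
#' @param band_halfwidth half-width in pixels of the admissible band
#'   (>= 1).
#' @param which interface name when `path` is an `interface_set`.
#' @param sigma,w_min as in [segment_bscan()].
#' @param neighbors optional list with `above` and/or `below` row vectors
#'   (neighbouring interfaces); ordering against them is re-validated and an
#'   ordering error is raised when the corrected path violates it.
#' @return The revised `interface_path`.
#' @export
refine_interface <- function(bscan, path, correction, band_halfwidth = 5L,
                             which = NULL, sigma = c(0.3, 1.5),
                             w_min = 1e-5, neighbors = NULL) {
  if (inherits(path, "interface_set")) {
    stopifnot(!is.null(which))
    path <- path$paths[[which]]
  }
  stopifnot(inherits(path, "interface_path"))
  correction <- as.matrix(correction)
  if (nrow(correction) < 2 || length(unique(correction[, 1])) < 2) {
    stop("refine_interface: correction must span >= 2 columns",
         call. = FALSE)
  }
  if (band_halfwidth < 1) {
    stop("refine_interface: band_halfwidth must be >= 1", call. = FALSE)
  }
  nr <- nrow(bscan)
  nc <- ncol(bscan)
  target <- as.numeric(path$rows)
  span <- seq(max(1L, ceiling(min(correction[, 1]))),
              min(nc, floor(max(correction[, 1]))))
  target[span] <- stats::approx(correction[, 1], correction[, 2],
                                xout = span, rule = 2)$y

  row_mat <- matrix(seq_len(nr), nr, nc)
  region <- abs(row_mat - matrix(target, nr, nc, byrow = TRUE)) <=
    band_halfwidth
  scores <- gradient_scores(bscan, sigma)
  revised <- shortest_path(weight_graph(scores, region, w_min),
                           interface = path$interface)

  if (!is.null(neighbors)) {
    if (!is.null(neighbors$above) && any(revised$rows <= neighbors$above)) {
      stop(structure(class = c("retlayer_ordering_error", "error",
                               "condition"),
                     list(message = "refine_interface: revised path crosses the interface above",
                          call = NULL)))
    }
    if (!is.null(neighbors$below) && any(revised$rows >= neighbors$below)) {
      stop(structure(class = c("retlayer_ordering_error", "error",
                               "condition"),
                     list(message = "refine_interface: revised path crosses the interface below",
                          call = NULL)))
    }
  }
  revised
}

#' Segment every B-scan of a volume
#'
#' @param volume a `bscan_volume`.
#' @inheritParams segment_bscan
#' @return List of `interface_set`, one per B-scan.
#' @export
segment_volume <- function(volume, sigma = c(0.3, 1.5), w_min = 1e-5,
                           guard = 2L) {
  stopifnot(inherits(volume, "bscan_volume"))
  lapply(seq_along(volume$bscans), function(b) {
    tryCatch(
      segment_bscan(volume$bscans[[b]], sigma = sigma, w_min = w_min,
                    guard = guard),
      error = function(e) {
        stop("segment_volume: B-scan ", b, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
  })
}
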