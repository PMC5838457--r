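#' Per-column thickness measures from an interface set
#'
#' Converts interface row positions into the four thickness measures in
#' microns, using the shared-boundary definitions: IRT is the depth
#' separation vitreous/ILM to INL/OPL, ORT is INL/OPL to OS/RPE, TRT is
#' vitreous/ILM to OS/RPE (so TRT = IRT + ORT exactly), and OSL is ONL/ISe
#' to OS/RPE.
#'
#' @param ifc an [interface_set()].
#' @param axial_pitch axial pixel pitch in microns per pixel.
#' @return Data frame with columns `ascan`, `irt`, `ort`, `trt`, `osl`
#'   (microns).
#' @export
compute_thickness <- function(ifc, axial_pitch = 3.9) {
  stopifnot(inherits(ifc, "interface_set"))
  r1 <- ifc$paths$ilm$rows
  r2 <- ifc$paths$inl_opl$rows
  r3 <- ifc$paths$onl_ise$rows
  r4 <- ifc$paths$os_rpe$rows
  irt <- (r2 - r1) * axial_pitch
  ort <- (r4 - r2) * axial_pitch
  data.frame(
    ascan = seq_along(r1),
    irt = irt,
    ort = ort,
    trt = irt + ort, # telescoping sum: exact at machine precision
    osl = (r4 - r3) * axial_pitch
  )
}

#' Thickness maps for one eye
#'
#' Compiles per-B-scan thickness into 2-D maps on the native
#' (B-scan x A-scan) raster grid; no interpolation between B-scans is
#' performed. All pixels start valid; [apply_disk_exclusion()] flags the
#' optic-disk neighbourhood.
#'
#' @param segmentations list of [interface_set()]s, one per B-scan, in
#'   raster order.
#' @param axial_pitch axial pixel pitch, microns per pixel.
#' @param laterality `"left"` or `"right"`.
#' @param disk_center optional optic-disk centre `c(bscan, ascan)` carried
#'   for later exclusion.
#' @param disk_diameter optional disk diameter in grid units.
#' @return Object of class `thickness_maps`: `maps` (named list of
#'   `n_bscans x n_ascans` micron matrices `irt`, `ort`, `trt`, `osl`),
#'   `valid` (logical matrix), pitch and laterality metadata.
#' @export
build_maps <- function(segmentations, axial_pitch = 3.9,
                       laterality = "right", disk_center = NULL,
                       disk_diameter = NULL) {
  missing_idx <- which(vapply(segmentations, function(s) {
    is.null(s) || !inherits(s, "interface_set")
  }, logical(1)))
  if (length(missing_idx)) {
    stop("build_maps: missing segmentation for B-scan(s) ",
         paste(missing_idx, collapse = ", "), call. = FALSE)
  }
  th <- lapply(segmentations, compute_thickness, axial_pitch = axial_pitch)
  nb <- length(th)
  na <- nrow(th[[1]])
  maps <- lapply(MEASURES, function(m) {
    do.call(rbind, lapply(th, `[[`, m))
  })
  names(maps) <- MEASURES
  structure(list(
    maps = maps,
    valid = matrix(TRUE, nb, na),
    axial_pitch = axial_pitch,
    laterality = match.arg(laterality, c("left", "right")),
    oriented = FALSE,
    disk = list(center = disk_center, diameter = disk_diameter),
    n_bscans = nb,
    n_ascans = na
  ), class = "thickness_maps")
}

#' Thickness maps from phantom ground truth
#'
#' Wraps the exact micron maps implied by a phantom's geometry in a
#' `thickness_maps` object, so ground truth can flow through the same
#' exclusion, normative and statistics code paths as segmented data.
#'
#' @param truth a `ground_truth` object from [generate_phantom()].
#' @param laterality eye laterality.
#' @return A `thickness_maps` object.
#' @export
ground_truth_maps <- function(truth, laterality = "right") {
  stopifnot(inherits(truth, "ground_truth"))
  nb <- nrow(truth$true_maps$irt)
  na <- ncol(truth$true_maps$irt)
  structure(list(
    maps = truth$true_maps,
    valid = matrix(TRUE, nb, na),
    axial_pitch = truth$axial_pitch,
    laterality = match.arg(laterality, c("left", "right")),
    oriented = FALSE,
    disk = truth$disk,
    n_bscans = nb,
    n_ascans = na
  ), class = "thickness_maps")
}

#' @export
print.thickness_maps <- function(x, ...) {
  cat("<thickness_maps> ", x$n_bscans, " x ", x$n_ascans, " grid, ",
      sum(x$valid), " valid px (", x$laterality, " eye",
      if (x$oriented) ", oriented", ")\n", sep = "")
  for (m in MEASURES) {
    v <- x$maps[[m]][x$valid]
    cat(sprintf("  %-3s mean %6.1f um (range %.1f-%.1f)\n", toupper(m),
                mean(v), min(v), max(v)))
  }
  invisible(x)
}

#' Exclude the optic-disk neighbourhood from thickness maps
#'
#' Flags as invalid every grid point closer than 1.5 disk diameters to the
#' disk centre, horizontally and vertically. The default window is the
#' axis-aligned rectangle `|d_ascan| < 1.5 D & |d_bscan| < 1.5 D`; an
#' elliptical window with the same semi-axes is available via `shape`.
#' Values are retained but flagged invalid.
#'
#' @param maps a `thickness_maps` object.
#' @param disk_center disk centre `c(bscan, ascan)`; defaults to the centre
#'   stored in `maps`.
#' @param disk_diameter disk diameter in grid units (> 0).
#' @param shape `"rect"` (default) or `"ellipse"`.
#' @return The maps with an updated validity mask.
#' @export
apply_disk_exclusion <- function(maps, disk_center = maps$disk$center,
                                 disk_diameter = maps$disk$diameter,
                                 shape = c("rect", "ellipse")) {
  stopifnot(inherits(maps, "thickness_maps"))
  shape <- match.arg(shape)
  if (is.null(disk_center) || is.null(disk_diameter)) {
    stop("apply_disk_exclusion: disk_center and disk_diameter required",
         call. = FALSE)
  }
  if (!all(is.finite(c(disk_center, disk_diameter))) || disk_diameter <= 0) {
    stop("apply_disk_exclusion: disk parameters must be finite, diameter > 0",
         call. = FALSE)
  }
  db <- abs(matrix(seq_len(maps$n_bscans), maps$n_bscans, maps$n_ascans) -
              disk_center[1])
  da <- abs(matrix(seq_len(maps$n_ascans), maps$n_bscans, maps$n_ascans,
                   byrow = TRUE) - disk_center[2])
  r <- 1.5 * disk_diameter
  excl <- if (shape == "rect") {
    da < r & db < r
  } else {
    (da / r)^2 + (db / r)^2 < 1
  }
  maps$valid <- maps$valid & !excl
  maps$disk <- list(center = disk_center, diameter = disk_diameter)
  maps
}

#' Orient data to a right-eye configuration
#'
#' Left-eye data are mirrored along the A-scan (horizontal) axis so that
#' every eye shares the same nasal-to-temporal column convention; right-eye
#' data are returned unchanged. Applying the transform twice with
#' `laterality = "left"` is the identity.
#'
#' @param x a `thickness_maps` or `bscan_volume` object.
#' @param laterality `"left"` or `"right"`; defaults to the object's own
#'   laterality.
#' @return The object, oriented to a right-eye configuration.
#' @export
orient_right <- function(x, laterality = NULL) {
  UseMethod("orient_right")
}

#' @export
orient_right.thickness_maps <- function(x, laterality = NULL) {
  laterality <- laterality %||% x$laterality
  laterality <- match.arg(laterality, c("left", "right"))
  if (laterality == "left") {
    flip <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
    x$maps <- lapply(x$maps, flip)
    x$valid <- flip(x$valid)
    if (!is.null(x$disk$center)) {
      x$disk$center[2] <- x$n_ascans + 1 - x$disk$center[2]
    }
    x$laterality <- "right"
  }
  x$oriented <- TRUE
  x
}

#' @export
orient_right.bscan_volume <- function(x, laterality = NULL) {
  laterality <- laterality %||% x$metadata$laterality
  laterality <- match.arg(laterality, c("left", "right"))
  if (laterality == "left") {
    x$bscans <- lapply(x$bscans, function(m) {
      m[, rev(seq_len(ncol(m))), drop = FALSE]
    })
    if (!is.null(x$metadata$disk_center)) {
      x$metadata$disk_center[2] <- x$n_ascans + 1 - x$metadata$disk_center[2]
    }
    x$metadata$laterality <- "right"
  }
  x
}

#' @export
orient_right.default <- function(x, laterality = NULL) {
  stop("orient_right: unsupported object of class ", class(x)[1],
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
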