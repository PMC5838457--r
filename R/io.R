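#' Write a B-scan volume as a multi-page TIFF with JSON sidecar
#'
#' One TIFF page per B-scan, 32-bit float samples. TIFF samples are stored
#' on a 0-1 scale; intensities are divided by a common scale factor
#' (recorded in the sidecar) before writing and restored on read. The
#' sidecar also carries the raster geometry and eye metadata.
#'
#' @param volume a `bscan_volume`.
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "bscan_volume"))
  scale <- max(1, vapply(volume$bscans, max, numeric(1)))
  pages <- lapply(volume$bscans, function(m) pmax(m / scale, 0))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(
    n_bscans = volume$n_bscans, n_ascans = volume$n_ascans,
    depth_px = volume$depth_px, axial_pitch = volume$axial_pitch,
    intensity_scale = scale, metadata = volume$metadata
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a B-scan volume written by [write_volume()]
#'
#' @param path TIFF path with `<path>.json` sidecar alongside.
#' @return A `bscan_volume`.
#' @export
read_volume <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"),
                                 simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  bscans <- lapply(pages, function(p) p * sidecar$intensity_scale)
  md <- sidecar$metadata
  if (!is.null(md$disk_center)) md$disk_center <- as.numeric(md$disk_center)
  structure(list(
    bscans = bscans,
    n_bscans = sidecar$n_bscans, n_ascans = sidecar$n_ascans,
    depth_px = sidecar$depth_px, axial_pitch = sidecar$axial_pitch,
    metadata = md
  ), class = "bscan_volume")
}

#' Write detected interfaces as long-format CSV
#'
#' Columns: `bscan_index`, `ascan_index`, `interface_name`, `row_px`
#' (1-based).
#'
#' @param segmentations list of `interface_set`s (one per B-scan).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_interfaces <- function(segmentations, path) {
  rows <- do.call(rbind, lapply(seq_along(segmentations), function(b) {
    ifc <- segmentations[[b]]
    do.call(rbind, lapply(ifc$paths, function(p) {
      data.frame(bscan_index = b, ascan_index = seq_along(p$rows),
                 interface_name = p$interface, row_px = p$rows,
                 stringsAsFactors = FALSE)
    }))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read interfaces written by [write_interfaces()]
#'
#' @param path CSV path.
#' @return List of `interface_set`s in B-scan order.
#' @export
read_interfaces <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$bscan_index), function(b) {
    g <- split(b, b$interface_name)
    grab <- function(nm) g[[nm]]$row_px[order(g[[nm]]$ascan_index)]
    interface_set(grab("ilm"), grab("inl_opl"), grab("onl_ise"),
                  grab("os_rpe"))
  })
}

#' Write thickness maps as long-format CSV
#'
#' Columns: `bscan`, `ascan`, `measure`, `value_um`, `valid`.
#'
#' @param maps a `thickness_maps` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_maps_csv <- function(maps, path) {
  stopifnot(inherits(maps, "thickness_maps"))
  grid <- expand.grid(bscan = seq_len(maps$n_bscans),
                      ascan = seq_len(maps$n_ascans))
  rows <- do.call(rbind, lapply(MEASURES, function(m) {
    data.frame(grid, measure = m, value_um = as.vector(maps$maps[[m]]),
               valid = as.vector(maps$valid), stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write phantom ground truth as compressed CSV
#'
#' Columns: `bscan`, `ascan`, and for each interface the sub-pixel depth in
#' pixels and microns.
#'
#' @param truth a `ground_truth` object.
#' @param path output path (gzip-compressed when it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  nb <- nrow(truth$interfaces_px$ilm)
  na <- ncol(truth$interfaces_px$ilm)
  d <- expand.grid(bscan = seq_len(nb), ascan = seq_len(na))
  for (nm in names(truth$interfaces_px)) {
    d[[paste0(nm, "_px")]] <- as.vector(truth$interfaces_px[[nm]])
    d[[paste0(nm, "_um")]] <- as.vector(truth$interfaces_um[[nm]])
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.csv(d, con, row.names = FALSE)
  invisible(path)
}
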