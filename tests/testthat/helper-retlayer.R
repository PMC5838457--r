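# Shared fixtures and independent oracles for the test suite.

# A reduced-lateral-sampling phantom spec that keeps tests fast while
# preserving the default anatomy (IRT/ORT/TRT/OSL = 94/114/208/26 um).
small_spec <- function(n_bscans = 5L, n_ascans = 64L, depth_px = 128L,
                       speckle_level = 0, seed = 1L, ...) {
  phantom_spec(n_bscans = n_bscans, n_ascans = n_ascans,
               depth_px = depth_px, speckle_level = speckle_level,
               seed = seed, ...)
}

# Independent oracle for the path search: exhaustively enumerate every
# monotone left-to-right path (|d row| <= 1 per column) over the admissible
# nodes and accumulate edge weights w = 2 - (g_a + g_b) + wmin left to
# right, exactly as the graph defines them.
brute_force_min_cost <- function(scores, region = NULL, wmin = 1e-5) {
  nr <- nrow(scores)
  nc <- ncol(scores)
  if (is.null(region)) region <- matrix(TRUE, nr, nc)
  best <- Inf
  recurse <- function(r, c, cost) {
    if (c == nc) {
      best <<- min(best, cost)
      return(invisible())
    }
    for (r2 in (r - 1):(r + 1)) {
      if (r2 >= 1 && r2 <= nr && region[r2, c + 1]) {
        recurse(r2, c + 1,
                cost + (2 - scores[r, c] - scores[r2, c + 1] + wmin))
      }
    }
  }
  for (r in seq_len(nr)) {
    if (region[r, 1]) recurse(r, 1, 0)
  }
  best
}

# Median absolute row error of each detected interface against the
# sub-pixel ground truth of one B-scan.
interface_errors <- function(ifc, truth, bscan_index) {
  vapply(names(ifc$paths), function(nm) {
    median(abs(ifc$paths[[nm]]$rows -
                 truth$interfaces_px[[nm]][bscan_index, ]))
  }, numeric(1))
}

# Per-eye thickness maps through the standard orientation + disk exclusion
# steps, from segmentation or ground truth.
eye_maps_from_truth <- function(eye) {
  maps <- ground_truth_maps(eye$truth, laterality = eye$metadata$laterality)
  maps <- orient_right(maps)
  apply_disk_exclusion(maps)
}

segment_eye_maps <- function(eye, ...) {
  segs <- segment_volume(eye$volume, ...)
  maps <- build_maps(segs, axial_pitch = eye$volume$axial_pitch,
                     laterality = eye$metadata$laterality,
                     disk_center = c(eye$metadata$disk_bscan,
                                     eye$metadata$disk_ascan),
                     disk_diameter = eye$metadata$disk_diameter)
  maps <- orient_right(maps)
  apply_disk_exclusion(maps)
}

# Random strictly ordered interface set on an nb x na grid (no slope
# constraint; exercises the thickness algebra on arbitrary valid inputs).
random_interface_set <- function(n_ascans, depth_px = 200L) {
  r1 <- sample(5:20, n_ascans, replace = TRUE)
  r2 <- r1 + sample(10:40, n_ascans, replace = TRUE)
  r3 <- r2 + sample(5:30, n_ascans, replace = TRUE)
  r4 <- r3 + sample(2:10, n_ascans, replace = TRUE)
  interface_set(r1, r2, r3, r4)
}
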