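#' Gradient-weighted graph for interface detection
#'
#' Builds the weighted graph used by the layer-interface search. Each pixel
#' is a node; directed edges connect a pixel to its three right-hand
#' neighbours (up-right, right, down-right), which enforces one row per
#' column and a lateral slope of at most one pixel per column. The edge
#' weight between nodes `a` and `b` is
#' \deqn{w_{ab} = 2 - (g_a + g_b) + w_{min}}
#' where `g` is the dark-to-bright (positive) vertical gradient normalised
#' to `[0, 1]`, so strong dark-to-bright transitions get small weights and
#' the minimum-weight left-to-right path traces an interface.
#'
#' The image is pre-smoothed with a separable anisotropic Gaussian:
#' `sigma[1]` along depth and `sigma[2]` laterally (pixels; 0 disables
#' either axis; a scalar is used isotropically). The vertical SD is kept
#' small (default 0.3, a 3-tap kernel) so the gradient ridge stays centred
#' on the boundary row even next to thin bands such as the ISe and RPE;
#' speckle is suppressed by the wider lateral kernel (default 1.5), which
#' does not bias the vertical position of locally horizontal interfaces.
#' The vertical gradient is the central difference `(I[r+1] - I[r-1]) / 2`
#' with replicated borders, negative values are clipped to zero, and the
#' result is divided by its maximum. Because every admissible left-to-right
#' path has exactly `ncol - 1` weighted edges, this normalisation cannot
#' change which path is minimal.
#'
#' @param bscan numeric matrix (depth x A-scans), finite values.
#' @param region logical matrix of admissible nodes; `NULL` means all.
#'   Every column must contain at least one admissible pixel.
#' @param sigma Gaussian pre-smoothing SDs in pixels,
#'   `c(vertical, lateral)`; a scalar applies to both axes; 0 disables.
#' @param w_min small positive weight floor so all edge weights are > 0.
#' @return An object of class `weight_graph` with elements `scores`
#'   (normalised gradient), `region`, and `w_min`.
#' @export
build_weight_graph <- function(bscan, region = NULL, sigma = c(0.3, 1.5),
                               w_min = 1e-5) {
  if (!is.matrix(bscan) || !is.numeric(bscan)) {
    stop("build_weight_graph: bscan must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(bscan))) {
    stop("build_weight_graph: bscan contains non-finite values",
         call. = FALSE)
  }
  scores <- gradient_scores(bscan, sigma)
  weight_graph(scores, region = region, w_min = w_min)
}

#' Construct a weight graph from precomputed gradient scores
#'
#' Low-level constructor used by [build_weight_graph()] and directly in
#' tests, where the per-node scores can be hand-assigned.
#'
#' @param scores numeric matrix of per-node gradient scores in `[0, 1]`.
#' @param region logical matrix of admissible nodes (`NULL` = all).
#' @param w_min positive weight floor.
#' @return A `weight_graph` object.
#' @export
weight_graph <- function(scores, region = NULL, w_min = 1e-5) {
  if (w_min <= 0) stop("weight_graph: w_min must be > 0", call. = FALSE)
  if (is.null(region)) {
    region <- matrix(TRUE, nrow(scores), ncol(scores))
  }
  if (!identical(dim(scores), dim(region))) {
    stop("weight_graph: scores and region dimensions differ", call. = FALSE)
  }
  empty <- which(colSums(region) == 0)
  if (length(empty)) {
    stop(structure(class = c("retlayer_infeasible_region", "error",
                             "condition"),
                   list(message = paste0(
                     "weight_graph: region empty in column(s) ",
                     paste(utils::head(empty, 5), collapse = ", ")),
                     call = NULL)))
  }
  structure(list(scores = scores, region = region, w_min = w_min),
            class = "weight_graph")
}

# Positive vertical gradient, [0,1]-normalised. Shared by all four stages.
gradient_scores <- function(bscan, sigma = c(0.3, 1.5)) {
  img <- gaussian_blur(bscan, sigma)
  nr <- nrow(img)
  up <- img[c(1L, seq_len(nr - 1L)), , drop = FALSE]     # I[r-1], clamped
  down <- img[c(seq_len(nr)[-1L], nr), , drop = FALSE]   # I[r+1], clamped
  g <- pmax((down - up) / 2, 0)
  mx <- max(g)
  if (mx > 0) g <- g / mx
  g
}

# Separable, possibly anisotropic Gaussian blur with replicated borders
# (kernel radius 3*sigma per axis; sigma = c(vertical, lateral)).
gaussian_blur <- function(img, sigma) {
  sigma <- rep_len(sigma, 2L)
  kern <- function(s) {
    r <- ceiling(3 * s)
    k <- stats::dnorm(-r:r, sd = s)
    k / sum(k)
  }
  if (sigma[1] > 0) img <- conv_axis(img, kern(sigma[1]), 1L)
  if (sigma[2] > 0) img <- conv_axis(img, kern(sigma[2]), 2L)
  img
}

conv_axis <- function(img, k, axis) {
  r <- (length(k) - 1L) %/% 2L
  n <- dim(img)[axis]
  out <- 0
  for (i in seq_along(k)) {
    shift <- i - r - 1L
    idx <- pmin(pmax(seq_len(n) + shift, 1L), n)
    out <- out + k[i] * (if (axis == 1L) img[idx, , drop = FALSE]
                         else img[, idx, drop = FALSE])
  }
  out
}

#' Minimum-weight left-to-right path through a weight graph
#'
#' Runs Dijkstra's algorithm over the admissible nodes with deterministic
#' lexicographic (cost, column, row) tie-breaking. Zero-weight virtual
#' columns at both sides let the path start and end at any admissible row,
#' so a path across `n` columns accumulates `n - 1` weighted edges.
#'
#' @param graph a [weight_graph()].
#' @param interface optional interface label attached to the result.
#' @return An object of class `interface_path`: `rows` (1-based row index
#'   per column), `cost` (total path weight), and `interface`.
#' @export
shortest_path <- function(graph, interface = NA_character_) {
  stopifnot(inherits(graph, "weight_graph"))
  res <- dijkstra_path_cpp(graph$scores, graph$region, graph$w_min)
  if (!isTRUE(res$feasible)) {
    stop(structure(class = c("retlayer_infeasible_region", "error",
                             "condition"),
                   list(message = "shortest_path: no feasible left-to-right path in region",
                        call = NULL)))
  }
  interface_path(res$rows, interface = interface, cost = res$cost)
}

interface_path <- function(rows, interface = NA_character_, cost = NA_real_) {
  rows <- as.integer(rows)
  if (length(rows) > 1 && any(abs(diff(rows)) > 1L)) {
    stop("interface_path: |row(c+1) - row(c)| <= 1 violated", call. = FALSE)
  }
  structure(list(rows = rows, interface = interface, cost = cost),
            class = "interface_path")
}

#' @export
print.interface_path <- function(x, ...) {
  cat("<interface_path> ", x$interface, ": ", length(x$rows),
      " columns, rows ", min(x$rows), "-", max(x$rows),
      if (!is.na(x$cost)) paste0(", cost ", signif(x$cost, 6)), "\n",
      sep = "")
  invisible(x)
}
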