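#' Construct a retinotopic grid
#'
#' A regular two-dimensional grid of retinotopic positions (degrees of
#' visual angle) on which all rate fields and connectivity kernels are
#' discretized. Node coordinates are `x_i = (i - (n-1)/2) * delta`, so the
#' stimulus center (0, 0) coincides with the grid centroid; for even node
#' counts it falls between nodes and "the centered unit" means the node
#' nearest to the origin.
#'
#' @param n_x,n_y number of nodes along each axis (>= 2).
#' @param delta grid spacing in degrees (> 0).
#' @return An object of class `ssn_grid`: a list with `n_x`, `n_y`, `delta`,
#'   `n_nodes`, and `coords` (an `n_nodes x 2` matrix of x/y positions in
#'   degrees; node order is x fastest, then y).
#' @examples
#' g <- retinotopic_grid(12, 12, 6)
#' range(g$coords)  # +- 33 degrees
#' @export
retinotopic_grid <- function(n_x, n_y = n_x, delta = 6) {
  stopifnot(length(n_x) == 1, length(n_y) == 1, length(delta) == 1)
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  if (n_x < 2 || n_y < 2) {
    stop("grid needs at least 2 nodes along each axis")
  }
  if (!is.finite(delta) || delta <= 0) stop("grid spacing must be positive")
  xs <- (seq_len(n_x) - 1 - (n_x - 1) / 2) * delta
  ys <- (seq_len(n_y) - 1 - (n_y - 1) / 2) * delta
  coords <- cbind(
    x = rep(xs, times = n_y),
    y = rep(ys, each = n_x)
  )
  structure(
    list(n_x = n_x, n_y = n_y, delta = delta,
         n_nodes = n_x * n_y, coords = coords),
    class = "ssn_grid"
  )
}

#' @export
print.ssn_grid <- function(x, ...) {
  cat(sprintf("<ssn_grid> %d x %d nodes, spacing %g deg, extent [%g, %g] deg\n",
              x$n_x, x$n_y, x$delta, min(x$coords), max(x$coords)))
  invisible(x)
}

is_ssn_grid <- function(x) inherits(x, "ssn_grid")

# squared pairwise distances between nodes (n x n); cached on the grid's own
# environment would break copy semantics, so callers that need it repeatedly
# hold onto the result themselves
grid_dist2 <- function(grid) {
  dx <- outer(grid$coords[, 1], grid$coords[, 1], "-")
  dy <- outer(grid$coords[, 2], grid$coords[, 2], "-")
  dx * dx + dy * dy
}

# squared distance of each node from the stimulus center
grid_r2 <- function(grid) {
  rowSums(grid$coords^2)
}

#' Index of the grid node closest to the stimulus center
#'
#' @param grid an [retinotopic_grid()] object.
#' @return integer node index (ties broken by the first in node order).
#' @export
center_node <- function(grid) {
  which.min(grid_r2(grid))
}

same_grid <- function(a, b) {
  a$n_x == b$n_x && a$n_y == b$n_y && isTRUE(all.equal(a$delta, b$delta))
}
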