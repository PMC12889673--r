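#' Gaussian connectivity kernel matrix on a grid
#'
#' Discretizes the 2D isotropic Gaussian connectivity profile
#' `W(x - y) = amplitude / (2 * pi * scale^2) * exp(-|x - y|^2 / (2 scale^2))`
#' into a node-by-node coupling matrix. Multiplying a presynaptic rate
#' vector by this matrix and by the area element `delta^2` approximates the
#' continuous spatial integral; for a node far from the grid boundary the
#' row sum times `delta^2` approximates `amplitude` (open boundaries, no
#' wrap-around).
#'
#' @param grid an [retinotopic_grid()].
#' @param amplitude signed kernel amplitude (integral of the continuous
#'   kernel over space).
#' @param scale Gaussian spatial scale sigma in degrees (> 0).
#' @param dist2 optional precomputed squared-distance matrix (from repeated
#'   calls on the same grid).
#' @return `n_nodes x n_nodes` symmetric matrix.
#' @examples
#' g <- retinotopic_grid(5, 5, 6)
#' K <- gaussian_kernel_matrix(g, 1, 10)
#' K[1, 1] * 2 * pi * 100  # 1
#' @export
gaussian_kernel_matrix <- function(grid, amplitude, scale, dist2 = NULL) {
  if (!is_ssn_grid(grid)) stop("grid must be an ssn_grid")
  if (!is.finite(scale) || scale <= 0) stop("kernel scale must be positive")
  if (is.null(dist2)) dist2 <- grid_dist2(grid)
  amplitude / (2 * pi * scale^2) * exp(-dist2 / (2 * scale^2))
}

# Unit-amplitude kernels for every (postsynaptic A, presynaptic B) pair,
# deduplicated by sigma value: with the default uniform scale table all 28
# pairs share one matrix. Returns list(basis = list keyed by sigma string,
# key = 4 x 7 character matrix of keys into basis).
kernel_basis <- function(grid, scale_table, dist2 = NULL) {
  if (is.null(dist2)) dist2 <- grid_dist2(grid)
  sig <- unique(as.vector(scale_table))
  basis <- lapply(sig, function(s) gaussian_kernel_matrix(grid, 1, s, dist2))
  names(basis) <- format(sig, digits = 15)
  key <- matrix(format(as.vector(scale_table), digits = 15),
                nrow = nrow(scale_table),
                dimnames = dimnames(scale_table))
  list(basis = basis, key = key)
}

# Full stacked recurrent connectivity over the 4 recurrent populations:
# (4n x 4n) with the area element delta^2 folded in, block (A, B) =
# w[A, B] * kernel(sigma[A, B]) * delta^2. Block order follows
# ssn_recurrent_types().
stacked_recurrent_W <- function(model, kb = NULL) {
  grid <- model$grid
  n <- grid$n_nodes
  rec <- ssn_recurrent_types()
  if (is.null(kb)) kb <- kernel_basis(grid, model$scale)
  W <- matrix(0, 4 * n, 4 * n)
  d2 <- grid$delta^2
  for (ai in seq_along(rec)) for (bi in seq_along(rec)) {
    a <- rec[ai]; b <- rec[bi]
    w <- model$amplitude[a, b]
    if (w != 0) {
      W[block_idx(ai, n), block_idx(bi, n)] <-
        w * d2 * kb$basis[[kb$key[a, b]]]
    }
  }
  W
}

block_idx <- function(k, n) ((k - 1L) * n + 1L):(k * n)

# Current into each recurrent population from the external sources (L4, LM,
# R) plus the bias, per stimulus size: a list over sizes of n x 4 matrices.
external_currents <- function(model, drive, kb = NULL) {
  grid <- model$grid
  n <- grid$n_nodes
  rec <- ssn_recurrent_types()
  src <- ssn_source_types()
  if (is.null(kb)) kb <- kernel_basis(grid, model$scale)
  d2 <- grid$delta^2
  sizes <- drive$sizes
  lapply(seq_along(sizes), function(si) {
    ext <- matrix(0, n, 4, dimnames = list(NULL, rec))
    for (a in rec) {
      cur <- rep(model$bias[a], n)
      for (b in src) {
        w <- model$amplitude[a, b]
        if (w != 0) {
          rB <- drive$values[b, , si]
          cur <- cur + w * d2 * (kb$basis[[kb$key[a, b]]] %*% rB)[, 1]
        }
      }
      ext[, a] <- cur
    }
    ext
  })
}
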