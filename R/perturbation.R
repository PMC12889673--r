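#' Response matrix at a stable fixed point
#'
#' Linear response theory: a small input perturbation `dh` shifts the fixed
#' point by `dr = (I - F W)^-1 F dh = R dh`. Valid only at a stable fixed
#' point (leading Jacobian real part < 0); a singular `I - F W` means the
#' network sits at criticality and is reported as an error.
#'
#' @param ctx an `ssn_linearization` (see [build_linearization()]).
#' @return object of class `ssn_response`: list with `R` (full response
#'   matrix), `types` (row labels), `ctx`.
#' @export
response_matrix <- function(ctx) {
  if (!isTRUE(ctx$valid)) stop("linearization context is not valid")
  m <- nrow(ctx$W)
  A <- diag(m) - ctx$F * ctx$W
  rc <- tryCatch(rcond(A), error = function(e) 0)
  if (rc < 1e-14) stop("I - F W is singular: network at criticality")
  R <- solve(A) * rep(ctx$F, each = m)   # (I - FW)^-1 %*% diag(F)
  structure(list(R = R, types = ctx$types, ctx = ctx),
            class = "ssn_response")
}

#' Diagonal block of the response matrix with its eigenbasis
#'
#' Extracts `R_XX` for cell type `X` and computes its eigen-decomposition,
#' eigenvalues sorted ascending by real part (so `lambda_1` is the
#' "smallest", the one whose sign decides pattern-specific paradoxical
#' responses). Eigenvectors have unit Euclidean norm with deterministic
#' sign/phase (largest-magnitude entry positive). The coefficients
#' `c = V^-1 1` of the uniform pattern are obtained by a linear solve; a
#' condition number above 1e10 flags the basis as unreliable (defective).
#'
#' @param rc an `ssn_response`.
#' @param X cell type label.
#' @return list `Rxx`, `values` (complex, ascending by real part), `V`
#'   (columns = eigenvectors), `coef` (`c`), `defective`, `nodes` (row
#'   indices of X in the full matrix).
#' @export
response_block <- function(rc, X) {
  idx <- which(rc$types == X)
  if (!length(idx)) stop("no nodes of type ", X)
  Rxx <- rc$R[idx, idx, drop = FALSE]
  es <- eigen(Rxx)
  ord <- order(Re(es$values), abs(Im(es$values)))
  values <- es$values[ord]
  V <- es$vectors[, ord, drop = FALSE]
  V <- apply(V, 2, normalize_eigvec)
  if (is.null(dim(V))) V <- matrix(V, ncol = 1)
  sv <- tryCatch(svd(V, nu = 0, nv = 0)$d, error = function(e) c(1, 0))
  cond <- max(sv) / max(min(sv), .Machine$double.xmin)
  defective <- !is.finite(cond) || cond > 1e10
  coef <- if (defective) rep(NA_complex_, length(values)) else
    solve(V, rep(1, length(idx)))
  list(Rxx = Rxx, values = values, V = V, coef = coef,
       defective = defective, nodes = idx)
}

normalize_eigvec <- function(v) {
  v <- v / sqrt(sum(Mod(v)^2))
  k <- which.max(Mod(v))
  ph <- v[k] / Mod(v[k])
  v <- v / ph                    # largest-magnitude entry made real positive
  if (all(Im(v) == 0) || max(abs(Im(v))) < 1e-12 * max(abs(Re(v)))) {
    v <- complex(real = Re(v), imaginary = 0)
  }
  v
}

#' Predicted response to a uniform perturbation
#'
#' The uniform excitatory perturbation `gamma * 1_X` produces
#' `dr_X = gamma * sum_i c_i lambda_i v_i` in the eigenbasis of `R_XX`;
#' equivalently `R_XX (gamma 1)`. The mean change over the population can
#' be non-paradoxical even when `lambda_1 < 0`, because the cross terms of
#' the eigen-expansion can outweigh the `lambda_1 c_1^2 <v_1^2>` term; the
#' decomposition into that leading term and the remainder is returned for
#' diagnosis. When the eigenbasis is defective the prediction falls back to
#' the direct matrix-vector product.
#'
#' @param rc an `ssn_response`.
#' @param X target cell type.
#' @param gamma perturbation amplitude (> 0).
#' @return list with `delta_r` (per-node change), `mean` (per-neuron mean
#'   change), `dot_ones` (dot product with the all-ones vector, `N_X` times
#'   the mean), `leading_term` and `remainder` (eigen-decomposition of the
#'   mean), `paradoxical` (`dr . dh < 0`), `defective`.
#' @export
uniform_prediction <- function(rc, X, gamma) {
  stopifnot(gamma > 0)
  bl <- response_block(rc, X)
  n <- length(bl$nodes)
  ones <- rep(1, n)
  if (bl$defective) {
    dr <- as.vector(bl$Rxx %*% (gamma * ones))
    lead <- NA_real_; remainder <- NA_real_
  } else {
    dr_c <- gamma * as.vector(bl$V %*% (bl$coef * bl$values))
    dr <- Re(dr_c)
    lead_c <- gamma / n * bl$values[1] * bl$coef[1]^2 *
      sum(bl$V[, 1]^2)
    lead <- Re(lead_c)
    remainder <- mean(dr) - lead
  }
  dot <- sum(dr) * gamma          # dr . (gamma 1)
  list(delta_r = dr, mean = mean(dr), dot_ones = sum(dr),
       leading_term = lead, remainder = remainder,
       paradoxical = dot < 0, defective = bl$defective)
}

#' Predicted response to a patterned (eigenmode) perturbation
#'
#' A perturbation `gamma * v_i` along the i-th eigenvector of `R_XX` yields
#' `dr_X = gamma * lambda_i * v_i`, so its projection on the pattern is
#' `gamma * lambda_i |v_i|^2 = gamma * lambda_i` (unit-norm vectors): the
#' response is paradoxical along the pattern exactly when `lambda_i < 0`.
#' If `lambda_i` belongs to a complex conjugate pair the physical pattern
#' is the normalized real part of `v_i` and the projection is computed by
#' direct matrix action; this is flagged.
#'
#' @param rc an `ssn_response`.
#' @param X target cell type.
#' @param gamma perturbation amplitude (> 0).
#' @param i eigenmode index in ascending-real-part order (default 1, the
#'   smallest eigenvalue).
#' @return list `pattern` (real unit vector), `delta_r`, `projection`
#'   (`dr . pattern`), `lambda`, `paradoxical`, `complex_pair`.
#' @export
patterned_prediction <- function(rc, X, gamma, i = 1) {
  stopifnot(gamma > 0)
  bl <- response_block(rc, X)
  lam <- bl$values[i]
  v <- bl$V[, i]
  complex_pair <- abs(Im(lam)) > 1e-10 * max(abs(Re(bl$values)), 1e-300)
  if (complex_pair) {
    pat <- Re(v)
    pat <- pat / sqrt(sum(pat^2))
    dr <- as.vector(Re(bl$Rxx %*% (gamma * pat)))
  } else {
    pat <- Re(v)
    dr <- gamma * Re(lam) * pat
  }
  proj <- sum(dr * pat)
  list(pattern = pat, delta_r = dr, projection = proj, lambda = lam,
       paradoxical = proj < 0, complex_pair = complex_pair)
}

#' Specify a perturbation
#'
#' @param target `"PV"`, `"SST"`, `"VIP"`, or `"all_inhibitory"` (PV, SST
#'   and VIP jointly).
#' @param pattern `"uniform"`, an eigenmode index (integer, ascending order
#'   of `Re lambda` of `R_XX`; only for single-type targets), or a custom
#'   numeric vector with one entry per node of the target type.
#' @param gamma amplitude (> 0).
#' @param onset,duration perturbation onset time and total simulated time
#'   after onset, seconds.
#' @export
perturbation_spec <- function(target = "SST", pattern = "uniform",
                              gamma = 0.001, onset = 1, duration = 2) {
  stopifnot(gamma > 0, onset >= 0, duration > 0)
  targets <- c("PV", "SST", "VIP", "all_inhibitory")
  if (!target %in% targets) stop("target must be one of ",
                                 paste(targets, collapse = ", "))
  structure(list(target = target, pattern = pattern, gamma = gamma,
                 onset = onset, duration = duration),
            class = "ssn_perturbation_spec")
}

target_types <- function(target) {
  if (target == "all_inhibitory") c("PV", "SST", "VIP") else target
}

#' Simulate a perturbation experiment
#'
#' Integrates the rate dynamics starting from the steady state at stimulus
#' size `s`, adds the perturbing current `gamma * pattern` to the target
#' population's input from `onset` onward, and records the readouts used to
#' compare against the analytic linear-response predictions: for uniform
#' perturbations both the dot product of the activity change with the
#' all-ones vector and the per-neuron mean; for patterned perturbations the
#' projection of the activity change on the (unit-norm) pattern.
#'
#' Integration stops at `onset + duration` or earlier once the readout's
#' relative change per time constant falls below 1e-6.
#'
#' @param model an [ssn_model()].
#' @param drive source [rate_field()].
#' @param s stimulus size.
#' @param spec a [perturbation_spec()].
#' @param dt Euler step (default `min(tau)/10`).
#' @param rc optional precomputed [response_matrix()] (needed only to
#'   resolve an eigenmode-index pattern; computed on demand otherwise).
#' @return object of class `ssn_perturbation_result`: list with `times`,
#'   `projection` (readout time series, baseline-subtracted), `mean_change`
#'   series, `final_delta` (`n x 4` rate change at the end), `pattern`
#'   (full `n x 4` current pattern, unscaled), `paradoxical`
#'   (`delta_r . delta_h < 0` at the end), `diverged`, `spec`.
#' @export
simulate_perturbation <- function(model, drive, s, spec, dt = NULL,
                                  rc = NULL) {
  ctx <- make_sim_context(model, drive)
  si <- match_size(s, ctx$sizes)
  n <- ctx$n
  ss <- solve_fixed_point(ctx$W, ctx$ext[[si]], ctx$tau, ctx$nl, tol = 1e-10)
  if (!ss$converged) stop("steady state did not converge at size ", s)
  rec <- ssn_recurrent_types()
  tg <- target_types(spec$target)
  # build the full stacked current pattern (unit amplitude)
  pat_full <- numeric(4 * n)
  if (identical(spec$pattern, "uniform")) {
    for (t in tg) pat_full[block_idx(match(t, rec), n)] <- 1
    readout <- pat_full   # dot with ones over target nodes
  } else if (is.numeric(spec$pattern) && length(spec$pattern) == 1) {
    if (length(tg) > 1) stop("eigenmode patterns need a single target type")
    if (is.null(rc)) {
      lin <- build_linearization(model, drive, s)
      rc <- response_matrix(lin)
    }
    pp <- patterned_prediction(rc, tg, spec$gamma, i = as.integer(spec$pattern))
    pat_full[block_idx(match(tg, rec), n)] <- pp$pattern
    readout <- pat_full
  } else {
    if (length(tg) > 1) stop("custom patterns need a single target type")
    stopifnot(length(spec$pattern) == n)
    pat_full[block_idx(match(tg, rec), n)] <- spec$pattern
    readout <- pat_full
  }
  if (is.null(dt)) dt <- min(model$tau) / 10
  h <- ctx$ext[[si]]
  dh <- spec$gamma * pat_full
  r <- ss$rates
  step <- dt / ctx$tau
  n_steps <- base::ceiling((spec$onset + spec$duration) / dt)
  sample_every <- 10L
  times <- numeric(0); proj <- numeric(0); mean_ch <- numeric(0)
  tgt_idx <- which(rep(rec, each = n) %in% tg)
  base_proj <- sum(ss$rates * readout)
  last <- NA_real_
  for (k in seq_len(n_steps)) {
    hh <- if ((k - 1) * dt >= spec$onset) h + dh else h
    fu <- apply_nonlinearity(as.vector(ctx$W %*% r) + hh, ctx$nl)
    r <- r + step * (fu - r)
    if (any(!is.finite(r)) || max(r) > 1e6) {
      return(structure(list(times = times, projection = proj,
                            mean_change = mean_ch,
                            final_delta = stacked_to_mat(r - ss$rates, n),
                            pattern = stacked_to_mat(pat_full, n),
                            paradoxical = NA, diverged = TRUE, spec = spec),
                       class = "ssn_perturbation_result"))
    }
    if (k %% sample_every == 0L || k == n_steps) {
      tnow <- k * dt
      p <- sum(r * readout) - base_proj
      times <- c(times, tnow)
      proj <- c(proj, p)
      mean_ch <- c(mean_ch, sum((r - ss$rates)[tgt_idx]) / length(tgt_idx))
      if (tnow > spec$onset + 5 * max(model$tau)) {
        # early stop once the readout has settled
        rel <- abs(p - last) / (abs(p) + 1e-12)
        if (is.finite(rel) && rel < 1e-6 *
              (sample_every * dt / max(model$tau))) break
        last <- p
      } else last <- p
    }
  }
  delta <- r - ss$rates
  dot_dh <- sum(delta * dh)
  structure(list(times = times, projection = proj, mean_change = mean_ch,
                 final_delta = stacked_to_mat(delta, n),
                 pattern = stacked_to_mat(pat_full, n),
                 paradoxical = dot_dh < 0, diverged = FALSE, spec = spec),
            class = "ssn_perturbation_result")
}

#' Mode-counting diagnostics and the determinant-sign parity check
#'
#' At a stable fixed point, `det(-J_{-X})` and `det(R_XX)` have the same
#' sign, which forces the number of unstable modes of the subnetwork
#' excluding `X` (eigenvalues of `-J_{-X}` with negative real part) and the
#' number of paradoxically responding modes of `X` (eigenvalues of `R_XX`
#' with negative real part) to share parity — though not necessarily value.
#'
#' @param rc an `ssn_response`.
#' @param ctx an `ssn_linearization`.
#' @param X inhibitory cell type.
#' @return `count_paradoxical_modes` and `count_unstable_modes` return
#'   integers (complex conjugates counted individually); `parity_check`
#'   returns a list with both counts, `parity_match`, `det_sign_match`,
#'   `ok` (both conditions), and `indeterminate` (near-singular
#'   determinant).
#' @export
count_paradoxical_modes <- function(rc, X) {
  bl <- response_block(rc, X)
  sum(Re(bl$values) < 0)
}

#' @rdname count_paradoxical_modes
#' @export
count_unstable_modes <- function(ctx, X) {
  J <- subnetwork_jacobian(ctx, X)
  ev <- eigen(J, only.values = TRUE)$values
  sum(Re(ev) > 0)   # eigenvalues of -J with negative real part
}

#' @rdname count_paradoxical_modes
#' @export
parity_check <- function(ctx, X, rc = NULL) {
  if (is.null(rc)) rc <- response_matrix(ctx)
  n_par <- count_paradoxical_modes(rc, X)
  n_uns <- count_unstable_modes(ctx, X)
  Jx <- subnetwork_jacobian(ctx, X)
  bl <- response_block(rc, X)
  indeterminate <- rcond(Jx) < 1e-12 || rcond(Re(bl$Rxx)) < 1e-12
  sgn_J <- det_sign(-Jx)
  sgn_R <- det_sign(bl$Rxx)
  parity_match <- (n_par %% 2) == (n_uns %% 2)
  det_sign_match <- !indeterminate && sgn_J == sgn_R && sgn_J != 0
  list(paradoxical_modes = n_par, unstable_modes = n_uns,
       parity_match = parity_match, det_sign_match = det_sign_match,
       ok = parity_match && det_sign_match,
       indeterminate = indeterminate)
}

det_sign <- function(M) {
  d <- determinant(M, logarithm = TRUE)
  as.integer(d$sign)
}
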