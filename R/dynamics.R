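#' Assemble the total input current to each recurrent population
#'
#' For each recurrent type A at every node, sums the kernel-weighted
#' contributions from all seven presynaptic types/sources
#' (`sum_B (W_AB * r_B) * delta^2 + T_A`) and also returns the per-source
#' decomposition, which is what current-source analyses plot.
#'
#' @param model an [ssn_model()].
#' @param rates `n_nodes x 4` matrix of recurrent rates (columns in
#'   `ssn_recurrent_types()` order), or an [rate_field()] over the
#'   recurrent populations (then `s` selects the size slice).
#' @param drive an [rate_field()] over the sources `L4`, `LM`, `R`.
#' @param s stimulus size (must be one of `drive$sizes`).
#' @return list with `total` (`n_nodes x 4`) and `by_source`
#'   (`n_nodes x 4 x 7` array; bias excluded, so
#'   `total = apply(by_source, 1:2, sum) + bias`).
#' @export
total_input <- function(model, rates, drive, s) {
  grid <- model$grid
  if (!same_grid(grid, drive$grid)) stop("drive grid does not match model")
  rec <- ssn_recurrent_types(); pre <- ssn_presynaptic_types()
  if (inherits(rates, "ssn_rate_field")) {
    if (!same_grid(grid, rates$grid)) stop("rates grid does not match model")
    si <- match_size(s, rates$sizes)
    rmat <- t(rates$values[rec, , si])
  } else {
    rmat <- rates
  }
  si_d <- match_size(s, drive$sizes)
  kb <- kernel_basis(grid, model$scale)
  d2 <- grid$delta^2
  n <- grid$n_nodes
  by_source <- array(0, c(n, 4, 7), dimnames = list(NULL, rec, pre))
  for (a in rec) for (b in pre) {
    w <- model$amplitude[a, b]
    if (w == 0) next
    rB <- if (b %in% rec) rmat[, match(b, rec)] else drive$values[b, , si_d]
    by_source[, a, b] <- w * d2 * (kb$basis[[kb$key[a, b]]] %*% rB)[, 1]
  }
  total <- apply(by_source, c(1, 2), sum) +
    matrix(model$bias, n, 4, byrow = TRUE)
  list(total = total, by_source = by_source)
}

match_size <- function(s, sizes) {
  si <- which(abs(sizes - s) < 1e-9)
  if (length(si) != 1) stop("stimulus size ", s, " not available")
  si
}

# Precompute what the solvers need per (model, drive): the stacked 4n x 4n
# recurrent matrix (delta^2 folded in), the external+bias current per size
# as stacked 4n vectors, stacked taus. Building this once dominates setup
# cost, so fitting code reuses the kernel basis across parameter points.
make_sim_context <- function(model, drive, kb = NULL) {
  if (!same_grid(model$grid, drive$grid)) stop("drive grid does not match model")
  if (is.null(kb)) kb <- kernel_basis(model$grid, model$scale)
  n <- model$grid$n_nodes
  ext <- external_currents(model, drive, kb)
  list(
    W = stacked_recurrent_W(model, kb),
    ext = lapply(ext, as.vector),
    tau = rep(model$tau, each = n),
    nl = model$nonlinearity,
    n = n,
    sizes = drive$sizes
  )
}

#' Solve a rectified rate-network fixed point
#'
#' Low-level solver for `r = f(W r + h)`: explicit Euler on
#' `tau dr/dt = -r + f(W r + h)` until the relative residual
#' `max |f(W r + h) - r| / (max(r) + eps)` drops below `tol`. This is the
#' workhorse behind [steady_state()] but is exposed because it runs on bare
#' matrices, which makes small closed-form test networks (e.g. a 2-unit
#' E-I pair) easy to express.
#'
#' @param W square connectivity matrix (any stacking; area element already
#'   folded in, if relevant).
#' @param h input-current vector (external drive plus bias).
#' @param tau time-constant vector (recycled).
#' @param nonlinearity transfer function kind, see [apply_nonlinearity()].
#' @param r0 initial rates (default 0).
#' @param dt Euler step in seconds; default `min(tau)/2`, which preserves
#'   the stability of any fixed point whose Jacobian eigenvalues lie in the
#'   Euler stability disc — trajectories are not accurate at this step, but
#'   only the fixed point is wanted here.
#' @param tol relative residual tolerance.
#' @param max_steps step budget; non-convergence is reported, not thrown.
#' @param ceiling divergence ceiling: any rate above it aborts with
#'   `diverged = TRUE` (supralinear networks need not have a stable fixed
#'   point, and the fitter must see that as a high-loss point, not a crash).
#' @param accelerate once the Euler residual has dropped below 1e-2, polish
#'   with damped Newton iterations on `f(Wr + h) - r = 0` (the Euler phase
#'   has already selected the attractor; Newton only sharpens the last
#'   digits, which removes the slow tail of near-critical modes). Falls
#'   back to Euler if a Newton step fails to reduce the residual.
#' @param dt_fallback on non-convergence without divergence, retry once
#'   with `dt/5`: a failed iteration can reflect an unstable Euler step
#'   (strongly oscillatory Jacobian modes) rather than an unstable fixed
#'   point.
#' @return list `rates`, `converged`, `diverged`, `steps`, `residual`.
#' @export
solve_fixed_point <- function(W, h, tau, nonlinearity = "rectified_quadratic",
                              r0 = NULL, dt = NULL, tol = 1e-6,
                              max_steps = 1e5, ceiling = 1e6,
                              accelerate = TRUE, dt_fallback = TRUE) {
  m <- nrow(W)
  stopifnot(ncol(W) == m, length(h) == m)
  tau <- rep_len(as.numeric(tau), m)
  if (is.null(dt)) dt <- min(tau) / 2
  if (dt <= 0) stop("dt must be positive")
  r <- if (is.null(r0)) numeric(m) else rep_len(as.numeric(r0), m)
  kind <- match(match.arg(nonlinearity, c("rectified_quadratic",
                                          "rectified_linear")),
                c("rectified_quadratic", "rectified_linear")) - 1L
  out <- .fixed_point_cpp(W, h, tau, kind, r, dt, tol,
                          as.integer(max_steps), ceiling, accelerate)
  if (!out$converged && !out$diverged && dt_fallback) {
    # a non-convergent, non-divergent iteration can mean the Euler step --
    # not the fixed point -- is unstable (strongly oscillatory modes);
    # retry once with a much smaller step before reporting failure
    out2 <- .fixed_point_cpp(W, h, tau, kind, r, dt / 5, tol,
                             as.integer(max_steps), ceiling, accelerate)
    if (out2$converged) out <- out2
  }
  out$rates <- as.vector(out$rates)
  out
}

#' Integrate the rate dynamics
#'
#' Explicit Euler integration of
#' `tau_A dr_A/dt = -r_A + f(sum_B (W_AB r_B) delta^2 + T_A)` for all four
#' recurrent populations at one stimulus size, with the external drive held
#' fixed. Rates stay non-negative for non-negative initial conditions
#' because `f >= 0` and the Euler factor `dt/tau <= 1/5`.
#'
#' @param model an [ssn_model()].
#' @param drive source [rate_field()] (`L4`, `LM`, `R`).
#' @param s stimulus size, one of `drive$sizes`.
#' @param r0 `n_nodes x 4` initial rates (default 0).
#' @param dt Euler step, must satisfy `dt <= min(tau)/5`; default
#'   `min(tau)/10`.
#' @param duration simulated time in seconds.
#' @param sample_every record the state every this many steps (default 10).
#' @param perturbation optional `n_nodes x 4` current added to the input
#'   from `perturb_onset` (seconds) onward.
#' @param perturb_onset onset time of the perturbation.
#' @param ceiling divergence ceiling (see [solve_fixed_point()]).
#' @return list with `times`, `trajectory` (array
#'   `[n_samples, n_nodes, 4]`), `final` (`n_nodes x 4`), `diverged`.
#' @export
integrate_dynamics <- function(model, drive, s, r0 = NULL, dt = NULL,
                               duration = 1, sample_every = 10L,
                               perturbation = NULL, perturb_onset = 0,
                               ceiling = 1e6) {
  ctx <- make_sim_context(model, drive)
  si <- match_size(s, ctx$sizes)
  n <- ctx$n
  if (is.null(dt)) dt <- min(model$tau) / 10
  if (dt <= 0 || dt > min(model$tau) / 5) {
    stop("dt must be positive and at most min(tau)/5")
  }
  h <- ctx$ext[[si]]
  pert <- if (is.null(perturbation)) NULL else as.vector(perturbation)
  r <- if (is.null(r0)) numeric(4 * n) else as.vector(r0)
  step <- dt / ctx$tau
  n_steps <- base::ceiling(duration / dt)
  keep <- seq(0L, n_steps, by = as.integer(sample_every))
  traj <- matrix(NA_real_, length(keep), 4 * n)
  traj[1, ] <- r
  ki <- 2L
  for (k in seq_len(n_steps)) {
    hh <- h
    if (!is.null(pert) && (k - 1) * dt >= perturb_onset) hh <- h + pert
    fu <- apply_nonlinearity(as.vector(ctx$W %*% r) + hh, ctx$nl)
    r <- r + step * (fu - r)
    if (any(!is.finite(r)) || max(r) > ceiling) {
      return(list(times = keep[seq_len(ki - 1L)] * dt,
                  trajectory = stack_to_array(traj[seq_len(ki - 1L), ,
                                                   drop = FALSE], n),
                  final = matrix(r, n, 4), diverged = TRUE))
    }
    if (ki <= length(keep) && k == keep[ki]) {
      traj[ki, ] <- r
      ki <- ki + 1L
    }
  }
  list(times = keep * dt,
       trajectory = stack_to_array(traj, n),
       final = stacked_to_mat(r, n),
       diverged = FALSE)
}

stacked_to_mat <- function(r, n) {
  matrix(r, n, 4, dimnames = list(NULL, ssn_recurrent_types()))
}

stack_to_array <- function(traj, n) {
  array(traj, c(nrow(traj), n, 4),
        dimnames = list(NULL, NULL, ssn_recurrent_types()))
}

#' Steady state of the network at one stimulus size
#'
#' Solves the fixed-point condition `r = f(input(r))` for the full
#' four-population spatial network. Non-convergence and divergence are
#' reported through the `converged`/`diverged` flags rather than thrown,
#' because the fitter routinely probes unstable parameter regions.
#'
#' @param model an [ssn_model()].
#' @param drive source [rate_field()].
#' @param s stimulus size, one of `drive$sizes`.
#' @param tol relative residual tolerance (default 1e-6).
#' @param r0 optional warm-start rates (`n_nodes x 4`).
#' @param dt,max_steps,ceiling forwarded to [solve_fixed_point()].
#' @return list `rates` (`n_nodes x 4`), `converged`, `diverged`,
#'   `residual`, `steps`.
#' @export
steady_state <- function(model, drive, s, tol = 1e-6, r0 = NULL, dt = NULL,
                         max_steps = 1e5, ceiling = 1e6) {
  ctx <- make_sim_context(model, drive)
  si <- match_size(s, ctx$sizes)
  out <- solve_fixed_point(ctx$W, ctx$ext[[si]], ctx$tau, ctx$nl,
                           r0 = if (is.null(r0)) NULL else as.vector(r0),
                           dt = dt, tol = tol, max_steps = max_steps,
                           ceiling = ceiling)
  out$rates <- stacked_to_mat(out$rates, ctx$n)
  out
}
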