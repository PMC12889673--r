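#' Specify a radially symmetric external-input profile
#'
#' The measured feedforward (L4) and feedback (LM) drive of the experiment
#' is unavailable here, so the generator emulates it with an explicit
#' synthetic stand-in: a radially symmetric field that holds a size-tuned
#' peak amplitude inside a plateau of roughly the stimulus radius and falls
#' off with a Gaussian edge outside (`kind = "plateau_gaussian_edge"`), or
#' a plain Gaussian bump (`kind = "gaussian"`).
#'
#' @param kind `"plateau_gaussian_edge"` or `"gaussian"`.
#' @param peak numeric vector of peak amplitudes, one per stimulus size.
#' @param radius plateau radius per size, degrees (typically `sizes / 2`);
#'   ignored for `kind = "gaussian"`.
#' @param edge Gaussian edge scale in degrees.
#' @export
input_profile_spec <- function(kind = c("plateau_gaussian_edge", "gaussian"),
                               peak, radius = NULL, edge = 6) {
  kind <- match.arg(kind)
  stopifnot(all(peak >= 0), edge > 0)
  if (kind == "plateau_gaussian_edge") {
    stopifnot(!is.null(radius), length(radius) == length(peak),
              all(diff(radius) >= 0))
  }
  structure(list(kind = kind, peak = peak, radius = radius, edge = edge),
            class = "ssn_input_profile_spec")
}

profile_value <- function(spec, d, si) {
  pk <- spec$peak[si]
  if (spec$kind == "gaussian") {
    return(pk * exp(-d^2 / (2 * spec$edge^2)))
  }
  rad <- spec$radius[si]
  ifelse(d <= rad, pk, pk * exp(-(d - rad)^2 / (2 * spec$edge^2)))
}

#' Default synthetic drive profiles
#'
#' The default size-tuned peak-amplitude tables for the synthetic L4 and LM
#' drives. L4 (feedforward) rises quickly with size and then declines
#' mildly, emulating a drive that is itself surround-suppressed; LM
#' (feedback) rises more slowly and stays sustained at large sizes. Both
#' are relatively weak at the smallest stimulus size, so small-stimulus
#' responses require recurrent amplification — the structural feature the
#' ablation analyses probe. These are explicit stand-ins for measured
#' fields, not estimates of them.
#'
#' @param sizes stimulus sizes in degrees.
#' @return list with elements `L4` and `LM`, each an
#'   [input_profile_spec()].
#' @export
default_drive_specs <- function(sizes = seq(5, 85, by = 10)) {
  stopifnot(length(sizes) == 9)
  list(
    L4 = input_profile_spec("plateau_gaussian_edge",
                            peak = c(0.25, 0.9, 1.15, 1.05, 0.8,
                                     0.62, 0.52, 0.47, 0.45),
                            radius = sizes / 2, edge = 6),
    LM = input_profile_spec("plateau_gaussian_edge",
                            peak = 0.8 * c(0.15, 0.45, 0.7, 0.9, 1.0,
                                           1.0, 0.97, 0.95, 0.93),
                            radius = sizes / 2, edge = 10)
  )
}

#' Build external input fields for all stimulus sizes
#'
#' Constructs the source [rate_field()] (`L4`, `LM`, `R`) on a grid: the
#' L4/LM fields from radially symmetric profile specs, and the residual
#' field from its Gaussian definition (see [residual_field()]).
#'
#' @param grid an [retinotopic_grid()].
#' @param sizes stimulus sizes in degrees.
#' @param spec_L4,spec_LM [input_profile_spec()]s with one peak per size.
#' @param sigma_R,residual_gain residual-field parameters (should match the
#'   model the drive will be paired with).
#' @return an `ssn_rate_field` over populations `L4`, `LM`, `R`.
#' @export
make_input_fields <- function(grid, sizes = seq(5, 85, by = 10),
                              spec_L4 = default_drive_specs(sizes)$L4,
                              spec_LM = default_drive_specs(sizes)$LM,
                              sigma_R = 30, residual_gain = 1 / 8) {
  stopifnot(length(spec_L4$peak) == length(sizes),
            length(spec_LM$peak) == length(sizes))
  d <- sqrt(grid_r2(grid))
  vals <- array(0, c(3, grid$n_nodes, length(sizes)),
                dimnames = list(ssn_source_types(), NULL, NULL))
  for (si in seq_along(sizes)) {
    vals["L4", , si] <- profile_value(spec_L4, d, si)
    vals["LM", , si] <- profile_value(spec_LM, d, si)
    vals["R", , si] <- residual_field(grid, sizes[si], sigma_R, residual_gain)
  }
  rate_field(vals, grid, sizes)
}

#' Convert a 1D radial profile to a 2D field
#'
#' Experimental analyses summarize responses by the distance between a
#' neuron's receptive-field center and the stimulus center; this lifts such
#' a 1D profile onto the 2D grid by linear interpolation in `|x|`, holding
#' the last value beyond the largest tabulated distance.
#'
#' @param profile 2-column matrix or data frame: distance (deg, sorted,
#'   non-negative) and rate.
#' @param grid an [retinotopic_grid()].
#' @return numeric vector over grid nodes (rotationally symmetric).
#' @export
radial_profile_to_field <- function(profile, grid) {
  profile <- as.matrix(profile)
  if (nrow(profile) == 0) stop("empty profile")
  d <- profile[, 1]; v <- profile[, 2]
  if (any(d < 0) || is.unsorted(d)) stop("distances must be sorted, >= 0")
  r <- sqrt(grid_r2(grid))
  if (nrow(profile) == 1) return(rep(v, grid$n_nodes))
  stats::approx(d, v, xout = pmin(pmax(r, d[1]), d[length(d)]),
                rule = 2)$y
}

# baseline amplitude table of the ground-truth generator (see the methods
# vignette for the rationale of each entry); rows E/PV/SST/VIP, columns
# E/PV/SST/VIP/L4/LM/R
base_truth_amplitude <- function() {
  tab <- rbind(
    E   = c(1.70, -1.00, -0.55, -0.02, 1.20, 1.00, 0.70),
    PV  = c(1.30, -0.70, -0.30, -0.05, 0.90, 0.40, 0.30),
    SST = c(1.00,  0.00,  0.00, -0.40, 0.10, 0.40, 0.70),
    VIP = c(0.60, -0.15, -0.15,  0.00, 0.20, 0.50, 0.40)
  )
  colnames(tab) <- ssn_presynaptic_types()
  tab
}

#' Generate a ground-truth network model
#'
#' Draws a model around the package's baseline parameter set (amplitudes
#' jittered multiplicatively, U(0.9, 1.1) per entry) and, in the `"isn"`
#' regime, enforces the inhibition-stabilized operating point the analyses
#' assume: at the 55 degree steady state the E subnetwork must be unstable
#' while the full network is stable, and steady states must converge at
#' every size. If a draw fails, the recurrent amplitudes are rescaled
#' (up when the E subnetwork was stable, down when the full network was
#' unstable or diverged) and the draw is retried, up to `max_attempts`.
#' The `"weak"` regime scales all recurrent amplitudes by 0.01, giving a
#' stable, non-ISN control network.
#'
#' @param seed integer seed; the same seed returns the identical model.
#' @param grid an [retinotopic_grid()] (default 12 x 12 at 6 deg).
#' @param scale kernel scale table or scalar, degrees (default 10).
#' @param regime `"isn"` or `"weak"`.
#' @param sizes stimulus sizes used for the convergence/ISN validation.
#' @param drive optional drive [rate_field()]; built from
#'   [default_drive_specs()] when missing.
#' @param max_attempts retry budget for the ISN search.
#' @return an [ssn_model()].
#' @export
make_ground_truth_model <- function(seed = 1,
                                    grid = retinotopic_grid(12, 12, 6),
                                    scale = 10,
                                    regime = c("isn", "weak"),
                                    sizes = seq(5, 85, by = 10),
                                    drive = NULL,
                                    max_attempts = 20) {
  regime <- match.arg(regime)
  rng <- local_rng(seed)
  rec <- ssn_recurrent_types()
  if (is.null(drive)) {
    drive <- make_input_fields(grid, sizes)
  }
  rescale <- 1
  for (attempt in seq_len(max_attempts)) {
    amp <- base_truth_amplitude() *
      matrix(rng$runif(28, 0.9, 1.1), 4, 7)
    if (regime == "weak") {
      amp[, rec] <- amp[, rec] * 0.01
      model <- ssn_model(grid, amp, scale = scale, bias = rep(0.1, 4))
      return(model)
    }
    amp[, rec] <- amp[, rec] * rescale
    model <- ssn_model(grid, amp, scale = scale, bias = rep(0.1, 4))
    status <- check_isn(model, drive, sizes)
    if (status == "ok") return(model)
    rescale <- if (status == "not_isn") rescale * 1.15 else rescale * 0.85
  }
  stop("no ISN-stable model found after ", max_attempts, " attempts")
}

# validates convergence at all sizes and the ISN condition at 55 deg (or
# the size closest to 55); returns "ok", "not_isn", or "unstable"
check_isn <- function(model, drive, sizes) {
  ctx <- make_sim_context(model, drive)
  r0 <- NULL
  sref <- sizes[which.min(abs(sizes - 55))]
  lin <- NULL
  for (si in seq_along(sizes)) {
    ss <- solve_fixed_point(ctx$W, ctx$ext[[si]], ctx$tau, ctx$nl, r0 = r0)
    if (!ss$converged) return("unstable")
    r0 <- ss$rates
    if (abs(sizes[si] - sref) < 1e-9) {
      u <- as.vector(ctx$W %*% ss$rates) + ctx$ext[[si]]
      lin <- linearization_context(
        W = ctx$W, F = nonlinearity_deriv(u, ctx$nl), tau = ctx$tau,
        types = rep(ssn_recurrent_types(), each = ctx$n),
        fixed_point = stacked_to_mat(ss$rates, ctx$n), size = sizes[si])
    }
  }
  lam_full <- Re(pick_leading(eigen(jacobian_matrix(lin),
                                    only.values = TRUE)$values))
  if (lam_full >= 0) return("unstable")
  JE <- subnetwork_jacobian(lin, c("PV", "SST", "VIP"))
  lam_E <- Re(pick_leading(eigen(JE, only.values = TRUE)$values))
  if (lam_E <= 0) return("not_isn")
  "ok"
}

# seed-local RNG that does not disturb the global .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    s
  }
  draw <- function(fun, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fun(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    out
  }
  list(
    runif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
    rnorm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd)
  )
}

#' Specify observation noise
#'
#' @param kind `"gaussian_additive"` or `"gaussian_multiplicative"`.
#' @param sd noise standard deviation; with `relative = TRUE` (default) it
#'   is a fraction of each population's peak rate (default 5%), otherwise
#'   an absolute rate.
#' @param seed integer seed.
#' @param relative interpret `sd` as a fraction of the population peak.
#' @export
noise_spec <- function(kind = c("gaussian_additive",
                                "gaussian_multiplicative"),
                       sd = 0.05, seed = 1, relative = TRUE) {
  kind <- match.arg(kind)
  stopifnot(sd >= 0)
  structure(list(kind = kind, sd = sd, seed = seed, relative = relative),
            class = "ssn_noise_spec")
}

#' Generate a synthetic "experimental" dataset
#'
#' Runs the ground-truth model to its steady state at every stimulus size,
#' adds observation noise, clips at zero, and (optionally) writes the
#' observed rates and the drive in the rate-table CSV format.
#'
#' @param truth ground-truth [ssn_model()].
#' @param drive source [rate_field()].
#' @param noise a [noise_spec()]; `sd = 0` gives the steady states exactly.
#' @param dir optional output directory; writes `observed.csv`,
#'   `drive.csv`, and `truth_model.yaml`.
#' @param ss_tol steady-state tolerance.
#' @return list of class `ssn_synthetic_dataset`: `truth`, `drive`,
#'   `observed` (noisy [rate_field()]), `noiseless` (steady states), and
#'   `files` (paths, if written).
#' @export
generate_dataset <- function(truth, drive, noise = noise_spec(),
                             dir = NULL, ss_tol = 1e-8) {
  ctx <- make_sim_context(truth, drive)
  sizes <- drive$sizes
  rec <- ssn_recurrent_types()
  vals <- array(0, c(4, ctx$n, length(sizes)),
                dimnames = list(rec, NULL, NULL))
  r0 <- NULL
  for (si in seq_along(sizes)) {
    ss <- solve_fixed_point(ctx$W, ctx$ext[[si]], ctx$tau, ctx$nl,
                            r0 = r0, tol = ss_tol)
    if (!ss$converged) {
      stop("ground-truth steady state did not converge at size ", sizes[si])
    }
    r0 <- ss$rates
    vals[, , si] <- t(stacked_to_mat(ss$rates, ctx$n))
  }
  noiseless <- rate_field(vals, truth$grid, sizes)
  obs_vals <- vals
  if (noise$sd > 0) {
    rng <- local_rng(noise$seed)
    eps <- array(rng$rnorm(length(vals)), dim(vals))
    for (p in rec) {
      sdp <- if (noise$relative) noise$sd * max(vals[p, , ]) else noise$sd
      if (noise$kind == "gaussian_additive") {
        obs_vals[p, , ] <- vals[p, , ] + sdp * eps[match(p, rec), , ]
      } else {
        obs_vals[p, , ] <- vals[p, , ] * (1 + sdp * eps[match(p, rec), , ])
      }
    }
    obs_vals <- pmax(obs_vals, 0)
  }
  observed <- rate_field(obs_vals, truth$grid, sizes)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(observed = file.path(dir, "observed.csv"),
               drive = file.path(dir, "drive.csv"),
               truth = file.path(dir, "truth_model.yaml"))
    write_rate_table(observed, files[["observed"]])
    write_rate_table(drive, files[["drive"]])
    write_model_config(truth, files[["truth"]])
  }
  structure(list(truth = truth, drive = drive, observed = observed,
                 noiseless = noiseless, files = files),
            class = "ssn_synthetic_dataset")
}

#' The package's default synthetic fixture
#'
#' A small, fast configuration used throughout the tests and the worked
#' examples: 12 x 12 grid at 6 degree spacing, the nine standard stimulus
#' sizes (5 to 85 deg in 10 deg steps), the default drive profiles, and an
#' ISN-regime ground-truth model. Results are cached per (seed, noise) in
#' the session so repeated calls are cheap.
#'
#' @param seed generator seed (default 1).
#' @param noise_sd observation-noise fraction (default 0, i.e. noiseless).
#' @return `ssn_synthetic_dataset` (see [generate_dataset()]).
#' @export
default_fixture <- function(seed = 1, noise_sd = 0) {
  key <- paste0("fx_", seed, "_", noise_sd)
  if (!is.null(fixture_cache[[key]])) return(fixture_cache[[key]])
  grid <- retinotopic_grid(12, 12, 6)
  sizes <- seq(5, 85, by = 10)
  drive <- make_input_fields(grid, sizes)
  truth <- make_ground_truth_model(seed, grid, regime = "isn",
                                   sizes = sizes, drive = drive)
  ds <- generate_dataset(truth, drive,
                         noise = noise_spec(sd = noise_sd, seed = seed))
  fixture_cache[[key]] <- ds
  ds
}

fixture_cache <- new.env(parent = emptyenv())

#' Search for a model dissociating uniform and patterned SST perturbations
#'
#' Scans ground-truth generator seeds for a network exhibiting the central
#' dynamical signature of cell-type-specific stabilization: SST is
#' required to stabilize the circuit (the subnetwork without SST has a
#' leading eigenvalue with positive real part), yet a uniform excitatory
#' perturbation of SST *increases* mean SST activity, while the patterned
#' perturbation along the smallest eigenmode `v_1` of `R_SSTSST` produces
#' a negative (paradoxical) projection. The search uses a wider grid than
#' the default fixture (20 x 20 at 6 deg) so that the stimulus does not
#' fill the grid: spatially heterogeneous activity, with SST stabilization
#' localized at the stimulus center, is what makes the uniform-perturbation
#' readout non-paradoxical (the eigen-expansion cross terms outweigh the
#' `lambda_1` term).
#'
#' @param seed_start first generator seed to try.
#' @param max_seeds how many consecutive seeds to scan.
#' @param grid search grid (default 20 x 20 at 6 deg).
#' @param size stimulus size at which the conditions are evaluated
#'   (default 55 deg, where SST involvement is strongest).
#' @param gamma_uniform,gamma_patterned perturbation amplitudes.
#' @return list with `model`, `seed`, `drive`, `uniform`
#'   ([uniform_prediction()] output), `patterned`
#'   ([patterned_prediction()] output), `sst_required`.
#' @export
find_sst_dissociation <- function(seed_start = 1, max_seeds = 20,
                                  grid = retinotopic_grid(20, 20, 6),
                                  size = 55,
                                  gamma_uniform = 0.001,
                                  gamma_patterned = 0.005) {
  sizes <- seq(5, 85, by = 10)
  drive <- make_input_fields(grid, sizes)
  for (seed in seed_start:(seed_start + max_seeds - 1)) {
    m <- tryCatch(
      make_ground_truth_model(seed, grid, sizes = sizes, drive = drive),
      error = function(e) NULL)
    if (is.null(m)) next
    lin <- build_linearization(m, drive, size)
    if (!lin$valid) next
    JS <- subnetwork_jacobian(lin, "SST")
    sst_required <- Re(leading_eigenvalue(JS, method = "dense")) > 0
    if (!sst_required) next
    rc <- response_matrix(lin)
    up <- uniform_prediction(rc, "SST", gamma_uniform)
    pp <- patterned_prediction(rc, "SST", gamma_patterned)
    if (up$mean > 0 && pp$projection < 0) {
      return(list(model = m, seed = seed, drive = drive, uniform = up,
                  patterned = pp, sst_required = TRUE, size = size))
    }
  }
  stop("no dissociating model found in ", max_seeds, " seeds")
}
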