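#' Linearize the network at a steady state
#'
#' Builds the ingredients of the Jacobian `J = Tmat^-1 (-I + F W)` at the
#' fixed point for stimulus size `s`: the stacked node-level connectivity
#' `W` over the four recurrent populations (kernel blocks times the area
#' element), the diagonal gain `F = f'(u*)` evaluated at the fixed-point
#' input, and the time constants. For the rectified quadratic, `f'(u) =
#' 2 max(u, 0)`, so silent units have zero gain and decouple from `J`.
#'
#' @param model an [ssn_model()].
#' @param drive source [rate_field()].
#' @param s stimulus size, one of `drive$sizes`.
#' @param ss_tol steady-state tolerance used before linearizing.
#' @param r0 optional warm start for the steady-state solve.
#' @return object of class `ssn_linearization`: list with `W` (4n x 4n),
#'   `F` and `tau` (length-4n vectors), `types` (type label per row),
#'   `fixed_point` (`n x 4` rates), `size`, `valid` (FALSE when the steady
#'   state did not converge), `n` nodes per population.
#' @export
build_linearization <- function(model, drive, s, ss_tol = 1e-8, r0 = NULL) {
  ctx <- make_sim_context(model, drive)
  si <- match_size(s, ctx$sizes)
  ss <- solve_fixed_point(ctx$W, ctx$ext[[si]], ctx$tau, ctx$nl,
                          r0 = if (is.null(r0)) NULL else as.vector(r0),
                          tol = ss_tol)
  u <- as.vector(ctx$W %*% ss$rates) + ctx$ext[[si]]
  linearization_context(
    W = ctx$W,
    F = nonlinearity_deriv(u, ctx$nl),
    tau = ctx$tau,
    types = rep(ssn_recurrent_types(), each = ctx$n),
    fixed_point = stacked_to_mat(ss$rates, ctx$n),
    size = s,
    valid = ss$converged && !ss$diverged
  )
}

#' Construct a linearization context directly
#'
#' Lower-level constructor used for small closed-form networks (e.g. the
#' classic 2-unit E-I pair) where `W`, the gains and the time constants are
#' written down by hand rather than derived from a spatial model.
#'
#' @param W square connectivity matrix (post-discretization).
#' @param F vector of gains `f'(u*)` (>= 0), one per row of `W`.
#' @param tau vector of time constants (> 0), recycled.
#' @param types character vector of cell-type labels per row; `"E"` rows
#'   are never removable by [subnetwork_jacobian()].
#' @param fixed_point,size,valid optional bookkeeping.
#' @export
linearization_context <- function(W, F, tau, types, fixed_point = NULL,
                                  size = NA_real_, valid = TRUE) {
  m <- nrow(W)
  stopifnot(ncol(W) == m, length(F) == m, length(types) == m)
  tau <- rep_len(tau, m)
  if (any(F < 0)) stop("gains must be non-negative")
  if (any(tau <= 0)) stop("time constants must be positive")
  structure(list(W = W, F = F, tau = tau, types = types,
                 fixed_point = fixed_point, size = size, valid = valid),
            class = "ssn_linearization")
}

#' Jacobian matrix of a linearization
#'
#' `J = Tmat^-1 (-I + F W)`, with `F` applied as a row scaling.
#'
#' @param ctx an `ssn_linearization`.
#' @export
jacobian_matrix <- function(ctx) {
  m <- nrow(ctx$W)
  J <- ctx$F * ctx$W          # diag(F) %*% W, row scaling
  diag(J) <- diag(J) - 1
  J / ctx$tau                  # diag(1/tau) %*% (.), row scaling
}

#' Jacobian of a subnetwork with inhibitory populations removed
#'
#' Removes the rows and columns of all nodes belonging to the excluded
#' inhibitory cell types. A leading eigenvalue with positive real part of
#' the reduced Jacobian means the excluded population(s) are required to
#' stabilize the circuit. E can never be excluded.
#'
#' @param ctx an `ssn_linearization`.
#' @param excluded character vector, subset of `c("PV","SST","VIP")` (or of
#'   the context's inhibitory labels).
#' @export
subnetwork_jacobian <- function(ctx, excluded = character(0)) {
  if ("E" %in% excluded) stop("the excitatory population cannot be excluded")
  bad <- setdiff(excluded, ctx$types)
  if (length(bad)) stop("unknown cell types: ", paste(bad, collapse = ", "))
  keep <- !(ctx$types %in% excluded)
  J <- jacobian_matrix(ctx)
  J[keep, keep, drop = FALSE]
}

#' Leading eigenvalue (maximal real part)
#'
#' Dense eigendecomposition for matrices up to `dense_limit` rows; above
#' that an iterative ARPACK solve for the largest-real-part eigenvalue.
#' Ties are broken deterministically: largest real part, then smallest
#' |imaginary part|, and the representative of a conjugate pair has
#' non-negative imaginary part.
#'
#' @param M square matrix.
#' @param method `"auto"`, `"dense"` or `"arpack"`.
#' @param dense_limit crossover dimension for `"auto"` (default 2000).
#' @return complex scalar.
#' @export
leading_eigenvalue <- function(M, method = c("auto", "dense", "arpack"),
                               dense_limit = 2000) {
  method <- match.arg(method)
  m <- nrow(M)
  if (method == "auto") method <- if (m <= dense_limit) "dense" else "arpack"
  if (method == "dense") {
    ev <- eigen(M, only.values = TRUE)$values
    pick_leading(ev)
  } else {
    res <- igraph::arpack(
      function(x, extra) as.vector(M %*% x),
      sym = FALSE,
      options = list(n = m, nev = min(4L, m - 2L), ncv = min(m, 25L),
                     which = "LR", maxiter = 5000)
    )
    pick_leading(as.complex(res$values))
  }
}

pick_leading <- function(ev) {
  ev <- as.complex(ev)
  ord <- order(-Re(ev), abs(Im(ev)))
  lead <- ev[ord[1]]
  if (Im(lead) < 0) lead <- Conj(lead)
  lead
}

#' Classify cell-type-specific inhibition stabilization
#'
#' For every stimulus size, evaluates the leading eigenvalue of the
#' Jacobian of five (sub)networks at the steady state: the E subnetwork
#' (all inhibition removed), the three subnetworks with one inhibitory type
#' removed, and the full network. The derived flags follow the sign of the
#' leading real parts: the circuit is inhibition-stabilized when the E
#' subnetwork is unstable but the full network is stable, and an
#' inhibitory type is "required" when removing it destabilizes the rest.
#'
#' @param model an [ssn_model()].
#' @param drive source [rate_field()].
#' @param sizes stimulus sizes to analyze (default all of `drive$sizes`).
#' @param ss_tol steady-state tolerance.
#' @return object of class `ssn_stability_report`: list with `table` (one
#'   row per size x subnetwork: `size`, `subnetwork`, `re_lead`, `im_lead`,
#'   `n_unstable`, `valid`), `flags` (one row per size:
#'   `inhibition_stabilized`, `PV_required`, `SST_required`,
#'   `VIP_required`, `full_stable`), and `tau` (the time constants the
#'   Jacobians used, since they scale the spectra).
#' @export
classify_stabilization <- function(model, drive, sizes = drive$sizes,
                                   ss_tol = 1e-8) {
  subnets <- list(
    E = c("PV", "SST", "VIP"),
    `E-SST-VIP` = "PV",
    `E-PV-VIP` = "SST",
    `E-PV-SST` = "VIP",
    full = character(0)
  )
  rows <- list()
  flags <- list()
  r0 <- NULL
  for (s in sizes) {
    ctx <- build_linearization(model, drive, s, ss_tol = ss_tol, r0 = r0)
    if (ctx$valid) r0 <- ctx$fixed_point
    lead <- list()
    for (nm in names(subnets)) {
      if (!ctx$valid) {
        rows[[length(rows) + 1]] <- data.frame(
          size = s, subnetwork = nm, re_lead = NA_real_, im_lead = NA_real_,
          n_unstable = NA_integer_, valid = FALSE)
        next
      }
      J <- subnetwork_jacobian(ctx, subnets[[nm]])
      ev <- eigen(J, only.values = TRUE)$values
      lam <- pick_leading(ev)
      lead[[nm]] <- lam
      rows[[length(rows) + 1]] <- data.frame(
        size = s, subnetwork = nm, re_lead = Re(lam), im_lead = Im(lam),
        n_unstable = sum(Re(ev) > 0), valid = TRUE)
    }
    flags[[length(flags) + 1]] <- if (ctx$valid) data.frame(
      size = s,
      inhibition_stabilized = Re(lead$E) > 0 && Re(lead$full) < 0,
      PV_required = Re(lead$`E-SST-VIP`) > 0,
      SST_required = Re(lead$`E-PV-VIP`) > 0,
      VIP_required = Re(lead$`E-PV-SST`) > 0,
      full_stable = Re(lead$full) < 0
    ) else data.frame(size = s, inhibition_stabilized = NA,
                      PV_required = NA, SST_required = NA,
                      VIP_required = NA, full_stable = NA)
  }
  structure(list(table = do.call(rbind, rows),
                 flags = do.call(rbind, flags),
                 tau = model$tau),
            class = "ssn_stability_report")
}

#' @export
print.ssn_stability_report <- function(x, ...) {
  cat("<ssn_stability_report>\n")
  print(x$flags, row.names = FALSE)
  invisible(x)
}
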