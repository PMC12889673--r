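#' Configure the connectivity fit
#'
#' The fitter infers the 32 free parameters of the circuit — the 28 kernel
#' amplitudes and the 4 biases — by constrained gradient descent on the
#' normalized loss (see [ssn_loss()]), from multiple random restarts. Box
#' constraints implement the sign rules (outgoing weights of E/L4/LM/R
#' non-negative, of PV/SST/VIP non-positive).
#'
#' @param weights non-negative loss weight `c_A` per recurrent type
#'   (default equal).
#' @param n_restarts number of random restarts (default 50).
#' @param top_k how many ranked fits [fit_multistart()] returns
#'   (default 10).
#' @param variant `"full"`, `"no_recurrent"` (all 16 recurrent amplitudes
#'   pinned at 0), `"no_E_projections"` (the four `w[A,E]` pinned at 0), or
#'   `"linear_nl"` (rectified-linear transfer function, all 32 free).
#' @param amp_max box half-width for amplitude magnitudes.
#' @param bias_range init range for biases (box is `c(-5, 5)`).
#' @param init_scale amplitudes are initialized uniformly in
#'   `[0, init_scale]` times the sign; diverging inits are resampled (up
#'   to 20 times).
#' @param seed RNG seed for the restarts (full determinism contract).
#' @param maxit,factr L-BFGS-B iteration cap and tolerance.
#' @param ss_tol,ss_max_steps steady-state solver settings inside the
#'   objective.
#' @param penalty loss assigned when every steady state diverges (each
#'   non-converged size contributes `penalty^2` times its data norm to the
#'   squared numerator; 10 = ten times the loss of predicting all zeros).
#' @param normalization `"global"` (single denominator, the default
#'   reading) or `"per_size"` (each size normalized by its own data norm).
#' @export
fit_config <- function(weights = c(E = 1, PV = 1, SST = 1, VIP = 1),
                       n_restarts = 50, top_k = 10,
                       variant = c("full", "no_recurrent",
                                   "no_E_projections", "linear_nl"),
                       amp_max = 5, bias_range = c(-1, 1),
                       init_scale = 1, seed = 1,
                       maxit = 200, factr = 1e9,
                       ss_tol = 1e-8, ss_max_steps = 3000,
                       penalty = 10,
                       normalization = c("global", "per_size")) {
  variant <- match.arg(variant)
  normalization <- match.arg(normalization)
  weights <- as_named_vec(weights, ssn_recurrent_types(), "weights")
  if (any(weights < 0) || all(weights == 0)) {
    stop("weights must be non-negative with at least one positive")
  }
  stopifnot(n_restarts >= 1, top_k <= n_restarts, amp_max > 0)
  structure(list(weights = weights, n_restarts = n_restarts, top_k = top_k,
                 variant = variant, amp_max = amp_max,
                 bias_range = bias_range, init_scale = init_scale,
                 seed = seed, maxit = maxit, factr = factr,
                 ss_tol = ss_tol, ss_max_steps = ss_max_steps,
                 penalty = penalty, normalization = normalization),
            class = "ssn_fit_config")
}

#' Normalized fitting loss
#'
#' `L = sqrt( sum_s sum_A sum_x c_A (r - rtilde)^2 /
#'            sum_s sum_A sum_x c_A rtilde^2 )`:
#' the weighted root-squared error between predicted and observed rate
#' fields, normalized by the weighted data norm so that predicting zero
#' everywhere gives exactly 1. The denominator is a pure normalization; an
#' alternative per-size normalization (each size divided by its own data
#' norm before summing) is available via `normalization`.
#'
#' @param predicted,observed [rate_field()]s over the same populations,
#'   grid, and sizes.
#' @param weights non-negative weight per recurrent type.
#' @param normalization `"global"` or `"per_size"`.
#' @return non-negative scalar.
#' @export
ssn_loss <- function(predicted, observed,
                     weights = c(E = 1, PV = 1, SST = 1, VIP = 1),
                     normalization = c("global", "per_size")) {
  normalization <- match.arg(normalization)
  pops <- observed$populations
  stopifnot(identical(predicted$populations, pops),
            length(predicted$sizes) == length(observed$sizes))
  weights <- as_named_vec(weights[pops], pops, "weights")
  cw <- array(weights, dim(observed$values))
  den_s <- apply(cw * observed$values^2, 3, sum)
  if (all(den_s == 0)) stop("all-zero observed rates: loss undefined")
  sq <- cw * (predicted$values - observed$values)^2
  num_s <- apply(sq, 3, sum)
  if (normalization == "global") {
    sqrt(sum(num_s) / sum(den_s))
  } else {
    sqrt(sum(num_s / den_s))
  }
}

#' Predict steady-state rate fields of a model
#'
#' Stacks [steady_state()] solutions over stimulus sizes into a
#' [rate_field()], warm-starting each size from the previous one.
#' Non-converged sizes are zero-filled and flagged in the `converged`
#' attribute; the fitter maps them to a penalty rather than an error.
#'
#' @param object an [ssn_model()].
#' @param drive source [rate_field()].
#' @param sizes subset of `drive$sizes` (default all).
#' @param ss_tol residual tolerance.
#' @param ... unused.
#' @return `ssn_rate_field` with attribute `converged` (logical per size).
#' @export
predict.ssn_model <- function(object, drive, sizes = drive$sizes,
                              ss_tol = 1e-8, ...) {
  ctx <- make_sim_context(object, drive)
  rec <- ssn_recurrent_types()
  vals <- array(0, c(4, ctx$n, length(sizes)),
                dimnames = list(rec, NULL, NULL))
  conv <- logical(length(sizes))
  r0 <- NULL
  for (k in seq_along(sizes)) {
    si <- match_size(sizes[k], ctx$sizes)
    ss <- solve_fixed_point(ctx$W, ctx$ext[[si]], ctx$tau, ctx$nl,
                            r0 = r0, tol = ss_tol)
    conv[k] <- ss$converged
    if (ss$converged) {
      vals[, , k] <- t(stacked_to_mat(ss$rates, ctx$n))
      r0 <- ss$rates
    }
  }
  out <- rate_field(vals, object$grid, sizes)
  attr(out, "converged") <- conv
  out
}

# ---- parameter vector plumbing -------------------------------------------

# free-parameter layout: the 28 amplitudes (column-major over the 4 x 7
# table) then the 4 biases; variants pin a subset at zero
param_template <- function(config) {
  rec <- ssn_recurrent_types(); pre <- ssn_presynaptic_types()
  sign <- matrix(rep(ifelse(pre %in% excitatory_presynaptic(), 1, -1),
                     each = 4), 4, 7, dimnames = list(rec, pre))
  fixed <- matrix(FALSE, 4, 7, dimnames = list(rec, pre))
  if (config$variant == "no_recurrent") fixed[, rec] <- TRUE
  if (config$variant == "no_E_projections") fixed[, "E"] <- TRUE
  free <- c(!fixed, rep(TRUE, 4))
  lower <- c(ifelse(sign > 0, 0, -config$amp_max), rep(-5, 4))
  upper <- c(ifelse(sign > 0, config$amp_max, 0), rep(5, 4))
  list(sign = sign, free = free, lower = lower[free], upper = upper[free],
       n_free = sum(free))
}

vec_to_params <- function(p, tmpl) {
  full <- numeric(32)
  full[tmpl$free] <- p
  list(amplitude = matrix(full[1:28], 4, 7,
                          dimnames = dimnames(tmpl$sign)),
       bias = stats::setNames(full[29:32], ssn_recurrent_types()))
}

params_to_vec <- function(amplitude, bias, tmpl) {
  c(as.vector(amplitude), as.numeric(bias))[tmpl$free]
}

# ---- objective with implicit-function gradient ---------------------------

# Precomputes everything reusable across parameter points: unit-amplitude
# kernel matrices, their products with the (fixed) source fields, the data
# tensors. The gradient differentiates loss(steady_state(params)) through
# the fixed-point relation r = f(Wr + h): dr/dp = (I - FW)^-1 F du/dp,
# evaluated by one adjoint solve per stimulus size.
make_objective <- function(template, data, drive, config) {
  grid <- template$grid
  n <- grid$n_nodes
  rec <- ssn_recurrent_types(); pre <- ssn_presynaptic_types()
  src <- ssn_source_types()
  nl <- if (config$variant == "linear_nl") "rectified_linear" else
    template$nonlinearity
  kb <- kernel_basis(grid, template$scale)
  sizes <- data$sizes
  n_sizes <- length(sizes)
  si_drive <- vapply(sizes, match_size, integer(1), sizes = drive$sizes)
  # source-field kernel products, fixed across parameter points:
  # src_cur[[a]][[b]] is an n x n_sizes matrix
  src_cur <- lapply(stats::setNames(nm = rec), function(a) {
    lapply(stats::setNames(nm = src), function(b) {
      G <- kb$basis[[kb$key[a, b]]]
      sapply(seq_len(n_sizes), function(k) {
        grid$delta^2 * (G %*% drive$values[b, , si_drive[k]])[, 1]
      })
    })
  })
  w <- config$weights
  cw_pop <- rep(w, each = n)                      # stacked weight vector
  obs <- lapply(seq_len(n_sizes), function(k) {
    as.vector(t(data$values[rec, , k]))            # stacked 4n
  })
  den_s <- vapply(seq_len(n_sizes), function(k) sum(cw_pop * obs[[k]]^2),
                  numeric(1))
  den_tot <- sum(den_s)
  tau <- rep(template$tau, each = n)
  tmpl <- param_template(config)
  d2 <- grid$delta^2
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L

  eval_point <- function(p) {
    key <- paste(format(p, digits = 17), collapse = ",")
    if (identical(cache$key, key)) return(cache$val)
    pars <- vec_to_params(p, tmpl)
    amp <- pars$amplitude
    # stacked recurrent W and external currents
    W <- matrix(0, 4 * n, 4 * n)
    for (ai in 1:4) for (bi in 1:4) {
      wab <- amp[ai, bi]
      if (wab != 0) {
        W[block_idx(ai, n), block_idx(bi, n)] <-
          wab * d2 * kb$basis[[kb$key[rec[ai], rec[bi]]]]
      }
    }
    ext <- lapply(seq_len(n_sizes), function(k) {
      h <- numeric(4 * n)
      for (ai in 1:4) {
        cur <- rep(pars$bias[ai], n)
        for (b in src) {
          wab <- amp[ai, b]
          if (wab != 0) cur <- cur + wab * src_cur[[ai]][[b]][, k]
        }
        h[block_idx(ai, n)] <- cur
      }
      h
    })
    # each solve starts from the observed rates of that size (fixed cold
    # fallback): the objective is then a deterministic function of the
    # parameters, which a quasi-Newton optimizer requires
    states <- vector("list", n_sizes)
    conv <- logical(n_sizes)
    for (k in seq_len(n_sizes)) {
      ss <- solve_fixed_point(W, ext[[k]], tau, nl, r0 = obs[[k]],
                              tol = config$ss_tol,
                              max_steps = config$ss_max_steps)
      if (!ss$converged) {
        ss <- solve_fixed_point(W, ext[[k]], tau, nl, tol = config$ss_tol,
                                max_steps = config$ss_max_steps)
      }
      conv[k] <- ss$converged
      if (ss$converged) states[[k]] <- ss$rates
    }
    num_s <- vapply(seq_len(n_sizes), function(k) {
      if (!conv[k]) return(config$penalty^2 * den_s[k])
      sum(cw_pop * (states[[k]] - obs[[k]])^2)
    }, numeric(1))
    loss <- if (config$normalization == "global") {
      sqrt(sum(num_s) / den_tot)
    } else {
      sqrt(sum(num_s / den_s))
    }
    # gradient by adjoint solve per converged size
    gr <- numeric(tmpl$n_free)
    if (loss > 1e-12 && any(conv)) {
      gfull <- numeric(32)
      for (k in seq_len(n_sizes)) {
        if (!conv[k]) next
        r <- states[[k]]
        u <- as.vector(W %*% r) + ext[[k]]
        Fv <- nonlinearity_deriv(u, nl)
        denom <- if (config$normalization == "global") den_tot else den_s[k]
        g_r <- cw_pop * (r - obs[[k]]) / (loss * denom)
        A <- -(Fv * W); diag(A) <- diag(A) + 1     # I - diag(F) W
        a <- solve(t(A), g_r)
        adj <- Fv * a                               # dL/du at fixed r
        for (ai in 1:4) {
          ia <- block_idx(ai, n)
          adj_a <- adj[ia]
          for (bi in seq_along(pre)) {
            b <- pre[bi]
            if (!tmpl$free[(bi - 1) * 4 + ai]) next
            du <- if (b %in% rec) {
              d2 * (kb$basis[[kb$key[rec[ai], b]]] %*%
                      r[block_idx(match(b, rec), n)])[, 1]
            } else {
              src_cur[[ai]][[b]][, k]
            }
            gfull[(bi - 1) * 4 + ai] <- gfull[(bi - 1) * 4 + ai] +
              sum(adj_a * du)
          }
          gfull[28 + ai] <- gfull[28 + ai] + sum(adj_a)
        }
      }
      gr <- gfull[tmpl$free]
    }
    n_eval <<- n_eval + 1L
    cache$key <- key
    cache$val <- list(loss = loss, grad = gr, converged = conv)
    cache$val
  }

  list(
    fn = function(p) eval_point(p)$loss,
    gr = function(p) eval_point(p)$grad,
    detail = function(p) eval_point(p),
    tmpl = tmpl,
    n_eval = function() n_eval,
    nl = nl
  )
}

#' Fit the 32 free parameters from one starting point
#'
#' Local constrained minimization of the loss over amplitudes and biases
#' with `stats::optim` (L-BFGS-B; the box constraints encode the sign
#' rules and any variant pinning). Gradients are computed analytically by
#' implicit differentiation of the fixed-point condition, which matches
#' central finite differences of the objective to better than 1e-3
#' relative (tested). Parameter points whose dynamics diverge are assigned
#' a fixed large penalty with zero gradient, so line searches back off
#' instead of crashing.
#'
#' @param template an [ssn_model()] supplying everything that is not
#'   fitted (grid, kernel scales, taus, nonlinearity, residual
#'   parameters); its amplitudes/biases are the default init.
#' @param data observed [rate_field()] over the recurrent populations.
#' @param drive source [rate_field()].
#' @param config an [fit_config()].
#' @param init optional list with `amplitude` (4 x 7) and `bias` (4) to
#'   start from (defaults to the template's values); must respect the
#'   bounds.
#' @return object of class `ssn_fit`: list with `model` (fitted
#'   [ssn_model()]), `loss`, `converged` (optimizer reported convergence
#'   and all steady states converged at the optimum), `counts`,
#'   `message`, `restart` (index, when run under [fit_multistart()]).
#' @export
fit_once <- function(template, data, drive, config = fit_config(),
                     init = NULL) {
  obj <- make_objective(template, data, drive, config)
  if (is.null(init)) {
    init <- list(amplitude = template$amplitude, bias = template$bias)
  }
  if (config$variant == "no_recurrent") {
    init$amplitude[, ssn_recurrent_types()] <- 0
  }
  if (config$variant == "no_E_projections") init$amplitude[, "E"] <- 0
  p0 <- params_to_vec(init$amplitude, init$bias, obj$tmpl)
  p0 <- pmin(pmax(p0, obj$tmpl$lower), obj$tmpl$upper)
  opt <- stats::optim(p0, fn = obj$fn, gr = obj$gr, method = "L-BFGS-B",
                      lower = obj$tmpl$lower, upper = obj$tmpl$upper,
                      control = list(maxit = config$maxit,
                                     factr = config$factr))
  # guard against round-off just outside the box
  opt$par <- pmin(pmax(opt$par, obj$tmpl$lower), obj$tmpl$upper)
  det <- obj$detail(opt$par)
  pars <- vec_to_params(opt$par, obj$tmpl)
  model <- set_fitted_params(template, pars$amplitude, pars$bias)
  if (config$variant == "linear_nl") {
    model$nonlinearity <- "rectified_linear"
  }
  structure(list(model = model, loss = det$loss,
                 converged = opt$convergence == 0 && all(det$converged),
                 optim_convergence = opt$convergence,
                 message = opt$message,
                 counts = opt$counts, n_eval = obj$n_eval(),
                 restart = NA_integer_),
            class = "ssn_fit")
}

#' @export
print.ssn_fit <- function(x, ...) {
  cat(sprintf("<ssn_fit> loss %.5f | converged %s | %d evaluations\n",
              x$loss, x$converged, x$n_eval))
  invisible(x)
}

#' Multi-start fit with ranking
#'
#' Runs [fit_once()] from `n_restarts` random initializations (amplitudes
#' uniform in sign-respecting boxes, biases uniform in `bias_range`;
#' initializations whose dynamics already diverge at every size are
#' resampled, up to 20 times each) and returns the `top_k` fits ranked by
#' loss. Fully reproducible given `config$seed`.
#'
#' @inheritParams fit_once
#' @return object of class `ssn_fit_ranking`: list with `fits` (ranked
#'   list of `ssn_fit`), `ranking` (data frame: rank, restart, loss,
#'   converged), `config`.
#' @export
fit_multistart <- function(template, data, drive, config = fit_config()) {
  rng <- local_rng(config$seed)
  tmpl <- param_template(config)
  probe <- make_objective(template, data, drive, config)
  inits <- vector("list", config$n_restarts)
  for (i in seq_len(config$n_restarts)) {
    for (try in 1:20) {
      amp <- matrix(rng$runif(28, 0, config$init_scale), 4, 7) * tmpl$sign
      dimnames(amp) <- dimnames(tmpl$sign)
      bias <- rng$runif(4, config$bias_range[1], config$bias_range[2])
      if (config$variant == "no_recurrent") {
        amp[, ssn_recurrent_types()] <- 0
      }
      if (config$variant == "no_E_projections") amp[, "E"] <- 0
      p <- params_to_vec(amp, bias, tmpl)
      det <- probe$detail(p)
      if (all(det$converged)) break
    }
    inits[[i]] <- list(amplitude = amp, bias = bias)
  }
  fits <- vector("list", config$n_restarts)
  for (i in seq_len(config$n_restarts)) {
    f <- fit_once(template, data, drive, config, init = inits[[i]])
    f$restart <- i
    fits[[i]] <- f
  }
  ord <- order(vapply(fits, function(f) f$loss, numeric(1)))
  keep <- ord[seq_len(config$top_k)]
  ranking <- data.frame(
    rank = seq_along(keep),
    restart = vapply(fits[keep], function(f) f$restart, integer(1)),
    loss = vapply(fits[keep], function(f) f$loss, numeric(1)),
    converged = vapply(fits[keep], function(f) f$converged, logical(1))
  )
  structure(list(fits = fits[keep], ranking = ranking, config = config),
            class = "ssn_fit_ranking")
}

#' @export
print.ssn_fit_ranking <- function(x, ...) {
  cat("<ssn_fit_ranking>\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}
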