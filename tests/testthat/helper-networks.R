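# shared builders for small test networks

# model with all kernel amplitudes zero: steady state is f(bias) exactly
zero_coupling_model <- function(bias = rep(2, 4), n = 4, delta = 6,
                                nonlinearity = "rectified_quadratic") {
  ssn_model(retinotopic_grid(n, n, delta),
            amplitude = matrix(0, 4, 7), bias = bias,
            nonlinearity = nonlinearity)
}

# drive field of zeros on a model's grid
zero_drive <- function(grid, sizes = c(5, 15)) {
  vals <- array(0, c(3, grid$n_nodes, length(sizes)),
                dimnames = list(ssn_source_types(), NULL, NULL))
  rate_field(vals, grid, sizes)
}

# classic 2-population E-I pair as a linearization context;
# gains F and weights chosen directly
ei_toy_ctx <- function(wEE, wEI, wIE, wII, FE = 1, FI = 1,
                       tau = c(0.02, 0.01)) {
  W <- matrix(c(wEE, wIE, -wEI, -wII), 2, 2)  # columns: from E, from I
  linearization_context(W = W, F = c(FE, FI), tau = tau,
                        types = c("E", "PV"), valid = TRUE)
}

# closed-form 2x2 oracle for the E-I pair: response matrix entries from
# the determinant formula R = adj(I - FW) F / det(I - FW)
ei_toy_R_oracle <- function(wEE, wEI, wIE, wII, FE = 1, FI = 1) {
  A <- matrix(c(1 - FE * wEE, -FI * wIE, FE * wEI, 1 + FI * wII), 2, 2)
  solve(A) %*% diag(c(FE, FI))
}

# moderate-strength amplitude table guaranteed well inside the stable
# regime, for tests that need nontrivial spatial coupling
base_amp_for_tests <- function() {
  ssnspace:::base_truth_amplitude() * 0.6
}

# random stable 4-type spatial network on a small grid, as a linearization
# context; returns NULL when the draw is unstable or has silent units
random_stable_ctx <- function(seed, n = 4, size = 35) {
  set.seed(seed)
  grid <- retinotopic_grid(n, n, 6)
  sizes <- seq(5, 85, by = 10)
  amp <- matrix(runif(28, 0, 1), 4, 7)
  sign <- rep(c(1, -1, -1, -1, 1, 1, 1), each = 4)
  amp <- amp * matrix(sign, 4, 7)
  m <- ssn_model(grid, amp, scale = 10, bias = runif(4, 0.2, 0.6))
  drive <- make_input_fields(grid, sizes)
  lin <- tryCatch(build_linearization(m, drive, size),
                  error = function(e) NULL)
  if (is.null(lin) || !lin$valid) return(NULL)
  if (any(lin$fixed_point <= 1e-6)) return(NULL)   # silent units decouple
  lead <- Re(leading_eigenvalue(jacobian_matrix(lin), method = "dense"))
  if (lead >= 0) return(NULL)
  lin
}
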