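test_that("zero-coupling Jacobian is diagonal with eigenvalues -1/tau", {
  m <- zero_coupling_model(bias = rep(2, 4))
  lin <- build_linearization(m, zero_drive(m$grid), 5)
  J <- jacobian_matrix(lin)
  expect_equal(J, diag(-1 / lin$tau))
  ev <- sort(unique(round(Re(eigen(J, only.values = TRUE)$values), 9)))
  expect_equal(ev, sort(unique(-1 / m$tau)))
})

test_that("Jacobian blocks follow T^-1 F W off the diagonal", {
  m <- zero_coupling_model(bias = c(1, 0.8, 0.6, 0.5), n = 3)
  m$amplitude["E", "PV"] <- -0.7
  m$amplitude["PV", "E"] <- 0.9
  lin <- build_linearization(m, zero_drive(m$grid), 5)
  J <- jacobian_matrix(lin)
  n <- m$grid$n_nodes
  blk <- function(a, b) J[((a - 1) * n + 1):(a * n),
                          ((b - 1) * n + 1):(b * n)]
  W <- stacked_recurrent_W(m)
  Wab <- function(a, b) W[((a - 1) * n + 1):(a * n),
                          ((b - 1) * n + 1):(b * n)]
  FE <- lin$F[1:n]
  expect_equal(blk(1, 2), (FE * Wab(1, 2)) / m$tau[["E"]])
  FP <- lin$F[(n + 1):(2 * n)]
  expect_equal(blk(2, 1), (FP * Wab(2, 1)) / m$tau[["PV"]])
})

test_that("Jacobian matches finite differences of the dynamics map", {
  # tiny 2x2 grid so the full FD Jacobian is cheap
  grid <- retinotopic_grid(2, 2, 6)
  amp <- base_amp_for_tests()
  m <- ssn_model(grid, amp, scale = 10, bias = rep(0.3, 4))
  drive <- make_input_fields(grid)
  lin <- build_linearization(m, drive, 35, ss_tol = 1e-12)
  expect_true(lin$valid)
  J <- jacobian_matrix(lin)
  ctx <- ssnspace:::make_sim_context(m, drive)
  si <- ssnspace:::match_size(35, ctx$sizes)
  G <- function(r) {
    (-r + apply_nonlinearity(as.vector(ctx$W %*% r) + ctx$ext[[si]],
                             ctx$nl)) / ctx$tau
  }
  r0 <- as.vector(lin$fixed_point)
  eps <- 1e-6
  Jfd <- sapply(seq_along(r0), function(i) {
    e <- numeric(length(r0)); e[i] <- eps
    (G(r0 + e) - G(r0 - e)) / (2 * eps)
  })
  expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-4)
})

test_that("subnetwork extraction removes the right rows and columns", {
  ds <- default_fixture(1)
  lin <- build_linearization(ds$truth, ds$drive, 55)
  n <- ds$truth$grid$n_nodes
  J <- jacobian_matrix(lin)
  expect_equal(subnetwork_jacobian(lin, character(0)), J)
  JE <- subnetwork_jacobian(lin, c("PV", "SST", "VIP"))
  expect_equal(JE, J[1:n, 1:n])
  for (k in 1:3) {
    ex <- combn(c("PV", "SST", "VIP"), k)[, 1]
    expect_equal(nrow(subnetwork_jacobian(lin, ex)), (4 - k) * n)
  }
  expect_error(subnetwork_jacobian(lin, "E"), "cannot be excluded")
  expect_error(subnetwork_jacobian(lin, "L4"), "unknown")
})

test_that("leading eigenvalue picks maximal real part deterministically", {
  expect_equal(leading_eigenvalue(diag(c(-1, -2))), -1 + 0i)
  expect_equal(leading_eigenvalue(matrix(c(0, 1, 1, 0), 2)), 1 + 0i)
  # conjugate-pair representative has non-negative imaginary part
  rot <- matrix(c(-0.1, -1, 1, -0.1), 2)
  lam <- leading_eigenvalue(rot)
  expect_gte(Im(lam), 0)
  expect_equal(Re(lam), -0.1)
  # dense and ARPACK paths agree on a random matrix at the crossover
  set.seed(99)
  M <- matrix(rnorm(60 * 60), 60) / sqrt(60)
  diag(M) <- diag(M) - 0.5
  ld <- leading_eigenvalue(M, method = "dense")
  la <- leading_eigenvalue(M, method = "arpack")
  expect_equal(Re(la), Re(ld), tolerance = 1e-8)
  expect_equal(abs(Im(la)), abs(Im(ld)), tolerance = 1e-8)
})

test_that("stabilization classification separates weak and ISN regimes", {
  grid <- retinotopic_grid(12, 12, 6)
  drive <- make_input_fields(grid)
  mw <- make_ground_truth_model(3, grid, regime = "weak", drive = drive)
  rep_w <- classify_stabilization(mw, drive, c(5, 55))
  expect_false(any(rep_w$flags$inhibition_stabilized))
  expect_false(any(rep_w$flags$PV_required | rep_w$flags$SST_required |
                     rep_w$flags$VIP_required))
  ds <- default_fixture(1)
  rep_i <- classify_stabilization(ds$truth, ds$drive, c(55))
  expect_true(rep_i$flags$inhibition_stabilized)
  expect_true(rep_i$flags$full_stable)
  expect_equal(nrow(rep_i$table), 5)
  full_tab <- classify_stabilization(ds$truth, ds$drive, c(5, 55, 85))
  expect_equal(nrow(full_tab$table), 15)
  # sign consistency: converged fixed points are stable
  expect_true(all(full_tab$table$re_lead[full_tab$table$subnetwork ==
                                           "full"] < 0))
})

test_that("rescaling all taus rescales the spectrum but not the flags", {
  ds <- default_fixture(1)
  for (fac in c(0.5, 3)) {
    m2 <- ds$truth
    m2$tau <- ds$truth$tau * fac
    lin1 <- build_linearization(ds$truth, ds$drive, 55)
    lin2 <- build_linearization(m2, ds$drive, 55)
    ev1 <- eigen(jacobian_matrix(lin1), only.values = TRUE)$values
    ev2 <- eigen(jacobian_matrix(lin2), only.values = TRUE)$values
    expect_equal(sort(Re(ev2)), sort(Re(ev1) / fac), tolerance = 1e-6)
    r1 <- classify_stabilization(ds$truth, ds$drive, 55)
    r2 <- classify_stabilization(m2, ds$drive, 55)
    expect_identical(r1$flags[, -1], r2$flags[, -1])
  }
})
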