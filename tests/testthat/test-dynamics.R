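test_that("zero-coupling steady states equal f(bias) exactly", {
  m <- zero_coupling_model(bias = c(2, 3, -1, 0.5))
  drive <- zero_drive(m$grid)
  ss <- steady_state(m, drive, 5, tol = 1e-10)
  expect_true(ss$converged)
  expect_equal(ss$rates[, "E"], rep(4, m$grid$n_nodes), tolerance = 1e-8)
  expect_equal(ss$rates[, "PV"], rep(9, m$grid$n_nodes), tolerance = 1e-8)
  expect_equal(ss$rates[, "SST"], rep(0, m$grid$n_nodes))
  expect_equal(ss$rates[, "VIP"], rep(0.25, m$grid$n_nodes),
               tolerance = 1e-8)
  ml <- zero_coupling_model(bias = c(0.5, -1, 2, 0),
                            nonlinearity = "rectified_linear")
  ssl <- steady_state(ml, zero_drive(ml$grid), 5, tol = 1e-10)
  expect_equal(ssl$rates[, "E"], rep(0.5, 16), tolerance = 1e-8)
  expect_equal(ssl$rates[, "PV"], rep(0, 16))
  expect_equal(ssl$rates[, "SST"], rep(2, 16), tolerance = 1e-8)
})

test_that("total input decomposes by source and respects kernel mass", {
  ds <- default_fixture(1)
  rates <- matrix(1, ds$truth$grid$n_nodes, 4)
  ti <- total_input(ds$truth, rates, ds$drive, 55)
  recon <- apply(ti$by_source, c(1, 2), sum) +
    matrix(ds$truth$bias, nrow(rates), 4, byrow = TRUE)
  expect_equal(ti$total, recon, tolerance = 1e-12)
  # single presynaptic source, uniform rate: interior current ~ w * c + T
  m <- zero_coupling_model(bias = rep(0.5, 4), n = 13)
  m$amplitude["E", "PV"] <- -0.8
  drive13 <- zero_drive(m$grid)
  rates_u <- matrix(3, m$grid$n_nodes, 4)
  ti2 <- total_input(m, rates_u, drive13, 5)
  cn <- center_node(m$grid)
  expect_equal(unname(ti2$total[cn, "E"]), -0.8 * 3 + 0.5,
               tolerance = 0.01)
  expect_error(total_input(zero_coupling_model(), rates, ds$drive, 55),
               "grid")
})

test_that("Euler integration converges, stays nonnegative, is dt-robust", {
  m <- zero_coupling_model(bias = c(2, -1, 1, 1))
  drive <- zero_drive(m$grid)
  out <- integrate_dynamics(m, drive, 5, duration = 0.6)
  expect_false(out$diverged)
  expect_true(all(out$trajectory >= 0))
  expect_equal(out$final[, "E"], rep(4, 16), tolerance = 1e-3)
  expect_equal(out$final[, "PV"], rep(0, 16))
  out2 <- integrate_dynamics(m, drive, 5, duration = 0.6,
                             dt = min(m$tau) / 20)
  expect_equal(out$final, out2$final, tolerance = 1e-3)
  expect_error(integrate_dynamics(m, drive, 5, dt = min(m$tau)),
               "min\\(tau\\)/5")
})

test_that("divergent dynamics are flagged, not thrown", {
  m <- zero_coupling_model(bias = rep(1, 4))
  m$amplitude["E", "E"] <- 4   # runaway excitation, no inhibition
  drive <- zero_drive(m$grid)
  ss <- steady_state(m, drive, 5)
  expect_false(ss$converged)
  expect_true(ss$diverged)
  out <- integrate_dynamics(m, drive, 5, duration = 2)
  expect_true(out$diverged)
})

test_that("fixed point matches a damped fixed-point-iteration oracle", {
  # 2-unit E-I pair in the stacked representation
  W <- matrix(c(0.3, 0.4, -0.5, -0.2), 2, 2)
  h <- c(1.2, 0.8)
  sol <- solve_fixed_point(W, h, tau = c(0.02, 0.01), tol = 1e-10)
  expect_true(sol$converged)
  # oracle: heavily damped Picard iteration, independent of the solver
  r <- c(0, 0)
  for (k in 1:200000) {
    r <- 0.98 * r + 0.02 * pmax(as.vector(W %*% r) + h, 0)^2
  }
  expect_equal(sol$rates, r, tolerance = 1e-6)
})

test_that("steady state is independent of initialization within the basin", {
  ds <- default_fixture(1)
  ss1 <- steady_state(ds$truth, ds$drive, 55, tol = 1e-9)
  r0 <- matrix(0.5, ds$truth$grid$n_nodes, 4)
  ss2 <- steady_state(ds$truth, ds$drive, 55, tol = 1e-9, r0 = r0)
  expect_true(ss1$converged && ss2$converged)
  expect_equal(ss1$rates, ss2$rates, tolerance = 1e-6)
  expect_lt(ss1$residual, 1e-9)
})

test_that("shifting the input shifts the interior steady-state response", {
  grid <- retinotopic_grid(15, 15, 6)
  sizes <- c(25)
  # drive bump at the center vs shifted one node in x
  mk_drive <- function(x0) {
    d <- sqrt((grid$coords[, 1] - x0)^2 + grid$coords[, 2]^2)
    vals <- array(0, c(3, grid$n_nodes, 1),
                  dimnames = list(ssn_source_types(), NULL, NULL))
    vals["L4", , 1] <- exp(-d^2 / (2 * 12^2))
    vals["LM", , 1] <- 0.5 * exp(-d^2 / (2 * 15^2))
    rate_field(vals, grid, sizes)
  }
  m <- ssn_model(grid, amplitude = base_amp_for_tests(), scale = 10,
                 bias = rep(0.1, 4))
  ss0 <- steady_state(m, mk_drive(0), 25, tol = 1e-9)
  ss1 <- steady_state(m, mk_drive(6), 25, tol = 1e-9)
  expect_true(ss0$converged && ss1$converged)
  # compare E rates on the interior: node (i, j) of shifted == (i-1, j)
  idx <- function(ix, iy) (iy - 1) * 15 + ix
  inner <- expand.grid(ix = 5:10, iy = 5:11)
  a <- ss1$rates[idx(inner$ix + 1, inner$iy), "E"]
  b <- ss0$rates[idx(inner$ix, inner$iy), "E"]
  expect_lt(max(abs(a - b)), 0.02 * max(abs(b)))
})
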