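test_that("zero coupling gives a diagonal response matrix R = F", {
  m <- zero_coupling_model(bias = rep(2, 4))
  lin <- build_linearization(m, zero_drive(m$grid), 5)
  rc <- response_matrix(lin)
  expect_equal(rc$R, diag(lin$F))
  # gains 2[u]+ = 4 everywhere, no paradoxical modes, parity trivially holds
  for (X in c("PV", "SST", "VIP")) {
    expect_equal(count_paradoxical_modes(rc, X), 0)
    expect_equal(count_unstable_modes(lin, X), 0)
    pc <- parity_check(lin, X, rc)
    expect_true(pc$ok)
  }
  bl <- response_block(rc, "PV")
  expect_equal(Re(bl$values), rep(4, m$grid$n_nodes), tolerance = 1e-9)
})

test_that("the 2-population E-I pair reproduces the classic paradox rule", {
  # the inhibitory response to input into I is negative iff the E
  # subnetwork alone is unstable (1 - FE*wEE < 0)
  cases <- list(
    isn = list(wEE = 1.5, wEI = 1.0, wIE = 1.2, wII = 0.3),
    non_isn = list(wEE = 0.5, wEI = 1.0, wIE = 1.2, wII = 0.3)
  )
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    ctx <- do.call(ei_toy_ctx, cs)
    # fixed point stable in both cases
    expect_lt(Re(leading_eigenvalue(jacobian_matrix(ctx))), 0)
    rc <- response_matrix(ctx)
    oracle <- do.call(ei_toy_R_oracle, cs)
    expect_equal(rc$R, oracle, tolerance = 1e-12)
    R_II <- rc$R[2, 2]
    e_unstable <- cs$wEE > 1
    expect_identical(R_II < 0, e_unstable)
    pc <- parity_check(ctx, "PV", rc)
    expect_equal(pc$unstable_modes, as.integer(e_unstable))
    expect_equal(pc$paradoxical_modes, as.integer(e_unstable))
    expect_true(pc$ok)
  }
})

test_that("uniform predictions agree with direct matrix action", {
  ds <- default_fixture(1)
  lin <- build_linearization(ds$truth, ds$drive, 55)
  rc <- response_matrix(lin)
  for (X in c("PV", "SST", "VIP")) {
    up <- uniform_prediction(rc, X, 0.001)
    bl <- response_block(rc, X)
    direct <- as.vector(bl$Rxx %*% rep(0.001, length(bl$nodes)))
    expect_equal(up$delta_r, direct, tolerance = 1e-8)
    expect_equal(up$dot_ones, sum(direct), tolerance = 1e-8)
    expect_equal(up$mean, up$leading_term + up$remainder, tolerance = 1e-10)
    # linearity: response flips with the perturbation direction, so the
    # paradoxical classification (sign of dr . dh) is direction-invariant
    dot_pos <- sum(direct * 0.001)
    dot_neg <- sum((-direct) * -0.001)
    expect_equal(dot_pos, dot_neg)
  }
  # diagonal block: mean change is gamma times the diagonal gain
  mz <- zero_coupling_model(bias = rep(2, 4))
  linz <- build_linearization(mz, zero_drive(mz$grid), 5)
  rcz <- response_matrix(linz)
  upz <- uniform_prediction(rcz, "SST", 0.01)
  expect_equal(upz$mean, 0.01 * 4, tolerance = 1e-8)
  expect_false(upz$paradoxical)
})

test_that("patterned predictions follow gamma * lambda_1", {
  ds <- default_fixture(1)
  lin <- build_linearization(ds$truth, ds$drive, 55)
  rc <- response_matrix(lin)
  for (X in c("PV", "SST", "VIP")) {
    bl <- response_block(rc, X)
    pp <- patterned_prediction(rc, X, 0.005)
    if (!pp$complex_pair) {
      expect_equal(pp$projection, 0.005 * Re(bl$values[1]),
                   tolerance = 1e-8)
      expect_equal(sum(pp$pattern^2), 1, tolerance = 1e-10)
    }
    expect_identical(pp$paradoxical, pp$projection < 0)
    # mode with positive eigenvalue is never paradoxical
    k <- which(Re(bl$values) > 0 & abs(Im(bl$values)) < 1e-10)
    if (length(k)) {
      ppk <- patterned_prediction(rc, X, 0.005, i = k[length(k)])
      expect_false(ppk$paradoxical)
    }
  }
})

test_that("simulated perturbations match the analytic predictions", {
  ds <- default_fixture(1)
  lin <- build_linearization(ds$truth, ds$drive, 55)
  rc <- response_matrix(lin)
  # gamma = 0: nothing happens
  null_spec <- perturbation_spec("SST", "uniform", gamma = 1e-300)
  sim0 <- simulate_perturbation(ds$truth, ds$drive, 55, null_spec, rc = rc)
  expect_lt(max(abs(sim0$projection)), 1e-8)
  # uniform SST at gamma = 0.001: late-time dot product within 10%
  up <- uniform_prediction(rc, "SST", 0.001)
  sim <- simulate_perturbation(ds$truth, ds$drive, 55,
                               perturbation_spec("SST", "uniform", 0.001),
                               rc = rc)
  late <- tail(sim$projection, 1)
  expect_lt(abs(late - up$dot_ones), 0.1 * abs(up$dot_ones))
  # linear range: doubling gamma doubles the response within 5%
  sim2 <- simulate_perturbation(ds$truth, ds$drive, 55,
                                perturbation_spec("SST", "uniform", 0.002),
                                rc = rc)
  ratio <- tail(sim2$projection, 1) / late
  expect_lt(abs(ratio - 2), 0.1)
  # joint perturbation of all inhibitory populations runs and reports
  simj <- simulate_perturbation(ds$truth, ds$drive, 55,
                                perturbation_spec("all_inhibitory",
                                                  "uniform", 0.001))
  expect_false(simj$diverged)
  expect_length(simj$projection, length(simj$times))
})

test_that("parity between unstable and paradoxical mode counts holds", {
  ds <- default_fixture(1)
  lin <- build_linearization(ds$truth, ds$drive, 55)
  rc <- response_matrix(lin)
  for (X in c("PV", "SST", "VIP")) {
    pc <- parity_check(lin, X, rc)
    expect_true(pc$parity_match)
    expect_true(pc$det_sign_match)
  }
})
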