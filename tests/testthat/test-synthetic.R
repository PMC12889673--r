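test_that("input profile fields have the specified radial structure", {
  grid <- retinotopic_grid(9, 9, 6)
  sizes <- seq(5, 85, by = 10)
  drive <- make_input_fields(grid, sizes)
  d <- sqrt(rowSums(grid$coords^2))
  cn <- center_node(grid)
  specs <- default_drive_specs(sizes)
  for (si in c(1, 5, 9)) {
    # center value equals the specified peak (center node is at 0 deg)
    expect_equal(unname(drive$values["L4", cn, si]), specs$L4$peak[si])
    expect_equal(unname(drive$values["LM", cn, si]), specs$LM$peak[si])
    # monotone nonincreasing along a ray from the center
    ray <- which(grid$coords[, 2] == 0 & grid$coords[, 1] >= 0)
    ray <- ray[order(grid$coords[ray, 1])]
    for (p in c("L4", "LM", "R")) {
      expect_true(all(diff(drive$values[p, ray, si]) <= 1e-12))
    }
  }
  # gaussian kind ignores the plateau: pure Gaussian bump
  gspec <- input_profile_spec("gaussian", peak = rep(2, length(sizes)),
                              edge = 8)
  dg <- make_input_fields(grid, sizes, spec_L4 = gspec)
  expect_equal(dg$values["L4", , 3], 2 * exp(-d^2 / (2 * 8^2)))
})

test_that("radial profiles lift to rotationally symmetric fields", {
  grid <- retinotopic_grid(5, 5, 5)
  expect_equal(radial_profile_to_field(cbind(c(0, 10), c(3, 3)), grid),
               rep(3, 25))
  f <- radial_profile_to_field(cbind(c(0, 10), c(4, 0)), grid)
  expect_equal(f[grid$coords[, 1] == 5 & grid$coords[, 2] == 0], 2)
  # held constant beyond the last tabulated distance
  expect_equal(f[grid$coords[, 1] == 10 & grid$coords[, 2] == 10], 0)
  d <- round(sqrt(rowSums(grid$coords^2)), 9)
  expect_true(all(tapply(f, d, function(v) diff(range(v))) < 1e-12))
  expect_error(radial_profile_to_field(matrix(0, 0, 2), grid), "empty")
})

test_that("ground-truth generator is deterministic and regime-correct", {
  grid <- retinotopic_grid(12, 12, 6)
  drive <- make_input_fields(grid)
  m1 <- make_ground_truth_model(3, grid, drive = drive)
  m2 <- make_ground_truth_model(3, grid, drive = drive)
  expect_identical(m1$amplitude, m2$amplitude)
  # weak regime: full network and E subnetwork both stable
  mw <- make_ground_truth_model(3, grid, regime = "weak", drive = drive)
  linw <- build_linearization(mw, drive, 55)
  expect_lt(Re(leading_eigenvalue(jacobian_matrix(linw))), 0)
  JEw <- subnetwork_jacobian(linw, c("PV", "SST", "VIP"))
  expect_lt(Re(leading_eigenvalue(JEw)), 0)
  # isn regime: E subnetwork unstable, full network stable
  lin <- build_linearization(m1, drive, 55)
  expect_lt(Re(leading_eigenvalue(jacobian_matrix(lin))), 0)
  JE <- subnetwork_jacobian(lin, c("PV", "SST", "VIP"))
  expect_gt(Re(leading_eigenvalue(JE)), 0)
})

test_that("synthetic datasets reproduce steady states and respect seeds", {
  ds <- default_fixture(1)
  expect_identical(ds$observed$values, ds$noiseless$values)
  expect_equal(ssn_loss(ds$noiseless, ds$observed), 0)
  pred <- predict(ds$truth, ds$drive)
  expect_true(all(attr(pred, "converged")))
  expect_lt(ssn_loss(pred, ds$observed), 1e-6)
  # noise: different seeds differ, truth identical, values clipped at 0
  n1 <- generate_dataset(ds$truth, ds$drive, noise_spec(sd = 0.05, seed = 1))
  n2 <- generate_dataset(ds$truth, ds$drive, noise_spec(sd = 0.05, seed = 2))
  expect_false(identical(n1$observed$values, n2$observed$values))
  expect_identical(n1$truth$amplitude, n2$truth$amplitude)
  expect_true(all(n1$observed$values >= 0))
})

test_that("the default fixture shows surround suppression in E", {
  ds <- default_fixture(1)
  st <- size_tuning(ds$noiseless, "E")
  peak <- which.max(st)
  expect_gt(peak, 1)
  expect_lt(peak, length(st))
  expect_lt(st[length(st)], 0.8 * st[peak])
})
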