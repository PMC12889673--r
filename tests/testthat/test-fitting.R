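test_that("loss is the normalized weighted RMS error", {
  ds <- default_fixture(1)
  obs <- ds$observed
  expect_equal(ssn_loss(obs, obs), 0)
  zero <- rate_field(array(0, dim(obs$values),
                           dimnames = dimnames(obs$values)),
                     obs$grid, obs$sizes)
  expect_equal(ssn_loss(zero, obs), 1)
  expect_equal(ssn_loss(zero, obs, normalization = "per_size"),
               sqrt(length(obs$sizes)))
  # homogeneity: scaling the residual scales the loss
  half <- rate_field(obs$values + 0.5 * (zero$values - obs$values),
                     obs$grid, obs$sizes)
  expect_equal(ssn_loss(half, obs), 0.5)
  # invariance to node ordering (same permutation of both fields)
  set.seed(1)
  perm <- sample(obs$grid$n_nodes)
  p1 <- obs; p1$values <- obs$values[, perm, , drop = FALSE]
  p2 <- zero; p2$values <- zero$values[, perm, , drop = FALSE]
  expect_equal(ssn_loss(p2, p1), 1)
  # weights: zeroing a population removes its residual
  w <- c(E = 1, PV = 0, SST = 0, VIP = 0)
  pv_only <- obs
  pv_only$values["PV", , ] <- 0
  expect_equal(ssn_loss(pv_only, obs, weights = w), 0)
  expect_error(ssn_loss(zero, zero), "all-zero")
})

test_that("prediction stacks steady states over sizes", {
  m <- zero_coupling_model(bias = rep(2, 4))
  drive <- zero_drive(m$grid, sizes = c(5, 15, 25))
  pred <- predict(m, drive)
  expect_true(all(attr(pred, "converged")))
  expect_equal(as.vector(pred$values), rep(4, length(pred$values)),
               tolerance = 1e-7)
  expect_identical(pred$values, predict(m, drive)$values)
})

test_that("the no-recurrent variant equals direct evaluation of inputs", {
  ds <- default_fixture(1)
  m <- ds$truth
  m$amplitude[, ssn_recurrent_types()] <- 0
  pred <- predict(m, ds$drive, ss_tol = 1e-10)
  # without recurrence the fixed point is f(source currents + bias)
  for (s in c(5, 55)) {
    ti <- total_input(m, matrix(0, m$grid$n_nodes, 4), ds$drive, s)
    direct <- apply_nonlinearity(ti$total, m$nonlinearity)
    si <- which(ds$drive$sizes == s)
    expect_equal(t(pred$values[, , si]), direct, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("analytic gradients match central finite differences", {
  ds <- default_fixture(1)
  cfg <- fit_config(ss_tol = 1e-10, seed = 5)
  obj <- ssnspace:::make_objective(ds$truth, ds$observed, ds$drive, cfg)
  tmpl <- obj$tmpl
  p_true <- ssnspace:::params_to_vec(ds$truth$amplitude, ds$truth$bias,
                                     tmpl)
  set.seed(17)
  for (rep in 1:3) {
    p <- p_true * runif(length(p_true), 0.8, 1.2)
    p <- pmin(pmax(p, tmpl$lower), tmpl$upper)
    g <- obj$gr(p)
    for (i in sample(length(p), 3)) {
      h <- 1e-5 * max(abs(p[i]), 0.1)
      pp <- p; pp[i] <- p[i] + h; f1 <- obj$fn(pp)
      pp[i] <- p[i] - h; f2 <- obj$fn(pp)
      fd <- (f1 - f2) / (2 * h)
      expect_lt(abs(g[i] - fd) / max(abs(fd), 1e-8), 1e-3)
    }
  }
})

test_that("a fit initialized at the truth stays at the truth", {
  ds <- default_fixture(1)
  cfg <- fit_config(seed = 2, maxit = 50)
  f <- fit_once(ds$truth, ds$observed, ds$drive, cfg)
  expect_lt(f$loss, 1e-6)
  expect_lt(max(abs(f$model$amplitude - ds$truth$amplitude)), 1e-6)
  expect_lt(max(abs(f$model$bias - ds$truth$bias)), 1e-6)
})

test_that("ablation variants pin the right parameters at zero", {
  ds <- default_fixture(1)
  rec <- ssn_recurrent_types()
  cfg_nr <- fit_config(variant = "no_recurrent", maxit = 3, seed = 1)
  f_nr <- fit_once(ds$truth, ds$observed, ds$drive, cfg_nr)
  expect_true(all(f_nr$model$amplitude[, rec] == 0))
  cfg_ne <- fit_config(variant = "no_E_projections", maxit = 3, seed = 1)
  f_ne <- fit_once(ds$truth, ds$observed, ds$drive, cfg_ne)
  expect_true(all(f_ne$model$amplitude[, "E"] == 0))
  expect_false(all(f_ne$model$amplitude[, "PV"] == 0))
  cfg_ln <- fit_config(variant = "linear_nl", maxit = 3, seed = 1)
  f_ln <- fit_once(ds$truth, ds$observed, ds$drive, cfg_ln)
  expect_identical(f_ln$model$nonlinearity, "rectified_linear")
})

test_that("multistart ranking is sorted, seeded, and reduces to fit_once", {
  ds <- default_fixture(1)
  cfg <- fit_config(n_restarts = 2, top_k = 2, maxit = 8, seed = 11)
  rk1 <- fit_multistart(ds$truth, ds$observed, ds$drive, cfg)
  rk2 <- fit_multistart(ds$truth, ds$observed, ds$drive, cfg)
  expect_identical(rk1$ranking, rk2$ranking)
  expect_true(!is.unsorted(rk1$ranking$loss))
  expect_equal(nrow(rk1$ranking), 2)
  # all inits respect the sign boxes by construction
  for (f in rk1$fits) {
    expect_true(all(f$model$amplitude[, c("E", "L4", "LM", "R")] >= 0))
    expect_true(all(f$model$amplitude[, c("PV", "SST", "VIP")] <= 0))
  }
  cfg1 <- fit_config(n_restarts = 1, top_k = 1, maxit = 8, seed = 11)
  rk <- fit_multistart(ds$truth, ds$observed, ds$drive, cfg1)
  expect_equal(nrow(rk$ranking), 1)
  expect_s3_class(rk$fits[[1]], "ssn_fit")
})
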