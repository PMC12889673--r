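test_that("grid coordinates are centered and validated", {
  g <- retinotopic_grid(12, 12, 6)
  expect_equal(g$n_nodes, 144)
  expect_equal(colMeans(g$coords), c(x = 0, y = 0))
  expect_equal(range(g$coords[, 1]), c(-33, 33))
  # even grid: center falls between nodes, nearest-node readout applies
  expect_equal(abs(unname(g$coords[center_node(g), ])), c(3, 3))
  g_odd <- retinotopic_grid(5, 5, 6)
  expect_equal(unname(g_odd$coords[center_node(g_odd), ]), c(0, 0))
  expect_error(retinotopic_grid(1, 5, 6), "at least 2")
  expect_error(retinotopic_grid(5, 5, 0), "positive")
})

test_that("gaussian kernel matches the 2D Gaussian form and is symmetric", {
  g <- retinotopic_grid(6, 6, 6)
  sigma <- 9
  K <- gaussian_kernel_matrix(g, 1.5, sigma)
  expect_equal(diag(K), rep(1.5 / (2 * pi * sigma^2), g$n_nodes))
  expect_equal(K, t(K))
  d2 <- sum((g$coords[1, ] - g$coords[14, ])^2)
  expect_equal(K[1, 14],
               1.5 / (2 * pi * sigma^2) * exp(-d2 / (2 * sigma^2)))
  expect_error(gaussian_kernel_matrix(g, 1, -1), "positive")
})

test_that("kernel row sums (x delta^2) integrate to the amplitude", {
  # center row of the reference 30 x 30 grid: within 1% of the amplitude
  g <- retinotopic_grid(30, 30, 6)
  K <- gaussian_kernel_matrix(g, 2, 12)
  cn <- center_node(g)
  expect_equal(sum(K[cn, ]) * 36, 2, tolerance = 0.01)
  # convergence with grid extent at fixed sigma
  errs <- sapply(c(10, 16, 22), function(n) {
    gg <- retinotopic_grid(n, n, 6)
    KK <- gaussian_kernel_matrix(gg, 1, 10)
    abs(sum(KK[center_node(gg), ]) * 36 - 1)
  })
  expect_true(all(diff(errs) <= 0))
  expect_lt(errs[3], 1e-3)
})

test_that("residual field follows the sqrt-size Gaussian definition", {
  g <- retinotopic_grid(5, 5, 6)
  cn <- center_node(g)
  expect_equal(residual_field(g, 4, sigma_R = 30)[cn], 0.25)
  expect_equal(residual_field(g, 0, sigma_R = 30), rep(0, 25))
  r <- residual_field(g, 9, sigma_R = 10, gain = 1)
  d2 <- grid_r2 <- rowSums(g$coords^2)
  expect_equal(r, 3 * exp(-d2 / 200))
  # amplitude ratio largest/smallest size under both scalings
  pk <- function(s, sc) residual_field(g, s, 30, scaling = sc)[cn]
  expect_equal(pk(85, "sqrt") / pk(5, "sqrt"), sqrt(17))
  expect_equal(pk(85, "linear") / pk(5, "linear"), 17)
  expect_error(residual_field(g, -1), "non-negative")
})
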