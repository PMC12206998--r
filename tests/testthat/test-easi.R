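# Implicit utility, design construction, system estimation, numeraire recovery.

test_that("implicit utility reduces to known closed forms", {
  expect_equal(implicit_utility(c(0, 0), log(50), c(0.3, 0.2, 0.5),
                                matrix(rnorm(4), 2), matrix(rnorm(4), 2)),
               log(50))
  # Stone arithmetic: w1 = 0.3 on ln_p = 0.1
  expect_equal(implicit_utility(c(0.1, 0), log(100), c(0.3, 0.2, 0.5)),
               log(100) - 0.03)
})

test_that("implicit utility matches an independent evaluation of the formula", {
  set.seed(40)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    lnp <- runif(k, -0.5, 0.5)
    w <- runif(k + 1); w <- w / sum(w)
    A <- crossprod(matrix(runif(k * k, -0.3, 0.3), k))
    B <- matrix(runif(k * k, -0.05, 0.05), k); B <- (B + t(B)) / 2
    lnx <- runif(1, 3, 9)
    oracle <- (lnx - sum(w[1:k] * lnp) + 0.5 * sum(lnp * (A %*% lnp))) /
      (1 - 0.5 * sum(lnp * (B %*% lnp)))
    expect_equal(implicit_utility(lnp, lnx, w, A, B), oracle, tolerance = 1e-12)
  }
})

test_that("design has the documented column layout and count", {
  dgp <- make_dgp(c(0.2, 0.3, 0.5), engel_order = 1,
                  shifters = c("hh_size", "lsm"), seed = 3)
  pan <- mc_panel(dgp, 130, 3, seed = 4)
  cfg <- easi_config(engel_order = 1, shifters = c("hh_size", "lsm"))
  y <- pan$noiseless$y
  X <- build_design(pan$shares, pan$prices, y, cfg)
  # 1 intercept + R + K + (J-1) = 1 + 1 + 2 + 2
  expect_identical(ncol(X), 6L)
  expect_identical(colnames(X),
                   c("(Intercept)", "y", "hh_size", "lsm_higher",
                     "ln_p1", "ln_p2"))

  # closed-form count under the full default flags: 1 + R + K + 2(J-1) + K
  cfg2 <- easi_config(engel_order = 3, shifters = c("hh_size", "lsm"),
                      include_price_utility_interactions = TRUE,
                      include_shifter_utility_interactions = TRUE)
  X2 <- build_design(pan$shares, pan$prices, y, cfg2)
  expect_identical(ncol(X2), 1L + 3L + 2L + 2L * 2L + 2L)

  # two rows with identical covariates give identical design rows
  sh2 <- rbind(pan$shares[1], pan$shares[1])
  sh2$household_id <- c("HA", "HB")
  pr2 <- rbind(pan$prices[1], pan$prices[1])
  pr2$household_id <- c("HA", "HB")
  X3 <- build_design(sh2, pr2, rep(y[1], 2),
                     easi_config(engel_order = 1, shifters = "hh_size"))
  expect_identical(unname(X3[1, ]), unname(X3[2, ]))
})

test_that("noiseless panels identify the generating coefficients", {
  dgp <- mc_dgp()
  dgp$noise_sd[] <- 0
  pan <- mc_panel(dgp, 700, 6, seed = 11)
  fit <- fit_easi(pan$shares, pan$prices, mc_config(dgp))
  expect_lt(max(abs(fit$coef$A - dgp$A)), 1e-6)
  expect_lt(max(abs(fit$coef$b - dgp$b)), 1e-6)
  expect_lt(max(abs(fit$coef$b0 - dgp$m)), 1e-6)
  expect_lt(max(abs(fit$coef$gamma - dgp$gamma)), 1e-6)

  # implied numeraire coefficients match the generator's implied numeraire
  full <- recover_numeraire(fit)
  expect_lt(max(abs(full$b0[dgp$J] - (1 - sum(dgp$m)))), 1e-6)
  expect_lt(max(abs(full$A - easidemand:::extend_adding_up(dgp$A))), 1e-6)
  expect_true(attr(full, "derived_not_estimated"))
})

test_that("a price-free specification needs a single pass", {
  dgp <- mc_dgp()
  pan <- mc_panel(dgp, 400, 5, seed = 12)
  cfg <- easi_config(engel_order = 2, shifters = c("hh_size", "lsm"),
                     include_prices = FALSE)
  fit <- fit_easi(pan$shares, pan$prices, cfg)
  expect_identical(fit$convergence$iterations, 1L)
  expect_true(all(fit$coef$A == 0))
})

test_that("numeraire recovery cancels equal and opposite coefficients", {
  toy <- list(b0 = c(0.3, 0.3), b = matrix(c(0.05, -0.05), 2, 1),
              gamma = matrix(0, 2, 0), A = matrix(0, 2, 2),
              B = matrix(0, 2, 2))
  full <- recover_numeraire(toy)
  expect_equal(full$b[3, 1], 0)
  expect_equal(full$b0[3], 0.4)
})

test_that("recovered full system predicts shares that sum to one anywhere", {
  dgp <- mc_dgp()
  pan <- mc_panel(dgp, 400, 5, seed = 13)
  fit <- fit_easi(pan$shares, pan$prices, mc_config(dgp))
  full <- recover_numeraire(fit)
  set.seed(2)
  for (i in 1:10) {
    y <- runif(1, 6, 10); lnp <- runif(4, -0.4, 0.4); z <- runif(2, -2, 2)
    u <- y - fit$config$y_center
    w_full <- full$b0 + as.vector(full$b %*% u^seq_len(ncol(full$b))) +
      as.vector(full$gamma[, c("hh_size", "lsm_higher")] %*% z) +
      as.vector(full$A[, 1:4] %*% lnp)
    expect_lt(abs(sum(w_full) - 1), 1e-12)
  }
})

test_that("stacked covariance is PSD and matches a hand-built cluster sandwich", {
  dgp <- mc_dgp()
  pan <- mc_panel(dgp, 350, 5, seed = 14)
  fit <- fit_easi(pan$shares, pan$prices, mc_config(dgp))
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)

  # independent CR sandwich for equation 1 (HC0 with the standard CR1-style
  # adjustment used by sandwich::vcovCL defaults)
  X <- easidemand:::prune_design(easidemand:::build_design_mat(
    fit$y, fit$data$Z, fit$data$P, fit$config, TRUE))
  e1 <- fit$data$W[, 1] - X %*% fit$coef_matrix[, 1]
  cl <- fit$data$cluster
  Xe <- rowsum(as.matrix(X * as.numeric(e1)), cl)
  G <- nrow(Xe); n <- nrow(X); k <- ncol(X)
  meat <- crossprod(Xe) * G / (G - 1) * (n - 1) / (n - k)
  bread <- solve(crossprod(X))
  V1 <- bread %*% meat %*% bread
  expect_equal(unname(fit$vcov[1:k, 1:k]), unname(V1), tolerance = 1e-8)
})

test_that("minimum-distance symmetrisation enforces symmetry and helps on average", {
  dgp <- tiny_dgp()
  errs <- matrix(NA_real_, 20, 2)
  for (s in 1:20) {
    pan <- mc_panel(dgp, 300, 5, seed = 700 + s)
    cfg <- easi_config(engel_order = 1, shifters = "hh_size",
                       y_center = dgp$y_ref)
    f1 <- fit_easi(pan$shares, pan$prices, cfg)
    cfg$impose_symmetry <- TRUE
    f2 <- fit_easi(pan$shares, pan$prices, cfg)
    expect_lt(max(abs(f2$coef$A - t(f2$coef$A))), 1e-10)
    errs[s, ] <- c(sqrt(sum((f1$coef$A - dgp$A)^2)),
                   sqrt(sum((f2$coef$A - dgp$A)^2)))
  }
  expect_lte(mean(errs[, 2]), mean(errs[, 1]))
})
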