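# Share derivatives, point and averaged elasticities, delta-method SEs,
# and the finite-difference oracle.

test_that("derivatives reduce to closed forms in the interaction-free cases", {
  dgp <- tiny_dgp()
  d <- share_derivatives(dgp, rep(0, 3), dgp$y_ref)
  expect_equal(unname(d$Gamma),
               unname(easidemand:::extend_adding_up(dgp$A)))
  expect_equal(d$dy_dlnx, 1)                       # B = 0 at the base point

  # R = 1, B = 0: mu is the constant linear Engel slope
  d2 <- share_derivatives(dgp, c(0.2, -0.1, 0.05), dgp$y_ref + 0.7)
  expect_equal(unname(d2$mu[1:3]), unname(dgp$b[, 1]))
})

test_that("derivatives match numerical differentiation of the share equations", {
  set.seed(50)
  h <- 1e-6
  for (i in 1:10) {
    sh <- runif(4, 0.5, 2)
    dgp <- make_dgp(sh / sum(sh), engel_order = 2, shifters = "hh_size",
                    seed = 60 + i)
    # direct construction of a valid share vector
    par <- easidemand:::as_easi_params(dgp)
    lnp <- runif(3, -0.3, 0.3)
    y <- dgp$y_ref + runif(1, -0.8, 0.8)
    d <- share_derivatives(dgp, lnp, y)
    # dw/dlnp at fixed y
    for (j in 1:3) {
      pp <- lnp; pp[j] <- pp[j] + h
      pm <- lnp; pm[j] <- pm[j] - h
      fd <- (easidemand:::share_rhs(par, matrix(pp, 1), y, matrix(0, 1, 1)) -
               easidemand:::share_rhs(par, matrix(pm, 1), y, matrix(0, 1, 1))) / (2 * h)
      expect_equal(unname(d$Gamma[1:3, j]), drop(fd), tolerance = 1e-6)
    }
    # dw/dy at fixed prices
    fdy <- (easidemand:::share_rhs(par, matrix(lnp, 1), y + h, matrix(0, 1, 1)) -
              easidemand:::share_rhs(par, matrix(lnp, 1), y - h, matrix(0, 1, 1))) / (2 * h)
    expect_equal(unname(d$mu[1:3]), drop(fdy), tolerance = 1e-6)
  }
})

test_that("a constant-share system gives the Cobb-Douglas pattern", {
  J <- 4
  w <- c(0.2, 0.3, 0.1, 0.4)
  pt <- point_elasticities(matrix(0, J, J), rep(0, J), 1, w)
  expect_equal(unname(pt$expenditure), rep(1, J))
  expect_equal(unname(pt$hicksian),
               matrix(w, J, J, byrow = TRUE) - diag(J))
  expect_equal(unname(pt$marshallian), -diag(J))
})

test_that("aggregation and Slutsky identities hold at arbitrary points", {
  set.seed(70)
  for (i in 1:15) {
    dgp <- tiny_dgp(seed = 100 + i)
    lnp <- runif(3, -0.3, 0.3)
    lnx <- dgp$y_ref + runif(1, -1, 1)
    w <- solve_shares(dgp, lnp, lnx)
    d <- share_derivatives(dgp, lnp, attr(w, "y"))
    pt <- point_elasticities(d$Gamma, d$mu, d$dy_dlnx, as.numeric(w))
    w <- as.numeric(w)
    expect_lt(abs(sum(w * pt$expenditure) - 1), 1e-10)                    # Engel
    expect_lt(max(abs(colSums(w * pt$marshallian) + w)), 1e-10)           # Cournot
    expect_lt(max(abs(rowSums(pt$marshallian) + pt$expenditure)), 1e-8)   # homogeneity
    expect_lt(max(abs(pt$marshallian -
                        (pt$hicksian - pt$expenditure %o% w))), 1e-10)    # Slutsky
  }
})

test_that("the finite-difference oracle matches closed forms and is step-robust", {
  cs <- make_dgp(c(0.2, 0.3, 0.5), engel_order = 1,
                 expenditure_elasticities = c(1, 1),
                 price_matrix_A = matrix(0, 2, 2), shifter_scale = 0, seed = 2)
  fd <- fd_oracle_elasticities(cs, c(0.1, -0.2), log(400))
  expect_equal(unname(fd$marshallian), -diag(3), tolerance = 1e-6)

  dgp <- tiny_dgp()
  f1 <- fd_oracle_elasticities(dgp, c(0.1, 0.05, -0.1), dgp$y_ref, h = 1e-4)
  f2 <- fd_oracle_elasticities(dgp, c(0.1, 0.05, -0.1), dgp$y_ref, h = 1e-5)
  expect_lt(max(abs(f1$marshallian - f2$marshallian)), 1e-6)
})

test_that("averaging matches per-point arithmetic and modes agree on constant panels", {
  dgp <- mc_dgp()
  pan <- mc_panel(dgp, 350, 5, seed = 16)
  fit <- fit_easi(pan$shares, pan$prices, mc_config(dgp))

  # two-row weighted average against hand arithmetic from point calls
  par <- easidemand:::params_of(fit)
  P2 <- fit$data$P[1:2, , drop = FALSE]
  y2 <- fit$y[1:2]
  W2 <- fit$fitted[1:2, , drop = FALSE]
  wts <- c(1, 3)
  avg <- easidemand:::elasticity_avg_rows(par, P2, y2, W2, weights = wts)
  pts <- lapply(1:2, function(r) {
    d <- share_derivatives(par, P2[r, ], y2[r])
    point_elasticities(d$Gamma, d$mu, d$dy_dlnx, W2[r, ])
  })
  hand_M <- (1 * pts[[1]]$marshallian + 3 * pts[[2]]$marshallian) / 4
  expect_equal(avg$M, unname(hand_M), tolerance = 1e-10)
  hand_E <- (1 * pts[[1]]$expenditure + 3 * pts[[2]]$expenditure) / 4
  expect_equal(avg$E, unname(hand_E), tolerance = 1e-10)

  # identical rows: per-observation and at-means coincide
  sh <- pan$shares[rep(1L, 30)]
  sh$household_id <- sprintf("H%03d", 1:30)
  pr <- pan$prices[rep(1L, 30)]
  pr$household_id <- sh$household_id
  fit2 <- fit
  fit2$data$P <- fit$data$P[rep(1L, 30), ]
  fit2$data$W <- fit$data$W[rep(1L, 30), ]
  fit2$data$Z <- fit$data$Z[rep(1L, 30), , drop = FALSE]
  fit2$data$ln_x <- rep(fit$data$ln_x[1], 30)
  fit2$data$weight <- rep(1, 30)
  fit2$n <- 30L
  a1 <- average_elasticities(fit2, mode = "per_observation")
  a2 <- average_elasticities(fit2, mode = "at_means")
  expect_equal(a1$marshallian, a2$marshallian, tolerance = 1e-10)
  expect_equal(a1$expenditure, a2$expenditure, tolerance = 1e-10)
})

test_that("delta SEs vanish with a zero covariance and track the bootstrap", {
  dgp <- tiny_dgp()
  pan <- mc_panel(dgp, 250, 5, seed = 17)        # about 1000 household-quarters
  cfg <- easi_config(engel_order = 1, shifters = "hh_size",
                     y_center = dgp$y_ref)
  fit <- fit_easi(pan$shares, pan$prices, cfg)

  fit0 <- fit
  fit0$vcov <- fit$vcov * 0
  se0 <- delta_se(fit0)
  expect_true(all(se0$se_marshallian == 0))
  expect_true(all(se0$se_expenditure == 0))

  bad <- fit
  bad$vcov <- -diag(nrow(fit$vcov))
  expect_error(delta_se(bad), "positive semi-definite")

  # cluster bootstrap oracle for the averaged own-price elasticities
  se <- delta_se(fit)
  hh <- unique(pan$shares$household_id)
  reps <- 200L
  own <- matrix(NA_real_, reps, dgp$J)
  set.seed(99)
  for (b in seq_len(reps)) {
    draw <- sample(hh, length(hh), replace = TRUE)
    idx <- unlist(lapply(seq_along(draw), function(i) {
      which(pan$shares$household_id == draw[i])
    }))
    sh <- pan$shares[idx]
    sh$household_id <- rep(sprintf("B%04d", seq_along(draw)),
                           times = vapply(draw, function(h)
                             sum(pan$shares$household_id == h), integer(1)))
    pr <- pan$prices[idx]
    pr$household_id <- sh$household_id
    fb <- fit_easi(sh, pr, cfg)
    own[b, ] <- diag(average_elasticities(fb)$marshallian)
  }
  boot_se <- apply(own, 2, sd)
  ratio <- diag(se$se_marshallian) / boot_se
  expect_true(all(ratio > 0.5 & ratio < 2))
})
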