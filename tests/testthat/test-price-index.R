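# Unit values, imputation, Fisher indices.

test_that("unit values are quantity-weighted spend/quantity", {
  base <- data.frame(household_id = "H1", quarter = 1L, province = "Gauteng",
                     lsm = "lower", group = 1L)
  one <- cbind(base, brand = "b1", spend = 12, quantity = 1000)
  uv <- compute_unit_values(one)
  expect_equal(uv$unit_value[uv$observed], 0.012)

  two <- rbind(cbind(base, brand = "b1", spend = 10, quantity = 500),
               cbind(base, brand = "b1", spend = 30, quantity = 1500))
  uv2 <- compute_unit_values(two)
  expect_equal(uv2$unit_value[uv2$observed], 0.02)

  bad <- cbind(base, brand = "b1", spend = 5, quantity = 0)
  expect_error(compute_unit_values(bad), "non-positive")
})

test_that("noise-free synthetic unit values equal the generator's prices", {
  dgp <- tiny_dgp(seed = 4,
                  price_sd = c(quarter = 0.05, province = 0.05,
                               quarter_province = 0.04, idiosyncratic = 0))
  pan <- simulate_panel(dgp, 60, 3, seed = 5, p_northern_cape = 0,
                        p_child_anomaly = 0)
  uv <- compute_unit_values(pan$records)
  m <- merge(uv[observed == TRUE], pan$price_truth,
             by = c("brand", "quarter", "province"))
  expect_gt(nrow(m), 100)
  expect_lt(max(abs(log(m$unit_value) - m$ln_price_sys)), 1e-10)
})

test_that("imputation is a no-op without gaps and never alters observed cells", {
  dgp <- tiny_dgp(seed = 4)
  pan <- simulate_panel(dgp, 80, 3, seed = 6)
  uv <- compute_unit_values(pan$records)
  comp <- impute_missing_prices(uv)
  expect_identical(comp$unit_value[comp$observed], uv$unit_value[uv$observed])
  expect_true(all(!is.na(comp$unit_value)))
  expect_identical(which(comp$imputed), which(!uv$observed))

  full <- uv[observed == TRUE]
  same <- impute_missing_prices(full)
  expect_identical(same$unit_value, full$unit_value)
})

test_that("intercept-only imputation fills with the geometric mean", {
  uv <- data.table::data.table(
    household_id = c("A", "B", "C"), quarter = 1L, province = "Gauteng",
    lsm = "lower", group = 1L, brand = "b1",
    unit_value = c(0.01, 0.04, NA), quantity = c(100, 100, NA),
    observed = c(TRUE, TRUE, FALSE)
  )
  comp <- impute_missing_prices(uv)
  expect_equal(comp$unit_value[3], exp(mean(log(c(0.01, 0.04)))))
  # a group with nothing observed is an error naming the group
  uv$observed <- FALSE
  uv$unit_value <- NA_real_
  expect_error(impute_missing_prices(uv), "group 1")
})

test_that("imputed prices track the systematic truth within the idiosyncratic SD", {
  errs <- numeric(0)
  for (s in 1:20) {
    dgp <- dgp_table2(seed = 2)
    pan <- simulate_panel(dgp, 120, 6, seed = 600 + s)
    uv <- compute_unit_values(pan$records)
    obs_idx <- which(uv$observed)
    set.seed(s)
    mask <- sample(obs_idx, round(0.3 * length(obs_idx)))   # MCAR
    uv$unit_value[mask] <- NA
    uv$observed[mask] <- FALSE
    comp <- impute_missing_prices(uv)
    tr <- merge(comp[mask], pan$price_truth,
                by = c("brand", "quarter", "province"))
    errs <- c(errs, sqrt(mean((log(tr$unit_value) - tr$ln_price_sys)^2)))
  }
  expect_lt(mean(errs), dgp$price_sd[["idiosyncratic"]])
})

test_that("the Fisher kernel matches hand-evaluated Laspeyres and Paasche sums", {
  f <- fisher_from_vectors(p = c(2, 2), p0 = c(1, 2), q = c(1, 3), q0 = c(1, 1))
  expect_equal(f$laspeyres, 4 / 3)
  expect_equal(f$paasche, 8 / 7)
  expect_equal(f$fisher, sqrt((4 / 3) * (8 / 7)))

  # base-period identity and single-brand case
  expect_equal(fisher_from_vectors(c(1, 2), c(1, 2), c(5, 1), c(1, 1))$fisher, 1)
  expect_equal(fisher_from_vectors(4, 2, 9, 3)$fisher, 2)
})

test_that("Fisher satisfies homogeneity, mean-value bounds and time reversal", {
  set.seed(11)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    p0 <- runif(k, 0.5, 2); p1 <- runif(k, 0.5, 2)
    q0 <- runif(k, 0.5, 3); q1 <- runif(k, 0.5, 3)
    f <- fisher_from_vectors(p1, p0, q1, q0)$fisher
    for (lam in c(0.5, 2, 10)) {
      expect_lt(abs(fisher_from_vectors(lam * p1, p0, q1, q0)$fisher - lam * f),
                1e-12 * lam * f)
    }
    r <- range(p1 / p0)
    expect_gte(f, r[1] - 1e-12)
    expect_lte(f, r[2] + 1e-12)
    back <- fisher_from_vectors(p0, p1, q0, q1)$fisher
    expect_lt(abs(f * back - 1), 1e-12)
  }
})

test_that("household-quarter index table behaves at the base and for non-purchasers", {
  # two households, one brand per group; household B never buys group 1
  rec <- data.table::data.table(
    household_id = rep(c("A", "A", "B"), each = 1),
    quarter = 1L, province = "Gauteng", lsm = "lower",
    group = c(1L, 2L, 2L), brand = c("g1", "g2", "g2"),
    spend = c(10, 20, 30), quantity = c(100, 200, 300)
  )
  uv <- compute_unit_values(rec)
  comp <- impute_missing_prices(uv)
  fi <- fisher_index(comp, numeraire_group = 2L)
  # only group 1 is reported; B's price is imputed at A's level (base), so
  # both rows sit at the base: log index 0
  expect_equal(fi$ln_p1, c(0, 0), tolerance = 1e-12)

  # a non-purchaser's Fisher equals its Laspeyres (base-quantity fallback)
  base <- attr(fi, "base")
  expect_identical(sort(unique(base$group)), c(1L, 2L))
})
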