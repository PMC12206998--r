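# Classification, exclusion filters, budget shares, descriptives.

test_that("classification applies the sugar split and its exceptions", {
  expect_identical(classify_item("soft_drink", 4.0, TRUE), 3L)   # boundary: <= 4 is low-sugar
  expect_identical(classify_item("soft_drink", 4.1, TRUE), 4L)
  expect_identical(classify_item("soft_drink", 9, FALSE), 4L)    # non-taxable HS still HS group
  expect_identical(classify_item("flavored_water", 2, FALSE), 1L)
  expect_identical(classify_item("flavored_water", 6, FALSE), 13L)
  expect_identical(classify_item("coffee_tea_drink", 6, FALSE), 13L)
  expect_identical(classify_item("dairy_drink", 7, FALSE), 7L)
  expect_identical(classify_item("dairy_drink", 3, FALSE), 6L)
  expect_identical(classify_item("juice_100", 11, FALSE), 2L)
  expect_identical(classify_item("fvns"), 12L)
  expect_identical(classify_item("other_food"), 13L)
  expect_error(classify_item("soft_drink", NA), "sugar")
})

test_that("the shipped schema resource matches the in-code schema", {
  path <- system.file("extdata", "group_schema.yaml", package = "easidemand")
  expect_true(nzchar(path))
  res <- yaml::read_yaml(path)
  sch <- group_schema()
  expect_identical(unlist(res$groups), sch$groups)
  expect_identical(res$numeraire_index, sch$numeraire_index)
  expect_identical(res$sugar_threshold_g_per_100ml, sch$sugar_threshold)
})

test_that("classification is total over the vocabulary x sugar domain", {
  voc <- easidemand:::item_vocabulary()
  for (i in seq_len(nrow(voc))) {
    for (sugar in list(NA_real_, 2, 9)) {
      for (tax in c(TRUE, FALSE)) {
        g <- easidemand:::classify_vec(voc$item_type[i], sugar, tax)
        if (is.na(g)) {
          expect_true(voc$sugar_split[i] && is.na(sugar))
          expect_error(classify_item(voc$item_type[i], sugar, tax), "sugar")
        } else {
          expect_true(g %in% 1:13)
        }
      }
    }
  }
})

test_that("exclusion filters reproduce the documented record-by-record decisions", {
  toy <- toy_records()
  out <- apply_exclusions(toy[, setdiff(names(toy),
                                        c("expected_keep", "expected_group"))],
                          group_stats = toy_group_stats())
  kept <- toy[toy$expected_keep, ]
  expect_identical(nrow(out$records), nrow(kept))
  key <- function(d) paste(d$household_id, d$item_type, d$package_size, d$spend)
  expect_setequal(key(out$records), key(kept))
  expect_identical(out$records$group[match(key(kept), key(out$records))],
                   kept$expected_group)
  expect_identical(unname(out$audit),
                   c(2L, 1L, 1L, 2L, 2L, 12L))
  expect_identical(sum(out$audit), nrow(toy))
})

test_that("audit counts always conserve records", {
  dgp <- dgp_table2(seed = 2)
  pan <- simulate_panel(dgp, 120, 3, seed = 21)
  out <- apply_exclusions(pan$records)
  expect_identical(sum(out$audit), nrow(pan$records))
  expect_identical(out$audit[["retained"]], nrow(out$records))
  # empty input: zeroed audit, no error
  empty <- apply_exclusions(pan$records[0])
  expect_identical(sum(empty$audit), 0L)
})

test_that("budget shares follow the documented arithmetic", {
  base <- data.frame(household_id = "H1", quarter = 1L, province = "Gauteng",
                     lsm = "lower", lifecycle = "families", hh_size = 3,
                     n_children = 1, weight = 1)
  one <- cbind(base, group = 13L, brand = "b", spend = 100, quantity = 1)
  sp <- compute_budget_shares(one)
  expect_equal(sp$w13, 1)
  expect_equal(sum(sp[, paste0("w", 1:12), with = FALSE]), 0)
  expect_equal(sp$ln_expenditure, log(100))

  two <- rbind(cbind(base, group = 4L, brand = "b", spend = 20, quantity = 1),
               cbind(base, group = 13L, brand = "b", spend = 80, quantity = 1))
  sp2 <- compute_budget_shares(two)
  expect_equal(sp2$w4, 0.2)
  expect_equal(sp2$w13, 0.8)
})

test_that("record aggregation reproduces the generator's model-level shares", {
  dgp <- dgp_table2(seed = 2)
  pan <- simulate_panel(dgp, 150, 4, seed = 9)
  exc <- apply_exclusions(pan$records)
  sp <- compute_budget_shares(exc$records)
  m <- merge(sp, pan$shares, by = c("household_id", "quarter"))
  expect_gt(nrow(m), 100)
  W1 <- as.matrix(m[, paste0("w", 1:13, ".x"), with = FALSE])
  W2 <- as.matrix(m[, paste0("w", 1:13, ".y"), with = FALSE])
  expect_lt(max(abs(W1 - W2)), 1e-8)
})

test_that("descriptives compute the three share summaries and their identity", {
  toy <- data.frame(household_id = c("A", "B"), quarter = 1L,
                    w1 = c(0, 0.2), w2 = c(1, 0.8),
                    weight = c(1, 1), hh_size = c(2, 3), lsm = "lower")
  d <- describe_sample(toy)$budget_shares$all
  expect_equal(d$w[1], 0.10)
  expect_equal(d$p_zero[1], 0.5)
  expect_equal(d$w_cond[1], 0.20)

  toy$weight <- c(1, 3)
  d2 <- describe_sample(toy)$budget_shares$all
  expect_equal(d2$w[1], (1 * 0 + 3 * 0.2) / 4)
  expect_equal(d2$w_cond[1], 0.2)

  expect_error(describe_sample(toy, by = "banana"), "stratification")
})

test_that("w = (1 - p_zero) * w_cond holds exactly on simulated panels", {
  dgp <- dgp_table2(seed = 2)
  for (s in c(14, 15)) {
    pan <- simulate_panel(dgp, 250, 4, seed = s, records = FALSE)
    d <- describe_sample(pan$shares, by = "lsm")
    for (blk in d$budget_shares) {
      err <- abs(blk$w - (1 - blk$p_zero) * blk$w_cond)
      expect_lt(max(err), 1e-12)
    }
    # simulated zero-share rate close to the generator's probability
    d_all <- d$budget_shares$all
    expect_lt(max(abs(d_all$p_zero[c(1, 3, 7)] -
                        dgp$nonpurchase_prob[c(1, 3, 7)])), 0.06)
  }
})
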