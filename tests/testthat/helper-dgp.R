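# Shared fixtures: small ground-truth systems and a hand-built record toy.

# Compact 4-group system for fast unit tests.
tiny_dgp <- function(seed = 8, noise_sd = 0.02, ...) {
  make_dgp(c(0.15, 0.2, 0.25, 0.4), engel_order = 1, shifters = "hh_size",
           noise_sd = noise_sd, seed = seed, ...)
}

# The Monte-Carlo study system: 5 groups with shares large enough that the
# additive share noise (SD 0.02) essentially never truncates at zero, so
# recovery checks measure estimator properties rather than censoring.
mc_dgp <- function(seed = 5) {
  make_dgp(c(0.12, 0.15, 0.18, 0.15, 0.40), engel_order = 2,
           shifters = c("hh_size", "lsm"), noise_sd = 0.02, seed = seed)
}

mc_config <- function(dgp) {
  easi_config(engel_order = dgp$R, shifters = dgp$shifters,
              y_center = dgp$y_ref)
}

# Model-level panel without the ingestion nuisances (no Northern Cape, no
# child anomalies, no records).
mc_panel <- function(dgp, n_households, n_quarters, seed) {
  simulate_panel(dgp, n_households, n_quarters, seed = seed,
                 p_northern_cape = 0, p_child_anomaly = 0, records = FALSE)
}

# Truth for averaged elasticities: the estimator's functional evaluated at
# the true parameters, noiseless shares and noiseless utility.
true_avg_elasticities <- function(dgp, panel) {
  par <- easidemand:::as_easi_params(dgp)
  Z <- easidemand:::encode_shifters(panel$shares, dgp$shifters)
  P <- as.matrix(panel$prices[, paste0("ln_p", seq_len(dgp$J - 1L)),
                              with = FALSE])
  easidemand:::elasticity_avg_rows(par, P, panel$noiseless$y,
                                   panel$noiseless$shares, Z)
}

# A 20-record purchase toy covering every exclusion rule, with the expected
# decision for each record worked out by hand.
toy_records <- function() {
  rec <- function(hh, prov, size, nch, type, sugar, tax, unit, pkg, qty, spd,
                  brand = "b1", month = 1L) {
    data.frame(household_id = hh, quarter = 1L, month = month,
               province = prov, lsm = "lower", lifecycle = "families",
               hh_size = size, n_children = nch, item_type = type,
               sugar_per_100ml = sugar, taxable = tax, unit = unit,
               package_size = pkg, quantity = qty, spend = spd,
               brand = brand, weight = 1)
  }
  rows <- rbind(
    rec("H1", "Gauteng", 4, 1, "soft_drink", 2, FALSE, "ml", 500, 1000, 12),    # 1 keep (g3)
    rec("H1", "Gauteng", 4, 1, "soft_drink", 9, TRUE, "ml", 2000, 2000, 26),    # 2 keep (g4)
    rec("H1", "Gauteng", 4, 1, "soft_drink", NA, TRUE, "ml", 500, 500, 7),      # 3 drop: sugar missing
    rec("H1", "Gauteng", 4, 1, "flavored_water", 6, FALSE, "ml", 500, 500, 5),  # 4 keep (numeraire)
    rec("H1", "Gauteng", 4, 1, "flavored_water", NA, FALSE, "ml", 500, 500, 5), # 5 drop: sugar missing
    rec("H2", "Limpopo", 3, 0, "snack", NA, FALSE, "g", 10, 100, 7),            # 6 keep: size exactly 10
    rec("H2", "Limpopo", 3, 0, "snack", NA, FALSE, "g", 9, 90, 6),              # 7 drop: integer size < 10
    rec("H2", "Limpopo", 3, 0, "snack", NA, FALSE, "g", 9.5, 95, 6.5),          # 8 keep: non-integer size
    rec("H2", "Limpopo", 3, 0, "other_food", NA, FALSE, "g", 5, 500, 10),       # 9 keep: numeraire exempt
    rec("H3", "Free State", 2, 0, "dessert", NA, FALSE, "g", 500, 500, 25),     # 10 keep (uv 0.05)
    rec("H3", "Free State", 2, 0, "dessert", NA, FALSE, "g", 500, 500, 91.8,
        brand = "b2", month = 2L),                                              # 11 drop: uv ~6.5 SD out
    rec("H4", "Northern Cape", 3, 1, "soft_drink", 2, FALSE, "ml", 500, 500, 6),# 12 drop: Northern Cape
    rec("H4", "Northern Cape", 3, 1, "other_food", NA, FALSE, "g", 500, 500, 9),# 13 drop: Northern Cape
    rec("H5", "Gauteng", 2, 2, "fvns", NA, FALSE, "g", 500, 800, 20),           # 14 drop: children >= size
    rec("H6", "Gauteng", 3, 3, "chocolate_candy", NA, FALSE, "g", 100, 100, 9), # 15 drop: children >= size
    rec("H7", "Western Cape", 5, 2, "dairy_drink", 7, FALSE, "ml", 500, 1000, 20), # 16 keep (g7)
    rec("H7", "Western Cape", 5, 2, "dairy_drink", 3, FALSE, "ml", 1000, 2000, 28),# 17 keep (g6)
    rec("H7", "Western Cape", 5, 2, "coffee_tea", NA, FALSE, "g", 250, 250, 30),   # 18 keep (g5)
    rec("H8", "KwaZulu-Natal", 4, 1, "juice_100", 11, FALSE, "ml", 1000, 1000, 16),# 19 keep (g2)
    rec("H8", "KwaZulu-Natal", 4, 1, "alcohol", NA, FALSE, "ml", 750, 750, 34)     # 20 keep (g8)
  )
  rows$expected_keep <- c(TRUE, TRUE, FALSE, TRUE, FALSE,
                          TRUE, FALSE, TRUE, TRUE, TRUE,
                          FALSE, FALSE, FALSE, FALSE, FALSE,
                          TRUE, TRUE, TRUE, TRUE, TRUE)
  rows$expected_group <- c(3L, 4L, NA, 13L, NA,
                           11L, 11L, 11L, 13L, 10L,
                           10L, 3L, 13L, 12L, 9L,
                           7L, 6L, 5L, 2L, 8L)
  rows
}

# Hand-set unit-value statistics making toy record 11 a >5 SD outlier within
# the dessert group (one-pass statistics over so few cells cannot flag it).
toy_group_stats <- function() {
  data.table::data.table(group = 10L, unit = "g", mean = log(0.05), sd = 0.2,
                         n_cells = 2L)
}
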