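#' Simulate a household scanner panel from a known demand system
#'
#' Draws household demographics, quarterly presence, brand-level prices and
#' total at-home food/beverage expenditure, solves the implicit share system
#' for every household-quarter, adds truncated share noise, imposes
#' non-purchase by thinning (a non-purchasing household-quarter-group has a
#' zero share, its mass moved into the numeraire, and no purchase records),
#' and expands the result to item-level purchase records with per-group brand
#' draws. Every draw is governed by `seed`, so identical calls return
#' identical panels.
#'
#' The panel is unbalanced: each household is present in a given quarter with
#' probability `presence_prob` (at least one quarter per household), emulating
#' the high panel turnover of commercial scanner panels, where the median
#' household contributes well under half of the quarters.
#'
#' @param dgp an `easi_dgp` ground-truth specification from [make_dgp()].
#' @param n_households number of households.
#' @param n_quarters number of quarters (the study window has 13).
#' @param seed integer seed; required for reproducibility.
#' @param presence_prob per-quarter presence probability.
#' @param p_northern_cape fraction of households placed in Northern Cape;
#'   these exist to exercise the geographic exclusion filter and are encoded
#'   at the reference province in the share equations.
#' @param p_child_anomaly probability that a household reports at least as
#'   many children as members (dropped later by the demographic filter).
#' @param records if `FALSE`, skip the record-level expansion (model-level
#'   panel only).
#' @return An object of class `easi_panel`: a list with `shares`
#'   (household-quarter budget shares `w1..wJ`, `ln_expenditure`,
#'   demographics, `weight`), `prices` (household-quarter log group price
#'   indices `ln_p1..ln_p{J-1}`, ground truth), `records` (item-level
#'   purchases or `NULL`), `truth` (the `easi_dgp`), `noiseless` (pre-noise
#'   share matrix and implicit utility), `price_truth` (systematic
#'   brand-quarter-province log prices) and `true_elasticities`.
#' @seealso [make_dgp()], [dgp_table2()], [write_panel()]
#' @export
simulate_panel <- function(dgp, n_households, n_quarters, seed,
                           presence_prob = 0.4,
                           p_northern_cape = 0.02,
                           p_child_anomaly = 0.01,
                           records = TRUE) {
  stopifnot(inherits(dgp, "easi_dgp"))
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stopf("simulate_panel() requires an integer `seed` for reproducibility")
  }
  n_households <- as.integer(n_households)
  n_quarters <- as.integer(n_quarters)
  if (n_households < 1L || n_quarters < 1L) {
    stopf("n_households and n_quarters must both be >= 1")
  }
  J <- dgp$J

  with_seed(seed, {
    ## -- households ---------------------------------------------------------
    prov_all <- c(province_levels(), "Northern Cape")
    prov_p <- c(0.31, 0.12, 0.08, 0.08, 0.17, 0.06, 0.06, 0.13)
    prov_p <- c(prov_p / sum(prov_p) * (1 - p_northern_cape), p_northern_cape)
    hh <- data.table::data.table(
      household_id = sprintf("H%05d", seq_len(n_households)),
      lsm = sample(lsm_levels(), n_households, TRUE, prob = c(0.45, 0.55)),
      province = sample(prov_all, n_households, TRUE, prob = prov_p),
      lifecycle = sample(lifecycle_levels(), n_households, TRUE,
                         prob = c(0.51, 0.13, 0.16, 0.03, 0.17)),
      hh_size = sample(1:8, n_households, TRUE,
                       prob = c(0.20, 0.19, 0.17, 0.17, 0.14, 0.07, 0.04, 0.02)),
      weight = stats::rlnorm(n_households, 0, 0.3)
    )
    hh[, n_children := pmin(stats::rpois(.N, 0.9), pmax(hh_size - 1L, 0L))]
    anom <- runif(n_households) < p_child_anomaly
    hh[anom, n_children := hh_size]

    ## -- presence -----------------------------------------------------------
    pres <- matrix(runif(n_households * n_quarters) < presence_prob,
                   n_households, n_quarters)
    none <- !rowSums(pres)
    if (any(none)) {
      pres[cbind(which(none), sample.int(n_quarters, sum(none), TRUE))] <- TRUE
    }
    idx <- which(pres, arr.ind = TRUE)
    panel <- hh[idx[, 1L]]
    panel[, quarter := idx[, 2L]]
    data.table::setorder(panel, household_id, quarter)
    n <- nrow(panel)

    ## -- brand-level systematic prices -------------------------------------
    bm <- data.table::copy(dgp$brand_map)
    nb <- nrow(bm)
    np <- length(prov_all)
    sd_qp <- if ("quarter_province" %in% names(dgp$price_sd))
      dgp$price_sd[["quarter_province"]] else 0
    qeff <- matrix(rnorm(nb * n_quarters, 0, dgp$price_sd[["quarter"]]),
                   nb, n_quarters, dimnames = list(bm$brand, NULL))
    peff <- matrix(rnorm(nb * np, 0, dgp$price_sd[["province"]]),
                   nb, np, dimnames = list(bm$brand, prov_all))
    qpeff <- array(rnorm(nb * n_quarters * np, 0, sd_qp),
                   c(nb, n_quarters, np))
    # The numeraire is the price normalisation: its systematic price is flat.
    num_brands <- bm$group == J
    qeff[num_brands, ] <- 0
    peff[num_brands, ] <- 0
    qpeff[num_brands, , ] <- 0

    price_truth <- data.table::CJ(brand = bm$brand, quarter = seq_len(n_quarters),
                                  province = prov_all, sorted = FALSE)
    price_truth <- merge(price_truth, bm[, .(brand, group, base_price)],
                         by = "brand", sort = FALSE)
    price_truth[, ln_price_sys := {
      bi <- match(brand, bm$brand)
      pi <- match(province, prov_all)
      log(base_price) + qeff[cbind(bi, quarter)] + peff[cbind(bi, pi)] +
        qpeff[cbind(bi, quarter, pi)]
    }]

    ## -- group log price indices (expenditure-share weighted deviations) ----
    bm[, w0 := base_price * base_quantity]
    bm[, w0 := w0 / sum(w0), by = group]
    # ln P_g(t, pr) = sum_b w0_b * (quarter + province effects)
    grp_q <- rowsum(qeff * bm$w0, bm$group)           # J x T
    grp_p <- rowsum(peff * bm$w0, bm$group)           # J x n_prov
    grp_qp <- apply(qpeff * bm$w0, c(2L, 3L),
                    function(v) rowsum(v, bm$group))  # J x T x n_prov
    dim(grp_qp) <- c(J, n_quarters, np)
    prov_idx <- match(panel$province, prov_all)
    lnP <- t(grp_q[seq_len(J - 1L), panel$quarter, drop = FALSE] +
               grp_p[seq_len(J - 1L), prov_idx, drop = FALSE])
    for (g in seq_len(J - 1L)) {
      lnP[, g] <- lnP[, g] + grp_qp[cbind(g, panel$quarter, prov_idx)]
    }
    colnames(lnP) <- paste0("ln_p", seq_len(J - 1L))

    ## -- expenditure, shifters, noiseless shares ----------------------------
    panel[, ln_expenditure := rnorm(n, dgp$y_ref, dgp$expenditure_sd)]
    Z <- encode_shifters(panel, dgp$shifters)
    W0 <- matrix(NA_real_, n, J)
    y0 <- numeric(n)
    strata <- if (dgp$lsm_price_scale != 1) c("lower", "higher") else "higher"
    for (s in strata) {
      rows <- if (length(strata) == 1L) seq_len(n) else which(panel$lsm == s)
      if (!length(rows)) next
      sol <- solve_shares_mat(as_easi_params(dgp, lsm = s),
                              lnP[rows, , drop = FALSE],
                              panel$ln_expenditure[rows],
                              Z[rows, , drop = FALSE])
      W0[rows, ] <- sol$W
      y0[rows] <- sol$y
    }

    ## -- share noise (clip negatives, renormalise) --------------------------
    W <- W0[, -J, drop = FALSE] +
      matrix(rnorm(n * (J - 1L)), n, J - 1L) %*% diag(dgp$noise_sd, J - 1L)
    M <- cbind(W, 1 - rowSums(W))
    M[M < 0] <- 0
    M <- M / rowSums(M)

    ## -- non-purchase thinning ----------------------------------------------
    for (g in seq_len(J - 1L)) {
      p <- dgp$nonpurchase_prob[g]
      if (p <= 0) next
      z <- runif(n) < p
      M[z, J] <- M[z, J] + M[z, g]
      M[z, g] <- 0
    }
    if (dgp$nonpurchase_prob[J] > 0) {
      z <- runif(n) < dgp$nonpurchase_prob[J] & rowSums(M[, -J, drop = FALSE]) > 0
      M[z, J] <- 0
      M[z, ] <- M[z, , drop = FALSE] / rowSums(M[z, , drop = FALSE])
    }
    colnames(M) <- paste0("w", seq_len(J))

    shares <- cbind(panel, data.table::as.data.table(M))

    ## -- record-level expansion ---------------------------------------------
    recs <- NULL
    if (records) {
      recs <- expand_records(dgp, shares, M, price_truth)
    }

    out <- structure(
      list(
        shares = shares,
        prices = cbind(panel[, .(household_id, quarter)],
                       data.table::as.data.table(lnP)),
        records = recs,
        truth = dgp,
        noiseless = list(shares = W0, y = y0),
        price_truth = price_truth[, .(brand, group, quarter, province,
                                      ln_price_sys)],
        seed = seed
      ),
      class = "easi_panel"
    )
    out$true_elasticities <- truth_elasticities(out)
    out
  })
}

#' @export
print.easi_panel <- function(x, ...) {
  cat(sprintf("Synthetic scanner panel: %d household-quarters, %d households, %d groups\n",
              nrow(x$shares), length(unique(x$shares$household_id)), x$truth$J))
  if (!is.null(x$records)) {
    cat(sprintf("  %d purchase records across %d brands\n",
                nrow(x$records), length(unique(x$records$brand))))
  }
  cat(sprintf("  seed %s; mean ln expenditure %.2f\n", format(x$seed),
              mean(x$shares$ln_expenditure)))
  invisible(x)
}

# Expand household-quarter group spends into item-level purchase records.
expand_records <- function(dgp, shares, M, price_truth) {
  J <- dgp$J
  bm <- dgp$brand_map
  sd_i <- dgp$price_sd[["idiosyncratic"]]
  x_tot <- exp(shares$ln_expenditure)
  out <- vector("list", J)
  for (g in seq_len(J)) {
    rows <- which(M[, g] > 0)
    if (!length(rows)) next
    bg <- bm[group == g]
    kb <- nrow(bg)
    ncell <- length(rows)
    spend_g <- M[rows, g] * x_tot[rows]
    b1 <- sample.int(kb, ncell, TRUE, prob = bg$base_quantity)
    two <- kb > 1L & runif(ncell) < 0.35
    b2 <- ifelse(two, (b1 %% kb) + 1L, NA_integer_)
    f1 <- ifelse(two, runif(ncell, 0.55, 0.8), 1)
    cell <- rbind(
      data.table::data.table(row = rows, bidx = b1, spend = spend_g * f1),
      data.table::data.table(row = rows[two], bidx = b2[two],
                             spend = (spend_g * (1 - f1))[two])
    )
    cell[, `:=`(
      brand = bg$brand[bidx],
      item_type = bg$item_type[bidx],
      sugar_per_100ml = bg$sugar_per_100ml[bidx],
      taxable = bg$taxable[bidx],
      unit = bg$unit[bidx],
      package_size = bg$package_size[bidx],
      group = g
    )]
    out[[g]] <- cell
  }
  recs <- data.table::rbindlist(out)
  keys <- shares[recs$row,
                 .(household_id, quarter, province, lsm, lifecycle, hh_size,
                   n_children, weight)]
  recs <- cbind(keys, recs[, .(group, brand, item_type, sugar_per_100ml,
                               taxable, unit, package_size, spend)])
  recs[, month := (quarter - 1L) * 3L + sample.int(3L, .N, TRUE)]
  recs <- merge(recs, price_truth[, .(brand, quarter, province, ln_price_sys)],
                by = c("brand", "quarter", "province"), sort = FALSE)
  recs[, unit_price := exp(ln_price_sys + rnorm(.N, 0, sd_i))]
  recs[, quantity := spend / unit_price]
  recs[, c("ln_price_sys", "unit_price") := NULL]
  data.table::setcolorder(recs, c("household_id", "quarter", "month",
                                  "province", "lsm", "lifecycle", "hh_size",
                                  "n_children", "group", "brand", "item_type",
                                  "sugar_per_100ml", "taxable", "unit",
                                  "package_size", "quantity", "spend",
                                  "weight"))
  data.table::setorder(recs, household_id, quarter, group, brand)
  recs[]
}

#' Write a synthetic panel to plain-text files
#'
#' Emits `records.csv` (item-level purchases), `shares.csv` (household-quarter
#' budget shares and shifters), `prices.csv` (ground-truth log group price
#' indices) and `truth.json` (the generator parameters) under `dir`.
#'
#' @param panel an `easi_panel` from [simulate_panel()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "easi_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    shares = file.path(dir, "shares.csv"),
    prices = file.path(dir, "prices.csv"),
    truth = file.path(dir, "truth.json")
  )
  data.table::fwrite(panel$shares, paths[["shares"]])
  data.table::fwrite(panel$prices, paths[["prices"]])
  dgp <- panel$truth
  truth <- list(
    J = dgp$J, R = dgp$R, labels = dgp$labels, mean_shares = dgp$mean_shares,
    intercepts = dgp$m, engel_coeffs = dgp$b, shifter_coeffs = dgp$gamma,
    shifter_names = shifter_names(dgp$shifters), A = dgp$A, B = dgp$B,
    noise_sd = dgp$noise_sd, nonpurchase_prob = dgp$nonpurchase_prob,
    y_ref = dgp$y_ref, lsm_price_scale = dgp$lsm_price_scale, seed = dgp$seed
  )
  jsonlite::write_json(truth, paths[["truth"]], digits = NA, auto_unbox = TRUE)
  if (!is.null(panel$records)) {
    paths <- c(paths, records = file.path(dir, "records.csv"))
    data.table::fwrite(panel$records, paths[["records"]])
  }
  invisible(paths)
}
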