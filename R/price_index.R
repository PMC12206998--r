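#' Household-quarter unit values by brand
#'
#' Unit values (spend divided by quantity, ZAR per g or ml) aggregated to the
#' household-quarter x brand level by the quantity-weighted mean (total spend
#' over total quantity). The result is a complete grid over observed
#' household-quarters and the brand universe: cells the household-quarter did
#' not buy carry a missing unit value and `observed = FALSE`.
#'
#' @param records retained purchase records with positive quantities.
#' @return A `data.table` (class `unit_value_table`) with columns
#'   `household_id`, `quarter`, `province`, `lsm`, `group`, `brand`,
#'   `unit_value`, `quantity`, `observed`.
#' @export
compute_unit_values <- function(records) {
  rec <- data.table::as.data.table(records)
  if (any(rec$quantity <= 0)) {
    stopf("records contain non-positive quantities; exclude them upstream")
  }
  uv <- rec[, .(spend_sum = sum(spend), qty_sum = sum(quantity)),
            by = .(household_id, quarter, group, brand)]
  uv[, unit_value := spend_sum / qty_sum]
  hq <- unique(rec[, .(household_id, quarter, province, lsm)])
  brands <- unique(rec[, .(group, brand)])
  nb <- nrow(brands)
  grid <- cbind(hq[rep(seq_len(nrow(hq)), each = nb)],
                brands[rep(seq_len(nb), times = nrow(hq))])
  out <- merge(grid, uv[, .(household_id, quarter, brand, unit_value,
                            quantity = qty_sum)],
               by = c("household_id", "quarter", "brand"), all.x = TRUE)
  out[, observed := !is.na(unit_value)]
  data.table::setorder(out, household_id, quarter, group, brand)
  data.table::setattr(out, "class",
                      c("unit_value_table", class(out)))
  out[]
}

#' Impute unit values missing through non-purchase
#'
#' For each group, fits a linear regression of log unit value on quarter,
#' province, LSM stratum and brand indicators over the observed cells, and
#' fills each missing cell with the exponentiated prediction. Observed cells
#' are never altered. Covariate families with a single level (or collinear
#' columns) are dropped automatically; with no usable covariates the
#' prediction degenerates to the geometric mean of the observed unit values.
#'
#' @param uv a `unit_value_table` from [compute_unit_values()].
#' @param covariates character vector of covariate columns to use (subset of
#'   `quarter`, `province`, `lsm`, `brand`).
#' @param log_scale fit on the log scale (default) or on levels.
#' @return The completed table with all `unit_value` cells filled and an
#'   `imputed` flag column; the fitted group models are attached as
#'   `attr(, "models")` (coefficient vectors).
#' @export
impute_missing_prices <- function(uv,
                                  covariates = c("quarter", "province",
                                                 "lsm", "brand"),
                                  log_scale = TRUE) {
  out <- data.table::copy(data.table::as.data.table(uv))
  covariates <- intersect(covariates, names(out))
  out[, imputed := !observed]
  if (!any(out$imputed)) {
    return(out[])
  }
  models <- list()
  for (g in sort(unique(out$group))) {
    rows <- which(out$group == g)
    obs <- rows[out$observed[rows]]
    mis <- rows[!out$observed[rows]]
    if (!length(obs)) {
      stopf("group %s has no observed unit values; cannot impute", g)
    }
    if (!length(mis)) next
    # design over all of the group's rows so prediction needs no new levels
    terms <- character(0)
    df <- out[rows]
    for (v in covariates) {
      if (length(unique(df[[v]])) > 1L) terms <- c(terms, sprintf("factor(%s)", v))
    }
    yobs <- if (log_scale) log(out$unit_value[obs]) else out$unit_value[obs]
    if (!length(terms)) {
      pred <- rep(mean(yobs), length(mis))
      beta <- c(`(Intercept)` = mean(yobs))
    } else {
      X <- stats::model.matrix(stats::as.formula(paste("~", paste(terms, collapse = "+"))),
                               data = df)
      obs_local <- match(obs, rows)
      mis_local <- match(mis, rows)
      fit <- stats::lm.fit(X[obs_local, , drop = FALSE], yobs)
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0            # collinear columns dropped
      pred <- drop(X[mis_local, , drop = FALSE] %*% beta)
    }
    out$unit_value[mis] <- if (log_scale) exp(pred) else pred
    models[[as.character(g)]] <- beta
  }
  data.table::setattr(out, "models", models)
  out[]
}

#' Laspeyres, Paasche and Fisher indices for one group of brands
#'
#' The elementary index kernel: given current prices `p`, base prices `p0`,
#' current quantities `q` and base quantities `q0` over the same brand set,
#' returns the Laspeyres index (base-quantity weights), the Paasche index
#' (current-quantity weights) and their geometric mean, the Fisher index.
#'
#' @param p,p0 current and base prices, strictly positive.
#' @param q,q0 current and base quantities; `q` may be all zero (the Paasche
#'   weights then fall back to `q0`, so Fisher = Laspeyres).
#' @return A list with `laspeyres`, `paasche`, `fisher`.
#' @export
fisher_from_vectors <- function(p, p0, q, q0) {
  stopifnot(length(p) == length(p0), length(p) == length(q),
            length(p) == length(q0))
  if (any(p <= 0) || any(p0 <= 0)) stopf("nonpositive price entering an index")
  if (any(q0 < 0) || any(q < 0)) stopf("negative quantity entering an index")
  if (sum(q) == 0) q <- q0
  L <- sum(p * q0) / sum(p0 * q0)
  P <- sum(p * q) / sum(p0 * q)
  list(laspeyres = L, paasche = P, fisher = sqrt(L * P))
}

#' Household-quarter Fisher price indices by group
#'
#' Builds the log Fisher price index of each non-numeraire group for every
#' household-quarter, over group-brand elements, with base prices and
#' quantities set at their sample means (unweighted means over observed
#' household-quarter-brand cells). For household-quarters with no purchase in
#' a group, the Paasche weights fall back to the base quantities, so the
#' index reduces to its Laspeyres form — this keeps a price defined for every
#' household-quarter, which the demand system requires.
#'
#' @param completed a completed `unit_value_table` (all prices filled, e.g.
#'   from [impute_missing_prices()]).
#' @param base optional base list (per-brand `p0`, `q0`) from a previous call
#'   (e.g. the full-sample base reused for a stratum); computed from
#'   `completed` when `NULL`.
#' @param numeraire_group group index treated as numeraire and excluded from
#'   the output (its log price is the normalisation); defaults to the largest
#'   group index.
#' @return A `data.table` with `household_id`, `quarter` and `ln_p{g}` columns
#'   for each non-numeraire group; the base vectors are attached as
#'   `attr(, "base")`.
#' @export
fisher_index <- function(completed, base = NULL, numeraire_group = NULL) {
  uv <- data.table::as.data.table(completed)
  if (any(is.na(uv$unit_value))) {
    stopf("completed table still has missing unit values; run impute_missing_prices()")
  }
  if (any(uv$unit_value <= 0)) stopf("nonpositive price entering an index")
  if (is.null(numeraire_group)) numeraire_group <- max(uv$group)
  if (is.null(base)) {
    base <- uv[observed == TRUE,
               .(p0 = mean(unit_value),
                 q0 = mean(quantity)),
               by = .(group, brand)]
    base <- base[q0 > 0]     # brands never purchased in-sample are excluded
  }
  base <- data.table::as.data.table(base)

  hq <- unique(uv[, .(household_id, quarter)])
  data.table::setorder(hq, household_id, quarter)
  hq[, key_ := paste(household_id, quarter, sep = "\r")]
  out <- data.table::copy(hq)

  groups <- setdiff(sort(unique(base$group)), numeraire_group)
  for (g in groups) {
    bg <- base[group == g]
    sub <- merge(uv[group == g, .(household_id, quarter, brand, unit_value,
                                  quantity)],
                 bg[, .(brand, p0, q0)], by = "brand")
    sub[, key_ := paste(household_id, quarter, sep = "\r")]
    ridx <- match(sub$key_, hq$key_)
    bidx <- match(sub$brand, bg$brand)
    n <- nrow(hq)
    Pm <- matrix(NA_real_, n, nrow(bg))
    Qm <- matrix(0, n, nrow(bg))
    Pm[cbind(ridx, bidx)] <- sub$unit_value
    Qm[cbind(ridx, bidx)] <- ifelse(is.na(sub$quantity), 0, sub$quantity)
    if (anyNA(Pm)) {
      stopf("group %s: some household-quarters lack a completed price", g)
    }
    no_q <- rowSums(Qm) == 0
    if (any(no_q)) Qm[no_q, ] <- matrix(bg$q0, sum(no_q), nrow(bg), byrow = TRUE)
    L <- drop(Pm %*% bg$q0) / sum(bg$p0 * bg$q0)
    Pa <- rowSums(Pm * Qm) / drop(Qm %*% bg$p0)
    out[, (paste0("ln_p", g)) := 0.5 * (log(L) + log(Pa))]
  }
  out[, key_ := NULL]
  data.table::setattr(out, "base", base)
  out[]
}
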