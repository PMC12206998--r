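#' Apply the record-level exclusion filters
#'
#' Drops, in a fixed documented order: (1) beverages subject to the sugar
#' split whose sugar content is missing (unclassifiable); (2) non-numeraire
#' items whose printed package size is a whole number below 10 g or 10 ml
#' (suspect size or unit of measure; non-integer sizes such as 9.5 are kept);
#' (3) non-numeraire household-month-items whose unit value lies more than
#' five standard deviations from the item's group mean (groups split by unit
#' of measure; one pass, statistics computed on the input set before any
#' dropping); (4) all records of Northern Cape households; (5) all records of
#' households reporting a household size less than or equal to the number of
#' children. When an `item_type` column is present, records are (re)classified
#' into groups as part of rule 1; otherwise the existing `group` column is
#' trusted.
#'
#' @param records a `data.table`/`data.frame` of purchase records (see
#'   [simulate_panel()] for the column layout).
#' @param group_stats optional precomputed unit-value statistics from
#'   [unit_value_group_stats()]; computed from `records` when `NULL`.
#' @param log_scale if `TRUE` (default) the 5-SD outlier rule operates on log
#'   unit values, otherwise on the level scale.
#' @return A list with `records` (retained rows, with a `group` column) and
#'   `audit`, a named integer vector of per-rule drop counts plus the retained
#'   count; the audit always sums to the input row count.
#' @export
apply_exclusions <- function(records, group_stats = NULL, log_scale = TRUE) {
  rec <- data.table::copy(data.table::as.data.table(records))
  n_in <- nrow(rec)
  audit <- c(sugar_unclassifiable = 0L, small_integer_package = 0L,
             unit_value_outlier = 0L, northern_cape = 0L,
             children_exceed_size = 0L, retained = 0L)
  if (n_in == 0L) {
    return(list(records = rec, audit = audit))
  }
  numeraire <- group_schema()$numeraire_index
  if (is.null(group_stats)) {
    group_stats <- unit_value_group_stats(rec, log_scale = log_scale)
  }

  # (1) classification / missing sugar
  if ("item_type" %in% names(rec) && !all(is.na(rec$item_type))) {
    g <- classify_vec(rec$item_type, rec$sugar_per_100ml, rec$taxable)
    keep <- !is.na(g)
    audit[["sugar_unclassifiable"]] <- sum(!keep)
    rec <- rec[keep]
    rec[, group := g[keep]]
  }

  # (2) whole-number package size < 10
  if ("package_size" %in% names(rec)) {
    ps <- rec$package_size
    bad <- rec$group != numeraire & is.finite(ps) & ps == floor(ps) & ps < 10
    audit[["small_integer_package"]] <- sum(bad)
    rec <- rec[!bad]
  }

  # (3) 5-SD unit-value outliers at household-month-item granularity
  if (!"month" %in% names(rec)) rec[, month := quarter]
  uv <- rec[, .(uv = sum(spend) / sum(quantity)),
            by = .(household_id, month, brand, group, unit)]
  uv <- merge(uv, group_stats, by = c("group", "unit"), all.x = TRUE)
  uv[, val := if (log_scale) log(uv) else uv]
  uv[, out := !is.na(sd) & sd > 0 & abs(val - mean) > 5 * sd]
  bad_cells <- uv[out == TRUE, .(household_id, month, brand)]
  if (nrow(bad_cells)) {
    rec[, rid__ := .I]
    flagged <- merge(rec[group != numeraire,
                         .(rid__, household_id, month, brand)],
                     bad_cells, by = c("household_id", "month", "brand"))
    audit[["unit_value_outlier"]] <- nrow(flagged)
    if (nrow(flagged)) rec <- rec[-flagged$rid__]
    rec[, rid__ := NULL]
  }

  # (4) Northern Cape households
  nc <- rec$province == "Northern Cape"
  audit[["northern_cape"]] <- sum(nc)
  rec <- rec[!nc]

  # (5) household size <= number of children
  if ("n_children" %in% names(rec)) {
    bad <- rec$hh_size <= rec$n_children
    audit[["children_exceed_size"]] <- sum(bad)
    rec <- rec[!bad]
  }

  audit[["retained"]] <- nrow(rec)
  stopifnot(sum(audit) == n_in)
  list(records = rec[], audit = audit)
}

#' Per-group unit-value statistics for the outlier filter
#'
#' Mean and SD of (log) unit values across household-month-items, by group and
#' unit of measure, computed in a single pass over the input records.
#'
#' @param records purchase records.
#' @param log_scale statistics on log unit values (default) or levels.
#' @return `data.table` with columns `group`, `unit`, `mean`, `sd`, `n_cells`.
#' @export
unit_value_group_stats <- function(records, log_scale = TRUE) {
  rec <- data.table::copy(data.table::as.data.table(records))
  if (!"month" %in% names(rec)) rec[, month := quarter]
  if (!"unit" %in% names(rec)) rec[, unit := "g"]
  if (any(rec$quantity <= 0)) stopf("records contain non-positive quantities")
  uv <- rec[, .(uv = sum(spend) / sum(quantity)),
            by = .(household_id, month, brand, group, unit)]
  uv[, val := if (log_scale) log(uv) else uv]
  uv[, .(mean = mean(val), sd = stats::sd(val), n_cells = .N),
     by = .(group, unit)]
}

#' Build household-quarter budget shares from purchase records
#'
#' One row per household-quarter: the share of each group in the
#' household-quarter's total spend, log total expenditure, and the
#' demographics carried along for use as demand shifters. The last group's
#' share is computed as one minus the sum of the others, so shares add to 1
#' exactly.
#'
#' @param records retained, classified purchase records.
#' @param n_groups number of demand groups J (defaults to the 13-group
#'   schema).
#' @return A `data.table` with columns `household_id`, `quarter`,
#'   demographics, `weight`, `ln_expenditure` and `w1..wJ`. Household-quarters
#'   with zero total spend are dropped; their count is in
#'   `attr(, "dropped_zero_spend")`.
#' @export
compute_budget_shares <- function(records, n_groups = 13L) {
  rec <- data.table::as.data.table(records)
  stopifnot(all(rec$group >= 1L & rec$group <= n_groups))
  demo_cols <- intersect(c("province", "lsm", "lifecycle", "hh_size",
                           "n_children", "weight"), names(rec))
  tot <- rec[, c(.(total_spend = sum(spend)),
                 lapply(.SD, data.table::first)),
             by = .(household_id, quarter), .SDcols = demo_cols]
  n_zero <- sum(tot$total_spend <= 0)
  tot <- tot[total_spend > 0]
  if (n_zero > 0L) {
    warning(sprintf("dropped %d household-quarters with zero total spend", n_zero))
  }
  grp <- rec[, .(spend = sum(spend)), by = .(household_id, quarter, group)]
  wide <- data.table::dcast(grp, household_id + quarter ~ group,
                            value.var = "spend", fill = 0)
  have <- as.integer(setdiff(names(wide), c("household_id", "quarter")))
  for (g in setdiff(seq_len(n_groups), have)) wide[, (as.character(g)) := 0]
  data.table::setcolorder(wide, c("household_id", "quarter",
                                  as.character(seq_len(n_groups))))
  out <- merge(tot, wide, by = c("household_id", "quarter"))
  W <- as.matrix(out[, as.character(seq_len(n_groups)), with = FALSE]) /
    out$total_spend
  W[, n_groups] <- 1 - rowSums(W[, -n_groups, drop = FALSE])
  colnames(W) <- paste0("w", seq_len(n_groups))
  out[, (as.character(seq_len(n_groups))) := NULL]
  out[, ln_expenditure := log(total_spend)]
  out[, total_spend := NULL]
  out <- cbind(out, data.table::as.data.table(W))
  data.table::setorder(out, household_id, quarter)
  data.table::setattr(out, "dropped_zero_spend", n_zero)
  out[]
}

#' Weighted sample descriptives and budget-share summaries
#'
#' Weighted category percentages and means for the demographics, and for each
#' demand group the three standard budget-share summaries: the unconditional
#' weighted mean share `w`, the weighted proportion of zero-share
#' household-quarters `p_zero`, and the conditional-on-purchase mean share
#' `w_cond`. These satisfy `w = (1 - p_zero) * w_cond` identically.
#'
#' @param panel a share panel from [compute_budget_shares()] or
#'   [simulate_panel()]`$shares`.
#' @param by optional stratification column, one of `"lsm"`, `"province"`,
#'   `"lifecycle"`; summaries are produced overall and per stratum.
#' @param labels optional group labels.
#' @return A list of class `easi_descriptives` with elements `demographics`
#'   and `budget_shares` (one block per stratum).
#' @export
describe_sample <- function(panel, by = NULL, labels = NULL) {
  dt <- data.table::as.data.table(panel)
  wcols <- grep("^w[0-9]+$", names(dt), value = TRUE)
  wcols <- wcols[order(as.integer(sub("w", "", wcols)))]
  J <- length(wcols)
  if (is.null(labels)) {
    labels <- if (J == 13L) group_schema()$groups else wcols
  }
  if (!"weight" %in% names(dt)) dt[, weight := 1]
  if (any(dt$weight <= 0)) stopf("weights must be strictly positive")
  if (!is.null(by) && (!length(by) == 1L || !by %in% c("lsm", "province", "lifecycle"))) {
    stopf("unknown stratification key: %s", paste(by, collapse = ", "))
  }
  strata <- list(all = rep(TRUE, nrow(dt)))
  if (!is.null(by)) {
    for (lev in sort(unique(dt[[by]]))) strata[[lev]] <- dt[[by]] == lev
  }

  share_block <- function(d) {
    wt <- d$weight / sum(d$weight)
    out <- lapply(seq_len(J), function(g) {
      w <- d[[wcols[g]]]
      pz <- sum(wt * (w == 0))
      wc <- if (pz < 1) sum(wt * w) / (1 - pz) else NA_real_
      data.table::data.table(group = labels[g], w = sum(wt * w),
                             p_zero = pz, w_cond = wc)
    })
    data.table::rbindlist(out)
  }
  demo_block <- function(d) {
    wt <- d$weight / sum(d$weight)
    stats <- list(
      mean_hh_size = sum(wt * d$hh_size),
      n_obs = nrow(d),
      n_households = length(unique(d$household_id))
    )
    if ("n_children" %in% names(d)) {
      stats$mean_children <- sum(wt * d$n_children)
    }
    for (v in intersect(c("lsm", "lifecycle", "province"), names(d))) {
      tab <- vapply(split(wt, d[[v]]), sum, numeric(1))
      names(tab) <- paste0(v, ":", names(tab))
      stats <- c(stats, as.list(tab))
    }
    stats
  }

  structure(
    list(
      demographics = lapply(strata, function(i) demo_block(dt[i])),
      budget_shares = lapply(strata, function(i) share_block(dt[i])),
      by = by
    ),
    class = "easi_descriptives"
  )
}

#' @export
print.easi_descriptives <- function(x, ...) {
  for (s in names(x$budget_shares)) {
    cat("Stratum:", s, "\n")
    b <- x$budget_shares[[s]]
    cat(sprintf("  %-42s %6s %8s %8s\n", "group", "w (%)", "w=0 (%)",
                "w|w>0 (%)"))
    for (i in seq_len(nrow(b))) {
      cat(sprintf("  %-42s %6.1f %8.1f %8.1f\n", b$group[i], 100 * b$w[i],
                  100 * b$p_zero[i], 100 * b$w_cond[i]))
    }
  }
  invisible(x)
}
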