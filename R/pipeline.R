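#' Run the full demand-analysis pipeline
#'
#' Orchestrates simulate/ingest → clean → price indices → system fit →
#' elasticities, overall and stratified by LSM. Stratified runs re-estimate
#' everything on the household subsample but reuse the full-sample Fisher
#' bases by default (indices are built once, before stratification), so
#' elasticities are comparable across strata. Identical config and seed give
#' byte-identical artifacts.
#'
#' @param config a named list or a YAML file path. Recognised fields:
#'   \describe{
#'     \item{dgp}{an `easi_dgp`, or a list of [make_dgp()] arguments, or
#'       `list(preset = "table2", ...)` for [dgp_table2()].}
#'     \item{records_csv}{path to a record-level CSV to ingest instead of
#'       simulating.}
#'     \item{n_households, n_quarters, seed}{simulation size and seed
#'       (seed also controls any stochastic stage downstream).}
#'     \item{level}{`"records"` (default; full ingest + price-index chain) or
#'       `"model"` (fit directly on the generator's model-level panel).}
#'     \item{strata}{subsamples to estimate; subset of
#'       `c("all", "lower", "higher")`.}
#'     \item{easi}{list of [easi_config()] arguments.}
#'     \item{mode, share_source, compute_se}{elasticity averaging options.}
#'     \item{stratum_bases}{if `TRUE`, rebuild Fisher bases per stratum.}
#'     \item{out_dir}{output directory.}
#'   }
#' @return An object of class `easi_run`: per-stratum fits and elasticity
#'   tables, the exclusion audit, descriptives, file paths and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- resolve_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  audit <- NULL
  descr <- NULL
  panel_obj <- NULL
  if (!is.null(cfg$records_csv)) {
    records <- data.table::fread(cfg$records_csv)
    level <- "records"
  } else {
    panel_obj <- simulate_panel(cfg$dgp, cfg$n_households, cfg$n_quarters,
                                seed = cfg$seed,
                                presence_prob = cfg$presence_prob,
                                records = identical(cfg$level, "records"))
    records <- panel_obj$records
    level <- cfg$level
  }

  if (identical(level, "records")) {
    exc <- apply_exclusions(records)
    audit <- exc$audit
    shares_panel <- compute_budget_shares(exc$records,
                                          n_groups = cfg$n_groups)
    uv <- compute_unit_values(exc$records)
    completed <- impute_missing_prices(uv)
    prices <- fisher_index(completed, numeraire_group = cfg$n_groups)
  } else {
    shares_panel <- panel_obj$shares
    prices <- panel_obj$prices
  }
  descr <- describe_sample(shares_panel,
                           by = if ("lsm" %in% names(shares_panel)) "lsm")

  results <- list()
  for (s in cfg$strata) {
    rows <- switch(s,
                   all = rep(TRUE, nrow(shares_panel)),
                   lower = shares_panel$lsm == "lower",
                   higher = shares_panel$lsm == "higher",
                   stopf("unknown stratum: %s", s))
    sub <- shares_panel[rows]
    if (!nrow(sub)) stopf("stratum '%s' is empty", s)
    spr <- prices
    if (cfg$stratum_bases && identical(level, "records") && s != "all") {
      hh <- unique(sub$household_id)
      uv_s <- compute_unit_values(exc$records[household_id %in% hh])
      spr <- fisher_index(impute_missing_prices(uv_s),
                          numeraire_group = cfg$n_groups)
    }
    fit <- tryCatch(
      fit_easi(sub, spr, cfg$easi),
      error = function(e) stopf("stage fit_easi failed in stratum '%s': %s",
                                s, conditionMessage(e))
    )
    elas <- tryCatch(
      average_elasticities(fit, mode = cfg$mode,
                           share_source = cfg$share_source,
                           se = cfg$compute_se, stratum = s),
      error = function(e) stopf("stage elasticities failed in stratum '%s': %s",
                                s, conditionMessage(e))
    )
    results[[s]] <- list(fit = fit, elasticities = elas)
  }

  paths <- write_run_artifacts(cfg, results, audit, descr)
  manifest <- list(
    package = "easidemand",
    seed = cfg$seed,
    config = cfg$serializable,
    files = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)

  structure(
    list(config = cfg, results = results, audit = audit,
         descriptives = descr, panel = panel_obj,
         paths = c(paths, manifest = manifest_path),
         manifest = manifest),
    class = "easi_run"
  )
}

#' @export
print.easi_run <- function(x, ...) {
  cat("Pipeline run:", length(x$results), "strata ->", x$config$out_dir, "\n")
  for (s in names(x$results)) {
    own <- diag(x$results[[s]]$elasticities$marshallian)
    cat(sprintf("  %-7s own-price range [%.2f, %.2f]\n", s,
                min(own, na.rm = TRUE), max(own, na.rm = TRUE)))
  }
  invisible(x)
}

resolve_run_config <- function(config) {
  cfg <- list(
    n_households = config$n_households %||% 800L,
    n_quarters = config$n_quarters %||% 13L,
    seed = as.integer(config$seed %||% stopf("run config needs a `seed`")),
    presence_prob = config$presence_prob %||% 0.4,
    level = config$level %||% "records",
    strata = config$strata %||% c("all", "lower", "higher"),
    mode = config$mode %||% "per_observation",
    share_source = config$share_source %||% "fitted",
    compute_se = config$compute_se %||% TRUE,
    stratum_bases = isTRUE(config$stratum_bases),
    out_dir = config$out_dir %||% stopf("run config needs an `out_dir`"),
    records_csv = config$records_csv
  )
  # YAML deserialises sequences as lists; flatten scalar-list arguments
  flatten_args <- function(x) {
    if (!is.list(x)) return(x)
    lapply(x, function(el) if (is.list(el) && all(lengths(el) == 1L))
      unlist(el) else el)
  }
  dgp_spec <- config$dgp
  if (is.list(dgp_spec) && !inherits(dgp_spec, "easi_dgp")) {
    dgp_spec <- flatten_args(dgp_spec)
  }
  if (is.null(dgp_spec) && is.null(cfg$records_csv)) {
    dgp_spec <- list(preset = "table2")
  }
  if (inherits(dgp_spec, "easi_dgp")) {
    cfg$dgp <- dgp_spec
    dgp_ser <- list(object = TRUE, J = dgp_spec$J, seed = dgp_spec$seed)
  } else if (!is.null(dgp_spec)) {
    dgp_ser <- dgp_spec
    if (identical(dgp_spec$preset, "table2")) {
      args <- dgp_spec[setdiff(names(dgp_spec), "preset")]
      cfg$dgp <- do.call(dgp_table2, args)
    } else {
      cfg$dgp <- do.call(make_dgp, dgp_spec)
    }
  } else {
    dgp_ser <- NULL
  }
  cfg$n_groups <- if (!is.null(cfg$dgp)) cfg$dgp$J else 13L
  easi_args <- config$easi %||% list()
  easi_args <- lapply(easi_args, function(el)
    if (is.list(el) && all(lengths(el) == 1L)) unlist(el) else el)
  cfg$strata <- unlist(cfg$strata)
  cfg$easi <- do.call(easi_config, easi_args)
  cfg$serializable <- list(
    dgp = dgp_ser, n_households = cfg$n_households,
    n_quarters = cfg$n_quarters, seed = cfg$seed,
    presence_prob = cfg$presence_prob, level = cfg$level,
    strata = cfg$strata, easi = easi_args, mode = cfg$mode,
    share_source = cfg$share_source, compute_se = cfg$compute_se,
    stratum_bases = cfg$stratum_bases, out_dir = cfg$out_dir,
    records_csv = cfg$records_csv
  )
  cfg
}

write_run_artifacts <- function(cfg, results, audit, descr) {
  paths <- character(0)
  emit <- function(p) { paths <<- c(paths, p); p }
  for (s in names(results)) {
    d <- file.path(cfg$out_dir, s)
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    el <- results[[s]]$elasticities
    fit <- results[[s]]$fit
    J <- fit$J
    tab <- data.table::data.table(group = fit$labels)
    for (j in seq_len(J)) tab[[paste0("e_", j)]] <- el$marshallian[, j]
    tab$expenditure <- el$expenditure
    data.table::fwrite(tab, emit(file.path(d, "elasticities_marshallian.csv")))
    htab <- data.table::data.table(group = fit$labels)
    for (j in seq_len(J)) htab[[paste0("e_", j)]] <- el$hicksian[, j]
    data.table::fwrite(htab, emit(file.path(d, "elasticities_hicksian.csv")))
    if (!is.null(el$se_marshallian)) {
      stab <- data.table::data.table(group = fit$labels)
      for (j in seq_len(J)) stab[[paste0("se_", j)]] <- el$se_marshallian[, j]
      stab$se_expenditure <- el$se_expenditure
      data.table::fwrite(stab, emit(file.path(d, "se_marshallian.csv")))
    }
    fit_json <- list(
      labels = fit$labels, columns = fit$colnames,
      coefficients = fit$coef_matrix,
      A = fit$coef$A, B = fit$coef$B,
      convergence_trace = fit$convergence$trace,
      config = fit$config[c("engel_order", "include_price_utility_interactions",
                            "include_shifter_utility_interactions",
                            "impose_symmetry", "include_prices", "tol",
                            "y_center", "use_weights")],
      log = fit$log, n = fit$n
    )
    jsonlite::write_json(fit_json, emit(file.path(d, "fit.json")),
                         digits = NA, auto_unbox = TRUE)
    data.table::fwrite(data.table::as.data.table(fit$vcov),
                       emit(file.path(d, "vcov.csv")))
    rep_lines <- c(
      sprintf("EASI fit, stratum %s: %d rows, %d households", s, fit$n,
              length(unique(fit$data$cluster))),
      sprintf("converged in %d passes (last |dy| = %.3e)",
              fit$convergence$iterations,
              fit$convergence$trace[length(fit$convergence$trace)]),
      fit$log, "",
      "own-price (Marshallian) / expenditure elasticities:",
      sprintf("  %-42s %8.3f %8.3f", fit$labels,
              diag(el$marshallian), el$expenditure)
    )
    writeLines(rep_lines, emit(file.path(d, "fit_report.txt")))
  }
  if (!is.null(audit)) {
    jsonlite::write_json(as.list(audit),
                         emit(file.path(cfg$out_dir, "audit.json")),
                         digits = NA, auto_unbox = TRUE)
  }
  if (!is.null(descr)) {
    blocks <- lapply(names(descr$budget_shares), function(s) {
      b <- data.table::copy(descr$budget_shares[[s]])
      b[, stratum := s]
      b
    })
    data.table::fwrite(data.table::rbindlist(blocks),
                       emit(file.path(cfg$out_dir, "descriptives.csv")))
  }
  paths
}

format_elasticity_cell <- function(est, se = NA_real_) {
  if (is.na(est)) return("")
  if (is.na(se)) return(sprintf("%.2f", est))
  p <- 2 * stats::pnorm(-abs(est / se))
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  sprintf("%.2f (%.2f)%s", est, se, stars)
}

#' Render formatted elasticity tables
#'
#' Emits, per stratum, an aligned plain-text table in the conventional demand
#' layout — 13 price columns plus an expenditure column, standard errors in
#' parentheses, significance stars at the 0.05/0.01/0.001 two-sided normal
#' thresholds, own-price elasticities on the diagonal — plus a by-stratum
#' comparison of own-price elasticities (CSV and text).
#'
#' @param run an `easi_run` from [run_pipeline()], or its `results` list.
#' @param out_dir output directory (defaults to the run's).
#' @return Invisibly, the written paths.
#' @export
render_tables <- function(run, out_dir = NULL) {
  results <- if (inherits(run, "easi_run")) run$results else run
  out_dir <- out_dir %||% (if (inherits(run, "easi_run"))
    run$config$out_dir else stopf("out_dir required"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in names(results)) {
    el <- results[[s]]$elasticities
    if (is.null(el)) stopf("stratum '%s' has no elasticity table", s)
    J <- length(el$expenditure)
    labels <- names(el$expenditure)
    se_m <- el$se_marshallian
    se_e <- el$se_expenditure
    lines <- c(sprintf("Average Marshallian price and expenditure elasticities - stratum %s", s),
               "(standard errors in parentheses; *p<0.05 **p<0.01 ***p<0.001; diagonal = own-price)",
               "")
    header <- sprintf("%-44s %s %14s", "group",
                      paste(sprintf("%14s", paste0("j=", seq_len(J))),
                            collapse = " "), "expenditure")
    lines <- c(lines, header)
    for (i in seq_len(J)) {
      cells <- vapply(seq_len(J), function(j) {
        format_elasticity_cell(el$marshallian[i, j],
                               if (is.null(se_m)) NA_real_ else se_m[i, j])
      }, character(1))
      ecell <- format_elasticity_cell(el$expenditure[i],
                                      if (is.null(se_e)) NA_real_ else se_e[i])
      lines <- c(lines, sprintf("%-44s %s %14s", substr(labels[i], 1, 44),
                                paste(sprintf("%14s", cells), collapse = " "),
                                ecell))
    }
    p <- file.path(out_dir, paste0("table_elasticities_", s, ".txt"))
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  # by-stratum own-price comparison
  strata <- names(results)
  labels <- names(results[[1L]]$elasticities$expenditure)
  cmp <- data.table::data.table(group = labels)
  for (s in strata) {
    cmp[[paste0("own_price_", s)]] <- diag(results[[s]]$elasticities$marshallian)
    cmp[[paste0("expenditure_", s)]] <- results[[s]]$elasticities$expenditure
  }
  p <- file.path(out_dir, "own_price_by_stratum.csv")
  data.table::fwrite(cmp, p)
  paths <- c(paths, p)
  invisible(paths)
}
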