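#' Construct a demand-system data-generating process
#'
#' Builds a fully parameterised implicit-utility (EASI) share system with
#' known ground truth: polynomial Engel curves, demographic shifters, a
#' symmetric log-price semi-elasticity matrix `A`, an optional price-utility
#' interaction matrix `B`, per-group non-purchase probabilities and a
#' group-brand price model. The construction anchors the system so that at the
#' reference point (all log prices 0, implicit utility at its reference value,
#' shifters at their reference levels) the implied budget shares equal
#' `mean_shares` exactly, and — when `A` is not supplied — the own-price and
#' expenditure elasticities at that point equal the requested targets.
#'
#' @param mean_shares numeric vector of J >= 3 positive budget shares summing
#'   to 1; the last element is the numeraire.
#' @param engel_order polynomial order R >= 1 of the Engel curves (default 3).
#' @param labels optional group labels (length J).
#' @param expenditure_elasticities length J-1 targets for the expenditure
#'   elasticities at the reference point; drawn in \[0.9, 1.3\] if `NULL`.
#' @param own_price_elasticities length J-1 targets for the Marshallian
#'   own-price elasticities at the reference point; drawn in \[-1.8, -1.2\]
#'   if `NULL`. Ignored when `price_matrix_A` is supplied.
#' @param price_matrix_A optional (J-1)x(J-1) log-price coefficient matrix;
#'   drawn symmetric with a negative diagonal by default.
#' @param price_utility_matrix_B optional (J-1)x(J-1) price-utility interaction
#'   matrix (default all zero).
#' @param off_diag_scale scale of the random symmetric off-diagonal entries of
#'   the default `A` (relative to `sqrt(w_i w_j)`).
#' @param shifters demographic shifter families entering the share equations;
#'   any subset of `c("hh_size", "lifecycle", "lsm", "province")`.
#' @param shifter_scale scale of the random shifter coefficients (relative to
#'   each group's mean share).
#' @param noise_sd additive share-equation error SD; scalar or length J-1.
#' @param nonpurchase_prob per-group probability that a household-quarter
#'   purchases nothing in the group; scalar or length J, each in \[0, 1\].
#' @param y_ref reference log expenditure (ZAR per quarter); the Engel
#'   polynomial is centred here.
#' @param expenditure_sd SD of simulated log expenditure around `y_ref`.
#' @param price_sd named vector with the SDs of the `quarter`, `province`,
#'   `quarter_province` (region-by-time shocks; these identify the price
#'   coefficients when the demand design carries quarter and province fixed
#'   effects) and `idiosyncratic` components of brand-level log prices.
#' @param brand_map optional `data.frame` mapping groups to brands (columns
#'   `group`, `brand`, `item_type`, `sugar_per_100ml`, `taxable`, `unit`,
#'   `package_size`, `base_price`, `base_quantity`); a default map is built
#'   when `NULL`.
#' @param lsm_price_scale multiplier applied to `A` for lower-LSM households
#'   (1 = no socioeconomic heterogeneity in price responses).
#' @param strict_law_of_demand if `TRUE`, a requested `A` with any positive
#'   diagonal entry is rejected.
#' @param seed integer seed controlling the random draws of this constructor.
#' @return An object of class `easi_dgp`.
#' @seealso [simulate_panel()], [solve_shares()], [dgp_table2()]
#' @export
make_dgp <- function(mean_shares,
                     engel_order = 3,
                     labels = NULL,
                     expenditure_elasticities = NULL,
                     own_price_elasticities = NULL,
                     price_matrix_A = NULL,
                     price_utility_matrix_B = NULL,
                     off_diag_scale = 0.1,
                     shifters = c("hh_size", "lifecycle", "lsm", "province"),
                     shifter_scale = 0.05,
                     noise_sd = 0.02,
                     nonpurchase_prob = 0,
                     y_ref = log(3000),
                     expenditure_sd = 0.5,
                     price_sd = c(quarter = 0.05, province = 0.05,
                                  quarter_province = 0.04,
                                  idiosyncratic = 0.1),
                     brand_map = NULL,
                     lsm_price_scale = 1,
                     strict_law_of_demand = FALSE,
                     seed = 1L) {
  J <- length(mean_shares)
  if (J < 3L) stopf("need at least 3 groups, got %d", J)
  R <- as.integer(engel_order)
  if (R < 1L) stopf("engel_order must be >= 1")
  if (any(!is.finite(mean_shares)) || any(mean_shares <= 0)) {
    stopf("mean_shares must all be strictly positive")
  }
  if (abs(sum(mean_shares) - 1) > 1e-8) {
    stopf("mean_shares must sum to 1 (got %.10f)", sum(mean_shares))
  }
  if (is.null(labels)) {
    labels <- if (J == 13L) group_schema()$groups else
      c(paste0("group_", seq_len(J - 1L)), "numeraire")
  }
  stopifnot(length(labels) == J)
  shifters <- match.arg(shifters,
                        c("hh_size", "lifecycle", "lsm", "province"),
                        several.ok = TRUE)
  if (length(nonpurchase_prob) == 1L) {
    nonpurchase_prob <- c(rep(nonpurchase_prob, J - 1L), 0)
  }
  stopifnot(length(nonpurchase_prob) == J)
  if (any(nonpurchase_prob < 0 | nonpurchase_prob > 1)) {
    stopf("nonpurchase_prob entries must lie in [0, 1]")
  }
  if (length(noise_sd) == 1L) noise_sd <- rep(noise_sd, J - 1L)
  stopifnot(length(noise_sd) == J - 1L, all(noise_sd >= 0))
  check_scalar(y_ref, "y_ref")
  check_scalar(lsm_price_scale, "lsm_price_scale", lower = 0)

  m <- mean_shares[-J]
  K <- length(shifter_names(shifters))

  obj <- with_seed(seed, {
    e_tgt <- expenditure_elasticities %||% runif(J - 1L, 0.9, 1.3)
    stopifnot(length(e_tgt) == J - 1L)
    b <- matrix(0, J - 1L, R)
    b[, 1L] <- m * (e_tgt - 1)
    if (R >= 2L) {
      hi_scale <- c(0.05, 0.02, rep(0.01, max(0L, R - 3L)))
      for (r in 2:R) b[, r] <- m * hi_scale[r - 1L] * runif(J - 1L, -1, 1)
    }
    gamma <- if (K > 0L) {
      matrix(m * shifter_scale, J - 1L, K) *
        matrix(runif((J - 1L) * K, -1, 1), J - 1L, K)
    } else {
      matrix(0, J - 1L, 0L)
    }
    if (is.null(price_matrix_A)) {
      tau <- own_price_elasticities %||% runif(J - 1L, -1.8, -1.2)
      stopifnot(length(tau) == J - 1L)
      A <- matrix(0, J - 1L, J - 1L)
      if (J > 2L) {
        for (i in seq_len(J - 2L)) {
          for (k in (i + 1L):(J - 1L)) {
            A[i, k] <- A[k, i] <- off_diag_scale * sqrt(m[i] * m[k]) *
              runif(1, -1, 1)
          }
        }
      }
      diag(A) <- m * (tau + 1 - m + e_tgt * m)
    } else {
      A <- as.matrix(price_matrix_A)
      stopifnot(all(dim(A) == J - 1L))
    }
    if (strict_law_of_demand && any(diag(A) > 0)) {
      stopf("strict_law_of_demand: price matrix A has a positive diagonal entry")
    }
    B <- if (is.null(price_utility_matrix_B)) {
      matrix(0, J - 1L, J - 1L)
    } else {
      as.matrix(price_utility_matrix_B)
    }
    stopifnot(all(dim(B) == J - 1L))
    list(b = b, gamma = gamma, A = A, B = B)
  })

  if (is.null(brand_map)) brand_map <- default_brand_map(J, labels)
  brand_map <- data.table::as.data.table(brand_map)
  req <- c("group", "brand", "base_price", "base_quantity", "unit")
  if (!all(req %in% names(brand_map))) {
    stopf("brand_map must have columns %s", paste(req, collapse = ", "))
  }
  if (any(brand_map$base_price <= 0)) stopf("brand base prices must be > 0")
  if (any(brand_map$base_quantity <= 0)) stopf("brand base quantities must be > 0")

  structure(
    list(
      J = J, R = R, labels = labels, mean_shares = mean_shares,
      m = m, b = obj$b, gamma = obj$gamma, A = obj$A, B = obj$B,
      shifters = shifters, noise_sd = noise_sd,
      nonpurchase_prob = nonpurchase_prob,
      y_ref = y_ref, expenditure_sd = expenditure_sd,
      price_sd = price_sd, brand_map = brand_map,
      lsm_price_scale = lsm_price_scale, seed = seed
    ),
    class = "easi_dgp"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.easi_dgp <- function(x, ...) {
  cat(sprintf("EASI data-generating process: %d groups, Engel order %d, %d shifters\n",
              x$J, x$R, ncol(x$gamma)))
  cat(sprintf("  reference shares: %s\n",
              paste(sprintf("%.3f", x$mean_shares), collapse = " ")))
  cat(sprintf("  noise SD %.3g-%.3g, non-purchase %.2f-%.2f, LSM price scale %.2f\n",
              min(x$noise_sd), max(x$noise_sd), min(x$nonpurchase_prob),
              max(x$nonpurchase_prob), x$lsm_price_scale))
  invisible(x)
}

# Ground-truth parameters in the common form used by the solver, the
# finite-difference oracle and the analytic elasticity formulas.
# lsm = "lower" applies the stratified price-response scaling.
as_easi_params <- function(x, lsm = "higher") {
  if (inherits(x, "easi_dgp")) {
    A <- if (identical(lsm, "lower")) x$lsm_price_scale * x$A else x$A
    list(J = x$J, R = x$R, b0 = x$m, b = x$b, gamma = x$gamma,
         A = A, B = x$B, y_center = x$y_ref, labels = x$labels)
  } else if (inherits(x, "easi_fit")) {
    list(J = x$J, R = x$R, b0 = x$coef$b0, b = x$coef$b, gamma = x$coef$gamma,
         A = x$coef$A, B = x$coef$B, y_center = x$config$y_center,
         labels = x$labels)
  } else {
    stopf("cannot interpret object of class %s as EASI parameters",
          paste(class(x), collapse = "/"))
  }
}

# Share-equation right-hand side for parameter list `par` at utility y:
# w_j = b0_j + sum_r b_jr (y - y_center)^r + z'gamma_j + (A p)_j + y (B p)_j
share_rhs <- function(par, P, y, Z) {
  n <- length(y)
  U <- y - par$y_center
  W <- matrix(par$b0, n, par$J - 1L, byrow = TRUE)
  for (r in seq_len(par$R)) W <- W + (U^r) %o% par$b[, r]
  if (ncol(par$gamma) > 0L) W <- W + Z %*% t(par$gamma)
  W <- W + P %*% t(par$A)
  if (any(par$B != 0)) W <- W + y * (P %*% t(par$B))
  W
}

# Damped fixed-point solution of the share system for n rows at once.
solve_shares_mat <- function(par, P, ln_x, Z,
                             damping = 0.5, tol = 1e-10, max_iter = 500L,
                             start = NULL) {
  n <- length(ln_x)
  Jm1 <- par$J - 1L
  stopifnot(is.matrix(P), ncol(P) == Jm1, nrow(P) == n)
  if (is.null(Z)) Z <- matrix(0, n, ncol(par$gamma))
  den <- 1 - 0.5 * quad_form(P, par$B)
  if (any(abs(den) < 1e-6)) {
    stopf("implicit-utility denominator within 1e-6 of zero (min |den| = %.2e)",
          min(abs(den)))
  }
  W <- if (is.null(start)) matrix(par$b0, n, Jm1, byrow = TRUE) else start
  resid <- Inf
  for (it in seq_len(max_iter)) {
    y <- (ln_x - rowSums(W * P) + 0.5 * quad_form(P, par$A)) / den
    W_new <- share_rhs(par, P, y, Z)
    resid <- max(abs(W_new - W))
    W <- (1 - damping) * W + damping * W_new
    if (resid < tol) break
  }
  if (resid >= tol) {
    stopf("share fixed point did not converge in %d iterations (last residual %.3e)",
          max_iter, resid)
  }
  y <- (ln_x - rowSums(W * P) + 0.5 * quad_form(P, par$A)) / den
  list(W = cbind(W, 1 - rowSums(W)), y = y, iterations = it, residual = resid)
}

#' Solve the implicit share system at one evaluation point
#'
#' The budget shares and the implicit utility of the EASI system are mutually
#' dependent (utility deflates expenditure by the share-weighted Stone price
#' index), so the shares at a given price/expenditure point are the fixed
#' point of the share equations. This solves that fixed point by damped
#' iteration (damping 0.5, tolerance 1e-10 on the maximum absolute share
#' change, at most 500 iterations).
#'
#' @param dgp an `easi_dgp` object (or a fitted system via [recover_numeraire()]
#'   semantics is not needed here: any object understood by the package's
#'   parameter accessor).
#' @param log_prices length J-1 vector of log price indices relative to the
#'   numeraire (whose log price is identically 0).
#' @param log_expenditure scalar log total expenditure.
#' @param shifters optional named shifter vector (defaults to the reference
#'   point, all zeros).
#' @param tol,max_iter,damping solver controls.
#' @param lsm `"higher"` (default) or `"lower"`: which stratum's price-response
#'   matrix to use when the DGP has stratified price sensitivity.
#' @return Numeric length-J share vector summing to 1, with attributes `y`
#'   (implicit utility at the solution) and `iterations`.
#' @export
solve_shares <- function(dgp, log_prices, log_expenditure, shifters = NULL,
                         tol = 1e-10, max_iter = 500L, damping = 0.5,
                         lsm = "higher") {
  par <- as_easi_params(dgp, lsm = lsm)
  stopifnot(length(log_prices) == par$J - 1L,
            all(is.finite(log_prices)), is.finite(log_expenditure))
  K <- ncol(par$gamma)
  z <- if (is.null(shifters)) rep(0, K) else shifters
  stopifnot(length(z) == K)
  sol <- solve_shares_mat(par, matrix(log_prices, 1L), log_expenditure,
                          matrix(z, 1L), damping = damping, tol = tol,
                          max_iter = max_iter)
  structure(drop(sol$W), names = par$labels, y = sol$y,
            iterations = sol$iterations)
}

# ---- shifter encoding ------------------------------------------------------

# Canonical demographic levels. Reference levels head each vector; they are
# dropped in the dummy encoding, so the reference household (family household,
# lower LSM, Gauteng, size 3) sits at shifter value zero.
lifecycle_levels <- function() {
  c("families", "empty_nesters", "mature_no_children", "retired",
    "young_no_children")
}
province_levels <- function() {
  c("Gauteng", "Western Cape", "Eastern Cape", "Free State",
    "KwaZulu-Natal", "North-West", "Mpumalanga", "Limpopo")
}
lsm_levels <- function() c("lower", "higher")
hh_size_reference <- function() 3

shifter_names <- function(families, quarter_levels = NULL) {
  nm <- character(0)
  if ("hh_size" %in% families) nm <- c(nm, "hh_size")
  if ("lifecycle" %in% families) {
    nm <- c(nm, paste0("lifecycle_", lifecycle_levels()[-1L]))
  }
  if ("lsm" %in% families) nm <- c(nm, "lsm_higher")
  if ("province" %in% families) {
    nm <- c(nm, paste0("province_", province_levels()[-1L]))
  }
  if ("quarter" %in% families && length(quarter_levels) > 1L) {
    nm <- c(nm, paste0("quarter_", quarter_levels[-1L]))
  }
  nm
}

# Encode demographics into the shifter matrix shared by the generator and the
# estimator. `df` needs columns for the requested families; unknown provinces
# (e.g. Northern Cape rows kept only to exercise the exclusion filters) are
# encoded at the reference level.
encode_shifters <- function(df, families, quarter_levels = NULL) {
  n <- nrow(df)
  blocks <- list()
  if ("hh_size" %in% families) {
    blocks$hh_size <- matrix(df$hh_size - hh_size_reference(),
                             dimnames = list(NULL, "hh_size"))
  }
  if ("lifecycle" %in% families) {
    f <- factor(df$lifecycle, levels = lifecycle_levels())
    blocks$lifecycle <- dummy_cols(f, "lifecycle_")
  }
  if ("lsm" %in% families) {
    blocks$lsm <- matrix(as.numeric(df$lsm == "higher"),
                         dimnames = list(NULL, "lsm_higher"))
  }
  if ("province" %in% families) {
    pv <- ifelse(df$province %in% province_levels(), df$province,
                 province_levels()[1L])
    f <- factor(pv, levels = province_levels())
    blocks$province <- dummy_cols(f, "province_")
  }
  if ("quarter" %in% families && length(quarter_levels) > 1L) {
    f <- factor(df$quarter, levels = quarter_levels)
    blocks$quarter <- dummy_cols(f, "quarter_")
  }
  if (!length(blocks)) return(matrix(numeric(0), n, 0L))
  out <- do.call(cbind, blocks)
  rownames(out) <- NULL
  out
}

# ---- default brand map -----------------------------------------------------

# Plausible ZAR-per-unit base prices and pack sizes by group; magnitudes only
# matter relative to each other. For J != 13 a generic two-brand map is built.
default_brand_map <- function(J, labels) {
  if (J == 13L) {
    spec <- list(
      list(1L, "bottled_water", 0, FALSE, "ml", c(500, 1500), 0.006),
      list(2L, "juice_100", 10, FALSE, "ml", c(1000, 330), 0.016),
      list(3L, "soft_drink", 2, FALSE, "ml", c(500, 2000), 0.012),
      list(4L, "soft_drink", 9, TRUE, "ml", c(500, 2000, 330), 0.013),
      list(5L, "coffee_tea", NA, FALSE, "g", c(250, 100), 0.12),
      list(6L, "milk", NA, FALSE, "ml", c(1000, 2000), 0.014),
      list(7L, "dairy_drink", 8, TRUE, "ml", c(500, 1000), 0.022),
      list(8L, "alcohol", NA, FALSE, "ml", c(750, 340), 0.045),
      list(9L, "chocolate_candy", NA, FALSE, "g", c(80, 150), 0.09),
      list(10L, "dessert", NA, FALSE, "g", c(500, 150), 0.05),
      list(11L, "snack", NA, FALSE, "g", c(125, 200), 0.07),
      list(12L, "fvns", NA, FALSE, "g", c(500, 1000), 0.03),
      list(13L, "other_food", NA, FALSE, "g", c(1000, 500, 2000), 0.02)
    )
    rows <- lapply(spec, function(s) {
      nb <- length(s[[6]])
      data.table::data.table(
        group = s[[1]],
        brand = sprintf("g%02d_b%d", s[[1]], seq_len(nb)),
        item_type = s[[2]],
        sugar_per_100ml = s[[3]],
        taxable = s[[4]],
        unit = s[[5]],
        package_size = s[[6]],
        base_price = s[[7]] * seq(1, by = 0.15, length.out = nb),
        base_quantity = s[[6]] * 2
      )
    })
    data.table::rbindlist(rows)
  } else {
    rows <- lapply(seq_len(J), function(g) {
      data.table::data.table(
        group = g,
        brand = sprintf("g%02d_b%d", g, 1:2),
        item_type = if (g == J) "other_food" else NA_character_,
        sugar_per_100ml = NA_real_,
        taxable = FALSE,
        unit = "g",
        package_size = c(500, 1000),
        base_price = 0.02 * c(1, 1.2),
        base_quantity = c(1000, 800)
      )
    })
    data.table::rbindlist(rows)
  }
}
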