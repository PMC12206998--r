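#' Estimation settings for the EASI share system
#'
#' @param engel_order polynomial order R of the Engel curves (default 3,
#'   sensible range 1-5).
#' @param include_price_utility_interactions include `ln p x y` terms (the
#'   `B` matrix); off by default.
#' @param include_shifter_utility_interactions include `z x y` terms; off by
#'   default.
#' @param impose_symmetry post-hoc minimum-distance symmetrisation of the
#'   price matrix `A` with covariance adjustment; off by default (symmetry
#'   cannot be imposed directly under equation-by-equation estimation).
#' @param include_prices set to `FALSE` to drop all price terms (imposes
#'   A = B = 0; the implicit utility then never changes and the fit needs a
#'   single pass).
#' @param max_iter,tol iteration controls for the implicit-utility update
#'   (tolerance on the maximum absolute change in y).
#' @param shifters demographic shifter families to include in the design.
#' @param y_center centring constant for the Engel polynomial (0 for raw
#'   implicit utility; set to the generator's reference log expenditure to
#'   compare coefficients with ground truth directly).
#' @param cluster column used for cluster-robust covariances.
#' @param use_weights use the panel's survey weights in estimation
#'   (default unweighted).
#' @return A list of class `easi_config`.
#' @export
easi_config <- function(engel_order = 3,
                        include_price_utility_interactions = FALSE,
                        include_shifter_utility_interactions = FALSE,
                        impose_symmetry = FALSE,
                        include_prices = TRUE,
                        max_iter = 100L,
                        tol = 1e-8,
                        shifters = c("hh_size", "lifecycle", "lsm",
                                     "province", "quarter"),
                        y_center = 0,
                        cluster = "household_id",
                        use_weights = FALSE) {
  stopifnot(engel_order >= 1L, tol > 0, max_iter >= 1L)
  structure(
    list(engel_order = as.integer(engel_order),
         include_price_utility_interactions = include_price_utility_interactions,
         include_shifter_utility_interactions = include_shifter_utility_interactions,
         impose_symmetry = impose_symmetry,
         include_prices = include_prices,
         max_iter = as.integer(max_iter), tol = tol,
         shifters = shifters, y_center = y_center,
         cluster = cluster, use_weights = use_weights),
    class = "easi_config"
  )
}

#' Implicit utility of the EASI system
#'
#' `y = (ln x - sum_j w_j ln p_j + 0.5 ln_p' A ln_p) / (1 - 0.5 ln_p' B ln_p)`,
#' with the Stone deflator running over the J-1 non-numeraire groups (the
#' numeraire's log price is identically 0). With `A = B = 0` this is the
#' Stone-index-deflated log expenditure.
#'
#' @param ln_p length J-1 log price vector.
#' @param ln_x scalar log expenditure.
#' @param w share vector of length J or J-1 (only the first J-1 entries enter
#'   the Stone index).
#' @param A,B (J-1)x(J-1) coefficient matrices.
#' @return Scalar implicit utility.
#' @export
implicit_utility <- function(ln_p, ln_x, w, A = NULL, B = NULL) {
  k <- length(ln_p)
  if (is.null(A)) A <- matrix(0, k, k)
  if (is.null(B)) B <- matrix(0, k, k)
  stopifnot(all(dim(A) == k), all(dim(B) == k),
            length(w) %in% c(k, k + 1L), all(is.finite(ln_p)),
            is.finite(ln_x))
  drop(implicit_utility_mat(matrix(ln_p, 1L), ln_x, matrix(w[seq_len(k)], 1L),
                            A, B))
}

implicit_utility_mat <- function(P, ln_x, W, A, B) {
  den <- 1 - 0.5 * quad_form(P, B)
  if (any(abs(den) < 1e-8)) {
    stopf("implicit-utility denominator within 1e-8 of zero")
  }
  (ln_x - rowSums(W * P) + 0.5 * quad_form(P, A)) / den
}

# Design-matrix column layout for one equation.
design_blocks <- function(R, shifter_nm, Jm1, price_y, shifter_y) {
  cols <- c("(Intercept)", if (R >= 1L) paste0("y", c("", if (R > 1L) 2:R)),
            shifter_nm, paste0("ln_p", seq_len(Jm1)))
  blocks <- list(
    intercept = 1L,
    engel = 1L + seq_len(R),
    shifters = if (length(shifter_nm)) 1L + R + seq_along(shifter_nm) else integer(0),
    price = 1L + R + length(shifter_nm) + seq_len(Jm1)
  )
  k <- length(cols)
  if (price_y) {
    cols <- c(cols, paste0("y_x_ln_p", seq_len(Jm1)))
    blocks$price_y <- k + seq_len(Jm1)
    k <- k + Jm1
  } else blocks$price_y <- integer(0)
  if (shifter_y && length(shifter_nm)) {
    cols <- c(cols, paste0("y_x_", shifter_nm))
    blocks$shifter_y <- k + seq_along(shifter_nm)
  } else blocks$shifter_y <- integer(0)
  list(cols = cols, blocks = blocks)
}

build_design_mat <- function(y, Z, P, config, include_prices = TRUE) {
  n <- length(y)
  R <- config$engel_order
  U <- y - config$y_center
  Ypow <- vapply(seq_len(R), function(r) U^r, numeric(n))
  Ypow <- matrix(Ypow, nrow = n)
  X <- cbind(1, Ypow, Z)
  if (include_prices) {
    X <- cbind(X, P)
    if (config$include_price_utility_interactions) X <- cbind(X, y * P)
  }
  if (config$include_shifter_utility_interactions && ncol(Z)) {
    X <- cbind(X, U * Z)
  }
  layout <- design_blocks(R, colnames(Z), ncol(P),
                          include_prices && config$include_price_utility_interactions,
                          config$include_shifter_utility_interactions)
  if (!include_prices) {
    keep <- setdiff(seq_along(layout$cols),
                    c(layout$blocks$price, layout$blocks$price_y))
    layout$cols <- layout$cols[keep]
    layout$blocks$price <- integer(0)
    layout$blocks$price_y <- integer(0)
    # recompute shifted indices for shifter_y block
    layout$blocks$shifter_y <- if (length(layout$blocks$shifter_y))
      seq(ncol(X) - length(layout$blocks$shifter_y) + 1L, ncol(X)) else integer(0)
  }
  colnames(X) <- layout$cols
  attr(X, "blocks") <- layout$blocks
  X
}

#' Build the per-equation regressor matrix
#'
#' Columns, in order: intercept; the Engel polynomial `y, y^2, ..., y^R`;
#' demographic shifters (household size centred at 3, life-cycle, LSM,
#' province and quarter dummies, one reference level dropped per family); the
#' J-1 log price indices; optional `y x ln_p` and `y x z` interaction blocks.
#'
#' @param panel a share panel (see [compute_budget_shares()]).
#' @param prices a Fisher index table aligned on household-quarter keys.
#' @param y per-row implicit utility.
#' @param config an [easi_config()].
#' @return The design matrix with a `blocks` attribute mapping column indices
#'   to blocks. Errors if the design is rank deficient (after removal of
#'   all-zero dummy columns), listing the offending columns.
#' @export
build_design <- function(panel, prices, y, config = easi_config()) {
  al <- align_panel_prices(panel, prices)
  Z <- encode_shifters(al$panel, config$shifters,
                       quarter_levels = sort(unique(al$panel$quarter)))
  X <- prune_design(build_design_mat(y, Z, al$P, config, config$include_prices))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stopf("design is rank deficient; offending columns: %s",
          paste(bad, collapse = ", "))
  }
  X
}

relocate_blocks <- function(blocks, keep) {
  newpos <- cumsum(keep)
  lapply(blocks, function(ix) newpos[ix[keep[ix]]])
}

# Drop structurally empty or constant columns (a dummy family can collapse in
# a stratum subsample: an absent level gives a zero column, a saturated level
# a constant one, collinear with the intercept).
prune_design <- function(X) {
  rng <- apply(X, 2L, function(col) max(col) - min(col))
  drop <- rng == 0 & colnames(X) != "(Intercept)"
  if (any(drop)) {
    blocks <- attr(X, "blocks")
    X2 <- X[, !drop, drop = FALSE]
    attr(X2, "blocks") <- relocate_blocks(blocks, !drop)
    X <- X2
  }
  X
}

align_panel_prices <- function(panel, prices) {
  dt <- data.table::as.data.table(panel)
  pr <- data.table::as.data.table(prices)
  pcols <- grep("^ln_p[0-9]+$", names(pr), value = TRUE)
  pcols <- pcols[order(as.integer(sub("ln_p", "", pcols)))]
  merged <- merge(dt, pr[, c("household_id", "quarter", pcols), with = FALSE],
                  by = c("household_id", "quarter"), sort = TRUE)
  if (nrow(merged) < nrow(dt)) {
    stopf("%d household-quarters in the panel have no price index",
          nrow(dt) - nrow(merged))
  }
  P <- as.matrix(merged[, pcols, with = FALSE])
  wcols <- grep("^w[0-9]+$", names(merged), value = TRUE)
  wcols <- wcols[order(as.integer(sub("w", "", wcols)))]
  list(panel = merged, P = P, wcols = wcols)
}

#' Fit the EASI share system equation by equation
#'
#' Iterated estimation of the J-1 non-numeraire share equations. The implicit
#' utility is initialised with the Stone-index approximation (A = B = 0); each
#' iteration fits every equation by least squares (the Gaussian maximum
#' likelihood point estimate) on the current design, recomputes the implicit
#' utility from the updated price matrices using the *observed* shares (which
#' keeps the estimator linear given y), and repeats until the maximum change
#' in y falls below `tol`. The covariance of the stacked coefficient vector is
#' assembled block-diagonally from per-equation cluster-robust (by household)
#' covariances — cross-equation covariances are set to zero, an explicit
#' approximation that comes with separate estimation and is recorded in the
#' fit log.
#'
#' @param panel share panel with `w1..wJ`, `ln_expenditure`, demographics and
#'   `household_id`/`quarter` keys.
#' @param prices Fisher index table with `ln_p1..ln_p{J-1}`.
#' @param config an [easi_config()].
#' @return An object of class `easi_fit`.
#' @export
fit_easi <- function(panel, prices, config = easi_config()) {
  al <- align_panel_prices(panel, prices)
  dt <- al$panel
  P <- al$P
  W <- as.matrix(dt[, al$wcols, with = FALSE])
  J <- ncol(W)
  Jm1 <- J - 1L
  if (ncol(P) != Jm1) {
    stopf("price table has %d groups but panel has %d", ncol(P) + 1L, J)
  }
  n <- nrow(dt)
  Wn <- W[, -J, drop = FALSE]
  ln_x <- dt$ln_expenditure
  Z <- encode_shifters(dt, config$shifters,
                       quarter_levels = sort(unique(dt$quarter)))
  wts <- if (config$use_weights) dt$weight else NULL
  min_rows <- 5L
  A <- matrix(0, Jm1, Jm1)
  B <- matrix(0, Jm1, Jm1)
  y <- implicit_utility_mat(P, ln_x, Wn, A, B)   # Stone initialisation

  fit_pass <- function(y) {
    X <- prune_design(build_design_mat(y, Z, P, config, config$include_prices))
    f <- if (is.null(wts)) stats::lm.fit(X, Wn) else stats::lm.wfit(X, Wn, wts)
    if (any(is.na(f$coefficients))) {
      bad <- unique(rownames(f$coefficients)[
        apply(is.na(as.matrix(f$coefficients)), 1L, any)])
      stopf("design is rank deficient; offending columns: %s",
            paste(bad, collapse = ", "))
    }
    list(X = X, coef = as.matrix(f$coefficients), blocks = attr(X, "blocks"))
  }
  extract_AB <- function(pass) {
    bl <- pass$blocks
    A <- if (length(bl$price)) t(pass$coef[bl$price, , drop = FALSE]) else
      matrix(0, Jm1, Jm1)
    B <- if (length(bl$price_y)) t(pass$coef[bl$price_y, , drop = FALSE]) else
      matrix(0, Jm1, Jm1)
    list(A = A, B = B)
  }

  if (n < min_rows * (2L + config$engel_order + ncol(Z) + Jm1)) {
    stopf("too few rows (%d) for the requested design", n)
  }

  trace <- numeric(0)
  pass <- fit_pass(y)
  for (it in seq_len(config$max_iter)) {
    ab <- extract_AB(pass)
    y_new <- implicit_utility_mat(P, ln_x, Wn, ab$A, ab$B)
    delta <- max(abs(y_new - y))
    trace <- c(trace, delta)
    y <- y_new
    if (delta < config$tol) break
    pass <- fit_pass(y)
  }
  if (trace[length(trace)] >= config$tol) {
    stopf("implicit-utility iteration did not converge in %d passes (|dy| trace: %s)",
          config$max_iter,
          paste(sprintf("%.2e", utils::tail(trace, 5)), collapse = " "))
  }
  if (length(trace) >= 5L && any(diff(utils::tail(trace, 5)) > 0)) {
    warning("implicit-utility updates were not monotone over the last 5 iterations")
  }
  pass <- fit_pass(y)        # final coefficients at the converged utility
  ab <- extract_AB(pass)

  fit <- structure(
    list(J = J, R = config$engel_order,
         labels = if (J == 13L) group_schema()$groups else
           c(paste0("group_", seq_len(Jm1)), "numeraire"),
         coef = NULL, coef_matrix = pass$coef, blocks = pass$blocks,
         colnames = colnames(pass$X),
         vcov = NULL, y = y, config = config,
         data = list(W = W, P = P, Z = Z, ln_x = ln_x,
                     weight = dt$weight %||% rep(1, n),
                     cluster = dt[[config$cluster]],
                     keys = dt[, .(household_id, quarter)],
                     lsm = dt$lsm %||% rep(NA_character_, n)),
         convergence = list(trace = trace, iterations = length(trace)),
         log = character(0), n = n),
    class = "easi_fit"
  )
  fit <- set_coef_from_matrix(fit, ab)
  fit$vcov <- cluster_vcov(fit)
  fit$log <- c(fit$log,
               "system vcov assembled block-diagonally from per-equation cluster-robust covariances; cross-equation covariance set to zero (separate estimation)")

  if (config$impose_symmetry) fit <- symmetrize_A(fit)
  fit$fitted <- fitted_shares(fit)
  fit
}

set_coef_from_matrix <- function(fit, ab = NULL) {
  bl <- fit$blocks
  cf <- fit$coef_matrix
  Jm1 <- fit$J - 1L
  if (is.null(ab)) {
    A <- if (length(bl$price)) t(cf[bl$price, , drop = FALSE]) else
      matrix(0, Jm1, Jm1)
    B <- if (length(bl$price_y)) t(cf[bl$price_y, , drop = FALSE]) else
      matrix(0, Jm1, Jm1)
    ab <- list(A = A, B = B)
  }
  fit$coef <- list(
    b0 = cf[bl$intercept, ],
    b = t(cf[bl$engel, , drop = FALSE]),
    gamma = if (length(bl$shifters)) t(cf[bl$shifters, , drop = FALSE]) else
      matrix(0, Jm1, 0L),
    A = ab$A, B = ab$B,
    lambda = if (length(bl$shifter_y)) t(cf[bl$shifter_y, , drop = FALSE]) else
      NULL
  )
  dimnames(fit$coef$A) <- NULL
  fit
}

fitted_shares <- function(fit) {
  X <- build_design_mat(fit$y, fit$data$Z, fit$data$P, fit$config,
                        fit$config$include_prices)
  X <- X[, colnames(X) %in% fit$colnames, drop = FALSE]
  Wf <- X %*% fit$coef_matrix
  cbind(Wf, 1 - rowSums(Wf))
}

# Block-diagonal stacked covariance from per-equation cluster-robust
# covariances (sandwich::vcovCL on each equation's lm fit).
cluster_vcov <- function(fit) {
  X <- build_design_mat(fit$y, fit$data$Z, fit$data$P, fit$config,
                        fit$config$include_prices)
  X <- X[, colnames(X) %in% fit$colnames, drop = FALSE]
  Jm1 <- fit$J - 1L
  p <- ncol(X)
  V <- matrix(0, Jm1 * p, Jm1 * p)
  nm <- character(Jm1 * p)
  Wn <- fit$data$W[, -fit$J, drop = FALSE]
  cl <- fit$data$cluster
  wts <- if (fit$config$use_weights) fit$data$weight else NULL
  for (j in seq_len(Jm1)) {
    df <- data.frame(.w = Wn[, j])
    f <- if (is.null(wts)) stats::lm(.w ~ 0 + X, data = df) else
      stats::lm(.w ~ 0 + X, data = df, weights = wts)
    Vj <- sandwich::vcovCL(f, cluster = cl)
    ix <- (j - 1L) * p + seq_len(p)
    V[ix, ix] <- Vj
    nm[ix] <- paste0("eq", j, ":", colnames(X))
  }
  dimnames(V) <- list(nm, nm)
  V
}

# Post-hoc minimum-distance symmetrisation of A with covariance adjustment,
# followed by a refit of the remaining coefficients with the price term held
# fixed (offset) and a final utility update.
symmetrize_A <- function(fit) {
  if (fit$config$include_price_utility_interactions) {
    stopf("impose_symmetry is not supported together with price-utility interactions")
  }
  Jm1 <- fit$J - 1L
  bl <- fit$blocks
  p <- length(fit$colnames)
  a_idx <- as.vector(vapply(seq_len(Jm1),
                            function(j) (j - 1L) * p + bl$price,
                            integer(length(bl$price))))
  a_hat <- as.vector(t(fit$coef$A))      # eq-major: (a_j1..a_jJm1) per eq j
  Va <- fit$vcov[a_idx, a_idx]
  # duplication: map lower-triangle params to the full vector
  pairs <- which(lower.tri(matrix(0, Jm1, Jm1), diag = TRUE), arr.ind = TRUE)
  D <- matrix(0, Jm1 * Jm1, nrow(pairs))
  for (s in seq_len(nrow(pairs))) {
    i <- pairs[s, 1L]; k <- pairs[s, 2L]
    D[(i - 1L) * Jm1 + k, s] <- 1
    D[(k - 1L) * Jm1 + i, s] <- 1
  }
  Vinv <- solve(Va + diag(1e-12, nrow(Va)))
  M <- solve(t(D) %*% Vinv %*% D)
  s_hat <- M %*% t(D) %*% Vinv %*% a_hat
  a_sym <- as.vector(D %*% s_hat)
  A_sym <- t(matrix(a_sym, Jm1, Jm1))
  # refit non-price coefficients with the symmetrised price term as offset
  cfg <- fit$config
  P <- fit$data$P; Z <- fit$data$Z
  Wn <- fit$data$W[, -fit$J, drop = FALSE]
  f <- NULL
  for (pass in 1:25) {
    y <- implicit_utility_mat(P, fit$data$ln_x, Wn, A_sym, fit$coef$B)
    off <- P %*% t(A_sym)
    X <- build_design_mat(y, Z, P, cfg, include_prices = FALSE)
    X <- X[, colnames(X) %in% fit$colnames, drop = FALSE]
    f <- stats::lm.fit(X, Wn - off)
    dy <- max(abs(y - fit$y))
    fit$y <- y
    if (dy < cfg$tol) break
  }
  cf <- fit$coef_matrix
  free_idx <- setdiff(seq_len(nrow(cf)), bl$price)   # same order as X's columns
  stopifnot(length(free_idx) == nrow(f$coefficients))
  cf[free_idx, ] <- as.matrix(f$coefficients)
  cf[bl$price, ] <- t(A_sym)
  fit$coef_matrix <- cf
  fit <- set_coef_from_matrix(fit)
  # covariance of the symmetrised A block
  fit$vcov[a_idx, a_idx] <- D %*% M %*% t(D)
  fit$log <- c(fit$log, "price matrix A symmetrised by minimum distance; A-block covariance replaced accordingly")
  fit
}

#' @export
print.easi_fit <- function(x, ...) {
  cat(sprintf("EASI fit: %d groups, %d rows, Engel order %d\n",
              x$J, x$n, x$R))
  cat(sprintf("  converged in %d utility passes (last |dy| = %.2e)\n",
              x$convergence$iterations,
              x$convergence$trace[length(x$convergence$trace)]))
  cat(sprintf("  design: %s\n", paste(x$colnames, collapse = ", ")))
  own <- diag(x$coef$A)
  cat(sprintf("  diag(A): %s\n", paste(sprintf("%.4f", own), collapse = " ")))
  invisible(x)
}

#' Recover the numeraire equation by adding-up
#'
#' The numeraire share equation is not estimated; adding-up implies its
#' coefficients are the negatives of the column sums of the estimated J-1
#' equations, block by block (the intercept is one minus the sum of
#' intercepts). The price matrices are extended by a numeraire row *and*
#' column (homogeneity: prices enter relative to the numeraire).
#'
#' @param fit an `easi_fit`.
#' @return A list of full J-system coefficient blocks (`b0`, `b`, `gamma`,
#'   `A`, `B`), marked `derived_not_estimated`.
#' @export
recover_numeraire <- function(fit) {
  cf <- if (inherits(fit, "easi_fit")) fit$coef else
    params_of(fit)[c("b0", "b", "gamma", "A", "B")]
  out <- list(
    b0 = c(cf$b0, 1 - sum(cf$b0)),
    b = rbind(cf$b, -colSums(cf$b)),
    gamma = rbind(cf$gamma, if (ncol(cf$gamma)) -colSums(cf$gamma) else
      numeric(0)),
    A = extend_adding_up(cf$A),
    B = extend_adding_up(cf$B)
  )
  attr(out, "derived_not_estimated") <- TRUE
  out
}
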