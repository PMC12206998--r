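# Marshallian/Hicksian/expenditure elasticities, delta-method standard errors
# and the finite-difference oracle.

new_elasticity_table <- function(M, H, E, labels,
                                 se_M = NULL, se_H = NULL, se_E = NULL,
                                 eval_info = list()) {
  dimnames(M) <- dimnames(H) <- list(labels, labels)
  names(E) <- labels
  if (!is.null(se_M)) dimnames(se_M) <- dimnames(M)
  if (!is.null(se_H)) dimnames(se_H) <- dimnames(H)
  if (!is.null(se_E)) names(se_E) <- labels
  structure(
    list(marshallian = M, hicksian = H, expenditure = E,
         se_marshallian = se_M, se_hicksian = se_H, se_expenditure = se_E,
         eval_info = eval_info),
    class = "elasticity_table"
  )
}

#' @export
print.elasticity_table <- function(x, ...) {
  J <- length(x$expenditure)
  cat(sprintf("Elasticity table (%d groups; %s)\n", J,
              x$eval_info$mode %||% "point"))
  own <- diag(x$marshallian)
  for (i in seq_len(J)) {
    se <- if (!is.null(x$se_marshallian)) {
      sprintf(" (%.2f)", x$se_marshallian[i, i])
    } else ""
    cat(sprintf("  %-42s own-price %6.2f%s  expenditure %5.2f\n",
                names(x$expenditure)[i], own[i], se, x$expenditure[i]))
  }
  invisible(x)
}

# normalise anything parameter-like to the canonical list
params_of <- function(x, lsm = "higher") {
  if (inherits(x, c("easi_dgp", "easi_fit"))) return(as_easi_params(x, lsm))
  stopifnot(is.list(x), all(c("b0", "b", "A", "B") %in% names(x)))
  x$J <- x$J %||% (length(x$b0) + 1L)
  x$R <- x$R %||% ncol(x$b)
  x$gamma <- x$gamma %||% matrix(0, x$J - 1L, 0L)
  x$y_center <- x$y_center %||% 0
  x$labels <- x$labels %||% c(paste0("group_", seq_len(x$J - 1L)), "numeraire")
  x
}

# dw/dy for n rows, full J columns (numeraire by adding-up).
mu_matrix <- function(par, y, P, Z = NULL) {
  n <- length(y)
  U <- y - par$y_center
  mu <- matrix(0, n, par$J - 1L)
  for (r in seq_len(par$R)) {
    mu <- mu + (r * U^(r - 1L)) %o% par$b[, r]
  }
  if (any(par$B != 0)) mu <- mu + P %*% t(par$B)
  if (!is.null(par$lambda) && !is.null(Z) && ncol(Z)) {
    mu <- mu + Z %*% t(par$lambda)
  }
  cbind(mu, -rowSums(mu))
}

# d y / d ln x for n rows: exact derivative of the implicit-utility identity,
# including the Stone-deflator feedback through the shares.
dy_dlnx_vec <- function(par, P, mu) {
  den <- 1 - 0.5 * quad_form(P, par$B) +
    rowSums(mu[, seq_len(par$J - 1L), drop = FALSE] * P)
  if (any(abs(den) < 1e-8)) {
    stopf("utility-derivative denominator within 1e-8 of zero")
  }
  1 / den
}

#' Semi-elasticities of shares at an evaluation point
#'
#' Returns the building blocks of the elasticity formulas at one point: the
#' compensated (utility-held-fixed) price semi-elasticity matrix
#' `Gamma = A + y B`, the utility gradient of shares `mu`, and the derivative
#' `dy_dlnx` of implicit utility with respect to log expenditure. All three
#' are extended to the numeraire row/column by adding-up (for the price
#' dimension, by homogeneity: prices enter relative to the numeraire).
#' `dy_dlnx` is the exact derivative of the implicit-utility identity; it
#' includes the Stone-deflator feedback term and reduces to
#' `1/(1 - 0.5 ln_p' B ln_p)` when all log prices are zero.
#'
#' @param params an `easi_dgp`, `easi_fit` or parameter list.
#' @param ln_p length J-1 log price vector.
#' @param y scalar implicit utility at the point.
#' @param z optional shifter vector (enters only through shifter-utility
#'   interactions, when the specification has them).
#' @param w unused placeholder for API symmetry (shares enter the elasticity
#'   formulas in [point_elasticities()], not the derivatives).
#' @return List with `Gamma` (J x J), `mu` (length J), `dy_dlnx` (scalar).
#' @export
share_derivatives <- function(params, ln_p, y, z = NULL, w = NULL) {
  par <- params_of(params)
  stopifnot(length(ln_p) == par$J - 1L)
  P <- matrix(ln_p, 1L)
  Z <- if (is.null(z)) NULL else matrix(z, 1L)
  mu <- mu_matrix(par, y, P, Z)
  Gamma <- par$A + y * par$B
  list(
    Gamma = extend_adding_up(Gamma),
    mu = drop(mu),
    dy_dlnx = dy_dlnx_vec(par, P, mu)
  )
}

#' Point elasticities from semi-elasticities and shares
#'
#' Expenditure: `e_i = 1 + mu_i * dy_dlnx / w_i`. Hicksian (compensated):
#' `eH_ij = Gamma_ij / w_i + w_j - delta_ij`. Marshallian via the Slutsky
#' identity: `eM_ij = eH_ij - e_i w_j`. Groups with non-positive shares at
#' the evaluation point get `NA` rows (a zero share admits no finite quantity
#' elasticity); their count is recorded in `eval_info`.
#'
#' @param Gamma,mu,dy_dlnx outputs of [share_derivatives()] (full J system).
#' @param w length-J share vector at the evaluation point.
#' @param labels optional group labels.
#' @return An `elasticity_table` (no standard errors).
#' @export
point_elasticities <- function(Gamma, mu, dy_dlnx, w, labels = NULL) {
  J <- length(w)
  stopifnot(all(dim(Gamma) == J), length(mu) == J)
  if (is.null(labels)) labels <- rownames(Gamma) %||% paste0("g", seq_len(J))
  ok <- w > 0
  wi <- ifelse(ok, w, NA_real_)
  E <- 1 + mu * dy_dlnx / wi
  H <- Gamma / wi + matrix(w, J, J, byrow = TRUE) - diag(J)
  M <- H - E %o% w
  new_elasticity_table(M, H, E, labels,
                       eval_info = list(mode = "point", shares = w,
                                        excluded = sum(!ok)))
}

# Vectorised per-observation elasticities, averaged with weights; the i-th
# row of each matrix is averaged over rows where that group's evaluation
# share is positive.
elasticity_avg_rows <- function(par, P, y, W_eval, Z = NULL, weights = NULL,
                                W_mask = W_eval) {
  n <- length(y)
  J <- par$J
  mu <- mu_matrix(par, y, P, Z)
  D <- dy_dlnx_vec(par, P, mu)
  A_full <- extend_adding_up(par$A)
  B_full <- extend_adding_up(par$B)
  wts <- weights %||% rep(1, n)
  M <- H <- matrix(NA_real_, J, J)
  E <- numeric(J)
  counts <- integer(J)
  for (i in seq_len(J)) {
    wi <- W_eval[, i]
    mask <- is.finite(wi) & wi > 0 & W_mask[, i] > 0
    counts[i] <- sum(!mask)
    wm <- wts[mask] / sum(wts[mask])
    Gi <- matrix(A_full[i, ], sum(mask), J, byrow = TRUE)
    if (any(B_full != 0)) Gi <- Gi + y[mask] %o% B_full[i, ]
    eH <- Gi / wi[mask] + W_eval[mask, , drop = FALSE]
    eH[, i] <- eH[, i] - 1
    ei <- 1 + mu[mask, i] * D[mask] / wi[mask]
    eM <- eH - ei * W_eval[mask, , drop = FALSE]
    H[i, ] <- colSums(wm * eH)
    M[i, ] <- colSums(wm * eM)
    E[i] <- sum(wm * ei)
  }
  list(M = M, H = H, E = E, counts = counts)
}

#' Average elasticities over a fitted sample
#'
#' In the default `per_observation` mode, point elasticities are computed at
#' every household-quarter whose *observed* share of the group concerned is
#' positive (a zero share admits no finite quantity elasticity), and
#' averaged; in `at_means` mode a single evaluation is made at the
#' weighted-mean shares, prices and utility. The evaluation shares entering
#' the formulas are the fitted shares by default — they are stable where an
#' observed share is small — with observed shares available via
#' `share_source`; rows whose evaluation share is non-positive are also
#' excluded.
#'
#' @param fit an `easi_fit` from [fit_easi()].
#' @param mode `"per_observation"` (default) or `"at_means"`.
#' @param weights optional per-row weights (defaults to equal weights; pass
#'   `fit$data$weight` for survey-weighted averages).
#' @param share_source `"fitted"` (default) or `"observed"`.
#' @param se if `TRUE`, attach delta-method standard errors via [delta_se()].
#' @param stratum optional label recorded in `eval_info`.
#' @return An `elasticity_table`.
#' @export
average_elasticities <- function(fit,
                                 mode = c("per_observation", "at_means"),
                                 weights = NULL,
                                 share_source = c("fitted", "observed"),
                                 se = FALSE, stratum = NA_character_) {
  mode <- match.arg(mode)
  share_source <- match.arg(share_source)
  stopifnot(inherits(fit, "easi_fit"))
  if (fit$n == 0L) stopf("empty sample%s",
                         if (is.na(stratum)) "" else paste0(" in stratum ", stratum))
  theta <- as.vector(fit$coef_matrix)
  res <- avg_from_theta(theta, fit, mode, weights, share_source)
  tab <- new_elasticity_table(res$M, res$H, res$E, fit$labels,
                              eval_info = list(mode = mode,
                                               share_source = share_source,
                                               excluded = res$counts,
                                               stratum = stratum,
                                               n = fit$n))
  if (se) {
    ses <- delta_se(fit, mode = mode, weights = weights,
                    share_source = share_source)
    tab$se_marshallian <- ses$se_marshallian
    tab$se_hicksian <- ses$se_hicksian
    tab$se_expenditure <- ses$se_expenditure
    dimnames(tab$se_marshallian) <- dimnames(tab$marshallian)
    dimnames(tab$se_hicksian) <- dimnames(tab$hicksian)
    names(tab$se_expenditure) <- names(tab$expenditure)
  }
  tab
}

# Recompute the averaged elasticities from a stacked coefficient vector,
# re-deriving the implicit utility, the design and the fitted shares from
# scratch (this is the functional differentiated by the delta method).
avg_from_theta <- function(theta, fit, mode, weights, share_source) {
  p <- length(fit$colnames)
  Jm1 <- fit$J - 1L
  cfm <- matrix(theta, p, Jm1)
  bl <- fit$blocks
  A <- if (length(bl$price)) t(cfm[bl$price, , drop = FALSE]) else
    matrix(0, Jm1, Jm1)
  B <- if (length(bl$price_y)) t(cfm[bl$price_y, , drop = FALSE]) else
    matrix(0, Jm1, Jm1)
  par <- list(J = fit$J, R = fit$config$engel_order,
              b0 = cfm[bl$intercept, ],
              b = t(cfm[bl$engel, , drop = FALSE]),
              gamma = if (length(bl$shifters)) t(cfm[bl$shifters, , drop = FALSE])
              else matrix(0, Jm1, 0L),
              A = A, B = B,
              lambda = if (length(bl$shifter_y)) t(cfm[bl$shifter_y, , drop = FALSE])
              else NULL,
              y_center = fit$config$y_center, labels = fit$labels)
  P <- fit$data$P
  Wobs <- fit$data$W
  y <- implicit_utility_mat(P, fit$data$ln_x, Wobs[, -fit$J, drop = FALSE],
                            A, B)
  W_eval <- if (share_source == "observed") {
    Wobs
  } else {
    X <- build_design_mat(y, fit$data$Z, P, fit$config,
                          fit$config$include_prices)
    zero <- !(colnames(X) %in% fit$colnames)
    if (any(zero)) X <- X[, !zero, drop = FALSE]
    Wf <- X %*% cfm
    cbind(Wf, 1 - rowSums(Wf))
  }
  if (mode == "at_means") {
    wts <- weights %||% rep(1, length(y))
    wts <- wts / sum(wts)
    pbar <- colSums(wts * P)
    ybar <- sum(wts * y)
    zbar <- colSums(wts * fit$data$Z)
    wbar <- colSums(wts * W_eval)
    d <- share_derivatives(par, pbar, ybar, z = zbar)
    pt <- point_elasticities(d$Gamma, d$mu, d$dy_dlnx, wbar, fit$labels)
    list(M = pt$marshallian, H = pt$hicksian, E = pt$expenditure,
         counts = rep(0L, fit$J))
  } else {
    elasticity_avg_rows(par, P, y, W_eval, Z = fit$data$Z, weights = weights,
                        W_mask = Wobs)
  }
}

#' Delta-method standard errors for averaged elasticities
#'
#' SE = sqrt(g' V g), where V is the fit's stacked cluster-robust coefficient
#' covariance and g the gradient of each averaged elasticity with respect to
#' the stacked coefficient vector, computed by central finite differences
#' (relative step `rel_step`). The averaging mode is applied inside the
#' differentiated functional, so the standard errors correspond exactly to
#' the reported averages.
#'
#' @param fit an `easi_fit`.
#' @param mode,weights,share_source as in [average_elasticities()].
#' @param rel_step relative finite-difference step.
#' @return List with `se_marshallian`, `se_hicksian` (J x J) and
#'   `se_expenditure` (length J).
#' @export
delta_se <- function(fit, mode = "per_observation", weights = NULL,
                     share_source = "fitted", rel_step = 1e-6) {
  V <- fit$vcov
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    stopf("coefficient covariance is not positive semi-definite (min eigenvalue %.2e)",
          min(ev))
  }
  theta <- as.vector(fit$coef_matrix)
  J <- fit$J
  flatten <- function(r) c(r$M, r$H, r$E)
  nth <- length(theta)
  base <- flatten(avg_from_theta(theta, fit, mode, weights, share_source))
  G <- matrix(0, nth, length(base))
  for (k in seq_len(nth)) {
    h <- rel_step * max(1, abs(theta[k]))
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    G[k, ] <- (flatten(avg_from_theta(tp, fit, mode, weights, share_source)) -
                 flatten(avg_from_theta(tm, fit, mode, weights, share_source))) /
      (2 * h)
  }
  se2 <- colSums(G * (V %*% G))
  se <- sqrt(pmax(se2, 0))
  list(
    se_marshallian = matrix(se[seq_len(J * J)], J, J),
    se_hicksian = matrix(se[J * J + seq_len(J * J)], J, J),
    se_expenditure = se[2L * J * J + seq_len(J)]
  )
}

#' Finite-difference oracle for point elasticities
#'
#' An independent verification path that never touches the analytic
#' derivative formulas: each log price (and log expenditure) is perturbed by
#' `+/- h`, the implicit share system is re-solved at the perturbed point,
#' shares are converted to log quantities (`ln q_i = ln w_i + ln x - ln p_i`)
#' and elasticities are taken as central differences. The numeraire price
#' column follows from homogeneity, and the Hicksian matrix is recovered via
#' the Slutsky identity.
#'
#' @param params an `easi_dgp`, `easi_fit` or parameter list.
#' @param ln_p,ln_x evaluation point.
#' @param shifters optional shifter vector.
#' @param h finite-difference step on the log scale.
#' @param lsm stratum whose price-response matrix to use (for stratified
#'   generators).
#' @return An `elasticity_table` (no standard errors).
#' @export
fd_oracle_elasticities <- function(params, ln_p, ln_x, shifters = NULL,
                                   h = 1e-5, lsm = "higher") {
  par <- params_of(params, lsm = lsm)
  J <- par$J
  Z <- matrix(if (is.null(shifters)) rep(0, ncol(par$gamma)) else shifters, 1L)
  solve_at <- function(p, lx) {
    sol <- solve_shares_mat(par, matrix(p, 1L), lx, Z, tol = 1e-13,
                            max_iter = 2000L)
    drop(sol$W)
  }
  w0 <- solve_at(ln_p, ln_x)
  if (any(w0 <= 0)) {
    stopf("oracle point has non-positive shares; no finite quantity elasticity")
  }
  lnq <- function(w, p_full, lx) log(w) + lx - p_full
  p_full0 <- c(ln_p, 0)
  M <- matrix(NA_real_, J, J)
  for (j in seq_len(J - 1L)) {
    pp <- ln_p; pp[j] <- pp[j] + h
    pm <- ln_p; pm[j] <- pm[j] - h
    qp <- lnq(solve_at(pp, ln_x), c(pp, 0), ln_x)
    qm <- lnq(solve_at(pm, ln_x), c(pm, 0), ln_x)
    M[, j] <- (qp - qm) / (2 * h)
  }
  qp <- lnq(solve_at(ln_p, ln_x + h), p_full0, ln_x + h)
  qm <- lnq(solve_at(ln_p, ln_x - h), p_full0, ln_x - h)
  E <- (qp - qm) / (2 * h)
  # numeraire price column by homogeneity: sum_j eM_ij + e_i = 0
  M[, J] <- -rowSums(M[, -J, drop = FALSE]) - E
  H <- M + E %o% w0
  new_elasticity_table(M, H, E, par$labels,
                       eval_info = list(mode = "fd_oracle", shares = w0,
                                        h = h))
}

# Ground-truth elasticity tables for a simulated panel, evaluated at the
# stratum mean point of the noiseless shares/utility; "all" is the
# row-count-weighted mean across strata when price responses are stratified.
truth_elasticities <- function(panel) {
  dgp <- panel$truth
  Z <- encode_shifters(panel$shares, dgp$shifters)
  P <- as.matrix(panel$prices[, paste0("ln_p", seq_len(dgp$J - 1L)),
                              with = FALSE])
  one <- function(rows, lsm) {
    par <- as_easi_params(dgp, lsm = lsm)
    pbar <- colMeans(P[rows, , drop = FALSE])
    ybar <- mean(panel$noiseless$y[rows])
    zbar <- if (ncol(Z)) colMeans(Z[rows, , drop = FALSE]) else numeric(0)
    wbar <- colMeans(panel$noiseless$shares[rows, , drop = FALSE])
    d <- share_derivatives(par, pbar, ybar, z = zbar)
    point_elasticities(d$Gamma, d$mu, d$dy_dlnx, wbar, dgp$labels)
  }
  if (dgp$lsm_price_scale != 1) {
    lo <- which(panel$shares$lsm == "lower")
    hi <- which(panel$shares$lsm == "higher")
    tl <- one(lo, "lower")
    th <- one(hi, "higher")
    fl <- length(lo) / (length(lo) + length(hi))
    all_tab <- new_elasticity_table(
      fl * tl$marshallian + (1 - fl) * th$marshallian,
      fl * tl$hicksian + (1 - fl) * th$hicksian,
      fl * tl$expenditure + (1 - fl) * th$expenditure,
      dgp$labels, eval_info = list(mode = "truth_mixture"))
    list(all = all_tab, lower = tl, higher = th)
  } else {
    list(all = one(seq_len(nrow(panel$shares)), "higher"))
  }
}
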