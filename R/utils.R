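# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# x' M x for a single vector, or row-wise x_i' M x_i for a matrix of rows.
quad_form <- function(x, M) {
  if (is.matrix(x)) rowSums((x %*% M) * x) else drop(crossprod(x, M %*% x))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stopf("`%s` must be a finite scalar in [%s, %s]", name, lower, upper)
  }
  invisible(x)
}

# Deterministic 0/1 dummy encoding with the first level dropped.
dummy_cols <- function(f, prefix) {
  f <- as.factor(f)
  lev <- levels(f)
  if (length(lev) < 2L) {
    return(matrix(numeric(0), nrow = length(f), ncol = 0L))
  }
  out <- vapply(lev[-1L], function(l) as.numeric(f == l), numeric(length(f)))
  out <- matrix(out, nrow = length(f),
                dimnames = list(NULL, paste0(prefix, lev[-1L])))
  out
}

# Pad/extend a (J-1)-system quantity to the full J system by adding-up:
# vectors get a last element equal to minus their sum; matrices get a last
# row and column equal to minus the corresponding sums.
extend_adding_up <- function(x) {
  if (is.matrix(x)) {
    x <- rbind(x, -colSums(x))
    cbind(x, -rowSums(x))
  } else {
    c(x, -sum(x))
  }
}
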