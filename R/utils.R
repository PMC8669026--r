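# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all reported percentages, as
#' opposed to the banker's rounding of [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(31.45, 1) # 31.5
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Derive a child seed from a master seed and a stream label
#'
#' Every stage of the pipeline draws its randomness from a named child
#' stream of the single master seed, so stage-level reruns reproduce
#' pipeline-level results. The derivation is a fixed integer hash of the
#' label folded into the seed modulo 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param label character stream name.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
child_seed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  v <- utf8ToInt(label)
  h <- sum(v * seq_along(v)) %% 1000003
  as.integer((abs(as.numeric(seed)) * 1009 + h) %% 2147483647)
}

# Evaluate code under a temporary RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Drop constant columns from a design data.frame, warning with their names.
drop_constant_cols <- function(df, keep = character()) {
  const <- vapply(df, function(x) length(unique(x)) < 2L, logical(1))
  const[names(df) %in% keep] <- FALSE
  if (any(const)) {
    warning("dropping constant covariate column(s): ",
            paste(names(df)[const], collapse = ", "))
    df <- df[, !const, drop = FALSE]
  }
  df
}

# Row-wise OLS of every row of Y (features x N) on a shared design X (N x p).
# Returns estimate/se/t/p for the coefficient named `coef`.
fit_ols_rows <- function(Y, X, coef) {
  stopifnot(ncol(Y) == nrow(X), coef %in% colnames(X))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  B <- Y %*% X %*% xtx_inv                       # features x p
  R <- Y - B %*% t(X)
  df <- nrow(X) - ncol(X)
  sigma2 <- rowSums(R^2) / df
  j <- match(coef, colnames(X))
  est <- B[, j]
  se <- sqrt(sigma2 * xtx_inv[j, j])
  tval <- est / se
  data.frame(estimate = est, se = se, t = tval,
             p = 2 * stats::pt(-abs(tval), df), row.names = rownames(Y))
}

# All permutations of seq_len(n) as an n! x n integer matrix.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
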