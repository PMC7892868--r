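# Physical constants and shared numeric helpers.

# Universal gas constant, J K^-1 mol^-1.
R_GAS <- 8.314

# Base-10 log factor as conventionally printed in van't Hoff / double-log
# treatments (2.303 rather than ln(10) = 2.302585...); used consistently in
# both the simulator and the fits so round trips are exact.
LOG10_FACTOR <- 2.303

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1L)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Ordinary least squares of y on x with R^2 as the squared Pearson correlation.
ols_line <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r2 <- if (stats::sd(y) == 0 || stats::sd(x) == 0) NA_real_ else stats::cor(x, y)^2
  list(intercept = unname(co[1L]), slope = unname(co[2L]), r2 = r2,
       n = length(x))
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  }
  if (finite && !is.finite(x)) {
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

# Format a number for display tables: 3 significant digits, scientific where
# large, trimmed.
fmt_sig3 <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x)) return("NA")
  format(signif(x, 3L), scientific = abs(x) >= 1e4 || (x != 0 && abs(x) < 1e-3))
}

# kJ-scale energy with 3 decimals.
fmt_kj <- function(x_j) {
  if (is.null(x_j) || is.na(x_j)) return("NA")
  sprintf("%.3f", x_j / 1000)
}
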