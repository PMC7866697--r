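# Group-comparison statistics: pooled-variance Student t, Holm-Sidak
# step-down adjustment, simple linear regression with slope F test, and a
# robust outlier flagger.

#' Pooled-variance two-sample Student t test
#'
#' Classical (equal-variance) Student t, two-sided, with
#' `df = nA + nB - 2`; Welch's correction is available by flag.
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @param welch Use Welch's unequal-variance t instead (default FALSE).
#' @return Object of class `"test_result"`: `statistic`, `df`, `p_value`,
#'   `method`, `mean_a`, `mean_b`, `se_a`, `se_b`.
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs n >= 2", call. = FALSE)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (welch) {
    se2 <- va / na + vb / nb
    t <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    method <- "Welch t"
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
    method <- "Student t (pooled)"
  }
  if (!is.finite(t)) { t <- 0; }
  structure(list(statistic = t, df = df,
                 p_value = 2 * stats::pt(-abs(t), df),
                 method = method,
                 mean_a = ma, mean_b = mb,
                 se_a = sqrt(va / na), se_b = sqrt(vb / nb)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: t(%.4g) = %.4g, p = %.4g (means %.4g vs %.4g)\n",
              x$method, x$df, x$statistic, x$p_value, x$mean_a, x$mean_b))
  invisible(x)
}

#' Holm-Sidak step-down p-value adjustment
#'
#' Sorts ascending, applies the Sidak correction with decreasing
#' multiplicity `adj_i = 1 - (1 - p_i)^(m - i + 1)`, enforces monotone
#' nondecreasing adjusted values and restores the input order.
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same order as the input.
#' @export
holm_sidak_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]", call. = FALSE)
  m <- length(p_values)
  if (m <= 1L) return(p_values)
  o <- order(p_values)
  ps <- p_values[o]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

#' Simple linear regression with slope F test
#'
#' Ordinary least squares of `y` on `x` with the overall F test on the
#' slope, `df = (1, n - 2)`.
#'
#' @param x,y Numeric vectors, `n >= 3`, `x` not constant.
#' @return List: `slope`, `intercept`, `r_squared`, `f`, `df1`, `df2`,
#'   `p_value`.
#' @export
simple_regression <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (stats::var(x) == 0) stop("`x` is constant; regression degenerate", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  ssr <- sum((fitted - mean(y))^2)
  sse <- sum((y - fitted)^2)
  sst <- ssr + sse
  f <- if (sse <= 0) Inf else (ssr / 1) / (sse / (n - 2))
  list(slope = slope, intercept = intercept,
       r_squared = if (sst > 0) ssr / sst else NA_real_,
       f = f, df1 = 1, df2 = n - 2,
       p_value = stats::pf(f, 1, n - 2, lower.tail = FALSE))
}

#' Flag outliers by robust residuals
#'
#' Documented approximation to a robust-regression outlier screen for
#' univariate samples: residuals from the median scaled by the normalized
#' MAD give two-sided normal p values, screened by Benjamini-Hochberg at
#' false-discovery rate `q_frac`.  Points are flagged, never silently
#' removed.
#'
#' @param values Numeric sample, `n >= 3`.
#' @param q_frac False-discovery rate (default 0.01, i.e. Q = 1%).
#' @return List with `kept` (values with flagged points removed), `flags`
#'   (logical, TRUE = outlier) and `values`.
#' @export
flag_outliers <- function(values, q_frac = 0.01) {
  n <- length(values)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  med <- stats::median(values)
  s <- stats::mad(values)
  flags <- rep(FALSE, n)
  if (s > 0) {
    p <- 2 * stats::pnorm(-abs(values - med) / s)
    flags <- stats::p.adjust(p, method = "BH") < q_frac
  }
  list(kept = values[!flags], flags = flags, values = values)
}
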