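#' Per-offset Higuchi curve length
#'
#' Length of the coarse-grained curve built from every k-th point of a series,
#' starting at offset `m`, with Higuchi's normalization:
#' \deqn{L_m(k) = \frac{1}{k}\left[\sum_{i=1}^{\lfloor (N-m)/k \rfloor}
#'   |x_{m+ik} - x_{m+(i-1)k}|\right]\frac{N-1}{\lfloor (N-m)/k \rfloor \, k}}
#'
#' @param x numeric vector, the series (length N >= 2, all finite).
#' @param k integer coarse-graining interval, `k >= 1`.
#' @param m integer starting offset, `1 <= m <= k`; at least one increment
#'   must fit, i.e. `floor((N - m)/k) >= 1`.
#' @return Nonnegative scalar, the normalized curve length `L_m(k)`.
#' @seealso [mean_curve_length()], [higuchi()]
#' @export
#' @examples
#' curve_length(0:4, k = 1, m = 1)  # linear ramp: 4
curve_length <- function(x, k, m) {
  x <- check_series(x)
  n <- length(x)
  k <- check_count(k, "k")
  m <- check_count(m, "m")
  if (m > k)
    stop("offset 'm' (", m, ") must not exceed interval 'k' (", k, ")")
  n_inc <- (n - m) %/% k
  if (n_inc < 1)
    stop("interval 'k' = ", k, " with offset 'm' = ", m,
         " leaves no increments in a series of length ", n)
  idx <- seq.int(m, n, by = k)
  sum(abs(diff(x[idx]))) * (n - 1) / (n_inc * k) / k
}

#' Mean Higuchi curve length L(k)
#'
#' Average of the per-offset lengths `L_m(k)` over all offsets `m = 1..k`.
#' The decay of `L(k)` with `k` as `k^-D` defines the Higuchi fractal
#' dimension `D`.
#'
#' @inheritParams curve_length
#' @return Nonnegative scalar `L(k)`.
#' @export
#' @examples
#' mean_curve_length(0:8, k = 2)  # ramp: (N-1)/k = 4
mean_curve_length <- function(x, k) {
  x <- check_series(x)
  n <- length(x)
  k <- check_count(k, "k")
  if ((n - k) %/% k < 1)
    stop("'k' = ", k, " too large for series of length ", n,
         "; maximum admissible k is ", (n - 1) %/% 2)
  mean(vapply(seq_len(k), function(m) curve_length(x, k, m), numeric(1)))
}

#' Default kmax for a series length
#'
#' 8 for series of length >= 128, otherwise `floor((N - 1)/2)` capped at 8.
#'
#' @param n integer series length.
#' @return Integer kmax.
#' @export
default_kmax <- function(n) {
  n <- as.integer(n)
  if (n >= 128L) 8L else max(2L, min(8L, (n - 1L) %/% 2L))
}

#' Higuchi fractal dimension of a series
#'
#' Estimates the fractal dimension of the curve representing a finite series
#' from the scaling \eqn{L(k) \propto k^{-D}}: mean curve lengths `L(k)` are
#' computed for `k = 1..kmax` and an unweighted ordinary least-squares line is
#' fitted to `(log k, log L(k))`; the estimate is minus the slope. For
#' curve-like series the dimension lies between 1 (smooth curve) and 2
#' (plane-filling); finite-sample noise may push estimates slightly outside.
#' The estimate is invariant under affine amplitude transforms
#' `x -> a*x + c`, `a != 0`.
#'
#' @param x numeric vector, the series; length must admit `kmax`
#'   (`kmax <= floor((N - 1)/2)`).
#' @param kmax largest coarse-graining interval (integer >= 2). Defaults to
#'   [default_kmax()] of the series length. Small `kmax` (e.g. 4) suits short
#'   windows; larger values reduce variance on long series.
#' @param label optional free-text label stored with the fit.
#' @return An object of class `"higuchi"`: a list with components
#'   \item{df}{the fractal dimension estimate (minus the log-log slope)}
#'   \item{intercept}{intercept of the natural-log fit}
#'   \item{lengths}{named numeric vector, `L(k)` for `k = 1..kmax`}
#'   \item{fit_r2}{coefficient of determination of the log-log fit}
#'   \item{n_points}{series length used}
#'   \item{kmax, label}{as supplied}
#' @details Constant or otherwise degenerate series (any `L(k) = 0`) are an
#'   error: the log-log fit is undefined and a silent default would hide data
#'   problems.
#' @seealso [sliding_fd()] for windowed estimates, [gen_fbm()] for validation
#'   series with known dimension `2 - H`.
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 1024)
#' fit <- higuchi(sin(th), kmax = 8)   # smooth curve: dimension near 1
#' coef(fit)
higuchi <- function(x, kmax = NULL, label = NULL) {
  x <- check_series(x)
  n <- length(x)
  if (is.null(kmax)) kmax <- default_kmax(n)
  kmax <- check_count(kmax, "kmax")
  if (kmax < 2L)
    stop("'kmax' must be at least 2, got ", kmax)
  if (kmax > (n - 1L) %/% 2L)
    stop("'kmax' = ", kmax, " inadmissible for series of length ", n,
         "; maximum admissible kmax is ", (n - 1L) %/% 2L)
  lk <- vapply(seq_len(kmax), function(k) mean_curve_length(x, k), numeric(1))
  if (any(lk <= 0))
    stop("degenerate series: L(k) = 0 at k = ",
         paste(which(lk <= 0), collapse = ", "),
         " (constant or k-periodic input); fractal dimension undefined")
  logk <- log(seq_len(kmax))
  logl <- log(lk)
  fit <- stats::lm.fit(cbind(1, logk), logl)
  slope <- unname(fit$coefficients[2L])
  r2 <- 1 - sum(fit$residuals^2) / sum((logl - mean(logl))^2)
  structure(list(
    df        = -slope,
    intercept = unname(fit$coefficients[1L]),
    lengths   = stats::setNames(lk, seq_len(kmax)),
    fit_r2    = r2,
    n_points  = n,
    kmax      = kmax,
    label     = label,
    logk      = logk,
    logl      = logl
  ), class = "higuchi")
}

#' @export
print.higuchi <- function(x, digits = 4, ...) {
  cat("Higuchi fractal dimension fit",
      if (!is.null(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  cat("  D_f = ", format(x$df, digits = digits),
      "  (kmax = ", x$kmax, ", N = ", x$n_points,
      ", R^2 = ", format(x$fit_r2, digits = digits), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.higuchi <- function(object, ...) {
  tab <- data.frame(k = as.integer(names(object$lengths)),
                    L = unname(object$lengths),
                    log_k = object$logk,
                    log_L = object$logl)
  out <- list(df = object$df, intercept = object$intercept,
              fit_r2 = object$fit_r2, n_points = object$n_points,
              kmax = object$kmax, label = object$label, table = tab)
  class(out) <- "summary.higuchi"
  out
}

#' @export
print.summary.higuchi <- function(x, digits = 4, ...) {
  cat("Higuchi fractal dimension fit",
      if (!is.null(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  cat("  N = ", x$n_points, ", kmax = ", x$kmax, "\n", sep = "")
  cat("  D_f = ", format(x$df, digits = digits),
      ", intercept = ", format(x$intercept, digits = digits),
      ", R^2 = ", format(x$fit_r2, digits = digits), "\n\n", sep = "")
  print(x$table, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
coef.higuchi <- function(object, ...) {
  c(df = object$df, intercept = object$intercept)
}

#' @export
fitted.higuchi <- function(object, ...) {
  exp(object$intercept - object$df * object$logk)
}

#' @export
residuals.higuchi <- function(object, ...) {
  object$logl - (object$intercept - object$df * object$logk)
}

#' Predicted mean curve length at interval k
#'
#' Evaluates the fitted power law `L(k) = exp(intercept) * k^-df` at new
#' coarse-graining intervals.
#'
#' @param object a [higuchi()] fit.
#' @param k numeric vector of intervals (default: the fitted `1..kmax`).
#' @param ... unused.
#' @return Numeric vector of predicted `L(k)`.
#' @export
predict.higuchi <- function(object, k = NULL, ...) {
  if (is.null(k)) k <- as.numeric(names(object$lengths))
  if (any(k <= 0)) stop("'k' must be positive")
  exp(object$intercept - object$df * log(k))
}

#' Log-log diagnostic plot of a Higuchi fit
#'
#' @param x a [higuchi()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.higuchi <- function(x, ...) {
  graphics::plot(x$logk, x$logl, xlab = "log k", ylab = "log L(k)",
                 main = sprintf("Higuchi fit: D_f = %.3f", x$df), ...)
  graphics::abline(a = x$intercept, b = -x$df, lty = 2)
  invisible(x)
}

# ---- input validation helpers ------------------------------------------

check_series <- function(x) {
  if (is.list(x) && !is.null(x$values)) x <- x$values
  x <- as.numeric(x)
  if (length(x) < 2L)
    stop("series must have at least 2 values, got ", length(x))
  if (!all(is.finite(x)))
    stop("series contains non-finite values")
  x
}

check_count <- function(v, name) {
  if (length(v) != 1L || !is.finite(v) || v < 1 || v != as.integer(v))
    stop("'", name, "' must be a single positive integer")
  as.integer(v)
}
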