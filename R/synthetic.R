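#' Fractional Brownian motion sample path
#'
#' Generates an fBm path of length `n` with Hurst exponent `H` by exact
#' circulant embedding (Davies-Harte): fractional Gaussian noise with the
#' exact target autocovariance
#' \eqn{\gamma(h) = \tfrac12(|h+1|^{2H} - 2|h|^{2H} + |h-1|^{2H})}
#' is synthesized spectrally and cumulated. The graph of fBm has fractal
#' dimension `2 - H`, which makes these paths a validation oracle for the
#' Higuchi estimator. `H = 0.5` reduces to ordinary Brownian motion
#' (independent Gaussian increments).
#'
#' @param n series length (integer >= 16).
#' @param hurst Hurst exponent, in (0, 1). Lower values give rougher paths
#'   (higher fractal dimension).
#' @param seed integer seed; the path is reproducible from it.
#' @return Numeric vector of length `n`, the fBm path (unit-variance
#'   increments).
#' @references Davies, R.B. and Harte, D.S. (1987) Tests for Hurst effect.
#'   Biometrika 74, 95-101.
#' @export
#' @examples
#' x <- gen_fbm(1024, hurst = 0.5, seed = 1)
#' higuchi(x, kmax = 8)  # dimension near 2 - 0.5 = 1.5
gen_fbm <- function(n, hurst, seed) {
  n <- check_count(n, "n")
  if (n < 16L) stop("'n' must be at least 16, got ", n)
  if (length(hurst) != 1L || !is.finite(hurst) || hurst <= 0 || hurst >= 1)
    stop("'hurst' must lie strictly between 0 and 1")
  seed <- as.integer(seed)
  set.seed(seed)
  cumsum(gen_fgn(n, hurst))
}

# fractional Gaussian noise via Davies-Harte circulant embedding;
# uses the current RNG state (callers seed)
gen_fgn <- function(n, hurst) {
  h2 <- 2 * hurst
  g <- 0.5 * (abs(0:n + 1)^h2 - 2 * abs(0:n)^h2 + abs(0:n - 1)^h2)
  row <- c(g, g[n:2])                       # circulant first row, length 2n
  lam <- Re(stats::fft(row))
  # exact embedding is nonnegative-definite for fGn; guard rounding error
  if (min(lam) < -1e-8 * max(lam))
    stop("circulant embedding failed for hurst = ", hurst)
  lam[lam < 0] <- 0
  m <- 2L * n
  a <- complex(m)
  a[1L] <- sqrt(lam[1L]) * stats::rnorm(1L)
  a[n + 1L] <- sqrt(lam[n + 1L]) * stats::rnorm(1L)
  z1 <- stats::rnorm(n - 1L)
  z2 <- stats::rnorm(n - 1L)
  a[2:n] <- sqrt(lam[2:n] / 2) * complex(real = z1, imaginary = z2)
  a[m:(n + 2L)] <- Conj(a[2:n])
  Re(stats::fft(a))[seq_len(n)] / sqrt(m)
}

#' Synthetic grayscale texture with controlled directional roughness
#'
#' Builds an image whose horizontal (row-sum) and vertical (column-sum)
#' landscapes are affine images of two independent fBm profiles, so the
#' landscape fractal dimensions are controlled by the two Hurst exponents
#' (expected `dh` near `2 - hurst_rows`, `dv` near `2 - hurst_cols`). Each
#' profile is rescaled to `[-1, 1]` and the pixel value at (m, n) is
#' `round(128 + 63*p[m] + 63*q[n])`, which stays inside `[0, 255]` without
#' clipping — the rescaling does not change a profile's fractal dimension.
#'
#' @param rows,cols image dimensions (each >= 64).
#' @param hurst_rows Hurst exponent of the row profile (controls the
#'   horizontal landscape; lower = rougher = higher `dh`).
#' @param hurst_cols Hurst exponent of the column profile (controls the
#'   vertical landscape).
#' @param seed integer seed.
#' @return A [gray_image()] of the requested size, bit depth 8.
#' @export
gen_texture_image <- function(rows, cols, hurst_rows = 0.5, hurst_cols = 0.5,
                              seed = 1L) {
  rows <- check_count(rows, "rows")
  cols <- check_count(cols, "cols")
  if (rows < 64L || cols < 64L)
    stop("texture dimensions must be at least 64 x 64, got ",
         rows, " x ", cols)
  p <- gen_fbm(rows, hurst_rows, seed = as.integer(seed))
  q <- gen_fbm(cols, hurst_cols, seed = as.integer(seed) + 1L)
  p <- p - mean(p); p <- p / max(abs(p))
  q <- q - mean(q); q <- q / max(abs(q))
  px <- round(128 + 63 * outer(p, rep(1, cols)) + 63 * outer(rep(1, rows), q))
  gray_image(px, bit_depth = 8L)
}

#' Synthetic contour specifications
#'
#' Parameter sets for [gen_contour()] / [gen_contour_cohort()]. A contour is
#' star-shaped about the origin with radius
#' `r(theta) = ellipse(theta) + macro_amp * sin(macro_lobes * theta + phase)
#'  + micro_amp * z(theta)`,
#' where `z` is a standardized periodic fBm bridge with Hurst exponent
#' `micro_hurst`. The macro term models smooth low-frequency lobulation; the
#' micro term models fine-scale boundary roughness.
#'
#' `benign_contour_spec()` emulates a mass boundary with many small
#' fine-scale irregularities (rough micro term, modest lobes), which drives
#' the signature's fractal dimension well above 1.
#' `malignant_contour_spec()` emulates a smoothly macro-lobulated boundary
#' with almost no fine-scale roughness, whose signature stays close to
#' dimension 1. Units are pixels.
#'
#' @param i_points number of boundary points I (>= 64).
#' @param semi_axes ellipse semi-axes `c(a, b)`.
#' @param macro_lobes count of low-frequency radial undulations.
#' @param macro_amp amplitude of the undulation.
#' @param micro_amp amplitude (standard deviation) of the fine-scale radial
#'   noise.
#' @param micro_hurst Hurst exponent of the fine-scale noise.
#' @return A list of class `"contour_spec"`.
#' @export
contour_spec <- function(i_points = 1024L, semi_axes = c(100, 70),
                         macro_lobes = 4L, macro_amp = 4,
                         micro_amp = 0.8, micro_hurst = 0.25) {
  i_points <- check_count(i_points, "i_points")
  if (i_points < 64L) stop("'i_points' must be at least 64")
  if (length(semi_axes) != 2L || any(!is.finite(semi_axes)) ||
      any(semi_axes <= 0))
    stop("'semi_axes' must be two positive numbers")
  if (macro_amp < 0 || micro_amp < 0)
    stop("amplitudes must be nonnegative")
  if (micro_amp > 0 && (micro_hurst <= 0 || micro_hurst >= 1))
    stop("'micro_hurst' must lie strictly between 0 and 1")
  structure(list(i_points = i_points, semi_axes = as.numeric(semi_axes),
                 macro_lobes = as.integer(macro_lobes),
                 macro_amp = macro_amp, micro_amp = micro_amp,
                 micro_hurst = micro_hurst),
            class = "contour_spec")
}

#' @rdname contour_spec
#' @export
benign_contour_spec <- function() {
  contour_spec(macro_lobes = 4L, macro_amp = 4, micro_amp = 0.8,
               micro_hurst = 0.25)
}

#' @rdname contour_spec
#' @export
malignant_contour_spec <- function() {
  contour_spec(macro_lobes = 7L, macro_amp = 18, micro_amp = 0.5,
               micro_hurst = 0.5)
}

#' Generate one synthetic closed contour
#'
#' Samples the radius function of [contour_spec()] at `i_points` angles
#' spanning `[0, 2*pi)` and returns the boundary points in order. The
#' fine-scale noise is an fBm bridge (endpoints tied) so the radius closes
#' smoothly across the starting angle.
#'
#' @param spec a [contour_spec()].
#' @param seed integer seed.
#' @param case_id optional identifier used in error messages.
#' @return A [contour_xy()] centered at the origin.
#' @export
gen_contour <- function(spec = contour_spec(), seed = 1L, case_id = NULL) {
  stopifnot(inherits(spec, "contour_spec"))
  I <- spec$i_points
  theta <- 2 * pi * (seq_len(I) - 1L) / I
  a <- spec$semi_axes[1L]; b <- spec$semi_axes[2L]
  r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  if (spec$macro_amp > 0 && spec$macro_lobes > 0) {
    set.seed(as.integer(seed))
    phase <- stats::runif(1, 0, 2 * pi)
    r <- r + spec$macro_amp * sin(spec$macro_lobes * theta + phase)
  }
  if (spec$micro_amp > 0) {
    f <- gen_fbm(I, spec$micro_hurst, seed = as.integer(seed) + 1000L)
    f <- f - seq(0, 1, length.out = I) * (f[I] - f[1L]) - f[1L]  # bridge
    s <- stats::sd(f)
    if (s > 0) r <- r + spec$micro_amp * (f - mean(f)) / s
  }
  if (any(r <= 0))
    stop("contour parameters produce nonpositive radii",
         if (!is.null(case_id)) paste0(" for case '", case_id, "'"),
         " (min r = ", format(min(r), digits = 4),
         "); reduce amplitudes")
  contour_xy(r * cos(theta), r * sin(theta))
}

#' Generate a cohort of synthetic contours
#'
#' Produces `n_cases` independent contours from one [contour_spec()], with
#' per-case seeds derived from `seed` so the cohort is reproducible.
#'
#' @param n_cases number of contours.
#' @param spec a [contour_spec()]; see [benign_contour_spec()] and
#'   [malignant_contour_spec()] for the two preset morphologies.
#' @param seed integer base seed.
#' @return A list of [contour_xy()] objects, named `case_1 ... case_n`.
#' @export
gen_contour_cohort <- function(n_cases, spec = contour_spec(), seed = 1L) {
  n_cases <- check_count(n_cases, "n_cases")
  out <- lapply(seq_len(n_cases), function(i) {
    gen_contour(spec, seed = as.integer(seed) + 37L * i,
                case_id = paste0("case_", i))
  })
  names(out) <- paste0("case_", seq_len(n_cases))
  out
}
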