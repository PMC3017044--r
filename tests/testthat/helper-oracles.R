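# Brute-force oracle for the mean Higuchi curve length: literal triple loop
# over offsets m, strides i, following the defining formula with 1-based
# indexing. Deliberately naive and independent of the package internals.
naive_mean_curve_length <- function(x, k) {
  n <- length(x)
  total <- 0
  for (m in seq_len(k)) {
    n_inc <- floor((n - m) / k)
    s <- 0
    for (i in seq_len(n_inc)) {
      s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
    }
    total <- total + s * (n - 1) / (n_inc * k) / k
  }
  total / k
}

# a non-degenerate random series of length n
rand_series <- function(n) stats::rnorm(n)

# unit-ellipse-family contour sampled on a uniform angle grid
ellipse_contour <- function(a = 2, b = 1, n = 256, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  contour_xy(center[1] + a * cos(th), center[2] + b * sin(th))
}
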