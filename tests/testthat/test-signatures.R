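test_that("centroid is the coordinate mean and shifts with translation", {
  sq <- contour_xy(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(contour_centroid(sq), c(x0 = 0.5, y0 = 0.5))
  tri <- contour_xy(c(0, 3, 0), c(0, 0, 3))
  expect_equal(contour_centroid(tri), c(x0 = 1, y0 = 1))
  shifted <- contour_xy(sq$x + 2.5, sq$y - 4)
  expect_equal(contour_centroid(shifted), c(x0 = 3, y0 = -3.5))
})

test_that("explicit closing duplicates are dropped before averaging", {
  open4 <- contour_xy(c(0, 1, 1, 0), c(0, 0, 1, 1))
  closed5 <- contour_xy(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_length(closed5$x, 4)
  expect_equal(contour_centroid(closed5), contour_centroid(open4))
})

test_that("contour validation rejects degenerate inputs", {
  expect_error(contour_xy(c(0, 1), c(0, 1)), "at least 3")
  expect_error(contour_xy(rep(2, 5), rep(3, 5)), "identical")
  expect_error(contour_xy(c(0, Inf, 1), c(0, 0, 1)), "finite")
  expect_error(contour_xy(1:4, 1:3), "equal length")
})

test_that("radial signature matches closed forms", {
  sq <- contour_xy(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(radial_signature(sq)$r, rep(sqrt(0.5), 4))
  # points on a unit circle, off-center: all r = 1
  circ <- ellipse_contour(1, 1, 128, center = c(10, -3))
  expect_equal(radial_signature(circ)$r, rep(1, 128), tolerance = 1e-12)
  # ellipse semi-axes (2, 1): r_j = sqrt(4 cos^2 + sin^2) about the origin
  th <- 2 * pi * (0:255) / 256
  ell <- ellipse_contour(2, 1, 256)
  expect_equal(radial_signature(ell)$r, sqrt(4 * cos(th)^2 + sin(th)^2),
               tolerance = 1e-12)
})

test_that("signature is translation invariant, scales with the contour", {
  con <- gen_contour(benign_contour_spec(), seed = 11)
  r0 <- radial_signature(con)$r
  moved <- contour_xy(con$x + 123.4, con$y - 56.7)
  expect_equal(radial_signature(moved)$r, r0, tolerance = 1e-12)
  scaled <- contour_xy(3 * con$x, 3 * con$y)
  expect_equal(radial_signature(scaled)$r, 3 * r0, tolerance = 1e-9)
  # fractal dimension is invariant under the uniform scaling
  expect_equal(signature_fd(scaled, kmax = 8)$df,
               signature_fd(con, kmax = 8)$df, tolerance = 1e-9)
})

test_that("circle signatures are flagged as degenerate", {
  circ <- ellipse_contour(1, 1, 512)
  expect_error(signature_fd(circ), "degenerate contour signature")
})

test_that("smooth ellipse signature sits near dimension 1, noise raises it", {
  ell <- ellipse_contour(2, 1, 1024)
  smooth_df <- signature_fd(ell, kmax = 4)$df
  expect_lt(abs(smooth_df - 1), 0.05)
  # add small-amplitude high-frequency radial noise
  set.seed(21)
  th <- 2 * pi * (0:1023) / 1024
  r <- radial_signature(ell)$r + 0.01 * stats::rnorm(1024)
  noisy <- contour_xy(r * cos(th), r * sin(th))
  expect_gt(signature_fd(noisy, kmax = 4)$df, smooth_df)
})

test_that("shifting the starting point barely changes the dimension", {
  con <- gen_contour(benign_contour_spec(), seed = 31)
  base_df <- signature_fd(con, kmax = 4)$df
  set.seed(5)
  shifts <- sample(length(con$x) - 1, 20)
  diffs <- vapply(shifts, function(s) {
    idx <- c((s + 1):length(con$x), 1:s)
    abs(signature_fd(contour_xy(con$x[idx], con$y[idx]), kmax = 4)$df -
          base_df)
  }, numeric(1))
  expect_lt(mean(diffs), 0.05)
})

test_that("contour files round-trip in both CSV dialects", {
  con <- gen_contour(malignant_contour_spec(), seed = 2)
  p <- tempfile(fileext = ".csv")
  write_contour(con, p)
  back <- read_contour(p)
  expect_equal(back$x, con$x, tolerance = 1e-9)
  expect_equal(back$y, con$y, tolerance = 1e-9)
  # tab-separated without header
  p2 <- tempfile(fileext = ".tsv")
  writeLines(sprintf("%.10f\t%.10f", con$x, con$y), p2)
  back2 <- read_contour(p2)
  expect_equal(back2$x, con$x, tolerance = 1e-8)
  expect_error(read_contour(tempfile()), "not found")
})

test_that("signature writer emits index and radius columns", {
  con <- contour_xy(c(0, 1, 1, 0), c(0, 0, 1, 1))
  p <- tempfile(fileext = ".csv")
  write_signature(radial_signature(con), p)
  d <- utils::read.csv(p)
  expect_equal(d$r, rep(sqrt(0.5), 4), tolerance = 1e-9)
})

test_that("contour resampling preserves shape on uniform grids", {
  ell <- ellipse_contour(2, 1, 512)
  rs <- resample_contour(ell, 256)
  expect_length(rs$x, 256)
  # resampled points remain near the ellipse
  expect_true(all(abs((rs$x / 2)^2 + rs$y^2 - 1) < 0.01))
})
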