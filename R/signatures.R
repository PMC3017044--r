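#' Closed planar contour
#'
#' An ordered sequence of boundary points (x_i, y_i), i = 1..I, consecutive
#' along a closed curve; the point after i = I is i = 1. If the input repeats
#' the first point as the last (explicit closure, equal to within 1e-9), the
#' duplicate is dropped so it is not double-counted in the centroid.
#'
#' @param x,y numeric vectors of coordinates, or `x` a two-column
#'   matrix/data.frame.
#' @return An object of class `"contour_xy"`: list with numeric vectors `x`,
#'   `y` of equal length `I >= 3`.
#' @export
contour_xy <- function(x, y = NULL) {
  if (is.null(y)) {
    x <- as.matrix(x)
    if (ncol(x) < 2L) stop("contour input must have two columns (x, y)")
    y <- as.numeric(x[, 2L]); x <- as.numeric(x[, 1L])
  }
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("contour coordinates must all be finite")
  n <- length(x)
  if (n >= 2L && abs(x[1L] - x[n]) < 1e-9 && abs(y[1L] - y[n]) < 1e-9) {
    x <- x[-n]; y <- y[-n]
  }
  if (length(x) < 3L)
    stop("contour must have at least 3 distinct points, got ", length(x))
  if (all(x == x[1L]) && all(y == y[1L]))
    stop("degenerate contour: all points identical")
  structure(list(x = x, y = y), class = "contour_xy")
}

#' @export
print.contour_xy <- function(x, ...) {
  cat("closed contour with ", length(x$x), " points\n", sep = "")
  invisible(x)
}

#' Read a contour from two-column delimited text
#'
#' Accepts comma- or tab-separated x,y pairs, dot decimal separator, with or
#' without a header line.
#'
#' @param path file path.
#' @return A [contour_xy()].
#' @export
read_contour <- function(path) {
  if (!file.exists(path)) stop("contour file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, sep, fixed = TRUE)[[1L]][1L])))
  d <- utils::read.table(path, sep = sep, header = has_header)
  if (ncol(d) < 2L) stop("contour file must have two columns: ", path)
  contour_xy(d[[1L]], d[[2L]])
}

#' Write a contour as two-column CSV
#' @param contour a [contour_xy()].
#' @param path output file path.
#' @export
write_contour <- function(contour, path) {
  if (!inherits(contour, "contour_xy")) stop("'contour' must be a contour_xy")
  utils::write.csv(data.frame(x = contour$x, y = contour$y), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Contour centroid
#'
#' Arithmetic means of the x and y coordinates over the distinct contour
#' points.
#'
#' @param contour a [contour_xy()].
#' @return Named numeric vector `c(x0 = ..., y0 = ...)`.
#' @export
contour_centroid <- function(contour) {
  contour <- as_contour(contour)
  c(x0 = mean(contour$x), y0 = mean(contour$y))
}

#' Radial signature of a closed contour
#'
#' The 1-D signature of the 2-D contour: the Euclidean distance of each
#' boundary point from the coordinate centroid,
#' \eqn{r_i = \sqrt{(x_i - x_0)^2 + (y_i - y_0)^2}}, in boundary order.
#' Translating the contour leaves the signature unchanged; uniform scaling by
#' `s > 0` multiplies it by `s` (and leaves its fractal dimension unchanged).
#'
#' @param contour a [contour_xy()] (or two-column matrix, coerced).
#' @return An object of class `"signature"`: list with `r` (nonnegative
#'   series, one value per contour point) and `centroid`.
#' @export
#' @examples
#' sq <- contour_xy(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' radial_signature(sq)$r  # all sqrt(0.5)
radial_signature <- function(contour) {
  contour <- as_contour(contour)
  cen <- contour_centroid(contour)
  r <- sqrt((contour$x - cen["x0"])^2 + (contour$y - cen["y0"])^2)
  structure(list(r = unname(r), centroid = cen), class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat("radial signature, length ", length(x$r),
      ", centroid (", format(x$centroid[1L], digits = 6), ", ",
      format(x$centroid[2L], digits = 6), ")\n", sep = "")
  invisible(x)
}

#' Write a signature as two-column CSV
#' @param x a [radial_signature()].
#' @param path output file path.
#' @export
write_signature <- function(x, path) {
  if (!inherits(x, "signature")) stop("'x' must be a signature")
  utils::write.csv(data.frame(index = seq_along(x$r), r = x$r), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fractal dimension of a contour's radial signature
#'
#' Computes the [radial_signature()] and fits [higuchi()] to it. A constant
#' signature (a perfect circle) is degenerate and raises an error.
#'
#' @inheritParams radial_signature
#' @param kmax largest coarse-graining interval; default [default_kmax()].
#' @return A [higuchi()] fit of the signature series.
#' @export
signature_fd <- function(contour, kmax = NULL) {
  sig <- radial_signature(contour)
  # a circle's radii differ only by floating-point noise; the log-log fit
  # on that noise would be meaningless rather than merely imprecise
  if (diff(range(sig$r)) <= 1e-9 * max(abs(sig$r), 1))
    stop("degenerate contour signature (circle-like, constant radius)",
         call. = FALSE)
  tryCatch(
    higuchi(sig$r, kmax = kmax, label = "contour signature"),
    error = function(e) {
      if (grepl("degenerate series", conditionMessage(e)))
        stop("degenerate contour signature (circle-like, constant radius): ",
             conditionMessage(e), call. = FALSE)
      stop(e)
    })
}

as_contour <- function(x) {
  if (inherits(x, "contour_xy")) x else contour_xy(x)
}
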