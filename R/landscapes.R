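#' Grayscale image container
#'
#' A thin validated wrapper around an integer matrix of gray values. Rows run
#' top to bottom (index m = 1..M), columns left to right (n = 1..N); pixel
#' values lie in `[0, 2^bit_depth - 1]`.
#'
#' @param pixels numeric matrix of gray values (M rows x N columns).
#' @param bit_depth integer bit depth b; gray values must lie in
#'   `[0, 2^b - 1]`. Default 8.
#' @return An object of class `"gray_image"`: the pixel matrix with a
#'   `bit_depth` attribute.
#' @export
gray_image <- function(pixels, bit_depth = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("image must be at least 2 x 2, got ",
         nrow(pixels), " x ", ncol(pixels))
  bit_depth <- check_count(bit_depth, "bit_depth")
  gmax <- 2^bit_depth - 1
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > gmax))
    stop("pixel values must lie in [0, ", gmax,
         "] for bit depth ", bit_depth)
  structure(round(pixels), bit_depth = bit_depth, class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat("gray_image: ", nrow(x), " x ", ncol(x),
      " pixels, bit depth ", attr(x, "bit_depth"), "\n", sep = "")
  invisible(x)
}

#' Transpose a grayscale image
#' @param x a [gray_image()].
#' @export
t.gray_image <- function(x) {
  gray_image(t(unclass(x)), attr(x, "bit_depth"))
}

#' Read a raster image as 8-bit grayscale
#'
#' Reads PNG, TIFF, or PGM (ASCII `P2` or binary `P5`) files. Color images
#' are converted to luminance with ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B), rounded to the nearest integer; an alpha
#' channel, if present, is dropped.
#'
#' @param path path to the image file; format inferred from the extension
#'   (`.png`, `.tif`/`.tiff`, `.pgm`).
#' @return A [gray_image()].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = tryCatch(png::readPNG(path),
                    error = function(e) stop("failed to read PNG '", path,
                                             "': ", conditionMessage(e))),
    tif  = ,
    tiff = tryCatch(tiff::readTIFF(path),
                    error = function(e) stop("failed to read TIFF '", path,
                                             "': ", conditionMessage(e))),
    pgm  = return(read_pgm(path)),
    stop("unsupported image format '", ext, "' (expected png, tiff or pgm)")
  )
  # png/tiff readers return values scaled to [0,1]
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3L] >= 3L) {
      arr <- 0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    } else {
      arr <- arr[, , 1L]
    }
  }
  gray_image(round(arr * 255), bit_depth = 8L)
}

# PGM (portable graymap): P2 ASCII or P5 binary, maxval <= 65535
read_pgm <- function(path) {
  raw_all <- readBin(path, what = "raw", n = file.info(path)$size)
  # header tokens: magic, width, height, maxval; '#' starts a comment
  pos <- 1L
  tokens <- character(0)
  while (length(tokens) < 4L && pos <= length(raw_all)) {
    ch <- rawToChar(raw_all[pos])
    if (ch == "#") {
      while (pos <= length(raw_all) && rawToChar(raw_all[pos]) != "\n")
        pos <- pos + 1L
    } else if (grepl("[[:space:]]", ch)) {
      pos <- pos + 1L
    } else {
      start <- pos
      while (pos <= length(raw_all) &&
             !grepl("[[:space:]]", rawToChar(raw_all[pos])) &&
             rawToChar(raw_all[pos]) != "#")
        pos <- pos + 1L
      tokens <- c(tokens, rawToChar(raw_all[start:(pos - 1L)]))
    }
  }
  if (length(tokens) < 4L) stop("truncated PGM header in '", path, "'")
  magic <- tokens[1L]
  wid <- as.integer(tokens[2L]); hei <- as.integer(tokens[3L])
  maxval <- as.integer(tokens[4L])
  if (is.na(wid) || is.na(hei) || is.na(maxval) || wid < 1L || hei < 1L)
    stop("invalid PGM dimensions in '", path, "'")
  bit_depth <- ceiling(log2(maxval + 1))
  if (magic == "P2") {
    txt <- rawToChar(raw_all[pos:length(raw_all)])
    vals <- suppressWarnings(as.numeric(strsplit(trimws(txt),
                                                 "[[:space:]]+")[[1L]]))
    if (length(vals) < wid * hei || anyNA(vals))
      stop("truncated or corrupt PGM pixel data in '", path, "'")
    px <- matrix(vals[seq_len(wid * hei)], nrow = hei, ncol = wid,
                 byrow = TRUE)
  } else if (magic == "P5") {
    pos <- pos + 1L  # single whitespace after maxval
    bytes_per <- if (maxval > 255L) 2L else 1L
    need <- wid * hei * bytes_per
    if (length(raw_all) - pos + 1L < need)
      stop("truncated PGM pixel data in '", path, "'")
    body <- raw_all[pos:(pos + need - 1L)]
    if (bytes_per == 1L) {
      vals <- as.integer(body)
    } else {
      vals <- readBin(body, what = "integer", n = wid * hei, size = 2L,
                      signed = FALSE, endian = "big")
    }
    px <- matrix(vals, nrow = hei, ncol = wid, byrow = TRUE)
  } else {
    stop("unsupported PGM magic '", magic, "' (expected P2 or P5)")
  }
  gray_image(px, bit_depth = max(bit_depth, 1L))
}

#' Landscape series of a grayscale image
#'
#' The horizontal landscape sums gray values row by row (`G_m`, m = 1..M) and
#' normalizes by the largest sum, `NGS_m = G_m / max(G)`; the vertical
#' landscape does the same column by column. The normalization maps the
#' series into `[0, 1]` but does not affect the fractal dimension, which is
#' scale invariant.
#'
#' @param img a [gray_image()] (or plain numeric matrix, coerced with bit
#'   depth 8).
#' @return An object of class `"landscape"`: list with `ngs` (normalized
#'   series), `raw_sums`, and `orientation` (`"horizontal"` or `"vertical"`).
#' @details An all-zero image is an error: the normalization divides by the
#'   maximal sum.
#' @export
#' @examples
#' img <- gray_image(rbind(c(10, 20, 30), c(5, 5, 5)))
#' horizontal_landscape(img)$ngs   # (1, 0.25)
horizontal_landscape <- function(img) {
  img <- as_gray_image(img)
  sums <- rowSums(unclass(img))
  make_landscape(sums, "horizontal")
}

#' @rdname horizontal_landscape
#' @export
vertical_landscape <- function(img) {
  img <- as_gray_image(img)
  sums <- colSums(unclass(img))
  make_landscape(sums, "vertical")
}

make_landscape <- function(sums, orientation) {
  mx <- max(sums)
  if (mx <= 0)
    stop("degenerate all-zero image: landscape normalization undefined")
  structure(list(ngs = sums / mx, raw_sums = sums, orientation = orientation),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(x$orientation, " landscape, length ", length(x$ngs), "\n", sep = "")
  invisible(x)
}

as_gray_image <- function(img) {
  if (inherits(img, "gray_image")) img else gray_image(img)
}

#' Fractal dimensions of the two landscapes of an image
#'
#' Computes the horizontal landscape dimension `dh`, the vertical landscape
#' dimension `dv`, and their difference (a directional-anisotropy measure:
#' an isotropic texture has `dh` close to `dv`).
#'
#' @inheritParams horizontal_landscape
#' @param kmax largest coarse-graining interval for the Higuchi fit; default
#'   [default_kmax()] per landscape length.
#' @return An object of class `"landscape_fd"`: list with `dh`, `dv`,
#'   `anisotropy = dh - dv`, and the two underlying [higuchi()] fits
#'   (`fit_h`, `fit_v`).
#' @export
landscape_fd <- function(img, kmax = NULL) {
  img <- as_gray_image(img)
  fh <- higuchi(horizontal_landscape(img)$ngs, kmax = kmax,
                label = "horizontal landscape")
  fv <- higuchi(vertical_landscape(img)$ngs, kmax = kmax,
                label = "vertical landscape")
  structure(list(dh = fh$df, dv = fv$df, anisotropy = fh$df - fv$df,
                 fit_h = fh, fit_v = fv),
            class = "landscape_fd")
}

#' @export
print.landscape_fd <- function(x, digits = 4, ...) {
  cat("Landscape fractal dimensions\n")
  cat("  D_h = ", format(x$dh, digits = digits),
      "  D_v = ", format(x$dv, digits = digits),
      "  anisotropy (D_h - D_v) = ",
      format(x$anisotropy, digits = digits), "\n", sep = "")
  invisible(x)
}

#' Write a landscape as two-column CSV
#'
#' @param x a landscape from [horizontal_landscape()] or
#'   [vertical_landscape()].
#' @param path output file path.
#' @export
write_landscape <- function(x, path) {
  if (!inherits(x, "landscape")) stop("'x' must be a landscape")
  utils::write.csv(data.frame(index = seq_along(x$ngs), ngs = x$ngs),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
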