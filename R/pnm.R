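## Plain-text netpbm I/O (PGM "P2" grayscale, PPM "P3" color). Used for 2-D
## DSA frames, ROI masks and color-map artifacts: the target environment has
## no PNG/TIFF codec, and text netpbm keeps every artifact diff-able.

#' Write a matrix as a plain (P2) PGM image
#'
#' Values are linearly rescaled from `range` to `0..maxval`. Matrices are
#' stored row = image row (first dimension = height).
#'
#' @param mat numeric matrix (H x W)
#' @param path output path
#' @param maxval maximum stored integer (default 65535 for 16-bit precision)
#' @param range intensity range mapped to 0..maxval; default the data range
#' @return list with the scaling actually used (`range`, `maxval`), invisibly
#' @export
write_pgm <- function(mat, path, maxval = 65535L, range = NULL) {
  stopifnot_msg(is.matrix(mat), "mat must be a matrix")
  if (is.null(range)) {
    range <- range(mat)
    if (range[1] == range[2]) range[2] <- range[1] + 1
  }
  scaled <- round((mat - range[1]) / (range[2] - range[1]) * maxval)
  scaled <- pmin(pmax(scaled, 0), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(mat), nrow(mat)), as.character(maxval)), con)
  ## one image row per line
  writeLines(apply(scaled, 1, paste, collapse = " "), con)
  invisible(list(range = range, maxval = maxval))
}

#' Read a plain (P2) PGM image
#'
#' @param path PGM file
#' @param range optional intensity range to map 0..maxval back onto; when
#'   `NULL` raw integers are returned
#' @return numeric matrix (H x W); attribute `maxval`
#' @export
read_pgm <- function(path, range = NULL) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  stopifnot_msg(toks[1] == "P2", "not a plain PGM (P2) file: %s", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3]); maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  stopifnot_msg(length(vals) == w * h, "corrupt PGM payload in %s", path)
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  if (!is.null(range)) m <- range[1] + m / maxval * (range[2] - range[1])
  attr(m, "maxval") <- maxval
  m
}

#' Write an RGB array as a plain (P3) PPM image
#'
#' @param rgb H x W x 3 array with values in `[0, 1]`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ppm <- function(rgb, path) {
  stopifnot_msg(is.array(rgb) && length(dim(rgb)) == 3 && dim(rgb)[3] == 3,
                "rgb must be an H x W x 3 array")
  v <- round(pmin(pmax(rgb, 0), 1) * 255)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  ## interleave channels pixel by pixel, row-major
  inter <- matrix(0L, nrow = h, ncol = 3 * w)
  inter[, seq(1, 3 * w, 3)] <- v[, , 1]
  inter[, seq(2, 3 * w, 3)] <- v[, , 2]
  inter[, seq(3, 3 * w, 3)] <- v[, , 3]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  writeLines(apply(inter, 1, paste, collapse = " "), con)
  invisible(path)
}
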