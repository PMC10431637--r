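# Image I/O. Two formats: PNG (8-bit grayscale, via the `png` package) and
# plain-text PGM (P2; 8- or 16-bit), which needs no external reader and is
# the route for 16-bit round trips. Intensities live in [0, 1] in memory and
# are quantized to the target bit depth on write.

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) return("png")
  if (ext %in% c("pgm")) return("pgm")
  stop("unsupported image format '", ext, "' for file: ", path,
       call. = FALSE)
}

read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (length(tok) < 4L || tok[1L] != "P2")
    stop("not a plain (P2) PGM file: ", path, call. = FALSE)
  W <- as.integer(tok[2L]); H <- as.integer(tok[3L])
  maxval <- as.numeric(tok[4L])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != H * W)
    stop("corrupt PGM (expected ", H * W, " pixels, got ", length(vals),
         "): ", path, call. = FALSE)
  matrix(vals, nrow = H, ncol = W, byrow = TRUE) / maxval
}

write_pgm <- function(img, path, bit_depth = 8L) {
  maxval <- if (bit_depth == 16L) 65535L else 255L
  q <- matrix(as.integer(round(clip01(img) * maxval)), nrow(img), ncol(img))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  utils::write.table(q, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a grayscale image into a \[0, 1\] matrix
#'
#' Supports PNG (via the `png` package) and plain-text PGM (P2). A
#' multi-channel PNG is reduced to one channel with Rec. 709 luminance
#' weights (0.2126, 0.7152, 0.0722) and a warning.
#'
#' @param path file path ending in `.png` or `.pgm`.
#' @return Numeric matrix with intensities in \[0, 1\] (rows = y, cols = x).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path,
                               call. = FALSE)
  fmt <- img_format(path)
  if (fmt == "pgm") return(read_pgm(path))
  if (!requireNamespace("png", quietly = TRUE))
    stop("reading PNG requires the 'png' package; use .pgm instead",
         call. = FALSE)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3L]
    if (nc >= 3L) {
      warning("multi-channel image '", path,
              "' converted to luminance (Rec. 709 weights)", call. = FALSE)
      a <- 0.2126 * a[, , 1L] + 0.7152 * a[, , 2L] + 0.0722 * a[, , 3L]
    } else {
      a <- a[, , 1L]
    }
  }
  a
}

#' Write a \[0, 1\] matrix as a grayscale image
#'
#' PNG output is 8-bit; PGM (plain P2) supports `bit_depth` 8 or 16. Values
#' are clipped to \[0, 1\] and quantized, so a write/read round trip is exact
#' to within one quantization step (1/255 or 1/65535).
#'
#' @param img numeric matrix in \[0, 1\].
#' @param path output path ending in `.png` or `.pgm`.
#' @param bit_depth 8 (default) or 16 (PGM only).
#' @return The path, invisibly.
#' @export
write_image <- function(img, path, bit_depth = 8L) {
  check_image(img)
  if (!bit_depth %in% c(8L, 16L))
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  fmt <- img_format(path)
  if (fmt == "pgm") return(write_pgm(img, path, bit_depth))
  if (bit_depth == 16L)
    stop("16-bit output is supported for PGM only; use a .pgm path",
         call. = FALSE)
  if (!requireNamespace("png", quietly = TRUE))
    stop("writing PNG requires the 'png' package; use .pgm instead",
         call. = FALSE)
  png::writePNG(clip01(img), path)
  invisible(path)
}

#' Read a score matrix from CSV
#'
#' The CSV has one column per method and one row per (experiment, metric)
#' sample. An optional `orientation` column declares, per row, whether larger
#' values are better (`higher_better`/`lower_better`); absent, all rows are
#' higher-is-better.
#'
#' @param path CSV file path.
#' @return A [score_matrix].
#' @export
read_score_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ori <- "higher_better"
  if ("orientation" %in% names(df)) {
    ori <- df$orientation
    df$orientation <- NULL
  }
  score_matrix(as.matrix(df), methods = names(df), orientation = ori)
}

#' Write a score matrix to CSV
#'
#' @param scores a [score_matrix].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_score_csv <- function(scores, path) {
  df <- as.data.frame(scores$values)
  if (length(unique(scores$orientation)) > 1L ||
      any(scores$orientation != "higher_better"))
    df$orientation <- scores$orientation
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
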