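#' @section Coordinate conventions:
#' Images are plain numeric matrices with `nrow = height` and
#' `ncol = width`; element `[i, j]` is the pixel in row `i`, column `j`.
#' All user-facing coordinates are 0-based pixel centers with
#' `x = column - 1` (increasing rightwards) and `y = row - 1` (increasing
#' downwards), so the pixel at matrix index `[i, j]` has center
#' `(x, y) = (j - 1, i - 1)`. Angles are measured from the positive
#' x-axis, increasing towards positive y (i.e. clockwise on screen).
#'
#' @name macde-conventions
#' @keywords internal
NULL

#' Validate a grayscale image matrix
#'
#' @param img numeric matrix of intensities (raw units, typically 0-255).
#' @return the matrix, invisibly, after validation.
#' @keywords internal
assert_gray_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix", call. = FALSE)
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (!all(is.finite(img)))
    stop("image contains non-finite pixel values", call. = FALSE)
  invisible(img)
}

#' Read an 8-bit grayscale image
#'
#' Reads PNG, PGM (plain `P2` or raw `P5`) or TIFF images into a numeric
#' matrix on the 0-255 intensity scale. Color inputs are converted to
#' luminance as `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param path path to a `.png`, `.pgm`, `.tif`/`.tiff` file.
#' @return numeric matrix (rows = image height) with values in 0-255.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF images", call. = FALSE)
    a <- tiff::readTIFF(path)
  } else if (ext == "pgm") {
    return(read_pgm(path))
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3]
    a <- if (nc >= 3L) {
      0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a[, , 1]
    }
  }
  a * 255
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param img numeric matrix on the 0-255 scale (clipped on write).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  assert_gray_image(img)
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}

#' Write a binary mask as PNG
#'
#' @param mask 0/1 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask > 0, 1, 0), path)
  invisible(path)
}

#' Read a binary mask from PNG (nonzero = foreground)
#' @param path PNG path.
#' @return 0/1 integer matrix.
#' @export
read_mask_png <- function(path) {
  img <- read_gray_image(path)
  (img > 127) * 1L
}

# Minimal PGM reader: plain (P2) and binary 8-bit (P5).
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PGM header", call. = FALSE)
      if (ch == "#") { # comment to end of line
        repeat {
          c2 <- readChar(con, 1L, useBytes = TRUE)
          if (length(c2) == 0L || c2 == "\n") break
        }
      } else if (!grepl("[ \t\r\n]", ch)) {
        word <- ch
        repeat {
          c2 <- readChar(con, 1L, useBytes = TRUE)
          if (length(c2) == 0L || grepl("[ \t\r\n]", c2)) break
          word <- paste0(word, c2)
        }
        return(word)
      }
    }
  }
  magic <- tok()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  w <- as.integer(tok()); h <- as.integer(tok()); maxv <- as.integer(tok())
  if (magic == "P5") {
    raw <- readBin(con, "integer", n = w * h, size = 1L, signed = FALSE)
    m <- matrix(raw, nrow = h, ncol = w, byrow = TRUE)
  } else {
    vals <- integer(0)
    repeat {
      line <- readLines(con, n = 1L)
      if (length(line) == 0L) break
      vals <- c(vals, as.integer(strsplit(trimws(line), "[ \t]+")[[1]]))
      if (length(vals) >= w * h) break
    }
    m <- matrix(vals[seq_len(w * h)], nrow = h, ncol = w, byrow = TRUE)
  }
  m * (255 / maxv)
}

#' Write a plain-text PGM (P2) image
#' @param img numeric matrix on 0-255.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path) {
  assert_gray_image(img)
  v <- round(pmin(pmax(img, 0), 255))
  lines <- c("P2", paste(ncol(img), nrow(img)), "255",
             apply(v, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Write a contour as CSV
#'
#' MACDE contours carry columns `section,angle_deg,r,x,y,fitness`;
#' plain contours are written as `index,x,y`. Coordinates are 0-based
#' with `x` the column.
#'
#' @param contour data frame with at least `x` and `y` columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  if (!all(c("x", "y") %in% names(contour)))
    stop("contour must have x and y columns", call. = FALSE)
  if (!"index" %in% names(contour) && !"section" %in% names(contour))
    contour <- cbind(index = seq_len(nrow(contour)) - 1L, contour)
  utils::write.csv(contour, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a contour CSV written by [write_contour_csv()]
#' @param path CSV path.
#' @return data frame with `x` and `y` columns.
#' @export
read_contour_csv <- function(path) {
  utils::read.csv(path)
}
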