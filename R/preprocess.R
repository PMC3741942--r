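# Preprocessing chain: median denoising -> Canny edges -> Euclidean
# distance map. The distance map is the potential surface minimized by
# both the greedy snake (in edm mode) and the sectional DE populations.

#' Median filter with square window
#'
#' Replaces each pixel by the median of the `window` x `window`
#' neighborhood centered on it. Borders are handled by edge replication,
#' so no out-of-range values can enter a window.
#'
#' @param img numeric image matrix.
#' @param window odd positive integer window size (default 3).
#' @return filtered matrix, same shape.
#' @export
median_filter <- function(img, window = 3L) {
  assert_gray_image(img)
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive integer", call. = FALSE)
  if (window == 1L) return(img)
  r <- (window - 1L) %/% 2L
  p <- pad_replicate(img, r)
  h <- nrow(img); w <- ncol(img); k <- window * window
  vals <- matrix(0, h * w, k)
  idx <- 1L
  for (dy in -r:r) {
    for (dx in -r:r) {
      vals[, idx] <- as.vector(p[(1 + r + dy):(h + r + dy),
                                 (1 + r + dx):(w + r + dx)])
      idx <- idx + 1L
    }
  }
  # row-wise sort via a single order() call; median = middle column
  sorted <- matrix(vals[order(row(vals), vals)], ncol = k, byrow = TRUE)
  matrix(sorted[, (k + 1L) %/% 2L], h, w)
}

# replicate-pad a matrix by r pixels on each side
pad_replicate <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  m[c(rep(1L, r), seq_len(h), rep(h, r)),
    c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
}

# separable convolution with replicate borders; ky along rows (y),
# kx along columns (x); kernels of odd length
conv_separable <- function(m, ky, kx) {
  h <- nrow(m); w <- ncol(m)
  ry <- (length(ky) - 1L) %/% 2L
  rx <- (length(kx) - 1L) %/% 2L
  if (ry > 0L) {
    p <- m[c(rep(1L, ry), seq_len(h), rep(h, ry)), , drop = FALSE]
    acc <- matrix(0, h, w)
    for (o in seq_along(ky))
      acc <- acc + ky[o] * p[o:(o + h - 1L), , drop = FALSE]
    m <- acc
  }
  if (rx > 0L) {
    p <- m[, c(rep(1L, rx), seq_len(w), rep(w, rx)), drop = FALSE]
    acc <- matrix(0, h, w)
    for (o in seq_along(kx))
      acc <- acc + kx[o] * p[, o:(o + w - 1L), drop = FALSE]
    m <- acc
  }
  m
}

#' Gaussian smoothing with replicate borders
#'
#' @param img numeric image matrix.
#' @param sigma Gaussian standard deviation in pixels; `sigma <= 0`
#'   returns the image untouched.
#' @return smoothed matrix.
#' @export
gaussian_blur <- function(img, sigma) {
  assert_gray_image(img)
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv_separable(img, k, k)
}

# Sobel 3x3 gradient components (unnormalized); gx along x (columns),
# gy along y (rows, increasing downward)
sobel_gradient <- function(img) {
  gx <- conv_separable(img, c(1, 2, 1), c(-1, 0, 1))
  gy <- conv_separable(img, c(-1, 0, 1), c(1, 2, 1))
  list(gx = gx, gy = gy)
}

#' Canny edge detection
#'
#' Standard Canny chain: Gaussian smoothing, Sobel 3x3 gradient,
#' non-maximum suppression along the quantized gradient direction, and
#' hysteresis thresholding with 8-connected linking. Thresholds apply to
#' the raw (unnormalized) Sobel gradient magnitude of a 0-255 image;
#' with `normalized = TRUE` they are instead fractions of the maximum
#' gradient magnitude.
#'
#' @param img numeric image matrix (0-255 scale).
#' @param sigma Gaussian smoothing standard deviation (default 1.3).
#' @param t_low,t_high hysteresis thresholds, `t_low < t_high`
#'   (defaults 10 and 30).
#' @param normalized interpret thresholds as fractions of the maximum
#'   gradient magnitude instead of raw values.
#' @return 0/1 integer matrix of edge pixels, same shape as `img`.
#' @export
canny_edges <- function(img, sigma = 1.3, t_low = 10.0, t_high = 30.0,
                        normalized = FALSE) {
  assert_gray_image(img)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (t_low >= t_high) stop("t_low must be < t_high", call. = FALSE)
  sm <- gaussian_blur(img, sigma)
  g <- sobel_gradient(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  # quantize so NMS tie-breaking is immune to last-ulp noise (keeps the
  # output invariant under constant intensity shifts)
  mag <- round(mag * 1e6) / 1e6
  h <- nrow(mag); w <- ncol(mag)
  if (normalized) {
    mx <- max(mag)
    t_low <- t_low * mx
    t_high <- t_high * mx
  }

  # quantize gradient direction into 4 bins (0, 45, 90, 135 degrees)
  ang <- atan2(g$gy, g$gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  bin <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L

  shift0 <- function(m, dy, dx) {
    out <- matrix(0, h, w)
    ys <- max(1L, 1L - dy):min(h, h - dy)
    xs <- max(1L, 1L - dx):min(w, w - dx)
    out[ys, xs] <- m[ys + dy, xs + dx]
    out
  }
  # neighbor offsets along the gradient direction per bin:
  # bin 0 -> horizontal gradient, compare left/right pixels, etc.
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- matrix(FALSE, h, w)
  for (b in 0:3) {
    o <- offs[[b + 1L]]
    sel <- bin == b
    # strict on the positive direction so plateau ties keep one pixel
    ok <- mag > shift0(mag, o[1], o[2]) & mag >= shift0(mag, -o[1], -o[2])
    keep[sel & ok] <- TRUE
  }
  weak <- keep & mag >= t_low
  strong <- keep & mag >= t_high

  # hysteresis: grow strong set through 8-connected weak pixels
  cur <- strong
  repeat {
    grown <- cur
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      grown <- grown | shift0(cur, dy, dx)
    }
    grown <- grown & weak
    if (all(grown == cur)) break
    cur <- grown
  }
  mode(cur) <- "integer"
  cur
}

# exact 1-D squared distance transform (lower envelope of parabolas);
# f may contain Inf (no site); returns squared distances
dt1d_squared <- function(f) {
  n <- length(f)
  d <- rep(Inf, n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 0L
  for (q in seq_len(n)) {
    if (!is.finite(f[q])) next
    if (k == 0L) {
      k <- 1L; v[1L] <- q; z[1L] <- -Inf; z[2L] <- Inf
      next
    }
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (s <= z[k]) {
        k <- k - 1L
        if (k == 0L) { s <- -Inf; break }
      } else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  if (k == 0L) return(d)
  j <- 1L
  for (q in seq_len(n)) {
    while (z[j + 1L] < q) j <- j + 1L
    d[q] <- (q - v[j])^2 + f[v[j]]
  }
  d
}

#' Exact Euclidean distance map of an edge image
#'
#' Computes, for every pixel, the exact Euclidean distance from its
#' center to the nearest edge-pixel center (the classic two-pass
#' separable parabolic-envelope transform). Far from the object the map
#' takes high values, and it is exactly zero on edge pixels, which makes
#' it the potential surface whose minima trace the object boundary.
#'
#' @param edges 0/1 matrix of edge pixels.
#' @return numeric matrix of distances (pixel units). If `edges` has no
#'   edge pixel, every value is `Inf` and a warning is emitted.
#' @export
euclidean_distance_map <- function(edges) {
  if (!is.matrix(edges)) stop("edges must be a matrix", call. = FALSE)
  h <- nrow(edges); w <- ncol(edges)
  if (!any(edges > 0)) {
    warning("edge map has no edge pixels; distance map is infinite")
    return(matrix(Inf, h, w))
  }
  # pass 1 (vectorized over columns): squared distance to the nearest
  # edge within each column
  d <- matrix(Inf, h, w)
  d[edges > 0] <- 0
  if (h > 1L) {
    for (i in 2:h) d[i, ] <- pmin(d[i, ], d[i - 1L, ] + 1)
    for (i in (h - 1L):1L) d[i, ] <- pmin(d[i, ], d[i + 1L, ] + 1)
  }
  d <- d^2
  # pass 2: 1-D parabolic envelope along each row
  for (i in seq_len(h)) d[i, ] <- dt1d_squared(d[i, ])
  sqrt(d)
}

#' Bilinear sampling of a map at continuous coordinates
#'
#' Interpolates the four pixel values surrounding a continuous position;
#' at integer coordinates the pixel value is returned exactly.
#' Coordinates are 0-based with `x` the column (see package coordinate
#' conventions).
#'
#' @param map numeric matrix.
#' @param x,y numeric vectors of coordinates, `0 <= x <= ncol-1`,
#'   `0 <= y <= nrow-1`.
#' @return numeric vector of interpolated values.
#' @export
sample_map <- function(map, x, y) {
  h <- nrow(map); w <- ncol(map)
  if (any(x < 0 | x > w - 1 | y < 0 | y > h - 1, na.rm = TRUE) ||
      any(!is.finite(x)) || any(!is.finite(y)))
    stop("sample coordinates outside image bounds", call. = FALSE)
  x0 <- pmin(floor(x), w - 2)
  y0 <- pmin(floor(y), h - 2)
  if (w == 1L) x0 <- rep(0, length(x))
  if (h == 1L) y0 <- rep(0, length(y))
  fx <- x - x0
  fy <- y - y0
  i0 <- y0 + 1L; j0 <- x0 + 1L
  i1 <- pmin(i0 + 1L, h); j1 <- pmin(j0 + 1L, w)
  v00 <- map[cbind(i0, j0)]; v01 <- map[cbind(i0, j1)]
  v10 <- map[cbind(i1, j0)]; v11 <- map[cbind(i1, j1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Run the full preprocessing chain
#'
#' Median filter, Canny edge detection and Euclidean distance map, in
#' that order, with the package defaults (3x3 median; Canny sigma 1.3,
#' hysteresis thresholds 10 and 30 on the raw Sobel magnitude).
#'
#' @param img numeric image matrix.
#' @param median_window odd median window size (default 3).
#' @param sigma,t_low,t_high Canny parameters.
#' @param normalized see [canny_edges()].
#' @return list with elements `smoothed`, `edges`, `distance`.
#' @export
preprocess_image <- function(img, median_window = 3L, sigma = 1.3,
                             t_low = 10.0, t_high = 30.0,
                             normalized = FALSE) {
  sm <- median_filter(img, median_window)
  edges <- canny_edges(sm, sigma = sigma, t_low = t_low, t_high = t_high,
                       normalized = normalized)
  dist <- if (any(edges > 0)) euclidean_distance_map(edges) else {
    warning("edge map has no edge pixels; distance map is infinite")
    matrix(Inf, nrow(img), ncol(img))
  }
  list(smoothed = sm, edges = edges, distance = dist)
}
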