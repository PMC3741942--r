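# Validation metrics on binary masks and point sets: Jaccard and Dice
# region overlap, Hausdorff boundary distance, plus the even-odd
# polygon rasterizer that turns contours into masks.

#' Rasterize a closed contour into a binary mask
#'
#' Even-odd (crossing-number) fill over 0-based pixel centers; pixels
#' whose center lies exactly on the polygon boundary count as inside.
#' Self-intersecting polygons are filled by the same even-odd rule
#' after a warning; zero-area (degenerate) contours warn and produce an
#' empty mask.
#'
#' @param contour data frame with `x`, `y` (0-based pixel coordinates),
#'   at least 3 points, implicitly closed.
#' @param shape `c(height, width)` of the target mask.
#' @return 0/1 integer matrix.
#' @export
rasterize_contour <- function(contour, shape) {
  xs <- contour$x; ys <- contour$y
  n <- length(xs)
  if (n < 3L) stop("contour needs at least 3 points", call. = FALSE)
  h <- shape[1L]; w <- shape[2L]
  x_next <- c(xs[-1L], xs[1L]); y_next <- c(ys[-1L], ys[1L])
  area2 <- sum(xs * y_next - x_next * ys)  # shoelace, twice the area
  if (abs(area2) < 1e-12) {
    warning("contour has zero area; returning an empty mask")
    return(matrix(0L, h, w))
  }
  if (polygon_self_intersects(xs, ys))
    warning("contour is self-intersecting; applying even-odd fill")
  px <- rep(0:(w - 1L), each = h)
  py <- rep(0:(h - 1L), times = w)
  inside <- rep(FALSE, h * w)
  on_edge <- rep(FALSE, h * w)
  x2 <- c(xs[-1L], xs[1L]); y2 <- c(ys[-1L], ys[1L])
  eps <- 1e-9
  for (k in seq_len(n)) {
    ax <- xs[k]; ay <- ys[k]; bx <- x2[k]; by <- y2[k]
    crosses <- (ay > py) != (by > py)
    if (any(crosses)) {
      xi <- ax + (py[crosses] - ay) / (by - ay) * (bx - ax)
      hit <- inside[crosses]
      flip <- px[crosses] < xi
      inside[crosses] <- xor(hit, flip)
    }
    # centers exactly on the segment
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    if (len2 < eps) {
      on_edge <- on_edge | (abs(px - ax) < eps & abs(py - ay) < eps)
    } else {
      t <- ((px - ax) * dx + (py - ay) * dy) / len2
      cross <- (px - ax) * dy - (py - ay) * dx
      on_edge <- on_edge |
        (t >= -eps & t <= 1 + eps & abs(cross) < eps * sqrt(len2) * 1e3)
    }
  }
  m <- matrix(0L, h, w)
  m[cbind(py + 1L, px + 1L)[inside | on_edge, , drop = FALSE]] <- 1L
  m
}

# O(n^2) proper-crossing test between non-adjacent edges
polygon_self_intersects <- function(xs, ys) {
  n <- length(xs)
  if (n < 4L) return(FALSE)
  x2 <- c(xs[-1L], xs[1L]); y2 <- c(ys[-1L], ys[1L])
  seg_cross <- function(i, j) {
    d1 <- (x2[i] - xs[i]) * (ys[j] - ys[i]) -
      (y2[i] - ys[i]) * (xs[j] - xs[i])
    d2 <- (x2[i] - xs[i]) * (y2[j] - ys[i]) -
      (y2[i] - ys[i]) * (x2[j] - xs[i])
    d3 <- (x2[j] - xs[j]) * (ys[i] - ys[j]) -
      (y2[j] - ys[j]) * (xs[i] - xs[j])
    d4 <- (x2[j] - xs[j]) * (y2[i] - ys[j]) -
      (y2[j] - ys[j]) * (x2[i] - xs[j])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent around the wrap
      if (seg_cross(i, j)) return(TRUE)
    }
  }
  FALSE
}

check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("masks must have the same shape", call. = FALSE)
}

#' Jaccard index of two binary masks
#'
#' `|A intersect B| / |A union B|`; completely superimposed regions
#' score 1, completely different regions score 0. Two empty masks
#' score 1 by convention.
#'
#' @param a,b 0/1 matrices of equal shape.
#' @return scalar in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  check_same_shape(a, b)
  ai <- a > 0; bi <- b > 0
  u <- sum(ai | bi)
  if (u == 0) return(1)
  sum(ai & bi) / u
}

#' Dice index of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; equals `2J / (1 + J)` with `J`
#' the Jaccard index. Two empty masks score 1 by convention.
#'
#' @param a,b 0/1 matrices of equal shape.
#' @return scalar in \[0, 1\].
#' @export
dice_index <- function(a, b) {
  check_same_shape(a, b)
  ai <- a > 0; bi <- b > 0
  s <- sum(ai) + sum(bi)
  if (s == 0) return(1)
  2 * sum(ai & bi) / s
}

#' Boundary pixel coordinates of a mask
#'
#' Mask pixels with at least one of their 8 neighbors outside the mask
#' (image-border pixels count as boundary).
#'
#' @param mask 0/1 matrix.
#' @return two-column matrix of `(x, y)` 0-based coordinates.
#' @export
mask_boundary <- function(mask) {
  m <- mask > 0
  h <- nrow(m); w <- ncol(m)
  p <- matrix(FALSE, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  all_nb <- p[2:(h + 1L), 2:(w + 1L)]
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    all_nb <- all_nb & p[(2:(h + 1L)) + dy, (2:(w + 1L)) + dx]
  }
  bnd <- m & !all_nb
  idx <- which(bnd, arr.ind = TRUE)
  cbind(x = idx[, 2L] - 1L, y = idx[, 1L] - 1L)
}

#' Hausdorff distance between two point sets or masks
#'
#' Directed mode: `max over a in A of min over b in B of ||a - b||`
#' (Euclidean). Symmetric mode takes the maximum of both directions.
#' Mask inputs are reduced to their 8-connected boundary pixels first.
#'
#' @param a,b two-column `(x, y)` matrices of points, or 0/1 mask
#'   matrices.
#' @param mode `"directed"` (default) or `"symmetric"`.
#' @return scalar distance in pixel units.
#' @export
hausdorff_distance <- function(a, b, mode = c("directed", "symmetric")) {
  mode <- match.arg(mode)
  # two-column matrices are point sets; anything else is a binary mask
  as_points <- function(m) {
    if (!is.matrix(m))
      stop("inputs must be point matrices or binary masks", call. = FALSE)
    if (ncol(m) == 2L) m else mask_boundary(m)
  }
  pa <- as_points(a); pb <- as_points(b)
  if (nrow(pa) == 0L || nrow(pb) == 0L)
    stop("Hausdorff distance needs nonempty point sets", call. = FALSE)
  directed <- function(p, q) {
    # min over q for each p, computed blockwise
    d2 <- outer(p[, 1L], q[, 1L], "-")^2 + outer(p[, 2L], q[, 2L], "-")^2
    max(sqrt(apply(d2, 1L, min)))
  }
  if (mode == "directed") directed(pa, pb)
  else max(directed(pa, pb), directed(pb, pa))
}

#' Evaluate a predicted mask against a reference mask
#'
#' @param pred,ref 0/1 matrices of equal shape.
#' @return list with `jaccard`, `dice`, `hausdorff_directed`,
#'   `hausdorff_symmetric`.
#' @export
evaluate_masks <- function(pred, ref) {
  check_same_shape(pred, ref)
  hd <- if (any(pred > 0) && any(ref > 0)) {
    bp <- mask_boundary(pred); br <- mask_boundary(ref)
    c(hausdorff_distance(bp, br, "directed"),
      hausdorff_distance(bp, br, "symmetric"))
  } else c(NA_real_, NA_real_)
  list(jaccard = jaccard_index(pred, ref),
       dice = dice_index(pred, ref),
       hausdorff_directed = hd[1L],
       hausdorff_symmetric = hd[2L])
}
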