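# Independent oracles used by the property tests. These deliberately
# use naive algorithms (full scans, double loops, per-pixel tests) so
# they stay independent of the package implementations they check.

# exact distance map by scanning every edge pixel for every pixel
brute_force_edt <- function(edges) {
  h <- nrow(edges); w <- ncol(edges)
  sites <- which(edges > 0, arr.ind = TRUE)
  out <- matrix(Inf, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      out[i, j] <- sqrt(min((i - sites[, 1])^2 + (j - sites[, 2])^2))
    }
  }
  out
}

# directed Hausdorff by explicit double loop
brute_force_hausdorff <- function(a, b) {
  worst <- 0
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (d < best) best <- d
    }
    if (best > worst) worst <- best
  }
  worst
}

# even-odd point-in-polygon test for a single point
point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py)) {
      xi <- xs[i] + (py - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
      if (px < xi) inside <- !inside
    }
    j <- i
  }
  inside
}

# exact disk mask on 0-based pixel centers
disk_truth <- function(shape, center, radius) {
  h <- shape[1]; w <- shape[2]
  dx <- matrix(rep(0:(w - 1), each = h), h, w) - center[1]
  dy <- matrix(rep(0:(h - 1), times = w), h, w) - center[2]
  (dx^2 + dy^2 <= radius^2) * 1L
}

# 4-connected reachability from one mask pixel (iterative dilation)
connected_component_4 <- function(mask, start_rc) {
  h <- nrow(mask); w <- ncol(mask)
  cur <- matrix(FALSE, h, w)
  cur[start_rc[1], start_rc[2]] <- TRUE
  m <- mask > 0
  shift <- function(x, dy, dx) {
    out <- matrix(FALSE, h, w)
    ys <- max(1, 1 - dy):min(h, h - dy)
    xs <- max(1, 1 - dx):min(w, w - dx)
    out[ys, xs] <- x[ys + dy, xs + dx]
    out
  }
  repeat {
    grown <- cur | shift(cur, 1, 0) | shift(cur, -1, 0) |
      shift(cur, 0, 1) | shift(cur, 0, -1)
    grown <- grown & m
    if (all(grown == cur)) break
    cur <- grown
  }
  cur
}

# clean ring edge map at radius rho around a seed, plus a preprocessing
# list usable as the `pre` argument of run_macde
ring_pre <- function(shape, seed, rho) {
  th <- seq(0, 2 * pi, length.out = 8L * ceiling(2 * pi * rho))
  edges <- matrix(0L, shape[1], shape[2])
  edges[cbind(round(seed[2] + rho * sin(th)) + 1,
              round(seed[1] + rho * cos(th)) + 1)] <- 1L
  list(smoothed = matrix(0, shape[1], shape[2]), edges = edges,
       distance = euclidean_distance_map(edges))
}
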