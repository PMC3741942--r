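# Classical active contour (snake) with greedy window search. Each
# control point is moved within a small square window to the candidate
# with lowest local energy; the candidate score includes the terms of
# the neighboring points that depend on the moved point, so the total
# snake energy is non-increasing across sweeps by construction.

#' Snake parameters
#'
#' @param alpha tension weight on the squared first difference
#'   (default 0.01).
#' @param beta rigidity weight on the squared second difference
#'   (default 0.9).
#' @param gamma external-energy weight (default 0.05).
#' @param window_half half-width of the square search window; the
#'   window has `(2 * window_half + 1)^2` integer-offset candidates
#'   (default 2, i.e. 5x5).
#' @param max_iters maximum number of greedy sweeps (default 200).
#' @param smooth_sigma Gaussian smoothing applied to the image before
#'   taking the gradient in gradient mode; 0 (default) uses the raw
#'   image gradient as in the classical formulation.
#' @return an object of class `snake_params`.
#' @export
snake_params <- function(alpha = 0.01, beta = 0.9, gamma = 0.05,
                         window_half = 2L, max_iters = 200L,
                         smooth_sigma = 0) {
  if (alpha < 0 || beta < 0 || gamma < 0)
    stop("alpha, beta and gamma must be nonnegative", call. = FALSE)
  if (alpha == 0 && beta == 0 && gamma == 0)
    stop("alpha, beta and gamma cannot all be zero", call. = FALSE)
  window_half <- as.integer(window_half)
  if (is.na(window_half) || window_half < 1L)
    stop("window_half must be a positive integer", call. = FALSE)
  max_iters <- as.integer(max_iters)
  if (is.na(max_iters) || max_iters < 1L)
    stop("max_iters must be a positive integer", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 window_half = window_half, max_iters = max_iters,
                 smooth_sigma = smooth_sigma),
            class = "snake_params")
}

#' Discrete internal snake energy at a candidate position
#'
#' `0.5 * (alpha * |q - prev|^2 + beta * |prev - 2q + next|^2)` with
#' squared Euclidean norms: tension penalizes stretch relative to the
#' previous point, rigidity penalizes the discrete curvature.
#'
#' @param prev,cand,nxt length-2 numeric `(x, y)` positions; `cand` is
#'   the candidate for the current control point.
#' @param params a [snake_params()].
#' @return scalar energy.
#' @export
internal_energy <- function(prev, cand, nxt, params) {
  if (!all(is.finite(c(prev, cand, nxt))))
    stop("points must be finite", call. = FALSE)
  d1 <- cand - prev
  d2 <- prev - 2 * cand + nxt
  0.5 * (params$alpha * sum(d1^2) + params$beta * sum(d2^2))
}

#' External snake energy at a position
#'
#' In `gradient` mode returns `-(gamma / 2) |grad I|^2` with the
#' central-difference gradient of the (optionally smoothed) image; in
#' `edm` mode returns `gamma * D(pos)`, the bilinearly sampled distance
#' map. Both are minimized: the gradient form is lowest on strong
#' edges, the distance form is zero on them.
#'
#' @param map_or_img distance map (`edm` mode) or grayscale image
#'   (`gradient` mode).
#' @param pos length-2 `(x, y)` position (0-based).
#' @param params a [snake_params()].
#' @param mode `"gradient"` or `"edm"`.
#' @return scalar energy.
#' @export
external_energy <- function(map_or_img, pos, params,
                            mode = c("gradient", "edm")) {
  mode <- match.arg(mode)
  if (mode == "edm") {
    params$gamma * sample_map(map_or_img, pos[1L], pos[2L])
  } else {
    gm2 <- gradient_sq_mag(map_or_img, params$smooth_sigma)
    -(params$gamma / 2) * sample_map(gm2, pos[1L], pos[2L])
  }
}

# squared central-difference gradient magnitude of the (smoothed) image
gradient_sq_mag <- function(img, smooth_sigma = 0) {
  sm <- gaussian_blur(img, smooth_sigma)
  h <- nrow(sm); w <- ncol(sm)
  ix <- c(1L, seq_len(w - 1L)); ixp <- c(2:w, w)
  iy <- c(1L, seq_len(h - 1L)); iyp <- c(2:h, h)
  gx <- (sm[, ixp, drop = FALSE] - sm[, ix, drop = FALSE]) / 2
  gy <- (sm[iyp, , drop = FALSE] - sm[iy, , drop = FALSE]) / 2
  gx^2 + gy^2
}

#' Initialize a circular snake
#'
#' @param center length-2 `(x, y)` center.
#' @param radius circle radius in pixels.
#' @param n number of control points (default 42).
#' @return data frame with `x` and `y`, ordered by angle.
#' @export
init_circle_contour <- function(center, radius, n = 42L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  data.frame(x = center[1L] + radius * cos(th),
             y = center[2L] + radius * sin(th))
}

#' Greedy snake minimization
#'
#' Sweeps the contour in fixed index order; each control point is moved
#' to the integer-offset candidate in its `(2 window_half + 1)^2`
#' window that minimizes its local energy (tension and rigidity
#' relative to the current neighbors, plus the external term). Stops
#' when a sweep moves no point or after `max_iters` sweeps, and logs
#' the total snake energy (the sum of the per-point local minima) after
#' every sweep.
#'
#' @param contour data frame with `x`, `y` (0-based, inside the image).
#' @param external numeric matrix of external energy per pixel
#'   (already weighted; sampled bilinearly at candidates). Use
#'   [external_energy_map()] to build one.
#' @param params a [snake_params()].
#' @return list with `contour` (same row count), `energy` (total snake
#'   energy after each sweep, non-increasing), and `sweeps`.
#' @export
greedy_minimize <- function(contour, external, params = snake_params()) {
  px <- contour$x; py <- contour$y
  n <- length(px)
  h <- nrow(external); w <- ncol(external)
  if (any(px < 0 | px > w - 1 | py < 0 | py > h - 1))
    stop("contour lies outside the image", call. = FALSE)
  wh <- params$window_half
  offs <- expand.grid(dx = -wh:wh, dy = -wh:wh)

  idx <- function(i) ((i - 1L) %% n) + 1L
  point_energy <- function(i, qx, qy) {
    # local energy of point i at candidate q: tension + rigidity
    # relative to the current neighbors, plus the external term
    pm1x <- px[idx(i - 1L)]; pm1y <- py[idx(i - 1L)]
    pp1x <- px[idx(i + 1L)]; pp1y <- py[idx(i + 1L)]
    0.5 * params$alpha * ((qx - pm1x)^2 + (qy - pm1y)^2) +
      0.5 * params$beta * ((pm1x - 2 * qx + pp1x)^2 +
                             (pm1y - 2 * qy + pp1y)^2) +
      sample_map(external, qx, qy)
  }

  total_energy <- function() {
    tot <- 0
    for (i in seq_len(n)) {
      tot <- tot + internal_energy(c(px[idx(i - 1L)], py[idx(i - 1L)]),
                                   c(px[i], py[i]),
                                   c(px[idx(i + 1L)], py[idx(i + 1L)]),
                                   params) +
        sample_map(external, px[i], py[i])
    }
    tot
  }

  energy_log <- numeric(0)
  for (sweep in seq_len(params$max_iters)) {
    moved <- FALSE
    for (i in seq_len(n)) {
      qx <- px[i] + offs$dx
      qy <- py[i] + offs$dy
      ok <- qx >= 0 & qx <= w - 1 & qy >= 0 & qy <= h - 1
      if (!any(ok)) next
      e <- rep(Inf, nrow(offs))
      e[ok] <- point_energy(i, qx[ok], qy[ok])
      cur <- point_energy(i, px[i], py[i])
      k <- which.min(e)
      if (e[k] < cur - 1e-12) {
        px[i] <- qx[k]
        py[i] <- qy[k]
        moved <- TRUE
      }
    }
    energy_log <- c(energy_log, total_energy())
    if (!moved) break
  }
  list(contour = data.frame(x = px, y = py), energy = energy_log,
       sweeps = length(energy_log))
}

#' Build the per-pixel external energy map for the greedy snake
#'
#' @param img grayscale image (used in `gradient` mode).
#' @param distance distance map (used in `edm` mode).
#' @param params a [snake_params()].
#' @param mode `"gradient"` or `"edm"`.
#' @return numeric matrix of external energies to be minimized.
#' @export
external_energy_map <- function(img = NULL, distance = NULL,
                                params = snake_params(),
                                mode = c("gradient", "edm")) {
  mode <- match.arg(mode)
  if (mode == "gradient") {
    if (is.null(img)) stop("gradient mode needs the image", call. = FALSE)
    -(params$gamma / 2) * gradient_sq_mag(img, params$smooth_sigma)
  } else {
    if (is.null(distance)) stop("edm mode needs the distance map",
                                call. = FALSE)
    params$gamma * distance
  }
}

#' Segment an image with the classical greedy snake
#'
#' Convenience wrapper: builds the external energy map and runs
#' [greedy_minimize()] from a circular initialization.
#'
#' @param img grayscale image matrix.
#' @param center `(x, y)` circle center for the initial contour.
#' @param radius initial circle radius.
#' @param n_points number of control points (default 42).
#' @param params a [snake_params()].
#' @param mode external energy mode, `"gradient"` (default) or `"edm"`.
#' @param distance distance map, required for `edm` mode.
#' @return the [greedy_minimize()] result.
#' @export
run_acm <- function(img, center, radius, n_points = 42L,
                    params = snake_params(),
                    mode = c("gradient", "edm"), distance = NULL) {
  mode <- match.arg(mode)
  ext <- external_energy_map(img = img, distance = distance,
                             params = params, mode = mode)
  contour <- init_circle_contour(center, radius, n_points)
  greedy_minimize(contour, ext, params)
}
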