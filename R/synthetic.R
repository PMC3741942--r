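# Synthetic phantoms with exact ground-truth masks: a star with deep
# concavities, a disk with additive Gaussian noise, a multi-lobed
# concave object, and smoothly drifting stacks emulating sequential
# slice studies. Every phantom is star-convex about its center, so a
# single boundary point exists on every polar ray from the center --
# the geometric assumption behind one-snaxel-per-section segmentation.

phantom_center <- function(size) c((size[2L] - 1) / 2, (size[1L] - 1) / 2)

disk_mask <- function(size, center, radius) {
  h <- size[1L]; w <- size[2L]
  dx <- matrix(rep(0:(w - 1L), each = h), h, w) - center[1L]
  dy <- matrix(rep(0:(h - 1L), times = w), h, w) - center[2L]
  (dx * dx + dy * dy <= radius * radius) * 1L
}

paint <- function(mask, fg, bg) bg + (fg - bg) * (mask > 0)

#' Star phantom with deep concavities
#'
#' A filled regular star polygon (alternating outer and inner vertices)
#' centered in the image; the mask is the exact even-odd rasterization
#' of the analytic polygon.
#'
#' @param size `c(height, width)`, default `c(160, 160)`.
#' @param n_points number of star points (default 5).
#' @param r_outer,r_inner outer and inner vertex radii in pixels
#'   (defaults 60 and 25; `r_inner < r_outer`).
#' @param fg,bg foreground and background intensities (defaults 200, 0).
#' @return list with `image`, `mask`, `center`, `vertices` (the star
#'   polygon as a data frame), and `spec`.
#' @export
make_star <- function(size = c(160L, 160L), n_points = 5L,
                      r_outer = 60, r_inner = 25, fg = 200, bg = 0) {
  if (n_points < 3L) stop("n_points must be >= 3", call. = FALSE)
  if (r_inner > r_outer)
    stop("r_inner must not exceed r_outer", call. = FALSE)
  ctr <- phantom_center(size)
  if (r_outer > min(ctr, size[1L] - 1 - ctr[2L], size[2L] - 1 - ctr[1L]) - 5)
    stop("star does not fit inside the image with a 5 px margin",
         call. = FALSE)
  k <- 2L * n_points
  ang <- -pi / 2 + (seq_len(k) - 1L) * pi / n_points
  rad <- rep(c(r_outer, r_inner), n_points)
  verts <- data.frame(x = ctr[1L] + rad * cos(ang),
                      y = ctr[2L] + rad * sin(ang))
  mask <- rasterize_contour(verts, size)
  list(image = paint(mask, fg, bg), mask = mask, center = ctr,
       vertices = verts,
       spec = list(kind = "star", size = size, n_points = n_points,
                   r_outer = r_outer, r_inner = r_inner,
                   fg = fg, bg = bg))
}

#' Disk phantom with additive Gaussian noise
#'
#' A filled disk with zero-mean Gaussian noise of standard deviation
#' `noise_sigma` on the normalized \[0, 1\] intensity scale (the image
#' is rescaled to 0-255 and clipped). The ground-truth mask is the
#' exact noiseless disk; noise never alters it.
#'
#' @param size `c(height, width)`, default `c(300, 300)`.
#' @param radius disk radius in pixels (default 100).
#' @param noise_sigma noise standard deviation on \[0, 1\]
#'   (default 0.04).
#' @param fg,bg intensities (defaults 200, 0).
#' @param seed RNG seed for the noise (default 1); same seed, same
#'   image.
#' @return list with `image`, `mask`, `center`, and `spec`.
#' @export
make_noisy_circle <- function(size = c(300L, 300L), radius = 100,
                              noise_sigma = 0.04, fg = 200, bg = 0,
                              seed = 1L) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  ctr <- phantom_center(size)
  if (radius > min(size) / 2 - 5)
    stop("disk does not fit inside the image with a 5 px margin",
         call. = FALSE)
  mask <- disk_mask(size, ctr, radius)
  img <- paint(mask, fg, bg)
  if (noise_sigma > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    noise <- matrix(stats::rnorm(prod(size), 0, noise_sigma),
                    size[1L], size[2L])
    img <- pmin(pmax(img / 255 + noise, 0), 1) * 255
  }
  list(image = img, mask = mask, center = ctr,
       spec = list(kind = "noisy_circle", size = size, radius = radius,
                   noise_sigma = noise_sigma, fg = fg, bg = bg,
                   seed = as.integer(seed)))
}

#' Multi-lobed concave phantom
#'
#' The union of overlapping disks, each containing the common anchor
#' point, so the union is connected and star-convex about the anchor
#' while its boundary has a concavity between every pair of adjacent
#' lobes.
#'
#' @param size `c(height, width)`, default `c(150, 150)`.
#' @param lobes data frame with columns `angle_deg`, `dist`, `radius`:
#'   each lobe is a disk of `radius` centered `dist` pixels from the
#'   image center along `angle_deg`. Every lobe must satisfy
#'   `dist < radius` (anchor inside every disk). Default: three lobes
#'   of radius 35 at distance 20 along 0, 120 and 240 degrees.
#' @param fg,bg intensities (defaults 200, 0).
#' @return list with `image`, `mask`, `center`, and `spec`.
#' @export
make_concave_blob <- function(size = c(150L, 150L),
                              lobes = data.frame(
                                angle_deg = c(0, 120, 240),
                                dist = 20, radius = 35),
                              fg = 200, bg = 0) {
  if (nrow(lobes) < 2L) stop("need at least 2 lobes", call. = FALSE)
  if (any(lobes$dist >= lobes$radius))
    stop(paste("every lobe must contain the center (dist < radius)",
               "so the union stays connected and star-convex"),
         call. = FALSE)
  ctr <- phantom_center(size)
  if (any(lobes$dist + lobes$radius > min(size) / 2 - 5))
    stop("lobes do not fit inside the image with a 5 px margin",
         call. = FALSE)
  mask <- matrix(0L, size[1L], size[2L])
  for (k in seq_len(nrow(lobes))) {
    a <- lobes$angle_deg[k] * pi / 180
    c_k <- ctr + lobes$dist[k] * c(cos(a), sin(a))
    mask <- pmax(mask, disk_mask(size, c_k, lobes$radius[k]))
  }
  list(image = paint(mask, fg, bg), mask = mask, center = ctr,
       spec = list(kind = "concave_blob", size = size, lobes = lobes,
                   fg = fg, bg = bg))
}

#' Plain (noise-free) disk phantom
#'
#' @param size `c(height, width)`.
#' @param radius disk radius.
#' @param fg,bg intensities.
#' @return list with `image`, `mask`, `center`, and `spec`.
#' @export
make_plain_circle <- function(size = c(200L, 200L), radius = 60,
                              fg = 200, bg = 0) {
  make_noisy_circle(size = size, radius = radius, noise_sigma = 0,
                    fg = fg, bg = bg)
}

#' Sequential phantom stack with smooth drift
#'
#' Emulates a stack of sequential slices: the base phantom is
#' regenerated per slice with its linear dimensions scaled and its
#' center shifted by per-slice increments. One shared seed point (the
#' base center) must stay inside the region of every slice.
#'
#' @param kind `"star"`, `"noisy_circle"`, `"concave_blob"` or
#'   `"plain_circle"`.
#' @param n_slices number of slices (default 18).
#' @param scale_step multiplicative size change per slice (e.g. -0.02
#'   shrinks every slice by 2% of the base size; default -0.02).
#' @param center_step `(dx, dy)` center drift per slice (default
#'   `c(0, 0)`).
#' @param ... parameters passed to the base phantom generator; the
#'   noisy circle's `seed` is offset per slice.
#' @return list of per-slice phantom lists, with the shared seed point
#'   attached as attribute `seed_point`.
#' @export
make_stack <- function(kind = c("plain_circle", "star", "noisy_circle",
                                "concave_blob"),
                       n_slices = 18L, scale_step = -0.02,
                       center_step = c(0, 0), ...) {
  kind <- match.arg(kind)
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L) stop("n_slices must be >= 1", call. = FALSE)
  dots <- list(...)
  slices <- vector("list", n_slices)
  base_center <- NULL
  for (s in seq_len(n_slices)) {
    sc <- 1 + (s - 1L) * scale_step
    if (sc <= 0) stop("scale_step shrinks slices to nothing",
                      call. = FALSE)
    args <- dots
    ph <- switch(kind,
      plain_circle = {
        args$radius <- (if (is.null(dots$radius)) 60 else dots$radius) * sc
        do.call(make_plain_circle, args)
      },
      noisy_circle = {
        args$radius <- (if (is.null(dots$radius)) 100 else dots$radius) * sc
        args$seed <- (if (is.null(dots$seed)) 1L else dots$seed) + s - 1L
        do.call(make_noisy_circle, args)
      },
      star = {
        args$r_outer <- (if (is.null(dots$r_outer)) 60 else dots$r_outer) * sc
        args$r_inner <- (if (is.null(dots$r_inner)) 25 else dots$r_inner) * sc
        do.call(make_star, args)
      },
      concave_blob = {
        lob <- if (is.null(dots$lobes))
          data.frame(angle_deg = c(0, 120, 240), dist = 20, radius = 35)
        else dots$lobes
        lob$dist <- lob$dist * sc
        lob$radius <- lob$radius * sc
        args$lobes <- lob
        do.call(make_concave_blob, args)
      })
    if (any(center_step != 0)) {
      sh <- round((s - 1L) * center_step)
      ph$image <- shift_image(ph$image, sh, ph$spec$bg)
      ph$mask <- shift_image(ph$mask, sh, 0L)
      ph$center <- ph$center + sh
    }
    if (is.null(base_center)) base_center <- phantom_center(dim(ph$mask))
    si <- round(base_center) + 1L
    if (ph$mask[si[2L], si[1L]] == 0L)
      stop("drift moved the shared seed point outside slice ", s,
           call. = FALSE)
    slices[[s]] <- ph
  }
  attr(slices, "seed_point") <- round(base_center)
  slices
}

# integer shift of an image with constant fill
shift_image <- function(m, shift, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  dx <- shift[1L]; dy <- shift[2L]
  ys <- max(1L, 1L + dy):min(h, h + dy)
  xs <- max(1L, 1L + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}
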