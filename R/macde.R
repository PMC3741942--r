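# Multiple active contours guided by differential evolution. The search
# domain is split into angular sections around a user seed point; each
# section owns one DE population over polar (r, theta) individuals and
# contributes exactly one optimal snaxel. The fitness is the external
# energy sampled on the Euclidean distance map, so the minima of every
# section lie on the detected object boundary.

#' Build the polar section grid around a seed point
#'
#' Divides the plane around the seed into `floor(360 / dg)` contiguous
#' counterclockwise sections of `dg` degrees starting at the positive
#' x-axis, plus one truncated section when `dg` does not divide 360.
#'
#' @param seed length-2 `(x, y)` seed point, strictly inside the image.
#' @param dg degrees per polar section (default 15).
#' @param r_min,r_max radial search band in pixels; `NULL` picks
#'   `r_min = 0.1 * min(image dim) / 2` and `r_max` the largest radius
#'   whose disk stays inside the image.
#' @param img_shape `c(height, width)` of the image.
#' @return an object of class `polar_grid` with fields `seed`,
#'   `dg`, `n_sections`, `theta_lo`, `theta_hi` (radians), `r_min`,
#'   `r_max`.
#' @export
build_polar_grid <- function(seed, dg = 15, r_min = NULL, r_max = NULL,
                             img_shape) {
  h <- img_shape[1L]; w <- img_shape[2L]
  if (seed[1L] <= 0 || seed[1L] >= w - 1 || seed[2L] <= 0 ||
      seed[2L] >= h - 1)
    stop("seed point must lie strictly inside the image", call. = FALSE)
  if (dg <= 0 || dg > 90)
    stop("dg must yield at least 4 sections (0 < dg <= 90)",
         call. = FALSE)
  inscribed <- min(seed[1L], w - 1 - seed[1L], seed[2L], h - 1 - seed[2L])
  if (is.null(r_min)) r_min <- 0.1 * min(h, w) / 2
  if (is.null(r_max)) r_max <- inscribed
  if (r_min < 0 || r_min >= r_max)
    stop("need 0 <= r_min < r_max", call. = FALSE)
  if (r_max > inscribed + 1e-9)
    stop(sprintf(
      "disk of radius %.3g around the seed leaves the image; largest usable r_max is %.3g",
      r_max, inscribed), call. = FALSE)
  n_full <- floor(360 / dg)
  rem <- 360 - n_full * dg
  n_sections <- n_full + (rem > 1e-9)
  dg_rad <- dg * pi / 180
  theta_lo <- (seq_len(n_sections) - 1L) * dg_rad
  theta_hi <- pmin(seq_len(n_sections) * dg_rad, 2 * pi)
  structure(list(seed = as.numeric(seed), dg = dg,
                 n_sections = as.integer(n_sections),
                 theta_lo = theta_lo, theta_hi = theta_hi,
                 r_min = r_min, r_max = r_max,
                 img_shape = as.integer(img_shape)),
            class = "polar_grid")
}

#' MACDE configuration
#'
#' @param de a [de_config()]; its `np` is overridden by `n_snakes`.
#' @param dg degrees per polar section (default 15).
#' @param n_snakes number of concentric initial contours; equals the
#'   per-section DE population size (default 15, minimum 4).
#' @param r_min,r_max radial band; `NULL` for the
#'   [build_polar_grid()] defaults.
#' @param shape initial contour shape, `"circle"` or `"ellipse"`.
#' @param ellipse_axes `(a, b)` semi-axes used when `shape = "ellipse"`;
#'   radii are scaled by the ellipse's relative radius at each section
#'   midangle.
#' @param fitness_mode `"edm"` (distance-map potential, default) or
#'   `"gradient"`.
#' @param gamma external-energy weight (default 0.05).
#' @param median_window,sigma,t_low,t_high preprocessing parameters
#'   (see [preprocess_image()]).
#' @return an object of class `macde_config`.
#' @export
macde_config <- function(de = de_config(), dg = 15, n_snakes = 15L,
                         r_min = NULL, r_max = NULL,
                         shape = c("circle", "ellipse"),
                         ellipse_axes = NULL,
                         fitness_mode = c("edm", "gradient"),
                         gamma = 0.05, median_window = 3L, sigma = 1.3,
                         t_low = 10.0, t_high = 30.0) {
  shape <- match.arg(shape)
  fitness_mode <- match.arg(fitness_mode)
  n_snakes <- as.integer(n_snakes)
  if (is.na(n_snakes) || n_snakes < 4L)
    stop("n_snakes must be an integer >= 4 (DE population minimum)",
         call. = FALSE)
  if (shape == "ellipse" &&
      (is.null(ellipse_axes) || length(ellipse_axes) != 2L ||
         any(ellipse_axes <= 0)))
    stop("shape = 'ellipse' needs positive ellipse_axes = c(a, b)",
         call. = FALSE)
  de$np <- n_snakes
  structure(list(de = de, dg = dg, n_snakes = n_snakes,
                 r_min = r_min, r_max = r_max, shape = shape,
                 ellipse_axes = ellipse_axes,
                 fitness_mode = fitness_mode, gamma = gamma,
                 median_window = as.integer(median_window),
                 sigma = sigma, t_low = t_low, t_high = t_high),
            class = "macde_config")
}

# relative ellipse radius (<= 1) at angle theta for semi-axes (a, b)
ellipse_scale <- function(theta, axes) {
  a <- axes[1L]; b <- axes[2L]
  r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  r / max(a, b)
}

#' Initialize one DE population per polar section
#'
#' `n_snakes` concentric circles (or ellipses) with radii equally
#' spaced on `[r_min, r_max]`; contour `k` contributes to each section
#' the point at radius `r_k` and the section midangle, so every section
#' population has exactly `n_snakes` (r, theta) individuals spanning
#' the radial band.
#'
#' @param grid a [build_polar_grid()] result.
#' @param config a [macde_config()].
#' @return list of length `n_sections`; each element a list with
#'   `section_index`, `theta_lo`, `theta_hi` and `individuals`
#'   (an `n_snakes` x 2 matrix of `(r, theta)` rows).
#' @export
init_populations <- function(grid, config) {
  radii <- seq(grid$r_min, grid$r_max, length.out = config$n_snakes)
  lapply(seq_len(grid$n_sections), function(i) {
    mid <- (grid$theta_lo[i] + grid$theta_hi[i]) / 2
    r_i <- radii
    if (config$shape == "ellipse")
      r_i <- pmax(radii * ellipse_scale(mid, config$ellipse_axes),
                  grid$r_min)
    list(section_index = i - 1L,
         theta_lo = grid$theta_lo[i], theta_hi = grid$theta_hi[i],
         individuals = cbind(r = r_i, theta = rep(mid, length(r_i))))
  })
}

#' Restrict a trial vector to its polar section
#'
#' Clips the radius to `[r_min, r_max]` and the angle to the section's
#' half-open wedge, so the Cartesian point stays inside the image disk
#' and the one-snaxel-per-section contract holds.
#'
#' @param v length-2 `(r, theta)` vector.
#' @param section one element of [init_populations()].
#' @param grid a [build_polar_grid()] result.
#' @return clipped `(r, theta)` vector.
#' @export
section_repair <- function(v, section, grid) {
  eps <- 1e-9
  c(min(max(v[1L], grid$r_min), grid$r_max),
    min(max(v[2L], section$theta_lo), section$theta_hi - eps))
}

#' Polar-section fitness (external energy)
#'
#' Converts `(r, theta)` to Cartesian coordinates around the seed
#' (`x = seed_x + r cos theta`, `y = seed_y + r sin theta`, y
#' downward) and evaluates the external energy there: in `edm` mode
#' `gamma * D(x, y)` with bilinear sampling of the distance map, in
#' `gradient` mode `-(gamma / 2) |grad I|^2` on the smoothed image.
#' Points falling outside the image score `+Inf`.
#'
#' @param v length-2 `(r, theta)`.
#' @param grid a [build_polar_grid()] result.
#' @param potential numeric matrix: the distance map (`edm`) or the
#'   squared gradient magnitude map (`gradient`).
#' @param config a [macde_config()].
#' @return scalar fitness, minimized.
#' @export
section_fitness <- function(v, grid, potential, config) {
  x <- grid$seed[1L] + v[1L] * cos(v[2L])
  y <- grid$seed[2L] + v[1L] * sin(v[2L])
  h <- nrow(potential); w <- ncol(potential)
  if (x < 0 || x > w - 1 || y < 0 || y > h - 1) return(Inf)
  val <- sample_map(potential, x, y)
  if (config$fitness_mode == "edm") config$gamma * val
  else -(config$gamma / 2) * val
}

#' Segment an image with MACDE
#'
#' Runs the preprocessing chain (median filter, Canny, Euclidean
#' distance map), builds the polar grid and per-section populations,
#' optimizes each section independently with differential evolution
#' under the sectional restriction, and assembles the best individual
#' of every section, ordered by angle, into the closed output contour.
#'
#' @param img grayscale image matrix (0-255).
#' @param seed_point `(x, y)` seed, strictly inside the object.
#' @param config a [macde_config()].
#' @param rng_seed integer master seed; each section's DE run uses a
#'   sub-seed derived from it by a fixed offset, so runs with the same
#'   seed are bitwise reproducible. `NULL` leaves the RNG state alone.
#' @param pre optional precomputed [preprocess_image()] result, to
#'   reuse across repeated runs on the same image.
#' @return list of class `macde_result` with `contour` (data frame
#'   `section,angle_deg,r,x,y,fitness`), `traces` (per-section DE
#'   traces), `fitness_histories`, `grid`, `pre`, and `metadata`
#'   (all parameters plus the master seed).
#' @export
run_macde <- function(img, seed_point, config = macde_config(),
                      rng_seed = NULL, pre = NULL) {
  assert_gray_image(img)
  if (is.null(pre))
    pre <- preprocess_image(img, config$median_window, config$sigma,
                            config$t_low, config$t_high)
  if (!any(pre$edges > 0))
    stop(paste("no edge pixels detected; lower the Canny thresholds",
               "or check the image"), call. = FALSE)
  potential <- if (config$fitness_mode == "edm") pre$distance
  else gradient_sq_mag(pre$smoothed, 0)

  grid <- build_polar_grid(seed_point, config$dg, config$r_min,
                           config$r_max, dim(img))
  sections <- init_populations(grid, config)

  results <- vector("list", grid$n_sections)
  for (i in seq_len(grid$n_sections)) {
    sec <- sections[[i]]
    de_cfg <- config$de
    de_cfg$np <- config$n_snakes
    if (!is.null(rng_seed))
      de_cfg$seed <- (as.integer(rng_seed) %% 1000003L) * 2048L + i
    results[[i]] <- run_de(
      fn = function(v) section_fitness(v, grid, potential, config),
      lower = c(grid$r_min, sec$theta_lo),
      upper = c(grid$r_max, sec$theta_hi),
      config = de_cfg,
      init = sec$individuals,
      repair = function(v) section_repair(v, sec, grid))
  }

  best <- t(vapply(results, function(r) r$best, numeric(2L)))
  fx <- grid$seed[1L] + best[, 1L] * cos(best[, 2L])
  fy <- grid$seed[2L] + best[, 1L] * sin(best[, 2L])
  contour <- data.frame(
    section = seq_len(grid$n_sections) - 1L,
    angle_deg = best[, 2L] * 180 / pi,
    r = best[, 1L], x = fx, y = fy,
    fitness = vapply(results, function(r) r$best_fitness, numeric(1L)))

  metadata <- list(
    method = "macde", dg = config$dg, n_snakes = config$n_snakes,
    n_sections = grid$n_sections, r_min = grid$r_min,
    r_max = grid$r_max, shape = config$shape,
    ellipse_axes = config$ellipse_axes,
    fitness_mode = config$fitness_mode, gamma = config$gamma,
    generations = config$de$generations, F = config$de$f,
    CR = config$de$cr, stability_window = config$de$stability_window,
    median_window = config$median_window, sigma = config$sigma,
    t_low = config$t_low, t_high = config$t_high,
    seed_point = as.numeric(seed_point),
    rng_seed = if (is.null(rng_seed)) NA_integer_ else
      as.integer(rng_seed),
    per_section_best_fitness = contour$fitness)

  structure(list(contour = contour,
                 traces = lapply(results, `[[`, "trace"),
                 fitness_histories = lapply(results, `[[`,
                                            "fitness_history"),
                 grid = grid, pre = pre, metadata = metadata),
            class = "macde_result")
}

#' Mean population fitness across sections per generation
#'
#' Averages the fitness of every individual of every section at each
#' generation, the series used for convergence plots. Sections that
#' early-stopped carry their last fitnesses forward.
#'
#' @param histories list of per-section fitness-history matrices
#'   (rows = generations including generation 0), as returned in
#'   `fitness_histories` by [run_macde()], or a `macde_result`.
#' @return numeric vector indexed by generation (starting at 0).
#' @export
mean_population_fitness <- function(histories) {
  if (inherits(histories, "macde_result"))
    histories <- histories$fitness_histories
  if (!length(histories)) stop("no fitness histories", call. = FALSE)
  g_max <- max(vapply(histories, nrow, integer(1L)))
  sums <- numeric(g_max)
  counts <- numeric(g_max)
  for (h in histories) {
    m <- h
    if (nrow(m) < g_max) {
      last <- m[nrow(m), , drop = FALSE]
      m <- rbind(m, last[rep(1L, g_max - nrow(m)), , drop = FALSE])
    }
    sums <- sums + rowSums(m)
    counts <- counts + ncol(m)
  }
  sums / counts
}
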