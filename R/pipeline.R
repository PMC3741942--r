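# Run orchestration behind the command-line interface: single-image
# segmentation with artifact export, sequential-stack segmentation with
# one shared seed point, and mask/contour evaluation.

#' Segment a single image and optionally write artifacts
#'
#' Runs the preprocessing chain and either MACDE or the classical
#' greedy snake. When `out_dir` is given, writes `contour.csv`,
#' `mask.png`, `overlay.png`, `metadata.json` and `trace.csv` there.
#'
#' @param input image path or numeric matrix.
#' @param seed_x,seed_y seed point (MACDE) or initial-circle center
#'   (ACM), 0-based.
#' @param method `"macde"` (default) or `"acm"`.
#' @param config a [macde_config()] (MACDE).
#' @param acm_params a [snake_params()] (ACM).
#' @param acm_radius initial circle radius for ACM; `NULL` picks 0.9
#'   of the largest inscribed radius at the center.
#' @param acm_points number of ACM control points (default 42).
#' @param acm_mode ACM external mode, `"gradient"` (default) or
#'   `"edm"`.
#' @param rng_seed master RNG seed (default 42).
#' @param out_dir output directory, created if missing; `NULL` skips
#'   writing.
#' @return list with `contour`, `mask`, `metadata`, `result` (the
#'   method result object) and `status` (0 on success).
#' @export
segment_image <- function(input, seed_x, seed_y,
                          method = c("macde", "acm"),
                          config = macde_config(),
                          acm_params = snake_params(),
                          acm_radius = NULL, acm_points = 42L,
                          acm_mode = c("gradient", "edm"),
                          rng_seed = 42L, out_dir = NULL) {
  method <- match.arg(method)
  acm_mode <- match.arg(acm_mode)
  img <- if (is.matrix(input)) input else read_gray_image(input)
  h <- nrow(img); w <- ncol(img)
  if (seed_x <= 0 || seed_x >= w - 1 || seed_y <= 0 || seed_y >= h - 1)
    stop("seed point outside the image", call. = FALSE)

  if (method == "macde") {
    res <- run_macde(img, c(seed_x, seed_y), config, rng_seed = rng_seed)
    contour <- res$contour
    metadata <- res$metadata
    trace <- do.call(rbind, lapply(seq_along(res$traces), function(i) {
      cbind(section = i - 1L, res$traces[[i]])
    }))
  } else {
    if (is.null(acm_radius)) {
      inscribed <- min(seed_x, w - 1 - seed_x, seed_y, h - 1 - seed_y)
      acm_radius <- 0.9 * inscribed
    }
    distance <- NULL
    if (acm_mode == "edm") {
      pre <- preprocess_image(img, config$median_window, config$sigma,
                              config$t_low, config$t_high)
      if (!any(pre$edges > 0))
        stop("no edge pixels detected for edm mode", call. = FALSE)
      distance <- pre$distance
    }
    res <- run_acm(img, c(seed_x, seed_y), acm_radius,
                   n_points = acm_points, params = acm_params,
                   mode = acm_mode, distance = distance)
    contour <- cbind(index = seq_len(nrow(res$contour)) - 1L,
                     res$contour)
    metadata <- list(method = "acm", alpha = acm_params$alpha,
                     beta = acm_params$beta, gamma = acm_params$gamma,
                     window_half = acm_params$window_half,
                     max_iters = acm_params$max_iters,
                     smooth_sigma = acm_params$smooth_sigma,
                     mode = acm_mode, n_points = acm_points,
                     init_radius = acm_radius,
                     seed_point = c(seed_x, seed_y),
                     rng_seed = as.integer(rng_seed),
                     sweeps = res$sweeps,
                     final_energy = utils::tail(res$energy, 1L))
    trace <- data.frame(sweep = seq_along(res$energy),
                        energy = res$energy)
  }
  mask <- rasterize_contour(contour, c(h, w))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_contour_csv(contour, file.path(out_dir, "contour.csv"))
    write_mask_png(mask, file.path(out_dir, "mask.png"))
    write_overlay_png(img, contour, file.path(out_dir, "overlay.png"))
    jsonlite::write_json(metadata, file.path(out_dir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    utils::write.csv(trace, file.path(out_dir, "trace.csv"),
                     row.names = FALSE)
  }
  list(contour = contour, mask = mask, metadata = metadata,
       result = res, status = 0L)
}

# draw the contour polygon onto the image (diagnostic overlay)
write_overlay_png <- function(img, contour, path) {
  h <- nrow(img); w <- ncol(img)
  rgb <- array(rep(pmin(pmax(img / 255, 0), 1), 3L), c(h, w, 3L))
  xs <- contour$x; ys <- contour$y
  n <- length(xs)
  x2 <- c(xs[-1L], xs[1L]); y2 <- c(ys[-1L], ys[1L])
  for (k in seq_len(n)) {
    len <- max(2, ceiling(2 * sqrt((x2[k] - xs[k])^2 + (y2[k] - ys[k])^2)))
    t <- seq(0, 1, length.out = len)
    px <- round(xs[k] + t * (x2[k] - xs[k])) + 1L
    py <- round(ys[k] + t * (y2[k] - ys[k])) + 1L
    ok <- px >= 1L & px <= w & py >= 1L & py <= h
    rgb[cbind(py[ok], px[ok], 1L)] <- 1
    rgb[cbind(py[ok], px[ok], 2L)] <- 0
    rgb[cbind(py[ok], px[ok], 3L)] <- 0
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Segment an ordered stack of slices with one shared seed point
#'
#' Applies [segment_image()] to every slice with the same seed point
#' and parameters, continuing past failing slices. Writes per-slice
#' artifact directories `slice_000`, `slice_001`, ... plus a combined
#' `stack_contours.csv` (`slice,section,...`) suitable for external
#' 3-D rendering of the stacked contours.
#'
#' @param inputs ordered character vector of slice paths, or a list of
#'   image matrices.
#' @param seed_x,seed_y shared seed point.
#' @param out_dir output directory, or `NULL`.
#' @param ... passed on to [segment_image()].
#' @return list with `results` (per slice; `NULL` where failed),
#'   `failed` (indices), `stacked` (combined contour data frame) and
#'   `status` (0 iff no slice failed).
#' @export
segment_stack <- function(inputs, seed_x, seed_y, out_dir = NULL, ...) {
  n <- length(inputs)
  if (n < 1L) stop("need at least one slice", call. = FALSE)
  results <- vector("list", n)
  failed <- integer(0)
  rows <- list()
  for (s in seq_len(n)) {
    slice_dir <- if (is.null(out_dir)) NULL
    else file.path(out_dir, sprintf("slice_%03d", s - 1L))
    res <- tryCatch(
      segment_image(if (is.list(inputs)) inputs[[s]] else inputs[s],
                    seed_x, seed_y, out_dir = slice_dir, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, s)
      warning("slice ", s, " failed: ", conditionMessage(res),
              call. = FALSE)
    } else {
      results[[s]] <- res
      rows[[length(rows) + 1L]] <- cbind(slice = s - 1L, res$contour)
    }
  }
  stacked <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(out_dir) && !is.null(stacked)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(stacked, file.path(out_dir, "stack_contours.csv"),
                     row.names = FALSE)
  }
  list(results = results, failed = failed, stacked = stacked,
       status = if (length(failed)) 1L else 0L)
}

#' Re-run a MACDE segmentation from its run metadata
#'
#' The metadata JSON written by [segment_image()] records every
#' parameter plus the master RNG seed; replaying it on the same image
#' reproduces the contour bit-for-bit.
#'
#' @param input image path or matrix.
#' @param metadata metadata list or path to a `metadata.json`.
#' @param out_dir optional artifact directory.
#' @return the [segment_image()] result.
#' @export
rerun_from_metadata <- function(input, metadata, out_dir = NULL) {
  md <- if (is.character(metadata)) jsonlite::read_json(metadata,
                                                        simplifyVector = TRUE)
  else metadata
  if (!identical(md$method, "macde"))
    stop("only macde metadata can be replayed", call. = FALSE)
  cfg <- macde_config(
    de = de_config(np = md$n_snakes, generations = md$generations,
                   f = md$F, cr = md$CR,
                   stability_window = md$stability_window),
    dg = md$dg, n_snakes = md$n_snakes, r_min = md$r_min,
    r_max = md$r_max, shape = md$shape,
    ellipse_axes = md$ellipse_axes, fitness_mode = md$fitness_mode,
    gamma = md$gamma, median_window = md$median_window,
    sigma = md$sigma, t_low = md$t_low, t_high = md$t_high)
  segment_image(input, md$seed_point[1L], md$seed_point[2L],
                method = "macde", config = cfg,
                rng_seed = md$rng_seed, out_dir = out_dir)
}

#' Evaluate predicted vs reference segmentations from files
#'
#' Accepts mask PNGs or contour CSVs (rasterized to `shape`).
#'
#' @param pred,ref paths to mask PNGs or contour CSVs, or 0/1
#'   matrices.
#' @param shape `c(height, width)`, required when contours are given.
#' @return the [evaluate_masks()] list.
#' @export
evaluate_files <- function(pred, ref, shape = NULL) {
  load_mask <- function(p) {
    if (is.matrix(p)) return(p)
    if (grepl("\\.csv$", p, ignore.case = TRUE)) {
      if (is.null(shape))
        stop("shape is required to rasterize contour CSVs",
             call. = FALSE)
      rasterize_contour(read_contour_csv(p), shape)
    } else read_mask_png(p)
  }
  evaluate_masks(load_mask(pred), load_mask(ref))
}
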