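test_that("phantoms have the published sizes and exact mask geometry", {
  st <- make_star()
  expect_equal(dim(st$image), c(160L, 160L))
  expect_equal(dim(st$mask), c(160L, 160L))

  nc <- make_noisy_circle()
  expect_equal(dim(nc$image), c(300L, 300L))

  cb <- make_concave_blob()
  expect_equal(dim(cb$image), c(150L, 150L))
})

test_that("star mask equals the point-in-polygon oracle area and degenerates
           to a regular polygon when radii coincide", {
  st <- make_star(size = c(80, 80), r_outer = 30, r_inner = 12)
  cnt <- 0
  for (i in seq_len(80)) for (j in seq_len(80)) {
    if (point_in_polygon(j - 1, i - 1, st$vertices$x, st$vertices$y))
      cnt <- cnt + 1
  }
  # boundary-center pixels may add a thin rim on top of the open-set count
  expect_gte(sum(st$mask), cnt)
  expect_lte(sum(st$mask) - cnt, 4 * 80)

  deg <- make_star(size = c(80, 80), r_outer = 25, r_inner = 25)
  # regular decagon: convex, area close to the analytic polygon area
  a10 <- 0.5 * 10 * 25^2 * sin(2 * pi / 10)
  expect_lt(abs(sum(deg$mask) - a10) / a10, 0.05)
})

test_that("noisy circle: noise statistics match the spec'd sigma, the mask
           is the exact noiseless disk, and generation is deterministic", {
  nc <- make_noisy_circle(seed = 9)
  clean <- make_noisy_circle(noise_sigma = 0)
  expect_equal(nc$mask, clean$mask)
  expect_equal(nc$mask, disk_truth(c(300, 300), nc$center, 100))
  # sample sd of (noisy - clean) over interior pixels (no clipping there)
  interior <- disk_truth(c(300, 300), nc$center, 90) > 0
  s <- stats::sd((nc$image - clean$image)[interior])
  expect_lt(abs(s - 0.04 * 255) / (0.04 * 255), 0.05)

  again <- make_noisy_circle(seed = 9)
  expect_identical(nc$image, again$image)
  expect_false(identical(nc$image, make_noisy_circle(seed = 10)$image))
})

test_that("concave blob is the union of its lobes with at least two boundary
           concavities, and invalid lobe sets are rejected", {
  cb <- make_concave_blob()
  # union area equals per-disk membership oracle
  u <- matrix(0L, 150, 150)
  for (k in 1:3) {
    a <- cb$spec$lobes$angle_deg[k] * pi / 180
    ck <- cb$center + 20 * c(cos(a), sin(a))
    u <- pmax(u, disk_truth(c(150, 150), ck, 35))
  }
  expect_equal(cb$mask, u)
  # boundary radius about the center varies (concavities exist)
  b <- mask_boundary(cb$mask)
  r <- sqrt((b[, 1] - cb$center[1])^2 + (b[, 2] - cb$center[2])^2)
  expect_gt(max(r) - min(r), 8)

  expect_error(make_concave_blob(lobes = data.frame(
    angle_deg = c(0, 180), dist = 40, radius = 30)), "star-convex")
  expect_error(make_concave_blob(lobes = data.frame(
    angle_deg = 0, dist = 10, radius = 30)), "2 lobes")
})

test_that("every phantom mask is nonempty, 4-connected and star-convex about
           its center", {
  phantoms <- list(make_star(), make_noisy_circle(seed = 2),
                   make_concave_blob())
  for (ph in phantoms) {
    expect_gt(sum(ph$mask), 0)
    start <- c(round(ph$center[2]) + 1, round(ph$center[1]) + 1)
    comp <- connected_component_4(ph$mask, start)
    expect_equal(sum(comp), sum(ph$mask))
  }
  # star-convexity of the analytic shapes along rays from the center
  st <- make_star()
  for (ang in seq(0.05, 2 * pi, length.out = 36)) {
    inside_prev <- TRUE
    transitions <- 0
    for (r in seq(0.5, 70, by = 0.5)) {
      p <- st$center + r * c(cos(ang), sin(ang))
      inside <- point_in_polygon(p[1], p[2], st$vertices$x,
                                 st$vertices$y)
      if (inside != inside_prev) transitions <- transitions + 1
      inside_prev <- inside
    }
    expect_lte(transitions, 1)
  }
})

test_that("phantom stacks drift smoothly, keep the shared seed valid and
           degenerate correctly", {
  single <- make_stack("plain_circle", n_slices = 1)
  expect_length(single, 1)

  st <- make_stack("plain_circle", n_slices = 6, scale_step = -0.05,
                   size = c(120, 120), radius = 40)
  areas <- vapply(st, function(s) sum(s$mask), numeric(1))
  expect_true(all(diff(areas) < 0))
  sp <- attr(st, "seed_point")
  for (s in st) expect_equal(s$mask[sp[2] + 1, sp[1] + 1], 1L)

  frozen <- make_stack("plain_circle", n_slices = 3, scale_step = 0,
                       size = c(100, 100), radius = 30)
  expect_identical(frozen[[1]]$mask, frozen[[3]]$mask)

  expect_error(make_stack("plain_circle", n_slices = 5,
                          scale_step = -0.3, size = c(100, 100),
                          radius = 30), "nothing|seed")
})
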