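test_that("polar grid tiles the circle for exact and inexact divisors", {
  g4 <- build_polar_grid(c(50, 50), dg = 90, img_shape = c(101, 101))
  expect_equal(g4$n_sections, 4L)
  expect_equal(g4$theta_lo, c(0, 90, 180, 270) * pi / 180)
  expect_equal(g4$theta_hi, c(90, 180, 270, 360) * pi / 180)

  g24 <- build_polar_grid(c(50, 50), dg = 15, img_shape = c(101, 101))
  expect_equal(g24$n_sections, 24L)

  # 360 / 13 = 27.7: 27 full sections plus one truncated to end at 360
  g28 <- build_polar_grid(c(50, 50), dg = 13, img_shape = c(101, 101))
  expect_equal(g28$n_sections, 28L)
  expect_equal(g28$theta_hi[28], 2 * pi)
  expect_lt(g28$theta_hi[28] - g28$theta_lo[28], 13 * pi / 180)

  expect_error(build_polar_grid(c(0, 50), dg = 15,
                                img_shape = c(101, 101)), "inside")
  expect_error(build_polar_grid(c(50, 50), dg = 15, r_min = 5, r_max = 80,
                                img_shape = c(101, 101)), "r_max")
})

test_that("population initialization spaces radii equally and assigns one
           individual per initial contour per section", {
  g <- build_polar_grid(c(50, 50), dg = 90, r_min = 10, r_max = 40,
                        img_shape = c(101, 101))
  cfg <- macde_config(dg = 90, n_snakes = 4)
  pops <- init_populations(g, cfg)
  expect_length(pops, 4)
  expect_equal(pops[[1]]$individuals[, "r"], c(10, 20, 30, 40),
               ignore_attr = TRUE)
  # every individual sits at the section midangle
  expect_equal(pops[[2]]$individuals[, "theta"],
               rep((pi / 2 + pi) / 2, 4), ignore_attr = TRUE)

  g24 <- build_polar_grid(c(80, 80), dg = 15, img_shape = c(161, 161))
  pops24 <- init_populations(g24, macde_config(dg = 15, n_snakes = 15))
  expect_length(pops24, 24)
  expect_true(all(vapply(pops24, function(p) nrow(p$individuals),
                         integer(1)) == 15L))
})

test_that("elliptical initialization scales radii by the ellipse radius at
           the section midangle", {
  g <- build_polar_grid(c(50, 50), dg = 90, r_min = 4, r_max = 40,
                        img_shape = c(101, 101))
  cfg <- macde_config(dg = 90, n_snakes = 4, shape = "ellipse",
                      ellipse_axes = c(40, 20))
  pops <- init_populations(g, cfg)
  # section 2 midangle is 135 deg; relative ellipse radius ab/sqrt(...)/a
  mid <- (pi / 2 + pi) / 2
  sc <- 40 * 20 / sqrt((20 * cos(mid))^2 + (40 * sin(mid))^2) / 40
  expect_equal(pops[[2]]$individuals[, "r"],
               pmax(c(4, 16, 28, 40) * sc, 4), ignore_attr = TRUE)
})

test_that("section repair clips radius and angle into the wedge", {
  g <- build_polar_grid(c(50, 50), dg = 90, r_min = 10, r_max = 40,
                        img_shape = c(101, 101))
  sec <- init_populations(g, macde_config(dg = 90, n_snakes = 4))[[1]]
  expect_equal(section_repair(c(20, 0.5), sec, g), c(20, 0.5))
  expect_equal(section_repair(c(45, 0.5), sec, g)[1], 40)
  expect_equal(section_repair(c(20, sec$theta_lo - 0.3), sec, g)[2],
               sec$theta_lo)
  expect_lt(section_repair(c(20, 9), sec, g)[2], sec$theta_hi)
})

test_that("section fitness is zero on edge pixels and composes the bilinear
           sampler on a single-site distance map", {
  edges <- matrix(0L, 41, 41)
  edges[21, 31] <- 1L  # (x, y) = (30, 20)
  d <- euclidean_distance_map(edges)
  g <- build_polar_grid(c(20, 20), dg = 90, r_min = 1, r_max = 19,
                        img_shape = c(41, 41))
  cfg <- macde_config(dg = 90, gamma = 0.05)
  # the edge site lies at angle 0, radius 10 from the seed
  expect_equal(section_fitness(c(10, 0), g, d, cfg), 0)
  v <- c(7, 0.4)
  x <- 20 + 7 * cos(0.4); y <- 20 + 7 * sin(0.4)
  expect_equal(section_fitness(v, g, d, cfg),
               0.05 * sample_map(d, x, y))
})

test_that("MACDE recovers a clean circular edge map within sub-pixel radial
           error and yields one snaxel per wedge", {
  pre <- ring_pre(c(200, 200), seed = c(100, 100), rho = 60)
  cfg <- macde_config()
  res <- run_macde(matrix(0, 200, 200), c(100, 100), cfg, rng_seed = 7,
                   pre = pre)
  expect_equal(nrow(res$contour), 24)
  expect_true(all(abs(res$contour$r - 60) <= 1.5))
  # wedge membership and radial band
  th <- res$contour$angle_deg * pi / 180
  expect_true(all(th >= res$grid$theta_lo & th < res$grid$theta_hi))
  expect_true(all(res$contour$r >= res$grid$r_min &
                    res$contour$r <= res$grid$r_max))
  mask <- rasterize_contour(res$contour, c(200, 200))
  expect_gte(dice_index(mask, disk_truth(c(200, 200), c(100, 100), 60)),
             0.98)
})

test_that("MACDE runs are bitwise reproducible under a fixed master seed
           and the mean population fitness never ends above its start", {
  ph <- make_concave_blob()
  cfg <- macde_config(de = de_config(generations = 5))
  r1 <- run_macde(ph$image, c(75, 75), cfg, rng_seed = 13)
  r2 <- run_macde(ph$image, c(75, 75), cfg, rng_seed = 13)
  expect_identical(r1$contour, r2$contour)

  mpf <- mean_population_fitness(r1)
  expect_lte(mpf[length(mpf)], mpf[1])
  # per-individual elitism: every section's fitness history is
  # non-increasing columnwise
  for (h in r1$fitness_histories)
    expect_true(all(apply(h, 2, function(col) all(diff(col) <= 1e-12))))
})

test_that("mean population fitness averages known fitness lists", {
  h1 <- rbind(c(2, 4), c(1, 3))  # generations 0 and 1
  h2 <- rbind(c(6, 8), c(5, 7))
  expect_equal(mean_population_fitness(list(h1, h2)),
               c(mean(c(2, 4, 6, 8)), mean(c(1, 3, 5, 7))))
  expect_equal(mean_population_fitness(list(matrix(0, 3, 4))),
               rep(0, 3))
})

test_that("an empty edge map aborts with advice to adjust thresholds", {
  flat <- matrix(100, 64, 64)
  expect_error(suppressWarnings(run_macde(flat, c(32, 32))),
               "threshold")
})
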