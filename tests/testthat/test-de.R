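test_that("mutation follows the rand/1 formula and its degenerate cases", {
  pop <- matrix(rep(c(2, -1), each = 5), 5, 2) # identical individuals
  set.seed(1)
  expect_equal(de_mutate(pop, 1, f = 0.7), c(2, -1))

  set.seed(2)
  pop2 <- matrix(rnorm(10), 5, 2)
  set.seed(3)
  v <- de_mutate(pop2, 2, f = 0)
  set.seed(3)
  r <- sample(setdiff(1:5, 2), 3)
  expect_equal(v, pop2[r[1], ]) # F = 0 copies the first donor

  # replay the documented RNG protocol and evaluate the formula by hand
  set.seed(9)
  v2 <- de_mutate(pop2, 4, f = 0.35)
  set.seed(9)
  r2 <- sample(setdiff(1:5, 4), 3)
  expect_equal(v2, pop2[r2[1], ] + 0.35 * (pop2[r2[2], ] - pop2[r2[3], ]))

  expect_error(de_mutate(pop2[1:3, ], 1, 0.5), "at least 4")
})

test_that("binomial crossover honors CR extremes and replays the uniform
           draws componentwise", {
  x <- c(1, 2, 3, 4); v <- c(10, 20, 30, 40)
  set.seed(4)
  expect_equal(de_crossover(x, v, cr = 1), v)

  set.seed(4)
  u0 <- de_crossover(x, v, cr = 0)
  expect_equal(sum(u0 != x), 1) # only the forced component

  set.seed(7)
  u <- de_crossover(x, v, cr = 0.8)
  set.seed(7)
  take <- stats::runif(4) <= 0.8
  j <- sample.int(4, 1)
  take[j] <- TRUE
  expect_equal(u, ifelse(take, v, x))

  # pure variant may return the target unchanged
  set.seed(123)
  expect_equal(de_crossover(x, v, cr = 0, pure = TRUE), x)
})

test_that("selection is strict minimization and treats non-finite fitness as
           worst", {
  s <- de_select(c(0, 0), c(1, 1), f_target = 5, f_trial = 5)
  expect_equal(s$x, c(0, 0)) # tie retains target
  s <- de_select(c(0, 0), c(1, 1), f_target = 5, f_trial = 4.9)
  expect_equal(s$x, c(1, 1))
  s <- de_select(c(0, 0), c(1, 1), f_target = 5, f_trial = NaN)
  expect_equal(s$x, c(0, 0))
  # agrees with direct comparison on a sphere function
  sphere <- function(v) sum(v^2)
  set.seed(8)
  for (k in 1:20) {
    a <- rnorm(2); b <- rnorm(2)
    s <- de_select(a, b, sphere(a), sphere(b))
    expect_equal(s$x, if (sphere(b) < sphere(a)) b else a)
  }
})

test_that("run_de minimizes a 2-D sphere function reliably", {
  target <- c(1.7, -2.3)
  ok <- 0
  for (s in 1:25) {
    cfg <- de_config(np = 15, generations = 40, f = 0.5, cr = 0.8,
                     seed = s)
    r <- run_de(function(v) sum((v - target)^2),
                lower = c(-5, -5), upper = c(5, 5), config = cfg)
    if (r$best_fitness < 1e-3) ok <- ok + 1
    expect_true(all(diff(r$trace$best) <= 1e-15))
    expect_true(all(r$population >= -5 & r$population <= 5))
  }
  expect_gte(ok, 24)
})

test_that("an all-identical initial population is a fixed point of the DE
           dynamics", {
  init <- matrix(rep(c(0.5, -0.25), each = 8), 8, 2)
  cfg <- de_config(np = 8, generations = 15, f = 1.3, cr = 0.6, seed = 3)
  r <- run_de(function(v) sum(v^2), lower = c(-1, -1), upper = c(1, 1),
              config = cfg, init = init)
  expect_equal(r$population, init, ignore_attr = TRUE)
  expect_equal(diff(r$trace$best), rep(0, 15))
})

test_that("two runs with the same seed and config are bitwise identical", {
  cfg <- de_config(np = 10, generations = 20, f = 0.6, cr = 0.9, seed = 77)
  fn <- function(v) (v[1] - 0.3)^2 + 2 * (v[2] + 0.4)^2
  r1 <- run_de(fn, c(-2, -2), c(2, 2), cfg)
  r2 <- run_de(fn, c(-2, -2), c(2, 2), cfg)
  expect_identical(r1, r2)
})

test_that("stability window stops the run once the best fitness stalls", {
  # constant fitness can never improve: the run must stop after exactly
  # stability_window generations
  cfg <- de_config(np = 10, generations = 200, f = 0.5, cr = 0.9,
                   seed = 5, stability_window = 10)
  r <- run_de(function(v) 1, c(-1, -1), c(1, 1), cfg)
  expect_equal(r$generations_run, 10)
  expect_equal(nrow(r$trace), 11)
  expect_true(all(diff(r$trace$best) <= 1e-15))
})

test_that("configuration validation rejects invalid settings", {
  expect_error(de_config(np = 3), ">= 4")
  expect_error(de_config(f = 0), "\\(0, 2\\]")
  expect_error(de_config(cr = 1.5), "\\[0, 1\\]")
  expect_error(run_de(function(v) 0, numeric(0), numeric(0)),
               "nonempty")
})
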