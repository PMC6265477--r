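test_that("bias energy of a single hill is Gaussian with the stated scale", {
  log <- hills_log("x", centers = matrix(0.3), sigmas = 0.1, heights = 0.1)
  expect_equal(bias_energy(log, 0.3), 0.1)
  expect_equal(bias_energy(log, 0.4), 0.1 * exp(-0.5), tolerance = 1e-12)
  empty <- hills_log("x")
  expect_equal(bias_energy(empty, 0.3), 0)
  log2d <- hills_log(c("a", "b"), centers = matrix(0, 1, 2), sigmas = 0.1,
                     heights = 0.1)
  expect_error(bias_energy(log2d, c(1, 2, 3)), "dimension|multiple")
})

test_that("bias force is the negative analytic gradient of the bias", {
  log <- hills_log("x", centers = matrix(0), sigmas = 0.1, heights = 0.1)
  expect_equal(bias_force(log, 0), matrix(0))
  # at +sigma the force pushes away from the centre with magnitude h e^-1/2 / sigma
  f <- bias_force(log, 0.1)
  expect_equal(as.numeric(f), 0.1 * exp(-0.5) / 0.1, tolerance = 1e-12)
  expect_gt(f[1], 0)
  # random log vs finite differences
  set.seed(4)
  rl <- hills_log(c("a", "b"), centers = matrix(rnorm(20), 10, 2),
                  sigmas = matrix(runif(20, 0.05, 0.3), 10, 2),
                  heights = runif(10, 0, 0.2))
  for (i in 1:5) {
    s <- rnorm(2)
    fr <- bias_force(rl, s)
    e <- 1e-6
    for (j in 1:2) {
      sp <- s; sm <- s
      sp[j] <- sp[j] + e; sm[j] <- sm[j] - e
      fd <- -(bias_energy(rl, sp) - bias_energy(rl, sm)) / (2 * e)
      expect_equal(fr[1, j], fd, tolerance = 1e-6)
    }
  }
})

test_that("total deposited bias integrates to sum(h) * (sigma sqrt(2 pi))^d", {
  log <- hills_log("x", centers = matrix(c(-0.4, 0.2, 0.1)),
                   sigmas = matrix(c(0.1, 0.15, 0.2)),
                   heights = c(0.1, 0.05, 0.2))
  num <- stats::integrate(function(x) bias_energy(log, matrix(x)),
                          -10, 10, rel.tol = 1e-10)$value
  ana <- sum(log$heights * log$sigmas[, 1] * sqrt(2 * pi))
  expect_equal(num, ana, tolerance = 1e-8)
})

test_that("hill deposition schedule: pace 200 over 1000 steps gives 5 hills", {
  dw <- make_double_well(5, 2)
  cfg <- sampler_config(steps_per_walker = 1000, pace = 200, seed = 1)
  run <- run_walker(dw, cfg, initial_s = -1)
  expect_equal(n_hills(run$log), 5)
  expect_true(all(diff(run$log$times) > 0))
  expect_true(all(run$log$heights == 0.1))
  expect_true(all(run$log$sigmas == 0.1))
})

test_that("zero-temperature dynamics from a minimum stays at the minimum", {
  dw <- make_double_well(5, 2)
  cfg <- sampler_config(temperature = 0, hill_height = 0,
                        steps_per_walker = 2000, seed = 1)
  run <- run_walker(dw, cfg, initial_s = -1)
  expect_lt(max(abs(run$trajectories[[1]] + 1)), 1e-6)
})

test_that("unbiased Langevin dynamics satisfies equipartition", {
  hw <- make_harmonic_well(1)
  cfg <- sampler_config(hill_height = 0, steps_per_walker = 1e6,
                        record_stride = 10, seed = 42)
  run <- run_walker(hw, cfg, initial_s = 0)
  s2 <- mean(run$trajectories[[1]]^2)
  expect_equal(s2, 0.0019872041 * 298.15 / 1, tolerance = 0.05)
})

test_that("runs are reproducible under a fixed seed", {
  dw <- make_double_well(5, 2)
  cfg <- sampler_config(steps_per_walker = 2000, n_walkers = 2, seed = 33)
  a <- run_multiwalker(dw, cfg, initial_s = -1)
  b <- run_multiwalker(dw, cfg, initial_s = -1)
  expect_identical(a$log$centers, b$log$centers)
  expect_identical(a$trajectories, b$trajectories)
})

test_that("multi-walker with one walker reduces to run_walker", {
  dw <- make_double_well(5, 2)
  cfg <- sampler_config(steps_per_walker = 3000, n_walkers = 1, seed = 8)
  a <- run_walker(dw, cfg, initial_s = -1)
  b <- run_multiwalker(dw, cfg, initial_s = -1)
  expect_identical(a$log$centers, b$log$centers)
  expect_identical(a$trajectories[[1]], b$trajectories[[1]])
})

test_that("pooled bias equals the sum over per-walker hill subsets", {
  dw <- make_double_well(5, 2)
  cfg <- sampler_config(steps_per_walker = 4000, n_walkers = 3, seed = 2)
  run <- run_multiwalker(dw, cfg, initial_s = -1)
  log <- run$log
  s <- matrix(seq(-1.5, 1.5, length.out = 7))
  pooled <- bias_energy(log, s)
  split_sum <- rep(0, nrow(s))
  for (w in unique(log$walkers)) {
    i <- log$walkers == w
    sub <- hills_log(log$cv_names, centers = log$centers[i, , drop = FALSE],
                     sigmas = log$sigmas[i, , drop = FALSE],
                     heights = log$heights[i])
    split_sum <- split_sum + bias_energy(sub, s)
  }
  expect_equal(pooled, split_sum, tolerance = 1e-12)
})

test_that("walkers escape a filled double well", {
  dw <- make_double_well(5, 2)
  cfg <- sampler_config(n_walkers = 8, steps_per_walker = 60000, seed = 13)
  run <- run_multiwalker(dw, cfg, initial_s = -1)
  crossed <- vapply(run$trajectories, function(tr) any(tr > 0.5), logical(1))
  expect_true(all(crossed))
})

test_that("initial point outside the domain box is rejected", {
  dw <- make_double_well(5, 2)
  cfg <- sampler_config(steps_per_walker = 100)
  expect_error(run_walker(dw, cfg, initial_s = 5), "domain box")
})
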