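test_that("double well has the stated shape and symmetric barriers", {
  dw <- make_double_well(5, 2)
  expect_equal(surface_energy(dw, 0), 5)
  expect_equal(surface_energy(dw, 1), 0)
  expect_equal(surface_energy(dw, -1), 0)
  # forward and reverse barriers are equal by symmetry
  xs <- seq(-1, 1, by = 0.01)
  v <- surface_energy(dw, matrix(xs, ncol = 1))
  expect_equal(max(v[xs <= 0]) - v[1], max(v[xs >= 0]) - v[length(v)])
  expect_error(make_double_well(-1, 2))
  expect_error(make_double_well(5, 0))
})

test_that("numeric minimisation stays at the listed double-well minima", {
  for (pars in list(c(5, 2), c(3, 1.2), c(12, 4))) {
    dw <- make_double_well(pars[1], pars[2])
    for (i in which(dw$known_features$energy == 0)) {
      x0 <- dw$known_features$position[[i]]
      expect_equal(oracle_minimize(dw, x0), x0, tolerance = 1e-6)
    }
  }
})

test_that("mechanism surface features are exact stationary points", {
  for (args in list(list(6, 21.6, 0), list(4, 8, 0), list(5, 15, 0.2))) {
    ms <- do.call(make_mechanism_surface, args)
    for (i in seq_len(nrow(ms$known_features))) {
      p <- ms$known_features$position[[i]]
      expect_equal(surface_energy(ms, p), ms$known_features$energy[i],
                   tolerance = 1e-10)
      expect_lt(max(abs(surface_gradient(ms, p))), 1e-6)
    }
    # highest listed saddle sits at the main barrier
    expect_equal(max(ms$known_features$energy), args[[2]])
  }
  expect_error(make_mechanism_surface(10, 8), "exceed")
  expect_error(make_mechanism_surface(-1, 8))
})

test_that("mechanism surface reactant is the global minimum on a 50^3 scan", {
  ms <- make_mechanism_surface()
  gr <- surface_fes_grid(ms, 50)
  # the (normalised) grid minimum must lie within one grid cell of the
  # listed reactant
  node <- which.min(gr$values)
  coords <- ribotrim:::.node_coords(gr, node)
  h <- (gr$axes$max - gr$axes$min) / (gr$axes$n - 1)
  expect_true(all(abs(coords - c(-0.8, -0.8, -0.8)) <= h + 1e-12))
})

test_that("analytic surface gradients match central finite differences", {
  surfaces <- list(make_double_well(5, 2), make_mechanism_surface(),
                   make_harmonic_well(c(1, 2), c(0.5, -0.5)))
  set.seed(42)
  for (sf in surfaces) {
    d <- sf$dimension
    pts <- matrix(runif(20 * d, sf$domain_box[1, ], sf$domain_box[2, ]),
                  ncol = d, byrow = TRUE)
    g <- surface_gradient(sf, pts)
    for (j in seq_len(d)) {
      e <- 1e-5
      pp <- pts; pm <- pts
      pp[, j] <- pp[, j] + e; pm[, j] <- pm[, j] - e
      fd <- (surface_energy(sf, pp) - surface_energy(sf, pm)) / (2 * e)
      expect_equal(g[, j], fd, tolerance = 1e-4)
    }
  }
})

test_that("toy cluster interpolates the deprotonation CV from -0.8 to +0.8", {
  cl0 <- make_toy_reaction_cluster(0)
  cl5 <- make_toy_reaction_cluster(0.5)
  cl1 <- make_toy_reaction_cluster(1)
  cv <- function(cl) antisym_stretch(cl$coords, "O2p", "H2p", "NE2_120",
                                     labels = cl$labels)$value
  expect_equal(cv(cl0), -0.8)
  expect_equal(cv(cl5), 0)
  expect_equal(cv(cl1), 0.8)
  # the other two coordinate triples interpolate analogously
  pt <- function(cl) antisym_stretch(cl$coords, "O5p", "P", "O2p",
                                     labels = cl$labels)$value
  lg <- function(cl) antisym_stretch(cl$coords, "NE2_208", "HE2_208", "O5p",
                                     labels = cl$labels)$value
  expect_equal(pt(cl0), -0.8); expect_equal(pt(cl1), 0.8)
  expect_equal(lg(cl0), -0.8); expect_equal(lg(cl1), 0.8)
  # physical sanity: no clashes at any progress
  for (p in seq(0, 1, by = 0.1)) {
    coords <- make_toy_reaction_cluster(p)$coords
    expect_gt(min(dist(coords)), 0.5)
  }
  expect_error(make_toy_reaction_cluster(1.2))
  expect_error(make_toy_reaction_cluster(-0.1))
})

test_that("hydration generator plants the shell and is seed-deterministic", {
  hs <- sample_hydration_shell(3, 2.8, density_bulk = 0, n_frames = 1, seed = 5)
  r <- rdf(hs, r_max = 6, bin_width = 0.1, density_bulk = 1)
  expect_equal(r$n_integrated[max(which(r$bin_centers <= 3.2))], 3)
  hs2 <- sample_hydration_shell(3, 2.8, density_bulk = 0, n_frames = 1, seed = 5)
  expect_identical(hs$frames, hs2$frames)
  hs3 <- sample_hydration_shell(3, 2.8, density_bulk = 0, n_frames = 1, seed = 6)
  expect_false(identical(hs$frames, hs3$frames))
  # all points inside the box
  expect_true(all(unlist(hs$frames) >= 0 & unlist(hs$frames) <= hs$box))
})

test_that("background-only snapshots behave as an ideal gas (g ~ 1)", {
  hs <- sample_hydration_shell(0, 2.8, density_bulk = 0.0334, n_frames = 200,
                               seed = 7)
  r <- rdf(hs, r_max = 8, bin_width = 0.1, density_bulk = 0.0334)
  far <- r$bin_centers > 5
  expect_equal(mean(r$g[far]), 1, tolerance = 0.05)
})

test_that("kinetics generator reproduces the Michaelis-Menten law exactly", {
  # at S = Km the velocity is half of Vmax = kcat * E0
  ks <- generate_mm_kinetics(11.85e-3, 3.12, 0.1, S = c(1, 3.12, 10, 55))
  v_half <- ks$data$velocity_uM_per_s[ks$data$substrate_uM == 3.12]
  expect_equal(v_half, 11.85e-3 * 0.1 / 2) # 5.925e-4 uM/s
  # saturation limit
  ks2 <- generate_mm_kinetics(2e-3, 5, 0.2, S = c(1, 2, 4, 5e6))
  vmax_obs <- max(ks2$data$velocity_uM_per_s) / 0.2
  expect_equal(vmax_obs, 2e-3, tolerance = 1e-4)
  # seeded noise is reproducible
  a <- generate_mm_kinetics(1e-3, 3, 0.1, noise_sd = 5e-5, replicates = 2,
                            seed = 42)
  b <- generate_mm_kinetics(1e-3, 3, 0.1, noise_sd = 5e-5, replicates = 2,
                            seed = 42)
  expect_identical(a$data, b$data)
  expect_true(all(a$data$velocity_uM_per_s >= 0))
  expect_error(generate_mm_kinetics(-1, 3, 0.1))
})
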