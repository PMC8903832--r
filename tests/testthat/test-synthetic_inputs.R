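test_that("undulated inoculum has the prescribed geometry", {
  grid <- make_grid(dx = 10, Lx = 4000, lambda = 800)
  spec <- inoculum_spec(lambda = 800, A0 = 300, x_center = 1500)
  b <- make_undulated_inoculum(spec, grid)
  expect_equal(max(b), 0.95, tolerance = 1e-6)

  # phase convention: centreline valley at y = 0, peak at y = lambda/2
  x0 <- inoculum_centerline(grid$y, spec)
  expect_equal(grid$y[which.min(x0)], 0)
  expect_equal(grid$y[which.max(x0)], 400)
  expect_equal(max(x0) - min(x0), 600)

  # measured FWHM of a ridge cross-section = 100 um (+- dx)
  j <- 1L
  row <- b[, j]
  half <- max(row) / 2
  xs <- grid$x[row >= half]
  expect_lt(abs((max(xs) - min(xs)) - 100), grid$dx + 1e-9)

  # edge amplitude at half peak equals A0 within dx
  edge <- extract_leading_edge(b, 0.95 / 2, grid)
  ap <- amplitude_and_position(edge)
  expect_lt(abs(ap$A - 300), grid$dx)

  # A0 = 0 gives a y-independent ridge
  bf <- make_undulated_inoculum(inoculum_spec(lambda = 800, A0 = 0,
                                              x_center = 1500), grid)
  expect_equal(bf, bf[, c(2, seq_len(grid$ny - 1))], tolerance = 1e-12)

  # mass within 2% of the analytic Gaussian-ridge mass at dx <= 20
  # (the node sum spans ny*dx in y on the node-centred grid)
  for (dx in c(20, 10)) {
    gg <- make_grid(dx = dx, Lx = 4000, lambda = 800)
    bb <- make_undulated_inoculum(spec, gg)
    sigma <- 100 / (2 * sqrt(2 * log(2)))
    mass_true <- 0.95 * sqrt(2 * pi) * sigma * (gg$ny * dx)
    expect_lt(abs(sum(bb) * dx^2 / mass_true - 1), 0.02)
  }
  expect_error(make_undulated_inoculum(
    inoculum_spec(lambda = 800, A0 = 3000, x_center = 1500), grid), "fit")
})

test_that("uniform nutrient field honours units and bounds", {
  grid <- make_grid(dx = 40, Lx = 400, lambda = 160)
  cc <- make_uniform_nutrient(1e4, grid)
  expect_true(all(cc == 1e4))
  expect_equal(dim(cc), c(grid$nx, grid$ny))
  expect_true(all(make_uniform_nutrient(10, grid) == 10))
  expect_true(all(make_uniform_nutrient(0, grid) == 0))
  expect_error(make_uniform_nutrient(-1, grid), "non-negative")
})

test_that("synthetic amplitude series are reproducible and well-shaped", {
  s <- synth_amplitude_series(300, 2.5 * 3600, 3600, 8 * 3600, 300)
  expect_equal(s$A[s$t < 3600], rep(300, sum(s$t < 3600)))
  expect_equal(s$A[s$t >= 3600],
               300 * exp(-(s$t[s$t >= 3600] - 3600) / (2.5 * 3600)))
  # flat (tau = Inf) series encodes non-smoothing
  sf <- synth_amplitude_series(300, Inf, 3600, 8 * 3600, 300)
  expect_true(all(sf$A == 300))
  # seeded noise is bit-reproducible and does not touch the global RNG
  set.seed(99); before <- runif(1); set.seed(99)
  n1 <- synth_amplitude_series(300, 9000, 3600, 8 * 3600, 300,
                               noise_sd = 6, seed = 11)
  n2 <- synth_amplitude_series(300, 9000, 3600, 8 * 3600, 300,
                               noise_sd = 6, seed = 11)
  expect_identical(n1, n2)
  expect_identical(runif(1), before)
  expect_error(synth_amplitude_series(300, 9000, 3600, 8 * 3600, 300,
                                      noise_sd = 6), "seed")
})

test_that("image-stack rendering is monotone, invertible, and writes TIFF", {
  grid <- make_grid(dx = 40, Lx = 1600, lambda = 400)
  spec <- inoculum_spec(lambda = 400, A0 = 100, x_center = 600)
  b1 <- make_undulated_inoculum(spec, grid)
  b2 <- 0.5 * b1
  expect_error(render_image_stack(list()), "empty")

  f <- tempfile(fileext = ".tif")
  st <- render_image_stack(list(b1, b2), file = f)
  expect_length(st$frames, 2L)
  # uniform field maps to a uniform image
  su <- render_image_stack(list(matrix(0.2, 4, 4)))
  expect_equal(max(su$frames[[1]]) - min(su$frames[[1]]), 0)
  # intensity max tracks the density max exactly (monotone transform)
  expect_equal(which.max(st$frames[[1]]), which.max(b1))
  # transform inverts up to 16-bit quantization
  back <- unrender_image(st$frames[[1]], st$b_ref, st$s_max)
  expect_lt(max(abs(back - b1)), 1e-3 * max(b1))
  # file round-trips through the TIFF reader
  frames <- tiff::readTIFF(f, all = TRUE)
  expect_length(frames, 2L)
  expect_equal(frames[[1]], st$frames[[1]], tolerance = 1e-4)
})

test_that("starvation signal follows the depletion-history rule", {
  grid <- make_grid(dx = 40, Lx = 400, lambda = 160)
  p <- model_params()
  nt <- 6
  times <- seq(0, 5) * 3600
  b <- lapply(seq_len(nt), function(k) matrix(0.1, grid$nx, grid$ny))
  # one node depleted from t = 0; another never depleted
  cs <- lapply(seq_len(nt), function(k) {
    m <- matrix(1e4, grid$nx, grid$ny)
    m[2, 2] <- 0.5  # below c_star = 1 uM from the start
    m
  })
  run <- structure(list(times = times, b = b, c = cs, grid = grid,
                        params = p), class = "ks_run")
  sig <- apply_starvation_signal(run)
  # before the delay elapses: signal equals density everywhere
  expect_equal(sig[[2]][2, 2], 0.1)  # t = 1 hr < tau_delay = 2 hr
  expect_true(all(sig[[nt]][3, 3] == 0.1))  # never-depleted node
  # after the delay: exponential decay from the depletion time
  t4 <- times[5]  # 4 hr > tau_delay
  expect_equal(sig[[5]][2, 2], 0.1 * exp(-t4 / p$tau_starve))
  # direct substitution at t = tau_delay + tau_starve
  tt <- p$tau_delay + p$tau_starve
  run2 <- structure(list(times = c(0, tt), b = b[1:2], c = cs[1:2],
                         grid = grid, params = p), class = "ks_run")
  sig2 <- apply_starvation_signal(run2)
  expect_equal(sig2[[2]][2, 2], 0.1 * exp(-tt / p$tau_starve))
  # signal never exceeds density
  expect_true(all(sig[[nt]] <= b[[nt]] + 1e-15))
})
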