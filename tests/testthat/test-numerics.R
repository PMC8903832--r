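test_that("Laplacian is exact on quadratics and spectrally accurate on sinusoids", {
  ts <- tiny_setup()
  g <- ts$grid
  # uniform field: identically zero, boundaries included
  expect_equal(laplacian(matrix(3.7, g$nx, g$ny), g),
               matrix(0, g$nx, g$ny))
  # x^2: second difference of a quadratic is exact on the interior
  f <- outer(g$x, rep(1, g$ny)) ^ 2
  lap <- laplacian(f, g)
  expect_equal(lap[2:(g$nx - 1), ], matrix(2, g$nx - 2, g$ny),
               tolerance = 1e-10)
  # sinusoid along y: O(dx^2) convergence (error drops ~4x per halving)
  err_for <- function(dx) {
    gg <- make_grid(dx = dx, Lx = 400, lambda = 400)
    s <- outer(rep(1, gg$nx), sin(2 * pi * gg$y / gg$Ly))
    truth <- -(2 * pi / gg$Ly)^2 * s
    max(abs(laplacian(s, gg)[, 3:(gg$ny - 2)] -
              truth[, 3:(gg$ny - 2)]))
  }
  e1 <- err_for(20); e2 <- err_for(10)
  expect_gt(e1 / e2, 3.4)
  expect_error(make_grid(dx = 20, Lx = 400, lambda = 40), "ny >= 4")
})

test_that("flux divergence conserves mass and reduces to diffusion", {
  ts <- tiny_setup()
  g <- ts$grid; p <- ts$params; m <- ts$medium
  # uniform fields: no transport anywhere
  b <- matrix(0.01, g$nx, g$ny); cc <- matrix(100, g$nx, g$ny)
  expect_equal(flux_divergence(b, cc, g, p, m), matrix(0, g$nx, g$ny))
  # random dilute fields: discrete conservation to round-off
  set.seed(42)
  b <- matrix(1e-4 * runif(g$nx * g$ny), g$nx, g$ny)
  cc <- matrix(100 * runif(g$nx * g$ny), g$nx, g$ny)
  dv <- flux_divergence(b, cc, g, p, m)
  expect_lt(abs(sum(dv)), 1e-12 * max(abs(dv)) * g$nx * g$ny)
  # chi = 0, dilute b (correction 1): must equal Db * laplacian(b) on
  # the interior (at boundaries the zero-face-flux form and the
  # mirror-ghost Laplacian are different, equally valid no-flux
  # closures)
  p0 <- model_params(knockout = "chemotaxis")
  interior <- function(mm) mm[2:(g$nx - 1), 2:(g$ny - 1)]
  expect_equal(interior(flux_divergence(b, cc, g, p0, m)),
               interior(m$Db0 * laplacian(b, g)), tolerance = 1e-10)
  expect_error(flux_divergence(b * NA, cc, g, p, m), "non-finite")
})

test_that("compiled RHS agrees with the R reference implementation", {
  ts <- tiny_setup()
  g <- ts$grid; p <- ts$params; m <- ts$medium
  set.seed(7)
  # include crowded densities so the motility correction is exercised
  b <- matrix(runif(g$nx * g$ny, 0, 1), g$nx, g$ny)
  cc <- matrix(runif(g$nx * g$ny, 0, 1e4), g$nx, g$ny)
  r_ref <- ks_rhs(b, cc, g, p, m, include_consumption = TRUE)
  r_cpp <- chemosmooth:::cpp_rhs(b, cc, g$dx, p$Dc, p$kappa, p$c_half,
                                 p$gamma, p$c_minus, p$c_plus, FALSE,
                                 p$c_lin, m$Db0, m$chi0, m$f_pore, m$l_c,
                                 p$d_cell, TRUE)
  expect_equal(r_cpp$dbdt, r_ref$dbdt, tolerance = 1e-12)
  expect_equal(r_cpp$dcdt, r_ref$dcdt, tolerance = 1e-12)
})

test_that("RHS simplifies correctly in degenerate configurations", {
  ts <- tiny_setup()
  g <- ts$grid; p <- ts$params; m <- ts$medium
  cc <- outer(g$x / g$Lx, rep(1, g$ny)) * 100
  # b = 0: nutrient evolves by pure diffusion, no cell dynamics
  r <- ks_rhs(matrix(0, g$nx, g$ny), cc, g, p, m)
  expect_equal(r$dcdt, p$Dc * laplacian(cc, g))
  expect_equal(r$dbdt, matrix(0, g$nx, g$ny))
  # uniform state: operators vanish, only kinetics remain
  b <- matrix(0.01, g$nx, g$ny); cu <- matrix(50, g$nx, g$ny)
  r <- ks_rhs(b, cu, g, p, m)
  expect_equal(r$dcdt, matrix(-0.01 * p$kappa * 50 / 51, g$nx, g$ny))
  expect_equal(r$dbdt, matrix(0.01 * p$gamma * 50 / 51, g$nx, g$ny))
})

test_that("starter and ABM stepper reproduce exponential decay", {
  rhs <- function(t, y) -y
  h <- start_history(1, 0, rhs, 0.01)
  expect_equal(h$ys[[1]], 1)
  expect_equal(h$ys[[3]], exp(-0.02), tolerance = 1e-8)
  # dy/dt = 0: history exactly constant
  h0 <- start_history(2.5, 0, function(t, y) 0 * y, 0.1)
  expect_identical(unlist(h0$ys), c(2.5, 2.5, 2.5))

  # starter order >= 3: error drops >= 8x when dt halves
  starter_err <- function(dt) {
    n <- round(0.5 / (2 * dt))
    y <- 1; t <- 0
    for (k in seq_len(n)) {
      hh <- start_history(y, t, rhs, dt)
      y <- hh$ys[[3]]; t <- hh$t
    }
    abs(y - exp(-t))
  }
  expect_gt(starter_err(0.02) / starter_err(0.01), 8)

  # integrate dy/dt = -y to t = 1 with the PECE loop
  integrate_scalar <- function(dt) {
    hist <- start_history(1, 0, rhs, dt)
    n <- round(1 / dt)
    for (k in 3:n) hist <- abm_step(hist, rhs, dt)
    hist
  }
  hist <- integrate_scalar(0.01)
  expect_equal(hist$t, 1, tolerance = 1e-9)
  expect_equal(hist$ys[[3]], exp(-1), tolerance = 1e-5)
  # stationary problem: step is exact
  hs <- abm_step(start_history(3, 0, function(t, y) 0 * y, 0.1),
                 function(t, y) 0 * y, 0.1)
  expect_identical(hs$ys[[3]], 3)
  # global order >= 2: halving dt shrinks the error ~4x (allow
  # pre-asymptotic slack)
  e1 <- abs(integrate_scalar(0.02)$ys[[3]] - exp(-1))
  e2 <- abs(integrate_scalar(0.01)$ys[[3]] - exp(-1))
  expect_gt(e1 / e2, 3.5)
})

test_that("stiff consumption split matches a reference stiff solver", {
  p <- model_params()
  # packed cells deplete 10 mM nutrient: reference solution by lsoda
  b <- 0.95; c0 <- 1e4
  ref <- deSolve::lsoda(c(c = c0), seq(0, 1, by = 0.05),
                        function(t, y, parms) {
                          list(-b * p$kappa * max(y, 0) /
                                 (max(y, 0) + p$c_half))
                        }, NULL, rtol = 1e-10, atol = 1e-8)
  cc <- c0
  for (k in seq_len(20)) cc <- deplete_nutrient(cc, b, 0.05, p)
  # backward Euler at dt = 0.05 on a near-linear-decay segment
  expect_equal(cc, unname(ref[nrow(ref), "c"]), tolerance = 2e-2)
  # positivity and monotonicity even for huge steps
  expect_gt(deplete_nutrient(1e4, 0.95, 10, p), 0)
  expect_lt(deplete_nutrient(1e4, 0.95, 10, p), 1e4)
  # dilute/slow regime reduces to the explicit rate
  c1 <- deplete_nutrient(1e4, 1e-6, 0.05, p)
  expect_equal((1e4 - c1) / 0.05, 1e-6 * p$kappa * 1e4 / (1e4 + 1),
               tolerance = 1e-4)
})

test_that("pure-diffusion run conserves mass and matches the heat kernel", {
  # Gaussian ridge diffusing with constant Db (chi = gamma = kappa ~ 0)
  grid <- make_grid(dx = 10, Lx = 2000, lambda = 200)
  p <- model_params(kappa_printed = 1e-30, gamma = 0,
                    knockout = "chemotaxis")
  m <- porous_medium(1.7, Db0 = 2, chi0 = 0, f_pore = 0.17, l_c = 3.1)
  s0 <- 50
  b0 <- outer(grid$x, rep(1, grid$ny),
              function(x, y) 1e-4 * exp(-(x - 1000)^2 / (2 * s0^2)))
  cc0 <- make_uniform_nutrient(1e4, grid)
  run <- run_simulation(field_state(b0, cc0, 0, grid), grid, p, m,
                        integrator_config(dt = 0.02, output_interval = 600,
                                          max_time = 3600))
  tot <- run_totals(run)
  expect_lt(max(abs(tot$cells / tot$cells[1] - 1)), 1e-6)
  # analytic Gaussian spreading: sigma^2(t) = s0^2 + 2 Db t
  bT <- run$b[[length(run$b)]]
  tT <- run$times[length(run$times)]
  sT2 <- s0^2 + 2 * m$Db0 * tT
  truth <- 1e-4 * s0 / sqrt(sT2) * exp(-(grid$x - 1000)^2 / (2 * sT2))
  rel_l2 <- sqrt(sum((bT[, 3] - truth)^2) / sum(truth^2))
  expect_lt(rel_l2, 0.01)
})

test_that("chemotactic advection moves a dilute pulse at the exact drift speed", {
  # linear sensing with c = c_lin (v/chi) x gives a constant grad f =
  # v/chi, so a dilute Gaussian must advect rigidly at speed v; nutrient
  # dynamics are frozen by vanishing Dc and kappa
  grid <- make_grid(dx = 10, Lx = 3000, lambda = 40)
  v <- 0.2
  m <- porous_medium(1.7, Db0 = 1e-12, chi0 = 9, f_pore = 0.17, l_c = 3.1)
  p <- model_params(Dc = 1e-12, kappa_printed = 1e-30, gamma = 0,
                    sensing_mode = "linear")
  cc <- outer(grid$x, rep(1, grid$ny),
              function(x, y) p$c_lin * (v / m$chi0) * x)
  b0 <- outer(grid$x, rep(1, grid$ny),
              function(x, y) 1e-5 * exp(-(x - 800)^2 / (2 * 80^2)))
  run <- run_simulation(field_state(b0, cc, 0, grid), grid, p, m,
                        integrator_config(dt = 0.2, output_interval = 1000,
                                          max_time = 2000))
  bT <- run$b[[length(run$b)]]
  centroid <- function(b) sum(grid$x * b[, 2]) / sum(b[, 2])
  expect_equal(centroid(bT) - centroid(b0), v * 2000, tolerance = 1e-3)
  # shape is preserved (no spurious diffusion or steepening)
  expect_equal(max(bT) / max(b0), 1, tolerance = 0.01)
})

test_that("no-flux totals evolve monotonically and symmetry is preserved", {
  grid <- make_grid(dx = 40, Lx = 2000, lambda = 400)
  p <- model_params()
  m <- porous_medium(1.7)
  spec <- inoculum_spec(lambda = 400, A0 = 100, x_center = 600)
  b0 <- make_undulated_inoculum(spec, grid)
  run <- run_simulation(field_state(b0, make_uniform_nutrient(1e4, grid),
                                    0, grid), grid, p, m,
                        integrator_config(dt = 0.2, output_interval = 300,
                                          max_time = 1800))
  tot <- run_totals(run)
  # nutrient only ever consumed; cells only ever produced
  expect_true(all(diff(tot$nutrient) < 0))
  expect_true(all(diff(tot$cells) > 0))
  # initial condition is symmetric about y = lambda/2: stays symmetric
  bT <- run$b[[length(run$b)]]
  expect_equal(bT, bT[, rev(seq_len(grid$ny))], tolerance = 1e-10)
})

test_that("R and compiled engines produce the same trajectory", {
  grid <- make_grid(dx = 40, Lx = 1200, lambda = 160)
  p <- model_params()
  m <- porous_medium(1.7)
  spec <- inoculum_spec(lambda = 160, A0 = 40, x_center = 400)
  s0 <- field_state(make_undulated_inoculum(spec, grid),
                    make_uniform_nutrient(1e4, grid), 0, grid)
  cfg <- integrator_config(dt = 0.2, output_interval = 2, max_time = 10)
  r_cpp <- run_simulation(s0, grid, p, m, cfg, engine = "cpp")
  r_r <- run_simulation(s0, grid, p, m, cfg, engine = "r")
  expect_equal(r_cpp$times, r_r$times)
  last <- length(r_cpp$times)
  expect_equal(r_cpp$b[[last]], r_r$b[[last]], tolerance = 1e-10)
  expect_equal(r_cpp$c[[last]], r_r$c[[last]], tolerance = 1e-10)
})

test_that("integrator guards: stability check and zero-duration runs", {
  ts <- tiny_setup()
  s0 <- field_state(matrix(1e-4, ts$grid$nx, ts$grid$ny),
                    make_uniform_nutrient(1e4, ts$grid), 0, ts$grid)
  expect_error(
    run_simulation(s0, ts$grid, ts$params, ts$medium,
                   integrator_config(dt = 2, max_time = 10)),
    "stability")
  r0 <- run_simulation(s0, ts$grid, ts$params, ts$medium,
                       integrator_config(dt = 0.2, max_time = 0))
  expect_length(r0$times, 1L)
  expect_equal(r0$b[[1]], s0$b)
})
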