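test_that("Monod factor has its defining values and bounds", {
  p <- model_params()
  expect_equal(monod_g(p$c_half, p), 0.5)
  expect_equal(monod_g(0, p), 0)
  expect_equal(monod_g(9, p), 0.9)
  expect_error(monod_g(-1, p), "negative")

  cs <- 10^seq(-3, 6, length.out = 200)
  g <- monod_g(cs, p)
  expect_true(all(g >= 0 & g < 1))
  expect_true(all(diff(g) > 0))
})

test_that("sensing function: limits, linear variant, concavity", {
  p <- model_params()
  expect_equal(sensing_f(0, p), 0)
  # saturation limit log(c_plus/c_minus) = log 30
  expect_equal(sensing_f(1e9, p), log(30), tolerance = 1e-6)

  pl <- model_params(sensing_mode = "linear")
  expect_equal(pl$c_lin, 30 / 29)
  expect_equal(sensing_f(0, pl), 0)
  expect_equal(sensing_f(1, pl), 29 / 30)

  # concavity of the logarithmic form; exact linearity of the variant
  cs <- 10^seq(-2, 6, length.out = 120)
  h <- 1e-3 * cs
  d2 <- (sensing_f(cs + h, p) - 2 * sensing_f(cs, p) +
           sensing_f(cs - h, p)) / h^2
  expect_true(all(d2 < 0))
  d2l <- (sensing_f(cs + h, pl) - 2 * sensing_f(cs, pl) +
            sensing_f(cs - h, pl)) / h^2
  expect_true(all(abs(d2l) < 1e-6))
})

test_that("analytic response function matches numerical differentiation", {
  p <- model_params()
  expect_equal(sensing_fprime(0, p), 29 / 30)
  expect_lt(sensing_fprime(1e9, p), 1e-8)
  pl <- model_params(sensing_mode = "linear")
  expect_equal(sensing_fprime(123, pl), 29 / 30)

  cs <- 10^seq(-2, 5, length.out = 80)
  h <- 1e-5 * pmax(cs, 1)
  num <- (sensing_f(cs + h, p) - sensing_f(cs - h, p)) / (2 * h)
  expect_equal(sensing_fprime(cs, p), num, tolerance = 1e-6)
  # strictly decreasing (receptor saturation)
  expect_true(all(diff(sensing_fprime(cs, p)) < 0))
})

test_that("cell separation and motility correction behave as derived", {
  p <- model_params()
  m <- porous_medium(1.7)
  # l_cell = 0 exactly at b = 3 f / (4 pi d^3)
  b_jam <- 3 * m$f_pore / (4 * pi * p$d_cell^3)
  expect_equal(mean_cell_separation(b_jam, m, p), 0, tolerance = 1e-12)
  expect_equal(b_jam, 0.0406, tolerance = 1e-2)
  # l_cell = l_c at b = 3 f / (4 pi (l_c + d)^3)
  b_dilute <- 3 * m$f_pore / (4 * pi * (m$l_c + p$d_cell)^3)
  expect_equal(mean_cell_separation(b_dilute, m, p), m$l_c,
               tolerance = 1e-12)
  expect_equal(b_dilute, 5.89e-4, tolerance = 1e-2)
  expect_equal(mean_cell_separation(0, m, p), Inf)

  # correction: 1 at the dilute threshold, 0.25 at half separation,
  # 0 at the packed density (for every preset)
  expect_equal(motility_correction(b_dilute, m, p), 1)
  b_half <- 3 * m$f_pore / (4 * pi * (m$l_c / 2 + p$d_cell)^3)
  expect_equal(motility_correction(b_half, m, p), 0.25, tolerance = 1e-12)
  for (xi in c(1.2, 1.7, 2.2)) {
    expect_equal(motility_correction(0.95, porous_medium(xi), p), 0)
  }
  # non-increasing in density
  for (xi in c(1.2, 1.7, 2.2)) {
    mm <- porous_medium(xi)
    bs <- 10^seq(-6, 0, length.out = 100)
    expect_true(all(diff(motility_correction(bs, mm, p)) <= 0))
  }
})

test_that("reaction terms and unit conversion reproduce printed rates", {
  p <- model_params()
  # kappa round-trip through printed units is exact
  expect_identical(kappa_to_printed(kappa_to_internal(1.6e-11)), 1.6e-11)
  expect_equal(p$kappa, 1.6e4)

  b <- matrix(0.01, 4, 4); cc <- matrix(1e4, 4, 4)
  r <- reaction_terms(b, cc, p)
  expect_equal(r$consumption[1, 1], -0.01 * 1.6e4 * (1e4 / (1e4 + 1)),
               tolerance = 1e-12)
  expect_equal(r$consumption[1, 1], -160, tolerance = 1e-3)
  expect_true(all(r$growth >= 0))

  r0 <- reaction_terms(matrix(0, 4, 4), cc, p)
  expect_true(all(r0$consumption == 0) && all(r0$growth == 0))

  pg <- model_params(knockout = "growth")
  rg <- reaction_terms(b, cc, pg)
  expect_true(all(rg$growth == 0))
  expect_error(reaction_terms(matrix(0, 2, 2), matrix(0, 3, 3), p), "shape")
})

test_that("time-scale estimates match the slow passive mechanisms", {
  s1 <- scale_estimates(1000, 2.32, log(2) / 3600, 300, 2)
  expect_equal(s1$diffusive_hr, 1e6 / 2.32 / 3600, tolerance = 1e-12)
  s2 <- scale_estimates(1000, 0.42, log(2) / 3600, 300, 2)
  expect_equal(s2$diffusive_hr, 661.4, tolerance = 1e-3)
  s3 <- scale_estimates(1000, 2.32, 1 / 3600, 300, 2)
  expect_equal(s3$proliferative_hr, log2(150), tolerance = 1e-12)
  expect_error(scale_estimates(1000, 1, 1, 1, 2), "exceed")
})

test_that("medium presets carry the measured triples and validate", {
  tab <- medium_presets()
  expect_equal(tab$Db0[tab$xi == 2.2], 2.32)
  expect_equal(tab$chi0[tab$xi == 1.7], 9)
  expect_equal(tab$f_pore[tab$xi == 1.2], 0.04)
  expect_equal(tab$l_c, c(4.6, 3.1, 2.4))
  expect_error(porous_medium(3.0), "no preset")
  expect_error(porous_medium(1.7, Db0 = 1, chi0 = 1, f_pore = 1.2, l_c = 1),
               "f_pore")
})

test_that("parameter construction enforces invariants", {
  expect_error(model_params(c_minus = 30, c_plus = 1), "c_minus")
  expect_error(model_params(Dc = -1), "positive")
  p <- model_params(sensing_mode = "linear")
  expect_equal(1 / p$c_lin, 1 / p$c_minus - 1 / p$c_plus)
  pk <- model_params(knockout = "growth")
  expect_identical(pk$gamma, 0)
})
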