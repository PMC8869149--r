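test_that("structural functions match their analytic projections", {
  expect_equal(eval_structure(structural_model("sphere_surface", 100), 0),
               1 / 200)
  expect_equal(eval_structure(structural_model("sphere_surface", 100), 150),
               0)
  expect_equal(eval_structure(structural_model("sphere_volume", 100), 0),
               0.0075)
  expect_equal(eval_structure(structural_model("disc_solid", 100), 0),
               2 / (pi * 100))
  # ring rim: +Inf limit convention, zero outside support
  ring <- structural_model("disc_ring", 50)
  expect_identical(eval_structure(ring, c(-50, 50)), c(Inf, Inf))
  expect_identical(eval_structure(ring, c(-51, 51)), c(0, 0))
})

test_that("parameter validation rejects degenerate models", {
  expect_error(structural_model("sphere_surface", -1), "radius")
  expect_error(structural_model("sphere_surface", 0), "radius")
  expect_error(gaussian_kernel(0), "sigma")
  expect_error(gaussian_kernel(-5), "sigma")
  expect_error(eval_convolved(structural_model("sphere_surface", 50),
                              list(sigma = 10), 0), "gaussian_kernel")
  expect_error(model_profile(structural_model("sphere_surface", 50),
                             gaussian_kernel(10), amplitude = -1),
               "amplitude")
})

test_that("kernel and structural densities integrate to one", {
  k <- gaussian_kernel(17)
  expect_equal(integrate(function(x) dnorm(x, sd = k$sigma), -Inf, Inf,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  for (sh in c("sphere_surface", "sphere_volume", "disc_solid")) {
    m <- structural_model(sh, 60)
    expect_equal(integrate(function(x) eval_structure(m, x), -60, 60,
                           rel.tol = 1e-9)$value, 1, tolerance = 1e-8,
                 label = sh)
  }
  # ring: integrable despite the rim divergence (sine substitution)
  expect_equal(integrate(function(th) rep(1 / pi, length(th)),
                         -pi / 2, pi / 2)$value, 1, tolerance = 1e-6)
  m <- structural_model("disc_ring", 60)
  expect_equal(integrate(function(x) eval_structure(m, x), -60 + 1e-9,
                         60 - 1e-9, rel.tol = 1e-8,
                         subdivisions = 2000L)$value, 1, tolerance = 1e-6)
})

test_that("convolution conserves mass and is even, for every shape", {
  for (sh in c("sphere_surface", "sphere_volume", "disc_solid",
               "disc_ring")) {
    m <- structural_model(sh, 50)
    k <- gaussian_kernel(20)
    mass <- integrate(function(x) eval_convolved(m, k, x), -50 - 200,
                      50 + 200, rel.tol = 1e-9, subdivisions = 500L)$value
    expect_equal(mass, 1, tolerance = 1e-6, label = paste(sh, "mass"))
    xg <- seq(0.5, 170, length.out = 40)
    expect_equal(eval_convolved(m, k, xg), eval_convolved(m, k, -xg),
                 tolerance = 1e-12, label = paste(sh, "symmetry"))
  }
})

test_that("closed forms agree with the quadrature oracle to 1e-8", {
  # the full (R, sigma) grid runs in the acceptance suite; spot-check here
  cases <- list(c(25, 5), c(50, 20), c(100, 50))
  for (sh in c("sphere_surface", "sphere_volume", "disc_solid",
               "disc_ring")) {
    for (cs in cases) {
      m <- structural_model(sh, cs[1])
      k <- gaussian_kernel(cs[2])
      xg <- seq(-3 * cs[1], 3 * cs[1], length.out = 31)
      expect_lt(max(abs(eval_convolved(m, k, xg) -
                          quadrature_oracle(m, k, xg))), 1e-8)
    }
  }
})

test_that("oracle example value matches the analytic closed form", {
  m <- structural_model("sphere_surface", 50)
  k <- gaussian_kernel(20)
  expect_equal(eval_convolved(m, k, 0), 0.01 * (2 * pnorm(2.5) - 1),
               tolerance = 1e-10)
  expect_equal(quadrature_oracle(m, k, 0), 0.0098758067, tolerance = 1e-8)
})

test_that("sigma -> 0 recovers the structural function", {
  m <- structural_model("sphere_surface", 50)
  k <- gaussian_kernel(50e-6)
  xg <- seq(-45, 45, by = 5)
  expect_equal(eval_convolved(m, k, xg), eval_structure(m, xg),
               tolerance = 1e-6)
})

test_that("R -> 0 converges to the bare Gaussian kernel", {
  s <- 20
  xg <- seq(-100, 100, by = 1)
  for (sh in c("sphere_surface", "sphere_volume", "disc_solid",
               "disc_ring")) {
    m <- structural_model(sh, s / 1000)
    d <- eval_convolved(m, gaussian_kernel(s), xg)
    expect_lt(max(abs(d - dnorm(xg, sd = s))), 1e-6, label = sh)
  }
})

test_that("disc_ring convolution is finite and bimodal at moderate blur", {
  m <- structural_model("disc_ring", 50)
  k <- gaussian_kernel(20)
  xg <- seq(-100, 100, by = 1)
  v <- eval_convolved(m, k, xg)
  expect_true(all(is.finite(v)))
  locmax <- which(diff(sign(diff(v))) == -2) + 1L
  expect_length(locmax, 2L)
  expect_equal(xg[locmax[1]], -xg[locmax[2]])
  expect_gt(abs(xg[locmax[1]]), 0)
})

test_that("sphere-surface FWHM grows with R and with sigma", {
  fwhm_of <- function(R, s) {
    D <- function(x) eval_convolved(structural_model("sphere_surface", R),
                                    gaussian_kernel(s), x)
    h <- D(0) / 2
    2 * uniroot(function(x) D(x) - h, c(0, R + 10 * s), tol = 1e-10)$root
  }
  Rs <- c(20, 50, 100, 200)
  ss <- c(5, 20, 50)
  for (s in ss) {
    w <- vapply(Rs, fwhm_of, numeric(1), s = s)
    expect_true(all(diff(w) > 0))
  }
  for (R in Rs) {
    w <- vapply(ss, function(s) fwhm_of(R, s), numeric(1))
    expect_true(all(diff(w) >= 0))
  }
})

test_that("model profile predicts counts above background and conserves mass", {
  mp <- model_profile(structural_model("sphere_volume", 80),
                      gaussian_kernel(15), amplitude = 3000,
                      background = 4, center = -20)
  xg <- seq(-600, 560, by = 4)
  pred <- predict(mp, xg, 4)
  expect_true(all(pred >= mp$background))
  # with background 0, total counts over a wide window equal the amplitude
  mp0 <- model_profile(mp$model, mp$kernel, amplitude = 3000, center = -20)
  expect_equal(sum(predict(mp0, xg, 4)), 3000, tolerance = 1e-4)
})
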