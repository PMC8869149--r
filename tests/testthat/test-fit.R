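test_that("initial_guess lands near the truth on clean profiles", {
  prof <- make_model_profile(R = 100, sigma = 20, A = 5000, b = 2,
                             center = 13)
  g <- initial_guess(prof, "sphere_surface")
  expect_lt(abs(g$center - 13), prof$bin_width)
  expect_gt(g$model$radius, prof$bin_width - 1e-12)
  expect_true(is.finite(g$amplitude) && g$amplitude > 0)
})

test_that("initial_guess degenerate inputs follow the contract", {
  x <- seq(-50, 55, by = 5)
  expect_error(initial_guess(line_profile(x, rep(0, length(x))),
                             "sphere_surface"), "all-zero")
  # uniform plateau: no FWHM, falls back to the span heuristic
  g <- initial_guess(line_profile(x, rep(9, length(x))), "sphere_surface")
  expect_equal(g$model$radius, (max(x) - min(x)) / 2)
  expect_error(initial_guess(line_profile(seq(0, 20, by = 5), 1:5),
                             "sphere_surface"), "8 bins")
})

test_that("initial radius is within a factor 2 on simulated spheres", {
  ok <- vapply(1:25, function(s) {
    prof <- sim_sphere_profile(seed = 500 + s, n_fluor = 667L)
    r <- initial_guess(prof, "sphere_surface")$model$radius
    r > 25 && r < 100
  }, logical(1))
  expect_true(all(ok))
})

test_that("noiseless self-consistency recovers all parameters to 1e-6", {
  for (sh in c("sphere_surface", "sphere_volume", "disc_solid",
               "disc_ring")) {
    prof <- make_model_profile(shape = sh, R = 100, sigma = 20, A = 5000,
                               b = 2, center = 13)
    fit <- fit_sba(prof, sh)
    expect_true(fit$converged, label = sh)
    expect_equal(fit$diameter_hat, 200, tolerance = 1e-6, label = sh)
    expect_equal(fit$sigma_hat, 20, tolerance = 1e-6, label = sh)
    expect_equal(fit$amplitude_hat, 5000, tolerance = 1e-6, label = sh)
    expect_equal(fit$background_hat, 2, tolerance = 1e-6, label = sh)
    expect_equal(fit$center_hat, 13, tolerance = 1e-6 * 13, label = sh)
    expect_lte(fit$rss, fit$rss_initial)
  }
})

test_that("fix_sigma is honored and reduces the free parameter count", {
  prof <- make_model_profile(R = 75, sigma = 18, A = 4000, b = 1,
                             center = 0)
  fit <- fit_sba(prof, "sphere_surface", fix_sigma = 18)
  expect_identical(fit$sigma_hat, 18)
  expect_true(fit$sigma_fixed)
  expect_true(is.na(fit$stderr[["sigma"]]))
  expect_equal(fit$diameter_hat, 150, tolerance = 1e-6)
  expect_equal(fit$dof, length(prof$counts) - 4L)
})

test_that("poisson weighting runs and stays close on clean data", {
  prof <- make_model_profile(R = 100, sigma = 20, A = 5000, b = 2)
  fit <- fit_sba(prof, "sphere_surface", weights = "poisson")
  expect_equal(fit$diameter_hat, 200, tolerance = 1e-5)
})

test_that("underdetermined fits are refused", {
  x <- seq(0, 35, by = 5)
  prof <- line_profile(x, c(1, 2, 5, 9, 8, 4, 2, 1))
  # 8 bins support a 5-parameter fit; 5 bins must not
  expect_error(fit_sba(line_profile(x[1:5], c(1, 5, 9, 5, 1))),
               "at least 8 bins|underdetermined")
})

test_that("fit is translation- and scale-equivariant", {
  prof <- make_model_profile(R = 100, sigma = 20, A = 5000, b = 2,
                             center = 0)
  fit0 <- fit_sba(prof, "sphere_surface")
  delta <- 137.5
  shifted <- line_profile(prof$bin_centers + delta, prof$counts,
                          bin_width = prof$bin_width)
  fit1 <- fit_sba(shifted, "sphere_surface")
  expect_equal(fit1$center_hat - fit0$center_hat, delta, tolerance = 1e-9)
  expect_equal(fit1$diameter_hat, fit0$diameter_hat, tolerance = 1e-9)
  cc <- 3
  scaled <- line_profile(prof$bin_centers * cc, prof$counts,
                         bin_width = prof$bin_width * cc)
  fit2 <- fit_sba(scaled, "sphere_surface")
  expect_equal(fit2$diameter_hat, cc * fit0$diameter_hat,
               tolerance = 1e-9 * cc * fit0$diameter_hat)
  expect_equal(fit2$sigma_hat, cc * fit0$sigma_hat, tolerance = 1e-6)
})

test_that("Monte-Carlo sphere recovery: accurate mean, SBA beats FWHM", {
  # reduced-scale version of the 100-replicate property (30 replicates,
  # d = 100 nm, sigma_loc = 20 nm, ~1000 localizations); the full-scale
  # run lives in the acceptance suite
  profs <- lapply(1:30, function(s) sim_sphere_profile(seed = 2000 + s))
  cmp <- compare_estimators(profs, "sphere_surface", true_size = 100,
                            fix_sigma = 20)
  s <- cmp$summary
  expect_lt(abs(s$mean[s$estimator == "sba"] - 100) / 100, 0.05)
  expect_lt(s$sd[s$estimator == "sba"], s$sd[s$estimator == "fwhm"])
  expect_true(all(s$n == 30))
})

test_that("compare_estimators honors its contract on edge cases", {
  prof <- make_model_profile(R = 50, sigma = 15, A = 2000, b = 0,
                             center = 0, from = -200, to = 200)
  cmp <- compare_estimators(list(prof, prof), "sphere_surface")
  expect_equal(cmp$summary$sd, c(0, 0), tolerance = 1e-9)
  expect_false("bias" %in% names(cmp$summary))
  cmp2 <- compare_estimators(list(prof, prof), "sphere_surface",
                             true_size = 100)
  expect_true(all(c("bias", "rmse") %in% names(cmp2$summary)))
  expect_error(compare_estimators(list(prof), "sphere_surface"), "2")
})

test_that("fit reports serialize to JSON and delimited tables", {
  prof <- make_model_profile(R = 60, sigma = 15, A = 1000, b = 1)
  fit <- fit_sba(prof, "sphere_surface")
  df <- as.data.frame(fit)
  expect_equal(df$name, c("diameter", "sigma", "amplitude", "background",
                          "center"))
  tf <- tempfile(fileext = ".json")
  write_fit_report(fit, tf, "json")
  back <- jsonlite::read_json(tf)
  expect_equal(back$diameter_hat, fit$diameter_hat, tolerance = 1e-9)
  tf2 <- tempfile(fileext = ".csv")
  write_fit_report(fit, tf2, "csv")
  expect_equal(nrow(read.csv(tf2)), 5L)
})
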