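test_that("density closed-form values and normalization", {
  expect_equal(dist_pdf(dist_spec("Normal", mu = 0, sigma = 1), 0),
               1 / sqrt(2 * pi), tolerance = 1e-10)
  expect_equal(dist_pdf(dist_spec("Exponential", mu = 2), 0), 0.5,
               tolerance = 1e-12)
  w <- dist_spec("Weibull", alpha = 2, beta = 1)
  expect_equal(integrate_pdf(w, 0, Inf), 1, tolerance = 1e-8)
})

test_that("density integrates to 1 for randomized valid parameters", {
  withr::with_seed(7, {
    for (fam in roc_families()) {
      for (rep in 1:3) {
        spec <- random_spec(fam)
        b <- support_bounds(spec)
        expect_equal(integrate_pdf(spec, b[1], b[2]), 1, tolerance = 1e-6,
                     label = paste("integral of", fam, "density"))
      }
    }
  })
})

test_that("densities vanish outside the support", {
  expect_equal(dist_pdf(dist_spec("Weibull", alpha = 2, beta = 1), -1), 0)
  expect_equal(dist_pdf(dist_spec("GP", k = 0.3, sigma = 1), -0.5), 0)
  gp_neg <- dist_spec("GP", k = -0.5, sigma = 1)     # support [0, 2]
  expect_equal(dist_pdf(gp_neg, 2.5), 0)
  gev <- dist_spec("GEV", k = 0.5, sigma = 1, mu = 0) # support x > -2
  expect_equal(dist_pdf(gev, -3), 0)
})

test_that("cdf closed-form values, limits and family identities", {
  expect_equal(dist_cdf(dist_spec("Weibull", alpha = 2, beta = 1), 1),
               1 - exp(-1), tolerance = 1e-12)
  expect_equal(dist_cdf(dist_spec("Exponential", mu = 1), 0), 0)
  g <- dist_spec("Gamma", alpha = 1, beta = 0.5)
  e <- dist_spec("Exponential", mu = 2)
  x <- seq(0.01, 20, length.out = 200)
  expect_equal(dist_cdf(g, x), dist_cdf(e, x), tolerance = 1e-10)
  # nondecreasing on a grid for every family
  withr::with_seed(8, {
    for (fam in roc_families()) {
      spec <- random_spec(fam)
      x <- sort(dist_sample(spec, 200, seed = 1))
      expect_true(all(diff(dist_cdf(spec, x)) >= 0), label = fam)
    }
  })
})

test_that("quantile function inverts the cdf for all families", {
  expect_equal(dist_icdf(dist_spec("Exponential", mu = 2), 0.5),
               -2 * log(0.5), tolerance = 1e-9)
  expect_equal(dist_icdf(dist_spec("Weibull", alpha = 2, beta = 1),
                         1 - exp(-1)), 1, tolerance = 1e-9)
  gev <- dist_spec("GEV", k = 0.5, sigma = 1, mu = 0)
  expect_equal(dist_cdf(gev, dist_icdf(gev, exp(-1))), exp(-1),
               tolerance = 1e-9)
  p <- c(0.001, 0.05, 0.3, 0.5, 0.7, 0.95, 0.999)
  withr::with_seed(9, {
    for (fam in roc_families()) {
      spec <- random_spec(fam)
      expect_equal(dist_cdf(spec, dist_icdf(spec, p)), p, tolerance = 1e-9,
                   label = paste(fam, "cdf(icdf(p))"))
      x <- dist_sample(spec, 50, seed = 2)
      expect_equal(dist_icdf(spec, dist_cdf(spec, x)), x, tolerance = 1e-7,
                   label = paste(fam, "icdf(cdf(x))"))
    }
  })
  expect_error(dist_icdf(dist_spec("Normal", mu = 0, sigma = 1), 1.2),
               "probabilities")
})

test_that("sampling is reproducible, in-support, and mean-consistent", {
  e <- dist_spec("Exponential", mu = 1)
  x <- dist_sample(e, 1e5, seed = 11)
  expect_length(x, 1e5)
  expect_lt(abs(mean(x) - 1), 3 / sqrt(1e5))
  expect_identical(x, dist_sample(e, 1e5, seed = 11))
  w <- dist_sample(dist_spec("Weibull", alpha = 2, beta = 1), 10, seed = 3)
  expect_true(all(w > 0))
})

test_that("closed-form MLEs: Normal and Exponential", {
  f <- fit_dist(c(1, 2, 3, 4), "Normal")
  expect_equal(unname(f$spec$params["mu"]), 2.5)
  expect_equal(unname(f$spec$params["sigma"]), sqrt(mean((1:4 - 2.5)^2)),
               tolerance = 1e-10)
  expect_equal(unname(f$spec$params["sigma"]), 1.11803, tolerance = 1e-5)
  e <- fit_dist(c(0.5, 1.5, 2), "Exponential")
  expect_equal(unname(e$spec$params["mu"]), mean(c(0.5, 1.5, 2)))
  expect_true(is.finite(f$loglik) && f$converged)
})

test_that("Weibull and Gamma MLEs satisfy their score equations", {
  x <- dist_sample(dist_spec("Weibull", alpha = 1.7, beta = 2.2), 800,
                   seed = 21)
  w <- fit_dist(x, "Weibull")
  a <- w$spec$params[["alpha"]]
  b <- w$spec$params[["beta"]]
  # scale equation residual and profile shape-equation residual
  expect_lt(abs(b - mean(x^a)^(1 / a)), 1e-8)
  expect_lt(abs(sum(x^a * log(x)) / sum(x^a) - 1 / a - mean(log(x))), 1e-8)

  y <- dist_sample(dist_spec("Gamma", alpha = 2.5, beta = 1.3), 800, seed = 22)
  g <- fit_dist(y, "Gamma")
  ag <- g$spec$params[["alpha"]]
  expect_lt(abs(log(ag) - digamma(ag) - (log(mean(y)) - mean(log(y)))), 1e-8)
  expect_equal(g$spec$params[["beta"]], ag / mean(y), tolerance = 1e-10)
})

test_that("maximum-likelihood fits recover generating parameters", {
  x <- dist_sample(dist_spec("Gamma", alpha = 2, beta = 2), 5000, seed = 42)
  g <- fit_dist(x, "Gamma")
  expect_lt(abs(g$spec$params[["alpha"]] - 2), 0.15)

  # bias shrinks with n for a spread of families
  cases <- list(
    list(fam = "Weibull", spec = dist_spec("Weibull", alpha = 2, beta = 1),
         par = "alpha", truth = 2),
    list(fam = "EV", spec = dist_spec("EV", mu = 1, sigma = 2),
         par = "sigma", truth = 2),
    list(fam = "GP", spec = dist_spec("GP", k = 0.2, sigma = 1),
         par = "k", truth = 0.2)
  )
  for (cs in cases) {
    err <- vapply(c(500, 5000), function(n) {
      f <- fit_dist(dist_sample(cs$spec, n, seed = 77), cs$fam)
      abs(f$spec$params[[cs$par]] - cs$truth)
    }, numeric(1))
    expect_lt(err[2], err[1] + 0.02)
    expect_lt(err[2], 0.15)
  }
})

test_that("fits agree with an independent fitting library", {
  skip_if_not_installed("fitdistrplus")
  x <- dist_sample(dist_spec("Weibull", alpha = 1.4, beta = 2), 1000,
                   seed = 31)
  ours <- fit_dist(x, "Weibull")
  ref <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(unname(ours$spec$params["alpha"]),
               unname(ref$estimate[["shape"]]), tolerance = 1e-3)
  expect_equal(unname(ours$spec$params["beta"]),
               unname(ref$estimate[["scale"]]), tolerance = 1e-3)
  y <- dist_sample(dist_spec("Gamma", alpha = 3, beta = 1.5), 1000, seed = 32)
  oursg <- fit_dist(y, "Gamma")
  refg <- fitdistrplus::fitdist(y, "gamma")
  expect_equal(unname(oursg$spec$params["alpha"]),
               unname(refg$estimate[["shape"]]), tolerance = 1e-3)
})

test_that("support violations and bad parameters raise clear errors", {
  expect_error(fit_dist(c(-1, 1, 2), "Weibull"), "fit-infeasible")
  expect_error(fit_dist(c(-1, 1, 2), "GP"), "fit-infeasible")
  expect_error(dist_spec("Normal", mu = 0, sigma = -1), "sigma > 0")
  expect_error(dist_spec("Gamma", alpha = -2, beta = 1), "alpha > 0")
  expect_error(dist_spec("Nope", mu = 0), "unknown family")
  f <- fit_dist(rep(3, 10), "Normal")    # constant data: flagged, not fatal
  expect_false(f$converged)
})

test_that("feasibility filtering keeps only families matching the support", {
  x <- c(rnorm(50), -2)
  fits <- fit_all_families(x)
  expect_setequal(names(fits), c("Normal", "EV", "GEV"))
  y <- abs(rnorm(50)) + 0.1
  expect_setequal(names(fit_all_families(y)), roc_families())
})

test_that("tidy and glance summarize fitted distributions", {
  f <- fit_dist(dist_sample(dist_spec("Weibull", alpha = 2, beta = 1), 300,
                            seed = 5), "Weibull")
  td <- tidy(f)
  expect_equal(td$term, c("alpha", "beta"))
  gl <- glance(f)
  expect_equal(gl$n, 300L)
  expect_true(gl$converged)
})
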