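# Shared oracle helpers: independent brute-force computations the tests
# compare the package against.

# numeric quadrature of a density over its support
integrate_pdf <- function(spec, lower, upper) {
  stats::integrate(function(x) dist_pdf(spec, x), lower, upper,
                   rel.tol = 1e-10, subdivisions = 500L)$value
}

# dense-trapezoid AUC of a Universal ROC function (oracle for quadrature)
trapezoid_auc <- function(pair, n_grid = 1e6) {
  p <- seq(0, 1, length.out = n_grid + 1)
  pracma::trapz(p, uroc_function(pair)(p))
}

# closed-form binormal AUC
binormal_auc <- function(mu1, s1, mu0, s0) {
  stats::pnorm((mu1 - mu0) / sqrt(s0^2 + s1^2))
}

# a small pool of valid parameter draws per family for property tests
random_spec <- function(family) {
  switch(family,
    Normal      = dist_spec("Normal", mu = stats::runif(1, -2, 2),
                            sigma = stats::runif(1, 0.3, 3)),
    Exponential = dist_spec("Exponential", mu = stats::runif(1, 0.3, 4)),
    Weibull     = dist_spec("Weibull", alpha = stats::runif(1, 0.6, 4),
                            beta = stats::runif(1, 0.4, 3)),
    Gamma       = dist_spec("Gamma", alpha = stats::runif(1, 0.6, 5),
                            beta = stats::runif(1, 0.3, 3)),
    EV          = dist_spec("EV", mu = stats::runif(1, -1, 2),
                            sigma = stats::runif(1, 0.3, 2)),
    GEV         = dist_spec("GEV", k = stats::runif(1, -0.3, 0.5),
                            sigma = stats::runif(1, 0.4, 2),
                            mu = stats::runif(1, -1, 1)),
    GP          = dist_spec("GP", k = stats::runif(1, -0.3, 0.4),
                            sigma = stats::runif(1, 0.4, 2), mu = 0)
  )
}

support_bounds <- function(spec) {
  p <- spec$params
  switch(spec$family,
    Normal = c(-Inf, Inf),
    EV = c(-Inf, Inf),
    Exponential = c(0, Inf),
    Weibull = c(0, Inf),
    Gamma = c(0, Inf),
    GEV = if (abs(p[["k"]]) < 1e-9) c(-Inf, Inf)
          else if (p[["k"]] > 0) c(p[["mu"]] - p[["sigma"]] / p[["k"]], Inf)
          else c(-Inf, p[["mu"]] - p[["sigma"]] / p[["k"]]),
    GP = if (p[["k"]] >= 0) c(p[["mu"]], Inf)
         else c(p[["mu"]], p[["mu"]] - p[["sigma"]] / p[["k"]])
  )
}
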