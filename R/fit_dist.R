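# Maximum-likelihood fitting for the seven families. Weibull and Gamma use
# their score-equation reductions (profile shape equation and the digamma
# equation); Normal/Exponential are closed-form; EV/GEV/GP are fitted by
# bounded quasi-Newton on log-scale parameters with moment starts.

new_fitted_dist <- function(spec, loglik, n, converged, notes = "") {
  structure(
    list(spec = spec, loglik = loglik, n = n, converged = converged,
         notes = notes),
    class = "fitted_dist"
  )
}

#' @export
print.fitted_dist <- function(x, ...) {
  cat("<fitted_dist> ", x$spec$family, "(",
      paste(sprintf("%s = %.5g", names(x$spec$params), x$spec$params),
            collapse = ", "),
      ")  logLik = ", format(x$loglik, digits = 6),
      "  n = ", x$n,
      if (!x$converged) "  [not converged]" else "", "\n", sep = "")
  if (nzchar(x$notes)) cat("  note: ", x$notes, "\n", sep = "")
  invisible(x)
}

# Profile equation for the Weibull shape: the scale equation
# beta = (mean(x^alpha))^(1/alpha) substituted into the shape score gives
# h(alpha) = sum(x^a log x)/sum(x^a) - 1/a - mean(log x) = 0, strictly
# increasing in alpha. Solved by safeguarded Newton.
weibull_shape_equation <- function(a, x, mlog) {
  xa <- x^a
  sum(xa * log(x)) / sum(xa) - 1 / a - mlog
}

fit_weibull_mle <- function(x, tol = 1e-10, maxit = 500) {
  mlog <- mean(log(x))
  # Menon-type moment start from the log-scale spread
  s <- stats::sd(log(x))
  a <- if (is.finite(s) && s > 0) 1.2 / (s * sqrt(6) / pi) else 1
  a <- max(a, 1e-3)
  converged <- FALSE
  for (i in seq_len(maxit)) {
    h <- weibull_shape_equation(a, x, mlog)
    eps <- 1e-6 * max(a, 1)
    dh <- (weibull_shape_equation(a + eps, x, mlog) - h) / eps
    step <- h / dh
    a_new <- a - step
    if (!is.finite(a_new) || a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < tol * max(1, a)) {
      a <- a_new
      converged <- TRUE
      break
    }
    a <- a_new
  }
  beta <- mean(x^a)^(1 / a)
  list(alpha = a, beta = beta, converged = converged)
}

# Gamma shape from the digamma equation log(a) - psi(a) = log(mean) -
# mean(log x); rate follows as beta = alpha / mean.
fit_gamma_mle <- function(x, tol = 1e-12) {
  s <- log(mean(x)) - mean(log(x))
  if (s <= 0) {
    return(list(alpha = NA_real_, beta = NA_real_, converged = FALSE))
  }
  start <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  g <- function(a) log(a) - digamma(a) - s
  lo <- start / 10
  hi <- start * 10
  while (g(lo) < 0 && lo > 1e-10) lo <- lo / 10
  while (g(hi) > 0 && hi < 1e10) hi <- hi * 10
  root <- stats::uniroot(g, c(lo, hi), tol = tol)
  alpha <- root$root
  list(alpha = alpha, beta = alpha / mean(x), converged = TRUE)
}

# Generic bounded quasi-Newton fit on transformed parameters. `to_par` maps
# the optimizer vector to a named parameter vector for dist_spec.
fit_numeric_mle <- function(family, x, start, to_par, maxit = 500) {
  nll <- function(theta) {
    par <- to_par(theta)
    spec <- try(dist_spec(family, par), silent = TRUE)
    if (inherits(spec, "try-error")) return(1e10)
    ll <- dist_loglik(spec, x)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  opt <- try(stats::optim(start, nll, method = "BFGS",
                          control = list(maxit = maxit, reltol = 1e-12)),
             silent = TRUE)
  if (inherits(opt, "try-error")) {
    opt <- stats::optim(start, nll, method = "Nelder-Mead",
                        control = list(maxit = 2000))
  }
  # polish with Nelder-Mead if BFGS stopped on a penalty plateau
  if (opt$value >= 1e9) {
    opt <- stats::optim(start, nll, method = "Nelder-Mead",
                        control = list(maxit = 5000))
  }
  list(par = to_par(opt$par), value = opt$value,
       converged = opt$convergence == 0 && opt$value < 1e9)
}

#' Fit a distribution family by maximum likelihood
#'
#' Normal and Exponential have closed-form MLEs (the Normal scale uses the
#' divisor-`n` MLE). The Weibull shape solves its profile score equation by
#' safeguarded Newton iteration and the scale follows in closed form; the
#' Gamma shape solves the digamma equation and the rate is `alpha / mean`.
#' EV, GEV and GP are fitted by numeric likelihood maximization with
#' method-of-moments starting values; the GP location is fixed at 0.
#'
#' @param x Numeric data vector (strictly positive for Exponential, Weibull,
#'   Gamma and GP).
#' @param family One of [roc_families()].
#' @return A `fitted_dist` object: the estimated [dist_spec()], the attained
#'   log-likelihood, the sample size, and a convergence flag.
#' @export
#' @examples
#' fit_dist(dist_sample(dist_spec("Gamma", alpha = 2, beta = 2), 500, seed = 1),
#'          "Gamma")
fit_dist <- function(x, family) {
  family <- match_family(family)
  x <- as.numeric(x)
  if (length(x) == 0 || any(!is.finite(x))) {
    stop("data must be a nonempty finite numeric vector", call. = FALSE)
  }
  if (!dist_support_ok(family, x)) {
    stop("fit-infeasible: ", family,
         " requires strictly positive data", call. = FALSE)
  }
  n <- length(x)

  if (stats::sd(x) == 0) {
    # constant data: degenerate; report a Normal-style point mass guard
    spec <- if (family == "Normal") {
      dist_spec("Normal", mu = mean(x), sigma = 1e-12)
    } else {
      stop("fit-infeasible: constant data cannot identify ", family,
           " parameters", call. = FALSE)
    }
    return(new_fitted_dist(spec, loglik = NA_real_, n = n, converged = FALSE,
                           notes = "constant data; sigma floored at 1e-12"))
  }

  res <- switch(family,
    Normal = {
      mu <- mean(x)
      sigma <- sqrt(mean((x - mu)^2))
      list(spec = dist_spec("Normal", mu = mu, sigma = sigma), converged = TRUE)
    },
    Exponential = {
      list(spec = dist_spec("Exponential", mu = mean(x)), converged = TRUE)
    },
    Weibull = {
      w <- fit_weibull_mle(x)
      list(spec = dist_spec("Weibull", alpha = w$alpha, beta = w$beta),
           converged = w$converged)
    },
    Gamma = {
      g <- fit_gamma_mle(x)
      if (!g$converged) {
        stop("fit-infeasible: Gamma digamma equation has no root ",
             "(zero log-moment spread)", call. = FALSE)
      }
      list(spec = dist_spec("Gamma", alpha = g$alpha, beta = g$beta),
           converged = TRUE)
    },
    EV = {
      s0 <- stats::sd(x) * sqrt(6) / pi
      m0 <- mean(x) + 0.5772156649 * s0    # min-Gumbel mean is mu - gamma*sigma
      f <- fit_numeric_mle("EV", x, c(m0, log(s0)),
                           function(th) c(mu = th[1], sigma = exp(th[2])))
      list(spec = dist_spec("EV", f$par), converged = f$converged)
    },
    GEV = {
      s0 <- stats::sd(x) * sqrt(6) / pi
      m0 <- mean(x) - 0.5772156649 * s0    # max-Gumbel moment start
      f <- fit_numeric_mle("GEV", x, c(0.1, log(s0), m0),
                           function(th) c(k = th[1], sigma = exp(th[2]),
                                          mu = th[3]))
      list(spec = dist_spec("GEV", f$par), converged = f$converged)
    },
    GP = {
      m <- mean(x); v <- stats::var(x)
      k0 <- (1 - m^2 / v) / 2
      k0 <- min(max(k0, -0.9), 0.45)
      s0 <- m * (1 - k0)
      f <- fit_numeric_mle("GP", x, c(k0, log(max(s0, 1e-8))),
                           function(th) c(k = th[1], sigma = exp(th[2]),
                                          mu = 0))
      list(spec = dist_spec("GP", f$par), converged = f$converged)
    }
  )

  new_fitted_dist(res$spec, loglik = dist_loglik(res$spec, x), n = n,
                  converged = res$converged)
}

#' Fit every feasible family to one sample
#'
#' Applies [fit_dist()] for each requested family, skipping families whose
#' support the data violate (e.g. positive-support families on data with
#' negative values).
#'
#' @param x Numeric data vector.
#' @param families Families to try; defaults to all seven.
#' @return Named list of `fitted_dist` objects for the feasible families.
#' @export
fit_all_families <- function(x, families = roc_families()) {
  families <- vapply(families, match_family, character(1))
  feasible <- families[vapply(families, dist_support_ok, logical(1), x = x)]
  fits <- lapply(feasible, function(f) {
    tryCatch(fit_dist(x, f), error = function(e) NULL)
  })
  names(fits) <- feasible
  fits[!vapply(fits, is.null, logical(1))]
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted distribution
#'
#' @param x A `fitted_dist` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`family`, `term`, `estimate`).
#' @export
tidy.fitted_dist <- function(x, ...) {
  tibble::tibble(
    family = x$spec$family,
    term = names(x$spec$params),
    estimate = unname(x$spec$params)
  )
}

#' One-row summary of a fitted distribution
#'
#' @param x A `fitted_dist` object.
#' @param ... Unused.
#' @return A tibble with `family`, `logLik`, `n`, `n_par`, `converged`.
#' @export
glance.fitted_dist <- function(x, ...) {
  tibble::tibble(
    family = x$spec$family,
    logLik = x$loglik,
    n = x$n,
    n_par = length(x$spec$params),
    converged = x$converged
  )
}
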