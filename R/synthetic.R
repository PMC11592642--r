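# Synthetic-data generators. The feature-table generator emulates the shape
# of a two-class numeric benchmark (569 instances x 30 features by default,
# the Wisconsin-breast-cancer layout) with a configurable planted informative
# subset; the score generator draws per-class samples from any two
# distribution specifications at the study's 200/300 class sizes.

#' Synthetic two-class Gaussian feature table
#'
#' Features are independent Gaussians with standard deviation `noise_sd`.
#' The first `n_informative` columns are shifted upward by
#' `effect_size * noise_sd` in class 1; the remaining columns are pure noise.
#'
#' @param n_instances Number of rows (default 569).
#' @param n_features Number of feature columns (default 30).
#' @param n_informative Number of planted informative features (default 5).
#' @param class_balance Proportion of class-1 rows (default 0.373, the
#'   malignant fraction of the emulated benchmark).
#' @param effect_size Standardized mean shift of informative features in
#'   class 1 (default 2).
#' @param noise_sd Feature standard deviation (default 1).
#' @param seed Integer seed (local RNG state).
#' @return Tibble with columns `f1 ... f<n_features>` and 0/1 `label`;
#'   attribute `informative` records the planted column indices.
#' @export
#' @examples
#' simulate_feature_table(n_instances = 50, n_features = 4, n_informative = 1,
#'                        seed = 1)
simulate_feature_table <- function(n_instances = 569, n_features = 30,
                                   n_informative = 5, class_balance = 0.373,
                                   effect_size = 2, noise_sd = 1, seed = 1) {
  stopifnot(n_informative <= n_features, class_balance > 0, class_balance < 1)
  withr::with_seed(seed, {
    n1 <- round(n_instances * class_balance)
    y <- sample(c(rep(1L, n1), rep(0L, n_instances - n1)))
    x <- matrix(stats::rnorm(n_instances * n_features, sd = noise_sd),
                n_instances, n_features)
    if (n_informative > 0) {
      shift <- effect_size * noise_sd
      x[y == 1L, seq_len(n_informative)] <-
        x[y == 1L, seq_len(n_informative)] + shift
    }
    colnames(x) <- paste0("f", seq_len(n_features))
    out <- tibble::as_tibble(x)
    out$label <- y
    attr(out, "informative") <- seq_len(n_informative)
    out
  })
}

#' Synthetic score/label sample from a generating pair
#'
#' Draws `n_pos` scores from the positive-class distribution and `n_neg` from
#' the negative-class distribution, labels them 1/0, and shuffles the rows.
#'
#' @param pos,neg Generating [dist_spec()]s.
#' @param n_pos,n_neg Class sizes (defaults 300 and 200).
#' @param seed Integer seed (local RNG state).
#' @return Tibble with columns `score` and `label`.
#' @export
#' @examples
#' simulate_scores(dist_spec("Weibull", alpha = 2, beta = 1),
#'                 dist_spec("Gamma", alpha = 2, beta = 2), seed = 1)
simulate_scores <- function(pos, neg, n_pos = 300, n_neg = 200, seed = 1) {
  withr::with_seed(seed, {
    s <- c(dist_icdf(as_dist_spec(pos), stats::runif(n_pos)),
           dist_icdf(as_dist_spec(neg), stats::runif(n_neg)))
    y <- c(rep(1L, n_pos), rep(0L, n_neg))
    o <- sample(length(s))
    tibble::tibble(score = s[o], label = y[o])
  })
}

#' Serialize fitted distributions to JSON
#'
#' Records `{family, params, loglik, n, converged}` per fit.
#'
#' @param fits A `fitted_dist` or list of them.
#' @param path File path.
#' @export
write_fits_json <- function(fits, path) {
  if (inherits(fits, "fitted_dist")) fits <- list(fits)
  recs <- lapply(fits, function(f) {
    list(family = f$spec$family, params = as.list(f$spec$params),
         loglik = f$loglik, n = f$n, converged = f$converged)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fits_json
#' @return `read_fits_json` returns a list of `fitted_dist` objects.
#' @export
read_fits_json <- function(path) {
  recs <- jsonlite::read_json(path)
  lapply(recs, function(r) {
    new_fitted_dist(dist_spec(r$family, unlist(r$params)),
                    loglik = r$loglik %||% NA_real_, n = r$n,
                    converged = isTRUE(r$converged))
  })
}
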