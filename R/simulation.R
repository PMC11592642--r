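# Monte Carlo distribution-pair recovery harness.
#
# Each run draws a negative and a positive class sample from a pseudo-true
# generating pair, fits every feasible family to each class by maximum
# likelihood, scores all candidate (positive-family, negative-family) pairs
# with AUC / AIC-ROC / ICOMP-ROC, and records which candidate each criterion
# selects. Over many runs the per-candidate selection counts form a
# frequency-of-success table.

#' Default candidate pair list
#'
#' The sixteen (positive family, negative family) combinations scored in each
#' run: the seven matched pairs plus nine mixed pairs.
#'
#' @return Tibble with columns `pos`, `neg`, `candidate`.
#' @export
default_candidate_pairs <- function() {
  pairs <- rbind(
    cbind(roc_families(), roc_families()),
    c("Exponential", "Normal"),
    c("Gamma", "Normal"),
    c("Weibull", "Normal"),
    c("EV", "Normal"),
    c("GEV", "Normal"),
    c("GP", "Normal"),
    c("Weibull", "Gamma"),
    c("Weibull", "Exponential"),
    c("Gamma", "Exponential")
  )
  tibble::tibble(pos = pairs[, 1], neg = pairs[, 2],
                 candidate = paste0(pairs[, 1], "-", pairs[, 2]))
}

#' Monte Carlo scenario specification
#'
#' @param true_pos,true_neg Generating [dist_spec()]s for the positive and
#'   negative class.
#' @param n_pos,n_neg Class sample sizes (defaults 300 and 200).
#' @param candidate_pairs Tibble as from [default_candidate_pairs()].
#' @param n_runs Number of Monte Carlo runs.
#' @param master_seed Integer master seed; run `i` uses `master_seed + i`.
#' @param points,lackfit Passed through to [score_candidate()].
#' @return A `mc_scenario` object.
#' @export
#' @examples
#' mc_scenario(dist_spec("Weibull", alpha = 2, beta = 1),
#'             dist_spec("Gamma", alpha = 2, beta = 2), n_runs = 3)
mc_scenario <- function(true_pos, true_neg, n_pos = 300, n_neg = 200,
                        candidate_pairs = default_candidate_pairs(),
                        n_runs = 25, master_seed = 1,
                        points = "pooled", lackfit = "standard") {
  stopifnot(inherits(true_pos, "dist_spec"), inherits(true_neg, "dist_spec"),
            n_pos >= 1, n_neg >= 1, nrow(candidate_pairs) >= 1, n_runs >= 1)
  structure(
    list(true_pos = true_pos, true_neg = true_neg,
         n_pos = n_pos, n_neg = n_neg,
         candidate_pairs = candidate_pairs,
         n_runs = n_runs, master_seed = as.integer(master_seed),
         points = points, lackfit = lackfit),
    class = "mc_scenario"
  )
}

#' Preset scenarios
#'
#' `"nn"` is the Normal-Normal study (positive Normal(1, 1.87), negative
#' Normal(0.99, 0.71)); `"wg"` is the Weibull-Gamma study (positive Weibull
#' shape 1 / scale 2, negative Gamma shape 2 / rate 2, i.e. positive class
#' mean 2 versus negative class mean 1). Class sizes are 300 positive / 200
#' negative.
#'
#' @param case `"nn"` or `"wg"`.
#' @param ... Further arguments to [mc_scenario()].
#' @return A `mc_scenario`.
#' @export
mc_scenario_preset <- function(case = c("nn", "wg"), ...) {
  case <- match.arg(case)
  switch(case,
    nn = mc_scenario(dist_spec("Normal", mu = 1, sigma = 1.87),
                     dist_spec("Normal", mu = 0.99, sigma = 0.71), ...),
    wg = mc_scenario(dist_spec("Weibull", alpha = 1, beta = 2),
                     dist_spec("Gamma", alpha = 2, beta = 2), ...)
  )
}

#' Score all candidate pairs on one simulated dataset
#'
#' Draws the two class samples under `run_seed`, fits each family once per
#' class (candidates whose families violate the data's support are marked
#' excluded rather than aborting the run), and scores every candidate pair.
#'
#' @param scenario A [mc_scenario()].
#' @param run_seed Integer seed for this run's draws.
#' @return Tibble of one [score_candidate()] row per candidate, with excluded
#'   candidates carrying `NA` criteria and `excluded = TRUE`.
#' @export
mc_run_once <- function(scenario, run_seed) {
  x_pos <- dist_sample(scenario$true_pos, scenario$n_pos, seed = run_seed)
  x_neg <- dist_sample(scenario$true_neg, scenario$n_neg, seed = run_seed + 500000L)
  score_candidates_on_samples(x_pos, x_neg, scenario)
}

score_candidates_on_samples <- function(x_pos, x_neg, scenario) {
  fams <- unique(c(scenario$candidate_pairs$pos, scenario$candidate_pairs$neg))
  fits_pos <- fit_all_families(x_pos, fams)
  fits_neg <- fit_all_families(x_neg, fams)
  pooled <- c(x_pos, x_neg)
  n <- length(pooled)
  purrr::pmap_dfr(scenario$candidate_pairs, function(pos, neg, candidate) {
    fp <- fits_pos[[pos]]
    fn <- fits_neg[[neg]]
    if (is.null(fp) || is.null(fn)) {
      return(tibble::tibble(candidate = candidate, auc = NA_real_,
                            aic_roc = NA_real_, icomp_roc = NA_real_,
                            c1 = NA_real_, r = NA_real_, n = n,
                            excluded = TRUE))
    }
    pair <- biroc_pair(fp, fn)
    score_candidate(pair, n = n, pooled = pooled,
                    points = scenario$points, lackfit = scenario$lackfit,
                    candidate = candidate)
  })
}

#' Select the winning candidate under one criterion
#'
#' AUC is maximized; AIC-ROC and ICOMP-ROC are minimized. Excluded candidates
#' never win. Exact ties go to the earlier candidate in canonical order, with
#' a `tie` attribute set.
#'
#' @param reports Tibble of candidate rows from [mc_run_once()].
#' @param criterion `"auc"`, `"aic_roc"` or `"icomp_roc"`.
#' @return Winning candidate label (with attribute `tie`).
#' @export
select_winner <- function(reports, criterion = c("auc", "aic_roc", "icomp_roc")) {
  criterion <- match.arg(criterion)
  ok <- reports[!reports$excluded & is.finite(reports[[criterion]]), ]
  if (nrow(ok) == 0) stop("no non-excluded candidate reports", call. = FALSE)
  v <- ok[[criterion]]
  if (criterion == "auc") v <- -v
  i <- which.min(v)                        # first index wins ties
  structure(ok$candidate[i], tie = sum(v == v[i]) > 1)
}

#' Run the full Monte Carlo recovery experiment
#'
#' @param scenario A [mc_scenario()].
#' @param keep_runs Keep the per-run report tibbles in the result?
#' @return A `mc_frequency` tibble: one row per candidate with selection
#'   counts `auc`, `aic_roc`, `icomp_roc` and the mean exclusion count
#'   `n_excluded`; attributes `n_runs` and (optionally) `runs`.
#' @export
#' @examples
#' \donttest{
#' run_monte_carlo(mc_scenario_preset("wg", n_runs = 3))
#' }
run_monte_carlo <- function(scenario, keep_runs = FALSE) {
  stopifnot(inherits(scenario, "mc_scenario"))
  counts <- matrix(0L, nrow(scenario$candidate_pairs), 3,
                   dimnames = list(scenario$candidate_pairs$candidate,
                                   c("auc", "aic_roc", "icomp_roc")))
  n_excluded <- stats::setNames(numeric(nrow(scenario$candidate_pairs)),
                                scenario$candidate_pairs$candidate)
  runs <- if (keep_runs) vector("list", scenario$n_runs) else NULL
  n_valid <- 0L
  for (i in seq_len(scenario$n_runs)) {
    reports <- tryCatch(mc_run_once(scenario, scenario$master_seed + i),
                        error = function(e) NULL)
    if (is.null(reports) || all(reports$excluded)) {
      warning("run ", i, " invalid; excluded from denominators")
      next
    }
    n_valid <- n_valid + 1L
    for (crit in c("auc", "aic_roc", "icomp_roc")) {
      w <- select_winner(reports, crit)
      counts[w, crit] <- counts[w, crit] + 1L
    }
    n_excluded <- n_excluded + as.numeric(reports$excluded)
    if (keep_runs) runs[[i]] <- reports
  }
  out <- tibble::tibble(
    candidate = rownames(counts),
    pos = scenario$candidate_pairs$pos,
    neg = scenario$candidate_pairs$neg,
    auc = unname(counts[, "auc"]),
    aic_roc = unname(counts[, "aic_roc"]),
    icomp_roc = unname(counts[, "icomp_roc"]),
    n_excluded = unname(n_excluded)
  )
  structure(out, class = c("mc_frequency", class(out)),
            n_runs = n_valid, runs = runs)
}

#' Write a Monte Carlo frequency table as CSV
#'
#' @param freq A `mc_frequency` tibble.
#' @param path File path.
#' @export
write_frequency_csv <- function(freq, path) {
  utils::write.csv(as.data.frame(freq), path, row.names = FALSE)
  invisible(path)
}
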