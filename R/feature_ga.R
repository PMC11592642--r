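# Genetic-algorithm feature-subset selection. Chromosomes are binary
# inclusion masks over the feature columns; fitness evaluates a classifier on
# the masked subset by cross-validation and returns the configured objective
# (always minimized internally; AUC and accuracy are negated). Two stock
# configurations mirror the GA1/GA2 settings: GA1 uses fixed single-point
# crossover (pc 0.8, pm 0.3), GA2 a generation-cycled crossover scheme
# (pc 0.6, pm 0.001).

#' GA configuration
#'
#' @param preset `"ga1"` or `"ga2"`; sets the crossover/mutation defaults
#'   (GA1: pc 0.8, pm 0.3, fixed scheme; GA2: pc 0.6, pm 0.001, dynamic).
#' @param generations Number of generations (default 50).
#' @param pop_size Population size (default 100, at least 2).
#' @param crossover_prob Crossover probability.
#' @param mutation_prob Per-bit mutation probability.
#' @param scheme `"fixed"` (single-point) or `"dynamic"` (cycles single-point,
#'   two-point, uniform by generation index).
#' @param elitism Number of best individuals copied unchanged (default 1).
#' @param seed Integer seed for the run's generator.
#' @param fitness Objective: `"auc"` (default, maximized), `"accuracy"`
#'   (maximized), `"icomp_roc"` or `"aic_roc"` (minimized). The information
#'   criteria reward near-collinear ROC point sets, which in feature selection
#'   favors non-discriminative subsets; they are offered for criterion studies
#'   rather than as a recovery-oriented default.
#' @param clf Classifier id from [classifier_specs()] used inside the fitness.
#' @param k Cross-validation folds for the fitness.
#' @return A `ga_config` list.
#' @export
#' @examples
#' ga_config("ga1", seed = 7)
ga_config <- function(preset = c("ga1", "ga2"), generations = 50,
                      pop_size = 100, crossover_prob = NULL,
                      mutation_prob = NULL, scheme = NULL, elitism = 1,
                      seed = 1, fitness = c("auc", "accuracy", "icomp_roc",
                                            "aic_roc"),
                      clf = "lr", k = 5) {
  preset <- match.arg(preset)
  fitness <- match.arg(fitness)
  defaults <- switch(preset,
    ga1 = list(crossover_prob = 0.8, mutation_prob = 0.3, scheme = "fixed"),
    ga2 = list(crossover_prob = 0.6, mutation_prob = 0.001,
               scheme = "dynamic")
  )
  cfg <- list(
    preset = preset,
    generations = generations,
    pop_size = pop_size,
    crossover_prob = crossover_prob %||% defaults$crossover_prob,
    mutation_prob = mutation_prob %||% defaults$mutation_prob,
    scheme = scheme %||% defaults$scheme,
    elitism = elitism,
    seed = as.integer(seed),
    fitness = fitness,
    clf = clf,
    k = k
  )
  stopifnot(cfg$pop_size >= 2,
            cfg$crossover_prob >= 0, cfg$crossover_prob <= 1,
            cfg$mutation_prob >= 0, cfg$mutation_prob <= 1,
            cfg$scheme %in% c("fixed", "dynamic"))
  structure(cfg, class = "ga_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

repair_mask <- function(mask) {
  if (!any(mask)) mask[sample.int(length(mask), 1)] <- TRUE
  mask
}

#' Initial GA population
#'
#' Bits are independent Bernoulli(0.5); all-zero masks are repaired by
#' switching on one uniformly chosen bit.
#'
#' @param d Chromosome length (number of features).
#' @param config A [ga_config()] (only `pop_size` is used here).
#' @return List of logical masks. Draws from the current RNG stream.
#' @export
ga_init_population <- function(d, config) {
  stopifnot(d >= 1)
  lapply(seq_len(config$pop_size), function(i) {
    repair_mask(stats::runif(d) < 0.5)
  })
}

#' GA fitness of one feature mask
#'
#' Evaluates the configured classifier on the masked feature subset via
#' [evaluate_classifier()] and returns the configured objective on the
#' minimized scale (AUC and accuracy are negated). Classifier failure yields
#' `+Inf`.
#'
#' @param mask Logical inclusion mask over the feature columns.
#' @param data Feature table (features plus label column).
#' @param label Label column name (tidy-eval).
#' @param config A [ga_config()].
#' @return Scalar fitness (smaller is better).
#' @export
ga_fitness <- function(mask, data, label = label, config) {
  if (!any(mask)) return(Inf)
  label_quo <- rlang::enquo(label)
  features <- dplyr::select(data, -!!label_quo)
  sub <- dplyr::bind_cols(features[, mask, drop = FALSE],
                          dplyr::select(data, !!label_quo))
  if (config$fitness %in% c("auc", "accuracy")) {
    # cheap path: only the out-of-fold scores are needed
    oof <- tryCatch(
      cv_scores(sub, !!label_quo, clf = config$clf, k = config$k,
                seed = config$seed),
      error = function(e) NULL
    )
    if (is.null(oof)) return(Inf)
    if (config$fitness == "accuracy") return(-mean(oof$estimate == oof$truth))
    return(-roc_auc(roc_empirical_vec(oof$score, oof$truth)))
  }
  rep <- tryCatch(
    evaluate_classifier(sub, !!label_quo, clf = config$clf, k = config$k,
                        seed = config$seed),
    error = function(e) NULL
  )
  if (is.null(rep)) return(Inf)
  switch(config$fitness,
    icomp_roc = rep$icomp_roc,
    aic_roc = rep$aic_roc
  )
}

#' Roulette-wheel parent selection on rank-scaled fitness
#'
#' Raw criterion values can be negative, so selection weights come from ranks:
#' the best (smallest fitness) individual gets weight `pop_size`, the worst
#' weight 1, and parents are drawn with replacement proportionally.
#'
#' @param fitnesses Numeric vector of evaluated fitnesses.
#' @param n_pairs Number of parent pairs to draw.
#' @return Integer matrix `n_pairs x 2` of parent indices.
#' @export
ga_select_parents <- function(fitnesses, n_pairs) {
  m <- length(fitnesses)
  w <- m + 1 - rank(fitnesses, ties.method = "average")
  idx <- sample.int(m, 2 * n_pairs, replace = TRUE, prob = w / sum(w))
  matrix(idx, ncol = 2)
}

crossover_single <- function(a, b) {
  d <- length(a)
  if (d < 2) return(list(a, b))
  cut <- sample.int(d - 1, 1)
  list(c(a[1:cut], b[(cut + 1):d]), c(b[1:cut], a[(cut + 1):d]))
}

crossover_two_point <- function(a, b) {
  d <- length(a)
  if (d < 3) return(crossover_single(a, b))
  cuts <- sort(sample.int(d - 1, 2))
  mid <- (cuts[1] + 1):cuts[2]
  ao <- a; bo <- b
  ao[mid] <- b[mid]; bo[mid] <- a[mid]
  list(ao, bo)
}

crossover_uniform <- function(a, b) {
  pick <- stats::runif(length(a)) < 0.5
  ao <- ifelse(pick, a, b)
  bo <- ifelse(pick, b, a)
  list(ao, bo)
}

#' Crossover operator
#'
#' Applied with probability `crossover_prob`, otherwise the parents pass
#' through unchanged. The `"fixed"` scheme always uses single-point crossover;
#' `"dynamic"` cycles single-point, two-point and uniform by generation index
#' modulo 3.
#'
#' @param a,b Parent masks.
#' @param config A [ga_config()].
#' @param generation Zero-based generation index (drives the dynamic cycle).
#' @return List of two offspring masks.
#' @export
ga_crossover <- function(a, b, config, generation = 0) {
  if (stats::runif(1) >= config$crossover_prob) return(list(a, b))
  if (config$scheme == "fixed") return(crossover_single(a, b))
  switch(generation %% 3 + 1,
         crossover_single(a, b),
         crossover_two_point(a, b),
         crossover_uniform(a, b))
}

#' Bit-flip mutation
#'
#' Each bit flips independently with probability `mutation_prob`; an all-zero
#' result is repaired.
#'
#' @param mask Logical mask.
#' @param config A [ga_config()].
#' @return Mutated mask.
#' @export
ga_mutate <- function(mask, config) {
  flip <- stats::runif(length(mask)) < config$mutation_prob
  repair_mask(xor(mask, flip))
}

#' Run the genetic algorithm
#'
#' Generational loop with elitism: evaluate, select parents by rank-scaled
#' roulette, cross over, mutate, and carry the elite through unchanged. All
#' randomness comes from one generator seeded by `config$seed`; fitness values
#' are cached by mask, so repeated masks cost nothing.
#'
#' @param data Feature table (features plus label column).
#' @param label Label column name (tidy-eval).
#' @param config A [ga_config()].
#' @return A `ga_result`: `best_mask` (logical), `best_fitness`, `trace`
#'   tibble (per-generation best-ever fitness), `evaluations`, `config`.
#' @export
#' @examples
#' \donttest{
#' tbl <- simulate_feature_table(n_instances = 100, n_features = 8,
#'                               n_informative = 2, effect_size = 2, seed = 1)
#' ga_run(tbl, label, ga_config("ga1", generations = 3, pop_size = 10, seed = 1))
#' }
ga_run <- function(data, label = label, config = ga_config("ga1")) {
  label_quo <- rlang::enquo(label)
  d <- ncol(dplyr::select(data, -!!label_quo))
  cache <- new.env(parent = emptyenv())
  evaluations <- 0L
  eval_mask <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    evaluations <<- evaluations + 1L
    val <- ga_fitness(mask, data, !!label_quo, config)
    cache[[key]] <- val
    val
  }
  withr::with_seed(config$seed, {
    pop <- ga_init_population(d, config)
    fit <- vapply(pop, eval_mask, numeric(1))
    best_i <- which.min(fit)
    best_mask <- pop[[best_i]]
    best_fit <- fit[best_i]
    trace <- numeric(config$generations)
    for (g in seq_len(config$generations)) {
      n_pairs <- ceiling(config$pop_size / 2)
      parents <- ga_select_parents(fit, n_pairs)
      children <- vector("list", 2 * n_pairs)
      for (j in seq_len(n_pairs)) {
        off <- ga_crossover(pop[[parents[j, 1]]], pop[[parents[j, 2]]],
                            config, generation = g - 1)
        children[[2 * j - 1]] <- ga_mutate(off[[1]], config)
        children[[2 * j]] <- ga_mutate(off[[2]], config)
      }
      children <- children[seq_len(config$pop_size)]
      # elitism: replace the tail with the best of the previous generation
      if (config$elitism > 0) {
        elite <- order(fit)[seq_len(min(config$elitism, config$pop_size))]
        children[seq_along(elite)] <- pop[elite]
      }
      pop <- children
      fit <- vapply(pop, eval_mask, numeric(1))
      gi <- which.min(fit)
      if (fit[gi] < best_fit) {
        best_fit <- fit[gi]
        best_mask <- pop[[gi]]
      }
      trace[g] <- best_fit
    }
    structure(
      list(best_mask = best_mask, best_fitness = best_fit,
           trace = tibble::tibble(generation = seq_len(config$generations),
                                  best_fitness = trace),
           evaluations = evaluations, config = config),
      class = "ga_result"
    )
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat("<ga_result> ", x$config$preset, ": ", sum(x$best_mask), "/",
      length(x$best_mask), " features selected, best ", x$config$fitness,
      " fitness ", format(x$best_fitness, digits = 6),
      " (", x$evaluations, " evaluations)\n", sep = "")
  cat("  selected: {", paste(which(x$best_mask), collapse = ", "), "}\n",
      sep = "")
  invisible(x)
}

#' Intersect two selected feature masks
#'
#' Bitwise AND of two masks (the GA1 and GA2 consensus subset). An empty
#' intersection is returned as-is with attribute `empty = TRUE`, never
#' repaired.
#'
#' @param m1,m2 Logical masks of equal length (or `ga_result`s).
#' @return Logical mask with attribute `empty`.
#' @export
ga_intersect <- function(m1, m2) {
  if (inherits(m1, "ga_result")) m1 <- m1$best_mask
  if (inherits(m2, "ga_result")) m2 <- m2$best_mask
  stopifnot(length(m1) == length(m2))
  out <- m1 & m2
  structure(out, empty = !any(out))
}
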