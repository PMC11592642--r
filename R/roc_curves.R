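# Bi-distributional (Universal) and empirical ROC curves, plus AUC.
#
# A Bi-distributional ROC assumes a family for the negative-class score
# distribution F0 and one for the positive-class distribution F1; the curve is
# R(p) = 1 - F1(F0^{-1}(1 - p)). Empirical curves come straight from
# score/label data with tied scores grouped into single diagonal steps.

#' Pair two class distributions into a Bi-distributional ROC model
#'
#' @param pos Positive-class (F1) [dist_spec()] or `fitted_dist`.
#' @param neg Negative-class (F0) [dist_spec()] or `fitted_dist`.
#' @return A `biroc_pair` with a `"PosFamily-NegFamily"` label.
#' @export
#' @examples
#' biroc_pair(dist_spec("Normal", mu = 1, sigma = 1),
#'            dist_spec("Normal", mu = 0, sigma = 1))
biroc_pair <- function(pos, neg) {
  pos_spec <- as_dist_spec(pos)
  neg_spec <- as_dist_spec(neg)
  structure(
    list(pos = pos, neg = neg, pos_spec = pos_spec, neg_spec = neg_spec,
         label = paste0(pos_spec$family, "-", neg_spec$family)),
    class = "biroc_pair"
  )
}

#' @export
print.biroc_pair <- function(x, ...) {
  cat("<biroc_pair> ", x$label, "\n", sep = "")
  cat("  positive (F1): "); print(x$pos_spec)
  cat("  negative (F0): "); print(x$neg_spec)
  invisible(x)
}

#' Universal ROC function of a Bi-distributional pair
#'
#' Returns the curve `R(p) = 1 - F1(F0^{-1}(1 - p))` as a vectorized function
#' of the false positive rate `p`. Interior probabilities are clipped to
#' `[1e-12, 1 - 1e-12]` before inversion so extreme quantiles stay finite;
#' `R(0) = 0` and `R(1) = 1` by convention, and values are clipped to `[0, 1]`.
#'
#' @param pair A [biroc_pair()].
#' @return A function mapping `p` in `[0, 1]` to true positive rates.
#' @export
#' @examples
#' R <- uroc_function(biroc_pair(dist_spec("Normal", mu = 1, sigma = 1),
#'                               dist_spec("Normal", mu = 0, sigma = 1)))
#' R(0.5)  # 1 - pnorm(-1)
uroc_function <- function(pair) {
  stopifnot(inherits(pair, "biroc_pair"))
  pos <- pair$pos_spec
  neg <- pair$neg_spec
  function(p) {
    pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    r <- 1 - dist_cdf(pos, dist_icdf(neg, 1 - pc))
    r[p <= 0] <- 0
    r[p >= 1] <- 1
    pmin(pmax(r, 0), 1)
  }
}

new_roc_curve <- function(fpr, tpr, kind, source, thresholds = NULL) {
  out <- tibble::tibble(fpr = fpr, tpr = tpr)
  if (!is.null(thresholds)) out$threshold <- thresholds
  structure(out, class = c("roc_curve", class(out)),
            kind = kind, source = source)
}

#' Parametric ROC points at a fixed threshold set
#'
#' Evaluates `FPR(x) = 1 - F0(x)` and `TPR(x) = 1 - F1(x)` at each threshold
#' (typically the pooled sample's order statistics), orders points by
#' decreasing threshold, and appends the `(0, 0)` and `(1, 1)` endpoints.
#'
#' @param pair A [biroc_pair()].
#' @param thresholds Numeric vector of score thresholds (the pooled sample).
#' @return A `roc_curve` tibble with columns `fpr`, `tpr`, `threshold`.
#' @export
roc_parametric <- function(pair, thresholds) {
  stopifnot(inherits(pair, "biroc_pair"), length(thresholds) >= 1)
  x <- sort(thresholds, decreasing = TRUE)
  fpr <- 1 - dist_cdf(pair$neg_spec, x)
  tpr <- 1 - dist_cdf(pair$pos_spec, x)
  new_roc_curve(
    fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
    kind = "parametric", source = pair$label,
    thresholds = c(Inf, x, -Inf)
  )
}

#' Empirical ROC curve from scores and labels
#'
#' Thresholds sit at the unique observed score values in decreasing order;
#' tied scores move the curve in a single (diagonal) step, matching the
#' trapezoidal AUC convention of standard ROC routines. The point set starts
#' at `(0, 0)` and ends at `(1, 1)`.
#'
#' @param data A data frame with a numeric score column and a 0/1 label column.
#' @param score,label Column names (tidy-eval) of scores and labels.
#' @return A `roc_curve` tibble with columns `fpr`, `tpr`, `threshold`.
#' @export
#' @examples
#' d <- tibble::tibble(s = c(0.9, 0.8, 0.4, 0.3), y = c(1, 1, 0, 0))
#' roc_empirical(d, s, y)
roc_empirical <- function(data, score = score, label = label) {
  scores <- dplyr::pull(data, {{ score }})
  labels <- dplyr::pull(data, {{ label }})
  roc_empirical_vec(scores, labels)
}

#' @rdname roc_empirical
#' @param scores Numeric score vector.
#' @param labels 0/1 label vector of the same length.
#' @export
roc_empirical_vec <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0) stop("positive class absent from labels", call. = FALSE)
  if (n_neg == 0) stop("negative class absent from labels", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  last <- cumsum(rle(s)$lengths)          # last index of each tie group
  tp <- cumsum(y)[last]
  fp <- cumsum(1L - y)[last]
  new_roc_curve(
    fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos),
    kind = "empirical", source = "empirical",
    thresholds = c(Inf, s[last])
  )
}

#' Area under the ROC curve
#'
#' For a Bi-distributional pair the AUC is the integral of the Universal ROC
#' function over `[0, 1]`, evaluated by adaptive Gauss-Kronrod quadrature at
#' absolute tolerance `1e-8` (falling back to a 10^4-point trapezoid with a
#' warning if quadrature fails). For an explicit curve the trapezoidal rule on
#' the point set is used.
#'
#' @param x A [biroc_pair()] or a `roc_curve`.
#' @param ... Unused.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(x, ...) UseMethod("roc_auc")

#' @rdname roc_auc
#' @export
roc_auc.biroc_pair <- function(x, ...) {
  R <- uroc_function(x)
  val <- tryCatch(
    pracma::quadgk(R, 0, 1, tol = 1e-8),
    error = function(e) NA_real_
  )
  if (!is.finite(val)) {
    warning("Gauss-Kronrod quadrature failed; using 10^4-point trapezoid")
    p <- seq(0, 1, length.out = 10001)
    val <- pracma::trapz(p, R(p))
  }
  min(max(val, 0), 1)
}

#' @rdname roc_auc
#' @export
roc_auc.roc_curve <- function(x, ...) {
  o <- order(x$fpr, x$tpr)
  pracma::trapz(x$fpr[o], x$tpr[o])
}

#' Write / read ROC point sets as CSV
#'
#' @param curve A `roc_curve`.
#' @param path File path.
#' @return `write_roc_csv` returns `path` invisibly; `read_roc_csv` returns a
#'   `roc_curve` tibble.
#' @export
write_roc_csv <- function(curve, path) {
  df <- as.data.frame(curve)
  if (!"threshold" %in% names(df)) df$threshold <- NA_real_
  utils::write.csv(df[, c("threshold", "fpr", "tpr")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roc_csv
#' @export
read_roc_csv <- function(path) {
  df <- utils::read.csv(path)
  new_roc_curve(df$fpr, df$tpr, kind = "empirical", source = path,
                thresholds = df$threshold)
}
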