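# AIC-ROC and ICOMP-ROC.
#
# Both criteria view the (FPR, TPR) point set of a candidate ROC curve through
# a standardized bivariate normal with correlation matrix R = [[1, r], [r, 1]].
# The lack-of-fit term is n * (log 2pi + log|R| + 1) with n the TOTAL sample
# size n1 + n2 (never the number of curve points). AIC-ROC adds 2 * rank(R);
# ICOMP-ROC adds twice the maximal entropic complexity C1 of the inverse
# Fisher information matrix (IFIM) of the model, assembled block-diagonally
# from R and a duplication-matrix transform of R (x) R.

#' Duplication matrix
#'
#' The unique `p^2 x p(p+1)/2` matrix `D_p` with `D_p %*% vech(A) == vec(A)`
#' for every symmetric `p x p` matrix `A`, where `vech` stacks the lower
#' triangle column-wise.
#'
#' @param p Matrix dimension (`p >= 1`).
#' @return Numeric matrix of 0/1 entries.
#' @export
#' @examples
#' duplication_matrix(2)
duplication_matrix <- function(p) {
  if (p < 1 || p != round(p)) stop("p must be a positive integer", call. = FALSE)
  m <- p * (p + 1) / 2
  D <- matrix(0, p * p, m)
  # column index of (i, j), i >= j, in vech order
  vech_index <- function(i, j) (j - 1) * p - (j - 1) * j / 2 + i
  for (j in seq_len(p)) {
    for (i in seq_len(p)) {
      col <- if (i >= j) vech_index(i, j) else vech_index(j, i)
      D[(j - 1) * p + i, col] <- 1
    }
  }
  D
}

#' Moore-Penrose inverse of the duplication matrix
#'
#' Computed as `(D' D)^{-1} D'`; `D' D` is diagonal so the inverse is exact.
#' Satisfies `duplication_pinv(p) %*% duplication_matrix(p) == diag(p(p+1)/2)`
#' and maps `vec(A)` back to `vech(A)` for symmetric `A`.
#'
#' @inheritParams duplication_matrix
#' @return Numeric matrix `p(p+1)/2 x p^2`.
#' @export
duplication_pinv <- function(p) {
  D <- duplication_matrix(p)
  solve(crossprod(D), t(D))
}

#' Inverse Fisher information matrix of the standardized bivariate normal
#'
#' For correlation `r` and total sample size `n`, the IFIM is block-diagonal:
#' the `2 x 2` correlation matrix `R` itself, and the `3 x 3` block
#' `(2/n) * D2plus (R \%x\% R) t(D2plus)` built from the Moore-Penrose inverse
#' of the duplication matrix. Its rank is `s = 5` whenever `|r| < 1`.
#'
#' @param r Pearson correlation in `(-1, 1)`; values at or beyond `1` in
#'   magnitude are clamped to `1 - 1e-10` with a warning.
#' @param n Total sample size (`n1 + n2`, at least 2).
#' @return An `ifim_blocks` list: `block1`, `block2`, `s`, `trace`, `logdet`.
#' @export
#' @examples
#' ifim_bivariate_corr(0, 500)$trace  # 2 + 5/500
ifim_bivariate_corr <- function(r, n) {
  stopifnot(n >= 2)
  r <- clamp_correlation(r, warn = TRUE)
  R <- matrix(c(1, r, r, 1), 2, 2)
  Dp <- duplication_pinv(2)
  B2 <- (2 / n) * Dp %*% (R %x% R) %*% t(Dp)
  det2 <- det(B2)
  if (!is.finite(det2) || det2 <= 0) {
    # near the |r| clamp the 3x3 determinant underflows below floating-point
    # cancellation error; fall back to its analytic value (1-r^2)^3 (2/n)^3 / 2
    det2 <- (1 - r^2)^3 * (2 / n)^3 / 2
  }
  logdet <- as.numeric(determinant(R, logarithm = TRUE)$modulus) + log(det2)
  structure(
    list(block1 = R, block2 = B2, s = 5L,
         trace = sum(diag(R)) + sum(diag(B2)),
         logdet = logdet),
    class = "ifim_blocks"
  )
}

clamp_correlation <- function(r, warn = FALSE) {
  lim <- 1 - 1e-10
  if (is.na(r)) return(0)
  if (abs(r) > lim) {
    if (warn) warning("|r| >= 1 clamped to ", lim)
    r <- sign(r) * lim
  }
  r
}

#' Maximal entropic complexity C1
#'
#' `C1(F) = (s/2) * log(trace(F)/s) - (1/2) * log det(F)` for a positive
#' definite matrix summarized by its trace, log-determinant and rank. C1
#' contrasts the average total variation (trace) with the generalized
#' variance (determinant); it vanishes for scalar multiples of the identity
#' and diverges as the matrix approaches singularity.
#'
#' @param blocks An `ifim_blocks` object from [ifim_bivariate_corr()], or a
#'   list with elements `trace`, `logdet`, `s`.
#' @return Scalar complexity value (may be negative for small `n`).
#' @export
c1_complexity <- function(blocks) {
  tr <- blocks$trace
  ld <- blocks$logdet
  s <- blocks$s
  if (!is.finite(tr) || tr <= 0 || !is.finite(ld)) {
    stop("C1 requires a finite positive trace and finite log-determinant",
         call. = FALSE)
  }
  s / 2 * log(tr / s) - ld / 2
}

#' Correlation summary of a ROC point set
#'
#' Pearson correlation of the FPR and TPR coordinates of a curve's point set
#' (endpoints included), assembled into the 2 x 2 correlation matrix used by
#' the criteria. Zero variance in either coordinate yields a zero correlation
#' with a warning; `|r|` is clamped below 1 so log-determinants stay finite.
#'
#' @param curve A `roc_curve` with at least 3 distinct points.
#' @param n Total sample size `n1 + n2` to carry into the criteria.
#' @return A `roc_correlation` list: `r`, `R`, `det_R`, `n`, `m` (number of
#'   curve points used).
#' @export
roc_correlation <- function(curve, n) {
  fpr <- curve$fpr
  tpr <- curve$tpr
  if (nrow(unique(cbind(fpr, tpr))) < 3) {
    stop("need at least 3 distinct ROC points", call. = FALSE)
  }
  if (stats::sd(fpr) == 0 || stats::sd(tpr) == 0) {
    warning("zero variance in a ROC coordinate; r set to 0")
    r <- 0
  } else {
    r <- stats::cor(fpr, tpr)
  }
  r <- clamp_correlation(r)
  structure(
    list(r = r, R = matrix(c(1, r, r, 1), 2, 2), det_R = 1 - r^2,
         n = as.integer(n), m = length(fpr)),
    class = "roc_correlation"
  )
}

# Lack-of-fit term shared by both criteria. "standard" is the default reading
# n*(log 2pi + log|R| + 1); "full" is the complete bivariate-Gaussian
# -2 log-likelihood n*(2 log 2pi + log|R| + 2). For fixed n the two differ by
# a constant, so model ranking is identical; the switch keeps the choice
# auditable.
roc_lackfit <- function(summary, lackfit = c("standard", "full")) {
  lackfit <- match.arg(lackfit)
  n <- summary$n
  ld <- log(summary$det_R)
  switch(lackfit,
    standard = n * (log(2 * pi) + ld + 1),
    full     = n * (2 * log(2 * pi) + ld + 2)
  )
}

#' ICOMP-ROC criterion
#'
#' `ICOMP-ROC = n * (log 2pi + log|R| + 1) + 2 * C1(IFIM)` where the IFIM is
#' the inverse Fisher information of the standardized bivariate normal at the
#' observed ROC-point correlation. Smaller is better.
#'
#' @param summary A [roc_correlation()].
#' @param lackfit `"standard"` (default) or `"full"`; see Details in
#'   [aic_roc()].
#' @return Scalar criterion value.
#' @export
icomp_roc <- function(summary, lackfit = c("standard", "full")) {
  blocks <- ifim_bivariate_corr(summary$r, summary$n)
  roc_lackfit(summary, lackfit) + 2 * c1_complexity(blocks)
}

#' AIC-ROC criterion
#'
#' `AIC-ROC = n * (log 2pi + log|R| + 1) + 2 * rank(R)`, with `rank(R) = 2`
#' whenever `|r| < 1`. Smaller is better.
#'
#' The printed bracketing of the lack-of-fit term admits two readings; the
#' default multiplies the whole bracket by `n`, and `lackfit = "full"` uses
#' the complete bivariate-Gaussian form `n * (2 log 2pi + log|R| + 2)`. The
#' two differ by a constant at fixed `n`, so rankings agree.
#'
#' @inheritParams icomp_roc
#' @return Scalar criterion value.
#' @export
aic_roc <- function(summary, lackfit = c("standard", "full")) {
  roc_lackfit(summary, lackfit) + 2 * qr(summary$R)$rank
}

#' Score one candidate ROC model with AUC, AIC-ROC and ICOMP-ROC
#'
#' For a Bi-distributional pair, the AUC comes from Gauss-Kronrod quadrature
#' of the Universal ROC function and the (FPR, TPR) correlation from the
#' parametric curve evaluated at the pooled sample's order statistics (or at
#' a uniform 512-point grid on the FPR axis via `points = "grid"`). For an
#' explicit `roc_curve`, the trapezoidal AUC and the curve's own point set
#' are used.
#'
#' @param x A [biroc_pair()] or a `roc_curve`.
#' @param n Total sample size `n1 + n2` entering the criteria.
#' @param pooled Pooled score sample providing thresholds (required for
#'   pairs when `points = "pooled"`).
#' @param points `"pooled"` (default) or `"grid"`.
#' @param lackfit Passed to [aic_roc()] / [icomp_roc()].
#' @param candidate Label for the report row; defaults to the pair label.
#' @return A one-row tibble: `candidate`, `auc`, `aic_roc`, `icomp_roc`,
#'   `c1`, `r`, `n`, `excluded`.
#' @export
score_candidate <- function(x, n, pooled = NULL,
                            points = c("pooled", "grid"),
                            lackfit = c("standard", "full"),
                            candidate = NULL) {
  points <- match.arg(points)
  if (inherits(x, "biroc_pair")) {
    auc <- roc_auc(x)
    curve <- if (points == "pooled") {
      if (is.null(pooled)) {
        stop("pooled thresholds required when points = 'pooled'", call. = FALSE)
      }
      roc_parametric(x, pooled)
    } else {
      R <- uroc_function(x)
      p <- seq(0, 1, length.out = 512)
      new_roc_curve(p, R(p), kind = "parametric", source = x$label)
    }
    if (is.null(candidate)) candidate <- x$label
  } else if (inherits(x, "roc_curve")) {
    auc <- roc_auc(x)
    curve <- x
    if (is.null(candidate)) candidate <- attr(x, "source")
  } else {
    stop("x must be a biroc_pair or roc_curve", call. = FALSE)
  }
  summ <- roc_correlation(curve, n)
  blocks <- ifim_bivariate_corr(summ$r, summ$n)
  c1 <- c1_complexity(blocks)
  lf <- roc_lackfit(summ, lackfit)
  tibble::tibble(
    candidate = candidate,
    auc = auc,
    aic_roc = lf + 4,
    icomp_roc = lf + 2 * c1,
    c1 = c1,
    r = summ$r,
    n = summ$n,
    excluded = FALSE
  )
}

#' Write criterion reports to CSV
#'
#' @param reports Tibble of [score_candidate()] rows.
#' @param path File path.
#' @export
write_criteria_csv <- function(reports, path) {
  cols <- c("candidate", "auc", "aic_roc", "icomp_roc", "c1", "r", "n")
  utils::write.csv(as.data.frame(reports)[, cols], path, row.names = FALSE)
  invisible(path)
}
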