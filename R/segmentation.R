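#' Build the sorted log-score curve
#'
#' Keeps features with strictly positive score (a feature never entering
#' any path is trivially uninformative and log(0) is undefined), sorts
#' them by increasing score with ties broken by feature index, and takes
#' natural logs.  At least 9 positive scores are required — three segments
#' of at least three points each.
#'
#' @param x a `"fealect"` object, or a named numeric score vector.
#' @return object of class `"score_curve"`: list with `rank` (1..L),
#'   `log_score`, `score`, `feature_id` (original indices), `feature_name`
#'   and `n_zero` (count of excluded zero-score features).
#' @export
build_score_curve <- function(x) {
  scores <- if (inherits(x, "fealect")) x$scores else x
  if (is.null(names(scores))) names(scores) <- paste0("V", seq_along(scores))
  pos <- which(scores > 0)
  if (length(pos) < 9L) {
    stop("need at least 9 features with positive score to fit three segments; got ",
         length(pos))
  }
  ord <- pos[order(scores[pos], pos)]   # increasing score, ties by index
  structure(list(
    rank = seq_along(ord),
    log_score = log(as.numeric(scores[ord])),
    score = as.numeric(scores[ord]),
    feature_id = ord,
    feature_name = names(scores)[ord],
    n_zero = length(scores) - length(pos)
  ), class = "score_curve")
}

#' Fit the quadratic-linear-quadratic three-segment model
#'
#' Exhaustively searches all admissible knot pairs (k1, k2) — each of the
#' three segments must span at least `min_seg` points — and for each fits,
#' by least squares, a continuous piecewise function that is quadratic on
#' ranks `1..k1`, linear on `k1..k2` and quadratic on `k2..L`.  Continuity
#' at both knots is enforced by the hinge parameterization
#' `b0 + b1 r + b3 (k1-r)_+ + b4 (k1-r)_+^2 + b5 (r-k2)_+ + b6 (r-k2)_+^2`;
#' no derivative constraint is imposed.  The minimum-SSE pair wins, ties
#' going to the smallest `(k1, k2)`.  The search is exact (no heuristics)
#' and runs in O(L^2) via prefix moment sums, with a QR refit of the
#' winning pair for numerical accuracy.
#'
#' The linear middle segment captures the geometrically decaying scores of
#' irrelevant features; `threshold_score` — the observed score at the
#' upper knot, which itself belongs to the linear segment — is the
#' analytic selection threshold.
#'
#' @param curve a `"score_curve"` (or a `"fealect"` object, converted via
#'   [build_score_curve()]).
#' @param min_seg minimum points per segment (default 3).
#' @return object of class `"segment_fit"`: knots `k1 < k2`, `beta` (the
#'   six hinge-basis coefficients on the rank scale), `coefficients` (the
#'   three segments in standard polynomial form), `sse`,
#'   `threshold_score`, and the curve length `L`.
#' @export
fit_three_segment <- function(curve, min_seg = 3L) {
  if (inherits(curve, "fealect")) curve <- build_score_curve(curve)
  stopifnot(inherits(curve, "score_curve"))
  yy <- curve$log_score
  L <- length(yy)
  if (L < 3L * min_seg) stop("curve has ", L, " points; need at least ", 3L * min_seg)
  res <- cpp_segment_search(yy, as.integer(min_seg))
  k1 <- res$k1; k2 <- res$k2
  # rescale coefficients from u = r/L (used internally for conditioning)
  # back to the rank scale r
  b <- res$beta
  beta <- c(b[1], b[2] / L, b[3] / L, b[4] / L^2, b[5] / L, b[6] / L^2)
  names(beta) <- c("b0", "b1", "hinge1", "hinge1.sq", "hinge2", "hinge2.sq")
  g2 <- c(intercept = beta[[1]], slope = beta[[2]])
  g1 <- c(intercept = beta[[1]] + beta[[3]] * k1 + beta[[4]] * k1^2,
          slope = beta[[2]] - beta[[3]] - 2 * beta[[4]] * k1,
          quad = beta[[4]])
  g3 <- c(intercept = beta[[1]] - beta[[5]] * k2 + beta[[6]] * k2^2,
          slope = beta[[2]] + beta[[5]] - 2 * beta[[6]] * k2,
          quad = beta[[6]])
  structure(list(
    k1 = k1, k2 = k2, beta = beta,
    coefficients = list(g1 = g1, g2 = g2, g3 = g3),
    sse = res$sse,
    threshold_score = curve$score[k2],
    L = L, min_seg = as.integer(min_seg), curve = curve
  ), class = "segment_fit")
}

#' @export
predict.segment_fit <- function(object, newdata = NULL, ...) {
  r <- if (is.null(newdata)) seq_len(object$L) else as.numeric(newdata)
  b <- object$beta
  b[[1]] + b[[2]] * r +
    b[[3]] * pmax(object$k1 - r, 0) + b[[4]] * pmax(object$k1 - r, 0)^2 +
    b[[5]] * pmax(r - object$k2, 0) + b[[6]] * pmax(r - object$k2, 0)^2
}

#' @export
residuals.segment_fit <- function(object, ...) {
  object$curve$log_score - predict(object)
}

#' @export
print.segment_fit <- function(x, ...) {
  cat("Three-segment fit to the log-score curve\n")
  cat(sprintf("  %d points; knots at ranks %d and %d; SSE = %.4g\n",
              x$L, x$k1, x$k2, x$sse))
  cat(sprintf("  linear (irrelevant) segment slope = %.4g\n",
              x$coefficients$g2[["slope"]]))
  cat(sprintf("  selection threshold score = %.6g\n", x$threshold_score))
  invisible(x)
}

#' Select informative features above the linear segment
#'
#' Features whose score strictly exceeds the score at the upper knot —
#' i.e. those on the upper quadratic segment of the fitted curve — are
#' declared informative.  The knot point itself belongs to the linear
#' (irrelevant) segment and is excluded.
#'
#' @param x a `"fealect"` object (the fit is computed) or a named score
#'   vector.
#' @param fit optional precomputed `"segment_fit"` for the same scores.
#' @return object of class `"fealect_selection"`: `selected_id`,
#'   `selected_name`, `threshold_score`, `segment_counts` (points per
#'   segment, summing to the curve length) and `n_zero`.
#' @export
select_informative <- function(x, fit = NULL) {
  scores <- if (inherits(x, "fealect")) x$scores else x
  if (is.null(fit)) fit <- fit_three_segment(build_score_curve(scores))
  stopifnot(inherits(fit, "segment_fit"))
  thr <- fit$threshold_score
  sel <- unname(which(scores > thr))
  sel <- sel[order(scores[sel], decreasing = TRUE)]
  structure(list(
    selected_id = sel,
    selected_name = names(scores)[sel],
    threshold_score = thr,
    segment_counts = c(lower_quadratic = fit$k1,
                       linear = fit$k2 - fit$k1,
                       upper_quadratic = fit$L - fit$k2),
    n_zero = fit$curve$n_zero,
    fit = fit
  ), class = "fealect_selection")
}

#' @export
print.fealect_selection <- function(x, ...) {
  cat(sprintf("  informative features (score > %.6g): %d\n",
              x$threshold_score, length(x$selected_id)))
  cat("   ", paste(head(x$selected_name, 10L), collapse = ", "),
      if (length(x$selected_name) > 10L) ", ..." else "", "\n")
  cat(sprintf("  segment sizes: %d / %d / %d (+ %d zero-score features)\n",
              x$segment_counts[1L], x$segment_counts[2L], x$segment_counts[3L],
              x$n_zero))
  invisible(x)
}
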