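#' Draw one subsample without replacement
#'
#' Draws `floor(gamma * n)` distinct sample indices uniformly at random,
#' the resampling unit of the scoring loop.  Subsampling is without
#' replacement: the inclusion probability of a fixed r-subset is then the
#' hypergeometric ratio computed by [inclusion_probability_exact()], and
#' tends to gamma^r as n grows.
#'
#' @param n number of samples.
#' @param gamma fraction of samples per subsample, in (0, 1].
#' @return sorted integer vector of `floor(gamma * n)` distinct indices in
#'   `1..n`.
#' @examples
#' set.seed(1)
#' draw_subsample(85, 3 / 4)   # 63 indices, the classic n = 85 setting
#' @export
draw_subsample <- function(n, gamma) {
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  b <- floor(gamma * n)
  if (b < 2L) stop("floor(gamma * n) must be >= 2; got ", b)
  sort(sample.int(n, b))
}

#' Per-subsample score contributions from an entry order
#'
#' A feature that enters the path at rank j is active at every path size
#' k = j..K_B and earns 1/k at each, i.e. H(K_B) - H(j - 1) in total,
#' where H is the harmonic number and K_B the realized path length.
#' Features absent from the order earn 0.  Summed over all features the
#' contributions telescope to exactly K_B.
#'
#' @param order an `"entry_order"` (or list with `order` and `k`).
#' @param d total number of features.
#' @return numeric vector of length `d`.
#' @examples
#' o <- structure(list(order = c(3L, 1L), k = 2L), class = "entry_order")
#' bootstrap_contribution(o, d = 4)   # feature 3: 1 + 1/2, feature 1: 1/2
#' @export
bootstrap_contribution <- function(order, d) {
  kb <- order$k
  out <- numeric(d)
  if (kb == 0L) return(out)
  h <- harmonic_seq(kb)                    # H_0 .. H_kb
  j <- seq_len(length(order$order))
  out[order$order] <- h[kb + 1L] - h[j]    # H_kb - H_{j-1}
  out
}

# Shared scoring loop.  `engine(xs, ys, max_features, idx)` must return an
# "entry_order"; the default pipeline standardizes each subsample first,
# while the theory harness injects a mock engine with standardize = FALSE.
score_loop <- function(x, y, gamma, m, max_features, seed, engine,
                       standardize = TRUE, max_retries = 10L) {
  n <- nrow(x); d <- ncol(x)
  b <- floor(gamma * n)
  if (b < 2L) stop("floor(gamma * n) must be >= 2")
  set.seed(seed)
  # substream seeds drawn sequentially: the first t draws are identical for
  # every m >= t, so increasing m extends rather than reshuffles the run
  subseeds <- sample.int(.Machine$integer.max - 1L, m, replace = TRUE)
  scores <- numeric(d)
  sizes <- integer(m)
  for (t in seq_len(m)) {
    set.seed(subseeds[t])
    ord <- NULL
    for (try in seq_len(max_retries)) {
      idx <- draw_subsample(n, gamma)
      if (standardize) {
        std <- tryCatch(
          suppressWarnings(standardize_features(x[idx, , drop = FALSE], y[idx])),
          error = function(e) NULL)
        if (is.null(std)) next
        o <- engine(std$x, std$y, max_features, idx)
        # map entry indices of the kept columns back to original columns
        o$order <- std$kept[o$order]
      } else {
        o <- engine(x[idx, , drop = FALSE], y[idx], max_features, idx)
      }
      ord <- o
      break
    }
    if (is.null(ord)) stop("subsample ", t, " failed standardization after ",
                           max_retries, " retries")
    sizes[t] <- ord$k
    scores <- scores + bootstrap_contribution(ord, d) / m
  }
  list(scores = scores, sizes = sizes)
}

#' Score feature relevance by subsampled LARS paths
#'
#' The core estimator.  Draws `m` subsamples of size `floor(gamma * n)`
#' without replacement; on each, standardizes the subsample, recovers the
#' LARS entry order of up to `max_features` features, and credits a
#' feature entering at rank j with `1/k` for every path size `k >= j` it
#' is active at.  The total score of a feature is the average of these
#' harmonic credits over subsamples — features that enter early and often
#' score near the maximum `H(K)`, features that enter only when a
#' particular subset of samples is present decay geometrically
#' (`~ gamma^r` for an r-sample over-fitting set), and features that never
#' enter score 0.
#'
#' The scores satisfy the conservation identity
#' `sum(scores) == mean(path lengths)` exactly (up to float round-off),
#' and `scores / sum(scores)` is a probability vector.
#'
#' @param x numeric feature matrix, samples in rows; column names are the
#'   feature names.
#' @param y numeric response; binary classes encoded as -1/+1.
#' @param gamma fraction of samples per subsample (default 3/4).
#' @param m number of subsamples (default 1000; scores stabilize quickly,
#'   100 is typically indistinguishable in rank order).
#' @param max_features cap on the path length per subsample (default
#'   `min(d, 60)`); additionally capped at `n_B - 1` by the path itself.
#' @param seed integer RNG seed; runs are fully reproducible, and the
#'   first `t` subsamples coincide for any two runs with `m >= t`.
#' @return object of class `"fealect"`: list with `scores` (named, length
#'   d), `sizes` (realized path length per subsample), and the
#'   configuration (`gamma`, `m`, `max_features`, `seed`, `n`, `d`).
#' @seealso [select_informative()] for the analytic threshold,
#'   [plot.fealect()] for the log-score curve.
#' @examples
#' sim <- generate_sparse_regression(n = 30, d = 40, s = 2, snr = 10, seed = 1)
#' fit <- fealect(sim$x, sim$y_class, m = 50, seed = 1)
#' head(sort(coef(fit), decreasing = TRUE))
#' @export
fealect <- function(x, y, gamma = 3 / 4, m = 1000L,
                    max_features = min(ncol(x), 60L), seed = 1L) {
  v <- validate_xy(x, y)
  x <- v$x; y <- v$y
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  if (m < 1L) stop("m must be >= 1")
  if (max_features < 1L) stop("max_features must be >= 1")
  engine <- function(xs, ys, kmax, idx) lars_entry_order(xs, ys, kmax)
  res <- score_loop(x, y, gamma, m, max_features, seed, engine)
  structure(list(
    scores = stats::setNames(res$scores, colnames(x)),
    sizes = res$sizes,
    gamma = gamma, m = as.integer(m),
    max_features = as.integer(max_features), seed = as.integer(seed),
    n = nrow(x), d = ncol(x)
  ), class = "fealect")
}

#' @export
print.fealect <- function(x, ...) {
  cat("Feature relevance scores from subsampled LARS paths\n")
  cat(sprintf("  %d samples, %d features; gamma = %.3g, m = %d, max path size = %d\n",
              x$n, x$d, x$gamma, x$m, x$max_features))
  cat(sprintf("  realized path lengths: %d-%d (mean %.2f)\n",
              min(x$sizes), max(x$sizes), mean(x$sizes)))
  cat("  top scores:\n")
  print(head(sort(x$scores, decreasing = TRUE), 6L))
  invisible(x)
}

#' @export
coef.fealect <- function(object, ...) object$scores

#' @export
summary.fealect <- function(object, ...) {
  sel <- tryCatch(select_informative(object), error = function(e) NULL)
  out <- list(fit = object, selection = sel)
  class(out) <- "summary.fealect"
  out
}

#' @export
print.summary.fealect <- function(x, ...) {
  print(x$fit)
  if (is.null(x$selection)) {
    cat("  (too few positive scores for three-segment selection)\n")
  } else {
    print(x$selection)
  }
  invisible(x)
}

#' Plot the sorted log-score curve
#'
#' Features with positive score sorted by increasing score, on the natural
#' log scale; if a [fit_three_segment()] fit is supplied (or can be
#' computed) the fitted quadratic-linear-quadratic model and its knots are
#' overlaid.  The middle linear stretch is the signature of irrelevant
#' features; the upturned right tail holds the informative ones.
#'
#' @param x a `"fealect"` object.
#' @param fit optional `"segment_fit"`; computed from `x` when possible.
#' @param ... passed to [plot()].
#' @export
plot.fealect <- function(x, fit = NULL, ...) {
  curve <- build_score_curve(x)
  plot(curve$rank, curve$log_score, xlab = "feature rank (increasing score)",
       ylab = "log score", pch = 16, cex = 0.6, ...)
  if (is.null(fit)) fit <- tryCatch(fit_three_segment(curve), error = function(e) NULL)
  if (!is.null(fit)) {
    r <- seq_along(curve$rank)
    graphics::lines(r, predict(fit, r), col = "red3", lwd = 2)
    graphics::abline(v = c(fit$k1, fit$k2), lty = 3, col = "grey40")
  }
  invisible(x)
}
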