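#' Bolasso and Bolasso-S feature selection
#'
#' The bootstrap-intersection baseline: draws `m` bootstrap replicates of
#' size n *with* replacement, fits the Lasso on each (penalty chosen per
#' replicate by 5-fold cross-validation, or fixed at `mu0 / sqrt(n)` under
#' `lambda_rule = "root_n"`), records the non-zero support, and keeps the
#' features selected in at least a fraction `threshold` of replicates.
#' `threshold = 1` is the hard Bolasso intersection; the soft variant
#' Bolasso-S conventionally uses 0.9.
#'
#' @param x numeric feature matrix (samples x features).
#' @param y numeric response (-1/+1 for classification).
#' @param m number of bootstrap replicates.
#' @param threshold selection frequency cut-off in (0, 1].
#' @param lambda_rule `"cv"` (per-replicate 5-fold cross-validation,
#'   default) or `"root_n"` (fixed `mu0 * n^{-1/2}`).
#' @param mu0 constant for the `root_n` rule.
#' @param seed RNG seed.
#' @return object of class `"bolasso"`: `selected_id`, `selected_name`,
#'   `frequency` (per-feature selection frequency over replicates),
#'   `threshold`, `m`.
#' @export
bolasso <- function(x, y, m = 100L, threshold = 0.9,
                    lambda_rule = c("cv", "root_n"), mu0 = 1,
                    seed = 1L) {
  v <- validate_xy(x, y); x <- v$x; y <- v$y
  lambda_rule <- match.arg(lambda_rule)
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  n <- nrow(x); d <- ncol(x)
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, m, replace = TRUE)
  freq <- numeric(d)
  for (t in seq_len(m)) {
    set.seed(subseeds[t])
    idx <- NULL
    for (try in 1:25) {
      cand <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[cand])) > 1L && any(apply(x[cand, , drop = FALSE], 2L, sd) > 0)) {
        idx <- cand; break
      }
    }
    if (is.null(idx)) stop("replicate ", t, " degenerate after bounded retries")
    freq <- freq + (lasso_support(x[idx, , drop = FALSE], y[idx],
                                  lambda_rule, mu0) / m)
  }
  names(freq) <- colnames(x)
  sel <- unname(which(freq >= threshold - 1e-12))
  structure(list(selected_id = sel, selected_name = colnames(x)[sel],
                 frequency = freq, threshold = threshold, m = as.integer(m),
                 lambda_rule = lambda_rule),
            class = "bolasso")
}

#' @export
print.bolasso <- function(x, ...) {
  cat(sprintf("Bolasso (%d bootstrap replicates, frequency threshold %.2f, lambda: %s)\n",
              x$m, x$threshold, x$lambda_rule))
  cat("  selected:", if (length(x$selected_name)) paste(x$selected_name, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

# 0/1 indicator of the Lasso support for one (re)sample
lasso_support <- function(x, y, lambda_rule, mu0) {
  n <- nrow(x)
  if (lambda_rule == "cv") {
    fit <- glmnet::cv.glmnet(x, y, nfolds = 5L, standardize = TRUE)
    beta <- as.numeric(coef(fit, s = "lambda.min"))[-1L]
  } else {
    fit <- glmnet::glmnet(x, y, lambda = mu0 / sqrt(n), standardize = TRUE)
    beta <- as.numeric(coef(fit))[-1L]
  }
  as.numeric(beta != 0)
}

#' Area under the ROC curve (Mann-Whitney, midrank ties)
#'
#' @param pred real-valued predictions (larger = more positive).
#' @param labels binary labels; any coding with exactly two distinct
#'   values works, the larger value is the positive class.
#' @return AUC in \[0, 1\]; a constant predictor scores exactly 0.5.
#' @export
stat_auc <- function(pred, labels) {
  lv <- sort(unique(labels))
  if (length(lv) != 2L) stop("AUC is undefined unless both classes are present")
  pos <- labels == lv[2L]
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(pred)                              # midranks: ties count 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit a linear model on a feature subset and score held-out AUC
#'
#' Restricts the design to `features`, fits a linear model on the
#' training data (ordinary least squares for a single feature,
#' cross-validated Lasso otherwise — at small n the penalty is what keeps
#' the fit defined), and returns the AUC of the real-valued predictions
#' against the binary test labels.
#'
#' @param x_train,y_train training data; `y_train` real-valued or -1/+1.
#' @param x_test,y_test held-out data; `y_test` must contain both classes.
#' @param features column indices (or names) of the feature subset.
#' @return AUC in \[0, 1\].
#' @export
fit_and_score <- function(x_train, y_train, x_test, y_test, features) {
  if (length(features) == 0L) stop("feature subset must be non-empty")
  xtr <- as.matrix(x_train)[, features, drop = FALSE]
  xte <- as.matrix(x_test)[, features, drop = FALSE]
  if (ncol(xtr) == 1L) {
    b <- stats::cov(xtr[, 1L], y_train) / max(stats::var(xtr[, 1L]), 1e-12)
    pred <- xte[, 1L] * b
  } else {
    fit <- glmnet::cv.glmnet(xtr, y_train,
                             nfolds = max(3L, min(5L, nrow(xtr))),
                             standardize = TRUE)
    pred <- as.numeric(predict(fit, xte, s = "lambda.min"))
  }
  stat_auc(pred, y_test)
}

#' Compare feature selectors by held-out AUC over random splits
#'
#' The evaluation protocol for the three-way comparison: for each repeat,
#' a uniformly random training split of `n_train` samples is drawn, every
#' selector is run on the training data only, a linear classifier is fit
#' on the selected features, and the AUC is measured on the held-out
#' remainder.
#'
#' Selectors: `"fealect"` ranks features by subsampled-path score and
#' keeps the spline-selected set (or the top `top_k` if given, or if the
#' curve is too short to segment); `"lars"` is the pure Lasso-CV
#' classifier on all features; `"bolasso"` keeps the Bolasso-S set (an
#' empty selection predicts a constant, AUC 0.5).
#'
#' @param x,y data; `y` in -1/+1.
#' @param n_train training set size (< n).
#' @param repeats number of random splits.
#' @param seed RNG seed.
#' @param selectors subset of `c("fealect", "lars", "bolasso")`.
#' @param m_score subsamples for the score run per split.
#' @param m_bolasso bootstrap replicates for Bolasso per split.
#' @param top_k optional fixed number of top-scored features for the
#'   fealect selector (sweep mode); `NULL` uses the spline threshold.
#' @return data.frame with one row per (selector, repeat): `selector`,
#'   `rep`, `n_train`, `n_features`, `auc`; summary (mean and standard
#'   error per selector) attached as attribute `"summary"`.
#' @export
compare_selectors <- function(x, y, n_train, repeats = 100L, seed = 1L,
                              selectors = c("fealect", "lars", "bolasso"),
                              m_score = 100L, m_bolasso = 50L, top_k = NULL) {
  v <- validate_xy(x, y); x <- v$x; y <- v$y
  n <- nrow(x)
  if (n_train >= n) stop("n_train must be smaller than the number of samples")
  selectors <- match.arg(selectors, several.ok = TRUE)
  set.seed(seed)
  repseeds <- sample.int(.Machine$integer.max - 1L, repeats, replace = TRUE)
  rows <- list()
  for (r in seq_len(repeats)) {
    set.seed(repseeds[r])
    tr <- sort(sample.int(n, n_train))
    te <- setdiff(seq_len(n), tr)
    if (length(unique(y[te])) < 2L) {        # redraw until test has both classes
      for (try in 1:50) {
        tr <- sort(sample.int(n, n_train)); te <- setdiff(seq_len(n), tr)
        if (length(unique(y[te])) > 1L) break
      }
    }
    for (s in selectors) {
      feats <- switch(s,
        fealect = {
          fit <- fealect(x[tr, , drop = FALSE], y[tr], m = m_score,
                         seed = repseeds[r])
          if (!is.null(top_k)) {
            names(sort(coef(fit), decreasing = TRUE))[seq_len(min(top_k, ncol(x)))]
          } else {
            sel <- tryCatch(select_informative(fit), error = function(e) NULL)
            if (is.null(sel) || length(sel$selected_name) == 0L) {
              names(sort(coef(fit), decreasing = TRUE))[seq_len(min(5L, ncol(x)))]
            } else sel$selected_name
          }
        },
        lars = colnames(x),
        bolasso = bolasso(x[tr, , drop = FALSE], y[tr], m = m_bolasso,
                          threshold = 0.9, seed = repseeds[r])$selected_name)
      auc <- if (length(feats) == 0L) 0.5 else {
        fit_and_score(x[tr, , drop = FALSE], y[tr],
                      x[te, , drop = FALSE], y[te], feats)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        selector = s, rep = r, n_train = n_train,
        n_features = length(feats), auc = auc)
    }
  }
  out <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(out$auc, out$selector), function(a) {
    data.frame(mean_auc = mean(a), se = sd(a) / sqrt(length(a)), n = length(a))
  }))
  agg$selector <- rownames(agg)
  attr(out, "summary") <- agg[, c("selector", "mean_auc", "se", "n")]
  out
}
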