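#' LARS entry order of features
#'
#' Runs least-angle regression (the pure, no-drop variant) on a
#' standardized design and records the order in which features enter the
#' active set.  The first k entered features form the size-k active set
#' F_k of the regularization path, so the sets are nested by construction:
#' F_1 \eqn{\subset} F_2 \eqn{\subset} \ldots.  The path is truncated at
#' `min(max_features, d, n - 1)` (centered columns span at most an
#' (n-1)-dimensional space, so no more than n - 1 features can enter).
#'
#' Ties in the entry criterion (equal absolute correlation with the
#' evolving residual, e.g. duplicated columns) are broken by the lowest
#' column index, making the order deterministic.
#'
#' @param x standardized design matrix: zero-mean, unit-Euclidean-norm
#'   columns (see [standardize_features()]).  Non-standardized input is an
#'   error.
#' @param y centered numeric response.
#' @param max_features upper bound on the number of path steps.
#' @param tol numerical tolerance for correlation comparisons and for
#'   declaring the residual fully explained.
#' @return object of class `"entry_order"`: list with `order` (integer
#'   column indices in entry sequence) and `k` (its length, the realized
#'   path size K).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), 10, 4)
#' s <- standardize_features(x, rnorm(10))
#' lars_entry_order(s$x, s$y, max_features = 3)
#' @export
lars_entry_order <- function(x, y, max_features = ncol(x), tol = 1e-10) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (max_features < 1L) stop("max_features must be >= 1")
  if (!is_standardized(x, y)) {
    stop("lars_entry_order() requires standardized input; call standardize_features() first")
  }
  kmax <- min(max_features, d, n - 1L)
  active <- integer(0)
  signs <- numeric(0)
  mu <- numeric(n)
  inactive <- rep(TRUE, d)
  repeat {
    cvec <- drop(crossprod(x, y - mu))
    ci <- abs(cvec)
    ci[!inactive] <- -Inf
    cmax <- max(ci)
    if (!is.finite(cmax) || cmax < tol) break     # residual orthogonal to the rest
    j <- unname(which(ci >= cmax - tol))[1L]      # ties: lowest index
    active <- c(active, j)
    signs <- c(signs, sign(cvec[j]))
    inactive[j] <- FALSE
    if (length(active) >= kmax) break
    # equiangular direction over the signed active columns
    xa <- x[, active, drop = FALSE] * rep(signs, each = n)
    g <- crossprod(xa)
    ginv1 <- tryCatch(solve(g, rep(1, ncol(xa))), error = function(e) NULL)
    if (is.null(ginv1) || any(!is.finite(ginv1)) || sum(ginv1) <= tol) break  # collinear active set
    aa <- 1 / sqrt(sum(ginv1))
    u <- drop(xa %*% (aa * ginv1))
    cc <- max(abs(cvec[active]))
    a <- drop(crossprod(x, u))
    idx <- which(inactive)
    cand <- c((cc - cvec[idx]) / (aa - a[idx]),
              (cc + cvec[idx]) / (aa + a[idx]))
    cand <- cand[is.finite(cand) & cand > tol]
    gamma <- if (length(cand)) min(cand, cc / aa) else cc / aa
    mu <- mu + gamma * u
  }
  structure(list(order = active, k = length(active)), class = "entry_order")
}

#' @export
print.entry_order <- function(x, ...) {
  cat("LARS entry order (", x$k, " features):\n", sep = "")
  print(x$order)
  invisible(x)
}
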