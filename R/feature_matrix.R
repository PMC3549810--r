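#' Validate a feature matrix and response
#'
#' Checks the invariants every entry point of the package relies on: a
#' numeric matrix with finite entries, unique feature names, a finite
#' response of matching length, and at least 4 samples (fewer makes
#' subsampling degenerate).
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @param y numeric response of length `nrow(x)`; binary classes are
#'   expected to be encoded as -1/+1 real values (see [read_dataset()]).
#' @return `x` as a numeric matrix with column names (invisibly usable),
#'   with attribute `"response"` unset; called for its checks.
#' @keywords internal
validate_xy <- function(x, y) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("feature matrix must be numeric")
  if (nrow(x) < 4L) stop("at least 4 samples are required, got ", nrow(x))
  if (anyNA(x) || !all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite feature value at row %d, column %d", bad[1L], bad[2L]))
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) stop("feature names must be unique")
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("response length must equal the number of samples")
  if (!all(is.finite(y))) stop("non-finite response values")
  list(x = x, y = y)
}

#' Standardize features for a well-defined LARS entry order
#'
#' Centers every feature column to zero mean and rescales it to unit
#' Euclidean norm, centers the response, and drops zero-variance columns
#' (they can never enter a regularization path).  Standardization is
#' applied per (sub)sample so that the entry order reflects that sample's
#' geometry.
#'
#' @param x numeric matrix (samples x features).
#' @param y numeric response.
#' @param tol columns whose centered norm falls below `tol` are treated as
#'   zero-variance and removed.
#' @return list with components `x` (standardized matrix), `y` (centered
#'   response), `kept` (original column indices retained) and `removed`
#'   (names of dropped columns).
#' @examples
#' s <- standardize_features(cbind(a = c(1, 2, 3, 4), b = rep(5, 4)), c(0, 1, 0, 1))
#' colSums(s$x)            # ~0
#' colSums(s$x^2)          # 1
#' s$removed               # "b"
#' @export
standardize_features <- function(x, y, tol = 1e-12) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  xc <- sweep(x, 2L, colMeans(x), "-")
  nrm <- sqrt(colSums(xc^2))
  keep <- nrm > tol
  if (!any(keep)) stop("all feature columns have zero variance; matrix is unusable")
  removed <- colnames(x)[!keep]
  if (length(removed)) {
    warning("removed ", length(removed), " zero-variance column(s): ",
            paste(head(removed, 5L), collapse = ", "),
            if (length(removed) > 5L) ", ..." else "")
  }
  xs <- sweep(xc[, keep, drop = FALSE], 2L, nrm[keep], "/")
  list(x = xs, y = as.numeric(y) - mean(y),
       kept = unname(which(keep)), removed = removed)
}

is_standardized <- function(x, y, tol = 1e-8) {
  all(abs(colMeans(x)) < tol) &&
    all(abs(colSums(x^2) - 1) < tol) &&
    abs(mean(y)) < tol
}
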