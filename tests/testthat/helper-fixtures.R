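# Shared fixtures, all generated in code.

# n x d design with orthonormal, zero-mean columns (d <= n - 1)
orthonormal_design <- function(n, d) {
  stopifnot(d <= n - 1L)
  m <- scale(matrix(rnorm(n * (d + 1L)), n, d + 1L), scale = FALSE)
  qr.Q(qr(m))[, seq_len(d), drop = FALSE]
}

# noise-free continuous quadratic-linear-quadratic curve in the hinge basis
# used by the fit: y(r) = b0 + b1 r + b3 (k1-r)_+ + b4 (k1-r)_+^2
#                          + b5 (r-k2)_+ + b6 (r-k2)_+^2
make_qlq_curve <- function(L, k1, k2, b = c(0, 0.05, -0.3, 0.04, 0.2, 0.1)) {
  r <- seq_len(L)
  h1 <- pmax(k1 - r, 0); h2 <- pmax(r - k2, 0)
  b[1] + b[2] * r + b[3] * h1 + b[4] * h1^2 + b[5] * h2 + b[6] * h2^2
}

as_score_curve <- function(y) {
  structure(list(rank = seq_along(y), log_score = y, score = exp(y),
                 feature_id = seq_along(y),
                 feature_name = paste0("V", seq_along(y)), n_zero = 0L),
            class = "score_curve")
}

# independent brute-force knot search: plain lm.fit per knot pair
segment_oracle <- function(y, min_seg = 3L) {
  L <- length(y); r <- seq_len(L)
  best <- list(sse = Inf, k1 = NA, k2 = NA)
  for (k1 in min_seg:(L - 2L * min_seg)) {
    for (k2 in (k1 + min_seg):(L - min_seg)) {
      h1 <- pmax(k1 - r, 0); h2 <- pmax(r - k2, 0)
      X <- cbind(1, r, h1, h1^2, h2, h2^2)
      sse <- sum(lm.fit(X, y)$residuals^2)
      if (sse < best$sse - 1e-12) best <- list(sse = sse, k1 = k1, k2 = k2)
    }
  }
  best
}
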