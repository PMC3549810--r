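#' Exact inclusion probability of a fixed subset under subsampling
#'
#' Probability that a fixed set U of r samples is contained in a uniform
#' without-replacement draw of b = floor(gamma * n) samples out of n:
#' `choose(n - r, b - r) / choose(n, b)`, computed in log space.  As n
#' grows with gamma fixed this tends to `gamma^r` with an O(1/n) error —
#' the origin of the geometric score decay of over-fitting features.
#'
#' @param n number of samples.
#' @param r size of the fixed subset U.
#' @param gamma subsample fraction in (0, 1].
#' @return probability in \[0, 1\]; 0 when `r > b`.
#' @examples
#' inclusion_probability_exact(4, 1, 0.5)   # 3/6 of the C(4,2) subsets
#' @export
inclusion_probability_exact <- function(n, r, gamma) {
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  if (r < 0) stop("r must be non-negative")
  if (r > n) stop("r cannot exceed n")
  b <- floor(gamma * n)
  if (r > b) return(0)
  exp(lchoose(n - r, b - r) - lchoose(n, b))
}

#' Empirical score of a feature that over-fits on a sample set U
#'
#' A feature "over-fits on U" when it enters the path of a subsample B at
#' every size if and only if U is contained in B.  This harness enforces
#' that biconditional exactly, by running the ordinary scoring loop with a
#' mock path engine: the engine returns a full-length-K path whose rank-1
#' feature is the over-fitting one when U is in the subsample, and a path
#' without it otherwise.  The feature's expected score is therefore
#' `H(K) * Pr(U in B)`, which tends to `H(K) * gamma^r` — log-linear in
#' r with slope `log(gamma)`, the exponential law that makes the middle
#' segment of the score curve a straight line.
#'
#' @param U integer vector of sample indices (the over-fitting set; may be
#'   empty).
#' @param n number of samples.
#' @param gamma subsample fraction.
#' @param m number of subsamples.
#' @param K mock path length per subsample.
#' @param seed RNG seed.
#' @return list with `score` (the over-fitting feature's empirical score),
#'   `frequency` (empirical `Pr(U in B)`), `h_k` (`H(K)`), and `m`.
#' @export
mock_overfit_score <- function(U, n, gamma, m, K = 10L, seed = 1L) {
  U <- as.integer(U)
  if (length(U) && (min(U) < 1L || max(U) > n)) stop("U must be indices in 1..n")
  if (m < 1L) stop("m must be >= 1")
  # feature 1 is the over-fitting feature; a second, always-present filler
  # feature keeps the entry order non-empty when U is absent from B
  engine <- function(xs, ys, kmax, idx) {
    ord <- if (all(U %in% idx)) c(1L, 2L) else 2L
    structure(list(order = ord, k = as.integer(K)), class = "entry_order")
  }
  x <- matrix(0, n, 2L)
  res <- score_loop(x, numeric(n), gamma, m, max_features = K, seed = seed,
                    engine = engine, standardize = FALSE)
  hk <- harmonic(K)
  list(score = res$scores[1L], frequency = res$scores[1L] / hk, h_k = hk, m = m)
}

#' Simulate a sparse linear model in the n << d regime
#'
#' Standard-normal design, `s` support features with equal-magnitude
#' coefficients scaled so that `var(signal) / var(noise) = snr` (unit
#' noise), Gaussian noise.  Binary labels are the median split of the real
#' response (balanced classes by construction); the real response is
#' retained for regression use.  Fully reproducible from the seed.
#'
#' @param n samples; `d` features; `s` support size; `snr` signal-to-noise
#'   variance ratio; `seed` RNG seed.
#' @param d,s,snr,seed see above.
#' @return object of class `"sparse_sim"`: `x` (n x d, named columns),
#'   `y` (real response), `y_class` (-1/+1 median split), `support`
#'   (indices of the s true features), `beta` (coefficient vector),
#'   `noise_sd`, `snr`, `seed`.
#' @export
generate_sparse_regression <- function(n, d, s, snr = 5, seed = 1L) {
  if (s > d) stop("s cannot exceed d")
  if (n < 4L) stop("n must be at least 4")
  if (s > 0 && snr < 0) stop("snr must be non-negative")
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d,
              dimnames = list(NULL, sprintf("f%03d", seq_len(d))))
  beta <- numeric(d)
  support <- integer(0)
  if (s > 0) {
    support <- sort(sample.int(d, s))
    beta[support] <- sqrt(snr / s)       # var(x %*% beta) = s * beta^2 = snr
  }
  y <- drop(x %*% beta) + rnorm(n)       # noise_sd = 1
  y_class <- ifelse(y > median(y), 1, -1)
  structure(list(x = x, y = y, y_class = y_class, support = support,
                 beta = beta, noise_sd = 1, snr = snr, seed = as.integer(seed)),
            class = "sparse_sim")
}

#' @export
print.sparse_sim <- function(x, ...) {
  cat(sprintf("sparse linear simulation: n = %d, d = %d, |support| = %d, snr = %g, seed = %d\n",
              nrow(x$x), ncol(x$x), length(x$support), x$snr, x$seed))
  if (length(x$support)) cat("  support:", paste(colnames(x$x)[x$support], collapse = ", "), "\n")
  invisible(x)
}

#' Run the combinatorial validation suites
#'
#' `"inclusion"` checks the exact subset-inclusion probability against
#' exhaustive enumeration for all n <= `n_enum` and verifies that the gap
#' to `gamma^r` shrinks like O(1/n) along a doubling n-grid.  `"decay"`
#' runs the mock over-fitting harness for r = 1..`r_max` and checks that
#' the least-squares slope of `log(score)` against r equals `log(gamma)`
#' within `slope_tol`.
#'
#' @param suite `"inclusion"` or `"decay"`.
#' @param seed RNG seed (used by the `decay` Monte-Carlo harness).
#' @param gamma subsample fraction (default 3/4).
#' @param n_enum enumeration bound for `inclusion` (default 12).
#' @param n,m,r_max,K,slope_tol `decay` harness settings.
#' @return list with `suite`, `pass` (logical) and suite-specific details.
#' @export
validate_theory <- function(suite = c("inclusion", "decay"), seed = 1L,
                            gamma = 3 / 4, n_enum = 12L,
                            n = 400L, m = 20000L, r_max = 6L, K = 10L,
                            slope_tol = 0.03) {
  suite <- match.arg(suite)
  if (suite == "inclusion") {
    max_gap <- 0
    for (nn in 4:n_enum) {
      for (g in c(0.25, 0.5, 0.75, 1)) {
        b <- floor(g * nn)
        if (b < 1L) next
        for (r in 0:b) {
          exact <- inclusion_probability_exact(nn, r, g)
          enum <- enumerate_inclusion_probability(nn, r, b)
          max_gap <- max(max_gap, abs(exact - enum))
        }
      }
    }
    grid <- c(20L, 40L, 80L, 160L, 320L)
    r <- 3L
    gaps <- vapply(grid, function(nn)
      abs(inclusion_probability_exact(nn, r, gamma) - gamma^r), numeric(1))
    shrinking <- all(diff(gaps) < 0)
    bounded <- all(gaps * grid <= gaps[1L] * grid[1L] * 1.01)  # n*gap non-increasing => O(1/n)
    list(suite = "inclusion", pass = max_gap < 1e-12 && shrinking && bounded,
         max_enumeration_gap = max_gap, n_grid = grid, gamma_power_gaps = gaps)
  } else {
    rs <- seq_len(r_max)
    scores <- vapply(rs, function(r) {
      mock_overfit_score(seq_len(r), n = n, gamma = gamma, m = m, K = K,
                         seed = seed + r)$score
    }, numeric(1))
    slope <- unname(coef(stats::lm(log(scores) ~ rs))[2L])
    list(suite = "decay", pass = abs(slope - log(gamma)) <= slope_tol,
         slope = slope, expected_slope = log(gamma), tol = slope_tol,
         scores = scores, r = rs, n = n, m = m)
  }
}

# brute-force oracle: enumerate all size-b subsets of 1..n and count those
# containing 1..r (small n only)
enumerate_inclusion_probability <- function(n, r, b) {
  if (r > b) return(0)
  subsets <- utils::combn(n, b)
  mean(apply(subsets, 2L, function(s) all(seq_len(r) %in% s)))
}
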