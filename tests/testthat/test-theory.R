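test_that("subset inclusion probability matches exhaustive enumeration", {
  # hand case: n = 4, b = 2, r = 1 -> 3 of the 6 subsets contain the sample
  expect_equal(inclusion_probability_exact(4, 1, 0.5), 0.5)
  expect_equal(inclusion_probability_exact(10, 0, 0.3), 1)       # empty set
  expect_equal(inclusion_probability_exact(10, 5, 0.3), 0)       # r > b
  expect_error(inclusion_probability_exact(10, 11, 0.5), "exceed")

  for (n in c(5L, 8L, 11L)) {
    for (b in seq_len(n)) {
      for (r in 0:b) {
        enum <- mean(apply(utils::combn(n, b), 2L,
                           function(s) all(seq_len(r) %in% s)))
        expect_equal(inclusion_probability_exact(n, r, b / n), enum,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("inclusion probability is monotone in r and gamma", {
  for (n in c(12L, 40L)) {
    for (g in c(0.3, 0.5, 0.75)) {
      b <- floor(g * n)
      p <- vapply(0:b, function(r) inclusion_probability_exact(n, r, g), 1)
      expect_true(all(diff(p) <= 1e-15))
    }
    gs <- c(0.3, 0.5, 0.7, 0.9, 1)
    p <- vapply(gs, function(g) inclusion_probability_exact(n, 3, g), 1)
    expect_true(all(diff(p) >= -1e-15))
  }
})

test_that("the gamma^r limit is approached at rate O(1/n)", {
  gamma <- 3 / 4; r <- 3
  grid <- c(20L, 40L, 80L, 160L, 320L)
  gaps <- vapply(grid, function(n)
    abs(inclusion_probability_exact(n, r, gamma) - gamma^r), 1)
  expect_true(all(diff(gaps) < 0))
  expect_true(all(gaps * grid <= gaps[1] * grid[1] * 1.01))  # n * gap bounded
})

test_that("the mock over-fitting harness is exact in degenerate cases and unbiased", {
  hk <- sum(1 / (1:10))
  expect_equal(mock_overfit_score(integer(0), n = 30, gamma = 0.6, m = 50,
                                  K = 10, seed = 1)$score, hk)      # r = 0
  expect_equal(mock_overfit_score(1:4, n = 12, gamma = 1, m = 30,
                                  K = 10, seed = 2)$score, hk)      # gamma = 1
  # unbiasedness: empirical frequency ~ exact probability within 3 MC SEs
  n <- 20; gamma <- 0.75; r <- 2; m <- 2000
  p <- inclusion_probability_exact(n, r, gamma)
  f <- mock_overfit_score(seq_len(r), n, gamma, m, K = 10, seed = 3)$frequency
  expect_lt(abs(f - p), 3 * sqrt(p * (1 - p) / m))
})

test_that("log mock scores are affine in r with slope log(gamma)", {
  gamma <- 0.7
  scores <- vapply(1:4, function(r)
    mock_overfit_score(seq_len(r), n = 300, gamma = gamma, m = 4000,
                       K = 8, seed = 10 + r)$score, 1)
  slope <- unname(coef(lm(log(scores) ~ seq_len(4)))[2])
  expect_equal(slope, log(gamma), tolerance = 0.05)
})

test_that("the sparse simulator is reproducible and calibrated", {
  s1 <- generate_sparse_regression(24, 60, 4, 5, seed = 99)
  s2 <- generate_sparse_regression(24, 60, 4, 5, seed = 99)
  expect_identical(s1, s2)
  expect_length(s1$support, 4L)
  expect_identical(sort(unique(s1$y_class)), c(-1, 1))
  expect_equal(sum(s1$y_class), 0)                    # balanced median split
  big <- generate_sparse_regression(20000, 5, 2, 5, seed = 100)
  expect_equal(var(drop(big$x %*% big$beta)), 5, tolerance = 0.2)
  expect_error(generate_sparse_regression(10, 5, 6), "exceed")
})

test_that("under the null every feature's mean score is exchangeable", {
  means <- matrix(0, 25, 15)
  for (i in 1:25) {
    sim <- generate_sparse_regression(20, 15, 0, 5, seed = 300 + i)
    means[i, ] <- coef(fealect(sim$x, sim$y, m = 30, seed = 400 + i))
  }
  grand <- mean(means)
  se <- sd(colMeans(means))
  expect_true(all(abs(colMeans(means) - grand) <= 3 * se + 1e-12))
})

test_that("validate_theory returns passing structured reports", {
  l4 <- validate_theory("inclusion", n_enum = 8L)
  expect_true(l4$pass)
  expect_lt(l4$max_enumeration_gap, 1e-12)
  t5 <- validate_theory("decay", seed = 17, n = 200L, m = 3000L,
                        r_max = 4L, slope_tol = 0.08)
  expect_true(t5$pass)
  expect_equal(t5$slope, log(3 / 4), tolerance = 0.08)
})
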