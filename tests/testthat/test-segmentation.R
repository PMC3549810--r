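test_that("the score curve sorts positive log-scores and records exclusions", {
  scores <- c(exp(4:9), exp(1), exp(2), exp(3), 0, 0)
  names(scores) <- paste0("f", seq_along(scores))
  cv <- build_score_curve(scores)
  expect_equal(cv$log_score[1:3], c(1, 2, 3))
  expect_true(all(diff(cv$log_score) >= 0))
  expect_identical(cv$n_zero, 2L)
  expect_identical(length(cv$rank) + cv$n_zero, length(scores))

  flat <- setNames(rep(2.5, 9), paste0("f", 1:9))
  expect_equal(build_score_curve(flat)$log_score, rep(log(2.5), 9))

  expect_error(build_score_curve(setNames(c(1:8, 0), paste0("f", 1:9))),
               "at least 9")
})

test_that("constructed quadratic-linear-quadratic curves are recovered exactly", {
  y <- make_qlq_curve(40, 10, 30)
  fit <- fit_three_segment(as_score_curve(y))
  expect_identical(c(fit$k1, fit$k2), c(10L, 30L))
  expect_lt(fit$sse, 1e-12)
  # fitted values reproduce the construction and are continuous at the knots
  expect_equal(predict(fit), y, tolerance = 1e-8)
  for (kn in c(fit$k1, fit$k2)) {
    expect_lt(abs(predict(fit, kn - 1e-9) - predict(fit, kn + 1e-9)), 1e-8)
  }
  # standard-form segment polynomials agree with the hinge form
  g1 <- fit$coefficients$g1; g3 <- fit$coefficients$g3
  r1 <- 1:10; r3 <- 30:40
  expect_equal(g1[[1]] + g1[[2]] * r1 + g1[[3]] * r1^2, y[r1], tolerance = 1e-8)
  expect_equal(g3[[1]] + g3[[2]] * r3 + g3[[3]] * r3^2, y[r3], tolerance = 1e-8)
})

test_that("a perfectly linear curve is fit exactly with zero curvature", {
  y <- 1 + 0.3 * (1:15)
  fit <- fit_three_segment(as_score_curve(y))
  expect_equal(fit$coefficients$g2[["slope"]], 0.3, tolerance = 1e-9)
  expect_lt(abs(fit$coefficients$g1[["quad"]]), 1e-9)
  expect_lt(abs(fit$coefficients$g3[["quad"]]), 1e-9)
  expect_lt(fit$sse, 1e-18)
})

test_that("the knot search matches independent brute-force enumeration", {
  set.seed(601)
  for (i in 1:12) {
    L <- sample(9:15, 1L)
    y <- sort(cumsum(abs(rnorm(L))))           # noisy increasing curve
    fit <- fit_three_segment(as_score_curve(y))
    oracle <- segment_oracle(y)
    expect_identical(c(fit$k1, fit$k2), c(oracle$k1, oracle$k2))
    expect_equal(fit$sse, oracle$sse, tolerance = 1e-8)
  }
})

test_that("selection is an upper order-ideal above the linear segment", {
  y <- make_qlq_curve(30, 8, 22, b = c(-4, 0.08, -0.2, 0.05, 0.5, 0.12))
  scores <- setNames(exp(y), paste0("f", 1:30))
  fit <- fit_three_segment(build_score_curve(scores))
  sel <- select_informative(scores, fit)
  expect_identical(sum(sel$segment_counts), 30L)
  expect_identical(unname(sel$segment_counts[3L]), 30L - fit$k2)
  unsel <- setdiff(which(scores > 0), sel$selected_id)
  expect_gt(min(scores[sel$selected_id]), max(scores[unsel]))
  expect_true(all(scores[sel$selected_id] > sel$threshold_score))
})

test_that("selection is invariant to positive rescaling of the scores", {
  sim <- generate_sparse_regression(30, 40, 3, 8, seed = 41)
  fit <- fealect(sim$x, sim$y, m = 50, seed = 42)
  s1 <- coef(fit); s2 <- s1 * 17.3
  f1 <- fit_three_segment(build_score_curve(s1))
  f2 <- fit_three_segment(build_score_curve(s2))
  expect_identical(c(f1$k1, f1$k2), c(f2$k1, f2$k2))
  expect_identical(select_informative(s1, f1)$selected_id,
                   select_informative(s2, f2)$selected_id)
})

test_that("appending a higher-scoring feature keeps previous selections", {
  y <- make_qlq_curve(30, 8, 22, b = c(-4, 0.08, -0.2, 0.05, 0.5, 0.12))
  scores <- setNames(exp(y), paste0("f", 1:30))
  sel_old <- select_informative(scores)
  y2 <- c(y, make_qlq_curve(31, 8, 22, b = c(-4, 0.08, -0.2, 0.05, 0.5, 0.12))[31])
  scores2 <- setNames(exp(y2), paste0("f", 1:31))
  sel_new <- select_informative(scores2)
  expect_true(all(sel_old$selected_name %in% sel_new$selected_name))
})

test_that("boundary knot placement selects exactly the trailing segment", {
  # linear everywhere except a sharp upturn on the last three points
  r <- 1:20
  y <- 0.1 * r
  y[18:20] <- y[18:20] + c(1, 4, 9)
  fit <- fit_three_segment(as_score_curve(y))
  expect_identical(fit$k2, 17L)
  sel <- select_informative(setNames(exp(y), paste0("f", r)), fit)
  expect_identical(sort(sel$selected_id), 18:20)
})
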