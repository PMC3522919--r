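fixture_points <- function() {
  # 10 fixed points in 2-D, two loose groups
  matrix(c(
    0.10, 0.20, 0.15, 0.25, 0.20, 0.15, 0.05, 0.10, 0.25, 0.30,
    0.80, 0.75, 0.85, 0.90, 0.70, 0.78, 0.88, 0.82, 0.76, 0.95
  ), ncol = 2, dimnames = list(NULL, c("a", "b")))
}

test_that("single-cluster CFCM has the weighted-mean closed form", {
  x <- fixture_points()
  w <- seq(0.1, 1, length.out = 10)
  fit <- cfcm(x, w, clusters = 1, seed = 3, tol = 1e-12)
  expect_equal(as.numeric(fit$memberships), w, tolerance = 1e-12)
  v_expected <- colSums(w^2 * x) / sum(w^2)
  expect_equal(as.numeric(fit$centers), unname(v_expected), tolerance = 1e-10)
})

test_that("membership update splits weight symmetrically and handles coincidence", {
  # one point equidistant from two centers, w = 0.8
  D2 <- matrix(c(0.5, 0.5), nrow = 2)
  expect_equal(as.numeric(tsklm:::cfcm_membership(D2, 0.8, m = 2)), c(0.4, 0.4))
  # point coincident with center 2 takes its full weight there
  D2 <- matrix(c(0.5, 0), nrow = 2)
  expect_equal(as.numeric(tsklm:::cfcm_membership(D2, 0.7, m = 2)), c(0, 0.7))
})

test_that("CFCM matches a brute-force scalar-loop oracle from the same seed", {
  x <- fixture_points()
  ctx <- make_uniform_contexts(seq(0, 1, length.out = 10), p = 2)
  w <- context_membership(ctx, seq(0, 1, length.out = 10), which = 2)
  fit <- cfcm(x, w, clusters = 2, m = 2, tol = 1e-12, max_iter = 2000, seed = 42)
  oracle <- brute_force_cfcm(x, w, 2, m = 2, tol = 1e-12, seed = 42)
  expect_lt(max(abs(fit$centers - oracle$centers)), 1e-8)
  expect_lt(max(abs(fit$memberships - oracle$memberships)), 1e-8)
})

test_that("membership columns conserve the context weight at every sweep", {
  x <- fixture_points()
  w <- c(0, 0.2, 0.5, 1, 0.8, 0.3, 0.9, 0.1, 0.6, 0.4)
  fit <- cfcm(x, w, clusters = 3, seed = 9, keep_trace = TRUE)
  for (U in fit$u_trace) {
    expect_lt(max(abs(colSums(U) - w)), 1e-12)
    expect_true(all(U >= 0))
    expect_true(all(U <= rep(w, each = nrow(U)) + 1e-12))
  }
})

test_that("the clustering objective is non-increasing", {
  x <- fixture_points()
  w <- seq(1, 0.1, length.out = 10)
  fit <- cfcm(x, w, clusters = 3, seed = 5, tol = 1e-12, max_iter = 500)
  expect_true(all(diff(fit$objective_trace) <= 1e-10))
})

test_that("with unit weights CFCM reduces to standard fuzzy c-means", {
  skip_if_not_installed("e1071")
  # two well-separated groups so the FCM optimum is sharp
  x <- matrix(c(0.1, 0.2, 0.15, 0.25, 0.2, 0.8, 0.9, 0.85, 0.75, 0.8,
                0.2, 0.1, 0.25, 0.15, 0.2, 0.8, 0.7, 0.9, 0.85, 0.75),
              ncol = 2)
  fit <- cfcm(x, rep(1, 10), clusters = 2, seed = 17, tol = 1e-13,
              max_iter = 2000)
  ref <- e1071::cmeans(x, centers = 2, m = 2, iter.max = 2000,
                       control = list(reltol = 1e-16))
  ours <- fit$centers[order(fit$centers[, 1]), ]
  theirs <- ref$centers[order(ref$centers[, 1]), ]
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-5)
})

test_that("centers stay inside the bounding box of supported points", {
  set.seed(31)
  x <- matrix(runif(60), ncol = 2)
  w <- runif(30)
  w[sample(30, 5)] <- 0
  fit <- cfcm(x, w, clusters = 4, seed = 2)
  sup <- x[w > 0, , drop = FALSE]
  for (j in 1:2) {
    expect_true(all(fit$centers[, j] >= min(sup[, j]) - 1e-9))
    expect_true(all(fit$centers[, j] <= max(sup[, j]) + 1e-9))
  }
})

test_that("identical seeds give bit-identical results", {
  x <- fixture_points()
  w <- runif(10)
  expect_identical(cfcm(x, w, clusters = 2, seed = 77),
                   cfcm(x, w, clusters = 2, seed = 77))
})

test_that("invalid clustering inputs are rejected", {
  x <- fixture_points()
  expect_error(cfcm(x, rep(0, 10), clusters = 2), "empty context")
  expect_error(cfcm(x, c(rep(1, 3), rep(0, 7)), clusters = 5),
               "positive weight")
  expect_error(cfcm(x, rep(0.5, 10), clusters = 2, m = 1), "m")
  expect_error(cfcm(x, rep(2, 10), clusters = 2), "\\[0, 1\\]")
})
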