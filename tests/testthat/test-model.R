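train_data <- function(n = 76, seed = 5) {
  simulate_activity(activity_profile("treadmill", n = n), seed = seed)
}

test_that("activations are a convex weighting of contexts", {
  # p = 2 contexts, one center each, symmetric about x = 0.5
  mod <- toy_model(
    break_points = c(0, 0, 1, 0, 1, 1),
    centers = list(matrix(c(0.2, 0.5), 1), matrix(c(0.8, 0.5), 1)),
    coefficients = rep(0, 4)
  )
  z <- activations(mod, data.frame(x1 = 0.5, x2 = 0.5))
  expect_equal(unname(as.numeric(z)), c(0.5, 0.5))

  # input coincident with a center: that context takes all membership
  z2 <- activations(mod, data.frame(x1 = 0.8, x2 = 0.5))
  expect_equal(unname(as.numeric(z2)), c(0, 1))

  # random inputs: non-negative, sum to one
  set.seed(8)
  xs <- data.frame(x1 = runif(200), x2 = runif(200))
  Z <- as.matrix(activations(mod, xs))
  expect_lt(max(abs(rowSums(Z) - 1)), 1e-12)
  expect_true(all(Z >= 0))
})

test_that("consequent LSE recovers exact linear structure", {
  set.seed(13)
  N <- 40
  X <- cbind(runif(N), runif(N))
  ctx1 <- tsklm:::new_context_set(0.2, c(0, 1), "uniform")  # single context, z == 1
  Z <- matrix(1, N, 1)
  y <- 2 * X[, 1] + 3 * X[, 2] + 0.2
  beta <- fit_consequents(Z, X, y, ctx1)
  expect_equal(unname(as.numeric(beta)), c(2, 3), tolerance = 1e-10)

  # targets equal to the context part leave zero residual -> zero coefficients
  ctx2 <- make_uniform_contexts(c(0, 1), p = 2)
  u <- runif(N)
  Z2 <- cbind(u, 1 - u)
  y2 <- as.numeric(Z2 %*% ctx2$break_points[, "r_mode"])
  expect_lt(max(abs(fit_consequents(Z2, X, y2, ctx2))), 1e-10)

  # duplicating all rows leaves the solution unchanged
  beta_dup <- fit_consequents(rbind(Z, Z), rbind(X, X), c(y, y), ctx1)
  expect_equal(beta_dup, beta, tolerance = 1e-12)
})

test_that("the bias is the mean residual and recentres training error", {
  expect_equal(compute_bias(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(compute_bias(c(1, 2), c(0.5, 1.5)), 0.5)
  set.seed(2)
  y <- rnorm(50)
  pred <- rnorm(50)
  b0 <- compute_bias(y, pred)
  expect_lt(abs(mean(y - (pred + b0))), 1e-12)
  expect_error(compute_bias(numeric(0), numeric(0)), "empty")
  expect_error(compute_bias(1:3, 1:2), "length")
})

test_that("modal prediction equals a term-by-term hand evaluation", {
  # 3-rule toy: hand evaluation of the defuzzified sum
  bp <- c(0.0, 0.1, 0.4,   0.3, 0.5, 0.7,   0.6, 0.9, 1.0)
  centers <- list(matrix(c(0.1, 0.2), 1), matrix(c(0.5, 0.5), 1),
                  matrix(c(0.9, 0.7), 1))
  coef <- c(0.2, -0.1, 0.05, 0.3, -0.2, 0.15)
  b0 <- 0.03
  mod <- toy_model(matrix(bp, ncol = 3, byrow = TRUE), centers, coef, bias = b0)

  x <- c(0.35, 0.65)
  # hand-rolled: FCM memberships over the three pooled centers, m = 2
  d2 <- sapply(centers, function(v) sum((x - as.numeric(v))^2))
  z <- (1 / d2) / sum(1 / d2)
  r <- c(0.1, 0.5, 0.9)
  B <- matrix(coef, 3, 2, byrow = TRUE)
  modal_hand <- sum(sapply(1:3, function(t) z[t] * (r[t] + sum(B[t, ] * x)))) + b0
  lower_hand <- sum(sapply(1:3, function(t) {
    z[t] * (c(0.0, 0.3, 0.6)[t] + sum(B[t, ] * x))
  })) + b0

  pred <- predict(mod, data.frame(x1 = x[1], x2 = x[2]))
  expect_equal(pred$.pred, modal_hand, tolerance = 1e-12)
  expect_equal(pred$.pred_lower, lower_hand, tolerance = 1e-12)
})

test_that("interval predictions are ordered and respond linearly to context width", {
  d <- train_data()
  fit <- tsklm(d, ee ~ hr + mi, contexts = 4, clusters = 3, seed = 11)
  set.seed(19)
  probe <- data.frame(hr = runif(1000, 85, 180), mi = runif(1000, 0.15, 0.95))
  pred <- predict(fit, probe)
  expect_true(all(pred$.pred_lower <= pred$.pred + 1e-12))
  expect_true(all(pred$.pred <= pred$.pred_upper + 1e-12))

  # degenerate contexts (r- = r = r+) collapse the interval
  deg <- fit
  deg$contexts$break_points[, "r_minus"] <- deg$contexts$break_points[, "r_mode"]
  deg$contexts$break_points[, "r_plus"] <- deg$contexts$break_points[, "r_mode"]
  pdeg <- predict(deg, probe[1:50, ])
  expect_equal(pdeg$.pred_lower, pdeg$.pred, tolerance = 1e-12)
  expect_equal(pdeg$.pred_upper, pdeg$.pred, tolerance = 1e-12)

  # widening every context by +/- eps shifts the bounds by exactly eps
  # (on the normalized scale; the output scale multiplies by the range)
  eps <- 0.01
  wide <- fit
  wide$contexts$break_points[, "r_minus"] <-
    wide$contexts$break_points[, "r_minus"] - eps
  wide$contexts$break_points[, "r_plus"] <-
    wide$contexts$break_points[, "r_plus"] + eps
  pw <- predict(wide, probe[1:50, ])
  scale <- fit$normalization$y_max - fit$normalization$y_min
  expect_equal(pw$.pred_lower, pred$.pred_lower[1:50] - eps * scale,
               tolerance = 1e-10)
  expect_equal(pw$.pred_upper, pred$.pred_upper[1:50] + eps * scale,
               tolerance = 1e-10)
  expect_equal(pw$.pred, pred$.pred[1:50], tolerance = 1e-12)
})

test_that("training is unbiased, deterministic, and dominates the baseline", {
  d <- train_data()
  fit <- tsklm(d, ee ~ hr + mi, contexts = 3, clusters = 3, seed = 23)
  # mean training residual of the modal output is zero after the bias step
  resid <- d$ee - predict(fit, d)$.pred
  expect_lt(abs(mean(resid)), 1e-10)

  refit <- tsklm(d, ee ~ hr + mi, contexts = 3, clusters = 3, seed = 23)
  expect_identical(fit[setdiff(names(fit), "call")],
                   refit[setdiff(names(refit), "call")])

  conv <- tsklm(d, ee ~ hr + mi, contexts = 3, clusters = 3, seed = 23,
                variant = "conventional")
  expect_true(all(conv$coefficients == 0))
  expect_identical(conv$bias, 0)
  # same seed -> same granulation, so the TSK fit can only improve on the
  # baseline's training error (extra LSE parameters plus bias)
  expect_lte(fit$trn_rmse, conv$trn_rmse)
  expect_identical(fit$centers, conv$centers)
})

test_that("normalization round-trips and single-input models work", {
  d <- train_data()
  fit <- tsklm(d, ee ~ hr, contexts = 3, clusters = 2, seed = 3)
  norm <- fit$normalization
  y <- runif(100, 2, 12)
  expect_equal(tsklm:::denormalize_output(tsklm:::normalize_output(y, norm), norm),
               y, tolerance = 1e-12)
  pred <- predict(fit, d)
  expect_true(all(is.finite(pred$.pred)))
  expect_error(tsklm(dplyr::mutate(d, hr = 100), ee ~ hr + mi),
               "degenerate input range")
  expect_error(tsklm(dplyr::mutate(d, ee = 5), ee ~ hr + mi),
               "degenerate output range")
})

test_that("models round-trip losslessly through JSON", {
  d <- train_data()
  for (variant in c("tsk", "conventional")) {
    fit <- tsklm(d, ee ~ hr + mi, contexts = 4, clusters = 2, seed = 31,
                 scheme = "flexible", variant = variant)
    path <- withr::local_tempfile(fileext = ".json")
    tsklm_to_json(fit, path)
    back <- tsklm_from_json(path)
    probe <- d[1:20, ]
    expect_identical(predict(back, probe), predict(fit, probe))
    expect_identical(back$coefficients, fit$coefficients)
    expect_identical(back$bias, fit$bias)
  }
})

test_that("tidiers summarise fitted models", {
  d <- train_data()
  fit <- tsklm(d, ee ~ hr + mi, contexts = 3, clusters = 2, seed = 41)
  td <- tidy(fit)
  expect_setequal(unique(td$term),
                  c("r_minus", "r_mode", "r_plus", "hr", "mi", "bias"))
  expect_equal(nrow(td), 3 * 5 + 1)
  gl <- glance(fit)
  expect_equal(gl$contexts, 3)
  expect_equal(gl$clusters, 2)
  expect_equal(gl$trn_rmse, fit$trn_rmse)
})
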