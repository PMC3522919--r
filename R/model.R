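#' Fit a TSK linguistic model
#'
#' Trains an interval-valued fuzzy predictor on tabular data. The pipeline
#' is: min-max normalize inputs and output to `[0, 1]` (statistics from the
#' training data only); build `p` triangular linguistic contexts on the
#' normalized output; run context-based fuzzy c-means ([cfcm()]) with `c`
#' clusters inside each context; compute rule activations for the training
#' inputs; estimate the linear consequent coefficients by a single global
#' least squares fit ([fit_consequents()]); and finally add a scalar bias
#' equal to the mean training residual ([compute_bias()]), which makes the
#' modal training prediction unbiased.
#'
#' Each rule's consequent is the context's fuzzy number `(r-, r, r+)` plus a
#' linear term in the inputs, so a prediction is itself a triangular fuzzy
#' number: the modal value uses the apexes `r_t`, the lower/upper bounds the
#' outer break points. `variant = "conventional"` drops the linear terms and
#' the bias, leaving the classic linguistic model whose consequents are the
#' context fuzzy numbers alone; it shares the granulation code path, so with
#' the same seed both variants use identical contexts and cluster centers.
#'
#' @param data A data frame containing the model variables.
#' @param formula Model formula, e.g. `ee ~ hr + mi`. No intercept or
#'   transformations; the right-hand side names the input columns.
#' @param contexts Number of linguistic contexts `p >= 2`.
#' @param clusters Number of clusters per context `c >= 1`.
#' @param scheme Context placement, `"uniform"` or `"flexible"` (see
#'   [make_contexts()]).
#' @param variant `"tsk"` for the full TSK linguistic model or
#'   `"conventional"` for the baseline linguistic model.
#' @param m Fuzzification factor (> 1), default 2.
#' @param tol,max_iter Convergence controls passed to [cfcm()].
#' @param seed Optional integer seed; fixes the clustering initialization so
#'   refits are bit-identical. The global RNG state is left untouched.
#'
#' @return A fitted `tsklm` object. Use [predict.tsklm()] for interval
#'   predictions, [tidy.tsklm()]/[glance.tsklm()] for summaries and
#'   [tsklm_to_json()] for serialization.
#' @examples
#' d <- simulate_activity(seed = 1)
#' fit <- tsklm(d, ee ~ hr + mi, contexts = 3, clusters = 2, seed = 1)
#' predict(fit, head(d))
#' @export
tsklm <- function(data, formula, contexts = 3, clusters = 3,
                  scheme = c("uniform", "flexible"),
                  variant = c("tsk", "conventional"),
                  m = 2, tol = 1e-5, max_iter = 200, seed = NULL) {
  scheme <- match.arg(scheme)
  variant <- match.arg(variant)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- as.numeric(stats::model.response(mf))
  x_names <- attr(stats::terms(mf), "term.labels")
  X <- as.matrix(mf[, x_names, drop = FALSE])
  storage.mode(X) <- "double"
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("inputs and output must be finite", call. = FALSE)
  }

  norm <- make_normalization(X, y)
  Xn <- normalize_inputs(X, norm)
  yn <- normalize_output(y, norm)

  ctx <- tryCatch(
    make_contexts(yn, p = contexts, scheme = scheme),
    error = function(e) stop("context construction: ", conditionMessage(e), call. = FALSE)
  )
  W <- context_membership(ctx, yn)

  fit_granules <- function() {
    lapply(seq_len(n_contexts(ctx)), function(t) {
      if (all(W[, t] == 0)) {
        stop("granulation: empty context ", t, call. = FALSE)
      }
      tryCatch(
        cfcm(Xn, W[, t], clusters = clusters, m = m, tol = tol,
             max_iter = max_iter, seed = NULL),
        error = function(e) {
          stop("granulation (context ", t, "): ", conditionMessage(e), call. = FALSE)
        }
      )
    })
  }
  granules <- if (is.null(seed)) fit_granules() else withr::with_seed(seed, fit_granules())

  centers <- lapply(granules, `[[`, "centers")
  model <- new_tsklm(
    variant = variant, contexts = ctx, centers = centers, m = m,
    coefficients = matrix(0, n_contexts(ctx), ncol(Xn),
                          dimnames = list(NULL, x_names)),
    bias = 0, normalization = norm,
    response = deparse(formula[[2]]), predictors = x_names
  )

  Z <- activation_matrix(model, Xn)
  if (variant == "tsk") {
    model$coefficients <- fit_consequents(Z, Xn, yn, ctx)
    modal_n <- as.numeric(Z %*% ctx$break_points[, "r_mode"] +
                            phi_matrix(Z, Xn) %*% as.vector(t(model$coefficients)))
    model$bias <- compute_bias(yn, modal_n)
  }

  fitted <- predict(model, data)
  model$trn_rmse <- rmse(y, fitted$.pred)
  model$n_train <- length(y)
  model$granule_info <- tibble::tibble(
    context = seq_along(granules),
    iterations = vapply(granules, `[[`, integer(1), "iterations"),
    converged = vapply(granules, `[[`, logical(1), "converged")
  )
  model$call <- match.call()
  model
}

new_tsklm <- function(variant, contexts, centers, m, coefficients, bias,
                      normalization, response, predictors) {
  structure(
    list(
      variant = variant, contexts = contexts, centers = centers, m = m,
      coefficients = coefficients, bias = bias,
      normalization = normalization,
      response = response, predictors = predictors
    ),
    class = "tsklm"
  )
}

make_normalization <- function(X, y) {
  x_min <- apply(X, 2, min)
  x_max <- apply(X, 2, max)
  if (any(x_max == x_min)) {
    stop("degenerate input range: constant input column", call. = FALSE)
  }
  y_rng <- range(y)
  if (y_rng[1] == y_rng[2]) stop("degenerate output range", call. = FALSE)
  list(x_min = x_min, x_max = x_max, y_min = y_rng[1], y_max = y_rng[2])
}

normalize_inputs <- function(X, norm) {
  sweep(sweep(X, 2, norm$x_min, "-"), 2, norm$x_max - norm$x_min, "/")
}
normalize_output <- function(y, norm) (y - norm$y_min) / (norm$y_max - norm$y_min)
denormalize_output <- function(yn, norm) yn * (norm$y_max - norm$y_min) + norm$y_min

#' Rule activation levels for new inputs
#'
#' Computes, for each input point, the fuzzy-c-means style membership to
#' every one of the `p * c` cluster centers pooled across contexts (with the
#' fitted fuzzifier `m`), then sums the memberships belonging to each
#' context. The resulting activation vector `z` is non-negative and sums to
#' 1, so the model output is a convex combination of the rule consequents.
#' A point coincident with one or more centers assigns all membership to
#' the coincident center(s).
#'
#' @param model A fitted `tsklm`.
#' @param new_data Data frame containing the model's predictor columns.
#' @return A tibble with one activation column `z<t>` per context.
#' @export
activations <- function(model, new_data) {
  stopifnot(inherits(model, "tsklm"))
  Xn <- normalize_inputs(predictor_matrix(model, new_data), model$normalization)
  Z <- activation_matrix(model, Xn)
  colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  tibble::as_tibble(Z)
}

predictor_matrix <- function(model, new_data) {
  missing <- setdiff(model$predictors, names(new_data))
  if (length(missing)) {
    stop("new_data lacks predictor column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(as.data.frame(new_data)[, model$predictors, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

# Pooled-center activations on already-normalized inputs (n x p).
activation_matrix <- function(model, Xn) {
  V <- do.call(rbind, model$centers)
  group <- rep(seq_along(model$centers), vapply(model$centers, nrow, integer(1)))
  D2 <- pmax(outer(rowSums(Xn^2), rowSums(V^2), "+") - 2 * Xn %*% t(V), 0)
  U <- t(cfcm_membership(t(D2), rep(1, nrow(Xn)), model$m))
  Z <- t(rowsum(t(U), group))
  dimnames(Z) <- NULL
  Z
}

#' Least squares estimation of the TSK consequent coefficients
#'
#' Solves the global linear least squares problem for all rules jointly:
#' the residual target `y - Z r` (observed output minus the context part of
#' the modal prediction, `r` the context apexes) is regressed on the
#' regressor matrix whose columns are the products `z_t * x_j` for every
#' (context, input) pair. Because the modal output is linear in all the
#' consequent coefficients jointly, this single solve minimizes the
#' training squared error of the modal prediction exactly. On rank
#' deficiency (or when there are fewer rows than coefficients) a small
#' ridge (`lambda = 1e-8`) regularizes the normal equations.
#'
#' @param Z `N x p` activation matrix (rows sum to 1).
#' @param X `N x d` input matrix (normalized scale).
#' @param y Length-`N` target vector (normalized scale).
#' @param contexts The `context_set` providing the apexes `r_t`.
#' @return A `p x d` coefficient matrix, row `t` holding the linear term of
#'   rule `t`.
#' @export
fit_consequents <- function(Z, X, y, contexts) {
  Z <- as.matrix(Z)
  X <- as.matrix(X)
  stopifnot(inherits(contexts, "context_set"))
  N <- nrow(X)
  if (N < 1 || length(y) != N || nrow(Z) != N) {
    stop("need at least one row and matching dimensions", call. = FALSE)
  }
  p <- ncol(Z)
  d <- ncol(X)
  resid <- y - as.numeric(Z %*% contexts$break_points[, "r_mode"])
  Phi <- phi_matrix(Z, X)
  qr_phi <- qr(Phi)
  beta <- if (qr_phi$rank < ncol(Phi)) {
    lambda <- 1e-8
    solve(crossprod(Phi) + diag(lambda, ncol(Phi)), crossprod(Phi, resid))
  } else {
    qr.coef(qr_phi, resid)
  }
  matrix(beta, nrow = p, ncol = d, byrow = TRUE,
         dimnames = list(NULL, colnames(X)))
}

# Regressor matrix with columns z_t * x_j, ordered context-major so that
# as.vector(t(coefficients)) matches the column order.
phi_matrix <- function(Z, X) {
  cols <- lapply(seq_len(ncol(Z)), function(t) Z[, t] * X)
  do.call(cbind, cols)
}

#' Bias term of the TSK linguistic model
#'
#' The mean training residual of the modal prediction,
#' `b0 = mean(target - predicted)`. Adding it recentres the model so the
#' mean training residual is exactly zero.
#'
#' @param y Observed targets.
#' @param modal_preds Modal predictions before bias correction.
#' @return The scalar bias.
#' @export
compute_bias <- function(y, modal_preds) {
  if (length(y) < 1) stop("empty input", call. = FALSE)
  if (length(y) != length(modal_preds)) stop("length mismatch", call. = FALSE)
  mean(y - modal_preds)
}

#' Interval predictions from a TSK linguistic model
#'
#' The model output is a triangular fuzzy number. Its modal value is
#' `sum_t z_t (r_t + b_t' x) + b0`; the lower and upper bounds replace the
#' apex `r_t` by the context break points `r_t-` and `r_t+` while keeping
#' the same activations and linear terms, so
#' `.pred_lower <= .pred <= .pred_upper` always. Predictions are reported on
#' the original (denormalized) output scale.
#'
#' @param object A fitted `tsklm`.
#' @param new_data Data frame with the model's predictor columns.
#' @param ... Ignored.
#' @return A tibble with columns `.pred_lower`, `.pred`, `.pred_upper`.
#' @export
predict.tsklm <- function(object, new_data, ...) {
  if (is.null(object$centers) || !length(object$centers)) {
    stop("model is not trained", call. = FALSE)
  }
  Xn <- normalize_inputs(predictor_matrix(object, new_data), object$normalization)
  Z <- activation_matrix(object, Xn)
  lin <- as.numeric(phi_matrix(Z, Xn) %*% as.vector(t(object$coefficients))) +
    object$bias
  bp <- object$contexts$break_points
  tibble::tibble(
    .pred_lower = denormalize_output(as.numeric(Z %*% bp[, "r_minus"]) + lin,
                                     object$normalization),
    .pred       = denormalize_output(as.numeric(Z %*% bp[, "r_mode"]) + lin,
                                     object$normalization),
    .pred_upper = denormalize_output(as.numeric(Z %*% bp[, "r_plus"]) + lin,
                                     object$normalization)
  )
}

#' @export
print.tsklm <- function(x, ...) {
  cat(sprintf(
    "<tsklm: %s variant, %d %s contexts x %d clusters, m = %g>\n",
    x$variant, n_contexts(x$contexts), x$contexts$scheme,
    nrow(x$centers[[1]]), x$m
  ))
  cat(sprintf("  %s ~ %s\n", x$response, paste(x$predictors, collapse = " + ")))
  if (!is.null(x$trn_rmse)) {
    cat(sprintf("  training RMSE: %.4g (n = %d)\n", x$trn_rmse, x$n_train))
  }
  invisible(x)
}

#' @export
tidy.tsklm <- function(x, ...) {
  bp <- x$contexts$break_points
  p <- nrow(bp)
  ctx_part <- tibble::tibble(
    context = rep(seq_len(p), each = ncol(x$coefficients) + 3),
    term = rep(c(colnames(bp), colnames(x$coefficients)), p),
    estimate = as.vector(t(cbind(bp, x$coefficients)))
  )
  dplyr::bind_rows(
    ctx_part,
    tibble::tibble(context = NA_integer_, term = "bias", estimate = x$bias)
  )
}

#' @export
glance.tsklm <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    scheme = x$contexts$scheme,
    contexts = n_contexts(x$contexts),
    clusters = nrow(x$centers[[1]]),
    m = x$m,
    bias = x$bias,
    trn_rmse = x$trn_rmse %||% NA_real_,
    n_train = x$n_train %||% NA_integer_
  )
}

#' Plot observed values with interval predictions
#'
#' Mirrors the usual presentation for interval predictors: samples ordered
#' along the x-axis, observed output as points, modal prediction as a line
#' and the lower/upper bounds as a ribbon.
#'
#' @param object A fitted `tsklm`.
#' @param new_data Data frame with predictor and response columns.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.tsklm <- function(object, new_data, ...) {
  preds <- predict(object, new_data)
  obs <- as.data.frame(new_data)[[object$response]]
  df <- dplyr::mutate(preds, observed = obs, sample = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$.pred_lower,
                                      ymax = .data$.pred_upper),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.pred)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::labs(x = "sample", y = object$response,
                  title = sprintf("%s interval prediction", object$variant))
}
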