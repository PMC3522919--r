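#' Root mean square error
#' @param y Observed values.
#' @param yhat Predicted values of the same length.
#' @return The scalar RMSE.
#' @examples
#' rmse(c(0, 2), c(0, 0))
#' @export
rmse <- function(y, yhat) {
  if (length(y) == 0 || length(y) != length(yhat)) {
    stop("`y` and `yhat` must have equal, nonzero length", call. = FALSE)
  }
  sqrt(mean((y - yhat)^2))
}

#' Repeated train/check evaluation over a (contexts, clusters) grid
#'
#' Reproduces the evaluation protocol used for the energy-expenditure
#' predictor: for each of `iterations` repetitions a random train/check
#' split is drawn (training fraction 0.6 by default, split sizes
#' `round(train_fraction * N)`), every combination of model variant, number
#' of contexts `p` and number of clusters per context `c` is trained on the
#' training rows, and RMSE is measured on both splits on the original
#' output scale. Normalization statistics are always recomputed from the
#' training split only and applied to its check split, so no information
#' leaks across the split. Per-iteration seeds are derived from `seed` by a
#' fixed counter (`seed + iteration`), so all grid cells and variants see
#' identical splits and clustering initializations and cell comparisons are
#' paired.
#'
#' A cell whose training fails (e.g. more clusters than points in some
#' context) is recorded with `NA` RMSEs and the error message; the run
#' continues.
#'
#' @param data Data frame with the model variables (at least 10 rows).
#' @param formula Model formula, default `ee ~ hr + mi`. Single-factor
#'   designs (`ee ~ hr`, `ee ~ mi`) are supported.
#' @param p_grid,c_grid Integer grids for the number of contexts and
#'   clusters; defaults 2..6.
#' @param variants Model variants to compare (see [tsklm()]).
#' @param scheme Context placement scheme.
#' @param train_fraction Fraction of rows in the training split, in (0, 1).
#' @param iterations Number of repeated random splits, default 10.
#' @param m,tol,max_iter Passed to [tsklm()].
#' @param seed Master seed for reproducibility.
#' @return A `tsklm_experiment` tibble with one row per
#'   (variant, p, c) cell: mean `trn_rmse` and `chk_rmse` over iterations,
#'   the number of successful iterations `n_ok`, and per-iteration values
#'   in the list-columns `trn_rmse_iter` / `chk_rmse_iter`. Failures are
#'   collected in `attr(, "errors")`.
#' @examples
#' d <- simulate_activity(seed = 7)
#' ex <- run_experiment(d, p_grid = 2:3, c_grid = 2, iterations = 2, seed = 7)
#' glance(ex)
#' @export
run_experiment <- function(data, formula = ee ~ hr + mi,
                           p_grid = 2:6, c_grid = 2:6,
                           variants = c("tsk", "conventional"),
                           scheme = c("uniform", "flexible"),
                           train_fraction = 0.6, iterations = 10,
                           m = 2, tol = 1e-5, max_iter = 200, seed = 1) {
  scheme <- match.arg(scheme)
  variants <- match.arg(variants, several.ok = TRUE)
  stopifnot(train_fraction > 0, train_fraction < 1,
            length(p_grid) > 0, length(c_grid) > 0, iterations >= 1)
  data <- as.data.frame(data)
  N <- nrow(data)
  if (N < 10) stop("need at least 10 rows", call. = FALSE)
  response <- deparse(formula[[2]])
  n_train <- round(train_fraction * N)

  grid <- tidyr::expand_grid(variant = variants, p = p_grid, c = c_grid)
  cells <- vector("list", iterations)
  errors <- list()
  splits <- experiment_splits(N, train_fraction, iterations, seed)
  for (iter in seq_len(iterations)) {
    iter_seed <- seed + iter
    idx_train <- splits[[iter]]
    d_train <- data[idx_train, , drop = FALSE]
    d_check <- data[-idx_train, , drop = FALSE]
    res <- purrr::pmap(grid, function(variant, p, c) {
      fit <- tryCatch(
        tsklm(d_train, formula, contexts = p, clusters = c, scheme = scheme,
              variant = variant, m = m, tol = tol, max_iter = max_iter,
              seed = iter_seed),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        errors[[length(errors) + 1]] <<- tibble::tibble(
          variant = variant, p = p, c = c, iteration = iter,
          message = conditionMessage(fit)
        )
        return(c(trn = NA_real_, chk = NA_real_))
      }
      c(
        trn = rmse(d_train[[response]], predict(fit, d_train)$.pred),
        chk = rmse(d_check[[response]], predict(fit, d_check)$.pred)
      )
    })
    cells[[iter]] <- dplyr::mutate(
      grid,
      iteration = iter,
      trn_rmse = vapply(res, `[[`, numeric(1), "trn"),
      chk_rmse = vapply(res, `[[`, numeric(1), "chk")
    )
  }

  long <- dplyr::bind_rows(cells)
  out <- long |>
    dplyr::group_by(.data$variant, .data$p, .data$c) |>
    dplyr::summarise(
      n_ok = sum(!is.na(.data$chk_rmse)),
      trn_rmse_iter = list(.data$trn_rmse),
      chk_rmse_iter = list(.data$chk_rmse),
      trn_rmse = mean(.data$trn_rmse, na.rm = TRUE),
      chk_rmse = mean(.data$chk_rmse, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::relocate("trn_rmse", "chk_rmse", .after = "c") |>
    dplyr::arrange(match(.data$variant, variants), .data$p, .data$c)
  attr(out, "errors") <- dplyr::bind_rows(errors)
  attr(out, "config") <- list(
    formula = deparse(formula), p_grid = p_grid, c_grid = c_grid,
    variants = variants, scheme = scheme, train_fraction = train_fraction,
    iterations = iterations, m = m, seed = seed, n = N, n_train = n_train
  )
  class(out) <- c("tsklm_experiment", class(out))
  out
}

# Seeded train-split indices, one integer vector per iteration; iteration i
# uses seed + i so every grid cell and variant sees the same split.
experiment_splits <- function(N, train_fraction, iterations, seed) {
  n_train <- round(train_fraction * N)
  lapply(seq_len(iterations), function(iter) {
    withr::with_seed(seed + iter, sample.int(N, n_train))
  })
}

#' Best grid cell per variant
#'
#' Selects, for each variant, the (p, c) cell with the minimal mean
#' checking RMSE — the model-selection rule of the evaluation protocol.
#' Only the most complete cells compete (those with the largest number of
#' successful iterations for that variant): means taken over different
#' subsets of splits are not comparable, and a cell that trained on a
#' single lucky split should not win the grid.
#'
#' @param x A `tsklm_experiment`.
#' @return A tibble with one row per variant.
#' @export
glance.tsklm_experiment <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$variant) |>
    dplyr::filter(.data$n_ok == max(.data$n_ok)) |>
    dplyr::slice_min(.data$chk_rmse, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("variant", "p", "c", "trn_rmse", "chk_rmse", "n_ok")
}

#' @export
tidy.tsklm_experiment <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select("variant", "p", "c", "trn_rmse_iter", "chk_rmse_iter") |>
    tidyr::unnest(c("trn_rmse_iter", "chk_rmse_iter")) |>
    dplyr::group_by(.data$variant, .data$p, .data$c) |>
    dplyr::mutate(iteration = dplyr::row_number(), .after = "c") |>
    dplyr::ungroup() |>
    dplyr::rename(trn_rmse = "trn_rmse_iter", chk_rmse = "chk_rmse_iter")
}

#' Relative improvement of one variant over a baseline
#'
#' Percentage reduction in mean RMSE, `(baseline - model) / baseline * 100`,
#' computed at each variant's own best cell (minimal mean checking RMSE)
#' for the training and checking splits.
#'
#' @param x A `tsklm_experiment` containing both variants.
#' @param model,baseline Variant names, defaults `"tsk"` vs
#'   `"conventional"`.
#' @return A tibble with columns `split` and `improvement_pct`.
#' @export
improvement <- function(x, model = "tsk", baseline = "conventional") {
  best <- glance(x)
  stopifnot(all(c(model, baseline) %in% best$variant))
  b <- best[best$variant == baseline, ]
  m_ <- best[best$variant == model, ]
  tibble::tibble(
    split = c("training", "checking"),
    baseline_rmse = c(b$trn_rmse, b$chk_rmse),
    model_rmse = c(m_$trn_rmse, m_$chk_rmse),
    improvement_pct = 100 * (.data$baseline_rmse - .data$model_rmse) /
      .data$baseline_rmse
  )
}

#' Plot an experiment grid
#'
#' Heatmap of mean checking RMSE over the (contexts, clusters) grid,
#' faceted by variant.
#'
#' @param object A `tsklm_experiment`.
#' @param metric Column to display, `"chk_rmse"` or `"trn_rmse"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.tsklm_experiment <- function(object, metric = c("chk_rmse", "trn_rmse"),
                                      ...) {
  metric <- match.arg(metric)
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$c), y = factor(.data$p),
                                   fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data[[metric]])),
                       colour = "white", size = 3) +
    ggplot2::facet_wrap(~variant) +
    ggplot2::labs(x = "clusters per context (c)", y = "contexts (p)",
                  fill = metric)
}
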