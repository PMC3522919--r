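#' Serialize a fitted model to JSON
#'
#' Writes every component needed to reproduce predictions — variant,
#' context break points, per-context cluster centers, consequent
#' coefficients, bias and the min-max normalization statistics — at full
#' floating-point precision, so a round trip through
#' [tsklm_from_json()] reproduces predictions bit for bit.
#'
#' @param model A fitted `tsklm`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
tsklm_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "tsklm"))
  obj <- list(
    variant = model$variant,
    scheme = model$contexts$scheme,
    p = n_contexts(model$contexts),
    c = nrow(model$centers[[1]]),
    m = model$m,
    break_points = unclass(model$contexts$break_points),
    context_range = model$contexts$range,
    centers = model$centers,
    coefficients = unclass(model$coefficients),
    bias = model$bias,
    normalization = model$normalization,
    response = model$response,
    predictors = model$predictors
  )
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Restore a fitted model from JSON
#' @param json JSON string or path to a file written by [tsklm_to_json()].
#' @return A `tsklm` object equivalent to the serialized one.
#' @export
tsklm_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  bp <- matrix(as.numeric(obj$break_points), ncol = 3,
               dimnames = list(NULL, c("r_minus", "r_mode", "r_plus")))
  ctx <- structure(
    list(break_points = bp, scheme = obj$scheme,
         range = as.numeric(obj$context_range)),
    class = "context_set"
  )
  centers <- if (is.list(obj$centers)) {
    lapply(obj$centers, function(v) matrix(v, ncol = length(obj$predictors)))
  } else if (length(dim(obj$centers)) == 3) {
    lapply(seq_len(dim(obj$centers)[1]), function(i) {
      matrix(obj$centers[i, , ], ncol = dim(obj$centers)[3])
    })
  } else {
    list(matrix(obj$centers, ncol = length(obj$predictors)))
  }
  coef <- matrix(as.numeric(obj$coefficients), nrow = obj$p,
                 dimnames = list(NULL, obj$predictors))
  centers <- lapply(centers, function(v) {
    storage.mode(v) <- "double"
    v
  })
  norm <- obj$normalization
  norm$x_min <- stats::setNames(as.numeric(norm$x_min), obj$predictors)
  norm$x_max <- stats::setNames(as.numeric(norm$x_max), obj$predictors)
  new_tsklm(
    variant = obj$variant, contexts = ctx, centers = centers, m = obj$m,
    coefficients = coef, bias = as.numeric(obj$bias), normalization = norm,
    response = obj$response, predictors = obj$predictors
  )
}
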