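#' Linguistic contexts over an output variable
#'
#' A linguistic context is a triangular fuzzy set over the output space,
#' described by break points (r-, r, r+): membership rises linearly from
#' `r_minus` to 1 at the apex `r_mode` and falls back to 0 at `r_plus`.
#' An ordered family of `p` half-overlapping contexts forms a Ruspini
#' partition (memberships sum to one everywhere on the output range), which
#' is what lets context memberships act as soft sample weights for
#' context-based fuzzy c-means clustering. The two boundary contexts are
#' open-shouldered: membership stays 1 beyond the outer apex, so the
#' partition of unity also holds at the range extremes. Their stored outer
#' break point is clamped to the range limit.
#'
#' Two placement schemes are available:
#' * `"uniform"`: apexes equally spaced from `min(y)` to `max(y)`; adjacent
#'   triangles cross at membership 0.5.
#' * `"flexible"`: apexes at the `p` equally spaced quantiles of the
#'   empirical distribution of `y` (levels `t/(p-1)`, `t = 0..p-1`), so each
#'   context covers roughly equal probability mass. This mitigates the data
#'   scarcity that uniform spacing suffers when the output distribution is
#'   skewed: a context spanning a sparse region yields too few effectively
#'   weighted points for clustering.
#'
#' @param y Numeric vector of observed output values (at least two distinct
#'   values).
#' @param p Number of contexts, an integer `>= 2`.
#' @param scheme Apex placement scheme, `"uniform"` or `"flexible"`.
#'
#' @return A `context_set`: a list with elements `break_points` (a `p x 3`
#'   matrix with columns `r_minus`, `r_mode`, `r_plus`), `scheme`, and
#'   `range` (the `(min, max)` of `y`).
#' @examples
#' cs <- make_contexts(runif(50), p = 3)
#' context_membership(cs, c(0.1, 0.5, 0.9))
#' @export
make_contexts <- function(y, p, scheme = c("uniform", "flexible")) {
  scheme <- match.arg(scheme)
  stopifnot(is.numeric(y), all(is.finite(y)))
  if (length(p) != 1L || !is.finite(p) || p < 2 || p != round(p)) {
    stop("`p` must be a single integer >= 2", call. = FALSE)
  }
  rng <- range(y)
  if (rng[1] == rng[2]) stop("degenerate output range: `y` is constant", call. = FALSE)
  apexes <- switch(scheme,
    uniform  = seq(rng[1], rng[2], length.out = p),
    flexible = unname(stats::quantile(y, probs = seq(0, 1, length.out = p)))
  )
  if (any(diff(apexes) <= 0)) {
    stop("insufficient output spread for ", p, " contexts: tied apexes", call. = FALSE)
  }
  new_context_set(apexes, rng, scheme)
}

#' @rdname make_contexts
#' @export
make_uniform_contexts <- function(y, p) make_contexts(y, p, scheme = "uniform")

#' @rdname make_contexts
#' @export
make_flexible_contexts <- function(y, p) make_contexts(y, p, scheme = "flexible")

new_context_set <- function(apexes, rng, scheme) {
  p <- length(apexes)
  bp <- cbind(
    r_minus = c(rng[1], apexes[-p]),
    r_mode  = apexes,
    r_plus  = c(apexes[-1], rng[2])
  )
  rownames(bp) <- NULL
  structure(
    list(break_points = bp, scheme = scheme, range = rng),
    class = "context_set"
  )
}

#' @export
print.context_set <- function(x, ...) {
  cat(sprintf(
    "<context_set: %d %s contexts on [%.4g, %.4g]>\n",
    n_contexts(x), x$scheme, x$range[1], x$range[2]
  ))
  print(tidy(x), ...)
  invisible(x)
}

#' Number of contexts in a context set
#' @param x A `context_set`.
#' @return Integer count of contexts.
#' @export
n_contexts <- function(x) nrow(x$break_points)

#' @export
tidy.context_set <- function(x, ...) {
  tibble::as_tibble(x$break_points) |>
    dplyr::mutate(context = dplyr::row_number(), .before = 1)
}

#' Evaluate context membership degrees
#'
#' Piecewise-linear triangular membership of the output values `y` in each
#' context. Boundary contexts are open-shouldered: the first context keeps
#' membership 1 below its apex and the last keeps membership 1 above its
#' apex, so the columns of the returned matrix sum to one for every `y`
#' inside the context range.
#'
#' @param contexts A `context_set` from [make_contexts()].
#' @param y Numeric vector of output values to evaluate.
#' @param which Optional single context index; if given, returns the
#'   membership vector of that context alone.
#' @return A `length(y) x p` matrix of membership degrees in `[0, 1]`, or a
#'   vector when `which` is supplied.
#' @export
context_membership <- function(contexts, y, which = NULL) {
  stopifnot(inherits(contexts, "context_set"), is.numeric(y))
  bp <- contexts$break_points
  p <- nrow(bp)
  W <- vapply(seq_len(p), function(t) {
    triangle_membership(
      y, bp[t, 1], bp[t, 2], bp[t, 3],
      left_shoulder = (t == 1L), right_shoulder = (t == p)
    )
  }, numeric(length(y)))
  W <- matrix(W, nrow = length(y), ncol = p)
  colnames(W) <- paste0("context_", seq_len(p))
  if (!is.null(which)) unname(W[, which]) else W
}

triangle_membership <- function(y, a, b, d, left_shoulder = FALSE,
                                right_shoulder = FALSE) {
  out <- numeric(length(y))
  if (left_shoulder) {
    out[y <= b] <- 1
  } else if (b > a) {
    up <- y > a & y <= b
    out[up] <- (y[up] - a) / (b - a)
  }
  if (right_shoulder) {
    out[y > b] <- 1
  } else if (d > b) {
    dn <- y > b & y < d
    out[dn] <- (d - y[dn]) / (d - b)
  }
  out
}

#' Serialize a context set to JSON
#'
#' @param contexts A `context_set`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
contexts_to_json <- function(contexts, path = NULL) {
  stopifnot(inherits(contexts, "context_set"))
  obj <- list(
    scheme = contexts$scheme,
    range = contexts$range,
    break_points = unname(apply(contexts$break_points, 1, identity, simplify = FALSE))
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Restore a context set from JSON
#' @param json A JSON string or path to a JSON file written by
#'   [contexts_to_json()].
#' @return A `context_set`.
#' @export
contexts_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  bp <- matrix(obj$break_points, ncol = 3,
               dimnames = list(NULL, c("r_minus", "r_mode", "r_plus")))
  structure(
    list(break_points = bp, scheme = obj$scheme, range = as.numeric(obj$range)),
    class = "context_set"
  )
}

#' Plot a context set
#'
#' Draws the triangular membership functions over the output range.
#'
#' @param object A `context_set`.
#' @param n Number of evaluation points along the range.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.context_set <- function(object, n = 400, ...) {
  ys <- seq(object$range[1], object$range[2], length.out = n)
  W <- context_membership(object, ys)
  df <- tibble::tibble(
    y = rep(ys, ncol(W)),
    membership = as.vector(W),
    context = factor(rep(seq_len(ncol(W)), each = length(ys)))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$membership,
                                   colour = .data$context)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "output", y = "membership",
                  title = sprintf("%s linguistic contexts", object$scheme))
}
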