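#' Context-based fuzzy c-means clustering
#'
#' Clusters the rows of `x` under a soft sample-weight vector `w`, the
#' context memberships of each point's output value. Where standard fuzzy
#' c-means constrains each membership column to sum to 1, CFCM constrains
#' it to sum to `w[k]`, so clusters form only among points that belong to
#' the conditioning context; points outside the context (`w[k] = 0`) do not
#' attract centers. With `w` identically 1 the algorithm reduces exactly to
#' standard fuzzy c-means.
#'
#' The update alternates, from a seeded random membership initialization
#' (uniform draws, columns rescaled to sum to `w[k]`):
#' \deqn{v_i = \sum_k u_{ik}^m x_k / \sum_k u_{ik}^m}
#' \deqn{u_{ik} = w_k \big/ \sum_j (\|x_k - v_i\| / \|x_k - v_j\|)^{2/(m-1)}}
#' until the largest membership change falls below `tol` or `max_iter`
#' sweeps. The objective \eqn{\sum_{i,k} u_{ik}^m \|x_k - v_i\|^2} is
#' non-increasing across sweeps (each half-step is the exact constrained
#' minimizer given the other block). A point coincident with one or more
#' centers receives its full weight `w[k]` split equally among the
#' coincident clusters.
#'
#' @param x Numeric matrix or data frame of points (rows) by features
#'   (columns); clustering uses Euclidean distance, so features are expected
#'   on comparable (e.g. min-max normalized) scales.
#' @param w Numeric weight vector in `[0, 1]`, one entry per row of `x`.
#' @param clusters Number of clusters `c >= 1`; must not exceed the number
#'   of points with positive weight.
#' @param m Fuzzification factor, `> 1`. Default 2.
#' @param tol Convergence threshold on the maximum absolute membership
#'   change. Default `1e-5`.
#' @param max_iter Maximum number of sweeps. Default 200.
#' @param seed Optional integer seed for the membership initialization; the
#'   global RNG state is restored afterwards. With `NULL` the current RNG
#'   stream is used (and advanced).
#' @param keep_trace If `TRUE`, store the membership matrix after every
#'   sweep in `u_trace` (for diagnostics; memory grows with `max_iter`).
#'
#' @return A `cfcm_fit` list: `centers` (`c x d`), `memberships` (`c x N`),
#'   `weights`, `m`, `objective_trace`, `iterations`, `converged`, and
#'   optionally `u_trace`.
#' @examples
#' x <- matrix(rnorm(40), 20, 2)
#' fit <- cfcm(x, w = rep(1, 20), clusters = 2, seed = 1)
#' tidy(fit)
#' @export
cfcm <- function(x, w, clusters, m = 2, tol = 1e-5, max_iter = 200,
                 seed = NULL, keep_trace = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  N <- nrow(x)
  stopifnot(is.numeric(w), length(w) == N, all(is.finite(x)), all(is.finite(w)))
  if (any(w < 0 | w > 1)) stop("context weights must lie in [0, 1]", call. = FALSE)
  if (all(w == 0)) stop("empty context: all weights are zero", call. = FALSE)
  if (m <= 1) stop("fuzzification factor `m` must be > 1", call. = FALSE)
  c_ <- as.integer(clusters)
  if (c_ < 1) stop("`clusters` must be >= 1", call. = FALSE)
  if (c_ > sum(w > 0)) {
    stop("`clusters` exceeds the number of points with positive weight", call. = FALSE)
  }

  run <- function() cfcm_engine(x, w, c_, m, tol, max_iter, keep_trace)
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(c(res, list(weights = w, m = m, clusters = c_)), class = "cfcm_fit")
}

cfcm_engine <- function(x, w, c_, m, tol, max_iter, keep_trace) {
  N <- nrow(x)
  U <- matrix(stats::runif(c_ * N), c_, N)
  U <- sweep(U, 2, colSums(U), "/") * rep(w, each = c_)
  obj <- numeric(0)
  trace <- if (keep_trace) vector("list", 0) else NULL
  converged <- FALSE
  it <- 0L
  xsq <- rowSums(x^2)
  while (it < max_iter) {
    it <- it + 1L
    Um <- U^m
    V <- (Um %*% x) / rowSums(Um)
    D2 <- pmax(outer(rowSums(V^2), xsq, "+") - 2 * (V %*% t(x)), 0)
    Unew <- cfcm_membership(D2, w, m)
    obj <- c(obj, sum(Unew^m * D2))
    delta <- max(abs(Unew - U))
    U <- Unew
    if (keep_trace) trace[[it]] <- U
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  out <- list(centers = V, memberships = U, objective_trace = obj,
              iterations = it, converged = converged)
  if (keep_trace) out$u_trace <- trace
  out
}

# Membership update: u_ik = w_k / sum_j (d_ik/d_jk)^(2/(m-1)), vectorized
# over columns; zero-distance columns get the weight split among the
# coincident clusters.
cfcm_membership <- function(D2, w, m, zero_tol = 1e-30) {
  c_ <- nrow(D2)
  Tm <- D2^(-1 / (m - 1))
  U <- sweep(Tm, 2, colSums(Tm), "/") * rep(w, each = c_)
  sing <- which(apply(D2, 2, min) < zero_tol)
  for (k in sing) {
    hit <- D2[, k] < zero_tol
    U[, k] <- 0
    U[hit, k] <- w[k] / sum(hit)
  }
  U
}

#' @export
print.cfcm_fit <- function(x, ...) {
  cat(sprintf(
    "<cfcm_fit: %d clusters, %d points, m = %g, %s in %d iterations>\n",
    x$clusters, ncol(x$memberships), x$m,
    if (x$converged) "converged" else "not converged", x$iterations
  ))
  print(x$centers, ...)
  invisible(x)
}

#' @export
tidy.cfcm_fit <- function(x, ...) {
  centers <- x$centers
  if (is.null(colnames(centers))) {
    colnames(centers) <- paste0("dim_", seq_len(ncol(centers)))
  }
  tibble::as_tibble(centers) |>
    dplyr::mutate(
      cluster = dplyr::row_number(),
      size = rowSums(x$memberships),
      .before = 1
    )
}

#' @export
glance.cfcm_fit <- function(x, ...) {
  tibble::tibble(
    clusters = x$clusters,
    n = ncol(x$memberships),
    m = x$m,
    objective = x$objective_trace[length(x$objective_trace)],
    iterations = x$iterations,
    converged = x$converged
  )
}
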