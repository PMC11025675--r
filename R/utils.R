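#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package internals never
#' disturb the caller's random stream. All randomness in hofcnet flows
#' through this helper.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Derive a reproducible child seed for a named pipeline stage
#'
#' A single run seed is fanned out to per-stage seeds so stages can be rerun
#' independently yet reproducibly. The result stays below 2^31 - 1.
#'
#' @param seed integer parent seed.
#' @param stage character stage name.
#' @return integer child seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

## shared argument checks ------------------------------------------------

assert_square_symmetric <- function(m, tol = 1e-12, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop(what, " must be symmetric (tolerance ", tol, ")", call. = FALSE)
  }
  invisible(m)
}

as_group_factor <- function(group) {
  g <- factor(as.character(group), levels = c("control", "patient"))
  if (anyNA(g)) {
    stop("group labels must be 'patient' or 'control'", call. = FALSE)
  }
  g
}

#' Trapezoidal integral of metric values over a sparsity grid
#'
#' @param values numeric vector of per-sparsity metric values.
#' @param grid strictly increasing numeric sparsity grid of the same length.
#' @return scalar area under the metric-versus-sparsity curve.
#' @examples
#' auc_over_sparsity(rep(2, 35), seq(0.06, 0.40, by = 0.01)) # 0.68
#' @export
auc_over_sparsity <- function(values, grid) {
  if (length(grid) < 2L) stop("sparsity grid needs at least 2 points", call. = FALSE)
  if (length(values) != length(grid)) {
    stop("values and grid lengths differ", call. = FALSE)
  }
  if (any(diff(grid) <= 0)) stop("sparsity grid must be strictly increasing", call. = FALSE)
  if (anyNA(values)) {
    stop("missing metric value at sparsity ",
         paste(grid[is.na(values)], collapse = ", "), call. = FALSE)
  }
  sum(diff(grid) * (head(values, -1) + tail(values, -1)) / 2)
}
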