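#' NBS configuration
#'
#' @param primary_p edgewise primary threshold (default 0.001).
#' @param n_perm number of permutations (default 1000).
#' @param alpha corrected significance level (default 0.01); like
#'   `primary_p`, just a threshold on the returned corrected p-values —
#'   0.05 is the other conventional choice.
#' @param tail `"both"` (default), `"patient_gt"` or `"control_gt"`.
#' @param seed integer seed.
#' @return object of class `nbs_config`.
#' @export
nbs_config <- function(primary_p = 0.001, n_perm = 1000, alpha = 0.01,
                       tail = c("both", "patient_gt", "control_gt"),
                       seed = 1) {
  if (primary_p <= 0 || primary_p >= 1) stop("primary_p must be in (0, 1)", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  structure(list(primary_p = primary_p, n_perm = n_perm, alpha = alpha,
                 tail = match.arg(tail), seed = as.integer(seed)),
            class = "nbs_config")
}

# stack upper triangles of per-subject matrices into an n x n_edges matrix
edge_value_matrix <- function(matrices) {
  vals <- lapply(matrices, function(m) {
    v <- if (inherits(m, "connectivity_matrix")) m$values else m
    v[upper.tri(v)]
  })
  do.call(rbind, vals)
}

# least-squares group-effect t statistics for many responses at once
group_lm_t <- function(y, group01, covariates = NULL) {
  n <- nrow(y)
  x <- cbind(1, group01)
  if (!is.null(covariates)) x <- cbind(x, as.matrix(covariates))
  k <- ncol(x)
  qr_x <- qr(x)
  if (qr_x$rank < k) {
    warning("design matrix rank deficient; dropping redundant covariates",
            call. = FALSE)
    x <- x[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
    k <- ncol(x)
    qr_x <- qr(x)
  }
  beta <- qr.coef(qr_x, y)
  resid <- y - x %*% beta
  df <- n - k
  sigma2 <- colSums(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(xtx_inv[2, 2] * sigma2)
  tt <- beta[2, ] / se
  zero_var <- sigma2 < .Machine$double.eps * 100
  if (any(zero_var)) {
    # a zero-residual fit leaves the sign of the effect but no error scale
    tt[zero_var] <- sign(beta[2, zero_var]) * Inf
  }
  list(t = tt, beta = beta[2, ], df = df, n_zero_var = sum(zero_var))
}

#' Covariate-adjusted edgewise group statistics
#'
#' For every region pair, fits edge value ~ intercept + group + covariates
#' by ordinary least squares and returns the t statistic of the group term
#' (patient minus control) and its two-sided p-value with n - k degrees of
#' freedom.
#'
#' @param matrices list of per-subject `connectivity_matrix` objects or
#'   symmetric matrices, in subject order.
#' @param groups vector of `"patient"` / `"control"` labels.
#' @param covariates optional numeric matrix or data.frame (n x K).
#' @return list with symmetric `t_matrix`, `p_matrix`, and `df`.
#' @export
edgewise_stats <- function(matrices, groups, covariates = NULL) {
  g <- as_group_factor(groups)
  if (min(table(g)) < 2) stop("need at least 2 subjects per group", call. = FALSE)
  y <- edge_value_matrix(matrices)
  stopifnot(nrow(y) == length(g))
  cov_m <- if (is.null(covariates)) NULL else data.matrix(covariates)
  fit <- group_lm_t(y, as.numeric(g == "patient"), cov_m)
  if (fit$n_zero_var > 0) {
    message(fit$n_zero_var,
            " edge(s) with zero residual variance; p set by effect sign")
  }
  p_edge <- 2 * stats::pt(-abs(fit$t), fit$df)
  p_edge[is.infinite(fit$t)] <- 0
  p_edge[is.nan(fit$t)] <- 1
  v1 <- if (inherits(matrices[[1]], "connectivity_matrix")) matrices[[1]]$values else matrices[[1]]
  p <- ncol(v1)
  t_matrix <- matrix(0, p, p); p_matrix <- matrix(1, p, p)
  t_matrix[upper.tri(t_matrix)] <- fit$t
  p_matrix[upper.tri(p_matrix)] <- p_edge
  t_matrix <- t_matrix + t(t_matrix)
  p_matrix[lower.tri(p_matrix)] <- t(p_matrix)[lower.tri(p_matrix)]
  dimnames(t_matrix) <- dimnames(p_matrix) <- dimnames(v1)
  list(t_matrix = t_matrix, p_matrix = p_matrix, df = fit$df)
}

#' Connected components of suprathreshold edges
#'
#' Edges with p below the primary threshold (and effect sign matching the
#' chosen tail) form a graph whose connected components are the candidate
#' subnetworks; component size is the EDGE count.
#'
#' @param p_matrix,t_matrix symmetric edgewise p and t matrices.
#' @param primary_p primary threshold.
#' @param tail `"both"`, `"patient_gt"` or `"control_gt"`.
#' @return list of components sorted by decreasing size, each a list with
#'   `edges` (m x 2 index matrix), `nodes`, `size` (edge count).
#' @export
extract_components <- function(p_matrix, t_matrix, primary_p = 0.001,
                               tail = "both") {
  supra <- p_matrix < primary_p
  if (tail == "patient_gt") supra <- supra & t_matrix > 0
  if (tail == "control_gt") supra <- supra & t_matrix < 0
  supra <- supra & upper.tri(supra)
  idx <- which(supra, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list())
  p <- ncol(p_matrix)
  adj <- matrix(0L, p, p)
  adj[idx] <- 1L
  adj <- adj + t(adj)
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(ig)
  keep <- which(comp$csize >= 2)
  out <- lapply(keep, function(ci) {
    nodes <- which(comp$membership == ci)
    sel <- idx[idx[, 1] %in% nodes & idx[, 2] %in% nodes, , drop = FALSE]
    list(edges = unname(sel), nodes = nodes, size = nrow(sel))
  })
  out[order(-vapply(out, `[[`, numeric(1), "size"))]
}

#' Network-based statistic with permutation FWE correction
#'
#' Scores each observed suprathreshold component against the permutation
#' distribution of the maximal component size obtained by permuting group
#' labels (covariates stay attached to their subjects). Corrected p-values
#' use +1 smoothing: `(1 + #\{null >= size\}) / (1 + n_perm)`.
#'
#' @param matrices per-subject connectivity matrices.
#' @param groups `"patient"` / `"control"` labels.
#' @param covariates optional n x K covariate table.
#' @param config an [nbs_config()].
#' @return object of class `nbs_result`: list with `t_matrix`, `p_matrix`,
#'   `components` (each with `corrected_p`), `null_max_sizes`, `config`.
#' @export
nbs_test <- function(matrices, groups, covariates = NULL,
                     config = nbs_config()) {
  stopifnot(inherits(config, "nbs_config"))
  g <- as_group_factor(groups)
  y <- edge_value_matrix(matrices)
  cov_m <- if (is.null(covariates)) NULL else data.matrix(covariates)
  obs <- edgewise_stats(matrices, groups, covariates)
  comps <- extract_components(obs$p_matrix, obs$t_matrix,
                              config$primary_p, config$tail)
  n <- length(g)
  v1 <- if (inherits(matrices[[1]], "connectivity_matrix")) matrices[[1]]$values else matrices[[1]]
  p <- ncol(v1)

  max_comp_size <- function(tt, df) {
    pe <- 2 * stats::pt(-abs(tt), df)
    pe[is.infinite(tt)] <- 0
    pm <- matrix(1, p, p); tm <- matrix(0, p, p)
    pm[upper.tri(pm)] <- pe; tm[upper.tri(tm)] <- tt
    pm[lower.tri(pm)] <- t(pm)[lower.tri(pm)]
    tm <- tm + t(tm)
    cc <- extract_components(pm, tm, config$primary_p, config$tail)
    if (length(cc) == 0) 0L else cc[[1]]$size
  }

  null_max <- with_rng_seed(config$seed, {
    vapply(seq_len(config$n_perm), function(b) {
      perm <- sample(as.numeric(g == "patient"))
      fit <- suppressWarnings(group_lm_t(y, perm, cov_m))
      max_comp_size(fit$t, fit$df)
    }, numeric(1))
  })
  comps <- lapply(comps, function(cmp) {
    cmp$corrected_p <- (1 + sum(null_max >= cmp$size)) / (1 + config$n_perm)
    cmp
  })
  structure(list(t_matrix = obs$t_matrix, p_matrix = obs$p_matrix,
                 components = comps, null_max_sizes = null_max,
                 config = config),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("nbs_result:", length(x$components), "suprathreshold component(s),",
      x$config$n_perm, "permutations\n")
  for (i in seq_along(x$components)) {
    cmp <- x$components[[i]]
    cat(sprintf("  component %d: %d edges, %d nodes, corrected p = %.4g\n",
                i, cmp$size, length(cmp$nodes), cmp$corrected_p))
  }
  invisible(x)
}
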