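#' Threshold a connectivity matrix at a target sparsity
#'
#' Retains the `floor(sparsity * P * (P - 1) / 2)` strongest off-diagonal
#' values as binary edges, keeping the original weights on retained edges.
#' By default only positive associations compete (`edge_sign =
#' "positive"`); `"absolute"` ranks by magnitude. Ties at the cutoff are
#' broken by value then lexicographic edge index, so the retained edge set
#' is deterministic. If fewer candidate edges exist than requested, all are
#' kept and the achieved sparsity is reported.
#'
#' @param m `connectivity_matrix` or symmetric numeric matrix.
#' @param sparsity fraction of possible edges to keep, in (0, 1].
#' @param edge_sign `"positive"` or `"absolute"`.
#' @return object of class `thresholded_graph`: list with binary
#'   `adjacency`, `weights` (original values on present edges, 0 elsewhere),
#'   `sparsity` (requested), `achieved_sparsity`, `graph` (igraph object).
#' @export
threshold_by_sparsity <- function(m, sparsity, edge_sign = c("positive", "absolute")) {
  edge_sign <- match.arg(edge_sign)
  v <- if (inherits(m, "connectivity_matrix")) m$values else m
  assert_square_symmetric(v, what = "connectivity matrix")
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]", call. = FALSE)
  p <- ncol(v)
  ut <- which(upper.tri(v))
  vals <- v[ut]
  score <- if (edge_sign == "absolute") abs(vals) else vals
  cand <- if (edge_sign == "absolute") score > 0 else vals > 0
  k <- floor(sparsity * p * (p - 1) / 2)
  n_cand <- sum(cand)
  if (n_cand < k) {
    message(sprintf(
      "only %d candidate edges for %d requested; achieved sparsity %.4f",
      n_cand, k, n_cand / (p * (p - 1) / 2)))
    k <- n_cand
  }
  ord <- order(-score, ut)          # value desc, then edge index
  keep <- ord[seq_len(k)]
  keep <- keep[cand[keep]]
  adj <- matrix(0L, p, p)
  adj[ut[keep]] <- 1L
  adj <- adj + t(adj)
  w <- matrix(0, p, p)
  w[ut[keep]] <- vals[keep]
  w <- w + t(w)
  dimnames(adj) <- dimnames(w) <- dimnames(v)
  structure(
    list(adjacency = adj, weights = w, sparsity = sparsity,
         achieved_sparsity = sum(adj) / 2 / (p * (p - 1) / 2),
         graph = igraph::graph_from_adjacency_matrix(adj, mode = "undirected")),
    class = "thresholded_graph"
  )
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf("thresholded_graph: %d nodes, %d edges (sparsity %.3f)\n",
              ncol(x$adjacency), sum(x$adjacency) / 2, x$achieved_sparsity))
  invisible(x)
}

as_tgraph <- function(g) {
  if (inherits(g, "thresholded_graph")) return(g$graph)
  if (igraph::is_igraph(g)) return(g)
  stop("expected a thresholded_graph or igraph object", call. = FALSE)
}

#' Global graph metrics on a binary graph
#'
#' Binary-graph definitions: `cp` is the mean binary local clustering
#' coefficient (nodes with degree < 2 contribute 0); `lp` is the mean
#' shortest-path length over connected ordered pairs (the disconnected-pair
#' fraction is returned as `frac_disconnected`); `eglob` is the mean of
#' 1/d over all ordered pairs with disconnected pairs contributing 0;
#' `eloc` is the mean over nodes of the global efficiency of each node's
#' neighborhood subgraph.
#'
#' @param g `thresholded_graph` or igraph object.
#' @return list with `cp`, `lp`, `eglob`, `eloc`, `frac_disconnected`.
#' @export
global_metrics <- function(g) {
  ig <- as_tgraph(g)
  n <- igraph::vcount(ig)
  if (igraph::ecount(ig) == 0) stop("graph has no edges", call. = FALSE)
  cl <- igraph::transitivity(ig, type = "local", isolates = "zero")
  cl[is.na(cl)] <- 0
  d <- igraph::distances(ig)
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  lp <- mean(off[finite])
  eglob <- mean(ifelse(finite, 1 / off, 0))
  eloc_i <- vapply(seq_len(n), function(i) {
    nb <- as.integer(igraph::neighbors(ig, i))
    if (length(nb) < 2) return(0)
    sub <- igraph::induced_subgraph(ig, nb)
    ds <- igraph::distances(sub)
    o <- ds[row(ds) != col(ds)]
    mean(ifelse(is.finite(o), 1 / o, 0))
  }, numeric(1))
  list(cp = mean(cl), lp = lp, eglob = eglob, eloc = mean(eloc_i),
       frac_disconnected = mean(!finite))
}

#' Nodal graph metrics on a binary graph
#'
#' `bc` is unnormalized betweenness centrality (each unordered pair counted
#' once, fractional credit for tied shortest paths), `dc` the binary
#' degree, and `ne` nodal efficiency: the mean over other nodes of the
#' inverse shortest-path distance, with unreachable nodes contributing 0.
#'
#' @param g `thresholded_graph` or igraph object.
#' @return list with numeric vectors `bc`, `dc`, `ne` of length P.
#' @export
nodal_metrics <- function(g) {
  ig <- as_tgraph(g)
  d <- igraph::distances(ig)
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  list(
    bc = igraph::betweenness(ig, directed = FALSE),
    dc = igraph::degree(ig),
    ne = rowSums(inv) / (igraph::vcount(ig) - 1)
  )
}

#' Degree-preserving rewired null ensemble
#'
#' Each null applies `10 * E` attempted double-edge swaps to the observed
#' graph, preserving every node's degree exactly while randomizing
#' topology. Seeded and deterministic.
#'
#' @param g `thresholded_graph` or igraph object with at least 2 edges.
#' @param n_nulls number of null graphs (>= 1).
#' @param seed integer seed.
#' @return list of igraph objects.
#' @export
rewired_nulls <- function(g, n_nulls = 100, seed = 1) {
  ig <- as_tgraph(g)
  if (n_nulls < 1) stop("n_nulls must be >= 1", call. = FALSE)
  if (igraph::ecount(ig) < 2) stop("need at least 2 edges to rewire", call. = FALSE)
  niter <- 10 * igraph::ecount(ig)
  with_rng_seed(seed, {
    lapply(seq_len(n_nulls), function(i) {
      igraph::rewire(ig, igraph::keeping_degseq(loops = FALSE, niter = niter))
    })
  })
}

#' Small-world indices normalized by a null ensemble
#'
#' gamma = Cp / mean null Cp, lambda = Lp / mean null Lp, and the
#' small-world index sigma = gamma / lambda. sigma > 1 with gamma > 1 and
#' lambda near 1 is the usual small-world signature.
#'
#' @param g `thresholded_graph` or igraph object.
#' @param nulls list of null graphs from [rewired_nulls()].
#' @return list with `gamma`, `lambda_`, `sigma`, `cp`, `lp`, `cp_rand`,
#'   `lp_rand`, `n_nulls`.
#' @export
small_world <- function(g, nulls) {
  if (length(nulls) == 0) stop("null ensemble is empty", call. = FALSE)
  obs <- global_metrics(g)
  null_cp <- vapply(nulls, function(x) global_metrics(x)$cp, numeric(1))
  null_lp <- vapply(nulls, function(x) global_metrics(x)$lp, numeric(1))
  cp_rand <- mean(null_cp)
  lp_rand <- mean(null_lp)
  if (cp_rand == 0) {
    warning("null ensemble has zero mean clustering; gamma undefined", call. = FALSE)
    gamma <- NA_real_
  } else {
    gamma <- obs$cp / cp_rand
  }
  lambda_ <- obs$lp / lp_rand
  list(gamma = gamma, lambda_ = lambda_, sigma = gamma / lambda_,
       cp = obs$cp, lp = obs$lp, cp_rand = cp_rand, lp_rand = lp_rand,
       n_nulls = length(nulls))
}

#' Per-subject graph metrics across a sparsity grid
#'
#' Thresholds each subject's connectivity matrix at every sparsity of the
#' grid, computes global, small-world and nodal metrics, and summarizes
#' each metric by its trapezoidal area under the curve over the grid.
#'
#' @param matrices named list of `connectivity_matrix` objects (one per
#'   subject).
#' @param grid sparsity grid, default `seq(0.06, 0.40, by = 0.01)`.
#' @param n_nulls rewired nulls per graph for the small-world indices; 0
#'   skips gamma/lambda/sigma.
#' @param seed integer seed for the null ensembles.
#' @return object of class `metric_table`: list with `global` (long
#'   data.frame subject x sparsity x metric), `nodal` (subject x sparsity x
#'   node x metric), `auc` (wide data.frame of per-subject AUC values),
#'   `nodal_auc` (subject x node x metric AUC), `grid`.
#' @export
compute_metric_table <- function(matrices, grid = seq(0.06, 0.40, by = 0.01),
                                 n_nulls = 100, seed = 1) {
  stopifnot(length(matrices) >= 1, length(grid) >= 2)
  subjects <- names(matrices) %||% paste0("S", seq_along(matrices))
  glob_rows <- list(); nodal_rows <- list()
  for (si in seq_along(matrices)) {
    m <- matrices[[si]]
    p <- ncol(if (inherits(m, "connectivity_matrix")) m$values else m)
    for (s in grid) {
      tg <- threshold_by_sparsity(m, s)
      gm <- global_metrics(tg)
      sw <- if (n_nulls > 0) {
        small_world(tg, rewired_nulls(tg, n_nulls,
                                      seed = derive_seed(seed, paste(subjects[si], s))))
      } else {
        list(gamma = NA_real_, lambda_ = NA_real_, sigma = NA_real_)
      }
      nm <- nodal_metrics(tg)
      glob_rows[[length(glob_rows) + 1L]] <- data.frame(
        subject = subjects[si], sparsity = s,
        cp = gm$cp, lp = gm$lp, eglob = gm$eglob, eloc = gm$eloc,
        gamma = sw$gamma, lambda = sw$lambda_, sigma = sw$sigma,
        stringsAsFactors = FALSE
      )
      nodal_rows[[length(nodal_rows) + 1L]] <- data.frame(
        subject = subjects[si], sparsity = s, node = seq_len(p),
        bc = nm$bc, dc = nm$dc, ne = nm$ne, stringsAsFactors = FALSE
      )
    }
  }
  glob <- do.call(rbind, glob_rows)
  nodal <- do.call(rbind, nodal_rows)

  metric_cols <- c("cp", "lp", "eglob", "eloc", "gamma", "lambda", "sigma")
  auc <- do.call(rbind, lapply(split(glob, glob$subject), function(df) {
    df <- df[order(df$sparsity), ]
    vals <- vapply(metric_cols, function(mc) {
      if (anyNA(df[[mc]])) NA_real_ else auc_over_sparsity(df[[mc]], df$sparsity)
    }, numeric(1))
    cbind(data.frame(subject = df$subject[1], stringsAsFactors = FALSE),
          as.data.frame(as.list(vals)))
  }))
  rownames(auc) <- NULL

  nodal_auc <- do.call(rbind, lapply(split(nodal, list(nodal$subject, nodal$node)),
    function(df) {
      df <- df[order(df$sparsity), ]
      data.frame(subject = df$subject[1], node = df$node[1],
                 bc = auc_over_sparsity(df$bc, df$sparsity),
                 dc = auc_over_sparsity(df$dc, df$sparsity),
                 ne = auc_over_sparsity(df$ne, df$sparsity),
                 stringsAsFactors = FALSE)
    }))
  rownames(nodal_auc) <- NULL

  structure(list(global = glob, nodal = nodal, auc = auc,
                 nodal_auc = nodal_auc, grid = grid),
            class = "metric_table")
}
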