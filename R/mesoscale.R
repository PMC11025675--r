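#' Mean intra- and inter-modular connection strengths
#'
#' Averages the (unthresholded, weighted) connectivity values over all
#' region pairs within each module and between each unordered module pair,
#' excluding the diagonal. Modules with a single region have no
#' within-module pair and get `NA` with a warning.
#'
#' @param m `connectivity_matrix` or symmetric matrix.
#' @param partition named character vector region -> module; names may be
#'   omitted when the matrix is unlabeled, in which case order is used.
#' @return list with `intra` (named numeric per module) and `inter`
#'   (data.frame module_a, module_b, strength).
#' @export
modular_strengths <- function(m, partition) {
  v <- if (inherits(m, "connectivity_matrix")) m$values else m
  assert_square_symmetric(v, what = "connectivity matrix")
  if (length(partition) != ncol(v)) {
    stop("partition must cover all ", ncol(v), " regions", call. = FALSE)
  }
  mods <- unname(partition)
  levs <- unique(mods)
  ut <- upper.tri(v)
  intra <- stats::setNames(rep(NA_real_, length(levs)), levs)
  for (k in levs) {
    sel <- outer(mods == k, mods == k) & ut
    if (sum(sel) == 0) {
      warning("module ", k, " has a single region; intra strength undefined",
              call. = FALSE)
    } else {
      intra[k] <- mean(v[sel])
    }
  }
  pairs <- utils::combn(levs, 2)
  inter <- data.frame(
    module_a = pairs[1, ], module_b = pairs[2, ],
    strength = apply(pairs, 2, function(pr) {
      sel <- (outer(mods == pr[1], mods == pr[2]) |
                outer(mods == pr[2], mods == pr[1])) & ut
      mean(v[sel])
    }),
    stringsAsFactors = FALSE
  )
  list(intra = intra, inter = inter)
}

#' Extract one named inter-module strength
#' @param strengths result of [modular_strengths()].
#' @param a,b module labels.
#' @return scalar mean strength of the a-b block.
#' @export
inter_strength <- function(strengths, a, b) {
  df <- strengths$inter
  hit <- (df$module_a == a & df$module_b == b) |
    (df$module_a == b & df$module_b == a)
  if (!any(hit)) stop("no inter-module block ", a, "-", b, call. = FALSE)
  df$strength[hit]
}

#' Rich-club nodes of a group-averaged network
#'
#' Averages the subjects' connectivity matrices entrywise, thresholds the
#' mean network at every sparsity of the grid, averages each node's binary
#' degree across the grid, and returns the `n_rich` top-ranked regions.
#' Ties at the boundary are broken by mean degree then region index,
#' deterministically, and reported. With `method = "strength"` the ranking
#' uses weighted nodal strength on the unthresholded mean matrix instead.
#'
#' @param group_matrices list of `connectivity_matrix` objects (>= 1).
#' @param grid sparsity grid, default `seq(0.06, 0.40, by = 0.01)`.
#' @param n_rich number of rich-club nodes, default 10.
#' @param method `"degree"` (default) or `"strength"`.
#' @return integer vector of `n_rich` region indices, named if regions are
#'   labeled; mean degrees in attribute `"mean_degree"`.
#' @export
rich_club_nodes <- function(group_matrices, grid = seq(0.06, 0.40, by = 0.01),
                            n_rich = 10, method = c("degree", "strength")) {
  method <- match.arg(method)
  stopifnot(length(group_matrices) >= 1)
  vals <- lapply(group_matrices, function(m) {
    if (inherits(m, "connectivity_matrix")) m$values else m
  })
  p <- ncol(vals[[1]])
  if (p < n_rich) stop("need at least ", n_rich, " regions", call. = FALSE)
  mean_mat <- Reduce(`+`, vals) / length(vals)
  if (method == "strength") {
    score <- rowSums(pmax(mean_mat, 0)) - pmax(diag(mean_mat), 0)
  } else {
    degs <- vapply(grid, function(s) {
      igraph::degree(threshold_by_sparsity(mean_mat, s)$graph)
    }, numeric(p))
    score <- rowMeans(degs)
  }
  ord <- order(-score, seq_len(p))
  cut_score <- score[ord[n_rich]]
  n_tied <- sum(score == cut_score)
  if (n_tied > 1 && any(score[ord[seq_len(n_rich)]] == cut_score) &&
      sum(score >= cut_score) > n_rich) {
    message(n_tied, " nodes tied at the rich-club boundary; ",
            "ties broken by region index")
  }
  rich <- sort(ord[seq_len(n_rich)])
  labs <- rownames(mean_mat)
  if (!is.null(labs)) names(rich) <- labs[rich]
  attr(rich, "mean_degree") <- score
  rich
}

#' Classify edges as rich-club, feeder or local connections
#'
#' Every edge of the thresholded graph is labeled by the rich-club
#' membership of its endpoints: both rich (`rich`), one rich (`feeder`),
#' neither (`local`). Returns the per-class mean of the original edge
#' weights; an empty class yields `NA` with a warning.
#'
#' @param g `thresholded_graph`.
#' @param rich_nodes integer vector of rich-club node indices.
#' @return list with `edges` (data.frame i, j, weight, class) and
#'   `mean_strength` (named numeric: rich, feeder, local).
#' @export
classify_connections <- function(g, rich_nodes) {
  stopifnot(inherits(g, "thresholded_graph"))
  p <- ncol(g$adjacency)
  if (any(rich_nodes < 1 | rich_nodes > p)) {
    stop("rich_nodes outside node range", call. = FALSE)
  }
  ut <- which(upper.tri(g$adjacency) & g$adjacency == 1, arr.ind = TRUE)
  is_rich <- seq_len(p) %in% rich_nodes
  n_rich_ends <- is_rich[ut[, 1]] + is_rich[ut[, 2]]
  cls <- c("local", "feeder", "rich")[n_rich_ends + 1L]
  edges <- data.frame(i = ut[, 1], j = ut[, 2],
                      weight = g$weights[ut], class = cls,
                      stringsAsFactors = FALSE)
  mean_strength <- vapply(c("rich", "feeder", "local"), function(k) {
    w <- edges$weight[edges$class == k]
    if (length(w) == 0) NA_real_ else mean(w)
  }, numeric(1))
  if (anyNA(mean_strength)) {
    warning("empty connection class: ",
            paste(names(mean_strength)[is.na(mean_strength)], collapse = ", "),
            call. = FALSE)
  }
  list(edges = edges, mean_strength = mean_strength)
}
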