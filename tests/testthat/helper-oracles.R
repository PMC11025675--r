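# Brute-force oracles, written independently of the package internals
# (explicit sums and loops; Floyd-Warshall; exhaustive path enumeration).

# product-moment correlation from explicit sums
bf_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

# loop-wise HOFC: second-round correlation of z-profiles with entries i, j
# removed from both rows
bf_hofc <- function(zm) {
  p <- ncol(zm)
  h <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      a <- zm[i, -c(i, j)]
      b <- zm[j, -c(i, j)]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      h[i, j] <- h[j, i] <- bf_pearson(a, b)
    }
  }
  h
}

# all-pairs shortest paths by Floyd-Warshall
bf_distances <- function(adj) {
  n <- ncol(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# count shortest paths between s and t passing through each vertex, by
# exhaustive enumeration of all paths of minimal length (n <= 8)
bf_betweenness <- function(adj) {
  n <- ncol(adj)
  d <- bf_distances(adj)
  bc <- numeric(n)
  enum_paths <- function(cur, target, len) {
    last <- cur[length(cur)]
    if (last == target) return(list(cur))
    if (len == 0) return(list())
    out <- list()
    for (nb in which(adj[last, ] > 0)) {
      if (!(nb %in% cur) && d[nb, target] == len - 1) {
        out <- c(out, enum_paths(c(cur, nb), target, len - 1))
      }
    }
    out
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t]) || d[s, t] == 0) next
      paths <- enum_paths(s, t, d[s, t])
      if (length(paths) == 0) next
      for (pth in paths) {
        inner <- setdiff(pth, c(s, t))
        bc[inner] <- bc[inner] + 1 / length(paths)
      }
    }
  }
  bc
}

bf_nodal_efficiency <- function(adj) {
  d <- bf_distances(adj)
  n <- ncol(adj)
  sapply(seq_len(n), function(i) {
    v <- d[i, -i]
    mean(ifelse(is.finite(v) & v > 0, 1 / v, 0))
  })
}

# ROC-AUC by brute-force pairwise comparison
bf_auc <- function(decision, is_positive) {
  pos <- decision[is_positive]
  neg <- decision[!is_positive]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# fixtures ---------------------------------------------------------------

toy_partition <- function(p, modules = c("SMN", "DMN", "FPN", "VN", "SN")) {
  k <- length(modules)
  stopifnot(p %% k == 0)
  setNames(rep(modules, each = p / k), paste0("R", seq_len(p)))
}

mini_config <- function(n_patient = 4, n_control = 4, p = 10, t_len = 80,
                        seed = 42, ...) {
  generator_config(n_patient = n_patient, n_control = n_control, p = p,
                   t_len = t_len,
                   partition = toy_partition(p, c("SMN", "DMN")),
                   seed = seed, ...)
}

# deterministic symmetric matrix with zero diagonal
random_sym <- function(p, seed = 1, positive = FALSE) {
  set.seed(seed)
  m <- matrix(rnorm(p * p), p)
  if (positive) m <- abs(m)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# adjacency matrix of a ring lattice where each node links to its k nearest
# neighbours
ring_lattice <- function(n, k) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (s in seq_len(k / 2)) {
      j1 <- ((i - 1 + s) %% n) + 1
      j2 <- ((i - 1 - s) %% n) + 1
      adj[i, j1] <- adj[j1, i] <- 1L
      adj[i, j2] <- adj[j2, i] <- 1L
    }
  }
  adj
}

graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

with_seed_graph <- function(fun, seed, ...) {
  set.seed(seed)
  fun(...)
}
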