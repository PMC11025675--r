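test_that("sparsity thresholding keeps the exact edge budget", {
  m <- random_sym(90, seed = 6, positive = TRUE)
  tg <- threshold_by_sparsity(m, 0.10)
  expect_equal(sum(tg$adjacency) / 2, 400)   # floor(0.10 * 4005)
  expect_equal(tg$adjacency, t(tg$adjacency))
  expect_equal(unname(diag(tg$adjacency)), rep(0L, 90))
  # retained weights are the largest off-diagonal values
  kept <- tg$weights[upper.tri(tg$weights) & tg$adjacency == 1]
  dropped <- m[upper.tri(m) & tg$adjacency == 0]
  expect_gte(min(kept), max(dropped))

  full <- threshold_by_sparsity(m, 1.0)
  expect_equal(sum(full$adjacency) / 2, 4005)
})

test_that("ties at the cutoff resolve deterministically", {
  m <- matrix(0, 6, 6)
  m[upper.tri(m)] <- c(5, 4, 3, 2, 2, 2, 2, 2, 1, 1, 1, 1, 1, 1, 1)
  m <- m + t(m)
  a <- threshold_by_sparsity(m, 0.4)
  b <- threshold_by_sparsity(m, 0.4)
  expect_identical(a$adjacency, b$adjacency)
  expect_equal(sum(a$adjacency) / 2, floor(0.4 * 15))
})

test_that("too few positive entries yields all of them with a log message", {
  m <- matrix(-1, 5, 5)
  m[1, 2] <- m[2, 1] <- 0.5
  m[3, 4] <- m[4, 3] <- 0.2
  diag(m) <- 0
  expect_message(tg <- threshold_by_sparsity(m, 0.9), "achieved sparsity")
  expect_equal(sum(tg$adjacency) / 2, 2)
})

test_that("global metrics match closed forms on canonical graphs", {
  k10 <- matrix(1, 10, 10); diag(k10) <- 0
  gm <- global_metrics(threshold_by_sparsity(k10, 1))
  expect_equal(gm$cp, 1)
  expect_equal(gm$lp, 1)
  expect_equal(gm$eglob, 1)
  expect_equal(gm$eloc, 1)

  # ring lattice N = 20, k = 4: Cp = 3(k-2) / (4(k-1)) = 0.5
  rl <- ring_lattice(20, 4)
  expect_equal(global_metrics(graph_from_adj(rl))$cp, 0.5)

  # path a-b-c: distances {1, 1, 2}
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  gm3 <- global_metrics(graph_from_adj(path3))
  expect_equal(gm3$lp, 4 / 3)
  expect_equal(gm3$eglob, 5 / 6)

  expect_error(global_metrics(graph_from_adj(matrix(0, 3, 3))), "no edges")
})

test_that("nodal metrics match closed forms and the enumeration oracle", {
  # star S5
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  nm <- nodal_metrics(graph_from_adj(star))
  expect_equal(nm$dc[1], 4)
  expect_equal(nm$bc[1], 6)          # C(4, 2) leaf pairs
  expect_equal(unname(nm$bc[2:5]), rep(0, 4))
  expect_equal(nm$ne[1], 1)

  # path a-b-c: Bc(b) = 1
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(nodal_metrics(graph_from_adj(path3))$bc[2], 1)

  # random 8-node graphs against exhaustive path enumeration
  for (s in 1:4) {
    set.seed(s)
    adj <- matrix(0L, 8, 8)
    adj[upper.tri(adj)] <- rbinom(28, 1, 0.4)
    adj <- adj + t(adj)
    if (sum(adj) == 0) next
    nm <- nodal_metrics(graph_from_adj(adj))
    expect_equal(unname(nm$bc), bf_betweenness(adj), tolerance = 1e-12)
    expect_equal(unname(nm$ne), bf_nodal_efficiency(adj), tolerance = 1e-12)
    expect_equal(unname(nm$dc), rowSums(adj))
    expect_equal(sum(nm$dc), sum(adj))   # sum Dc = 2 |E|
  }
})

test_that("global metrics agree with Floyd-Warshall oracles on small graphs", {
  for (s in 5:7) {
    set.seed(s)
    adj <- matrix(0L, 8, 8)
    adj[upper.tri(adj)] <- rbinom(28, 1, 0.5)
    adj <- adj + t(adj)
    if (sum(adj) == 0) next
    gm <- global_metrics(graph_from_adj(adj))
    d <- bf_distances(adj)
    off <- d[row(d) != col(d)]
    expect_equal(gm$lp, mean(off[is.finite(off)]), tolerance = 1e-12)
    expect_equal(gm$eglob, mean(ifelse(is.finite(off), 1 / off, 0)),
                 tolerance = 1e-12)
  }
})

test_that("rewired nulls preserve degrees, are seeded, and lose triangles", {
  rl <- ring_lattice(20, 4)
  tg <- graph_from_adj(rl)
  nulls <- rewired_nulls(tg, 10, seed = 3)
  for (nl in nulls) {
    expect_equal(sort(igraph::degree(nl)), sort(igraph::degree(tg)))
  }
  nulls2 <- rewired_nulls(tg, 10, seed = 3)
  expect_equal(lapply(nulls, igraph::as_edgelist),
               lapply(nulls2, igraph::as_edgelist))
  cp_nulls <- mean(sapply(nulls, function(g) global_metrics(g)$cp))
  expect_lt(cp_nulls, global_metrics(tg)$cp)
  expect_error(rewired_nulls(tg, 0), "n_nulls")
})

test_that("small-world indices are self-normalizing and consistent", {
  rl <- graph_from_adj(ring_lattice(20, 4))
  sw <- small_world(rl, list(rl))
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda_, 1)
  expect_equal(sw$sigma, 1)

  nulls <- rewired_nulls(rl, 20, seed = 2)
  sw2 <- small_world(rl, nulls)
  expect_equal(sw2$sigma * sw2$lambda_, sw2$gamma, tolerance = 1e-12)
})

test_that("AUC over sparsity is the trapezoidal integral", {
  grid <- seq(0.06, 0.40, by = 0.01)
  expect_equal(auc_over_sparsity(rep(3, length(grid)), grid), 0.34 * 3)
  expect_equal(auc_over_sparsity(grid, grid), (0.40^2 - 0.06^2) / 2)
  expect_error(auc_over_sparsity(1, 0.1), "2 points")
  vals <- grid; vals[5] <- NA
  expect_error(auc_over_sparsity(vals, grid), as.character(grid[5]))
})

test_that("global efficiency is monotone in sparsity for nested graphs", {
  m <- random_sym(30, seed = 17, positive = TRUE)
  grid <- seq(0.05, 0.5, by = 0.05)
  eg <- sapply(grid, function(s) global_metrics(threshold_by_sparsity(m, s))$eglob)
  expect_true(all(diff(eg) >= -1e-12))
})

test_that("metric tables cover every subject and sparsity with AUC summaries", {
  co <- generate_cohort(mini_config(n_patient = 2, n_control = 2, p = 10,
                                    t_len = 60, seed = 15))
  nets <- lapply(co$timeseries, lofc_matrix, region_labels = co$region_labels)
  grid <- seq(0.2, 0.4, by = 0.1)
  mt <- compute_metric_table(nets, grid = grid, n_nulls = 3, seed = 1)
  expect_equal(nrow(mt$global), 4 * length(grid))
  expect_equal(nrow(mt$nodal), 4 * length(grid) * 10)
  expect_equal(sort(mt$auc$subject), sort(co$subjects$subject_id))
  df <- mt$global[mt$global$subject == "sub-001", ]
  df <- df[order(df$sparsity), ]
  expect_equal(mt$auc$cp[mt$auc$subject == "sub-001"],
               auc_over_sparsity(df$cp, df$sparsity))
})
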