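# helper: per-subject symmetric matrices with optional planted block shift
sim_matrices <- function(n_per_group, p, delta = 0, planted = NULL, seed = 1,
                         sd = 0.1) {
  set.seed(seed)
  groups <- rep(c("patient", "control"), each = n_per_group)
  mats <- lapply(seq_along(groups), function(i) {
    m <- matrix(rnorm(p * p, sd = sd), p)
    m <- (m + t(m)) / 2
    if (groups[i] == "patient" && !is.null(planted)) {
      m[planted] <- m[planted] + delta
      m[planted[, c(2, 1)]] <- m[planted[, c(2, 1)]] + delta
    }
    diag(m) <- 0
    m
  })
  list(matrices = mats, groups = groups)
}

test_that("edgewise statistics vanish when the groups are identical", {
  set.seed(7)
  base <- lapply(1:4, function(i) random_sym(8, seed = i))
  res <- edgewise_stats(c(base, base),
                        rep(c("patient", "control"), each = 4))
  expect_lt(max(abs(res$t_matrix)), 1e-8)
})

test_that("planted edges carry the largest statistics", {
  p <- 15
  planted <- cbind(1:5, 6:10)
  sim <- sim_matrices(30, p, delta = 0.2, planted = planted, seed = 3)
  res <- edgewise_stats(sim$matrices, sim$groups)
  tt <- res$t_matrix[upper.tri(res$t_matrix)]
  top_k <- order(-abs(tt))[1:5]
  im <- matrix(0L, p, p)
  im[upper.tri(im)] <- seq_len(p * (p - 1) / 2)
  planted_idx <- im[cbind(pmin(planted[, 1], planted[, 2]),
                          pmax(planted[, 1], planted[, 2]))]
  overlap <- length(intersect(top_k, planted_idx)) / 5
  expect_gte(overlap, 0.8)
})

test_that("covariate adjustment attenuates confounded group effects", {
  set.seed(9)
  n <- 40
  groups <- rep(c("patient", "control"), each = n / 2)
  conf <- rnorm(n) + 2 * (groups == "patient")   # covariate tracks group
  mats <- lapply(seq_len(n), function(i) {
    m <- matrix(rnorm(64, sd = 0.1), 8)
    m <- (m + t(m)) / 2
    m <- m + 0.3 * conf[i]          # effect flows only through the covariate
    diag(m) <- 0
    m
  })
  raw <- edgewise_stats(mats, groups)
  adj <- edgewise_stats(mats, groups, covariates = data.frame(conf = conf))
  ratio <- mean(abs(adj$t_matrix[upper.tri(adj$t_matrix)])) /
    mean(abs(raw$t_matrix[upper.tri(raw$t_matrix)]))
  expect_lt(ratio, 0.5)
})

test_that("component extraction returns maximal connected subnetworks", {
  p <- 6
  pm <- matrix(1, p, p); tm <- matrix(0, p, p)
  set_edge <- function(i, j, pval, tval) {
    pm[i, j] <<- pm[j, i] <<- pval
    tm[i, j] <<- tm[j, i] <<- tval
  }
  # path a-b, b-c, c-d: one component of 3 edges, 4 nodes
  set_edge(1, 2, 1e-5, 4); set_edge(2, 3, 1e-5, 4); set_edge(3, 4, 1e-5, 4)
  comps <- extract_components(pm, tm, primary_p = 0.001)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$size, 3)
  expect_length(comps[[1]]$nodes, 4)

  # no suprathreshold edges
  expect_length(extract_components(matrix(1, p, p), tm, 0.001), 0)

  # two disjoint triangles
  pm <- matrix(1, 6, 6); tm <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    set_edge(e[1], e[2], 1e-5, 3)
  }
  comps2 <- extract_components(pm, tm, 0.001)
  expect_length(comps2, 2)
  expect_equal(sapply(comps2, `[[`, "size"), c(3, 3))

  # tails restrict by sign
  tm[1, 2] <- tm[2, 1] <- -3
  comps_pos <- extract_components(pm, tm, 0.001, tail = "patient_gt")
  expect_equal(sum(sapply(comps_pos, `[[`, "size")), 5)
})

test_that("NBS corrected p-values are valid, monotone and deterministic", {
  planted <- cbind(1:4, 5:8)
  sim <- sim_matrices(20, 12, delta = 0.3, planted = planted, seed = 5)
  cfg <- nbs_config(primary_p = 0.01, n_perm = 50, seed = 11)
  res <- nbs_test(sim$matrices, sim$groups, config = cfg)
  expect_s3_class(res, "nbs_result")
  ps <- sapply(res$components, `[[`, "corrected_p")
  sizes <- sapply(res$components, `[[`, "size")
  expect_true(all(ps >= 1 / 51 & ps <= 1))
  if (length(ps) > 1) {
    expect_true(all(diff(ps[order(-sizes)]) >= 0))
  }
  res2 <- nbs_test(sim$matrices, sim$groups, config = cfg)
  expect_equal(sapply(res2$components, `[[`, "corrected_p"), ps)
  expect_error(nbs_config(n_perm = 0), "n_perm")
})

test_that("a strongly planted subnetwork is recovered as significant", {
  planted <- cbind(c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5),
                   c(6, 7, 7, 8, 8, 9, 9, 10, 10, 6))
  sim <- sim_matrices(30, 20, delta = 0.25, planted = planted, seed = 8)
  res <- nbs_test(sim$matrices, sim$groups,
                  config = nbs_config(primary_p = 0.001, n_perm = 100, seed = 2))
  expect_gte(length(res$components), 1)
  expect_lt(res$components[[1]]$corrected_p, 0.05)
  found <- paste(res$components[[1]]$edges[, 1], res$components[[1]]$edges[, 2])
  truth <- paste(pmin(planted[, 1], planted[, 2]), pmax(planted[, 1], planted[, 2]))
  jacc <- length(intersect(found, truth)) / length(union(found, truth))
  expect_gte(jacc, 0.5)
})
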