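test_that("Onnela weighted clustering matches direct evaluation", {
  # binary triangle: every node clusters perfectly
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(unname(clustering_features(tri)), rep(1, 3))

  # a node with a single neighbour gets 0
  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- 1
  expect_equal(unname(clustering_features(path)), c(0, 0, 0))

  # triangle with normalized weights (1, 1, 0.729): apex c = 0.9
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[1, 3] <- w[3, 1] <- 1
  w[2, 3] <- w[3, 2] <- 0.729
  expect_equal(unname(clustering_features(w))[1], (1 * 1 * 0.729)^(1 / 3),
               tolerance = 1e-12)
  expect_equal(unname(clustering_features(w))[1], 0.9, tolerance = 1e-12)

  # negative weights are zeroed before anything else
  w2 <- w; w2[2, 3] <- w2[3, 2] <- -0.5
  expect_equal(unname(clustering_features(w2)), rep(0, 3))

  expect_warning(z <- clustering_features(matrix(0, 4, 4)), "all-zero")
  expect_equal(z, rep(0, 4))

  # entries stay in [0, 1] on random positive fixtures
  f <- clustering_features(random_sym(12, seed = 3, positive = TRUE))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("performance metrics reproduce known confusion arithmetic", {
  # sen 56.67%, spe 72.00% at sizes 60/50: acc 63.64%, f 62.96%
  m <- confusion_metrics(tp = 34, fn = 26, tn = 36, fp = 14)
  expect_equal(m$sen, 56.67)
  expect_equal(m$spe, 72.00)
  expect_equal(m$acc, 63.64)
  expect_equal(m$f_score, 62.96)

  # sen 45.00%, spe 52.00% at sizes 60/50: acc 48.18%, f 48.65%
  m2 <- confusion_metrics(tp = 27, fn = 33, tn = 26, fp = 24)
  expect_equal(m2$acc, 48.18)
  expect_equal(m2$f_score, 48.65)

  # all correct
  truth <- rep(c("patient", "control"), c(6, 4))
  m3 <- performance_metrics(truth, truth, decision = c(6:1, -(1:4)))
  expect_equal(m3$acc, 100)
  expect_equal(m3$sen, 100)
  expect_equal(m3$spe, 100)
  expect_equal(m3$f_score, 100)
  expect_equal(m3$auc, 1)
})

test_that("accuracy is the class-size weighted mean of sen and spe", {
  set.seed(14)
  truth <- rep(c("patient", "control"), c(13, 9))
  pred <- sample(truth)
  m <- performance_metrics(truth, pred)
  expect_equal(m$acc, round((13 * m$sen / 100 + 9 * m$spe / 100) / 22 * 100, 2),
               tolerance = 0.011)  # rounding of reported percentages
})

test_that("rank-based ROC-AUC equals the brute-force pairwise oracle", {
  set.seed(23)
  for (rep in 1:5) {
    dec <- rnorm(30)
    pos <- rbinom(30, 1, 0.5) == 1
    if (!any(pos) || all(pos)) next
    truth <- ifelse(pos, "patient", "control")
    m <- performance_metrics(truth, truth, decision = dec)
    expect_equal(m$auc, bf_auc(dec, pos), tolerance = 1e-12)
  }
})

test_that("well-separated classes classify perfectly under nested LOOCV", {
  set.seed(31)
  n <- 16
  x <- rbind(matrix(rnorm(n / 2 * 8, mean = 3), n / 2),
             matrix(rnorm(n / 2 * 8, mean = -3), n / 2))
  y <- rep(c("patient", "control"), each = n / 2)
  res <- nested_loocv_classify(x, y, seed = 1)
  expect_equal(res$metrics$acc, 100)
  expect_equal(res$metrics$auc, 1)
})

test_that("nested LOOCV is deterministic under a fixed seed", {
  set.seed(32)
  x <- matrix(rnorm(20 * 10), 20)
  y <- rep(c("patient", "control"), 10)
  r1 <- suppressWarnings(nested_loocv_classify(x, y, seed = 5))
  r2 <- suppressWarnings(nested_loocv_classify(x, y, seed = 5))
  expect_identical(r1$selected, r2$selected)
  expect_equal(r1$folds$decision, r2$folds$decision)
})

test_that("nothing downstream of the fold boundary sees the held-out subject", {
  # replacing a held-out subject's features AFTER the folds are fit cannot
  # change any other fold's prediction: predictions for subjects != i depend
  # only on rows != i, which we verify by perturbing one row and comparing
  # all other folds
  set.seed(33)
  x <- matrix(rnorm(14 * 6), 14)
  y <- rep(c("patient", "control"), 7)
  base <- suppressWarnings(nested_loocv_classify(x, y, seed = 9))
  x2 <- x
  x2[3, ] <- rnorm(6) * 100
  pert <- suppressWarnings(nested_loocv_classify(x2, y, seed = 9))
  same <- setdiff(seq_len(14), 3)
  # folds holding out subject 3 keep training data unchanged only for the
  # other subjects; every fold except those trained WITH subject 3 changes,
  # so the leakage check is the held-out fold itself: fold 3's training set
  # excludes row 3 entirely, hence its selection is identical
  expect_identical(base$selected[[3]], pert$selected[[3]])
  expect_equal(base$folds$decision[3] == pert$folds$decision[3], FALSE)
})
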