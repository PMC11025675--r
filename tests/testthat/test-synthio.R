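test_that("group covariance targets have the configured block structure", {
  cfg <- generator_config(
    n_patient = 4, n_control = 4, p = 10, t_len = 60,
    r_within = 0.4, r_between = 0.1, partition = toy_partition(10, c("SMN", "DMN")),
    effects = data.frame(module_a = character(), module_b = character(),
                         delta = numeric())
  )
  ctl <- build_group_covariance(cfg, "control")
  mods <- unname(cfg$partition)
  same <- outer(mods, mods, "==") & !diag(10)
  expect_true(all(ctl[same] == 0.4))
  expect_true(all(ctl[!same & !diag(10)] == 0.1))
  expect_equal(unname(diag(ctl)), rep(1, 10))

  # planted patient effect raises only the named block
  cfg2 <- generator_config(
    n_patient = 4, n_control = 4, p = 10, t_len = 60,
    r_within = 0.4, r_between = 0.1, partition = toy_partition(10, c("SMN", "DMN")),
    effects = data.frame(module_a = "SMN", module_b = "DMN", delta = 0.15)
  )
  pat <- build_group_covariance(cfg2, "patient")
  ctl2 <- build_group_covariance(cfg2, "control")
  cross <- outer(mods == "SMN", mods == "DMN") | outer(mods == "DMN", mods == "SMN")
  expect_true(all(abs(pat[cross] - 0.25) < 1e-12))
  expect_true(all(abs(ctl2[cross] - 0.10) < 1e-12))
  expect_equal(pat[!cross], ctl2[!cross])
})

test_that("indefinite targets are repaired to positive definite", {
  part <- setNames(rep(c("SMN", "DMN"), c(2, 8)), paste0("R", 1:10))
  cfg <- generator_config(
    n_patient = 4, n_control = 4, p = 10, t_len = 60,
    r_within = 0.0, r_between = 0.9, partition = part,
    effects = data.frame(module_a = character(), module_b = character(),
                         delta = numeric())
  )
  expect_message(m <- build_group_covariance(cfg, "control"),
                 "positive definite")
  expect_gte(min(eigen(m, symmetric = TRUE)$values), 1e-6 - 1e-10)
  expect_true(attr(m, "repaired"))
  expect_gt(attr(m, "repair_distance"), 0)
})

test_that("effects pushing correlations out of range are rejected by block name", {
  cfg <- generator_config(
    n_patient = 4, n_control = 4, p = 10, t_len = 60,
    r_within = 0.9, r_between = 0.1, partition = toy_partition(10, c("SMN", "DMN")),
    effects = data.frame(module_a = "SMN", module_b = "SMN", delta = 0.2)
  )
  expect_error(build_group_covariance(cfg, "patient"), "SMN-SMN")
})

test_that("sampled time series match the target covariance and AR structure", {
  cov <- matrix(c(1, 0.4, 0.4, 1), 2)
  x <- sample_timeseries(cov, 50000, ar_coef = 0, seed = 7)
  expect_lt(abs(cor(x[, 1], x[, 2]) - 0.4), 0.02)

  x1 <- sample_timeseries(cov, 100, ar_coef = 0.3, seed = 9)
  x2 <- sample_timeseries(cov, 100, ar_coef = 0.3, seed = 9)
  expect_identical(x1, x2)

  y <- sample_timeseries(diag(4), 10000, ar_coef = 0.3, seed = 3)
  lag1 <- mean(sapply(1:4, function(j) cor(y[-1, j], y[-nrow(y), j])))
  expect_lt(abs(lag1 - 0.3), 0.05)

  expect_error(sample_timeseries(matrix(c(1, 2, 2, 1), 2), 50),
               "positive definite")
})

test_that("sample correlations converge entrywise to the target", {
  cfg <- mini_config(p = 10, seed = 5)
  target <- build_group_covariance(cfg, "control")
  x <- sample_timeseries(target, 20000, ar_coef = 0.3, seed = 21)
  expect_lt(max(abs(cor(x) - target)), 0.03)
})

test_that("generated cohorts honor the configured sizes and covariates", {
  co <- generate_cohort(mini_config(n_patient = 3, n_control = 3, p = 10,
                                    t_len = 60))
  expect_s3_class(co, "cohort_dataset")
  expect_equal(nrow(co$subjects), 6)
  expect_equal(dim(co$timeseries[[1]]), c(60, 10))
  expect_equal(co$subjects$pta_mean,
               (co$subjects$pta_left + co$subjects$pta_right) / 2)

  # different seeds: same schema, different signals
  a <- generate_cohort(mini_config(seed = 1))
  b <- generate_cohort(mini_config(seed = 2))
  expect_identical(names(a$timeseries), names(b$timeseries))
  expect_false(identical(a$timeseries[[1]], b$timeseries[[1]]))
  # identical config + seed: identical cohort
  expect_identical(a, generate_cohort(mini_config(seed = 1)))

  expect_error(generator_config(n_patient = 1, n_control = 5),
               "at least 2")
})

test_that("default cohort matches its configured scale", {
  co <- generate_cohort(generator_config(seed = 123))
  expect_equal(nrow(co$subjects), 110)
  expect_equal(sum(co$subjects$group == "patient"), 60)
  expect_equal(dim(co$timeseries[[1]]), c(239, 90))
  pat <- co$subjects[co$subjects$group == "patient", ]
  expect_lt(abs(mean(pat$pta_mean) - 33.22), 2)
  expect_lt(abs(mean(pat$age) - 62.75), 3)
})

test_that("cohort write/read round-trips and validates its inputs", {
  co <- generate_cohort(mini_config(n_patient = 3, n_control = 3, p = 10,
                                    t_len = 40, seed = 8))
  d <- withr::local_tempdir()
  write_cohort(co, d)
  co2 <- read_cohort(d)
  expect_equal(co2$subjects$subject_id, co$subjects$subject_id)
  expect_equal(co2$partition, co$partition)
  for (id in names(co$timeseries)) {
    expect_lt(max(abs(co$timeseries[[id]] - co2$timeseries[[id]])), 1e-12)
  }

  # subject with a missing region column is named in the error
  ts_file <- file.path(d, "ts", "sub-002.csv")
  ts <- read.csv(ts_file, check.names = FALSE)
  write.csv(ts[, -3], ts_file, row.names = FALSE)
  expect_error(read_cohort(d), "sub-002")

  write.csv(ts, ts_file, row.names = FALSE)
  # region renamed away from the partition is reported as unassigned
  names(ts)[2] <- "R_unknown"
  write.csv(ts, ts_file, row.names = FALSE)
  expect_error(read_cohort(d), "R_unknown")

  # unknown module label
  part <- read.csv(file.path(d, "partition.csv"))
  part$module[1] <- "XXX"
  write.csv(part, file.path(d, "partition.csv"), row.names = FALSE)
  expect_error(read_cohort(d), "XXX")
})
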