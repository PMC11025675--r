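#' Covariate-adjusted two-sample comparison
#'
#' Least-squares fit of `value ~ intercept + group + covariates`; the
#' group term's t statistic and two-sided p-value (df = n - k) are the
#' covariate-adjusted analogue of a two-sample t-test.
#'
#' @param values numeric vector, one value per subject.
#' @param groups `"patient"` / `"control"` labels.
#' @param covariates optional n x K numeric table.
#' @return list with `t_stat`, `p_raw`, `df`, `direction` (sign of the
#'   adjusted patient-minus-control effect), `estimate`.
#' @export
adjusted_two_sample_test <- function(values, groups, covariates = NULL) {
  g <- as_group_factor(groups)
  if (min(table(g)) < 2) stop("need at least 2 subjects per group", call. = FALSE)
  if (anyNA(values) || stats::sd(values) == 0) {
    warning("constant or missing values; comparison undefined", call. = FALSE)
    return(list(t_stat = NA_real_, p_raw = NA_real_, df = NA_integer_,
                direction = 0, estimate = NA_real_))
  }
  cov_m <- if (is.null(covariates)) NULL else data.matrix(covariates)
  fit <- group_lm_t(matrix(values, ncol = 1), as.numeric(g == "patient"), cov_m)
  tt <- unname(fit$t[1])
  list(t_stat = tt, p_raw = 2 * stats::pt(-abs(tt), fit$df), df = fit$df,
       direction = sign(tt), estimate = unname(fit$beta[1]))
}

#' Bonferroni adjustment
#'
#' @param p_values numeric p-values in [0, 1].
#' @param m family size (default: length of `p_values`).
#' @return adjusted p-values `min(1, p * m)`.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (m < 1) stop("family size m must be >= 1", call. = FALSE)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  pmin(1, p_values * m)
}

#' Permutation two-sample comparison
#'
#' Group labels are permuted `n_perm` times; the two-sided p-value is
#' `(1 + #\{|t_perm| >= |t_obs|\}) / (1 + n_perm)`.
#'
#' @param values numeric vector per subject.
#' @param groups `"patient"` / `"control"` labels.
#' @param covariates optional covariate table (kept attached to subjects).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return list with `t_stat`, `p_raw`, `direction`, `n_perm`.
#' @export
permutation_compare <- function(values, groups, covariates = NULL,
                                n_perm = 1000, seed = 1) {
  g <- as_group_factor(groups)
  cov_m <- if (is.null(covariates)) NULL else data.matrix(covariates)
  y <- matrix(values, ncol = 1)
  obs <- unname(group_lm_t(y, as.numeric(g == "patient"), cov_m)$t[1])
  null_t <- with_rng_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      suppressWarnings(
        group_lm_t(y, sample(as.numeric(g == "patient")), cov_m)$t[1])
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_t) >= abs(obs))) / (1 + n_perm)
  list(t_stat = obs, p_raw = p, direction = sign(obs), n_perm = n_perm)
}

#' Compare a table of measures between groups with multiplicity control
#'
#' Each column of `measure_table` is compared between groups with the
#' covariate-adjusted t-test when both group distributions pass a
#' Shapiro-Wilk normality screen (p > 0.05), and with the permutation test
#' otherwise; the route is recorded per measure and can be forced with
#' `method`. Bonferroni adjustment uses `family_size` (default: number of
#' measures).
#'
#' @param measure_table n x M numeric matrix/data.frame, one column per
#'   measure.
#' @param groups `"patient"` / `"control"` labels.
#' @param covariates optional covariate table.
#' @param family_size Bonferroni family size.
#' @param method `"auto"` (Shapiro-Wilk routing), `"ttest"` or
#'   `"permutation"`.
#' @param n_perm permutations for the nonparametric route.
#' @param seed integer seed.
#' @return data.frame with measure, method, t_stat, p_raw, p_adjusted,
#'   direction.
#' @export
compare_measures <- function(measure_table, groups, covariates = NULL,
                             family_size = NULL,
                             method = c("auto", "ttest", "permutation"),
                             n_perm = 1000, seed = 1) {
  method <- match.arg(method)
  mt <- as.matrix(measure_table)
  g <- as_group_factor(groups)
  m <- family_size %||% ncol(mt)
  rows <- lapply(seq_len(ncol(mt)), function(j) {
    v <- mt[, j]
    if (anyNA(v)) {
      warning("measure ", colnames(mt)[j] %||% j,
              " has missing values; comparison skipped", call. = FALSE)
      return(data.frame(measure = colnames(mt)[j] %||% paste0("m", j),
                        method = "none", t_stat = NA_real_, p_raw = NA_real_,
                        direction = 0, stringsAsFactors = FALSE))
    }
    use <- method
    if (method == "auto") {
      normal <- all(vapply(split(v, g), function(x) {
        length(unique(x)) < 3 || stats::shapiro.test(x)$p.value > 0.05
      }, logical(1)))
      use <- if (normal) "ttest" else "permutation"
    }
    res <- if (use == "ttest") {
      adjusted_two_sample_test(v, g, covariates)
    } else {
      permutation_compare(v, g, covariates, n_perm = n_perm,
                          seed = derive_seed(seed, paste0("measure", j)))
    }
    data.frame(measure = colnames(mt)[j] %||% paste0("m", j), method = use,
               t_stat = res$t_stat, p_raw = res$p_raw,
               direction = res$direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni_adjust(out$p_raw, m)
  out
}

#' Demographic comparison table for a cohort
#'
#' Two-sample t-tests for continuous covariates and a chi-squared test for
#' gender, summarizing the cohort the way clinical baseline tables do.
#'
#' @param dataset a `cohort_dataset`.
#' @return data.frame with variable, patient_mean, patient_sd,
#'   control_mean, control_sd, p_value.
#' @export
cohort_demographics <- function(dataset) {
  s <- dataset$subjects
  cont <- intersect(c("age", "education", "pta_left", "pta_right", "pta_mean"),
                    names(s))
  rows <- lapply(cont, function(v) {
    pat <- s[[v]][s$group == "patient"]; ctl <- s[[v]][s$group == "control"]
    data.frame(variable = v,
               patient_mean = mean(pat), patient_sd = stats::sd(pat),
               control_mean = mean(ctl), control_sd = stats::sd(ctl),
               p_value = stats::t.test(pat, ctl)$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tab <- table(s$group, s$gender)
  if (ncol(tab) > 1) {
    out <- rbind(out, data.frame(
      variable = "gender_male_frac",
      patient_mean = mean(s$gender[s$group == "patient"] == "M"),
      patient_sd = NA_real_,
      control_mean = mean(s$gender[s$group == "control"] == "M"),
      control_sd = NA_real_,
      p_value = suppressWarnings(stats::chisq.test(tab)$p.value),
      stringsAsFactors = FALSE
    ))
  }
  out
}
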