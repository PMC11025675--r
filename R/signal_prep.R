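#' Temporal preprocessing configuration
#'
#' @param drop_volumes initial volumes removed to let the signal reach
#'   steady state (default 5).
#' @param band passband in Hz, default `c(0.01, 0.08)`.
#' @param tr repetition time in seconds (sampling interval).
#' @return object of class `prep_config`.
#' @export
prep_config <- function(drop_volumes = 5, band = c(0.01, 0.08), tr = 2) {
  nyquist <- 1 / (2 * tr)
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= nyquist) {
    stop(sprintf(
      "passband (%g, %g) Hz must satisfy 0 < low < high < Nyquist = %g Hz at TR = %g s",
      band[1], band[2], nyquist, tr), call. = FALSE)
  }
  structure(list(drop_volumes = drop_volumes, band = band, tr = tr),
            class = "prep_config")
}

#' Drop initial volumes, detrend and band-pass filter region time series
#'
#' Removes the first `drop_volumes` rows, subtracts a per-column
#' least-squares line, then applies a zero-phase (forward-backward)
#' 4th-order Butterworth band-pass with the configured passband. Zero-phase
#' filtering preserves the relative timing of regional signals, which
#' matters when the next step is correlation.
#'
#' @param series T x P numeric matrix.
#' @param config a [prep_config()].
#' @return (T - drop_volumes) x P filtered matrix.
#' @export
detrend_and_bandpass <- function(series, config = prep_config()) {
  stopifnot(is.matrix(series))
  t_total <- nrow(series)
  if (t_total - config$drop_volumes < 30) {
    stop("need at least 30 timepoints after dropping ",
         config$drop_volumes, " volumes", call. = FALSE)
  }
  x <- series[(config$drop_volumes + 1):t_total, , drop = FALSE]
  tt <- seq_len(nrow(x))
  design <- cbind(1, tt)
  x <- x - design %*% qr.coef(qr(design), x)  # remove per-column linear trend
  fs <- 1 / config$tr
  bf <- signal::butter(2, config$band / (fs / 2), type = "pass")
  out <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  dimnames(out) <- dimnames(x)
  out
}

#' Regress nuisance signals out of region time series
#'
#' Ordinary least squares of each region on an intercept plus the supplied
#' regressor columns (e.g. white-matter and CSF signals and the Friston-24
#' motion expansion, supplied as data). Rank-deficient designs are handled
#' by the pseudoinverse (minimum-norm solution) with a warning rather than
#' an error, since motion-expansion regressor sets are often collinear.
#'
#' @param series T x P matrix.
#' @param nuisance T x K regressor matrix, K < T.
#' @return T x P residual matrix; residuals are orthogonal to the design.
#' @export
regress_nuisance <- function(series, nuisance) {
  stopifnot(is.matrix(series), is.matrix(nuisance),
            nrow(series) == nrow(nuisance))
  if (ncol(nuisance) >= nrow(nuisance)) {
    stop("more regressors than timepoints", call. = FALSE)
  }
  design <- cbind(intercept = 1, nuisance)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    warning("nuisance design is rank deficient (rank ", qr_d$rank, " of ",
            ncol(design), "); using pseudoinverse solution", call. = FALSE)
    sv <- svd(design)
    pos <- sv$d > max(sv$d) * 1e-10
    coef <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% series) / sv$d[pos])
    res <- series - design %*% coef
  } else {
    res <- series - design %*% qr.coef(qr_d, series)
  }
  dimnames(res) <- dimnames(series)
  res
}

#' Full temporal preprocessing for every subject of a cohort
#'
#' Fixed stage order: drop initial volumes, linear detrend, band-pass,
#' then nuisance regression (the regression-last order can be swapped with
#' `nuisance_first = TRUE`).
#'
#' @param dataset a `cohort_dataset`.
#' @param config a [prep_config()]; `tr` defaults to the cohort's TR.
#' @param nuisance optional named list of per-subject T' x K regressor
#'   matrices (T' = timepoints after dropping).
#' @param nuisance_first regress before filtering instead of after.
#' @return the cohort with filtered time series.
#' @export
preprocess_cohort <- function(dataset, config = NULL, nuisance = NULL,
                              nuisance_first = FALSE) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (is.null(config)) config <- prep_config(tr = dataset$tr)
  post_config <- config
  post_config$drop_volumes <- 0
  for (id in names(dataset$timeseries)) {
    x <- dataset$timeseries[[id]]
    nz <- nuisance[[id]]
    if (config$drop_volumes > 0) {
      x <- x[-seq_len(config$drop_volumes), , drop = FALSE]
    }
    if (!is.null(nz) && nuisance_first) x <- regress_nuisance(x, nz)
    x <- detrend_and_bandpass(x, post_config)
    if (!is.null(nz) && !nuisance_first) x <- regress_nuisance(x, nz)
    dataset$timeseries[[id]] <- x
  }
  dataset
}
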