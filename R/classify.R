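#' Weighted local clustering coefficient features
#'
#' Per-node Onnela weighted clustering coefficients of the unthresholded
#' connectivity matrix: negative weights are zeroed, weights are scaled by
#' the matrix maximum, and
#' `c_i = sum_(j,h) (w_ij w_ih w_jh)^(1/3) / (k_i (k_i - 1))`
#' with `k_i` the count of nonzero weights at node i; nodes with fewer
#' than two neighbors get 0. These length-P vectors are the classifier's
#' feature representation of each subject's network.
#'
#' @param m `connectivity_matrix` or symmetric matrix.
#' @return numeric vector of length P in [0, 1].
#' @export
clustering_features <- function(m) {
  v <- if (inherits(m, "connectivity_matrix")) m$values else m
  assert_square_symmetric(v, what = "connectivity matrix")
  w <- pmax(v, 0)
  diag(w) <- 0
  mx <- max(w)
  if (mx == 0) {
    warning("all-zero matrix after removing negative weights; features are 0",
            call. = FALSE)
    return(rep(0, ncol(w)))
  }
  w <- w / mx
  wc <- w^(1 / 3)
  tri <- diag(wc %*% wc %*% wc)        # counts each (j, h) ordered pair
  k <- rowSums(w > 0)
  c_i <- rep(0, ncol(w))
  ok <- k >= 2
  c_i[ok] <- tri[ok] / (k[ok] * (k[ok] - 1))
  names(c_i) <- rownames(v)
  c_i
}

#' Classification performance metrics
#'
#' Confusion-based metrics with patient as the positive class, plus
#' ROC-AUC computed from decision values by the rank (Mann-Whitney)
#' statistic. Percentages are reported to two decimals.
#'
#' @param truth factor/character of `"patient"` / `"control"` labels.
#' @param predicted predicted labels, same coding.
#' @param decision numeric decision values, larger = more patient-like;
#'   optional (`NA` AUC when absent).
#' @return list with `acc`, `sen`, `spe`, `f_score` (percent), `auc`, and
#'   confusion counts `tp`, `fn`, `tn`, `fp`.
#' @export
performance_metrics <- function(truth, predicted, decision = NULL) {
  truth <- as_group_factor(truth)
  predicted <- as_group_factor(predicted)
  tp <- sum(truth == "patient" & predicted == "patient")
  fn <- sum(truth == "patient" & predicted == "control")
  tn <- sum(truth == "control" & predicted == "control")
  fp <- sum(truth == "control" & predicted == "patient")
  confusion_metrics(tp = tp, fn = fn, tn = tn, fp = fp,
                    auc = if (is.null(decision)) NA_real_ else
                      rank_auc(decision, truth == "patient"))
}

#' Metrics from explicit confusion counts
#'
#' @param tp,fn,tn,fp confusion counts (patient positive).
#' @param auc optional ROC-AUC to carry through.
#' @return same structure as [performance_metrics()].
#' @export
confusion_metrics <- function(tp, fn, tn, fp, auc = NA_real_) {
  n <- tp + fn + tn + fp
  acc <- (tp + tn) / n
  sen <- tp / (tp + fn)
  spe <- tn / (tn + fp)
  if (tp + fp == 0) {
    warning("no positive predictions; F-score undefined", call. = FALSE)
    f <- NA_real_
  } else {
    prec <- tp / (tp + fp)
    f <- if (prec + sen == 0) 0 else 2 * prec * sen / (prec + sen)
  }
  list(acc = round(100 * acc, 2), sen = round(100 * sen, 2),
       spe = round(100 * spe, 2), f_score = round(100 * f, 2),
       auc = auc, tp = tp, fn = fn, tn = tn, fp = fp)
}

# ROC-AUC as the normalized Mann-Whitney rank statistic
rank_auc <- function(decision, is_positive) {
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(decision)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Nested leave-one-out LASSO + linear SVM classification
#'
#' For each held-out subject: features are standardized with training-fold
#' means and SDs only; the LASSO penalty is chosen by inner 5-fold
#' cross-validation (logistic LASSO over a 50-point logarithmic grid) on
#' the training fold; features with nonzero LASSO coefficients feed a
#' linear soft-margin SVM (C = 1); the held-out subject's label and
#' decision value are recorded. No information from the held-out subject
#' reaches scaling, selection or fitting. A fold in which the LASSO
#' selects nothing falls back to all features (reported in the fold
#' record).
#'
#' @param features n x P numeric matrix (rows = subjects).
#' @param labels `"patient"` / `"control"` vector of length n.
#' @param cost SVM regularization constant, default 1.
#' @param n_inner_folds inner CV folds for the penalty, default 5.
#' @param n_lambda LASSO penalty grid size, default 50.
#' @param seed integer seed controlling inner-fold assignment.
#' @return object of class `classification_result`: list with `folds`
#'   (per-subject data.frame: truth, predicted, decision, n_selected,
#'   fallback), `selected` (list of per-fold feature index vectors),
#'   `metrics` from [performance_metrics()].
#' @export
nested_loocv_classify <- function(features, labels, cost = 1,
                                  n_inner_folds = 5, n_lambda = 50,
                                  seed = 1) {
  stopifnot(is.matrix(features))
  truth <- as_group_factor(labels)
  if (min(table(truth)) < 2) stop("need at least 2 subjects per class", call. = FALSE)
  n <- nrow(features)
  pred <- character(n); dec <- numeric(n)
  selected <- vector("list", n); fallback <- logical(n)

  for (i in seq_len(n)) {
    tr_x <- features[-i, , drop = FALSE]
    tr_y <- truth[-i]
    mu <- colMeans(tr_x)
    sdv <- apply(tr_x, 2, stats::sd)
    sdv[sdv == 0] <- 1
    tr_s <- scale(tr_x, center = mu, scale = sdv)
    te_s <- (features[i, ] - mu) / sdv

    k_folds <- min(n_inner_folds, min(table(tr_y)))
    foldid <- with_rng_seed(derive_seed(seed, paste0("fold", i)), {
      # stratified assignment keeps both classes in every inner fold
      fid <- integer(nrow(tr_s))
      for (lv in levels(tr_y)) {
        idx <- which(tr_y == lv)
        fid[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
      }
      fid
    })
    cv <- glmnet::cv.glmnet(tr_s, as.numeric(tr_y == "patient"),
                            family = "binomial", foldid = foldid,
                            nlambda = n_lambda)
    coefs <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
    sel <- which(coefs != 0)
    if (length(sel) == 0) {
      fallback[i] <- TRUE
      sel <- seq_len(ncol(features))
    }
    selected[[i]] <- sel

    fit <- e1071::svm(tr_s[, sel, drop = FALSE], tr_y, kernel = "linear",
                      cost = cost, scale = FALSE)
    pv <- stats::predict(fit, matrix(te_s[sel], nrow = 1),
                         decision.values = TRUE)
    d <- as.numeric(attr(pv, "decision.values"))
    # orient decision values so larger means more patient-like
    if (grepl("^control/", colnames(attr(pv, "decision.values"))[1])) d <- -d
    pred[i] <- as.character(pv)
    dec[i] <- d
  }
  folds <- data.frame(
    subject = rownames(features) %||% seq_len(n),
    truth = as.character(truth), predicted = pred, decision = dec,
    n_selected = lengths(selected), fallback = fallback,
    stringsAsFactors = FALSE
  )
  structure(
    list(folds = folds, selected = selected,
         metrics = performance_metrics(truth, pred, dec)),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "classification_result (LOOCV, n = %d): AUC %.3f  ACC %.2f%%  SEN %.2f%%  SPE %.2f%%  F %.2f%%\n",
    nrow(x$folds), m$auc, m$acc, m$sen, m$spe, m$f_score))
  invisible(x)
}

#' ROC curve points from decision values
#'
#' @param truth `"patient"` / `"control"` labels.
#' @param decision numeric decision values (larger = patient).
#' @return data.frame with `threshold`, `tpr`, `fpr`.
#' @export
roc_points <- function(truth, decision) {
  truth <- as_group_factor(truth)
  thr <- c(Inf, sort(unique(decision), decreasing = TRUE), -Inf)
  pos <- truth == "patient"
  data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(decision[pos] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(decision[!pos] >= t), numeric(1))
  )
}
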