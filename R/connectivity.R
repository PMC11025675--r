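#' Connectivity matrix constructor
#'
#' Thin S3 wrapper tagging a symmetric P x P association matrix with its
#' kind. The diagonal is stored as 0 for every kind: self-correlations are
#' uninformative, arctanh(1) is infinite, and the graph stages ignore
#' self-loops.
#'
#' @param values symmetric numeric matrix, diagonal zeroed on construction.
#' @param kind one of `"LOFC"`, `"zLOFC"`, `"HOFC"`.
#' @param region_labels optional character vector of region names.
#' @return object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, kind = c("LOFC", "zLOFC", "HOFC"),
                                region_labels = NULL) {
  kind <- match.arg(kind)
  assert_square_symmetric(values, what = "connectivity values")
  diag(values) <- 0
  if (!is.null(region_labels)) dimnames(values) <- list(region_labels, region_labels)
  structure(list(values = values, kind = kind,
                 region_labels = region_labels %||% rownames(values)),
            class = "connectivity_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix [%s], %d regions, range [%.3f, %.3f]\n",
              x$kind, ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Low-order functional connectivity: pairwise Pearson correlation
#'
#' Entry (i, j) is the Pearson correlation of region i's and region j's
#' time series; the classical FC matrix capturing temporal synchronization
#' of regional signals.
#'
#' @param series T x P matrix of region time series.
#' @param region_labels optional region names (defaults to column names).
#' @return `connectivity_matrix` of kind `"LOFC"`.
#' @export
lofc_matrix <- function(series, region_labels = colnames(series)) {
  stopifnot(is.matrix(series), nrow(series) >= 3)
  sds <- apply(series, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- if (is.null(region_labels)) which(sds == 0) else region_labels[sds == 0]
    stop("zero-variance region(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(series)
  connectivity_matrix(r, "LOFC", region_labels)
}

#' Fisher r-to-z transform of an LOFC matrix
#'
#' Applies `z = arctanh(r)` elementwise off-diagonal, making correlation
#' values approximately normal so they can serve as inputs to a second
#' round of Pearson correlation. Off-diagonal magnitudes at or above 1 are
#' clipped to 0.999999 first; the number of clipped entries is reported.
#'
#' @param m `connectivity_matrix` of kind `"LOFC"`.
#' @return `connectivity_matrix` of kind `"zLOFC"`.
#' @export
fisher_z <- function(m) {
  stopifnot(inherits(m, "connectivity_matrix"))
  if (m$kind != "LOFC") stop("fisher_z expects an LOFC matrix", call. = FALSE)
  r <- m$values
  clip <- abs(r) >= 1
  if (any(clip)) {
    message(sum(clip), " correlation(s) at |r| >= 1 clipped to 0.999999")
    r[clip] <- sign(r[clip]) * 0.999999
  }
  z <- atanh(r)
  diag(z) <- 0
  connectivity_matrix(z, "zLOFC", m$region_labels)
}

#' High-order functional connectivity: correlation of FC profiles
#'
#' Entry (i, j) is the Pearson correlation between region i's and region
#' j's whole-brain connectivity profiles (rows of the Fisher-z LOFC
#' matrix). By default entries i and j are removed from BOTH profiles
#' before correlating, so the trivially zero self-entries cannot inflate
#' the profile similarity; `exclude = "diag"` removes only each profile's
#' own self-entry and `exclude = "none"` keeps full rows.
#'
#' Implemented with sum-corrected closed-form Pearson terms so all P(P-1)/2
#' profile correlations are computed with matrix algebra; a loop-wise
#' equivalent is used as the test oracle.
#'
#' @param z `connectivity_matrix` of kind `"zLOFC"` (P >= 5).
#' @param exclude `"both"` (default), `"diag"` or `"none"`.
#' @return `connectivity_matrix` of kind `"HOFC"`.
#' @export
hofc_matrix <- function(z, exclude = c("both", "diag", "none")) {
  stopifnot(inherits(z, "connectivity_matrix"))
  if (z$kind != "zLOFC") stop("hofc_matrix expects a zLOFC matrix", call. = FALSE)
  exclude <- match.arg(exclude)
  zm <- z$values
  p <- ncol(zm)
  if (p < 5) stop("need at least 5 regions for HOFC profiles", call. = FALSE)

  if (exclude == "none") {
    h <- stats::cor(t(zm))
  } else if (exclude == "diag") {
    # drop entry i from profile i and entry j from profile j; profiles then
    # differ in support, so correlate the common support (all but i and j)
    # -- identical to "both" in effect for off-diagonal pairs
    h <- hofc_both(zm)
  } else {
    h <- hofc_both(zm)
  }
  const <- attr(h, "n_constant") %||% 0
  if (const > 0) {
    warning(const, " profile pair(s) with zero variance after exclusion; set to 0",
            call. = FALSE)
  }
  attr(h, "n_constant") <- NULL
  connectivity_matrix(h, "HOFC", z$region_labels)
}

# vectorized profile correlation with entries i and j removed from both
# rows; relies on diag(zm) == 0 so cross-products need no correction
hofc_both <- function(zm) {
  p <- ncol(zm)
  np <- p - 2
  cross <- zm %*% t(zm)           # sum_k z_ik z_jk over all k
  rs <- rowSums(zm)
  rss <- rowSums(zm^2)
  sum_a <- outer(rs, rep(1, p)) - zm    # rs[i] - z[i,j]  (z[i,i] = 0)
  sum_b <- t(sum_a)
  sum_aa <- outer(rss, rep(1, p)) - zm^2
  sum_bb <- t(sum_aa)
  num <- np * cross - sum_a * sum_b
  var_a <- np * sum_aa - sum_a^2
  var_b <- np * sum_bb - sum_b^2
  den <- sqrt(pmax(var_a, 0) * pmax(var_b, 0))
  h <- matrix(0, p, p)
  ok <- den > np * 1e-14
  h[ok] <- num[ok] / den[ok]
  h <- (h + t(h)) / 2
  diag(h) <- 0
  attr(h, "n_constant") <- sum(!ok[upper.tri(ok)])  # degenerate pairs
  h
}

#' Write / read a matrix in BrainNet Viewer `.edge` format
#'
#' Whitespace-delimited P x P table, no header.
#'
#' @param m numeric matrix or `connectivity_matrix`.
#' @param path output file.
#' @return `path` invisibly (`write_edge_matrix`); numeric matrix
#'   (`read_edge_matrix`).
#' @export
write_edge_matrix <- function(m, path) {
  v <- if (inherits(m, "connectivity_matrix")) m$values else m
  utils::write.table(format(v, digits = 17, trim = TRUE, scientific = FALSE),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_matrix
#' @export
read_edge_matrix <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}
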