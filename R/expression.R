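#' Detection filter: minimum reads-per-million in a minimum number of libraries
#'
#' Retains transcripts with RPM strictly greater than `min_rpm` in at least
#' `min_libraries` libraries, where `RPM = count / (library_total / 1e6)` and
#' the library total is the number of aligned reads (not the filtered column
#' sum).  Row order is preserved; the filter is idempotent.
#'
#' @param counts integer count matrix, transcripts x libraries, with row and
#'   column names.
#' @param library_totals aligned-read totals per library; defaults to the
#'   column sums of `counts`.
#' @param min_rpm RPM threshold (strict inequality; default 1).
#' @param min_libraries minimum number of libraries exceeding the threshold
#'   (default 4).
#' @return The retained rows of `counts`.
#' @export
filter_low_abundance <- function(counts, library_totals = NULL,
                                 min_rpm = 1, min_libraries = 4) {
  counts <- as.matrix(counts)
  if (is.null(library_totals)) library_totals <- colSums(counts)
  if (any(library_totals <= 0)) stop("library totals must be positive")
  if (min_libraries > ncol(counts))
    stop("'min_libraries' exceeds the number of libraries")
  rpm <- sweep(counts, 2, library_totals / 1e6, "/")
  keep <- rowSums(rpm > min_rpm) >= min_libraries
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios library size factors
#'
#' The reference expression of a transcript is its geometric mean across
#' libraries (transcripts with any zero count are excluded); the size factor
#' of a library is the median across transcripts of the ratio of its count to
#' the reference.
#'
#' @inheritParams filter_low_abundance
#' @return Positive numeric vector of size factors, one per library.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use))
    stop("cannot estimate size factors: no transcript has nonzero counts ",
         "in every library")
  sf <- apply(log(counts[use, , drop = FALSE]) - loggeo[use], 2,
              stats::median)
  setNames(exp(sf), colnames(counts))
}

#' Log-transform size-corrected counts
#'
#' `value = log2(count / size_factor + pseudocount)`.
#'
#' @inheritParams filter_low_abundance
#' @param size_factors positive per-library factors from
#'   [estimate_size_factors()].
#' @param pseudocount added before taking logs (default 1).
#' @return Matrix of log2-scale normalized expression, same shape as
#'   `counts`.
#' @export
log_transform <- function(counts, size_factors, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (any(size_factors <= 0)) stop("size factors must be positive")
  if (length(size_factors) != ncol(counts))
    stop("need one size factor per library")
  log2(sweep(counts, 2, size_factors, "/") + pseudocount)
}

#' Filter, size-correct and log-transform a count matrix
#'
#' Convenience wrapper: detection filter, median-of-ratios size factors on
#' the filtered matrix, then log2 transform.
#'
#' @inheritParams filter_low_abundance
#' @inheritParams log_transform
#' @return A list with `expr` (log2 expression matrix), `size_factors`, and
#'   `counts` (the filtered count matrix).
#' @export
normalize_counts <- function(counts, library_totals = NULL, min_rpm = 1,
                             min_libraries = 4, pseudocount = 1) {
  filtered <- filter_low_abundance(counts, library_totals, min_rpm,
                                   min_libraries)
  sf <- estimate_size_factors(filtered)
  list(expr = log_transform(filtered, sf, pseudocount),
       size_factors = sf, counts = filtered)
}

#' Kolmogorov-Smirnov normality QC of log expression
#'
#' Per transcript, standardizes the values (estimated mean and SD) and tests
#' them against the standard normal with a one-sample KS test.  Because the
#' parameters are estimated, the test is conservative; this QC is advisory,
#' not gating.  Zero-variance transcripts are flagged as degenerate and
#' excluded from the passing fraction's denominator.
#'
#' @param expr log-scale expression matrix, transcripts x libraries (at
#'   least 8 libraries).
#' @param alpha p-value above which a transcript counts as passing
#'   (default 0.05).
#' @return A list with `p` (per-transcript KS p, `NA` for degenerate rows),
#'   `passing_fraction`, and `degenerate` (logical vector).
#' @export
normality_qc <- function(expr, alpha = 0.05) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 8) stop("need at least 8 libraries for normality QC")
  sds <- apply(expr, 1, stats::sd)
  degenerate <- sds == 0 | !is.finite(sds)
  p <- rep(NA_real_, nrow(expr))
  for (i in which(!degenerate)) {
    z <- (expr[i, ] - mean(expr[i, ])) / sds[i]
    p[i] <- suppressWarnings(stats::ks.test(z, "pnorm")$p.value)
  }
  list(p = setNames(p, rownames(expr)),
       passing_fraction = mean(p[!degenerate] > alpha),
       degenerate = setNames(degenerate, rownames(expr)))
}
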