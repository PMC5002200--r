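#' REML variance components of one transcript's expression
#'
#' Fits a grand-mean linear random-effects model with crossed random
#' intercepts for TREE, SITE, PROVENANCE and DATE by REML and extracts the
#' variance component of each factor plus the residual variance.  Factors
#' with fewer than two observed levels carry no variance and are recorded as
#' zero.  Two-level factors (SITE, PROVENANCE) are deliberately kept as
#' random effects despite their weak identifiability; boundary estimates at
#' zero are reported, not suppressed.
#'
#' @param y per-library expression vector (log scale).
#' @param samples sample table with columns `TREE`, `SITE`, `PROVENANCE`,
#'   `DATE` (one row per library, same order as `y`).
#' @param factors which factors to include (default all four).
#' @return A list of class `plast_varcomp`: `sigma2` (named, one entry per
#'   requested factor), `sigma2_resid`, `converged`, `loglik_reml`.
#' @export
fit_variance_components <- function(y, samples,
                                    factors = c("TREE", "SITE",
                                                "PROVENANCE", "DATE")) {
  stopifnot(all(factors %in% names(samples)))
  d <- data.frame(y = y, lapply(samples[factors], factor))
  active <- factors[vapply(d[factors], nlevels, 0L) >= 2]
  if (length(active) == 0)
    stop("no factor has at least 2 levels; nothing to decompose")
  form <- stats::as.formula(paste(
    "y ~ 1 +", paste(sprintf("(1 | %s)", active), collapse = " + ")))
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(
                      calc.derivs = FALSE,
                      check.nobs.vs.nlev = "ignore",
                      check.nobs.vs.rankZ = "ignore",
                      check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2 <- setNames(rep(0, length(factors)), factors)
  for (f in active)
    sigma2[f] <- vc$vcov[vc$grp == f]
  structure(list(
    sigma2 = sigma2,
    sigma2_resid = vc$vcov[vc$grp == "Residual"],
    converged = length(fit@optinfo$conv$lme4) == 0,
    loglik_reml = as.numeric(stats::logLik(fit))
  ), class = "plast_varcomp")
}

#' Variance proportions from a variance-components fit
#'
#' Each component is divided by the sum of all variance components plus the
#' residual variance, so the proportions (including the residual) sum to 1.
#'
#' @param vc a `plast_varcomp` object.
#' @return Named vector of proportions for each factor plus `residual`.
#' @export
variance_proportions <- function(vc) {
  stopifnot(inherits(vc, "plast_varcomp"))
  tot <- sum(vc$sigma2) + vc$sigma2_resid
  if (tot <= 0) stop("all variance components are zero; proportions undefined")
  c(vc$sigma2, residual = vc$sigma2_resid) / tot
}

#' Variance decomposition across a whole expression matrix
#'
#' Runs [fit_variance_components()] on every transcript and returns the
#' per-transcript variance proportions.  Fits are independent across
#' transcripts, so results do not depend on row order.
#'
#' @param expr log-scale expression matrix, transcripts x libraries.
#' @param samples sample table (see [fit_variance_components()]).
#' @inheritParams fit_variance_components
#' @return A data.frame with one row per transcript: proportions per factor,
#'   `residual`, and a `converged` flag.
#' @export
decompose_variance <- function(expr, samples,
                               factors = c("TREE", "SITE",
                                           "PROVENANCE", "DATE")) {
  expr <- .as_expr_matrix(expr)
  rows <- lapply(seq_len(nrow(expr)), function(i) {
    vc <- fit_variance_components(expr[i, ], samples, factors)
    pr <- variance_proportions(vc)
    data.frame(transcript_id = rownames(expr)[i], t(pr),
               converged = vc$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
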