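#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment across a vector of p-values (one vector
#' per tested term, across transcripts).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Build a fixed-effects model matrix from term names over the per-library
# data.  Factors: DATE (site-specific sampling date level), PROVENANCE.
# Continuous: TAW, TEMPERATURE, DAYLENGTH.  Dummy coding uses the
# alphabetically first level as reference (R default for factors).
.build_design <- function(terms, data) {
  if (length(terms) == 0L) {
    X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
    return(X)
  }
  stats::model.matrix(stats::reformulate(terms), data = data)
}

.model_data <- function(samples, regressors = NULL) {
  d <- data.frame(
    TREE = factor(samples$TREE),
    PROVENANCE = factor(samples$PROVENANCE),
    DATE = factor(samples$DATE),
    row.names = NULL
  )
  if (!is.null(regressors)) {
    i <- match(samples$library_id, regressors$library_id)
    if (anyNA(i))
      stop("regressor table is missing libraries: ",
           paste(samples$library_id[is.na(i)], collapse = ", "))
    d$TAW <- regressors$TAW[i]
    d$TEMPERATURE <- regressors$TEMPERATURE[i]
    d$DAYLENGTH <- regressors$DAYLENGTH[i]
  }
  d
}

# Drop aliased columns (e.g. interaction cells emptied by missingness),
# warning once; errors only if a tested term vanishes entirely.
.drop_aliased <- function(X) {
  qrX <- qr(X)
  if (qrX$rank == ncol(X)) return(X)
  aliased <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
  warning("dropping aliased design columns: ",
          paste(aliased, collapse = ", "), call. = FALSE)
  X[, setdiff(colnames(X), aliased), drop = FALSE]
}

# Restriction matrix selecting the full-model columns absent from the
# reduced design.
.drop_L <- function(cn_full, cn_red) {
  dropped <- setdiff(cn_full, cn_red)
  L <- matrix(0, length(dropped), length(cn_full),
              dimnames = list(dropped, cn_full))
  L[cbind(seq_along(dropped), match(dropped, cn_full))] <- 1
  L
}

# One nested comparison given precomputed preps and (optionally) cached full
# fits; returns the per-term statistics row.
.compare_prepped <- function(y, prep_full, prep_red, fullR = NULL,
                             fullM = NULL, adj = NULL, slope_term = NULL) {
  if (is.null(fullR)) fullR <- .lmm_fit(prep_full, y, reml = TRUE)
  if (is.null(fullM)) fullM <- .lmm_fit(prep_full, y, reml = FALSE)
  if (is.null(adj)) adj <- .kr_adjust(fullR)
  redR <- .lmm_fit(prep_red, y, reml = TRUE)
  redM <- .lmm_fit(prep_red, y, reml = FALSE)
  L <- .drop_L(colnames(prep_full$X), colnames(prep_red$X))
  kt <- .kr_test(adj, L)
  slope_sign <- NA_character_
  if (!is.null(slope_term) && slope_term %in% names(fullR$beta))
    slope_sign <- if (fullR$beta[[slope_term]] >= 0) "+" else "-"
  data.frame(
    F = kt$F, ndf = kt$ndf, ddf = kt$ddf, p = kt$p,
    dAIC = redM$aic - fullM$aic,
    dR2 = marginal_r2(fullR) - marginal_r2(redR),
    slope_sign = slope_sign,
    stringsAsFactors = FALSE
  )
}

#' Compare nested mixed models for one transcript
#'
#' Fits the full model and the model without `dropped_term` (both with a TREE
#' random intercept), tests the dropped coefficients with a Kenward-Roger
#' F-test, and reports the AIC difference (from ML refits; REML likelihoods
#' are not comparable across fixed-effect structures), the marginal
#' R-squared difference, and the slope sign for continuous terms.
#'
#' @param y expression vector for one transcript (libraries in the order of
#'   `samples`).
#' @param full_terms character vector of fixed-effect terms, e.g.
#'   `c("TAW", "TEMPERATURE", "DAYLENGTH", "PROVENANCE")`.
#' @param dropped_term the term to test (must be in `full_terms`).
#' @param samples sample table with columns `library_id`, `TREE`,
#'   `PROVENANCE`, `SITE`, `DATE`.
#' @param regressors regressor table from [assemble_regressors()]; required
#'   when `full_terms` contains continuous regressors.
#' @return A one-row data.frame with `F`, `ndf`, `ddf`, `p`, `dAIC`
#'   (`AIC(reduced) - AIC(full)`), `dR2` and `slope_sign`.
#' @export
compare_nested <- function(y, full_terms, dropped_term, samples,
                           regressors = NULL) {
  if (!dropped_term %in% full_terms)
    stop("'", dropped_term, "' is not among the full-model terms")
  d <- .model_data(samples, regressors)
  X_full <- .drop_aliased(.build_design(full_terms, d))
  X_red <- .drop_aliased(.build_design(setdiff(full_terms, dropped_term), d))
  if (!length(setdiff(colnames(X_full), colnames(X_red))))
    stop("term '", dropped_term, "' has no estimable coefficients")
  slope_term <- if (dropped_term %in% c("TAW", "TEMPERATURE", "DAYLENGTH"))
    dropped_term else NULL
  cbind(term = dropped_term,
        .compare_prepped(y, lmm_prep(X_full, d$TREE), lmm_prep(X_red, d$TREE),
                         slope_term = slope_term),
        stringsAsFactors = FALSE)
}

# Shared driver: per transcript fit the full model once (REML + ML + KR
# adjustment), then run each drop-one comparison; BH-adjust per term.
.run_family <- function(expr, d, full_terms, tests, fdr, dr2,
                        gate_terms = character()) {
  X_full <- .drop_aliased(.build_design(full_terms, d))
  prep_full <- lmm_prep(X_full, d$TREE)
  preps_red <- lapply(tests, function(te) {
    X_red <- .drop_aliased(.build_design(te$reduced_terms, d))
    if (!length(setdiff(colnames(X_full), colnames(X_red))))
      stop("term '", te$term, "' has no estimable coefficients")
    lmm_prep(X_red, d$TREE)
  })
  ids <- rownames(expr)
  rows <- vector("list", nrow(expr) * length(tests))
  k <- 0L
  for (i in seq_len(nrow(expr))) {
    y <- expr[i, ]
    fullR <- .lmm_fit(prep_full, y, reml = TRUE)
    fullM <- .lmm_fit(prep_full, y, reml = FALSE)
    adj <- .kr_adjust(fullR)
    for (t_i in seq_along(tests)) {
      te <- tests[[t_i]]
      res <- .compare_prepped(y, prep_full, preps_red[[t_i]], fullR, fullM,
                              adj, slope_term = te$slope_term)
      k <- k + 1L
      rows[[k]] <- cbind(transcript_id = ids[i], term = te$term, res,
                         stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$term, vapply(tests, `[[`, "", "term")),
                   out$transcript_id), , drop = FALSE]
  out$q <- NA_real_
  for (te in tests) {
    sel <- out$term == te$term
    out$q[sel] <- bh_adjust(out$p[sel])
  }
  out$responder <- out$q < fdr &
    (!(out$term %in% gate_terms) | out$dR2 > dr2)
  rownames(out) <- NULL
  out
}

#' Differential expression across sampling dates and provenances
#'
#' Per transcript, the provenance-by-date interaction is tested by comparing
#' `DATE + PROVENANCE + DATE:PROVENANCE` against `DATE + PROVENANCE`; the
#' interaction is then removed and `DATE` and `PROVENANCE` main effects are
#' each tested by dropping them from the additive model.  All models carry a
#' TREE random intercept; p-values are BH-adjusted per term across
#' transcripts and a transcript is a responder for a term when `q < fdr`.
#'
#' @param expr matrix of log-scale expression, transcripts x libraries
#'   (column order must match `samples`).
#' @param samples sample table (`library_id`, `TREE`, `PROVENANCE`, `SITE`,
#'   `DATE`).
#' @param fdr FDR threshold for the responder call (default 0.01).
#' @return A long data.frame: one row per transcript x term
#'   (`DATE:PROVENANCE`, `DATE`, `PROVENANCE`) with test statistics, `q`,
#'   `dAIC`, `dR2` and the responder flag.
#' @export
run_date_provenance <- function(expr, samples, fdr = 0.01) {
  d <- .model_data(samples)
  if (nlevels(d$DATE) < 2 || nlevels(d$PROVENANCE) < 2)
    stop("need at least 2 DATE levels and 2 provenances")
  expr <- .as_expr_matrix(expr)
  inter <- .run_family(
    expr, d, c("DATE", "PROVENANCE", "DATE:PROVENANCE"),
    list(list(term = "DATE:PROVENANCE",
              reduced_terms = c("DATE", "PROVENANCE"), slope_term = NULL)),
    fdr = fdr, dr2 = Inf)
  mains <- .run_family(
    expr, d, c("DATE", "PROVENANCE"),
    list(list(term = "DATE", reduced_terms = "PROVENANCE", slope_term = NULL),
         list(term = "PROVENANCE", reduced_terms = "DATE", slope_term = NULL)),
    fdr = fdr, dr2 = Inf)
  rbind(inter, mains)
}

#' Differential expression against environmental regressors
#'
#' Drop-one comparisons against the full model
#' `TAW + TEMPERATURE + DAYLENGTH + PROVENANCE` (TREE random intercept).
#' Environmental responders must pass both the FDR gate (`q < fdr`) and the
#' effect-size gate (`dR2 > dr2`); `PROVENANCE` is tested within the same
#' model family with the FDR gate only.  Slope signs are taken from the full
#' model's coefficient.
#'
#' Regressors are first checked for multicollinearity; the run refuses to
#' proceed if any variance inflation factor exceeds `vif_limit` (the rule
#' that excluded SITE from this model family).
#'
#' @inheritParams run_date_provenance
#' @param regressors regressor table from [assemble_regressors()].
#' @param dr2 marginal R-squared gate for environmental terms (default 0.2).
#' @param vif_limit refuse to fit when any regressor VIF exceeds this.
#' @return Long data.frame, one row per transcript x term (`TAW`,
#'   `TEMPERATURE`, `DAYLENGTH`, `PROVENANCE`).
#' @export
run_environment <- function(expr, samples, regressors, fdr = 0.01,
                            dr2 = 0.2, vif_limit = 10) {
  d <- .model_data(samples, regressors)
  Xv <- cbind(TAW = d$TAW, TEMPERATURE = d$TEMPERATURE,
              DAYLENGTH = d$DAYLENGTH,
              PROVENANCE = as.numeric(d$PROVENANCE != levels(d$PROVENANCE)[1]))
  vif <- variance_inflation(Xv)
  if (any(vif > vif_limit))
    stop("collinear regressors (VIF > ", vif_limit, "): ",
         paste(names(vif)[vif > vif_limit], collapse = ", "),
         "; refusing to fit the environmental model family")
  expr <- .as_expr_matrix(expr)
  env_terms <- c("TAW", "TEMPERATURE", "DAYLENGTH")
  full_terms <- c(env_terms, "PROVENANCE")
  # with two provenances the dummy coefficient sign gives the direction
  # (positive = higher in the non-reference provenance)
  prov_dummy <- if (nlevels(d$PROVENANCE) == 2)
    paste0("PROVENANCE", levels(d$PROVENANCE)[2]) else NULL
  tests <- lapply(full_terms, function(te)
    list(term = te, reduced_terms = setdiff(full_terms, te),
         slope_term = if (te %in% env_terms) te else prov_dummy))
  .run_family(expr, d, full_terms, tests, fdr = fdr, dr2 = dr2,
              gate_terms = env_terms)
}

.as_expr_matrix <- function(expr) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)))
    rownames(expr) <- sprintf("PUT%05d", seq_len(nrow(expr)))
  expr
}

#' Extract responder transcript sets by regressor and direction
#'
#' @param de long results from [run_environment()].
#' @return Named list of transcript-id vectors, e.g. `TAW_up`, `TAW_down`,
#'   ..., `PROVENANCE_up`, `PROVENANCE_down` (for PROVENANCE, "up" means
#'   higher in the non-reference provenance, i.e. a positive dummy
#'   coefficient).
#' @export
responder_sets <- function(de) {
  sets <- list()
  for (te in unique(de$term)) {
    sub <- de[de$term == te & de$responder, , drop = FALSE]
    if (!anyNA(sub$slope_sign)) {
      sets[[paste0(te, "_up")]] <- sub$transcript_id[sub$slope_sign == "+"]
      sets[[paste0(te, "_down")]] <- sub$transcript_id[sub$slope_sign == "-"]
    } else {
      sets[[paste0(te, "_responders")]] <- sub$transcript_id
    }
  }
  sets
}
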