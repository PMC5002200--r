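#' One-sided Fisher overrepresentation test for one GO category
#'
#' Tests whether the study set (responder transcripts) is overrepresented in
#' a category, with the one-sided (greater) hypergeometric tail — identical
#' to the one-sided Fisher exact test on the 2x2 table.  Fold enrichment is
#' observed over expected: `observed / (|study| * |term| / |universe|)`.
#'
#' @param study character vector of study transcripts (subset of
#'   `universe`).
#' @param universe character vector of all eligible transcripts.
#' @param term_members transcripts annotated to the category (subset of
#'   `universe`).
#' @return A list with `p`, `fold`, `observed` and `expected`.
#' @export
fisher_overrep <- function(study, universe, term_members) {
  N <- length(unique(universe))
  if (N == 0) stop("empty universe")
  study <- intersect(study, universe)
  term_members <- intersect(term_members, universe)
  n <- length(study)
  K <- length(term_members)
  x <- length(intersect(study, term_members))
  p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  expected <- n * K / N
  list(p = p, fold = if (expected > 0) x / expected else NA_real_,
       observed = x, expected = expected)
}

#' Resampled GO overrepresentation over best-hit groups
#'
#' Assembled transcript sets contain redundant fragments of the same gene
#' (shared best hit), which inflates annotation counts.  Each repeat samples
#' exactly one transcript per best-hit group (uniformly; singleton groups
#' are kept deterministically), restricts study, universe and category
#' memberships to the sampled set, and runs the Fisher test for every
#' category and direction.  Per-category means of p, fold and observed count
#' over the repeats are reported, and significance is evaluated on the
#' means: `mean_p < alpha` and `mean_observed > min_observed`.
#'
#' @param responders named list of study sets, one per (regressor,
#'   direction), e.g. from [responder_sets()].
#' @param annotation propagated annotation (named list transcript -> term
#'   ids, closed under ancestors; see [propagate_annotations()]).
#' @param besthit named vector transcript -> best-hit group id; transcripts
#'   absent from it form their own singleton groups.
#' @param universe eligible transcripts; defaults to all annotated
#'   transcripts (unannotated ones cannot enter any table).
#' @param repeats number of resampling repeats (default 100).
#' @param seed integer seed for reproducibility.
#' @param alpha,min_observed significance rule on the means (defaults 0.01
#'   and 10; `min_observed` is a strict "more than" bound).
#' @return Data.frame of class `plast_enrichment`: `term_id`, `direction`,
#'   `mean_p`, `mean_fold`, `mean_observed`, `n_repeats`, `significant`.
#' @export
resampled_overrep <- function(responders, annotation, besthit = NULL,
                              universe = NULL, repeats = 100, seed = 1L,
                              alpha = 0.01, min_observed = 10) {
  if (is.null(universe)) universe <- names(annotation)
  universe <- unique(universe)
  universe <- universe[universe %in% names(annotation)]
  if (is.null(besthit)) besthit <- setNames(universe, universe)
  grp <- besthit[universe]
  grp[is.na(grp)] <- paste0(".singleton.", universe[is.na(grp)])
  groups <- split(universe, grp)
  multi <- groups[lengths(groups) > 1]
  fixed <- unlist(groups[lengths(groups) == 1], use.names = FALSE)
  # term -> member index over the universe
  ann <- annotation[universe]
  term_of <- split(rep(seq_along(universe), lengths(ann)),
                   unlist(ann, use.names = FALSE))
  terms <- names(term_of)
  resp_idx <- lapply(responders, function(s) match(intersect(s, universe),
                                                   universe))
  set.seed(seed)
  acc <- list()
  for (dn in names(responders))
    acc[[dn]] <- list(p = matrix(NA_real_, length(terms), repeats),
                      fold = matrix(NA_real_, length(terms), repeats),
                      obs = matrix(NA_real_, length(terms), repeats))
  for (r in seq_len(repeats)) {
    sampled <- c(fixed,
                 vapply(multi, function(g) g[sample.int(length(g), 1)], ""))
    in_s <- logical(length(universe))
    in_s[match(sampled, universe)] <- TRUE
    N <- sum(in_s)
    K <- vapply(term_of, function(ix) sum(in_s[ix]), 0L)
    for (dn in names(responders)) {
      st <- resp_idx[[dn]]
      is_resp <- logical(length(universe))
      is_resp[st] <- TRUE
      n_st <- sum(in_s[st])
      x <- vapply(term_of, function(ix)
        sum(in_s[ix] & is_resp[ix]), 0L)
      p <- stats::phyper(x - 1, K, N - K, n_st, lower.tail = FALSE)
      expd <- n_st * K / N
      acc[[dn]]$p[, r] <- p
      acc[[dn]]$fold[, r] <- ifelse(expd > 0, x / expd, NA_real_)
      acc[[dn]]$obs[, r] <- x
    }
  }
  out <- do.call(rbind, lapply(names(responders), function(dn) {
    data.frame(term_id = terms, direction = dn,
               mean_p = rowMeans(acc[[dn]]$p),
               mean_fold = rowMeans(acc[[dn]]$fold, na.rm = TRUE),
               mean_observed = rowMeans(acc[[dn]]$obs),
               n_repeats = repeats, stringsAsFactors = FALSE)
  }))
  out$mean_fold[is.nan(out$mean_fold)] <- NA_real_
  out$significant <- out$mean_p < alpha & out$mean_observed > min_observed
  rownames(out) <- NULL
  class(out) <- c("plast_enrichment", class(out))
  out
}

#' Select significant enrichment results
#'
#' Keeps categories with `mean_p < alpha` and strictly more than
#' `min_observed` responder transcripts (averaged over repeats).
#'
#' @param results output of [resampled_overrep()].
#' @param alpha p-value threshold (default 0.01).
#' @param min_observed strict lower bound on the mean responder count
#'   (default 10).
#' @return The significant subset of `results`.
#' @export
select_significant <- function(results, alpha = 0.01, min_observed = 10) {
  results[results$mean_p < alpha & results$mean_observed > min_observed, ,
          drop = FALSE]
}
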