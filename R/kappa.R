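#' Cohen's kappa between two binary membership vectors
#'
#' Chance-corrected agreement `kappa = (O - A) / (1 - A)` where `O` is the
#' fraction of transcripts on which the two category membership vectors
#' agree (both 1 or both 0) and `A` is the agreement expected by chance from
#' the marginal frequencies, `A = p_m1 p_n1 + p_m0 p_n0`.
#'
#' @param m,n binary (0/1 or logical) vectors of equal length.
#' @return A list with `O`, `A` and `kappa`.
#' @export
cohens_kappa <- function(m, n) {
  m <- as.numeric(m); n <- as.numeric(n)
  if (length(m) != length(n)) stop("membership vectors differ in length")
  if (!all(m %in% 0:1) || !all(n %in% 0:1))
    stop("membership vectors must be binary")
  O <- mean(m == n)
  pm <- mean(m); pn <- mean(n)
  A <- pm * pn + (1 - pm) * (1 - pn)
  if (A >= 1) stop("chance agreement is 1; kappa undefined")
  list(O = O, A = A, kappa = (O - A) / (1 - A))
}

#' Pairwise kappa matrix of GO categories
#'
#' @param membership binary matrix, categories x transcripts (rows named by
#'   term id).  The column space is typically the union of responder
#'   transcripts annotated to at least one significant category.
#' @return Symmetric matrix of kappa scores with unit diagonal.
#' @export
kappa_matrix <- function(membership) {
  membership <- as.matrix(membership)
  if (nrow(membership) < 2) stop("need at least 2 categories")
  k <- nrow(membership)
  K <- diag(1, k)
  dimnames(K) <- list(rownames(membership), rownames(membership))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    K[i, j] <- K[j, i] <-
      cohens_kappa(membership[i, ], membership[j, ])$kappa
  }
  K
}

#' Hierarchical clustering of GO categories on kappa profiles
#'
#' Categories are clustered on euclidean distances between the rows of the
#' kappa matrix (each category's vector of kappa scores against all
#' categories is its feature profile); `1 - kappa` as a direct distance is
#' available as an alternative.  Rows are sorted by term id before
#' clustering so the output is invariant to input order.
#'
#' @param kappa symmetric kappa matrix from [kappa_matrix()].
#' @param linkage agglomeration method, `"average"` (default) or
#'   `"complete"`.
#' @param distance `"profiles"` (euclidean on kappa rows, default) or
#'   `"one_minus_kappa"`.
#' @return A list with `hclust` (the merge tree), `order` (leaf labels in
#'   dendrogram order) and `heights`.
#' @export
cluster_categories <- function(kappa, linkage = c("average", "complete"),
                               distance = c("profiles", "one_minus_kappa")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  if (nrow(kappa) < 2) stop("need at least 2 categories to cluster")
  ord <- order(rownames(kappa))
  kappa <- kappa[ord, ord, drop = FALSE]
  d <- if (distance == "profiles") stats::dist(kappa)
       else stats::as.dist(1 - kappa)
  hc <- stats::hclust(d, method = linkage)
  hc$call <- NULL
  list(hclust = hc, order = rownames(kappa)[hc$order], heights = hc$height)
}

#' Write a category merge tree in Newick format
#'
#' @param clustering result of [cluster_categories()].
#' @param path output file.
#' @export
write_cluster_newick <- function(clustering, path) {
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Build the category membership matrix for kappa clustering
#'
#' @param terms term ids (significant categories).
#' @param annotation propagated annotation (transcript -> terms).
#' @param transcripts column space; defaults to all transcripts annotated to
#'   at least one of `terms`.
#' @return Binary matrix, `terms` x `transcripts`.
#' @export
membership_matrix <- function(terms, annotation, transcripts = NULL) {
  if (is.null(transcripts))
    transcripts <- names(annotation)[vapply(annotation, function(tt)
      any(tt %in% terms), logical(1))]
  M <- matrix(0L, length(terms), length(transcripts),
              dimnames = list(terms, transcripts))
  for (tx in transcripts)
    M[intersect(annotation[[tx]], terms), tx] <- 1L
  M
}
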