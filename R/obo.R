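#' Read a minimal OBO ontology (is_a relations)
#'
#' Parses `[Term]` stanzas for `id`, `name`, `namespace` and `is_a` lines.
#' Only is_a edges are kept; obsolete terms are skipped.  This covers what
#' GO overrepresentation needs (term identity and the is_a closure); no
#' installed package in this stack parses OBO, so the reader is deliberately
#' minimal.
#'
#' @param path path to an OBO file.
#' @return A `plast_ontology`: list with `terms` (data.frame `id`, `name`,
#'   `namespace`) and `parents` (named list id -> character vector of
#'   is_a parents).
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  terms <- list(); parents <- list()
  cur <- NULL
  flush <- function(cur) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
      terms[[length(terms) + 1L]] <<- data.frame(
        id = cur$id, name = cur$name %||% "",
        namespace = cur$namespace %||% "", stringsAsFactors = FALSE)
      parents[[cur$id]] <<- cur$is_a %||% character(0)
    }
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(cur); cur <- list(); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(cur); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || ln == "") next
    kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) next
    key <- kv[2]; val <- trimws(kv[3])
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a" && nzchar(val)) cur$is_a <- c(cur$is_a, val)
    else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
  }
  flush(cur)
  structure(list(terms = do.call(rbind, terms), parents = parents),
            class = "plast_ontology")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a minimal OBO file
#'
#' @param ontology a `plast_ontology`.
#' @param path output path.
#' @export
write_obo <- function(ontology, path) {
  stopifnot(inherits(ontology, "plast_ontology"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(ontology$terms))) {
    id <- ontology$terms$id[i]
    ps <- ontology$parents[[id]]
    writeLines(c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", ontology$terms$name[i]),
                 paste0("namespace: ", ontology$terms$namespace[i]),
                 if (length(ps)) paste0("is_a: ", ps),
                 ""), con)
  }
  invisible(path)
}

#' All is_a ancestors of every term
#'
#' @param ontology a `plast_ontology`.
#' @return Named list: term id -> character vector of all distinct ancestors
#'   (the term itself excluded).  Errors on a cyclic graph.
#' @export
term_ancestors <- function(ontology) {
  stopifnot(inherits(ontology, "plast_ontology"))
  memo <- new.env(parent = emptyenv())
  anc <- function(id, trail) {
    if (id %in% trail) stop("ontology is cyclic at term ", id)
    if (!is.null(memo[[id]])) return(memo[[id]])
    ps <- ontology$parents[[id]]
    res <- unique(c(ps, unlist(lapply(ps, anc, trail = c(trail, id)))))
    memo[[id]] <- res %||% character(0)
    memo[[id]]
  }
  setNames(lapply(ontology$terms$id, anc, trail = character(0)),
           ontology$terms$id)
}

#' Propagate annotations to all ancestors
#'
#' Annotates every transcript to the full is_a closure of its direct terms,
#' so a transcript counted in a category is counted in every parent
#' category.  Idempotent.
#'
#' @param mapping named list: transcript id -> character vector of term ids.
#' @param ontology a `plast_ontology` containing every mapped term.
#' @return Named list of the same shape, closed under ancestors.
#' @export
propagate_annotations <- function(mapping, ontology) {
  known <- ontology$terms$id
  offenders <- setdiff(unique(unlist(mapping)), known)
  if (length(offenders) > 0)
    stop("unknown ontology terms in annotation: ",
         paste(offenders, collapse = ", "))
  anc <- term_ancestors(ontology)
  lapply(mapping, function(tt)
    sort(unique(c(tt, unlist(anc[tt], use.names = FALSE)))))
}

#' Keep terms with enough parental terms
#'
#' Basal GO terms carry little information; this keeps only terms whose set
#' of distinct is_a ancestors has at least `min_parents` members (ancestors
#' are counted as a set, not per path).
#'
#' @param terms character vector of term ids.
#' @param ontology a `plast_ontology`.
#' @param min_parents minimum number of distinct ancestors (default 5).
#' @return The retained subset of `terms`, in input order.
#' @export
depth_filter <- function(terms, ontology, min_parents = 5) {
  anc <- term_ancestors(ontology)
  unknown <- setdiff(terms, names(anc))
  if (length(unknown) > 0)
    stop("unknown ontology terms: ", paste(unknown, collapse = ", "))
  terms[vapply(anc[terms], length, 0L) >= min_parents]
}
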