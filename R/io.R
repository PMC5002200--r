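#' Write a synthetic study as a plain-text fixture directory
#'
#' Emits counts (transcripts x libraries, first column `transcript_id`),
#' library totals, sample table, environment series, regressor table, the
#' GO annotation and best-hit mappings, the toy ontology in OBO format, and
#' the ground-truth tables.  All files are tab-separated text.
#'
#' @param study a `plast_study`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "plast_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(data.frame(transcript_id = rownames(study$counts), study$counts,
                 check.names = FALSE), "counts.tsv")
  tsv(data.frame(library_id = names(study$library_totals),
                 total = study$library_totals), "totals.tsv")
  tsv(study$samples, "samples.tsv")
  tsv(study$environment, "environment.tsv")
  tsv(study$regressors, "regressors.tsv")
  ann <- study$go$annotation
  tsv(data.frame(transcript_id = rep(names(ann), lengths(ann)),
                 term_id = unlist(ann, use.names = FALSE)),
      "go_annotation.tsv")
  tsv(data.frame(transcript_id = names(study$go$besthit),
                 group = study$go$besthit), "besthit.tsv")
  write_obo(study$go$ontology, file.path(dir, "ontology.obo"))
  tsv(data.frame(transcript_id = rownames(study$truth$slopes),
                 study$truth$slopes), "truth_slopes.tsv")
  tsv(study$go$enriched_truth, "truth_enriched.tsv")
  invisible(dir)
}

#' Read a count matrix from TSV
#'
#' Expects a header row of library ids and a first column of transcript ids.
#'
#' @param path counts TSV.
#' @return Integer matrix with dimnames.
#' @export
read_counts <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Read a sample table from TSV
#'
#' @param path samples TSV with columns `library_id`, `TREE`, `PROVENANCE`,
#'   `SITE`, `DATE` and optionally `date`.
#' @return A data.frame; `date` is parsed as `Date` when present.
#' @export
read_samples <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("date" %in% names(d)) d$date <- as.Date(d$date)
  d
}

#' Read an environment series from TSV
#'
#' @param path environment TSV with columns `site`, `date`,
#'   `daily_mean_temp`, `midday_temp`, `day_length`, `taw`.
#' @return A data.frame with `date` parsed as `Date`.
#' @export
read_environment <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$date <- as.Date(d$date)
  d
}

#' Read a two-column mapping TSV into a named list
#'
#' @param path TSV whose first column is the transcript id and second the
#'   term id (one pair per row).
#' @return Named list: transcript -> character vector of terms.
#' @export
read_annotation <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(d[[2]], d[[1]])
}
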