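#' Read a response matrix from CSV
#'
#' Expected layout: header \code{subject_id,item_1,...,item_m} with
#' integer cells (raw Likert codes are fine; \code{\link{grm}} maps
#' category codes by rank).
#'
#' @param path CSV file path.
#' @return integer matrix with subject ids as row names.
#' @export
read_responses_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  x <- as.matrix(df[-1])
  storage.mode(x) <- "integer"
  rownames(x) <- ids
  x
}

#' Write a response matrix to CSV
#' @param responses integer matrix (row names used as subject ids).
#' @param path output path.
#' @export
write_responses_csv <- function(responses, path) {
  ids <- rownames(responses)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(responses)))
  cn <- colnames(responses)
  if (is.null(cn)) cn <- paste0("item_", seq_len(ncol(responses)))
  df <- data.frame(subject_id = ids, responses, row.names = NULL)
  names(df) <- c("subject_id", cn)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Read binary labels from CSV (columns subject_id, label)
#' @param path CSV file path.
#' @return factor of low/high labels named by subject id.
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path)
  stats::setNames(as_label(df$label), as.character(df$subject_id))
}

#' Write labels to CSV
#' @param labels low/high labels (names used as subject ids).
#' @param path output path.
#' @export
write_labels_csv <- function(labels, path) {
  ids <- names(labels)
  if (is.null(ids)) ids <- paste0("S", seq_along(labels))
  utils::write.csv(data.frame(subject_id = ids,
                              label = as.character(as_label(labels))),
                   path, row.names = FALSE)
}

#' Read a per-subject corpus from JSONL
#'
#' One JSON record per line: \code{{"subject_id": ..., "source": ...,
#' "text": ...}}. Multiple records per subject are concatenated with a
#' space.
#'
#' @param path JSONL file path.
#' @param ids optional subject-id order to enforce (subjects without any
#'   record get an empty document).
#' @return named character vector of documents.
#' @export
read_corpus_jsonl <- function(path, ids = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  sid <- vapply(recs, function(r) as.character(r$subject_id), character(1))
  txt <- vapply(recs, function(r) as.character(r$text), character(1))
  agg <- tapply(txt, sid, paste, collapse = " ")
  if (is.null(ids)) return(stats::setNames(as.character(agg), names(agg)))
  out <- stats::setNames(rep("", length(ids)), ids)
  hit <- intersect(ids, names(agg))
  out[hit] <- agg[hit]
  out
}

#' Write a per-subject corpus to JSONL
#' @param texts character vector of documents.
#' @param ids subject ids.
#' @param source source tag stored in each record.
#' @param path output path.
#' @export
write_corpus_jsonl <- function(texts, ids, source, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(texts)) {
    writeLines(jsonlite::toJSON(list(subject_id = ids[i], source = source,
                                     text = texts[i]), auto_unbox = TRUE),
               con)
  }
  invisible(path)
}
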