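#' Load a tokenized corpus from disk
#'
#' Two plain-text dialects are supported:
#' \describe{
#'   \item{jsonl}{one JSON object per line with keys `id`, `label` and
#'     `tokens` (array of strings).}
#'   \item{tsv}{three tab-separated UTF-8 columns: id, label,
#'     space-joined tokens.}
#' }
#'
#' @param path file path
#' @param format `"jsonl"` or `"tsv"`
#' @return a validated [corpus()]; class order is first-appearance order
#' @export
load_corpus <- function(path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  abort_if(!file.exists(path), "file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  abort_if(length(lines) == 0L, "empty corpus file: %s", path)
  if (format == "jsonl") {
    recs <- lapply(lines, jsonlite::fromJSON)
    bad <- which(vapply(recs, function(r)
      is.null(r$id) || is.null(r$label) || is.null(r$tokens), logical(1)))
    abort_if(length(bad) > 0L,
             "record(s) missing id/label/tokens at line(s): %s",
             paste(bad, collapse = ", "))
    corpus(ids = vapply(recs, function(r) as.character(r$id), character(1)),
           tokens = lapply(recs, function(r) as.character(r$tokens)),
           labels = vapply(recs, function(r) as.character(r$label), character(1)))
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    abort_if(any(lengths(parts) != 3L),
             "tsv line(s) without exactly 3 columns at line(s): %s",
             paste(which(lengths(parts) != 3L), collapse = ", "))
    corpus(ids = vapply(parts, `[`, character(1), 1L),
           tokens = lapply(parts, function(p) strsplit(p[3L], " ", fixed = TRUE)[[1L]]),
           labels = vapply(parts, `[`, character(1), 2L))
  }
}

#' Write a corpus as JSON lines
#'
#' Emits the same `id` / `label` / `tokens` dialect that [load_corpus()]
#' reads, one document per line.
#'
#' @param x a `corpus`
#' @param path output file path
#' @return `path` invisibly
#' @export
write_corpus_jsonl <- function(x, path) {
  stopifnot(inherits(x, "corpus"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(x$ids)) {
    writeLines(jsonlite::toJSON(
      list(id = x$ids[i], label = x$labels[i], tokens = x$tokens[[i]]),
      auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read a word-embedding table in word2vec text format
#'
#' Expects a header line `"<count> <dim>"` followed by one line per token:
#' the token then `dim` whitespace-separated floats. Zero-norm vectors are
#' rejected because cosine similarity is undefined for them.
#'
#' @param path file path
#' @return an [embedding_table()]
#' @export
read_word2vec <- function(path) {
  abort_if(!file.exists(path), "file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  header <- scan(text = lines[1L], what = numeric(), quiet = TRUE)
  abort_if(length(header) != 2L, "malformed word2vec header: %s", lines[1L])
  n <- as.integer(header[1L]); d <- as.integer(header[2L])
  body <- lines[-1L]
  abort_if(length(body) != n, "header promises %d vectors, file has %d",
           n, length(body))
  parts <- strsplit(body, "[ \t]+")
  abort_if(any(lengths(parts) != d + 1L),
           "vector line(s) with wrong dimension at line(s): %s",
           paste(1L + which(lengths(parts) != d + 1L), collapse = ", "))
  toks <- vapply(parts, `[`, character(1), 1L)
  mat <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
  rownames(mat) <- toks
  embedding_table(mat)
}

#' Write an embedding table in word2vec text format
#'
#' @param emb an [embedding_table()]
#' @param path output file path
#' @return `path` invisibly
#' @export
write_word2vec <- function(emb, path) {
  stopifnot(inherits(emb, "embedding_table"))
  m <- emb$vectors
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  writeLines(paste(rownames(m),
                   apply(m, 1L, function(v) paste(format(v, scientific = FALSE,
                                                         trim = TRUE), collapse = " "))),
             con)
  invisible(path)
}

#' Export a selected feature set as TSV
#'
#' Columns: class, feature, chi-square score — one row per selected feature,
#' for inspection of what the expansion step will emphasize.
#'
#' @param fs a [select_features()] result
#' @param path output file path
#' @return `path` invisibly
#' @export
write_feature_set <- function(fs, path) {
  stopifnot(inherits(fs, "selected_features"))
  utils::write.table(fs$table[, c("class", "feature", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Export a learning curve as long-format CSV
#'
#' Columns: method, scope, run, proportion, macro_f1.
#'
#' @param curve a [run_learning_curve()] result
#' @param path output file path
#' @param method label written in the `method` column
#' @return `path` invisibly
#' @export
write_curve_csv <- function(curve, path, method = "method") {
  utils::write.csv(as.data.frame(curve, method = method), path,
                   row.names = FALSE)
  invisible(path)
}
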