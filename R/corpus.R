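#' Construct a single-label tokenized corpus
#'
#' A corpus is the unit of all splitting and evaluation: a collection of
#' documents, each a non-empty token sequence carrying exactly one class
#' label (e.g. one patient record labeled with one disease).
#'
#' @param ids character vector of unique document identifiers
#' @param tokens list of character vectors, one per document, each non-empty
#' @param labels character vector of class labels, one per document
#' @param classes optional character vector fixing class order; defaults to
#'   first-appearance order of `labels`. Every label must be contained in it.
#' @return an object of class `corpus` with fields `ids`, `tokens`, `labels`,
#'   `classes`
#' @export
corpus <- function(ids, tokens, labels, classes = NULL) {
  ids <- as.character(ids)
  labels <- as.character(labels)
  abort_if(length(ids) != length(tokens) || length(ids) != length(labels),
           "ids, tokens and labels must have equal length")
  abort_if(length(ids) == 0L, "corpus must contain at least one document")
  dup <- ids[duplicated(ids)]
  abort_if(length(dup) > 0L, "duplicate document id(s): %s",
           paste(unique(dup), collapse = ", "))
  n_tok <- lengths(tokens)
  abort_if(any(n_tok == 0L), "document(s) with empty token list: %s",
           paste(ids[n_tok == 0L], collapse = ", "))
  if (is.null(classes)) {
    classes <- unique(labels)
  } else {
    classes <- as.character(classes)
    missing_cls <- setdiff(labels, classes)
    abort_if(length(missing_cls) > 0L,
             "label(s) not in supplied class set: %s",
             paste(unique(missing_cls), collapse = ", "))
    classes <- classes[classes %in% labels]  # every class must have >= 1 doc
  }
  structure(
    list(ids = ids, tokens = lapply(tokens, as.character),
         labels = labels, classes = classes),
    class = "corpus"
  )
}

#' Number of documents in a corpus
#' @param x a `corpus`
#' @return integer count
#' @export
n_docs <- function(x) {
  stopifnot(inherits(x, "corpus"))
  length(x$ids)
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d documents, %d classes, median length %d tokens\n",
              n_docs(x), length(x$classes),
              as.integer(stats::median(lengths(x$tokens)))))
  invisible(x)
}

#' Validate corpus invariants
#'
#' Checks id uniqueness, non-empty token lists, label/class consistency and
#' (optionally) the minimum class size required by stratified splitting.
#'
#' @param x a `corpus`
#' @param min_class_size smallest admissible number of documents per class
#'   (default 1; the learning-curve harness requires 2)
#' @return `x` invisibly; errors describe the offending document or class
#' @export
validate_corpus <- function(x, min_class_size = 1L) {
  abort_if(!inherits(x, "corpus"), "not a corpus object")
  corpus(x$ids, x$tokens, x$labels, classes = x$classes)  # re-run construction checks
  counts <- class_counts(x)
  small <- names(counts)[counts < min_class_size]
  abort_if(length(small) > 0L,
           "class(es) with fewer than %d document(s): %s (merge or drop them first)",
           min_class_size, paste(small, collapse = ", "))
  invisible(x)
}

# document counts per class, in class order
class_counts <- function(x) {
  cnt <- table(factor(x$labels, levels = x$classes))
  stats::setNames(as.integer(cnt), x$classes)
}

#' Class prevalence
#'
#' Fraction of corpus documents bearing each class label. A class present in
#' 2 of 10,000 records has prevalence 2e-4 (0.02%), the cutoff used for
#' "statistically rare" diseases.
#'
#' @param x a `corpus`
#' @return named numeric vector over `x$classes`, summing to 1
#' @export
class_prevalence <- function(x) {
  cnt <- class_counts(x)
  cnt / n_docs(x)
}

#' Rare-class subset
#'
#' Classes whose prevalence is at or below `threshold` (inclusive), e.g.
#' `threshold = 2e-4` selects diseases seen in no more than 2 of 10,000
#' records.
#'
#' @param x a `corpus`
#' @param threshold positive prevalence cutoff
#' @return character vector of class names (possibly empty), in class order
#' @export
rare_subset <- function(x, threshold = 2e-4) {
  abort_if(!is_scalar_number(threshold) || threshold <= 0,
           "threshold must be a positive number")
  prev <- class_prevalence(x)
  names(prev)[prev <= threshold]
}

# subset a corpus to a set of document ids, preserving document order and
# the parent class order (restricted to classes that remain present)
subset_corpus <- function(x, keep_ids) {
  sel <- x$ids %in% keep_ids
  corpus(x$ids[sel], x$tokens[sel], x$labels[sel],
         classes = x$classes)
}

#' Split plan for the learning-curve protocol
#'
#' @param test_fraction fraction of each class held out for test, in (0,1)
#' @param proportions strictly increasing training proportions ending at 1
#' @param n_runs number of independent resplits to average over
#' @param seed master seed; all runs derive their randomness from it
#' @return an object of class `split_plan`
#' @export
split_plan <- function(test_fraction = 0.2,
                       proportions = seq(0.1, 1, by = 0.1),
                       n_runs = 10L, seed = 1L) {
  abort_if(!is_scalar_number(test_fraction) || test_fraction <= 0 ||
             test_fraction >= 1, "test_fraction must lie in (0,1)")
  abort_if(length(proportions) < 1L || any(diff(proportions) <= 0) ||
             any(proportions <= 0) || abs(proportions[length(proportions)] - 1) > 1e-12,
           "proportions must be strictly increasing, in (0,1], and end at 1")
  abort_if(n_runs < 1L, "n_runs must be positive")
  structure(list(test_fraction = test_fraction, proportions = proportions,
                 n_runs = as.integer(n_runs), seed = as.integer(seed)),
            class = "split_plan")
}

#' Per-class stratified train/test split
#'
#' Shuffles each class independently with a child seed derived from `seed`
#' and the class index, then sends `ceiling((1 - test_fraction) * n_c)`
#' documents to training — but always at least one document to each side, so
#' every class appears in both training and test. Classes with a single
#' document cannot satisfy this and raise an error naming the class.
#'
#' @param x a `corpus`; every class must have at least 2 documents
#' @param test_fraction fraction held out, in (0,1)
#' @param seed integer seed; the same seed reproduces the same partition
#' @return list with `train` and `test` corpora forming a disjoint partition
#' @export
stratified_split <- function(x, test_fraction = 0.2, seed = 1L) {
  validate_corpus(x)
  counts <- class_counts(x)
  singletons <- names(counts)[counts < 2L]
  abort_if(length(singletons) > 0L,
           "class(es) with a single document cannot be split: %s",
           paste(singletons, collapse = ", "))
  train_ids <- character(0)
  for (ci in seq_along(x$classes)) {
    cls <- x$classes[ci]
    ids_c <- x$ids[x$labels == cls]
    n_c <- length(ids_c)
    set.seed(mix_seed(seed, ci))
    perm <- sample.int(n_c)
    n_train <- ceiling((1 - test_fraction) * n_c)
    n_train <- min(max(n_train, 1L), n_c - 1L)  # one doc forced to each side
    train_ids <- c(train_ids, ids_c[perm[seq_len(n_train)]])
  }
  list(train = subset_corpus(x, train_ids),
       test = subset_corpus(x, setdiff(x$ids, train_ids)))
}

#' Nested per-class training subsamples
#'
#' One seeded shuffle per class; the subset at proportion `p` takes the first
#' `ceiling(p * n_c)` shuffled documents of each class (at least 1), so the
#' subsets are nested (`subset_i` is contained in `subset_j` for `p_i < p_j`)
#' and the final subset equals the full training corpus. Nesting makes the
#' learning curve monotone in expectation and keeps one run comparable across
#' proportions.
#'
#' @param train training `corpus`
#' @param proportions strictly increasing proportions in (0,1] ending at 1
#' @param seed integer seed for the per-class shuffles
#' @return list of corpora, one per proportion
#' @export
nested_subsample <- function(train, proportions, seed = 1L) {
  abort_if(length(proportions) < 1L || any(diff(proportions) <= 0) ||
             any(proportions <= 0) || abs(proportions[length(proportions)] - 1) > 1e-12,
           "proportions must be strictly increasing, in (0,1], and end at 1")
  perms <- vector("list", length(train$classes))
  names(perms) <- train$classes
  for (ci in seq_along(train$classes)) {
    cls <- train$classes[ci]
    ids_c <- train$ids[train$labels == cls]
    set.seed(mix_seed(seed, 100000 + ci))
    perms[[ci]] <- ids_c[sample.int(length(ids_c))]
  }
  lapply(proportions, function(p) {
    keep <- unlist(lapply(perms, function(ids_c) {
      ids_c[seq_len(max(1L, ceiling(p * length(ids_c))))]
    }), use.names = FALSE)
    subset_corpus(train, keep)
  })
}
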