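#' Word-embedding table
#'
#' Wraps a token-by-dimension numeric matrix (rownames are tokens). All
#' vectors share one dimension; zero-norm vectors are rejected since they
#' have no direction for similarity queries.
#'
#' @param vectors numeric matrix with one row per token; rownames required
#' @return an object of class `embedding_table` with fields `vectors` and
#'   `dimension`
#' @export
embedding_table <- function(vectors) {
  abort_if(!is.matrix(vectors) || !is.numeric(vectors),
           "vectors must be a numeric matrix")
  abort_if(is.null(rownames(vectors)) || anyDuplicated(rownames(vectors)) > 0,
           "vectors must have unique token rownames")
  nrm <- sqrt(rowSums(vectors^2))
  abort_if(any(nrm == 0), "zero-norm vector(s): %s",
           paste(rownames(vectors)[nrm == 0], collapse = ", "))
  structure(list(vectors = vectors, dimension = ncol(vectors)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d tokens, dimension %d\n",
              nrow(x$vectors), x$dimension))
  invisible(x)
}

# rows of `emb$vectors` for `tokens` that have embeddings (NULL rows dropped);
# returns list(found = matrix, missing = character)
emb_lookup <- function(emb, tokens) {
  hit <- tokens %in% rownames(emb$vectors)
  list(found = emb$vectors[tokens[hit], , drop = FALSE],
       missing = tokens[!hit])
}

#' Training vocabulary in first-appearance order
#'
#' @param train a `corpus`
#' @return character vector of unique tokens
#' @export
fit_vocabulary <- function(train) {
  stopifnot(inherits(train, "corpus"))
  abort_if(n_docs(train) == 0L, "empty corpus")
  unique(unlist(train$tokens, use.names = FALSE))
}

#' Document-term count matrix
#'
#' Sparse documents-by-vocabulary matrix of raw token occurrence counts.
#' Tokens outside `vocab` (e.g. unseen test tokens) are dropped.
#'
#' @param x a `corpus`
#' @param vocab ordered token vector from [fit_vocabulary()]
#' @return a `dgCMatrix` with document ids as rownames, tokens as colnames
#' @export
count_matrix <- function(x, vocab) {
  stopifnot(inherits(x, "corpus"))
  toks <- unlist(x$tokens, use.names = FALSE)
  doc <- rep.int(seq_along(x$tokens), lengths(x$tokens))
  col <- match(toks, vocab)
  keep <- !is.na(col)
  m <- Matrix::sparseMatrix(i = doc[keep], j = col[keep], x = 1,
                            dims = c(n_docs(x), length(vocab)),
                            dimnames = list(x$ids, vocab))
  methods::as(m, "CsparseMatrix")
}

# presence/absence 2x2 contingency counts for all (feature, class) pairs.
# Returns list of feature-by-class matrices a,b,c,d and totals.
contingency_counts <- function(train, vocab) {
  P <- count_matrix(train, vocab) > 0          # docs x vocab, logical sparse
  Y <- Matrix::sparseMatrix(i = seq_len(n_docs(train)),
                            j = match(train$labels, train$classes), x = 1,
                            dims = c(n_docs(train), length(train$classes)),
                            dimnames = list(NULL, train$classes))
  a <- as.matrix(Matrix::crossprod(P, Y))      # present & in class
  present <- Matrix::colSums(P)                # docs containing feature
  n_class <- Matrix::colSums(Y)                # docs per class
  N <- n_docs(train)
  b <- present - a                             # present & not class
  cc <- rep(1, length(vocab)) %o% n_class - a  # absent & in class
  d <- N - a - b - cc
  list(a = a, b = b, cc = cc, d = d, N = N, present = present,
       n_class = n_class, vocab = vocab)
}

# chi-square statistic from the 2x2 counts; 0 wherever a margin vanishes
chi_square_from_counts <- function(ct) {
  num <- ct$N * (ct$a * ct$d - ct$b * ct$cc)^2
  denom <- (ct$a + ct$b) * (ct$cc + ct$d) * (ct$a + ct$cc) * (ct$b + ct$d)
  out <- num / denom
  out[!is.finite(out)] <- 0
  out
}

#' One-vs-rest chi-square score of a feature for a class
#'
#' Document-level presence/absence of the feature is crossed with
#' membership in the class to form a 2x2 table (a = present & class,
#' b = present & other, c = absent & class, d = absent & other); the
#' statistic is `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, defined as 0 when
#' any margin is 0.
#'
#' @param feature a token present in the training vocabulary
#' @param class a class identifier of `train`
#' @param train training `corpus`
#' @return non-negative chi-square statistic
#' @export
chi_square_score <- function(feature, class, train) {
  vocab <- fit_vocabulary(train)
  abort_if(!feature %in% vocab, "unknown feature: %s", feature)
  abort_if(!class %in% train$classes, "unknown class: %s", class)
  ct <- contingency_counts(train, vocab)
  chi_square_from_counts(ct)[match(feature, vocab), match(class, train$classes)]
}

#' Associate a feature with its most probable class
#'
#' Returns `argmax_c p(c | w)` where `p(c | w)` is the fraction of
#' training documents containing `w` that carry label `c`; ties break toward
#' the class earlier in corpus class order.
#'
#' @param feature a token occurring in at least one training document
#' @param train training `corpus`
#' @return a class identifier
#' @export
associate_class <- function(feature, train) {
  vocab <- fit_vocabulary(train)
  abort_if(!feature %in% vocab, "feature occurs in no document: %s", feature)
  ct <- contingency_counts(train, vocab)
  train$classes[max.col(ct$a[match(feature, vocab), , drop = FALSE],
                        ties.method = "first")]
}

#' Feature-selection configuration
#'
#' Defaults are the tuned values of the expansion method: the chi-square
#' metric, `k = 2` features per class, cosine threshold `t = 0.9`.
#'
#' @param metric feature scoring metric; only `"chi_square"` is implemented
#' @param k features kept per class (positive integer)
#' @param t cosine similarity threshold in (0, 1]
#' @return an object of class `fs_config`
#' @export
fs_config <- function(metric = "chi_square", k = 2L, t = 0.9) {
  abort_if(!identical(metric, "chi_square"),
           "unsupported feature selection metric: %s", metric)
  abort_if(k < 1L, "k must be a positive integer")
  abort_if(!is_scalar_number(t) || t <= 0 || t > 1, "t must lie in (0, 1]")
  structure(list(metric = metric, k = as.integer(k), t = t),
            class = "fs_config")
}

#' Select class-indicative features
#'
#' Every training-vocabulary feature is first associated with the class
#' maximizing `p(c | w)`; within each class's associated features, the `k`
#' highest by one-vs-rest chi-square are selected (fewer if fewer exist).
#' Ties break by score then lexicographically by token, so selection is
#' deterministic. The union over classes is the expansion feature set F.
#'
#' @param train training `corpus`
#' @param config an [fs_config()]
#' @return an object of class `selected_features` whose `table` has columns
#'   `feature`, `class` (the associated class) and `score`
#' @export
select_features <- function(train, config = fs_config()) {
  stopifnot(inherits(config, "fs_config"))
  vocab <- fit_vocabulary(train)
  ct <- contingency_counts(train, vocab)
  chi <- chi_square_from_counts(ct)
  assoc_idx <- max.col(ct$a, ties.method = "first")   # argmax_c p(c|w): a/present
  assoc <- train$classes[assoc_idx]
  score <- chi[cbind(seq_along(vocab), assoc_idx)]
  rows <- lapply(train$classes, function(cls) {
    cand <- which(assoc == cls)
    if (length(cand) == 0L) return(NULL)
    ord <- cand[order(-score[cand], vocab[cand])]
    take <- ord[seq_len(min(config$k, length(ord)))]
    data.frame(feature = vocab[take], class = cls, score = score[take],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, features = tab$feature, config = config),
            class = "selected_features")
}

#' @export
print.selected_features <- function(x, ...) {
  cat(sprintf("<selected_features> %d features over %d classes (k = %d)\n",
              nrow(x$table), length(unique(x$table$class)), x$config$k))
  invisible(x)
}

#' Cosine similarity of two vectors
#'
#' @param u,v numeric vectors of equal length and non-zero norm
#' @return `dot(u, v) / (||u|| ||v||)`, in `[-1, 1]`
#' @export
cosine_similarity <- function(u, v) {
  abort_if(length(u) != length(v), "vectors differ in dimension")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  abort_if(nu == 0 || nv == 0, "cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

# L2-normalize matrix rows (dense); zero rows left as zero
row_normalize <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Expand counts of selected features via embedding similarity
#'
#' For each token occurrence `u` of a document and each selected feature
#' `w` in F, if both have embeddings and `cos(u, w) >= t`, the count of `w`
#' in that document is incremented by 1 — conceptually adding `w` to the
#' document whenever one of its synonyms occurs. A selected feature present
#' in the document matches itself (`cos = 1 >= t`), doubling its emphasis.
#' Occurrences without embeddings trigger no increments. Counts of columns
#' outside F are untouched. Applied before the TFIDF transformation.
#'
#' @param x the `corpus` whose raw counts are being expanded
#' @param counts sparse document-term matrix from [count_matrix()] (its
#'   columns are the training vocabulary)
#' @param fs a [select_features()] result; only features that are columns of
#'   `counts` can receive increments
#' @param emb an [embedding_table()]
#' @param t cosine threshold in (0, 1]
#' @return the expanded count matrix; attribute `n_skipped` counts token
#'   occurrences without an embedding
#' @export
expand_counts <- function(x, counts, fs, emb, t = 0.9) {
  stopifnot(inherits(x, "corpus"), inherits(fs, "selected_features"),
            inherits(emb, "embedding_table"))
  abort_if(!is_scalar_number(t) || t <= 0 || t > 1, "t must lie in (0, 1]")
  feats <- intersect(fs$features, colnames(counts))
  toks <- unlist(x$tokens, use.names = FALSE)
  doc <- rep.int(seq_along(x$tokens), lengths(x$tokens))
  utoks <- unique(toks)
  have_u <- utoks %in% rownames(emb$vectors)
  have_w <- feats %in% rownames(emb$vectors)
  n_skipped <- sum(!toks %in% utoks[have_u])
  if (sum(have_u) > 0L && sum(have_w) > 0L) {
    U <- row_normalize(emb$vectors[utoks[have_u], , drop = FALSE])
    W <- row_normalize(emb$vectors[feats[have_w], , drop = FALSE])
    hits <- Matrix::Matrix((U %*% t(W)) >= t, sparse = TRUE) * 1
    # per-document occurrence counts of embeddable tokens
    col_u <- match(toks, utoks[have_u])
    keep <- !is.na(col_u)
    O <- Matrix::sparseMatrix(i = doc[keep], j = col_u[keep], x = 1,
                              dims = c(n_docs(x), sum(have_u)))
    inc <- O %*% hits                          # docs x embeddable features
    jw <- match(feats[have_w], colnames(counts))
    counts[, jw] <- counts[, jw, drop = FALSE] + inc
  }
  structure(methods::as(counts, "CsparseMatrix"), n_skipped = n_skipped)
}

#' Fit TFIDF statistics on (possibly expanded) training counts
#'
#' Smoothed inverse document frequency `idf = ln((1 + N) / (1 + df)) + 1`
#' computed on the training documents; a token appearing in every training
#' document gets idf exactly 1. Document frequency is taken on the counts
#' as given, i.e. after any expansion.
#'
#' @param counts training document-term count matrix
#' @return named idf vector over the matrix's columns
#' @export
fit_tfidf <- function(counts) {
  N <- nrow(counts)
  df <- Matrix::colSums(counts > 0)
  stats::setNames(log((1 + N) / (1 + df)) + 1, colnames(counts))
}

#' Apply a TFIDF transform with frozen idf
#'
#' Weight is raw term frequency times training idf; each non-zero row is
#' then L2-normalized. Test rows reuse the training idf.
#'
#' @param counts document-term count matrix (training or test)
#' @param idf idf vector from [fit_tfidf()], aligned with the columns
#' @return weighted sparse matrix with unit-norm non-zero rows
#' @export
tfidf_transform <- function(counts, idf) {
  abort_if(ncol(counts) != length(idf), "idf length does not match columns")
  w <- counts %*% Matrix::Diagonal(x = as.numeric(idf))
  nrm <- sqrt(Matrix::rowSums(w^2))
  nrm[nrm == 0] <- 1
  out <- Matrix::Diagonal(x = 1 / nrm) %*% w
  dimnames(out) <- dimnames(counts)
  methods::as(out, "CsparseMatrix")
}

#' Average-embedding (CBOW) document vector
#'
#' The unweighted mean of the embedding vectors of the document's token
#' occurrences (repeated tokens weigh more). Tokens without embeddings are
#' skipped; a document none of whose tokens has an embedding is an error.
#'
#' @param tokens character vector of document tokens
#' @param emb an [embedding_table()]
#' @return numeric vector of length `emb$dimension`
#' @export
cbow_vector <- function(tokens, emb) {
  stopifnot(inherits(emb, "embedding_table"))
  lk <- emb_lookup(emb, tokens)
  abort_if(nrow(lk$found) == 0L,
           "no token of the document has an embedding")
  colMeans(lk$found)
}

# dense docs x dim matrix of CBOW vectors; rows with no embedded token are
# zero when allow_empty, otherwise an error naming the document
cbow_matrix <- function(x, emb, allow_empty = FALSE) {
  out <- matrix(0, n_docs(x), emb$dimension,
                dimnames = list(x$ids, NULL))
  toks <- unlist(x$tokens, use.names = FALSE)
  doc <- rep.int(seq_along(x$tokens), lengths(x$tokens))
  hit <- toks %in% rownames(emb$vectors)
  if (any(hit)) {
    V <- emb$vectors[toks[hit], , drop = FALSE]
    sums <- rowsum(V, group = doc[hit])
    cnt <- tabulate(doc[hit], nbins = n_docs(x))
    rows <- as.integer(rownames(sums))
    out[rows, ] <- sums / cnt[rows]
  }
  empty <- setdiff(seq_len(n_docs(x)), doc[hit])
  if (length(empty) > 0L && !allow_empty) {
    abort_if(TRUE, "document(s) with no embedded token: %s",
             paste(x$ids[empty], collapse = ", "))
  }
  out
}
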