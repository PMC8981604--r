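#' Classifier configuration
#'
#' Five representation kinds share one linear-SVM back end:
#' \describe{
#'   \item{bow}{TFIDF-weighted bag-of-words.}
#'   \item{bow_exp}{bag-of-words with chi-square feature selection and
#'     embedding-based synonym expansion applied before TFIDF.}
#'   \item{bow_exp_kg}{as `bow_exp` with an alternative (knowledge-graph
#'     refined) embedding table — no other difference.}
#'   \item{cbow}{dense average-of-word-vectors document representation.}
#'   \item{cbow_kg}{as `cbow` with the alternative embedding table.}
#' }
#' The regularization strength defaults to `C = 1`, the value that wins the
#' grid `{0.001, 0.01, 0.1, 1, 10, 100}` on development data.
#'
#' @param kind representation kind, see above
#' @param C positive SVM regularization strength
#' @param embeddings an [embedding_table()] or path to a word2vec text file;
#'   required for `bow_exp*` and `cbow*` kinds
#' @param fs an [fs_config()]; used by the `bow_exp*` kinds
#' @return an object of class `classifier_config`
#' @export
classifier_config <- function(kind = c("bow", "bow_exp", "bow_exp_kg",
                                       "cbow", "cbow_kg"),
                              C = 1, embeddings = NULL, fs = fs_config()) {
  kind <- match.arg(kind)
  abort_if(!is_scalar_number(C) || C <= 0, "C must be a positive number")
  needs_emb <- kind != "bow"
  if (is.character(embeddings)) embeddings <- read_word2vec(embeddings)
  abort_if(needs_emb && is.null(embeddings),
           "kind '%s' requires an embedding table", kind)
  abort_if(!is.null(embeddings) && !inherits(embeddings, "embedding_table"),
           "embeddings must be an embedding_table or a file path")
  structure(list(kind = kind, C = C, embeddings = embeddings, fs = fs),
            class = "classifier_config")
}

#' The regularization grid searched in grid mode
#' @return numeric vector `c(0.001, 0.01, 0.1, 1, 10, 100)`
#' @export
c_grid <- function() c(0.001, 0.01, 0.1, 1, 10, 100)

# build the design matrix for a corpus under a trained (or fitting)
# representation state; state fields depend on kind
representation_matrix <- function(x, kind, state) {
  if (kind %in% c("bow", "bow_exp", "bow_exp_kg")) {
    m <- count_matrix(x, state$vocab)
    if (kind != "bow") {
      m <- expand_counts(x, m, state$fs_set, state$embeddings, state$t)
    }
    tfidf_transform(m, state$idf)
  } else {
    cbow_matrix(x, state$embeddings, allow_empty = TRUE)
  }
}

#' Train a multi-class text classifier
#'
#' Builds the configured representation on the training corpus only, then
#' fits an L2-regularized linear-kernel support vector machine one-vs-rest:
#' one binary margin per class, prediction by argmax of decision values.
#' Deterministic given `seed`.
#'
#' @param train training `corpus` with at least 2 classes
#' @param config a [classifier_config()]
#' @param seed integer seed
#' @return an object of class `trained_model`
#' @export
train_model <- function(train, config = classifier_config(), seed = 1L) {
  stopifnot(inherits(train, "corpus"), inherits(config, "classifier_config"))
  abort_if(length(train$classes) < 2L,
           "training corpus has a single class; nothing to separate")
  kind <- config$kind
  state <- list(kind = kind, embeddings = config$embeddings)
  if (kind %in% c("bow", "bow_exp", "bow_exp_kg")) {
    state$vocab <- fit_vocabulary(train)
    m <- count_matrix(train, state$vocab)
    if (kind != "bow") {
      state$fs_set <- select_features(train, config$fs)
      state$t <- config$fs$t
      m <- expand_counts(train, m, state$fs_set, state$embeddings, state$t)
    }
    state$idf <- fit_tfidf(m)   # document frequency measured after expansion
    X <- tfidf_transform(m, state$idf)
  } else {
    X <- representation_matrix(train, kind, state)
  }
  Xd <- as.matrix(X)  # libsvm back end takes dense input
  classes <- train$classes
  weights <- matrix(0, ncol(Xd), length(classes),
                    dimnames = list(NULL, classes))
  intercepts <- stats::setNames(numeric(length(classes)), classes)
  for (ci in seq_along(classes)) {
    y <- factor(ifelse(train$labels == classes[ci], "pos", "neg"),
                levels = c("pos", "neg"))
    set.seed(mix_seed(seed, ci))
    fit <- e1071::svm(Xd, y, kernel = "linear", cost = config$C,
                      scale = FALSE, fitted = FALSE)
    w <- as.numeric(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    # libsvm orients the margin toward the class of the first training row;
    # flip so that positive decision values always mean "pos"
    if (fit$levels[fit$labels[1L]] != "pos") {
      w <- -w; b <- -b
    }
    weights[, ci] <- w
    intercepts[ci] <- b
  }
  structure(list(config = config, state = state, classes = classes,
                 weights = weights, intercepts = intercepts),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> kind %s, %d classes, %d features, C = %g\n",
              x$config$kind, length(x$classes), nrow(x$weights), x$config$C))
  invisible(x)
}

#' Per-class decision values for a corpus
#'
#' @param model a [train_model()] result
#' @param x a `corpus` of documents to score
#' @return documents-by-classes numeric matrix of one-vs-rest decision values
#' @export
decision_values <- function(model, x) {
  stopifnot(inherits(model, "trained_model"), inherits(x, "corpus"))
  X <- representation_matrix(x, model$config$kind, model$state)
  dv <- as.matrix(X %*% model$weights)
  sweep(dv, 2L, model$intercepts, "+")
}

#' Predict class labels
#'
#' Per document, the class with the highest one-vs-rest decision value; ties
#' break toward the class earlier in training class order. Documents whose
#' tokens are all unseen are scored as the all-zeros vector, not an error.
#'
#' @param object a [train_model()] result
#' @param newdata a `corpus` of documents to label
#' @param ... unused
#' @return character vector of predicted labels, one per document, in order
#' @export
predict.trained_model <- function(object, newdata, ...) {
  dv <- decision_values(object, newdata)
  object$classes[max.col(dv, ties.method = "first")]
}

#' Save / load a trained model bundle
#'
#' The bundle holds the frozen representation state (vocabulary, idf vector,
#' selected feature set, embedding reference), the per-class linear weights
#' and intercepts, and the class order; a round-trip reproduces predictions
#' exactly.
#'
#' @param model a [train_model()] result
#' @param path file path for the serialized bundle
#' @return `path` ([save_model()]) or the restored model ([load_model()])
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  abort_if(!inherits(model, "trained_model"), "not a trained_model bundle")
  model
}
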