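#' Configuration of the synthetic corpus generator
#'
#' The generator emulates the statistical structure of long-tailed patient
#' disease-description corpora: a Zipf law over class frequencies (classes
#' as rare as 2 in 10,000 when the corpus is large enough), short documents
#' of a few dozen tokens, a small set of class-indicative signature words,
#' synonym clusters whose members are near-duplicates in embedding space,
#' and a Zipfian background vocabulary supplying noise tokens.
#'
#' @param n_classes number of classes (>= 2)
#' @param n_documents number of documents (>= 2 * n_classes)
#' @param zipf_exponent exponent of the class-frequency power law (0 = flat)
#' @param doc_length_mean mean document length in tokens (Poisson, min 1)
#' @param signature_words_per_class synonym clusters indicative of each class
#' @param synonyms_per_signature surface variants per cluster
#' @param signal_probability chance a token is drawn from the document
#'   class's signature clusters rather than the background
#' @param background_vocab_size size of the shared noise vocabulary
#' @param embedding_dimension word-vector dimension
#' @param intra_cluster_cosine_min minimum pairwise cosine within a synonym
#'   cluster; must exceed the expansion threshold `t` it is paired with
#' @param seed integer master seed
#' @return an object of class `synthetic_config`
#' @export
synthetic_config <- function(n_classes = 10L,
                             n_documents = 2000L,
                             zipf_exponent = 1.5,
                             doc_length_mean = 27,
                             signature_words_per_class = 2L,
                             synonyms_per_signature = 3L,
                             signal_probability = 0.15,
                             background_vocab_size = 500L,
                             embedding_dimension = 256L,
                             intra_cluster_cosine_min = 0.95,
                             seed = 1L) {
  abort_if(n_classes < 2L, "need at least 2 classes")
  abort_if(n_documents < 2L * n_classes,
           "n_documents must be at least 2 per class")
  abort_if(zipf_exponent < 0, "zipf_exponent must be >= 0")
  abort_if(doc_length_mean <= 0, "doc_length_mean must be positive")
  abort_if(signal_probability <= 0 || signal_probability >= 1,
           "signal_probability must lie in (0,1)")
  abort_if(intra_cluster_cosine_min <= 0 || intra_cluster_cosine_min > 1,
           "intra_cluster_cosine_min must lie in (0,1]")
  structure(list(n_classes = as.integer(n_classes),
                 n_documents = as.integer(n_documents),
                 zipf_exponent = zipf_exponent,
                 doc_length_mean = doc_length_mean,
                 signature_words_per_class = as.integer(signature_words_per_class),
                 synonyms_per_signature = as.integer(synonyms_per_signature),
                 signal_probability = signal_probability,
                 background_vocab_size = as.integer(background_vocab_size),
                 embedding_dimension = as.integer(embedding_dimension),
                 intra_cluster_cosine_min = intra_cluster_cosine_min,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# canonical token names
sig_token <- function(class_i, sig_j, variant_v) {
  sprintf("c%02d_s%d_v%d", class_i, sig_j, variant_v)
}
bg_token <- function(i) sprintf("bg%04d", i)
class_name <- function(i) sprintf("disease_%03d", i)

# expected class shares under the config's power law
zipf_shares <- function(n_classes, exponent) {
  w <- seq_len(n_classes)^(-exponent)
  w / sum(w)
}

# multinomial class counts with every class forced to >= 2 documents
realized_class_counts <- function(cfg) {
  shares <- zipf_shares(cfg$n_classes, cfg$zipf_exponent)
  cnt <- as.vector(stats::rmultinom(1L, cfg$n_documents, shares))
  while (any(cnt < 2L)) {
    i <- which(cnt < 2L)[1L]
    j <- which.max(cnt)
    cnt[i] <- cnt[i] + 1L
    cnt[j] <- cnt[j] - 1L
  }
  cnt
}

# vectorized token draw for a vector of (token slot -> class) assignments;
# variant_of: NULL for a uniform variant draw, or a single fixed variant
draw_tokens <- function(cfg, tok_class, variant = NULL) {
  n <- length(tok_class)
  is_signal <- stats::runif(n) < cfg$signal_probability
  out <- character(n)
  ns <- sum(is_signal)
  if (ns > 0L) {
    sig <- sample.int(cfg$signature_words_per_class, ns, replace = TRUE)
    var <- if (is.null(variant))
      sample.int(cfg$synonyms_per_signature, ns, replace = TRUE)
    else rep.int(variant, ns)
    out[is_signal] <- sig_token(tok_class[is_signal], sig, var)
  }
  nb <- n - ns
  if (nb > 0L) {
    pr <- zipf_shares(cfg$background_vocab_size, 1)
    out[!is_signal] <- bg_token(sample.int(cfg$background_vocab_size, nb,
                                           replace = TRUE, prob = pr))
  }
  out
}

# assemble a corpus from per-document class assignments
build_documents <- function(cfg, doc_class, id_prefix, variant = NULL) {
  n <- length(doc_class)
  lens <- pmax(1L, stats::rpois(n, cfg$doc_length_mean))
  tok_class <- rep.int(doc_class, lens)
  toks <- draw_tokens(cfg, tok_class, variant)
  tokens <- split(toks, rep.int(seq_len(n), lens))
  corpus(ids = sprintf("%s%05d", id_prefix, seq_len(n)),
         tokens = unname(tokens),
         labels = class_name(doc_class),
         classes = class_name(seq_len(cfg$n_classes)))
}

#' Generate a synthetic long-tailed corpus
#'
#' Class sizes are multinomial around a Zipf law over class rank (every
#' class forced to at least 2 documents); document lengths are Poisson with
#' minimum 1; each token is, with probability `signal_probability`, a
#' uniformly chosen synonym variant of one of the document class's
#' signature clusters, and otherwise a Zipf-distributed background token.
#' Fully reproducible from the config seed.
#'
#' @param cfg a [synthetic_config()]
#' @return a `corpus`
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(mix_seed(cfg$seed, 1L))
  cnt <- realized_class_counts(cfg)
  doc_class <- sample(rep.int(seq_len(cfg$n_classes), cnt))  # shuffle order
  build_documents(cfg, doc_class, id_prefix = "d")
}

#' Generate an embedding table matching the corpus vocabulary
#'
#' Every synonym cluster receives a random unit centroid; members are the
#' centroid plus small Gaussian noise, renormalized, resampled until every
#' intra-cluster pairwise cosine reaches `intra_cluster_cosine_min`.
#' Background tokens get independent random unit vectors. Cross-cluster
#' centroid pairs and background vectors are rejection-resampled until all
#' their cosines against cluster members stay below 0.9, so only true
#' synonyms can cross the expansion threshold.
#'
#' @param cfg a [synthetic_config()]
#' @param max_retries bounded resampling attempts before erroring (the
#'   requested separation may be unsatisfiable in a low dimension)
#' @return an [embedding_table()] covering all signature and background
#'   tokens
#' @export
generate_embeddings <- function(cfg, max_retries = 100L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(mix_seed(cfg$seed, 2L))
  d <- cfg$embedding_dimension
  n_clusters <- cfg$n_classes * cfg$signature_words_per_class
  sep_limit <- 0.9  # non-synonym cosines must stay below the usual threshold

  unit <- function(v) v / sqrt(sum(v^2))
  rand_unit <- function(n) row_normalize(matrix(stats::rnorm(n * d), n, d))

  # centroids, mutually separated
  centroids <- rand_unit(n_clusters)
  for (tries in seq_len(max_retries)) {
    g <- centroids %*% t(centroids)
    diag(g) <- 0
    bad <- unique(which(g >= sep_limit, arr.ind = TRUE)[, 1L])
    if (length(bad) == 0L) break
    abort_if(tries == max_retries,
             "dimension %d too small to separate %d clusters", d, n_clusters)
    centroids[bad, ] <- rand_unit(length(bad))
  }

  # cluster members: centroid + small noise, pairwise cosine constrained
  sigma <- sqrt(0.02 / d)
  members <- vector("list", n_clusters)
  for (k in seq_len(n_clusters)) {
    for (tries in seq_len(max_retries)) {
      m <- row_normalize(
        matrix(rep(centroids[k, ], each = cfg$synonyms_per_signature),
               cfg$synonyms_per_signature, d) +
          matrix(stats::rnorm(cfg$synonyms_per_signature * d, sd = sigma),
                 cfg$synonyms_per_signature, d))
      g <- m %*% t(m)
      if (min(g) >= cfg$intra_cluster_cosine_min) { members[[k]] <- m; break }
      abort_if(tries == max_retries,
               "could not satisfy intra-cluster cosine %g in dimension %d",
               cfg$intra_cluster_cosine_min, d)
    }
  }
  member_mat <- do.call(rbind, members)

  # background vectors, separated from every cluster member
  bg <- rand_unit(cfg$background_vocab_size)
  for (tries in seq_len(max_retries)) {
    g <- bg %*% t(member_mat)
    bad <- unique(which(g >= sep_limit, arr.ind = TRUE)[, 1L])
    if (length(bad) == 0L) break
    abort_if(tries == max_retries,
             "dimension %d too small to separate background vocabulary", d)
    bg[bad, ] <- rand_unit(length(bad))
  }

  cluster_grid <- expand.grid(v = seq_len(cfg$synonyms_per_signature),
                              s = seq_len(cfg$signature_words_per_class),
                              c = seq_len(cfg$n_classes))
  # members[[k]] rows are variants of cluster k = (class-1)*sigs + sig
  cluster_grid <- cluster_grid[order(cluster_grid$c, cluster_grid$s,
                                     cluster_grid$v), ]
  tok_names <- c(sig_token(cluster_grid$c, cluster_grid$s, cluster_grid$v),
                 bg_token(seq_len(cfg$background_vocab_size)))
  vec <- rbind(member_mat, bg)
  rownames(vec) <- tok_names
  embedding_table(vec)
}

#' Synonym-split train/test scenario
#'
#' A controlled regime in which surface-form bag-of-words must fail and
#' synonym expansion can recover the signal: training documents of every
#' class realize their signature clusters with variant 1 only, while test
#' documents use variant 2 of the same clusters, so the class-indicative
#' test tokens never occur in training. Class sizes are uniform; the split
#' into train and test is 2:1 per class.
#'
#' @param cfg a [synthetic_config()]; `synonyms_per_signature` must be >= 2
#' @return list with `train` and `test` corpora and the shared
#'   [embedding_table()] `emb`
#' @export
synonym_split_scenario <- function(cfg = synthetic_config(
                                     n_classes = 6L, n_documents = 180L,
                                     zipf_exponent = 0,
                                     signal_probability = 0.5,
                                     signature_words_per_class = 2L,
                                     synonyms_per_signature = 3L,
                                     background_vocab_size = 200L)) {
  stopifnot(inherits(cfg, "synthetic_config"))
  abort_if(cfg$synonyms_per_signature < 2L,
           "scenario needs at least 2 synonym variants per cluster")
  emb <- generate_embeddings(cfg)
  set.seed(mix_seed(cfg$seed, 3L))
  per_class <- max(3L, cfg$n_documents %/% cfg$n_classes)
  n_test <- max(1L, per_class %/% 3L)
  n_train <- per_class - n_test
  train <- build_documents(cfg, rep(seq_len(cfg$n_classes), each = n_train),
                           id_prefix = "tr", variant = 1L)
  test <- build_documents(cfg, rep(seq_len(cfg$n_classes), each = n_test),
                          id_prefix = "te", variant = 2L)
  list(train = train, test = test, emb = emb)
}
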