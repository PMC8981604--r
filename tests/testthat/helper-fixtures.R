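# Shared fixtures built in code: tiny handcrafted corpora and embedding
# tables with known geometry.

# two classes, each with an exclusive signature token plus shared noise
toy_corpus <- function() {
  corpus(
    ids = c("d1", "d2", "d3", "d4", "d5", "d6"),
    tokens = list(c("cough", "fever", "the"),
                  c("cough", "the", "a"),
                  c("cough", "fever"),
                  c("rash", "itch", "the"),
                  c("rash", "a"),
                  c("rash", "itch", "a")),
    labels = c("flu", "flu", "flu", "derm", "derm", "derm")
  )
}

# linearly separable corpus: every class has an exclusive token in all its docs
sep_corpus <- function(n_classes = 3L, n_per_class = 4L) {
  ids <- character(0); toks <- list(); labs <- character(0)
  for (ci in seq_len(n_classes)) {
    for (j in seq_len(n_per_class)) {
      ids <- c(ids, sprintf("c%d_%d", ci, j))
      toks <- c(toks, list(c(sprintf("sig%d", ci), "shared", "noise")))
      labs <- c(labs, sprintf("class%d", ci))
    }
  }
  corpus(ids, toks, labs)
}

# random corpus over a small vocabulary, for property tests
random_corpus <- function(n_docs = 50L, n_classes = 4L, vocab_size = 30L,
                          len = 8L, seed = 1L) {
  set.seed(seed)
  vocab <- sprintf("w%02d", seq_len(vocab_size))
  labs <- sprintf("cls%d", sample.int(n_classes, n_docs, replace = TRUE))
  # guarantee every class appears twice
  labs[seq_len(2L * n_classes)] <- sprintf("cls%d", rep(seq_len(n_classes), 2L))
  corpus(ids = sprintf("r%03d", seq_len(n_docs)),
         tokens = lapply(seq_len(n_docs), function(i)
           sample(vocab, len, replace = TRUE)),
         labels = labs)
}

# embedding table with controlled cosines:
#   syn_a / syn_b: cosine ~0.95 pair; far: orthogonal to both
toy_embeddings <- function() {
  a <- c(1, 0, 0, 0)
  b <- c(cos(acos(0.95)), sin(acos(0.95)), 0, 0)  # cosine with a exactly 0.95
  far <- c(0, 0, 1, 0)
  mid <- c(sqrt(0.5), 0, sqrt(0.5), 0)            # cosine 0.7071 with a
  embedding_table(rbind(syn_a = a, syn_b = b, far = far, mid = mid))
}

# one-document corpus wrapper for per-document expansion checks
one_doc <- function(tokens, label = "x", other = c("pad", "y")) {
  # a second dummy document keeps the corpus two-class and valid
  corpus(ids = c("doc", "dummy"),
         tokens = list(tokens, other),
         labels = c(label, "other"))
}
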