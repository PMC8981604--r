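test_that("vocabulary is first-appearance ordered and deterministic", {
  co <- corpus(c("d1", "d2"), list(c("a", "b"), c("b", "c")), c("x", "y"))
  expect_identical(fit_vocabulary(co), c("a", "b", "c"))
  one <- corpus(c("d1", "d2"), list(c("x", "x", "x"), "y"), c("p", "q"))
  expect_identical(fit_vocabulary(one), c("x", "y"))
})

test_that("chi-square matches the 2x2 formula and its margin conventions", {
  # feature present in all and only the class's docs: a=5, d=5 -> chi2 = N = 10
  co <- corpus(sprintf("d%d", 1:10),
               c(rep(list(c("sig", "pad")), 5), rep(list("pad"), 5)),
               c(rep("pos", 5), rep("neg", 5)))
  expect_equal(chi_square_score("sig", "pos", co), 10)

  # independent feature (a=b=c=d=2) -> 0
  ind <- corpus(sprintf("d%d", 1:8),
                c(rep(list(c("f", "pad")), 2), rep(list("pad"), 2),
                  rep(list(c("f", "pad")), 2), rep(list("pad"), 2)),
                c(rep("A", 4), rep("B", 4)))
  expect_equal(chi_square_score("f", "A", ind), 0)

  # feature in every document: zero margin -> 0 by convention
  expect_equal(chi_square_score("pad", "pos", co), 0)
  expect_error(chi_square_score("nope", "pos", co), "unknown feature")
})

test_that("chi-square agrees with stats::chisq.test on a random corpus", {
  co <- random_corpus(n_docs = 50, n_classes = 4, vocab_size = 25, seed = 21)
  vocab <- fit_vocabulary(co)
  for (f in vocab) {
    present <- vapply(co$tokens, function(tk) f %in% tk, logical(1))
    for (cls in co$classes) {
      inc <- co$labels == cls
      tab <- table(factor(present, levels = c(TRUE, FALSE)),
                   factor(inc, levels = c(TRUE, FALSE)))
      expected <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 0 else
        suppressWarnings(unname(stats::chisq.test(tab, correct = FALSE)$statistic))
      expect_equal(chi_square_score(f, cls, co), expected, tolerance = 1e-10)
    }
  }
})

test_that("class association maximizes p(class | word) with stable ties", {
  co <- corpus(sprintf("d%d", 1:6),
               list(c("w"), c("w"), c("w"), c("w"), c("only_b"), c("only_b")),
               c("A", "A", "A", "B", "B", "B"))
  expect_identical(associate_class("w", co), "A")        # 3/4 vs 1/4
  expect_identical(associate_class("only_b", co), "B")   # p = 1

  tie <- corpus(c("d1", "d2"), list("w", "w"), c("A", "B"))
  expect_identical(associate_class("w", tie), "A")       # earlier class wins
  expect_error(associate_class("ghost", tie), "no document")
})

test_that("feature selection takes top-k per associated class", {
  co <- sep_corpus(n_classes = 2, n_per_class = 4)   # sig1, sig2 exclusive
  fs <- select_features(co, fs_config(k = 2))
  # each class contributes its exclusive token; shared/noise tokens are
  # associated somewhere and may fill remaining slots
  expect_true(all(c("sig1", "sig2") %in% fs$features))
  expect_true(all(table(fs$table$class) <= 2))

  # every occurring feature is associated with exactly one class
  vocab <- fit_vocabulary(co)
  assoc <- vapply(vocab, associate_class, character(1), train = co)
  expect_length(assoc, length(vocab))
  expect_false(any(is.na(assoc)))

  # k larger than vocabulary: all features with that association
  fs_all <- select_features(co, fs_config(k = 100))
  expect_setequal(fs_all$features, vocab)
})

test_that("cosine similarity matches hand values and rejects zero vectors", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 0.7071, tolerance = 1e-4)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero vector")
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)), "dimension")
})

test_that("count expansion adds synonym and self-match increments only", {
  emb <- toy_embeddings()
  fs <- structure(list(table = data.frame(feature = "syn_a", class = "x",
                                          score = 1),
                       features = "syn_a", config = fs_config()),
                  class = "selected_features")

  # synonym occurrence: cos(syn_b, syn_a) = 0.95 >= 0.9 adds syn_a to the doc
  co <- one_doc(c("syn_b"))
  counts <- count_matrix(co, c("syn_b", "syn_a"))
  out <- expand_counts(co, counts, fs, emb, t = 0.9)
  expect_equal(out["doc", "syn_b"], 1)
  expect_equal(out["doc", "syn_a"], 1)

  # self-match: raw 1 + increment 1 = 2
  co2 <- one_doc(c("syn_a"))
  counts2 <- count_matrix(co2, c("syn_a"))
  out2 <- expand_counts(co2, counts2, fs, emb, t = 0.9)
  expect_equal(out2["doc", "syn_a"], 2)

  # below threshold: cos(mid, syn_a) = 0.7071 < 0.9 changes nothing
  co3 <- one_doc(c("mid"))
  counts3 <- count_matrix(co3, c("mid", "syn_a"))
  out3 <- expand_counts(co3, counts3, fs, emb, t = 0.9)
  expect_equal(out3["doc", "mid"], 1)
  expect_equal(out3["doc", "syn_a"], 0)

  # per-occurrence increments: the synonym appearing 3 times adds 3
  co4 <- one_doc(c("syn_b", "syn_b", "syn_b"))
  counts4 <- count_matrix(co4, c("syn_b", "syn_a"))
  out4 <- expand_counts(co4, counts4, fs, emb, t = 0.9)
  expect_equal(out4["doc", "syn_a"], 3)

  # tokens without embeddings trigger no increments
  co5 <- one_doc(c("unknown_token"))
  counts5 <- count_matrix(co5, c("unknown_token", "syn_a"))
  out5 <- expand_counts(co5, counts5, fs, emb, t = 0.9)
  expect_equal(out5["doc", "syn_a"], 0)
  expect_gt(attr(out5, "n_skipped"), 0)
})

test_that("expansion is monotone and leaves non-selected columns untouched", {
  cfg <- synthetic_config(n_classes = 4, n_documents = 80,
                          embedding_dimension = 16, seed = 33)
  co <- generate_corpus(cfg)
  emb <- generate_embeddings(cfg)
  vocab <- fit_vocabulary(co)
  raw <- count_matrix(co, vocab)
  fs <- select_features(co, fs_config(k = 2))
  out <- expand_counts(co, raw, fs, emb, t = 0.9)
  expect_true(all(out - raw >= 0))
  non_f <- setdiff(vocab, fs$features)
  expect_equal(out[, non_f], raw[, non_f])
})

test_that("tfidf uses smoothed log idf and unit row norms, frozen for test", {
  co <- corpus(c("d1", "d2"), list(c("everywhere", "once"), c("everywhere")),
               c("x", "y"))
  counts <- count_matrix(co, fit_vocabulary(co))
  idf <- fit_tfidf(counts)
  expect_equal(unname(idf["everywhere"]), 1)              # ln(1) + 1
  expect_equal(unname(idf["once"]), log(3 / 2) + 1, tolerance = 1e-10)

  w <- tfidf_transform(counts, idf)
  expect_equal(unname(sqrt(Matrix::rowSums(w^2))), c(1, 1), tolerance = 1e-12)

  # agreement with an independently coded dense reference on random counts
  set.seed(9)
  m <- matrix(rpois(60, 1.2), 10, 6,
              dimnames = list(sprintf("d%d", 1:10), sprintf("t%d", 1:6)))
  ref_idf <- log((1 + 10) / (1 + colSums(m > 0))) + 1
  ref <- m * rep(ref_idf, each = 10)
  ref <- ref / ifelse(sqrt(rowSums(ref^2)) == 0, 1, sqrt(rowSums(ref^2)))
  got <- tfidf_transform(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                     "CsparseMatrix"), fit_tfidf(m))
  expect_lt(max(abs(as.matrix(got) - ref)), 1e-9)
})

test_that("cbow vectors are per-occurrence means of embedded tokens", {
  emb <- embedding_table(rbind(a = c(1, 0), b = c(0, 1)))
  expect_equal(cbow_vector("a", emb), c(1, 0))
  expect_equal(cbow_vector(c("a", "b"), emb), c(0.5, 0.5))
  expect_equal(cbow_vector(c("a", "a", "b"), emb), c(2 / 3, 1 / 3))
  expect_equal(cbow_vector(c("a", "zz"), emb), c(1, 0))  # missing skipped
  expect_error(cbow_vector(c("zz"), emb), "no token")
})

test_that("representations are deterministic for fixed inputs", {
  cfg <- synthetic_config(n_classes = 3, n_documents = 40,
                          embedding_dimension = 8, seed = 5)
  co <- generate_corpus(cfg)
  emb <- generate_embeddings(cfg)
  build <- function() {
    raw <- count_matrix(co, fit_vocabulary(co))
    fs <- select_features(co)
    ex <- expand_counts(co, raw, fs, emb)
    tfidf_transform(ex, fit_tfidf(ex))
  }
  expect_identical(as.matrix(build()), as.matrix(build()))
})
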