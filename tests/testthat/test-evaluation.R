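test_that("F1 follows the confusion-count form with the zero convention", {
  expect_equal(f1_score(2, 1, 1), 2 / 3, tolerance = 1e-4)
  expect_equal(f1_score(0, 0, 0), 0)
  expect_equal(f1_score(5, 0, 0), 1.0)
})

test_that("the two printed forms of F1 agree wherever both are defined", {
  set.seed(14)
  for (i in 1:200) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    if (tp + fp == 0 || tp + fn == 0) next
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    harmonic <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    expect_equal(f1_score(tp, fp, fn), harmonic, tolerance = 1e-12)
  }
})

test_that("macro-F1 averages per-class F1 over exactly the given classes", {
  # per-class F1s 1.0, 0.0, 0.5 -> 0.5
  y_true <- c("a", "a", "b", "c", "c")
  y_pred <- c("a", "a", "c", "c", "b")
  # class a: perfect (F1=1); b: tp=0 (F1=0); c: tp=1,fp=1,fn=1 (F1=0.5)
  expect_equal(macro_f1(y_true, y_pred, c("a", "b", "c")), 0.5)
  expect_equal(macro_f1(y_true, y_true, c("a", "b", "c")), 1.0)

  # permutation invariance of the class set
  expect_equal(macro_f1(y_true, y_pred, c("c", "a", "b")),
               macro_f1(y_true, y_pred, c("a", "b", "c")))
  # a scoped class absent from truth and prediction contributes 0
  expect_equal(macro_f1(y_true, y_pred, c("a", "ghost")), 0.5)
  expect_error(macro_f1(c("a", "b"), "a"), "length")
})

test_that("macro-F1 matches a brute-force confusion enumeration", {
  set.seed(77)
  classes <- c("p", "q", "r")
  for (i in 1:50) {
    n <- sample(3:20, 1)
    yt <- sample(classes, n, replace = TRUE)
    yp <- sample(classes, n, replace = TRUE)
    brute <- mean(vapply(classes, function(cl) {
      tp <- 0; fp <- 0; fn <- 0
      for (j in seq_len(n)) {
        if (yt[j] == cl && yp[j] == cl) tp <- tp + 1
        if (yt[j] != cl && yp[j] == cl) fp <- fp + 1
        if (yt[j] == cl && yp[j] != cl) fn <- fn + 1
      }
      if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }, numeric(1)))
    expect_equal(macro_f1(yt, yp, classes), brute, tolerance = 1e-12)
  }
})

test_that("ALC is the grand mean, bounded by curve extremes", {
  flat <- structure(list(scores = matrix(0.8, 3, 4),
                         proportions = c(0.25, 0.5, 0.75, 1)),
                    class = "learning_curve")
  expect_equal(alc(flat), 0.8)
  expect_equal(alc(flat, "trapezoid"), 0.8)

  one_run <- structure(list(scores = matrix(c(0.2, 0.4, 0.6), 1, 3),
                            proportions = c(1 / 3, 2 / 3, 1)),
                       class = "learning_curve")
  expect_equal(alc(one_run), 0.4)

  set.seed(31)
  m <- matrix(runif(12), 3, 4)
  rnd <- structure(list(scores = m, proportions = c(0.25, 0.5, 0.75, 1)),
                   class = "learning_curve")
  expect_equal(alc(rnd), sum(m) / length(m), tolerance = 1e-12)
  for (meth in c("mean", "trapezoid")) {
    expect_gte(alc(rnd, meth), min(m))
    expect_lte(alc(rnd, meth), max(m))
  }
})

test_that("randomization test enumerates exactly and samples consistently", {
  expect_equal(fisher_randomization_test(c(1, 1, 1), c(1, 1, 1))$p_value, 1.0)
  res <- fisher_randomization_test(c(2, 3, 4), c(1, 2, 3))  # diffs +1,+1,+1
  expect_true(res$exact)
  expect_equal(res$p_value, 1 / 8)
  expect_error(fisher_randomization_test(1:3, 1:2), "length")

  set.seed(52)
  a <- runif(10); b <- a - rnorm(10, mean = 0.1, sd = 0.2)
  p_exact <- fisher_randomization_test(a, b)$p_value
  p_mc <- fisher_randomization_test(a, b, n_perm = 4000, seed = 6,
                                    exact = FALSE)$p_value
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(p_mc - p_exact), 3 * se + 1 / 4000)
})

test_that("two methods under one plan share document-level splits", {
  cfg <- synthetic_config(n_classes = 4, n_documents = 100,
                          embedding_dimension = 8, seed = 2)
  co <- generate_corpus(cfg)
  emb <- generate_embeddings(cfg)
  plan <- split_plan(n_runs = 2, proportions = c(0.5, 1.0), seed = 44)
  c1 <- run_learning_curve(co, classifier_config("bow"), plan)
  c2 <- run_learning_curve(co, classifier_config("bow_exp", embeddings = emb),
                           plan)
  expect_identical(c1$fingerprints, c2$fingerprints)
})

test_that("the learning curve fills a runs-by-proportions matrix in [0,1]", {
  co <- sep_corpus(n_classes = 3, n_per_class = 6)
  plan <- split_plan(n_runs = 1, proportions = 1.0, seed = 3)
  cv <- run_learning_curve(co, classifier_config("bow"), plan)
  expect_equal(dim(cv$scores), c(1L, 1L))
  expect_equal(unname(cv$scores[1, 1]), 1.0)   # separable toy corpus

  plan2 <- split_plan(n_runs = 2, proportions = c(0.5, 1.0), seed = 3)
  cv2 <- run_learning_curve(co, classifier_config("bow"), plan2,
                            class_scope = c("class1", "class2"))
  expect_equal(dim(cv2$scores), c(2L, 2L))
  expect_true(all(cv2$scores >= 0 & cv2$scores <= 1))
  df <- as.data.frame(cv2, method = "bow")
  expect_named(df, c("method", "scope", "run", "proportion", "macro_f1"))
  expect_equal(nrow(df), 4L)
})
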