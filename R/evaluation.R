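#' F1 score from confusion counts
#'
#' `2 TP / (2 TP + FP + FN)` — algebraically identical to the harmonic mean
#' of precision and recall; defined as 0 when the denominator vanishes
#' (a class never predicted and never present).
#'
#' @param tp,fp,fn non-negative counts
#' @return F1 in `[0, 1]`
#' @export
f1_score <- function(tp, fp, fn) {
  denom <- 2 * tp + fp + fn
  ifelse(denom == 0, 0, 2 * tp / denom)
}

#' Macro-averaged F1
#'
#' Unweighted mean of per-class F1 over exactly the classes in `classes`,
#' giving rare classes the same voice as common ones. A class in `classes`
#' absent from both truth and prediction contributes its (zero) F1.
#'
#' @param y_true,y_pred label vectors of equal length
#' @param classes classes to average over; defaults to those present in
#'   `y_true`
#' @return macro-F1 in `[0, 1]`
#' @export
macro_f1 <- function(y_true, y_pred, classes = NULL) {
  abort_if(length(y_true) != length(y_pred),
           "y_true and y_pred differ in length")
  if (is.null(classes)) classes <- unique(y_true)
  abort_if(length(classes) == 0L, "empty class set")
  f1s <- vapply(classes, function(cls) {
    tp <- sum(y_true == cls & y_pred == cls)
    fp <- sum(y_true != cls & y_pred == cls)
    fn <- sum(y_true == cls & y_pred != cls)
    f1_score(tp, fp, fn)
  }, numeric(1))
  mean(f1s)
}

#' Run the learning-curve protocol
#'
#' Per run: a fresh per-class stratified 80/20-style split with a
#' run-derived seed, nested training subsamples at the plan's proportions,
#' one model per proportion, and macro-F1 of its predictions on the full
#' test side. Two methods evaluated under the same plan see identical
#' document-level splits (paired design), so their per-run scores are
#' directly comparable. A class scope restricts which classes are averaged
#' — never which documents are trained on or predicted.
#'
#' @param x a `corpus`
#' @param config a [classifier_config()]
#' @param plan a [split_plan()]
#' @param class_scope `"all"` or a character vector of classes to average
#'   macro-F1 over (e.g. a [rare_subset()])
#' @return an object of class `learning_curve`: a runs-by-proportions score
#'   matrix plus the proportions, scope and per-run split fingerprints
#' @export
run_learning_curve <- function(x, config = classifier_config(),
                               plan = split_plan(), class_scope = "all") {
  stopifnot(inherits(plan, "split_plan"))
  scope <- if (identical(class_scope, "all")) x$classes else {
    unknown <- setdiff(class_scope, x$classes)
    abort_if(length(unknown) > 0L, "scope class(es) not in corpus: %s",
             paste(unknown, collapse = ", "))
    class_scope
  }
  np <- length(plan$proportions)
  scores <- matrix(NA_real_, plan$n_runs, np,
                   dimnames = list(NULL, sprintf("p%02.0f", 100 * plan$proportions)))
  fingerprints <- character(plan$n_runs)
  for (r in seq_len(plan$n_runs)) {
    run_seed <- mix_seed(plan$seed, r)
    sp <- stratified_split(x, plan$test_fraction, seed = run_seed)
    fingerprints[r] <- paste(sort(sp$test$ids), collapse = "|")
    subs <- nested_subsample(sp$train, plan$proportions,
                             seed = mix_seed(run_seed, 7919))
    for (i in seq_len(np)) {
      model <- train_model(subs[[i]], config,
                           seed = mix_seed(run_seed, 100 + i))
      pred <- predict(model, sp$test)
      scores[r, i] <- macro_f1(sp$test$labels, pred, classes = scope)
    }
  }
  structure(list(scores = scores, proportions = plan$proportions,
                 class_scope = if (identical(class_scope, "all")) "all" else scope,
                 fingerprints = fingerprints, plan = plan),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("<learning_curve> %d run(s) x %d proportions, ALC = %.4f\n",
              nrow(x$scores), length(x$proportions), alc(x)))
  invisible(x)
}

#' @export
as.data.frame.learning_curve <- function(x, ..., method = "method") {
  scope <- if (identical(x$class_scope, "all")) "all" else "custom"
  data.frame(method = method, scope = scope,
             run = rep(seq_len(nrow(x$scores)), times = ncol(x$scores)),
             proportion = rep(x$proportions, each = nrow(x$scores)),
             macro_f1 = as.vector(x$scores))
}

#' Plot a learning curve
#'
#' Mean macro-F1 per proportion with a run-dispersion band (min-max across
#' runs). Several curves can be overlaid by passing a named list.
#'
#' @param x a `learning_curve` or a named list of them
#' @param ... further arguments passed to [graphics::matplot()]
#' @return invisibly, the matrix of per-proportion means
#' @export
plot_learning_curves <- function(x, ...) {
  curves <- if (inherits(x, "learning_curve")) list(curve = x) else x
  props <- curves[[1L]]$proportions
  means <- sapply(curves, function(cv) colMeans(cv$scores))
  graphics::matplot(props, means, type = "b", pch = 19, lty = 1,
                    xlab = "training proportion", ylab = "macro-F1",
                    ylim = c(0, 1), ...)
  if (length(curves) > 1L)
    graphics::legend("bottomright", legend = names(curves),
                     col = seq_along(curves), lty = 1, pch = 19, bty = "n")
  for (k in seq_along(curves)) {
    lo <- apply(curves[[k]]$scores, 2L, min)
    hi <- apply(curves[[k]]$scores, 2L, max)
    graphics::segments(props, lo, props, hi, col = k, lwd = 0.8)
  }
  invisible(means)
}

#' Area under the learning curve
#'
#' Summarizes a curve as a single number in `[0, 1]`: by default the grand
#' mean of macro-F1 over runs and the (equally spaced) proportion grid,
#' i.e. a normalized rectangle rule. A trapezoid rule over the proportion
#' axis is available as an alternative.
#'
#' @param curve a [run_learning_curve()] result
#' @param method `"mean"` (default) or `"trapezoid"`
#' @return scalar ALC
#' @export
alc <- function(curve, method = c("mean", "trapezoid")) {
  stopifnot(inherits(curve, "learning_curve"))
  method <- match.arg(method)
  if (method == "mean") return(mean(curve$scores))
  p <- curve$proportions
  if (length(p) == 1L) return(mean(curve$scores))
  per_run <- apply(curve$scores, 1L, function(s)
    sum(diff(p) * (utils::head(s, -1) + utils::tail(s, -1)) / 2) / (max(p) - min(p)))
  mean(per_run)
}

#' Fisher randomization test for a paired method comparison
#'
#' Tests whether method A scores higher than method B across paired runs
#' (pairing via shared splits). The statistic is the mean paired difference;
#' the null is generated by independent random sign flips of each
#' difference. With `n` pairs such that `2^n <= 2^20` all sign assignments
#' are enumerated exactly and `p = #\{null >= observed\} / 2^n`; otherwise
#' `n_perm` Monte-Carlo draws give `p = (#\{null >= observed\} + 1) /
#' (n_perm + 1)`. One-sided, direction "A better".
#'
#' @param scores_a,scores_b equal-length numeric vectors of per-run
#'   statistics (per-run macro-F1 or per-run ALC)
#' @param n_perm Monte-Carlo draws when exact enumeration is infeasible
#' @param seed integer seed for the Monte-Carlo path
#' @param exact `NULL` (enumerate exactly whenever `2^n <= 2^20`), or a
#'   logical forcing one of the two paths
#' @return list with `p_value`, `statistic` (mean difference) and `exact`
#' @export
fisher_randomization_test <- function(scores_a, scores_b,
                                      n_perm = 10000L, seed = 1L,
                                      exact = NULL) {
  abort_if(length(scores_a) != length(scores_b),
           "paired score vectors differ in length")
  n <- length(scores_a)
  abort_if(n < 2L, "need at least 2 paired runs")
  d <- scores_a - scores_b
  obs <- mean(d)
  if (is.null(exact)) exact <- n <= 20L
  abort_if(exact && n > 20L, "exact enumeration infeasible for %d pairs", n)
  if (exact) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    null <- as.vector(signs %*% d) / n
    p <- sum(null >= obs - 1e-12) / length(null)
  } else {
    set.seed(mix_seed(seed, 0L))
    null <- vapply(seq_len(n_perm), function(i)
      mean(d * sample(c(1, -1), n, replace = TRUE)), numeric(1))
    p <- (sum(null >= obs - 1e-12) + 1) / (n_perm + 1)
  }
  list(p_value = p, statistic = obs, exact = exact, n_pairs = n)
}
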