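#' Config-driven experiment runner
#'
#' Runs several representation kinds through the shared learning-curve
#' protocol on one corpus, for the full class set and (optionally) a rare
#' subset, writes long-format curve CSVs, an ALC summary with paired
#' randomization p-values against a baseline, and a learning-curve plot per
#' scope. All methods share the plan, hence identical splits per run.
#'
#' @param x a `corpus`
#' @param methods named list of [classifier_config()]s (names label the
#'   output rows)
#' @param plan a [split_plan()]
#' @param rare_threshold prevalence cutoff for the rare scope, or `NULL` to
#'   skip the rare sub-analysis
#' @param baseline name of the method every other method is tested against
#'   (direction "method better than baseline"); `NULL` for no testing
#' @param out_dir output directory for CSVs and plots; `NULL` writes nothing
#' @return list with per-scope curve lists, the ALC summary data frame and
#'   the rare class set
#' @export
run_experiment <- function(x, methods, plan = split_plan(),
                           rare_threshold = 2e-4, baseline = NULL,
                           out_dir = NULL) {
  abort_if(length(methods) == 0L || is.null(names(methods)),
           "methods must be a non-empty named list of classifier configs")
  for (m in methods) stopifnot(inherits(m, "classifier_config"))
  abort_if(!is.null(baseline) && !baseline %in% names(methods),
           "baseline '%s' is not among the methods", baseline)
  scopes <- list(all = "all")
  rare <- character(0)
  if (!is.null(rare_threshold)) {
    rare <- rare_subset(x, rare_threshold)
    if (length(rare) > 0L) scopes$rare <- rare
  }
  curves <- lapply(scopes, function(scope) {
    lapply(methods, function(cfg)
      run_learning_curve(x, cfg, plan, class_scope = scope))
  })
  summary_rows <- list()
  for (sc in names(curves)) {
    for (mn in names(curves[[sc]])) {
      p <- NA_real_
      if (!is.null(baseline) && mn != baseline) {
        a <- rowMeans(curves[[sc]][[mn]]$scores)     # per-run ALC
        b <- rowMeans(curves[[sc]][[baseline]]$scores)
        p <- fisher_randomization_test(a, b, seed = plan$seed)$p_value
      }
      summary_rows[[length(summary_rows) + 1L]] <-
        data.frame(method = mn, scope = sc,
                   alc = alc(curves[[sc]][[mn]]),
                   p_vs_baseline = p)
    }
  }
  summary_df <- do.call(rbind, summary_rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (sc in names(curves)) {
      for (mn in names(curves[[sc]]))
        write_curve_csv(curves[[sc]][[mn]],
                        file.path(out_dir, sprintf("curve_%s_%s.csv", mn, sc)),
                        method = mn)
      grDevices::pdf(file.path(out_dir, sprintf("curves_%s.pdf", sc)),
                     width = 6, height = 4.5)
      plot_learning_curves(curves[[sc]], main = sprintf("scope: %s", sc))
      grDevices::dev.off()
    }
    utils::write.csv(summary_df, file.path(out_dir, "alc_summary.csv"),
                     row.names = FALSE)
  }
  list(curves = curves, summary = summary_df, rare_classes = rare)
}
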