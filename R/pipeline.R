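#' Run the full classifier-construction workflow
#'
#' Composes the pipeline stages end to end: read inputs, mine stable pairs
#' in a control cohort, optionally retain them in the training controls,
#' screen for significantly reversed pairs (one-sided Fisher + BH), select
#' candidates, grow per-pivot coverage combinations, rank by frequency,
#' select the odd-n panel maximising sqrt(PPV x NPV), classify the training
#' samples, and write every artifact plus a reproducibility manifest. With
#' fixed inputs and configuration the run is deterministic, so a rerun is
#' byte-identical.
#'
#' @param config A configuration list or path to a YAML file with entries:
#'   \describe{
#'     \item{inputs}{`matrix` (training expression TSV), `labels`
#'       (two-column TSV), optional `dialect`, optional `stable_matrix` /
#'       `stable_dialect` for a separate stable-pair mining cohort.}
#'     \item{thresholds}{`stability` (0.95), `q` (0.05), `min_reversal`
#'       (0.70), `max_top` (31).}
#'     \item{modes}{`alternative` ("greater"/"two.sided"), `coverage`
#'       ("union"/"intersection").}
#'     \item{out_dir}{Output directory (created if needed).}
#'     \item{seed}{Integer recorded in the manifest.}
#'   }
#' @return Invisibly, a list with the selection object, predictions,
#'   metrics, and the paths of all written artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  inputs <- config$inputs %||% abort("config needs an 'inputs' section")
  th <- config$thresholds %||% list()
  modes <- config$modes %||% list()
  stability <- th$stability %||% 0.95
  q_thr <- th$q %||% 0.05
  min_rev <- th$min_reversal %||% 0.70
  max_top <- th$max_top %||% 31
  alternative <- modes$alternative %||% "greater"
  coverage <- modes$coverage %||% "union"
  out_dir <- config$out_dir %||% abort("config needs 'out_dir'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
            parent = e)
    })
    inform(sprintf("[%s] done in %.2fs", name,
                   as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  mat <- stage("read-matrix",
               read_expression_matrix(inputs$matrix,
                                      dialect = inputs$dialect %||% "plain_tsv"))
  labels <- stage("read-labels", read_labels(inputs$labels))
  cohorts <- split_cohorts(mat, labels)
  inform(sprintf("[cohorts] %d controls, %d cases",
                 ncol(cohorts$controls) - 1L, ncol(cohorts$cases) - 1L))

  if (!is.null(inputs$stable_matrix)) {
    ext <- stage("read-stable-cohort",
                 read_expression_matrix(inputs$stable_matrix,
                                        dialect = inputs$stable_dialect %||%
                                          "plain_tsv"))
    stable <- stage("mine-stable", mine_stable_pairs(ext, stability))
    inform(sprintf("[mine-stable] %d stable pairs", nrow(stable)))
    stable <- stage("retain",
                    retain_in_cohort(stable, cohorts$controls, stability))
    inform(sprintf("[retain] %d pairs retained", nrow(stable)))
  } else {
    stable <- stage("mine-stable",
                    mine_stable_pairs(cohorts$controls, stability))
    inform(sprintf("[mine-stable] %d stable pairs", nrow(stable)))
  }
  paths <- list(stable_pairs = file.path(out_dir, "stable_pairs.tsv"))
  write_stable_pairs(stable, paths$stable_pairs)

  stats <- stage("test-reversal", {
    s <- contingency_counts(stable, cohorts$controls, cohorts$cases)
    s <- fisher_reversal_test(s, alternative = alternative)
    s$q_value <- bh_adjust(s$p_value)
    s
  })
  paths$pair_stats <- file.path(out_dir, "pair_stats.tsv")
  write_pair_stats(stats, paths$pair_stats)

  candidates <- stage("select-candidates",
                      select_candidates(stats, q_thr, min_rev))
  inform(sprintf("[select-candidates] %d candidates", nrow(candidates)))
  if (nrow(candidates) == 0) {
    abort("stage 'select-candidates' failed: no candidate pairs passed the thresholds")
  }
  paths$candidates <- file.path(out_dir, "candidates.tsv")
  write_pair_stats(candidates, paths$candidates)

  selection <- stage("build-classifier", {
    combos <- build_combinations(candidates, cohorts$cases, mode = coverage)
    ranked <- rank_by_frequency(combos)
    select_classifier(ranked, cohorts$cases, cohorts$controls,
                      max_top = max_top)
  })
  inform(sprintf("[build-classifier] chose n = %d (eval index %.4f)",
                 selection$chosen_n, selection$eval_index))
  paths$classifier <- file.path(out_dir, "classifier.json")
  write_classifier(selection$classifier, paths$classifier)
  paths$report <- file.path(out_dir, "selection_report.tsv")
  readr::write_tsv(selection$report, paths$report)

  predictions <- stage("predict", classify_matrix(mat, selection$classifier))
  paths$predictions <- file.path(out_dir, "predictions.tsv")
  readr::write_tsv(predictions, paths$predictions)

  metrics <- stage("evaluate", evaluate_predictions(predictions, labels))
  paths$metrics <- file.path(out_dir, "metrics.tsv")
  readr::write_tsv(metrics, paths$metrics)

  manifest <- list(
    package = "reopairs",
    version = as.character(utils::packageVersion("reopairs")),
    seed = config$seed %||% NA,
    thresholds = list(stability = stability, q = q_thr,
                      min_reversal = min_rev, max_top = max_top),
    modes = list(alternative = alternative, coverage = coverage),
    inputs = lapply(Filter(Negate(is.null),
                           inputs[intersect(names(inputs),
                                            c("matrix", "labels",
                                              "stable_matrix"))]),
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    counts = list(stable_pairs = nrow(stable),
                  candidates = nrow(candidates),
                  chosen_n = selection$chosen_n))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(selection = selection, predictions = predictions,
                 metrics = metrics, paths = paths))
}
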