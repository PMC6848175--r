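#' Run the full connectome analysis pipeline
#'
#' Sequences the package's stages over one output directory: obtain a cohort
#' (simulate one, or read one written by [write_cohort()]), run the TFNBS
#' omnibus test, post-hoc pairwise contrasts on the significant subnetwork,
#' and (optionally) the nested LOOCV classification. Every stage writes its
#' result as delimited text or JSON, and a run manifest records the package
#' version, configuration, seed, input checksums and timestamp, so a rerun
#' with the same configuration and seed reproduces the outputs byte for
#' byte.
#'
#' @param out_dir output directory (created if needed).
#' @param cohort optional [nos_cohort()]; if `NULL`, either `input_dir` is
#'   read or a cohort is simulated from `generator` arguments.
#' @param input_dir optional directory of a written cohort.
#' @param generator named list of arguments to [simulate_nos_cohort()]
#'   (ignored when a cohort is supplied or read).
#' @param tfnbs a [tfnbs_config()].
#' @param classifier a [classifier_config()] or `NULL` to skip
#'   classification.
#' @param contrast two group labels for the classification stage.
#' @param posthoc_perms permutations for the post-hoc stage.
#' @param seed integer seed governing every stochastic stage.
#' @return Invisibly, a list with the in-memory `cohort`, `tfnbs`
#'   ([tfnbs_inference()] result), `posthoc` data.frame (or `NULL` when no
#'   edge is significant) and `report` (classification, or `NULL`), plus
#'   `paths` of the written files.
#' @export
run_pipeline <- function(out_dir, cohort = NULL, input_dir = NULL,
                         generator = list(), tfnbs = tfnbs_config(),
                         classifier = classifier_config(),
                         contrast = c("MSA", "PD"), posthoc_perms = 10000,
                         seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohort)) {
    cohort <- if (!is.null(input_dir)) read_cohort(input_dir)
              else do.call(simulate_nos_cohort, c(generator, list(seed = seed)))
  }
  paths <- list(cohort = file.path(out_dir, "cohort"))
  write_cohort(cohort, paths$cohort)

  tfnbs$seed <- seed + 1L
  res <- tfnbs_inference(cohort, tfnbs)
  paths$stats <- file.path(out_dir, "edge_stats.csv")
  utils::write.csv(res$stats, paths$stats, row.names = FALSE)
  paths$subnetwork <- file.path(out_dir, "significant_subnetwork.csv")
  utils::write.csv(
    res$stats[res$stats$significant,
              c("roi_a", "roi_b", "f", "score", "p_fdr")],
    paths$subnetwork, row.names = FALSE
  )

  posthoc <- NULL
  if (length(res$significant)) {
    posthoc <- pairwise_posthoc(cohort, res$stats$edge[res$stats$significant],
                                n_perm = posthoc_perms, q = tfnbs$fdr_q,
                                seed = seed + 2L)
    paths$posthoc <- file.path(out_dir, "posthoc_contrasts.csv")
    utils::write.csv(posthoc, paths$posthoc, row.names = FALSE)
  }

  report <- NULL
  if (!is.null(classifier) && all(contrast %in% cohort$subjects$group)) {
    classifier$seed <- seed + 3L
    report <- loocv_classify(cohort, contrast = contrast, config = classifier)
    paths$folds <- file.path(out_dir, "classification_folds.csv")
    utils::write.csv(report$folds, paths$folds, row.names = FALSE)
    paths$stability <- file.path(out_dir, "feature_stability.csv")
    utils::write.csv(
      data.frame(feature = names(report$stability),
                 frequency = unname(report$stability)),
      paths$stability, row.names = FALSE
    )
    paths$report <- file.path(out_dir, "classification_report.json")
    jsonlite::write_json(
      list(contrast = contrast,
           metrics = lapply(report$metrics, function(v)
             if (is.numeric(v) && length(v) == 1) round(v, 2) else v),
           stable_features = names(report$stability[report$stability > 0.8])),
      paths$report, auto_unbox = TRUE, pretty = TRUE
    )
  }

  manifest <- list(
    package = "subconn",
    version = as.character(utils::packageVersion("subconn")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    tfnbs = unclass(tfnbs),
    classifier = if (is.null(classifier)) NULL else
      unclass(classifier)[c("c_grid", "inner_folds", "rfe_step", "k_fallback")],
    n_subjects = nrow(cohort$subjects),
    groups = as.list(table(cohort$subjects$group)),
    input_checksums = as.list(tools::md5sum(
      list.files(paths$cohort, recursive = TRUE, full.names = TRUE)
    ))
  )
  paths$manifest <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, tfnbs = res, posthoc = posthoc,
                 report = report, paths = paths))
}
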