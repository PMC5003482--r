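#' Configuration for the factorial benchmark
#'
#' @param strategies normalization strategies to evaluate.
#' @param approaches analytical approaches to evaluate (`"ttest"`,
#'   `"illumina"`, `"maxcover"`).
#' @param background apply background correction before normalization.
#' @param alpha significance threshold for the statistical approaches.
#' @param detection_threshold detection p-value threshold of the
#'   expressed-probe filter.
#' @param aggregate group-level detection aggregation (`"mean"` or `"min"`).
#' @param filter_first apply the detection filter before (instead of after)
#'   differential expression; the reference pipeline filters after, because
#'   the vendor software cannot drop probes before normalization.
#' @param fdr `NULL` or `"bh"` (passed to [ttest_de()]).
#' @param enrich_p,enrich_fold enrichment thresholds when an annotation is
#'   supplied.
#' @param maxcover list of arguments forwarded to [maxcover_de()].
#' @param seed master seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(strategies = c("none", "average", "cubic_spline",
                                            "quantile", "rank_invariant"),
                             approaches = c("ttest", "illumina", "maxcover"),
                             background = TRUE, alpha = 0.05,
                             detection_threshold = 0.01,
                             aggregate = "mean", filter_first = FALSE,
                             fdr = NULL, enrich_p = 0.05, enrich_fold = NULL,
                             maxcover = list(), seed = 1L) {
  stopifnot(length(strategies) >= 1L, length(approaches) >= 1L,
            alpha > 0, alpha < 1)
  structure(list(strategies = strategies, approaches = approaches,
                 background = background, alpha = alpha,
                 detection_threshold = detection_threshold,
                 aggregate = aggregate, filter_first = filter_first,
                 fdr = fdr, enrich_p = enrich_p, enrich_fold = enrich_fold,
                 maxcover = maxcover, seed = as.integer(seed)),
            class = "benchmark_config")
}

run_de_approach <- function(approach, norm, labels, cfg) {
  switch(approach,
         ttest = ttest_de(norm, labels, alpha = cfg$alpha, fdr = cfg$fdr),
         illumina = illumina_custom_de(norm, labels, alpha = cfg$alpha),
         maxcover = do.call(maxcover_de,
                            c(list(norm = norm, labels = labels),
                              cfg$maxcover)),
         stop("unknown approach: ", approach))
}

#' Run the factorial normalization x approach benchmark
#'
#' For every (strategy, approach) cell: optional background correction, then
#' normalization, then differential expression, then the detection-p filter
#' (after DE by default).  Produces one probe set per cell plus
#' cross-strategy concordance per approach, cross-approach concordance per
#' strategy and, when a pathway annotation is supplied, per-cell enrichment
#' with pathway concordance per strategy.  A stage error aborts only its
#' cell and is recorded in the manifest; the bundle is still produced.
#'
#' @param mat a [bead_summary_matrix()] with negative controls.
#' @param labels a [class_labels()].
#' @param annotation optional [pathway_annotation()].
#' @param config a [benchmark_config()].
#' @param out_dir optional directory; when given, probe-set tables,
#'   concordance reports and a JSON `manifest.json` are written there.
#' @return A list (invisibly when `out_dir` is used) with `probe_sets`
#'   (nested approach -> strategy), `strategy_concordance`,
#'   `approach_concordance`, `enrichment`, `pathway_concordance`, `manifest`.
#' @export
run_benchmark <- function(mat, labels, annotation = NULL,
                          config = benchmark_config(), out_dir = NULL) {
  stopifnot(inherits(mat, "bead_summary_matrix"))
  labels <- as_class_labels(labels)
  check_labels_cover(labels, sample_ids(mat))
  cfg <- config
  set.seed(cfg$seed)

  det <- detection_pvalues(mat, labels, aggregate = cfg$aggregate)
  base <- if (cfg$background) background_correct(mat) else mat
  if (cfg$filter_first) {
    keep <- filter_unexpressed(probe_ids(base), det,
                               threshold = cfg$detection_threshold)
    base <- subset_probes(base, keep)
  }

  cells <- list()
  sets <- list()
  for (strategy in cfg$strategies) {
    norm <- tryCatch(normalize_signal(base, strategy), error = identity)
    for (approach in cfg$approaches) {
      key <- paste(strategy, approach, sep = ".")
      cell <- tryCatch({
        if (inherits(norm, "error")) stop(conditionMessage(norm))
        ps <- run_de_approach(approach, norm, labels, cfg)
        if (!cfg$filter_first)
          ps <- filter_unexpressed(ps, det,
                                   threshold = cfg$detection_threshold)
        ps
      }, error = identity)
      if (inherits(cell, "error")) {
        cells[[key]] <- list(strategy = strategy, approach = approach,
                             status = "error",
                             message = conditionMessage(cell))
      } else {
        cells[[key]] <- list(strategy = strategy, approach = approach,
                             status = "ok", n_probes = length(cell$probe_ids))
        sets[[approach]][[strategy]] <- cell
      }
    }
  }

  strat_conc <- lapply(sets, function(by_strategy) {
    if (length(by_strategy) < 2L) return(NULL)
    tryCatch(strategy_concordance(by_strategy),
             error = function(e) conditionMessage(e))
  })
  appr_conc <- list()
  for (strategy in cfg$strategies) {
    by_approach <- lapply(sets, `[[`, strategy)
    by_approach <- by_approach[!vapply(by_approach, is.null, TRUE)]
    if (length(by_approach) >= 2L)
      appr_conc[[strategy]] <- approach_concordance(by_approach)
  }

  enrichment <- NULL
  path_conc <- NULL
  if (!is.null(annotation)) {
    enrichment <- list()
    path_sets_by_strategy <- list()
    for (approach in names(sets)) {
      for (strategy in names(sets[[approach]])) {
        er <- enrich_pathways(sets[[approach]][[strategy]], annotation,
                              p_cutoff = cfg$enrich_p,
                              fold_cutoff = cfg$enrich_fold)
        enrichment[[paste(strategy, approach, sep = ".")]] <- er
        path_sets_by_strategy[[strategy]][[approach]] <-
          er$pathway_id[er$significant]
      }
    }
    path_conc <- lapply(path_sets_by_strategy, function(ps) {
      if (length(ps) >= 2L) pathway_concordance(ps) else NULL
    })
  }

  manifest <- list(
    config = list(strategies = cfg$strategies, approaches = cfg$approaches,
                  background = cfg$background, alpha = cfg$alpha,
                  detection_threshold = cfg$detection_threshold,
                  aggregate = cfg$aggregate, filter_first = cfg$filter_first,
                  fdr = cfg$fdr, seed = cfg$seed),
    n_probes = nrow(mat$signal), n_samples = ncol(mat$signal),
    probe_sets = unname(cells))

  bundle <- list(probe_sets = sets, strategy_concordance = strat_conc,
                 approach_concordance = appr_conc, enrichment = enrichment,
                 pathway_concordance = path_conc, manifest = manifest)
  if (!is.null(out_dir)) {
    write_benchmark_bundle(bundle, out_dir)
    return(invisible(bundle))
  }
  bundle
}

write_benchmark_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (approach in names(bundle$probe_sets)) {
    for (strategy in names(bundle$probe_sets[[approach]])) {
      write_probe_set(bundle$probe_sets[[approach]][[strategy]],
                      file.path(out_dir, sprintf("probeset_%s_%s.tsv",
                                                 strategy, approach)))
    }
  }
  for (approach in names(bundle$strategy_concordance)) {
    sc <- bundle$strategy_concordance[[approach]]
    if (is.list(sc))
      write.table(sc$per_strategy,
                  file.path(out_dir,
                            sprintf("strategy_concordance_%s.tsv", approach)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (strategy in names(bundle$approach_concordance)) {
    write.table(bundle$approach_concordance[[strategy]]$counts,
                file.path(out_dir,
                          sprintf("approach_concordance_%s.tsv", strategy)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$enrichment)) {
    for (key in names(bundle$enrichment))
      write.table(bundle$enrichment[[key]],
                  file.path(out_dir, sprintf("enrichment_%s.tsv", key)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}
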