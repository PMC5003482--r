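#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a bead-summary matrix
#'
#' The central container: a probes x samples matrix of averaged bead
#' intensities with optional per-cell bead standard errors and detection
#' p-values, plus (optionally) the raw negative-control probe signals per
#' sample that background correction and detection p-values are computed
#' against.
#'
#' @param signal numeric matrix, probes x samples, with unique row and column
#'   names.  Intensities are on the native fluorescence scale; they may become
#'   negative after background correction.
#' @param bead_se optional numeric matrix of technical standard errors of the
#'   per-probe bead averages, same dimensions and dimnames as `signal`.
#' @param detection_p optional numeric matrix of detection p-values in
#'   \[0, 1\], same dimensions as `signal`.
#' @param neg_control optional list with elements `probe_ids` (character) and
#'   `signal` (controls x samples numeric matrix, columns matching
#'   `colnames(signal)`), giving raw negative-control bead-summary values.
#' @param background_corrected logical provenance flag; set by
#'   [background_correct()], which refuses to run twice.
#' @return An object of class `bead_summary_matrix`.
#' @seealso [read_bead_summary()], [simulate_experiment()]
#' @export
bead_summary_matrix <- function(signal, bead_se = NULL, detection_p = NULL,
                                neg_control = NULL,
                                background_corrected = FALSE) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("'signal' must be a numeric matrix")
  if (is.null(rownames(signal)) || is.null(colnames(signal)))
    stop("'signal' must have probe row names and sample column names")
  if (anyDuplicated(rownames(signal)))
    stop("duplicate probe ID: ",
         rownames(signal)[duplicated(rownames(signal))][1L])
  if (anyDuplicated(colnames(signal)))
    stop("duplicate sample ID: ",
         colnames(signal)[duplicated(colnames(signal))][1L])
  for (nm in c("bead_se", "detection_p")) {
    m <- get(nm)
    if (!is.null(m)) {
      if (!is.matrix(m) || !identical(dim(m), dim(signal)))
        stop("'", nm, "' must share the dimensions of 'signal'")
      dimnames(m) <- dimnames(signal)
      assign(nm, m)
    }
  }
  if (!is.null(detection_p)) {
    dp <- detection_p[!is.na(detection_p)]
    if (length(dp) && (min(dp) < 0 || max(dp) > 1))
      stop("detection p-values must lie in [0, 1]")
  }
  if (!is.null(neg_control)) {
    if (!is.list(neg_control) || is.null(neg_control$signal))
      stop("'neg_control' must be a list with a 'signal' matrix")
    nc <- neg_control$signal
    if (!is.matrix(nc) || ncol(nc) != ncol(signal))
      stop("negative-control matrix must have one column per sample")
    colnames(nc) <- colnames(signal)
    if (is.null(neg_control$probe_ids))
      neg_control$probe_ids <- rownames(nc) %||%
        sprintf("NC%04d", seq_len(nrow(nc)))
    rownames(nc) <- neg_control$probe_ids
    neg_control$signal <- nc
  }
  structure(
    list(signal = signal, bead_se = bead_se, detection_p = detection_p,
         neg_control = neg_control,
         background_corrected = isTRUE(background_corrected)),
    class = "bead_summary_matrix")
}

#' @export
print.bead_summary_matrix <- function(x, ...) {
  cat(sprintf("bead_summary_matrix: %d probes x %d samples\n",
              nrow(x$signal), ncol(x$signal)))
  cat(sprintf("  bead SE: %s | detection p: %s | neg controls: %s | background-corrected: %s\n",
              if (is.null(x$bead_se)) "absent" else "present",
              if (is.null(x$detection_p)) "absent" else "present",
              if (is.null(x$neg_control)) "absent"
              else sprintf("%d probes", nrow(x$neg_control$signal)),
              x$background_corrected))
  invisible(x)
}

#' @export
dim.bead_summary_matrix <- function(x) dim(x$signal)

#' Probe and sample identifiers of a bead-summary matrix
#' @param x a `bead_summary_matrix`.
#' @return Character vector of IDs.
#' @export
probe_ids <- function(x) rownames(x$signal)

#' @rdname probe_ids
#' @export
sample_ids <- function(x) colnames(x$signal)

#' Subset a bead-summary matrix to a set of probes
#' @param x a `bead_summary_matrix`.
#' @param probes character vector of probe IDs to keep (order preserved).
#' @return A `bead_summary_matrix`.
#' @export
subset_probes <- function(x, probes) {
  missing <- setdiff(probes, probe_ids(x))
  if (length(missing))
    stop("unknown probe ID(s): ", paste(head(missing, 3), collapse = ", "))
  bead_summary_matrix(
    x$signal[probes, , drop = FALSE],
    bead_se = if (!is.null(x$bead_se)) x$bead_se[probes, , drop = FALSE],
    detection_p = if (!is.null(x$detection_p))
      x$detection_p[probes, , drop = FALSE],
    neg_control = x$neg_control,
    background_corrected = x$background_corrected)
}

#' Per-sample negative-control summaries
#'
#' @param x a `bead_summary_matrix` with negative controls attached.
#' @return data.frame with columns `sample`, `count`, `mean`, `sd`.
#' @export
neg_control_stats <- function(x) {
  if (is.null(x$neg_control))
    stop("no negative-control data attached to this matrix")
  nc <- x$neg_control$signal
  data.frame(sample = colnames(nc), count = rep(nrow(nc), ncol(nc)),
             mean = colMeans(nc), sd = apply(nc, 2, sd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-class sample labels
#'
#' @param assignment named character vector or factor mapping sample IDs to
#'   exactly two class labels, or a data.frame with columns `sample` and
#'   `class`.
#' @param control which label is the control (baseline) class.  Defaults to a
#'   label named `"control"` when present, otherwise the alphabetically first
#'   label.
#' @return An object of class `class_labels` with elements `assignment`
#'   (named character), `control` and `test` (the two labels).
#' @export
class_labels <- function(assignment, control = NULL) {
  if (is.data.frame(assignment)) {
    if (!all(c("sample", "class") %in% names(assignment)))
      stop("data.frame labels need 'sample' and 'class' columns")
    assignment <- setNames(as.character(assignment$class),
                           as.character(assignment$sample))
  }
  assignment <- setNames(as.character(assignment), names(assignment))
  if (is.null(names(assignment)) || any(!nzchar(names(assignment))))
    stop("class assignment must be named by sample ID")
  if (anyDuplicated(names(assignment)))
    stop("duplicate sample ID in class assignment")
  lev <- sort(unique(assignment))
  if (length(lev) != 2L)
    stop("exactly two classes required, got: ", paste(lev, collapse = ", "))
  if (is.null(control))
    control <- if ("control" %in% lev) "control" else lev[1L]
  if (!control %in% lev) stop("'control' is not one of the class labels")
  sizes <- table(assignment)
  if (any(sizes < 2L))
    stop("each class needs at least 2 samples")
  if (any(sizes < 4L))
    warning("fewer than 4 replicates in a class; the design targets n >= 4 per group")
  structure(list(assignment = assignment, control = control,
                 test = setdiff(lev, control)),
            class = "class_labels")
}

as_class_labels <- function(x) {
  if (inherits(x, "class_labels")) x else class_labels(x)
}

#' Sample IDs of each class
#' @param labels a `class_labels` object.
#' @return Named list with elements `control` and `test`.
#' @export
class_members <- function(labels) {
  labels <- as_class_labels(labels)
  list(control = names(labels$assignment)[labels$assignment == labels$control],
       test = names(labels$assignment)[labels$assignment == labels$test])
}

check_labels_cover <- function(labels, samples) {
  missing <- setdiff(samples, names(labels$assignment))
  if (length(missing))
    stop("samples without class assignment: ",
         paste(head(missing, 3), collapse = ", "))
  invisible(labels)
}

#' Pathway annotation for over-representation analysis
#'
#' @param pathways named list; each element a character vector of gene IDs.
#' @param probe_to_gene named character vector mapping probe IDs to gene IDs.
#' @param background character vector of gene IDs on the array (the
#'   enrichment universe).  Defaults to all genes in `probe_to_gene`.
#' @return An object of class `pathway_annotation`.
#' @export
pathway_annotation <- function(pathways, probe_to_gene,
                               background = unique(unname(probe_to_gene))) {
  if (is.null(names(pathways)) || anyDuplicated(names(pathways)))
    stop("pathways must be uniquely named")
  if (any(lengths(pathways) == 0L)) stop("empty pathway gene set")
  background <- unique(as.character(background))
  annotated <- unique(unlist(pathways, use.names = FALSE))
  out <- setdiff(annotated, background)
  if (length(out))
    stop("annotated gene(s) missing from background: ",
         paste(head(out, 3), collapse = ", "))
  structure(list(pathways = lapply(pathways, unique),
                 probe_to_gene = probe_to_gene, background = background),
            class = "pathway_annotation")
}

#' A set of selected probes with per-probe scores and provenance
#'
#' @param ids character vector of selected probe IDs (unique, ordered).
#' @param scores data.frame with columns `probe_id`, `statistic`, `p_value`,
#'   `direction` for the selected probes (p_value may be `NA` for
#'   non-statistical selectors).
#' @param provenance named list recording at least `strategy`, `approach` and
#'   `filtered`.
#' @param table optional full per-probe results table (all tested probes).
#' @return An object of class `probe_set`.
#' @export
probe_set <- function(ids, scores = NULL, provenance = list(), table = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("probe IDs in a probe set must be unique")
  if (is.null(scores)) {
    scores <- data.frame(probe_id = ids,
                         statistic = rep(NA_real_, length(ids)),
                         p_value = rep(NA_real_, length(ids)),
                         direction = rep(NA_integer_, length(ids)),
                         stringsAsFactors = FALSE)
  }
  if (!setequal(scores$probe_id, ids))
    stop("scores must cover exactly the selected probes")
  pv <- scores$p_value[!is.na(scores$p_value)]
  if (length(pv) && (min(pv) < 0 || max(pv) > 1))
    stop("p-values must lie in [0, 1]")
  provenance <- modifyList(
    list(strategy = NA_character_, approach = NA_character_, filtered = FALSE),
    provenance)
  structure(list(probe_ids = ids,
                 scores = scores[match(ids, scores$probe_id), , drop = FALSE],
                 provenance = provenance, table = table),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("probe_set: %d probes (approach=%s, strategy=%s, filtered=%s)\n",
              length(x$probe_ids), x$provenance$approach,
              x$provenance$strategy, x$provenance$filtered))
  invisible(x)
}

#' @export
length.probe_set <- function(x) length(x$probe_ids)

as_probe_ids <- function(x) {
  if (inherits(x, "probe_set")) x$probe_ids else as.character(x)
}
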