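#' Background-correct a bead-summary matrix
#'
#' Subtracts each sample's mean negative-control signal from every probe
#' signal in that sample.  Negative results are retained as-is (no clipping:
#' the downstream quantile and rank operations are order-based, and clipping
#' would create artificial ties).  Bead standard errors are unchanged.  The
#' matrix is flagged as corrected; correcting twice is an error.
#'
#' @param m a [bead_summary_matrix()] with negative controls attached.
#' @return A corrected `bead_summary_matrix`.
#' @export
background_correct <- function(m) {
  stopifnot(inherits(m, "bead_summary_matrix"))
  if (m$background_corrected)
    stop("matrix is already background-corrected")
  if (is.null(m$neg_control))
    stop("background correction needs negative-control data for every sample")
  means <- colMeans(m$neg_control$signal)
  bead_summary_matrix(sweep(m$signal, 2, means, `-`),
                      bead_se = m$bead_se, detection_p = m$detection_p,
                      neg_control = m$neg_control,
                      background_corrected = TRUE)
}

#' Empirical detection p-values against negative-control probes
#'
#' The detection p-value estimates the probability of seeing a probe's signal
#' without probe-target hybridization.  With `N` raw negative-control values
#' in a sample, the add-one empirical estimate is
#' `p = (#\{controls >= signal\} + 1) / (N + 1)`, which stays in `(0, 1]` and
#' is antitone in signal.  Detection is computed on uncorrected signals so
#' that background correction cannot flip detection calls.
#'
#' @param m an uncorrected [bead_summary_matrix()] with raw negative-control
#'   values.
#' @param labels optional [class_labels()]; when given, per-group detection
#'   p-values are added.
#' @param aggregate how to aggregate per-sample p-values within a group:
#'   `"mean"` (default) or `"min"`.
#' @return A `detection_matrix`: list with `detection_p` (probe x sample),
#'   `group_detection_p` (probe x 2, when labels given), `method` and
#'   `aggregate` tags.
#' @export
detection_pvalues <- function(m, labels = NULL,
                              aggregate = c("mean", "min")) {
  stopifnot(inherits(m, "bead_summary_matrix"))
  aggregate <- match.arg(aggregate)
  if (m$background_corrected)
    stop("detection p-values are defined on uncorrected signals; ",
         "compute them before background_correct()")
  if (is.null(m$neg_control))
    stop("no raw negative-control values available")
  ctrl <- m$neg_control$signal
  if (nrow(ctrl) < 10L)
    warning("fewer than 10 negative controls; detection p-values will be coarse")
  N <- nrow(ctrl)
  detp <- m$signal
  for (s in seq_len(ncol(detp))) {
    v <- sort(ctrl[, s])
    n_lt <- findInterval(m$signal[, s], v, left.open = TRUE)  # controls < x
    detp[, s] <- (N - n_lt + 1) / (N + 1)
  }
  out <- list(detection_p = detp, group_detection_p = NULL,
              method = "empirical_add_one", aggregate = aggregate)
  if (!is.null(labels)) {
    labels <- as_class_labels(labels)
    check_labels_cover(labels, colnames(detp))
    grp <- class_members(labels)
    agg <- switch(aggregate, mean = rowMeans,
                  min = function(x) apply(x, 1, min))
    out$group_detection_p <- cbind(
      control = agg(detp[, grp$control, drop = FALSE]),
      test = agg(detp[, grp$test, drop = FALSE]))
  }
  structure(out, class = "detection_matrix")
}

#' Remove probes at background level in both groups
#'
#' A probe is eliminated if and only if its group-level detection p-value
#' exceeds `threshold` in *both* classes (strict inequality), i.e. it is
#' undetected in control and test alike.  Mirroring the reference pipeline,
#' this filter is applied *after* normalization and differential-expression
#' analysis.
#'
#' @param ps a [probe_set()] (or character vector of probe IDs).
#' @param det a `detection_matrix` from [detection_pvalues()] with group
#'   p-values.
#' @param threshold detection p-value threshold (default 0.01, the 1% false
#'   positive rate recommended by the array vendor).
#' @return The filtered `probe_set` (provenance gains `filtered = TRUE` and
#'   the threshold).
#' @export
filter_unexpressed <- function(ps, det, threshold = 0.01) {
  if (!inherits(det, "detection_matrix") || is.null(det$group_detection_p))
    stop("'det' must be a detection_matrix with group-level p-values")
  ids <- as_probe_ids(ps)
  missing <- setdiff(ids, rownames(det$group_detection_p))
  if (length(missing))
    stop("probe(s) absent from the detection matrix: ",
         paste(head(missing, 3), collapse = ", "))
  g <- det$group_detection_p[ids, , drop = FALSE]
  keep <- ids[!(g[, "control"] > threshold & g[, "test"] > threshold)]
  if (inherits(ps, "probe_set")) {
    prov <- ps$provenance
    prov$filtered <- TRUE
    prov$detection_threshold <- threshold
    probe_set(keep,
              scores = ps$scores[ps$scores$probe_id %in% keep, , drop = FALSE],
              provenance = prov, table = ps$table)
  } else keep
}
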