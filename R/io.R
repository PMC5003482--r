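#' Column-naming dialect for bead-summary exports
#'
#' GenomeStudio "Sample Probe Profile" exports place one probe per row with
#' per-sample column triplets.  Export layouts vary by software version, so
#' the statistic prefixes are configurable; columns are expected to be named
#' `"<STAT>.<sample>"` (for example `AVG_Signal.S1`).
#'
#' @param probe_id name of the probe identifier column.
#' @param signal,se,detection statistic prefixes for the average signal, bead
#'   standard error and detection p-value columns.
#' @return A named list used as the `dialect` argument of
#'   [read_bead_summary()] and [write_bead_summary()].
#' @export
bead_dialect <- function(probe_id = "ProbeID", signal = "AVG_Signal",
                         se = "BEAD_STDERR", detection = "Detection.Pval") {
  list(probe_id = probe_id, signal = signal, se = se, detection = detection)
}

parse_numeric_columns <- function(df, cols, path) {
  out <- matrix(NA_real_, nrow(df), length(cols),
                dimnames = list(NULL, cols))
  for (cn in cols) {
    v <- df[[cn]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & trimws(as.character(v)) != "")
    if (length(bad))
      stop(sprintf("non-numeric cell in '%s': row %d, column '%s' (value '%s')",
                   path, bad[1L], cn, v[bad[1L]]))
    out[, cn] <- num
  }
  out
}

#' Read a GenomeStudio-style bead-summary table
#'
#' Parses a tab-delimited probe profile with one probe per row and per-sample
#' `AVG_Signal` (required), `BEAD_STDERR` and `Detection Pval` (optional)
#' columns.  Sample order follows the order of the `AVG_Signal` columns.
#' Missing optional statistics yield absent fields, never zeros.
#'
#' @param path path to the tab-delimited file.
#' @param dialect column-naming configuration from [bead_dialect()].
#' @param control_probes optional character vector of probe IDs that are
#'   negative-control probes; their rows are moved into the `neg_control`
#'   slot.
#' @param controls_path optional path to a separate bead-summary table (same
#'   dialect) holding only negative-control probes.
#' @return A [bead_summary_matrix()].
#' @export
read_bead_summary <- function(path, dialect = bead_dialect(),
                              control_probes = NULL, controls_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   stringsAsFactors = FALSE)
  if (!dialect$probe_id %in% names(df))
    stop("missing probe-ID column '", dialect$probe_id, "' in ", path)
  ids <- df[[dialect$probe_id]]
  if (anyDuplicated(ids))
    stop("duplicate probe ID in ", path, ": ", ids[duplicated(ids)][1L])

  split_stat <- function(prefix) {
    pre <- paste0(prefix, ".")
    cols <- names(df)[startsWith(names(df), pre)]
    setNames(substring(cols, nchar(pre) + 1L), cols)
  }
  if (any(names(df) == dialect$signal))
    stop("'", dialect$signal, "' column without a sample name in ", path)
  sig_cols <- split_stat(dialect$signal)
  if (!length(sig_cols))
    stop("no '", dialect$signal, ".<sample>' columns found in ", path)
  if (any(!nzchar(sig_cols)))
    stop("'", dialect$signal, "' column without a sample name in ", path)
  samples <- unname(sig_cols)

  grab <- function(prefix) {
    cols <- split_stat(prefix)
    if (!length(cols)) return(NULL)
    extra <- setdiff(unname(cols), samples)
    if (length(extra))
      stop("'", prefix, "' column for unknown sample: ", extra[1L])
    if (!setequal(unname(cols), samples))
      stop("'", prefix, "' columns present for only a subset of samples")
    m <- parse_numeric_columns(df, names(cols)[match(samples, unname(cols))],
                               path)
    dimnames(m) <- list(ids, samples)
    m
  }
  signal <- parse_numeric_columns(df, names(sig_cols), path)
  dimnames(signal) <- list(ids, samples)
  bead_se <- grab(dialect$se)
  detection_p <- grab(dialect$detection)

  neg_control <- NULL
  if (!is.null(controls_path)) {
    cm <- read_bead_summary(controls_path, dialect = dialect)
    if (!setequal(sample_ids(cm), samples))
      stop("control file samples do not match the main table")
    neg_control <- list(probe_ids = probe_ids(cm),
                        signal = cm$signal[, samples, drop = FALSE])
  } else if (!is.null(control_probes)) {
    missing <- setdiff(control_probes, ids)
    if (length(missing))
      stop("control probe(s) absent from table: ",
           paste(head(missing, 3), collapse = ", "))
    neg_control <- list(probe_ids = control_probes,
                        signal = signal[control_probes, , drop = FALSE])
    keep <- setdiff(ids, control_probes)
    signal <- signal[keep, , drop = FALSE]
    if (!is.null(bead_se)) bead_se <- bead_se[keep, , drop = FALSE]
    if (!is.null(detection_p)) detection_p <- detection_p[keep, , drop = FALSE]
  }
  bead_summary_matrix(signal, bead_se = bead_se, detection_p = detection_p,
                      neg_control = neg_control)
}

#' Write a bead-summary matrix as a GenomeStudio-style table
#'
#' Emits a tab-delimited file with one probe per row and a deterministic
#' column order: the probe-ID column, then for each sample `AVG_Signal`,
#' `BEAD_STDERR` (if present) and `Detection Pval` (if present).  The file is
#' the exact inverse of [read_bead_summary()].
#'
#' @param m a [bead_summary_matrix()].
#' @param path output path for the probe table.
#' @param dialect column-naming configuration from [bead_dialect()].
#' @param controls_path optional path; when given and `m` carries negative
#'   controls, they are written there in the same format.
#' @return `path`, invisibly.
#' @export
write_bead_summary <- function(m, path, dialect = bead_dialect(),
                               controls_path = NULL) {
  stopifnot(inherits(m, "bead_summary_matrix"))
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))  # lossless
  build <- function(signal, bead_se, detection_p) {
    df <- data.frame(rownames(signal), stringsAsFactors = FALSE,
                     check.names = FALSE)
    names(df) <- dialect$probe_id
    for (s in colnames(signal)) {
      df[[paste0(dialect$signal, ".", s)]] <- fmt(signal[, s])
      if (!is.null(bead_se))
        df[[paste0(dialect$se, ".", s)]] <- fmt(bead_se[, s])
      if (!is.null(detection_p))
        df[[paste0(dialect$detection, ".", s)]] <- fmt(detection_p[, s])
    }
    df
  }
  wr <- function(df, p) {
    con <- tryCatch(file(p, "w"), error = function(e)
      stop("cannot open '", p, "' for writing: ", conditionMessage(e)))
    on.exit(close(con))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(build(m$signal, m$bead_se, m$detection_p), path)
  if (!is.null(controls_path) && !is.null(m$neg_control))
    wr(build(m$neg_control$signal, NULL, NULL), controls_path)
  invisible(path)
}

#' Read / write a two-column sample-to-class table
#'
#' @param path tab-delimited file with columns `sample` and `class`.
#' @param ... passed to [class_labels()].
#' @return [read_class_labels()] returns a `class_labels` object.
#' @export
read_class_labels <- function(path, ...) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  class_labels(df, ...)
}

#' @rdname read_class_labels
#' @param labels a `class_labels` object.
#' @export
write_class_labels <- function(labels, path) {
  labels <- as_class_labels(labels)
  write.table(data.frame(sample = names(labels$assignment),
                         class = unname(labels$assignment)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT pathway file and a probe-to-gene map
#'
#' GMT lines are `pathway_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' The probe map is a two-column tab-delimited table (`probe_id`, `gene_id`).
#'
#' @param gmt_path path to the GMT file.
#' @param map_path path to the probe-to-gene table.
#' @param background optional gene universe; defaults to all mapped genes.
#' @return A [pathway_annotation()].
#' @export
read_pathway_annotation <- function(gmt_path, map_path, background = NULL) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], " (need id, description, >=1 gene)")
  pathways <- setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                       vapply(parts, `[[`, "", 1L))
  map <- read.delim(map_path, stringsAsFactors = FALSE)
  if (ncol(map) < 2L) stop("probe-to-gene map needs two columns")
  probe_to_gene <- setNames(as.character(map[[2L]]), as.character(map[[1L]]))
  if (is.null(background)) background <- unique(unname(probe_to_gene))
  pathway_annotation(pathways, probe_to_gene, background = background)
}

#' @rdname read_pathway_annotation
#' @param ann a `pathway_annotation`.
#' @export
write_pathway_annotation <- function(ann, gmt_path, map_path) {
  lines <- vapply(names(ann$pathways), function(p)
    paste(c(p, "na", ann$pathways[[p]]), collapse = "\t"), "")
  writeLines(lines, gmt_path)
  write.table(data.frame(probe_id = names(ann$probe_to_gene),
                         gene_id = unname(ann$probe_to_gene)),
              map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(gmt_path)
}

#' Read / write a probe-set results table
#'
#' Four tab-delimited columns: `probe_id`, `statistic`, `p_value`,
#' `direction`.
#'
#' @param path file path.
#' @param provenance provenance list attached to the returned set.
#' @return [read_probe_set()] returns a `probe_set`.
#' @export
read_probe_set <- function(path, provenance = list()) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "statistic", "p_value", "direction")
  if (!all(need %in% names(df)))
    stop("probe-set table needs columns: ", paste(need, collapse = ", "))
  probe_set(df$probe_id, scores = df[need], provenance = provenance)
}

#' @rdname read_probe_set
#' @param ps a `probe_set`.
#' @export
write_probe_set <- function(ps, path) {
  write.table(ps$scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
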