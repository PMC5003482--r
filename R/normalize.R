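signal_of <- function(x) {
  if (inherits(x, "bead_summary_matrix")) x$signal
  else if (inherits(x, "normalization_result")) x$signal
  else if (is.matrix(x)) x
  else stop("expected a matrix, bead_summary_matrix or normalization_result")
}

new_norm_result <- function(input, signal, strategy, diagnostics = list()) {
  raw <- signal_of(input)
  diagnostics$scale_factors <- colMeans(signal) / colMeans(raw)
  out <- list(signal = signal, strategy = strategy, diagnostics = diagnostics,
              matrix = NULL)
  if (inherits(input, "bead_summary_matrix")) {
    out$matrix <- bead_summary_matrix(
      signal, bead_se = input$bead_se, detection_p = input$detection_p,
      neg_control = input$neg_control,
      background_corrected = input$background_corrected)
  }
  structure(out, class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf("normalization_result (%s): %d probes x %d samples\n",
              x$strategy, nrow(x$signal), ncol(x$signal)))
  invisible(x)
}

#' Normalize bead-summary signals
#'
#' Dispatches to one of the five strategies of the factorial evaluation:
#' `none` (identity), `average` (scaling to the grand mean of sample means),
#' `quantile` (classical order-statistic averaging), `cubic_spline`
#' (monotone spline through quantile anchors against the per-rank mean
#' reference curve), or `rank_invariant` (smooth scaling curve fitted through
#' probes whose rank is stable against a reference sample).
#'
#' @param m a [bead_summary_matrix()] or a probes x samples numeric matrix.
#' @param strategy one of `"none"`, `"average"`, `"quantile"`,
#'   `"cubic_spline"`, `"rank_invariant"`.
#' @param ... passed to the strategy function.
#' @return A `normalization_result`: list with `signal` (normalized matrix),
#'   `strategy`, `diagnostics` (always includes per-sample `scale_factors` =
#'   mean out / mean in; strategy-specific entries are documented in each
#'   `normalize_*` function) and, when the input was a bead-summary matrix,
#'   `matrix` (the input with normalized signal).
#' @export
normalize_signal <- function(m, strategy = c("none", "average", "quantile",
                                             "cubic_spline",
                                             "rank_invariant"), ...) {
  switch(match.arg(strategy),
         none = normalize_none(m),
         average = normalize_average(m),
         quantile = normalize_quantile(m),
         cubic_spline = normalize_cubic_spline(m, ...),
         rank_invariant = normalize_rank_invariant(m, ...))
}

#' @rdname normalize_signal
#' @export
normalize_none <- function(m) {
  new_norm_result(m, signal_of(m), "none")
}

#' @rdname normalize_signal
#' @details `average`: each sample is rescaled multiplicatively so that its
#'   mean equals the grand mean of all sample means; the per-sample factors
#'   are recorded in `diagnostics$factors`.  A sample whose mean is <= 0
#'   (possible after background correction) cannot be scaled and is an error.
#' @export
normalize_average <- function(m) {
  x <- signal_of(m)
  means <- colMeans(x)
  if (any(means <= 0))
    stop("cannot average-normalize: sample(s) with mean <= 0: ",
         paste(colnames(x)[means <= 0], collapse = ", "))
  factors <- mean(means) / means
  new_norm_result(m, sweep(x, 2, factors, `*`), "average",
                  list(factors = factors))
}

#' @rdname normalize_signal
#' @details `quantile`: for each rank, every sample's order statistic is
#'   replaced by the mean of all samples' order statistics; tied values
#'   receive the mean of the reference values over the ranks they cover.
#' @export
normalize_quantile <- function(m) {
  x <- signal_of(m)
  if (ncol(x) < 2L) stop("quantile normalization needs >= 2 samples")
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    xs <- x[o, j]
    grp <- cumsum(c(TRUE, diff(xs) != 0))           # tie groups, rank order
    vals <- vapply(split(ref, grp), mean, 0)
    out[o, j] <- vals[grp]
  }
  new_norm_result(m, out, "quantile")
}

# monotone interpolator through (ax, ay) with linear extension of the
# boundary segments beyond the anchor range
monotone_map <- function(ax, ay) {
  keep <- !duplicated(ax)
  ax <- ax[keep]; ay <- cummax(ay[keep])
  if (length(ax) < 2L) {
    off <- ay[1L] - ax[1L]
    return(function(x) x + off)
  }
  f <- splinefun(ax, ay, method = "monoH.FC")
  k <- length(ax)
  slo <- (ay[2L] - ay[1L]) / (ax[2L] - ax[1L])
  shi <- (ay[k] - ay[k - 1L]) / (ax[k] - ax[k - 1L])
  function(x) {
    y <- f(x)
    lo <- x < ax[1L]; hi <- x > ax[k]
    y[lo] <- ay[1L] + slo * (x[lo] - ax[1L])
    y[hi] <- ay[k] + shi * (x[hi] - ax[k])
    y
  }
}

#' @rdname normalize_signal
#' @param n_anchors number of quantile anchors for the cubic-spline strategy
#'   (>= 4).
#' @details `cubic_spline`: the reference curve is the per-rank mean of order
#'   statistics (the same target as quantile normalization).  For each sample
#'   a monotone cubic spline is fitted through `n_anchors` evenly spaced
#'   quantile anchor pairs (sample quantile -> reference quantile) and applied
#'   to all values; values outside the anchor range follow the linear
#'   extension of the boundary segments.  Anchors are recorded in
#'   `diagnostics$anchors`.
#' @export
normalize_cubic_spline <- function(m, n_anchors = 16) {
  x <- signal_of(m)
  if (ncol(x) < 2L) stop("cubic-spline normalization needs >= 2 samples")
  if (n_anchors < 4L) stop("n_anchors must be >= 4")
  ref <- rowMeans(apply(x, 2, sort))
  probs <- seq(0.5 / n_anchors, 1 - 0.5 / n_anchors, length.out = n_anchors)
  ref_q <- unname(quantile(ref, probs, type = 7))
  out <- x
  anchors <- list()
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    n_distinct <- length(unique(v))
    if (n_distinct < 4L)
      stop("sample ", colnames(x)[j],
           " has fewer than 4 distinct values; cannot fit a spline")
    k <- n_anchors
    if (n_distinct < n_anchors) {
      k <- n_distinct
      warning("sample ", colnames(x)[j], ": anchors reduced to ", k,
              " (fewer distinct values than requested anchors)")
    }
    pj <- seq(0.5 / k, 1 - 0.5 / k, length.out = k)
    ax <- unname(quantile(v, pj, type = 7))
    ay <- unname(quantile(ref, pj, type = 7))
    out[, j] <- monotone_map(ax, ay)(v)
    anchors[[colnames(x)[j]]] <- cbind(sample = ax, reference = ay)
  }
  new_norm_result(m, out, "cubic_spline",
                  list(anchors = anchors, reference_quantiles = ref_q))
}

#' @rdname normalize_signal
#' @param rank_tol maximum allowed normalized-rank difference (fraction of
#'   probes) for a probe to count as rank-invariant against the reference
#'   sample.
#' @param min_set minimum rank-invariant set size; below it the sample falls
#'   back to average scaling with a warning.
#' @details `rank_invariant`: the reference sample is the one whose mean is
#'   the median of sample means.  For every other sample, probes whose
#'   normalized rank differs from the reference by at most `rank_tol` form
#'   the rank-invariant set; a running-median-smoothed monotone cubic curve
#'   through the invariant (sample, reference) pairs maps the sample onto the
#'   reference.  Diagnostics record the reference sample and the invariant
#'   sets.
#' @export
normalize_rank_invariant <- function(m, rank_tol = 0.05, min_set = 50) {
  x <- signal_of(m)
  if (ncol(x) < 2L) stop("rank-invariant normalization needs >= 2 samples")
  n <- nrow(x)
  means <- colMeans(x)
  ref_j <- order(means)[floor((ncol(x) + 1) / 2)]   # median-mean sample
  ref <- x[, ref_j]
  rr <- rank(ref, ties.method = "average") / n
  out <- x
  inv_sets <- setNames(vector("list", ncol(x)), colnames(x))
  inv_sets[[ref_j]] <- rownames(x)
  for (j in seq_len(ncol(x))) {
    if (j == ref_j) next
    v <- x[, j]
    rs <- rank(v, ties.method = "average") / n
    inv <- abs(rs - rr) <= rank_tol
    inv_sets[[j]] <- rownames(x)[inv]
    if (sum(inv) < min_set) {
      warning("sample ", colnames(x)[j], ": rank-invariant set (",
              sum(inv), ") below min_set; falling back to average scaling")
      out[, j] <- v * mean(ref) / mean(v)
      next
    }
    o <- order(v[inv])
    px <- v[inv][o]
    py <- ref[inv][o]
    k <- min(length(px), max(5L, 2L * floor(0.025 * length(px)) + 1L))
    if (k %% 2L == 0L) k <- k + 1L
    py <- runmed(py, k)
    # compress to <= 32 monotone anchors (bin means along the sorted axis)
    nb <- min(32L, max(4L, length(px) %/% 4L))
    bins <- cut(seq_along(px), nb, labels = FALSE)
    ax <- vapply(split(px, bins), mean, 0)
    ay <- vapply(split(py, bins), mean, 0)
    out[, j] <- monotone_map(ax, ay)(v)
  }
  new_norm_result(m, out, "rank_invariant",
                  list(reference_sample = colnames(x)[ref_j],
                       invariant_sets = inv_sets,
                       rank_tol = rank_tol, min_set = min_set))
}
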