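de_inputs <- function(norm, labels) {
  x <- signal_of(norm)
  labels <- as_class_labels(labels)
  check_labels_cover(labels, colnames(x))
  grp <- class_members(labels)
  if (length(grp$control) < 2L || length(grp$test) < 2L)
    stop("each class needs >= 2 samples for differential expression")
  list(x = x, labels = labels, grp = grp,
       strategy = if (inherits(norm, "normalization_result")) norm$strategy
                  else "none")
}

row_var <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1L)
}

finish_probe_set <- function(tab, selected, strategy, approach, alpha,
                             extra_prov = list()) {
  prov <- modifyList(list(strategy = strategy, approach = approach,
                          alpha = alpha, filtered = FALSE), extra_prov)
  probe_set(tab$probe_id[selected],
            scores = tab[selected, c("probe_id", "statistic", "p_value",
                                     "direction"), drop = FALSE],
            provenance = prov, table = tab)
}

#' Unpaired t-test differential expression
#'
#' Per probe, a two-sided unpaired Student t test of test vs control on the
#' normalized signals.  The default pools the group variances (the classic
#' GeneSpring-era behaviour); `var_equal = FALSE` switches to Welch.  Probes
#' with p < `alpha` enter the set; no multiple-testing correction is applied
#' by default (`fdr = "bh"` selects on Benjamini-Hochberg adjusted p-values
#' instead).
#'
#' Degenerate probes (zero variance in both groups) get p = 1 when the means
#' are equal and p = 0 with a `degenerate` flag when they differ.
#'
#' @param norm a `normalization_result` (or matrix / bead-summary matrix).
#' @param labels a [class_labels()].
#' @param alpha inclusion threshold on the (adjusted) p-value.
#' @param var_equal pool the variances (`TRUE`, default) or use Welch.
#' @param fdr `NULL` (none) or `"bh"`.
#' @return A [probe_set()]; `$table` holds statistics for every probe tested.
#' @export
ttest_de <- function(norm, labels, alpha = 0.05, var_equal = TRUE,
                     fdr = NULL) {
  d <- de_inputs(norm, labels)
  xc <- d$x[, d$grp$control, drop = FALSE]
  xt <- d$x[, d$grp$test, drop = FALSE]
  n1 <- ncol(xc); n2 <- ncol(xt)
  m1 <- rowMeans(xc); m2 <- rowMeans(xt)
  v1 <- row_var(xc); v2 <- row_var(xt)
  diff <- m2 - m1
  if (var_equal) {
    vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(vp * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(diff))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  stat <- diff / se
  p <- 2 * pt(-abs(stat), df)
  degen <- se == 0
  stat[degen & diff == 0] <- 0
  p[degen & diff == 0] <- 1
  stat[degen & diff != 0] <- sign(diff[degen & diff != 0]) * Inf
  p[degen & diff != 0] <- 0
  p_sel <- if (identical(fdr, "bh")) p.adjust(p, "BH") else p
  tab <- data.frame(probe_id = rownames(d$x), statistic = stat, p_value = p,
                    p_selection = p_sel, direction = sign(diff),
                    degenerate = degen, row.names = NULL,
                    stringsAsFactors = FALSE)
  finish_probe_set(tab, which(p_sel < alpha), d$strategy, "ttest", alpha,
                   list(var_equal = var_equal, fdr = fdr))
}

#' Surrogate three-component error-model differential expression
#'
#' A z test in the spirit of the proprietary "Illumina Custom" algorithm,
#' which assesses three components of variation: sequence-specific biological
#' variation, non-specific biological variation, and technical error.  Per
#' group the surrogate variance is
#' `var_g = s2_bio_g + s2_tech_g + s2_floor`, where `s2_bio_g` is the
#' across-replicate variance of the normalized signals, `s2_tech_g` the mean
#' squared bead standard error (rescaled by each sample's normalization scale
#' factor), and `s2_floor` the variance of the per-sample negative-control
#' means.  Then `z = (mean_test - mean_ctrl) / sqrt(var_t/n_t + var_c/n_c)`
#' with a two-sided normal p-value.  This is a documented surrogate, not the
#' proprietary formula; provenance records `approach = "illumina"` with
#' `surrogate = TRUE`.
#'
#' @inheritParams ttest_de
#' @return A [probe_set()].
#' @export
illumina_custom_de <- function(norm, labels, alpha = 0.05) {
  d <- de_inputs(norm, labels)
  bsm <- if (inherits(norm, "normalization_result")) norm$matrix
         else if (inherits(norm, "bead_summary_matrix")) norm
  factors <- if (inherits(norm, "normalization_result"))
    norm$diagnostics$scale_factors
  else setNames(rep(1, ncol(d$x)), colnames(d$x))
  se2 <- NULL
  if (!is.null(bsm) && !is.null(bsm$bead_se)) {
    se_scaled <- sweep(bsm$bead_se[, colnames(d$x), drop = FALSE], 2,
                       factors[colnames(d$x)], `*`)
    se2 <- se_scaled^2
  } else {
    warning("no bead standard errors available; technical component set to 0")
  }
  s2_floor <- 0
  if (!is.null(bsm) && !is.null(bsm$neg_control)) {
    s2_floor <- var(colMeans(bsm$neg_control$signal))
  } else {
    warning("no negative controls available; non-specific floor set to 0")
  }
  comp <- function(samples) {
    xs <- d$x[, samples, drop = FALSE]
    s2_tech <- if (is.null(se2)) 0
               else rowMeans(se2[, samples, drop = FALSE])
    list(n = length(samples), mean = rowMeans(xs),
         var = row_var(xs) + s2_tech + s2_floor)
  }
  ctrl <- comp(d$grp$control)
  test <- comp(d$grp$test)
  diff <- test$mean - ctrl$mean
  se <- sqrt(test$var / test$n + ctrl$var / ctrl$n)
  z <- diff / se
  p <- 2 * pnorm(-abs(z))
  degen <- se == 0
  z[degen & diff == 0] <- 0
  p[degen & diff == 0] <- 1
  z[degen & diff != 0] <- sign(diff[degen & diff != 0]) * Inf
  p[degen & diff != 0] <- 0
  tab <- data.frame(probe_id = rownames(d$x), statistic = z, p_value = p,
                    direction = sign(diff), degenerate = degen,
                    row.names = NULL, stringsAsFactors = FALSE)
  finish_probe_set(tab, which(p < alpha), d$strategy, "illumina", alpha,
                   list(surrogate = TRUE))
}
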