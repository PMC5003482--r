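#' Configuration for the synthetic bead-summary generator
#'
#' Describes a two-class bead-summary experiment dominated by small
#' (<2-fold) expression changes.  Expressed probes get a lognormal baseline
#' intensity well above the negative-control background; a fraction of probes
#' is "unexpressed" and indistinguishable from negative controls; planted
#' differentially expressed (DE) probes multiply the test-group mean by a
#' sampled fold change.  Each observed cell is
#' `array_scale * (array-power distortion of the biological mean) + bead
#' averaging noise`, with the bead standard error reported per cell.
#'
#' @param n_probes number of (non-control) probes.
#' @param n_neg_controls number of negative-control probes.
#' @param n_per_group replicates per class, `c(control, test)`; the design
#'   targets n >= 4 per group.
#' @param frac_de fraction of probes planted as differentially expressed
#'   (always drawn from the expressed probes).
#' @param frac_unexpressed fraction of probes whose signal is pure background.
#' @param fold_range range of planted fold changes; the default emulates a
#'   predominantly-below-2-fold regime.
#' @param fold_tail_mass fraction of planted changes above 2-fold.  Presets:
#'   `preset = "heart"` sets 0.021, `preset = "brain"` sets 0.004 (observed
#'   tail fractions in mouse heart/brain iron-loading arrays).
#' @param fold_sampler optional function(n) returning n fold changes > 1;
#'   overrides `fold_range`/`fold_tail_mass`.
#' @param fold_direction `"both"` flips a fair coin per DE probe between up-
#'   and down-regulation; `"up"` plants all changes upward.
#' @param baseline_log_mean,baseline_log_sd lognormal (meanlog/sdlog)
#'   parameters of expressed-probe baseline intensities.
#' @param bio_cv biological coefficient of variation across replicates
#'   (lognormal, mean-preserving).
#' @param array_scale_cv CV of the per-array multiplicative technical scale
#'   factor (the distortion all classical normalizers correct).
#' @param array_power_sd SD of an optional per-array power-law exponent
#'   (mean 1); nonzero values create smooth intensity-dependent distortion
#'   that stresses the non-linear normalizers.
#' @param bead_count_mean mean number of beads averaged per probe (Poisson,
#'   floored at 1).
#' @param bead_cv bead-level CV; the reported bead SE is
#'   `bead_cv * signal / sqrt(bead count)`.
#' @param neg_mean,neg_sd Gaussian negative-control signal distribution.
#' @param preset `"heart"` or `"brain"` fold-tail preset, or `NULL`.
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_probes = 5000, n_neg_controls = 100,
                              n_per_group = c(control = 5, test = 5),
                              frac_de = 0.1, frac_unexpressed = 0.3,
                              fold_range = c(1.1, 2.5),
                              fold_tail_mass = 0.021,
                              fold_sampler = NULL,
                              fold_direction = c("both", "up"),
                              baseline_log_mean = log(1000),
                              baseline_log_sd = 0.8,
                              bio_cv = 0.2, array_scale_cv = 0.05,
                              array_power_sd = 0,
                              bead_count_mean = 30, bead_cv = 0.2,
                              neg_mean = 100, neg_sd = 20,
                              preset = NULL, seed = 1L) {
  fold_direction <- match.arg(fold_direction)
  if (!is.null(preset)) {
    fold_tail_mass <- switch(match.arg(preset, c("heart", "brain")),
                             heart = 0.021, brain = 0.004)
  }
  cfg <- list(n_probes = as.integer(n_probes),
              n_neg_controls = as.integer(n_neg_controls),
              n_per_group = setNames(as.integer(n_per_group),
                                     c("control", "test")),
              frac_de = frac_de, frac_unexpressed = frac_unexpressed,
              fold_range = fold_range, fold_tail_mass = fold_tail_mass,
              fold_sampler = fold_sampler, fold_direction = fold_direction,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              bio_cv = bio_cv, array_scale_cv = array_scale_cv,
              array_power_sd = array_power_sd,
              bead_count_mean = bead_count_mean, bead_cv = bead_cv,
              neg_mean = neg_mean, neg_sd = neg_sd, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_probes >= 1L, n_neg_controls >= 1L, all(n_per_group >= 1L),
              frac_de >= 0, frac_de <= 1,
              frac_unexpressed >= 0, frac_unexpressed <= 1,
              fold_tail_mass >= 0, fold_tail_mass <= 1,
              bio_cv >= 0, array_scale_cv >= 0, bead_cv >= 0,
              bead_count_mean >= 1, neg_sd >= 0)
  })
  structure(cfg, class = "simulation_config")
}

sample_folds <- function(cfg, n) {
  if (n == 0L) return(numeric(0))
  if (!is.null(cfg$fold_sampler)) {
    f <- cfg$fold_sampler(n)
  } else {
    lo <- cfg$fold_range[1L]; hi <- cfg$fold_range[2L]
    if (hi <= 2 || lo >= 2) {
      f <- exp(runif(n, log(lo), log(hi)))
    } else {
      # log-uniform below 2-fold, with a stated tail mass above 2-fold
      tail <- runif(n) < cfg$fold_tail_mass
      f <- numeric(n)
      f[!tail] <- exp(runif(sum(!tail), log(lo), log(2)))
      f[tail] <- exp(runif(sum(tail), log(2), log(hi)))
    }
  }
  if (any(f <= 0)) stop("fold sampler returned non-positive fold change")
  f
}

# mean-preserving lognormal noise factors with the requested CV
lnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sl <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sl^2 / 2, sl))
}

#' Simulate a two-class bead-summary experiment with planted truth
#'
#' @param config a [simulation_config()].
#' @return A list with elements
#'   `matrix` (a [bead_summary_matrix()] with bead SEs and negative controls,
#'   detection p-values left absent -- compute them with
#'   [detection_pvalues()]),
#'   `labels` (a [class_labels()]), and
#'   `truth` (list with `de_probes`, a named vector of true test/control fold
#'   changes, and `expressed_probes`).
#' @examples
#' sim <- simulate_experiment(simulation_config(n_probes = 200, seed = 7))
#' sim$matrix
#' @export
simulate_experiment <- function(config = simulation_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_probes
  ids <- sprintf("P%05d", seq_len(n))
  samples <- c(sprintf("C%02d", seq_len(cfg$n_per_group["control"])),
               sprintf("T%02d", seq_len(cfg$n_per_group["test"])))
  classes <- rep(c("control", "test"), cfg$n_per_group)
  ns <- length(samples)

  n_unexpr <- round(cfg$frac_unexpressed * n)
  unexpr <- if (n_unexpr > 0) sample(ids, n_unexpr) else character(0)
  expressed <- setdiff(ids, unexpr)
  n_de <- round(cfg$frac_de * n)
  if (n_de > 0 && length(expressed) - n_de <= 0)
    stop("frac_de too large: no non-DE expressed probes would remain")
  de <- if (n_de > 0) sample(expressed, n_de) else character(0)
  folds <- sample_folds(cfg, length(de))
  if (cfg$fold_direction == "both" && length(de)) {
    down <- runif(length(de)) < 0.5
    folds[down] <- 1 / folds[down]
  }
  names(folds) <- de

  mu <- setNames(rlnorm(n, cfg$baseline_log_mean, cfg$baseline_log_sd), ids)
  mean_mat <- matrix(mu, n, ns, dimnames = list(ids, samples))
  if (length(de))
    mean_mat[de, classes == "test"] <-
      mean_mat[de, classes == "test", drop = FALSE] * folds

  base <- mean_mat * matrix(lnoise(n * ns, cfg$bio_cv), n, ns)
  # unexpressed probes: pure background, exchangeable with negative controls
  if (length(unexpr))
    base[unexpr, ] <- pmax(rnorm(length(unexpr) * ns, cfg$neg_mean,
                                 cfg$neg_sd), 1e-6)
  ctrl <- matrix(pmax(rnorm(cfg$n_neg_controls * ns, cfg$neg_mean,
                            cfg$neg_sd), 1e-6),
                 cfg$n_neg_controls, ns,
                 dimnames = list(sprintf("NC%04d",
                                         seq_len(cfg$n_neg_controls)),
                                 samples))

  scale_s <- lnoise(ns, cfg$array_scale_cv)
  expo_s <- if (cfg$array_power_sd > 0) rnorm(ns, 1, cfg$array_power_sd)
            else rep(1, ns)
  distort <- function(m) {
    if (cfg$array_power_sd > 0)
      m <- exp(sweep(log(m), 2, expo_s, `*`))
    sweep(m, 2, scale_s, `*`)
  }
  base <- distort(base)
  ctrl <- distort(ctrl)

  add_bead_noise <- function(m) {
    counts <- matrix(pmax(1, rpois(length(m), cfg$bead_count_mean)),
                     nrow(m), ncol(m))
    se <- cfg$bead_cv * m / sqrt(counts)
    list(signal = m + rnorm(length(m), 0, 1) * se, se = se)
  }
  bm <- add_bead_noise(base)
  bc <- add_bead_noise(ctrl)

  list(matrix = bead_summary_matrix(
         bm$signal, bead_se = bm$se,
         neg_control = list(probe_ids = rownames(ctrl), signal = bc$signal)),
       labels = class_labels(setNames(classes, samples)),
       truth = list(de_probes = folds, expressed_probes = expressed))
}

#' Simulate a pathway annotation with planted enrichment
#'
#' Maps each probe to a gene one-to-one, then draws pathways from the gene
#' background.  A stated fraction of pathways is "enriched": their genes are
#' sampled with the odds of a DE gene multiplied by `de_odds`; the remaining
#' pathways are sampled uniformly.
#'
#' @param truth the `truth` element returned by [simulate_experiment()].
#' @param n_pathways number of pathways.
#' @param pathway_size genes per pathway.
#' @param enriched_frac fraction of pathways preferentially loaded with DE
#'   genes.
#' @param de_odds odds multiplier applied to DE genes in enriched pathways.
#' @param probe_ids probes forming the array background; defaults to the
#'   expressed probes in `truth`.
#' @param seed RNG seed.
#' @return A [pathway_annotation()]; enriched pathway IDs carry the prefix
#'   `"EP"`, background pathways `"BP"`.
#' @export
simulate_pathways <- function(truth, n_pathways = 20, pathway_size = 25,
                              enriched_frac = 0.25, de_odds = 8,
                              probe_ids = truth$expressed_probes, seed = 1L) {
  # mix the seed so that reusing the experiment seed does not replay the
  # experiment's RNG stream (which would alias pathway draws onto DE picks)
  set.seed((as.integer(seed) * 69069L + 1013904223L) %% 2147483647L)
  probe_to_gene <- setNames(sub("^P", "G", probe_ids), probe_ids)
  background <- unname(probe_to_gene)
  if (pathway_size > length(background))
    stop("pathway_size exceeds the background size")
  de_genes <- unname(probe_to_gene[intersect(names(truth$de_probes),
                                             probe_ids)])
  n_enr <- round(enriched_frac * n_pathways)
  w_enr <- ifelse(background %in% de_genes, de_odds, 1)
  pathways <- list()
  for (i in seq_len(n_pathways)) {
    enriched <- i <= n_enr
    pathways[[if (enriched) sprintf("EP%03d", i)
              else sprintf("BP%03d", i)]] <-
      sample(background, pathway_size,
             prob = if (enriched) w_enr else NULL)
  }
  pathway_annotation(pathways, probe_to_gene, background = background)
}
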