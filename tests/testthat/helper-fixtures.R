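# Shared fixtures and independent oracles.  Oracles are deliberately written
# in a different style (loops, table()) than the package code they check.

toy_bsm <- function(n_probes = 6, n_samples = 4, n_controls = 20, seed = 42,
                    bead_se = TRUE, detection_p = FALSE) {
  set.seed(seed)
  sig <- matrix(rlnorm(n_probes * n_samples, log(500), 0.5),
                n_probes, n_samples,
                dimnames = list(sprintf("P%02d", seq_len(n_probes)),
                                sprintf("S%d", seq_len(n_samples))))
  ctrl <- matrix(rnorm(n_controls * n_samples, 100, 15),
                 n_controls, n_samples,
                 dimnames = list(sprintf("NC%02d", seq_len(n_controls)),
                                 colnames(sig)))
  bead_summary_matrix(
    sig,
    bead_se = if (bead_se) sig * 0.04,
    detection_p = if (detection_p)
      matrix(runif(n_probes * n_samples), n_probes, n_samples),
    neg_control = list(probe_ids = rownames(ctrl), signal = ctrl))
}

toy_labels <- function(samples = c("S1", "S2", "S3", "S4"),
                       classes = c("control", "control", "test", "test")) {
  suppressWarnings(class_labels(setNames(classes, samples)))
}

# --- independent sort-average-unsort quantile oracle ------------------------
oracle_quantile <- function(X) {
  out <- X
  sorted <- sapply(seq_len(ncol(X)), function(j) sort(X[, j]))
  avg <- apply(sorted, 1, mean)
  for (j in seq_len(ncol(X))) {
    o <- order(X[, j])
    for (r in seq_len(nrow(X))) out[o[r], j] <- avg[r]
  }
  out
}

# --- brute-force entropy/MDL discretization oracle --------------------------
oracle_entropy <- function(y) {
  if (!length(y)) return(0)
  tt <- table(y)
  p <- tt / sum(tt)
  -sum(p * log2(p))
}

oracle_fayyad_irani <- function(v, cl) {
  n <- length(v)
  sv <- sort(unique(v))
  if (length(sv) < 2) {
    return(list(threshold = NA_real_, accepted = FALSE, gain = 0))
  }
  cuts <- (sv[-length(sv)] + sv[-1]) / 2
  E <- numeric(length(cuts))
  bnd <- logical(length(cuts))
  for (i in seq_along(cuts)) {
    left <- cl[v <= cuts[i]]
    right <- cl[v > cuts[i]]
    E[i] <- length(left) / n * oracle_entropy(left) +
      length(right) / n * oracle_entropy(right)
    bnd[i] <- length(unique(c(cl[v == sv[i]], cl[v == sv[i + 1]]))) > 1
  }
  cand <- which(E <= min(E) + 1e-12)
  cb <- cand[bnd[cand]]
  pick <- if (length(cb)) cb[1] else cand[1]
  left <- cl[v <= cuts[pick]]
  right <- cl[v > cuts[pick]]
  gain <- oracle_entropy(cl) - E[pick]
  delta <- log2(3^2 - 2) -
    (2 * oracle_entropy(cl) -
       length(unique(left)) * oracle_entropy(left) -
       length(unique(right)) * oracle_entropy(right))
  list(threshold = cuts[pick],
       accepted = gain > log2(n - 1) / n + delta / n,
       gain = gain)
}

# --- brute-force pair coverage + exhaustive feature-set oracle --------------
oracle_pair_cover <- function(binary, classes) {
  samples <- colnames(binary)
  pairs <- list()
  for (i in seq_along(samples)) {
    for (j in seq_along(samples)) {
      if (i < j) pairs[[length(pairs) + 1]] <- c(i, j)
    }
  }
  type <- sapply(pairs, function(p)
    if (classes[p[1]] == classes[p[2]]) "intra" else "inter")
  cov <- matrix(0L, nrow(binary), length(pairs),
                dimnames = list(rownames(binary), NULL))
  for (f in seq_len(nrow(binary))) {
    for (p in seq_along(pairs)) {
      same <- binary[f, pairs[[p]][1]] == binary[f, pairs[[p]][2]]
      cov[f, p] <- if (type[p] == "intra") as.integer(same)
                   else as.integer(!same)
    }
  }
  list(cover = cov, type = type)
}

oracle_feasible <- function(cover, feats, demand) {
  for (p in seq_along(demand)) {
    if (sum(cover[feats, p]) < demand[p]) return(FALSE)
  }
  TRUE
}

oracle_min_k <- function(cover, demand, k_max = nrow(cover)) {
  for (k in seq_len(k_max)) {
    subsets <- combn(nrow(cover), k, simplify = FALSE)
    for (s in subsets) {
      if (oracle_feasible(cover, s, demand)) return(k)
    }
  }
  NA_integer_
}

# --- exhaustive hypergeometric upper-tail oracle ----------------------------
oracle_hyper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# analytic two-sided power of the pooled two-sample t test for a planted
# multiplicative fold change under mean-proportional (CV) noise
analytic_t_power <- function(fold, cv, n, alpha = 0.05) {
  ncp <- (fold - 1) / (cv * sqrt((1 + fold^2) / n))
  df <- 2 * n - 2
  tc <- qt(1 - alpha / 2, df)
  pt(-tc, df, ncp) + 1 - pt(tc, df, ncp)
}
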