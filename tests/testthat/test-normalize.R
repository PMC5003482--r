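rand_mat <- function(n = 30, k = 4, seed = 1) {
  set.seed(seed)
  matrix(rlnorm(n * k, log(300), 0.6), n, k,
         dimnames = list(sprintf("P%03d", seq_len(n)),
                         sprintf("S%d", seq_len(k))))
}

test_that("none is the identity with unit scale factors", {
  x <- rand_mat()
  r <- normalize_none(x)
  expect_identical(r$signal, x)
  expect_equal(unname(r$diagnostics$scale_factors), rep(1, ncol(x)))
  expect_identical(normalize_none(r$signal)$signal, x)  # idempotent
})

test_that("average normalization scales to the grand mean of sample means", {
  x <- matrix(c(5, 10, 15, 10, 20, 30), 3, 2,
              dimnames = list(paste0("P", 1:3), c("S1", "S2")))
  r <- normalize_average(x)                 # means 10 and 20, grand mean 15
  expect_equal(unname(r$diagnostics$factors), c(1.5, 0.75))
  expect_equal(unname(colMeans(r$signal)), c(15, 15))

  same <- cbind(S1 = c(1, 2, 3), S2 = c(3, 2, 1))
  rownames(same) <- paste0("P", 1:3)
  expect_equal(normalize_average(same)$signal, same)    # means already equal
  one <- rand_mat(k = 1)
  expect_equal(normalize_average(one)$signal, one)      # single sample
  neg <- x; neg[, 1] <- -neg[, 1]
  expect_error(normalize_average(neg), "mean <= 0")
})

test_that("quantile normalization matches the hand example and its contract", {
  x <- cbind(S1 = c(1, 2, 3), S2 = c(8, 4, 6))
  rownames(x) <- paste0("P", 1:3)
  r <- normalize_quantile(x)
  expect_equal(unname(r$signal[, "S1"]), c(2.5, 4.0, 5.5))
  expect_equal(unname(r$signal[, "S2"]), c(5.5, 2.5, 4.0))

  same <- cbind(S1 = c(4, 1, 9), S2 = c(4, 1, 9))
  rownames(same) <- paste0("P", 1:3)
  expect_equal(normalize_quantile(same)$signal, same)

  y <- rand_mat(seed = 4)
  q <- normalize_quantile(y)$signal
  for (j in 2:ncol(q))
    expect_equal(unname(sort(q[, 1])), unname(sort(q[, j])))  # one multiset
  expect_equal(normalize_quantile(q)$signal, q, tolerance = 1e-12)
})

test_that("quantile ties receive the mean of their covered ranks", {
  x <- cbind(S1 = c(10, 10, 30, 40), S2 = c(1, 2, 3, 4))
  rownames(x) <- paste0("P", 1:4)
  ref <- rowMeans(cbind(sort(x[, 1]), sort(x[, 2])))
  r <- normalize_quantile(x)$signal
  expect_equal(unname(r[1:2, "S1"]), rep(mean(ref[1:2]), 2))
  expect_equal(unname(r[3:4, "S1"]), ref[3:4], ignore_attr = TRUE)
})

test_that("cubic-spline normalization inverts a pure scale distortion", {
  set.seed(7)
  a <- sort(rlnorm(400, log(500), 0.7))
  x <- cbind(A = a, B = 2 * a)
  rownames(x) <- sprintf("P%03d", seq_along(a))
  r <- normalize_cubic_spline(x)$signal
  interior <- a >= quantile(a, 0.05) & a <= quantile(a, 0.95)
  rel <- abs(r[interior, "B"] - r[interior, "A"]) / r[interior, "A"]
  expect_lt(max(rel), 0.01)
  expect_true(all(diff(r[, "B"]) > 0))      # monotone in, monotone out

  same <- cbind(A = a, B = a)
  rownames(same) <- rownames(x)
  expect_equal(normalize_cubic_spline(same)$signal, same, tolerance = 1e-9)
})

test_that("cubic-spline anchor guards fire", {
  x <- cbind(A = rep(c(1, 2, 5, 9, 12), 4), B = 1:20 + 0.5)
  rownames(x) <- sprintf("P%02d", 1:20)
  expect_warning(normalize_cubic_spline(x, n_anchors = 8),
                 "anchors reduced")
  x3 <- cbind(A = rep(c(1, 2, 3), 4), B = seq_len(12))
  rownames(x3) <- sprintf("P%02d", 1:12)
  expect_error(normalize_cubic_spline(x3), "fewer than 4 distinct")
  expect_error(normalize_cubic_spline(rand_mat(), n_anchors = 3), ">= 4")
})

test_that("rank-invariant normalization maps a scaled sample onto the reference", {
  set.seed(8)
  ref <- rlnorm(400, log(500), 0.7)
  x <- cbind(A = ref, B = 3 * ref, C = ref * exp(rnorm(400, 0, 0.01)))
  rownames(x) <- sprintf("P%03d", seq_len(400))
  r <- normalize_rank_invariant(x)
  # reference is the sample whose mean is the median of sample means
  means <- colMeans(x)
  expect_equal(r$diagnostics$reference_sample,
               names(means)[order(means)][2])
  # B = 3 x reference: every probe is rank-invariant, map is x/3
  expect_length(r$diagnostics$invariant_sets$B, 400)
  interior <- x[, "A"] >= quantile(x[, "A"], 0.05) &
    x[, "A"] <= quantile(x[, "A"], 0.95)
  ref_sig <- x[, r$diagnostics$reference_sample]
  rel <- abs(r$signal[interior, "B"] - ref_sig[interior]) / ref_sig[interior]
  expect_lt(max(rel), 0.01)
})

test_that("a rank-jumping probe is excluded from the invariant set", {
  set.seed(9)
  base <- sort(rlnorm(200, log(500), 0.5))
  jump <- base
  jump[1] <- base[195]          # bottom decile in reference, top in sample
  x <- cbind(A = base, B = jump * 1.01, C = base * 0.99)
  rownames(x) <- sprintf("P%03d", seq_len(200))
  r <- normalize_rank_invariant(x, rank_tol = 0.05)
  expect_false(identical(r$diagnostics$reference_sample, "B"))
  expect_false("P001" %in% r$diagnostics$invariant_sets[["B"]])
})

test_that("rank-invariant falls back to average scaling when the set is tiny", {
  set.seed(10)
  x <- cbind(A = rlnorm(100, log(500), 0.5), B = rlnorm(100, log(500), 0.5))
  rownames(x) <- sprintf("P%03d", 1:100)
  expect_warning(r <- normalize_rank_invariant(x, rank_tol = 1e-6,
                                               min_set = 50),
                 "falling back to average")
  ref <- r$diagnostics$reference_sample
  other <- setdiff(colnames(x), ref)
  expect_equal(mean(r$signal[, other]), mean(x[, ref]))
})

test_that("all strategies preserve within-sample rank order", {
  x <- rand_mat(n = 60, k = 5, seed = 12)
  for (s in c("none", "average", "quantile", "cubic_spline",
              "rank_invariant")) {
    # iid columns make the rank-invariant set tiny; the fallback warning is
    # expected on this stress input
    r <- suppressWarnings(normalize_signal(x, s))
    for (j in seq_len(ncol(x)))
      expect_equal(rank(r$signal[, j], ties.method = "first"),
                   rank(x[, j], ties.method = "first"),
                   info = s)
  }
})

test_that("every strategy but none undoes per-array scale distortion", {
  # pure scale-factor distortion, no DE: >= 10x reduction in the mean
  # across-sample variance of each probe's signal, over 10 seeds
  for (seed in 1:10) {
    sim <- simulate_experiment(simulation_config(
      n_probes = 300, frac_de = 0, frac_unexpressed = 0,
      bio_cv = 0.02, array_scale_cv = 0.2, bead_cv = 0.02, seed = seed))
    x <- sim$matrix$signal
    raw_var <- mean(apply(x, 1, var) / rowMeans(x)^2)
    for (s in c("average", "quantile", "cubic_spline", "rank_invariant")) {
      r <- normalize_signal(x, s)
      norm_var <- mean(apply(r$signal, 1, var) / rowMeans(r$signal)^2)
      expect_gt(raw_var / norm_var, 10)
    }
  }
})
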