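lab_ab <- function(n_a, n_b) {
  toy_labels(samples = c(sprintf("A%d", seq_len(n_a)),
                         sprintf("B%d", seq_len(n_b))),
             classes = rep(c("control", "test"), c(n_a, n_b)))
}

test_that("the worked six-sample split is found and MDL-accepted", {
  v <- setNames(c(1, 2, 3, 10, 11, 12),
                c("A1", "A2", "A3", "B1", "B2", "B3"))
  r <- fayyad_irani_discretize(v, lab_ab(3, 3))
  expect_equal(r$threshold, 6.5)
  expect_equal(r$gain, 1)                                # one clean bit
  expect_equal(r$mdl_bound, log2(5) / 6 + (log2(7) - 2) / 6,
               tolerance = 1e-12)
  expect_equal(r$mdl_bound, 0.5215, tolerance = 1e-3)
  expect_true(r$accepted)
})

test_that("interleaved and constant features are rejected", {
  v <- setNames(c(1, 2, 3, 4), c("A1", "B1", "A2", "B2"))
  lab <- toy_labels(samples = names(v),
                    classes = c("control", "test", "control", "test"))
  r <- fayyad_irani_discretize(v, lab)
  expect_false(r$accepted)
  flat <- setNames(rep(2, 6), c("A1", "A2", "A3", "B1", "B2", "B3"))
  rf <- fayyad_irani_discretize(flat, lab_ab(3, 3))
  expect_false(rf$accepted)
  expect_true(is.na(rf$threshold))
})

test_that("chosen cuts minimize entropy and lie at class boundaries", {
  set.seed(51)
  lab <- lab_ab(4, 4)
  for (i in 1:60) {
    v <- setNames(rnorm(8), names(lab$assignment))
    r <- fayyad_irani_discretize(v, lab)
    o <- oracle_fayyad_irani(unname(v), unname(lab$assignment))
    expect_equal(r$threshold, o$threshold)
    expect_equal(r$accepted, o$accepted)
    # boundary-point theorem: the cut is a midpoint between adjacent samples
    # of different classes
    sv <- sort(v)
    cuts <- (sv[-1] + sv[-8]) / 2
    cls <- lab$assignment[names(sv)]
    expect_true(r$threshold %in% cuts[cls[-8] != cls[-1]])
  }
})

test_that("discretize_matrix keeps exactly the discriminative features", {
  lab <- lab_ab(3, 3)
  x <- rbind(SEP = c(1, 2, 3, 10, 11, 12),
             FLAT1 = rep(5, 6), FLAT2 = rep(1, 6))
  colnames(x) <- names(lab$assignment)
  d <- discretize_matrix(x, lab)
  expect_equal(d$retained, "SEP")
  expect_setequal(d$dropped, c("FLAT1", "FLAT2"))
  expect_equal(unname(d$binary["SEP", ]), c(0, 0, 0, 1, 1, 1))
  expect_equal(unname(d$thresholds["SEP"]), 6.5)

  allflat <- x[2:3, , drop = FALSE]
  expect_length(discretize_matrix(allflat, lab)$retained, 0)

  # permutation invariance of the retained set
  perm <- x[, c(4, 2, 6, 1, 3, 5)]
  expect_identical(discretize_matrix(perm, lab)$retained, d$retained)
})

test_that("pair coverage matches exhaustive enumeration", {
  lab4 <- lab_ab(2, 2)
  b1 <- rbind(F1 = c(0, 0, 1, 1), F2 = c(0, 1, 0, 1))
  colnames(b1) <- names(lab4$assignment)
  cov1 <- build_coverage(b1, lab4)
  inter_ab <- which(cov1$pairs$a == "A1" & cov1$pairs$b == "B1")
  intra_aa <- which(cov1$pairs$a == "A1" & cov1$pairs$b == "A2")
  expect_equal(cov1$pairs$type[inter_ab], "inter")
  expect_equal(cov1$pairs$type[intra_aa], "intra")
  expect_equal(unname(cov1$cover["F1", inter_ab]), 1)  # differ across classes
  expect_equal(unname(cov1$cover["F1", intra_aa]), 1)  # agree within class
  expect_equal(unname(cov1$cover["F2", intra_aa]), 0)  # disagreement misses

  b4 <- rbind(F1 = c(0, 0, 1, 1), F2 = c(0, 1, 0, 1), F3 = c(1, 1, 1, 1))
  colnames(b4) <- names(lab4$assignment)
  cov4 <- build_coverage(b4, lab4)
  o <- oracle_pair_cover(b4, unname(lab4$assignment))
  expect_equal(unname(cov4$cover), unname(o$cover))
  expect_equal(cov4$pairs$type, o$type)
  # every pair is exactly one of inter/intra
  expect_equal(nrow(cov4$pairs), choose(4, 2))
})

test_that("(alpha, beta) ceilings count feature support per pair", {
  lab4 <- lab_ab(2, 2)
  b <- rbind(F1 = c(0, 0, 1, 1))
  colnames(b) <- names(lab4$assignment)
  cov <- build_coverage(b, lab4)
  expect_equal(max_alpha_beta(cov), list(alpha_max = 1L, beta_max = 1L))
  # duplicating every feature doubles both ceilings
  b2 <- rbind(b, F1b = b[1, ])
  cov2 <- build_coverage(b2, lab4)
  expect_equal(max_alpha_beta(cov2), list(alpha_max = 2L, beta_max = 2L))

  b3 <- rbind(F1 = c(0, 0, 1, 1), F2 = c(0, 1, 0, 1), F3 = c(1, 1, 1, 1))
  colnames(b3) <- names(lab4$assignment)
  cov3 <- build_coverage(b3, lab4)
  o <- oracle_pair_cover(b3, unname(lab4$assignment))
  expect_equal(max_alpha_beta(cov3)$alpha_max,
               min(colSums(o$cover)[o$type == "inter"]))
  expect_equal(max_alpha_beta(cov3)$beta_max,
               min(colSums(o$cover)[o$type == "intra"]))
})

test_that("solver handles the singleton, infeasible and max_cover cases", {
  lab4 <- lab_ab(2, 2)
  b <- rbind(GOOD = c(0, 0, 1, 1), NOISY = c(0, 1, 0, 1))
  colnames(b) <- names(lab4$assignment)
  cov <- build_coverage(b, lab4)
  for (solver in c("greedy", "exact")) {
    sol <- solve_feature_set(cov, list(alpha = 1, beta = 1), mode = "min_k",
                             solver = solver)
    expect_equal(sol$features, "GOOD")
    expect_equal(sol$params$k, 1)
    expect_true(sol$feasible)
  }
  expect_error(solve_feature_set(cov, list(alpha = 2, beta = 1)),
               "infeasible")
  # max_cover fills up to k with surplus-coverage features
  mc <- solve_feature_set(cov, list(alpha = 1, beta = 1),
                          mode = "max_cover", k = 2)
  expect_setequal(mc$features, c("GOOD", "NOISY"))
  expect_true(mc$feasible)
  expect_error(solve_feature_set(cov, list(alpha = 1, beta = 1),
                                 mode = "max_cover", k = 0),
               "below the minimal")
})

test_that("greedy is feasible and never beats the exact minimum", {
  set.seed(52)
  for (i in 1:60) {
    nf <- sample(3:10, 1)
    ns <- sample(4:8, 1)
    cls <- rep(c("control", "test"), c(2, ns - 2))
    lab <- toy_labels(samples = sprintf("S%d", seq_len(ns)), classes = cls)
    b <- matrix(rbinom(nf * ns, 1, 0.5), nf, ns,
                dimnames = list(sprintf("F%02d", seq_len(nf)),
                                names(lab$assignment)))
    cov <- build_coverage(b, lab)
    ceil <- max_alpha_beta(cov)
    if (ceil$alpha_max < 1) next
    alpha <- sample(ceil$alpha_max, 1)
    beta <- sample(0:ceil$beta_max, 1)
    g <- solve_feature_set(cov, list(alpha = alpha, beta = beta),
                           mode = "min_k")
    e <- solve_feature_set(cov, list(alpha = alpha, beta = beta),
                           mode = "min_k", solver = "exact")
    o <- oracle_pair_cover(b, unname(lab$assignment))
    demand <- ifelse(o$type == "inter", alpha, beta)
    expect_true(oracle_feasible(o$cover, match(g$features, rownames(b)),
                                demand))
    expect_true(oracle_feasible(o$cover, match(e$features, rownames(b)),
                                demand))
    expect_equal(e$params$k, oracle_min_k(o$cover, demand))
    expect_gte(g$params$k, e$params$k)
  }
})

test_that("the exact solver guard refuses large instances", {
  lab <- lab_ab(2, 2)
  b <- matrix(rbinom(25 * 4, 1, 0.5), 25, 4,
              dimnames = list(sprintf("F%02d", 1:25),
                              names(lab$assignment)))
  cov <- build_coverage(b, lab)
  ceil <- max_alpha_beta(cov)
  if (ceil$alpha_max >= 1)
    expect_error(solve_feature_set(cov, list(alpha = 1, beta = 0),
                                   solver = "exact"),
                 "guarded")
})

test_that("maxcover_de returns the separating probe and handles empties", {
  lab <- lab_ab(3, 3)
  x <- rbind(SEP = c(1, 2, 3, 10, 11, 12),
             FLAT = rep(5, 6))
  colnames(x) <- names(lab$assignment)
  ps <- maxcover_de(x, lab)
  expect_equal(ps$probe_ids, "SEP")
  expect_equal(ps$provenance$approach, "maxcover")
  expect_equal(ps$provenance$k, 1)
  expect_equal(ps$scores$direction, 1)
  expect_true(is.na(ps$scores$p_value))

  expect_warning(empty <- maxcover_de(x["FLAT", , drop = FALSE], lab),
                 "no features survived")
  expect_length(empty$probe_ids, 0)
})

test_that("strongly separated planted probes all survive discretization", {
  sim <- simulate_experiment(simulation_config(
    n_probes = 300, frac_de = 0.1, frac_unexpressed = 0,
    fold_sampler = function(n) rep(2, n), fold_direction = "up",
    bio_cv = 0.05, array_scale_cv = 0, bead_cv = 0.02,
    n_per_group = c(5, 5), seed = 53))
  d <- discretize_matrix(sim$matrix$signal, sim$labels)
  de <- names(sim$truth$de_probes)
  expect_true(all(de %in% d$retained))
  expect_true(all(d$gains[de] > 0.9))          # near one clean bit
  ps <- maxcover_de(sim$matrix$signal, sim$labels)
  expect_true(ps$provenance$alpha >= 1)
  expect_true(ps$provenance$total_coverage > 0)
})
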