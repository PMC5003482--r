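entropy2 <- function(codes, n = length(codes)) {
  if (!n) return(0)
  p <- tabulate(codes, 2L) / n
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Entropy/MDL (Fayyad-Irani) binarization of one feature
#'
#' Candidate cut points are the midpoints between consecutive distinct sorted
#' values; the chosen cut minimizes the weighted class-information entropy
#' `E(S;T) = |S1|/N * Ent(S1) + |S2|/N * Ent(S2)`.  Ties are resolved in
#' favour of class-boundary midpoints (where the minimum provably lies), then
#' the smallest cut.  The cut is accepted iff
#' `Gain > log2(N-1)/N + Delta/N` with
#' `Delta = log2(3^c - 2) - [c*Ent(S) - c1*Ent(S1) - c2*Ent(S2)]`
#' (`c` = 2 classes; `c1`, `c2` = classes present on each side): the minimum
#' description length criterion for a single binary split.
#'
#' @param values numeric per-sample signals for one feature, named by sample
#'   ID (or aligned with the label order).
#' @param labels a [class_labels()].
#' @return List with `threshold` (NA for constant features), `accepted`,
#'   `gain`, `mdl_bound` and `entropy` (class entropy of the full sample).
#' @export
fayyad_irani_discretize <- function(values, labels) {
  labels <- as_class_labels(labels)
  if (!is.null(names(values))) {
    check_labels_cover(labels, names(values))
    cls <- labels$assignment[names(values)]
  } else {
    if (length(values) != length(labels$assignment))
      stop("unnamed values must align with the label vector")
    cls <- labels$assignment
  }
  n <- length(values)
  ci <- ifelse(cls == labels$control, 1L, 2L)
  ent_s <- entropy2(ci)
  reject <- list(threshold = NA_real_, accepted = FALSE, gain = 0,
                 mdl_bound = NA_real_, entropy = ent_s)
  ord <- order(values)
  vs <- values[ord]; cs <- ci[ord]
  dv <- unique(vs)
  if (length(dv) < 2L) return(reject)
  cuts <- (dv[-length(dv)] + dv[-1L]) / 2
  grp_cls <- lapply(split(cs, match(vs, dv)), unique)
  boundary <- vapply(seq_along(cuts), function(i)
    length(unique(c(grp_cls[[i]], grp_cls[[i + 1L]]))) > 1L, logical(1))
  ev <- vapply(cuts, function(tc) {
    left <- ci[values <= tc]
    right <- ci[values > tc]
    e1 <- entropy2(left); e2 <- entropy2(right)
    c(E = length(left) / n * e1 + length(right) / n * e2,
      e1 = e1, e2 = e2,
      k1 = length(unique(left)), k2 = length(unique(right)))
  }, numeric(5))
  E <- ev["E", ]
  best <- which(E <= min(E) + 1e-12)
  bb <- best[boundary[best]]
  pick <- if (length(bb)) bb[1L] else best[1L]
  gain <- unname(ent_s - E[pick])
  delta <- log2(3^2 - 2) -
    unname(2 * ent_s - ev["k1", pick] * ev["e1", pick] -
             ev["k2", pick] * ev["e2", pick])
  bound <- log2(n - 1) / n + delta / n
  list(threshold = unname(cuts[pick]), accepted = gain > bound,
       gain = gain, mdl_bound = bound, entropy = ent_s)
}

#' Discretize a whole matrix, keeping only MDL-accepted features
#'
#' Applies [fayyad_irani_discretize()] to every feature (probe) and retains
#' those whose best split passes the MDL filter.  Retained features become
#' rows of a binary matrix: values <= threshold map to 0, values above it to
#' 1.
#'
#' @param norm a `normalization_result`, [bead_summary_matrix()] or numeric
#'   matrix (features x samples).
#' @param labels a [class_labels()].
#' @return A `discretized_matrix`: list with `binary` (retained features x
#'   samples, 0/1), `thresholds`, `gains`, `retained`, `dropped`.
#' @export
discretize_matrix <- function(norm, labels) {
  x <- signal_of(norm)
  labels <- as_class_labels(labels)
  check_labels_cover(labels, colnames(x))
  res <- apply(x, 1, function(v) fayyad_irani_discretize(v, labels),
               simplify = FALSE)
  acc <- vapply(res, `[[`, logical(1), "accepted")
  retained <- rownames(x)[acc]
  thresholds <- vapply(res[acc], `[[`, 0, "threshold")
  gains <- vapply(res[acc], `[[`, 0, "gain")
  binary <- (x[retained, , drop = FALSE] >
               matrix(thresholds, length(retained), ncol(x))) * 1L
  structure(list(binary = binary, thresholds = thresholds, gains = gains,
                 retained = retained, dropped = rownames(x)[!acc]),
            class = "discretized_matrix")
}

binary_of <- function(d) {
  if (inherits(d, "discretized_matrix")) d$binary
  else if (is.matrix(d)) d
  else stop("expected a discretized_matrix or a binary matrix")
}

#' Build the pair-coverage structure of the (alpha,beta)-k problem
#'
#' Every unordered pair of samples is classified as inter-class (different
#' labels) or intra-class (same label).  A feature covers an inter-class pair
#' iff its binary values differ across the pair, and covers an intra-class
#' pair iff its values agree.
#'
#' @param d a `discretized_matrix` (or a binary features x samples matrix).
#' @param labels a [class_labels()].
#' @return A `pair_coverage`: list with `pairs` (data.frame `a`, `b`, `type`),
#'   `cover` (features x pairs 0/1 matrix) and `n_samples`.
#' @export
build_coverage <- function(d, labels) {
  b <- binary_of(d)
  if (nrow(b) < 1L) stop("no retained features to build coverage from")
  labels <- as_class_labels(labels)
  check_labels_cover(labels, colnames(b))
  samples <- colnames(b)
  idx <- combn(length(samples), 2)
  a <- samples[idx[1L, ]]; bb <- samples[idx[2L, ]]
  type <- ifelse(labels$assignment[a] == labels$assignment[bb],
                 "intra", "inter")
  agree <- (b[, a, drop = FALSE] == b[, bb, drop = FALSE]) * 1L
  cover <- ifelse(rep(type == "intra", each = nrow(b)), agree, 1L - agree)
  dim(cover) <- dim(agree)
  dimnames(cover) <- list(rownames(b), paste(a, bb, sep = "|"))
  structure(list(pairs = data.frame(a = a, b = bb, type = type,
                                    stringsAsFactors = FALSE),
                 cover = cover, n_samples = length(samples)),
            class = "pair_coverage")
}

#' Maximum achievable (alpha, beta) from the retained features
#'
#' `alpha_max` is the minimum, over inter-class pairs, of the number of
#' features covering the pair; `beta_max` likewise over intra-class pairs.
#' A pair covered by no feature yields 0 for its side.
#'
#' @param cov a `pair_coverage` from [build_coverage()].
#' @return List with integer `alpha_max` and `beta_max`.
#' @export
max_alpha_beta <- function(cov) {
  counts <- colSums(cov$cover)
  inter <- cov$pairs$type == "inter"
  list(alpha_max = if (any(inter)) as.integer(min(counts[inter])) else 0L,
       beta_max = if (any(!inter)) as.integer(min(counts[!inter])) else 0L)
}

coverage_feasible <- function(cover01, demand) {
  all(colSums(cover01) >= demand)
}

solution_total_coverage <- function(cover01, demand) {
  counts <- colSums(cover01)
  sum(pmin(counts, demand)) + sum(pmax(counts - demand, 0))
}

#' Solve the Max Cover (alpha,beta)-k feature-set problem
#'
#' Demands: every inter-class pair must be covered by at least `alpha`
#' selected features and every intra-class pair by at least `beta`.
#'
#' * `mode = "min_k"` finds a small feasible set.  The greedy multicover
#'   heuristic repeatedly adds the feature meeting the largest number of
#'   still-unmet pair demands, breaking ties by ascending feature ID.
#'   Greedy is always feasible when `(alpha, beta) <= (alpha_max, beta_max)`.
#' * `mode = "max_cover"` first reaches feasibility, then keeps adding the
#'   feature covering the most pairs (surplus coverage) until `k` features
#'   are selected.
#' * `solver = "exact"` replaces the greedy phase by exhaustive subset search
#'   certifying the minimal k (guarded to <= 20 features and <= 10 samples);
#'   it serves as an oracle and for small real runs.
#'
#' @param cov a `pair_coverage`.
#' @param params list with `alpha` (>= 1) and `beta` (>= 0); see
#'   [max_alpha_beta()].
#' @param mode `"min_k"` or `"max_cover"`.
#' @param k target set size for `max_cover` (default: the minimal feasible
#'   size found).
#' @param solver `"greedy"` or `"exact"`.
#' @return A `feature_set_solution`: list with `features`, `params`
#'   (`alpha`, `beta`, `k`), `total_coverage` (met demand plus surplus),
#'   `feasible` and `solver`.
#' @export
solve_feature_set <- function(cov, params, mode = c("min_k", "max_cover"),
                              k = NULL, solver = c("greedy", "exact")) {
  mode <- match.arg(mode)
  solver <- match.arg(solver)
  alpha <- params$alpha; beta <- params$beta
  stopifnot(alpha >= 1, beta >= 0)
  ceil <- max_alpha_beta(cov)
  if (alpha > ceil$alpha_max || beta > ceil$beta_max)
    stop(sprintf("infeasible demands: requested (alpha=%d, beta=%d) but the retained features support at most (%d, %d)",
                 alpha, beta, ceil$alpha_max, ceil$beta_max))
  C <- cov$cover[order(rownames(cov$cover)), , drop = FALSE]  # id-order ties
  demand <- ifelse(cov$pairs$type == "inter", alpha, beta)

  core <- character(0)
  if (solver == "exact") {
    if (nrow(C) > 20L || cov$n_samples > 10L)
      stop("exact solver is guarded to <= 20 features and <= 10 samples")
    found <- NULL
    for (size in seq_len(nrow(C))) {
      subsets <- combn(nrow(C), size)
      for (j in seq_len(ncol(subsets))) {
        sel <- subsets[, j]
        if (coverage_feasible(C[sel, , drop = FALSE], demand)) {
          found <- rownames(C)[sel]
          break
        }
      }
      if (!is.null(found)) break
    }
    core <- found
  } else {
    d <- demand
    avail <- rep(TRUE, nrow(C))
    while (sum(d) > 0) {
      score <- as.vector(C %*% (d > 0))
      score[!avail] <- -1L
      pick <- which.max(score)   # first max = smallest feature id
      avail[pick] <- FALSE
      core <- c(core, rownames(C)[pick])
      hit <- C[pick, ] == 1L & d > 0
      d[hit] <- d[hit] - 1L
    }
  }

  features <- core
  if (mode == "max_cover") {
    if (is.null(k)) k <- length(core)
    if (k < length(core))
      stop("k = ", k, " is below the minimal feasible set size (",
           length(core), ")")
    avail <- !(rownames(C) %in% features)
    totals <- rowSums(C)
    while (length(features) < k) {
      if (!any(avail)) break
      score <- ifelse(avail, totals, -1)
      pick <- which.max(score)
      avail[pick] <- FALSE
      features <- c(features, rownames(C)[pick])
    }
  }
  sel <- cov$cover[features, , drop = FALSE]
  structure(list(features = features,
                 params = list(alpha = alpha, beta = beta,
                               k = length(features)),
                 total_coverage = solution_total_coverage(sel, demand),
                 feasible = coverage_feasible(sel, demand),
                 solver = solver),
            class = "feature_set_solution")
}

#' Max Cover (alpha,beta)-k feature-set differential expression
#'
#' The full two-stage pipeline: entropy/MDL binarization
#' ([discretize_matrix()]), pair-coverage construction, (alpha, beta)
#' ceiling computation and feature-set optimization.  By default the solver
#' targets the robust ceiling `(alpha, beta) = (alpha_max, beta_max)` in
#' `max_cover` mode at the greedy-minimal k.  Unlike the statistical
#' approaches this selector carries no p-values; scores are the per-feature
#' information gain.
#'
#' @param norm a `normalization_result` (or matrix / bead-summary matrix).
#' @param labels a [class_labels()].
#' @param alpha,beta demands; default: the achievable maxima.
#' @param k target set size for `max_cover` mode.
#' @param mode `"max_cover"` (default) or `"min_k"`.
#' @param solver `"greedy"` (default) or `"exact"` (guarded).
#' @return A [probe_set()] whose provenance records (alpha, beta, k) and the
#'   solver; empty (with a warning) when no feature survives the MDL filter.
#' @export
maxcover_de <- function(norm, labels, alpha = NULL, beta = NULL, k = NULL,
                        mode = c("max_cover", "min_k"),
                        solver = c("greedy", "exact")) {
  mode <- match.arg(mode)
  solver <- match.arg(solver)
  labels <- as_class_labels(labels)
  strategy <- if (inherits(norm, "normalization_result")) norm$strategy
              else "none"
  d <- discretize_matrix(norm, labels)
  if (!length(d$retained)) {
    warning("no features survived MDL discretization; returning an empty probe set")
    return(probe_set(character(0),
                     provenance = list(strategy = strategy,
                                       approach = "maxcover",
                                       filtered = FALSE)))
  }
  cov <- build_coverage(d, labels)
  ceil <- max_alpha_beta(cov)
  if (is.null(alpha)) alpha <- max(ceil$alpha_max, 1L)
  if (is.null(beta)) beta <- ceil$beta_max
  sol <- solve_feature_set(cov, list(alpha = alpha, beta = beta),
                           mode = mode, k = k, solver = solver)
  grp <- class_members(labels)
  bsel <- d$binary[sol$features, , drop = FALSE]
  direction <- sign(rowMeans(bsel[, grp$test, drop = FALSE]) -
                      rowMeans(bsel[, grp$control, drop = FALSE]))
  scores <- data.frame(probe_id = sol$features,
                       statistic = unname(d$gains[sol$features]),
                       p_value = NA_real_,
                       direction = unname(direction),
                       stringsAsFactors = FALSE)
  probe_set(sol$features, scores = scores,
            provenance = list(strategy = strategy, approach = "maxcover",
                              filtered = FALSE, alpha = sol$params$alpha,
                              beta = sol$params$beta, k = sol$params$k,
                              mode = mode, solver = solver,
                              total_coverage = sol$total_coverage,
                              thresholds = d$thresholds[sol$features]))
}
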