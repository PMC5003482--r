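#' NOG / POG overlap between two probe sets
#'
#' NOG is the number of overlapping probes; POG expresses it as a percentage
#' of each set's size.  Percentages are undefined (NA) for empty sets.
#'
#' @param a,b [probe_set()] objects or character vectors of probe IDs.
#' @return List with `nog`, `pog_a`, `pog_b`.
#' @export
pairwise_overlap <- function(a, b) {
  ia <- as_probe_ids(a); ib <- as_probe_ids(b)
  nog <- length(intersect(ia, ib))
  list(nog = nog,
       pog_a = if (length(ia)) 100 * nog / length(ia) else NA_real_,
       pog_b = if (length(ib)) 100 * nog / length(ib) else NA_real_)
}

#' Concordance across normalization strategies for one approach
#'
#' For each strategy, the mean NOG over all its pairwise comparisons with the
#' other strategies, and the mean POG attributed to that strategy's side of
#' each pair.  Strategies with empty probe sets are excluded with a warning
#' (the empty-set side of a POG is undefined and would bias the means), as
#' can strategies named in `exclude`.
#'
#' @param sets named list (strategy -> probe set) for a single analytical
#'   approach.
#' @param exclude optional character vector of strategies to leave out of all
#'   comparisons.
#' @return List with `per_strategy` (data.frame `strategy`, `n_probes`,
#'   `mean_nog`, `mean_pog`) and `pairs` (data.frame of all pairwise
#'   comparisons with both POG sides).
#' @export
strategy_concordance <- function(sets, exclude = NULL) {
  sets <- sets[!names(sets) %in% exclude]
  sizes <- vapply(sets, function(s) length(as_probe_ids(s)), 0L)
  if (any(sizes == 0L)) {
    warning("excluding strategies with empty probe sets: ",
            paste(names(sets)[sizes == 0L], collapse = ", "))
    sets <- sets[sizes > 0L]
    sizes <- sizes[sizes > 0L]
  }
  if (length(sets) < 2L)
    stop("need >= 2 non-empty strategies to compute concordance")
  nm <- names(sets)
  idx <- combn(length(nm), 2)
  pairs <- data.frame(strategy_a = nm[idx[1L, ]], strategy_b = nm[idx[2L, ]],
                      nog = NA_real_, pog_a = NA_real_, pog_b = NA_real_,
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(pairs))) {
    ov <- pairwise_overlap(sets[[pairs$strategy_a[r]]],
                           sets[[pairs$strategy_b[r]]])
    pairs$nog[r] <- ov$nog
    pairs$pog_a[r] <- ov$pog_a
    pairs$pog_b[r] <- ov$pog_b
  }
  per <- do.call(rbind, lapply(nm, function(s) {
    own <- c(pairs$pog_a[pairs$strategy_a == s],
             pairs$pog_b[pairs$strategy_b == s])
    nog <- pairs$nog[pairs$strategy_a == s | pairs$strategy_b == s]
    data.frame(strategy = s, n_probes = sizes[[s]], mean_nog = mean(nog),
               mean_pog = mean(own), stringsAsFactors = FALSE)
  }))
  list(per_strategy = per, pairs = pairs)
}

#' Full / partial / no concordance across analytical approaches
#'
#' Under one fixed normalization strategy, each probe found by at least one
#' approach is classified by how many of the m approaches found it: all m =
#' full concordance, 2..m-1 = partial, exactly 1 = no concordance.  For every
#' approach the full/partial/none counts partition its probe set.
#'
#' @param sets named list (approach -> probe set) for a single normalization
#'   strategy; the classical design uses exactly three approaches.
#' @return List with `per_probe` (data.frame `probe_id`, `n_found`, `class`)
#'   and `counts` (data.frame `approach`, `total`, `full`, `partial`,
#'   `none`).
#' @export
approach_concordance <- function(sets) {
  if (length(sets) < 2L) stop("need >= 2 approaches")
  ids <- lapply(sets, as_probe_ids)
  m <- length(ids)
  all_ids <- unique(unlist(ids, use.names = FALSE))
  n_found <- Reduce(`+`, lapply(ids, function(s)
    as.integer(all_ids %in% s)))
  cls <- ifelse(n_found == m, "full", ifelse(n_found == 1L, "none", "partial"))
  per_probe <- data.frame(probe_id = all_ids, n_found = n_found, class = cls,
                          stringsAsFactors = FALSE)
  counts <- do.call(rbind, lapply(names(ids), function(a) {
    inset <- all_ids %in% ids[[a]]
    data.frame(approach = a, total = sum(inset),
               full = sum(inset & cls == "full"),
               partial = sum(inset & cls == "partial"),
               none = sum(inset & cls == "none"),
               stringsAsFactors = FALSE)
  }))
  list(per_probe = per_probe, counts = counts)
}

#' Pathway-level concordance across approaches
#'
#' A pathway counts as concordant for an approach when it is also enriched
#' in at least one other approach's pathway set.
#'
#' @param path_sets named list (approach -> character vector of enriched
#'   pathway IDs).
#' @return data.frame with columns `approach`, `total`, `concordant`.
#' @export
pathway_concordance <- function(path_sets) {
  nm <- names(path_sets)
  do.call(rbind, lapply(nm, function(a) {
    others <- unique(unlist(path_sets[setdiff(nm, a)], use.names = FALSE))
    data.frame(approach = a, total = length(path_sets[[a]]),
               concordant = sum(path_sets[[a]] %in% others),
               stringsAsFactors = FALSE)
  }))
}
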