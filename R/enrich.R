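#' Hypergeometric pathway over-representation
#'
#' Maps the probes of a set to genes (deduplicating genes hit by several
#' probes), then tests every pathway for over-representation against the
#' array background: with `N` background genes, `K` of them in the pathway,
#' `n` mapped query genes and `k` query genes in the pathway, the upper-tail
#' p-value is `P[X >= k]` for `X ~ Hypergeom(N, K, n)` and
#' `fold_enrichment = (k/n) / (K/N)`.  The EASE variant replaces `k` by
#' `k - 1` in the tail, a conservative penalty used by DAVID.
#'
#' @param probes a [probe_set()] or character vector of probe IDs.
#' @param ann a [pathway_annotation()].
#' @param p_cutoff significance threshold on the p-value (default 0.05).
#' @param fold_cutoff optional additional threshold on fold enrichment (a
#'   stringent published variant uses fold > 1.9 with p < 0.01).
#' @param ease use the EASE-penalized tail instead of the plain
#'   hypergeometric.
#' @return data.frame sorted by p-value with columns `pathway_id`, `k`, `n`,
#'   `K`, `N`, `fold_enrichment`, `p_value`, `significant`.
#' @export
enrich_pathways <- function(probes, ann, p_cutoff = 0.05, fold_cutoff = NULL,
                            ease = FALSE) {
  stopifnot(inherits(ann, "pathway_annotation"))
  ids <- as_probe_ids(probes)
  genes <- unique(unname(ann$probe_to_gene[intersect(ids,
                                                     names(ann$probe_to_gene))]))
  genes <- intersect(genes, ann$background)
  N <- length(ann$background)
  n <- length(genes)
  if (n == 0L) {
    warning("no query probes map to background genes; empty enrichment result")
    return(data.frame(pathway_id = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      fold_enrichment = numeric(0), p_value = numeric(0),
                      significant = logical(0)))
  }
  res <- do.call(rbind, lapply(names(ann$pathways), function(pid) {
    pw <- intersect(ann$pathways[[pid]], ann$background)
    K <- length(pw)
    k <- length(intersect(genes, pw))
    k_tail <- if (ease) max(k - 1L, 0L) else k
    p <- phyper(k_tail - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = pid, k = k, n = n, K = K, N = N,
               fold_enrichment = (k / n) / (K / N), p_value = p,
               stringsAsFactors = FALSE)
  }))
  res$significant <- res$p_value < p_cutoff &
    (if (is.null(fold_cutoff)) TRUE else res$fold_enrichment >= fold_cutoff)
  res[order(res$p_value, res$pathway_id), , drop = FALSE]
}
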