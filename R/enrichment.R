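#' Hypergeometric upper-tail probability
#'
#' Over-representation p-value `P(X >= k)` for drawing `k` or more members
#' of a `K`-gene term in a sample of `n` genes from a universe of `N`,
#' `X ~ Hypergeometric(N, K, n)`. Computed via the log-space tail of
#' `stats::phyper`.
#'
#' @param k observed overlap, `0 <= k <= min(K, n)`.
#' @param K term size in the universe.
#' @param n sample (sector) size in the universe.
#' @param N universe size.
#' @return the upper-tail probability (scalar in `[0, 1]`).
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (K < 0 || n < 0 || K > N || n > N || k < 0 || k > min(K, n)) {
    stop("hypergeom_upper_tail: impossible counts (k=", k, ", K=", K,
         ", n=", n, ", N=", N, ")")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Per-sector over-representation analysis
#'
#' Tests every (sector, term) pair with overlap `k >= 1` using the
#' hypergeometric upper tail, then applies Benjamini-Hochberg correction
#' across the terms tested within each sector. Results are flagged
#' significant when the raw `p < alpha` and sorted by `(sector_id, p)`.
#'
#' @param partition a `sector_partition` (see [angular_gap_clusters()]) or a
#'   data frame with columns `node` and `sector_id`.
#' @param gene_sets a `gene_sets` collection.
#' @param universe character vector of universe genes; must contain every
#'   sector member. Defaults to the union of sector members, but for sectors
#'   cut out of a larger embedded network the full network's node set should
#'   be supplied.
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @return data frame with columns `sector_id`, `term`, `term_name`, `k`,
#'   `K`, `n`, `N`, `p`, `q`, `significant`.
#' @export
enrich_sectors <- function(partition, gene_sets, universe = NULL,
                           alpha = 0.05) {
  stopifnot(alpha > 0, alpha <= 1)
  assign_df <- if (inherits(partition, "sector_partition"))
    partition$assignments else partition
  stopifnot(all(c("node", "sector_id") %in% names(assign_df)))
  members <- split(as.character(assign_df$node), assign_df$sector_id)
  if (is.null(universe)) universe <- unique(as.character(assign_df$node))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("enrich_sectors: empty universe")
  missing <- setdiff(unlist(members), universe)
  if (length(missing)) {
    stop("enrich_sectors: universe does not cover sector member(s): ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  N <- length(universe)
  term_genes <- lapply(gene_sets, function(gs) intersect(gs$genes, universe))
  Ks <- lengths(term_genes)
  out <- vector("list", length(members))
  for (si in seq_along(members)) {
    sec <- members[[si]]
    n <- length(sec)
    ks <- vapply(term_genes, function(tg) length(intersect(tg, sec)),
                 integer(1))
    tested <- which(ks >= 1 & Ks >= 1)
    if (!length(tested)) next
    p <- vapply(tested, function(ti) {
      hypergeom_upper_tail(ks[ti], Ks[ti], n, N)
    }, numeric(1))
    out[[si]] <- data.frame(
      sector_id = as.integer(names(members)[si]),
      term = names(gene_sets)[tested],
      term_name = vapply(gene_sets[tested], `[[`, "", "name"),
      k = ks[tested], K = Ks[tested], n = n, N = N,
      p = p, q = stats::p.adjust(p, method = "BH"),
      significant = p < alpha,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) {
    res <- data.frame(sector_id = integer(0), term = character(0),
                      term_name = character(0), k = integer(0),
                      K = integer(0), n = integer(0), N = integer(0),
                      p = numeric(0), q = numeric(0),
                      significant = logical(0))
  }
  res <- res[order(res$sector_id, res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
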