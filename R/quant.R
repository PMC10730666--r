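#' Select enriched genes from a differential-enrichment table
#'
#' Applies the standard selection rule for transcripts enriched in one
#' condition: `p < p_max` (or the adjusted p-value when `use_adjusted`) and
#' `log2FC > lfc_min`. Input order is preserved.
#'
#' @param records data frame with columns `gene`, `log2FC` and `p`
#'   (plus `adj_p` when `use_adjusted = TRUE`).
#' @param p_max p-value cutoff in (0, 1] (default 0.05).
#' @param lfc_min exclusive lower bound on `log2FC` (default 0).
#' @param use_adjusted filter on `adj_p` instead of `p`.
#' @return character vector of selected gene identifiers.
#' @export
filter_enriched <- function(records, p_max = 0.05, lfc_min = 0,
                            use_adjusted = FALSE) {
  stopifnot(p_max > 0, p_max <= 1)
  pcol <- if (use_adjusted) "adj_p" else "p"
  need <- c("gene", "log2FC", pcol)
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("filter_enriched: missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  keep <- records[[pcol]] < p_max & records$log2FC > lfc_min
  keep[is.na(keep)] <- FALSE
  as.character(records$gene[keep])
}

#' Relative expression by the 2^-dCt method
#'
#' qPCR relative expression of a target normalized to a housekeeping
#' reference: `2^-(Ct_target - Ct_reference)`.
#'
#' @param ct_target,ct_reference finite cycle-threshold values (vectors
#'   recycle).
#' @return numeric vector of relative expression values.
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop("relative_expression: Ct values must be finite")
  }
  2^(-(ct_target - ct_reference))
}

#' Reporter signal ratio
#'
#' Plain ratio used for Firefly/Renilla dual-luciferase readouts,
#' cytoplasmic/total expression comparisons, and fluorescent-dye
#' signal/background normalization.
#'
#' @param numerator numeric signal.
#' @param denominator numeric signal, strictly positive.
#' @return `numerator / denominator`.
#' @export
signal_ratio <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("signal_ratio: denominator must be > 0")
  numerator / denominator
}

#' Two-group comparison (Welch t-test)
#'
#' Summarizes two sets of replicate measurements as mean +/- SD and
#' compares them with a two-sided Welch (unequal-variance) t-test. With
#' zero variance in both groups the degenerate limits are returned
#' (`t = 0, p = 1` for equal means; `p = 0` otherwise).
#'
#' @param a,b numeric vectors with at least 2 values each.
#' @return list with `mean_a`, `sd_a`, `mean_b`, `sd_b`, `t`, `df`, `p`.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("compare_groups: need at least 2 values per group")
  }
  m_a <- mean(a); m_b <- mean(b)
  s_a <- stats::sd(a); s_b <- stats::sd(b)
  se2 <- s_a^2 / length(a) + s_b^2 / length(b)
  if (se2 == 0) {
    t_stat <- if (m_a == m_b) 0 else sign(m_a - m_b) * Inf
    return(list(mean_a = m_a, sd_a = s_a, mean_b = m_b, sd_b = s_b,
                t = t_stat, df = length(a) + length(b) - 2,
                p = if (m_a == m_b) 1 else 0))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(mean_a = m_a, sd_a = s_a, mean_b = m_b, sd_b = s_b,
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
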