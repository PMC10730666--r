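# Shared fixtures and small independent oracles for the test suite.

# write a 6-column interaction table (symA, idA, symB, idB, score, evidence)
write_edge_table <- function(a, b, score, path = tempfile(fileext = ".tsv"),
                             header = FALSE) {
  lines <- sprintf("%s\t%d\t%s\t%d\t%s\t-", a, seq_along(a) * 10, b,
                   seq_along(b) * 10 + 1, format(score, trim = TRUE))
  if (header) lines <- c("#sym_a\tid_a\tsym_b\tid_b\tscore\tevidence", lines)
  writeLines(lines, path)
  path
}

toy_graph <- function(edges) {
  igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]), directed = FALSE)
}

random_gnp <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

# is `x` a rotation (possibly reversed) of `ref`?
is_circular_shift <- function(x, ref) {
  n <- length(ref)
  if (length(x) != n) return(FALSE)
  for (rev_it in c(FALSE, TRUE)) {
    y <- if (rev_it) rev(x) else x
    for (s in 0:(n - 1)) {
      if (identical(y, c(ref[(s + 1):n], ref[seq_len(s)])[seq_len(n)])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# independent angular-gap clustering oracle: two nodes share a sector iff
# some arc between them (one direction around the circle) crosses no gap > g
oracle_gap_partition <- function(theta, g) {
  n <- length(theta)
  ord <- order(theta)
  gaps <- c(diff(theta[ord]), 2 * pi - theta[ord][n] + theta[ord][1])
  cut <- gaps > g
  # walk the circle grouping consecutive sorted nodes not separated by a cut
  grp <- integer(n)
  cur <- 1L
  grp[ord[1]] <- cur
  for (k in seq_len(n - 1)) {
    if (cut[k]) cur <- cur + 1L
    grp[ord[k + 1]] <- cur
  }
  if (!cut[n] && cur > 1L) grp[grp == cur] <- 1L # wrap joins last to first
  grp
}

# canonical representation of a partition for comparisons
partition_sets <- function(ids, labels) {
  sets <- split(ids, labels)
  sets <- lapply(sets, sort)
  unname(sets[order(vapply(sets, `[[`, "", 1))])
}

# exhaustive hypergeometric upper tail via log-binomials
oracle_hyper_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# naive PWM rescoring oracle (double loop, bits)
oracle_scan <- function(seqc, pwm, pseudocount) {
  alph <- c("A", "C", "G", "U")
  chars <- strsplit(seqc, "")[[1]]
  M <- length(chars); w <- pwm$width
  if (M < w) return(numeric(0))
  vapply(0:(M - w), function(off) {
    s <- 0
    for (j in seq_len(w)) {
      base <- chars[off + j]
      s <- s + if (base == "N") 0 else
        log2(((pwm$mat[j, base] + pseudocount) / (1 + 4 * pseudocount)) /
               pwm$background)
    }
    s
  }, numeric(1))
}
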