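#' Consecutive angular gaps around the circle
#'
#' Sorts angles ascending and returns the `n` consecutive differences,
#' including the wrap-around gap `2*pi - theta_(n) + theta_(1)`; the gaps
#' sum to `2*pi`.
#'
#' @param thetas numeric vector of `>= 2` angles in `[0, 2*pi)`.
#' @return numeric vector of `length(thetas)` gaps; gap `k` separates the
#'   `k`-th and `(k+1)`-th sorted angle (gap `n` wraps to the first).
#' @export
circular_gaps <- function(thetas) {
  if (length(thetas) < 2) stop("circular_gaps: need at least 2 angles")
  stopifnot(all(thetas >= 0), all(thetas < 2 * pi))
  s <- sort(thetas)
  c(diff(s), 2 * pi - s[length(s)] + s[1])
}

# Internal: circular runs between cut gaps. Returns a list of integer
# vectors of *sorted positions*; `cuts` indexes gaps (gap k follows sorted
# position k).
.runs_from_cuts <- function(n, cuts) {
  if (!length(cuts)) return(list(seq_len(n)))
  cuts <- sort(cuts)
  starts <- (cuts %% n) + 1L
  ends <- c(cuts[-1], cuts[1])
  lapply(seq_along(cuts), function(j) {
    s <- starts[j]; e <- ends[j]
    if (s <= e) s:e else c(s:n, 1:e)
  })
}

#' Partition embedded nodes into angular sectors
#'
#' Sorts nodes by angle (ties broken by node id), computes consecutive gaps
#' including the wrap-around gap, and cuts the circle at every gap strictly
#' greater than `g`; each maximal uncut run is a sector. Sectors smaller
#' than `min_size` are handled by `policy`: `"keep"` (default; a warning is
#' emitted) or `"merge"` (repeatedly join an undersized sector with its
#' neighbour across the smaller adjacent gap until all sectors reach
#' `min_size` or one sector remains). Sector ids are numbered `1..k` by
#' increasing angular start position beginning just after the largest gap.
#'
#' @param coords data frame with columns `node` and `theta` (radians).
#' @param g angular gap threshold in radians, `> 0`.
#' @param min_size minimum sector membership (default 5).
#' @param policy `"keep"` or `"merge"`.
#' @return an object of class `sector_partition`: list with `assignments`
#'   (data frame `node`, `sector_id`, `theta`), `sectors` (data frame
#'   `sector_id`, `size`, `theta_start`, `theta_end`), and the parameters.
#' @export
angular_gap_clusters <- function(coords, g, min_size = 5,
                                 policy = c("keep", "merge")) {
  policy <- match.arg(policy)
  stopifnot(g > 0, min_size >= 1, nrow(coords) >= 1)
  theta <- norm_angle(coords$theta)
  node <- as.character(coords$node)
  ord <- order(theta, node, method = "radix")
  node <- node[ord]; theta <- theta[ord]
  n <- length(theta)
  if (n == 1) {
    runs <- list(1L)
    gaps <- 2 * pi
  } else {
    gaps <- c(diff(theta), 2 * pi - theta[n] + theta[1])
    runs <- .runs_from_cuts(n, which(gaps > g))
  }
  # merge policy: join undersized sectors across their smaller boundary gap
  if (policy == "merge") {
    boundary <- function(runs) {
      # gap index after the last member of each run (the cut to the next run)
      vapply(runs, function(rr) rr[length(rr)], integer(1))
    }
    while (length(runs) > 1 && any(lengths(runs) < min_size)) {
      sizes <- lengths(runs)
      i <- which(sizes < min_size)[which.min(sizes[sizes < min_size])]
      k <- length(runs)
      nxt <- if (i == k) 1L else i + 1L
      prv <- if (i == 1) k else i - 1L
      bg <- boundary(runs)
      gap_right <- gaps[bg[i]]    # between run i and the next run
      gap_left <- gaps[bg[prv]]   # between previous run and run i
      if (gap_left <= gap_right) {
        runs[[prv]] <- c(runs[[prv]], runs[[i]])
        runs[[i]] <- NULL
      } else {
        runs[[i]] <- c(runs[[i]], runs[[nxt]])
        runs[[nxt]] <- NULL
      }
    }
  }
  k <- length(runs)
  # number sectors from just after the largest boundary gap, in circular order
  if (k > 1) {
    last_gap <- vapply(runs, function(rr) gaps[rr[length(rr)]], numeric(1))
    start_at <- (which.max(last_gap) %% k) + 1L
    order_ids <- ((seq_len(k) - start_at) %% k) + 1L
  } else {
    order_ids <- 1L
  }
  sector_id <- integer(n)
  for (j in seq_len(k)) sector_id[runs[[j]]] <- order_ids[j]
  if (policy == "keep" && any(lengths(runs) < min_size)) {
    warning("angular_gap_clusters: ", sum(lengths(runs) < min_size),
            " sector(s) smaller than min_size = ", min_size)
  }
  sec <- data.frame(
    sector_id = order_ids,
    size = lengths(runs),
    theta_start = vapply(runs, function(rr) theta[rr[1]], numeric(1)),
    theta_end = vapply(runs, function(rr) theta[rr[length(rr)]], numeric(1))
  )
  sec <- sec[order(sec$sector_id), , drop = FALSE]
  rownames(sec) <- NULL
  structure(list(
    assignments = data.frame(node = node, sector_id = sector_id,
                             theta = theta, stringsAsFactors = FALSE),
    sectors = sec, g = g, min_size = min_size, policy = policy
  ), class = "sector_partition")
}

#' @export
print.sector_partition <- function(x, ...) {
  cat("sector_partition:", nrow(x$sectors), "sectors over",
      nrow(x$assignments), "nodes (g =", signif(x$g, 4),
      ", min_size =", x$min_size, ")\n")
  print(x$sectors)
  invisible(x)
}

#' Tune the angular gap threshold
#'
#' Every distinct observed gap value defines a candidate partition (cut the
#' circle at all gaps at least that large). Among the candidates in which
#' every sector holds at least `min_size` members, the one with the most
#' sectors wins; ties are broken in favour of cutting fewer (larger) gaps.
#' The returned `g` is the largest threshold that reproduces the winning
#' partition under the strict `gap > g` rule of [angular_gap_clusters()],
#' i.e. the largest uncut gap (or just below the smallest cut gap when every
#' gap is cut). The worst case, where no multi-sector candidate satisfies
#' the size constraint, returns the largest observed gap, which yields a
#' single sector.
#'
#' Under `policy = "keep"` a candidate is valid only if every raw sector
#' already meets the size floor; a single angularly isolated node therefore
#' vetoes multi-sector partitions. Under `policy = "merge"` each candidate
#' partition is evaluated after undersized sectors have been absorbed across
#' their smaller boundary gap, which is robust to such stragglers.
#'
#' @param coords data frame with columns `node` and `theta`.
#' @param min_size minimum sector size; `nrow(coords)` must be `>= min_size`.
#' @param policy size-enforcement policy used when evaluating candidates;
#'   must match the policy later passed to [angular_gap_clusters()].
#' @return the selected gap threshold `g` (scalar, radians).
#' @export
tune_gap_threshold <- function(coords, min_size = 5,
                               policy = c("keep", "merge")) {
  policy <- match.arg(policy)
  stopifnot(nrow(coords) >= min_size)
  theta <- norm_angle(coords$theta)
  if (length(theta) < 2) return(2 * pi)
  node <- as.character(coords$node)
  ord <- order(theta, node, method = "radix")
  ts <- theta[ord]
  n <- length(ts)
  sgaps <- c(diff(ts), 2 * pi - ts[n] + ts[1])
  # Inf = cut nothing (single sector), always a valid fallback
  cands <- c(Inf, sort(unique(sgaps[sgaps > 0]), decreasing = TRUE))
  strict_g <- function(v) {
    uncut <- sgaps[sgaps < v & sgaps > 0]
    if (length(uncut)) max(uncut) else v * (1 - 1e-12)
  }
  best_v <- Inf; best_k <- 0L
  for (v in cands) {
    if (policy == "keep") {
      runs <- .runs_from_cuts(n, which(sgaps >= v))
      if (any(lengths(runs) < min_size)) next
      k <- length(runs)
    } else {
      part <- angular_gap_clusters(coords, g = strict_g(v),
                                   min_size = min_size, policy = "merge")
      if (any(part$sectors$size < min_size) && nrow(part$sectors) > 1) next
      k <- nrow(part$sectors)
    }
    if (k > best_k) {
      best_k <- k; best_v <- v
    }
  }
  strict_g(best_v)
}
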