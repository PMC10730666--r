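#' @title LaBNE+HM hyperbolic embedding
#' @name embedding
#' @description Infer polar coordinates for every node of a connected
#'   network: a Laplacian-eigenmaps angular layout with degree-ranked radii
#'   (LaBNE), optionally followed by windowed maximum-likelihood angular
#'   refinement (HM).
NULL

.embedded_network <- function(network, coords, params, loglik_trace) {
  structure(list(network = network, coords = coords, params = params,
                 loglik_trace = loglik_trace),
            class = "embedded_network")
}

#' @export
print.embedded_network <- function(x, ...) {
  cat("embedded_network:", nrow(x$coords), "nodes | gamma =", x$params$gamma,
      "| T =", x$params$temp, "| R =", signif(x$params$R, 6), "\n")
  cat("log-likelihood trace:",
      paste(signif(x$loglik_trace, 8), collapse = " -> "), "\n")
  invisible(x)
}

# Canonicalize eigenvector sign: largest-|entry| coordinate made positive.
.canon_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' Laplacian-based network embedding (LaBNE)
#'
#' Builds the symmetric normalized graph Laplacian
#' \eqn{L = I - D^{-1/2} A D^{-1/2}}, takes the eigenvectors of its two
#' smallest strictly positive eigenvalues as planar coordinates
#' \eqn{(x_i, y_i)} and sets \eqn{\theta_i = \mathrm{atan2}(y_i, x_i)}.
#' Radii come from [radial_from_degree_rank()] with
#' \eqn{\beta = 1/(\gamma - 1)}; the connection radius from
#' [connection_radius()]. Eigenvector signs are canonicalized (largest-
#' magnitude entry positive) so repeated runs give identical output; the
#' layout is meaningful up to a global rotation/reflection.
#'
#' @param network a connected `igraph` with named vertices, `N >= 3`.
#' @param gamma degree exponent of the assumed PS model (default 2.97).
#' @param temp temperature used for the connection radius and any subsequent
#'   likelihood work (default 0.83).
#' @param m expected links per new node; estimated as
#'   `max(1, round(mean_degree / 2))` when `NULL`.
#' @return an `embedded_network` (network, coords, params, loglik_trace).
#' @export
labne <- function(network, gamma = 2.97, temp = 0.83, m = NULL) {
  stopifnot(igraph::is_igraph(network), gamma >= 2)
  N <- igraph::vcount(network)
  if (N < 3) stop("labne: need at least 3 nodes")
  if (!igraph::is_connected(network)) {
    stop("labne: network is disconnected; run extract_lcc() first")
  }
  nodes <- igraph::V(network)$name
  A <- as.matrix(igraph::as_adjacency_matrix(network, type = "both"))
  deg <- rowSums(A)
  dinv <- 1 / sqrt(deg)
  Lsym <- diag(N) - (dinv %o% dinv) * A
  eig <- eigen(Lsym, symmetric = TRUE)
  # eigenvalues come in decreasing order; smallest strictly positive ones sit
  # at the tail just before the single ~0 eigenvalue of a connected graph
  pos <- which(eig$values > 1e-9)
  if (length(pos) < 2) stop("labne: fewer than two positive Laplacian eigenvalues")
  i1 <- pos[length(pos)]       # smallest strictly positive
  i2 <- pos[length(pos) - 1L]  # second smallest
  x <- .canon_sign(eig$vectors[, i1])
  y <- .canon_sign(eig$vectors[, i2])
  theta <- norm_angle(atan2(y, x))
  beta <- 1 / (gamma - 1)
  degv <- deg
  names(degv) <- nodes
  r <- radial_from_degree_rank(degv, beta = beta, N = N)
  if (is.null(m)) m <- max(1, round(mean(deg) / 2))
  R <- connection_radius(N, m = m, temp = temp, beta = beta)
  coords <- data.frame(node = nodes, r = unname(r), theta = theta,
                       stringsAsFactors = FALSE)
  params <- list(gamma = gamma, temp = temp, beta = beta, w = NA_real_,
                 m = m, R = R)
  ll <- network_loglikelihood(network, coords, R = R, temp = temp)
  .embedded_network(network, coords, params, loglik_trace = ll)
}

#' HyperMap-style maximum-likelihood angular refinement (HM)
#'
#' Visits nodes in decreasing degree order; for each node, evaluates the
#' local log-likelihood of its adjacency row against all other nodes at its
#' current angle plus `n_candidates` angles uniformly gridded over
#' `[theta - w/2, theta + w/2]` (mod 2*pi), and moves the node to the argmax.
#' Because the incumbent angle is always a candidate, the total network
#' log-likelihood never decreases; it is recorded per sweep in
#' `loglik_trace`. Radii are never refined.
#'
#' @param embedded an `embedded_network` from [labne()].
#' @param temp temperature `> 0`; defaults to the embedding's parameter.
#' @param w angular search window in radians, `0 < w <= 2*pi` (default
#'   `2*pi`, a global search).
#' @param n_candidates number of grid angles per node (default 100).
#' @param n_sweeps number of full passes over the nodes (default 1).
#' @return the refined `embedded_network` with an extended `loglik_trace`.
#' @export
hm_refine <- function(embedded, temp = NULL, w = 2 * pi, n_candidates = 100,
                      n_sweeps = 1) {
  stopifnot(inherits(embedded, "embedded_network"), n_candidates >= 2,
            n_sweeps >= 0)
  if (w <= 0 || w > 2 * pi) stop("hm_refine: window w must be in (0, 2*pi]")
  if (is.null(temp)) temp <- embedded$params$temp
  stopifnot(temp > 0)
  g <- embedded$network
  nodes <- igraph::V(g)$name
  coords <- embedded$coords
  idx <- match(nodes, coords$node)
  r <- coords$r[idx]
  th <- coords$theta[idx]
  A <- as.matrix(igraph::as_adjacency_matrix(g, type = "both"))
  R <- embedded$params$R
  deg <- rowSums(A)
  visit <- order(-deg, nodes, method = "radix")
  trace <- embedded$loglik_trace
  n <- length(nodes)
  grid_off <- seq(-w / 2, w / 2, length.out = n_candidates)
  for (sweep in seq_len(n_sweeps)) {
    for (i in visit) {
      cands <- norm_angle(c(th[i], th[i] + grid_off))
      others <- setdiff(seq_len(n), i)
      a <- A[i, others]
      dth <- pi - abs(pi - abs(outer(cands, th[others], "-")) %% (2 * pi))
      nc <- length(cands)
      R2 <- matrix(r[others], nc, n - 1, byrow = TRUE)
      X <- .hyp_dist_core(r[i], R2, dth)
      P <- connection_probability(X, R, temp, clip = TRUE)
      ll <- as.vector(log(P) %*% a + log1p(-P) %*% (1 - a))
      th[i] <- cands[which.max(ll)]
    }
    coords$theta[idx] <- th
    ll_tot <- network_loglikelihood(g, coords, R = R, temp = temp)
    if (ll_tot < trace[length(trace)] - 1e-6) {
      stop("hm_refine: log-likelihood decreased across a sweep (",
           trace[length(trace)], " -> ", ll_tot, ")")
    }
    trace <- c(trace, ll_tot)
  }
  coords$theta[idx] <- th
  params <- embedded$params
  params$temp <- temp
  params$w <- w
  .embedded_network(g, coords, params, trace)
}

#' Full LaBNE+HM embedding
#'
#' Composition of [labne()] and [hm_refine()] with the defaults used for
#' human PIN analysis: `gamma = 2.97`, `temp = 0.83`, `w = 2*pi`,
#' 100 candidate angles, one refinement sweep.
#'
#' @inheritParams labne
#' @inheritParams hm_refine
#' @return an `embedded_network`.
#' @export
embed_labne_hm <- function(network, gamma = 2.97, temp = 0.83, w = 2 * pi,
                           n_candidates = 100, n_sweeps = 1, m = NULL) {
  emb <- labne(network, gamma = gamma, temp = temp, m = m)
  hm_refine(emb, temp = temp, w = w, n_candidates = n_candidates,
            n_sweeps = n_sweeps)
}
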