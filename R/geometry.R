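#' Normalize angles to [0, 2*pi)
#'
#' @param theta numeric vector of angles in radians.
#' @return numeric vector with every angle reduced modulo `2*pi`.
#' @export
norm_angle <- function(theta) theta %% (2 * pi)

# Shortest angular separation on the circle, in [0, pi].
.ang_sep <- function(t1, t2) {
  d <- abs(t1 - t2) %% (2 * pi)
  pi - abs(pi - d)
}

# Vectorized hyperbolic distance from precomputed angular separations.
# r1, r2 recycle against dth (dth may be a matrix, r1/r2 conforming vectors
# or scalars already expanded by the caller).
.hyp_dist_core <- function(r1, r2, dth) {
  arg <- cosh(r1) * cosh(r2) - sinh(r1) * sinh(r2) * cos(dth)
  x <- acosh(pmax(arg, 1))
  big <- (r1 + r2) > 40
  if (any(big)) {
    # asymptotic form; sin(dth/2) -> 0 gives -Inf, guarded by the radial geodesic
    xa <- r1 + r2 + 2 * log(sin(dth / 2))
    xa <- pmax(xa, abs(r1 - r2))
    x[big] <- xa[big]
  }
  x
}

#' Hyperbolic distance between points of the hyperbolic plane
#'
#' Distance between points given in native polar coordinates \eqn{(r, \theta)}
#' with curvature -1:
#' \deqn{x = \mathrm{arccosh}(\cosh r_p \cosh r_q - \sinh r_p \sinh r_q \cos\Delta\theta)}
#' with \eqn{\Delta\theta = \pi - |\pi - |\theta_p - \theta_q||}. When
#' \eqn{r_p + r_q > 40} the numerically safe asymptotic form
#' \eqn{x \approx r_p + r_q + 2\ln\sin(\Delta\theta/2)} is used, bounded below
#' by the radial geodesic \eqn{|r_p - r_q|}.
#'
#' All arguments are recycled, so pairwise vectors of points can be compared
#' in one call.
#'
#' @param r1,theta1 polar coordinates of the first point(s).
#' @param r2,theta2 polar coordinates of the second point(s).
#' @return numeric vector of non-negative distances.
#' @export
hyperbolic_distance <- function(r1, theta1, r2, theta2) {
  stopifnot(is.finite(r1), is.finite(r2), r1 >= 0, r2 >= 0)
  .hyp_dist_core(r1, r2, .ang_sep(theta1, theta2))
}

# Full pairwise distance matrix for coordinate vectors (used by likelihood
# and by the embedding refinement).
.pairwise_hyp_dist <- function(r, theta) {
  n <- length(r)
  d <- abs(outer(theta, theta, "-")) %% (2 * pi)
  dth <- pi - abs(pi - d)
  R1 <- matrix(r, n, n)
  .hyp_dist_core(R1, t(R1), dth)
}

#' Fermi-Dirac connection probability
#'
#' Probability that two nodes at hyperbolic distance `x` are connected in a
#' popularity-similarity network with connection radius `R` and temperature
#' `temp`:
#' \deqn{p(x) = 1 / (1 + e^{(x - R)/(2T)})}
#' At `temp = 0` the kernel degenerates to the step function
#' \eqn{1\{x \le R\}}.
#'
#' @param x hyperbolic distance(s), non-negative.
#' @param R connection radius.
#' @param temp temperature, `>= 0`.
#' @param clip if `TRUE`, clip the result into `[1e-12, 1 - 1e-12]` so that
#'   log-likelihood terms stay finite. Default `FALSE` (exact probabilities).
#' @return numeric vector of probabilities.
#' @export
connection_probability <- function(x, R, temp, clip = FALSE) {
  stopifnot(temp >= 0)
  if (temp == 0) {
    p <- as.numeric(x <= R)
  } else {
    p <- 1 / (1 + exp((x - R) / (2 * temp)))
  }
  if (clip) p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  p
}

#' Radial coordinates from degree rank
#'
#' Assigns each node the radius dictated by the popularity-similarity model:
#' sorting nodes by decreasing degree, the node of rank i (1-based) receives
#' \deqn{r_i = 2\beta \ln i + 2(1 - \beta)\ln N .}
#' Hubs therefore sit near the disc centre. Degree ties are broken by
#' lexicographic node identifier, which makes the assignment deterministic.
#'
#' @param degrees named numeric vector of node degrees.
#' @param beta popularity-fading parameter in (0, 1], `beta = 1/(gamma - 1)`.
#' @param N number of nodes (defaults to `length(degrees)`).
#' @return named numeric vector of radii in the input order of `degrees`.
#' @export
radial_from_degree_rank <- function(degrees, beta, N = length(degrees)) {
  stopifnot(N >= 2, beta > 0, beta <= 1, !is.null(names(degrees)))
  ord <- order(-degrees, names(degrees), method = "radix")
  rank_of <- integer(length(degrees))
  rank_of[ord] <- seq_along(degrees)
  r <- 2 * beta * log(rank_of) + 2 * (1 - beta) * log(N)
  names(r) <- names(degrees)
  r
}

#' Connection radius of the popularity-similarity model
#'
#' Closed-form radius at which the Fermi-Dirac kernel reproduces, in
#' expectation, `m` links per newly arriving node in a PS network of final
#' size `N`:
#' \deqn{R = 2\ln N - 2\ln\!\left( \frac{2T}{\sin(T\pi)} \cdot
#'       \frac{1 - N^{-(1-\beta)}}{m(1-\beta)} \right)}
#' At `temp = 0` the prefactor `2T/sin(T*pi)` is replaced by its limit
#' `2/pi`; at `beta = 1` the ratio `(1 - N^-(1-beta))/(1-beta)` is replaced
#' by its limit `ln N`.
#'
#' @param N network size (`>= 2`).
#' @param m expected links per new node (`>= 1`), i.e. half the mean degree.
#' @param temp temperature in `[0, 1)`; the kernel is undefined at `T >= 1`.
#' @param gamma degree exponent (`>= 2`); used to derive `beta` when `beta`
#'   is not given.
#' @param beta popularity fading in (0, 1]; overrides `gamma`.
#' @return connection radius `R` (scalar).
#' @export
connection_radius <- function(N, m, temp, gamma = NULL, beta = NULL) {
  if (is.null(beta)) {
    stopifnot(!is.null(gamma), gamma >= 2)
    beta <- 1 / (gamma - 1)
  }
  stopifnot(N >= 2, m >= 1, beta > 0, beta <= 1, temp >= 0)
  if (temp >= 1) {
    stop("connection_radius: temperature must be < 1 (kernel undefined)")
  }
  pref <- if (temp == 0) 2 / pi else 2 * temp / sin(temp * pi)
  grow <- if (beta == 1) log(N) else (1 - N^(-(1 - beta))) / (1 - beta)
  2 * log(N) - 2 * log(pref * grow / m)
}

#' Log-likelihood of a network under the PS connection model
#'
#' Bernoulli log-likelihood of the observed adjacency given node coordinates:
#' \deqn{L = \sum_{i<j} a_{ij}\ln p(x_{ij}) + (1 - a_{ij})\ln(1 - p(x_{ij}))}
#' where \eqn{p} is the Fermi-Dirac kernel with probabilities clipped into
#' `[1e-12, 1 - 1e-12]` so non-edges at tiny distance do not yield `-Inf`.
#'
#' @param network an `igraph` object with named vertices.
#' @param coords data frame with columns `node`, `r`, `theta` covering every
#'   vertex of `network`.
#' @param R connection radius.
#' @param temp temperature, `> 0`.
#' @return scalar log-likelihood.
#' @export
network_loglikelihood <- function(network, coords, R, temp) {
  stopifnot(igraph::is_igraph(network), temp > 0)
  nodes <- igraph::V(network)$name
  idx <- match(nodes, coords$node)
  if (anyNA(idx)) {
    stop("network_loglikelihood: missing coordinates for node(s): ",
         paste(nodes[is.na(idx)], collapse = ", "))
  }
  r <- coords$r[idx]
  th <- coords$theta[idx]
  A <- as.matrix(igraph::as_adjacency_matrix(network, type = "both"))
  X <- .pairwise_hyp_dist(r, th)
  P <- connection_probability(X, R, temp, clip = TRUE)
  iu <- upper.tri(A)
  sum(A[iu] * log(P[iu]) + (1 - A[iu]) * log1p(-P[iu]))
}
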