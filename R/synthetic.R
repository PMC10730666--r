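#' @title Synthetic data with planted ground truth
#' @name synthetic
#' @description Generators that emulate the statistical structure the
#'   analysis assumes: popularity-similarity networks with known polar
#'   coordinates, gene-set collections with planted angular-block
#'   enrichments, transcript sets with planted PWM motifs, and differential
#'   enrichment tables with a planted enriched-gene fraction. All generators
#'   are pure functions of their parameters and seed.
NULL

# run code under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a popularity-similarity (PS) model network
#'
#' Grows a network of `N` nodes in the hyperbolic plane. Node `t` is born at
#' angle \eqn{\theta_t \sim U[0, 2\pi)} and radius \eqn{r_t = 2\ln t}; every
#' earlier node `s` fades outward to \eqn{r_s(t) = \beta r_s + (1-\beta)r_t}
#' with \eqn{\beta = 1/(\gamma - 1)}. A new node with at least `m`
#' predecessors connects to `m` of them: at `temp = 0` the `m` hyperbolically
#' nearest; at `temp > 0`, `m` draws without replacement weighted by the
#' Fermi-Dirac probability at the growing connection radius `R_t` (so the
#' edge budget is deterministic). Nodes with fewer than `m` predecessors
#' connect to all of them, making the first `m + 1` nodes a clique and the
#' network connected by construction.
#'
#' @param N number of nodes, `> m`.
#' @param m links per new node, `>= 1`.
#' @param gamma target degree exponent, `>= 2`.
#' @param temp temperature in `[0, 1)`.
#' @param seed RNG seed (required; generation is a pure function of it).
#' @return a list with `network` (an `igraph`, vertices named `g1..gN`) and
#'   `ground_truth` (class `ps_ground_truth`): final-time coordinates
#'   (`node`, `r`, `theta`, `birth`) and the model parameters.
#' @export
generate_ps_network <- function(N, m, gamma, temp, seed) {
  stopifnot(N > m, m >= 1, gamma >= 2, temp >= 0, temp < 1)
  if (missing(seed)) stop("generate_ps_network: seed is required")
  beta <- 1 / (gamma - 1)
  .with_seed(seed, {
    theta <- stats::runif(N, 0, 2 * pi)
    from <- integer(0); to <- integer(0)
    birth_r <- 2 * log(seq_len(N)) # r_s at birth; log(1) = 0
    for (t in 2:N) {
      earlier <- seq_len(t - 1)
      if (length(earlier) <= m) {
        from <- c(from, earlier); to <- c(to, rep.int(t, length(earlier)))
        next
      }
      r_t <- 2 * log(t)
      r_now <- beta * birth_r[earlier] + (1 - beta) * r_t
      x <- hyperbolic_distance(r_now, theta[earlier], r_t, theta[t])
      if (temp == 0) {
        targets <- earlier[order(x, earlier)[seq_len(m)]]
      } else {
        R_t <- connection_radius(t, m = m, temp = temp, beta = beta)
        p <- pmax(connection_probability(x, R_t, temp), 1e-12)
        targets <- sample(earlier, m, replace = FALSE, prob = p)
      }
      from <- c(from, targets); to <- c(to, rep.int(t, m))
    }
    nodes <- paste0("g", seq_len(N))
    g <- igraph::graph_from_data_frame(
      data.frame(from = nodes[from], to = nodes[to]),
      directed = FALSE, vertices = nodes
    )
    r_final <- 2 * beta * log(seq_len(N)) + 2 * (1 - beta) * log(N)
    gt <- structure(list(
      coords = data.frame(node = nodes, r = r_final, theta = theta,
                          birth = seq_len(N), stringsAsFactors = FALSE),
      params = list(N = N, m = m, gamma = gamma, temp = temp, beta = beta,
                    seed = seed)
    ), class = "ps_ground_truth")
    list(network = g, ground_truth = gt)
  })
}

#' Estimate the power-law tail exponent of a degree sequence
#'
#' Thin wrapper over `igraph::fit_power_law()` (the Clauset-Shalizi-Newman
#' maximum-likelihood fit), used to check that PS networks reproduce the
#' requested degree exponent.
#'
#' @param degrees integer vector of node degrees.
#' @param xmin lower cut for the tail fit; estimated when `NULL`.
#' @return the fitted exponent `alpha` (scalar).
#' @export
degree_tail_exponent <- function(degrees, xmin = NULL) {
  fit <- igraph::fit_power_law(degrees, xmin = xmin)
  fit$alpha
}

#' Generate gene-set collections with planted angular enrichments
#'
#' Splits the circle into contiguous angular blocks (rotated by a seeded
#' random offset) and plants one term per block whose membership is the
#' block's nodes, optionally diluted with noise; the remaining terms are
#' uniform random subsets of the nodes. Planted assignments are recorded in
#' the `planted` attribute for recovery tests.
#'
#' @param ground_truth a `ps_ground_truth` (or any object with a `coords`
#'   data frame holding `node` and `theta`).
#' @param n_terms total number of terms, `>= 1`.
#' @param enriched_sector_fraction fraction of terms that are planted,
#'   in (0, 1].
#' @param seed RNG seed.
#' @param noise probability for each non-block node to also join a planted
#'   term (default 0: planted membership equals the block exactly).
#' @param random_set_sizes size range for the uniform terms (default 5:50).
#' @return a `gene_sets` collection; `attr(, "planted")` is a data frame
#'   with `term`, `theta_start`, `theta_end`, `size`.
#' @export
generate_sector_gene_sets <- function(ground_truth, n_terms,
                                      enriched_sector_fraction, seed,
                                      noise = 0, random_set_sizes = 5:50) {
  stopifnot(n_terms >= 1)
  if (enriched_sector_fraction <= 0 || enriched_sector_fraction > 1) {
    stop("generate_sector_gene_sets: enriched_sector_fraction must be in (0, 1]")
  }
  coords <- ground_truth$coords
  nodes <- coords$node
  theta <- norm_angle(coords$theta)
  n_planted <- max(1L, round(enriched_sector_fraction * n_terms))
  .with_seed(seed, {
    rot <- stats::runif(1, 0, 2 * pi)
    edges <- seq(0, 2 * pi, length.out = n_planted + 1)
    shifted <- norm_angle(theta - rot)
    block <- findInterval(shifted, edges, rightmost.closed = TRUE)
    out <- vector("list", n_terms)
    planted <- data.frame(term = character(0), theta_start = numeric(0),
                          theta_end = numeric(0), size = integer(0),
                          stringsAsFactors = FALSE)
    for (b in seq_len(n_planted)) {
      members <- nodes[block == b]
      if (!length(members)) {
        stop("generate_sector_gene_sets: angular block ", b,
             " is empty; use fewer planted terms or more nodes")
      }
      if (noise > 0) {
        extra <- nodes[block != b]
        members <- c(members, extra[stats::runif(length(extra)) < noise])
      }
      id <- sprintf("PLANTED_%02d", b)
      out[[b]] <- list(name = sprintf("planted angular block %d", b),
                       genes = members)
      names(out)[b] <- id
      planted <- rbind(planted, data.frame(
        term = id,
        theta_start = norm_angle(edges[b] + rot),
        theta_end = norm_angle(edges[b + 1] + rot),
        size = sum(block == b), stringsAsFactors = FALSE))
    }
    for (j in seq_len(n_terms - n_planted)) {
      sz <- sample(random_set_sizes, 1)
      out[[n_planted + j]] <- list(name = sprintf("random term %d", j),
                                   genes = sample(nodes, min(sz, length(nodes))))
      names(out)[n_planted + j] <- sprintf("RANDOM_%03d", j)
    }
    structure(out, class = "gene_sets", planted = planted)
  })
}

#' Build a near-deterministic consensus PWM from a word
#'
#' Convenience constructor for planted-motif experiments: position `j` gives
#' probability `prob` to the `j`-th base of `word` and `(1 - prob)/3` to the
#' others.
#'
#' @param word RNA word over `A, C, G, U` (DNA `T` accepted).
#' @param prob probability mass on the consensus base (default 0.97).
#' @inheritParams make_pwm
#' @return a `pwm` object.
#' @export
consensus_pwm <- function(word, prob = 0.97, background = 0.25, threshold = 6) {
  word <- chartr("T", "U", toupper(word))
  bases <- strsplit(word, "")[[1]]
  stopifnot(all(bases %in% c("A", "C", "G", "U")))
  mat <- matrix((1 - prob) / 3, nrow = length(bases), ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "U")))
  for (j in seq_along(bases)) mat[j, bases[j]] <- prob
  make_pwm(mat, background = background, threshold = threshold)
}

#' Generate sequences with planted PWM motifs
#'
#' Background bases are i.i.d. uniform over `A, C, G, U`. Each sequence is
#' planted with probability `plant_rate`; a planted sequence receives one
#' word sampled from the PWM column distributions, written at a uniformly
#' chosen offset that is recorded in the plant log.
#'
#' @param n_seqs number of sequences.
#' @param length sequence length in nt, `>= pwm$width`.
#' @param pwm a `pwm` object.
#' @param plant_rate planting probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return a list with `sequences` (named character, `seq1..seqn`) and
#'   `plants` (data frame `seq_id`, `offset` (0-based), `word`).
#' @export
generate_planted_motif_sequences <- function(n_seqs, length, pwm, plant_rate,
                                             seed) {
  stopifnot(inherits(pwm, "pwm"), length >= pwm$width,
            plant_rate >= 0, plant_rate <= 1)
  alph <- c("A", "C", "G", "U")
  .with_seed(seed, {
    seqs <- character(n_seqs)
    ids <- paste0("seq", seq_len(n_seqs))
    plant <- stats::runif(n_seqs) < plant_rate
    log_id <- character(0); log_off <- integer(0); log_word <- character(0)
    for (i in seq_len(n_seqs)) {
      chars <- sample(alph, length, replace = TRUE)
      if (plant[i]) {
        word <- vapply(seq_len(pwm$width), function(j) {
          sample(alph, 1, prob = pwm$mat[j, ])
        }, "")
        off <- sample.int(length - pwm$width + 1, 1) - 1L
        chars[(off + 1):(off + pwm$width)] <- word
        log_id <- c(log_id, ids[i])
        log_off <- c(log_off, off)
        log_word <- c(log_word, paste(word, collapse = ""))
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    names(seqs) <- ids
    list(sequences = seqs,
         plants = data.frame(seq_id = log_id, offset = log_off,
                             word = log_word, stringsAsFactors = FALSE))
  })
}

#' Generate a differential-enrichment table with planted signal
#'
#' Emulates the statistical shape of a differential-expression results table
#' consumed downstream: per-gene `log2FC ~ Normal(0, 1)` for null genes and
#' `Normal(effect_size, 1)` for a planted fraction; two-sided p-values from
#' the standard-normal null; Benjamini-Hochberg adjusted p-values. The
#' planted labels are kept as a logical column for recovery tests.
#'
#' @param n_genes number of genes.
#' @param enriched_fraction planted fraction in `[0, 1]`.
#' @param effect_size mean shift of planted genes, `> 0`.
#' @param seed RNG seed.
#' @param genes optional gene names (default `g1..gn`), e.g. network node
#'   names so the table can seed a subnetwork.
#' @return data frame with columns `gene`, `log2FC`, `p`, `adj_p`, `planted`.
#' @export
generate_de_table <- function(n_genes, enriched_fraction, effect_size, seed,
                              genes = NULL) {
  stopifnot(enriched_fraction >= 0, enriched_fraction <= 1, effect_size > 0)
  if (is.null(genes)) genes <- paste0("g", seq_len(n_genes))
  stopifnot(length(genes) == n_genes)
  .with_seed(seed, {
    n_plant <- round(enriched_fraction * n_genes)
    planted <- rep(FALSE, n_genes)
    if (n_plant > 0) planted[sample.int(n_genes, n_plant)] <- TRUE
    lfc <- stats::rnorm(n_genes, mean = ifelse(planted, effect_size, 0), sd = 1)
    p <- 2 * stats::pnorm(-abs(lfc))
    data.frame(gene = genes, log2FC = lfc, p = p,
               adj_p = stats::p.adjust(p, method = "BH"),
               planted = planted, stringsAsFactors = FALSE)
  })
}
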