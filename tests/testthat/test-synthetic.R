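test_that("PS growth initializes as a clique and keeps the m-link budget", {
  # N = m + 1 gives the complete graph
  ps <- generate_ps_network(4, 3, 2.5, 0.3, seed = 1)
  expect_equal(igraph::ecount(ps$network), choose(4, 2))
  # deterministic edge budget: m(N - m) + C(m+1, 2) edges in total
  for (temp in c(0, 0.4)) {
    ps <- generate_ps_network(50, 3, 2.5, temp, seed = 2)
    expect_equal(igraph::ecount(ps$network),
                 3 * (50 - 3) + choose(3, 2))
    expect_true(igraph::is_connected(ps$network))
  }
})

test_that("zero-temperature attachment picks the hyperbolically nearest nodes", {
  m <- 2; N <- 9
  ps <- generate_ps_network(N, m, 2.5, 0, seed = 6)
  gt <- ps$ground_truth
  beta <- gt$params$beta
  theta <- gt$coords$theta # birth angles are never moved
  A <- as.matrix(igraph::as_adjacency_matrix(ps$network))
  nodes <- igraph::V(ps$network)$name
  A <- A[order(match(nodes, gt$coords$node)),
         order(match(nodes, gt$coords$node))]
  # replay the growth: at each birth, the new node must link the m nearest
  for (t in (m + 2):N) {
    r_t <- 2 * log(t)
    earlier <- seq_len(t - 1)
    r_now <- beta * 2 * log(earlier) + (1 - beta) * r_t
    x <- hyperbolic_distance(r_now, theta[earlier], r_t, theta[t])
    nearest <- earlier[order(x, earlier)[seq_len(m)]]
    linked <- which(A[t, seq_len(t - 1)] == 1)
    expect_setequal(linked, nearest)
  }
})

test_that("PS generator is a pure function of its parameters and seed", {
  a <- generate_ps_network(80, 3, 2.7, 0.5, seed = 9)
  b <- generate_ps_network(80, 3, 2.7, 0.5, seed = 9)
  expect_identical(igraph::as_data_frame(a$network),
                   igraph::as_data_frame(b$network))
  expect_identical(a$ground_truth$coords, b$ground_truth$coords)
  expect_error(generate_ps_network(10, 12, 2.5, 0.3, seed = 1))
  expect_error(generate_ps_network(10, 2, 1.5, 0.3, seed = 1))
})

test_that("planted gene sets align with their angular blocks", {
  ps <- generate_ps_network(300, 3, 2.5, 0.2, seed = 3)
  gs <- generate_sector_gene_sets(ps$ground_truth, n_terms = 12,
                                  enriched_sector_fraction = 0.25, seed = 4)
  planted <- attr(gs, "planted")
  expect_equal(nrow(planted), 3)
  theta <- setNames(ps$ground_truth$coords$theta, ps$ground_truth$coords$node)
  in_arc <- function(th, a, b) {
    if (a <= b) th >= a & th < b else th >= a | th < b
  }
  for (i in seq_len(nrow(planted))) {
    members <- gs[[planted$term[i]]]$genes
    expect_true(all(in_arc(theta[members], planted$theta_start[i],
                           planted$theta_end[i])))
    expect_equal(length(members), planted$size[i]) # noise 0: exact block
  }
  # same seed, same collection
  gs2 <- generate_sector_gene_sets(ps$ground_truth, n_terms = 12,
                                   enriched_sector_fraction = 0.25, seed = 4)
  expect_identical(unclass(gs), unclass(gs2))
  expect_error(generate_sector_gene_sets(ps$ground_truth, 12, 0, seed = 1),
               "fraction")
})

test_that("planted terms dominate uniform terms in their own block", {
  ps <- generate_ps_network(400, 3, 2.5, 0.2, seed = 13)
  gs <- generate_sector_gene_sets(ps$ground_truth, n_terms = 20,
                                  enriched_sector_fraction = 0.2, seed = 14)
  planted <- attr(gs, "planted")
  # sectors = the ground-truth blocks themselves
  theta <- ps$ground_truth$coords$theta
  part <- data.frame(node = ps$ground_truth$coords$node, sector_id = NA_integer_)
  for (i in seq_len(nrow(planted))) {
    memb <- gs[[planted$term[i]]]$genes
    part$sector_id[part$node %in% memb] <- i
  }
  enr <- enrich_sectors(part, gs, universe = part$node)
  uniform_terms <- grep("^RANDOM", names(gs), value = TRUE)
  for (i in seq_len(nrow(planted))) {
    e <- enr[enr$sector_id == i, ]
    expect_equal(e$term[which.min(e$p)], planted$term[i])
    med_uniform <- median(e$p[e$term %in% uniform_terms])
    expect_lt(e$p[e$term == planted$term[i]], med_uniform)
  }
})

test_that("motif planting logs offsets and is deterministic", {
  pwm <- consensus_pwm("UGUAAUCC")
  none <- generate_planted_motif_sequences(10, 200, pwm, 0, seed = 1)
  expect_equal(nrow(none$plants), 0)
  all_in <- generate_planted_motif_sequences(20, 120, pwm, 1, seed = 2)
  expect_equal(nrow(all_in$plants), 20)
  expect_true(all(all_in$plants$offset >= 0 &
                    all_in$plants$offset <= 120 - pwm$width))
  again <- generate_planted_motif_sequences(20, 120, pwm, 1, seed = 2)
  expect_identical(all_in, again)
  expect_true(all(nchar(all_in$sequences) == 120))
})

test_that("synthetic DE tables have calibrated nulls and powered signals", {
  null_tab <- generate_de_table(5000, 0, 1, seed = 21)
  expect_lt(abs(mean(null_tab$p < 0.05) - 0.05), 0.02)
  sig <- generate_de_table(2000, 0.1, 6, seed = 22)
  sel <- filter_enriched(sig, p_max = 0.05, lfc_min = 0)
  expect_gte(mean(sig$gene[sig$planted] %in% sel), 0.95)
  expect_identical(generate_de_table(100, 0.2, 3, seed = 5),
                   generate_de_table(100, 0.2, 3, seed = 5))
  # BH adjustment is bounded and ordered with p
  expect_true(all(sig$adj_p >= sig$p - 1e-15))
  expect_true(all(sig$adj_p <= 1))
})

test_that("PS degree sequences recover the requested tail exponent", {
  ps <- generate_ps_network(2000, 3, 2.5, 0.4, seed = 1)
  alpha <- degree_tail_exponent(igraph::degree(ps$network))
  expect_lt(abs(alpha - 2.5), 0.3)
})
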