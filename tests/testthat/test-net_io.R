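test_that("interaction tables are filtered, deduplicated and self-loop cleaned", {
  path <- write_edge_table(
    a = c("A", "C", "E", "G", "I", "B"),
    b = c("B", "D", "F", "H", "I", "A"),
    score = c(0.9, 0.71, 0.70, 0.5, 0.71, 0.85))
  g <- read_interaction_table(path, score_threshold = 0.71)
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C", "D"))
  # duplicate keeps the max score
  e_ab <- igraph::E(g)[igraph::V(g)["A"] %--% igraph::V(g)["B"]]
  expect_equal(e_ab$score, 0.9)
  # threshold 0 keeps everything except the self-pair
  g0 <- read_interaction_table(path, score_threshold = 0)
  expect_equal(igraph::ecount(g0), 4)
  # self-pairs survive when not discarded
  g_self <- read_interaction_table(path, score_threshold = 0,
                                   discard_self = FALSE)
  expect_equal(igraph::ecount(g_self), 5)
})

test_that("interaction reading is idempotent in the threshold", {
  set.seed(1)
  n <- 40
  a <- paste0("P", sample(20, n, TRUE)); b <- paste0("P", sample(20, n, TRUE))
  path <- write_edge_table(a, b, round(runif(n), 3), header = TRUE)
  g1 <- read_interaction_table(path, 0.5)
  el <- igraph::as_data_frame(g1, what = "edges")
  path2 <- write_edge_table(el$from, el$to, el$score)
  g2 <- read_interaction_table(path2, 0.5)
  key <- function(g) {
    el <- igraph::as_data_frame(g, what = "edges")
    sort(paste(pmin(el$from, el$to), pmax(el$from, el$to)))
  }
  expect_identical(key(g2), key(g1))
})

test_that("malformed interaction tables fail with positional messages", {
  p <- tempfile()
  writeLines(c("A\t1\tB\t2\t0.9\t-", "broken row"), p)
  expect_error(read_interaction_table(p), "line 2")
  writeLines(c("A\t1\tB\t2\tnot_a_number\t-"), p)
  expect_error(read_interaction_table(p), "line 1")
  writeLines(character(0), p)
  expect_error(read_interaction_table(p), "empty")
  # symbol '-' falls back to the numeric identifier
  writeLines(c("-\t111\tB\t2\t0.9\t-"), p)
  expect_setequal(igraph::V(read_interaction_table(p, 0))$name,
                  c("111", "B"))
})

test_that("largest connected component extraction is correct and induced", {
  g <- toy_graph(cbind(c("a", "b", "c", "d", "x", "y"),
                       c("b", "c", "d", "e", "y", "z")))
  lcc <- extract_lcc(g)
  expect_setequal(igraph::V(lcc)$name, c("a", "b", "c", "d", "e"))
  # already-connected graph is returned whole
  expect_equal(igraph::vcount(extract_lcc(lcc)), 5)
  # size tie broken by smallest lexicographic node id
  g2 <- toy_graph(cbind(c("B", "A"), c("C", "D")))
  expect_setequal(igraph::V(extract_lcc(g2))$name, c("A", "D"))
  expect_error(extract_lcc(igraph::make_empty_graph()), "empty")
  # property: LCC output is connected and node-induced, random instances
  for (seed in 1:5) {
    gr <- random_gnp(30, 0.05, seed)
    lc <- extract_lcc(gr)
    expect_true(igraph::is_connected(lc))
    sub <- igraph::induced_subgraph(gr, igraph::V(lc)$name)
    expect_equal(igraph::ecount(lc), igraph::ecount(sub))
  }
})

test_that("GMT collections parse, deduplicate and round-trip", {
  p <- tempfile(fileext = ".gmt")
  writeLines(c("T1\tfirst term\tg1\tg2\tg3",
               "T2\tsecond term\tg2\tg2\tg4"), p)
  gs <- read_gene_sets(p)
  expect_length(gs, 2)
  expect_setequal(gs$T1$genes, c("g1", "g2", "g3"))
  expect_setequal(gs$T2$genes, c("g2", "g4")) # duplicate collapsed
  p2 <- tempfile(fileext = ".gmt")
  write_gene_sets(gs, p2)
  expect_identical(unclass(read_gene_sets(p2)), unclass(gs))
  writeLines("T1\tonly two fields", p)
  expect_error(read_gene_sets(p), "line 1")
})

test_that("FASTA reading normalizes T to U and preserves order", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "acgt", ">s2", "GGUU", ">s3", "TTTT"), p)
  seqs <- read_fasta(p)
  expect_identical(names(seqs), c("s1", "s2", "s3"))
  expect_identical(unname(seqs[1]), "ACGU")
  expect_identical(unname(seqs[3]), "UUUU")
  p2 <- tempfile(fileext = ".fa")
  write_fasta(seqs, p2)
  expect_identical(read_fasta(p2), seqs)
  writeLines(c(">empty", "", ">ok", "ACGU"), p)
  expect_error(read_fasta(p), "empty")
})

test_that("CIS-BP PWMs parse, renormalize and reject bad rows", {
  p <- tempfile(fileext = ".txt")
  writeLines(c("Pos\tA\tC\tG\tU",
               "1\t0.25\t0.25\t0.25\t0.25",
               "2\t1\t0\t0\t0",
               "3\t0.2501\t0.25\t0.25\t0.2501"), p)
  pwm <- read_pwm(p)
  expect_s3_class(pwm, "pwm")
  expect_equal(pwm$width, 3)
  expect_equal(rowSums(pwm$mat), rep(1, 3)) # renormalized within 1e-3
  expect_equal(unname(pwm$mat[2, "A"]), 1)
  # DNA-style header accepted
  writeLines(c("Pos\tA\tC\tG\tT", "1\t0.25\t0.25\t0.25\t0.25"), p)
  expect_equal(read_pwm(p)$width, 1)
  # row deviating > 1e-3 rejected
  writeLines(c("Pos\tA\tC\tG\tU", "1\t0.2\t0.2\t0.2\t0.2"), p)
  expect_error(read_pwm(p), "deviates")
  # width out of range rejected
  writeLines(c("Pos\tA\tC\tG\tU",
               sprintf("%d\t0.25\t0.25\t0.25\t0.25", 1:31)), p)
  expect_error(read_pwm(p), "width")
  # round trip
  pwm2 <- consensus_pwm("ACGU", prob = 0.9)
  p3 <- tempfile()
  write_pwm(pwm2, p3)
  expect_equal(read_pwm(p3)$mat, pwm2$mat, tolerance = 1e-10)
})

test_that("coordinate, sector and enrichment tables round-trip precisely", {
  set.seed(5)
  coords <- data.frame(node = paste0("n", 1:50),
                       r = runif(50, 0, 25),
                       theta = runif(50, 0, 2 * pi))
  p <- tempfile()
  write_coordinates(coords, p)
  back <- read_coordinates(p)
  expect_identical(back$node, coords$node)
  expect_lt(max(abs(back$r - coords$r)), 1e-12)
  expect_lt(max(abs(back$theta - coords$theta)), 1e-12)

  part <- angular_gap_clusters(coords, g = 0.5, min_size = 1)
  write_sectors(part, p)
  sec <- read_sectors(p)
  expect_equal(nrow(sec), 50)
  expect_identical(sort(sec$node), sort(coords$node))

  # empty payload gives a header-only file
  write_sectors(data.frame(node = character(0), sector_id = integer(0),
                           theta = numeric(0)), p)
  expect_equal(nrow(read_sectors(p)), 0)
  expect_identical(readLines(p), "node\tsector_id\ttheta")

  enr <- data.frame(sector_id = 1L, term = "T1", k = 3L, K = 10L, n = 5L,
                    N = 100L, p = 1.234567890123e-7, q = 2.4e-7)
  write_enrichment(enr, p)
  back <- read_enrichment(p)
  expect_lt(abs(back$p - enr$p), 1e-12)
  expect_lt(abs(back$q - enr$q), 1e-12)
})
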