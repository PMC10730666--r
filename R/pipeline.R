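#' Read a differential-enrichment results table
#'
#' Accepts CSV or TSV (by extension) with a header containing at least
#' `gene`, `log2FC`, `p`; `adj_p` is required only when adjusted filtering
#' is requested downstream.
#'
#' @param path path to the table.
#' @return data frame.
#' @export
read_de_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("gene", "log2FC", "p")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_de_table: missing column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' Parse a flat key = value pipeline configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments are
#' ignored. Values that parse as numbers become numeric; `true`/`false`
#' become logical. Keys are merged over the pipeline defaults (see
#' [run_pipeline()]).
#'
#' @param path path to the configuration file.
#' @return a named list.
#' @export
parse_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("parse_config: line without '=': ", ln)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <-
      if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  out
}

.pipeline_defaults <- function() {
  list(score_threshold = 0.71, gamma = 2.97, temp = 0.83, w = 2 * pi,
       g = NA_real_, min_size = 5, p_max = 0.05, use_adjusted = TRUE,
       alpha = 0.05, n_candidates = 100, n_sweeps = 1, subnet_mode = "incident",
       sector_policy = "merge", seed = 1)
}

.stage <- function(name, expr, log) {
  log(sprintf("[%s] starting", name))
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full sector-enrichment analysis pipeline
#'
#' Executes, from a single configuration, the chain: read and filter the
#' interaction table, extract the LCC, embed it with LaBNE+HM (or reuse a
#' cached coordinates file, since embedding is the slow stage), select
#' enriched genes from the differential table, build the seed-neighbourhood
#' subnetwork, restrict the full-network coordinates to it, partition it
#' into angular sectors (at a fixed gap `g` or by tuning for `min_size`),
#' and run per-sector over-representation against a GMT collection with the
#' full network as universe. All outputs are written to `out_dir` together
#' with a JSON manifest recording parameters, per-stage row counts and MD5
#' checksums.
#'
#' Configuration keys (file paths): `edges`, `de_table`, `gene_sets`,
#' optional `coordinates` (cache), `out_dir`. Parameters (with defaults):
#' `score_threshold = 0.71`, `gamma = 2.97`, `temp = 0.83`, `w = 2*pi`,
#' `g` (NA = tune), `min_size = 5`, `p_max = 0.05`, `use_adjusted = TRUE`,
#' `alpha = 0.05`, `n_candidates = 100`, `n_sweeps = 1`,
#' `subnet_mode = "incident"`, `sector_policy = "merge"` (undersized sectors
#' are absorbed across their smaller boundary gap; set `"keep"` to retain
#' them), `seed = 1`.
#'
#' @param config a named list or the path of a flat `key = value` file
#'   (see [parse_config()]).
#' @param quiet suppress progress logging (default `FALSE`).
#' @return the manifest, invisibly, as a named list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- parse_config(config)
  }
  cfg <- utils::modifyList(.pipeline_defaults(), config)
  for (key in c("edges", "de_table", "gene_sets", "out_dir")) {
    if (is.null(cfg[[key]])) stop("run_pipeline: config key '", key,
                                  "' is required")
  }
  for (key in c("edges", "de_table", "gene_sets")) {
    if (!file.exists(cfg[[key]])) {
      stop("run_pipeline: input file for '", key, "' not found: ", cfg[[key]])
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- if (quiet) function(msg) invisible(NULL) else
    function(msg) message("run_pipeline: ", msg)

  net <- .stage("network", {
    g <- read_interaction_table(cfg$edges,
                                score_threshold = cfg$score_threshold)
    extract_lcc(g)
  }, log)
  log(sprintf("network: %d nodes, %d edges", igraph::vcount(net),
              igraph::ecount(net)))

  coords <- .stage("embedding", {
    if (!is.null(cfg$coordinates) && is.character(cfg$coordinates) &&
        file.exists(cfg$coordinates)) {
      log(paste("reusing cached coordinates:", cfg$coordinates))
      cc <- read_coordinates(cfg$coordinates)
      if (!setequal(cc$node, igraph::V(net)$name)) {
        stop("cached coordinates do not cover the network's node set")
      }
      cc
    } else {
      emb <- embed_labne_hm(net, gamma = cfg$gamma, temp = cfg$temp,
                            w = cfg$w, n_candidates = cfg$n_candidates,
                            n_sweeps = cfg$n_sweeps)
      emb$coords
    }
  }, log)
  coords_path <- file.path(cfg$out_dir, "coordinates.tsv")
  write_coordinates(coords, coords_path)

  seeds <- .stage("de_filter", {
    de <- read_de_table(cfg$de_table)
    filter_enriched(de, p_max = cfg$p_max, lfc_min = 0,
                    use_adjusted = isTRUE(cfg$use_adjusted))
  }, log)
  log(sprintf("de_filter: %d enriched genes", length(seeds)))

  subnet <- .stage("subnetwork", {
    seed_neighborhood(net, seeds, mode = cfg$subnet_mode)
  }, log)
  log(sprintf("subnetwork: %d nodes, %d edges", igraph::vcount(subnet),
              igraph::ecount(subnet)))
  subnet_path <- file.path(cfg$out_dir, "subnetwork.tsv")
  .write_tsv(igraph::as_data_frame(subnet, what = "edges"), subnet_path)

  partition <- .stage("sectors", {
    sub_coords <- restrict_coordinates(coords, subnet)
    g_used <- cfg$g
    if (is.null(g_used) || is.na(g_used) || identical(g_used, "tune")) {
      g_used <- tune_gap_threshold(sub_coords, min_size = cfg$min_size,
                                   policy = cfg$sector_policy)
      log(sprintf("sectors: tuned gap threshold g = %.6f", g_used))
    }
    suppressWarnings(
      angular_gap_clusters(sub_coords, g = g_used, min_size = cfg$min_size,
                           policy = cfg$sector_policy)
    )
  }, log)
  log(sprintf("sectors: %d sectors", nrow(partition$sectors)))
  sectors_path <- file.path(cfg$out_dir, "sectors.tsv")
  write_sectors(partition, sectors_path)

  enr <- .stage("enrichment", {
    gs <- read_gene_sets(cfg$gene_sets)
    enrich_sectors(partition, gs, universe = igraph::V(net)$name,
                   alpha = cfg$alpha)
  }, log)
  enrichment_path <- file.path(cfg$out_dir, "enrichment.tsv")
  write_enrichment(enr, enrichment_path)

  files <- c(coordinates = coords_path, subnetwork = subnet_path,
             sectors = sectors_path, enrichment = enrichment_path)
  manifest <- list(
    parameters = cfg[setdiff(names(cfg), "out_dir")],
    stages = list(
      network = list(nodes = igraph::vcount(net),
                     edges = igraph::ecount(net)),
      embedding = list(rows = nrow(coords)),
      de_filter = list(enriched_genes = length(seeds)),
      subnetwork = list(nodes = igraph::vcount(subnet),
                        edges = igraph::ecount(subnet)),
      sectors = list(count = nrow(partition$sectors),
                     g = partition$g),
      enrichment = list(rows = nrow(enr))
    ),
    checksums = as.list(unname(tools::md5sum(files))) |>
      stats::setNames(names(files))
  )
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log(paste("manifest written to", manifest_path))
  invisible(manifest)
}

#' Write a complete synthetic input bundle
#'
#' Generates, under one directory, every input the pipeline consumes, all
#' with known ground truth: a PS-model network written in the 6-column
#' interaction-table dialect (constant high confidence score), its
#' ground-truth coordinates, a gene-set collection with planted
#' angular-block terms (GMT), a differential table with planted enriched
#' genes drawn from the network's nodes (CSV), transcript sequences with
#' planted motifs (FASTA), and a JSON sidecar recording all planted truth.
#'
#' Defaults reflect a desk-scale but structurally realistic study: a
#' 500-node, `m = 4` PS network with degree exponent 2.5 at low temperature
#' 0.1 (clustered, embeddable), 30 gene sets of which a fifth are planted
#' blocks, a 10% planted DE fraction at effect size 6, and 50 motif-planted
#' transcripts of 500 nt.
#'
#' @param dir output directory (created if needed).
#' @param seed master RNG seed; sub-generators derive fixed offsets from it.
#' @param N,m,gamma,temp PS network parameters.
#' @param n_terms,enriched_sector_fraction gene-set collection parameters.
#' @param de_fraction,effect_size differential-table parameters.
#' @param n_seqs,seq_length,motif_word,plant_rate motif-sequence parameters.
#' @return invisibly, a list with `files` (named generated file paths) and
#'   `data` (the in-memory ground truth: `network`, `ground_truth`,
#'   `gene_sets`, `de_table`, `plants`, `pwm`).
#' @export
synthetic_bundle <- function(dir, seed, N = 500, m = 4, gamma = 2.5,
                             temp = 0.1, n_terms = 30,
                             enriched_sector_fraction = 0.2,
                             de_fraction = 0.1, effect_size = 6,
                             n_seqs = 50, seq_length = 500,
                             motif_word = "UGUAAUCC", plant_rate = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps <- generate_ps_network(N, m, gamma, temp, seed = seed)
  gs <- generate_sector_gene_sets(ps$ground_truth, n_terms = n_terms,
                                  enriched_sector_fraction =
                                    enriched_sector_fraction,
                                  seed = seed + 1)
  de <- generate_de_table(N, enriched_fraction = de_fraction,
                          effect_size = effect_size, seed = seed + 2,
                          genes = ps$ground_truth$coords$node)
  pwm <- consensus_pwm(motif_word)
  mot <- generate_planted_motif_sequences(n_seqs, seq_length, pwm,
                                          plant_rate, seed = seed + 3)
  paths <- list(
    edges = file.path(dir, "edges.tsv"),
    coordinates = file.path(dir, "coordinates_truth.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    de_table = file.path(dir, "de_table.csv"),
    fasta = file.path(dir, "transcripts.fasta"),
    pwm = file.path(dir, "motif.pwm"),
    truth = file.path(dir, "ground_truth.json")
  )
  el <- igraph::as_data_frame(ps$network, what = "edges")
  edge_tab <- data.frame(sym_a = el$from, id_a = match(el$from,
                           ps$ground_truth$coords$node),
                         sym_b = el$to, id_b = match(el$to,
                           ps$ground_truth$coords$node),
                         score = 0.99, evidence = "synthetic")
  utils::write.table(edge_tab, paths$edges, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_coordinates(ps$ground_truth$coords[c("node", "r", "theta")],
                    paths$coordinates)
  write_gene_sets(gs, paths$gene_sets)
  utils::write.csv(de, paths$de_table, row.names = FALSE, quote = FALSE)
  write_fasta(mot$sequences, paths$fasta)
  write_pwm(pwm, paths$pwm)
  jsonlite::write_json(list(
    ps_params = ps$ground_truth$params,
    planted_terms = attr(gs, "planted"),
    planted_genes = de$gene[de$planted],
    motif_plants = mot$plants,
    motif_word = motif_word
  ), paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(files = paths,
                 data = list(network = ps$network,
                             ground_truth = ps$ground_truth,
                             gene_sets = gs, de_table = de,
                             plants = mot$plants, pwm = pwm)))
}
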