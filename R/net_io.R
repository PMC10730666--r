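#' @importFrom utils read.delim write.table head
NULL

# ---------------------------------------------------------------------------
# Interaction edge tables (curated-database raw dialect)
# ---------------------------------------------------------------------------

#' Read a confidence-scored protein-interaction edge table
#'
#' Parses a tab-separated interaction table in the raw-download dialect of
#' curated human PIN databases: six positional columns
#' (gene symbol A, numeric id A, gene symbol B, numeric id B, confidence
#' score, evidence), with either no header or a `#`-prefixed header line.
#' Node identity is the gene symbol, falling back to the numeric identifier
#' when the symbol is `"-"` or empty.
#'
#' Processing order: duplicate unordered pairs are collapsed keeping the
#' maximum score, then interactions with `score >= score_threshold` are
#' retained, then self-interactions are dropped when `discard_self` is set.
#'
#' @param path path to the edge table.
#' @param score_threshold minimum confidence score in `[0, 1]` (default 0.71,
#'   the conventional high-confidence cut).
#' @param discard_self drop self-interactions (default `TRUE`).
#' @return an undirected, simple `igraph` with a `score` edge attribute.
#' @export
read_interaction_table <- function(path, score_threshold = 0.71,
                                   discard_self = TRUE) {
  stopifnot(score_threshold >= 0, score_threshold <= 1)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && startsWith(lines[1], "#")) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("read_interaction_table: empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 5)
  if (length(bad)) {
    stop("read_interaction_table: unparseable row at line ", bad[1],
         " (expected >= 5 tab-separated fields, got ", n_fields[bad[1]], ")")
  }
  get_col <- function(i) vapply(fields, `[[`, "", i)
  sym_a <- get_col(1); id_a <- get_col(2)
  sym_b <- get_col(3); id_b <- get_col(4)
  score <- suppressWarnings(as.numeric(get_col(5)))
  if (anyNA(score) || any(!is.finite(score))) {
    bad <- which(is.na(score) | !is.finite(score))[1]
    stop("read_interaction_table: non-numeric score at line ", bad)
  }
  pick_id <- function(sym, id) {
    out <- ifelse(sym == "-" | sym == "", id, sym)
    if (any(out == "-" | out == "")) {
      bad <- which(out == "-" | out == "")[1]
      stop("read_interaction_table: empty identifier at line ", bad)
    }
    out
  }
  a <- pick_id(sym_a, id_a)
  b <- pick_id(sym_b, id_b)
  # collapse duplicates (unordered pair) keeping the max score
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  mx <- tapply(score, key, max)
  keys <- names(mx)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  ea <- vapply(parts, `[[`, "", 1)
  eb <- vapply(parts, `[[`, "", 2)
  sc <- as.numeric(mx)
  keep <- sc >= score_threshold
  if (discard_self) keep <- keep & (ea != eb)
  ea <- ea[keep]; eb <- eb[keep]; sc <- sc[keep]
  g <- igraph::graph_from_data_frame(
    data.frame(from = ea, to = eb, score = sc, stringsAsFactors = FALSE),
    directed = FALSE
  )
  g
}

#' Extract the largest connected component
#'
#' Returns the induced subgraph on the largest connected component of a
#' network. Size ties are broken by the component containing the smallest
#' lexicographic node identifier.
#'
#' @param network an `igraph` object with named vertices.
#' @return the LCC as an `igraph`.
#' @export
extract_lcc <- function(network) {
  stopifnot(igraph::is_igraph(network))
  if (igraph::vcount(network) == 0) stop("extract_lcc: empty network")
  comp <- igraph::components(network)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    # tie-break: smallest lexicographic node id among tied components
    firsts <- vapply(best, function(ci) {
      min(igraph::V(network)$name[comp$membership == ci])
    }, "")
    best <- best[order(firsts)][1]
  } else {
    best <- best[1]
  }
  igraph::induced_subgraph(network, which(comp$membership == best))
}

# ---------------------------------------------------------------------------
# GMT gene sets
# ---------------------------------------------------------------------------

#' Read a GMT gene-set collection
#'
#' Standard GMT: one term per line, tab-separated as
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate member genes
#' within a line are collapsed.
#'
#' @param path path to a GMT file.
#' @return an object of class `gene_sets`: a named list, one element per
#'   term, each a list with `name` (description) and `genes` (character).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    stop("read_gene_sets: line ", bad[1], " has fewer than 3 fields")
  }
  ids <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(ids)) {
    stop("read_gene_sets: duplicated term id: ", ids[duplicated(ids)][1])
  }
  out <- lapply(fields, function(f) {
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("read_gene_sets: term '", f[1], "' has no members")
    list(name = f[2], genes = genes)
  })
  names(out) <- ids
  structure(out, class = "gene_sets")
}

#' Write a gene-set collection to GMT
#'
#' @param gene_sets a `gene_sets` collection (see [read_gene_sets()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(id) {
    gs <- gene_sets[[id]]
    paste(c(id, gs$name, gs$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_sets <- function(x, ...) {
  cat("gene_sets collection:", length(x), "terms;",
      "member counts", paste(range(lengths(lapply(x, `[[`, "genes"))),
                             collapse = "-"), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# FASTA transcript sequences
# ---------------------------------------------------------------------------

#' Read transcript sequences from FASTA
#'
#' Sequences are upper-cased and DNA `T` is normalized to RNA `U`; record
#' order is preserved.
#'
#' @param path path to a FASTA file.
#' @return a named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(set) == 0)) {
    bad <- names(set)[Biostrings::width(set) == 0][1]
    stop("read_fasta: record with empty sequence: ", bad)
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("T", "U", seqs)
  names(seqs) <- names(set)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Position weight matrices (CIS-BP text dialect)
# ---------------------------------------------------------------------------

#' Construct a position weight matrix object
#'
#' @param mat numeric matrix, one row per motif position, columns
#'   `A, C, G, U` (DNA column `T` is accepted and renamed). Each row must sum
#'   to 1 within `1e-6`.
#' @param background scalar background base probability (default 0.25,
#'   uniform).
#' @param threshold log-odds score cutoff in bits used by the scanner
#'   (default 6, the conventional value).
#' @return an object of class `pwm`.
#' @export
make_pwm <- function(mat, background = 0.25, threshold = 6) {
  mat <- as.matrix(mat)
  colnames(mat) <- chartr("T", "U", toupper(colnames(mat)))
  stopifnot(identical(colnames(mat), c("A", "C", "G", "U")))
  w <- nrow(mat)
  if (w < 1 || w > 30) stop("make_pwm: width must be in [1, 30], got ", w)
  sums <- rowSums(mat)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("make_pwm: row ", which(abs(sums - 1) > 1e-6)[1],
         " probabilities do not sum to 1")
  }
  structure(list(mat = mat, width = w, background = background,
                 threshold = threshold),
            class = "pwm")
}

#' Read a PWM in CIS-BP text format
#'
#' Expects a header line `Pos<TAB>A<TAB>C<TAB>G<TAB>U` (a DNA header with
#' `T` is accepted and converted), followed by one row per motif position:
#' position index plus four probabilities. Rows whose probabilities sum to 1
#' within `1e-3` are renormalized; larger deviations are an error.
#'
#' @param path path to the PWM text file.
#' @inheritParams make_pwm
#' @return a `pwm` object.
#' @export
read_pwm <- function(path, background = 0.25, threshold = 6) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("read_pwm: file has no matrix rows: ", path)
  hdr <- toupper(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  hdr <- chartr("T", "U", hdr)
  if (length(hdr) != 5 || hdr[1] != "POS" ||
      !identical(hdr[2:5], c("A", "C", "G", "U"))) {
    stop("read_pwm: malformed header line (expected 'Pos A C G U')")
  }
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 5)
  if (length(bad)) stop("read_pwm: line ", bad[1] + 1, " does not have 5 fields")
  probs <- t(vapply(rows, function(f) as.numeric(f[2:5]), numeric(4)))
  if (anyNA(probs)) stop("read_pwm: non-numeric probability entry")
  w <- nrow(probs)
  if (w < 1 || w > 30) stop("read_pwm: width must be in [1, 30], got ", w)
  sums <- rowSums(probs)
  if (any(abs(sums - 1) > 1e-3)) {
    stop("read_pwm: row ", which(abs(sums - 1) > 1e-3)[1],
         " sums to ", signif(sums[which(abs(sums - 1) > 1e-3)[1]], 4),
         " (deviates from 1 by more than 1e-3)")
  }
  probs <- probs / sums
  colnames(probs) <- c("A", "C", "G", "U")
  make_pwm(probs, background = background, threshold = threshold)
}

#' Write a PWM in CIS-BP text format
#'
#' @param pwm a `pwm` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path) {
  stopifnot(inherits(pwm, "pwm"))
  lines <- c("Pos\tA\tC\tG\tU",
             vapply(seq_len(pwm$width), function(i) {
               paste(c(i, sprintf("%.12g", pwm$mat[i, ])), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm: width", x$width, "| background", x$background,
      "| threshold", x$threshold, "bits\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Pipeline TSV outputs (coordinates, sectors, enrichment)
# ---------------------------------------------------------------------------

.write_tsv <- function(df, path) {
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write to '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Write / read node coordinate tables
#'
#' Coordinates are serialized as TSV with columns `node`, `r`, `theta`;
#' numerics use 12 decimal places so a round trip reproduces values to
#' better than 1e-12.
#'
#' @param coords data frame with columns `node`, `r`, `theta`.
#' @param path file path.
#' @return `path` invisibly (writer); a data frame (reader).
#' @export
write_coordinates <- function(coords, path) {
  stopifnot(all(c("node", "r", "theta") %in% names(coords)),
            all(is.finite(coords$r)), all(coords$r >= 0))
  out <- data.frame(node = as.character(coords$node),
                    r = sprintf("%.12f", coords$r),
                    theta = sprintf("%.12f", coords$theta),
                    stringsAsFactors = FALSE)
  .write_tsv(out, path)
}

#' @rdname write_coordinates
#' @export
read_coordinates <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "numeric", "numeric"))
  stopifnot(identical(names(df), c("node", "r", "theta")))
  df
}

#' Write / read sector assignment tables
#'
#' TSV with columns `node`, `sector_id`, `theta`.
#'
#' @param partition a `sector_partition` (see [angular_gap_clusters()]) or a
#'   data frame with columns `node`, `sector_id`, `theta`.
#' @param path file path.
#' @return `path` invisibly (writer); a data frame (reader).
#' @export
write_sectors <- function(partition, path) {
  df <- if (inherits(partition, "sector_partition")) partition$assignments
        else partition
  stopifnot(all(c("node", "sector_id", "theta") %in% names(df)))
  out <- data.frame(node = as.character(df$node),
                    sector_id = as.integer(df$sector_id),
                    theta = sprintf("%.12f", df$theta),
                    stringsAsFactors = FALSE)
  .write_tsv(out, path)
}

#' @rdname write_sectors
#' @export
read_sectors <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c("character", "integer", "numeric"))
}

#' Write / read per-sector enrichment tables
#'
#' TSV with columns `sector_id`, `term`, `k`, `K`, `n`, `N`, `p`, `q`.
#' p-values are serialized with 12 significant digits.
#'
#' @param enrichment data frame as returned by [enrich_sectors()].
#' @param path file path.
#' @return `path` invisibly (writer); a data frame (reader).
#' @export
write_enrichment <- function(enrichment, path) {
  need <- c("sector_id", "term", "k", "K", "n", "N", "p", "q")
  stopifnot(all(need %in% names(enrichment)))
  out <- enrichment[need]
  out$p <- sprintf("%.12g", out$p)
  out$q <- sprintf("%.12g", out$q)
  .write_tsv(out, path)
}

#' @rdname write_enrichment
#' @export
read_enrichment <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
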