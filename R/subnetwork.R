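#' Seed-neighbourhood subnetwork
#'
#' Builds a disease-specific PIN from seed genes: the subnetwork whose nodes
#' are the matched seeds together with their first neighbours and whose
#' edges are exactly the network edges incident to at least one matched
#' seed. Edges between two non-seed neighbours are excluded under the
#' default `"incident"` mode; `mode = "induced"` instead returns the full
#' induced subgraph on seeds plus neighbours.
#'
#' Seed identifiers absent from the network are reported with a warning; if
#' no seed matches, an error lists the unmatched identifiers.
#'
#' @param network an `igraph` with named vertices.
#' @param seeds character vector of seed gene identifiers.
#' @param mode `"incident"` (default) or `"induced"`.
#' @return an `igraph` subnetwork; attributes `seeds` (matched) and
#'   `unmatched` record the seed matching.
#' @export
seed_neighborhood <- function(network, seeds, mode = c("incident", "induced")) {
  mode <- match.arg(mode)
  stopifnot(igraph::is_igraph(network))
  seeds <- unique(as.character(seeds))
  nodes <- igraph::V(network)$name
  matched <- intersect(seeds, nodes)
  unmatched <- setdiff(seeds, nodes)
  if (!length(matched)) {
    stop("seed_neighborhood: no seed found in the network; unmatched: ",
         paste(unmatched, collapse = ", "))
  }
  if (length(unmatched)) {
    warning("seed_neighborhood: ", length(unmatched),
            " seed(s) not in the network: ",
            paste(utils::head(unmatched, 10), collapse = ", "),
            if (length(unmatched) > 10) ", ..." else "")
  }
  if (mode == "incident") {
    eids <- unique(unlist(igraph::incident_edges(
      network, igraph::V(network)[matched])))
    sub <- igraph::subgraph_from_edges(network, eids, delete.vertices = TRUE)
    # matched seeds that are isolated in the network would be dropped by the
    # edge-driven construction; add them back
    missing_seeds <- setdiff(matched, igraph::V(sub)$name)
    if (length(missing_seeds)) {
      sub <- igraph::add_vertices(sub, length(missing_seeds),
                                  name = missing_seeds)
    }
  } else {
    nb <- unique(unlist(igraph::adjacent_vertices(
      network, igraph::V(network)[matched])))
    keep <- union(match(matched, nodes), nb)
    sub <- igraph::induced_subgraph(network, keep)
  }
  igraph::graph_attr(sub, "seeds") <- matched
  igraph::graph_attr(sub, "unmatched") <- unmatched
  sub
}

#' Restrict an embedding's coordinates to a subnetwork
#'
#' Returns the coordinate table of a full-network embedding restricted to
#' the nodes of a subnetwork. Coordinates are those inferred on the full
#' network; the subnetwork is never re-embedded, so the values are
#' bit-identical to the parent embedding.
#'
#' @param embedded an `embedded_network` or a coordinates data frame
#'   (`node`, `r`, `theta`).
#' @param subnet an `igraph` whose vertices are a subset of the embedded
#'   nodes, or a character vector of node names.
#' @return a data frame `node`, `r`, `theta` (one row per subnet node, in
#'   subnet vertex order).
#' @export
restrict_coordinates <- function(embedded, subnet) {
  coords <- if (inherits(embedded, "embedded_network")) embedded$coords
            else embedded
  stopifnot(all(c("node", "r", "theta") %in% names(coords)))
  want <- if (igraph::is_igraph(subnet)) igraph::V(subnet)$name
          else as.character(subnet)
  idx <- match(want, coords$node)
  if (anyNA(idx)) {
    stop("restrict_coordinates: no coordinates for node(s): ",
         paste(utils::head(want[is.na(idx)], 10), collapse = ", "))
  }
  out <- coords[idx, c("node", "r", "theta")]
  rownames(out) <- NULL
  out
}
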