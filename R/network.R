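# SG protein-protein interaction network: construction from edge
# files, topology metrics, modularity and community detection.

#' Read a STRING-style links file
#'
#' Whitespace/tab-delimited with header columns protein1, protein2,
#' combined_score (0--1000 scale); edges at or below
#' `score_threshold` x 1000 are dropped (strict >).
#'
#' @param path links file.
#' @param score_threshold confidence cutoff on the 0--1 scale
#'   (default 0.7, i.e. combined_score > 700).
#' @return data.frame: from, to, provenance = "string".
#' @export
read_string_links <- function(path, score_threshold = 0.7) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("links file is missing column(s): ",
         paste(miss, collapse = ", "))
  keep <- tab$combined_score > score_threshold * 1000
  data.frame(from = tab$protein1[keep], to = tab$protein2[keep],
             provenance = "string", stringsAsFactors = FALSE)
}

#' Read a BioPlex-style pairwise interaction TSV
#'
#' The first two columns are taken as the interacting gene symbols.
#'
#' @param path TSV with header.
#' @return data.frame: from, to, provenance = "bioplex".
#' @export
read_bioplex <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2) stop("expected >= 2 columns in ", path)
  data.frame(from = as.character(tab[[1]]), to = as.character(tab[[2]]),
             provenance = "bioplex", stringsAsFactors = FALSE)
}

#' Build the classified-protein interaction graph
#'
#' Unions high-confidence STRING edges with BioPlex edges, restricts
#' both endpoints to the classified node set, undirects, drops
#' self-loops and merges duplicates (provenance concatenated).
#'
#' @param nodes data.frame with columns id and group (early/late/
#'   invariable).
#' @param string_links optional path to a STRING links file.
#' @param bioplex optional path to a BioPlex TSV.
#' @param edges optional pre-read edge data.frame (from, to,
#'   provenance) appended to the file-derived edges.
#' @param score_threshold STRING confidence cutoff (default 0.7).
#' @return igraph graph with vertex attribute `group` and edge
#'   attribute `provenance`; attributes `n_skipped_edges` (endpoints
#'   outside the node set) and `summary` (node/edge counts, largest
#'   connected component size).
#' @export
build_graph <- function(nodes, string_links = NULL, bioplex = NULL,
                        edges = NULL, score_threshold = 0.7) {
  if (!all(c("id", "group") %in% names(nodes)))
    stop("nodes needs columns id, group")
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  ee <- list()
  if (!is.null(string_links))
    ee <- c(ee, list(read_string_links(string_links, score_threshold)))
  if (!is.null(bioplex)) ee <- c(ee, list(read_bioplex(bioplex)))
  if (!is.null(edges)) ee <- c(ee, list(edges))
  ed <- do.call(rbind, ee)
  if (is.null(ed) || !nrow(ed))
    ed <- data.frame(from = character(), to = character(),
                     provenance = character())
  mapped <- ed$from %in% nodes$id & ed$to %in% nodes$id
  n_skipped <- sum(!mapped)
  ed <- ed[mapped & ed$from != ed$to, , drop = FALSE]
  # canonical order then merge duplicates, concatenating provenance
  a <- pmin(ed$from, ed$to); b <- pmax(ed$from, ed$to)
  key <- paste(a, b, sep = "\r")
  prov <- vapply(split(ed$provenance, key), function(p)
    paste(sort(unique(p)), collapse = "+"), "")
  uk <- names(prov)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  ed2 <- data.frame(from = vapply(parts, `[`, "", 1),
                    to = vapply(parts, `[`, "", 2),
                    provenance = unname(prov),
                    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed2, directed = FALSE,
                                     vertices = nodes)
  comp <- igraph::components(g)
  attr(g, "n_skipped_edges") <- n_skipped
  attr(g, "summary") <- list(
    n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
    largest_component = max(comp$csize))
  g
}

#' Topology metrics of a graph or induced subgraph
#'
#' Degree per node, density 2E/(N(N-1)), and the average shortest
#' path length -- over connected node pairs (default report) and,
#' additionally, within the largest connected component.
#'
#' @param g igraph graph.
#' @param subset optional node-name vector; metrics are computed on
#'   the induced subgraph.
#' @return list: degree (named), n_nodes, n_edges, density,
#'   avg_shortest_path (connected pairs), avg_shortest_path_lcc.
#' @export
network_metrics <- function(g, subset = NULL) {
  if (!is.null(subset))
    g <- igraph::induced_subgraph(g, subset)
  n <- igraph::vcount(g)
  if (n < 2) stop("need >= 2 nodes for density and path metrics")
  lcc <- igraph::induced_subgraph(
    g, which(igraph::components(g)$membership ==
               which.max(igraph::components(g)$csize)))
  list(
    degree = igraph::degree(g),
    n_nodes = n,
    n_edges = igraph::ecount(g),
    density = igraph::edge_density(g),
    avg_shortest_path = igraph::mean_distance(g, unconnected = TRUE),
    avg_shortest_path_lcc = if (igraph::vcount(lcc) > 1)
      igraph::mean_distance(lcc) else NA_real_
  )
}

#' Newman-Girvan modularity of a partition
#'
#' Q = sum_c [e_c/m - (d_c/2m)^2] with m the edge count, e_c the
#' intra-community edges and d_c the total degree of community c.
#'
#' @param g igraph graph (undirected, simple).
#' @param membership community id per node (named or in vertex order).
#' @return Q.
#' @export
modularity_q <- function(g, membership) {
  if (igraph::vcount(g) == 0) stop("empty graph")
  if (igraph::ecount(g) == 0) stop("graph has no edges")
  if (!is.null(names(membership)))
    membership <- membership[igraph::V(g)$name]
  if (length(membership) != igraph::vcount(g) || anyNA(membership))
    stop("membership must cover every node")
  igraph::modularity(g, as.integer(factor(membership)))
}

#' Greedy modularity-maximizing communities
#'
#' Agglomerative (fast-greedy) modularity optimization; deterministic
#' given the graph, the seed argument fixes any residual tie-breaking
#' randomness.
#'
#' @param g igraph graph.
#' @param seed integer seed.
#' @return list: membership (named), Q. An edgeless graph yields
#'   singleton communities with Q = 0 by convention.
#' @export
greedy_communities <- function(g, seed = 1) {
  if (igraph::vcount(g) == 0) stop("empty graph")
  if (igraph::ecount(g) == 0) {
    memb <- seq_len(igraph::vcount(g))
    names(memb) <- igraph::V(g)$name
    return(list(membership = memb, Q = 0))
  }
  set.seed(seed)
  cl <- igraph::cluster_fast_greedy(igraph::simplify(g))
  memb <- igraph::membership(cl)
  list(membership = memb, Q = modularity_q(g, as.integer(memb)))
}

#' Write a graph as an edge-list TSV (with provenance)
#' @param g igraph graph from [build_graph()].
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_edge_list <- function(g, path) {
  ed <- igraph::as_data_frame(g, what = "edges")
  write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
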