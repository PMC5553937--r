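#' Levenshtein edit distance
#'
#' Full dynamic-programming Levenshtein distance with unit costs for
#' substitution, insertion and deletion. This is the slow exact oracle
#' against which the fast distance-1 predicate and the network builder are
#' verified.
#'
#' @param a,b character vectors (recycled to common length).
#' @return integer vector of distances.
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  lev_dist_cpp(rep_len(as.character(a), n), rep_len(as.character(b), n))
}

#' Are two sequences at Levenshtein distance exactly 1?
#'
#' O(L) predicate: sequences of equal length must differ at exactly one
#' position; lengths differing by one must align as a single insertion;
#' any larger length difference is distance > 1. Agrees with
#' [levenshtein()] `== 1` on all inputs.
#'
#' @param a,b character vectors of non-empty amino-acid sequences
#'   (recycled to common length).
#' @return logical vector.
#' @export
within_distance_one <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  if (any(!nzchar(a)) || any(!nzchar(b)))
    stop("empty sequences are not allowed")
  is_dist1_cpp(a, b)
}

#' Build a CDR3 similarity network
#'
#' Constructs the undirected graph whose nodes are unique CDR3 amino-acid
#' sequences and whose edges join exactly the pairs at Levenshtein distance
#' 1 (one substitution, insertion or deletion). Candidate pairs are found
#' with a deletion-variant index — every sequence is bucketed under itself
#' and under each of its single-character deletions, so any pair at
#' distance <= 1 shares a bucket — and then verified with the exact
#' predicate, giving O(n L) candidate generation instead of O(n^2) pairs.
#'
#' @param x character vector of unique sequences, or a `tcr_repertoire`
#'   (nodes are its clonotypes; abundance and dominant V/J are attached).
#' @param provenance free-text description of the selection that produced
#'   the node set.
#' @return An object of class `tcr_network`: list with `nodes` (data.table
#'   `cdr3_aa`, `abundance`, `dominant_v`, `dominant_j`), `edges`
#'   (data.table `from`, `to`, lexicographically ordered within and across
#'   pairs), `graph` (igraph), `v_usage`/`j_usage` tallies when built from
#'   a repertoire, and `provenance`.
#' @export
build_network <- function(x, provenance = "") {
  v_usage <- j_usage <- NULL
  if (inherits(x, "tcr_repertoire")) {
    nodes <- data.table(cdr3_aa = x$clonotypes$cdr3_aa,
                        abundance = x$clonotypes$total_count)
    v_usage <- x$v_usage; j_usage <- x$j_usage
    if (!nzchar(provenance))
      provenance <- sprintf("repertoire %s (%d clonotypes)",
                            x$individual_id, nrow(nodes))
  } else {
    x <- as.character(x)
    nodes <- data.table(cdr3_aa = x, abundance = NA_real_)
  }
  if (anyDuplicated(nodes$cdr3_aa))
    stop("input sequences must be unique")
  if (nrow(nodes) && any(!nzchar(nodes$cdr3_aa)))
    stop("empty sequences are not allowed")

  edges <- .dist1_edges(nodes$cdr3_aa)
  dom <- function(us) {
    if (is.null(us) || !nrow(us)) return(rep(NA_character_, nrow(nodes)))
    d <- us[order(cdr3_aa, -count, gene), .(g = gene[1]), by = cdr3_aa]
    d$g[match(nodes$cdr3_aa, d$cdr3_aa)]
  }
  nodes[, dominant_v := dom(v_usage)]
  nodes[, dominant_j := dom(j_usage)]

  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes$cdr3_aa))
  net <- structure(list(nodes = nodes, edges = edges, graph = g,
                        v_usage = v_usage, j_usage = j_usage,
                        provenance = provenance),
                   class = "tcr_network")
  net$nodes[, cluster_id := cluster_membership(net)[cdr3_aa]]
  net
}

# Deletion-variant bucketing: emit candidate pairs sharing a bucket, then
# keep exactly those the O(L) predicate confirms at distance 1.
.dist1_edges <- function(seqs) {
  empty <- data.table(from = character(), to = character())
  if (length(seqs) < 2) return(empty)
  keys <- as.data.table(deletion_keys_cpp(seqs))
  pairs <- keys[keys, on = "key", allow.cartesian = TRUE][id < i.id,
                .(i = id, j = i.id)]
  if (!nrow(pairs)) return(empty)
  pairs <- unique(pairs)
  ok <- is_dist1_cpp(seqs[pairs$i], seqs[pairs$j])
  pairs <- pairs[ok]
  if (!nrow(pairs)) return(empty)
  a <- seqs[pairs$i]; b <- seqs[pairs$j]
  swap <- a > b
  edges <- data.table(from = ifelse(swap, b, a), to = ifelse(swap, a, b))
  setorder(edges, from, to)
  edges
}

#' @export
print.tcr_network <- function(x, ...) {
  cat(sprintf("<tcr_network> %d nodes, %d edges, %d clustered nodes in %d clusters\n",
              nrow(x$nodes), nrow(x$edges), clustered_node_count(x),
              nrow(network_clusters(x))))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Cluster membership of network nodes
#'
#' A cluster is a connected component with two or more nodes. Isolated
#' nodes remain in the network but belong to no cluster.
#'
#' @param net a `tcr_network`.
#' @return named integer vector over all nodes; `NA` for isolated nodes.
#'   Cluster ids are 1..k in decreasing size order (ties by smallest
#'   member sequence) so ids are deterministic.
#' @export
cluster_membership <- function(net) {
  comp <- igraph::components(net$graph)
  memb <- comp$membership
  keep <- comp$csize[memb] >= 2
  first_member <- vapply(split(names(memb), memb),
                         function(s) min(s), "")
  ord <- order(-comp$csize, first_member)
  rank <- match(seq_along(comp$csize), ord)
  out <- ifelse(keep, rank[memb], NA_integer_)
  names(out) <- names(memb)
  out[net$nodes$cdr3_aa]
}

#' Summary of network clusters
#'
#' @param net a `tcr_network`.
#' @return data.table with one row per cluster: `cluster_id`, `n_nodes`,
#'   `n_edges`.
#' @export
network_clusters <- function(net) {
  memb <- cluster_membership(net)
  if (all(is.na(memb)))
    return(data.table(cluster_id = integer(), n_nodes = integer(),
                      n_edges = integer()))
  nodes <- data.table(cdr3_aa = names(memb), cluster_id = memb)[!is.na(cluster_id)]
  e <- copy(net$edges)[, cluster_id := memb[from]]
  ecount <- e[, .(n_edges = .N), by = cluster_id]
  out <- nodes[, .(n_nodes = .N), by = cluster_id][ecount, on = "cluster_id"]
  setorder(out, cluster_id)
  out[]
}

#' Number of clustered nodes
#' @param net a `tcr_network`.
#' @return number of nodes lying in clusters (components of size >= 2).
#' @export
clustered_node_count <- function(net) sum(!is.na(cluster_membership(net)))

#' Number of edges
#' @param net a `tcr_network`.
#' @export
edge_count <- function(net) nrow(net$edges)

#' Node degree
#'
#' Number of distance-1 neighbors of each node within the network. Edges to
#' sequences outside the node selection do not exist by construction.
#'
#' @param net a `tcr_network`.
#' @return named integer vector.
#' @export
node_degree <- function(net) {
  d <- igraph::degree(net$graph)
  d[net$nodes$cdr3_aa]
}

#' Shortest-path betweenness centrality
#'
#' Sum over node pairs of the fraction of shortest paths passing through
#' each node, computed per connected component. Unnormalized by default
#' (the comparisons this supports are within equal-sized networks); set
#' `normalized = TRUE` to divide by `(n-1)(n-2)/2` for cross-size
#' comparisons.
#'
#' @param net a `tcr_network`.
#' @param normalized logical.
#' @return named numeric vector.
#' @export
node_betweenness <- function(net, normalized = FALSE) {
  b <- igraph::betweenness(net$graph, directed = FALSE,
                           normalized = normalized)
  b[net$nodes$cdr3_aa]
}

#' Dominant V or J gene of a cluster (or node set)
#'
#' Sums the V (or J) usage tallies over the member nodes and returns the
#' gene with the largest summed count together with the fraction of the
#' summed counts it explains — the cluster's gene homogeneity.
#'
#' @param net a `tcr_network` built from a repertoire (usage tallies
#'   required).
#' @param cluster_id cluster to summarize, or `NULL` with `members` given.
#' @param which `"V"` or `"J"`.
#' @param members optional explicit character vector of member nodes.
#' @return list with `gene` and `fraction`.
#' @export
cluster_dominant_gene <- function(net, cluster_id = NULL,
                                  which = c("V", "J"), members = NULL) {
  which <- match.arg(which)
  us <- if (which == "V") net$v_usage else net$j_usage
  if (is.null(us) || !nrow(us))
    stop("network carries no ", which, " usage data")
  if (is.null(members)) {
    stopifnot(!is.null(cluster_id))
    memb <- cluster_membership(net)
    members <- names(memb)[!is.na(memb) & memb == cluster_id]
    if (!length(members)) stop("no such cluster: ", cluster_id)
  }
  tot <- us[cdr3_aa %in% members, .(count = sum(count)), by = gene]
  if (!nrow(tot)) stop("no usage data for the requested members")
  setorder(tot, -count, gene)
  list(gene = tot$gene[1], fraction = tot$count[1] / sum(tot$count))
}

#' Export a network to GraphML or SIF
#'
#' GraphML exports carry node attributes and round-trip through
#' [igraph::read_graph()] with identical node and edge sets. SIF is the
#' plain-text Cytoscape format (`A pp B` per edge; isolated nodes on their
#' own line); pair it with [write_node_attributes()] for Cytoscape import.
#'
#' @param net a `tcr_network`.
#' @param path output path.
#' @param format `"graphml"` or `"sif"`.
#' @export
export_graph <- function(net, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- net$graph
    for (col in c("abundance", "dominant_v", "dominant_j", "cluster_id")) {
      v <- net$nodes[[col]][match(igraph::V(g)$name, net$nodes$cdr3_aa)]
      if (!all(is.na(v)))
        g <- igraph::set_vertex_attr(g, col, value = v)
    }
    igraph::write_graph(g, path, format = "graphml")
  } else {
    iso <- setdiff(net$nodes$cdr3_aa, c(net$edges$from, net$edges$to))
    lines <- c(sprintf("%s pp %s", net$edges$from, net$edges$to), iso)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Node attribute table
#'
#' One row per node: sequence, abundance, dominant V/J, cluster id, degree
#' and betweenness, plus any extra per-node columns supplied (e.g. sharing
#' level or category), suitable as a Cytoscape attribute CSV.
#'
#' @param net a `tcr_network`.
#' @param extra optional data.frame with a `cdr3_aa` column to join.
#' @return data.table with one row per node.
#' @export
node_attributes <- function(net, extra = NULL) {
  out <- copy(net$nodes)
  out[, degree := node_degree(net)[cdr3_aa]]
  out[, betweenness := node_betweenness(net)[cdr3_aa]]
  if (!is.null(extra)) {
    extra <- as.data.table(extra)
    stopifnot("cdr3_aa" %in% names(extra))
    out <- extra[out, on = "cdr3_aa"]
    setcolorder(out, "cdr3_aa")
  }
  out[]
}

#' Write the node attribute table as CSV
#' @param net a `tcr_network`.
#' @param path output path.
#' @param extra passed to [node_attributes()].
#' @export
write_node_attributes <- function(net, path, extra = NULL) {
  fwrite(node_attributes(net, extra), path)
  invisible(path)
}
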