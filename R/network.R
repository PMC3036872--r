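#' Minimum spanning network of haplotypes
#'
#' Builds the minimum spanning tree of the complete haplotype graph weighted
#' by substitution counts, using Kruskal's algorithm with deterministic
#' tie-breaking (weight, then lexicographic id pair). Every non-tree edge
#' whose weight equals the maximum edge weight on the tree path between its
#' endpoints is flagged as an equally-minimal alternative connection,
#' turning the tree into a minimum spanning network.
#'
#' @param hap_table a `cr_haplotypes` (used for node frequency metadata),
#'   or NULL.
#' @param diff_matrix K x K integer matrix of substitution counts between
#'   haplotypes.
#' @return data.frame of class `cr_msn`: columns `from`, `to`, `weight`,
#'   `in_mst`, `alternative`; attribute `"node_freq"` holds total haplotype
#'   frequencies when `hap_table` is given.
#' @export
minimum_spanning_network <- function(hap_table, diff_matrix) {
  K <- nrow(diff_matrix)
  if (is.null(K) || K < 1L) stop("empty difference matrix", call. = FALSE)
  if (K == 1L) {
    warning("single haplotype: empty network")
    out <- data.frame(from = integer(0), to = integer(0), weight = integer(0),
                      in_mst = logical(0), alternative = logical(0))
    class(out) <- c("cr_msn", "data.frame")
    return(out)
  }
  pairs <- which(upper.tri(diff_matrix), arr.ind = TRUE)
  edges <- data.frame(from = pairs[, 1], to = pairs[, 2],
                      weight = diff_matrix[pairs])
  edges <- edges[order(edges$weight, edges$from, edges$to), ]
  # Kruskal with union-find
  parent <- seq_len(K)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  in_mst <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    ra <- find(edges$from[e]); rb <- find(edges$to[e])
    if (ra != rb) {
      parent[ra] <- rb
      in_mst[e] <- TRUE
    }
  }
  edges$in_mst <- in_mst
  # adjacency of the tree, for path-max queries
  tree <- edges[in_mst, ]
  adj <- vector("list", K)
  for (e in seq_len(nrow(tree))) {
    a <- tree$from[e]; b <- tree$to[e]; w <- tree$weight[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  path_max <- function(a, b) {
    # BFS from a to b tracking the max edge weight along the path
    seen <- rep(FALSE, K); seen[a] <- TRUE
    front <- list(list(node = a, mx = 0))
    while (length(front)) {
      nxt <- list()
      for (f in front) {
        nbr <- adj[[f$node]]
        if (is.null(nbr)) next
        for (r in seq_len(nrow(nbr))) {
          v <- nbr[r, 1]; w <- nbr[r, 2]
          if (seen[v]) next
          mx <- max(f$mx, w)
          if (v == b) return(mx)
          seen[v] <- TRUE
          nxt[[length(nxt) + 1]] <- list(node = v, mx = mx)
        }
      }
      front <- nxt
    }
    Inf
  }
  edges$alternative <- FALSE
  nontree <- which(!edges$in_mst)
  for (e in nontree) {
    if (edges$weight[e] == path_max(edges$from[e], edges$to[e]))
      edges$alternative[e] <- TRUE
  }
  rownames(edges) <- NULL
  if (!is.null(hap_table)) {
    stopifnot(inherits(hap_table, "cr_haplotypes"),
              nrow(hap_table$counts) == K)
    attr(edges, "node_freq") <- rowSums(hap_table$counts)
    attr(edges, "node_counts") <- hap_table$counts
  }
  class(edges) <- c("cr_msn", "data.frame")
  edges
}

#' @export
print.cr_msn <- function(x, ...) {
  cat("<cr_msn> ", sum(x$in_mst), " tree edges, ",
      sum(x$alternative), " alternative edges\n", sep = "")
  print(as.data.frame(x)[x$in_mst | x$alternative, ], row.names = FALSE)
  invisible(x)
}

#' Write a haplotype network as edge-list CSV
#' @param net a `cr_msn`.
#' @param path output CSV.
#' @param all include non-network edges too.
#' @export
write_network_csv <- function(net, path, all = FALSE) {
  df <- as.data.frame(net)
  if (!all) df <- df[df$in_mst | df$alternative, ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a haplotype network in GraphML format
#'
#' Nodes carry total haplotype frequency (and per-population counts when
#' available); edges carry substitution counts and the tree/alternative
#' flags.
#'
#' @param net a `cr_msn`.
#' @param path output `.graphml` file.
#' @export
write_network_graphml <- function(net, path) {
  freq <- attr(net, "node_freq")
  counts <- attr(net, "node_counts")
  K <- max(net$from, net$to)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  w('  <key id="freq" for="node" attr.name="frequency" attr.type="int"/>')
  w('  <key id="pops" for="node" attr.name="population_counts" attr.type="string"/>')
  w('  <key id="w" for="edge" attr.name="substitutions" attr.type="int"/>')
  w('  <key id="alt" for="edge" attr.name="alternative" attr.type="boolean"/>')
  w('  <graph id="msn" edgedefault="undirected">')
  for (i in seq_len(K)) {
    w('    <node id="h%d">', i)
    if (!is.null(freq)) w('      <data key="freq">%d</data>', freq[i])
    if (!is.null(counts))
      w('      <data key="pops">%s</data>',
        paste(colnames(counts), counts[i, ], sep = ":", collapse = ";"))
    w('    </node>')
  }
  keep <- which(net$in_mst | net$alternative)
  for (e in keep) {
    w('    <edge source="h%d" target="h%d">', net$from[e], net$to[e])
    w('      <data key="w">%d</data>', net$weight[e])
    w('      <data key="alt">%s</data>',
      if (net$alternative[e]) "true" else "false")
    w('    </edge>')
  }
  w('  </graph>')
  w('</graphml>')
  invisible(path)
}
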