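#' Connected Erdos-Renyi random network
#'
#' Draws G(n, p) graphs until a connected one is obtained (the model needs
#' every agent to have at least one potential partner at initialization), up
#' to `max_tries` attempts. `p = 1` returns the complete graph.
#'
#' @param n Number of agents (>= 2).
#' @param p Edge probability in (0, 1].
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param max_tries Rejection-sampling attempt budget.
#' @return An undirected, connected `igraph` graph on `n` vertices.
#' @export
make_random_network <- function(n, p, seed = NULL, max_tries = 10000L) {
  stopifnot(n >= 2, p > 0, p <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (p == 1) return(igraph::make_full_graph(n))
  for (i in seq_len(max_tries)) {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) return(g)
  }
  stop(sprintf(
    "no connected G(n = %d, p = %g) graph found in %d attempts; increase p",
    n, p, max_tries))
}

#' Ring (cycle) network
#'
#' @param n Number of agents (>= 3).
#' @return The cycle graph on `n` vertices (every degree 2).
#' @export
make_ring <- function(n) {
  stopifnot(n >= 3)
  igraph::make_ring(n)
}

#' Connected caveman network
#'
#' Fully connected cliques arranged on a ring: in each clique one within-clique
#' edge is broken and the freed node is connected to a node of the neighbouring
#' clique (the last node of the preceding clique, so endpoints stay distinct
#' even with two cliques), keeping the total edge count at
#' `num_cliques * choose(clique_size, 2)` while the graph becomes connected.
#' With `clique_size = 2` that rewiring cannot keep the graph connected
#' (removing the only within-clique edge isolates a node), so the construction
#' degenerates to the ring on `2 * num_cliques` nodes.
#'
#' @param num_cliques Number of cliques (>= 2).
#' @param clique_size Agents per clique (>= 2).
#' @return A connected `igraph` graph on `num_cliques * clique_size` vertices.
#' @export
make_connected_caveman <- function(num_cliques, clique_size) {
  stopifnot(num_cliques >= 2, clique_size >= 2)
  n <- num_cliques * clique_size
  if (clique_size == 2L) return(igraph::make_ring(n))
  edges <- integer(0)
  for (c in seq_len(num_cliques) - 1L) {
    base <- c * clique_size
    pairs <- utils::combn(base + seq_len(clique_size), 2L)
    # break the (local 1, local 2) edge of each clique ...
    keep <- !(pairs[1L, ] == base + 1L & pairs[2L, ] == base + 2L)
    edges <- c(edges, as.integer(pairs[, keep]))
    # ... and connect the freed node to the last node of the preceding clique
    # (distinct endpoints even with only two cliques)
    prev_last <- ((c - 1L) %% num_cliques) * clique_size + clique_size
    edges <- c(edges, base + 1L, prev_last)
  }
  igraph::make_graph(edges, n = n, directed = FALSE)
}

#' Load an undirected edge list
#'
#' Reads `source,target[,weight]` rows (comma or tab separated; a header line
#' is auto-detected). Self-loops are dropped with a warning; duplicate edges
#' are collapsed (weights summed) with a warning. Vertex labels are mapped to
#' consecutive integer ids in lexicographic order; the original labels are
#' kept in the vertex attribute `label`.
#'
#' @param path Path to the edge-list file.
#' @param weighted If `TRUE`, a third column of strictly positive weights is
#'   required and stored as the edge attribute `weight`; if `FALSE`, any third
#'   column is ignored.
#' @return An undirected `igraph` graph.
#' @export
load_edge_list <- function(path, weighted = FALSE) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("edge-list file is empty: ", path)
  sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  # header detection: first row whose third field (if any) is non-numeric, or
  # whose first two fields look like column names used verbatim nowhere else
  first <- trimws(parts[[1L]])
  looks_header <- length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L])))
  if (!looks_header && length(first) >= 2L) {
    looks_header <- tolower(first[1L]) %in% c("source", "from", "node1") &&
      tolower(first[2L]) %in% c("target", "to", "node2")
  }
  if (looks_header) parts <- parts[-1L]
  if (length(parts) == 0L) stop("edge-list file has no data rows: ", path)

  src <- character(length(parts)); dst <- character(length(parts))
  w <- rep(1, length(parts))
  for (i in seq_along(parts)) {
    f <- trimws(parts[[i]])
    if (length(f) < 2L) stop("malformed edge-list row ", i, ": need source,target")
    src[i] <- f[1L]; dst[i] <- f[2L]
    if (weighted) {
      if (length(f) < 3L) stop("weighted = TRUE but row ", i, " has no weight")
      w[i] <- as.numeric(f[3L])
      if (is.na(w[i]) || w[i] <= 0) {
        stop("non-positive or non-numeric weight in row ", i, ": ", f[3L])
      }
    }
  }
  loop <- src == dst
  if (any(loop)) {
    warning(sum(loop), " self-loop row(s) dropped")
    src <- src[!loop]; dst <- dst[!loop]; w <- w[!loop]
  }
  if (length(src) == 0L) stop("edge list contains no usable edges")

  labels <- sort(unique(c(src, dst)))
  a <- match(src, labels); b <- match(dst, labels)
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate edge row(s) collapsed",
            if (weighted) " (weights summed)" else "")
    w <- as.numeric(tapply(w, key, sum)[unique(key)])
    lo <- lo[!duplicated(key)]; hi <- hi[!duplicated(key)]
  }
  g <- igraph::make_graph(rbind(lo, hi), n = length(labels), directed = FALSE)
  igraph::V(g)$label <- labels
  if (weighted) igraph::E(g)$weight <- w
  g
}

#' Summary statistics of a network
#'
#' Reports the statistics used to characterize the studied networks: node
#' count, average shortest-path length (always on the unweighted topology),
#' average clustering coefficient (mean local transitivity, isolated and
#' degree-1 nodes contributing 0), density, completeness, plain average degree
#' and — for weighted graphs — average weighted degree (mean vertex strength).
#' Average degree is reported both ways because published "connectivity"
#' columns for weighted networks are ambiguous between the two.
#'
#' @param net A connected `igraph` graph.
#' @return A list of class `network_stats` with fields `n`, `avg_path_length`,
#'   `avg_degree`, `avg_weighted_degree` (`NA` when unweighted), `clustering`,
#'   `density`, `is_complete`.
#' @export
network_stats <- function(net) {
  if (!igraph::is_connected(net)) {
    stop("network_stats requires a connected network (path length undefined)")
  }
  n <- igraph::vcount(net)
  weighted <- "weight" %in% igraph::edge_attr_names(net)
  structure(list(
    n = n,
    avg_path_length = igraph::mean_distance(net, weights = NA),
    avg_degree = mean(igraph::degree(net)),
    avg_weighted_degree = if (weighted) mean(igraph::strength(net)) else NA_real_,
    clustering = igraph::transitivity(net, type = "localaverage",
                                      isolates = "zero"),
    density = igraph::edge_density(net),
    is_complete = igraph::edge_density(net) == 1
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(
    "n = %d | path length = %.3f | avg degree = %.3f%s | clustering = %.3f | density = %.3f%s\n",
    x$n, x$avg_path_length, x$avg_degree,
    if (!is.na(x$avg_weighted_degree))
      sprintf(" (weighted %.3f)", x$avg_weighted_degree) else "",
    x$clustering, x$density,
    if (x$is_complete) " | complete" else ""))
  invisible(x)
}

#' Zachary karate club network
#'
#' The standard 34-node, 78-edge karate club graph, used as a built-in
#' real-world test network.
#'
#' @return An `igraph` graph.
#' @export
karate_club <- function() {
  igraph::make_graph("Zachary")
}

# adjacency as a plain list of integer neighbour vectors (+ weights), the
# representation the simulation engine consumes
as_adjacency <- function(net) {
  n <- igraph::vcount(net)
  weighted <- "weight" %in% igraph::edge_attr_names(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  wadj <- if (weighted) lapply(seq_len(n), function(i) numeric(0)) else NULL
  w <- if (weighted) igraph::E(net)$weight else NULL
  for (e in seq_len(nrow(el))) {
    a <- el[e, 1L]; b <- el[e, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
    if (weighted) {
      wadj[[a]] <- c(wadj[[a]], w[e])
      wadj[[b]] <- c(wadj[[b]], w[e])
    }
  }
  for (i in seq_len(n)) {
    o <- order(adj[[i]])
    adj[[i]] <- adj[[i]][o]
    if (weighted) wadj[[i]] <- wadj[[i]][o]
  }
  list(adj = adj, wadj = wadj, n = n, weighted = weighted)
}
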