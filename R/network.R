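#' Build a co-occurrence network from a thresholded correlation matrix
#'
#' Every ASV pair with |r| >= s_t becomes an undirected edge; the
#' correlation value, its absolute value (edge weight) and its sign are kept
#' as edge attributes. Isolated nodes are dropped from the graph but counted
#' in the graph attribute `n_isolated`.
#'
#' @param c_mat symmetric correlation matrix with named dimensions.
#' @param s_t correlation threshold in (0, 1\]; either a number or an
#'   `rmt_threshold` object.
#' @return an [igraph::graph] with attributes `threshold` and `n_isolated`.
#' @export
build_network <- function(c_mat, s_t) {
  if (inherits(s_t, "rmt_threshold")) s_t <- s_t$threshold
  stopifnot(is.numeric(s_t), s_t > 0, s_t <= 1)
  ids <- rownames(c_mat)
  if (is.null(ids)) ids <- paste0("node", seq_len(nrow(c_mat)))
  sel <- which(upper.tri(c_mat) & abs(c_mat) >= s_t, arr.ind = TRUE)
  edges <- data.frame(from = ids[sel[, 1L]], to = ids[sel[, 2L]],
                      r = c_mat[sel], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  if (nrow(edges)) {
    igraph::E(g)$weight <- abs(edges$r)
    igraph::E(g)$sign <- ifelse(edges$r >= 0, 1L, -1L)
  }
  iso <- igraph::degree(g) == 0
  g <- igraph::delete_vertices(g, which(iso))
  g <- igraph::set_graph_attr(g, "threshold", s_t)
  igraph::set_graph_attr(g, "n_isolated", sum(iso))
}

#' Topological characteristics of a co-occurrence network
#'
#' Computes the node count N, link count L, links per node L/N, average
#' connectivity avgK = 2L/N, modularity M of the greedy
#' modularity-maximizing partition (unweighted), connectedness Con (the
#' fraction of node pairs joined by a path; 1 iff the graph is connected),
#' and per-node degree and betweenness centrality (normalized by
#' (N-1)(N-2)/2).
#'
#' @param g an [igraph::graph] from [build_network()].
#' @return list of class `network_topology` with the scalar metrics and a
#'   `nodes` data.frame (asv_id, degree, betweenness).
#' @export
network_topology <- function(g) {
  n <- igraph::vcount(g)
  l <- igraph::ecount(g)
  if (n == 0L) stop("empty network")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = TRUE,
                             weights = NA)
  comm <- igraph::cluster_fast_greedy(g, weights = NULL)
  comp <- igraph::components(g)
  pairs_joined <- sum(choose(comp$csize, 2))
  con <- if (n > 1L) pairs_joined / choose(n, 2) else 1
  structure(list(
    n_nodes = n, n_links = l, links_per_node = l / n, avgK = 2 * l / n,
    modularity = igraph::modularity(comm),
    connectedness = con,
    n_components = comp$no,
    nodes = data.frame(asv_id = igraph::V(g)$name, degree = unname(deg),
                       betweenness = unname(btw), row.names = NULL,
                       stringsAsFactors = FALSE)),
    class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf(
    "Network: N = %d, L = %d, L/N = %.2f, avgK = %.2f, M = %.3f, Con = %.3f\n",
    x$n_nodes, x$n_links, x$links_per_node, x$avgK, x$modularity,
    x$connectedness))
  invisible(x)
}

#' Degree-preserving (Maslov-Sneppen) rewiring
#'
#' Randomizes the edges of a graph by repeated double-edge swaps that reject
#' self-loops and multi-edges, so node set, edge count and the full degree
#' sequence are exactly preserved. The swap budget counts proposal trials.
#'
#' @param g an [igraph::graph] with at least 2 edges.
#' @param n_swaps number of swap trials (default 100 x L).
#' @param seed integer seed.
#' @return the rewired graph.
#' @export
maslov_sneppen_rewire <- function(g, n_swaps = 100L * igraph::ecount(g),
                                  seed = 1L) {
  if (igraph::ecount(g) < 2L) stop("need at least 2 edges to rewire")
  set.seed(as.integer(seed))
  rg <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                 niter = n_swaps))
  stopifnot(identical(igraph::degree(rg), igraph::degree(g)),
            igraph::ecount(rg) == igraph::ecount(g),
            igraph::is_simple(rg))
  rg
}

#' Null ensemble of rewired networks
#'
#' Generates `n` Maslov-Sneppen rewirings of the empirical network, computes
#' the topology metrics of each, and reports the null mean, null standard
#' deviation and the Z-score of each empirical metric. Metrics fully
#' determined by the degree sequence (avgK, L/N) have zero null variance and
#' an undefined Z, reported as NA.
#'
#' @param g an [igraph::graph].
#' @param metrics which topology metrics to summarize.
#' @param n ensemble size.
#' @param seed integer seed (one rewiring seed is derived per replicate).
#' @return list of class `null_ensemble_summary` with a `summary`
#'   data.frame (metric, observed, null_mean, null_sd, z), `n_random`,
#'   `seed`.
#' @export
null_ensemble <- function(g, metrics = c("links_per_node", "avgK",
                                         "modularity", "connectedness"),
                          n = 100L, seed = 1L) {
  obs <- network_topology(g)
  vals <- matrix(NA_real_, n, length(metrics),
                 dimnames = list(NULL, metrics))
  for (i in seq_len(n)) {
    rg <- maslov_sneppen_rewire(g, seed = as.integer(seed) + i)
    ti <- network_topology(rg)
    vals[i, ] <- vapply(metrics, function(mm) ti[[mm]], numeric(1))
  }
  mu <- colMeans(vals)
  sdv <- apply(vals, 2L, stats::sd)
  obs_v <- vapply(metrics, function(mm) obs[[mm]], numeric(1))
  z <- ifelse(sdv > 0, (obs_v - mu) / sdv, NA_real_)
  structure(list(summary = data.frame(metric = metrics, observed = obs_v,
                                      null_mean = mu, null_sd = sdv, z = z,
                                      row.names = NULL,
                                      stringsAsFactors = FALSE),
                 n_random = n, seed = as.integer(seed)),
            class = "null_ensemble_summary")
}

#' @export
print.null_ensemble_summary <- function(x, ...) {
  cat(sprintf("Null ensemble of %d degree-preserving rewirings:\n",
              x$n_random))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Keystone species by combined degree and betweenness rank
#'
#' Nodes are ranked separately by decreasing degree and decreasing
#' betweenness centrality; the keystone score is the mean of the two ranks
#' and the top `k` nodes are returned (ties broken lexicographically by ASV
#' id). When the network has fewer than `k` nodes all are returned with
#' attribute `underpopulated = TRUE`.
#'
#' @param topo a `network_topology` from [network_topology()].
#' @param k number of keystone taxa to return.
#' @return data.frame (asv_id, degree, betweenness, score) in keystone
#'   order.
#' @export
keystone_species <- function(topo, k = 10L) {
  stopifnot(inherits(topo, "network_topology"))
  nodes <- topo$nodes
  rk_deg <- rank(-nodes$degree, ties.method = "average")
  rk_btw <- rank(-nodes$betweenness, ties.method = "average")
  nodes$score <- (rk_deg + rk_btw) / 2
  ord <- order(nodes$score, nodes$asv_id)
  nodes <- nodes[ord, , drop = FALSE]
  rownames(nodes) <- NULL
  if (nrow(nodes) < k) {
    attr(nodes, "underpopulated") <- TRUE
    nodes
  } else {
    utils::head(nodes, k)
  }
}

#' Write a network as an edge-list TSV
#'
#' Columns: source, target, r, sign.
#'
#' @param g an [igraph::graph] from [build_network()].
#' @param path output file.
#' @export
write_network_edgelist <- function(g, path) {
  el <- igraph::as_data_frame(g, what = "edges")
  names(el)[1:2] <- c("source", "target")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network as GraphML
#'
#' @inheritParams write_network_edgelist
#' @export
write_network_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
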