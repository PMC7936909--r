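# Compound-target network assembly, topology and key-node screening.

#' Assemble per-compound target sets from known and predicted edges
#'
#' Per compound, the merged set is the union of its known targets and its
#' `k` highest-scoring predicted targets. Ties at rank `k` are broken
#' deterministically by sorting on (score descending, symbol ascending) and
#' keeping the first `k`.
#'
#' @param known edge table (`source` = compound, `target` = gene) of known
#'   interactions.
#' @param predicted edge table with numeric `weight` scores.
#' @param k predicted targets retained per compound (default 15).
#' @return list of class `target_assembly` with named lists `known`,
#'   `predicted` (data.frames sorted by score) and `merged` (character
#'   vectors, deduplicated).
#' @export
assemble_targets <- function(known, predicted, k = 15) {
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  known$kind <- rep("compound_target", nrow(known))
  known <- canonicalize_edges(known)
  predicted$kind <- rep("compound_target", nrow(predicted))
  if (any(is.na(predicted$weight)) && nrow(predicted) > 0) {
    stop("predicted edges must carry numeric scores", call. = FALSE)
  }
  predicted <- canonicalize_edges(predicted)

  known_sets <- lapply(split(known$target, known$source), unique)
  pred_split <- split(predicted[, c("target", "weight")], predicted$source)
  pred_sorted <- lapply(pred_split, function(df) {
    df[order(-df$weight, df$target), , drop = FALSE]
  })
  compounds <- union(names(known_sets), names(pred_sorted))
  merged <- lapply(stats::setNames(compounds, compounds), function(cp) {
    kn <- known_sets[[cp]]
    pr <- pred_sorted[[cp]]
    top <- if (is.null(pr)) character() else utils::head(pr$target, k)
    unique(c(kn, top))
  })
  structure(list(known = known_sets, predicted = pred_sorted, merged = merged),
            class = "target_assembly")
}

#' Intersect two gene sets with a Venn audit
#'
#' @param a,b character vectors of canonicalized gene symbols.
#' @return list with `intersection` (sorted character vector) and `venn`
#'   (named integer vector: `a_only`, `b_only`, `both`).
#' @export
intersect_sets <- function(a, b) {
  a <- unique(a); b <- unique(b)
  both <- sort(intersect(a, b))
  list(intersection = both,
       venn = c(a_only = length(setdiff(a, b)),
                b_only = length(setdiff(b, a)),
                both = length(both)))
}

#' Build the bipartite component-target network
#'
#' Edge (compound, target) exists iff the target is in the compound's merged
#' target set and in the putative set (the drug/disease intersection).
#' Compounds left with no surviving edge are excluded from the graph and
#' reported -- this is how a library screened to n compounds can yield a
#' network over fewer components.
#'
#' @param merged_targets named list mapping compound name to target set (as
#'   in the `merged` element of [assemble_targets()]).
#' @param putative character vector of putative targets.
#' @return list with `graph` (igraph, node attribute `layer` in
#'   {`component`, `target`}, edge attribute `kind = "ct"`) and
#'   `excluded_compounds`.
#' @export
build_ct_network <- function(merged_targets, putative) {
  putative <- unique(canonicalize_symbols(putative))
  kept <- lapply(merged_targets, function(t) intersect(unique(t), putative))
  excluded <- names(kept)[lengths(kept) == 0]
  kept <- kept[lengths(kept) > 0]
  edges <- data.frame(
    from = rep(names(kept), lengths(kept)),
    to = unlist(kept, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  edges$kind <- rep("ct", nrow(edges))
  nodes <- data.frame(
    id = c(names(kept), unique(edges$to)),
    layer = c(rep("component", length(kept)),
              rep("target", length(unique(edges$to)))),
    stringsAsFactors = FALSE
  )
  list(graph = layered_graph(nodes, edges), excluded_compounds = excluded)
}

#' Per-node degree and normalized betweenness centrality
#'
#' Betweenness is the Brandes raw score scaled by `2 / ((N - 1) (N - 2))`,
#' the normalization to `[0, 1]` for undirected graphs. Scores are computed
#' over the whole (possibly disconnected) graph with unweighted geodesics;
#' unreachable pairs contribute nothing, and when several shortest paths tie
#' the credit is split equally among them. For graphs with fewer than 3
#' nodes betweenness is defined as 0.
#'
#' @param graph simple undirected igraph; node attribute `layer` carried
#'   through if present.
#' @return data.frame with columns `node`, `layer`, `degree`,
#'   `betweenness`.
#' @export
node_metrics <- function(graph) {
  n <- igraph::vcount(graph)
  deg <- igraph::degree(graph)
  btw <- if (n < 3) {
    rep(0, n)
  } else {
    igraph::betweenness(graph, directed = FALSE, weights = NA,
                        normalized = FALSE) * 2 / ((n - 1) * (n - 2))
  }
  layer <- if ("layer" %in% igraph::vertex_attr_names(graph)) {
    igraph::V(graph)$layer
  } else {
    rep(NA_character_, n)
  }
  data.frame(node = igraph::V(graph)$name, layer = layer,
             degree = as.integer(deg), betweenness = as.numeric(btw),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Whole-network topology summary
#'
#' Mean degree is `2E/N`; density is `2E / (N (N - 1))`; heterogeneity is
#' the coefficient of variation of the degree sequence (population standard
#' deviation over mean, 0 for regular graphs); `reachable_ordered_pairs`
#' counts ordered node pairs lying in the same connected component, and
#' `reachable_fraction` divides that by `N (N - 1)`.
#'
#' @param graph simple undirected igraph with at least 2 nodes.
#' @return list of class `network_summary`.
#' @export
network_summary <- function(graph) {
  n <- igraph::vcount(graph)
  stopifnot(n >= 2)
  e <- igraph::ecount(graph)
  deg <- igraph::degree(graph)
  mean_deg <- mean(deg)
  het <- if (mean_deg == 0) 0 else sqrt(mean((deg - mean_deg)^2)) / mean_deg
  comp_sizes <- igraph::components(graph)$csize
  reach <- sum(comp_sizes * (comp_sizes - 1))
  structure(
    list(n_nodes = n, n_edges = e,
         mean_degree = mean_deg,
         density = 2 * e / (n * (n - 1)),
         heterogeneity = het,
         reachable_ordered_pairs = as.integer(reach),
         reachable_fraction = reach / (n * (n - 1))),
    class = "network_summary"
  )
}

#' Topology arithmetic from node and edge counts alone
#'
#' Mean degree and density depend only on `N` and `E`, so they can be
#' recomputed from a published network's printed size without the network
#' itself. `avg_neighbors` is the same `2E/N` quantity under the name used
#' for PPI subgraphs.
#'
#' @param n_nodes,n_edges node and edge counts of a simple undirected graph.
#' @return list with `mean_degree`, `density`, `avg_neighbors`.
#' @export
summary_from_counts <- function(n_nodes, n_edges) {
  stopifnot(n_nodes >= 2, n_edges >= 0)
  list(mean_degree = 2 * n_edges / n_nodes,
       density = 2 * n_edges / (n_nodes * (n_nodes - 1)),
       avg_neighbors = 2 * n_edges / n_nodes)
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("nodes %d, edges %d, mean degree %.3f, density %.3f\n",
              x$n_nodes, x$n_edges, x$mean_degree, x$density))
  cat(sprintf("heterogeneity %.3f, reachable ordered pairs %d (%.1f%%)\n",
              x$heterogeneity, x$reachable_ordered_pairs,
              100 * x$reachable_fraction))
  invisible(x)
}

#' Dual-threshold key-node screen
#'
#' A node qualifies iff its degree and its betweenness centrality both
#' strictly exceed the respective thresholds. By default the thresholds are
#' the arithmetic means over all supplied nodes (components and targets
#' pooled); explicit thresholds may be given, e.g. to re-apply a published
#' screen to a published node table.
#'
#' @param metrics data.frame as from [node_metrics()] (columns `node`,
#'   `degree`, `betweenness`; extra columns carried through).
#' @param degree_threshold,betweenness_threshold optional explicit
#'   thresholds; default is the mean of the corresponding column.
#' @return list of class `keynode_result` with the thresholds, the counts
#'   above each single threshold, and `key_nodes` (rows of `metrics` above
#'   both, ordered by degree descending then node name).
#' @export
screen_key_nodes <- function(metrics, degree_threshold = NULL,
                             betweenness_threshold = NULL) {
  stopifnot(nrow(metrics) > 0)
  dt <- if (is.null(degree_threshold)) mean(metrics$degree) else degree_threshold
  bt <- if (is.null(betweenness_threshold)) mean(metrics$betweenness) else betweenness_threshold
  above_d <- metrics$degree > dt
  above_b <- metrics$betweenness > bt
  key <- metrics[above_d & above_b, , drop = FALSE]
  key <- key[order(-key$degree, key$node), , drop = FALSE]
  rownames(key) <- NULL
  structure(
    list(mean_degree_threshold = dt, mean_betweenness_threshold = bt,
         n_above_degree = sum(above_d), n_above_betweenness = sum(above_b),
         key_nodes = key),
    class = "keynode_result"
  )
}

#' @export
print.keynode_result <- function(x, ...) {
  cat(sprintf("key-node screen: degree > %.3f (%d nodes), betweenness > %.6f (%d nodes)\n",
              x$mean_degree_threshold, x$n_above_degree,
              x$mean_betweenness_threshold, x$n_above_betweenness))
  cat(sprintf("%d key nodes\n", nrow(x$key_nodes)))
  invisible(x)
}

#' Filter a PPI edge table by confidence
#'
#' Keeps edges with `confidence >= cutoff` (inclusive), drops nodes left
#' isolated, and reports the degree-sorted node ranking plus the average
#' neighbor count `2 E' / N'` of the retained subgraph.
#'
#' @param edges data.frame with columns `source`, `target` and either
#'   `weight` or `confidence` in `[0, 1]`.
#' @param cutoff confidence cutoff in `[0, 1]`.
#' @return list of class `ppi_result` with `graph` (igraph, `layer =
#'   "target"`), `ranking` (data.frame node/degree sorted by degree
#'   descending then node), `n_nodes`, `n_edges`, `avg_neighbors`.
#' @export
filter_ppi <- function(edges, cutoff = 0.95) {
  if (cutoff < 0 || cutoff > 1) stop("cutoff must be in [0, 1]", call. = FALSE)
  conf <- if ("confidence" %in% names(edges)) edges$confidence else edges$weight
  if (is.null(conf) || any(is.na(conf))) {
    stop("PPI edges must carry confidence scores", call. = FALSE)
  }
  if (any(conf < 0 | conf > 1)) stop("confidences must be in [0, 1]", call. = FALSE)
  ed <- data.frame(source = edges$source, target = edges$target,
                   weight = conf, kind = "ppi", stringsAsFactors = FALSE)
  ed <- canonicalize_edges(ed)
  ed <- ed[ed$weight >= cutoff, , drop = FALSE]
  ids <- sort(unique(c(ed$source, ed$target)))
  g <- layered_graph(
    data.frame(id = ids, layer = rep("target", length(ids)),
               stringsAsFactors = FALSE),
    data.frame(from = ed$source, to = ed$target,
               kind = rep("ppi", nrow(ed)), weight = ed$weight,
               stringsAsFactors = FALSE)
  )
  deg <- igraph::degree(g)
  ranking <- data.frame(node = names(deg), degree = as.integer(deg),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$degree, ranking$node), , drop = FALSE]
  rownames(ranking) <- NULL
  n <- igraph::vcount(g); e <- igraph::ecount(g)
  structure(
    list(graph = g, ranking = ranking, n_nodes = n, n_edges = e,
         avg_neighbors = if (n > 0) 2 * e / n else 0),
    class = "ppi_result"
  )
}

#' @export
print.ppi_result <- function(x, ...) {
  cat(sprintf("PPI subgraph: %d nodes, %d edges, avg neighbors %.3f\n",
              x$n_nodes, x$n_edges, x$avg_neighbors))
  invisible(x)
}
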