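# Four-layer Herb-Compound-Target-Pathway network assembly and ranking.

#' Assemble a Herb-Compound-Target-Pathway network
#'
#' Builds the four-layer graph from three edge tables, restricted to the
#' biologically verified core:
#' \enumerate{
#'   \item target-pathway edges are kept only for pathways in
#'     `common_pathways`;
#'   \item compound-target edges are kept for targets that are either
#'     verified or connected to a retained pathway (pathway membership can
#'     admit differentially expressed targets beyond the verified list);
#'   \item herb-compound edges are kept for compounds surviving step 2;
#'   \item no isolated nodes remain.
#' }
#' Gene symbols are canonicalized; compound and herb names are matched
#' verbatim (printed case/punctuation variants stay distinct nodes; see
#' [load_aliases()]).
#'
#' @param hc data.frame with `source` = herb, `target` = compound.
#' @param ct data.frame with `source` = compound, `target` = gene.
#' @param tp data.frame with `source` = gene, `target` = pathway.
#' @param verified_targets character vector of verified gene symbols.
#' @param common_pathways character vector of pathway names/ids to retain.
#' @return igraph with node attribute `layer` in
#'   {`herb`, `compound`, `target`, `pathway`} and edge attribute `kind` in
#'   {`hc`, `ct`, `tp`}.
#' @export
assemble_hctp <- function(hc, ct, tp, verified_targets, common_pathways) {
  verified <- unique(canonicalize_symbols(verified_targets))
  if (length(verified) == 0) {
    warning("empty verified target set; returning empty graph")
    return(layered_graph(data.frame(id = character(), layer = character()),
                         data.frame(from = character(), to = character(),
                                    kind = character())))
  }
  hc$kind <- rep("herb_compound", nrow(hc))
  ct$kind <- rep("compound_target", nrow(ct))
  tp$kind <- rep("target_pathway", nrow(tp))
  hc <- canonicalize_edges(hc)
  ct <- canonicalize_edges(ct)
  tp <- canonicalize_edges(tp)

  tp <- tp[tp$target %in% common_pathways, , drop = FALSE]
  admitted <- union(verified, tp$source)
  ct <- ct[ct$target %in% admitted, , drop = FALSE]
  hc <- hc[hc$target %in% ct$source, , drop = FALSE]

  ef <- function(df, kind) data.frame(from = df$source, to = df$target,
                                      kind = rep(kind, nrow(df)),
                                      stringsAsFactors = FALSE)
  edges <- rbind(ef(hc, "hc"), ef(ct, "ct"), ef(tp, "tp"))
  nf <- function(ids, layer) data.frame(id = ids,
                                        layer = rep(layer, length(ids)),
                                        stringsAsFactors = FALSE)
  nodes <- rbind(
    nf(unique(hc$source), "herb"),
    nf(unique(c(hc$target, ct$source)), "compound"),
    nf(unique(c(ct$target, tp$source)), "target"),
    nf(unique(tp$target), "pathway")
  )
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  g <- layered_graph(nodes, edges)
  igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
}

#' Split the packaged H-C-T-P connection table into edge tables
#'
#' Convenience accessor turning the long-format `table5` fixture (columns
#' `kind`, `node1`, `node2`) into the three `source`/`target` edge tables
#' [assemble_hctp()] consumes.
#'
#' @return list with data.frames `hc`, `ct`, `tp`.
#' @export
fixture_hctp_edges <- function() {
  t5 <- load_fixture("table5")
  as_edges <- function(kind) {
    df <- t5[t5$kind == kind, , drop = FALSE]
    data.frame(source = df$node1, target = df$node2, stringsAsFactors = FALSE)
  }
  list(hc = as_edges("hc"), ct = as_edges("ct"), tp = as_edges("tp"))
}

#' Per-layer degree ranking of an H-C-T-P network
#'
#' Degree counts incident edges of all kinds at a node (a target's degree is
#' its compounds plus its pathways). Within each layer nodes are sorted by
#' degree descending, ties by id; an optional band filter keeps nodes whose
#' degree falls inside a closed interval, the convention used to pick out
#' topologically prominent nodes.
#'
#' @param graph igraph from [assemble_hctp()].
#' @param band optional numeric length-2 vector `c(lo, hi)`; `NULL` keeps
#'   everything.
#' @return data.frame with columns `layer`, `node`, `degree`.
#' @export
rank_hctp <- function(graph, band = NULL) {
  deg <- igraph::degree(graph)
  out <- data.frame(layer = igraph::V(graph)$layer,
                    node = igraph::V(graph)$name,
                    degree = as.integer(deg), stringsAsFactors = FALSE)
  if (!is.null(band)) {
    stopifnot(length(band) == 2, band[1] <= band[2])
    out <- out[out$degree >= band[1] & out$degree <= band[2], , drop = FALSE]
  }
  layer_order <- c(herb = 1L, compound = 2L, target = 3L, pathway = 4L)
  out <- out[order(layer_order[out$layer], -out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}
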