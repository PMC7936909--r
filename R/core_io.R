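#' netpharm: network-pharmacology pipelines for multi-herb formulas
#'
#' Tools to screen herbal compound libraries by ADME parameters, assemble
#' compound-target-disease networks, screen key nodes by degree and
#' betweenness centrality, filter protein-protein interaction networks by
#' confidence, run over-representation statistics, call differentially
#' expressed genes from count data, verify targets across species, and build
#' four-layer Herb-Compound-Target-Pathway networks. A seeded synthetic-data
#' generator emulates every input so the whole pipeline runs without
#' database access.
#'
#' @keywords internal
"_PACKAGE"

# ---- canonicalization --------------------------------------------------

#' Canonicalize gene symbols
#'
#' Uppercases and trims whitespace. Gene/target identifiers are treated as
#' HGNC-style symbols throughout the package; all joins between target sets,
#' disease sets, annotation and DE results go through this canonical form.
#' Compound and herb names are never canonicalized (printed case variants
#' are deliberately preserved as distinct).
#'
#' @param x character vector of gene symbols.
#' @return character vector, trimmed and uppercased. Idempotent.
#' @export
#' @examples
#' canonicalize_symbols(c(" ptafr", "Casp3"))
canonicalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

# ---- configuration -----------------------------------------------------

#' Pipeline configuration
#'
#' Bundles the tunable thresholds of the workflow. Defaults follow common
#' practice in network-pharmacology studies: oral bioavailability >= 30%,
#' drug-likeness >= 0.18 for ADME screening; top 15 predicted targets per
#' compound; PPI confidence 0.95 for the primary target network and 0.4 for
#' the DE-gene network; 2-fold change and p <= 0.05 for DE calling; adjusted
#' p <= 0.05 for enrichment.
#'
#' @param ob_min minimum oral bioavailability, percent.
#' @param dl_min minimum drug-likeness, unitless in [0, 1].
#' @param top_k_predicted predicted targets retained per compound.
#' @param ppi_cutoff_primary PPI confidence cutoff for the putative-target
#'   network.
#' @param ppi_cutoff_deg PPI confidence cutoff for the DE-gene network.
#' @param fc_threshold fold-change threshold (linear scale) for DE calling.
#' @param p_threshold p-value threshold for DE calling.
#' @param padj_threshold adjusted-p threshold for enrichment reserve.
#' @param seed integer seed used by stochastic stages.
#' @return an object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(ob_min = 30, dl_min = 0.18, top_k_predicted = 15,
                            ppi_cutoff_primary = 0.95, ppi_cutoff_deg = 0.4,
                            fc_threshold = 2, p_threshold = 0.05,
                            padj_threshold = 0.05, seed = 1L) {
  stopifnot(
    ob_min >= 0, ob_min <= 100,
    dl_min >= 0, dl_min <= 1,
    top_k_predicted >= 0,
    ppi_cutoff_primary >= 0, ppi_cutoff_primary <= 1,
    ppi_cutoff_deg >= 0, ppi_cutoff_deg <= 1,
    fc_threshold >= 1,
    p_threshold > 0, p_threshold <= 1,
    padj_threshold > 0, padj_threshold <= 1
  )
  structure(
    list(
      ob_min = ob_min, dl_min = dl_min,
      top_k_predicted = as.integer(top_k_predicted),
      ppi_cutoff_primary = ppi_cutoff_primary,
      ppi_cutoff_deg = ppi_cutoff_deg,
      fc_threshold = fc_threshold, p_threshold = p_threshold,
      padj_threshold = padj_threshold, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

# ---- tabular readers ---------------------------------------------------

# Shared TSV reader with schema validation. All package tables are UTF-8,
# tab-separated, header row, "." decimal; scientific notation is accepted in
# numeric columns.
read_tsv_schema <- function(path, required = character(), numeric_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(numeric_cols, names(df))) {
    raw <- trimws(df[[col]])
    raw[raw == ""] <- NA_character_
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' in column '%s' at row %d",
                   raw[bad[1]], col, bad[1]), call. = FALSE)
    }
    df[[col]] <- val
  }
  for (col in setdiff(names(df), numeric_cols)) df[[col]] <- trimws(df[[col]])
  df
}

#' Read a compound library
#'
#' Reads a TSV with columns `herbs` (semicolon-separated herb codes),
#' `mol_id`, `name`, `mw`, `ob`, `dl`, `source` (`tcmsp` or `animal_db`) and
#' `whitelisted` (`TRUE`/`FALSE`). Empty numeric cells become `NA`,
#' mirroring compound-library exports where animal-medicine entries carry no
#' ADME parameters.
#'
#' @param path TSV path.
#' @return data.frame of compound records, one row per compound; row order
#'   preserved.
#' @export
read_compound_library <- function(path) {
  df <- read_tsv_schema(
    path,
    required = c("herbs", "name", "source", "whitelisted"),
    numeric_cols = c("mw", "ob", "dl")
  )
  if (!"mol_id" %in% names(df)) df$mol_id <- NA_character_
  df$mol_id[df$mol_id == ""] <- NA_character_
  df$whitelisted <- toupper(df$whitelisted) %in% c("TRUE", "T", "1", "YES")
  bad_src <- setdiff(unique(df$source), c("tcmsp", "animal_db"))
  if (length(bad_src) > 0) {
    stop("unknown source value(s): ", paste(bad_src, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$herbs == "")) stop("compound with empty herb attribution", call. = FALSE)
  ok_dl <- is.na(df$dl) | (df$dl >= 0 & df$dl <= 1)
  if (!all(ok_dl)) stop("drug-likeness outside [0, 1]", call. = FALSE)
  df
}

#' Split a semicolon-separated herb attribution
#'
#' @param herbs character vector of `;`-separated herb codes.
#' @return list of character vectors.
#' @export
split_herbs <- function(herbs) {
  lapply(strsplit(herbs, ";", fixed = TRUE), trimws)
}

#' Read an edge table
#'
#' Generic two-column (plus optional weight) edge list. Self-edges are
#' rejected; duplicate edges are collapsed (for `ppi` the pair is treated as
#' unordered before deduplication). For edge kinds whose endpoints are gene
#' symbols, those endpoints are canonicalized.
#'
#' @param path TSV with columns `source`, `target` and optionally `weight`.
#' @param kind one of `"herb_compound"`, `"compound_target"`, `"ppi"`,
#'   `"target_pathway"`, `"disease_target"`.
#' @return data.frame with columns `source`, `target`, `weight`, `kind`.
#' @export
read_edge_table <- function(path, kind = c("herb_compound", "compound_target",
                                           "ppi", "target_pathway",
                                           "disease_target")) {
  kind <- match.arg(kind)
  df <- read_tsv_schema(path, required = c("source", "target"),
                        numeric_cols = "weight")
  if (!"weight" %in% names(df)) df$weight <- rep(NA_real_, nrow(df))
  df$kind <- rep(kind, nrow(df))
  canonicalize_edges(df)
}

#' Canonicalize an edge table
#'
#' Uppercases gene-symbol endpoints (both ends for `ppi` and
#' `disease_target`; the target end for `compound_target`; the source end
#' for `target_pathway`), drops self-edges, and deduplicates on the
#' canonical (source, target, kind) triple -- with PPI pairs treated as
#' unordered. Idempotent.
#'
#' @param edges data.frame with `source`, `target`, `kind` and optionally
#'   `weight` columns.
#' @return canonicalized data.frame.
#' @export
canonicalize_edges <- function(edges) {
  stopifnot(all(c("source", "target", "kind") %in% names(edges)))
  if (!"weight" %in% names(edges)) edges$weight <- rep(NA_real_, nrow(edges))
  src_gene <- edges$kind %in% c("ppi", "disease_target")
  tgt_gene <- edges$kind %in% c("ppi", "disease_target", "compound_target")
  edges$source[src_gene] <- canonicalize_symbols(edges$source[src_gene])
  edges$target[tgt_gene] <- canonicalize_symbols(edges$target[tgt_gene])
  path_src <- edges$kind == "target_pathway"
  edges$source[path_src] <- canonicalize_symbols(edges$source[path_src])
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  a <- edges$source
  b <- edges$target
  swap <- edges$kind == "ppi" & a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, edges$kind, sep = "\r")
  keep <- !duplicated(key)
  out <- edges[keep, c("source", "target", "weight", "kind"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gene list (one symbol per line)
#'
#' @param path text file, one gene symbol per line; blank lines ignored.
#' @return character vector of unique canonicalized symbols, input order.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  x <- canonicalize_symbols(x[trimws(x) != ""])
  unique(x)
}

#' Read a GMT gene-set file
#'
#' GMT rows are `term_id <tab> description <tab> gene1 <tab> gene2 ...`.
#' Gene symbols are canonicalized and deduplicated within each set.
#'
#' @param path GMT path.
#' @return named list (by term id) of lists with `name` and `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[trimws(lines) != ""]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(ln, 1, 60), call. = FALSE)
    id <- trimws(parts[1])
    if (id %in% names(out)) stop("duplicate term id in GMT: ", id, call. = FALSE)
    genes <- unique(canonicalize_symbols(parts[-(1:2)]))
    out[[id]] <- list(name = trimws(parts[2]), genes = genes[genes != ""])
  }
  out
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list as returned by [read_gmt()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, sets[[id]]$name, sets[[id]]$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a count matrix with group labels
#'
#' @param path TSV with a `gene` column then one column per sample.
#' @param groups named character vector mapping sample id to group label; if
#'   `NULL`, all samples fall into one group `"all"`.
#' @return a `count_matrix`: list with integer matrix `counts` (genes x
#'   samples) and named character `groups`.
#' @export
read_count_matrix <- function(path, groups = NULL) {
  df <- read_tsv_schema(path, required = "gene")
  genes <- canonicalize_symbols(df$gene)
  samples <- setdiff(names(df), "gene")
  if (length(samples) == 0) stop("count matrix has no sample columns", call. = FALSE)
  mat <- sapply(samples, function(s) {
    v <- suppressWarnings(as.numeric(df[[s]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric count in sample '%s' at row %d", s, bad[1]),
           call. = FALSE)
    }
    v
  })
  mat <- matrix(mat, nrow = length(genes), dimnames = list(genes, samples))
  count_matrix(mat, groups)
}

#' Construct a count matrix object
#'
#' @param counts non-negative integer matrix, genes in rows, samples in
#'   columns, both dimnamed.
#' @param groups named character vector mapping sample id to group label.
#' @return a `count_matrix` object.
#' @export
count_matrix <- function(counts, groups = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), !is.null(colnames(counts)))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(groups)) {
    groups <- stats::setNames(rep("all", ncol(counts)), colnames(counts))
  }
  if (!all(colnames(counts) %in% names(groups))) {
    stop("every sample needs a group label", call. = FALSE)
  }
  structure(list(counts = counts, groups = groups[colnames(counts)]),
            class = "count_matrix")
}

#' Write a count matrix to TSV
#'
#' @param cm a `count_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path) {
  df <- data.frame(gene = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# ---- network IO --------------------------------------------------------

#' Build a layered graph
#'
#' Thin constructor around [igraph::graph_from_data_frame()] enforcing the
#' package conventions: every node carries a `layer` attribute and every
#' edge a `kind` attribute; graphs are simple and undirected.
#'
#' @param nodes data.frame with columns `id`, `layer` (and optional extras).
#' @param edges data.frame with columns `from`, `to`, `kind` (and optional
#'   extras such as `weight`).
#' @return an undirected simple igraph object.
#' @export
layered_graph <- function(nodes, edges) {
  stopifnot(all(c("id", "layer") %in% names(nodes)))
  if (nrow(edges) > 0) stopifnot(all(c("from", "to", "kind") %in% names(edges)))
  g <- igraph::graph_from_data_frame(
    d = if (nrow(edges) > 0) edges else data.frame(from = character(), to = character()),
    directed = FALSE, vertices = nodes
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = "first")
}

# SIF interaction words per edge kind.
sif_words <- c(herb_compound = "hc", compound_target = "ct",
               ppi = "ppi", target_pathway = "tp", hc = "hc", ct = "ct",
               tp = "tp")

#' Write a network to disk
#'
#' Supported formats: `sif` (one `source<TAB>word<TAB>target` line per edge,
#' with an accompanying `.nodes.tsv` sidecar carrying layer attributes so
#' the round trip is lossless), `graphml`, and `json` (node-link).
#'
#' @param graph igraph object whose vertices carry a `layer` attribute.
#' @param path output path.
#' @param format `"sif"`, `"graphml"` or `"json"`.
#' @return `path`, invisibly. `read_network(write_network(g))` recovers the
#'   node set, edge set, and layer/kind attributes.
#' @export
write_network <- function(graph, path, format = c("sif", "graphml", "json")) {
  format <- match.arg(format)
  if (!"layer" %in% igraph::vertex_attr_names(graph)) {
    stop("graph nodes must carry a 'layer' attribute", call. = FALSE)
  }
  nodes <- data.frame(id = igraph::V(graph)$name,
                      layer = igraph::V(graph)$layer,
                      stringsAsFactors = FALSE)
  ed <- igraph::as_data_frame(graph, what = "edges")
  if (!"kind" %in% names(ed)) ed$kind <- rep("ppi", nrow(ed))
  switch(format,
    sif = {
      words <- ifelse(ed$kind %in% names(sif_words), sif_words[ed$kind], ed$kind)
      lines <- if (nrow(ed) > 0) paste(ed$from, words, ed$to, sep = "\t") else character()
      writeLines(lines, path, useBytes = TRUE)
      utils::write.table(nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
    },
    graphml = write_graphml(nodes, ed, path),
    json = {
      jsonlite::write_json(
        list(nodes = nodes, edges = ed[, c("from", "to", "kind"), drop = FALSE]),
        path, dataframe = "rows", auto_unbox = TRUE, digits = NA
      )
    }
  )
  invisible(path)
}

# Minimal GraphML writer (node key: layer; edge key: kind) built on xml2.
write_graphml <- function(nodes, edges, path) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  k1 <- xml2::xml_add_child(doc, "key", id = "layer", `for` = "node",
                            attr.name = "layer", attr.type = "string")
  k2 <- xml2::xml_add_child(doc, "key", id = "kind", `for` = "edge",
                            attr.name = "kind", attr.type = "string")
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  for (i in seq_len(nrow(nodes))) {
    n <- xml2::xml_add_child(g, "node", id = nodes$id[i])
    d <- xml2::xml_add_child(n, "data", key = "layer")
    xml2::xml_set_text(d, nodes$layer[i])
  }
  for (i in seq_len(nrow(edges))) {
    e <- xml2::xml_add_child(g, "edge", source = edges$from[i],
                             target = edges$to[i])
    d <- xml2::xml_add_child(e, "data", key = "kind")
    xml2::xml_set_text(d, edges$kind[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path input path.
#' @param format `"sif"`, `"graphml"` or `"json"`.
#' @return an igraph object with `layer` node and `kind` edge attributes.
#' @export
read_network <- function(path, format = c("sif", "graphml", "json")) {
  format <- match.arg(format)
  switch(format,
    sif = {
      lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
      lines <- lines[trimws(lines) != ""]
      parts <- strsplit(lines, "\t", fixed = TRUE)
      ed <- data.frame(
        from = vapply(parts, `[`, character(1), 1),
        kind = vapply(parts, `[`, character(1), 2),
        to = vapply(parts, `[`, character(1), 3),
        stringsAsFactors = FALSE
      )
      nodes <- read_tsv_schema(paste0(path, ".nodes.tsv"),
                               required = c("id", "layer"))
      layered_graph(nodes, ed[, c("from", "to", "kind")])
    },
    graphml = {
      doc <- xml2::read_xml(path)
      xml2::xml_ns_strip(doc)
      nn <- xml2::xml_find_all(doc, ".//node")
      nodes <- data.frame(
        id = xml2::xml_attr(nn, "id"),
        layer = vapply(nn, function(n) {
          xml2::xml_text(xml2::xml_find_first(n, "./data[@key='layer']"))
        }, character(1)),
        stringsAsFactors = FALSE
      )
      ee <- xml2::xml_find_all(doc, ".//edge")
      ed <- data.frame(
        from = xml2::xml_attr(ee, "source"),
        to = xml2::xml_attr(ee, "target"),
        kind = vapply(ee, function(e) {
          xml2::xml_text(xml2::xml_find_first(e, "./data[@key='kind']"))
        }, character(1)),
        stringsAsFactors = FALSE
      )
      layered_graph(nodes, ed)
    },
    json = {
      obj <- jsonlite::read_json(path, simplifyVector = TRUE)
      nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
      if (is.null(nodes$id)) nodes <- data.frame(id = character(),
                                                 layer = character())
      ed <- as.data.frame(obj$edges, stringsAsFactors = FALSE)
      if (is.null(ed$from)) ed <- data.frame(from = character(), to = character(),
                                             kind = character())
      layered_graph(nodes, ed)
    }
  )
}

# ---- packaged fixtures -------------------------------------------------

#' Load a packaged reference table
#'
#' The package ships transcriptions of the printed reference tables of a
#' published network-pharmacology study of an eight-herb formula against
#' acute hemorrhagic stroke, used as desk-checkable reference data:
#' \describe{
#'   \item{table1}{81-compound ADME library with herb attribution,
#'     whitelist flags and animal-medicine entries.}
#'   \item{table2}{74 key nodes (35 components + 39 targets) of the
#'     component-target network with degree and betweenness centrality.}
#'   \item{table3}{per-comparison DE gene counts (total/differential/up/down).}
#'   \item{table4}{33 KEGG pathways enriched in the DE genes, with input and
#'     background counts and raw/corrected p-values.}
#'   \item{table5}{long-format edge list of the printed
#'     Herb-Compound-Target-Pathway connections.}
#'   \item{verified14}{the 14 cross-verified target genes.}
#'   \item{mapk11}{the 11 genes reported on the MAPK signaling pathway map
#'     (as printed in the text; see [load_aliases()] for spelling variants
#'     against table5).}
#' }
#' Strings are kept verbatim as printed, including inconsistent spellings;
#' [load_aliases()] documents the known variants.
#'
#' @param name fixture name, see Details.
#' @return a data.frame (tables) or character vector (gene lists).
#' @export
load_fixture <- function(name = c("table1", "table2", "table3", "table4",
                                  "table5", "verified14", "mapk11")) {
  name <- match.arg(name)
  p <- function(f) system.file("extdata", f, package = "netpharm", mustWork = TRUE)
  switch(name,
    table1 = read_compound_library(p("table1_compounds.tsv")),
    table2 = read_tsv_schema(p("table2_keynodes.tsv"),
                             required = c("herb", "node", "degree", "betweenness"),
                             numeric_cols = c("degree", "betweenness")),
    table3 = read_tsv_schema(p("table3_de_summary.tsv"),
                             required = c("comparison", "total_genes",
                                          "differential", "up", "down"),
                             numeric_cols = c("total_genes", "differential",
                                              "up", "down")),
    table4 = read_tsv_schema(p("table4_kegg.tsv"),
                             required = c("pathway", "id", "input_number",
                                          "background_number", "p", "p_adj"),
                             numeric_cols = c("input_number",
                                              "background_number", "p", "p_adj")),
    table5 = read_tsv_schema(p("table5_hctp_edges.tsv"),
                             required = c("kind", "node1", "node2")),
    verified14 = read_gene_list(p("verified14_genes.txt")),
    mapk11 = read_gene_list(p("mapk11_genes.txt"))
  )
}

#' Known spelling variants in the packaged tables
#'
#' The printed tables are transcribed verbatim, so the same entity can
#' appear under more than one spelling (for example a gene printed once with
#' a duplicated trailing digit, or compound names differing in case and
#' hyphenation between tables). This table maps each printed variant to the
#' spelling used elsewhere, for joins that need to bridge tables. Node
#' identity in assembled graphs stays verbatim.
#'
#' @return data.frame with columns `printed`, `canonical`, `note`.
#' @export
load_aliases <- function() {
  read_tsv_schema(system.file("extdata", "aliases.tsv", package = "netpharm",
                              mustWork = TRUE),
                  required = c("printed", "canonical", "note"))
}
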