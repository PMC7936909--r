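# Over-representation statistics: hypergeometric / Fisher tests,
# Benjamini-Hochberg adjustment, GO-level classification, pathway overlap.

#' Upper-tail hypergeometric probability
#'
#' Returns `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` marked genes when `n` genes are drawn without
#' replacement from a universe of `N` genes of which `K` are marked.
#' Computed by explicit summation of the exact point masses of the tail.
#'
#' @param k observed overlap (input genes in the term).
#' @param K marked genes in the universe (background genes in the term).
#' @param n draws (annotated input genes).
#' @param N universe size (annotated background genes).
#' @return probability in (0, 1].
#' @export
hypergeom_upper <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N) {
    stop("invalid hypergeometric parameters: need 0 <= k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  }
  if (k == 0) return(1)
  hi <- min(K, n)
  sum(stats::dhyper(k:hi, m = K, n = N - K, k = n))
}

#' One-sided (greater) Fisher's exact test
#'
#' For the 2x2 table `[[a, b], [c, d]]` oriented as `a` = input genes in the
#' term, `b` = background-only genes in the term, `c` = input genes outside
#' the term, `d` = background-only genes outside the term. The one-sided
#' p-value is identically the hypergeometric upper tail
#' `hypergeom_upper(a, a + b, a + c, a + b + c + d)`.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return probability in (0, 1].
#' @export
fisher_exact_greater <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  hypergeom_upper(a, a + b, a + c, a + b + c + d)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment against `m` hypotheses: sort ascending, set
#' `adj(i) = min over j >= i of p(j) * m / j`, cap at 1, and return in the
#' input order. `m` may exceed the number of supplied p-values (tests whose
#' p-values were not retained still count toward the correction).
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @param m number of hypotheses; defaults to `length(pvalues)`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues, m = length(pvalues)) {
  if (m < length(pvalues)) {
    stop("m must be at least the number of p-values", call. = FALSE)
  }
  if (length(pvalues) == 0) return(numeric())
  if (any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must be in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH", n = m)
}

#' Over-representation analysis of a gene set against an annotation
#'
#' Hypergeometric upper-tail test of each annotated term, with the universe
#' restricted to annotated genes: the background defaults to the union of
#' all genes in the annotation, and both the input and any supplied
#' background are intersected with it before counting. One row is emitted
#' per term with at least one input hit; the BH correction uses the number
#' of tested terms as `m`.
#'
#' @param genes character vector of input gene symbols.
#' @param annotation gene-set collection as returned by [read_gmt()].
#' @param background optional character vector restricting the universe.
#' @param padj_threshold rows with `p_adj <= padj_threshold` are flagged
#'   `reserved`.
#' @return data.frame of class `enrichment_result`, sorted by `p` ascending
#'   (ties by term id), with columns `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `p`, `p_adj`, `reserved`, `hit_genes` (list column).
#' @export
run_ora <- function(genes, annotation, background = NULL,
                    padj_threshold = 0.05) {
  genes <- unique(canonicalize_symbols(genes))
  universe <- unique(unlist(lapply(annotation, `[[`, "genes"), use.names = FALSE))
  if (!is.null(background)) {
    universe <- intersect(universe, unique(canonicalize_symbols(background)))
  }
  input <- intersect(genes, universe)
  n <- length(input)
  N <- length(universe)
  empty <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), p_adj = numeric(),
                      reserved = logical(), stringsAsFactors = FALSE)
  if (n == 0) {
    warning("no input gene is annotated; empty enrichment result")
    empty$hit_genes <- list()
    class(empty) <- c("enrichment_result", class(empty))
    return(empty)
  }
  rows <- lapply(names(annotation), function(id) {
    term_genes <- intersect(annotation[[id]]$genes, universe)
    hits <- intersect(input, term_genes)
    if (length(hits) == 0) return(NULL)
    K <- length(term_genes)
    k <- length(hits)
    data.frame(term_id = id, term_name = annotation[[id]]$name,
               k = k, K = K, n = n, N = N,
               p = hypergeom_upper(k, K, n, N),
               hit_genes = I(list(sort(hits))),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    empty$hit_genes <- list()
    class(empty) <- c("enrichment_result", class(empty))
    return(empty)
  }
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p, m = nrow(res))
  res$reserved <- res$p_adj <= padj_threshold
  res <- res[order(res$p, res$term_id),
             c("term_id", "term_name", "k", "K", "n", "N", "p", "p_adj",
               "reserved", "hit_genes")]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Classify input genes over pre-leveled GO terms
#'
#' Counts input genes per term at a fixed ontology level, separately per
#' namespace, in the spirit of level-slice GO classification: a gene
#' belonging to several terms is counted in each (a classification, not a
#' partition). Ontology traversal is not performed; the levels are consumed
#' as data.
#'
#' @param genes character vector of input gene symbols.
#' @param leveled_annotation data.frame in long form with columns
#'   `term_id`, `term_name`, `namespace` (`BP`/`MF`/`CC`), `level`, `gene`.
#' @param level ontology level to slice at.
#' @param top_n terms reported per namespace, by gene count descending with
#'   ties broken by term id (default 20).
#' @return data.frame with columns `namespace`, `term_id`, `term_name`,
#'   `level`, `gene_count`, `genes` (list column).
#' @export
classify_go <- function(genes, leveled_annotation, level, top_n = 20) {
  stopifnot(all(c("term_id", "term_name", "namespace", "level", "gene") %in%
                  names(leveled_annotation)))
  genes <- unique(canonicalize_symbols(genes))
  ann <- leveled_annotation[leveled_annotation$level == level, , drop = FALSE]
  if (nrow(ann) == 0) {
    warning("no terms at level ", level)
    return(data.frame(namespace = character(), term_id = character(),
                      term_name = character(), level = integer(),
                      gene_count = integer(), stringsAsFactors = FALSE))
  }
  ann$gene <- canonicalize_symbols(ann$gene)
  ann <- ann[ann$gene %in% genes, , drop = FALSE]
  key <- paste(ann$namespace, ann$term_id, sep = "\r")
  per_term <- split(ann, key)
  rows <- lapply(per_term, function(df) {
    g <- sort(unique(df$gene))
    data.frame(namespace = df$namespace[1], term_id = df$term_id[1],
               term_name = df$term_name[1], level = level,
               gene_count = length(g), genes = I(list(g)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$namespace, -out$gene_count, out$term_id), , drop = FALSE]
  out <- do.call(rbind, lapply(split(out, out$namespace), utils::head, top_n))
  rownames(out) <- NULL
  out
}

# Name normalization for pathway matching: case-folded, whitespace
# collapsed; punctuation and wording kept.
normalize_pathway_name <- function(x) {
  gsub("\\s+", " ", tolower(trimws(x)))
}

#' Intersect two enrichment result lists
#'
#' Terms are matched by `term_id` when both rows carry one, otherwise by
#' normalized term name (case-folded, whitespace collapsed).
#'
#' @param list_a,list_b data.frames with `term_id` and/or `term_name`
#'   columns (e.g. [run_ora()] output or a published pathway table).
#' @return data.frame of matched pairs with columns `term_id_a`,
#'   `term_name_a`, `term_id_b`, `term_name_b`, `matched_by`.
#' @export
intersect_pathways <- function(list_a, list_b) {
  get <- function(df, col) if (col %in% names(df)) df[[col]] else rep(NA_character_, nrow(df))
  a_id <- get(list_a, "term_id"); a_nm <- get(list_a, "term_name")
  b_id <- get(list_b, "term_id"); b_nm <- get(list_b, "term_name")
  rows <- list()
  used_b <- rep(FALSE, length(b_id))
  for (i in seq_along(a_id)) {
    j <- NA_integer_
    by <- NA_character_
    if (!is.na(a_id[i])) {
      hit <- which(!used_b & !is.na(b_id) & b_id == a_id[i])
      if (length(hit) > 0) { j <- hit[1]; by <- "id" }
    }
    if (is.na(j) && !is.na(a_nm[i])) {
      hit <- which(!used_b & !is.na(b_nm) &
                     normalize_pathway_name(b_nm) == normalize_pathway_name(a_nm[i]))
      if (length(hit) > 0) { j <- hit[1]; by <- "name" }
    }
    if (!is.na(j)) {
      used_b[j] <- TRUE
      rows[[length(rows) + 1]] <- data.frame(
        term_id_a = a_id[i], term_name_a = a_nm[i],
        term_id_b = b_id[j], term_name_b = b_nm[j],
        matched_by = by, stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(term_id_a = character(), term_name_a = character(),
                      term_id_b = character(), term_name_b = character(),
                      matched_by = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
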