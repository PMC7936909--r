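# Count-based differential expression, ortholog mapping and
# cross-verification of DE genes against putative targets.

#' Counts-per-million normalization
#'
#' @param cm a `count_matrix`.
#' @return numeric matrix of the same shape: `count / library_size * 1e6`.
#' @export
cpm_normalize <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  lib <- colSums(cm$counts)
  zero <- names(lib)[lib == 0]
  if (length(zero) > 0) {
    stop("sample(s) with zero library size: ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  sweep(cm$counts, 2, lib, "/") * 1e6
}

#' Exact conditional test for two-group count data
#'
#' A deterministic, fully specified differential-expression test on pooled
#' counts. Per gene, counts are summed within each group; conditional on the
#' gene's grand total `T`, the group-a total is Binomial(`T`,
#' `L_a / (L_a + L_b)`) under the null of equal relative expression, where
#' `L_a`, `L_b` are the pooled library sizes. The two-sided p-value doubles
#' the smaller exact tail and is capped at 1. The fold change is computed on
#' group-mean CPM with a 0.5 pseudocount:
#' `log2fc = log2((mean_cpm_b + 0.5) / (mean_cpm_a + 0.5))`.
#'
#' This pooled binomial test models counting (technical) variation only; it
#' is the Poisson limit of negative-binomial exact tests and becomes
#' anti-conservative when biological dispersion between replicates is
#' large.
#'
#' Direction calls use the config thresholds inclusively: `up` iff
#' `log2fc >= log2(fc_threshold)` and `p <= p_threshold`; `down`
#' symmetrically; otherwise `ns`. Genes with zero total count get `p = 1`,
#' `log2fc = 0`, `ns`. A BH-adjusted `fdr` column is reported alongside but
#' plays no part in the direction call.
#'
#' @param cm a `count_matrix`.
#' @param group_a,group_b group labels present in `cm$groups`.
#' @param config a [pipeline_config()]; supplies `fc_threshold` and
#'   `p_threshold`.
#' @return data.frame with columns `gene`, `mean_cpm_a`, `mean_cpm_b`,
#'   `log2fc`, `p`, `fdr`, `direction`.
#' @export
de_exact_test <- function(cm, group_a, group_b, config = pipeline_config()) {
  stopifnot(inherits(cm, "count_matrix"))
  sa <- names(cm$groups)[cm$groups == group_a]
  sb <- names(cm$groups)[cm$groups == group_b]
  if (length(sa) == 0 || length(sb) == 0) {
    stop("both groups must have at least one sample", call. = FALSE)
  }
  cpm <- cpm_normalize(cm)
  la <- sum(cm$counts[, sa])
  lb <- sum(cm$counts[, sb])
  p0 <- la / (la + lb)
  xa <- rowSums(cm$counts[, sa, drop = FALSE])
  tot <- xa + rowSums(cm$counts[, sb, drop = FALSE])

  p <- rep(1, length(tot))
  nz <- tot > 0
  lower <- stats::pbinom(xa[nz], tot[nz], p0)
  upper <- stats::pbinom(xa[nz] - 1, tot[nz], p0, lower.tail = FALSE)
  p[nz] <- pmin(1, 2 * pmin(lower, upper))

  mean_a <- rowMeans(cpm[, sa, drop = FALSE])
  mean_b <- rowMeans(cpm[, sb, drop = FALSE])
  log2fc <- ifelse(nz, log2((mean_b + 0.5) / (mean_a + 0.5)), 0)

  lfc_min <- log2(config$fc_threshold)
  direction <- rep("ns", length(tot))
  direction[log2fc >= lfc_min & p <= config$p_threshold] <- "up"
  direction[log2fc <= -lfc_min & p <= config$p_threshold] <- "down"

  data.frame(gene = rownames(cm$counts), mean_cpm_a = mean_a,
             mean_cpm_b = mean_b, log2fc = log2fc, p = p,
             fdr = stats::p.adjust(p, method = "BH"),
             direction = direction, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Split DE results into up/down calls
#'
#' @param results data.frame from [de_exact_test()].
#' @return list with `up` and `down` (rows sorted by p ascending) and
#'   `totals` (named integer vector `up`, `down`, `total`).
#' @export
call_degs <- function(results) {
  up <- results[results$direction == "up", , drop = FALSE]
  down <- results[results$direction == "down", , drop = FALSE]
  up <- up[order(up$p, up$gene), , drop = FALSE]
  down <- down[order(down$p, down$gene), , drop = FALSE]
  rownames(up) <- rownames(down) <- NULL
  list(up = up, down = down,
       totals = c(up = nrow(up), down = nrow(down),
                  total = nrow(up) + nrow(down)))
}

#' Map gene symbols across species through an ortholog table
#'
#' One-to-many source rows are resolved by an explicit `rank` column (rank 1
#' wins); a source appearing twice at its best rank is an input error.
#' Unmapped genes are dropped and counted; several sources collapsing onto
#' one target are deduplicated and audited.
#'
#' @param genes character vector of source-species symbols.
#' @param map data.frame with columns `source_symbol`, `target_symbol` and
#'   optionally `rank` (missing rank treated as 1).
#' @return list with `mapped` (unique target symbols, input order of first
#'   appearance) and `audit` (list: `n_input`, `n_unmapped`, `unmapped`,
#'   `n_collapsed`, i.e. how many extra sources merged into an already-seen
#'   target).
#' @export
map_orthologs <- function(genes, map) {
  stopifnot(all(c("source_symbol", "target_symbol") %in% names(map)))
  genes <- canonicalize_symbols(genes)
  map$source_symbol <- canonicalize_symbols(map$source_symbol)
  map$target_symbol <- canonicalize_symbols(map$target_symbol)
  if (!"rank" %in% names(map)) map$rank <- 1L
  map <- map[order(map$source_symbol, map$rank), , drop = FALSE]
  best <- map[!duplicated(map$source_symbol), , drop = FALSE]
  best_key <- paste(best$source_symbol, best$rank, sep = "\r")
  at_best <- map[paste(map$source_symbol, map$rank, sep = "\r") %in% best_key, ,
                 drop = FALSE]
  n_targets <- tapply(at_best$target_symbol, at_best$source_symbol,
                      function(t) length(unique(t)))
  if (any(n_targets > 1)) {
    stop("tied ortholog ranks for source(s): ",
         paste(names(n_targets)[n_targets > 1], collapse = ", "),
         call. = FALSE)
  }
  lookup <- stats::setNames(best$target_symbol, best$source_symbol)
  hit <- genes %in% names(lookup)
  targets <- unname(lookup[genes[hit]])
  mapped <- unique(targets)
  list(mapped = mapped,
       audit = list(n_input = length(genes),
                    n_unmapped = sum(!hit),
                    unmapped = genes[!hit],
                    n_collapsed = length(targets) - length(mapped)))
}

#' Verify DE genes against putative targets
#'
#' Intersects (human-mapped) DE genes with the putative-target set, carrying
#' each verified gene's direction from the DE call.
#'
#' @param deg_human data.frame with columns `gene` and `direction` (the
#'   mapped DE genes).
#' @param putative character vector of putative target symbols.
#' @return list of class `verification_result` with `verified` (data.frame
#'   `gene`, `direction`, sorted by gene), `n_deg_human`, `n_putative`.
#' @export
verify_targets <- function(deg_human, putative) {
  stopifnot(all(c("gene", "direction") %in% names(deg_human)))
  deg_human$gene <- canonicalize_symbols(deg_human$gene)
  putative <- unique(canonicalize_symbols(putative))
  hit <- deg_human[deg_human$gene %in% putative, c("gene", "direction"),
                   drop = FALSE]
  hit <- hit[!duplicated(hit$gene), , drop = FALSE]
  hit <- hit[order(hit$gene), , drop = FALSE]
  rownames(hit) <- NULL
  structure(
    list(verified = hit,
         n_deg_human = length(unique(deg_human$gene)),
         n_putative = length(putative)),
    class = "verification_result"
  )
}

#' @export
print.verification_result <- function(x, ...) {
  cat(sprintf("%d of %d DE genes verified against %d putative targets\n",
              nrow(x$verified), x$n_deg_human, x$n_putative))
  invisible(x)
}
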