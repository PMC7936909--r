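# Seeded synthetic-data generators for every pipeline input, plus an
# end-to-end driver running the whole workflow on a synthetic world.

#' Synthetic-world configuration
#'
#' Parameters of the synthetic generators. Every generator is a pure
#' function of this configuration: the global `seed` expands into
#' per-generator child seeds by fixed offsets, so adding a generator never
#' perturbs the streams of existing ones.
#'
#' Compound ADME values are drawn OB ~ log-normal (parameterized by its
#' percent-scale mean and sd) and DL ~ Beta(`dl_alpha`, `dl_beta`). Counts
#' are negative binomial with `variance = mu + dispersion * mu^2`;
#' per-gene means are log-normal. `de_frac` of genes get their group-b mean
#' multiplied by `2^(+-de_log2fc)` with alternating sign.
#'
#' @param seed integer global seed.
#' @param n_herbs,compounds_per_herb library dimensions.
#' @param shared_compound_frac fraction of compounds attributed to more
#'   than one herb.
#' @param ob_mean,ob_sd mean and sd of oral bioavailability, percent.
#' @param dl_alpha,dl_beta Beta shapes for drug-likeness.
#' @param targets_per_compound integer range (length 2) of known and of
#'   predicted targets per compound.
#' @param n_target_universe size of the target symbol universe.
#' @param disease_set_size,disease_overlap_frac disease gene-set size and
#'   the fraction of it drawn from the drug-target set.
#' @param ppi_edge_prob Bernoulli probability of a PPI edge.
#' @param ppi_conf_high_frac fraction of PPI confidences drawn above 0.95.
#' @param n_genes,n_per_group count-matrix dimensions.
#' @param mu_meanlog,mu_sdlog log-normal parameters of per-gene mean counts.
#' @param nb_dispersion negative-binomial dispersion (see Details).
#' @param de_frac,de_log2fc fraction of genes planted as differential and
#'   the planted effect in log2 units.
#' @param pathway_count,pathway_size_range annotation dimensions
#'   (`pathway_size_range` is an integer range of length 2).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_herbs = 8L, compounds_per_herb = 10L,
                         shared_compound_frac = 0.15,
                         ob_mean = 40, ob_sd = 22,
                         dl_alpha = 2, dl_beta = 4,
                         targets_per_compound = c(3L, 15L),
                         n_target_universe = 500L,
                         disease_set_size = 300L,
                         disease_overlap_frac = 0.4,
                         ppi_edge_prob = 0.02,
                         ppi_conf_high_frac = 0.3,
                         n_genes = 2000L, n_per_group = 3L,
                         mu_meanlog = log(50), mu_sdlog = 1,
                         nb_dispersion = 0.001,
                         de_frac = 0.05, de_log2fc = 2,
                         pathway_count = 50L,
                         pathway_size_range = c(10L, 100L)) {
  cfg <- list(seed = as.integer(seed), n_herbs = as.integer(n_herbs),
              compounds_per_herb = as.integer(compounds_per_herb),
              shared_compound_frac = shared_compound_frac,
              ob_mean = ob_mean, ob_sd = ob_sd,
              dl_alpha = dl_alpha, dl_beta = dl_beta,
              targets_per_compound = as.integer(targets_per_compound),
              n_target_universe = as.integer(n_target_universe),
              disease_set_size = as.integer(disease_set_size),
              disease_overlap_frac = disease_overlap_frac,
              ppi_edge_prob = ppi_edge_prob,
              ppi_conf_high_frac = ppi_conf_high_frac,
              n_genes = as.integer(n_genes),
              n_per_group = as.integer(n_per_group),
              mu_meanlog = mu_meanlog, mu_sdlog = mu_sdlog,
              nb_dispersion = nb_dispersion,
              de_frac = de_frac, de_log2fc = de_log2fc,
              pathway_count = as.integer(pathway_count),
              pathway_size_range = as.integer(pathway_size_range))
  stopifnot(
    cfg$n_herbs >= 1, cfg$compounds_per_herb >= 1,
    cfg$shared_compound_frac >= 0, cfg$shared_compound_frac <= 1,
    cfg$ob_mean > 0, cfg$ob_sd > 0, cfg$dl_alpha > 0, cfg$dl_beta > 0,
    length(cfg$targets_per_compound) == 2,
    cfg$targets_per_compound[1] >= 1,
    cfg$targets_per_compound[1] <= cfg$targets_per_compound[2],
    cfg$n_target_universe >= 1, cfg$disease_set_size >= 1,
    cfg$disease_overlap_frac >= 0, cfg$disease_overlap_frac <= 1,
    cfg$ppi_edge_prob >= 0, cfg$ppi_edge_prob <= 1,
    cfg$ppi_conf_high_frac >= 0, cfg$ppi_conf_high_frac <= 1,
    cfg$n_genes >= 1, cfg$n_per_group >= 1,
    cfg$nb_dispersion > 0, cfg$de_frac >= 0, cfg$de_frac <= 1,
    cfg$pathway_count >= 1, length(cfg$pathway_size_range) == 2
  )
  class(cfg) <- "synth_config"
  cfg
}

# Child-seed offsets, fixed forever (new generators append, never renumber).
synth_child_seed <- function(config, stream) {
  offsets <- c(library = 101L, targets = 202L, disease = 303L,
               counts = 404L, annotation = 505L)
  (config$seed + offsets[[stream]]) %% .Machine$integer.max
}

# Log-normal meanlog/sdlog from a percent-scale mean and sd.
lnorm_params <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  c(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Analytic ADME pass fraction of the synthetic library
#'
#' Closed-form `P(OB >= ob_min) * P(DL >= dl_min)` under the generator's
#' OB/DL distributions (OB and DL are drawn independently).
#'
#' @param config a [synth_config()].
#' @param ob_min,dl_min screening thresholds.
#' @return probability.
#' @export
synth_pass_prob <- function(config, ob_min = 30, dl_min = 0.18) {
  lp <- lnorm_params(config$ob_mean, config$ob_sd)
  stats::plnorm(ob_min, lp["meanlog"], lp["sdlog"], lower.tail = FALSE) *
    stats::pbeta(dl_min, config$dl_alpha, config$dl_beta, lower.tail = FALSE)
}

#' Generate a synthetic compound library
#'
#' Herb codes are `H01 ...`; `shared_compound_frac` of the compounds are
#' attributed to 2 or 3 herbs, the rest to one. OB is log-normal on the
#' percent scale, DL is Beta, independently per compound. All entries carry
#' `source = "tcmsp"` and an empty whitelist.
#'
#' @param config a [synth_config()].
#' @return data.frame in [read_compound_library()] layout.
#' @export
gen_compound_library <- function(config) {
  set.seed(synth_child_seed(config, "library"))
  n <- config$n_herbs * config$compounds_per_herb
  herbs <- sprintf("H%02d", seq_len(config$n_herbs))
  primary <- rep(herbs, each = config$compounds_per_herb)
  n_shared <- round(config$shared_compound_frac * n)
  shared_idx <- if (n_shared > 0) sample.int(n, n_shared) else integer()
  herb_attr <- as.list(primary)
  for (i in shared_idx) {
    extra <- sample(setdiff(herbs, primary[i]),
                    size = min(sample(1:2, 1), config$n_herbs - 1))
    herb_attr[[i]] <- c(primary[i], extra)
  }
  lp <- lnorm_params(config$ob_mean, config$ob_sd)
  data.frame(
    herbs = vapply(herb_attr, paste, character(1), collapse = ";"),
    mol_id = sprintf("SYN%04d", seq_len(n)),
    name = sprintf("CPD%04d", seq_len(n)),
    mw = round(stats::runif(n, 150, 800), 2),
    ob = round(stats::rlnorm(n, lp["meanlog"], lp["sdlog"]), 2),
    dl = round(stats::rbeta(n, config$dl_alpha, config$dl_beta), 3),
    source = "tcmsp",
    whitelisted = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Generate known and scored predicted compound-target edges
#'
#' Per compound, the number of known targets and of predicted targets are
#' each drawn uniformly from `targets_per_compound`; targets come from a
#' universe of `n_target_universe` symbols `T0001 ...`. Predicted edges
#' carry strictly decreasing scores.
#'
#' @param config a [synth_config()].
#' @param compounds character vector of compound names; defaults to the
#'   names of [gen_compound_library()] under the same config.
#' @return list with edge-table data.frames `known` and `predicted`
#'   (columns `source`, `target`, `weight`).
#' @export
gen_target_edges <- function(config, compounds = NULL) {
  if (is.null(compounds)) compounds <- gen_compound_library(config)$name
  set.seed(synth_child_seed(config, "targets"))
  universe <- sprintf("T%04d", seq_len(config$n_target_universe))
  rng <- config$targets_per_compound
  draw <- function(cp) {
    nk <- sample(rng[1]:rng[2], 1)
    np <- sample(rng[1]:rng[2], 1)
    kn <- sample(universe, nk)
    pr <- sample(universe, np)
    scores <- sort(stats::runif(np), decreasing = TRUE)
    list(known = data.frame(source = cp, target = kn, weight = NA_real_,
                            stringsAsFactors = FALSE),
         predicted = data.frame(source = cp, target = pr, weight = scores,
                                stringsAsFactors = FALSE))
  }
  per <- lapply(compounds, draw)
  list(known = do.call(rbind, lapply(per, `[[`, "known")),
       predicted = do.call(rbind, lapply(per, `[[`, "predicted")))
}

#' Generate a disease gene set with controlled drug-target overlap
#'
#' Exactly `round(disease_overlap_frac * disease_set_size)` genes are drawn
#' from `drug_targets`, the remainder from symbols outside it (`D0001 ...`
#' padding the universe where needed).
#'
#' @param config a [synth_config()].
#' @param drug_targets character vector of drug-associated targets.
#' @return character vector of disease genes.
#' @export
gen_disease_set <- function(config, drug_targets) {
  set.seed(synth_child_seed(config, "disease"))
  drug_targets <- unique(drug_targets)
  size <- config$disease_set_size
  n_overlap <- round(config$disease_overlap_frac * size)
  if (n_overlap > length(drug_targets)) {
    stop("overlap_frac * size exceeds the number of drug targets", call. = FALSE)
  }
  universe <- sprintf("T%04d", seq_len(config$n_target_universe))
  pool <- setdiff(universe, drug_targets)
  need <- size - n_overlap
  if (length(pool) < need) {
    pool <- c(pool, sprintf("D%04d", seq_len(need - length(pool))))
  }
  sample(c(sample(drug_targets, n_overlap),
           sample(pool, need)))
}

#' Generate a count matrix with planted differential genes
#'
#' Genes `RG0001 ...`; two groups `groupA`/`groupB` with `n_per_group`
#' samples each. Counts are NB with per-gene log-normal means and
#' `variance = mu + dispersion * mu^2`. The first `round(de_frac * n_genes)`
#' genes (a deterministic slice, so the truth table is trivially stable)
#' have their group-b mean multiplied by `2^(de_log2fc)` with alternating
#' sign.
#'
#' @param config a [synth_config()].
#' @return list with `matrix` (a `count_matrix`) and `truth` (data.frame
#'   `gene`, `direction`, `log2fc`; empty when `de_frac = 0`).
#' @export
gen_counts <- function(config) {
  set.seed(synth_child_seed(config, "counts"))
  n <- config$n_genes
  genes <- sprintf("RG%04d", seq_len(n))
  mu <- stats::rlnorm(n, config$mu_meanlog, config$mu_sdlog)
  n_de <- round(config$de_frac * n)
  sign <- rep(c(1, -1), length.out = n_de)
  fc <- rep(1, n)
  if (n_de > 0) fc[seq_len(n_de)] <- 2^(sign * config$de_log2fc)
  size <- 1 / config$nb_dispersion
  ns <- config$n_per_group
  draw_group <- function(mu_g) {
    matrix(stats::rnbinom(n * ns, mu = rep(mu_g, ns), size = size),
           nrow = n, ncol = ns)
  }
  counts <- cbind(draw_group(mu), draw_group(mu * fc))
  samples <- c(sprintf("A%d", seq_len(ns)), sprintf("B%d", seq_len(ns)))
  dimnames(counts) <- list(genes, samples)
  groups <- stats::setNames(rep(c("groupA", "groupB"), each = ns), samples)
  truth <- data.frame(gene = genes[seq_len(n_de)],
                      direction = ifelse(sign > 0, "up", "down")[seq_len(n_de)],
                      log2fc = (sign * config$de_log2fc)[seq_len(n_de)],
                      stringsAsFactors = FALSE)
  list(matrix = count_matrix(counts, groups), truth = truth)
}

#' Generate annotation, ortholog map and PPI edges
#'
#' Pathway gene sets are sampled uniformly from the supplied universe
#' (structureless, i.e. a null annotation) unless `planted` is given, in
#' which case an extra term `PLANTED` carrying exactly those genes is
#' appended. The ortholog map sends rat symbols `RG%04d` to the universe
#' symbols position-wise (extra rat genes get fresh `HG%04d` targets), with
#' `n_collapse` adjacent pairs collapsed onto one human target. PPI edges
#' are Bernoulli(`ppi_edge_prob`) over the universe with
#' `ppi_conf_high_frac` of confidences drawn in [0.95, 1].
#'
#' @param config a [synth_config()].
#' @param universe character vector of (human) gene symbols; defaults to
#'   the generator's target universe.
#' @param planted optional character vector of genes for one planted
#'   enriched term.
#' @param n_rat_genes number of rat symbols to map (defaults to
#'   `config$n_genes`).
#' @param n_collapse many-to-one collapses planted in the ortholog map.
#' @return list with `annotation` (as [read_gmt()]), `orthologs`
#'   (data.frame `source_symbol`, `target_symbol`, `rank`), `ppi`
#'   (data.frame `source`, `target`, `confidence`).
#' @export
gen_annotation <- function(config, universe = NULL, planted = NULL,
                           n_rat_genes = config$n_genes, n_collapse = 0L) {
  set.seed(synth_child_seed(config, "annotation"))
  if (is.null(universe)) {
    universe <- sprintf("T%04d", seq_len(config$n_target_universe))
  }
  rng <- config$pathway_size_range
  ann <- lapply(seq_len(config$pathway_count), function(i) {
    sz <- sample(rng[1]:rng[2], 1)
    list(name = sprintf("synthetic pathway %02d", i),
         genes = sample(universe, min(sz, length(universe))))
  })
  names(ann) <- sprintf("SYN%05d", seq_len(config$pathway_count))
  if (!is.null(planted)) {
    ann$PLANTED <- list(name = "planted enriched term",
                        genes = unique(canonicalize_symbols(planted)))
  }

  rat <- sprintf("RG%04d", seq_len(n_rat_genes))
  human <- if (n_rat_genes <= length(universe)) {
    universe[seq_len(n_rat_genes)]
  } else {
    c(universe, sprintf("HG%04d", seq_len(n_rat_genes - length(universe))))
  }
  if (n_collapse > 0) {
    for (i in seq_len(min(n_collapse, floor(n_rat_genes / 2)))) {
      human[2 * i] <- human[2 * i - 1]
    }
  }
  ortho <- data.frame(source_symbol = rat, target_symbol = human, rank = 1L,
                      stringsAsFactors = FALSE)

  pairs <- utils::combn(universe, 2)
  keep <- stats::runif(ncol(pairs)) < config$ppi_edge_prob
  n_e <- sum(keep)
  high <- stats::runif(n_e) < config$ppi_conf_high_frac
  conf <- ifelse(high, stats::runif(n_e, 0.95, 1), stats::runif(n_e, 0, 0.95))
  ppi <- data.frame(source = pairs[1, keep], target = pairs[2, keep],
                    confidence = conf, stringsAsFactors = FALSE)
  list(annotation = ann, orthologs = ortho, ppi = ppi)
}

#' Run the whole pipeline on a synthetic world
#'
#' Generates every input under `config` and chains all stages: ADME screen,
#' target assembly, disease intersection, component-target network with
#' topology and key-node screen, PPI confidence filtering,
#' over-representation of the putative targets, differential expression,
#' ortholog mapping, verification against the putative targets, and H-C-T-P
#' assembly. Common pathways are the matched terms reserved (adjusted p
#' below threshold) in both the putative-target and the DE-gene enrichment;
#' when that match is empty, the top 10 terms by p of each side are matched
#' instead so the four-layer graph stays informative.
#'
#' @param config a [synth_config()].
#' @param pconfig a [pipeline_config()].
#' @return list with all intermediate and final results (see element
#'   names).
#' @export
run_synth_pipeline <- function(config = synth_config(),
                               pconfig = pipeline_config()) {
  library <- gen_compound_library(config)
  screen <- screen_compounds(library, pconfig)
  edges <- gen_target_edges(config, screen$passed$name)
  assembly <- assemble_targets(edges$known, edges$predicted,
                               k = pconfig$top_k_predicted)
  drug_targets <- unique(unlist(assembly$merged, use.names = FALSE))
  disease <- gen_disease_set(config, drug_targets)
  overlap <- intersect_sets(drug_targets, disease)
  putative <- overlap$intersection

  ct <- build_ct_network(assembly$merged, putative)
  metrics <- node_metrics(ct$graph)
  summary <- network_summary(ct$graph)
  keynodes <- screen_key_nodes(metrics)

  world <- gen_annotation(config, n_collapse = 0L)
  ppi_edges <- world$ppi[world$ppi$source %in% putative &
                           world$ppi$target %in% putative, , drop = FALSE]
  ppi <- filter_ppi(ppi_edges, cutoff = pconfig$ppi_cutoff_primary)

  ora_putative <- run_ora(putative, world$annotation,
                          padj_threshold = pconfig$padj_threshold)

  sim <- gen_counts(config)
  de <- de_exact_test(sim$matrix, "groupA", "groupB", pconfig)
  degs <- call_degs(de)
  deg_rat <- rbind(degs$up, degs$down)
  mapping <- map_orthologs(deg_rat$gene, world$orthologs)
  deg_human <- data.frame(
    gene = unname(stats::setNames(world$orthologs$target_symbol,
                                  world$orthologs$source_symbol)[deg_rat$gene]),
    direction = deg_rat$direction, stringsAsFactors = FALSE
  )
  deg_human <- deg_human[!is.na(deg_human$gene) & !duplicated(deg_human$gene), ]
  verification <- verify_targets(deg_human, putative)

  ora_deg <- run_ora(deg_human$gene, world$annotation,
                     padj_threshold = pconfig$padj_threshold)
  common <- intersect_pathways(ora_putative[ora_putative$reserved, , drop = FALSE],
                               ora_deg[ora_deg$reserved, , drop = FALSE])
  if (nrow(common) == 0) {
    common <- intersect_pathways(utils::head(ora_putative, 10),
                                 utils::head(ora_deg, 10))
  }
  common_ids <- common$term_id_a

  hc_edges <- data.frame(
    source = unlist(split_herbs(screen$passed$herbs)),
    target = rep(screen$passed$name,
                 lengths(split_herbs(screen$passed$herbs))),
    stringsAsFactors = FALSE
  )
  kept_targets <- lapply(assembly$merged, intersect, putative)
  ct_edges <- data.frame(
    source = rep(names(kept_targets), lengths(kept_targets)),
    target = unlist(kept_targets, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  tp_rows <- lapply(common_ids, function(id) {
    data.frame(source = world$annotation[[id]]$genes, target = id,
               stringsAsFactors = FALSE)
  })
  tp_edges <- if (length(tp_rows) > 0) do.call(rbind, tp_rows) else
    data.frame(source = character(), target = character())
  hctp <- assemble_hctp(hc_edges, ct_edges, tp_edges,
                        verified_targets = verification$verified$gene,
                        common_pathways = common_ids)

  list(library = library, screen = screen, assembly = assembly,
       disease = disease, venn = overlap$venn, putative = putative,
       ct_network = ct, metrics = metrics, summary = summary,
       keynodes = keynodes, ppi = ppi, ora_putative = ora_putative,
       counts = sim, de = de, degs = degs, ortholog_audit = mapping$audit,
       deg_human = deg_human, verification = verification,
       ora_deg = ora_deg, common_pathways = common, hctp = hctp,
       hctp_ranking = rank_hctp(hctp))
}
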