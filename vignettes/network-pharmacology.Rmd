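---
title: "Methods: network pharmacology with cross-omics verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network pharmacology with cross-omics verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

netpharm implements the integration workflow used to dissect multi-herb
formulas: screen a compound library by ADME parameters, assemble per-compound
target sets, intersect them with disease genes, analyse the bipartite
component-target network, filter a protein-protein interaction (PPI) network
by confidence, run over-representation statistics, call differentially
expressed genes (DEGs) from count data, verify DEGs against the putative
targets, and assemble the four-layer Herb-Compound-Target-Pathway (H-C-T-P)
network. This vignette records the modelling choices, the parameters that
matter, and the limits of what the synthetic tests demonstrate.

## ADME screening

A compound passes iff its oral bioavailability (OB, percent) and
drug-likeness (DL, unitless in $[0,1]$) satisfy
$\mathrm{OB} \ge \mathrm{ob\_min}$ **and** $\mathrm{DL} \ge
\mathrm{dl\_min}$, with defaults 30% and 0.18 — the thresholds in common use
for TCMSP-style libraries. Both comparisons are *inclusive*: the packaged
compound library contains an entry with DL exactly 0.18 that the original
screen retained, which pins the convention down. Two deliberate escape
hatches exist:

* a **whitelist** column marks literature-added compounds that fail the
  thresholds but are retained for pharmacological importance. Whitelisting is
  data (a boolean per row), not a name-matching rule, because such additions
  are an editorial act;
* **animal-medicine entries** (`source = "animal_db"`) carry no OB/DL at all
  — they come from a separate collection route that reports none — and are
  retained unconditionally.

A compound with exactly one of OB/DL present is rejected as malformed input
rather than silently screened on one axis.

## The component-target network

Per compound, the merged target set is the union of its known targets and
its `top_k_predicted` (default 15) highest-scoring predicted targets. Score
ties at rank $k$ are broken by symbol order (score descending, then symbol
ascending) so results never depend on input row order. Putative targets are
the intersection of the merged drug targets with the disease gene set; the
bipartite graph has an edge $(c, t)$ iff $t$ is in compound $c$'s merged set
and putative. Compounds left edgeless are excluded and reported — this is
how a screened library of $n$ compounds can yield a network over fewer
components.

Topology statistics on the simple undirected graph with $N$ nodes and $E$
edges:

* mean degree $2E/N$ and density $2E/(N(N-1))$;
* **heterogeneity**: the coefficient of variation of the degree sequence,
  $\sqrt{\operatorname{Var}(d)}/\bar d$ (population variance), 0 for regular
  graphs;
* **reachable ordered pairs**: ordered node pairs in the same connected
  component, and their fraction of $N(N-1)$ — the "how much of the network
  can see itself" statistic reported alongside shortest-path counts.

Betweenness centrality is the Brandes raw score scaled by $2/((N-1)(N-2))$,
the $[0,1]$ normalization for undirected graphs. It is computed over the
whole graph, disconnected components included (unreachable pairs contribute
0); tied geodesics split credit equally; for $N < 3$ it is defined as 0.
The graph is treated as undirected and unweighted — edge scores never enter
the geodesics. The implementation rides on igraph's Brandes scores; the test
suite checks it against an exhaustive simple-path enumeration oracle on all
3- and 4-node graphs and seeded samples of 5- and 6-node graphs, to 1e-12.

**Key nodes** are nodes whose degree *and* betweenness both *strictly*
exceed thresholds, by default the arithmetic means over all nodes of the
mixed graph (components and targets pooled — the single published mean
degree of such networks is exactly $2E/N$ over the pooled graph). Strict
inequality matters: nodes at the mean are excluded, so a regular graph has
no key nodes. Explicit thresholds can be supplied to re-apply a published
screen to a published node table.

PPI filtering keeps edges with confidence $\ge$ cutoff (inclusive; default
0.95 for the primary network, 0.4 for DEG networks), treats pairs as
unordered, drops isolated nodes, and reports the degree ranking and the
average neighbor count $2E'/N'$.

## Over-representation statistics

The enrichment p-value for a term with $K$ annotated genes, given $n$
annotated input genes in a universe of $N$, is the exact hypergeometric
upper tail $P(X \ge k)$, computed by summation of `dhyper` point masses.
The one-sided Fisher test on the oriented $2\times2$ table is identically
this tail, and the suite checks both against enumeration of all
$\binom{N}{n}$ draws for $N \le 12$.

Choices a user should know:

* the **universe is the annotated universe**: $N$ defaults to the union of
  all genes in the supplied GMT, and any explicit background is intersected
  with it. Published tools each carry their own internal background, so
  corrected p-values from those tools are generally not reproducible from
  the printed inputs; the packaged enrichment table is shipped as data, not
  as a regression target.
* **BH correction uses $m$ = number of terms actually tested** (terms with
  at least one input hit), the clusterProfiler convention. `bh_adjust()`
  also accepts a larger $m$ when the caller knows how many tests were run.
* one row per term with $\ge 1$ hit, sorted by p; rows with adjusted
  p $\le$ `padj_threshold` are flagged `reserved`.

Exact tests are discrete: their null p-values are super-uniform, and with
small terms the discreteness is visible. The calibration test therefore
draws term sizes in the hundreds over a universe of thousands, where the
point masses are small and a Kolmogorov–Smirnov test against the uniform is
meaningful; with toy term sizes a KS test rejects for reasons unrelated to
miscalibration.

GO classification is a level slice: genes are counted per term at a fixed,
precomputed ontology level (top 20 terms per namespace, count ties broken by
term id). Ontology traversal is deliberately out of scope — levels are
consumed as data so the ontology need not be bundled.

## Differential expression

The DE stage is a fully specified exact test, chosen over an edgeR
dependency so that every number it produces is reproducible from the
definition. Per gene, counts are pooled within each group; conditional on
the grand total $T$, the group-a total is
$\mathrm{Binomial}(T,\, L_a/(L_a+L_b))$ under the null, with $L$ the pooled
library sizes. The two-sided p doubles the smaller exact tail, capped at 1.
This is the Poisson limit of negative-binomial exact tests: it models
counting noise only.

**This is the package's sharpest limitation.** With biological replicates
(gene-level dispersion $\varphi$ in the 0.01–0.1 range typical of animal
tissue), pooled-count tests are anti-conservative: the variance of a group
total is $n(\mu + \varphi\mu^2)$, inflating the binomial variance by
$1 + \varphi\mu$. The synthetic null used for calibration therefore sets
$\varphi = 0.001$ — shot-noise-dominated replication matched to the test's
assumptions. Passing calibration on that world shows the implementation is
correct, **not** that the test is calibrated on real replicated RNA-seq;
for real data an NB-moderated test is the right tool and this stage should
be read as the transparent, deterministic stand-in it is.

Other conventions: fold change is computed on group-mean CPM with a 0.5
pseudocount, $\log_2\!\frac{\bar c_b + 0.5}{\bar c_a + 0.5}$, so all-zero
genes are well-defined (they get $p = 1$, fold change 0, `ns`). Direction
calls are inclusive at both thresholds ($\ge$ 2-fold, $p \le 0.05$ by
default) and use the **raw** p-value; a BH-adjusted column is reported
alongside but never used for calling, mirroring the thresholding convention
of the workflow this package reimplements.

Ortholog mapping is table-driven: one-to-many rows are resolved by an
explicit `rank` column (rank 1 wins; ties at the winning rank are an input
error, because a silent arbitrary choice would be irreproducible). Unmapped
genes are dropped and counted; many-to-one collapses are audited.
Verification is then a canonicalized intersection of the mapped DEGs with
the putative targets, carrying each gene's direction.

## The H-C-T-P network

The four-layer graph is assembled by restriction: target-pathway edges to
the common pathways; compound-target edges to targets that are verified
*or* members of a retained pathway (pathway membership can admit
differentially expressed targets beyond the verified list, which is why the
target layer can be larger than the verified set); herb-compound edges to
surviving compounds; no isolated nodes. Degree counts edges of all kinds at
a node — a target's degree is its compounds plus its pathways — and the
per-layer ranking supports a closed degree band (default $[10, 33]$) for
picking out topologically prominent nodes.

Node identity is verbatim: gene symbols are uppercased, but compound names
are never case-folded, and printed variants differing in case or
hyphenation remain distinct nodes. The packaged alias table
(`load_aliases()`) documents the known variants so joins across tables can
bridge them deliberately rather than silently.

## The synthetic world

Every pipeline input can be generated from a `synth_config()`: a compound
library (OB log-normal on the percent scale, DL Beta, a configurable
fraction of compounds shared between herbs), known/predicted target edges
with ordered scores, a disease set with an exact planted overlap fraction,
NB counts with planted DE genes, a structureless (null) pathway annotation
with an optional planted term, an ortholog map with planted collapses, and
Bernoulli PPI edges with a controlled high-confidence fraction.

Design points:

* **determinism**: every generator is a pure function of the config; the
  global seed expands to per-generator child seeds by fixed offsets, so
  adding a generator never perturbs existing streams;
* **NB parameterization**: $\operatorname{Var} = \mu + \varphi\mu^2$,
  stated explicitly because "dispersion" is ambiguous across tools;
* defaults describe a small, fast world (8 herbs × 10 compounds, 500-symbol
  target universe, 300-gene disease set with 0.4 overlap, 2000 genes × 3 vs
  3 samples, 50 pathways): large enough for the statistical checks below,
  small enough that the full pipeline runs in seconds;
* the planted DE slice is the first `de_frac` of genes with alternating
  up/down signs of size `de_log2fc` — a deterministic truth table.

What the synthetic world does **not** emulate: real TCMSP score
distributions, correlated expression between genes, realistic biological
dispersion (see above), annotation structure (real pathways overlap
non-randomly), or symbol-mapping noise beyond rank-resolved tables. Green
tests on this world demonstrate correctness of the algebra and calibration
of the statistics under their stated assumptions — not performance on real
study data.

Simulation sizes used by the shipped tests: exhaustive graph enumeration to
4 nodes plus seeded 5–6-node samples for the betweenness oracle; all draws
at $N \le 12$ for the hypergeometric oracle; 1000 single-term replicates
for ORA calibration; 2000 genes for DE calibration and recovery; one full
pipeline run per seed.

## Degenerate inputs and tie-breaks, collected

* thresholds inclusive everywhere (`>=`/`<=`), except the key-node screen,
  which is strict (`>`) by definition of "exceeds the average";
* predicted-target rank ties: (score desc, symbol asc);
* GO/ranking count ties: term id / node id ascending;
* betweenness at $N<3$: 0; empty graphs: valid empty documents on write;
* zero-count genes: $p=1$, fold change 0; zero library sizes: an error
  naming the sample;
* PPI self-edges dropped, pairs unordered, duplicates collapsed before
  filtering;
* empty annotated input to ORA and empty verified set to H-C-T-P assembly:
  empty results with a warning, never an error.
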