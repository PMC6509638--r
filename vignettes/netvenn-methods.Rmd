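---
title: "netvenn: model, methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netvenn: model, methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netvenn)
```

## The problem

Biologists routinely compare lists of differentially expressed (DE) genes
from several related experiments — two genotypes under the same treatment,
a time course, a mutant panel. Venn diagrams answer *how many* genes the
lists share, but not *which* genes, *in which direction* each was
regulated, or *what those genes do*. netvenn represents the comparison as
a bipartite graph instead: one hub node per experiment, one node per
distinct gene, and an edge for every (experiment, gene) membership
carrying the gene's regulation code in that experiment (1 = up, 2 = down,
relative to whatever fold-change cutoff the user applied upstream —
calling DE genes is explicitly not this package's job).

Gene nodes are colored by their cross-experiment regulation class:

* **UP** (red): code 1 in every experiment that contains the gene;
* **DOWN** (blue): code 2 everywhere;
* **DISCORDANT** (yellow): up in at least one experiment and down in at
  least one other.

The Venn-region decomposition is derived from the same membership map: a
gene's *signature* is the exact set of experiments containing it, and a
region is all genes sharing a signature. Regions partition the gene
universe; signatures realized by no gene are omitted (with up to eight
lists there are 255 potential signatures, almost all of them noise).
Between two and eight lists are accepted — a hard limit, not a soft
default.

## Over-representation analysis

Any gene selection (all genes, one region, a subset graph) can be tested
against each annotated term. For a term annotating $K$ of the $N$
background genes, with $n$ genes selected and $k$ of them in the term,
the null distribution of $k$ is hypergeometric and the one-sided
over-representation p-value is the upper tail

$$p = P[X \ge k], \qquad X \sim \mathrm{Hypergeom}(N, K, n).$$

Two variants are provided because "modified Fisher exact test" is used
loosely in the enrichment literature:

* `standard` (default): the exact tail above;
* `ease`: the EASE score, the same tail computed at $\max(k-1, 0)$ — a
  deliberately conservative variant (popularized by DAVID) that damps
  significance driven by a single overlapping gene. By construction
  $p_{\text{ease}} \ge p_{\text{standard}}$ always.

The tail is computed with `stats::phyper`; the test suite verifies it
against an independent enumeration of binomial coefficients over every
feasible table with $N \le 30$ to $10^{-10}$ absolute.

**Background universe.** The default is `annotated_genome` — every gene
annotated to at least one term in the supplied table. It can be switched
to the union of the uploaded lists or to any user-supplied gene set. The
choice matters: a background far larger than the population genes were
actually drawn from inflates significance. The default mirrors the common
DAVID-style convention.

**Multiple testing.** Raw p-values are reported by default, matching how
such tools conventionally print per-term p's; Benjamini–Hochberg
adjustment (`adjust = "bh"`) is available and is applied within each
annotation category separately, since pathways and the three GO aspects
are distinct term families. Depletion testing and GO-graph propagation of
annotations to ancestor terms are out of scope: terms are tested exactly
as annotated, which can differ from tools that propagate up the GO DAG.

## Layout, rendering, determinism

The layout is a Fruchterman–Reingold spring embedding
(`igraph::layout_with_fr`), seeded: identical (model, iterations, seed)
produce bit-identical coordinates, and every output format (graph JSON,
SVG, info-table TSV) is serialized with fixed field order and fixed
numeric formatting, so identical runs are byte-identical — the
reproducibility contract replaces the interactive animation of a browser
tool. An optional `pin_experiments` flag fixes the hub nodes on a circle
(via per-vertex box constraints), which stabilizes very large graphs; the
relative force strengths are otherwise igraph's defaults, an admitted
extrapolation since "force-directed" does not pin them down.

SVG is the source of truth (deterministic text, element counts equal node
and edge counts; squares for highlighted genes render as `rect`
elements). PNG draws the same scene on a cairo raster device at
`canvas × dpi / 72` pixels; it is not byte-stable across platforms and is
not part of the determinism contract. Gene labels are hidden automatically
above 200 gene nodes (`labels = "auto"`).

## The synthetic world

`simulate_collection()` distributes synthetic gene ids over requested
Venn-region sizes *exactly*, then draws every (gene, experiment) direction
code independently as Bernoulli($p_{\text{up}}$), default 0.5. A gene
shared by two experiments is therefore discordant with probability
$2p(1-p)$. This emulates the shape of a multi-genotype DE comparison
(shared and private genes, partially concordant regulation). It does
**not** model fold-change magnitudes, gene–gene correlation, or real GO
DAG structure — so a green test establishes the combinatorics and the
statistics of the pipeline, not biological realism of any particular
dataset.

`simulate_annotations()` plants one term with an exact overlap: $k^\*$
genes from a target region plus $K - k^\*$ fillers from the rest of the
universe, among uniform null terms. The default effect — universe 2,000
genes, selection region 100, $K = 40$, $k^\* = 25$, 100 null terms of
size 40 — puts the planted term's p around $10^{-24}$, far below any null
term, so planted-term recovery is a stable target (observed in 200/200
seeded replicates by the acceptance suite) while null terms stay at the
nominal level. Codes are independent across experiments; correlated
direction structure is a noted extension, not a default.

## Type-I calibration and discreteness

The exact test is *conservative*: because the hypergeometric tail is a
step function, the attained level at a 0.05 threshold is the largest tail
value not exceeding 0.05, which in coarse regimes sits far below 0.05.
With the planted-fixture geometry ($N = 2000$, $n = 100$, $K = 40$, mean
overlap 2) the attained level is roughly 0.01 — no implementation could
place it in a confidence band centered at 0.05. Calibration is therefore
checked in two parts, fixed before any test was run:

1. **Fine-grained regime** (universe 20,000; selection 10,000; 4,000 null
   terms of sizes 500–4,000, where the point masses near the threshold
   are small): the fraction of null terms with $p < 0.05$ must fall in
   the 99% binomial CI around 0.05.
2. **Coarse regime** (the planted-fixture geometry, end-to-end through
   the generator): the fraction must not *exceed* 0.05 beyond Monte-Carlo
   noise — conservatism is asserted, anti-conservatism excluded.

## Numerical and interface choices

* Tail probabilities are clamped into $(0, 1]$ (underflow at extreme
  signals is clamped to the smallest positive double rather than 0).
* Enrichment results sort by raw p, ties broken by term id, so output
  order is total and stable.
* Region output orders by signature cardinality (descending), then
  lexicographically.
* Gene-id matching is case-sensitive and whitespace-trimmed;
  `case_insensitive = TRUE` folds to upper case at parse time. A
  duplicated id with conflicting codes in one file is an error, not
  last-wins.
* A header line in a gene list is auto-detected only when its second
  field is not `"1"`/`"2"`; otherwise the line is data.
* GMT descriptions may carry a `|CATEGORY` suffix; without one, `GO:`
  ids default to `GO_BP` and others to `PATHWAY`.
* Keyword search is case-insensitive literal substring by default
  (`regex = TRUE` opts into regular expressions).
* The odds ratio reported is the sample odds ratio of the 2×2 table,
  `Inf` when the only nonzero cells are diagonal, 0 when the overlap is 0.

## Worked example

```{r example}
sim <- simulate_collection(c(WT = 300, OX = 300, "WT+OX" = 100),
                           p_up = 0.5, seed = 7)
regions <- venn_regions(build_membership(sim$collection))
regions[, c("signature", "n_genes", "n_up", "n_down", "n_discordant")]

ann <- simulate_annotations(sim$truth, target_signature = "WT+OX", seed = 7)
res <- enrich(sim$truth$regions[["WT+OX"]], ann$annotation,
              background = ann$universe)
head(res[, c("term_id", "k", "K", "n", "N", "p_raw")], 3)

model <- build_graph(sim$collection)
lay <- layout_graph(model, iterations = 200)
sub <- subset_graph(model, genes_for_term(ann$annotation, "SIM:PLANTED"))
sub
```

## Known limitations

* No gene-id cross-mapping between namespaces; the annotation file must
  use the same ids as the gene lists.
* No live database access; annotation currency is the user's business.
* Enrichment tests flat gene sets; no GO propagation, no topology-aware
  pathway scoring, no ranked (GSEA-style) tests.
* PNG output depends on the local cairo/fontconfig stack and is not
  byte-reproducible; use SVG where determinism matters.
* The force-directed layout is deterministic but igraph-version-dependent;
  regenerating figures after an igraph upgrade may move nodes.
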