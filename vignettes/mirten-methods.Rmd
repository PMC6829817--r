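---
title: "Methods and design notes for mirten"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mirten}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirten)
```

This vignette is the package's own account of the statistics it
implements, the choices made where several conventions circulate, and what
its simulation-based validation does and does not establish.

## 1. The over-representation model

An interaction database is a deduplicated set of (miRNA, gene) pairs —
predicted pairs carry a ranking score (context++ convention: more negative
means stronger predicted repression), validated pairs carry an evidence
category (*strong* for direct experimental methods such as luciferase
assays and western blots, *weak* for high-throughput evidence such as
CLIP). Given an input list, each candidate item is scored by the
hypergeometric upper tail

$$p = 1 - \sum_{i=0}^{X-1}
  \frac{\binom{K}{i}\binom{M-K}{N-i}}{\binom{M}{N}},$$

with $M$ the number of interactions in the database, $N$ the deduplicated
input-list length, $K$ the candidate's interaction count, and $X$ the
overlap between the candidate's interactions and the list.

**Universe semantics.** This convention counts the universe in
*interactions* while the draw is a list of *genes* (or miRNAs). It is not
a self-consistent urn: when the catalogue holds many interactions per
gene, $M$ is much larger than the number of distinct genes, the null
expectation $NK/M$ understates the true chance overlap, and the test is
anti-conservative. We keep it as the default because it is the field's
established convention for this analysis, and expose a coherent
alternative (`enrich(universe = "entities")`: $M$ = distinct partner
entities, $N$ = matched input members) for users who want calibrated
p-values. The choice is recorded in the result's attributes. The
consequences are visible in our own evaluation (§5): at high planted
activity the default detector flags most of the database — high
sensitivity at the price of specificity.

**Candidate set for FDR.** The Benjamini–Hochberg adjustment runs over
*all* items present in the database ($K \ge 1$), not only those
overlapping the input ($X \ge 1$). Adjusting only over the overlapping
items would understate the number of implicit tests and be
anti-conservative on top of the universe issue. Only $X \ge 1$ rows are
*reported*, but their adjusted values reflect the full candidate set.

**Numerics.** The tail sum is evaluated on the upper side in log space
(`lchoose`), so it is accurate for small upper tails (the regime that
matters for ranking) and stable for $M$ up to millions; terms outside the
feasible support contribute $e^{-\infty} = 0$ without special-casing. The
suite verifies exact agreement (to $10^{-12}$) with exhaustive enumeration
of all draws for every $(M, K, N, X)$ with $M \le 12$, and with the
classical distribution function on random larger instances.

## 2. Reading interaction tables

Column dialects map TargetScan-style and miRTarBase-style headers onto the
canonical fields; the canonical output of `write_interactions()` reloads
byte-identically. Conventions, fixed once:

* duplicate (miRNA, gene) pairs collapse to one interaction — best (most
  negative) score for predicted tables, strongest evidence for validated
  ones; the number of collapsed support rows is kept (`n_evidence`);
* miRTarBase support-type strings containing "(Weak)" are *weak*,
  everything else *strong*;
* miRNA identifiers are case-sensitive (miRBase distinguishes hsa-miR
  from hsa-mir); gene symbols are upper-cased before matching, because
  symbol case in the wild is unreliable;
* "top $k$ targets" of a miRNA ranks predicted interactions by ascending
  score and validated ones by descending `n_evidence`, with lexicographic
  tie-breaks, so the ranking is deterministic. Validated catalogues have
  no score, and evidence multiplicity is the natural surrogate for how
  well-supported an interaction is.

## 3. Network topology

The filtered enrichment rows induce a bipartite graph: surviving items
plus their overlap partners, with the overlap interactions as edges. Per
node we report degree, betweenness, closeness, average shortest path
length, eccentricity, and the local clustering coefficient, all on
unweighted shortest paths (computed with igraph, and checked in the test
suite against a brute-force BFS/path-counting oracle on hundreds of random
small graphs).

Filtered networks are routinely disconnected, so distance-based metrics
are computed within each node's connected component; closeness is the
classical $(n_c - 1)/\sum d$ with $n_c$ the component size. Betweenness is
reported unnormalized by default (`normalized_betweenness = TRUE` rescales
by $2/((n-1)(n-2))$ — both conventions circulate). The triangle-based
clustering coefficient is *identically zero* on a bipartite graph; we keep
it for completeness and comparability, and expose the square (four-cycle)
clustering coefficient — the bipartite analogue — behind
`clustering = "square"`.

**Power-law fit.** `fit_power_law()` does ordinary least squares of
$\log_{10} P(k)$ on $\log_{10} k$ over degrees with nonzero observed
probability; the exponent is the negated slope, with $r^2$ as the quality
report. This is exactly what a straight line on the log-log degree plot
implies, and it is exact on collinear input. It is *not* a tail estimator:
on unbounded heavy-tailed samples the raw histogram's singleton tail bins
flatten the OLS slope (a well-known bias of histogram regression;
maximum-likelihood tail estimators exist for that problem but answer a
different question). Our recovery test therefore uses a
configuration-model network whose degree law is truncated (support 1–30 at
2000 nodes), where every bin is well populated and the estimator is
consistent — recovering $\gamma = 2.5$ within $\pm 0.4$. On small filtered
enrichment networks, degree supports are short and dense, which is the
regime the fit is meant for.

## 4. Functional ORA

`ora()` maps each GMT category onto the same hypergeometric code path:
$M$ = background size, $K$ = category size within the background, $N$ =
target genes in the background, $X$ = hits. The background defaults to
the union of all category members — the conservative, self-contained
choice when no assayed-genome background is supplied. The reported *gene
ratio* is hits over **category size**; the more common hits-over-input
convention is available (`ratio = "input"`) and the convention in use is
recorded in the output. A null-draw test keeps the fraction of categories
at $p \le 0.05$ near (in practice slightly below, by discreteness) the
nominal level.

## 5. The simulation harness

The generator plants miRNA activity in a genes-by-samples matrix over the
database's genes:

* every entry starts i.i.d. standard normal, $E(g,s) \sim N(0,1)$;
* `n_active` miRNAs are drawn uniformly among those whose catalogue can
  cover the largest budget; the $j$-th represses its top
  `target_counts[j]` targets;
* in each *affected* sample (a random `n_affected` of `n_samples`), each
  repressed target is reduced by $\alpha + \varepsilon$,
  $\varepsilon \sim N(0,1)$: the entry becomes
  $E(g,s) = N(0,1) - (\alpha + N(0,1))$, hence mean $-\alpha$ and
  variance 2.

Full-scale defaults are 100 samples (50 affected), 10 active miRNAs with
budgets 100–1000, and $\alpha$ swept 0.3–1 in 0.05 steps.

**From matrix to input list.** How the simulated matrix becomes the gene
list fed to enrichment is genuinely open; we use the simplest defensible
reading of repression: a per-gene Welch two-sample $t$-test, one-sided for
down-regulation in affected samples, BH-adjusted, keeping genes at FDR
$\le 0.05$. The vectorized statistics match `stats::t.test` row by row in
the tests.

**Detection and ROC.** A miRNA is *detected* when it survives the default
enrichment filter (FDR $\le 0.05$, overlap $\ge 1$). Each $\alpha$ yields
one operating point (TPR over the planted miRNAs, FPR over the rest);
each level is simulated independently with a seed derived from the master
seed by a fixed offset, so the sweep is reproducible and uncoupled. The
curve is the monotone staircase through the points sorted by FPR, anchored
at (0,0) and (1,1), integrated trapezoidally — so the AUC is invariant to
the order the levels are run in. An oracle detector scores AUC 1; a
coin-flip detector scores ≈ 0.5.

**Scaled study conditions.** The validation suite runs the study at desk
scale: a synthetic database of 200 miRNAs over 5000 genes with truncated
power-law catalogues (exponent 1.8, 50–2000 targets — dense enough that
five miRNAs with ≥ 500 targets always exist), 5 active miRNAs with
budgets 100–500, the full $\alpha$ grid, and 10 replicate seeds; mean AUC
exceeds 0.9. Sub-minute component tests use a 40 × 1500 database with two
active miRNAs whose budgets cover about a quarter of the genome, matching
the planted-fraction regime of the full-scale conditions (where per-gene
discovery power, which depends on the BH threshold and hence on the
planted fraction, is high).

**Tissue PPV.** `select_representative_mirnas()` averages repeat
measurements and keeps miRNAs strictly above the 75th percentile of the
profile (linear-interpolation quantile, `type = 7`: for values 1–100 the
cutoff is 75.25, selecting 76–100);
`select_representative_proteins()` keeps genes at immunohistochemistry
level "High". `ppv_evaluation()` runs gene-list enrichment on the
representative proteins and reports $PPV = TP/(TP+FP)$ over the detected
miRNAs, with a guarded `NA` when nothing is detected. The acceptance
script exercises this on a synthetic tissue: 300 miRNAs over 12 000 genes
(catalogue sizes 30–300, the sparsity regime of real genome-scale
catalogues), 8 planted tissue miRNAs whose top-50 regulons form the
protein list and whose profile expression is elevated; precision comes
out well above the 25% base rate of the representative set.

**What the synthetic data does not emulate.** Independent Gaussian
expression (no gene-gene correlation, no library-size or batch
structure), uniform interaction scores, independent random target sets
(no seed-family structure, so real shared-seed miRNAs would be far more
confounded), and planted effects that are homogeneous across targets.
Passing these tests shows the pipeline's statistics and bookkeeping are
right at realistic scales — not that the detection rates transfer to any
particular real dataset, which depends on the catalogue and expression
structure.

## 6. Degenerate inputs and edge handling

Empty input lists, inputs fully absent from the database (reported, not
silently dropped), empty filtered networks (empty network plus a
warning), single-degree distributions (degenerate-fit error), all-equal
expression profiles (empty selection: strictly-greater rule), and
zero-detection PPV (NA with a flag) are all defined behaviours with
tests. Errors are classed (`mirten_error_format`, `_usage`, `_domain`,
`_lookup`, `_parameter`) so callers can distinguish bad files from bad
parameters.

## 7. Known limitations

* The default interaction-universe test is anti-conservative by
  construction (§1); treat default p-values as a ranking device, as the
  ecosystem does, or switch to the entity universe.
* Multi-site predicted records collapse to the best score per pair;
  site-level information is not retained.
* No identifier conversion beyond case normalization: inputs must be gene
  symbols and mature miRNA IDs consistent with the database used.
* The power-law fit is a descriptive straight line on the log-log plot,
  not a tail-index estimator (§3).
* ROC points come from one simulation per activity level, so individual
  points carry Monte-Carlo noise; replicate seeds (as the acceptance
  script does) before comparing AUCs.
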