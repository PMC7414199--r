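---
title: "mirffl: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirffl: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistics it implements,
the parameters that matter, and the places where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The pipeline and its assumptions

`mirffl` chains five stages over tabular inputs:

1. **Differential-expression meta-analysis** over K case/control expression
   studies (log2 scale, already background-corrected and normalized — the
   package performs no probe-level preprocessing).
2. **Gene-set over-representation** of the screened DEG list.
3. **PPI hub calling** on evidence-filtered up- and down-regulated networks.
4. **Feed-forward-loop mining** over typed miRNA/TF/gene regulatory edges
   with a human–mouse conservation filter.
5. **Topology statistics** of the merged motif network.

The statistical assumptions are the conventional ones for this workflow:
expression values approximately Gaussian on the log2 scale within groups;
per-study tests independent across studies (required by Fisher's sum of
logs); gene sets treated as flat membership lists; PPI and regulatory edge
tables trusted up to their per-source confidence columns.

## Stage models

### Per-study tests and the moderated t

`per_study_test()` offers a pooled-variance Student t (`"student"`) and, as
the default, a moderated t (`"moderated"`): each gene's pooled variance $s^2$
(residual df $d$) is shrunk toward a prior,

$$\tilde{s}^2 = \frac{d_0 s_0^2 + d\, s^2}{d_0 + d},$$

and the statistic $t = \mathrm{lfc} / \sqrt{\tilde s^2 (1/n_1 + 1/n_2)}$ is
referred to a t distribution with $d + d_0$ df. The prior $(d_0, s_0^2)$ is
fitted by moment matching on $\log s^2$: writing
$e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$, the excess variance
$\mathrm{var}(e) - \psi'(d/2)$ determines $d_0$ through the trigamma inverse
(Newton iteration, relative tolerance $10^{-10}$) and the mean of $e$
determines $s_0^2$. When the observed variance of $e$ is at or below
$\psi'(d/2)$ the prior df is infinite and every gene receives $s_0^2$
(complete shrinkage, normal reference distribution). `d0 = 0` reduces the
moderated mode to the student mode exactly, which the tests use as a limiting
case; the full moderated path is cross-checked against limma's
empirical-Bayes fit on a simulated study.

The choice to implement both modes, with the moderated t as default, reflects
that small-cohort microarray meta-analyses conventionally delegate testing to
shrinkage-based packages without pinning down the statistic; implementing the
estimator in-package keeps the pipeline self-contained and exactly testable.

Degenerate inputs are handled explicitly: genes with zero posterior variance
and equal group means get $t = 0,\ p = 1$; with unequal means the p-value is
clamped to the smallest representable positive double and flagged
(`zero_variance`), so such genes can never silently dominate rankings.

### Combination, adjustment, screening

Per-study p-values for the genes *common to all studies* are combined as
$X = -2\sum_i \ln p_i \sim \chi^2(2K)$; genes present in only some studies
are reported separately (`unshared_genes` attribute) and never screened.
Combined p-values are BH-adjusted (`bh_adjust()` delegates to the standard
step-up implementation; a brute-force step-up oracle verifies it in the
tests). Screening uses strict inequalities at both thresholds — BH-p
strictly below `de_alpha` and |weighted mean log2FC| strictly above
`lfc_cut` — matching the convention the thresholds are quoted in.

Effect sizes are summarized as the per-study log2 fold changes weighted by
total study sample size (the standard fixed-effect choice). When per-study
fold changes disagree in sign the gene is labeled `"conflict"`, its combined
p is still reported, and it is excluded from both DEG lists: combination of
two-sided p-values is direction-blind, and excluding sign-discordant genes is
the conservative resolution.

### Over-representation

`fisher_enrich()` computes the one-sided over-representation p as the upper
hypergeometric tail $P(X \ge a)$ against a fixed universe. Two open choices
were resolved as follows: the **universe** defaults to all genes present in
the expression data after probe collapse (self-consistent, reproducible
without external catalogs, overridable by argument), and **BH adjustment is
applied within each library separately**, never pooled across libraries,
mirroring how per-library significance is conventionally reported. Only
over-representation is tested; depletion is out of scope. Sets are
intersected with the universe before testing, and sets disjoint from it are
skipped with a warning rather than tested vacuously.

### PPI networks and hub genes

`build_ppi()` keeps BioGRID-like edges with `evidence_count >= 1` and
HIPPIE-like edges with score in `[hippie_min_score, 1]`. The lower bound is
**inclusive** at 0.63: the interval is read as "medium and high confidence",
which 0.63 itself belongs to. Only edges incident to at least one seed gene
survive; the graph is simple and undirected with merged provenance, and seed
genes are retained even when isolated.

Centralities follow their textbook definitions: unnormalized betweenness
$\sum_{s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}$ over unordered pairs;
stress as the same sum without the denominator; closeness per component,
$(n_c - 1)/\sum_w d(v, w)$, 0 for isolates. Reporting betweenness
unnormalized is immaterial for hub calling: any monotone normalization
preserves ranks, which a test asserts. **EPC** — named in the hub-calling
literature but rarely defined operationally — is implemented as Monte-Carlo
edge percolation: each of `epc_reps` realizations keeps every edge
independently with probability `epc_retain_p`, a node scores the number of
nodes it remains connected to, and EPC is the mean. The definition is fully
testable through its limits (retention 1 gives exactly $n-1$ on a connected
graph; retention 0 gives 0) and through replicate-variance bounds.

Hub calling takes, per measure, the top-n under **dense ranking with all
boundary ties included** — avoiding arbitrary exclusion among tied nodes —
then intersects the five sets and restricts to seed DEGs. Centralities are
computed on the full network (seeds plus interactors) and seed restriction is
applied last: this reading reconciles ranking "the top n DEGs" with
per-measure top sets of different sizes. Both behaviors are available (the
`seeds` argument of `identify_hubs()`), and n defaults to the number of seed
DEGs in each network, with explicit overrides in the configuration.

### Regulatory filtering, conservation, motif mining

Per-dialect retention rules: miRWalk-like edges need score ≥
`mirna_score_min` (inclusive, default 0.95), a 3'-UTR region and binding gap
1; miRSearch-like edges need the categorical high-confidence flag (the
"green band" reading, mapped to a boolean); Starbase-like edges need the
score alone; ChIPBase-like TF edges need a binding site within
`upstream_window_bp` (inclusive, default 1000 bp); Enrichr-TF-like edges need
evidence p strictly below `tf_p_max`; ITFP-like edges are curated and carry
no threshold column, so they pass as-is.

The conservation filter keeps miRNAs whose **base name** — species prefix
stripped, case-insensitive, arm suffix (-5p/-3p) kept — appears as an edge
source in both species, then prunes all miRNA edges of non-conserved miRNAs.
Keeping the arm is the stricter, reproducible identity; `keep_arm = FALSE`
relaxes it. TF→gene edges are never pruned by conservation: the filter is
defined on miRNA identity only, and extending it to TFs would be a guess.

`enumerate_ffls()` returns exactly the triples (m, T, g) with m→T, m→g and
T→g present, sorted lexicographically; it is invariant to edge order and
duplicates, and is verified against a brute-force scan over all
|M|·|T|·|G| triples. `build_ffl_network()` merges, by default, **only edges
participating in at least one motif** — the composition of the merged motif
network is then a pure function of the motif list — with
`include_all_edges = TRUE` available when the looser reading (all filtered
edges) is wanted. The gene class entering the motif search downstream of the
pipeline is the hub-gene set, not the full DEG list.

### Topology statistics

Computed on the undirected projection of the merged graph (direction remains
in the motif list): local clustering $C_v = 2e_v/(k_v(k_v-1))$ with $C_v = 0$
for $k_v < 2$; topological coefficient $T_v = \mathrm{avg}_u J(v,u)/k_v$ over
partners sharing at least one neighbor, $J$ counting shared neighbors plus 1
for adjacency; betweenness and closeness as above; the shortest-path-length
histogram over connected pairs. The degree histogram is summarized by a
**least-squares line through log10(count) vs log10(degree) over nonzero
bins** with $R^2$ — the straight line drawn through a log-log degree plot —
rather than maximum-likelihood tail fitting, which answers a different
question and is out of scope. With fewer than two usable bins the fit is
reported as NA; with exactly two bins the line interpolates them and
$R^2 = 1$ by construction.

## The synthetic-data module

The generator produces every input the pipeline reads, with the structure the
analysis assumes, and always emits ground truth alongside (planted DEG table,
planted motif list) that only tests may read.

* **Expression**: per-gene baselines from Normal(7, 2) on the log2 scale
  (typical post-normalization intensity range; any finite choice works, this
  one keeps values realistic), shared across studies; planted genes get
  ±`effect_lfc` on case means in every study; i.i.d. Gaussian noise. The
  reference conditions are 500 genes, 25 up + 25 down planted at |lfc| = 1.5,
  noise SD 0.5, two studies of 10 vs 10, seed 7.
* **PPI**: the first seed is wired to every other seed with high-confidence
  edges (a designed central hub), each satellite seed receives on average
  `ppi_extra_partners` leaf interactors of which the first always passes the
  evidence filter, and the remainder draw random scores so a subset
  deliberately falls below the thresholds. This gives the hub-calling stage
  clear margins: every seed keeps degree ≥ 2 while decoy leaves stay at
  degree 1, so the hub set is insensitive to EPC Monte-Carlo noise — a
  property the tests assert over replicate seeds.
* **Regulatory**: planted (miRNA, TF, gene) triples contribute their three
  edges with passing metadata; decoy edges alternate between
  failing-metadata edges (exercising the filters) and passing edges sampled
  with rejection so they never complete an unplanted motif
  (`allow_accidental_ffls = TRUE` disables rejection for stress tests).
  Conservation is applied per miRNA — all of a conserved miRNA's edges are
  mirrored into the mouse set with the `mmu-` prefix — because the
  downstream filter operates on miRNA identity; `conserved_frac` defaults
  to 1 so planted motifs survive conservation.
* **Exact composition** (`simulate_regulatory_exact()`): a deterministic
  constructive layout for hitting exact per-class node counts and per-type
  edge counts with *every* edge in at least one motif. One dense gene is
  targeted by all miRNAs and by all but `n_gene - 1` TFs; each remaining gene
  gets one satellite TF and one supporting miRNA; surplus miRNA-gene and
  TF-gene budgets are routed through a designated anchor TF; the remaining
  miRNA→TF budget fills the miRNA × dense-TF grid in diagonal order, which
  touches every row and column. Requests that violate the layout's counting
  constraints raise errors that name the constraint. The default composition
  (26 miRNAs, 20 TFs, 5 genes; 32/21/144 per-type edges) reproduces the
  published asthma FFL network's 51 nodes and 197 edges.

What the generator does **not** emulate: probe-level intensities, array batch
effects, correlated gene-gene expression, realistic miRNA seed-match
thermodynamics, or scale-free PPI topology beyond the hub-and-leaves
skeleton. Passing tests therefore demonstrate correctness of the statistical
machinery under its stated assumptions — not performance on real cohorts,
where effect sizes are heterogeneous and networks are denser and noisier.

## Parameters at a glance

| parameter | default | unit | role |
|---|---|---|---|
| `de_alpha` | 0.05 | probability | BH threshold on combined p (strict <) |
| `lfc_cut` | 0.5 | log2 units | absolute fold-change screen (strict >) |
| `test_mode` | moderated | — | per-study statistic |
| `enrich_alpha` | 0.05 | probability | BH threshold per gene-set library |
| `hippie_min_score` | 0.63 | score | PPI confidence lower bound (inclusive) |
| `mirna_score_min` | 0.95 | score | miRNA-target score bound (inclusive) |
| `tf_p_max` | 0.05 | probability | TF-library evidence bound (strict <) |
| `upstream_window_bp` | 1000 | bp | TF binding-site window (inclusive) |
| `epc_reps` | 1000 | count | percolation realizations |
| `epc_retain_p` | 0.5 | probability | per-edge retention |
| `rng_seed` | — | integer | drives every stochastic stage |

## Numerical choices and degenerate inputs

* Probe collapse averages a gene's probes arithmetically; unmapped probes are
  dropped and counted, and probes mapped to more than one gene are dropped as
  ambiguous rather than double-counted.
* `fisher_combine()` rejects p ≤ 0 (log undefined) and p > 1 outright.
* Rank ties share a dense rank everywhere; top-n cutoffs include all boundary
  ties; `n` above the node count is clamped with a warning.
* Empty results are legal values, not errors: an empty enriched union, an
  empty hub set, an empty motif list and an empty conservation survivor set
  all propagate as empty tables.
* All report files are tab-separated UTF-8 with "." decimals and mandatory
  headers, written deterministically so byte-identity across reruns is
  meaningful.

## Problem sizes

The test suite runs at desk scale by design: exhaustive oracle equivalence
over all labeled connected graphs on ≤ 5 nodes plus fixed-seed samples of
6–7-node graphs, 200 random tripartite motif instances, 1000-realization EPC
with six replicate seeds on a 20-node fixture, and the 500-gene two-study
reference fixture for end-to-end runs. These sizes were chosen so the whole
suite exercises every contract in well under typical package-check budgets
while keeping Monte-Carlo standard errors far below the decision margins
being tested.

## Known limitations

* Fisher's sum of logs assumes independent studies; overlapping cohorts would
  inflate the combined evidence.
* The moderated-t prior assumes exchangeable gene variances; strong
  mean-variance trends would call for a trend-aware prior, which is not
  implemented.
* The power-law fit is descriptive (log-log least squares), not an MLE tail
  fit, and is reported with its $R^2$ rather than a goodness-of-fit p-value.
* Conservation matching is purely lexical on miRNA base names; true orthology
  can differ.
* No network/database retrieval, no probe-level preprocessing, no GO-graph
  propagation: inputs are taken as the flat tables the readers define.
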