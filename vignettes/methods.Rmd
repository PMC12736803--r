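---
title: "Methods: consensus stress DE, promoter motifs, and integrated networks"
author: "solgrn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus stress DE, promoter motifs, and integrated networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`solgrn` implements an integrative meta-analysis workflow for plant stress
transcriptomes: consensus differential expression across independent
experiments, promoter motif enrichment, tri-evidence gene regulatory
network (GRN) assembly, cross-species ortholog concordance, and NG86
Ka/Ks selection contrasts. Every stage runs on synthetic data with known
ground truth, so the whole pipeline is testable without external data.
This vignette documents the models, the tunable parameters, and the design
choices that were genuinely open.

## The synthetic study conditions

The generator (`sim_config()`, `simulate_bundle()`) emulates the
statistical structure of a multi-experiment crop-stress meta-analysis:

* **Counts.** Gene counts are negative binomial with
  $\mathrm{Var} = \mu + \alpha\mu^2$ and mean
  $\mu_{gs} = b_g \cdot f_s \cdot 2^{\beta_{ge} + x_s\,\lambda_g + m_{gs}}$,
  where $b_g$ is a log-normal baseline (log2 mean 5, sd 2, creating a
  realistic dynamic range that exercises independent filtering), $f_s$ a
  log-normal sample size factor, $\beta_{ge} \sim N(0, \texttt{batch\_sd})$
  a *gene-specific* per-experiment batch shift (making the experiment
  covariate consequential), $x_s$ the stress indicator and $\lambda_g$ the
  planted log2 fold change, and $m_{gs}$ a latent module term. Default
  dispersion is $\alpha = 0.05$, matching the downstream GLM.
* **Planted truth.** Defaults: 2000 genes, 6 experiments, 3 replicates per
  arm, 10% up- and 10% downregulated genes planted at $|\mathrm{LFC}| =
  1.5$, batch sd 0.5. Planted effects are constant at the configured
  magnitude so the planted-set mean is the configured value exactly.
* **TF modules.** A minority of planted genes (5 TFs per direction with 10
  targets each by default) share a latent factor with loading 0.4 log2
  units. The loading is deliberately subordinate to the treatment effect:
  co-expression is the minority evidence layer in stress GRNs, and module
  noise comparable to the treatment effect would be an unrealistic
  generator regime in which consensus recovery is impossible by design.
* **Promoters.** One gene per slot on one synthetic chromosome, strand
  random, 0-order random background sequence. Planted motifs are sampled
  from their PWM *conditional on scoring at or above the scan threshold*,
  so a planting rate of 1.0 makes every target promoter detectable by
  construction. Coordinates are 0-based half-open internally and 1-based
  inclusive in the emitted GFF3 (the standard dialect).
* **Codon pairs.** A random stop-free coding sequence accumulates
  synonymous and nonsynonymous events at per-site rates `ks_target` and
  `omega * ks_target` (events sampled proportional to the number of
  available changes of that class, mirroring NG86 fractional site counts);
  stop codons are avoided by construction. Jukes-Cantor correction then
  recovers the planted rates in expectation.
* **Orthologs.** Pairs link planted genes to a second species' ids whose
  planted direction agrees with probability `concordance_rate` (0.9).

What the generator does **not** emulate: cross-experiment heterogeneity of
the stress response (every experiment shares one true LFC per gene),
read-level artifacts, isoform structure, codon-usage bias, and correlated
PPI/motif noise. Consequences are discussed under *Known limitations*.

## Consensus differential expression

Two complementary strategies, one calling rule.

**Per-experiment contrasts.** Within each experiment, a per-gene NB
log-link GLM (intercept + stress) is fitted by IRLS with median-of-ratios
size factors as offsets. Dispersions are per-gene method-of-moments
estimates on normalized counts, shrunk 50:50 on the log scale toward a
log-linear mean-dispersion trend — untempered moment estimates are
unstable at 3 replicates per arm, and the full Cox-Reid machinery of
dedicated DE packages is out of scope here. The Wald test targets the
composite null $|\mathrm{LFC}| \le 0.32$ (log2), evaluated at the nearer
boundary: $p = \min(1,\, 2\min_b P(Z > (|\hat\beta| - b)/\mathrm{se}))$,
the standard TOST-style treatment of an effect-size threshold. Genes with
mean normalized count below 1 are excluded before testing (an explicit,
reproducible independent filter); all-zero genes are flagged untestable
with $p = 1$.

**Shrinkage and s-values.** Raw effects are shrunk with a closed-form
normal-normal empirical Bayes model: prior $N(0, \tau^2)$ with
$\tau^2 = \max(0, \mathrm{var}(\hat\beta) - \overline{\mathrm{se}^2})$ by
method of moments. The s-value is the posterior probability that the true
effect's sign differs from the reported sign, preserving the
false-sign-rate semantics of mixture-based shrinkage estimators while
staying exactly testable. Moment estimation is restricted to genes with
se ≤ 10 log2 units: a gene with one all-zero arm has a divergent MLE whose
se carries no information but would dominate the mean otherwise. If
$\tau^2 = 0$ the result is flagged degenerate (all shrunken effects 0,
s-value 0.5).

**Calling and consensus.** A gene is a DEG iff s-value < 0.005 (strict)
and $|\mathrm{shrunk\ LFC}| \ge 0.32$ (inclusive) — the same rule for
per-experiment and combined calls. Occurrence is the number of
per-experiment comparisons calling the gene; direction must be unanimous
(otherwise *discordant* and dropped). The final set intersects
consensus-retained genes with combined-model DEGs of matching direction,
ordered by (occurrence ↓, |combined shrunken LFC| ↓, gene id ↑) — a total
order — and capped at 500 per direction; smaller pools are returned whole.
The default occurrence cutoff is the 5-of-6 majority analogous to the
published per-condition cutoffs (10/17, 6/8, 13/18), which are
data-dependent; in this package the comparison inventory is one contrast
per experiment, and grouping is configuration.

With the default conditions (seed 1) the selected up-set attains precision
1.00 and recall 0.73 against planted truth; the per-experiment calling
rule at 3+3 replicates is genuinely strict, and recall is bounded by
low-expression planted genes whose per-experiment evidence cannot reach
s < 0.005.

**Type-I behaviour.** At a true effect of zero the composite-null Wald
test is conservative by construction (the null hypothesis is an interval
and zero is interior); the nominal level is an upper bound, not a target.
The measured null rejection rate is ~0.016 at $\alpha = 0.05$.

## Promoter motifs

Promoters default to 1000 bp upstream of the gene start (not specified by
upstream conventions; common Solanaceae practice, configurable), truncated
at contig bounds, minus-strand sequences reverse-complemented. Scanning
uses log2-odds matrices (pseudocount 0.01 per cell, renormalized) against
a uniform background on both strands; the default threshold is 70% of each
motif's maximal score — a deterministic, documented site-calling rule.
Enrichment uses presence/absence (≥ 1 hit) in a one-sided Fisher 2×2
against the full scanned background, with BH correction jointly across all
(motif, set) pairs and retention at q < 0.05. Motif-to-TF mapping consumes
precomputed tabular alignment hits and applies identity ≥ 50%, relative
aligned-length difference ≤ 30% (relative to the *shorter* sequence, so
100 vs 140 is a 40% difference), and coverage ≥ 50% on both sides.

## Co-expression and modules

Expression is $\log_2(\mathrm{count}/\mathrm{sizefactor} + 1)$; batch
structure is removed by per-gene linear models on batch and condition
indicators, subtracting only the batch terms (condition effects are
protected; confounded designs error with the offending batch named). The
correlation threshold adapts to the number of experiments: 0.9 for ≤ 3,
0.4 otherwise (table-driven, overridable; values outside the published
table fall through to the default rule and carry a provenance note).
Networks are unsigned: edges keep $|r| \ge$ threshold, negative
correlations flagged by their sign.

Module detection builds adjacency $|r|^\beta$ with $\beta$ the smallest
power on the grid reaching scale-free fit $R^2 \ge 0.8$ (log-log
regression over 10 degree bins; else the argmax), unsigned topological
overlap, average-linkage clustering on $1 - \mathrm{TOM}$, a **static**
cut at 0.995 × the maximum merge height (the dynamic hybrid tree cut is a
separate algorithm; the static variant preserves the downstream use of
module membership and is logged prominently as a deviation), minimum
module size 30, and iterative merging of module pairs with eigengene
correlation > 0.75. Eigengene signs are fixed to correlate positively with
mean module expression so merge decisions cannot flip between runs.

## Network integration

The GRN is a typed multigraph: parallel edges of different evidence are
kept distinct because per-evidence edge counts are first-class outputs
(per-evidence counts must sum to the total after same-evidence
deduplication — asserted on every run). Motif nodes are first-class nodes,
so motif-mediated clustering operates through shared motif nodes. Edges:
co-expression (thresholded correlations over the selected universe), motif
→ gene for genes of the enriched set with ≥ 1 promoter hit plus motif → TF
from the association map, and PPI at score ≥ 0.400 (medium confidence).
Records referencing genes outside the selection are dropped with a log
message.

Clustering follows the evidence priority: (1) connected components of the
co-expression subgraph; (2) motif nodes adopt the majority cluster of
their clustered neighbours or seed new clusters, and unclustered genes
join their majority motif's cluster — a gene sharing enriched motifs from
different clusters goes to the majority motif, ties to the larger cluster
then the smaller label (the priority rule does not specify this case; the
choice is deterministic and documented); (3) remaining genes cluster by
PPI components among themselves. Labels are renumbered by descending gene
count, ties by ascending smallest member id. Hubs are TFs with degree
> 40, parallel edges counted separately; high-degree non-TF genes are
reported separately, never as hub TFs.

## Orthologs and selection regimes

Concordance counts ortholog pairs with both ends present and directions
defined; many-to-many orthology contributes each qualifying pair once (no
collapse rule is imposed). The estimator is exactly
$n_\mathrm{same}/n_\mathrm{shared}$. Stress-associated orthogroups are
flagged by the at-least-one-DEG-member rule, with per-species member
counts.

Ka/Ks uses the NG86 estimator: per-position synonymous site fractions
averaged over both sequences (changes to stop codons count as
nonsynonymous sites), pathway-averaged difference counts for multi-hit
codons with equal pathway weights and stop-containing pathways skipped
(all-blocked codons fall back to all pathways), and Jukes-Cantor
correction $K = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, flagged saturated at
$p \ge 3/4$. Model-based estimators from dedicated calculators were not
reimplemented: the downstream conclusions rest on distribution shapes,
which NG86 preserves, and NG86 is exactly testable against hand and
brute-force oracles. Pair filters: alignment length ≥ 300 nt, and a Ks
band that by default excludes Ks < 0.01 (near-identical pairs carry no
rate information) and Ks > 3 (saturation). A published description of this
filter reads as excluding Ks > 0.01, which would discard nearly all
diverged pairs; both readings are supported (`ks_band = c(-Inf, 0.01)`
gives the literal one) and the default is the band above. Distribution
contrasts use two-sided Mann-Whitney tests per group pair plus summaries
(median, quartiles, fraction < 0.3 for purifying selection, fraction in
0.7-1.3 for the neutral band).

## Problem sizes and determinism

The analysis scripts and tests run the full study conditions (2000 genes ×
36 samples × 6 experiments per species, 500-gene enrichment backgrounds,
500 codon pairs per omega, 200 ortholog pairs), chosen so each stage
completes in seconds to a few minutes on a single CPU while keeping
Monte-Carlo errors well inside the asserted tolerances. All randomness
flows from the configuration seed; a fixed seed yields byte-identical
output files, verified by hashing every artifact across repeated runs.

## Known limitations

* Because every experiment shares one true LFC per gene, condition-driven
  covariation dominates pairwise correlations among selected genes; at the
  default scale the co-expression layer is therefore dense and stage-1
  clustering yields one large cluster. Real meta-analyses show sparser
  co-expression because stress responses are heterogeneous across
  experiments — a heterogeneity the generator intentionally omits so the
  consensus machinery has a clean planted truth. Clustering and hub rules
  are therefore additionally exercised on adversarial hand-built fixtures.
* The log2(x+1) transform compresses fold changes at moderate expression
  (a true 2× appears as ~0.93 log2 at a mean of 10), so effect-recovery
  oracles evaluate strongly expressed genes.
* Median-of-ratios normalization assumes most genes unchanged; strongly
  one-sided planting (e.g. 30% up, 0% down) shifts the size factors and
  attenuates recovered effects. Balanced planting is the default.
* The s-value model is normal-normal, not a mixture; it preserves
  false-sign-rate semantics but not the adaptive unimodal prior of
  mixture-based estimators.
* Cross-species comparison in the synthetic setting uses planted partner
  directions; the generator does not simulate a second full expression
  bundle tied to the first through the ortholog map.
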