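---
title: "Methods: motif calibration, methylome accounting and regulon conservation scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif calibration, methylome accounting and regulon conservation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonscan)
```

`regulonscan` studies how a methylation-linked bacterial regulon — the set
of genes activated by GcrA at promoters carrying CcrM's GANTC methylation
mark — is conserved or rewired across related Alphaproteobacteria. This
vignette documents the models, the tunable parameters, the synthetic-data
generators that stand in for sequencing data, and the numerical and design
choices a maintainer should know about.

## Coordinates and formats

All internal coordinates are 0-based half-open `[start, end)`; GFF3 input
and output use 1-based inclusive coordinates and are converted exactly (the
bijection is property-tested). For a minus-strand gene the translational
start is the end-most base of its annotated interval, since GFF stores
intervals in forward-strand coordinates. `N` bases are allowed in genomes;
any scanned window containing `N` never matches, a deliberately
conservative rule.

## Motif model and threshold calibration

A PSSM is estimated from aligned equal-length sites with an additive
pseudocount $\alpha$ per base (default 0.25, a Laplace-style smoothing
proportional to the uniform background; configurable). Scores are log2
likelihood ratios against a mononucleotide background, by default uniform —
these genomes are GC-rich, and `build_pssm()` accepts a genome-estimated
background where that matters, but the uniform default keeps the calibrated
false positive rate interpretable against the synthetic generators, which
also default to 50% GC. Words hitting a zero frequency score $-\infty$; the
sentinel propagates through sums and never enters threshold support.

Several site collections (e.g. per-species alignments of extended-GANTC
promoter sites) can be combined as a mixture motif. Two choices here were
genuinely open and are package decisions:

* **Mixture scoring** is the log-sum-exp of component log-odds with the
  mixture weights, so a score remains the log likelihood ratio of the site
  mixture against the background.
* **Mixture information content** is the weight-averaged component IC; a
  mixture has no closed-form IC, and the weighted average is the natural
  plug-in for the calibration rule below.

The background score distribution is computed exactly: for $L \le 12$ by
enumerating all $4^L$ words weighted by their background probability, and
for longer additive PSSMs by per-position convolution on a score grid of
width $\delta = 0.01$ bits. The two routes agree within one bin per
position (tested for $L \le 8$). The significance threshold $t^*$ is the
smallest support value with $-\log_2 \mathrm{FPR}(t^*) \ge \mathrm{IC}$;
ties at the threshold count as passing, which makes the FPR well defined at
support points. If no support value reaches the IC the maximum support is
returned with a warning flag rather than an error, so batch calibration
over many motifs cannot die half-way.

## Promoter extraction and scanning

Operons are predicted with a simple distance rule — consecutive same-strand
genes on one contig with an intergenic gap of at most 50 bp share an operon
— standing in for a full operon predictor; an external operon table
overrides it. Only the operon lead (5'-most member on the operon's strand)
receives a promoter window.

Three windows, all anchored at the translational start and taken
irrespective of other annotated features, are used in different contexts:
(−200, +100) for conservation scanning, (−200, 0) for the
methylation-site-in-promoter rule, and (−100, +100) for ChIP peak overlap.
All are configurable.

Genome-wide enumeration of a fixed IUPAC motif reports both strands
separately, so a palindromic motif such as GANTC is counted twice per
duplex site — the convention used when quoting genome totals. Within a
promoter's scored hit list, by contrast, forward/reverse hits at the same
interval are collapsed to one hit keeping the higher score: a palindrome is
one biological site, and leaving both reads in would inflate the site-count
factor of the conservation score. Whether the original analyses collapsed
such double hits per promoter is not documented; collapsing is this
package's default and can be disabled.

## Methylation calls

A strand's adenine is methylated iff its IPD ratio exceeds 1 **and** its QV
passes (default 30). A ratio of exactly 1 is called unmethylated — only
ratios strictly above or below 1 are defined as evidence, and the tie is
broken conservatively — and a failing QV likewise counts as unmethylated
for that strand. The per-motif summary reports the methylated fraction
*truncated*, not rounded, to the table precision: 7765/7800 = 0.9955…
prints as 0.99 and 150/455 = 0.3296… as 0.329, which is how such summary
tables are conventionally printed. One consensus IPD ratio per site and
strand is assumed as input; aggregation across reads is upstream of this
package.

## Regulon sets

Differential-expression cutoffs read "p < 0.01" strictly on the raw
p-value column (configurable to an adjusted column — the choice of column
is the caller's) and "fold ≥ f" non-strictly on the fold scale
(`|log2fc| >= log2(f)`); ">2-fold" is ambiguous about the boundary and the
non-strict reading is documented here once and used everywhere. Direct-target
flags are computed on the operon lead's promoter and inherited by members.
Cross-species cascades apply ordered predicates to ortholog-mapped records,
and the stage sets are nested by construction. Orthology is one-to-one:
`reciprocal_best_hits()` pairs genes only on mutual unique best similarity
scores, and exact ties for best leave a gene unpaired rather than guessing.

## Conservation scoring

$\langle WS_{max}\rangle$ multiplies the mean per-species best hit score,
the fraction of ortholog-bearing species with at least one hit, and the
mean per-species hit count. The two means are taken over the species that
*have* at least one site, not over all ortholog-bearing species: averaging
over all species would penalise absence twice, once in the mean and once in
the pervasiveness ratio. Both conventions are arguable; this one is the
package default and the only one its tests pin down.

The posterior probability of regulation uses an explicit independent-sites
model: each scanned position independently carries a site with probability
$q$ (default one expected site per window, $q = 1/\text{positions}$), giving
likelihood ratio $L = \prod_j [(1-q) + q\,2^{s_j}]$ and posterior
$\pi L/(\pi L + 1 - \pi)$ with prior $\pi = 0.5$. The formulation honours
the stated assumptions of the published score — all sites contribute
independently, position within the window does not matter — but the exact
published formula is not reproduced in accessible text, so this is a
documented stand-in, computed on the log scale for numerical safety.
Positions scoring $-\infty$ contribute the background factor $1-q$; an
empty score vector returns the prior.

Ranked heatmap tables normalise `wsmax` and the ortholog count to (0,1)
over the retained groups (`(x - min)/(max - min)`; all-equal columns map to
0 by convention), break `wsmax` ties lexicographically by group id for
determinism, and keep absent orthologs as `NA`, distinct from a posterior
of 0. The Spearman permutation test uses average ranks, permutes `y` with a
seeded generator, and reports the two-sided
$p = (1 + \#\{|\rho_b| \ge |\rho_{obs}|\})/(1 + n_{perm})$; the seed is part
of the result object. ChIP enrichment is aggregated per group as the
maximum peak enrichment within the promoter window (mean is available); the
published analyses do not state their aggregation.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, with ground
truth, under one seeded `sim_config()`. Defaults are the package's study
conditions and are not tuned per test:

* 23 species, 200 ortholog groups, ortholog presence probability 0.95
  (groups present in roughly ≥ 20 of 23 species), promoters of 300 bp
  (−200..+100).
* 10% of groups "regulated": their member promoters receive planted sites
  with per-species probability 0.9, versus 0.05 for background groups —
  well-separated conservation levels for the ranking-recovery checks.
  Site counts are `max(1, Poisson(1))`, placed uniformly without overlap,
  on a random strand, sampled letter-wise from the planting PWM (the
  8-word YGAKTCK consensus PSSM, IC = 11 bits) so sub-consensus words occur
  naturally.
* Expression: 2000 genes, 5% differentially expressed with
  $|\log_2 FC| \sim U(1,3)$ and random sign, negative-binomial counts
  (mean 100, dispersion 0.02) over 3 replicates per condition. The emitted
  p-value is a two-sided t-test on `log2(count + 1)` — a documented
  stand-in so that nothing downstream depends on any particular
  count-model implementation, whose statistics are treated as *inputs*
  throughout this package.
* ChIP: 100-bp peaks centred on planted sites with ±10 bp jitter and
  lognormal enrichment, plus spurious peaks at 5 × 10⁻⁵ per bp.
* IPD ratios: methylated $\sim \mathrm{LogNormal}(\ln 2.0, 0.15)$,
  unmethylated $\sim \mathrm{LogNormal}(\ln 0.85, 0.10)$ — well separated
  at the ratio-1 threshold — with duplex state probabilities
  0.99/0.005/0.005 (full/hemi/unmethylated) and fixed QV 40.

What the generators do **not** emulate: phylogenetic correlation among
species (each species' promoter set is independent, so conservation levels
are cleaner than in real clades), GC-rich genome composition and its
k-mer structure, read-level noise (counts and IPD ratios are drawn at the
summary level), and operon structure in the multi-species panel (one
promoter per ortholog). Passing the recovery suites therefore shows the
*machinery* is correct under controlled conditions, not that real-data
performance matches the synthetic rates.

## Problem sizes and determinism

The test and acceptance runs use the default panel (200 groups × 23
species, ~4,600 promoters), 200 random promoters for the spurious-hit
check, 500 replicates × 199 permutations for the permutation-test
calibration, and 2000 genes for expression recovery — sizes at which every
stochastic check is stable across seeds while the whole suite stays fast.
All generators and the permutation test take explicit seeds, save and
restore the global RNG state, and are byte-deterministic given a config;
pipeline reruns with the same config produce identical tables.

## Known limitations

* The genome-wide GANTC accounting of a real chromosome requires that
  chromosome's FASTA; the package ships none and does no downloading.
* Transcriptional start sites are not modelled; all windows anchor at the
  translational start.
* The posterior model and the mixture-combination and FPR rules are
  explicit stand-ins where the published descriptions are silent (each is
  flagged above).
* Many-to-many orthology is out of scope; paralog ties must be resolved
  upstream or they drop out of the reciprocal-best-hit map.
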