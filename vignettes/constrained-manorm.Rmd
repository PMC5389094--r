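---
title: "Constrained MAnorm normalization for globally shifted histone marks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained MAnorm normalization for globally shifted histone marks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marknorm)
```

# The problem

Polycomb repressive complexes deposit two marks on chromatin:
PRC1-type H2A monoubiquitination (H2AK121ub in *Arabidopsis*) and
PRC2-type H3K27me3. Comparing ChIP-seq occupancy of such marks between a
wild type and a mutant raises a normalization trap: most quantitative
ChIP-seq comparisons (MAnorm being the canonical one) assume that the
majority of peaks common to both samples are unchanged, and use them to
estimate a rescaling function. In mutants of the depositing complex
itself — *atbmi1a/b/c* for H2AK121ub — that assumption is false: *most*
common peaks are genuinely reduced. A rescaling fitted on all common
peaks then absorbs the biology, under-calls reductions and invents
increases.

This package implements the corrected procedure: the reference set for
the rescaling regression is **constrained** to common peaks that look
individually unchanged (mutant/WT RPKM ratio within ±20 %) and whose
associated genes are not differentially expressed. The rest of the
pipeline — nearest-downstream-gene annotation, marked-gene calling,
retention classification, co-occupancy statistics, coverage profiles —
surrounds that core.

# The model and its steps

## Peak matching and the M–A transform

For one wild-type/mutant replicate pair, peak intervals overlapping by
at least 1 bp are merged into union regions. Wild-type-only peaks stay
in the universe (flagged non-common) and mutant reads are counted over
the wild-type interval, so a retention estimate exists even where the
mutant peak caller found nothing — exactly the peaks most reduced.
Mutant-only peaks are not part of the universe; the reverse comparison
covers them.

Counts are scaled to reads per million and log-transformed:

$$M = \log_2 \frac{x_{mut}/L_{mut}}{x_{wt}/L_{wt}}, \qquad
A = \tfrac12\left(\log_2 \tilde x_{mut} + \log_2 \tilde x_{wt}\right)$$

with library sizes $L$. **Pseudocount choice.** Zero counts need a
pseudocount; we apply 0.5 as a *floor* (`max(x, 0.5)`) rather than
additively. The additive form perturbs every M by a depth-dependent term
($\log_2\frac{rc+0.5}{r(c+0.5)} \approx 10^{-4}$ at depth 1000), which
breaks an identity we consider diagnostic: if the mutant counts are an
exact global rescaling of the wild-type counts and all peaks are
reference-eligible, every percent-of-WT must equal 100 to floating
precision, because the regression must absorb a pure scale factor
exactly. The floor form preserves M exactly for positive counts,
satisfies the same zero-count role, and keeps the antisymmetry
$M(wt, mut) = -M(mut, wt)$.

## Constrained reference and robust fit

A region is reference when it is common, its RPKM ratio lies in the
inclusive window $[0.8, 1.2]$, and (when DEG exclusion is on) its linked
gene is not differentially expressed. The window is measured on RPKM;
RPM is an equivalent choice up to the length normalization and is not
separately implemented. The regression $M = a + b A$ is fitted by Huber
M-estimation (tuning constant 1.345, convergence 1e-8, at most 50
iterations, via `MASS::rlm`); an exactly linear reference short-circuits
to least squares (the robust scale estimate degenerates at zero
residuals, and robustness is moot there). Constant reference A falls
back to an intercept-only fit with a warning. Fewer than `min_reference`
(default 50) reference regions is a hard error: a rescaling model fitted
on a handful of peaks is worse than none.

Every region — reference or not, common or not — is then rescaled:
$M' = M - (a + bA)$, percent-of-WT $= 100 \cdot 2^{M'}$.

## Significance, classes, replicates, genes

An "adjusted p < 0.05" cutoff needs a test behind it; the analyses this
package descends from do not name one, so the principal inferential
choice here is an
**exact binomial read-allocation test**: under the null of no change
after rescaling, each of the region's $x_{wt} + x_{mut}$ reads is mutant
with probability $p_0 = r/(1+r)$, $r = (L_{mut}/L_{wt})\,2^{a+bA}$. The
two-sided exact binomial p is BH-adjusted across regions. This is in the
spirit of the original MAnorm Bernoulli model and is swappable.

Classes: percent < 80 and significant → *reduced*; > 120 and
significant → *increased*; otherwise *unchanged* (80–120 % is WT level).
Reporting bands run in 20-point steps below 80 plus 120–200 and > 200.
A region is finally differential only when called so in **both**
replicates (each replicate is analyzed separately with its own counts
and model, on a shared region universe built from the pooled replicate
peak sets). A gene takes the call of its associated region with minimal
percent-of-WT; ties go to the smaller region id and are logged.

## Annotation conventions

All internal arithmetic is 0-based half-open; GFF3 converts at the
boundary. The 2-kb upstream rule is inclusive at exactly 2000 bp,
measured peak edge to TSS. Overlap beats proximity: a peak overlapping
gene X and lying within 2 kb of gene Y's TSS belongs to X. When one peak
overlaps several regions of its gene, the single linkage label follows
the precedence first exon > 5′UTR > 3′UTR > gene body > promoter,
reflecting the first-exon anchoring of PRC1-type marks; the set-valued
per-region occupancy statistics are unaffected by the precedence.
Equidistant-TSS ties resolve to the lexicographically smaller gene id
and are logged. Because the promoter is itself an annotated region, the
`upstream-within-2kb` class survives only at the exact 2,000-bp
boundary; it is kept for the boundary semantics.

# Statistical primitives

**Wilcoxon rank-sum.** Exact by full enumeration of all
$\binom{n_1+n_2}{n_1}$ rank assignments (midranks under ties) when both
groups have ≤ 8 observations; otherwise the tie-corrected normal
approximation with continuity correction (without it, the approximation
misses the exact p by up to ~0.05 at $n=8$; with it, within ~0.01).
Gene-level coverage comparisons use the unpaired rank-sum even though
gene means are pairable, mirroring the plain "Wilcoxon test" usage this
analysis descends from; a paired test would be a one-line swap.

**Fisher and hypergeometric.** `stats::fisher.test` provides the
conditional-likelihood two-sided p (all tables with the observed margins
whose point probability does not exceed the observed); the reported odds
ratio is the *sample* odds ratio $n_{11}n_{00}/(n_{10}n_{01})$, so
degenerate tables give 0 or ∞ with a finite p. Term enrichment is the
upper hypergeometric tail per term with BH across terms; the gene→term
map is caller-supplied and flat (no ontology graph propagation). The
test suite checks both against brute-force enumeration (all 2×2 tables
with $N \le 40$; margins ≤ 30 for the tail).

**Permutation overlap enrichment.** Each shuffle repositions every peak
uniformly on its own chromosome preserving length; shuffled peaks may
overlap each other and the null preserves neither spacing nor exclusion.
The statistic is the number of peaks overlapping the class;
$p = (1 + \#\{null \ge obs\})/(n_{shuffles}+1)$, never 0, BH across
classes. Because the statistic is integer-valued, the p-value is
conservative under ties; calibration checks use enough peaks (hundreds,
variable lengths) that the null statistic has wide support.

# The synthetic-data generator

The generator emulates the study conditions the analysis assumes, not
raw sequencing:

* **Genome and genes.** Five 3-Mb chromosomes by default; genes of
  length U(800, 4000) bp placed with ≥ 5 kb between gene intervals and
  2 kb edge clearance. Non-overlap plus the 5-kb gap keeps each gene's
  ±2-kb territory private, so the generator's peak→gene assignment is
  the unique NDG answer and annotation recovery is testable exactly.
  Real genomes have overlapping genes; that ambiguity is deliberately
  absent from the ground truth.
* **Marks.** Mark A: mean 600 bp, first-exon-centred. Mark B: mean
  1700 bp, spanning promoter plus gene. These are the published mean
  peak lengths of H2AK121ub and H3K27me3 (0.6 / 1.7 kb). Class
  fractions default to co-occupied 0.18, only-A 0.33, only-B 0.07 —
  the published partition (4979 / 9109 / 1864) over ~27.7k genes.
* **Counts.** Per peak, a latent wild-type intensity (lognormal around
  `mean_depth`, CV ≈ 0.53 across peaks) shared by both replicates;
  counts are negative binomial with size = `dispersion` (default 100,
  i.e. ~12 % extra-Poisson noise at depth 200 — chosen to reproduce the
  high replicate concordance of the real data; the exact value is a
  free parameter, not an estimate). `Inf` gives Poisson. Mutant means
  are multiplied by a per-peak retention factor drawn from a
  configurable mixture; the default 70 % at 1.0 / 30 % U(0.1, 0.6)
  describes a strong-loss mutant. Reads (100 bp, the platform's read
  length) are placed uniformly within peaks.
* **Peak-caller dropout.** A sample's called peak list keeps template
  regions with count ≥ 10, so strongly reduced mutant peaks vanish from
  the mutant peak set as they do in real peak calling — this exercises
  the WT-only retention rule.
* **Expression.** Co-marked and only-B genes are drawn mostly below the
  FPKM > 5 threshold; 60 % of only-A genes above it (the published
  fraction of transcriptionally active only-H2AK121ub genes). Genes
  with retention ≤ 0.6 are flagged differentially expressed
  (upregulated, |log2 FC| > 1) with probability 0.5, emulating
  derepression and feeding the DEG-exclusion rule.
* **Determinism.** Every stage reseeds from `seed` plus a fixed offset;
  identical configurations give byte-identical output files.

What passing tests on this generator do **not** show: robustness to
mappability artifacts, input/background structure, overlapping gene
models, fragment-length effects, or peak-caller boundary noise — none of
which the generator produces.

# Problem sizes and defaults

The validation scenarios are desk-scale by design: 2,000 peaks at mean
depth 200 with a 1.5× library imbalance for the bias-correction
property; 1,000 peaks at depth 100 for retention recovery; 1,000 null
trials of 500 shuffles for permutation calibration. Metagene grids
default to 100 body bins and 1-kb/50-bin flanks (figure axes of the
source analysis imply scaled bodies but no bin counts); coverage bins
default to 10 bp; heatmap rows order by descending total signal. Band
edges for expression (0, 1, 5, 25, 100) are explicit configuration and
are an invented default — the source figures do not print theirs.

# Known limitations

* The binomial read-allocation test treats reads as independent;
  overdispersion beyond the rescaled null inflates significance at very
  high depth. The percent-of-WT classes, which gate every downstream
  claim, are unaffected.
* Mutant-only peaks are invisible to a single comparison direction.
* The crosstab's row universe defaults to all co-marked genes; a
  significant-only mode is provided (`mode = "significant"`).
* The shuffle null allows shuffled peaks to overlap; fragmented,
  highly-clustered region classes with near-saturating peak densities
  would need an exclusion-aware null.
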