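---
title: "Methods: ceRNA triplet inference and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA triplet inference and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAsponge)
```

## The model

Competing endogenous RNAs (ceRNAs) are transcripts — lncRNAs, circRNAs,
or other mRNAs — that share miRNA binding sites with an mRNA and can
titrate ("sponge") the shared miRNAs away from it. Under the ceRNA
hypothesis, a genuine (ceRNA, miRNA, mRNA) triplet should show three
signatures at once in expression data:

1. **Targeting with repression.** The miRNA has predicted binding sites
   on both the ceRNA and the mRNA, and is negatively co-expressed with
   each of them (Spearman rank correlation SCC < −0.7, strict).
2. **Co-expression of the competitors.** The ceRNA and the mRNA, being
   pushed by the same repressor, are positively co-expressed (Pearson
   correlation PCC > 0.9, strict).
3. **Shared-sponge enrichment.** The two transcripts share more
   regulator miRNAs than chance predicts. With a universe of $U$ miRNAs,
   of which $M$ regulate gene $A$ (set $C$), $N$ regulate gene $B$ (set
   $D$) and $x$ regulate both, the upper-tail hypergeometric probability

   $$P(X \ge x) \;=\; \sum_{k=x}^{\min(M,N)}
     \frac{\binom{M}{k}\binom{U-M}{N-k}}{\binom{U}{N}}$$

   must fall below 0.05 (strict, uncorrected — the selection rule is a
   raw p-value; `assemble_triplets()` exposes the threshold should a
   user want to BH-adjust externally).

All three gates are applied to features that individually pass the
differential-expression gate: fold change ≥ 2 (inclusive, i.e.
|log2FC| ≥ 1, condition B vs A with pseudocount 1) and BH FDR < 0.05
(strict). A triplet is emitted per (ceRNA, miRNA, mRNA) combination; the
sponge test is computed once per (ceRNA, mRNA) pair and attached to each
of its triplets.

### Numerical notes

The sponge tail is computed from binomial coefficients directly whenever
they fit in double precision (which makes small cases exactly the
rational enumeration probability, e.g. $P = 1/20$ at $x=M=N=1$, $U=20$
— relevant because the 0.05 threshold is strict), falling back to
log-space accumulation of `lchoose` terms for large universes.
Correlations are delegated to `stats::cor`; zero-variance input has no
defined correlation and is returned as `NA`, which never passes a gate.
$U$ defaults to the number of miRNAs left after DE filtering — our
reading of "all the miRNAs in the work" — and is configurable.
Correlations are computed on log2(CPM + 1) across all samples of both
conditions jointly: with three replicates per condition that is the only
interpretation leaving n ≥ 3, and it is the scale on which the DE test
also operates.

## Upstream components

**Differential expression.** No specific test engine is prescribed for
this workflow, so the package uses a deliberately transparent one:
per-feature Welch t-tests on log2(CPM + 1), BH-adjusted. This is a
documented extension point — the gate semantics (`call_de()`), not the
engine, are the fixed contract. A consequence worth knowing: CPM is a
compositional normalization, so heavily unbalanced differential
expression shifts library sizes and can bias fold changes (no
TMM/median-of-ratios correction is applied).

**Target prediction.** Canonical seed matching in the TargetScan
taxonomy: a site locus is a match to the reverse complement of miRNA
positions 2–7 on the target, classified as 8mer / 7mer-m8 / 7mer-A1 /
6mer by the position-8 match and the A opposite position 1, strongest
type per locus. Whole transcripts are scanned (lncRNA/circRNA "targets"
have no annotated UTR). The default floor of 7mer-m8 trades sensitivity
for precision at desk scale; thermodynamics, conservation and
non-canonical sites are out of scope.

**Small-RNA tag handling.** Raw tags are filtered by, in order: mean
quality ≤ 20 (only when quality is supplied — tag-level FASTA carries
none; whether the rule is per-base or per-read is ambiguous in the
protocol and we chose the mean), adapter presence, length < 18 nt, and
polyA. "polyA" is defined here as ≥ 80% A — no fraction is standard, and
this catches homopolymer artifacts without discarding A-rich miRNAs.
Multi-database annotation is resolved by the fixed priority
rRNA-like > exist miRNA > exist miRNA edit > known miRNA > repeat >
exon > novel miRNA > intron, with unmatched tags recorded as `unann`;
the databases themselves are not queried — membership flags are inputs.

**Positional lncRNA classes.** Candidates are labelled relative to
protein-coding models by strict precedence: sense-overlapping (same
strand, ≥ 1 bp exonic overlap), intronic (same strand, span inside one
intron), antisense (opposite strand, any span overlap), bidirectional
(no overlap, opposite-strand TSS within a window), else intergenic. The
window defaults to 1,000 bp, a common divergent-promoter definition; the
TSS is the span start on `+` and the span end on `-`. Opposite-strand
intron containment deliberately falls to antisense — the precedence
order is the rule, so every candidate gets exactly one label and
permuting the reference list cannot change it. Setting the window to 0
converts exactly the bidirectional calls to intergenic.

## What the synthetic scenarios emulate

`generate_scenario()` builds the whole input bundle — counts for the
four classes, DNA FASTA, GTF, ground truth — from a seed, emulating the
3-vs-3 broody/laying ovary design (and scaled-up versions of it):

* counts are negative binomial with per-sample log-normal(0, 0.1)
  library factors per class; decoys draw log-normal feature means around
  `base_mean` (default 200, dispersion default 0.1);
* each planted triplet's miRNA gets a ±`de_log2fc` group shift on the
  log2 scale plus N(0, 0.25) per-sample biological noise; directions
  alternate in pairs so both ceRNA classes stay balanced and CPM
  composition is not distorted;
* its two targets' means are multiplied by
  $\exp(-\text{coupling\_strength}\cdot z)$, $z$ the standardized miRNA
  signal — producing the monotone negative miRNA–target and positive
  ceRNA–mRNA associations the filters assume;
* planted targets carry one 8mer site for their miRNA (300 nt
  transcripts); decoy sequences are screened free of every planted
  miRNA's seed core, and miRNA seeds are drawn mutually compatible so a
  planted site can never embed a foreign core;
* transcript models place lncRNAs round-robin into all five positional
  classes around two-exon coding genes spaced 10 kb apart.

The generator is deterministic given the seed, and
`write_scenario()` / `load_scenario()` round-trip it exactly through
plain-text formats.

What it does **not** emulate — and therefore what passing tests do not
demonstrate about real data: sequencing-error and read-level effects,
compositional library biases beyond the log-normal factors, correlated
decoys (co-regulation modules), multi-miRNA targeting of one transcript,
isoform ambiguity, and real seed-site statistics (decoys are actively
scrubbed, so target-prediction specificity is by construction, not an
empirical finding).

## Validation design and problem sizes

The test-suite checks pair each computation with an independent oracle:
exhaustive enumeration for the hypergeometric tail (every admissible
$(x, M, N, U)$ with $U \le 12$) and the annotation priority (all 255
subsets), textbook-formula re-implementations for Pearson/Spearman and
the $O(m^2)$ step-up definition for BH (1,000 random vectors each), a
hand-drawn ten-transcript interval fixture for the positional
classifier, and the printed 25-gene association table for the
candidate-subnetwork counts (THBS1 + MYLK → 2 mRNA, 5 miRNA, 18 lncRNA,
4 circRNA).

The stochastic suites run at 20 replicates per condition, dispersion
0.05: a null design (no coupling, no planted DE, 2,000 features split
1000/500/400/100 across mRNA/lncRNA/circRNA/miRNA) that must show a
~5% raw type-I rate, no joint-gate calls and no triplets; and a recovery
design (30 planted triplets at coupling 2.0 over a 300-feature decoy
background split 60/80/80/80 miRNA/mRNA/lncRNA/circRNA, ten seeds) that
must recover the planted triplets with median recall and precision
≥ 0.8. These sizes keep each suite under a few minutes on one CPU while
leaving the correlation filters well inside their informative regime.
The demo workflow under `analysis/` uses the same recovery design at 10
replicates per condition.

## Known limitations

* The DE engine is a per-feature Welch t-test: no dispersion shrinkage,
  no compositional correction — at 3-vs-3 its power is limited, and the
  published DE counts from the motivating study depend on tooling and
  raw data outside this package's scope.
* The sponge universe $U$ materially changes small-overlap p-values
  (x = M = N = 1 is significant only for U > 20); treat cross-study
  comparisons of triplet counts with care.
* Correlation gates at |SCC| > 0.7 / PCC > 0.9 are very strict at small
  n; with 3 replicates per group (6 samples) rank correlations take few
  distinct values and the gates behave almost combinatorially.
* The positional classifier trusts the supplied models; it does not
  assemble transcripts or assess coding potential.
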