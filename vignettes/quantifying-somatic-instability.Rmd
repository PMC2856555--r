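---
title: "Quantifying tissue-specific CAG repeat instability and modeling it from gene expression"
author: "RepeatInstability authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tissue-specific CAG repeat instability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RepeatInstability)
```

# Background

Expanded trinucleotide repeats, such as the CAG tract responsible for
Huntington's disease, change length somatically in a strongly
tissue-specific way: in knock-in mouse models the striatum accumulates large
expansions while tissues such as heart, lung or testis remain essentially
stable.  Because disease severity tracks repeat length, the machinery behind
this tissue specificity is of direct therapeutic interest.  This package
implements a quantitative toolkit for studying it:

1. an **instability index** computed from fragment-analysis (capillary
   electrophoresis) peak traces with a relative peak-height threshold;
2. a **synthetic-data generator** producing ground-truthed repeat-length
   distributions, rendered peak traces and expression matrices;
3. a **gene-expression signature model** (correlation-ranked forward
   selection + partial least squares regression) predicting tissue
   instability from expression;
4. **continuous-phenotype gene set enrichment** with a phenotype-permutation
   null.

# The instability index

PCR across a repeat tract yields a cluster of peaks one repeat unit apart.
The boundary between signal and PCR noise is not sharp, so each analysis is
background-corrected with a *relative peak-height threshold*: the cutoff is
a fixed fraction (default 20%) of the tallest peak in that same analysis,
and everything below it is discarded.  The surviving peaks are anchored to
the *main allele* — the tallest peak of the same animal's tail trace, the
constitutive repeat length — giving each peak a signed repeat change
$\Delta$.  The index is the normalised, height-weighted mean change:

$$ I \;=\; \sum_{\Delta} \frac{h_\Delta}{\sum_{\Delta'} h_{\Delta'}}\;\Delta, $$

interpretable as the mean repeat-unit change per cell.  A height-symmetric
trace gives exactly zero; expansion-biased tissues give positive values.
Because both the threshold and the normalisation are relative, the index is
invariant to uniform height scaling, i.e. to the amount of template DNA.

The same thresholded, anchored ladder supports the companion metrics:
expansion and contraction indices (the $\Delta>0$ / $\Delta<0$ parts of the
same sum — we use the shared denominator so they add up to the index
exactly), above-threshold peak counts, the percent composition of
contracted/unchanged/expanded signal, and the main-allele shift (the
$\Delta$ of the tissue's tallest peak).  A small-pool variant computes the
analogous index from single-molecule repeat-length frequency distributions,
with distances taken from the modal length.

```{r index-example}
ladder <- RepeatLadder(delta = c(-1, 0, 1, 2),
                       height = c(300, 1000, 500, 250))
instabilityIndex(ladder, thresholdFactor = 0.20)
expansionContractionIndices(ladder)
composition(ladder)
```

## Parameters that matter

* `thresholdFactor` (fraction of the tallest peak, default **0.20**): a
  conservative cut that keeps only well-measured peaks and is robust to
  amplification variation; 0.10 or 0.05 quantify more sensitively when
  signal is strong.  The tail trace receives the same correction before
  main-allele detection (harmless: the maximum always survives).
* `unitSpacing` (bp per repeat, default **3.0**) and `tolerance` (default
  **1.0 bp**, strictly below half the spacing): peaks are assigned
  $\Delta = \mathrm{round}((size - size_{main})/spacing)$ and rejected when
  their residual from the ideal rung exceeds the tolerance.  An optional
  one-pass least-squares recalibration (`recalibrate = TRUE`) re-estimates
  spacing for traces with electrophoretic mobility drift.
* Ties: an exact height tie for the tallest peak resolves to the smaller
  fragment size (the constitutive allele precedes its expansion products);
  two peaks rounding to the same rung are treated as a split peak and
  summed.

Degenerate inputs are hard errors (empty traces, empty ladders), not silent
zeros; off-ladder peaks and negative-height rows are dropped with counted
warnings.

# The synthetic-data generator

Every downstream module is validated against simulated data with exact
ground truth.

**Somatic distributions.** The per-cell repeat-change distribution is a
closed-form mixture: a point mass at $\Delta=0$, a geometric expansion tail
over $\Delta \ge 1$ (decay `tailShape`) scaled to contribute exactly
`expansionRate` to the mean, and a contraction mass split 2:1 over
$\Delta\in\{-1,-2\}$.  The exact mean
$\mu = expansionRate - \tfrac43\,contractionMass$ is recorded on the object,
so recovery can be scored without Monte-Carlo error.

**Trace rendering** emulates the two artifacts that shape real traces:
PCR stutter, modelled as a minus-one-dominant geometric slippage kernel
(mass $\propto ratio^{k}$ at $-k$; the kernel sums to one, conserving
signal), and the amplification advantage of shorter alleles, a per-repeat
weight $(1+ampBias)^{-\Delta}$.  Heights are scaled by a template-amount
factor and optionally perturbed by zero-truncated Gaussian noise.  With
stutter, bias and noise disabled the rendered trace is exactly proportional
to the distribution, so the measured index equals the true mean — the
simulator identity exploited by the test suite.

Defaults (`stutterRatio = 0.15`, `ampBias = 0.01`) were fixed once so that
the bundled 17-tissue preset panel, rendered and quantified with the default
20% threshold, spans the range observed in knock-in mice (striatum ≈ +6.4
down to ≈ −1.0 in the most stable tissues).  Two facts discovered during
that calibration are worth recording.  First, heavier stutter or bias makes
high indices unreachable: the relative threshold is set by the tallest peak,
and once the contraction/stutter peak dominates, the long expansion tail
falls below 20% of it and is discarded wholesale.  Second, measured indices
are *not* the distributions' true means — thresholding truncates the tail
and stutter/bias drag the trace toward contraction, exactly as on real
traces; stable tissues read negative for this reason.  The presets therefore
store per-tissue `expansion_rate`/`contraction_mass` values obtained by root
finding on the full render-and-quantify pipeline against literature-scale
per-tissue targets.  The contracted-cell fraction is 0.15 for most tissues,
0.05 for the two strongly expanding ones (expansion leaves few unchanged
cells) and larger in stable tissues, whose negative readings the model
attributes to contraction plus PCR artifact.

**Expression matrices** are simulated directly at normalised log2 scale
(array preprocessing is out of scope): probe baselines $\sim N(8,1)$; a
planted signature subset responds linearly to the tissue's true index with
slope `effectSize` (default **0.25** log2 units per index unit, random sign
per probe) plus i.i.d. residual noise (`noiseSd`, default **0.25** —
chosen as a realistic per-array replicate SD that still leaves planted
probes separable from the best of 20,000 null probes at $n = 32$ arrays).
Replicates share their tissue's true index as phenotype.  Planted probe
identities and slopes are stored in the object metadata.

What the generator does **not** emulate: probe-level cross-hybridisation,
correlated probe blocks other than the planted signature, batch effects,
age/genetic-background differences between the expression source and the
instability measurements, and mobility curvature in electrophoresis.
Passing tests therefore demonstrate correctness of the computations and
recoverability under idealised noise, not robustness to every artifact of
real arrays or real traces.

# The signature model

Training samples are tissues with a measured instability index (two
expression replicates each by default).  The pipeline is:

1. **Rank** all probes by the two-sided p-value of their Pearson correlation
   with the phenotype (equivalently by $|r|$; ties break by probe id;
   zero-variance probes are flagged and ranked last).  Correlation is used
   *only* for ranking — the regression consumes raw expression values.
2. **Forward selection**: for each candidate signature size $n$ in
   `nGrid` (default 5, 10, 25, 50, 75, 100, 150, 200, 300, 500), estimate a
   leave-one-tissue-out RMSEP.  The cross-validation unit is the tissue —
   both replicates are held out together, since replicates of one tissue are
   not exchangeable with other samples.  Probes are **re-ranked within every
   fold** on the retained samples only; without this, probe selection sees
   the held-out tissue and the curve is optimistically biased.  (The biased
   global-ranking variant is available as `rerankInFolds = FALSE` for
   comparison.)  The held-out predictions are exposed so the honesty
   property — a tissue's prediction never depends on its own phenotype — is
   testable directly.
3. **PLS regression** (univariate response, NIPALS) with predictors and
   response mean-centered only; no unit-variance scaling, matching the
   common default for expression data where the log2 scale is already
   comparable across probes.  The component count is chosen per fit by an
   inner leave-one-tissue-out RMSEP over 1..`maxComponents` (default cap
   10); requests beyond the rank of the centered data are reduced with a
   warning.  With a full-rank component set PLS1 coincides with ordinary
   least squares, which the test suite uses as an independent oracle.
4. **Final fit** on all training samples at the CV-minimising size (ties to
   the smaller size), with coefficients exported to original probe space so
   prediction is a single linear map; models serialise to JSON and
   round-trip exactly.

On the default planted-signature simulation (16 tissues × 2 replicates,
20,000 probes, 150 planted), the CV curve attains its minimum at the planted
size, all planted probes are recovered, and held-out tissues are predicted
with correlation above 0.99; a phenotype permuted across tissues before the
whole pipeline yields no predictive skill.  These problem sizes are the
package's standard validation conditions and run in well under a minute.

# Enrichment analysis

Pathway-level association with instability uses the weighted running-sum
enrichment statistic on the signed correlation ranking: walking the ranking
from most positively to most negatively correlated, members of a set add
$|r|^{w}/\sum_{hits}|r|^{w}$ (default $w=1$) and non-members subtract
$1/(N-K)$; the enrichment score is the signed extremum.  At $w=0$ this is
the classic Kolmogorov–Smirnov statistic, which the tests verify
exhaustively on small universes.

Significance is by **phenotype permutation**: the per-tissue instability
values are permuted across tissues (replicates carry their tissue's value as
a block, preserving the replicate structure — gene permutation would break
inter-probe correlation and is deliberately not offered).  Per set,
$NES = ES / \overline{|ES_{null}|}$ over same-signed null scores, and the
nominal p is the same-signed exceedance fraction with a +1 pseudocount so
finite permutation counts never report zero.  Sets are intersected with the
expression universe and filtered to 15–500 members by default; gene-symbol
sets expand to probes via an annotation table, each gene contributing all
its probes.

A numerical limitation worth knowing: with few tissues, *near-tied
phenotype values create permutation quasi-symmetries*.  In the preset panel
the two strongly unstable tissues dominate the phenotype's variance, and
roughly 1/120 of permutations keep them on top, reproducing the observed
ranking almost exactly; the attainable nominal p for a strongly coherent set
is then floored at a few times $1/120$ regardless of how real the signal
is.  The calibration suite therefore runs its power check on a
well-separated phenotype spanning the same range, where the planted set
reaches p < 0.01 at 1,000 permutations, and the null check confirms the
p < 0.05 fraction stays within Monte-Carlo error of 5%.

# Design choices made where the design was open

* **Shared denominator** for expansion/contraction indices (the sum over
  *all* above-threshold peaks), so additivity with the instability index is
  exact by construction; renormalising within each subset would break it.
* **Anchoring** always uses the tail main allele, even when the tissue's
  tallest peak has shifted; the shift is reported separately.  Anchoring to
  the tissue mode is available as an explicit alternative workflow (build
  the ladder against the tissue's own mode) but is not the default.
* **Tissue-level cross-validation** rather than per-sample: replicates of a
  held-out tissue must leave together or the fold leaks its identity.
  Per-sample folds remain available (`foldBy = "sample"`).
* **Fold-internal re-ranking** is the default because the alternative is
  measurably optimistic; both modes are implemented.
* **Geometric stutter kernel** with a configurable (default zero) plus-one
  component: minus-one slippage dominates in practice, and the contraction
  bias it induces is the accepted explanation for stable tissues reading
  negative.
* The **command-line entry point** (`inst/cli/repeat-instability.R`) is a
  thin dispatcher over `cmdQuantify()`, `cmdSimulate()`, `cmdTrain()`,
  `cmdPredict()` and `cmdGsea()`; every run writes a `run_config.json` echo
  so outputs are self-describing.

# Known limitations

* Raw electropherogram (.fsa) decoding, dye calibration and size-standard
  fitting are upstream of this package; sizes are assumed assigned.
* The small-pool module consumes tabulated molecule counts; Poisson
  dilution planning for single-molecule PCR is out of scope.
* The instability index deliberately summarises the bulk of the
  distribution; rare large expansions visible to single-molecule methods
  are below its sensitivity.
* Nominal enrichment p-values only; no FDR across sets.
* With strongly degenerate phenotypes the permutation p floor discussed
  above applies to any phenotype-permutation method, including this one.
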