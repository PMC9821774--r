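---
title: "Inferring circRNA–miRNA–mRNA sponge networks from multi-tissue counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring circRNA–miRNA–mRNA sponge networks from multi-tissue counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAsponge)
```

## The scientific problem

Competing endogenous RNA (ceRNA) regulation rests on shared miRNA response
elements: a circRNA that binds ("sponges") a miRNA derepresses that miRNA's
mRNA targets. In expression data this leaves a characteristic signature —
the miRNA is *negatively* co-expressed with both the circRNA and the mRNA,
while the circRNA and mRNA are *positively* co-expressed — and the two
transcripts share more common miRNA regulators than chance would allow.

`ceRNAsponge` implements this inference chain for a two-condition,
multi-tissue design such as a heat-stress study of the
hypothalamic–pituitary–mammary (HPM) axis in dairy cattle: a non-heat-stress
(NHS) control group and a heat-stress (HS) group, three tissues, small
numbers of biological replicates. Heat exposure itself is characterised by
the temperature–humidity index,

$$\mathrm{THI} = (1.8\,T + 32) - (0.55 - 0.55\,\mathrm{RH})\,(1.8\,T - 26),$$

with $T$ in °C and $\mathrm{RH}$ a relative-humidity fraction.
`computeTHI()` treats RH as a fraction in $[0,1]$: with RH as a raw percent
the formula produces absurdly negative values far outside the range the
index is defined on (roughly 40–100), so percent inputs are auto-scaled
with a note.

## The inference chain

For each tissue, the pipeline executes four stages, all with *strict*
decision thresholds (a value sitting exactly on a threshold is excluded):

1. **Differential expression per RNA class.** A feature is significant if
   its fold change satisfies $|\log_2 \mathrm{FC}| \ge 1$ **and** its
   probability gate holds: $p < 0.05$ for circRNAs and miRNAs, but
   $\mathrm{FDR} < 0.05$ (Benjamini–Hochberg within the tissue × class
   stratum) for mRNAs — mRNA features are far more numerous, and the FDR
   gate keeps their false-discovery burden comparable.
2. **Negative miRNA–target co-expression.** Among *predicted* miRNA–target
   pairs whose two members are both significant, keep those with Spearman
   rank correlation $\rho < -0.7$ across all samples of the tissue.
3. **Positive circRNA–mRNA co-expression.** Candidate circRNA–mRNA pairs
   are those sharing at least one common miRNA among the retained negative
   pairs; a candidate is kept if its Pearson correlation $r > 0.9$.
4. **Shared-sponge significance.** For a kept pair, let $K$ and $n$ be the
   sizes of the circRNA's and mRNA's retained miRNA sets, $k$ their
   overlap, and $N$ the miRNA universe size. The pair is retained if the
   hypergeometric upper tail $P(X \ge k)$ is below 0.05.

Retained edges are assembled into a typed tripartite `CeRNANetwork`
(circRNA, miRNA, mRNA nodes; `circ_mirna`, `mirna_mrna`, `circ_mrna`
edges), with every `circ_mrna` edge carrying its shared-miRNA witnesses.
`auditNetwork()` re-validates all construction rules on the finished
object, and the pipeline refuses to emit a network that fails its own
audit.

### The differential-expression test

Published analyses of this kind typically run edgeR; its exact settings
(normalization, dispersion handling, test variant) are rarely stated. This
package instead ships a fully specified, oracle-checkable exact test of the
same shape, so that every number it produces can be re-derived
independently:

* **Normalization** is plain counts-per-million (`normalizeCPM()`); fold
  changes are $\log_2$ ratios of group-mean CPM with a pseudocount
  (default 1) for stability at zero.
* **Library equalization**: counts are rescaled to the geometric-mean
  library size and rounded (`equalizeLibrarySizes()`), so all samples share
  one effective depth.
* **Dispersion** is a single value per tissue × class, maximizing the
  conditional (Dirichlet-multinomial) likelihood of within-group counts
  given group totals — the group mean cancels under equal library sizes,
  which is what makes per-feature terms poolable. The search is a
  golden-section optimization of the profile log-likelihood over
  $\phi \in [10^{-4}, 10]$ on the log scale.
* **The test** conditions on a feature's total pseudo-count $t$ and
  evaluates the negative-binomial probability of every split of $t$
  between the two groups (group sums of i.i.d. NB variables are NB). The
  two-sided p-value is the *minimum-likelihood* sum — the total probability
  of all splits at most as likely as the observed one — which is
  well-defined for asymmetric discrete distributions; a relative tie
  tolerance of $10^{-7}$ guards floating-point ties. At dispersion 0 the
  conditional law collapses to a Binomial$(t, n_1/(n_1+n_2))$ split, which
  is how the implementation is checked against exact rational enumeration.

This test is *not* a numerical replica of edgeR; it is the package's own
DE procedure with the same decision-rule shape.

### Numerical choices

* Spearman uses mid-ranks (average ranks for ties) — with integer counts,
  ties are routine. A constant expression vector makes a correlation
  undefined; such pairs are excluded and counted, never scored 0, because
  0 would silently pass no threshold while misrepresenting undefinedness.
* Pearson for circRNA–mRNA pairs is computed on $\log_2(\mathrm{CPM}+1)$
  — the standard co-expression scale; raw-count Pearson is dominated by a
  handful of extreme values. Spearman is computed on CPM (it is invariant
  to the log anyway).
* Correlations pool both conditions of a tissue (the default): the
  condition contrast is itself a genuine part of the co-expression signal.
  A `correlationPooling = "within"` switch computes per-condition
  coefficients and keeps the one closest to zero (a pair then passes only
  if it passes in *every* condition); this stricter alternative is exposed
  without a claimed empirical basis.
* The hypergeometric tail is summed in log space (`lchoose` +
  log-sum-exp), stable for large universes; it matches exact rational
  enumeration to $<10^{-12}$ on all configurations with $N \le 12$.
* The miRNA universe $N$ defaults to the distinct miRNAs of the
  interaction table that are DE-significant (`universeMode = "de"`), which
  makes the test self-contained; `"interactions"` and `"profiled"` are
  available. Note a structural consequence: with a single shared miRNA
  ($k = K = n = 1$) the tail is $1/N$, so no sponge edge can pass
  $p < 0.05$ unless $N > 20$. Small DE-miRNA universes therefore produce
  empty networks *by design*, not by accident.
* Sponge p-values are gated raw by default; BH adjustment is available
  (`adjustSponge = TRUE`) and flagged in the output, but off, matching the
  raw-p convention for this step.
* Serialization is deterministic: nodes sorted by (type, id), edges by
  (type, endpoints) — networks can be diffed and hashed.

## The synthetic-data generator

Real studies of this design deposit raw reads; re-quantifying them is out
of scope here. Instead, `simulateCounts()` emulates the *statistical*
structure the inference chain assumes, with a ground-truth ledger for
benchmarking:

* **Design**: 3 tissues × {NHS, HS} × 3 replicates by default (18
  samples), sample IDs like `NHS_H1` … `HS_M3`.
* **Counts**: negative binomial around log-normal baseline means
  (`meanlog = 6`, `sdlog = 1` — several hundred counts for a typical
  feature, so correlation estimates are not drowned by shot noise), one
  class-level dispersion (0.1), and per-sample library-size factors
  uniform in ±20% of nominal depth — enough to exercise normalization
  without dominating it.
* **Planted DE**: a fraction (default 10%) of features per class get a
  planted $|\log_2\mathrm{FC}|$ of 2.5, applied as $\pm\mathrm{lfc}/2$ in
  the two conditions with balanced up/down directions. The symmetric split
  and balanced directions keep library composition comparable between
  conditions — with one-sided effects, CPM normalization would bias *all*
  fold changes toward zero (the classic composition problem that TMM-style
  normalization addresses and plain CPM cannot).
* **Planted triads**: each triad (circRNA, miRNA, mRNA) shares a
  per-sample latent factor on the log-mean scale — positive sign for the
  circRNA and mRNA, negative for the miRNA — scaled by
  `couplingStrength * latentScale` (`latentScale = 1.5`). The latent is
  *uniform* (variance 1, bounded): a Gaussian's heavy multiplicative tail
  lets single samples dominate group means and destroy fold-change
  estimates at amplitudes that rank correlations need. The multiplier is
  mean-centred so baselines keep their meaning. Triad circRNA and mRNA
  also carry condition effects opposite in sign to their miRNA, the
  expression signature sponge regulation predicts.
* **Interactions**: all planted miRNA→target edges plus decoy edges
  sampled at `interactionDensity` (default 0.05) among non-planted
  combinations.

At `couplingStrength = 1` with 50 replicates, planted miRNA–target pairs
show Spearman $< -0.7$ in well over 95% of triads — the generator's own
coupling target, verified in the test suite.

What the generator does *not* emulate: read-level artefacts (no FASTQ, no
alignment or back-splice detection), between-tissue correlation of the
same animal, batch effects, trended or feature-specific dispersion, and
annotation errors in the interaction table. Passing tests therefore
demonstrate the *inference chain's* correctness and calibration under its
own assumptions, not robustness to everything real data can do.

## Problem sizes and verification

The package's checks run at desk scale, chosen so the full suite completes
in minutes while keeping binomial standard errors informative:

* oracle sweeps: all hypergeometric configurations with $N \le 12$; all
  binomial splits with totals $\le 30$;
* null calibration and dispersion recovery: 2000 features per class,
  3 vs 3;
* planted-triad recovery: 30 triads, coupling 0.95, 20 replicates per
  condition, decoy density 0.05, single tissue; the matching no-triad
  null over 20 seeds.

Under these conditions the rejection rate of the exact test on null data
sits near 4.9% (the minimum-likelihood two-sided p is mildly conservative
on discrete data), the dispersion estimate lands within a few percent of
the truth, recovery of planted triads is ≥ 90% with precision 1, and null
runs emit no triads. `scripts/acceptance.R` recomputes all of these from
scratch.

## Known limitations

* The DE stand-in does not reproduce any specific edgeR version's numbers;
  replicating a published study's DE counts additionally requires its raw
  reads and upstream settings.
* Plain CPM normalization is composition-sensitive; strongly asymmetric DE
  in small feature classes (especially miRNA panels) biases fold changes.
* With few DE miRNAs the hypergeometric gate cannot fire (see above);
  interpret empty networks accordingly.
* Correlation thresholds at $n = 6$ samples (3 vs 3) sit on a coarse
  discrete null; the −0.7/0.9 defaults are usable but unforgiving at such
  depths, and more replicates help far more than looser thresholds.
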