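# ceRNAsponge

Inference of circRNA–miRNA–mRNA competing-endogenous-RNA (ceRNA) networks
from multi-tissue, two-condition RNA-seq count matrices — with a seeded
synthetic-data generator that plants ground-truth sponge triads for
benchmarking.

## Who this is for

Transcriptomics analysts who have circRNA, miRNA and mRNA count matrices
from a control-vs-treatment design (the motivating setting is heat stress
across the hypothalamic–pituitary–mammary axis of dairy cattle: NHS vs HS
groups, three tissues, three biological replicates each) plus a table of
predicted miRNA→target interactions, and who want the standard
correlation-plus-hypergeometric ceRNA construction as tested, auditable,
reproducible code rather than a one-off script.

## The method

Per tissue, with every threshold a *strict* inequality:

1. **Differential expression** per RNA class, using the package's exact
   conditional negative-binomial test (CPM normalization, geometric-mean
   library equalization, one conditional-likelihood dispersion per class,
   minimum-likelihood two-sided p). Gates: |log2FC| ≥ 1 and p < 0.05 for
   circRNA/miRNA; |log2FC| ≥ 1 and BH-FDR < 0.05 for mRNA.
2. **miRNA–target filtering**: predicted pairs whose members are both DE
   and whose Spearman rank correlation is < −0.7 across the tissue's
   samples.
3. **circRNA–mRNA filtering**: pairs sharing ≥ 1 retained common miRNA,
   kept when Pearson correlation (log2 CPM) is > 0.9.
4. **Shared-sponge test**: hypergeometric upper tail
   P(X ≥ k) for k shared miRNAs given regulator-set sizes K, n in a miRNA
   universe of size N; keep if p < 0.05.

Surviving edges become a typed tripartite `CeRNANetwork` whose structural
constraints (tripartiteness, thresholds, shared-miRNA witnesses) are
re-verified by `auditNetwork()`. `recoveryMetrics()` scores a network
against the generator's planted truth. `computeTHI()` evaluates the
temperature–humidity index
`THI = (1.8·T + 32) − (0.55 − 0.55·RH)·(1.8·T − 26)` used to characterise
heat-stress exposure.

See `vignettes/cerna-network-inference.Rmd` for the model, parameter and
calibration details.

## Worked example

```r
library(ceRNAsponge)

design <- generateDesign(tissues = "mammary_gland", replicates = 20L)
cfg    <- simulationConfig(nTriads = 30L, couplingStrength = 0.95, seed = 42L)
res    <- runPipeline(pipelineConfig(seed = 42L),
                      design = design, simConfig = cfg)

net <- res$networks$mammary_gland
net
#> CeRNANetwork [mammary_gland]
#>   nodes: 29 circRNA, 29 miRNA, 29 mRNA
#>   edges: 29 circ-miRNA, 29 miRNA-mRNA, 29 circRNA-mRNA pairs

recoveryMetrics(net, res$truth)[c("recall", "precision")]
#> $recall
#> [1] 0.9666667
#> $precision
#> [1] 1

anchorReport(net, "ENSBTAG00000000013")
#>               anchor n_circRNA n_miRNA n_circ_mrna_pairs
#> 1 ENSBTAG00000000013         1       1                 1

computeTHI(30, 0.6)   # severe heat load
#> [1] 79.84
```

Reading: of 30 planted sponge triads, 29 were recovered end-to-end
(recall 0.97) and nothing spurious was emitted (precision 1). The anchor
report mirrors the usual single-gene subnetwork summary — here the mRNA is
regulated by one circRNA through one shared miRNA. A THI of 79.84 (30 °C,
60% RH) is well into the heat-stress range; winter conditions evaluate
near 45.

The per-stage manifest (`res$manifest$stages`) records feature counts, DE
calls, pairs tested/retained, the miRNA universe size and audit results
for every tissue.

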