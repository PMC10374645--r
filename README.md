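# EcoStates

Cell-state and multicellular-ecotype immunophenotyping of bulk tumor
transcriptomes, with a planted-truth synthetic cohort generator for
end-to-end validation.

## The problem

A bulk tumor expression profile mixes malignant, immune and stromal cells
in unknown proportions. Beyond composition, two layers of structure carry
clinical signal: within each cell type, patients split into discrete
**transcriptional states** (e.g. fibroblast sub-programs), and states of
different cell types **co-occur** in the same patients, forming
multicellular communities (**ecotypes**) associated with survival and
therapy response. EcoStates is for computational biologists who want that
full inference chain on bulk cohorts as composable, tested R functions.

## The model

With bulk expression `B` (genes x samples) and a signature matrix `S`
(genes x cell types), per-sample fractions `f_s` solve

    min || B[,s] - S f_s ||^2   s.t.  f_s >= 0,  sum(f_s) = 1

Purified per-type expression scales the per-gene fitted level `x_gc` (from
a cross-sample non-negative regression of `B` on the fractions) by each
sample's standardized residual share. Per cell type, z-scored purified
expression split into positive/negative parts `V` is factorized as

    V ~ W H,   W, H >= 0

by multiplicative updates; the rank is chosen where the cophenetic
coefficient of the subsampled-restart consensus matrix is closest to 0.95.
Samples take their most abundant state (argmax of H). The binary assignment
matrix `A` (states x samples, `A_ij = 1` iff state i is assigned to patient
j) yields pairwise Jaccard indices, gated by a one-sided hypergeometric
co-occurrence test (p <= 0.01); average-linkage clustering of the gated
matrix, cut at the silhouette-maximizing k, defines the ecotypes. Held-out
cohorts are projected onto the fixed basis W and recovery of each state is
tested by a marker-permutation z-score (significant: z > 1.65, one-sided
p < 0.05). States and ecotypes are screened one-vs-rest with log-rank tests
and Cox proportional-hazards models, and responder/non-responder benefit is
tested within units.

## Worked example

```r
library(EcoStates)

truth <- generateTruth(seed = 7)          # planted states + communities
truth
#> SyntheticTruth: 600 genes, 3 cell types, 200 samples, 3 communities
#>  states per type: B.cells:2 Fibroblasts:3 Epithelial.cells:4

bulk <- simulateBulk(truth, seed = 8)     # mixed, noisy bulk cohort
signature <- signatureFromTruth(truth)
fractions <- estimateFractions(bulk, signature)
max(abs(exprs(fractions) - truth@fractions))
#> [1] 0.233     # compositions recovered to ~0.2 under 0.5 log2 noise

purified <- purifyExpression(bulk, fractions, "Fibroblasts")
model <- discoverStates(purified, ranks = 2:6, nRestarts = 20, seed = 9,
                        maxIter = 500, tol = 1e-5, nTopGenes = 150)
model
#> StateModel [Fibroblasts]: 3 states, 200 samples
#>  cophenetic trace: 2:0.674 3:0.931 4:0.910 5:0.873 6:0.835
#>  markers per state: 21, 27, 23

assign <- assignStates(model)
adjustedRandIndex(assign@state,
                  truth@sampleStates[names(assign@state), "Fibroblasts"])
#> [1] 0.85
```

The cophenetic trace peaks at the planted rank (3 fibroblast states), each
retained state carries 21–27 marker genes (30 planted), and the discrete
assignments agree with the planted states at ARI 0.85.

`runPipeline()` executes the whole chain (deconvolution, per-type
discovery, ecotypes, survival and benefit screens, enrichment, recovery on
a validation cohort) from one seeded configuration and writes every
artifact plus a manifest; rerunning the same configuration reproduces every
file byte for byte. See the methods vignette
(`vignettes/ecostates-methods.Rmd`) for the model details, parameter
defaults and known limitations.

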