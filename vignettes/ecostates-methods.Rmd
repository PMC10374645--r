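---
title: "Cell states and multicellular ecotypes from bulk tumor transcriptomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell states and multicellular ecotypes from bulk tumor transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

A bulk tumor transcriptome is a mixture: each sample's expression profile
averages over the malignant cells and the immune and stromal populations of
its microenvironment, weighted by their (unknown) proportions. Two layers of
structure are of interest beyond composition. First, within a cell type,
patients split into discrete *transcriptional states* — sub-populations of,
say, fibroblasts that run different programs in different tumors. Second,
states of *different* cell types co-occur in the same patients, forming
multicellular communities ("ecotypes") that associate with prognosis and
therapy response.

EcoStates implements the full inference chain on bulk cohorts:

1. **Deconvolution** — per-sample cell-type fractions by non-negative least
   squares against a signature matrix, and per-type "purified" expression.
2. **State discovery** — consensus non-negative matrix factorization (NMF)
   per cell type with cophenetic-coefficient rank selection, marker
   extraction and state filtering.
3. **State recovery** — projection of held-out cohorts onto the learned
   basis with a permutation test of recovery.
4. **Ecotype discovery** — significance-gated Jaccard co-occurrence of
   discrete state assignments, hierarchically clustered with
   silhouette-width model selection.
5. **Clinical association** — log-rank and Cox proportional-hazards screens
   of states and ecotypes, and responder/non-responder benefit screens.
6. **Enrichment** — hypergeometric over-representation of marker genes and
   preranked GSEA on a signed Wilcoxon rank score.

Because the real cohorts such analyses run on are external and large, the
package ships a first-class synthetic-cohort generator with planted ground
truth; every stage is validated by parameter recovery against that truth.

# The synthetic generator

`generateTruth()` plants, in order: a log-normal baseline expression profile
per gene per cell type (log2 mean 3, sd 1.5 — a microarray-like dynamic
range); disjoint marker-gene blocks per (cell type, state) whose expression
is up-shifted by `effectSizeLog2` (default 2) in their state; community
definitions (community *j* uses state `((j - 1) mod K_t) + 1` of each type
*t*); per-sample community labels and per-(sample, type) states, flipped to
a random other state with probability `communityNoiseRate` (default 0.1);
and Dirichlet cell-type fractions (concentration 2 — substantial
compositional variation across patients, as bulk tumors show).
`simulateBulk()` mixes the per-type state profiles by the fractions and
applies multiplicative log-normal noise (`noiseSdLog2`, default 0.5).
Survival times are exponential with a per-community hazard multiplier;
censoring is an independent exponential whose rate is solved numerically to
hit the requested marginal censoring fraction. Therapy response labels are
assigned 50/50 independently of states, and responders inside designated
benefit states get their hazard multiplied by `benefitHazardReduction`, so
any detected benefit is attributable to the state-response interaction
alone.

What the generator does *not* emulate: batch effects and platform
differences between cohorts, correlated marker programs shared between cell
types, gene-gene correlation beyond the planted states, single-cell data,
and non-proportional hazards. Passing the recovery tests therefore shows
that the chain of estimators is consistent under its own generative
assumptions — not that those assumptions hold for any particular real
cohort.

Two deliberate sizing rules in the validation cohorts: a planted state
count is only *identifiable* when every state is populated, so
rank-recovery experiments use as many communities as the largest per-type
state count; and a community is only *recoverable as an ecotype* when it
owns a distinct state in (nearly) every cell type, so ecotype-recovery
experiments use K equal to the community count in every type. With fewer
communities than states, the surplus states are visited only by noise
flips; with fewer states than communities, two communities share a state
and no hard partition of states can represent both.

# Deconvolution and purification

`estimateFractions()` solves, per sample, a non-negative least squares of
the (linearized) bulk profile on the signature over shared genes
(Lawson–Hanson active set via `pracma::lsqnonneg`) and renormalizes the
coefficients to the simplex. Log2 input is linearized as `2^x - 1`
beforehand; the two encodings give identical fractions.

`purifyExpression()` attributes expression to one cell type. Per gene, the
bulk values are regressed (non-negatively) on the fraction matrix across
samples, giving a fitted level `x_gc` per type. This cross-sample
regression is the engine of type separation: a gene whose variation tracks
a type's abundance is credited to that type. The per-sample purified value
is `x_gc` scaled by the sample's *standardized residual share*: the ratio
of observed bulk to fitted mixture value, with the log-share divided by the
type's mean fraction (a deviation of one type's expression is diluted in
the bulk by roughly that fraction; the exponent is capped at 20 to protect
rare types), then rescaled per gene so the purified sample mean equals
`x_gc` exactly. Without the un-dilution the planted log2 fold-changes of
2.0 appear as ~0.6 in purified space and fall below any sensible marker
threshold; with it they are recovered near 2.0.

Purification also computes a per-gene *type-specificity score*: the
Spearman correlation of the gene's absolute relative residual with the
target type's fraction, contrasted against the best competing type. State
discovery uses this score to choose its gene panel (`nTopGenes`, default
150 in the pipeline): without it, the states of *other* cell types leak
into every purified matrix (the residual is shared), and because state
co-occurrence communities are real structure, the leaked signal makes
over-ranked factorizations spuriously stable.

Genes judged unreliable (fitted level below `minExpression`, or a target
type below `minMeanFraction` mean abundance) are flagged, never dropped.

# Consensus NMF and rank selection

Per cell type, reliable genes are log2-transformed, z-scored, and split
into positive/negative parts, giving a non-negative feature matrix that
preserves signed structure. Factorization uses Lee–Seung multiplicative
updates under the Frobenius loss (RcppArmadillo; objective checked every 10
iterations, non-increasing by construction; convergence at relative change
`tol` or `maxIter`).

Rank selection scans ranks 2..`maxRank`. At each rank, `nRestarts`
(default 20) factorizations are run, each on a random 35% subsample of
samples, and the co-clustering consensus matrix is assembled over
co-present sample pairs (the standard consensus-clustering construction).
The cophenetic coefficient of the consensus — the correlation between
`1 - consensus` and the cophenetic distances of its average-linkage tree —
is averaged over 3 replicate consensus matrices to reduce its variance, and
the rank whose coefficient is closest to 0.95 is selected (ties toward the
smaller rank).

Why subsample at all? With full-cohort, fully-converged restarts the
consensus is essentially binary at *every* rank (multiplicative updates
find the same basin from almost any start), the cophenetic trace hugs 1.0,
and "closest to 0.95" degenerates to "largest scanned rank". Perturbing
each restart by subsampling makes stability informative: the trace peaks
near 0.95 at the planted state count and falls off at over- and
under-fitted ranks. The 35% rate and the replicate count were fixed ex ante
as the configuration under which the trace is discriminative on cohorts of
n = 200; both are exposed as parameters.

The final model refits on the full cohort at the selected rank (best
objective of `nRestarts` restarts, always run to full convergence), with W
column-normalized so the abundance rows of H are comparable.

**Markers.** A gene is a marker of the state where its positive-part basis
loading (row-normalized) is maximal, provided its log2 fold-change — mean
purified linear expression in the state versus all others, pseudocount 1 —
is at least `minLog2FC` (default 1). Argmax candidacy makes marker sets
disjoint across states.

**Filtering.** States with fewer than `minMarkers` (default 10) markers are
dropped. An additional abundance-false-positive proxy — the absolute
Spearman correlation between a state's abundance row and the total purified
signal of non-marker ("background") genes, threshold 0.4 — is implemented
behind `applyAFIFilter` to flag components that capture depth rather than a
transcriptional program. It defaults to **off**: on cohorts with
co-occurrence communities the background totals themselves carry cross-type
community structure, every genuine state correlates with them at 0.4–0.55,
and the filter removes planted states. Remaining abundances are
renormalized so each sample's retained states sum to 1; samples are
assigned their most abundant state (lowest index on ties).

# Recovery in new cohorts

`recoverAbundances()` projects a new cohort onto the learned basis: the new
matrix is standardized with the *discovery* transform parameters over the
genes shared with the model (at least 50% coverage required), and H' is
re-solved jointly on all samples by multiplicative updates with W fixed
(constant initialization — fully deterministic).

The recovery statistic R_s for state *s* is the Pearson correlation between
the discovery marker log2 fold-change vector and the fold-changes of the
same genes recomputed in the new cohort under the recovered assignments —
"the recovered state looks like the discovered state". The null replaces
the marker set by random same-size gene draws from the new cohort
(`nPerm` = 1000 by default); z is the standardized observed value and the
one-sided empirical p uses the add-one rule. A state is significantly
recovered when z > 1.65 and p < 0.05. Permuting gene labels (rather than
samples) preserves the expression distribution while destroying gene
identity; the package treats this as its definition of the recovery test.

# Ecotype discovery

Discrete assignments across cell types form the binary states x samples
matrix A. The Jaccard index of every cross-type state pair is gated by a
one-sided hypergeometric test of co-assignment overlap (population =
samples assigned in both types): pairs with p > 0.01 are zeroed, the rest
keep their Jaccard value. The published description of this gate reads
"set to 1 if P-value was greater than 0.01", which would reward avoidance;
the package defaults to the standard reading and offers the literal one as
`gate = "literal"` for comparison. Same-type pairs are always zeroed
(states of one type are mutually exclusive by construction).

Average-linkage clustering of `1 - gated Jaccard` is cut at the k (2..20)
maximizing the mean silhouette width. Candidate ecotypes with fewer than 3
member states are dismissed. A sample's ecotype abundance is the mean of
the member states' normalized abundances, renormalized across retained
ecotypes; the dominant ecotype is the argmax.

A calibration fact worth knowing when interpreting recovery numbers: with
10% community noise per (sample, type) and 3 cell types, even an *oracle*
that knows every sample's true per-type states recovers the community label
with an adjusted Rand index of only ~0.92 (median over seeds) — flipped
states genuinely vote for the wrong community. Per-type assignment is
itself information-limited by mixing and measurement noise (ARI ~0.85 with
oracle marker panels under the default noise). The pipeline's
dominant-ecotype ARI of ~0.87 sits close to the composition of those two
ceilings.

# Clinical association

Survival machinery is delegated to the `survival` package: `survdiff` for
the Mantel–Cox log-rank statistic (chi-square, g - 1 df) and `coxph` with
Breslow tie handling for hazard ratios (Wald 95% CI; non-convergence,
including separation, is flagged and the estimate marked untrustworthy).
Breslow ties are simpler than Efron's default and adequate for continuous
simulated times; the choice is recorded here because some packages default
otherwise. Screens compare each state or ecotype one-vs-rest; direction is
adverse for HR > 1, favorable for HR < 1; raw p-values at 0.05 by default
(matching common reporting practice for such screens), with a
Benjamini-Hochberg option.

Therapy-benefit screens compare responders versus non-responders *within*
each unit by log-rank; because that test is two-sided, the benefit flag
additionally requires the responders' restricted mean survival time (to the
unit's last follow-up) to exceed the non-responders' — the directional
condition "responders live longer" operationalized.

# Enrichment

Marker over-representation uses the one-sided hypergeometric test against a
user-supplied GMT collection (sets intersected with the universe, then
filtered to 15–500 genes), BH adjustment, and the dual significance rule
p < 0.01 and adjusted p < 0.05; the ten sets with the highest overlap
counts are flagged for display. The rank score for GSEA is
`S = -log10(p) * sign(log FC)` with a two-group Wilcoxon rank-sum p (exact
when sample sizes and ties permit, else normal approximation with tie and
continuity corrections) and a linear fold change with pseudocount 1; the
log base for p is 10 (the score's ordering is invariant to that choice).
GSEA uses the weighted running-sum enrichment score (hit increments
proportional to |S|^weight, weight 1), a gene-label permutation null, NES
normalized by the mean same-sign null magnitude, and add-one empirical p.
Gene-label permutation is much cheaper than phenotype permutation and
adequate for the screening role enrichment plays here.

# Numerical choices and degenerate inputs

* NMF tolerance 1e-6 relative Frobenius change (scan stages may use 1e-5),
  iteration cap 2000; restart sub-seeds derived from the master seed by
  fixed integer arithmetic, so every stage is reproducible from one seed.
* NNLS via Lawson-Hanson; fraction rows renormalized to the simplex;
  all-zero solutions become uniform with a warning.
* Constant consensus dissimilarities define cophenetic coefficient 1 (a
  flat consensus is no evidence of instability), with a warning.
* Empty Jaccard unions are 0; zero-population hypergeometric pairs get
  p = 1 with a warning.
* Ties are always broken toward the lowest index (states, ranks, cluster
  counts, dominant ecotypes), making every argmax deterministic.
* Zero-variance genes are dropped from the NMF transform with a warning;
  constant genes get Wilcoxon p = 1 and rank score 0.

# Problem sizes used by the tests and the acceptance script

The packaged validation runs use cohorts of 200 samples, 600 genes, 3 cell
types with 2-4 states each, 30 markers per state, and rank scans over
2..6 with 20 subsampled restarts x 3 consensus replicates — sizes at which
every recovery experiment completes in minutes while leaving the planted
structure realistically hard (per-type assignment does not saturate). The
acceptance script repeats each experiment over 5 cohorts; the test suite's
end-to-end recovery checks use 10.

# Known limitations

* Purification assumes the signature spans the mixture; unmodeled cell
  types bias both fractions and purified levels.
* The un-dilution exponent (1 / mean fraction) amplifies noise for rare
  types; below ~5% abundance (cap 20) purified state signal degrades
  quickly, and below 0.5% purification is refused.
* The recovery statistic follows marker fold-change correlation; a state
  whose identity rests on down-regulation alone recovers weakly.
* Hard ecotype partitions cannot represent states shared between
  communities; such communities are dismissed by the minimum-size rule
  rather than split.
* Survival screens are marginal (one-vs-rest, single covariate); no
  adjustment for stage, age or other clinical covariates is provided.
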