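---
title: "Profiling gut bifidobacteria from groEL amplicons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling gut bifidobacteria from groEL amplicons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifidoprof)
```

## Why a groEL pipeline

16S rRNA amplicons rarely resolve *Bifidobacterium* below the genus, yet
the ecology of this genus — infant colonisation, diet response, probiotic
niche opportunity — plays out at the species level. The single-copy
chaperonin gene *groEL* diverges fast enough to separate species, so a
*groEL* amplicon (≈460 bp) sequenced alongside 16S gives a species-level
picture of the bifidobacterial community that can be rescaled onto the
whole-community axis. `bifidoprof` implements that workflow end to end:
reference-database construction, taxonomy assignment with a dual-database
arbitration rule, composite species abundances, diversity analyses, and
the covariate-association battery used in population-scale studies of the
genus, plus a synthetic cohort generator so every stage is testable
without any sequence download.

## Reference database construction (`build_refdb`)

The *groEL* amplicon region is located in each genome by in-silico PCR:
the forward primer site and the nearest downstream reverse-complemented
reverse primer site are matched with IUPAC-aware comparison, allowing up
to `max_mismatches` mismatches per primer (default 3, roughly a 10% error
rate on a typical 25-nt primer). Both strands are scanned; reverse-strand
products are re-oriented. Primer bases are removed from the product —
trimming to the insert is the convention of standard read-trimming tools —
and products outside a 350–600 nt window (centred on the ≈460 bp amplicon)
are rejected. When several primer matches overlap, the leftmost forward
match paired with its nearest acceptable reverse match wins and scanning
resumes past the product.

Exact duplicate sequences are collapsed, keeping the first record seen;
the `dedup_map` records every collapse so the provenance of each
representative is auditable. The primer sequences themselves are supplied
by configuration: `default_primers()` is a documented synthetic
placeholder used by the genome simulator, not a published primer set.

Database QC follows the usual marker-database argument: in-group
(*Bifidobacterium*) sequence pairs should be mutually alignable at high
identity while the outgroup (*Lactobacillus*) stays well below. Identity
is defined as matching columns over alignment length of a pairwise global
alignment; the contract is the identity definition, not the aligner, so a
pairwise aligner is used rather than a progressive multiple alignment.
This is quadratic in database size and intended for databases of a few
hundred records.

## Taxonomy assignment (`classify_table`)

ZOTUs (zero-radius OTUs — exact denoised amplicon variants) arrive with
two BLAST-style tabular hit sets: one against a general nucleotide
database ("NT") and one against the *groEL* database ("BIF"). Hits are
screened at e-value ≤ 1e-10, query coverage ≥ 60, percent identity ≥ 75,
and at most 1000 targets per query (kept by bit score); a separate parser
cap of 2000 rows per query guards ingestion. Per database, assignment uses
the top-percent LCA rule: hits below a bit score of 100 are dropped, hits
within 10% of the best bit score are retained, and the assignment is the
longest common prefix of the retained lineages. A minimum-support
parameter common in read-level LCA tools is a no-op at per-ZOTU
granularity and is therefore not exposed.

The two databases are then reconciled per ZOTU by bit-score arbitration,
with `bNT`/`bBIF` the maximum bit scores (absent database → 0):

1. no hits anywhere → discarded;
2. NT lineage outside *Bifidobacterium* and `bNT > bBIF` → discarded
   (the ZOTU is better explained by a non-bifidobacterial source);
3. identical NT and BIF lineages → assigned (`agree`);
4. `bBIF = bNT`, or `bBIF > bNT` but `0.9·bBIF ≤ bNT` → the two scores
   are comparable; the finer-rank lineage wins (rank tie → BIF);
5. `bBIF` dominates (`0.9·bBIF > bNT`) → BIF lineage;
6. `bNT > bBIF` with a bifidobacterial NT lineage → NT lineage, with a
   warning (this branch is not expected to occur in practice).

Two genuinely open readings were settled as follows. "Higher taxonomy
level" in rule 4 is read as the *finer* (more specific) rank: the whole
point of the dual-database design is species-level resolution, and the
coarser reading would make rule 4 discard exactly the information the BIF
database exists to provide. And the minimum-score filter is applied
*before* the top-percent cutoff, the order used by the standard LCA
implementation. Bit scores are compared exactly as parsed — BLAST prints
limited precision, so no epsilon is added.

## Composite species abundance (`composite_abundance`)

Within a sample, a species' share of the bifidobacterial community is its
reads over all reads assigned within the genus; multiplying by the
sample's 16S-derived *Bifidobacterium* fraction places it on the
whole-community scale:

    abundance(s) = reads(s) / reads(genus) × bif16s

Genus-level-only assignments pool into `"Bifidobacterium (unclassified)"`.
Discarded and non-bifidobacterial ZOTUs enter neither numerator nor
denominator — "total bifidobacterial reads" is taken literally. Row sums
therefore equal the 16S fraction exactly (a conservation property the
tests assert to 1e-12), and the result is invariant to rescaling a
sample's read counts. Composite abundances are computed from the
*non-rarefied* table; rarefaction (to 2000 reads, without replacement,
i.e. multivariate hypergeometric, under a recorded seed) is applied only
for alpha- and beta-diversity, and samples under the depth are dropped
with a logged count.

## Diversity

Alpha diversity on the rarefied table: observed ZOTUs, Shannon entropy
with natural logarithm, and Faith's phylogenetic diversity as the branch
length of the minimal subtree connecting the observed tips *including the
path to the root* (the convention of the mainstream amplicon toolchain;
base-2 users can divide Shannon by `ln 2`). Beta diversity: Bray–Curtis on
raw vectors, and Jensen–Shannon divergence on renormalised vectors, again
with natural logarithm and `0·ln 0 = 0`; JSD is reported as the divergence
itself (range `[0, ln 2]`), not its square root.

The adjacent-age trajectory floors ages to integer years (infants below
one year occupy bin 0) and emits Bray–Curtis distances for every cross
pair between bins `a` and `a−1`, with a loess trend over the points. It
operates on species profiles rather than ZOTU tables — the question it
answers is about community composition, not sequence-variant turnover;
both choices are arguments, not constants. Per-feature age trends report
a loess curve, an OLS slope ± SE, and the smoothed values at ages 16 and
30. Those two ages are descriptive annotations of where bifidobacterial
communities have been observed to change; no change-point detection is
claimed or performed.

## The association battery

**dbRDA** (`dbrda_univariate`). The dissimilarity matrix is embedded by
Gower-centred principal coordinates; negative-eigenvalue axes (a generic
feature of Bray–Curtis) are dropped with a message rather than corrected —
the simplest defensible default, and the variance they carry is reported.
The coordinates are regressed on the covariate's centred model matrix
(multi-level factors enter as full dummy blocks whose rank feeds the
degrees of freedom); R² is the constrained fraction of the positive
inertia; adjusted R² uses the Ezekiel formula
`1 − (1 − R²)(n − 1)/(n − m − 1)`; and the p-value comes from row
permutations of the covariate, `p = (1 + #{R²_perm ≥ R²}) / (1 + n_perm)`.
Because the permuted quantity is a projection of fixed coordinates,
permutations are scored by matrix products against the precomputed axes,
which is what makes the simulation-based tests affordable.

**Stepwise dbRDA** (`dbrda_stepwise`). Forward selection: at each step the
candidate yielding the highest adjusted R² is identified, its added
contribution is tested by conditional permutation (pseudo-F of the added
term, permuting only that candidate), and it joins the model if `p ≤
alpha`. Selection stops when the best candidate fails the test, adds no
adjusted R², or — with the scope rule active — when its model's adjusted
R² would exceed the global all-covariates model's. One property of that
scope rule deserves note: when the non-selected candidates explain
nothing, the global model's adjusted R² is an *unbiased* estimate of the
selected model's, so the scope comparison at the first step is close to a
coin flip. This is inherent to the rule (the reference implementation in
the community ordination package behaves identically), which is why
`r2_scope` is an argument: leave it on to reproduce the published
procedure; switch it off when the question is which candidate ranks
first, as the package's own recovery simulations do.

**Ridge screen** (`ridge_associate`, `ridge_screen`). Population
covariates (geography, ethnicity, diet, urbanisation) are strongly
collinear, which is the textbook setting for L2 regularisation.
Continuous covariates and the response are z-scored; categorical
covariates are dummy-coded against fixed reference levels (female, Han,
rice, rural, April); the intercept is unpenalised. The penalty is chosen
by generalized cross-validation over a log-spaced grid (`10^-4`–`10^4`,
101 points); the ridge package used in the original analyses selects its
penalty semi-automatically by a different rule, and GCV is this package's
own choice — at `λ = 0` the estimator reduces exactly to OLS, which the
tests assert to 1e-8. Standard errors use the ridge sandwich
`Var(β) = σ²(X'X + λI)⁻¹X'X(X'X + λI)⁻¹` with `σ² = RSS/(n − df)` and
`df = tr(H)`; p-values are two-sided t-tests. Across features, each
term's p-values are BH-adjusted.

**The rest.** Mantel tests wrap the standard permutation implementation
(Pearson on lower triangles, simultaneous row/column permutation).
One-way ANOVA is followed by Fisher's LSD pairwise t-tests on the pooled
error mean square, BH-corrected — the letters answer "which groups
differ after correction", so the classical uncorrected LSD is
deliberately not used — and a compact letter display built from maximal
cliques of the non-significance graph. Mann–Whitney tests of per-genome
gene counts enumerate the full permutation distribution when
`choose(nA+nB, nA) ≤ 20000` (exact even under ties, which count data
guarantee) and fall back to the tie-corrected normal approximation
otherwise. Genome-distance–geography correlations use haversine
great-circle distances, with the latitudinal component as `|Δlat|` along
a meridian and the longitudinal component scaled by the cosine of the
mean latitude. Significance conventions follow the field defaults
surfaced in `pipeline_config()`: raw `p < 0.05`, `p.adj < 0.1`.

## The synthetic cohort generator (`simulate_cohort`)

The generator is first-class code: it defines the conditions under which
the pipeline's statistical guarantees are demonstrated. Its defaults
emulate a population cohort: 600 samples drawn from 12 sites spanning
23–46 °N and 87–127 °E with two high-altitude sites; site-linked
ethnicity, staple food (wheat probability rising with latitude),
and residence covariates; ages uniform over 0.1–90 years; eight named
*Bifidobacterium* species plus one genus-level-only taxon (exercising the
unclassified bucket) spread over 40 ZOTUs.

Species abundances follow an *absolute-abundance* log-linear model:

    log A_is = baseline_s + age_s(age_i) + Σ_k effect_ks · x_ik + ε_is

with piecewise-linear age terms breaking at ages 16 and 30, continuous
covariate effects on the z-scale, categorical offsets (wheat +0.8
log-units on *B. adolescentis* and *B. longum*; Tibetan and Uygur
offsets; an urbanisation shift), and Gaussian noise (SD 1). An
independent log-normal background community sets the genus 16S fraction
as `bif16s = T/(T + background)` with `T = Σ_s A_is`. This choice is what
makes recovery targets well-defined: because the background dominates the
denominator, a planted effect on one species barely perturbs the others'
composite abundances, so unplanted species are genuinely null — a pure
within-genus compositional model would leak planted effects into every
species and no FDR statement could hold. Sequencing depths are negative
binomial (mean 15000, size 3) floored at the 2000-read rarefaction depth,
and ZOTU counts are multinomial with fixed per-species ZOTU weights.

What the generator does **not** emulate: read-level error and chimeras,
realistic BLAST score distributions (hit tables are constructed to
exercise arbitration branches, with ordering constraints only),
subspecies structure, seasonal confounding, or measurement error in the
16S genus fraction. Passing tests therefore demonstrate the statistical
machinery under the stated generative model, not robustness to upstream
sequencing artefacts.

## Numerical choices and problem sizes

Permutation defaults are 999 everywhere; the simulation-heavy tests use
199 permutations (p granularity 0.005 against an entry threshold of
0.05) and fixed seeds, with cohorts of n = 600 and 100 replicates —
sizes chosen so the whole suite runs on a desktop in minutes. PCoA drops
eigenvalues below `1e-8` of the spectral radius; rank decisions in model
matrices use QR with tolerance `1e-9`; bit-score ties are exact
comparisons; BH is the standard step-up procedure. All randomness flows
from explicit seed arguments, and rerunning any stage with the same seed
is byte-identical.

## Known limitations

Relative, not absolute, quantification: everything is conditioned on the
16S genus fraction supplied as input. The marker itself cannot separate
some close relatives (e.g. members of the *B. longum* complex at
subspecies rank), and a genus-level bucket absorbs what the databases
cannot resolve. The identity QC aligner is quadratic in database size.
dbRDA drops negative-eigenvalue axes rather than applying a Lingoes or
Cailliez correction. The ridge penalty selection differs from the
original analysis package (GCV here), so coefficient magnitudes are not
expected to match that software exactly even on identical data.
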