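---
title: "Methods: random-subspace LDA ensembles for BCRP substrate screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-subspace LDA ensembles for BCRP substrate screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrpscreen)
```

## The problem and the model

BCRP (ABCG2) is a polyspecific efflux transporter: it recognizes
structurally diverse ligands, plausibly through at least two distinct
binding sites. For a ligand-based classifier this polyspecificity is the
central obstacle — "substrate" is a union of several structure-activity
relationships, and a single linear discriminant, which can only draw one
hyperplane, cannot represent a union of half-spaces. The package therefore
implements a *random subspace* ensemble of linear discriminants: many weak
linear models, each built on a random combination of descriptor blocks, are
combined in pairs by simple score fusion. Different subspaces see different
facets of the substrate space (a pool containing the descriptors that
resolve one binding site but not the other yields a model specialized for
that site), and fusing two complementary models approximates the OR of two
half-spaces that one LDA cannot express.

Each individual model is a discriminant function

$$\mathrm{df}(x) = a_0 + \sum_i a_i d_i(x),$$

fitted by pooled-covariance two-class LDA with equal priors on descriptors
chosen by forward stepwise multiple linear regression of the class dummy
(+1 substrate, −1 nonsubstrate). The intercept places the decision boundary
at df = 0 with substrates scoring positive; a df of exactly 0 is called
nonsubstrate, the conservative choice for a filter whose purpose is to
discard substrates. Selection and final coefficients deliberately come from
two different fits (MLR for selection, LDA for the coefficients): stepwise
MLR on the dummy gives the classical F-to-enter machinery, while the LDA
parameterization makes the score an estimated log-odds direction under the
homoscedastic Gaussian model.

Assumptions worth keeping in mind: LDA assumes a shared within-class
covariance; equal priors reflect the deliberately balanced training set
rather than any population prevalence; and the stepwise procedure is greedy
— it finds good, not optimal, subsets (exhaustive subset search over ~200
descriptors is not computationally feasible, and the random-subspace
averaging is the intended antidote to its instability).

## Tunable parameters

Selection (`selection_config()`):

* `tolerance_min` (default 0.1) — minimum tolerance, 1 − R² of a candidate
  regressed on the already-selected descriptors. Dimensionless; guards
  against entering near-collinear descriptor pairs, which would make the
  pooled covariance ill-conditioned and coefficients unstable.
* `alpha_enter` (default 0.05) — entry significance level for the
  candidate's coefficient.
* `max_steps` (default 15) — hard cap on entered descriptors; the model
  sweep in the analysis scripts varies it over 10–15 together with
  tolerance 0.1–0.5 to diversify the model pool.
* `min_cases_per_predictor` (default 11) — overfitting guard; with 164
  training compounds it caps models at 14 descriptors.

Subspaces (`generate_pools()`): pools are random block combinations with
total size within ±20% of `target_size = 200` descriptors. For up to 20
blocks the feasible combinations are enumerated exactly, so infeasible
configurations are detected, and duplicate combinations are drawn only when
fewer distinct feasible combinations exist than requested pools.

Fusion and selection (`enumerate_ensembles()`): operator AVE or MAX on the
raw df scale; ensembles ranked by ascending test-set false-positive count,
then descending pAUC over Sp ∈ [`sp_lo`, 1] (default 0.70), then total AUC,
then model ids. Scores are fused unstandardized — the df scales of models
fitted on one training set are comparable only loosely, and no
standardization step is part of the reference procedure — but
`fuse_scores(standardize = TRUE)` offers per-model z-scoring as an option.

ROC machinery: pAUC is reported **unnormalized** (an area over a band of
width w has maximum w); `n_boot = 2000` stratified bootstrap replicates;
percentile 95% confidence intervals. Enrichment: EF selection fraction
`x = 0.10` with integer selection size ⌊xN⌋ (an explicit `n_select`
overrides it); RIE/BEDROC exponent `alpha = 20`, the convention of the
metric's source, meaning roughly the top 1/20th of the list dominates the
score. Every report prints the convention it used.

Partition (`partition_config()`): test fractions 0.50 (substrates) and
0.25 (nonsubstrates) per cluster; structural similarity cutoff 0.4 on
FP2-fingerprint Tanimoto as the open stand-in for a 9-atom
maximum-common-substructure floor.

## What the synthetic generator emulates — and what it does not

`generate_polyspecific()` produces the statistical structure the workflow
assumes, at the reference study's scale by default: 262 compounds, 864
descriptors in 12 equicorrelated Gaussian blocks (within-block correlation
0.3, mimicking families of related molecular descriptors), expected
substrate fraction 0.6. Labels arise from two latent linear site rules
joined by OR; each site's score is
`effect_size · (wᵏ'x)/sd + ε, ε ~ N(0,1)`, with the site thresholds set
analytically so the OR fires at the configured class balance, and emitted
labels flipped with probability `label_noise` (default 0.1, standing in for
assay heterogeneity and polyspecific ambiguity in literature-curated data).

Two generator design choices deserve explanation:

* **Contrast weights.** Site weights alternate in sign (+1, −1, …), making
  each rule orthogonal to its block's shared common factor. With
  all-positive weights the rule would essentially *be* the block factor:
  every descriptor in the block would correlate with the labels, the
  informative ones would be mutually redundant, and recovering them
  individually would be statistically impossible. As contrasts, each
  informative descriptor carries identifiable, non-redundant signal.
* **Compact sites.** Each site rule spans 4 descriptors by default.
  Spreading a fixed effect over many correlated descriptors pushes each
  one's marginal F below any reasonable entry threshold at n in the
  hundreds — an identifiability limit of forward selection, not of the
  generator — so the default keeps sites compact enough that selection can
  see them.

What the generator does **not** emulate: real descriptor marginals (counts,
skewed and discrete, not Gaussian), structure-driven cluster geometry
(synthetic compounds have no scaffolds, so the structural-clustering route
is exercised on real SMILES fixtures instead), dose- or assay-dependent
label definitions, and any relationship between descriptor blocks and
chemistry. Green tests on synthetic data therefore certify the statistical
machinery — selection, fusion, ROC and enrichment arithmetic, protocol
shapes — not chemical validity of any particular descriptor set.

## Numerical choices and degenerate inputs

* F-to-enter is computed by QR residualization of the response and all
  candidates against the selected set — numerically equivalent to refitting
  per candidate but one matrix product per step. Entry ties are broken by
  lexicographic descriptor name, making selection fully deterministic.
* Zero-variance descriptors are skipped (and reported); a singular pooled
  covariance aborts the LDA fit naming the collinear descriptors.
* Empirical ROC curves dichotomize at every distinct observed score; tied
  scores produce diagonal segments, and the trapezoid AUC then equals the
  Mann–Whitney statistic with ties counted ½ (asserted against an exhaustive
  pair-counting oracle in the tests). All-identical scores give the chance
  diagonal with a warning.
* The accumulation curve treats a tie group as one linear segment, which
  keeps the identity AUC = AUCc/Rᵢ − Rₐ/(2Rᵢ) exact (to 1e−10 in the tests)
  in the presence of ties.
* The pAUC bootstrap resamples hits and non-hits separately and asserts,
  replicate by replicate, that the strata sizes are preserved.
* Near-constant descriptor filtering (training rows only): variance below
  1e−8 relative to the squared column scale, or a modal value covering more
  than 95% of training rows. The rule is idempotent and provably
  independent of test rows.
* Descriptor CSVs are written with 17 significant digits so doubles
  round-trip bit-identically.
* k-means refinement is initialized from the hierarchical cluster means
  (Hartigan-Wong, falling back to Lloyd if a cluster empties); z-scoring
  uses the compounds being clustered. Per-cluster test counts round
  half-to-even; singleton clusters go to training so rare scaffolds stay
  available for modeling.
* Decoy generation is rejection sampling from the substrate-generating
  region, so decoys are genuine "putative substrates" under the ground
  truth; they are never counted as screening hits.

## Open design choices

Several aspects of the reference procedure are underdetermined; the package
fixes them as follows. The randomization test re-runs descriptor selection
on every scrambled-label replicate (the stronger null — reusing the original
selection would understate chance performance). LGO stratification keeps
each removed group of 10 within one compound of the training class ratio,
and the sampler prefers not-yet-removed compounds, which guarantees the
coverage property by construction. The hit orientation of a ranking is
explicit in every `scored_ranking`: screening reports use nonsubstrates as
hits ranked by ascending df, while training-set ROC curves may use
substrates as hits; both are supported and stated in output. The two EF
conventions in circulation (integer top-n vs fractional selection) are both
available (`n_select` vs `x`), and the one used is printed.

One empirical observation from the analysis scripts, worth recording as a
caveat: ranking ensembles primarily by false-positive count at the fixed
df = 0 cutoff structurally favors the MAX operator, because taking
elementwise maxima inflates fused scores and thus calls fewer compounds
nonsubstrate regardless of ranking quality. AVE fusion, by contrast, tends
to win on ranking-quality criteria — the acceptance experiment asserts that
the best AVE pair beats the best individual model on training AUC in at
least 80% of seeds. Users selecting an operational ensemble should weigh
the FP criterion against pAUC/AUC rather than reading the FP-sorted
leaderboard alone, or re-optimize the threshold via `optimize_threshold()`
afterwards.

## Problem sizes used by the test suite

The suite runs the full-scale generator (262 × 864) where the scale itself
matters and reduced shapes elsewhere: the ensemble-advantage experiment uses
20 seeds × 20 pools at n = 164 (85:79 expected balance), the recovery
property 10 seeds, the z-test calibration 2000 Monte-Carlo replicates at
n = 200, the pAUC bootstrap 2000 replicates, and protocol-shape checks the
reference sizes (50 randomization scrambles; 50 LGO rounds of 10 on
n = 164). These sizes are the package's chosen compromise between the
stability of stochastic assertions and a test suite that runs in minutes.

## Known limitations

* The open descriptor engine (8 blocks, ~88 descriptors from the molecular
  graph) mirrors the *families* of the classical commercial 0D–2D panels,
  not their exact definitions or count (~867); block-level workflow
  behavior transfers, per-descriptor values do not.
* Formal charges, stereochemistry and tautomers are ignored; multi-fragment
  SMILES (salts) are rejected rather than standardized. Elements outside
  H, B, C, N, O, F, Si, P, S, Cl, Br, I are rejected.
* Score fusion on the raw df scale assumes loosely comparable model scales;
  models from very different pools can violate this (the standardization
  option exists for that case).
* RIE/EF depend on the order within tied scores; the implementation uses a
  stable sort and documents it, but heavily tied scores deserve caution.
* The structural-clustering stand-in (complete linkage on FP2 Tanimoto) is
  reproducible but only approximates maximum-common-substructure
  clustering; the similarity cutoff mapping to an atom-count floor is
  heuristic and configurable.
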