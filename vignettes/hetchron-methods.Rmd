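---
title: "Methods: detecting heterochronic expression shifts with hetchron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting heterochronic expression shifts with hetchron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model of the data

`hetchron` analyses comparative follicle transcriptomes from five
live-bearing fish species — two placental/non-placental sister pairs plus a
non-placental outgroup — sampled at four ordered developmental stages
(`egg`, `early`, `middle`, `late`). Its goal is to classify genes whose
expression timing changed when placentas evolved: *neoteny* candidates
(egg-stage provisioning expression retained through development in the
placental lineage) and *hypermorphosis* candidates (late-stage expression
derived relative to both the non-placental sister and the reconstructed
pair ancestor, in the same direction).

The chain is: one-to-one orthologue mapping, FPKM normalization and binary
encoding, two-state phylogenetic likelihood on the binary characters
(expression phylogenies plus marginal ancestral reconstruction on the fixed
species tree), and threshold filters on stage-mean expression.

## The two-state substitution model

A gene's binarized expression state (1 = FPKM at or above 2.0, 0 = below)
is modelled as a reversible two-state Markov chain along the species tree.
With two states the general time-reversible model collapses to one exchange
rate plus the stationary frequency $\pi_1$ ("GTR2 + FO"): the rate matrix
has $q_{01} = \pi_1 s$, $q_{10} = \pi_0 s$ with $s = 1/(2\pi_0\pi_1)$ so a
branch length of 1 is one expected change per variable character, and the
transition kernel has the closed form
$P(t) = \Pi + e^{-s r t}(I - \Pi)$, where $\Pi$ stacks the stationary row
$(\pi_0, \pi_1)$ and $r$ is a per-category rate multiplier. The closed form
replaces generic matrix exponentials; the tests verify it against
`Matrix::expm` to 1e-10 and check Chapman–Kolmogorov and detailed balance.

Rate heterogeneity across characters uses the standard mixtures:

* `+I` — an invariant class of proportion $p_{inv}$. Internally it is
  simply the rate-0 mixture category, so its likelihood contribution
  reduces to $\pi_s$ for characters constant (state $s$) across observed
  taxa and to 0 otherwise, with no special-casing of "potentially constant"
  patterns containing missing values.
* `+G4` — four equal-weight discrete-gamma categories with mean-of-bin
  rates (rates average exactly 1 for any shape $\alpha$).
* `+R2` — two free (rate, weight) pairs.

Bookkeeping convention: mixture weights sum to 1 and the weighted mean rate
of the *non-invariant* categories is 1, i.e. $\sum_k w_k r_k = 1 - p_{inv}$.
Branch lengths are therefore expected changes per variable character; tools
that rescale rates so the total mean is 1 will report branch lengths
differing by the factor $1 - p_{inv}$. A doubled invariant term in a model
label (e.g. `"GTR2+FO+I+I+R2"`) is collapsed to a single `+I`, since a
second invariant class is not identifiable.

Likelihoods come from Felsenstein pruning over compressed site patterns
(with five or six taxa there are at most $3^6$ distinct columns, so
branch-length sweeps, tree search and bootstrap cost almost nothing extra
as characters grow). Missing states enter as partial likelihood $(1,1)$;
characters missing in every taxon contribute 0 to the log-likelihood and
are reported. The pruning implementation is checked against brute-force
enumeration over all internal-node assignments on all fifteen five-taxon
topologies under every rate-model family, at tolerance 1e-8.

## Fitting, model ranking, search, support

`fit_model()` maximizes the likelihood by round-robin sweeps: each branch
length by bounded scalar optimization (preorder sweep order, bounds
[0, 10]), then all model parameters jointly by bounded quasi-Newton
(L-BFGS-B) — the invariant proportion, gamma shape and branch lengths are
strongly correlated, and one-dimensional coordinate steps alone zigzag.
Bounds: $\pi_1 \in [10^{-4}, 1-10^{-4}]$, $\alpha \in [0.05, 100]$,
$p_{inv} \in [0, 0.99]$. `+R2` is parameterized by $(v_1, r_1)$ with
$r_2 = (1 - v_1 r_1)/(1 - v_1)$, which enforces the mean-1 constraint and
orders $r_1 < 1 < r_2$, removing label switching. Convergence is declared
when a full sweep improves lnL by less than `tol` (default 1e-6).
Initialization: empirical state-1 frequency for $\pi_1$, half the
constant-pattern fraction for $p_{inv}$, $\alpha = 1$, symmetric free
rates. Degenerate input (all characters constant) makes $p_{inv}$
unidentifiable; the fit warns and returns the boundary solution.

`select_model()` ranks candidate rate models by
$AICc = -2\ln L + 2k + 2k(k+1)/(n-k-1)$ with $n$ = characters and $k$
counting branch lengths as free parameters; candidates with $n \le k+1$
are inadmissible. Ties break toward fewer parameters.

`search_topology()` hill-climbs through nearest-neighbour interchanges from
a neighbour-joining start on Hamming distances (missing entries
pairwise-excluded), optionally adding random starting topologies. Model
parameters are estimated once on the starting tree and held fixed while
topologies are compared (each candidate gets short branch-length sweeps);
the final topology is refit in full. The returned tree scores at least as
well as each of its NNI neighbours. `bootstrap_support()` resamples
characters with replacement, re-searches each replicate, and reports
bipartition frequencies as percentages — the standard nonparametric
bootstrap; fast approximate resampling schemes are out of scope.

`ancestral_reconstruction()` computes marginal posteriors by the up-down
algorithm, mixing over rate categories, on the fixed species phylogeny. A
state is called when its posterior reaches the floor (default 0.50,
*inclusive*, mirroring a minimum-threshold semantics; floors below 0.5 are
rejected because calls would not be unique, and an exact 0.5/0.5 tie is
called state 1). Ambiguous node-characters propagate: downstream filters
skip those genes and report them.

## Expression encoding

FPKM = counts × 10⁹ / (gene length bp × total mapped fragments), computed
from uniquely mapped fragments. Normalization uses median-of-ratios size
factors within species (reference = per-gene geometric mean over that
species' samples, excluding genes with any zero or missing value; fewer
than 10 usable reference genes is an error). The canonical implementation
of this estimator operates on raw counts; here the same construction is
applied to FPKM directly, since the pipeline contract upstream delivers
FPKM matrices — factors then absorb residual depth/composition differences
left after the FPKM scaling. The tests confirm the construction agrees
with `DESeq2::estimateSizeFactorsForMatrix` up to the geometric-mean
reference convention.

Binarization codes FPKM ≥ 2.0 as expressed (boundary inclusive), < 2.0 as
silent, missing as missing. Two encoding routes exist because different
stages of the chain want different units: per-sample binary matrices feed
the expression phylogenies (samples as tips), while per-species consensus
states (majority over a species' replicates at one stage, ties → missing)
feed the ancestral reconstruction on the five-taxon species tree, and
stage means feed the candidate filters. PCA (centred, unscaled, on
log2(FPKM+1) by default — raw FPKM is available by flag) and logistic PCA
provide the ordination views; logistic PCA fits a rank-constrained
Bernoulli natural-parameter matrix $\Theta = \mu + AB^\top$ by
majorization-minimization (quadratic majorizer with curvature 1/4, working
matrix $Z = \Theta + 4(Y - \sigma(\Theta))$, offsets then truncated SVD),
excludes missing entries from the objective rather than imputing them, and
is monotone in the observed-data log-likelihood at every iteration.

## Candidate filters

With stage means $\bar{x}$ and a pseudocount $c$ (default 0.01 FPKM) every
fold change is $(\bar{x}_a + c)/(\bar{x}_b + c)$. For a
placental/non-placental pair (P, N):

* **Neoteny**: FC(P late, N late) ≥ 4; FC(N egg, N late) ≥ 2; P late ≥ 2
  FPKM; P egg ≥ 1 FPKM. All floors inclusive.
* **Derived-up**: FC(P late, N late) ≥ 4, P late > 2 FPKM, ancestral
  egg-stage state 0. **Derived-down**: FC(N late, P late) ≥ 4, P late < 2
  FPKM, ancestral state 1. The binary ancestral state stands in for the
  ancestor's FPKM-above/below-2 condition — the reconstruction is performed
  on characters encoded with the same threshold. Note the asymmetry kept
  from the printed rules: the placental-late conditions here are strict
  (> 2 / < 2) while the encoding boundary is inclusive (≥ 2).

Fold-change floors are compared with a 1e-8 *relative* tolerance: the
pseudocount drags the ratio of exactly-at-threshold means infinitesimally
below the floor (e.g. $(8+c)/(2+c) < 4$), and the inclusive "at least
fourfold" semantics must keep such genes. Absolute FPKM floors involve no
pseudocount and are compared exactly. No p-value gate is added to the
fold-change criteria: the filters reproduce the stated rules, and a
count-model differential-expression test is a documented non-goal.
`matrotrophy_index()` regresses mean dry mass on stage ordinal by unweighted
OLS (log-mass by flag) and returns predicted mass at the final stage over
predicted mass at stage 0; non-positive endpoint predictions are an error.

## Orthology

Hits below the E-value cutoff (default 1e-7, boundary inclusive) enter
reciprocal-best-hit calling; "best" is lexicographic on bit score, then
alignment rate (aligned length over query protein length — the denominator
choice is ours, the combination order follows how the criteria are usually
listed), then percent identity, and a query whose top two hits tie on all
three keys is dropped entirely. The synteny filter keeps a pair only when
the RBH partners of its flanking genes (window 1 by default, exposed as a
flag) equal the partner gene's flanks, orientation-agnostic so local
inversions pass. End policy: `strict` (default) drops pairs that cannot be
evaluated on both sides, trading recall for precision; `permissive`
evaluates the sides that exist, with a pair of genes both at scaffold ends
matching vacuously but a one-sided flankless gene counting as a mismatch.
Merging keeps reference genes with synteny-passing partners in *every*
species, in reference-coordinate order; duplicate partner claims violate
one-to-one and remove all involved rows.

## The synthetic-data generator: study conditions

The generator is first-class, tested code; its defaults *are* the
conditions under which the package validates itself:

* 5 species in the two-pairs-plus-outgroup layout; species tree
  `((plac1,nonplac1),(plac2,nonplac2),outgroup)` with terminal/stem
  branches 0.1 and an outgroup branch 0.2 (in expected changes per
  character — short enough that pairs are hard cherries, long enough that
  characters carry signal).
* 4 stages × 3 replicates (the real design's 58 follicles over 5 species
  and up to 4 stages gives roughly 3 per cell; the count is configurable
  because the per-cell replication is not fixed by the design).
* 2000 genes; per pair 20 neoteny, and per placental species 30 derived-up
  and 30 derived-down planted genes, plus 50 egg-provisioning genes — the
  key negative controls for the neoteny filter — leaving the bulk as
  background (a scale that keeps the full chain and the 100-replicate
  recovery experiments comfortable on a single CPU while leaving planted
  classes in a realistic minority).
* Regime means 10.0 FPKM ("on") and 0.2 ("off"), chosen to clear the
  fourfold and FPKM-2 thresholds with margin at replicate noise up to
  `noise_sd` 0.4; default noise is log-normal with sd 0.3 on the log scale,
  multiplicative noise being the natural first-order model for RNA-seq
  abundances. Background genes draw a per-gene baseline from a wide
  log-normal (meanlog 1.5, sdlog 1.5) shared across species.
* Whole gene × species blocks go missing with probability 0.02, mimicking
  genes dropped from one species' annotation.
* Planted effects are deterministic regime means, not evolved quantitative
  traits: sufficient to exercise threshold filters, and quantitative-trait
  evolution is a non-goal. The outgroup and the non-focal placental species
  follow the non-placental (ancestral) regime for every planted class.

Binary characters for the phylogenetic experiments are evolved exactly
under the two-state model (root from stationarity, per-branch closed-form
transitions, per-site rate categories). The late-stage condition plants a
convergent placental programme with `plant_convergence()`; the package's
validation fixes that fraction at 15% of characters. The choice is
deliberate: at 10% the data sit on the phase boundary where the true ML
topology is still usually the species tree, and pilot runs at 15% put the
maximum-likelihood tree on the placental clade in every replicate —
matching the qualitative behaviour the method is supposed to expose
(egg-stage trees recover the species phylogeny; late-stage trees group by
provisioning mode).

What the generator does *not* emulate: read-level sampling noise and
mapping bias, annotation errors beyond whole-block missingness,
evolutionary divergence of background expression between species (baselines
are shared, so species-level *egg* trees from expression data carry no
phylogenetic signal — the character-level route is the controlled version
of the tree experiments), batch effects beyond a recorded label, and
correlated expression between genes. Passing tests therefore demonstrate
correctness of the inference chain under its stated model, not robustness
to the full messiness of real RNA-seq.

## Numerical choices and degenerate inputs

* Pattern compression keys include missingness; empty matrices are legal
  everywhere (0 characters ⇒ lnL 0, empty simulation ⇒ 0-column matrix).
* Branch-length optimization tolerance is 1e-6 during final fits and 1e-3
  during topology comparison (two sweeps per candidate), which pilot runs
  showed is enough to rank five-taxon topologies while keeping
  100-replicate experiments under a couple of minutes.
* NJ starting trees may contain non-positive branch lengths; these are
  clamped to small positive values before optimization.
* Exact 0.5/0.5 ASR posteriors are called state 1 (boundary inclusive);
  `min_posterior < 0.5` is rejected.
* The matrotrophy regression refuses non-positive predicted endpoint
  masses instead of returning a negative index.
* All seeds are plain integers fed to R's default RNG; every stochastic
  function takes a `seed` argument and is bit-reproducible given it.

## Known limitations

* The likelihood engine targets small taxon sets (the study design: 5–6
  taxa; per-sample trees with tens of tips remain feasible but pattern
  counts grow as $3^{taxa}$, so very large trees would need a different
  implementation strategy).
* No partial-likelihood scaling is implemented; with the bounded branch
  lengths (≤ 10) and small trees underflow is not reachable, but the
  engine should not be pointed at hundreds of taxa.
* Tree search explores NNI only; with 5 taxa the neighbourhood covers the
  space quickly from an NJ start, but larger problems would want SPR.
* The hypermorphosis ancestor condition compares placental *late*
  expression to the ancestral *egg*-stage state, exactly as the rules are
  printed; whether that cross-stage comparison is intentional shorthand in
  the original formulation cannot be resolved from the text, so it is
  implemented literally.
* Orthology assumes protein-level hits and gene-order coordinates are
  trustworthy; it does not attempt paralogy-tree reconciliation.
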