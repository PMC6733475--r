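---
title: "Maximum-entropy models of repeat-protein sequence space: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-entropy models of repeat-protein sequence space: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

Repeat proteins (ankyrin, TPR, leucine-rich repeats, ...) are tandem arrays
of ~30-residue units. This package models the sequence statistics of a *pair
of consecutive repeats*: a sequence is a vector of `2L` symbols over a
21-letter alphabet (20 amino acids plus the gap, which is treated as an
ordinary 21st state throughout). The family distribution is the maximum-entropy
distribution consistent with three sets of empirical observables
from a curated alignment:

* per-site amino-acid frequencies `f_i(a)`,
* joint pair frequencies `f_ij(a, b)` for all site pairs,
* the distribution `P(ID)` of the inter-repeat overlap
  `ID(sigma) = #{i <= L : sigma_i = sigma_{i+L}}`, which absorbs the
  phylogenic similarity of consecutive repeats (they share a recent common
  ancestor within the array).

Lagrange duality gives a disordered Potts model,

```
P(sigma) = exp(-E(sigma)) / Z
E(sigma) = - sum_i h_i(sigma_i) - sum_{i<j in mask} J_ij(sigma_i, sigma_j)
           + lambda_{ID(sigma)}
```

with each unordered pair counted once. The *mask* restricts which pairs may
interact: everything (`E_full`, `E_2`), only intra-repeat pairs with
parameters tied across the two halves (`E_ir`, `E_ir_lambda`), pairs within
a linear range `|i - j| <= W`, or pairs within a 3D distance cutoff taken
from a residue-residue distance matrix. Removing all couplings gives the
independent-sites model `E_1` (`h = log f`, closed form), and removing
everything gives the uniform model `E_rand` with entropy `2L log2(21)` bits
— 290, 211 and 299 bits for repeat lengths 33, 24 and 34, the three
families' dimensions.

Two conventions worth stating because they change numbers: gap==gap counts
as a match in `ID` (the overlap is a Kronecker delta on the full 21-letter
alphabet), and ambiguous residue codes (X/B/Z/U/O) are read as gaps so the
alphabet never grows past 21.

## Curation and observables

`read_pair_alignment()` expects an already-paired alignment (`2L` columns).
Columns with more than 80% gaps are removed; because the input is paired,
column `i` and its homolog `i + L` are removed together — a deliberate
adaptation of gap-column curation to pre-paired input, keeping `ID`
well defined. Redundancy is corrected by greedy identity clustering at 90%
(input order, gaps included in the identity), each sequence weighted by
`1 / cluster size`, so weights sum to the number of clusters. The greedy
order and tie-breaks of the reference clustering tool are not specified
anywhere authoritative, so the package fixes input order and documents it;
at 90% identity the partition is robust to this choice.

## Fitting: Boltzmann-machine learning with an L1 tube

`fit_model()` iterates: sample an ensemble from the current model
(Metropolis, single-site proposals excluding the current symbol, `exp(-dE)`
acceptance), measure its observables, and update

```
h      <- h + eps_m * (f1_data - f1_model)
lambda <- lambda - eps_id * (P_data - P_model)    # lambda enters E with +
J      <- four-case L1 proximal step, strength gamma
```

The coupling step keeps `J = 0` while the observed discrepancy stays inside
the `gamma` tube, activates it along the soft-thresholded gradient when the
discrepancy exceeds `gamma`, follows the penalized gradient while active,
and clamps to zero on sign crossing. The L1 tube is what absorbs sampling
noise — no pseudocounts are applied to the pair targets. Convergence is
declared when `max(|df1|, |df2|, 5 |dP_ID|)` drops below 0.02; the `P(ID)`
term participates only for models that constrain it, and `|df2|` runs over
the fitted mask.

Defaults are the published optimization settings (`eps_m = 0.1`,
`eps_j = 0.05`, `eps_id = 10`, `gamma = 0.001`, tolerance 0.02 with the x5
overlap weight, 80000 sequences per iteration). Two desk-scale adaptations,
both exposed in `fit_config()`:

* **Thinning is per-site.** "Record every 1000 proposals" at 66 sites is 15
  sweeps; the package defaults to `15 * 2L` proposals between samples so the
  same per-site decorrelation holds at any system size. Steps are counted as
  proposals, not acceptances.
* **`eps_id` at small `L`.** With 6-residue repeats `P(ID)` has 7 bins with
  probabilities up to ~0.4, and the gradient step `eps_id = 10` exceeds the
  stability limit set by the bin variance — the multipliers oscillate and
  the fit never converges. The analyses here use `eps_id = 2`, which is
  stable at these bin sizes; at `L = 33` (34 small bins) the published value
  is marginally stable, which is presumably why it worked there.

Burn-in (unspecified in the protocol this follows) defaults to 100x the
thinning interval, i.e. 1500 sweeps. This is deliberately generous: with a
short burn-in (10x) the interpolated ensembles of rugged desk-scale models
are measurably out of equilibrium, and the thermodynamic-integration
entropy lands 1-2 standard errors below its exact value; at 100x the bias
is gone and the added cost is about two percent of the sampling budget.

**Seeding matters.** De novo fits of fully connected models from an
independent-sites start converge to systematically weaker couplings and
overestimate the entropy (we observe ~0.5 bits at desk scale; the same
pathology is what the progressive-learning control in the source analysis
detects). `fit_range_sweep()` therefore learns models along an increasing
interaction range, each initialized from the previous fit, and the
full-model fit used in the analyses is the endpoint of that ladder
(`fit_variant_suite(..., seed_ladder = )` wires this in). The suite seeds
`E_2` from `E_full` (drop `lambda`, relearn) and `E_ir_lambda` from `E_ir`;
`E_ir` descends from the ladder model at `W = L - 1` with inter-repeat
couplings removed when a ladder is used, and from the independent model
otherwise — at desk scale the tied single-repeat problem is small enough
that both converge.

Tied fits symmetrize both the data targets and the per-iteration model
observables across the two halves (Eq-style averages
`f'_i = (f_i + f_{i+L}) / 2`), so mirrored parameters receive identical
updates and stay tied without explicit projection.

## Entropy by thermodynamic integration

`S = <E> - F(1)`, with `F(1)` obtained by integrating the mean interaction
energy over the interpolation `E_alpha = -sum h + alpha (-sum J + lambda_ID)`
from the closed-form independent free energy
`F(0) = -sum_i log sum_a exp(h_i(a))`. The stated protocol ("50 alpha values
at spacing 0.02 on [0, 1]") is internally inconsistent — that grid has 51
points; the package uses 51 so the composite Simpson rule applies cleanly.
`<E>` comes from a fresh ensemble at `alpha = 1`.

Error model, three components:

* *Monte-Carlo*: per-alpha standard errors combined through the Simpson
  weights, plus the `<E>` standard error, in quadrature
  (`mc_error_bits`).
* *Finite data*: first-order multinomial propagation for the
  independent-sites entropy, `Var(S) = (1/N_s) sum_i [sum_a p (log p)^2 -
  S_i^2]` (`entropy_error_independent()`). The printed form of this formula
  in the source subtracts the square of the *total* entropy, which is
  negative for any multi-site system; the per-site form implemented here is
  the one that follows from independent sites, and we read the printed form
  as a typo.
* *Learning bias*: sample the fitted model, compute the independent-sites
  entropy of its single-site frequencies, compare with the same functional
  of the data frequencies (`estimate_learning_bias()`). Interactions are
  assumed not to change its order of magnitude.

`entropy_exact_enumeration()` is the brute-force oracle (refuses more than
1e7 states); thermodynamic integration is validated against it on planted
models at `q = 3..4`, `2L = 8..12`.

## Landscape: quenches, basins, configurational entropy

`quench()` performs zero-temperature descent with the overlap term forced
off (the landscape of interest is the functional one, not the phylogenic
bias): enumerate all strictly improving moves, pick one uniformly, repeat
until none remain. Moves are single-site substitutions plus, when the two
halves agree at a homologous position, the synchronized double substitution
— without it, residual phylogenic signal in the couplings manufactures
spurious minima. When a single improving move and a double containing it are
both available they sit in one uniform pool (the protocol does not specify
a precedence; the choice only affects which of several valid descents is
taken). Quenches are stochastic near ridges; partitions fix and record a
seed, with seed 0 as the published-partition convention.

`basin_decomposition()` groups starts by their exact endpoint (discrete
states, so equality needs no tolerance), weights basins by start weights
(curation weights for natural starts, uniform for generated ones),
and reports `S_conf = -sum_b P(b) log2 P(b)`. `minima_clustering()` takes
the largest basins reaching 90% cumulative weight, computes pairwise
Hamming distances, and organizes them by average-linkage agglomeration.
Consensus ties (equal column frequencies) break to the lowest symbol index.

## Family divergence

`kl_divergence()` estimates `D(A||B) = <E_B - E_A>_A + F_A - F_B` in bits,
sampling each model and evaluating the other through an explicit column
map; free energies come from the same thermodynamic integration. Partial
maps are refused — KL over a column subset is undefined for these models —
and producing the inter-family alignment is the user's responsibility. The
divergence from random polypeptides is the entropy deficit
`n_sites log2(q) - S`; `n_sites` is the model's full span (`2L` for pair
models), which is the dimension the models actually live in.

## The synthetic generator, and what passing tests mean

`make_planted_model()` draws Gaussian fields (sd 0.5) and Gaussian coupling
blocks (sd 1.0) on a random 15% of candidate pairs, defaults chosen once so
that desk-scale models (`2L = 12..16`, `q = 3..4`) are neither trivially
random nor frozen — they exhibit genuine frustration and multiple basins
while remaining enumeration-checkable. Optional overlap profiles (negative
`lambda` at high ID) emulate phylogenic repeat similarity; `tie_repeats`
with intra-only couplings builds the non-interacting-repeats control. The
generator emulates the statistical structure the analysis assumes —
sparse couplings, biased sites, overlap bias. It does *not* emulate
phylogenetic descent along a tree (the overlap constraint is the model's
proxy for that), alignment errors, insertions, or gap-pattern correlations;
passing the recovery tests therefore validates the machinery, not the
adequacy of the Potts form for any real family.

Desk-scale problem sizes used by the analyses and checks, stated here as
the package's choices: families of 20000 sequences at `2L = 12`, `q = 4`;
20000 Monte-Carlo sequences per learning iteration; 2000-10000 sequences
per integration grid point; enumeration oracles at `3^8` to `4^12` states.

## Known limitations

* No gauge fixing is applied to `h`/`J`; the L1 penalty selects a
  representative, so individual parameter values are comparison-safe only
  within one fit (entropies and divergences are gauge-invariant).
* Metropolis sampling mixes slowly in strongly bimodal planted landscapes;
  observables from a single chain can then be biased. The detailed-balance
  and recovery tests run in regimes where mixing is verified against
  enumeration.
* The convergence rule stops at observable error 0.02, which bounds
  parameter accuracy by the data's information content; entropies of
  converged fits still carry the learning bias quantified above, and the
  seeded ladder is the mitigation. In the package's own generative-recovery
  experiment (planted couplings of unit scale at `2L = 12`, `q = 4`,
  recomputed by `scripts/acceptance.R`) the relearned entropy remains ~0.4
  bits (about 2%) above the planted truth even after seeded learning — a
  coupling-driven bias that the single-site error proxy underestimates
  severalfold at this coupling strength. Entropy differences between
  variants fit to the *same* data are more reliable than absolute
  entropies, since the bias largely cancels.
* Whether the secondary entropy drop sits at `W = L` or `W = L - 1` depends
  on an off-by-one the source leaves ambiguous; `W` here is an inclusive
  bound and the sweep simply exhibits the drop where the homologous pairs
  enter the mask.
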