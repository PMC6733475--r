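# repeatpotts

Maximum-entropy (Potts) models of repeat-protein sequence space: how large
is a protein family, and what does its energy landscape look like?

Repeat proteins — ankyrin (ANK), tetratricopeptide (TPR), leucine-rich
(LRR) repeats — are tandem arrays of ~30-residue units. For an alignment of
*pairs of consecutive repeats* (`2L` columns, 21 states: 20 amino acids +
gap), the package fits the least-structured distribution that reproduces
the per-site frequencies `f_i(a)`, the pair frequencies `f_ij(a,b)`, and
the distribution `P(ID)` of the inter-repeat overlap
`ID(σ) = #{i ≤ L : σ_i = σ_{i+L}}`, which captures the phylogenic
similarity of neighboring repeats:

    P(σ) = exp(−E(σ)) / Z
    E(σ) = − Σ_i h_i(σ_i) − Σ_{i<j} J_ij(σ_i, σ_j) + λ_ID(σ)

On top of the fitted models it computes:

* **family entropies** `S = ⟨E⟩ − F`, with the free energy obtained by
  thermodynamic integration of Monte-Carlo ensembles over an interaction
  interpolation `α ∈ [0, 1]` (Simpson rule, 51 points), for the whole
  hierarchy of model variants (`E_rand`, `E_1`, `E_ir`, `E_ir,λ`, `E_2`,
  `E_full`) and for interaction masks restricted by linear range
  `|i − j| ≤ W` or 3D distance cutoffs;
* **the multi-basin landscape**: zero-temperature quenches (overlap term
  off), basins of attraction, configurational entropy
  `S_conf = −Σ_b P(b) log2 P(b)`, and average-linkage organization of the
  dominant minima by Hamming distance;
* **family divergence**: both directions of
  `D_KL(A‖B) = ⟨E_B − E_A⟩_A + F_A − F_B` through an explicit column map,
  and the divergence from random polypeptides `2L·log2(21) − S`.

Everything is testable offline: a planted-model generator produces
ground-truth families at reduced alphabet sizes where exact enumeration of
the state space serves as the oracle for entropies, divergences, and local
minima. Learning is Boltzmann-machine gradient ascent with L1-regularized
couplings and the published step sizes; the methods vignette
(`vignettes/repeat-potts-methods.Rmd`) documents every numerical choice and
desk-scale adaptation.

## Worked example

The `analysis/` directory is a numbered walkthrough on a synthetic family
(two 6-residue repeats, 4-letter alphabet, 20000 sequences): simulate and
curate (`01`), fit the variant hierarchy (`02`), entropy table and
decomposition (`03`), interaction-range sweeps with controls (`04`),
landscape (`05`), inter-family divergence (`06`). Each script prints what
it finds and writes tables under `results/`.

A minimal session on the same family:

```r
library(repeatpotts)

L <- 6
truth <- make_planted_model(planted_spec(L = L, q = 4, coupling_pairs = "any",
                                         tie_repeats = TRUE,
                                         lambda_profile = -0.5 * (0:L) / L,
                                         seed = 42))
aln <- make_planted_alignment(truth, 20000, seed = 43)
obs <- compute_observables(cluster_weights(aln, 0.9))

cfg <- fit_config(eps_id = 2, n_samples = 20000, seed = 44)
sweep <- fit_range_sweep(obs, cfg, ranges = c(0:6, 8, 11), mode = "linear")
full <- sweep$models$W11

entropy_thermodynamic(full, n = 5000, seed = 1)
#> Entropy: 20.83 bits (14.44 nats), MC error 0.039 bits [n = 5000 per alpha]

part <- basin_decomposition(full, aln, seed = 0)
part
#> Basin partition: 20000 starts -> 13 minima, S_conf = 2.75 bits
#>   largest basins (P_b): 0.312, 0.228, 0.161, 0.100, 0.056
```

Reading: the fitted family occupies ~2^21 of the 4^12 = 2^24 possible
sequences (the random-model entropy is 24 bits), and its energy landscape
fragments into a handful of basins — the configurational entropy of 2.75
bits measures the effective number of sub-families. On natural ANK/TPR/LRR
alignments the same calls apply with `q = 21` and `L = 33/34/24`; the
random-model entropies are then 290, 299 and 211 bits.

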