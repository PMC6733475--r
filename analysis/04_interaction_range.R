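#!/usr/bin/env Rscript
# How far do the interactions that constrain the family reach?  Models are
# re-learned with couplings restricted to |i - j| <= W (seeded progressively
# in W, which converges better than de novo fits and is how the full model
# is best learned) and to 3D distance cutoffs on a toy repeat-geometry
# distance matrix.  Two synthetic controls validate the procedure: data from
# an independent-sites model must give a flat entropy profile, and data from
# two non-interacting repeats must show no drop when W crosses the repeat
# length.

library(repeatpotts)

L <- 6L
aln <- read_pair_alignment("results/synthetic_family.fasta", L = L, q = 4)
aln$weights <- utils::read.csv("results/sequence_weights.csv")$weight
obs <- compute_observables(aln)

cfg <- fit_config(eps_id = 2, n_samples = 20000L, max_iters = 500L, seed = 2L)

entropy_of <- function(models, obs, seed0) {
  out <- data.frame(range = names(models), S_bits = NA_real_,
                    mc_error_bits = NA_real_, bias_error_bits = NA_real_)
  for (k in seq_along(models)) {
    er <- entropy_thermodynamic(models[[k]], n = 5000, seed = seed0 + k)
    out$S_bits[k] <- er$S_bits
    out$mc_error_bits[k] <- er$mc_error_bits
    out$bias_error_bits[k] <- estimate_learning_bias(models[[k]], obs,
                                                     n = 5000,
                                                     seed = seed0 + 50 + k)
  }
  out
}

ws <- c(0:6, 8, 11)

cat("== linear-range sweep on the synthetic family ==\n")
sw <- fit_range_sweep(obs, cfg, ranges = ws, mode = "linear")
lin <- entropy_of(sw$models, obs, seed0 = 300L)
print(lin, digits = 4)
utils::write.csv(lin, "results/range_sweep_linear.csv", row.names = FALSE)

cat("== 3D-range sweep against a toy distance matrix ==\n")
d3 <- make_toy_distance_matrix(2L * L, L, near_range = 1, seed = 5L)
cuts <- c(5, 9, 15, 30)
sw3 <- fit_range_sweep(obs, cfg, ranges = cuts, mode = "3d", d3 = d3)
thr <- entropy_of(sw3$models, obs, seed0 = 400L)
print(thr, digits = 4)
utils::write.csv(thr, "results/range_sweep_3d.csv", row.names = FALSE)

cat("== control: independent-sites data -> flat profile ==\n")
ind_model <- make_planted_model(planted_spec(L = L, q = 4L,
                                             coupling_density = 0, seed = 60L))
ind_obs <- compute_observables(make_planted_alignment(ind_model, 20000, seed = 61L))
swi <- fit_range_sweep(ind_obs, cfg, ranges = ws, mode = "linear")
flat <- entropy_of(swi$models, ind_obs, seed0 = 500L)
print(flat, digits = 4)
utils::write.csv(flat, "results/control_independent.csv", row.names = FALSE)
cat(sprintf("entropy spread across W: %.3f bits (errors ~%.3f)\n",
            max(flat$S_bits) - min(flat$S_bits),
            stats::median(flat$mc_error_bits + flat$bias_error_bits)))

cat("== control: non-interacting repeats -> no drop at W = L ==\n")
nir_model <- make_planted_model(planted_spec(L = L, q = 4L,
                                             coupling_density = 0.4,
                                             coupling_pairs = "intra",
                                             tie_repeats = TRUE, seed = 62L))
nir_obs <- compute_observables(make_planted_alignment(nir_model, 20000, seed = 63L))
swn <- fit_range_sweep(nir_obs, cfg, ranges = ws, mode = "linear")
nod <- entropy_of(swn$models, nir_obs, seed0 = 600L)
print(nod, digits = 4)
utils::write.csv(nod, "results/control_noninteracting_repeats.csv", row.names = FALSE)
iL <- match(paste0("W", L), nod$range); iP <- match(paste0("W", L - 1), nod$range)
cat(sprintf("entropy change across W = L: %.3f bits\n",
            nod$S_bits[iL] - nod$S_bits[iP]))
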