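#' Metropolis-Hastings sampling of sequences from a Potts model
#'
#' Runs a single-site Metropolis chain on the interpolated energy
#' `E_alpha`: each step proposes a uniformly random site and a uniformly
#' random new symbol (excluding the current one, so the proposal is
#' symmetric), accepts energy-decreasing moves outright and others with
#' probability `exp(-dE)`. One sequence is recorded every `thinning`
#' proposals after `burn_in` proposals. The chain starts from a uniformly
#' random sequence unless `init` is given.
#'
#' @param model a `potts_model`.
#' @param n number of sequences to record.
#' @param alpha interaction interpolation parameter in `[0, 1]`.
#' @param thinning proposals between recorded sequences (default 1000).
#' @param burn_in discarded initial proposals (default `100 * thinning`).
#' @param seed integer seed (the sampler draws from R's RNG, so results are
#'   reproducible); `NULL` uses the current RNG state.
#' @param init optional starting sequence (0-based integers).
#' @return An object of class `sample_ensemble` with fields `seq`
#'   (`n x 2L` integer matrix), `alpha`, `thinning`, `burn_in`, `seed`,
#'   and the `model_fingerprint` of the generating model.
#' @export
metropolis_sample <- function(model, n, alpha = 1, thinning = 1000L,
                              burn_in = 100L * thinning, seed = NULL,
                              init = NULL) {
  stopifnot(inherits(model, "potts_model"), n >= 1, thinning >= 1,
            alpha >= 0, alpha <= 1)
  init <- if (is.null(init)) integer(0) else as.integer(init)
  seqs <- with_seed(seed,
    cpp_metropolis(model$h, model$pairs - 1L, flat_J(model), model$lambda,
                   alpha, model$L, as.integer(n), as.integer(thinning),
                   as.integer(burn_in), init))
  structure(list(seq = seqs, alpha = alpha, thinning = as.integer(thinning),
                 burn_in = as.integer(burn_in), seed = seed,
                 L = model$L, q = model$q,
                 model_fingerprint = model_fingerprint(model)),
            class = "sample_ensemble")
}

#' @export
print.sample_ensemble <- function(x, ...) {
  cat(sprintf("Sample ensemble: %d sequences of 2L = %d sites (alpha = %g, thinning = %d)\n",
              nrow(x$seq), 2L * x$L, x$alpha, x$thinning))
  invisible(x)
}

#' Empirical observables of a sampled ensemble
#'
#' Unweighted `f1`, `f2` (over all site pairs) and `P(ID)` of the ensemble,
#' in the same layout as [compute_observables()].
#'
#' @param ens a `sample_ensemble`, or a 0-based integer sequence matrix.
#' @param L,q required when `ens` is a bare matrix.
#' @return An `observable_set`.
#' @export
ensemble_observables <- function(ens, L = NULL, q = NULL) {
  if (inherits(ens, "sample_ensemble")) {
    seqs <- ens$seq; L <- ens$L; q <- ens$q
  } else seqs <- ens
  compute_observables(alignment_from_matrix(seqs, L, q))
}
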