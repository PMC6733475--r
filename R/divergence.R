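#' Kullback-Leibler divergence between two fitted family models
#'
#' Estimates both directions of
#' `D_KL(A||B) = <E_B - E_A>_A + F_A - F_B` by sampling from each model and
#' evaluating the other model's energy through a column map, with the free
#' energies obtained by thermodynamic integration. Reported in bits.
#'
#' The column map aligns the two models' sites: `map[i]` is the column of
#' model B homologous to column `i` of model A. It must be a bijection over
#' all columns of both models (so both models must span the same number of
#' sites); partial maps are refused because KL over a subset of columns is
#' not defined for these models. The identity map is used by default when
#' the models have equal length.
#'
#' @param modelA,modelB `potts_model`s.
#' @param map integer vector of length `2L_A`, a permutation of `1:(2L_B)`;
#'   `NULL` for the identity when lengths match.
#' @param n sequences per ensemble (and per TI grid point).
#' @param alpha_grid TI grid, as in [entropy_thermodynamic()].
#' @param thinning,burn_in sampling controls (`NULL`: defaults as elsewhere).
#' @param seed RNG seed.
#' @return List with `D_AB_bits`, `D_BA_bits` and their Monte-Carlo standard
#'   errors `se_AB_bits`, `se_BA_bits`.
#' @export
kl_divergence <- function(modelA, modelB, map = NULL, n = 80000L,
                          alpha_grid = seq(0, 1, length.out = 51),
                          thinning = NULL, burn_in = NULL, seed = NULL) {
  stopifnot(inherits(modelA, "potts_model"), inherits(modelB, "potts_model"))
  nA <- n_sites(modelA); nB <- n_sites(modelB)
  if (is.null(map)) {
    if (nA != nB)
      stop("models differ in length; an explicit full column map is required")
    map <- seq_len(nA)
  }
  map <- as.integer(map)
  if (length(map) != nA || !identical(sort(map), seq_len(nB)))
    stop("column map must be a bijection covering all columns of both models")
  if (modelA$q != modelB$q) stop("models must share the alphabet size")
  if (is.null(thinning)) thinning <- 15L * max(nA, nB)
  if (is.null(burn_in)) burn_in <- 100L * thinning

  cross_mean <- function(from, to, mp) {
    ens <- metropolis_sample(from, n, alpha = 1, thinning = thinning,
                             burn_in = burn_in)
    Eown <- energy(from, ens$seq)
    mapped <- ens$seq
    mapped[, mp] <- ens$seq
    Eother <- energy(to, mapped)
    d <- Eother - Eown
    c(mean = mean(d), se = stats::sd(d) / sqrt(n))
  }

  res <- with_seed(seed, {
    ab <- cross_mean(modelA, modelB, map)
    ba <- cross_mean(modelB, modelA, order(map))
    FA <- ti_free_energy(modelA, n, alpha_grid, thinning, burn_in)
    FB <- ti_free_energy(modelB, n, alpha_grid, thinning, burn_in)
    list(ab = ab, ba = ba, FA = FA, FB = FB)
  })
  D_AB <- res$ab["mean"] + res$FA$F1 - res$FB$F1
  D_BA <- res$ba["mean"] + res$FB$F1 - res$FA$F1
  seF <- sqrt(res$FA$se^2 + res$FB$se^2)
  list(D_AB_bits = log2e(unname(D_AB)), D_BA_bits = log2e(unname(D_BA)),
       se_AB_bits = log2e(sqrt(res$ab["se"]^2 + seF^2)),
       se_BA_bits = log2e(sqrt(res$ba["se"]^2 + seF^2)))
}

#' Divergence of a family model from random sequences
#'
#' `D_KL(model || rand) = n_sites * log2(q) - S_bits`: the entropy deficit
#' of the family relative to uniformly random sequences over the same
#' columns. `n_sites` is the model's full span (`2L` for pair-of-repeat
#' models).
#'
#' @param model a `potts_model`.
#' @param S_bits the model's entropy in bits (from
#'   [entropy_thermodynamic()] or [entropy_exact_enumeration()]).
#' @return Divergence in bits.
#' @export
kl_vs_random <- function(model, S_bits) {
  n_sites(model) * log2(model$q) - S_bits
}

#' Read a two-column TSV column map
#'
#' Each row maps a column of family A's alignment to the homologous column
#' of family B's alignment.
#'
#' @param path TSV file with columns `a` and `b` (1-based indices).
#' @return Integer vector usable as `map` in [kl_divergence()].
#' @export
read_column_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("a", "b"))
  map <- integer(max(tab$a))
  map[tab$a] <- tab$b
  if (any(map == 0) || anyDuplicated(tab$a) || anyDuplicated(tab$b))
    stop("column map must be one-to-one and cover every column")
  map
}
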