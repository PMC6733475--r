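#' Specification of a planted ground-truth model
#'
#' Describes a random Potts model used to generate synthetic two-repeat
#' families with known structure: Gaussian per-site fields, a sparse random
#' subset of site pairs carrying Gaussian coupling blocks, and optionally an
#' explicit overlap bias emulating the phylogenic similarity of consecutive
#' repeats. Default scales (`field_scale = 0.5`, `coupling_scale = 1`,
#' `coupling_density = 0.15` at `q = 4`) give landscapes that are neither
#' trivial (entropy near the random maximum) nor frozen (entropy near zero),
#' so frustration and multiple minima are exercised at enumeration-checkable
#' sizes.
#'
#' @param L repeat length (model spans `2L` sites).
#' @param q alphabet size (default 4 for desk-scale work).
#' @param field_scale standard deviation of the Gaussian fields.
#' @param coupling_density fraction of candidate pairs carrying a coupling
#'   block.
#' @param coupling_scale standard deviation of the Gaussian coupling entries.
#' @param coupling_pairs candidate pool: `"any"` pair, `"intra"`-repeat
#'   pairs only, or `"near"` pairs with `|i - j| <= near_range`.
#' @param near_range range for `coupling_pairs = "near"`.
#' @param tie_repeats build a repeat-structured model: fields and
#'   intra-repeat couplings are duplicated across the two halves, as in a
#'   family whose repeats are homologous. With `coupling_pairs = "intra"`
#'   this gives two identical non-interacting repeats; with `"any"`,
#'   inter-repeat coupling blocks are added on top (drawn freely, at the
#'   same density over the inter-repeat pair pool).
#' @param lambda_profile optional numeric vector of length `L + 1` of
#'   overlap multipliers (negative values at high ID favor similar repeats).
#' @param seed RNG seed; the model is fully reproducible from the spec.
#' @return A list of class `planted_spec`.
#' @export
planted_spec <- function(L, q = 4L, field_scale = 0.5, coupling_density = 0.15,
                         coupling_scale = 1.0,
                         coupling_pairs = c("any", "intra", "near"),
                         near_range = 2L, tie_repeats = FALSE,
                         lambda_profile = NULL, seed = 1L) {
  coupling_pairs <- match.arg(coupling_pairs)
  stopifnot(L >= 1, q >= 2, coupling_density >= 0, coupling_density <= 1,
            field_scale >= 0, coupling_scale >= 0)
  if (!is.null(lambda_profile)) stopifnot(length(lambda_profile) == L + 1)
  structure(list(L = as.integer(L), q = as.integer(q),
                 field_scale = field_scale,
                 coupling_density = coupling_density,
                 coupling_scale = coupling_scale,
                 coupling_pairs = coupling_pairs,
                 near_range = as.integer(near_range),
                 tie_repeats = tie_repeats,
                 lambda_profile = lambda_profile, seed = as.integer(seed)),
            class = "planted_spec")
}

#' Draw the planted model described by a spec
#'
#' @param spec a [planted_spec()].
#' @return A `potts_model` whose mask is exactly the set of planted pairs.
#' @export
make_planted_model <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  L <- spec$L; q <- spec$q; n <- 2L * L
  with_seed(spec$seed, {
    if (spec$tie_repeats) {
      h_half <- matrix(rnorm(q * L, sd = spec$field_scale), q, L)
      h <- cbind(h_half, h_half)
      pool <- all_pairs(n)
      pool <- pool[pool[, 2] <= L, , drop = FALSE]
      if (spec$coupling_pairs == "near")
        pool <- pool[pool[, 2] - pool[, 1] <= spec$near_range, , drop = FALSE]
      npick <- round(spec$coupling_density * nrow(pool))
      picked <- pool[sort(sample(nrow(pool), npick)), , drop = FALSE]
      Jh <- array(rnorm(q * q * npick, sd = spec$coupling_scale), c(q, q, npick))
      pairs <- rbind(picked, picked + L)
      J <- array(0, c(q, q, 2L * npick))
      if (npick > 0) { J[, , seq_len(npick)] <- Jh; J[, , npick + seq_len(npick)] <- Jh }
      if (spec$coupling_pairs == "any") {
        # homologous halves may still interact: free inter-repeat blocks
        inter <- all_pairs(n)
        inter <- inter[inter[, 1] <= L & inter[, 2] > L, , drop = FALSE]
        ni <- round(spec$coupling_density * nrow(inter))
        if (ni > 0) {
          ipick <- inter[sort(sample(nrow(inter), ni)), , drop = FALSE]
          pairs <- rbind(pairs, ipick)
          Ji <- array(rnorm(q * q * ni, sd = spec$coupling_scale), c(q, q, ni))
          J2 <- array(0, c(q, q, dim(J)[3] + ni))
          if (dim(J)[3] > 0) J2[, , seq_len(dim(J)[3])] <- J
          J2[, , dim(J)[3] + seq_len(ni)] <- Ji
          J <- J2
        }
      }
    } else {
      h <- matrix(rnorm(q * n, sd = spec$field_scale), q, n)
      pool <- switch(spec$coupling_pairs,
        any = all_pairs(n),
        intra = intra_repeat_pairs(L),
        near = make_mask_linear(n, spec$near_range))
      npick <- round(spec$coupling_density * nrow(pool))
      pairs <- pool[sort(sample(nrow(pool), npick)), , drop = FALSE]
      J <- array(rnorm(q * q * npick, sd = spec$coupling_scale), c(q, q, npick))
    }
    lambda <- if (is.null(spec$lambda_profile)) numeric(L + 1) else spec$lambda_profile
    potts_model(L, q, h = h, pairs = pairs, J = J, lambda = lambda)
  })
}

#' Sample a synthetic alignment from a planted model
#'
#' Draws `n` sequences from the model by Metropolis sampling at full
#' interaction strength and wraps them as a unit-weight alignment, ready for
#' the curation / fitting / entropy pipeline.
#'
#' @param model a `potts_model` (typically from [make_planted_model()]).
#' @param n number of sequences.
#' @param seed RNG seed.
#' @param thinning,burn_in chain controls (`NULL`: 15 proposals per site,
#'   burn-in 100x).
#' @return A `repeat_alignment`.
#' @export
make_planted_alignment <- function(model, n, seed = NULL, thinning = NULL,
                                   burn_in = NULL) {
  if (is.null(thinning)) thinning <- 15L * n_sites(model)
  if (is.null(burn_in)) burn_in <- 100L * thinning
  ens <- metropolis_sample(model, n, alpha = 1, thinning = thinning,
                           burn_in = burn_in, seed = seed)
  alignment_from_matrix(ens$seq, model$L, model$q,
                        ids = sprintf("synth%05d", seq_len(n)))
}

#' Toy residue-residue distance matrix with repeat geometry
#'
#' Emulates the contact pattern of an elongated repeat fold: short 3D
#' distances for sequence neighbors (`|i - j| <= near_range`) and for
#' homologous positions in consecutive repeats (`i, i + L`), large distances
#' elsewhere, with positive jitter. Thresholding it at a growing cutoff
#' first admits the local contacts and then, at a larger cutoff, the
#' inter-repeat contacts — a two-stage mask growth.
#'
#' @param n_sites number of sites (`2L`).
#' @param L repeat length.
#' @param near_range sequence-neighbor range given short distances.
#' @param seed RNG seed for the jitter.
#' @return Symmetric `n_sites x n_sites` matrix (angstrom-like units), zero
#'   diagonal.
#' @export
make_toy_distance_matrix <- function(n_sites, L, near_range = 1L, seed = 1L) {
  with_seed(seed, {
    d <- matrix(25, n_sites, n_sites) + matrix(abs(rnorm(n_sites^2, sd = 2)),
                                               n_sites, n_sites)
    for (i in seq_len(n_sites)) for (j in seq_len(n_sites)) {
      if (abs(i - j) <= near_range && i != j) d[i, j] <- 4 + abs(rnorm(1, sd = 0.5))
      if (abs(i - j) == L) d[i, j] <- 8 + abs(rnorm(1, sd = 0.5))
    }
    d <- (d + t(d)) / 2
    diag(d) <- 0
    d
  })
}
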