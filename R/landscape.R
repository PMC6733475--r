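#' Zero-temperature quench to a local energy minimum
#'
#' Greedy stochastic descent on the statistical energy with the overlap term
#' switched off (`lambda_ID = 0`): at each step all strictly
#' energy-decreasing moves are enumerated and one is drawn uniformly. The
#' move set contains every single-site substitution and, when
#' `allow_paired_double` and the two repeat halves carry the same symbol at
#' a homologous position, the synchronized double substitution writing the
#' same new symbol at both positions — this prevents residual phylogenic
#' signal in the couplings from creating spurious minima. Descent stops when
#' no move decreases the energy; the endpoint is a local minimum by
#' construction.
#'
#' @param model a `potts_model` (its `lambda` is ignored here).
#' @param start 0-based integer start sequence.
#' @param seed RNG seed for the uniform choice among improving moves.
#' @param allow_paired_double include synchronized double mutations?
#' @return List with `minimum` (the endpoint), `E_min` (its energy, overlap
#'   term off), and `n_steps`.
#' @export
quench <- function(model, start, seed = NULL, allow_paired_double = TRUE) {
  stopifnot(inherits(model, "potts_model"), length(start) == n_sites(model),
            all(start >= 0), all(start < model$q))
  with_seed(seed,
    cpp_quench(model$h, model$pairs - 1L, flat_J(model), as.integer(start),
               model$L, allow_paired_double))
}

#' Decompose a set of starting sequences into basins of attraction
#'
#' Quenches every start, groups starts by the exact local minimum they
#' reach, and weights each basin by the summed start weights. Basin
#' probabilities `P(b)` give the configurational entropy
#' `S_conf = -sum_b P(b) log2 P(b)` — the effective number of distinct
#' sub-families the landscape supports. Minima are returned ranked by basin
#' weight (largest first) together with their energies, ready for
#' rank-energy plots.
#'
#' @param model a `potts_model` (overlap term off during descent).
#' @param starts a `repeat_alignment` (its weights become the default start
#'   weights) or a 0-based integer matrix of sequences in rows.
#' @param start_weights optional per-start weights (default: alignment
#'   weights, else uniform).
#' @param seed RNG seed for the whole sweep of quenches.
#' @param allow_paired_double passed to [quench()].
#' @return Object of class `basin_partition`: `minima` (matrix, ranked),
#'   `E_min`, `sizes` (weighted), `P_b`, `assignment` (start to ranked
#'   minimum index), `S_conf_bits`, `n_starts`.
#' @export
basin_decomposition <- function(model, starts, start_weights = NULL, seed = 0L,
                                allow_paired_double = TRUE) {
  if (inherits(starts, "repeat_alignment")) {
    if (is.null(start_weights)) start_weights <- starts$weights
    starts <- starts$seq
  }
  stopifnot(is.matrix(starts), nrow(starts) >= 1,
            ncol(starts) == n_sites(model))
  if (is.null(start_weights)) start_weights <- rep(1, nrow(starts))
  stopifnot(length(start_weights) == nrow(starts), all(start_weights >= 0))

  res <- with_seed(seed, apply(starts, 1, function(s)
    cpp_quench(model$h, model$pairs - 1L, flat_J(model), as.integer(s),
               model$L, allow_paired_double),
    simplify = FALSE))
  minima_mat <- t(vapply(res, function(r) r$minimum, integer(ncol(starts))))
  keys <- apply(minima_mat, 1, paste, collapse = ",")
  uk <- unique(keys)
  idx <- match(keys, uk)
  sizes <- vapply(seq_along(uk), function(k) sum(start_weights[idx == k]), 0)
  E_min <- vapply(seq_along(uk), function(k)
    res[[which(idx == k)[1]]]$E_min, 0)
  ord <- order(-sizes, E_min)
  rank_of <- match(seq_along(uk), ord)
  P_b <- sizes[ord] / sum(sizes)
  S_conf <- max(-sum(ifelse(P_b > 0, P_b * log2(P_b), 0)), 0)
  structure(list(minima = minima_mat[!duplicated(keys), , drop = FALSE][ord, , drop = FALSE],
                 E_min = E_min[ord], sizes = sizes[ord], P_b = P_b,
                 assignment = rank_of[idx], S_conf_bits = S_conf,
                 n_starts = nrow(starts)),
            class = "basin_partition")
}

#' @export
print.basin_partition <- function(x, ...) {
  cat(sprintf("Basin partition: %d starts -> %d minima, S_conf = %.2f bits\n",
              x$n_starts, nrow(x$minima), x$S_conf_bits))
  cat(sprintf("  largest basins (P_b): %s\n",
              paste(sprintf("%.3f", head(x$P_b, 5)), collapse = ", ")))
  invisible(x)
}

#' Hierarchical organization of the dominant minima
#'
#' Selects the largest basins whose cumulative weight reaches `coverage`,
#' computes pairwise Hamming distances between their minima, and builds an
#' average-linkage agglomerative merge tree (cluster-cluster distance =
#' mean pairwise Hamming distance), whose leaf order lays out the block
#' structure of the distance matrix.
#'
#' @param partition a `basin_partition`.
#' @param coverage cumulative basin-weight target in (0, 1]; default 0.9.
#' @return List with `distance` (Hamming matrix over selected minima),
#'   `linkage` (an `hclust` tree, `NULL` if fewer than 2 minima selected),
#'   `selected` (indices into the ranked minima), and `order` (leaf order).
#' @export
minima_clustering <- function(partition, coverage = 0.9) {
  stopifnot(inherits(partition, "basin_partition"),
            coverage > 0, coverage <= 1)
  k <- which(cumsum(partition$P_b) >= coverage - 1e-12)[1]
  sel <- seq_len(k)
  mins <- partition$minima[sel, , drop = FALSE]
  if (k < 2)
    return(list(distance = matrix(0, k, k), linkage = NULL, selected = sel,
                order = sel))
  D <- matrix(0, k, k)
  for (i in 1:(k - 1)) for (j in (i + 1):k)
    D[i, j] <- D[j, i] <- sum(mins[i, ] != mins[j, ])
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  list(distance = D, linkage = hc, selected = sel, order = hc$order)
}

#' Energy of the consensus sequence
#'
#' Evaluates the model energy (overlap term off, as in the landscape
#' analyses) of the per-column most frequent symbol; ties go to the lowest
#' symbol index. Under an independent-sites model this is the global
#' minimum; under interacting models it need not be, which is the point of
#' comparing it with the quench minima.
#'
#' @param model a `potts_model`.
#' @param obs the `observable_set` defining the consensus.
#' @return Energy (scalar).
#' @export
consensus_energy <- function(model, obs) {
  energy(model, consensus_sequence(obs), use_lambda = FALSE)
}
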