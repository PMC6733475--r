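#' Amino-acid alphabet used throughout the package
#'
#' Twenty amino acids followed by the gap character. Symbols are coded
#' internally as 0-based integers, so the gap has index `q - 1 = 20`.
#' The gap is treated as a bona fide 21st state everywhere (energies,
#' overlap statistic, entropies), which is what makes the random-sequence
#' entropy `2L * log2(21)` bits.
#'
#' @return Character vector of length 21.
#' @export
aa_alphabet <- function() c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")

# map characters to 0-based symbol indices; '.' is a gap dialect and
# ambiguous residues (X/B/Z/U/O and anything else unknown) map to the gap,
# keeping q = 21 without inventing frequencies for rare codes
chars_to_int <- function(ch, q = 21L) {
  q <- as.integer(q)
  alpha <- aa_alphabet()
  idx <- match(toupper(ch), alpha) - 1L
  idx[toupper(ch) == "."] <- q - 1L
  idx[is.na(idx)] <- q - 1L
  idx
}

int_to_chars <- function(v) paste(aa_alphabet()[v + 1L], collapse = "")

new_alignment <- function(seq, ids, L, q = 21L, weights = NULL) {
  stopifnot(is.matrix(seq), ncol(seq) == 2L * L, all(seq >= 0L), all(seq < q))
  if (is.null(weights)) weights <- rep(1, nrow(seq))
  structure(list(seq = seq, ids = ids, L = as.integer(L), q = as.integer(q),
                 weights = weights),
            class = "repeat_alignment")
}

#' @export
print.repeat_alignment <- function(x, ...) {
  cat(sprintf("Two-repeat alignment: %d sequences, 2L = %d columns (L = %d), q = %d\n",
              nrow(x$seq), 2L * x$L, x$L, x$q))
  cat(sprintf("  effective sample size (sum of weights): %.1f\n", sum(x$weights)))
  invisible(x)
}

#' Construct an alignment from an integer matrix
#'
#' @param seq integer matrix (sequences in rows), symbols 0-based in `[0, q)`.
#' @param L repeat length; the matrix must have `2 * L` columns.
#' @param q alphabet size (default 21, gap = `q - 1`).
#' @param ids optional sequence identifiers.
#' @param weights optional per-sequence weights (default 1).
#' @return A `repeat_alignment`.
#' @export
alignment_from_matrix <- function(seq, L, q = 21L, ids = NULL, weights = NULL) {
  if (is.null(ids)) ids <- sprintf("seq%05d", seq_len(nrow(seq)))
  storage.mode(seq) <- "integer"
  new_alignment(seq, ids, L, q, weights)
}

#' Read a FASTA alignment of two-repeat sequences
#'
#' Every record must have exactly `2 * L` aligned columns. Both `-` and `.`
#' are read as gaps; ambiguous residue codes (X, B, Z, U, O) are mapped to
#' the gap state so the alphabet stays at 21 letters.
#'
#' @param path FASTA file.
#' @param L repeat length (half the number of alignment columns).
#' @param q alphabet size (default 21; smaller values are useful for
#'   synthetic reduced-alphabet families, which use the first `q` letters of
#'   [aa_alphabet()]).
#' @return A `repeat_alignment` with unit weights.
#' @export
read_pair_alignment <- function(path, L, q = 21L) {
  stopifnot(file.exists(path))
  recs <- Biostrings::readBStringSet(path)
  lens <- Biostrings::width(recs)
  if (length(unique(lens)) != 1L) {
    bad <- names(recs)[which(lens != lens[1])[1]]
    stop(sprintf("ragged alignment: record '%s' has %d columns, expected %d",
                 bad, lens[lens != lens[1]][1], lens[1]))
  }
  if (lens[1] != 2L * L)
    stop(sprintf("alignment has %d columns but 2*L = %d was requested", lens[1], 2L * L))
  chars <- strsplit(as.character(recs), "")
  seq <- t(vapply(chars, function(ch) chars_to_int(ch, q), integer(2L * L)))
  dimnames(seq) <- NULL
  if (any(seq >= q))
    stop(sprintf("alignment uses symbols outside the %d-letter alphabet", q))
  alignment_from_matrix(seq, L, q = q, ids = names(recs))
}

#' Write an alignment (or a plain sequence matrix) as FASTA
#'
#' @param x a `repeat_alignment` or 0-based integer matrix.
#' @param path output file.
#' @param ids identifiers used when `x` is a bare matrix.
#' @export
write_pair_alignment <- function(x, path, ids = NULL) {
  seq <- if (inherits(x, "repeat_alignment")) x$seq else x
  if (is.null(ids)) ids <- if (inherits(x, "repeat_alignment")) x$ids
                           else sprintf("seq%05d", seq_len(nrow(seq)))
  txt <- Biostrings::BStringSet(apply(seq, 1, int_to_chars))
  names(txt) <- ids
  Biostrings::writeXStringSet(txt, path)
  invisible(path)
}

#' Drop alignment columns dominated by gaps
#'
#' Columns whose gap fraction strictly exceeds `max_gap_frac` are removed.
#' Because the input is an alignment of already-paired repeats, positions
#' `i` and `i + L` are homologous and are dropped together if either side
#' exceeds the threshold, so the pair structure (and the ID statistic)
#' stays well defined; `L` shrinks accordingly.
#'
#' @param aln a `repeat_alignment`.
#' @param max_gap_frac gap-fraction threshold in (0, 1); default 0.8.
#' @return List with the curated `alignment` and the `kept` original column
#'   indices (both repeat halves).
#' @export
remove_gappy_columns <- function(aln, max_gap_frac = 0.8) {
  stopifnot(inherits(aln, "repeat_alignment"),
            max_gap_frac > 0, max_gap_frac < 1)
  gap <- aln$q - 1L
  gf <- colMeans(aln$seq == gap)
  L <- aln$L
  bad_half <- (gf[1:L] > max_gap_frac) | (gf[(L + 1):(2 * L)] > max_gap_frac)
  keep_half <- which(!bad_half)
  if (length(keep_half) == 0L) stop("all columns exceed the gap threshold")
  kept <- c(keep_half, keep_half + L)
  out <- alignment_from_matrix(aln$seq[, kept, drop = FALSE], length(keep_half),
                               q = aln$q, ids = aln$ids, weights = aln$weights)
  list(alignment = out, kept = kept)
}

#' Sequence reweighting by greedy identity clustering
#'
#' Greedy incremental clustering in input order: a sequence joins the first
#' cluster whose representative shares at least `identity_threshold` of its
#' `2L` columns (gaps included in the comparison); otherwise it seeds a new
#' cluster. Each sequence gets weight `1 / cluster size`, so weights sum to
#' the number of clusters and frequencies computed with them count every
#' cluster once. This is the usual redundancy correction applied before
#' computing alignment statistics.
#'
#' @param aln a `repeat_alignment`.
#' @param identity_threshold pairwise identity threshold in (0, 1); default 0.9.
#' @return The alignment with updated `weights` (and a `cluster` attribute on
#'   the weights giving the cluster index of each sequence).
#' @export
cluster_weights <- function(aln, identity_threshold = 0.9) {
  stopifnot(inherits(aln, "repeat_alignment"),
            identity_threshold > 0, identity_threshold < 1)
  cl <- cpp_cluster_greedy(aln$seq, identity_threshold)
  sizes <- tabulate(cl)
  w <- 1 / sizes[cl]
  attr(w, "cluster") <- cl
  aln$weights <- w
  aln
}

#' Empirical observables of a weighted alignment
#'
#' Computes the weighted single-site frequencies `f1` (a `q x 2L` matrix,
#' columns summing to 1), the joint pair frequencies `f2` for every ordered
#' site pair `i < j` (array `q x q x n_pairs`), and the distribution
#' `P(ID)` of the inter-repeat overlap `ID = #\{i : sigma_i == sigma_\{i+L\}\}`,
#' with gap matching gap counted as a match. These are the constraints the
#' Potts model is fit to.
#'
#' @param aln a `repeat_alignment` (run [cluster_weights()] first to
#'   correct for redundancy).
#' @return An object of class `observable_set` with fields `f1`, `f2`,
#'   `pairs`, `P_ID`, `n_eff`, `L`, `q`.
#' @export
compute_observables <- function(aln) {
  stopifnot(inherits(aln, "repeat_alignment"), aln$L >= 1L)
  n <- 2L * aln$L
  pairs <- all_pairs(n)
  raw <- cpp_observables(aln$seq, aln$weights, pairs - 1L, aln$q, aln$L)
  # C++ packs f2 with the second site's symbol fastest; reorder to [a, b, pair]
  f2 <- aperm(array(raw$f2, dim = c(aln$q, aln$q, nrow(pairs))), c(2, 1, 3))
  structure(list(f1 = raw$f1, f2 = f2, pairs = pairs,
                 P_ID = as.numeric(raw$pid), n_eff = raw$w_total,
                 L = aln$L, q = aln$q),
            class = "observable_set")
}

#' @export
print.observable_set <- function(x, ...) {
  cat(sprintf("Observables: 2L = %d sites, q = %d, %d site pairs, n_eff = %.1f\n",
              2L * x$L, x$q, nrow(x$pairs), x$n_eff))
  invisible(x)
}

# canonical ordering of all unordered site pairs, 1-based
all_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  unname(as.matrix(idx))
}

# lookup table: pair_index_matrix(n)[i, j] = row of all_pairs(n) holding (i, j)
pair_index_matrix <- function(n) {
  p <- all_pairs(n)
  M <- matrix(NA_integer_, n, n)
  M[cbind(p[, 1], p[, 2])] <- seq_len(nrow(p))
  M[cbind(p[, 2], p[, 1])] <- seq_len(nrow(p))
  M
}
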