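#' Construct a Potts model for a pair of repeats
#'
#' The statistical energy of a sequence `sigma` of `2L` sites is
#' \deqn{E(\sigma) = -\sum_i h_i(\sigma_i) - \sum_{(i<j) \in mask}
#'   J_{ij}(\sigma_i, \sigma_j) + \lambda_{ID(\sigma)},}
#' where `ID` is the number of positions at which the two repeat halves carry
#' the same symbol. Each unordered pair contributes once. The model defines
#' the family distribution `P(sigma) = exp(-E) / Z`.
#'
#' @param L repeat length (the model spans `2L` sites).
#' @param q alphabet size (default 21; gap is symbol `q - 1`).
#' @param h `q x 2L` matrix of fields (default 0).
#' @param pairs integer matrix (`m x 2`, 1-based, `i < j`) of interacting
#'   site pairs — the interaction mask. Default: no pairs.
#' @param J `q x q x m` array of couplings aligned with `pairs` (default 0).
#' @param lambda numeric vector of length `L + 1`, the overlap multipliers
#'   `lambda_ID` for `ID = 0..L` (default 0).
#' @return An object of class `potts_model`.
#' @export
potts_model <- function(L, q = 21L, h = NULL, pairs = NULL, J = NULL, lambda = NULL) {
  L <- as.integer(L); q <- as.integer(q)
  n <- 2L * L
  if (is.null(h)) h <- matrix(0, q, n)
  stopifnot(nrow(h) == q, ncol(h) == n)
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) > 0)
    stopifnot(all(pairs[, 1] < pairs[, 2]), all(pairs >= 1), all(pairs <= n))
  if (is.null(J)) J <- array(0, dim = c(q, q, nrow(pairs)))
  stopifnot(identical(dim(J), c(q, q, nrow(pairs))) || nrow(pairs) == 0)
  if (is.null(lambda)) lambda <- numeric(L + 1)
  stopifnot(length(lambda) == L + 1)
  structure(list(h = h, pairs = pairs, J = J, lambda = as.numeric(lambda),
                 L = L, q = q),
            class = "potts_model")
}

#' @export
print.potts_model <- function(x, ...) {
  nz <- if (length(x$J)) sum(apply(x$J, 3, function(b) any(b != 0))) else 0L
  cat(sprintf("Potts model: 2L = %d sites, q = %d, %d masked pairs (%d with nonzero J), %s overlap term\n",
              2L * x$L, x$q, nrow(x$pairs), nz,
              if (any(x$lambda != 0)) "active" else "zero"))
  invisible(x)
}

n_sites <- function(model) 2L * model$L

# flatten J for the C++ layer (index p*q*q + a*q + b, 0-based symbols)
flat_J <- function(model) {
  if (length(model$J) == 0) return(numeric(0))
  as.numeric(aperm(model$J, c(2, 1, 3)))
}

#' Statistical energy of sequences under a model
#'
#' @param model a `potts_model`.
#' @param seqs a single sequence (0-based integer vector of length `2L`) or a
#'   matrix of sequences in rows.
#' @param alpha interpolation parameter in `[0, 1]`: the interaction part
#'   (couplings and overlap term) is scaled by `alpha`, the fields are not.
#'   `alpha = 1` is the full energy; `alpha = 0` is the independent-sites
#'   part `-sum_i h_i(sigma_i)`.
#' @param use_lambda set `FALSE` to evaluate with the overlap term switched
#'   off (as in landscape quenches).
#' @return Numeric vector of energies.
#' @export
energy <- function(model, seqs, alpha = 1, use_lambda = TRUE) {
  stopifnot(inherits(model, "potts_model"), alpha >= 0, alpha <= 1)
  if (!is.matrix(seqs)) seqs <- matrix(seqs, nrow = 1)
  if (ncol(seqs) != n_sites(model))
    stop(sprintf("sequence length %d does not match model with 2L = %d",
                 ncol(seqs), n_sites(model)))
  stopifnot(all(seqs >= 0), all(seqs < model$q))
  storage.mode(seqs) <- "integer"
  lam <- if (use_lambda) model$lambda else numeric(0)
  cpp_energy(seqs, model$h, model$pairs - 1L, flat_J(model), lam, alpha, model$L)
}

#' Interaction mask from linear sequence distance
#'
#' Pair `(i, j)` is allowed iff `|i - j| <= W`. `W = 0` gives the empty mask
#' (independent sites); `W >= 2L - 1` gives the complete graph. Homologous
#' positions in the two repeats enter at `W = L`.
#'
#' @param n_sites number of sites (`2L`).
#' @param W inclusive interaction range, in sites.
#' @return Integer matrix of allowed pairs (1-based, `i < j`).
#' @export
make_mask_linear <- function(n_sites, W) {
  stopifnot(W >= 0)
  p <- all_pairs(n_sites)
  p[p[, 2] - p[, 1] <= W, , drop = FALSE]
}

#' Interaction mask from a 3D residue-residue distance matrix
#'
#' @param d3 symmetric `2L x 2L` matrix of minimum heavy-atom distances
#'   (angstroms), zero diagonal.
#' @param cutoff pairs with `d3[i, j] <= cutoff` are allowed.
#' @return Integer matrix of allowed pairs.
#' @export
make_mask_3d <- function(d3, cutoff) {
  stopifnot(is.matrix(d3), nrow(d3) == ncol(d3), cutoff > 0)
  p <- all_pairs(nrow(d3))
  p[d3[p] <= cutoff, , drop = FALSE]
}

#' Read a whitespace-delimited square distance matrix
#' @param path text file with a `2L x 2L` numeric matrix.
#' @return Numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == ncol(m))
  m
}

#' Independent-sites model from observed frequencies
#'
#' Sets `h_i(sigma) = log((f_i(sigma) + pc) / (1 + q * pc))` with no
#' couplings and no overlap term; in the limit of zero pseudocount this is
#' the exact maximum-entropy model matching the single-site frequencies,
#' with fields normalized so that `sum_sigma exp(h_i(sigma)) = 1` and hence
#' `F(0) = 0`.
#'
#' @param obs an `observable_set`.
#' @param pseudocount small positive constant guarding `log(0)`.
#' @return A `potts_model`.
#' @export
independent_model <- function(obs, pseudocount = 1e-6) {
  stopifnot(inherits(obs, "observable_set"), pseudocount >= 0)
  h <- log((obs$f1 + pseudocount) / (1 + obs$q * pseudocount))
  potts_model(obs$L, obs$q, h = h)
}

#' Symmetrize observables across the two repeat halves
#'
#' Replaces single-site and intra-repeat pair frequencies by their average
#' over the two repeats,
#' `f'_i = f'_\{i+L\} = (f_i + f_\{i+L\}) / 2` and similarly for `f'_ij`
#' with both sites in the same repeat. These are the fitting targets for the
#' tied single-repeat models (with or without the overlap constraint).
#' Inter-repeat pair frequencies are left untouched (they are not
#' constrained by those models). `P(ID)` is unchanged.
#'
#' @param obs an `observable_set` over `2L` sites.
#' @return A new `observable_set` with symmetrized targets.
#' @export
symmetrize_single_repeat <- function(obs) {
  stopifnot(inherits(obs, "observable_set"))
  L <- obs$L
  out <- obs
  for (i in 1:L) {
    avg <- (obs$f1[, i] + obs$f1[, i + L]) / 2
    out$f1[, i] <- avg
    out$f1[, i + L] <- avg
  }
  pm <- pair_index_matrix(2L * L)
  for (i in 1:(L - 1)) for (j in (i + 1):L) {
    a <- pm[i, j]; b <- pm[i + L, j + L]
    avg <- (obs$f2[, , a] + obs$f2[, , b]) / 2
    out$f2[, , a] <- avg
    out$f2[, , b] <- avg
  }
  out
}

#' Consensus sequence of an observable set
#'
#' Per-column most frequent symbol; ties broken by the lowest symbol index.
#' @param obs an `observable_set`.
#' @return 0-based integer vector of length `2L`.
#' @export
consensus_sequence <- function(obs) {
  as.integer(apply(obs$f1, 2, which.max)) - 1L
}

# deterministic numeric fingerprint used in ensemble provenance
model_fingerprint <- function(model) {
  v <- c(2L * model$L, model$q, nrow(model$pairs),
         sum(model$h), sum(model$h^2), sum(model$J), sum(model$J^2),
         sum(model$lambda), sum(model$lambda^2))
  paste(sprintf("%.10g", v), collapse = ":")
}

#' Serialize a Potts model to JSON
#'
#' Couplings are stored as sparse triplets (pair, symbol a, symbol b, value)
#' so files stay small for L1-sparse fits. A fingerprint of the parameters is
#' included so downstream ensembles can be traced to the model that produced
#' them.
#'
#' @param model a `potts_model`.
#' @param path output file.
#' @export
write_potts_json <- function(model, path) {
  nzi <- which(model$J != 0, arr.ind = TRUE)
  obj <- list(L = model$L, q = model$q, h = model$h,
              pairs = model$pairs,
              J_triplets = if (nrow(nzi)) cbind(nzi[, 3], nzi[, 1], nzi[, 2],
                                                model$J[nzi]) else matrix(0, 0, 4),
              lambda = model$lambda,
              fingerprint = model_fingerprint(model))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a Potts model written by [write_potts_json()]
#' @param path JSON file.
#' @return A `potts_model`.
#' @export
read_potts_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pr <- if (length(obj$pairs)) matrix(obj$pairs, ncol = 2) else NULL
  m <- potts_model(obj$L, obj$q, h = matrix(obj$h, obj$q), pairs = pr)
  tr <- obj$J_triplets
  if (length(tr) && nrow(tr <- matrix(tr, ncol = 4)) > 0)
    m$J[cbind(tr[, 2], tr[, 3], tr[, 1])] <- tr[, 4]
  m$lambda <- as.numeric(obj$lambda)
  m
}
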