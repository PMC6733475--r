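# Shared fixtures: tiny alignments and models built in code.

# alignment from character strings, e.g. aln_from_strings(c("ACDA", "ACDA"))
aln_from_strings <- function(strs, L = nchar(strs[1]) / 2, q = 21L) {
  seq <- t(vapply(strsplit(strs, ""), repeatpotts:::chars_to_int, integer(nchar(strs[1]))))
  alignment_from_matrix(seq, L, q)
}

# write a fasta file in a temp path
write_tmp_fasta <- function(strs, ids = sprintf("s%d", seq_along(strs))) {
  path <- tempfile(fileext = ".fa")
  writeLines(paste0(">", ids, "\n", strs), path)
  path
}

# small random model via the planted generator
small_model <- function(L = 3, q = 3, seed = 1, density = 0.25, lambda = NULL) {
  make_planted_model(planted_spec(L = L, q = q, coupling_density = density,
                                  lambda_profile = lambda, seed = seed))
}

# exact KL divergence between two same-shape models by enumeration (nats)
kl_exact_nats <- function(mA, mB) {
  eA <- repeatpotts:::cpp_enumerate(mA$h, mA$pairs - 1L, repeatpotts:::flat_J(mA),
                                    mA$lambda, 1, mA$L, FALSE, TRUE)
  eB <- repeatpotts:::cpp_enumerate(mB$h, mB$pairs - 1L, repeatpotts:::flat_J(mB),
                                    mB$lambda, 1, mB$L, FALSE, TRUE)
  lpA <- -eA$energies - eA$logZ
  lpB <- -eB$energies - eB$logZ
  sum(exp(lpA) * (lpA - lpB))
}

# all q^n sequences as a matrix (odometer order, site 1 fastest), 0-based
all_states <- function(n, q) {
  m <- as.matrix(expand.grid(rep(list(0:(q - 1)), n)))
  dimnames(m) <- NULL
  m
}
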