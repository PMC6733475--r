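# two binary ferromagnetic blocks: J > 0 rewards equal symbols inside a block,
# giving planted degenerate minima (all-0 / all-1 per block)
ferro_block_model <- function(blocks, J0 = 1) {
  n <- length(sort(unique(unlist(blocks))))
  pairs <- do.call(rbind, lapply(blocks, function(b) t(utils::combn(b, 2))))
  J <- array(0, c(2, 2, nrow(pairs)))
  for (p in seq_len(nrow(pairs))) { J[1, 1, p] <- J0; J[2, 2, p] <- J0 }
  potts_model(n / 2, 2, pairs = pairs, J = J)
}

test_that("quenching an independent model always reaches the consensus", {
  aln <- aln_from_strings(c("ACAC", "AAAC", "ACCC", "ACAA", "ACAC"))
  obs <- compute_observables(aln)
  im <- independent_model(obs, 1e-9)
  cons <- consensus_sequence(obs)
  set.seed(2)
  for (k in 1:10) {
    start <- sample(0:20, 4, replace = TRUE)
    qo <- quench(im, start, seed = k)
    expect_equal(qo$minimum, cons)
  }
  # a start already at the minimum returns unchanged with zero steps
  q0 <- quench(im, cons, seed = 1)
  expect_equal(q0$n_steps, 0)
  expect_equal(q0$minimum, cons)
})

test_that("a frustrated two-state toy quenches into one of its planted minima", {
  m <- ferro_block_model(list(1:4), J0 = 1)  # 2L = 4 binary, one block
  g0 <- rep(0L, 4); g1 <- rep(1L, 4)
  states <- all_states(4, 2)
  for (r in seq_len(nrow(states))) {
    qo <- quench(m, states[r, ], seed = r, allow_paired_double = FALSE)
    expect_true(identical(qo$minimum, g0) || identical(qo$minimum, g1))
    # descent must strictly reduce the energy
    expect_lte(energy(m, qo$minimum, use_lambda = FALSE),
               energy(m, states[r, ], use_lambda = FALSE))
  }
})

test_that("quench endpoints are true local minima by exhaustive neighbor check", {
  m <- small_model(L = 3, q = 3, seed = 17, density = 0.4)
  set.seed(5)
  for (k in 1:8) {
    start <- sample(0:2, 6, replace = TRUE)
    qo <- quench(m, start, seed = 10 + k, allow_paired_double = FALSE)
    e0 <- energy(m, qo$minimum, use_lambda = FALSE)
    for (site in 1:6) for (b in 0:2) {
      if (b == qo$minimum[site]) next
      nb <- qo$minimum; nb[site] <- b
      expect_gt(energy(m, nb, use_lambda = FALSE), e0)
    }
  }
})

test_that("quench ignores the overlap multipliers", {
  m <- small_model(L = 2, q = 3, seed = 23, density = 0.5)
  m_lam <- m
  m_lam$lambda <- c(5, 0, -5)  # large bias that must not alter descent
  q1 <- quench(m, c(0L, 1L, 2L, 0L), seed = 3)
  q2 <- quench(m_lam, c(0L, 1L, 2L, 0L), seed = 3)
  expect_identical(q1$minimum, q2$minimum)
  expect_identical(q1$E_min, q2$E_min)
})

test_that("basin decomposition yields the constructed configurational entropies", {
  # one basin: independent model, S_conf = 0
  obs <- compute_observables(aln_from_strings(c("ACAC", "AAAC", "ACCC")))
  im <- independent_model(obs, 1e-9)
  set.seed(8)
  starts1 <- matrix(sample(0:20, 20 * 4, replace = TRUE), 20)
  b1 <- basin_decomposition(im, starts1, seed = 0)
  expect_equal(nrow(b1$minima), 1)
  expect_equal(b1$S_conf_bits, 0)

  # two equal basins -> 1 bit (starts sit at the two planted minima)
  m2 <- ferro_block_model(list(1:4))
  b2 <- basin_decomposition(m2, rbind(rep(0L, 4), rep(1L, 4)), seed = 0,
                            allow_paired_double = FALSE)
  expect_equal(b2$S_conf_bits, 1)
  expect_equal(b2$P_b, c(0.5, 0.5))

  # four equal basins from two independent binary blocks -> 2 bits
  m4 <- ferro_block_model(list(1:2, 3:4))
  starts4 <- rbind(c(0L, 0L, 0L, 0L), c(0L, 0L, 1L, 1L),
                   c(1L, 1L, 0L, 0L), c(1L, 1L, 1L, 1L))
  b4 <- basin_decomposition(m4, starts4, seed = 0, allow_paired_double = FALSE)
  expect_equal(nrow(b4$minima), 4)
  expect_equal(b4$S_conf_bits, 2)
  # weighted starts shift P(b): weights (3,1) over two basins
  b2w <- basin_decomposition(m2, rbind(rep(0L, 4), rep(1L, 4)),
                             start_weights = c(3, 1), seed = 0,
                             allow_paired_double = FALSE)
  expect_equal(b2w$P_b, c(0.75, 0.25))
  expect_equal(b2w$S_conf_bits, -0.75 * log2(0.75) - 0.25 * log2(0.25))
})

test_that("without paired doubles, tied-repeat minima factorize over repeats", {
  # tied intra-repeat model: the pair landscape is a product of two copies
  spec <- planted_spec(L = 3, q = 3, coupling_density = 0.6,
                       coupling_pairs = "intra", tie_repeats = TRUE, seed = 31)
  m <- make_planted_model(spec)
  set.seed(41)
  starts <- matrix(sample(0:2, 30 * 6, replace = TRUE), 30)
  part <- basin_decomposition(m, starts, seed = 1, allow_paired_double = FALSE)
  # collect single-repeat minima reached from single-repeat quenches
  half_minima <- unique(part$minima[, 1:3, drop = FALSE])
  for (r in seq_len(nrow(part$minima))) {
    expect_true(any(apply(half_minima, 1, identical, part$minima[r, 1:3])))
    expect_true(any(apply(half_minima, 1, identical, part$minima[r, 4:6])))
  }
})

test_that("minima clustering selects basins to coverage and uses average linkage", {
  part <- structure(list(
    minima = rbind(c(0L, 0L, 0L, 0L), c(1L, 1L, 1L, 1L), c(0L, 1L, 0L, 1L)),
    E_min = c(-3, -2.5, -1), sizes = c(45, 45, 10), P_b = c(0.45, 0.45, 0.10),
    assignment = integer(0), S_conf_bits = NA, n_starts = 100L),
    class = "basin_partition")
  cl <- minima_clustering(part, coverage = 0.9)
  expect_equal(cl$selected, 1:2)  # the two large basins reach 90% exactly
  expect_equal(cl$distance[1, 2], 4)
  # distinct minima always at positive distance
  expect_true(all(cl$distance[upper.tri(cl$distance)] > 0))
  # average linkage: d({a},{b,c}) = mean of the two pairwise distances
  cl3 <- minima_clustering(part, coverage = 1)
  d <- cl3$distance
  hc <- cl3$linkage
  first <- which(hc$merge[, 1] < 0 & hc$merge[, 2] < 0)[1]
  pairm <- -hc$merge[first, ]
  singleton <- setdiff(1:3, pairm)
  expect_equal(hc$height[2], mean(d[singleton, pairm]))
  # single dominant basin -> trivial output
  part1 <- part; part1$P_b <- c(0.95, 0.04, 0.01)
  expect_null(minima_clustering(part1, coverage = 0.9)$linkage)
})

test_that("consensus energy bounds the landscape appropriately", {
  obs <- compute_observables(aln_from_strings(c("ACAC", "AAAC", "ACCC")))
  im <- independent_model(obs, 1e-9)
  # independent model: consensus is the global minimum (spot-check by sampling)
  set.seed(3)
  rand <- matrix(sample(0:20, 200 * 4, replace = TRUE), 200)
  expect_true(all(energy(im, rand, use_lambda = FALSE) >=
                  consensus_energy(im, obs) - 1e-12))
  # frustrated planted toy: consensus energy >= global minimum
  m <- small_model(L = 2, q = 3, seed = 51, density = 0.8)
  obs_m <- ensemble_observables(metropolis_sample(m, 2000, thinning = 20, seed = 6))
  Eall <- energy(m, all_states(4, 3), use_lambda = FALSE)
  expect_gte(consensus_energy(m, obs_m), min(Eall) - 1e-12)
})
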