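test_that("energy evaluates fields, couplings and the overlap term", {
  # L = 1, q = 2 toy with one coupled pair and an overlap profile
  m <- potts_model(1, 2, h = matrix(c(0.5, 0, 0, 0.3), 2, 2),
                   pairs = matrix(c(1, 2), 1), J = array(0, c(2, 2, 1)),
                   lambda = c(0.1, -0.1))
  m$J[1, 2, 1] <- 0.2
  # sigma = (A,B): ID = 0 -> E = -0.5 - 0.3 - 0.2 + 0.1
  expect_equal(energy(m, c(0L, 1L)), -0.9)
  # sigma = (A,A): ID = 1, J(A,A) = 0 -> E = -0.5 + (-0.1)
  expect_equal(energy(m, c(0L, 0L)), -0.6)
  # null model: E identically zero
  expect_equal(energy(potts_model(2, 3), matrix(c(0L, 1L, 2L, 0L), 1)), 0)
  expect_error(energy(m, c(0L, 1L, 0L)), "length")
})

test_that("the interpolated energy is linear in alpha with the right endpoints", {
  m <- small_model(L = 2, q = 3, seed = 4, lambda = c(0.3, -0.1, 0.2))
  s <- c(0L, 2L, 1L, 2L)
  e0 <- energy(m, s, alpha = 0)
  e1 <- energy(m, s, alpha = 1)
  expect_equal(e0, -sum(m$h[cbind(s + 1, 1:4)]))
  for (a in c(0.25, 0.5, 0.9))
    expect_equal(energy(m, s, alpha = a), (1 - a) * e0 + a * e1)
})

test_that("linear and 3D masks select the advertised pairs", {
  expect_equal(make_mask_linear(4, 1), rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(nrow(make_mask_linear(4, 3)), 6)    # complete graph
  expect_equal(nrow(make_mask_linear(4, 0)), 0)    # independent model
  # W = L admits the homologous pairs (i, i + L)
  mk <- make_mask_linear(8, 4)
  expect_true(all(apply(cbind(1:4, 5:8), 1, function(p)
    any(mk[, 1] == p[1] & mk[, 2] == p[2]))))
  # masks nest as W grows
  w2 <- make_mask_linear(8, 2); w5 <- make_mask_linear(8, 5)
  key <- function(p) p[, 1] * 100 + p[, 2]
  expect_true(all(key(w2) %in% key(w5)))

  d3 <- make_toy_distance_matrix(6, 3, near_range = 1, seed = 2)
  expect_equal(nrow(make_mask_3d(d3, cutoff = max(d3) + 1)), 15)
  expect_equal(nrow(make_mask_3d(d3, cutoff = min(d3[d3 > 0]) / 2)), 0)
  m10 <- make_mask_3d(d3, 10)
  expect_equal(nrow(m10), sum(d3[upper.tri(d3)] <= 10))
})

test_that("Boltzmann probabilities normalize and are gauge invariant", {
  m <- small_model(L = 2, q = 3, seed = 11, lambda = c(0.2, 0, -0.2))
  en <- entropy_exact_enumeration(m)
  states <- all_states(4, 3)
  p <- exp(-energy(m, states) - en$logZ)
  expect_equal(sum(p), 1, tolerance = 1e-10)
  # shifting any field column by a constant shifts all energies equally
  m2 <- m
  m2$h[, 2] <- m2$h[, 2] + 1.7
  en2 <- entropy_exact_enumeration(m2)
  p2 <- exp(-energy(m2, states) - en2$logZ)
  expect_equal(p, p2, tolerance = 1e-10)
  expect_equal(en$S_nats, en2$S_nats, tolerance = 1e-10)
})

test_that("independent model reproduces marginals and closed-form limits", {
  aln <- aln_from_strings(c("ACAC", "ACAA", "CAAC", "ACAC"))
  obs <- compute_observables(aln)
  im <- independent_model(obs, pseudocount = 0)
  # h = log f makes exp(h) sum to 1 per site and F(0) = 0 exactly
  expect_equal(free_energy_independent(im), 0, tolerance = 1e-9)
  # uniform frequencies -> equal fields
  u <- obs; u$f1 <- matrix(1 / obs$q, obs$q, 4)
  imu <- independent_model(u)
  expect_true(all(abs(imu$h - imu$h[1, 1]) < 1e-12))
  # one-hot frequencies: consensus symbol has the maximal field everywhere
  oh <- compute_observables(aln_from_strings(rep("ACAC", 3)))
  imo <- independent_model(oh, pseudocount = 1e-8)
  expect_equal(unname(apply(imo$h, 2, which.max)) - 1L, consensus_sequence(oh))
})

test_that("repeat symmetrization averages the halves and keeps marginals", {
  aln <- aln_from_strings(c("ACDA", "CCDA", "ACCA", "GHKL", "GHLL"))
  obs <- compute_observables(aln)
  so <- symmetrize_single_repeat(obs)
  L <- obs$L
  for (i in 1:L) {
    expect_equal(so$f1[, i], (obs$f1[, i] + obs$f1[, i + L]) / 2)
    expect_equal(so$f1[, i], so$f1[, i + L])
  }
  pm <- repeatpotts:::pair_index_matrix(2 * L)
  a <- pm[1, 2]; b <- pm[1 + L, 2 + L]
  expect_equal(so$f2[, , a], (obs$f2[, , a] + obs$f2[, , b]) / 2)
  expect_equal(so$f2[, , a], so$f2[, , b])
  # symmetrized pair blocks still marginalize to symmetrized singles
  expect_equal(rowSums(so$f2[, , a]), so$f1[, 1])
  # an already-symmetric observable set is a fixed point
  so2 <- symmetrize_single_repeat(so)
  expect_equal(so2$f1, so$f1)
  expect_equal(so2$f2, so$f2)
})

test_that("model JSON round-trips parameters exactly", {
  m <- small_model(L = 3, q = 4, seed = 9, lambda = c(0.5, 0, -0.2, 0.1))
  path <- tempfile(fileext = ".json")
  write_potts_json(m, path)
  m2 <- read_potts_json(path)
  expect_equal(m2$h, m$h)
  expect_equal(m2$J, m$J)
  expect_equal(m2$lambda, m$lambda)
  expect_equal(m2$pairs, m$pairs)
  s <- c(0L, 3L, 1L, 2L, 0L, 1L)
  expect_equal(energy(m2, s), energy(m, s))
})
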