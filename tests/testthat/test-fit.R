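# fits in this file use exact-enumeration observables where possible: fast,
# deterministic, and equal to the infinite-sample limit of the MC updates

all_pairs_of <- function(n) repeatpotts:::all_pairs(n)

test_that("a model already matching the data is an immediate fixed point", {
  m <- small_model(L = 2, q = 3, seed = 3, density = 0.5,
                   lambda = c(0.2, 0, -0.2))
  # targets = the model's own exact observables
  ex <- repeatpotts:::model_observables_for_fit(m, fit_config(), "exact")
  obs <- structure(list(f1 = ex$f1, f2 = NULL, pairs = all_pairs_of(4),
                        P_ID = ex$pid, n_eff = 1000, L = 2L, q = 3L),
                   class = "observable_set")
  # expand f2 over all pairs (model mask is a subset)
  full <- array(0, c(3, 3, 6))
  pm <- repeatpotts:::pair_index_matrix(4)
  full[, , pm[m$pairs]] <- ex$f2
  obs$f2 <- full
  f <- fit_model(obs, m, fit_config(), method = "exact")
  expect_true(f$report$converged)
  expect_equal(f$report$iterations, 1)
  expect_equal(f$model$h, m$h)
  expect_equal(f$model$J, m$J)
})

test_that("the L1 proximal rule applies its four cases literally", {
  up <- repeatpotts:::l1_coupling_update
  eps <- 0.05; gamma <- 0.001
  # zero coupling inside the tube stays zero
  expect_equal(up(array(0, c(1, 1, 1)), array(5e-4, c(1, 1, 1)), eps, gamma)[1], 0)
  # zero coupling outside the tube activates along the soft threshold
  expect_equal(up(array(0, c(1, 1, 1)), array(0.01, c(1, 1, 1)), eps, gamma)[1],
               eps * (0.01 - gamma))
  expect_equal(up(array(0, c(1, 1, 1)), array(-0.01, c(1, 1, 1)), eps, gamma)[1],
               eps * (-0.01 + gamma))
  # active coupling follows the penalized gradient
  expect_equal(up(array(0.2, c(1, 1, 1)), array(0.01, c(1, 1, 1)), eps, gamma)[1],
               0.2 + eps * (0.01 - gamma))
  # sign crossing clamps to zero
  expect_equal(up(array(1e-4, c(1, 1, 1)), array(-0.1, c(1, 1, 1)), eps, gamma)[1], 0)
})

test_that("exact-gradient fitting recovers a planted model's observables", {
  pm <- small_model(L = 3, q = 3, seed = 3, density = 0.3)
  aln <- make_planted_alignment(pm, 4000, seed = 5)
  obs <- compute_observables(aln)
  cfg <- fit_config(eps_id = 2, max_iters = 1500, seed = 9)
  init <- potts_model(3, 3, h = independent_model(obs)$h, pairs = all_pairs_of(6))
  f <- fit_model(obs, init, cfg, method = "exact")
  expect_true(f$report$converged)
  fe <- f$report$final_errors
  expect_lt(max(fe$err_f1, fe$err_f2, fe$err_pid), cfg$tol)
  # errors measured against the data are genuinely below tol at the solution
  ex <- repeatpotts:::model_observables_for_fit(f$model, cfg, "exact")
  expect_lt(max(abs(ex$f1 - obs$f1)), cfg$tol)
  expect_lt(5 * max(abs(ex$pid - obs$P_ID)), cfg$tol)
})

test_that("overlap multipliers learn a planted P(ID) bias", {
  lam <- -1.2 * (0:3) / 3
  pm <- make_planted_model(planted_spec(L = 3, q = 3, coupling_density = 0,
                                        lambda_profile = lam, seed = 8))
  aln <- make_planted_alignment(pm, 6000, seed = 9)
  obs <- compute_observables(aln)
  cfg <- fit_config(eps_id = 2, max_iters = 2000, seed = 10)
  init <- independent_model(obs)
  f <- fit_model(obs, init, cfg, fit_J = FALSE, fit_lambda = TRUE,
                 method = "exact")
  expect_true(f$report$converged)
  ex <- repeatpotts:::model_observables_for_fit(f$model, cfg, "exact")
  expect_lt(max(abs(ex$pid - obs$P_ID)), cfg$tol / cfg$id_penalty)
})

test_that("tied fits share parameters across repeats and match symmetrized targets", {
  pm <- make_planted_model(planted_spec(L = 2, q = 3, coupling_density = 1,
                                        coupling_pairs = "intra",
                                        tie_repeats = TRUE, seed = 12))
  aln <- make_planted_alignment(pm, 4000, seed = 13)
  obs <- compute_observables(aln)
  cfg <- fit_config(eps_id = 2, max_iters = 1500, seed = 14)
  init <- potts_model(2, 3, h = independent_model(obs)$h,
                      pairs = repeatpotts:::intra_repeat_pairs(2))
  f <- fit_model(obs, init, cfg, fit_lambda = FALSE, tie_repeats = TRUE,
                 method = "exact")
  expect_true(f$report$converged)
  m <- f$model
  expect_equal(m$h[, 1:2], m$h[, 3:4])
  # intra pair (1,2) equals its mirror (3,4)
  expect_equal(m$J[, , 1], m$J[, , 2])
  # a sequence and its repeat-swapped copy have equal energies
  s <- c(0L, 2L, 1L, 1L)
  expect_equal(energy(m, s, use_lambda = FALSE),
               energy(m, c(s[3:4], s[1:2]), use_lambda = FALSE))
  # a non-mirrored mask is refused
  expect_error(fit_model(obs, potts_model(2, 3, pairs = rbind(c(1L, 2L))),
                         cfg, tie_repeats = TRUE), "mirror")
})

test_that("update directions equal the analytic likelihood gradient", {
  # one exact iteration from a generic model: updates must be eps * (data - model)
  m <- small_model(L = 2, q = 3, seed = 30, density = 0.5,
                   lambda = c(0.1, 0, -0.1))
  aln <- make_planted_alignment(m, 1500, seed = 31)
  obs <- compute_observables(aln)
  cfg <- fit_config(max_iters = 1, seed = 1)
  init <- small_model(L = 2, q = 3, seed = 32, density = 0.5)
  f <- fit_model(obs, init, cfg, method = "exact")
  ex <- repeatpotts:::model_observables_for_fit(init, cfg, "exact")
  expect_equal(f$model$h, init$h + cfg$eps_m * (obs$f1 - ex$f1))
  expect_equal(f$model$lambda,
               init$lambda - cfg$eps_id * (obs$P_ID - ex$pid))
  pm <- repeatpotts:::pair_index_matrix(4)
  g <- obs$f2[, , pm[init$pairs], drop = FALSE] - ex$f2
  expect_equal(f$model$J,
               repeatpotts:::l1_coupling_update(init$J, g, cfg$eps_j, cfg$gamma))
})

test_that("the variant suite has the advertised structure", {
  pm <- small_model(L = 2, q = 3, seed = 40, density = 0.4,
                    lambda = c(0.4, 0, -0.4))
  aln <- make_planted_alignment(pm, 3000, seed = 41)
  obs <- compute_observables(aln)
  cfg <- fit_config(eps_id = 2, max_iters = 600, seed = 42)
  suite <- fit_variant_suite(obs, cfg, method = "exact")
  ms <- suite$models
  expect_named(ms, c("E_rand", "E_1", "E_full", "E_2", "E_ir", "E_ir_lambda"))
  # E_rand: all parameters zero
  expect_true(all(ms$E_rand$h == 0) && all(ms$E_rand$lambda == 0))
  # E_1: closed-form fields, no couplings
  expect_equal(nrow(ms$E_1$pairs), 0)
  # E_2 carries no overlap term; E_ir carries neither lambda nor inter-repeat J
  expect_true(all(ms$E_2$lambda == 0))
  expect_true(all(ms$E_ir$lambda == 0))
  expect_true(all(ms$E_ir$pairs[, 2] <= 2 | ms$E_ir$pairs[, 1] > 2))
  # entropies are ordered by constraint nesting (computed exactly here)
  S <- vapply(ms, function(m) entropy_exact_enumeration(m)$S_bits, 0)
  expect_gte(S[["E_rand"]] + 1e-6, S[["E_1"]])
  expect_gte(S[["E_1"]] + 0.05, S[["E_2"]])
  expect_gte(S[["E_2"]] + 0.05, S[["E_full"]])
})

test_that("seeded range sweeps are reproducible and nest correctly", {
  pm <- make_planted_model(planted_spec(L = 3, q = 3, coupling_density = 0.6,
                                        coupling_pairs = "near", near_range = 1,
                                        seed = 50))
  aln <- make_planted_alignment(pm, 3000, seed = 51)
  obs <- compute_observables(aln)
  cfg <- fit_config(eps_id = 2, max_iters = 400, seed = 52)
  sw <- fit_range_sweep(obs, cfg, ranges = c(0, 1, 3), fit_lambda = FALSE,
                        method = "exact")
  expect_named(sw$models, c("W0", "W1", "W3"))
  # W = 0 is an independent-sites fit
  expect_equal(nrow(sw$models$W0$pairs), 0)
  # masks nest along the sweep
  expect_true(nrow(sw$models$W1$pairs) < nrow(sw$models$W3$pairs))
  # identical seeds reproduce the whole sweep
  sw2 <- fit_range_sweep(obs, cfg, ranges = c(0, 1, 3), fit_lambda = FALSE,
                         method = "exact")
  expect_equal(sw$models$W3$J, sw2$models$W3$J)
  expect_equal(vapply(sw$reports, function(r) r$iterations, 0L),
               vapply(sw2$reports, function(r) r$iterations, 0L))
})
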