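#' Free energy of the independent-sites part of a model
#'
#' Closed form `F(0) = -sum_i log sum_sigma exp(h_i(sigma))`, the free
#' energy of the model at interpolation parameter `alpha = 0`. Computed with
#' log-sum-exp for overflow safety. For fields of the form `h = log f` (sums
#' of `exp(h)` equal to 1) this is exactly zero.
#'
#' @param model a `potts_model`.
#' @return `F(0)` in nats.
#' @export
free_energy_independent <- function(model) {
  h <- model$h
  mx <- apply(h, 2, max)
  -sum(mx + log(colSums(exp(sweep(h, 2, mx)))))
}

# entropy of an independent-sites distribution given per-site frequencies
indep_entropy_nats <- function(f1) {
  x <- f1 * log(f1)
  x[f1 == 0] <- 0
  -sum(x)
}

simpson_weights <- function(k, step) {
  stopifnot(k >= 3, k %% 2 == 1)
  w <- c(1, rep(c(4, 2), (k - 3) / 2), 4, 1)
  w * step / 3
}

# thermodynamic integration of dF/dalpha = <-sum J + lambda_ID>_alpha
# from the closed-form F(0); shared by the entropy and KL estimators.
# Draws from the current RNG stream.
ti_free_energy <- function(model, n, alpha_grid, thinning, burn_in) {
  k <- length(alpha_grid)
  stopifnot(k %% 2 == 1, abs(alpha_grid[1]) < 1e-12, abs(alpha_grid[k] - 1) < 1e-12,
            max(abs(diff(alpha_grid) - (alpha_grid[2] - alpha_grid[1]))) < 1e-9)
  mean_u <- se_u <- numeric(k)
  for (i in seq_len(k)) {
    ens <- metropolis_sample(model, n, alpha = alpha_grid[i],
                             thinning = thinning, burn_in = burn_in)
    # interaction part of the energy: E_1 - E_0 = -sum J + lambda_ID
    u <- energy(model, ens$seq, alpha = 1) - energy(model, ens$seq, alpha = 0)
    if (!all(is.finite(u)))
      stop(sprintf("non-finite integrand at alpha = %g", alpha_grid[i]))
    mean_u[i] <- mean(u)
    se_u[i] <- stats::sd(u) / sqrt(n)
  }
  w <- simpson_weights(k, alpha_grid[2] - alpha_grid[1])
  F0 <- free_energy_independent(model)
  list(F0 = F0, F1 = F0 + sum(w * mean_u), se = sqrt(sum((w * se_u)^2)),
       alpha_grid = alpha_grid, integrand = mean_u, integrand_se = se_u)
}

#' Entropy of a Potts model by thermodynamic integration
#'
#' Estimates `S = <E> - F(1)` where `F(1) = F(0) + int_0^1 <-sum J +
#' lambda_ID>_alpha dalpha`: ensembles are sampled at each grid value of the
#' interpolation parameter, the mean interaction energy is integrated by the
#' composite Simpson rule, and `<E>` is measured on a fresh ensemble at
#' `alpha = 1`. The default grid is 51 equally spaced points (step 0.02).
#' The Monte-Carlo error combines the per-alpha standard errors through the
#' Simpson weights with the standard error of `<E>` in quadrature.
#'
#' @param model a `potts_model`.
#' @param n sequences sampled per grid point.
#' @param alpha_grid uniform grid over `[0, 1]`, odd number of points.
#' @param thinning proposals between recorded sequences (`NULL`: 15 per site).
#' @param burn_in discarded proposals (`NULL`: `100 * thinning`).
#' @param seed RNG seed.
#' @return Object of class `entropy_result`: entropy in nats and bits,
#'   `mean_E`, `F0`, `F1`, the integrand table, and `mc_error_bits`.
#' @export
entropy_thermodynamic <- function(model, n = 80000L,
                                  alpha_grid = seq(0, 1, length.out = 51),
                                  thinning = NULL, burn_in = NULL, seed = NULL) {
  stopifnot(inherits(model, "potts_model"), n >= 2)
  if (is.null(thinning)) thinning <- 15L * n_sites(model)
  if (is.null(burn_in)) burn_in <- 100L * thinning
  res <- with_seed(seed, {
    fe <- ti_free_energy(model, n, alpha_grid, thinning, burn_in)
    ens <- metropolis_sample(model, n, alpha = 1, thinning = thinning,
                             burn_in = burn_in)
    E <- energy(model, ens$seq)
    list(fe = fe, mean_E = mean(E), se_E = stats::sd(E) / sqrt(n))
  })
  S <- res$mean_E - res$fe$F1
  mc <- sqrt(res$se_E^2 + res$fe$se^2)
  structure(list(S_nats = S, S_bits = log2e(S), mean_E = res$mean_E,
                 F0 = res$fe$F0, F1 = res$fe$F1,
                 alpha_grid = res$fe$alpha_grid, integrand = res$fe$integrand,
                 integrand_se = res$fe$integrand_se,
                 mc_error_nats = mc, mc_error_bits = log2e(mc), n = n),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("Entropy: %.2f bits (%.2f nats), MC error %.3f bits [n = %d per alpha]\n",
              x$S_bits, x$S_nats, x$mc_error_bits, x$n))
  invisible(x)
}

#' Exact entropy by full enumeration of the state space
#'
#' Brute-force oracle: sums over all `q^(2L)` sequences. Only feasible for
#' small systems; refuses state spaces above 1e7.
#'
#' @param model a `potts_model`.
#' @param alpha interpolation parameter (default 1, the full model).
#' @return List with `S_nats`, `S_bits`, `logZ` and `mean_E`.
#' @export
entropy_exact_enumeration <- function(model, alpha = 1) {
  stopifnot(inherits(model, "potts_model"))
  if (n_sites(model) * log(model$q) > log(1e7))
    stop("state space exceeds 1e7 sequences; enumeration refused")
  r <- cpp_enumerate(model$h, model$pairs - 1L, flat_J(model), model$lambda,
                     alpha, model$L, FALSE, FALSE)
  list(S_nats = r$S_nats, S_bits = log2e(r$S_nats), logZ = r$logZ,
       mean_E = r$mean_E)
}

#' Finite-sample error of the independent-sites entropy
#'
#' First-order error propagation from multinomial sampling noise in the
#' per-site frequencies: `Var(S) = (1/N_s) sum_i [sum_sigma p_i (log p_i)^2
#' - S_i^2]`, with `S_i` the entropy of site `i` and `N_s` the effective
#' sample size. Variances add over sites because sites are independent under
#' this model.
#'
#' @param obs an `observable_set` (uses `f1` and `n_eff`).
#' @return Standard deviation of the independent-sites entropy, in bits.
#' @export
entropy_error_independent <- function(obs) {
  stopifnot(inherits(obs, "observable_set"), obs$n_eff > 1)
  per_site <- apply(obs$f1, 2, function(p) {
    lp <- ifelse(p > 0, log(p), 0)
    sum(p * lp^2) - sum(p * lp)^2
  })
  log2e(sqrt(sum(per_site) / obs$n_eff))
}

#' Learning-bias error estimate for entropy values
#'
#' The systematic component of the entropy error bar: sample the fitted
#' model, build the independent-sites entropy from the sampled single-site
#' frequencies, and compare with the independent-sites entropy of the data
#' frequencies. The absolute difference is reported; interactions are
#' assumed not to change its order of magnitude.
#'
#' @param model fitted `potts_model`.
#' @param obs the data `observable_set` it was fit to.
#' @param n ensemble size.
#' @param thinning,burn_in,seed sampling controls as elsewhere.
#' @return Bias estimate in bits.
#' @export
estimate_learning_bias <- function(model, obs, n = 80000L, thinning = NULL,
                                   burn_in = NULL, seed = NULL) {
  stopifnot(inherits(model, "potts_model"), inherits(obs, "observable_set"))
  if (is.null(thinning)) thinning <- 15L * n_sites(model)
  if (is.null(burn_in)) burn_in <- 100L * thinning
  ens <- metropolis_sample(model, n, alpha = 1, thinning = thinning,
                           burn_in = burn_in, seed = seed)
  f1m <- ensemble_observables(ens)$f1
  log2e(abs(indep_entropy_nats(f1m) - indep_entropy_nats(obs$f1)))
}

#' Entropy of the unconstrained (random) model
#'
#' @param L repeat length; the model spans `2L` sites.
#' @param q alphabet size.
#' @return `2L * log2(q)` bits.
#' @export
entropy_random_bits <- function(L, q = 21L) 2 * L * log2(q)
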