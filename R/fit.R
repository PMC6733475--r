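#' Configuration for Boltzmann-machine learning
#'
#' Defaults are the published optimization hyperparameters: field step
#' `eps_m = 0.1`, coupling step `eps_j = 0.05`, overlap step `eps_id = 10`,
#' L1 strength `gamma = 0.001`, convergence threshold `tol = 0.02` on the
#' maximum observable error with the `P(ID)` error weighted by
#' `id_penalty = 5`, and 80000 Monte-Carlo sequences per iteration. The
#' per-iteration sample size and chain thinning are the knobs to scale the
#' fit down for small synthetic systems; `thinning = NULL` means 15 proposals
#' per site between recorded sequences (the per-site rate implied by the
#' published settings: 1000 proposals for 66 sites).
#'
#' @param eps_m,eps_j,eps_id gradient step sizes for fields, couplings and
#'   overlap multipliers.
#' @param gamma L1 regularization strength on couplings.
#' @param tol convergence threshold on the maximum observable error.
#' @param id_penalty weight multiplying the `P(ID)` error in the criterion.
#' @param n_samples Monte-Carlo sequences generated per iteration.
#' @param thinning proposals between recorded sequences (`NULL`: 15 per site).
#' @param burn_in discarded proposals before recording (`NULL`: `100 * thinning`).
#' @param max_iters iteration cap; hitting it reports `converged = FALSE`.
#' @param seed RNG seed for the whole fit.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(eps_m = 0.1, eps_j = 0.05, eps_id = 10, gamma = 0.001,
                       tol = 0.02, id_penalty = 5, n_samples = 80000L,
                       thinning = NULL, burn_in = NULL, max_iters = 500L,
                       seed = NULL) {
  stopifnot(eps_m > 0, eps_j > 0, eps_id > 0, gamma >= 0, tol > 0,
            n_samples >= 1, max_iters >= 1)
  structure(list(eps_m = eps_m, eps_j = eps_j, eps_id = eps_id, gamma = gamma,
                 tol = tol, id_penalty = id_penalty,
                 n_samples = as.integer(n_samples), thinning = thinning,
                 burn_in = burn_in, max_iters = as.integer(max_iters),
                 seed = seed),
            class = "fit_config")
}

cfg_thinning <- function(cfg, n_sites) {
  th <- if (is.null(cfg$thinning)) 15L * n_sites else as.integer(cfg$thinning)
  bi <- if (is.null(cfg$burn_in)) 100L * th else as.integer(cfg$burn_in)
  c(thinning = th, burn_in = bi)
}

# observables of the current model, over its own mask pairs
model_observables_for_fit <- function(model, cfg, method) {
  q <- model$q; m <- nrow(model$pairs)
  if (method == "exact") {
    r <- cpp_enumerate(model$h, model$pairs - 1L, flat_J(model), model$lambda,
                       1.0, model$L, TRUE, FALSE)
    f2 <- if (m > 0) aperm(array(r$f2, c(q, q, m)), c(2, 1, 3)) else array(0, c(q, q, 0))
    list(f1 = r$f1, f2 = f2, pid = as.numeric(r$pid))
  } else {
    tb <- cfg_thinning(cfg, n_sites(model))
    ens <- metropolis_sample(model, cfg$n_samples, alpha = 1,
                             thinning = tb["thinning"], burn_in = tb["burn_in"])
    raw <- cpp_observables(ens$seq, rep(1, nrow(ens$seq)), model$pairs - 1L,
                           q, model$L)
    f2 <- if (m > 0) aperm(array(raw$f2, c(q, q, m)), c(2, 1, 3)) else array(0, c(q, q, 0))
    list(f1 = raw$f1, f2 = f2, pid = as.numeric(raw$pid))
  }
}

# proximal L1 coupling update, the four-case rule applied entrywise:
# zero couplings stay at zero inside the gamma tube, otherwise activate along
# the soft-thresholded gradient; active couplings follow the penalized
# gradient and are clamped to zero if the step crosses sign.
l1_coupling_update <- function(J, g, eps, gamma) {
  out <- J
  zero <- J == 0
  act <- zero & (abs(g) > gamma)
  out[act] <- eps * (g[act] - gamma * sign(g[act]))
  nz <- !zero
  if (any(nz)) {
    cand <- J + eps * (g - gamma * sign(J))
    flip <- nz & (cand * J < 0)
    keep <- nz & !flip
    out[keep] <- cand[keep]
    out[flip] <- 0
  }
  out
}

# average h and J across the two repeat halves (used to keep tied models tied)
retie_model <- function(model, mirror) {
  L <- model$L
  havg <- (model$h[, 1:L] + model$h[, (L + 1):(2 * L)]) / 2
  model$h[, 1:L] <- havg
  model$h[, (L + 1):(2 * L)] <- havg
  if (length(mirror)) {
    first <- which(model$pairs[, 2] <= L)
    for (r in first) {
      avg <- (model$J[, , r] + model$J[, , mirror[r]]) / 2
      model$J[, , r] <- avg
      model$J[, , mirror[r]] <- avg
    }
  }
  model
}

#' Fit a Potts model by likelihood gradient ascent
#'
#' Boltzmann-machine learning: each iteration samples an ensemble from the
#' current model, measures its observables, and moves the parameters along
#' the likelihood gradient — fields by
#' `h <- h + eps_m (f_data - f_model)`, overlap multipliers by
#' `lambda <- lambda - eps_id (P_data - P_model)` (the sign reflects lambda
#' entering the energy with a plus), and couplings by an L1-penalized
#' proximal step that keeps the coupling matrix sparse. Iteration stops when
#' the maximum observable error — `max(|df1|, |df2|, id_penalty * |dP_ID|)`,
#' the `f2` errors taken over the fitted mask and the `P(ID)` term only when
#' `fit_lambda` — drops below `cfg$tol`, or at `cfg$max_iters` (reported, not
#' an error).
#'
#' @param obs data `observable_set` (the fitting targets).
#' @param init initial `potts_model`; its `pairs` mask defines which
#'   couplings are fit.
#' @param cfg a [fit_config()].
#' @param fit_J fit couplings (on the mask)?
#' @param fit_lambda fit the overlap multipliers?
#' @param tie_repeats fit a tied single-repeat model: targets are
#'   symmetrized across the two halves ([symmetrize_single_repeat()]) and
#'   `h`/intra-repeat `J` are shared between repeats. The mask must contain
#'   only intra-repeat pairs, mirrored in both halves.
#' @param method `"mc"` (Metropolis sampling) or `"exact"` (observables by
#'   full enumeration; only for small `q^(2L)`).
#' @param verbose print the error trace.
#' @return List with `model` (the fitted `potts_model`) and `report`
#'   (iterations, final errors, `converged` flag, per-iteration error trace).
#' @export
fit_model <- function(obs, init, cfg = fit_config(), fit_J = TRUE,
                      fit_lambda = TRUE, tie_repeats = FALSE,
                      method = c("mc", "exact"), verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(obs, "observable_set"), inherits(init, "potts_model"),
            obs$L == init$L, obs$q == init$q)
  model <- init
  L <- model$L
  pm <- pair_index_matrix(2L * L)
  m <- nrow(model$pairs)

  mirror <- integer(0)
  if (tie_repeats) {
    if (m > 0) {
      intra1 <- model$pairs[, 2] <= L
      intra2 <- model$pairs[, 1] > L
      if (!all(intra1 | intra2))
        stop("tie_repeats requires a mask of intra-repeat pairs only")
      mirror <- integer(m)
      key <- model$pairs[, 1] + (2L * L + 1L) * model$pairs[, 2]
      key_mirrored <- ifelse(intra1, model$pairs[, 1] + L, model$pairs[, 1] - L) +
        (2L * L + 1L) * ifelse(intra1, model$pairs[, 2] + L, model$pairs[, 2] - L)
      mirror <- match(key_mirrored, key)
      if (anyNA(mirror)) stop("tie_repeats mask must be mirrored across repeats")
    }
    obs <- symmetrize_single_repeat(obs)
    model <- retie_model(model, mirror)
  }

  sel <- if (m > 0) pm[model$pairs] else integer(0)
  f2d <- if (m > 0) obs$f2[, , sel, drop = FALSE] else array(0, c(obs$q, obs$q, 0))

  sym_mobs <- function(mobs) {
    # symmetrize the model's observables the same way as the data targets
    for (i in 1:L) {
      avg <- (mobs$f1[, i] + mobs$f1[, i + L]) / 2
      mobs$f1[, i] <- avg; mobs$f1[, i + L] <- avg
    }
    if (length(mirror)) {
      done <- rep(FALSE, m)
      for (r in seq_len(m)) {
        if (done[r]) next
        avg <- (mobs$f2[, , r] + mobs$f2[, , mirror[r]]) / 2
        mobs$f2[, , r] <- avg; mobs$f2[, , mirror[r]] <- avg
        done[r] <- TRUE; done[mirror[r]] <- TRUE
      }
    }
    mobs
  }

  run <- function() {
    trace <- data.frame(iter = integer(0), err_f1 = numeric(0),
                        err_f2 = numeric(0), err_pid = numeric(0),
                        err_max = numeric(0))
    converged <- FALSE
    it <- 0L
    while (it < cfg$max_iters) {
      it <- it + 1L
      mobs <- model_observables_for_fit(model, cfg, method)
      if (tie_repeats) mobs <- sym_mobs(mobs)
      d1 <- obs$f1 - mobs$f1
      d2 <- if (m > 0) f2d - mobs$f2 else array(0, c(obs$q, obs$q, 0))
      dp <- obs$P_ID - mobs$pid
      e1 <- max(abs(d1))
      e2 <- if (fit_J && m > 0) max(abs(d2)) else 0
      ep <- if (fit_lambda) cfg$id_penalty * max(abs(dp)) else 0
      emax <- max(e1, e2, ep)
      trace[nrow(trace) + 1L, ] <- list(it, e1, e2, ep, emax)
      if (verbose) message(sprintf("iter %4d  err_f1 %.4f  err_f2 %.4f  err_pid %.4f",
                                   it, e1, e2, ep))
      if (emax < cfg$tol) { converged <- TRUE; break }
      model$h <<- model$h + cfg$eps_m * d1
      if (fit_lambda)
        model$lambda <<- model$lambda - cfg$eps_id * dp
      if (fit_J && m > 0)
        model$J <<- l1_coupling_update(model$J, d2, cfg$eps_j, cfg$gamma)
      if (tie_repeats) model <<- retie_model(model, mirror)
    }
    list(iterations = it, converged = converged,
         final_errors = utils::tail(trace, 1), trace = trace)
  }
  report <- with_seed(cfg$seed, run())
  list(model = model, report = report)
}

intra_repeat_pairs <- function(L) {
  p <- all_pairs(2L * L)
  p[(p[, 2] <= L) | (p[, 1] > L), , drop = FALSE]
}

# new model on `mask`, inheriting h/lambda and any couplings of `prev` whose
# pair is still in the mask (newly unmasked couplings start at zero)
seed_model_on_mask <- function(prev, mask) {
  n <- 2L * prev$L
  init <- potts_model(prev$L, prev$q, h = prev$h, pairs = mask,
                      lambda = prev$lambda)
  if (nrow(mask) > 0 && nrow(prev$pairs) > 0) {
    keyn <- mask[, 1] + (n + 1L) * mask[, 2]
    keyp <- prev$pairs[, 1] + (n + 1L) * prev$pairs[, 2]
    hit <- match(keyp, keyn)
    ok <- !is.na(hit)
    init$J[, , hit[ok]] <- prev$J[, , ok]
  }
  init
}

#' Fit the full hierarchy of model variants
#'
#' Produces the six nested variants: `E_rand` (all parameters zero), `E_1`
#' (independent sites, closed form `h = log f`), `E_ir` (tied single-repeat
#' model, intra-repeat couplings only, no overlap term), `E_ir_lambda`
#' (same, plus the overlap multipliers; seeded from `E_ir`), `E_full` (all
#' couplings plus overlap term) and `E_2` (all couplings, no overlap term;
#' seeded from `E_full` with the overlap multipliers removed, as in the
#' published protocol).
#'
#' @param obs data `observable_set`.
#' @param cfg a [fit_config()].
#' @param method passed to [fit_model()].
#' @param seed_ladder optional ascending vector of linear ranges `W` ending
#'   at `2L - 1` or above: `E_full` is then learned as the endpoint of the
#'   progressively seeded range sweep (which converges to lower-entropy
#'   solutions than a de novo fit), and `E_ir` is seeded from the ladder
#'   model at `W = L - 1` with the inter-repeat couplings removed, following
#'   the published protocol. `NULL` fits `E_full` directly from the
#'   independent-sites start.
#' @return List with `models` (named list of `potts_model`) and `reports`.
#' @export
fit_variant_suite <- function(obs, cfg = fit_config(), method = "mc",
                              seed_ladder = NULL) {
  L <- obs$L; q <- obs$q; n <- 2L * L
  e_rand <- potts_model(L, q)
  e_1 <- independent_model(obs)
  models <- list(E_rand = e_rand, E_1 = e_1)
  reports <- list()

  base_ir <- NULL
  if (is.null(seed_ladder)) {
    init_full <- potts_model(L, q, h = e_1$h, pairs = all_pairs(n))
    ffull <- fit_model(obs, init_full, cfg, fit_J = TRUE, fit_lambda = TRUE,
                       method = method)
    models$E_full <- ffull$model; reports$E_full <- ffull$report
  } else {
    stopifnot(max(seed_ladder) >= n - 1L)
    sw <- fit_range_sweep(obs, cfg, ranges = seed_ladder, mode = "linear",
                          method = method)
    last <- length(sw$models)
    models$E_full <- sw$models[[last]]; reports$E_full <- sw$reports[[last]]
    wl1 <- paste0("W", L - 1L)
    if (wl1 %in% names(sw$models)) base_ir <- sw$models[[wl1]]
  }

  init_2 <- models$E_full
  init_2$lambda[] <- 0
  f2fit <- fit_model(obs, init_2, cfg, fit_J = TRUE, fit_lambda = FALSE,
                     method = method)
  models$E_2 <- f2fit$model; reports$E_2 <- f2fit$report

  init_ir <- if (is.null(base_ir)) {
    potts_model(L, q, h = e_1$h, pairs = intra_repeat_pairs(L))
  } else {
    ir <- seed_model_on_mask(base_ir, intra_repeat_pairs(L))
    ir$lambda[] <- 0
    ir
  }
  fir <- fit_model(obs, init_ir, cfg, fit_J = TRUE, fit_lambda = FALSE,
                   tie_repeats = TRUE, method = method)
  models$E_ir <- fir$model; reports$E_ir <- fir$report

  firl <- fit_model(obs, fir$model, cfg, fit_J = TRUE, fit_lambda = TRUE,
                    tie_repeats = TRUE, method = method)
  models$E_ir_lambda <- firl$model; reports$E_ir_lambda <- firl$report

  list(models = models, reports = reports)
}

#' Seeded sweep of models with growing interaction range
#'
#' Re-learns the model for each interaction range in `ranges`, each fit
#' initialized from the previous one (newly unmasked couplings start at
#' zero); the first fit starts from the independent model. Ranges are linear
#' sequence distances `|i - j| <= W` or 3D distance cutoffs against a
#' residue-residue distance matrix. The overlap term is fit throughout, so
#' the endpoints of a full linear sweep are the independent-plus-overlap
#' model and the fully constrained model.
#'
#' @param obs data `observable_set`.
#' @param cfg a [fit_config()].
#' @param ranges ascending vector of `W` values (sites) or cutoffs (angstroms).
#' @param mode `"linear"` or `"3d"`.
#' @param d3 distance matrix, required for `mode = "3d"`.
#' @param fit_lambda fit the overlap multipliers (default TRUE)?
#' @param method passed to [fit_model()].
#' @return List with `models`, `reports` and `ranges`.
#' @export
fit_range_sweep <- function(obs, cfg = fit_config(), ranges, mode = c("linear", "3d"),
                            d3 = NULL, fit_lambda = TRUE, method = "mc") {
  mode <- match.arg(mode)
  stopifnot(!is.unsorted(ranges))
  if (mode == "3d") stopifnot(is.matrix(d3), nrow(d3) == 2L * obs$L)
  n <- 2L * obs$L
  prev <- independent_model(obs)
  models <- list(); reports <- list()
  for (k in seq_along(ranges)) {
    mask <- if (mode == "linear") make_mask_linear(n, ranges[k])
            else make_mask_3d(d3, ranges[k])
    init <- seed_model_on_mask(prev, mask)
    fk <- fit_model(obs, init, cfg, fit_J = nrow(mask) > 0,
                    fit_lambda = fit_lambda, method = method)
    models[[k]] <- fk$model
    reports[[k]] <- fk$report
    prev <- fk$model
  }
  names(models) <- names(reports) <- paste0("W", ranges)
  list(models = models, reports = reports, ranges = ranges)
}
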