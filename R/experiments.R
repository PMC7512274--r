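# deterministic sub-seed derivation (kept below 2^31 - 1)
.sub_seed <- function(seed, a, b = 0) {
  ((seed %% 99991) * 20011 + a * 211 + b * 13 + 17) %% 2147483647
}

#' Study presets
#'
#' Bundled settings for the simulation studies. The `"paper"` preset is the
#' full protocol (10 trials, 100-point lambda grid, 300 sparse+low-rank
#' parameter pairs); the `"desk"` preset is a scaled-down version (3 trials,
#' 20-point lambda grid, 30 pairs, 2 trials for the baseline sweep) sized
#' for interactive runs.
#'
#' @param name `"desk"` or `"paper"`.
#' @return A list of study settings.
#' @export
study_preset <- function(name = c("desk", "paper")) {
  name <- match.arg(name)
  if (name == "paper") {
    list(name = name, n_trials = 10, T = 50000,
         lambda = seq(1e-3, 0.1, by = 1e-3),
         ks_values = c(2, 3, 15), nit_values = c(2, 3, 4),
         sl_trials = 10,
         sl_pairs = sl_pairs(lam = seq(0.1, 0.6, by = 0.1),
                             gamma = seq(0.01, 0.5, by = 0.01)))
  } else {
    list(name = name, n_trials = 3, T = 50000,
         lambda = seq(0.005, 0.1, by = 0.005),
         ks_values = c(2, 3, 15), nit_values = c(2, 3, 4),
         sl_trials = 2,
         sl_pairs = sl_pairs(lam = seq(0.1, 0.6, by = 0.1),
                             gamma = c(0.01, 0.1325, 0.255, 0.3775, 0.5)))
  }
}

#' Parameter pairs for the sparse+low-rank sweep
#'
#' @param lam vector of trace-penalty weights.
#' @param gamma vector of promoter ratios (promoter weight is
#'   `lam * gamma`); exactly one of `gamma`/`lam_gamma` must be given.
#' @param lam_gamma vector of promoter weights directly.
#' @return A data.frame with columns `lam` and `gamma`.
#' @export
sl_pairs <- function(lam, gamma = NULL, lam_gamma = NULL) {
  if (is.null(gamma) == is.null(lam_gamma))
    stop("give exactly one of 'gamma' or 'lam_gamma'")
  if (is.null(gamma)) {
    out <- expand.grid(lam = lam, lam_gamma = lam_gamma)
    out$gamma <- out$lam_gamma / out$lam
    out[, c("lam", "gamma")]
  } else {
    expand.grid(lam = lam, gamma = gamma)
  }
}

# simulate the manifest block of a synthetic system
.study_series <- function(gen, T, seed) {
  x <- simulate_var(gen$model, T, seed = seed)
  x[, seq_len(gen$pattern$k), drop = FALSE]
}

#' Oracle evaluation of the EM identification algorithm
#'
#' For each sparsity level `KS` and iteration budget `Nit`, simulates
#' trajectories from the synthetic system, runs the penalized EM loop over
#' the `lambda` grid and records the smallest distance between any candidate
#' pattern and the truth -- the distance an oracle with full knowledge of
#' the true pattern would achieve.
#'
#' @param ks_values sparsity levels to study.
#' @param nit_values EM iteration budgets.
#' @param n_trials trajectories per sparsity level.
#' @param T trajectory length.
#' @param lambda penalty grid.
#' @param threshold PSC threshold.
#' @param adaptive use the adaptive lambda sweep (default `TRUE`).
#' @param k,r,p synthetic-system dimensions.
#' @param seed master seed; model and trajectory seeds derive from it.
#' @param solver control list for the maximum-entropy solvers.
#' @param scale generator off-diagonal scale (default 1).
#' @return A data.frame with columns `ks`, `nit`, `trial`, `distance`;
#'   attribute `"summary"` holds the per-(ks, nit) mean distances.
#' @export
run_oracle_study <- function(ks_values = c(2, 3, 15),
                             nit_values = c(2, 3, 4), n_trials = 3,
                             T = 50000, lambda = seq(0.005, 0.1, by = 0.005),
                             threshold = 1e-3, adaptive = TRUE, k = 15,
                             r = 1, p = 1, seed = 1, solver = list(),
                             scale = 1) {
  rows <- list()
  for (ks in ks_values) {
    gen <- generate_synthetic_model(ks, k = k, r = r, p = p, scale = scale,
                                    seed = .sub_seed(seed, ks))
    for (trial in seq_len(n_trials)) {
      x <- .study_series(gen, T, .sub_seed(seed, ks, trial))
      for (nit in nit_values) {
        fit <- megvar(x, p = p, r = r, lambda = lambda, nit = nit,
                      threshold = threshold, adaptive = adaptive,
                      constrained = FALSE, score_loops = character(0),
                      solver = solver, keep_data = FALSE)
        dists <- vapply(fit$candidates, function(cd) {
          if (!isTRUE(cd$ok)) return(NA_real_)
          pattern_distance(cd$pattern, gen$pattern)
        }, 0)
        rows[[length(rows) + 1]] <-
          data.frame(ks = ks, nit = nit, trial = trial,
                     distance = min(dists, na.rm = TRUE))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- stats::aggregate(distance ~ ks + nit, out, mean)
  out
}

.selector_names <- function() c("oracle", .itc_names, "SF1", "SF2", "SF3")

#' Criterion-based selection study
#'
#' Runs the full algorithm (both EM loops) on synthetic trajectories and
#' lets every selection rule -- and an oracle knowing the truth -- pick its
#' winner among the lambda candidates; reports the distance of each selected
#' pattern to the true one, separately for criteria evaluated after the
#' penalized loop and after the constrained loop.
#'
#' @inheritParams run_oracle_study
#' @param nit EM iterations per loop (default 2).
#' @param gamma extended-criterion weight (default 1).
#' @param loops which loops to score: subset of
#'   `c("penalized", "constrained")` (default both).
#' @return A data.frame with columns `ks`, `trial`, `loop`, `selector`,
#'   `distance`; attribute `"summary"` holds per-(ks, loop, selector) means.
#' @export
run_selection_study <- function(ks_values = c(2, 3, 15), n_trials = 3,
                                T = 50000,
                                lambda = seq(0.005, 0.1, by = 0.005),
                                nit = 2, threshold = 1e-3, adaptive = TRUE,
                                k = 15, r = 1, p = 1, seed = 1, gamma = 1,
                                solver = list(), scale = 1,
                                loops = c("penalized", "constrained")) {
  loops <- match.arg(loops, several.ok = TRUE)
  rows <- list()
  for (ks in ks_values) {
    gen <- generate_synthetic_model(ks, k = k, r = r, p = p, scale = scale,
                                    seed = .sub_seed(seed, ks))
    for (trial in seq_len(n_trials)) {
      x <- .study_series(gen, T, .sub_seed(seed, ks, trial))
      fit <- megvar(x, p = p, r = r, lambda = lambda, nit = nit,
                    threshold = threshold, adaptive = adaptive,
                    constrained = "constrained" %in% loops,
                    score_loops = loops,
                    gamma = gamma, solver = solver, keep_data = FALSE)
      ok <- vapply(fit$candidates, function(cd) isTRUE(cd$ok), TRUE)
      cands <- fit$candidates[ok]
      dists <- vapply(cands, function(cd)
        pattern_distance(cd$pattern, gen$pattern), 0)
      for (loop in loops) {
        rows[[length(rows) + 1]] <-
          data.frame(ks = ks, trial = trial, loop = loop,
                     selector = "oracle", distance = min(dists))
        smat <- vapply(cands, function(cd) cd$scores[[loop]],
                       numeric(length(.itc_names) + 3))
        for (sel in rownames(smat)) {
          vals <- smat[sel, ]
          d <- if (any(is.finite(vals)))
            dists[which.min(vals)] else NA_real_
          rows[[length(rows) + 1]] <-
            data.frame(ks = ks, trial = trial, loop = loop,
                       selector = sel, distance = d)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <-
    stats::aggregate(distance ~ ks + loop + selector, out, mean)
  out
}

#' Sparse+low-rank baseline sweep
#'
#' Applies [solve_sparse_lowrank()] over a grid of `(lambda, gamma)` pairs
#' to the manifest sample covariances of synthetic trajectories, extracts
#' each candidate pattern by PSC thresholding of the sparse part
#' \eqn{\Delta(X+L)\Delta^H}, scores all selection rules and reports the
#' distance of every selector's pick to the true pattern.
#'
#' @inheritParams run_oracle_study
#' @param pairs data.frame of parameter pairs (see [sl_pairs()]).
#' @param gamma_itc extended-criterion weight (default 1).
#' @param gap_tol interior-point duality-gap target for the sweep (default
#'   1e-4; pattern extraction at the 1e-3 PSC threshold is insensitive to
#'   tighter solves).
#' @return A data.frame with columns `ks`, `trial`, `selector`, `distance`;
#'   attribute `"summary"` holds per-(ks, selector) means, attribute
#'   `"candidates"` the per-pair pattern distances.
#' @export
run_algosl_study <- function(ks_values = c(2, 3, 15), n_trials = 2,
                             T = 50000, pairs = sl_pairs(
                               lam = seq(0.1, 0.6, by = 0.1),
                               gamma = c(0.01, 0.1325, 0.255, 0.3775, 0.5)),
                             threshold = 1e-3, k = 15, r = 1, p = 1,
                             seed = 1, gamma_itc = 1, scale = 1,
                             gap_tol = 1e-4) {
  rows <- list()
  cand_rows <- list()
  for (ks in ks_values) {
    gen <- generate_synthetic_model(ks, k = k, r = r, p = p, scale = scale,
                                    seed = .sub_seed(seed, ks))
    for (trial in seq_len(n_trials)) {
      x <- .study_series(gen, T, .sub_seed(seed, ks, trial))
      rhat <- sample_covariances(x, p)
      corr_eval <- eval_trig_poly(correlogram_bartlett(x), freq_grid(512))
      dists <- rep(NA_real_, nrow(pairs))
      smat <- matrix(NA_real_, length(.itc_names) + 3, nrow(pairs),
                     dimnames = list(c(.itc_names, "SF1", "SF2", "SF3"),
                                     NULL))
      for (q in seq_len(nrow(pairs))) {
        sol <- tryCatch(
          solve_sparse_lowrank(rhat, pairs$lam[q], pairs$gamma[q],
                               control = list(t0 = 25, gap_tol = gap_tol)),
          error = function(e) NULL)
        if (is.null(sol)) next
        sparse_poly <- trig_poly(sol$D_sparse)
        sp <- tryCatch(extract_pattern(sparse_poly, threshold, k),
                       error = function(e) NULL)
        if (is.null(sp)) next
        dists[q] <- pattern_distance(sp, gen$pattern)
        sc <- tryCatch(
          .score_sl_candidate(sol, sp, x, rhat, corr_eval, p, k, r,
                              gamma_itc),
          error = function(e) NULL)
        if (!is.null(sc)) smat[, q] <- sc
        cand_rows[[length(cand_rows) + 1]] <-
          data.frame(ks = ks, trial = trial, lam = pairs$lam[q],
                     gamma = pairs$gamma[q], n0 = sp$n0,
                     distance = dists[q])
      }
      rows[[length(rows) + 1]] <-
        data.frame(ks = ks, trial = trial, selector = "oracle",
                   distance = min(dists, na.rm = TRUE))
      for (sel in rownames(smat)) {
        vals <- smat[sel, ]
        d <- if (any(is.finite(vals))) dists[which.min(vals)] else NA_real_
        rows[[length(rows) + 1]] <-
          data.frame(ks = ks, trial = trial, selector = sel, distance = d)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <-
    stats::aggregate(distance ~ ks + selector, out, mean)
  attr(out, "candidates") <- do.call(rbind, cand_rows)
  out
}

# selection scores for one sparse+low-rank candidate
.score_sl_candidate <- function(sol, sp, x, rhat, corr_eval, p, k, r,
                                gamma_itc) {
  tt <- nrow(x)
  phim_inv_poly <- trig_poly(sol$D)   # Delta X Delta^H
  fac <- spectral_factorize(phim_inv_poly)
  sig <- residual_covariance(x, fac)
  nef <- effective_params(sp, p)
  itc <- itc_all(sig, rhat$lags[[1]], nef, tt, k, gamma_itc,
                 n0 = sp$n0, p = p)
  phim_inv <- eval_trig_poly(phim_inv_poly, freq_grid(512))
  d <- relative_entropy_rate(corr_eval, phim_inv, den_inverse = TRUE)
  ne <- .edge_count(k, sp$n0, r)
  sf <- tryCatch(score_functions(d, ne, tt),
                 error = function(e) c(SF1 = NA_real_, SF2 = NA_real_,
                                       SF3 = NA_real_))
  c(itc, sf)
}
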