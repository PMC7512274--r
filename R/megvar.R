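#' Fit a latent-variable graphical VAR model by maximum-entropy EM
#'
#' Runs the full estimation pipeline on a multivariate time series: sample
#' covariances, the unpenalized maximum-entropy initialization and
#' eigenvalue-based latent coupling start, then, for every value on the
#' `lambda` grid, `nit` EM iterations alternating the expectation step with
#' the penalized maximum-entropy program, PSC thresholding of the resulting
#' inverse spectrum into a candidate sparsity pattern, `nit` further EM
#' iterations under the hard pattern constraints, spectral factorization of
#' the constrained inverse spectrum into a VAR model, and evaluation of all
#' selection criteria on the manifest fit. The candidate minimizing
#' `criterion` is selected.
#'
#' @param x numeric matrix, `T` rows by `K` manifest columns (or anything
#'   [read_ts()] returns).
#' @param p autoregressive order (default 1).
#' @param r number of latent variables (default 1).
#' @param lambda ascending grid of positive penalty values (default the
#'   regular grid on `[1e-3, 1e-1]` with step `1e-3`).
#' @param nit EM iterations per loop (default 2).
#' @param threshold PSC threshold for edge removal (default `1e-3`).
#' @param adaptive carry the latent coupling estimate from one `lambda` to
#'   the next (default `TRUE`) instead of re-initializing each time.
#' @param criterion selection rule: one of `"SBC"`, `"AICc"`, `"logFPE"`,
#'   `"RNML"`, `"EBIC"`, `"EBICFD"`, `"RNMLFD"`, `"SF1"`, `"SF2"`, `"SF3"`.
#' @param gamma extended-criterion weight (default 1).
#' @param constrained run the pattern-constrained loop (default `TRUE`).
#' @param score_loops which loops to factorize and score:
#'   subset of `c("penalized", "constrained")`; an empty vector skips
#'   scoring entirely (pattern-only runs).
#' @param n_grid frequency grid size for PD checks, PSC and quadrature
#'   (default 512).
#' @param window_len Bartlett half-window for the correlogram used by the
#'   score functions (default `floor(sqrt(T))`).
#' @param solver control list passed to [solve_me2()]/[solve_me3()].
#' @param keep_data store the series in the fit (default `TRUE`; needed by
#'   the `residuals` method).
#' @return An object of class `"megvar"`: the candidate list (one entry per
#'   `lambda`, with pattern, inverse-spectrum estimates, manifest model,
#'   residual covariance and criterion values) and the selected index.
#'   Methods: `print`, `summary`, `coef`, `plot`, `residuals`, `simulate`,
#'   `predict`.
#' @seealso [generate_synthetic_model()] to build test systems,
#'   [run_oracle_study()] for the simulation protocols.
#' @examples
#' \donttest{
#' g <- generate_synthetic_model(2, k = 6, seed = 4)
#' x <- simulate_var(g$model, 2000, seed = 1)[, 1:6]
#' fit <- megvar(x, lambda = c(0.02, 0.05, 0.1), nit = 1,
#'               score_loops = "constrained")
#' print(fit)
#' }
#' @export
megvar <- function(x, p = 1, r = 1,
                   lambda = seq(1e-3, 0.1, by = 1e-3),
                   nit = 2, threshold = 1e-3, adaptive = TRUE,
                   criterion = "RNMLFD", gamma = 1,
                   constrained = TRUE,
                   score_loops = if (constrained) "constrained" else "penalized",
                   n_grid = 512, window_len = NULL, solver = list(),
                   keep_data = TRUE) {
  cl <- match.call()
  x <- as.matrix(x)
  tt <- nrow(x)
  k <- ncol(x)
  if (tt < k * (p + 1)) stop("series too short for the requested order")
  if (any(diff(lambda) <= 0) || any(lambda <= 0))
    stop("'lambda' must be positive and strictly ascending")
  if (nit < 1) stop("'nit' must be at least 1")
  if (threshold <= 0) stop("'threshold' must be positive")
  criterion <- match.arg(criterion,
                         c(.itc_names, "SF1", "SF2", "SF3"))
  score_loops <- intersect(score_loops, c("penalized", "constrained"))
  if ("constrained" %in% score_loops && !constrained)
    stop("cannot score the constrained loop without running it")

  rhat <- sample_covariances(x, p)
  me1 <- solve_me1(rhat)
  g0 <- init_latent_from_eig(me1$D[[1]], r)
  qlm_init <- .qlm_zero_init(g0, p)

  corr_eval <- NULL
  if (length(score_loops)) {
    corr <- correlogram_bartlett(x, window_len)
    corr_eval <- eval_trig_poly(corr, freq_grid(n_grid))
  }

  candidates <- vector("list", length(lambda))
  qlm_carry <- qlm_init
  for (li in seq_along(lambda)) {
    lam <- lambda[li]
    qlm_start <- if (adaptive) qlm_carry else qlm_init
    cand <- tryCatch(
      .fit_one_lambda(x, rhat, qlm_start, lam, p, k, r, nit, threshold,
                      constrained, score_loops, n_grid, gamma, corr_eval,
                      solver),
      error = function(e) list(lambda = lam, ok = FALSE,
                               message = conditionMessage(e)))
    cand$lambda <- lam
    candidates[[li]] <- cand
    if (adaptive && isTRUE(cand$ok)) qlm_carry <- cand$qlm_pen
  }

  selected <- NA_integer_
  loop_pref <- if ("constrained" %in% score_loops) "constrained" else
    if ("penalized" %in% score_loops) "penalized" else NA
  if (!is.na(loop_pref)) {
    vals <- vapply(candidates, function(cd) {
      if (!isTRUE(cd$ok)) return(NA_real_)
      s <- cd$scores[[loop_pref]]
      if (is.null(s)) NA_real_ else unname(s[criterion])
    }, 0)
    if (any(is.finite(vals))) selected <- which.min(vals)
  }

  structure(
    list(call = cl, T = tt, K = k, p = p, r = r, lambda = lambda,
         nit = nit, threshold = threshold, adaptive = adaptive,
         criterion = criterion, gamma = gamma, n_grid = n_grid,
         candidates = candidates, selected = selected,
         score_loop = loop_pref, rhat = rhat,
         data = if (keep_data) x else NULL),
    class = "megvar")
}

# one lambda: penalized loop, pattern, constrained loop, factorization,
# scores; raises on solver failure (caller flags the candidate)
.fit_one_lambda <- function(x, rhat, qlm, lam, p, k, r, nit, threshold,
                            constrained, score_loops, n_grid, gamma,
                            corr_eval, solver) {
  tt <- nrow(x)
  sol2 <- NULL
  for (it in seq_len(nit)) {
    cc <- .ensure_pd_toeplitz(expectation_step(rhat, qlm))
    sol2 <- solve_me2(cc, lam, k, r, control = solver)
    qlm <- .qlm_from_solution(sol2, k, r)
  }
  isdm_pen <- .assemble_isdm(sol2, k, r)
  sp <- extract_pattern(isdm_pen, threshold, k, n_grid)
  out <- list(ok = TRUE, pattern = sp, n0 = sp$n0,
              nef = effective_params(sp, p), isdm_pen = isdm_pen,
              qlm_pen = qlm, gap_pen = sol2$gap, scores = list())
  if (constrained) {
    qlm_c <- qlm
    sol3 <- NULL
    for (it in seq_len(nit)) {
      cc <- .ensure_pd_toeplitz(expectation_step(rhat, qlm_c))
      sol3 <- solve_me3(cc, sp, k, r, control = solver)
      qlm_c <- .qlm_from_solution(sol3, k, r)
    }
    out$isdm_con <- .assemble_isdm(sol3, k, r)
    out$gap_con <- sol3$gap
  }
  for (loop in score_loops) {
    isdm <- if (loop == "penalized") isdm_pen else out$isdm_con
    sc <- .score_candidate(isdm, x, rhat$lags[[1]], sp, p, k, r, tt,
                           gamma, corr_eval, n_grid)
    out$scores[[loop]] <- sc$scores
    out[[paste0("model_", substr(loop, 1, 3))]] <- sc$model
    out[[paste0("sigma_", substr(loop, 1, 3))]] <- sc$sigma
    out[[paste0("d_", substr(loop, 1, 3))]] <- sc$d
  }
  out
}

# factorize an assembled full-model ISDM and evaluate every selection rule
.score_candidate <- function(isdm, x, r0_hat, sp, p, k, r, tt, gamma,
                             corr_eval, n_grid) {
  fac <- spectral_factorize(isdm)
  man <- manifest_truncate(fac, k)
  sig <- residual_covariance(x, man)
  nef <- effective_params(sp, p)
  itc <- itc_all(sig, r0_hat, nef, tt, k, gamma, n0 = sp$n0, p = p)
  phim_inv <- .manifest_inverse_spectrum(isdm, k, r, n_grid)
  d <- relative_entropy_rate(corr_eval, phim_inv, den_inverse = TRUE)
  ne <- .edge_count(k, sp$n0, r)
  sf <- tryCatch(score_functions(d, ne, tt),
                 error = function(e) c(SF1 = NA_real_, SF2 = NA_real_,
                                       SF3 = NA_real_))
  list(scores = c(itc, sf), model = man, sigma = sig, d = d)
}

# manifest inverse spectrum by Schur complement (latent block identity)
.manifest_inverse_spectrum <- function(isdm, k, r, n_grid) {
  vals <- eval_trig_poly(isdm, freq_grid(n_grid))
  man <- seq_len(k)
  lat <- k + seq_len(r)
  out <- array(0i, c(k, k, dim(vals)[3]))
  for (w in seq_len(dim(vals)[3])) {
    um <- vals[man, man, w]
    ulm <- vals[lat, man, w, drop = FALSE]
    dim(ulm) <- c(r, k)
    out[, , w] <- um - Conj(t(ulm)) %*% ulm
  }
  out
}

#' Run the EM sparsity-pattern identification algorithm
#'
#' A configuration-list interface over [megvar()] matching the tool-style
#' surface: `config` may carry `p`, `r`, `lambda`, `nit`, `threshold`,
#' `adaptive`, `criterion`, `gamma`, `n_grid` and `solver`.
#'
#' @param series time-series matrix (or file path readable by [read_ts()]).
#' @param config named list of settings; unset entries use the [megvar()]
#'   defaults.
#' @return A `"megvar"` fit.
#' @export
run_algoem <- function(series, config = list()) {
  if (is.character(series)) series <- read_ts(series)
  args <- c(list(x = series), config)
  do.call(megvar, args)
}

#' @export
print.megvar <- function(x, ...) {
  nok <- sum(vapply(x$candidates, function(cd) isTRUE(cd$ok), TRUE))
  cat("Latent-variable graphical VAR fit (maximum-entropy EM)\n")
  cat("  series: T = ", x$T, ", K = ", x$K, " manifest variables; p = ",
      x$p, ", r = ", x$r, "\n", sep = "")
  cat("  lambda grid: ", length(x$lambda), " values in [",
      format(min(x$lambda)), ", ", format(max(x$lambda)), "]; ",
      nok, " candidate(s) solved\n", sep = "")
  if (!is.na(x$selected)) {
    cd <- x$candidates[[x$selected]]
    cat("  selected by ", x$criterion, " (", x$score_loop, " loop): ",
        "lambda = ", format(cd$lambda), ", edges = ", cd$pattern$ks,
        ", zeros below diagonal = ", cd$n0, "\n", sep = "")
  } else {
    cat("  no criterion-based selection performed\n")
  }
  invisible(x)
}

#' @export
summary.megvar <- function(object, ...) {
  loop <- object$score_loop
  rows <- lapply(object$candidates, function(cd) {
    if (!isTRUE(cd$ok))
      return(data.frame(lambda = cd$lambda, ok = FALSE, n0 = NA,
                        nef = NA))
    base <- data.frame(lambda = cd$lambda, ok = TRUE, n0 = cd$n0,
                       nef = cd$nef)
    if (!is.na(loop) && !is.null(cd$scores[[loop]]))
      base <- cbind(base, as.data.frame(as.list(cd$scores[[loop]])))
    base
  })
  tab <- do.call(rbind, lapply(rows, function(rw) {
    miss <- setdiff(Reduce(union, lapply(rows, names)), names(rw))
    for (mm in miss) rw[[mm]] <- NA
    rw
  }))
  structure(list(table = tab, selected = object$selected,
                 criterion = object$criterion, loop = loop),
            class = "summary.megvar")
}

#' @export
print.summary.megvar <- function(x, ...) {
  cat("candidate models (", nrow(x$table), " lambda values)\n", sep = "")
  print(x$table, row.names = FALSE, digits = 5)
  if (!is.na(x$selected))
    cat("selected row: ", x$selected, " (argmin ", x$criterion, ")\n",
        sep = "")
  invisible(x)
}

.selected_candidate <- function(object) {
  if (is.na(object$selected))
    stop("fit has no selected candidate (no scoring loop was run)")
  object$candidates[[object$selected]]
}

#' @export
coef.megvar <- function(object, ...) {
  cd <- .selected_candidate(object)
  model <- if (!is.null(cd$model_con)) cd$model_con else cd$model_pen
  co <- model$coeffs
  names(co) <- paste0("A", seq_along(co))
  attr(co, "sigma") <- if (!is.null(cd$sigma_con)) cd$sigma_con else
    cd$sigma_pen
  co
}

#' Selected sparsity pattern of a fit
#'
#' @param object a `"megvar"` fit.
#' @return The [sparsity_pattern()] of the selected candidate.
#' @export
selected_pattern <- function(object) {
  .selected_candidate(object)$pattern
}

#' @export
residuals.megvar <- function(object, ...) {
  if (is.null(object$data))
    stop("fit was created with keep_data = FALSE")
  cd <- .selected_candidate(object)
  model <- if (!is.null(cd$model_con)) cd$model_con else cd$model_pen
  x <- object$data
  tt <- nrow(x)
  p <- object$p
  e <- x[(p + 1):tt, , drop = FALSE]
  for (i in seq_len(p))
    e <- e - x[(p + 1 - i):(tt - i), , drop = FALSE] %*% t(model$coeffs[[i]])
  e
}

#' @export
predict.megvar <- function(object, newdata = NULL, ...) {
  cd <- .selected_candidate(object)
  model <- if (!is.null(cd$model_con)) cd$model_con else cd$model_pen
  x <- if (is.null(newdata)) object$data else as.matrix(newdata)
  if (is.null(x)) stop("no data available for prediction")
  tt <- nrow(x)
  p <- object$p
  yhat <- matrix(0, tt - p, object$K)
  for (i in seq_len(p))
    yhat <- yhat + x[(p + 1 - i):(tt - i), , drop = FALSE] %*%
      t(model$coeffs[[i]])
  yhat
}

#' @export
simulate.megvar <- function(object, nsim = 1, seed = NULL, ...) {
  cd <- .selected_candidate(object)
  model <- if (!is.null(cd$model_con)) cd$model_con else cd$model_pen
  sig <- if (!is.null(cd$sigma_con)) cd$sigma_con else cd$sigma_pen
  sim_model <- var_model(model$coeffs, sig, names = model$names)
  simulate_var(sim_model, n = nsim, seed = seed, ...)
}

#' @export
plot.megvar <- function(x, which = c("path", "pattern"), ...) {
  which <- match.arg(which)
  if (which == "pattern") {
    cd <- .selected_candidate(x)
    adj <- cd$pattern$adjacency
    graphics::image(seq_len(x$K), seq_len(x$K),
                    t(adj[x$K:1, , drop = FALSE]),
                    col = c("grey90", "black"), axes = FALSE,
                    xlab = "", ylab = "",
                    main = "selected sparsity pattern")
    graphics::box()
    return(invisible(x))
  }
  ok <- vapply(x$candidates, function(cd) isTRUE(cd$ok), TRUE)
  lam <- x$lambda[ok]
  n0 <- vapply(x$candidates[ok], function(cd) cd$n0, 0)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(lam, n0, type = "b", xlab = expression(lambda),
                 ylab = "zeros below diagonal",
                 main = "regularization path")
  loop <- x$score_loop
  if (!is.na(loop)) {
    vals <- vapply(x$candidates[ok], function(cd)
      unname(cd$scores[[loop]][x$criterion]), 0)
    graphics::plot(lam, vals, type = "b", xlab = expression(lambda),
                   ylab = x$criterion)
    if (!is.na(x$selected))
      graphics::abline(v = x$lambda[x$selected], lty = 2)
  }
  invisible(x)
}
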