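#' Construct a stable vector autoregressive model
#'
#' A VAR(p) model \eqn{x_t = A_1 x_{t-1} + \dots + A_p x_{t-p} + \epsilon_t}
#' with Gaussian innovations of covariance \eqn{\Sigma}. The convention
#' \eqn{A_0 = -I} is used throughout the package when forming the transfer
#' function \eqn{A(\omega) = -\sum_{i=0}^p A_i e^{-j\omega i}}.
#'
#' @param coeffs list of `p` square coefficient matrices `A_1, ..., A_p`
#'   (an empty list gives white noise, order 0).
#' @param sigma symmetric positive definite innovation covariance.
#' @param names optional character vector of variable names.
#' @param validate check stability and positive definiteness (default `TRUE`).
#' @return An object of class `"var_model"` with elements `p`, `dim`,
#'   `coeffs`, `sigma` and `names`.
#' @examples
#' m <- var_model(list(matrix(c(0.5, 0, 0.1, 0.3), 2, 2)), diag(2))
#' m$p
#' @export
var_model <- function(coeffs, sigma, names = NULL, validate = TRUE) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  sigma <- as.matrix(sigma)
  k <- nrow(sigma)
  if (ncol(sigma) != k) stop("'sigma' must be square")
  coeffs <- lapply(coeffs, as.matrix)
  for (a in coeffs) {
    if (!all(dim(a) == c(k, k)))
      stop("every coefficient matrix must be ", k, "x", k)
  }
  if (is.null(names)) names <- paste0("x", seq_len(k))
  m <- structure(
    list(p = length(coeffs), dim = k, coeffs = coeffs, sigma = sigma,
         names = names),
    class = "var_model")
  if (validate) {
    if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma))))
      stop("'sigma' must be symmetric")
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("'sigma' must be positive definite (smallest eigenvalue ",
           format(min(ev)), ")")
    lam <- companion_eigenvalues(m)
    if (length(lam) && max(Mod(lam)) >= 1)
      stop("model is not stable: companion eigenvalue of modulus ",
           format(max(Mod(lam))))
  }
  m
}

#' @export
print.var_model <- function(x, ...) {
  cat("VAR(", x$p, ") model, dimension ", x$dim, "\n", sep = "")
  lam <- companion_eigenvalues(x)
  if (length(lam))
    cat("  spectral radius of companion matrix:",
        format(max(Mod(lam)), digits = 4), "\n")
  cat("  innovation covariance: ", x$dim, "x", x$dim,
      ", log det = ", format(determinant(x$sigma)$modulus[1], digits = 5),
      "\n", sep = "")
  invisible(x)
}

companion_matrix <- function(model) {
  p <- model$p
  k <- model$dim
  if (p == 0) return(matrix(0, 0, 0))
  comp <- matrix(0, k * p, k * p)
  for (i in seq_len(p))
    comp[seq_len(k), (i - 1) * k + seq_len(k)] <- model$coeffs[[i]]
  if (p > 1)
    comp[k + seq_len(k * (p - 1)), seq_len(k * (p - 1))] <-
      diag(k * (p - 1))
  comp
}

companion_eigenvalues <- function(model) {
  cm <- companion_matrix(model)
  if (nrow(cm) == 0) return(complex(0))
  eigen(cm, only.values = TRUE)$values
}

#' Test stability of a VAR model
#'
#' @param model a [var_model()].
#' @return `TRUE` when all companion-matrix eigenvalues have modulus < 1.
#' @export
is_stable <- function(model) {
  lam <- companion_eigenvalues(model)
  length(lam) == 0 || max(Mod(lam)) < 1
}

#' Simulate a trajectory from a VAR model
#'
#' Runs the autoregressive recursion with i.i.d. Gaussian innovations from a
#' zero initial state, discarding `burn_in` initial rows so that the retained
#' trajectory is (approximately) a draw from the stationary distribution.
#'
#' @param model a stable [var_model()].
#' @param n number of rows to return.
#' @param seed integer seed; the output is reproducible given the seed.
#' @param burn_in number of initial rows to discard (default 1000).
#' @return An `n` by `dim` numeric matrix, one column per variable.
#' @examples
#' m <- var_model(list(0.6 * diag(2)), diag(2))
#' x <- simulate_var(m, 200, seed = 1)
#' dim(x)
#' @export
simulate_var <- function(model, n, seed = NULL, burn_in = 1000) {
  stopifnot(inherits(model, "var_model"), n >= 1)
  if (!is_stable(model)) {
    lam <- companion_eigenvalues(model)
    stop("cannot simulate from an unstable model (companion eigenvalue ",
         format(lam[which.max(Mod(lam))]), ")")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  k <- model$dim
  p <- model$p
  ntot <- n + burn_in
  cs <- chol(model$sigma)
  eps <- matrix(stats::rnorm(ntot * k), ntot, k) %*% cs
  if (p == 0) {
    x <- eps
  } else {
    x <- matrix(0, ntot + p, k)
    at <- lapply(model$coeffs, t)
    for (t in seq_len(ntot)) {
      row <- eps[t, ]
      for (i in seq_len(p)) row <- row + x[t + p - i, ] %*% at[[i]]
      x[t + p, ] <- row
    }
    x <- x[p + seq_len(ntot), , drop = FALSE]
  }
  out <- x[burn_in + seq_len(n), , drop = FALSE]
  colnames(out) <- model$names
  out
}

#' @rdname simulate_var
#' @param object,nsim,... standard [stats::simulate()] arguments; `nsim` is
#'   the trajectory length.
#' @export
simulate.var_model <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_var(object, n = nsim, seed = seed, ...)
}

#' Exact autocovariances of a stable VAR process
#'
#' Solves the companion-form discrete Lyapunov equation for the stationary
#' covariance and propagates it through the Yule-Walker recursion, giving the
#' exact lags \eqn{C_i = E[x_{t+i} x_t^\top]} for `i = 0..q`.
#'
#' @param model a stable [var_model()].
#' @param q largest lag required.
#' @return A [cov_seq()] holding lags `0..q`.
#' @examples
#' m <- var_model(list(matrix(0.5)), matrix(1))
#' theoretical_covariances(m, 1)$lags[[1]]  # 1/(1-0.25)
#' @export
theoretical_covariances <- function(model, q) {
  stopifnot(inherits(model, "var_model"), q >= 0)
  if (!is_stable(model)) stop("model must be stable")
  k <- model$dim
  p <- model$p
  if (p == 0) {
    lags <- c(list(model$sigma), rep(list(matrix(0, k, k)), q))
    return(cov_seq(lags))
  }
  comp <- companion_matrix(model)
  sig_big <- matrix(0, k * p, k * p)
  sig_big[seq_len(k), seq_len(k)] <- model$sigma
  # vec(P) = (I - comp %x% comp)^{-1} vec(sig_big)
  n2 <- (k * p)^2
  vp <- solve(diag(n2) - comp %x% comp, as.vector(sig_big))
  pbig <- matrix(vp, k * p, k * p)
  pbig <- (pbig + t(pbig)) / 2
  lags <- vector("list", q + 1)
  # block (0, j) of P is C_j for j = 0..p-1
  for (i in 0:min(q, p - 1))
    lags[[i + 1]] <- pbig[seq_len(k), i * k + seq_len(k)]
  if (q >= p) {
    for (i in p:q) {
      ci <- matrix(0, k, k)
      for (j in seq_len(p)) {
        cl <- lags[[i - j + 1]]
        ci <- ci + model$coeffs[[j]] %*% cl
      }
      lags[[i + 1]] <- ci
    }
  }
  lags[[1]] <- (lags[[1]] + t(lags[[1]])) / 2
  cov_seq(lags)
}

#' Write or read a VAR model as JSON
#'
#' Models are stored as a JSON document holding the order, dimension,
#' coefficient matrices (row-major nested arrays), the innovation covariance
#' and optional seed provenance.
#'
#' @param model a [var_model()].
#' @param path file path.
#' @param seed optional integer recorded as provenance.
#' @return `write_var_model` returns `path` invisibly; `read_var_model`
#'   returns the reconstructed [var_model()].
#' @export
write_var_model <- function(model, path, seed = NULL) {
  doc <- list(
    p = model$p, dim = model$dim,
    coeffs = lapply(model$coeffs, function(a) unname(as.matrix(a))),
    sigma = unname(model$sigma), names = model$names)
  if (!is.null(seed)) doc$seed <- seed
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_var_model
#' @export
read_var_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  coeffs <- doc$coeffs
  if (is.array(coeffs) && length(dim(coeffs)) == 3) {
    coeffs <- lapply(seq_len(dim(coeffs)[1]), function(i) coeffs[i, , ])
  } else if (is.null(coeffs) || length(coeffs) == 0) {
    coeffs <- list()
  }
  var_model(coeffs, as.matrix(doc$sigma), names = doc$names)
}

#' Read or write a multivariate time series as delimited text
#'
#' The on-disk format is a delimited table (comma or tab), a header row of
#' variable names and one row per time point.
#'
#' @param path file path.
#' @param sep field separator; `","` or `"\t"`. For reading, `NULL` detects
#'   the separator from the header line.
#' @return `read_ts` returns a numeric matrix with column names; `write_ts`
#'   returns `path` invisibly.
#' @export
read_ts <- function(path, sep = NULL) {
  if (is.null(sep)) {
    head1 <- readLines(path, n = 1)
    sep <- if (grepl("\t", head1)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_ts
#' @param x numeric matrix (rows are time points).
#' @export
write_ts <- function(x, path, sep = ",") {
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  utils::write.table(x, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}
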