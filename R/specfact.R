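#' Spectral factorization of a positive inverse spectral density
#'
#' Factors a Hermitian matrix trigonometric polynomial \eqn{P(\omega) \succ 0}
#' of degree `p` as \eqn{A(\omega)^H \Sigma^{-1} A(\omega)} with
#' \eqn{A(\omega) = -\sum_{i=0}^p A_i e^{-j\omega i}}, \eqn{A_0 = -I} and
#' \eqn{\Sigma \succ 0}; under that normalization the minimum-phase (stable)
#' factor is unique. Because the inverse of a positive trigonometric
#' polynomial of degree `p` is exactly the spectrum of a stable VAR(p)
#' process, the factor is recovered by inverting \eqn{P} on a fine FFT grid
#' to obtain the exact autocovariances of that process and solving the
#' Yule-Walker system; the quadrature error decays exponentially in the grid
#' size and the grid is doubled until the reconstruction residual passes
#' `tol`.
#'
#' @param poly a [trig_poly()], positive definite on the frequency grid.
#' @param n_fft initial FFT grid size (default 2048).
#' @param tol maximum absolute coefficient error allowed in the
#'   reconstruction (default 1e-7).
#' @param max_fft largest grid size tried before giving up (default 32768).
#' @return A stable [var_model()] whose inverse spectral density reproduces
#'   `poly`.
#' @examples
#' m <- var_model(list(matrix(0.5)), matrix(1))
#' f <- spectral_factorize(isdm_from_var(m))
#' f$coeffs[[1]]  # 0.5
#' @export
spectral_factorize <- function(poly, n_fft = 2048, tol = 1e-7,
                               max_fft = 32768) {
  stopifnot(inherits(poly, "trig_poly"))
  m <- poly$dim
  p <- poly$degree
  me <- min_eig_on_grid(poly, 512)
  if (me <= 0)
    stop("polynomial is not positive definite on the grid (min eigenvalue ",
         format(me), ")")
  n <- n_fft
  repeat {
    covs <- .poly_inverse_covariances(poly, n, p)
    fac <- .yule_walker(covs)
    err <- .reconstruction_error(fac, poly)
    if (err <= tol || n >= max_fft) break
    n <- n * 2
  }
  if (err > tol)
    warning("spectral factorization residual ", format(err),
            " above tolerance ", format(tol))
  fac
}

# inverse-FFT the matrix inverse of the polynomial to covariance lags 0..q
.poly_inverse_covariances <- function(poly, n, q) {
  m <- poly$dim
  omega <- 2 * pi * (0:(n - 1)) / n
  vals <- eval_trig_poly(poly, omega)
  phi <- array(0i, c(m, m, n))
  for (w in seq_len(n)) phi[, , w] <- solve(vals[, , w])
  lags <- vector("list", q + 1)
  ph <- matrix(0i, n, q + 1)
  for (i in 0:q) ph[, i + 1] <- exp(1i * omega * i)
  flat <- matrix(phi, m * m, n)
  for (i in 0:q) {
    ci <- matrix(Re(flat %*% ph[, i + 1]) / n, m, m)
    lags[[i + 1]] <- ci
  }
  lags[[1]] <- (lags[[1]] + t(lags[[1]])) / 2
  cov_seq(lags)
}

# block Yule-Walker fit from exact covariances: A and Sigma of the VAR(q)
.yule_walker <- function(covs) {
  m <- covs$dim
  p <- covs$q
  if (p == 0) return(var_model(list(), covs$lags[[1]]))
  gm <- block_toeplitz(cov_seq(covs$lags[1:p]))
  b <- do.call(cbind, lapply(seq_len(p), function(i) cov_lag(covs, i)))
  arow <- b %*% chol2inv(chol(gm))
  coeffs <- lapply(seq_len(p), function(i) arow[, (i - 1) * m + seq_len(m)])
  sig <- covs$lags[[1]]
  for (i in seq_len(p)) sig <- sig - coeffs[[i]] %*% t(cov_lag(covs, i))
  sig <- (sig + t(sig)) / 2
  var_model(coeffs, sig)
}

.reconstruction_error <- function(model, poly) {
  rec <- isdm_from_var(model)
  err <- 0
  for (i in seq_len(poly$degree + 1))
    err <- max(err, max(abs(rec$coeffs[[i]] - poly$coeffs[[i]])))
  err
}

#' Keep only the manifest block of a factored model
#'
#' Truncates each coefficient matrix and the innovation covariance of a
#' latent-variable VAR model to their upper-left `K` by `K` blocks, the
#' entries corresponding to manifest variables.
#'
#' @param model a [var_model()] of dimension at least `K`.
#' @param k number of manifest variables to keep.
#' @return A [var_model()] of dimension `K` (not re-validated for stability:
#'   truncation does not preserve minimum phase in general).
#' @export
manifest_truncate <- function(model, k) {
  if (k > model$dim) stop("K exceeds the model dimension")
  idx <- seq_len(k)
  var_model(lapply(model$coeffs, function(a) a[idx, idx, drop = FALSE]),
            model$sigma[idx, idx, drop = FALSE],
            names = model$names[idx], validate = FALSE)
}

#' Residual covariance of a VAR coefficient set on data
#'
#' Computes one-step-ahead residuals \eqn{e_t = x_t - \sum_i A_i x_{t-i}} for
#' `t = p+1..T` and returns their sample covariance with divisor `T - p`.
#'
#' @param x numeric matrix of observations (rows are time points).
#' @param coeffs list of coefficient matrices `A_1..A_p` (or a
#'   [var_model()]).
#' @return Symmetric positive semidefinite matrix \eqn{\hat\Sigma}.
#' @export
residual_covariance <- function(x, coeffs) {
  if (inherits(coeffs, "var_model")) coeffs <- coeffs$coeffs
  x <- as.matrix(x)
  tt <- nrow(x)
  p <- length(coeffs)
  if (tt <= p) stop("series too short for order ", p)
  e <- x[(p + 1):tt, , drop = FALSE]
  for (i in seq_len(p)) {
    e <- e - x[(p + 1 - i):(tt - i), , drop = FALSE] %*% t(coeffs[[i]])
  }
  sig <- crossprod(e) / (tt - p)
  (sig + t(sig)) / 2
}
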