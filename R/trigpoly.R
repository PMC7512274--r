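#' Hermitian matrix trigonometric polynomials
#'
#' Represents \eqn{P(\omega) = \sum_{i=-d}^{d} Q_i e^{-j\omega i}} through its
#' real coefficient matrices `Q_0, ..., Q_d`; the negative-index coefficients
#' are implied by the Hermitian extension \eqn{Q_{-i} = Q_i^\top}, so the
#' evaluation at any frequency is a Hermitian matrix. Spectral density
#' matrices and their inverses are stored this way.
#'
#' @param coeffs list of square real matrices `Q_0, ..., Q_d`.
#' @param block_sizes optional `c(K, r)` manifest/latent split.
#' @return An object of class `"trig_poly"`.
#' @export
trig_poly <- function(coeffs, block_sizes = NULL) {
  stopifnot(is.list(coeffs), length(coeffs) >= 1)
  coeffs <- lapply(coeffs, as.matrix)
  m <- nrow(coeffs[[1]])
  for (q in coeffs) if (!all(dim(q) == c(m, m))) stop("ragged coefficients")
  if (!is.null(block_sizes) && sum(block_sizes) != m)
    stop("block sizes must sum to the matrix dimension")
  structure(list(coeffs = coeffs, degree = length(coeffs) - 1L, dim = m,
                 block_sizes = block_sizes),
            class = "trig_poly")
}

#' @export
print.trig_poly <- function(x, ...) {
  cat("matrix trigonometric polynomial: dimension ", x$dim, ", degree ",
      x$degree, "\n", sep = "")
  if (!is.null(x$block_sizes))
    cat("  manifest/latent split: ", x$block_sizes[1], " + ",
        x$block_sizes[2], "\n", sep = "")
  invisible(x)
}

#' Uniform frequency grid on (-pi, pi]
#'
#' @param n number of grid points.
#' @return Numeric vector of frequencies.
#' @export
freq_grid <- function(n = 512) {
  -pi + (2 * pi / n) * seq_len(n)
}

#' Evaluate a trigonometric polynomial on a frequency grid
#'
#' @param poly a [trig_poly()].
#' @param omega numeric vector of frequencies (default [freq_grid()]).
#' @return A complex array `dim x dim x length(omega)`; each slice is
#'   Hermitian.
#' @export
eval_trig_poly <- function(poly, omega = freq_grid()) {
  m <- poly$dim
  d <- poly$degree
  n <- length(omega)
  q0 <- poly$coeffs[[1]]
  q0 <- (q0 + t(q0)) / 2
  flat <- matrix(as.vector(q0), m * m, 1) %*% matrix(1 + 0i, 1, n)
  if (d >= 1) {
    qs <- vapply(poly$coeffs[-1], as.vector, numeric(m * m))
    qts <- vapply(poly$coeffs[-1], function(q) as.vector(t(q)),
                  numeric(m * m))
    ph <- exp(-1i * outer(seq_len(d), omega))        # d x n
    flat <- flat + qs %*% ph + qts %*% Conj(ph)
  }
  array(flat, c(m, m, n))
}

#' Minimum eigenvalue of a Hermitian trig polynomial over a grid
#'
#' @param poly a [trig_poly()].
#' @param n_grid grid size (default 512).
#' @return The smallest eigenvalue found over the grid.
#' @export
min_eig_on_grid <- function(poly, n_grid = 512) {
  vals <- eval_trig_poly(poly, freq_grid(n_grid))
  mn <- Inf
  for (w in seq_len(dim(vals)[3])) {
    ev <- eigen(vals[, , w], symmetric = TRUE, only.values = TRUE)$values
    mn <- min(mn, ev[length(ev)])
  }
  mn
}

#' Inverse spectral density of a VAR model
#'
#' Computes the coefficients \eqn{Q_i = \sum_{k=0}^{p-i} A_k^\top \Sigma^{-1}
#' A_{k+i}} (with \eqn{A_0 = -I}) of the inverse spectral density matrix
#' \eqn{\Phi^{-1}(\omega) = A(\omega)^H \Sigma^{-1} A(\omega)}. Zero entries
#' of the off-diagonal coefficient functions encode conditional independence
#' between the corresponding components at all frequencies.
#'
#' @param model a [var_model()].
#' @param block_sizes optional manifest/latent split recorded on the result.
#' @return A [trig_poly()] of degree `p`, positive definite on the frequency
#'   grid for a stable model.
#' @examples
#' m <- var_model(list(matrix(0.5)), matrix(1))
#' isdm_from_var(m)$coeffs  # (1+a^2)/s2 and -a/s2
#' @export
isdm_from_var <- function(model, block_sizes = NULL) {
  k <- model$dim
  p <- model$p
  ev <- eigen(model$sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) stop("singular innovation covariance")
  sinv <- chol2inv(chol(model$sigma))
  aa <- c(list(-diag(k)), model$coeffs)   # A_0 = -I, A_1..A_p
  coeffs <- vector("list", p + 1)
  for (i in 0:p) {
    qi <- matrix(0, k, k)
    for (kk in 0:(p - i)) {
      qi <- qi + t(aa[[kk + 1]]) %*% sinv %*% aa[[kk + i + 1]]
    }
    coeffs[[i + 1]] <- qi
  }
  coeffs[[1]] <- (coeffs[[1]] + t(coeffs[[1]])) / 2
  trig_poly(coeffs, block_sizes = block_sizes)
}
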