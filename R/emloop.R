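#' Initialize latent couplings from an eigenvalue decomposition
#'
#' Given the lag-0 manifest block \eqn{Q_0} of an inverse spectral density,
#' returns the `r` by `K` latent-manifest coupling
#' \eqn{G = D^{1/2}(1{:}r,1{:}r) U(:,1{:}r)^\top} built from the leading
#' eigenpairs of \eqn{Q_0 = U D U^\top} (eigenvalues in decreasing order of
#' magnitude); higher-lag couplings start at zero.
#'
#' @param q0 symmetric positive semidefinite `K` by `K` matrix.
#' @param r number of latent variables (at most `K`).
#' @return An `r` by `K` matrix.
#' @examples
#' init_latent_from_eig(diag(c(4, 1)), 1)  # c(2, 0)
#' @export
init_latent_from_eig <- function(q0, r) {
  k <- nrow(q0)
  if (r > k) stop("more latent variables than manifest dimensions")
  e <- eigen((q0 + t(q0)) / 2, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)
  vals <- e$values[ord][seq_len(r)]
  vecs <- e$vectors[, ord, drop = FALSE][, seq_len(r), drop = FALSE]
  # deterministic sign: largest-magnitude entry of each vector positive
  for (j in seq_len(r)) {
    lead <- which.max(abs(vecs[, j]))
    if (vecs[lead, j] < 0) vecs[, j] <- -vecs[, j]
  }
  diag(sqrt(pmax(vals, 0)), r) %*% t(vecs)
}

# latent-manifest coefficient list for i = -p..p (index p+1 is lag 0)
# extracted from a full-model maximum-entropy solution
.qlm_from_solution <- function(sol, K, r) {
  p <- sol$order
  man <- seq_len(K)
  lat <- K + seq_len(r)
  qlm <- vector("list", 2 * p + 1)
  for (i in 0:p) {
    qi <- sol$D[[i + 1]]
    qlm[[p + 1 + i]] <- qi[lat, man, drop = FALSE]
    if (i >= 1) qlm[[p + 1 - i]] <- t(qi[man, lat, drop = FALSE])
  }
  qlm
}

.qlm_zero_init <- function(g, p) {
  r <- nrow(g); k <- ncol(g)
  qlm <- rep(list(matrix(0, r, k)), 2 * p + 1)
  qlm[[p + 1]] <- g
  qlm
}

#' Expectation step: reconstruct full-model covariances
#'
#' Given the manifest sample covariances and the current latent-manifest
#' coupling polynomial, assembles the full `(K+r)`-dimensional covariance
#' lags implied by the current inverse-spectrum model (latent block of the
#' ISDM fixed at the identity): the manifest block is copied from the data,
#' the latent-manifest block is the convolution
#' \eqn{C_{\ell m,i} = -\sum_k Q_{\ell m,k} \hat R_{i-k}} (degree `2p`), and
#' the latent block \eqn{C_{\ell,i} = \delta_i I + \sum_k C_{\ell m,k}
#' Q_{\ell m,i-k}^\top} is truncated to degree `p`, the degree of the model.
#'
#' @param r_hat manifest [cov_seq()] with lags `0..p`.
#' @param qlm list of `2p+1` latent-manifest coefficient matrices (`r` by
#'   `K`), ordered lag `-p..p`.
#' @return A `(K+r)`-dimensional [cov_seq()] with lags `0..p`.
#' @export
expectation_step <- function(r_hat, qlm) {
  p <- r_hat$q
  k <- r_hat$dim
  if (length(qlm) != 2 * p + 1)
    stop("qlm must hold lags -p..p (", 2 * p + 1, " matrices)")
  r <- nrow(qlm[[1]])
  if (ncol(qlm[[1]]) != k) stop("qlm column count must match the manifest dimension")
  qat <- function(i) qlm[[p + 1 + i]]
  # latent-manifest block, lags -2p..2p
  clm <- vector("list", 4 * p + 1)
  for (i in (-2 * p):(2 * p)) {
    acc <- matrix(0, r, k)
    for (kk in max(-p, i - p):min(p, i + p)) {
      acc <- acc - qat(kk) %*% cov_lag(r_hat, i - kk)
    }
    clm[[2 * p + 1 + i]] <- acc
  }
  cat_clm <- function(i) clm[[2 * p + 1 + i]]
  # latent block, truncated to lags -p..p
  cl <- vector("list", 2 * p + 1)
  for (i in (-p):p) {
    acc <- if (i == 0) diag(r) else matrix(0, r, r)
    for (kk in max(-2 * p, i - p):min(2 * p, i + p)) {
      acc <- acc + cat_clm(kk) %*% t(qat(i - kk))
    }
    cl[[p + 1 + i]] <- acc
  }
  lags <- vector("list", p + 1)
  for (i in 0:p) {
    top <- cbind(cov_lag(r_hat, i), t(cat_clm(-i)))
    bot <- cbind(cat_clm(i), cl[[p + 1 + i]])
    lags[[i + 1]] <- rbind(top, bot)
  }
  lags[[1]] <- (lags[[1]] + t(lags[[1]])) / 2
  cov_seq(lags)
}

# assemble the full-model ISDM polynomial from an MEII/MEIII solution,
# snapping the latent block to its constrained values (identity at lag 0,
# zero at higher lags)
.assemble_isdm <- function(sol, K, r) {
  p <- sol$order
  lat <- K + seq_len(r)
  coeffs <- vector("list", p + 1)
  for (i in 0:p) {
    qi <- sol$D[[i + 1]]
    qi[lat, lat] <- if (i == 0) diag(r) else matrix(0, r, r)
    coeffs[[i + 1]] <- qi
  }
  coeffs[[1]] <- (coeffs[[1]] + t(coeffs[[1]])) / 2
  trig_poly(coeffs, block_sizes = c(K, r))
}

# max partial spectral coherence for every manifest pair: K x K matrix
.psc_max_matrix <- function(isdm, K, n_grid = 512) {
  man <- seq_len(K)
  sub <- trig_poly(lapply(isdm$coeffs, function(q) q[man, man, drop = FALSE]))
  vals <- eval_trig_poly(sub, freq_grid(n_grid))
  n <- dim(vals)[3]
  dg <- matrix(0, K, n)
  for (a in man) dg[a, ] <- Re(vals[a, a, ])
  if (min(dg) <= 0)
    stop("inverse spectrum is not positive definite on the grid")
  out <- matrix(0, K, K)
  if (K < 2) return(out)
  for (a in 2:K) {
    for (b in seq_len(a - 1)) {
      ratio <- abs(vals[a, b, ]) / sqrt(dg[a, ] * dg[b, ])
      out[a, b] <- out[b, a] <- max(ratio)
    }
  }
  out
}

#' Maximum partial spectral coherence of a variable pair
#'
#' The partial spectral coherence (PSC) of pair `(a, b)` is the modulus of
#' the normalized inverse-spectrum entry
#' \eqn{|\Phi^{-1}(\omega)_{ab}| / \sqrt{\Phi^{-1}(\omega)_{aa}
#' \Phi^{-1}(\omega)_{bb}}}; its maximum over the frequency grid is the
#' edge statistic thresholded during pattern extraction.
#'
#' @param isdm a [trig_poly()] inverse spectral density.
#' @param a,b distinct manifest indices.
#' @param n_grid frequency grid size (default 512).
#' @return Scalar in `[0, 1]`.
#' @export
max_psc <- function(isdm, a, b, n_grid = 512) {
  if (a == b) stop("indices must differ")
  m <- .psc_max_matrix(isdm, max(a, b), n_grid)
  m[a, b]
}

#' Extract a sparsity pattern by PSC thresholding
#'
#' A below-diagonal manifest pair is declared a non-edge (zero) exactly when
#' its maximum PSC over the frequency grid does not exceed `threshold`.
#'
#' @param isdm a [trig_poly()] inverse spectral density (manifest block is
#'   read from the leading `K` rows/columns).
#' @param threshold positive PSC threshold.
#' @param k number of manifest variables.
#' @param n_grid frequency grid size (default 512).
#' @return A [sparsity_pattern()].
#' @export
extract_pattern <- function(isdm, threshold, k, n_grid = 512) {
  if (threshold <= 0) stop("'threshold' must be positive")
  psc <- .psc_max_matrix(isdm, k, n_grid)
  adj <- psc > threshold
  diag(adj) <- TRUE
  sparsity_pattern(adj)
}
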