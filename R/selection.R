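#' Effective number of parameters of a sparse graphical VAR model
#'
#' \eqn{N_{ef} = K(K+1)/2 - N_0 + p(K^2 - 2 N_0)}, the count of free
#' parameters in the manifest inverse-spectrum coefficients once the
#' symmetries and the `N_0` zero pairs of the sparsity pattern are taken
#' into account; it replaces the raw parameter count in every criterion
#' penalty.
#'
#' @param sp a [sparsity_pattern()], or the number of manifest variables
#'   `K` when `n0` is given directly.
#' @param p autoregressive order.
#' @param n0 number of below-diagonal zeros (when `sp` is `K`).
#' @return Integer.
#' @examples
#' effective_params(15, p = 1, n0 = 0)    # 345
#' effective_params(15, p = 1, n0 = 103)  # 36
#' @export
effective_params <- function(sp, p, n0 = NULL) {
  if (inherits(sp, "sparsity_pattern")) {
    k <- sp$k
    n0 <- sp$n0
  } else {
    k <- sp
    if (is.null(n0)) stop("give 'n0' when 'sp' is a dimension")
  }
  k * (k + 1) / 2 - n0 + p * (k^2 - 2 * n0)
}

# total number of graph edges including latent-manifest ones
.edge_count <- function(k, n0, r) {
  k * (k - 1) / 2 - n0 + r * k
}

# log of the multivariate gamma function
.lmvgamma <- function(a, k) {
  k * (k - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(k)) / 2))
}

.itc_names <- c("SBC", "AICc", "logFPE", "RNML", "EBIC", "EBICFD", "RNMLFD")

#' Information-theoretic criteria for sparsity-pattern selection
#'
#' Evaluates one of the selection criteria for a candidate pattern from the
#' fitted residual covariance \eqn{\hat\Sigma}, the lag-0 sample covariance
#' \eqn{\hat R_0}, the effective parameter count and the sample size. All
#' criteria are "smaller is better". `EBIC` and `EBICFD` extend `SBC` with
#' a family-size penalty weighted by `gamma`; `RNMLFD` extends the
#' renormalized maximum-likelihood criterion `RNML` by `2 Nef log K`.
#'
#' @param name one of `"SBC"`, `"AICc"`, `"logFPE"`, `"RNML"`, `"EBIC"`,
#'   `"EBICFD"`, `"RNMLFD"`.
#' @param sigma_hat residual covariance (symmetric positive definite).
#' @param r0_hat lag-0 sample covariance (needed by RNML variants).
#' @param n_ef effective number of parameters.
#' @param T sample size.
#' @param K number of manifest variables.
#' @param gamma extended-criterion weight in `[0, 1]` (default 1).
#' @param n0 below-diagonal zero count (needed by EBIC; defaults to the
#'   value implied by `n_ef` at order `p = 1`).
#' @param p autoregressive order used to invert the `n_ef` formula when
#'   `n0` is missing.
#' @return Scalar criterion value.
#' @export
compute_itc <- function(name, sigma_hat, r0_hat = NULL, n_ef, T, K,
                        gamma = 1, n0 = NULL, p = 1) {
  name <- match.arg(name, .itc_names)
  lds <- 2 * sum(log(diag(chol(sigma_hat))))
  kbar <- K * (K - 1) / 2
  if (is.null(n0)) {
    n0 <- (K * (K + 1) / 2 + p * K^2 - n_ef) / (1 + 2 * p)
  }
  eta <- n_ef / K
  sbc <- T * lds + n_ef * log(T)
  switch(
    name,
    SBC = sbc,
    AICc = {
      if (T <= n_ef + 1) stop("AICc needs T > n_ef + 1")
      T * lds + 2 * n_ef * T / (T - n_ef - 1)
    },
    logFPE = lds + K * log((T + eta) / (T - eta)),
    RNML = .rnml(lds, r0_hat, sigma_hat, n_ef, T, K, eta),
    EBIC = sbc + 2 * gamma * (lgamma(kbar + 1) - lgamma(n0 + 1) -
                                lgamma(kbar - n0 + 1)),
    EBICFD = sbc + 4 * gamma * n_ef * log(K),
    RNMLFD = .rnml(lds, r0_hat, sigma_hat, n_ef, T, K, eta) +
      2 * n_ef * log(K)
  )
}

.rnml <- function(lds, r0_hat, sigma_hat, n_ef, T, K, eta) {
  if (is.null(r0_hat)) stop("RNML needs the lag-0 sample covariance")
  tra <- sum(diag(r0_hat - sigma_hat))
  if (tra <= 0) stop("RNML needs tr(R0 - Sigma) > 0")
  (T - eta - K + 1) / 2 * lds + n_ef / 2 * log(tra) -
    .lmvgamma((T - eta) / 2, K) - lgamma(n_ef / 2)
}

#' All selection criteria at once
#'
#' @inheritParams compute_itc
#' @return Named numeric vector over the seven criteria.
#' @export
itc_all <- function(sigma_hat, r0_hat, n_ef, T, K, gamma = 1, n0 = NULL,
                    p = 1) {
  vapply(.itc_names, compute_itc, 0, sigma_hat = sigma_hat,
         r0_hat = r0_hat, n_ef = n_ef, T = T, K = K, gamma = gamma,
         n0 = n0, p = p)
}

#' Bartlett-windowed correlogram spectral estimate
#'
#' \eqn{\hat\Phi^c(\omega) = \sum_{|i| \le M} (1 - |i|/(M+1)) \hat R_i
#' e^{-j\omega i}}: the triangular (Fejer) taper applied to the biased
#' sample covariances, which keeps the estimate positive semidefinite.
#'
#' @param x time-series matrix (rows are time points).
#' @param window_len half-window `M` (default `floor(sqrt(T))`).
#' @return A [trig_poly()] of degree `M`.
#' @export
correlogram_bartlett <- function(x, window_len = NULL) {
  x <- as.matrix(x)
  tt <- nrow(x)
  m <- if (is.null(window_len)) floor(sqrt(tt)) else window_len
  if (m >= tt) stop("window length must be below the sample size")
  covs <- sample_covariances(x, m)
  w <- 1 - (0:m) / (m + 1)
  trig_poly(lapply(0:m, function(i) w[i + 1] * covs$lags[[i + 1]]))
}

#' Relative entropy rate between two spectral densities
#'
#' \eqn{D(\Phi_1 \| \Phi_2) = -\frac{1}{4\pi} \int_{-\pi}^{\pi}
#' [\log\det\Omega(\omega) + tr(I - \Omega(\omega))] d\omega} with
#' \eqn{\Omega = \Phi_1 \Phi_2^{-1}}, evaluated by the trapezoid rule on the
#' shared uniform grid (exact for smooth periodic integrands up to
#' exponentially small terms). Nonnegative; zero iff the spectra agree.
#'
#' @param num numerator spectrum: complex array `K x K x n` of evaluations
#'   (or a [trig_poly()], evaluated on `freq_grid(n_grid)`).
#' @param den denominator spectrum, same form; with `den_inverse = TRUE`,
#'   `den` holds evaluations of \eqn{\Phi_2^{-1}} directly.
#' @param den_inverse interpret `den` as the inverse spectrum.
#' @param n_grid grid size used when polynomials are supplied.
#' @return Scalar \eqn{\ge 0} (up to quadrature error).
#' @export
relative_entropy_rate <- function(num, den, den_inverse = FALSE,
                                  n_grid = 512) {
  if (inherits(num, "trig_poly")) num <- eval_trig_poly(num, freq_grid(n_grid))
  if (inherits(den, "trig_poly")) den <- eval_trig_poly(den, freq_grid(n_grid))
  n <- dim(num)[3]
  if (!all(dim(den) == dim(num))) stop("spectra evaluated on different grids")
  k <- dim(num)[1]
  hlogdet <- function(h) {
    ev <- eigen(h, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("spectra must be positive definite on the grid")
    sum(log(ev))
  }
  tot <- 0
  for (w in seq_len(n)) {
    deninv <- if (den_inverse) den[, , w] else solve(den[, , w])
    # log det Omega = log det num - log det den; tr via the inverse
    ld <- hlogdet(num[, , w]) + hlogdet(deninv)
    om_tr <- Re(sum(t(num[, , w]) * deninv))
    tot <- tot + ld + k - om_tr
  }
  -tot / (2 * n)
}

#' Score functions based on the relative entropy rate
#'
#' Selection rules that combine the relative entropy rate `d` between the
#' Bartlett correlogram and the fitted manifest spectrum with the total
#' edge count `Ne` (manifest edges plus latent-manifest edges):
#' `logSF1 = log d + log Ne`, `SF2 = d + Ne/T`, `SF3 = d + Ne log(T)/T`.
#'
#' @param d relative entropy rate (positive for SF1).
#' @param n_e total number of edges.
#' @param T sample size.
#' @return Named vector `c(SF1, SF2, SF3)` (`SF1` on the log scale).
#' @export
score_functions <- function(d, n_e, T) {
  if (n_e < 1) stop("edge count must be at least 1")
  sf1 <- if (d > 0) log(d) + log(n_e) else stop("SF1 needs d > 0")
  c(SF1 = sf1, SF2 = d + n_e / T, SF3 = d + n_e * log(T) / T)
}
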