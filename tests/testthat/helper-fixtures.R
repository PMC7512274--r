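# shared fixtures for the test suite; everything is generated in code

# a random stable VAR(p): coefficients shrunk until the companion matrix is
# comfortably inside the unit circle
random_stable_var <- function(k, p, seed, radius = 0.7) {
  set.seed(seed)
  coeffs <- lapply(seq_len(p), function(i) matrix(rnorm(k * k, sd = 0.4), k))
  a <- matrix(rnorm(k * k, sd = 0.3), k)
  sigma <- crossprod(a) + diag(k)
  m <- var_model(coeffs, sigma, validate = FALSE)
  rho <- max(Mod(megvar:::companion_eigenvalues(m)))
  if (rho >= radius) {
    coeffs <- lapply(seq_along(coeffs),
                     function(i) coeffs[[i]] * (radius / rho)^i)
  }
  var_model(coeffs, sigma)
}

# a latent-variable ISDM obeying the algorithm's normalization (latent block
# of the coefficients is identity at lag 0, zero at higher lags) and a given
# manifest edge set; positive-definiteness is repaired on the manifest
# diagonal only so the normalization survives
normalized_latent_isdm <- function(k, cells, p = 1, lat_val = 0.3,
                                   edge_val = 0.5) {
  kk <- k + 1
  coeffs <- lapply(0:p, function(i) {
    qi <- diag(kk)
    qi[kk, kk] <- if (i == 0) 1 else 0
    for (e in seq_len(nrow(cells))) {
      v <- edge_val / (i + 1)
      qi[cells[e, 1], cells[e, 2]] <- v
      qi[cells[e, 2], cells[e, 1]] <- v
    }
    w <- lat_val / (i + 1)
    qi[kk, seq_len(k)] <- w
    qi[seq_len(k), kk] <- w
    qi
  })
  repeat {
    poly <- trig_poly(coeffs, block_sizes = c(k, 1))
    if (min_eig_on_grid(poly) > 1e-8) break
    coeffs[[1]][seq_len(k), seq_len(k)] <-
      coeffs[[1]][seq_len(k), seq_len(k)] + diag(k)
  }
  poly
}

pattern_from_cells <- function(k, cells) {
  adj <- diag(k) > 0
  for (e in seq_len(nrow(cells))) adj[cells[e, 1], cells[e, 2]] <- TRUE
  sparsity_pattern(adj)
}

# independent Yule-Walker oracle: solve the normal equations directly and
# expand the ISDM coefficients by the defining sum, without touching the
# package's maximum-entropy code path
yule_walker_isdm_oracle <- function(covs) {
  m <- covs$dim
  p <- covs$q
  gm <- matrix(0, m * p, m * p)
  for (h in seq_len(p)) {
    for (k2 in seq_len(p)) {
      gm[(h - 1) * m + seq_len(m), (k2 - 1) * m + seq_len(m)] <-
        cov_lag(covs, k2 - h)
    }
  }
  b <- do.call(cbind, lapply(seq_len(p), function(i) cov_lag(covs, i)))
  arow <- b %*% solve(gm)
  aa <- lapply(seq_len(p), function(i) arow[, (i - 1) * m + seq_len(m)])
  sig <- covs$lags[[1]]
  for (i in seq_len(p)) sig <- sig - aa[[i]] %*% t(cov_lag(covs, i))
  sinv <- solve((sig + t(sig)) / 2)
  full <- c(list(-diag(m)), aa)
  qs <- vector("list", p + 1)
  for (i in 0:p) {
    qi <- matrix(0, m, m)
    for (k2 in 0:(p - i)) qi <- qi + t(full[[k2 + 1]]) %*% sinv %*% full[[k2 + i + 1]]
    qs[[i + 1]] <- qi
  }
  qs
}
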