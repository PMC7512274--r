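#' Sparsity patterns of a conditional-independence graph
#'
#' A symmetric boolean `K` by `K` adjacency matrix with a `TRUE` diagonal;
#' `FALSE` at `(a, b)` means components `a` and `b` are conditionally
#' independent given all others (no edge). Derived counts: `n0`, the number
#' of zeros strictly below the diagonal; `ks`, the number of non-zeros there;
#' and `kbar = K(K-1)/2`, their total.
#'
#' @param adjacency logical (or 0/1) square matrix; symmetrized and its
#'   diagonal forced to `TRUE`.
#' @return An object of class `"sparsity_pattern"`.
#' @export
sparsity_pattern <- function(adjacency) {
  adjacency <- as.matrix(adjacency) != 0
  k <- nrow(adjacency)
  if (ncol(adjacency) != k) stop("adjacency must be square")
  adjacency <- adjacency | t(adjacency)
  diag(adjacency) <- TRUE
  kbar <- k * (k - 1) / 2
  ks <- sum(adjacency[lower.tri(adjacency)])
  structure(list(adjacency = adjacency, k = k, ks = ks, n0 = kbar - ks,
                 kbar = kbar),
            class = "sparsity_pattern")
}

#' @export
print.sparsity_pattern <- function(x, ...) {
  cat("sparsity pattern on ", x$k, " variables: ", x$ks,
      " edge(s), ", x$n0, " zero(s) below the diagonal\n", sep = "")
  invisible(x)
}

#' Distance between two sparsity patterns
#'
#' The number of positions strictly below the main diagonal where the two
#' patterns disagree; a metric on patterns with range `0..K(K-1)/2`.
#'
#' @param a,b [sparsity_pattern()] objects on the same number of variables.
#' @return Integer count of disagreements.
#' @export
pattern_distance <- function(a, b) {
  if (a$k != b$k) stop("patterns have different sizes")
  lt <- lower.tri(a$adjacency)
  sum(a$adjacency[lt] != b$adjacency[lt])
}

#' Synthetic latent-variable graphical VAR generator
#'
#' Builds the study model: a `K + r` dimensional VAR whose inverse spectral
#' density has unit diagonals in every coefficient matrix, `ks` prescribed
#' below-diagonal manifest entries equal to `scale * 0.5 / (i + 1)` in the
#' lag-`i` coefficient, and latent couplings (last rows/columns) equal to
#' `scale * 0.3 / (i + 1)`. Integer multiples of the identity are added to
#' the lag-0 coefficient until the polynomial is positive definite on a
#' 512-point frequency grid, and the result is spectrally factorized into a
#' stable VAR model.
#'
#' @param ks number of manifest edges (non-zeros below the diagonal).
#' @param k number of manifest variables (default 15).
#' @param r number of latent variables (default 1).
#' @param p autoregressive order (default 1).
#' @param scale multiplier on the off-diagonal entries (default 1; the
#'   short-sample study uses 50).
#' @param seed seed used to draw the edge positions when `positions` is
#'   `NULL`.
#' @param positions optional integer matrix with columns `(a, b)`, `a > b`,
#'   giving the manifest edge cells explicitly.
#' @return A list with elements `model` (stable [var_model()] of dimension
#'   `K + r`), `pattern` (the true manifest [sparsity_pattern()]), `isdm`
#'   (the constructed [trig_poly()]) and `positions`.
#' @examples
#' g <- generate_synthetic_model(2, k = 5, seed = 1)
#' g$pattern
#' @export
generate_synthetic_model <- function(ks, k = 15, r = 1, p = 1, scale = 1,
                                     seed = 1, positions = NULL) {
  kbar <- k * (k - 1) / 2
  if (ks < 0 || ks > kbar) stop("ks must lie in 0..", kbar)
  if (is.null(positions)) {
    cells <- which(lower.tri(matrix(0, k, k)), arr.ind = TRUE)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    pick <- sample.int(nrow(cells), ks)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    positions <- cells[pick, , drop = FALSE]
  } else {
    positions <- as.matrix(positions)
    if (ncol(positions) != 2 || nrow(positions) != ks)
      stop("'positions' must be a ks-by-2 matrix of (row, col) cells")
    if (any(positions[, 1] <= positions[, 2]))
      stop("'positions' must be strictly below the diagonal (row > col)")
  }
  kk <- k + r
  coeffs <- vector("list", p + 1)
  for (i in 0:p) {
    qi <- diag(kk)
    v <- scale * 0.5 / (i + 1)
    w <- scale * 0.3 / (i + 1)
    for (e in seq_len(nrow(positions))) {
      a <- positions[e, 1]; b <- positions[e, 2]
      qi[a, b] <- v
      qi[b, a] <- v
    }
    if (r > 0) {
      for (j in seq_len(k + r - 1)) {
        qi[kk, j] <- w
        qi[j, kk] <- w
      }
    }
    coeffs[[i + 1]] <- qi
  }
  # positive-definiteness repair: add 1*I to Q_0 until PD on the grid
  repeat {
    poly <- trig_poly(coeffs, block_sizes = c(k, r))
    if (min_eig_on_grid(poly, 512) > 1e-8) break
    coeffs[[1]] <- coeffs[[1]] + diag(kk)
  }
  model <- spectral_factorize(poly)
  adj <- diag(k) > 0
  for (e in seq_len(nrow(positions)))
    adj[positions[e, 1], positions[e, 2]] <- TRUE
  list(model = model, pattern = sparsity_pattern(adj), isdm = poly,
       positions = positions)
}
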