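---
title: "Identifying latent-variable graphical VAR models by maximum-entropy EM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying latent-variable graphical VAR models by maximum-entropy EM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Let $x_t \in \mathbb{R}^\kappa$ be a stationary, stable vector
autoregression of order $p$,
$$x_t = A_1 x_{t-1} + \dots + A_p x_{t-p} + \epsilon_t, \qquad
\epsilon_t \sim \mathcal{N}(0, \Sigma),$$
with $\kappa = K + r$: $K$ *manifest* components that are observed and $r$
*latent* components that are not. The object of interest is the inverse
spectral density matrix (ISDM)
$$\Phi^{-1}(\omega) = A(\omega)^H \Sigma^{-1} A(\omega)
  = \sum_{i=-p}^{p} Q_i e^{-j\omega i},
  \qquad A(\omega) = -\sum_{i=0}^p A_i e^{-j\omega i},\ A_0 = -I,$$
because two components are conditionally independent given all others
exactly when the corresponding ISDM entry function vanishes at every
frequency. The boolean matrix recording which manifest pairs are
conditionally dependent is the *sparsity pattern* — the adjacency of the
conditional-independence graph.

Marginalizing the latent block, the manifest inverse spectrum decomposes
as "sparse minus low rank": a few hidden confounders make the *observable*
inverse spectrum dense even when the graph among manifest variables is
sparse, which is why plain sparse estimation fails and the latent block
must be modelled. Without loss of generality the latent block of the ISDM
is normalized to the identity (lag-0 latent block $I$, higher lags $0$);
the latent influence is carried entirely by the latent–manifest coupling
$\Upsilon_{\ell m}(\omega)$.

## The estimation algorithm

Only the manifest sample covariances
$\hat R_i = T^{-1}\sum_{t=1}^{T-i} x_{t+i} x_t^\top$ (divisor $T$, the
biased estimator, which keeps the block-Toeplitz embedding positive
semidefinite) are computable from data. The EM scheme alternates:

* **Expectation step** (`expectation_step()`): with the current ISDM
  coefficients fixed, the full $(K+r)$-dimensional covariance lags are
  reconstructed. The manifest block is copied from the data; the
  latent–manifest block is a polynomial convolution of degree $2p$; the
  latent block, of nominal degree $3p$, is truncated to degree $p$, the
  degree of the model. Truncation can push the block-Toeplitz embedding
  marginally indefinite; when that happens the lag-0 block is shifted up
  by the violated amount plus a $10^{-8}$ relative margin (recorded on the
  returned object) so the maximization step stays well posed.
* **Maximization step**: a maximum-entropy covariance-extension program.
  Three variants are used (see below): the unpenalized manifest problem
  for initialization (`solve_me1()`), the group-penalized full-model
  problem inside the sweep (`solve_me2()`), and the pattern-constrained
  problem that refits under hard zeros (`solve_me3()`).

For each $\lambda$ on an ascending grid the penalized loop runs `nit` EM
iterations, the resulting inverse spectrum is thresholded into a candidate
pattern, and the constrained loop refits under that pattern — a step backed
by the maximum-entropy covariance-extension property: on exact covariances
of a pattern-true normalized system the constrained solution reproduces the
system exactly (this is tested). The latent coupling is initialized from
the leading eigenpairs of the lag-0 manifest ISDM block (deterministic
sign: the largest-magnitude entry of each eigenvector is made positive);
in the *adaptive* sweep (default) each $\lambda$ inherits the coupling
estimated at the previous grid point instead, which matters because
consecutive grid points are close.

Each constrained-loop inverse spectrum is spectrally factorized into a VAR
model, truncated to its manifest blocks, and the one-step-ahead residual
covariance $\hat\Sigma$ on the data (divisor $T-p$) feeds the selection
criteria. The candidate minimizing the configured criterion wins.

### Edge statistic

The penalty never produces exact zeros in finite precision, so edges are
removed by thresholding the maximum *partial spectral coherence*
$$\max_\omega \frac{|\Phi^{-1}(\omega)_{ab}|}
  {\sqrt{\Phi^{-1}(\omega)_{aa}\,\Phi^{-1}(\omega)_{bb}}} \le \mathrm{Th},$$
computed on the same uniform 512-point frequency grid used everywhere
else. The normalization makes the statistic invariant to rescaling of the
spectrum, so one threshold (default $10^{-3}$) serves all problems.

### The group penalty

The promoter is
$f(Z) = \sum_{a>b} \max_i |D_i(Z)(a,b)|$, where $D_i$ is the block trace
(the map from the semidefinite variable to the ISDM coefficients) and the
maximum runs over *all* coefficients of the $(a,b)$ entry polynomial: the
cells $(a,b)$ for $i = 0..p$ together with the mirrored cells $(b,a)$ for
$i \ge 1$, which carry the negative lags through the Hermitian symmetry
$Q_{-i} = Q_i^\top$. Grouping only the lower cells would leave the
negative-lag coefficients unpenalized at sampling-noise level
($\sim 1/\sqrt{T}$, i.e. $\approx 4\cdot10^{-3}$ at $T = 5\cdot10^4$ —
above any useful PSC threshold), and no edge could ever be removed; the
full group is also how the penalty is defined in the topology-selection
literature this estimator builds on.

## The convex solvers

All maximization steps have the form
$$\min_{X \succeq 0}\ \mathrm{tr}(T(C)X) - \log\det X_{00}
  + \lambda f(X) \quad \text{s.t. linear equalities},$$
with $T(C)$ the block-Toeplitz embedding and $X_{00}$ the leading block
(only $X_{00}$ enters the log-determinant, exactly as the problems are
posed). The package ships its own solvers, built on one identity: for
$N \succ 0$,
$$\min_{X \succeq 0} \mathrm{tr}(NX) - \log\det X_{00}
  = m + \log\det N - \log\det N_{11},$$
attained at $X^\* = N^{-1} - \mathrm{blkdiag}(0, N_{11}^{-1})$, where
$N_{11}$ is the trailing block and $m$ the block size. Dualizing the
penalty (per-pair $\ell_1$ balls of radius $\lambda$, the dual of the
group $\ell_\infty$ norm) and the equality constraints therefore yields a
*smooth* concave dual whose gradient is available in closed form — it is
exactly the vector of primal functional values at $X^\*$. Consequences:

* `solve_me1()` has no dual variables at all: the solution is the closed
  form above, and it coincides with the Yule–Walker fit (tested against an
  independently coded Yule–Walker oracle).
* `solve_me2()` maximizes the dual by a Barzilai–Borwein spectral
  projected gradient (nonmonotone Armijo, window 10, up to 3000
  iterations, projected-gradient tolerance $10^{-8}$), then polishes the
  equality multipliers by a few Newton steps so the latent identity
  constraints hold to $\approx 10^{-8}$ on the returned solution. The
  primal iterate is PSD by construction at every step.
* `solve_me3()` has a smooth unconstrained dual (multipliers for the
  latent identity constraints and for every zeroed cell) and is maximized
  by a damped Newton method with an analytic Hessian assembled from the
  entry lists of the constraint functionals (gradient tolerance
  $10^{-9}$; a line-search stall with gradient below $10^{-6}$ is
  accepted as converged).

Solutions of convex programs are solver-independent at the optimum, so
these choices are implementation detail, not model detail; every solve
reports its objective, dual value and gap.

The sparse-plus-low-rank baseline (`solve_sparse_lowrank()`) minimizes
$\mathrm{tr}(T(\hat R)X) - \log\det X_{00} + \lambda\gamma f(X+L) +
\lambda\,\mathrm{tr}(L)$ over $X, L \succeq 0$. Its dual is no longer
smooth-with-simple-constraints (the trace penalty turns into a
semidefinite dual constraint), so this one problem is solved in the primal
by a log-barrier interior-point method: the promoter in epigraph form (one
bound variable per pair), barriers on both cones and on the bound
constraints, damped Newton with an analytically assembled Hessian, barrier
multiplier 25, at most 25 Newton steps per stage, and a barrier duality
gap of $10^{-6}$ by default ($10^{-4}$ in the parameter sweeps, where the
$10^{-3}$ PSC threshold makes tighter solves indistinguishable).

## Spectral factorization

A positive-definite ISDM polynomial of degree $p$ is, by construction, the
inverse spectrum of a stable VAR($p$) process. `spectral_factorize()`
therefore inverts the polynomial on a fine FFT grid (2048 points to start),
reads off the process autocovariances (the quadrature error of the
trapezoid rule on a smooth periodic integrand decays exponentially in the
grid size), and solves the block Yule–Walker system — giving the unique
stable factor normalized to $A_0 = -I$. The reconstruction residual is
checked against a $10^{-7}$ coefficient tolerance and the grid doubled (up
to $2^{15}$) if needed; stability of the factor is validated on every
call. This replaces a semidefinite-programming formulation of the same
factorization; by uniqueness of the normalized minimum-phase factor, any
method meeting the reconstruction contract returns the same object, and
the round-trip and idempotence contracts are what the tests pin down.

## Model selection

With $N_0$ the number of below-diagonal zeros of a pattern, the effective
parameter count is $N_{ef} = K(K+1)/2 - N_0 + p(K^2 - 2N_0)$. The
criteria (all "smaller is better", evaluated from $\hat\Sigma$, $\hat R_0$,
$N_{ef}$, $T$, $K$):

* $\mathrm{SBC} = T\log\det\hat\Sigma + N_{ef}\log T$, and
  $\mathrm{AICc} = T\log\det\hat\Sigma + 2N_{ef}T/(T-N_{ef}-1)$;
* $\log\mathrm{FPE} = \log\det\hat\Sigma + K\log\{(T+\eta)/(T-\eta)\}$
  with $\eta = N_{ef}/K$;
* $\mathrm{RNML} = \frac{T-\eta-K+1}{2}\log\det\hat\Sigma +
  \frac{N_{ef}}{2}\log\mathrm{tr}(\hat R_0 - \hat\Sigma)
  - \log\Gamma_K\!\big(\frac{T-\eta}{2}\big)
  - \log\Gamma\!\big(\frac{N_{ef}}{2}\big)$, with $\Gamma_K$ the
  multivariate gamma function (computed as its finite sum of ordinary
  log-gamma terms);
* extended criteria that account for the $2^{\bar K}$-sized model family:
  $\mathrm{EBIC} = \mathrm{SBC} + 2\gamma\log\binom{\bar K}{N_0}$ (via
  log-gamma), $\mathrm{EBICFD} = \mathrm{SBC} + 4\gamma N_{ef}\log K$, and
  $\mathrm{RNMLFD} = \mathrm{RNML} + 2 N_{ef}\log K$. The default
  $\gamma = 1$. The two extensions behave differently by design: the
  $N_{ef}\log K$ penalties grow monotonically as the pattern densifies,
  while the binomial term peaks at $N_0 = \bar K/2$ (both shapes are
  asserted in the tests).

The score functions need no VAR coefficients: with
$d = D(\hat\Phi^c_m \,\|\, \hat\Phi_m)$ the relative entropy rate between
the Bartlett-windowed correlogram and the fitted manifest spectrum
(trapezoid quadrature of
$-\frac{1}{4\pi}\int [\log\det\Omega + \mathrm{tr}(I-\Omega)]\,d\omega$,
$\Omega = \hat\Phi^c_m \hat\Phi_m^{-1}$, on the shared 512-point grid) and
$N_e = K(K+1)/2 - N_0$ the edge count for one latent variable
(generalized to $K(K-1)/2 - N_0 + rK$ for $r \ge 1$ — a declared
generalization, asserted only at $r = 1$), they are
$\log\mathrm{SF1} = \log d + \log N_e$, $\mathrm{SF2} = d + N_e/T$,
$\mathrm{SF3} = d + N_e \log T/T$. The fitted manifest spectrum for the
EM candidates is obtained from the full-model inverse spectrum by the
Schur complement of its (identity) latent block; for the baseline it is
the inverse of $\Delta X \Delta^H$ directly.

The Bartlett half-window is not dictated by the method; the default is
$M = \lfloor\sqrt{T}\rfloor$, standard correlogram practice, and it is
exposed because the score-function values depend on it.

## The synthetic study systems

`generate_synthetic_model()` builds the benchmark: $K = 15$ manifest
variables, $r = 1$ latent, $p = 1$; every ISDM coefficient has a unit
diagonal; `ks` chosen below-diagonal manifest cells carry $0.5/(i+1)$ in
lag $i$; the latent row/column carries $0.3/(i+1)$; multiples of the
identity are added to the lag-0 coefficient until the polynomial is
positive definite on the 512-point grid (minimum-eigenvalue margin
$10^{-8}$); spectral factorization then yields the generating VAR.
A `scale` argument multiplies the off-diagonal entries (the short-sample
variant uses 50). Trajectories start from a zero state and discard a
1000-sample burn-in.

The benchmark fixes only the *number* of non-zero cells, not their
coordinates; the generator therefore draws them deterministically from
its seed (they can also be passed explicitly). The headline study
conclusions depend on the edge density rather than on the particular
cells, though individual criterion selections near the
sparsification boundary can differ between draws. Note two deliberate properties: the generated
system's latent block is *not* identity-normalized (the
positive-definiteness repair acts on the whole diagonal), so the
estimator's model family is mildly misspecified relative to the
generator — as it would be on real data; and the latent coupling after
normalization is weak relative to the manifest edges. What the generator
does *not* emulate: non-Gaussian innovations, nonstationarity, ARMA
dynamics, missing data, and heavier confounding than a single weak latent
factor — passing the study says nothing about those regimes.

## Study protocols and problem sizes

The simulation studies follow three protocols: an *oracle* evaluation
(the penalized sweep's candidate set is scored by its best achievable
distance to the true pattern — the number of below-diagonal disagreements),
a *criterion* study (each selection rule picks its own winner), and the
baseline sweep over $(\lambda, \gamma)$ pairs with the same PSC
post-processing applied to the sparse part $\Delta(X+L)\Delta^H$. The full
protocol uses 10 trials of length $T = 50{,}000$, a 100-point $\lambda$
grid on $[10^{-3}, 10^{-1}]$, and a $6\times50$ pair grid; the package's
test suite and the bundled `study_preset("desk")` run the same protocols
with 3 trials, a 20-point grid, and a $6\times5$ pair grid with 2 trials
for the baseline — sizes chosen so the whole suite completes in an
interactive session while leaving the per-trial protocol untouched.
`Nit = 2` is the default iteration budget: raising it does not reliably
improve the oracle distance, and the cost is linear in it.

## Limitations and open choices

* The VAR order $p$ and the latent count $r$ are assumed known; selecting
  them by criterion would require modifying $N_{ef}$ and is out of scope.
* "Fitting the selected model to the data" is read as evaluating one-step
  residuals with the factorized, manifest-truncated coefficients;
  re-estimating the coefficients by constrained least squares under the
  selected pattern is a defensible alternative not taken here.
* The truncated manifest model need not be minimum-phase; stability is
  validated only for full factorizations.
* Candidates whose solves fail are flagged and excluded from selection
  rather than aborting a sweep; the fitted object records the failure
  message per grid point.
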