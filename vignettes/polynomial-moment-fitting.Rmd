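---
title: "Polynomial density estimation by the method of moments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polynomial density estimation by the method of moments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polydens)
```

## The model

Let $f$ be a probability density supported (or effectively supported) on an
interval $[a, b]$, with raw moments

$$E_k = \int_a^b x^k f(x)\,dx, \qquad k = 0, \dots, N.$$

`polydens` approximates $f$ by the polynomial
$p(x) = \sum_{n=0}^{N} w_n x^n$ whose moments on $[a,b]$ equal the $E_k$.
Matching all $N+1$ moments gives the linear system $M w = E$ with the Hankel
matrix

$$M_{ij} = \int_a^b x^{i+j}\,dx = \frac{b^{i+j+1} - a^{i+j+1}}{i+j+1},
\qquad i, j = 0, \dots, N.$$

By the Weierstrass approximation theorem the polynomial approximation can be
made arbitrarily good for continuous $f$ as $N$ grows; in practice the
interesting questions are numerical (the system is severely ill-conditioned)
and structural (the fit need not be nonnegative).

The estimator proceeds in steps, implemented by `fit_polynomial_pdf()`:

1. obtain $E_0, \dots, E_N$ — analytically, by adaptive quadrature from a
   supplied density (`raw_moment_quadrature()`), or from a sample
   (`sample_moments()`);
2. build $M$ (`build_moment_matrix()`) and solve $M w = E$
   (`solve_weights()`);
3. check nonnegativity of $p$ on a *validity interval*
   $[a', b'] \subseteq [a, b]$ (`check_positivity()`, which locates every
   critical point via the roots of $p'$ rather than trusting a grid);
4. renormalize $p$ to unit mass on $[a', b']$ in closed form
   (`normalize()`);
5. score the result with a Kolmogorov–Smirnov statistic
   (`ks_statistic()`).

If positivity or the KS threshold fails at the requested degree $N$, the
driver searches degrees upward to `n_max` and then downward to `n_min`,
recording every attempt in `fit$trace`. The distinction between the moment
interval and the validity interval matters: high-degree fits routinely dip
a little below zero where the target density vanishes (tails, zeros), and
narrowing $[a', b']$ is the designed remedy rather than a workaround.

## Conditioning and the three solvers

On $[0, 1]$ the matrix $M$ is the Hilbert matrix, whose condition number
grows like $e^{3.5 N}$; at $N = 10$ it is already $\sim 10^{14}$ and the
moment systems solved here reach $10^{19}$ and beyond. Three solvers are
provided:

- **`factorized`** (default): LAPACK LU with `solve(..., tol = 0)`.
  Ill-conditioning makes the *coefficients* sensitive, but the solve is
  backward stable: the fitted polynomial reproduces the input moments to a
  small relative residual (reported as `attr(w, "residual")` and
  `fit$moment_residuals`), which is the quantity that matters for a moment
  fit.
- **`rescaled_hilbert`**: affinely maps $[a,b]$ to $[0,1]$, applies the
  *exact* Hilbert inverse — computed in hand-rolled big-integer arithmetic
  from the classical binomial formula and verified exactly by
  `hilbert_inverse_identity_exact()` — and maps back. Exact for $a = 0$;
  for $a \neq 0$ the binomial back-transform suffers cancellation, which is
  documented and tested.
- **`exact_rational`**: full Gaussian elimination in exact rational
  arithmetic, with the double-precision inputs converted exactly to
  rationals. The solution is the exact solution of the rounded system; its
  moment residual is at machine precision even at $N = 13$.

Because no arbitrary-precision library is assumed, the package carries a
small exact-integer layer (base-$10^6$ limb vectors with schoolbook
multiplication and long division) and reduced rationals on top of it; both
are exercised directly by the test suite.

## Goodness of fit

`ks_statistic()` computes the supremum distance between the polynomial's
closed-form CDF and either an empirical CDF (sample reference, using the
standard $\max(F(x_{(i)}) - (i-1)/n,\; i/n - F(x_{(i)}))$ form) or a
numerically accumulated CDF of an analytic reference. `density_errors()`
adds $L_1$ and $L_\infty$ density errors on any interval, used throughout
the tests as convergence diagnostics: for the Weibull(3, 2) target the
$L_1$ error on $[0.2, 4]$ decreases strictly through degrees 4, 6, 8, 10.

## Gram–Charlier and Edgeworth expansions

For comparison, `gc_density()` implements the type A series
$$f(x) \approx \phi_{\mu,\sigma}(x)\Bigl(1 + \sum_{i\ge 3} c_i
\mathrm{He}_i(z)\Bigr), \qquad z = (x-\mu)/\sigma,$$
with probabilists' Hermite polynomials and $c_i = E[\mathrm{He}_i(Z)]/i!$
computed from raw moments. The four-term truncation has
$c_3 = \gamma_1/6$ and $c_4 = \gamma_2/24$ (skewness and excess kurtosis);
`edgeworth_density()` adds the $\mathrm{He}_6$ term with coefficient
$\gamma_1^2/72$. Both corrections are mass-neutral (each
$\int \phi\,\mathrm{He}_i = 0$ for $i \ge 1$), collapse exactly to the
Normal when $\gamma_1 = \gamma_2 = 0$, and — like the polynomial fit — can
go negative, which the tests demonstrate on the exponential-like
Weibull(1, 1).

## Convolution of polynomial densities

The density of a sum of independent random variables with polynomial
densities on $[a_1,b_1]$ and $[a_2,b_2]$ is piecewise polynomial on
$[a_1+a_2,\, b_1+b_2]$ with breakpoints where the integration limits of
$\int p(x)\,q(t-x)\,dx$ change branch. `convolve_polynomial_densities()`
computes the pieces exactly by term-wise integration; correctness is checked
against a direct numerical convolution oracle, and mass, mean additivity,
commutativity and breakpoint continuity are verified. When a single
polynomial is preferred, the binomial identity
$E[(X+Y)^k] = \sum_j \binom{k}{j} E[X^j] E[Y^{k-j}]$
(`moments_of_sum()`) feeds the moments of the sum back into the fitting
pipeline (`refit_degree =`).

## The coagulation application

The Smoluchowski coagulation equation describes the mass distribution
$f(m, t)$ of coalescing particles under a kernel $K(m, m')$. For the
constant, linear ($K = A(m+m')$) and product kernels the time derivatives of
the raw moments close on finitely many moments, giving an ODE hierarchy
(`sce_moment_rhs()`, integrated with `deSolve` in
`sce_integrate_moments()`); the first-order moment (total mass) is conserved
exactly, and the product kernel gels at $t = 1/(A M_2(0))$, which the
integrator guards against.

For the linear kernel at unit amplitude an exact solution is known,
$$f(m, t) = \frac{1}{\sqrt{2\pi}}\, m^{-3/2}
\exp\!\bigl(-m e^{-2t}/2 - t\bigr),$$
with closed-form truncated moments expressible through incomplete gamma
functions (`sce_truncated_moment()`). The $m^{-3/2}$ factor makes a direct
polynomial fit on a mass band hopeless — the fitted polynomial oscillates
and changes sign (Runge-type behavior at the power-law singularity). The
implemented remedy, `sce_reconstruct()`, fits the polynomial to
$m^{3/2} f(m, t)$ instead (using band moments at half-integer shifted
orders, available in closed form) and returns
$p(m)/m^{3/2}$. The test suite quantifies the difference: mass-weighted
relative $L_1$ error around $5 \times 10^{-8}$ with removal, above $15$
without, at $t = 1$, degree 8, band $[0.05, 20]$.

## Synthetic generators

`generator_spec()`/`synth_sample()` provide reproducible samples from
Normal, Weibull, log-Normal and two-component Weibull mixtures, plus a
`household_like` emulator: a bimodal Weibull mixture (modes near 300 and
1500) clipped to $[100, 4000]$, mimicking the shape of household electric
power measurements. Its parameters are fixtures, not measured data.
`synth_density()` returns the matching analytic law (pre-clipping) so error
metrics can be computed against the truth.

## Numerical choices

- Adaptive quadrature (`stats::integrate`, relative tolerance $10^{-10}$)
  for all moment computations from densities; closed forms wherever a
  polynomial is involved.
- `solve(tol = 0)` to bypass R's reciprocal-condition guard deliberately:
  the guard rejects systems the backward-stable solve handles perfectly
  well in the residual sense, and a warning with the estimated condition
  number is raised instead.
- Positivity via `polyroot()` on the derivative plus endpoint and dense-grid
  checks, with a relative tolerance on the minimum.
- Upper incomplete gamma for non-positive order by downward recursion from a
  positive order, avoiding the divergence of the naive series.
- ODE integration with `lsoda` at `rtol = 1e-10`, `atol = 1e-12`.

## Limitations

- The `rescaled_hilbert` solver is exact only for moment intervals starting
  at 0; elsewhere its binomial back-transform cancels catastrophically.
- The coefficient vector itself is not stable under moment perturbations at
  high degree — only the fitted function and its moments are; treat
  `tidy()` output accordingly.
- Positivity failures near density zeros are intrinsic to the method; the
  package narrows the validity interval rather than constraining the fit.
- The Kolmogorov–Smirnov statistic is reported without a p-value: after
  moment fitting its null distribution is not the classical one, so only
  the threshold comparison (default 0.05) is offered.
- The exact coagulation results cover the linear kernel at unit amplitude;
  other kernels are supported at the moment-hierarchy level only.
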