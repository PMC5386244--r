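# polydens

Polynomial probability density estimation by the method of moments.

Given the first *N*+1 raw moments of a distribution on an interval
[*a*, *b*] — computed analytically, by quadrature from a known density, or
from a sample — `polydens` finds the degree-*N* polynomial whose moments
match them by solving the Hankel linear system

> M w = E,  with M<sub>ij</sub> = (b<sup>i+j+1</sup> − a<sup>i+j+1</sup>)/(i+j+1),

checks the resulting polynomial for nonnegativity on a (possibly narrower)
*validity interval* [*a*′, *b*′], renormalizes it to unit mass there, and
scores it with a Kolmogorov–Smirnov statistic. On the unit interval M is the
Hilbert matrix, so the system is notoriously ill-conditioned; the package
ships three solvers (backward-stable LAPACK, an exact big-integer Hilbert
inverse after affine rescaling, and a full rational-arithmetic elimination)
and reports the moment residual of whichever you use.

Alongside the core fit the package provides:

- **Gram–Charlier type A and Edgeworth expansions** (`gc_expansion`,
  `gc_density`, `edgeworth_density`) for comparison with the classical
  Gaussian-times-Hermite correction series.
- **Exact convolution** of compactly supported polynomial densities
  (`convolve_polynomial_densities`), returning a piecewise polynomial, plus
  the binomial moment identity for sums (`moments_of_sum`).
- **A Smoluchowski coagulation application** (`sce_*`): closed-form moment
  hierarchies for constant/linear/product kernels, the exact linear-kernel
  solution, closed-form truncated moments, and reconstruction of the particle
  size distribution from moments with power-law removal.
- **Synthetic generators** (`generator_spec`, `synth_sample`) including a
  clipped bimodal "household electricity" emulator, and a small CLI
  (`exec/polydens`, `polydens_cli()`) covering the whole pipeline.

## Worked example

Fit a polynomial to the moments of a Weibull(shape 3, scale 2) density on
[0, 5], restricting validity to [0, 4.2] to keep the fit nonnegative in the
far right tail where the density vanishes:

```r
library(polydens)

f   <- function(x) dweibull(x, 3, 2)
cfg <- fit_config(degree = 8, moment_interval = interval(0, 5),
                  validity_interval = interval(0, 4.2))
fit <- fit_polynomial_pdf(f, cfg)
print(fit)
#> Polynomial density fit: degree 10, passed
#>   validity interval [0, 4.2]; condition ~ 6.75e+19
#>   positivity: min 0.000521 at x = 4.2 (nonnegative)
#>   KS statistic: 0.0003579
#>   max moment residual: 1.41e-06
```

The degree search started at the requested degree 8, found its positivity
check failing, and walked up to degree 10, where the fit is nonnegative and
passes. Despite the condition number of about 7 × 10<sup>19</sup>, the
backward-stable solve reproduces the input moments to a relative residual of
1.4 × 10<sup>−6</sup>, and the fitted curve is accurate:

```r
density_errors(f, fit$density, interval(0.2, 4))
#> $l1
#> [1] 0.003800938
#> $linf
#> [1] 0.002002908

cdf(fit$density, 2)        # true value: pweibull(2, 3, 2) = 0.6321206
#> [1] 0.632195
```

`tidy(fit)` and `glance(fit)` expose the coefficients and diagnostics as
data frames, and `plot(fit, reference = f)` draws the fit against the truth.

## Coagulation example

For the linear coagulation kernel the package knows the exact
time-dependent size distribution, its closed-form truncated moments, and how
to reconstruct the distribution from moments. The distribution behaves like
m<sup>−3/2</sup> near the origin, which ruins a direct polynomial fit;
removing the power law first makes the moment fit essentially exact:

```r
rec <- sce_reconstruct(1, interval(0.05, 20), degree = 8, exponent = 1.5)
rec$density(c(0.1, 1, 5))
#> [1] 4.60973949 0.13716004 0.00935884
sce_exact_linear(c(0.1, 1, 5), 1)
#> [1] 4.60973949 0.13716004 0.00935884
```

The mass-weighted relative L1 error on the band is 4.5 × 10<sup>−8</sup>;
fitting the same moments *without* power-law removal yields an oscillating,
sign-changing polynomial with relative error above 15.

## Command line

```sh
exec/polydens simulate --family weibull --params k=3,lambda=2 \
    --n 5000 --seed 1 --out sample.csv
exec/polydens fit --sample sample.csv --degree 8 --a 0 --b 5 \
    --a-prime 0.2 --b-prime 4.5 --out coefficients.json
exec/polydens sce --times 0.5,1 --degree 8 --out reconstruction.csv
```

Exit codes: 0 success, 2 usage error, 3 numeric failure, 4 the fit completed
but failed its positivity/goodness-of-fit checks.

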