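# spanreg

Span-of-regularization (SpanReg) inversion for multi-exponential
relaxometry: recovery of non-negative T2 distribution functions (DFs) from
decay signals, and pixel-wise myelin-water-fraction (MWF) mapping from
multi-echo image stacks.

## The problem and the method

A multi-exponential decay is the Laplace transform of a non-negative
distribution of relaxation times,

```
y(t) = ∫ exp(-t/T2) f(T2) dT2,      f ≥ 0,
```

and recovering `f` from noisy samples of `y` is a severely ill-posed
inverse problem (the discretized kernel's condition number exceeds 1e15 on
the default 150 × 200 configuration). The standard treatment is
Tikhonov-regularized NNLS,

```
f_λ = argmin_{f ≥ 0} ||A f − y||² + λ² ||f||²,
```

with a selector — for example the Morozov discrepancy principle (DP),
which picks λ so the fit residual matches the expected noise norm
`ν √m σ` — that keeps exactly one λ and discards the rest.

SpanReg keeps them all: the estimate is a non-negative combination of
differently regularized solutions,

```
f*_α = Σ_j α*_j f_{λ_j},
```

combining the stability of the strongly regularized members with the
resolution of the weakly regularized ones. The weights α* are found by
matching two representations of the unknown DF in a dictionary of M
unit-area Gaussian atoms, built offline from ensemble averages of
noise-corrupted regularized inversions of each atom (⟨g_{i,λ_j}⟩ and
⟨β_{ij}⟩ over `n_run` noise draws at the data's noise level). The online
step solves one small simplex-constrained least-squares problem whose
matrix is dramatically better conditioned (≈1e5) than the kernel itself.
The per-noise-level offline computation is reusable across any number of
signals; imaging data use a bank of bases indexed by geometric SNR bins.

## Worked example

Two Gaussian components at 30 ms and 50 ms (SDs 3 and 5 ms) at SNR 500 —
close enough that single-λ methods typically merge them:

```r
library(spanreg)

grid <- t2_grid(200, 1, 200)                      # 1 ms spacing
A    <- build_kernel(time_grid(150, 0.3, 400), grid)
D    <- build_dictionary(grid)                    # M = 220 atoms
f    <- two_gaussian_df(phantom_spec(30, 3, 50, 5), grid)  # unit area

y0    <- synthesize_signal(A, f)
sigma <- max(abs(y0)) / 500
basis <- offline_basis(A, D, lambda_ladder(), sigma, n_run = 10, seed = 101)

y   <- add_noise(y0, sigma = sigma, seed = 2001)
fit <- spanreg(y, A, basis, check_sigma = FALSE)
dp  <- dp_select_lambda(A, y, sigma = sigma, nu = 1.05)

count_peaks(fit$f_alpha)          # 2   — both components resolved
count_peaks(dp$f)                 # 1   — DP merges them
relative_error(fit$f_alpha, f)    # 0.526
relative_error(dp$f, f)           # 0.581
```

`fit$f_alpha` is the reconstruction, `fit$alpha` the ladder weights and
`fit$c` the (simplex-constrained) dictionary weights. Across 10 noise
realizations of this phantom, SpanReg resolves both peaks in most runs
(7–10 of 10 across seeds) while the DP resolves them in none; over the 25-phantom simulation
grid (`phantom_grid()`, `run_comparison()`), SpanReg's relative error is
lower than the DP's in ≳20/25 cells at SNR 500.

For imaging, `synth_phantom_stack()` generates a fully synthetic
multi-echo stack with known per-pixel truth, `basis_bank()` precomputes
per-SNR-bin bases, and `mwf_map()` produces MWF maps by SpanReg, DP, or
plain NNLS; `sad()` compares maps. A thin command-line wrapper is
installed at `inst/cli/spanreg` (subcommands `offline`, `reconstruct`,
`simulate`, `phantom`, `map`).

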