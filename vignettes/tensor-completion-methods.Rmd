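---
title: "Core-tensor nuclear-norm completion with thin-QR updates: model, choices, and limits"
author: "ctnmqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-tensor nuclear-norm completion with thin-QR updates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctnmqr)
```

## The model and its assumptions

A partially observed order-N tensor $\mathcal{T}$ with observation set
$\Omega$ is completed under a low Tucker-rank model,
$\mathcal{X} = \mathcal{C} \times_1 U_1 \cdots \times_N U_N$, with
core $\mathcal{C} \in \mathbb{R}^{R_1 \times \cdots \times R_N}$ and
factors $U_i \in \mathbb{R}^{I_i \times R_i}$ constrained to
orthonormal columns. Because mode products with orthonormal-column
matrices preserve singular values of every unfolding, the weighted
tensor nuclear norm of $\mathcal{X}$ equals that of its core, so the
rank surrogate can be minimized on the core alone:

$$
\min_{\mathcal{C}, \{U_i\}, \mathcal{X}}
 \sum_{i=1}^N \alpha_i \lVert C_{(i)} \rVert_*
 + \frac{\lambda}{2}
 \lVert \mathcal{X} - \mathcal{C} \times_1 U_1 \cdots \times_N U_N \rVert_F^2
\quad \text{s.t.} \quad
\mathcal{X}_\Omega = \mathcal{T}_\Omega, \;\; U_i^\top U_i = I_{R_i}.
$$

The working assumptions are: the data are well approximated by a tensor
of known (user-supplied) Tucker rank; missingness is unrelated to the
values (the mask carries no signal); and entries are observed exactly
(no explicit noise term — noise is absorbed by the low-rank fit).

The constraint is written on the *thin* factor ($U_i^\top U_i =
I_{R_i}$): an $I_i \times R_i$ matrix with $R_i < I_i$ cannot satisfy
the $I_i \times I_i$ identity, so this is the only dimensionally
consistent reading.

Each consensus copy of the core is a tensor-valued auxiliary
$\mathcal{V}_i$ (not a matrix): the split $\mathcal{C} = \mathcal{V}_i$
keeps all $N$ nuclear-norm terms independent while every
$\mathcal{V}_i$ retains the full multiway structure. The ADMM sweep is
singular-value thresholding on each $\mathcal{V}_i$ (threshold
$\alpha_i/\mu$ on the mode-$i$ unfolding, a small $R_i \times \prod_{j
\ne i} R_j$ matrix), a closed-form core update, a Gauss–Seidel pass of
factor updates, re-imposition of the observed entries, and a multiplier
step $Y_i \leftarrow Y_i + \mu(\mathcal{C} - \mathcal{V}_i)$ followed by
$\mu \leftarrow \min(\rho\mu, \mu_{\max})$. Since the $\mathcal{V}_i$
subproblems do not involve each other, refreshing all of them from the
current core is simultaneously the Jacobi and the Gauss–Seidel sweep;
nothing hinges on that ordering.

The factor subproblem $\min_U \tfrac12\lVert \mathcal{Z}_i \times_i U -
\mathcal{X}\rVert_F^2$ (with $\mathcal{Z}_i$ the reconstruction that
skips mode $i$) is solved in two steps: the unconstrained least-squares
solution $\tilde U_i = X_{(i)} Z_{(i)}^\top (Z_{(i)} Z_{(i)}^\top)^{-1}$,
then a thin QR decomposition $\tilde U_i = QR$, keeping $Q$. This
replaces the SVD that an HOOI-style update would need; the per-sweep
orthogonalization cost is $O(\sum_i I_i R_i^2)$. The HOOI-style update
(top-$R_i$ left singular vectors of $X_{(i)} Z_{(i)}^\top$) is retained
as `factor_strategy = "hooi"` so the two strategies can be compared on
the same problems; they agree at the fixed point, and the test suite
checks their final accuracies stay within a factor of two of each other.

### What is — and is not — monotone in the factor sweep

The least-squares factor can only improve its subproblem:
$f(\tilde U_i^{k+1}) \le f(U_i^k)$ holds at every iteration, and the
solver asserts it (in `debug = TRUE` mode) and the tests verify it.
The *orthonormalized* factor $Q$ attains the same objective value only
once the triangular factor $R$ is absorbed into a modified core
($\tilde{\mathcal{C}} = \mathcal{C} \times_i R$) — a substitution the
algorithm does not apply, because the core has its own update. In
consequence the orthonormalized factor's objective merely *tends* to
decrease: during the first couple of sweeps, while the iterates are
still far from a fixed point, it can transiently increase. We verified
this empirically; asserting strict per-update monotonicity for $Q$
would be asserting something the method does not guarantee. The
invariant tested is therefore the least-squares one, which is the
provable statement.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `rank` | — (required) | target Tucker rank per mode; must be supplied (automatic rank selection is out of scope) |
| `alpha` | $1/N$ per mode | weights of the per-mode nuclear norms; must be $\ge 0$ and sum to 1. For RGB images the channel mode carries almost no rank structure, hence the `--preset image` weighting $(1, 1, 10^{-3})$, normalized |
| `lam` | `fnorm(t[mask])` (resolved at solve time) | weight of the Tucker-fit term; see below |
| `mu0` | $10^{-3}$ | initial ADMM penalty; small, so early sweeps are dominated by the data term |
| `mu_max` | $10^{10}$ | penalty cap |
| `rho` | 1.05 | geometric penalty growth, constrained to $(1.0, 1.1]$ |
| `tol` | $10^{-5}$ | relative-change stopping tolerance on the completed tensor |
| `max_iter` | 500 | iteration cap; the stop fires on whichever criterion is met first |
| `factor_strategy` | `"qr"` | `"qr"` (thin-QR) or `"hooi"` (SVD baseline) |
| `seed` | 1 | seed for the Gaussian factor initialization; fixes the whole run |

### Why `lam` is data-scaled

At a stationary point the multipliers are dual-bounded:
$\lVert Y_{i(i)} \rVert_2 \le \alpha_i$, so
$\lVert \sum_i Y_i \rVert_F \le \sum_i \alpha_i \sqrt{R_i}$ — an
*absolute* quantity, independent of the data scale. Stationarity of the
smooth part gives
$\lambda(\mathcal{C} - \mathcal{X} \times_1 U_1^\top \cdots) = -\sum_i Y_i$,
so the core is biased away from the data projection by up to
$\sum_i \alpha_i \sqrt{R_i} / \lambda$ in Frobenius norm. A fixed
$\lambda$ of order 1 therefore leaves a bias that is negligible for
large-norm tensors but dominates small ones (on a $20^3$ rank-2
problem it costs three orders of magnitude of RSE), and once
$\mu \gg \lambda$ the data term stops informing the core entirely.
Scaling $\lambda$ with the observed-data norm,
$\lambda = \lVert \mathcal{T}_\Omega \rVert_F$, makes the relative bias
uniformly negligible across problem sizes while leaving the
consensus/fit trade-off otherwise untouched. The value is exposed
(`lam` in `solver_config()`, `--lambda` on the command line) for
sensitivity sweeps.

## Numerical choices

* **Unfolding convention.** The mode-$n$ unfolding maps entry
  $(i_1,\dots,i_N)$ to row $i_n$, column
  $1 + \sum_{k \ne n}(i_k - 1)\prod_{m<k, m \ne n} I_m$ — remaining
  modes in increasing order, earlier ones varying fastest. This is
  normative (thresholding results depend on it only up to this
  invariance), so the tests pin the index map itself, not just round
  trips. The API is 1-based in the mode index.
* **Thin-QR sign convention.** The Q factor is normalized so the R
  diagonal is nonnegative, making factor updates unique and runs
  bit-reproducible across platforms. Rank-deficient inputs (possible in
  degenerate early iterates) are completed deterministically by the
  Householder construction, with a warning, rather than failing.
* **SVT via full SVD.** Thresholded matrices are core-sized
  ($R \times R^{N-1}$), so an economy SVD is exact and cheap; no
  randomized sketching.
* **Factor-update linear algebra.** When the other factors are
  orthonormal (they are, up to drift, by construction),
  $X_{(i)} Z_{(i)}^\top = \mathrm{unfold}_i(\mathcal{X} \times_{j \ne i}
  U_j^\top)\, C_{(i)}^\top$ and $Z_{(i)} Z_{(i)}^\top = C_{(i)}
  C_{(i)}^\top$, so the solve is $R_i \times R_i$ and the large tensor
  is touched once per mode. If orthonormality drift exceeds $10^{-8}$
  the matrices are formed explicitly; a singular Gram matrix falls back
  to the pseudoinverse with a warning.
* **Initialization** (the completion literature rarely states one):
  unobserved entries zero-filled; factors are seeded standard-normal
  matrices orthonormalized by thin QR; the initial core is the
  projection of the zero-filled data; $\mathcal{V}_i = \mathcal{C}$,
  $Y_i = 0$, $\mu = \mu_0$. Fully seeded, so identical inputs and seed
  give bitwise-identical results.
* **Degenerate inputs.** A zero-norm previous iterate makes the
  relative change $+\infty$ (documented sentinel, not an error);
  all-constant observed data is accepted; a zero-weight mode skips the
  SVT entirely (the prox of a zero multiple of the norm is the
  identity — no SVD round-trip error).
* **Stopping** uses only the relative change of $\mathcal{X}$ between
  sweeps, not primal residuals, with the `max_iter` cap as the second
  criterion.

## The synthetic generator, and what passing tests show

`random_tucker_tensor()` draws a core and factors with i.i.d.
standard-normal entries and multiplies them out, yielding a tensor of
*exactly* the requested Tucker rank (almost surely). Masks are sampled
with an exact observation count, $M = \mathrm{round}((1-\mathrm{mr})
\prod_n I_n)$ positions drawn uniformly without replacement, so the
printed missing rate is met to within one entry — tighter-variance and
more reproducible than independent Bernoulli sampling, which the
benchmark protocol otherwise matches.

These conditions emulate the standard synthetic-completion study:
exact low multilinear rank, homogeneous Gaussian magnitudes, uniform
missingness, correctly specified rank. Real data violate all four:
images and MRI volumes are only *approximately* low-rank (their
singular spectra decay but never vanish), intensities are bounded and
spatially correlated, missingness may be structured, and the best rank
is unknown (the CLI's `--rank` must be chosen by the user; a
`--rank-sweep`-style search over a user grid is the honest alternative
to inventing a selection rule). Passing the synthetic suite therefore
demonstrates correctness of the optimization machinery and
exact-recovery behaviour in the identifiable regime — it does not bound
reconstruction error on natural images, where accuracy is limited by
the rank-truncation error of the data itself, not by the solver.

## Benchmark problem sizes

The packaged study grid uses order-4 tensors $40^4$ at rank
$(5,5,5,5)$ (missing rates 30% and 80%), order-5 tensors $20^5$ at rank
$(5,\dots,5)$ (30% and 70%), a $100^3$ rank-$(10,10,10)$
convergence-speed problem at 80% missingness, and a $20^3$ rank-2
exact-recovery sanity check, with 10 seeded replicates per cell
(`run_benchmark()` exposes `replicates`; per-replicate seeds are
`seed_base + r`, so any cell reproduces independently). Ten replicates
keep a full grid in the minutes range on a single core while the
across-replicate standard error stays well inside the order-of-magnitude
bands these studies are judged by; the acceptance script
(`scripts/acceptance.R`) reruns exactly these cells from scratch.

```{r small-run}
truth <- random_tucker_tensor(c(15, 15, 15), c(2, 2, 2), seed = 1)
mask <- sample_mask(dim(truth), mr = 0.5, seed = 2)
fit <- ctnm_qr(truth, mask, solver_config(rank = c(2, 2, 2)))
glance(fit)
rse(fit$completed, truth)
```

## Known limitations

* Dense arrays only; memory is $O(\prod_n I_n)$ and several transient
  copies are made per sweep.
* No automatic Tucker-rank selection; a misspecified (too small) rank
  biases the completion and (too large) slows convergence and risks
  overfitting sparse observations.
* The CP decomposition appears only as background; tensor-train, tubal,
  and ring formats are out of scope.
* Real-image and MRI accuracy depends on the data's own approximate
  rank; the package's quantitative guarantees are for the synthetic
  regime above.
* The ADMM is nonconvex (orthogonality constraints); convergence is
  monitored empirically (relative-change trace, least-squares factor
  monotonicity, penalty schedule) rather than proved.
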