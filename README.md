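# ctnmqr

Low-rank tensor completion via core-tensor nuclear-norm minimization
with thin-QR factor updates (CTNM-QR).

## The problem

Dense multiway arrays — RGB images (`H x W x 3`), MRI volumes, video and
hyperspectral stacks — routinely arrive with missing entries. Because
natural tensor data concentrates most of its energy in a few singular
values of each mode unfolding, a partially observed tensor `T` can be
recovered by seeking the completion `X` of lowest Tucker rank that
agrees with the observations on the index set Ω. `ctnmqr` is for anyone
who needs a dependable, reproducible dense-tensor completion tool in R:
image and biomedical-imaging analysts with corrupted acquisitions, and
methodologists who want a benchmarked Tucker-based baseline.

## The method

Under the Tucker model `X = C ×₁ U₁ ×₂ … ×_N U_N` with orthonormal-column
factors `Uᵢ ∈ R^{Iᵢ×Rᵢ}`, the tensor nuclear norm of `X` equals that of
the much smaller core `C`, so the completion problem is posed on the
core:

    min_{C, {Uᵢ}, X}  Σᵢ αᵢ ‖C₍ᵢ₎‖★ + λ/2 ‖X − C ×₁ U₁ … ×_N U_N‖²_F
    s.t.  X_Ω = T_Ω,   Uᵢᵀ Uᵢ = I_{Rᵢ}

where `C₍ᵢ₎` is the mode-i unfolding and `‖·‖★` the nuclear norm.
Splitting with tensor-valued auxiliaries `Vᵢ = C` and multipliers `Yᵢ`,
an ADMM loop with penalty `μ` (grown geometrically by `ρ ∈ (1, 1.1]` up
to `μ_max`) iterates:

1. **Auxiliary update** — `Vᵢ ← foldᵢ(SVT_{αᵢ/μ}(unfoldᵢ(C + Yᵢ/μ)))`,
   singular-value soft-thresholding on core-sized matrices only;
2. **Core update** (closed form) —
   `C ← (μ Σᵢ (Vᵢ − Yᵢ/μ) + λ X ×₁ U₁ᵀ … ×_N U_Nᵀ) / (Nμ + λ)`;
3. **Factor updates** (Gauss–Seidel, the method's distinguishing step) —
   the least-squares solution `Ũᵢ = X₍ᵢ₎ Z₍ᵢ₎ᵀ (Z₍ᵢ₎Z₍ᵢ₎ᵀ)⁻¹` of each
   factor subproblem is orthonormalized by a **thin QR decomposition**
   instead of an SVD (the HOOI-style baseline, kept as
   `factor_strategy = "hooi"` for comparison), cutting the per-sweep
   cost to `O(Σᵢ Iᵢ Rᵢ²)`;
4. **Completion update** — `X ← T` on Ω, Tucker reconstruction on Ωᶜ;
5. **Multiplier/penalty update** — `Yᵢ ← Yᵢ + μ(C − Vᵢ)`, `μ ← min(ρμ, μ_max)`.

The loop stops when the relative change
`‖X^{k+1} − X^k‖_F / ‖X^k‖_F` drops to `tol`, or at `max_iter`.

The package also ships the synthetic study harness: exact
low-Tucker-rank generators (standard-normal core and factors), uniform
missing-entry masks at an exact missing rate, the RSE metric
`‖X − T‖_F / ‖T‖_F`, and a reproducible benchmark grid runner — plus
PNG/NIfTI/RDS/JSON readers and writers and a command-line interface.

## Worked example

```r
library(ctnmqr)

truth <- random_tucker_tensor(c(30, 30, 30), rank = c(4, 4, 4), seed = 7)
mask  <- sample_mask(dim(truth), mr = 0.6, seed = 8)   # 60% missing
fit   <- ctnm_qr(truth, mask, solver_config(rank = c(4, 4, 4), seed = 7))
fit
#> CTNM-QR tensor completion fit
#>   tensor     30 x 30 x 30
#>   rank       (4,4,4)
#>   iterations 40 (stop: tolerance)
#>   final relative change 8.897e-06
rse(fit$completed, truth)
#> [1] 3.468e-05
```

Forty ADMM sweeps reach the relative-change tolerance; the recovered
tensor differs from the truth by 0.003% in relative Frobenius error —
exact-recovery territory, as expected for a rank-(4,4,4) tensor with
40% of entries observed. `tidy(fit)` returns the per-iteration trace,
`glance(fit)` a one-row summary, and `autoplot(fit)` the convergence
curve. A benchmark over missing rates:

```r
grid <- tibble::tibble(shape = rep(list(c(30, 30, 30)), 2),
                       rank  = rep(list(c(4, 4, 4)), 2),
                       mr    = c(0.3, 0.7))
run_benchmark(grid, replicates = 3, seed_base = 1)
#> # A tibble: 2 × 8
#>   shape    rank     mr replicates   mean_rse mean_iterations failures ...
#> 1 30x30x30 4x4x4   0.3          3 0.00000635              15        0
#> 2 30x30x30 4x4x4   0.7          3 0.0000556               52        0
```

Accuracy degrades gracefully as the missing rate rises from 30% to 70%.

## Command line

```sh
inst/cli/ctnmqr simulate --shape 50,50,3 --rank 8,8,3 --mr 0.6 \
    --output img.rds --mask-output mask.rds
inst/cli/ctnmqr complete img.rds --mask mask.rds --rank 8,8,3 --output done.rds
inst/cli/ctnmqr metrics done.rds img.rds
inst/cli/ctnmqr benchmark --grid small --replicates 5 --seed 1 --output bench.csv
```

`complete` accepts PNG images (`--preset image` applies the
channel-weighted setting α = (1, 1, 10⁻³), normalized), NIfTI volumes
(header geometry preserved on write), and RDS/JSON containers; masks
come from a file, from NaN entries (`--mask-nan`), or are simulated
(`--mr`, seeded).

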