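# tamsim

`tamsim` is a hybrid discrete–continuum simulator of a vascularized tumor
lesion interacting with the three major tumor-associated macrophage (TAM)
phenotypes: cytotoxic **M1**, growth-promoting **M2**, and
vasculature-stabilizing Tie2-expressing macrophages (**TEM**). It is
aimed at computational oncology / systems-biology users who want to
explore how macrophage population composition shifts tumor growth,
angiogenesis and vascular remodeling — for example, what happens to a
lesion when TEMs are ablated but M2s remain.

## The model in brief

A 2D lesion grows in a regularly spaced (~250 µm) capillary grid.
Tumor tissue advances by Darcy flow,

    v_c = -mu grad(P),        div(v_c) = lambda_p,

with the net proliferation rate per region (proliferating Ω_P, hypoxic
Ω_H, necrotic Ω_N):

    lambda_p = (lambda_M + lambda_M2) sigma - (lambda_A + lambda_M1)   in Ω_P
             =  lambda_M2 sigma        - (lambda_A + lambda_M1)        in Ω_H
             = -G_N                                                    in Ω_N

Oxygen σ and all cytokines are steady-state reaction–diffusion fields,
e.g. the generic cytokine balance

    0 = div(D_C grad C) + λ_prod (1 - C) 1_Ω - λ_circ C 1_vessel - λ_decay C,

solved by red–black successive over-relaxation on a 100×100 lattice
(20 µm/site, the 2×2 mm panel). Monocytes extravasate from perfused
vessels in proportion to the tumor angiogenic factor, migrate
semi-stochastically, and differentiate with probabilities proportional to

    R_M1  ∝ k_M1 C_M1f
    R_M2  ∝ k_M2 (C_M2f + k_T2M2 C_IL10)
    R_TEM ∝ k_T2 C_T2f + k_Ang2 C_Ang2.

M1 agents kill adjacent tissue via nitric oxide; M2 agents secrete a
growth factor that boosts proliferation and transiently lowers the
viable-oxygen threshold; TEMs chemotax up angiopoietin-2 gradients,
sensitize vessel sprouting and remove the natural shrinking tendency
from Eq. `dR = (S_wss+S_p+S_m - S_s (1 - 1_TEM)) R dt` for adjacent
segments. Eight scenarios enable the subsets of {M1, M2, TEM}; disabled
subtypes are drawn but inert, so the monocyte pool is identical across
scenarios. See `vignettes/tamsim-methods.Rmd` for the full account,
including how the source tables' mixed nondimensional conventions are
reconciled.

## Worked example

```r
library(tamsim)
res <- run_case(case_spec(1, seed = 1), default_config())
res$onset_day
#> [1] 6.45
tail(res$metrics[, c("time", "tumor_radius_mm", "vascular_area_actual",
                     "n_M1", "n_M2", "n_TEM", "fraction_TEM_cum")], 2)
#>     time tumor_radius_mm vascular_area_actual n_M1 n_M2 n_TEM fraction_TEM_cum
#> 51 12.75       0.1716316             157332.0   35   48    89        0.5174419
#> 52 13.00       0.1746028             166366.2   35   48    89        0.5174419
```

Monocyte infiltration begins at hypoxia onset (day 6.45, lesion ≈ 175 µm
across); by day 13 this all-subtypes run carries a 0.17 mm lesion in
which 52% of the macrophages that differentiated were TEMs, with about
1.7 × 10⁵ µm² of intratumoral vascular surface. A shell
`inst/cli/tamsim` wraps the same functions
(`simulate | sweep | metrics | fixtures`).

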