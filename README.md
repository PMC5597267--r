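# porfiber

Lumped-pore modelling of preparative cation-exchange chromatography on
hydrogel-grafted fiber beds, for bioprocess engineers developing or scaling
monoclonal-antibody (mAb) capture steps on fiber-based stationary phases.

A packed bed of surface-grafted winged fibers behaves like a bed of porous
particles: convective transport channels between fibers (interstitial
voidage ε_b), and a ligand-bearing hydrogel layer that holds a stagnant
liquid phase (stationary-phase porosity ε_p). `porfiber` implements the
corresponding lumped-pore transport-dispersive column model and — the point
of the exercise — determines **every** model parameter from small-scale
experiments, correlations, or geometry, independent of the chromatographic
cycle itself, so that gradient-elution behavior is predicted a priori.

## The model

Mobile phase (per solute *i*, axial coordinate *z*):

    ∂C_i/∂t = −v ∂C_i/∂z + D_ax ∂²C_i/∂z² − ((1−ε_b)/ε_b)·A·k_eff·(C_i − C_f,i)

Stagnant (hydrogel) phase with local adsorption equilibrium:

    ε_p ∂C_f,i/∂t + (1−ε_p) ∂q_f,i/∂t = A·k_eff·(C_i − C_f,i)

with Danckwerts boundary conditions, and competitive multi-component
Langmuir binding whose parameters depend on the salt (modifier)
concentration c_mod:

    q_f,i = K_eq,i·q_max,i·C_f,i / (1 + Σ_j K_eq,j·C_f,j)
    q_max,i = a1·c_mod + a2        K_eq,i = b1·exp(−b2·c_mod)

Parameter determination:

| parameter | method | function |
|---|---|---|
| ε_T, ε_b, ε_p | inverse SEC plateau voidages + porosity identity ε_p = (ε_T−ε_b)/(1−ε_b) | `fit_isec`, `accessible_fraction`, `porosity_from_voidages` |
| D_ax = α·v | statistical moments of tracer pulses, extra-column corrected | `peak_moments`, `correct_extra_column`, `dax_from_moments`, `fit_dispersivity` |
| k_eff, A | Mackie–Meares D_eff, fiber-geometry k_int = 2·D_eff/r_F, A = 2/r_F, k_eff,A = (1−ε_b)·A·k_eff | `transport_chain`, `lump_keff_A` |
| a1, a2, b1, b2 | batch-adsorption Langmuir regression per salt level, then salt-dependence regression | `fit_langmuir`, `fit_salt_dependence` |
| extra-column dispersion | plug-flow delay + tanks-in-series, moment matched | `fit_system`, `convolve_system` |

The solver (`simulate_column`) semi-discretizes the column by finite
volumes (method of lines, compiled RHS) and integrates with a stiff-capable
adaptive solver; the synthetic-data generators (`gen_batch_dataset`,
`gen_tracer_peak`, `gen_isec_curve`, `gen_broth_elution`) emulate every
experimental input so the whole estimation workflow is testable end to end.

## Worked example

```r
library(porfiber)

bed <- bed_geometry()          # 3 cm x 1 cm fiber bed, eps_T 0.76, eps_b 0.54
transport_table(c(NaCl = 1.99e-9, acetone = 1.14e-9, mAb = 4.00e-11), bed)
#>    solute D_m_m2_s   D_eff_m2_s    k_int_m_s k_eff_A_1_s
#> 1    NaCl 1.99e-09 1.965633e-10 5.241687e-05   6.4298028
#> 2 acetone 1.14e-09 1.126041e-10 3.002776e-05   3.6834046
#> 3     mAb 4.00e-11 3.951020e-12 1.053605e-06   0.1292423
```

The lumped rate coefficient k_eff,A spans nearly two orders of magnitude
from the small salt ion to the 145 kDa antibody — the column behaves as an
equilibrium bed for tracers but is mass-transfer limited for the protein.
Predicting a bind–wash–gradient cycle:

```r
truth <- ground_truth()
sp <- list(species_def("salt", 6.43, is_salt = TRUE),
           species_def("mab", 0.129, isotherm = truth$binding$mab))
prog <- bind_elute_program(bed, load = c(mab = 4), F_ml_min = 3, grad_cv = 7.5)
sim <- simulate_column(bed, sp, prog)
peak_stats(sim$time_s, sim$chrom$mab, t_min = 250)[c("t_max", "fwhm_s")]
#> $t_max
#> [1] 412.7188
#> $fwhm_s
#> [1] 58.15352
sim$balance$closure
#> [1] 1 1
```

The 100 µL antibody pulse binds at 20 mM NaCl, elutes at ~209 mM in the
7.5 CV gradient (peak at 413 s), and the species mass balances close
exactly. The numbered scripts under `analysis/` run the full workflow —
bed characterization, mass-transfer table, isotherm fitting, transport
validation, gradient-elution prediction and sensitivity analysis — and
write their tables under `results/`.

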