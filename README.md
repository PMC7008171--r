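# odfpbpk

Mechanistic absorption modeling for orodispersible films (ODFs) in the
beagle dog, built around risperidone ODF. An ODF dissolves in the mouth
within minutes; the drug then reaches the circulation either directly
across the oral mucosa or — swallowed with saliva — through the gut, where
it faces first-pass extraction. This package answers the formulation
question "which route carries the dose, and does holding the film in the
mouth longer help?" with a fully coupled compartmental model:

- **Oral cavity**: six mucosal sites (buccal, gingival, palate, tongue
  top/bottom, mouth floor) around a stimulated-salivation pool;
  hold-and-swallow transit; film dissolution by z-factor kinetics; each
  epithelium resolved as a free-drug diffusion path with distributed
  vascular drainage.
- **Gut**: stomach, seven small-intestine segments and colon with
  first-order transit, pH-local solubility (Henderson–Hasselbalch, capped),
  luminal z-factor dissolution, precipitation, and absorption at
  `ka = 2*Peff/R`; portal drug reduced by the 51% first-pass fraction.
- **Disposition**: three-compartment mammillary model in micro-constant
  form; terminal half-life by eigenanalysis (`ln 2 / |lambda|_min`).
- **Evaluation**: non-compartmental analysis (Cmax, Tmax, AUC, MRT,
  lambda_z, t1/2, CL, Vd, relative F), fold-error validation
  (`max(obs/sim, sim/obs)`, 2-fold criterion), residence-time sensitivity
  factors (`(max - min)/max`), and a seeded synthetic-data generator for
  crossover plasma studies and dissolution profiles.

The central dissolution law is
`dXd/dt = z (Cs - Xd/V) (Xs/X0)^(2/3) X0`, and the mucosal uptake flux is
`A (D/delta) (fu_p * C_saliva - fu_t * C_tissue)` per site, scaled by two
calibration multipliers (`uptake_scale`, `transfer_scale`) that are solved
against published 2- and 10-minute oral-absorption anchors. See the
methods vignette (`vignettes/odf-absorption-model.Rmd`) for the model, its
assumptions and the design decisions.

## Worked example

```r
library(odfpbpk)

p <- beagle_risperidone_fixture()      # full published input record
terminal_half_life(p$disposition)
#> [1] 2.426877                         # published value: 2.43 h

scales <- calibrate_mucosa_scales(p)   # solve the two mucosal multipliers
scales$uptake_scale; scales$transfer_scale
#> [1] 1.11788
#> [1] 3.610593

sim <- simulate_route(p, "supralingual", hold_time = 2, scales = scales)
sim
#> <pbpk_simulation> supralingual (hold 2 min)
#>   Tmax 0.624 h, Cmax 38.31 ug/L, AUC0-inf 91.87 ug*h/L, F 49.0%
#>   oral fraction 0.070, gut Fa 1.000, mass-balance error 2.1e-13

summarize_exposure(sim)                # published prediction: Tmax 0.53 h,
#> # A tibble: 1 x 5                    # Cmax 38.43 ug/L, AUC 91.56 ug*h/L
#>    tmax  cmax auc_0t auc_inf bioavailability
#>   <dbl> <dbl>  <dbl>   <dbl>           <dbl>
#> 1 0.624  38.3   91.9    91.9            49.0

# the study's own accuracy criterion against the observed dog data
validate_predictions(data.frame(
  metric = c("tmax", "cmax", "auc_inf"),
  observed = c(0.62, 59.38, 101.87),
  simulated = c(0.53, 38.43, 91.56)))
#> # A tibble: 3 x 5
#>   metric  observed simulated fold_error within_criterion
#>   <chr>      <dbl>     <dbl>      <dbl> <lgl>
#> 1 tmax        0.62      0.53       1.17 TRUE
#> 2 cmax       59.38     38.43       1.55 TRUE
#> 3 auc_inf   101.87     91.56       1.11 TRUE

# residence-time sensitivity, 0-10 min
scan <- residence_time_scan(p, scales)
round(scan$factors, 2)
#>            tmax            cmax         auc_inf bioavailability
#>            0.21            0.02            0.00            0.00
```

The interpretation the numbers support: at a 2-minute hold only ~7% of the
dose crosses the oral mucosa; the gut absorbs essentially everything
swallowed; and prolonging the hold to 10 minutes barely moves exposure —
the gastrointestinal tract is the dominant absorption route for this
compound.

Tibble-first API throughout: results have `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` ggplot2 graphics; physiology tables, plasma curves
and dissolution profiles read/write plain CSV; a thin command-line wrapper
lives at `inst/cli/odfpbpk` (subcommands `simulate`, `nca`,
`fit-dissolution`, `fit-disposition`, `calibrate-mouth`, `sensitivity`,
`validate`, `synth`).

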