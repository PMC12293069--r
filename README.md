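# salmosim

Tumor-targeting *Salmonella* are a promising cancer immunotherapy: they
colonize solid tumors, invade cancer cells, kill some of them directly, and
— by delivering antigens and triggering inflammatory cytokines — redirect
cytotoxic T cells against the tumor. Which of these engineerable properties
actually drives efficacy is hard to untangle in vivo. `salmosim` is a
simulator for an eight-compartment ordinary differential equation model of
this therapy, built for researchers who want to explore strain-engineering
and combination-therapy questions in silico before running animal
experiments.

The state vector couples bacterial pharmacokinetics, tumor growth, and
adaptive immunity: blood and intratumoral bacteria ($S_B$, $S_T$),
uninvaded and invaded cancer cells ($T_U$, $T_I$), bacteria-specific,
pan-tumor, and naive T cells ($E_B$, $E_T$, $E_N$), and an inflammatory
cytokine pool ($I_C$). Tumor cells grow logistically toward the carrying
capacity $1/b$ and are killed by saturating T cell cytotoxicity,
e.g.

$$\dot T_U = a T_U\left(1 - b\,(T_U + T_I)\right) - k_2 S_T T_U
  - \frac{s_1 T_U E_T}{h_1 + E_T},$$

while T cell activation requires both target contact and cytokines
($I_C/(g_1+I_C)$ gating). The full system, every parameter with units, and
all numerical choices are documented in
`vignettes/salmonella-therapy-model.Rmd`.

On top of the core integrator (stiff-capable, with closed-form oracles for
limiting cases) the package provides trajectory metrics (peaks, AUCs,
time-to-capacity, invaded fractions, clearance), a declarative scenario
engine covering administration routes, hot/cold immune microenvironments,
dose-by-tumor-size grids and parameter sweeps, an LHS/PRCC global
sensitivity module, and a command-line front end.

## Worked example

Inject 10^6 CFU directly into a cold 10^6-cell tumor and summarize the
invaded-cell dynamics:

```r
library(salmosim)

params <- baseline_parameters()
ic <- baseline_initial_conditions("intratumoral", "cold",
                                  tumor_size = 1e6, dose = 1e6)
traj <- simulate_therapy(params, ic)
summarize_trajectory(traj, "T_I")
#> <summary_metrics> focal variable T_I
#>   peak 2.867e+05 at day 0.295; AUC[0,10] = 3.0677e+05
#>   time to 95% capacity: not reached; cleared: FALSE
#>   max invaded fraction (of initial tumor): 0.287
```

Invasion peaks about seven hours after injection (day 0.295) at roughly
2.9 × 10^5 invaded cells — under 29% of the initial tumor is ever invaded,
so direct bacterial killing cannot be the main therapeutic mechanism.
Comparing the two administration routes:

```r
res <- run_scenario(scenario_catalog()$route_comparison)
subset(res$table, metric %in% c("auc", "peak_value", "tumor_day30"))
#>             arm      metric       value      unit
#>     intravenous  peak_value    101353.1     cells
#>     intravenous         auc    299568.9 cells*day
#>     intravenous tumor_day30 539836540.8     cells
#>    intratumoral  peak_value    286714.4     cells
#>    intratumoral         auc    306772.7 cells*day
#>    intratumoral tumor_day30 128151491.9     cells
```

Both routes deliver nearly the same 10-day invaded-cell exposure
(AUC ≈ 3.0 × 10^5 cells·day), yet the intratumoral tumor is four times
smaller at day 30: the *timing* of invasion, not the cumulative number of
invaded cells, drives efficacy.

The same analyses run from a shell:

```sh
Rscript inst/cli/salmosim.R catalog
Rscript inst/cli/salmosim.R simulate --scenario route_comparison --out results/
Rscript inst/cli/salmosim.R sensitivity --with-bacteria --n 500 --seed 7 --out results/
```

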