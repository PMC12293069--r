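---
title: "An ODE model of Salmonella-based cancer immunotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An ODE model of Salmonella-based cancer immunotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salmosim)
```

## The model

Engineered *Salmonella* attack solid tumors through two coupled routes:
direct cytotoxicity after invading cancer cells, and immune activation —
invaded cells present bacterially delivered antigens and intratumoral
bacteria drive inflammatory cytokine production, both of which recruit
cytotoxic T cells. `salmosim` implements an eight-compartment ordinary
differential equation model of this interplay and the tooling to interrogate
it: a stiff integrator, trajectory metrics, a scenario engine, and a global
sensitivity module.

The state comprises bacteria in the blood ($S_B$, CFU) and extracellular
bacteria in the tumor ($S_T$, CFU); uninvaded and invaded cancer cells
($T_U$, $T_I$, cells); bacterial-antigen-specific and pan-tumor effector
T cells ($E_B$, $E_T$, cells) plus the naive pool ($E_N$, cells); and an
aggregate inflammatory cytokine concentration ($I_C$, ng/mL). The dynamics
are

$$
\begin{aligned}
\dot S_B &= -k_1 S_B, &
\dot S_T &= k_1 S_B - k_2 S_T T_U - d_1 S_T,\\
\dot T_U &= a T_U\!\left(1 - b\,(T_U{+}T_I)\right) - k_2 S_T T_U
            - \frac{s_1 T_U E_T}{h_1 + E_T}, &
\dot T_I &= k_2 S_T T_U - k_3 T_I - \frac{s_1 T_I E_T}{h_1 + E_T}
            - \frac{s_2 T_I E_B}{h_1 + E_B},\\
\dot E_B &= \frac{t_1 E_N T_I}{h_2 + T_I}\frac{I_C}{g_1 + I_C}
            - d_2 E_B T_I - d_3 E_B, &
\dot E_T &= \frac{t_2 E_N (T_U{+}T_I)}{h_3 + T_U + T_I}
            \frac{I_C}{g_1 + I_C} - d_2 E_T (T_U{+}T_I) - d_3 E_T,\\
\dot E_N &= i - \frac{t_1 E_N T_I}{h_2 + T_I}
            - \frac{t_2 E_N (T_U{+}T_I)}{h_3 + T_U + T_I}, &
\dot I_C &= l_1 S_T - l_2 I_C.
\end{aligned}
$$

Key structural assumptions: invaded cells do not proliferate but still count
against the shared logistic carrying capacity $1/b$; T cell killing and
activation saturate (Michaelis–Menten in the effector count and in the
target count, respectively); activation additionally requires cytokines
through the factor $I_C/(g_1+I_C)$, so a cytokine-poor tumor mounts almost
no T cell response; and CFU and cells are treated as commensurate counts
with no conversion factor. There is no spatial structure, no innate-immune
compartments, and no pharmacokinetics of co-administered drugs — checkpoint
blockade is mimicked only by lowering the exhaustion rate $d_3$.

## Parameters and treatment settings

`baseline_parameters()` returns the literature-derived defaults (units in
its help page): $k_1 = 0.5$, $k_2 = 2.97\times10^{-6}$, $k_3 = 3.2$,
$d_1 = 10^{-3}$, $a = 0.43$, $b = 1.02\times10^{-9}$ (capacity
$\approx 9.8\times10^8$ cells), $s_1 = 2.87$, $s_2 = 2.13$, $h_1 = 5000$,
$t_1 = 1.5$, $t_2 = 1.23$, $h_2 = h_3 = 2500$, $d_2 = 3.03\times10^{-10}$,
$d_3 = 0.11$, $i = 90$, $l_2 = 0.5137$, $g_1 = 120$. Two choices deserve
comment:

* **$l_1$ (cytokine production).** The plausible literature range is
  2.88–5.76 ng mL$^{-1}$ cell$^{-1}$ day$^{-1}$; the package defaults to
  2.97, the centre of the threefold production sweep in the scenario
  catalog and the single value consistent with the baseline trajectories
  (the 10-day invaded-cell exposures under the two injection routes match
  their reference values to four digits under it). It is an ordinary,
  overridable parameter.
* **$d_1$** enters the equations as a first-order rate constant on $S_T$
  and is implemented as such (not converted from a half-life).

An optional extra blood-clearance rate `d0` (bacteria leaving the blood
without reaching the tumor) is included as an extrapolation beyond the core
model; it defaults to 0 and does not affect any documented result.

`baseline_initial_conditions()` encodes the treatment settings: an
**intravenous** bolus starts in $S_B$, an **intratumoral** one in $S_T$;
a **cold** tumor starts at $I_C = 10$ ng/mL with the baseline degradation
rate, a **hot** tumor at $I_C = 100$ ng/mL with $l_2 = 0$ (sustained
inflammation), carried as a parameter override that `simulate_therapy()`
applies. Every setting starts with $T_I = E_B = E_T = 0$ and $E_N = 100$
cells; the standard tumor and dose are $10^6$ cells and $10^6$ CFU.

## Numerical choices

The system is stiff — invasion saturates within hours while tumor growth
plays out over weeks — so integration uses an adaptive stiff-capable
solver (`deSolve::lsoda`) at `rel_tol = 1e-8` with per-state absolute
tolerances (1e-6 for counts, 1e-9 for the cytokine). The reporting grid is
0.01 day so that the roughly seven-hour invasion peak of the intratumoral
route is resolved, over a default 30-day horizon. Halving the tolerances
moves every reported state by far less than 0.1% on the baseline scenarios,
and halving the reporting step moves grid-derived metrics by well under
0.5%; the closed forms for the decoupled blood compartment (exponential)
and the isolated tumor (logistic) are matched to within ten times the
relative tolerance.

Stiff solvers produce harmless negative excursions around zero. Their
magnitude scales with the solver's local error, `rel_tol * |y| + abs_tol`,
not with `abs_tol` alone, so the default `"clamp"` policy reports negatives
within that per-state scale as 0 and aborts on anything larger; the
stricter `"reject"` policy aborts beyond `-abs_tol` itself. With the
default tolerances the clamp threshold is still sub-cell-sized for every
compartment.

## Metrics: how verbal endpoints are operationalized

* *"Reached maximal volume"* — first time $T_U + T_I \ge 0.95/b$, linearly
  interpolated between grid points. The logistic asymptote is never
  attained exactly; 0.95 is the package's documented, configurable
  threshold. Under it the untreated cold tumor reaches capacity on day 23.
* *Route-comparison exposure* — area under the $T_I$ curve over days 0–10
  (trapezoidal), the window over which the two injection routes produce
  comparable numbers of invaded cells; configurable and recorded in output.
* *Peaks* — grid maximum refined by a local three-point quadratic, ties
  broken at the earliest time.
* *Clearance* — total burden below one cell with no later regrowth above
  one cell; sub-one counts are biologically extinct. The
  checkpoint-blockade endpoint ($d_3 = 0.001$) regresses the tumor
  monotonically from about day 20 but crosses the one-cell line only near
  day 190, so that comparison is evaluated on a 240-day horizon, long
  enough to decide the asymptotic outcome for both arms.

## The scenario catalog

`scenario_catalog()` encodes the standard in-silico experiments as
declarative specs: arbitrary parameter or initial-condition overrides
(initial conditions use a trailing `0`: `S_B0`, ..., `I_C0`) grouped into
named arms. Choices made where the design was open:

* The `k2_sweep` arms are one hundredth, one, and one hundred times the
  baseline $2.97\times10^{-6}$ — the same multiplicative pattern as every
  other sweep in the catalog — rather than rounded powers of ten; only at
  these values does the slow-invasion arm show its documented behaviour
  (peak of $\approx 4\times10^4$ invaded cells near day 7).
* "No T cell activation" means $t_1 = t_2 = 0$: total absence is the only
  unambiguous reading. Single knockouts (`knockout_EB`, `knockout_ET`)
  zero one activation rate each.
* The exhaustion sweep runs five log-spaced arms from $d_3 = 0.105$ down
  to 0.001 day$^{-1}$; only the endpoints are anchored to reference
  values.
* Every result table reports day-15 and day-30 burden so scenario output
  aligns with the sensitivity analysis (day 15) and the figure horizons
  (day 30).

## Global sensitivity

`run_sensitivity()` draws a Latin hypercube over the 19 model parameters —
log-uniform within an order of magnitude of baseline, $[v/10, 10v]$, except
$a$ and $b$ within a factor of two, $[v/2, 2v]$ — simulates the cold
intravenous setting with or without the $10^6$ CFU bolus, and takes the
total burden $T_U + T_I$ at day 15 as the output. Log-uniform sampling is
chosen because the ranges are multiplicative; a linear-uniform hypercube
concentrates draws in the top decade. Initial conditions are held fixed:
only parameters vary. PRCC follows the standard construction: rank all
columns, regress the focal parameter's ranks and the output's ranks on the
remaining parameters' ranks, and correlate the residuals; significance uses
$t = r\sqrt{(N-2-p)/(1-r^2)}$ with $p$ controlled parameters. Flags are
per-parameter at $\alpha = 0.05$; Holm-adjusted flags are reported as a
labeled extra column. Simulation failures are excluded with a recorded
count and more than 5% failures aborts (with the default tolerances the
full 500-sample design completes with none).

At $n = 500$ the untreated system is dominated by the growth rate $a$
(strongly positive PRCC $\approx 0.8$); under treatment $k_1$ and $s_1$
acquire significant negative coefficients. The day-15 effect of the
cell-invasion rate $k_2$ is genuinely weak: fast invasion shrinks the tumor
early but feeds it later, and the two regimes cross near day 15, so its
PRCC sits near the significance boundary ($\approx -0.1$) and its star
depends on the hypercube draw. The sensitivity runs integrate to day 15 on
a 0.5-day reporting grid at `rel_tol = 1e-6`, which is ample for a terminal
burden that only enters through its rank.

## What the simulations do and do not show

All inputs here are synthetic: the package simulates the stated model at
literature-derived point estimates. The scenario engine reproduces the
model's documented behaviour — route effects, hot/cold contrast,
dose-by-size monotonicity, the invasion-rate trade-off, exhaustion-driven
clearance — but none of that is evidence about real tumors beyond what the
model structure encodes. In particular the model has no spatial
heterogeneity (a major driver of immune escape), aggregates all innate
immunity into one cytokine pool, fixes parameters that are known to be
patient- and strain-variable, and treats invaded cells as a well-mixed
compartment. Parameter sets far outside the documented ranges can make the
system extremely stiff; the integrator will either resolve them or fail
loudly, never silently.

## Problem sizes

The default experiments are desk-scale: a 30-day simulation on the 0.01-day
grid takes a fraction of a second; the full catalog (about 35 arms) runs in
well under a minute; a 500-sample sensitivity pass takes a few seconds.
The package's test suite exercises the same configurations at these sizes.
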