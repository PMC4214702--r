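---
title: "A radial PDE model of IL-35-driven tumor growth, angiogenesis and anti-IL-35 treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A radial PDE model of IL-35-driven tumor growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(il35sim)
```

## The model

`il35sim` simulates the tumor microenvironment of two engineered mouse
plasmacytoma lines — J558-IL-35, transfected to secrete interleukin-35 at a
high rate, and J558-Ctrl, secreting very little — as ten coupled
reaction–diffusion–chemotaxis fields on the radius of a sphere of fixed
radius $R$: tumor cells $c$, M-CSF $q$, MDSCs $M$, IL-35 $\rho$, Tregs $R$,
TGF-$\beta$ $\beta$, activated CD8$^+$ T cells $T$, VEGF $h$, endothelial
cells $e$ and oxygen $w$. The wiring is:

* **Tumor cells** diffuse, proliferate logistically under an oxygen gate,
  die by oxygen-gated necrosis and by apoptosis, and are killed by CD8$^+$
  T cells at rate $\eta c T$.
* **M-CSF** is secreted by tumor cells ($s_q c$) and decays; its
  steady-state balance $q = s_q c / d_q$ also fixes the initial M-CSF
  profile.
* **MDSCs** have a constant tissue source $s_M$, an IL-35-enhanced source
  $\lambda_{M\rho}\,\rho/(K_\rho + \rho)$, an M-CSF-driven polarization
  source $\lambda_{MQ} M_0\, q/(K_q+q)$ from a myeloid precursor pool
  $M_0$, chemotax toward M-CSF, and die at rate $d_M$.
* **IL-35** is produced by tumor cells ($\lambda_{\rho c} c$; the single
  constant that distinguishes the two scenario presets), Tregs and MDSCs,
  and decays.
* **Tregs** are activated through MDSC-derived IL-10
  ($\lambda_{RM} M/(K_M+M)$) and TGF-$\beta$
  ($\lambda_{R\beta}\beta/(K_\beta+\beta)$).
* **TGF-$\beta$** is secreted by tumor cells and Tregs.
* **CD8$^+$ T cells**: the chemoattractant (MCP-1), the activating signal
  (IL-12) and the suppressing signal (IL-10) are all folded into
  MDSC-proportional concentrations $k_{MCP}M$, $k_{12M}M$, $k_{10M}M$,
  so activation is
  $\lambda_{T12}\,\frac{k_{12M}M}{K_{T2}+k_{12M}M}\cdot
  \frac{1}{1+k_{10M}M/K_{T1}}$. With the default thresholds the
  suppression factor dominates above the background MDSC density, so more
  MDSC means net fewer activated CD8$^+$ T cells — the immune-evasion arm
  of the model. The suppression factor is implemented as the named helper
  `il10_suppression()` because it is the easiest term to mis-transcribe.
* **VEGF** is secreted by tumor cells (IL-35-enhanced) and MDSCs
  (M-CSF-enhanced), both modulated by the hypoxia factor
  $G(w) = (w/w^*)e^{1-w/w^*}$, which vanishes at zero oxygen, peaks at the
  mild-hypoxia level $w^*$ and declines toward normoxia. The small
  baseline ratios $\varepsilon_c, \varepsilon_M < 1$ keep a residual
  signal-independent secretion.
* **EC** chemotax toward VEGF and proliferate logistically (capacity
  $e_{\max}$) through the thresholded factor
  $(h-h^*)_+/(K_h+h)$ — no proliferation below the VEGF threshold $h^*$.
* **Oxygen** is delivered by EC at rate $\lambda_w e (w_0 - w)$ and
  consumed by all four cell populations.

Boundary conditions: symmetry at $r=0$; no-flux at $r=R$ for every field
except EC and oxygen, which obey Robin exchanges
$D\,\partial_r u = \gamma\,(u_{\text{healthy}} - u)$ with the healthy-tissue
values $e_{\text{normal}}$, $w_0$ — endothelial cells (and with them
oxygen) enter from the surrounding tissue.

**Oxygen switches.** Proliferation is 0 up to the extreme-hypoxia bound
$w_{hyp}$, ramps linearly to 1 at $w_{normal}$; necrosis is 1 below the
necrotic bound $w_{nec}$, ramps to 0 at $w_{hyp}$. The two ramps share the
$w_{hyp}$ breakpoint, so no oxygen level both proliferates and necroses
maximally. The piecewise-linear corners are the model; an optional C$^1$
cubic smoothing (`smooth` argument) exists purely to help stiff adaptive
steppers and is off by default.

**Initial conditions.** The injected tumor is a centered Gaussian
$c_0(r) = c_{init}\,e^{-(r/r_{init})^2}$. M-CSF starts at the uniform
steady-state ratio $s_q/d_q$ times $c_0$; MDSC at its local steady state
shaped like the tumor (high at the center, negligible at the boundary);
TGF-$\beta$, Treg, IL-35 and VEGF at their quasi-steady local balances
given $c_0$; activated CD8$^+$ T cells at zero; EC and oxygen rising
quadratically from a central fraction (default one half) of the
healthy-tissue value to exactly $e_{\text{normal}}$ and $w_0$ at the
boundary. The proportionality constants all live in the parameter table,
not in code.

## Treatment

The anti-IL-35 drug adds a single term, a mass-action sink
$-\mu_A A(r,t)\rho$ in the IL-35 equation, with
$A(r,t) = \text{level}(t)\cdot e^{-\alpha (R-r)}$: the drug arrives through
the vasculature at the tumor rim and decays toward the center. Protocols:

* *continuous* — level $A_0$ for the whole window;
* *intermittent* — level $2A_0$, one week on, one week off.

Doubling the on-level makes the two schedules deliver identical total dose
whenever the window is a whole number of 14-day cycles; the package
therefore defaults to a 28-day month (configurable), keeping the
equal-dose identity exact rather than approximate. The integrator is
restarted at every switching instant so the adaptive stepper never
straddles a square-wave edge.

## Parameters and scaling

All 78 constants are transcribed once into
`inst/extdata/parameters.csv` — name, dimensional value, unit, the scaling
rule mapping it to dimensionless form, the stored dimensionless value, and
a description — with `inst/extdata/symbol_map.csv` recording which
equation and term each constant enters, so the transcription is auditable
and nothing is hard-coded. The two scenario presets live in
`scenarios.csv` and differ only in $\lambda_{\rho c}$ (a factor 20).

The baselines place the model in the regime the biology describes: cells
share one diffusion coefficient ($8.64\times10^{-7}$ cm²/day, i.e.
$10^{-11}$ cm²/s), cytokines diffuse $10^5$ times faster and turn over in
hours, oxygen has a penetration depth $\sqrt{D_w/k}$ of a few hundred
micrometers so the 0.5 cm sphere develops a hypoxic core whose rim-ward
oxygen gradient drives the outward migration of the tumor peak, MDSC
levels respond to IL-35 within days ($d_M = 0.1$/day), and at carrying
capacity the IL-35-enhanced MDSC source roughly doubles the MDSC pool in
the high-secretion scenario — the magnitude reported for the J558
experiments. Where a constant has an established literature value
(cytokine decay rates, cell motility, oxygen thresholds), the baseline
sits in that range; the remaining couplings were calibrated once so that
the high- vs low-IL-35 comparison reproduces the qualitative experimental
picture, and then frozen.

Nondimensionalization divides each field by a reference magnitude
(carrying capacity for tumor cells, typical concentrations for cytokines,
$w_0$-scale for oxygen), lengths by the domain radius and times by one
day; `nondimensionalize()` / `redimensionalize()` apply the per-parameter
scaling rules from the table and invert to $<10^{-12}$ relative error.
The stored dimensionless column is checked against the declared rules by
the test suite (the transcription audit).

## Numerics

* **Space**: finite volumes on shells of equal width. Weights are exact
  shell volumes, so the weights sum to the sphere volume to rounding and
  no-flux transport conserves mass to machine precision (the conservation
  test measures drift $\sim10^{-16}$). Chemotaxis uses first-order
  upwinding of the donor density at faces — conservation and positivity
  matter more here than formal order. The $r=0$ cell needs no special
  casing: its inner face has zero area.
* **Time**: `deSolve::lsode` with a banded, internally estimated Jacobian.
  Stacking the ten fields per cell keeps the half-bandwidth at 19. The
  kinetics are stiff (TGF-$\beta$ turns over at 499/day, oxygen locally
  at $\sim10^3$/day) so an implicit method is required. Defaults
  `rtol = 1e-6`, `atol = 1e-9` on the scaled fields.
* **Scaling inside the solver**: fields are divided by their reference
  magnitudes so tolerances act uniformly across ten orders of magnitude
  of dimensional scale.
* **Negativity policy**: undershoots are clipped to zero and counted in
  the diagnostics if they stay within the solver's absolute-error budget
  ($\max(10^{-10}, 10\,\mathrm{atol})$ in scaled units); anything larger
  aborts. Reference runs exhibit no undershoot at all.
* **Degenerate inputs**: an identically zero tumor stays zero; a zero
  attractant or zero cell density makes the chemotaxis term vanish
  identically; ties in `peak_location()` resolve to the outermost cell.

Verification: against the closed-form eigenfunction series for no-flux
diffusion on the sphere ($j_0(\mu r/R)$ modes with $\tan\mu = \mu$) the
solver is accurate to $6\times10^{-6}$ max relative error at 200 cells;
halving the grid spacing changes the week-2 tumor burden by under 0.03%.
The reference resolution is 200 cells; scenario comparisons in the test
suite use 60 cells and the sensitivity screen 20 cells, which the
convergence results justify for domain-integrated observables.

## Sensitivity analysis

`sensitivity_design()` screens 29 kinetic constants over half-to-twofold
ranges; the one exception is $\lambda_{\rho c}$, which spans the
control-line value up to three times the high-secretion baseline — the
interval over which the drug's leverage varies most, and the quantity the
study is about. `latin_hypercube()` (backed by the `lhs` package) places
exactly one sample per equal-width stratum per parameter; `run_design()`
simulates a treated/untreated pair per sample and records the efficacy
ratio at the horizon, recording failures rather than dropping them (> 5%
failures aborts); `prcc()` computes partial rank correlations by the
two-residual regression formulation — regress the rank-transformed target
column and output on all remaining rank-transformed columns and correlate
the residuals — with average ranks on ties and p-values from the
$t$-transform on $N - 2 - (k-1)$ degrees of freedom.

The screening defaults ($N = 100$, 14-day horizon, 20 cells) give
PRCC$(\lambda_{\rho c}) \approx -0.6$ with $p < 10^{-8}$: the drug's
relative efficacy improves as the tumor secretes more IL-35, consistent
with the dose study at full resolution. The full-resolution, month-scale
campaign ($N = 500$) is a straightforward `sensitivity_study()` call with
larger `N`, `horizon` and `n_cells`.

## What the dosing study shows

```{r}
dose_study(multipliers = c(1, 2, 3), n_cells = 60)
```

At equal total dose over two months, continuous dosing always ends the
window with a tumor burden at or below the intermittent schedule's (the
IL-35 sink is most valuable when it is never released), and the efficacy
ratio falls monotonically as tumor IL-35 production rises across the three
bundled production rates. Beyond roughly four times the baseline the
saturations $\rho/(K+\rho)$ pin near 1 with or without drug and the
relative efficacy turns back up — the three bundled multipliers (1, 2, 3)
deliberately span the monotone leverage region.

## What the synthetic comparisons do and do not show

The scenario comparison emulates the two-arm mouse experiment: identical
initial conditions, one constant changed. Passing tests show the model
reproduces the *direction and rough magnitude* of the IL-35 effects —
MDSC, VEGF, Treg/CD8 and tumor ratios above 1 at week 2, outward tumor
migration — under the package's calibrated baselines. They do not show
quantitative agreement with any particular animal's time course: real
tumors grow with a delayed MDSC influx, a moving boundary, systemic drug
pharmacokinetics and cytokines (IL-9, IL-10 acting beyond MDSC) that this
model deliberately omits. The domain radius is fixed; tumor "growth"
means densification and outward redistribution inside the sphere, so
tumor-burden ratios are conservative relative to freely growing tumors.

## Known limitations

* No moving tumor boundary, no 2D/3D geometry.
* No systemic pharmacokinetics: the drug's spatial profile is static.
* IL-10, IL-12, IL-2 and MCP-1 are not independent fields; they are
  algebraic functions of the MDSC density.
* The MDSC/IL-10 suppression dominance and the VEGF hypoxia factor shape
  are structural choices; alternatives (e.g. Gaussian hypoxia kernels)
  would change quantitative ratios but not the qualitative orderings the
  tests pin down.
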