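---
title: "Models and methods behind thermoslurry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thermoslurry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoslurry)
```

## The experiment the package models

Anaerobic marine sediment, slurried in mineral medium and sealed in serum
vials, is incubated along a 0--80 °C thermal gradient for up to 100 days.
Pore-water and headspace chemistry (sulphate, H~2~, CH~4~, acetate,
methylamine, ammonium, DIC) is sampled at a handful of days in triplicate;
^14^C radiotracer incubations quantify specific catabolic processes; qPCR
of 16S rRNA genes tracks bacterial and archaeal abundance. Temperature
does not act smoothly on such a system: each metabolism operates inside
one or more temperature "windows of opportunity", and around a narrow
critical temperature (~43 °C in tidal-flat sediment) the dominant
processes, the substrates of sulphate reduction, and the community
composition all switch together.

`thermoslurry` implements both halves of the quantitative workflow: a
forward simulator of the coupled substrate pools with *known* ground
truth, and the analysis chain applied to such data (tracer turnover rates,
sulphate removal rates, Arrhenius/Q~10~ kinetics, Gibbs energies, a CO~2~
mineralization balance, substrate partitioning and critical-temperature
detection, gene-copy-to-cell conversion). Because the simulator's truth is
known, every estimator in the chain is testable end to end.

## The pool model

Eight pools are tracked per temperature, all in µM referenced to slurry
volume (1 cm³ ≡ 1 mL, so 1 µM ≡ 1 nmol cm⁻³ and concentration differences
are directly rates in nmol cm⁻³ d⁻¹): sulphate, H~2~ and CH~4~
(gas-equivalents), acetate, methylamine, ammonium, DIC, and a metal-oxide
pool expressed as electron-accepting capacity. Each process couples a
fixed stoichiometry to a rate law

$$ r(T, t) = r_{\max}\; w(T)\; \prod_{s \in \text{substrates}}
   \frac{c_s}{c_s + K_s}\; \mathbf{1}[t \ge t_{\text{onset}}], $$

where $w(T)$ is the maximum over the process's asymmetric Gaussian
temperature windows (independent left/right spreads, weight ≤ 1, zero
beyond six sigma). Windows are combined by max, not sum, which produces
the observed activity gaps between mesophilic and thermophilic zones of
the same metabolism.

Integration is explicit Euler at `dt = 0.1` day with a per-step
limiting-substrate clamp: if the summed proposed consumption of a pool
exceeds what is present, every process drawing on that pool is scaled
down proportionally, so pools never go negative and stoichiometric ratios
stay exact at depletion. The pool dynamics are slow and smooth at this
step size; the clamp, not a smaller step, is what guarantees positivity.

Organic matter feeds the pools through two source routes, both recorded
in a carbon ledger so that total tracked carbon
(DIC + CH~4~ + 2·acetate + methylamine) minus the ledger is conserved to
machine precision: a mesophilic fermentation source of acetate (its own
temperature window, peaking near 28 °C and fading above ~40 °C as the
fermenter community does) and a thermal-activation source of H~2~ and
acetate rising sigmoidally above ~45 °C, standing for the abiotic release
of fermentable substrate from buried organic matter at elevated
temperature.

### The shipped catalogue and what it is calibrated to

The default catalogue encodes the classic activity zones: acetoclastic
metal-oxide reduction (optimum 25 °C, fading by ~34 °C), acetoclastic
sulphate reduction (optimum 29 °C, up to ~43 °C), hydrogenotrophic
sulphate reduction (optimum 65 °C, ~43--73 °C), methylotrophic
methanogenesis from methylamine (~12--43 °C), acetoclastic methanogenesis
with a small mesophilic window and a late hot window (50--65 °C, onset
day 60), hydrogenotrophic methanogenesis (a weak cold window and a hot
window, onset day 50), and hydrogenotrophic acetogenesis (43--80 °C).
Anaerobic methane oxidation and ammonium oxidation exist but are off by
default. All window positions, maxima and Monod constants are calibration
choices, overridable per process.

The calibration targets are qualitative surfaces, not fitted data: net
sulphate removal spanning ~3--73 °C with a bimodal profile; H~2~ held
near depletion between ~43 and ~67 °C and accumulating above ~67 °C;
methylamine consumed only below ~43 °C; acetate exceeding 1 mM above
50 °C by day 100; complete sulphate removal only in the
H~2~-fuelled zone. Matching the thermal H~2~ supply (1100 µM d⁻¹ at its
plateau) to the post-sulphate consumer capacity (acetogenesis plus
methanogenesis) is what keeps H~2~ down through 43--67 °C; the metal
oxide pool (600 mM electron-pair equivalents) is sized so metal reduction
is never capacity-limited within 100 days.

### What the simulator does not emulate

No pH/carbonate speciation (DIC is one pool), no isotope fractionation,
no community dynamics (windows are static, onsets are fixed lags), no
re-oxidation loops (sulphide is not tracked), and H~2~ in the unamended
scenario is a one-time initial pool (~45 µM) plus the thermal source —
not a continuously equilibrating headspace. Passing tests therefore
demonstrate that the *estimators* behave correctly on data with realistic
structure and noise, not that the simulator is a calibrated digital twin
of any particular sediment.

## Observation models

Concentrations receive multiplicative lognormal noise with unit mean and
CV 0.05 (concentrations cannot go negative); values under a species'
detection limit are reported *at* the limit and flagged, mirroring "<1 µM"
organic-acid and "~120 µM" methylamine reporting. Note the methylamine
limit exceeds the unamended initial pool, so methylamine is always
censored — as in the field data.

Tracer incubations are synthesized per process, temperature and sampling
day, in triplicate at three durations, with product activity fraction
(rate × duration)/pool. Where turnover is fast (acetate turns over in
hours at mesophilic optima) a fixed multi-day incubation would consume
the whole labelled pool and the linear form saturates; durations are
therefore capped at 10/20/30 % of the local turnover time, mirroring the
practice of using pilot "indicator" vials to set incubation times. The
actual duration is recorded per incubation, so the rate estimator needs
no knowledge of the cap.

Cell numbers follow a growth-yield model (cells per nmol of cumulative
catabolic turnover, bacterial yield on the oxidative processes, archaeal
on the methanogenic ones) times a thermal survival factor declining above
15 °C; qPCR observes cells × copies-per-cell (4.19 bacterial, 1.71
archaeal) with lognormal noise.

## The analysis chain

**Tracer rates.** `rate = (product/added) × pool / duration`, the
single-time-point first-order form without back-reaction or fractionation
corrections (the variant used in the cited protocols is not fully
specified; this is the minimal defensible form). Acetate oxidation
measured as ^14^CO~2~ is multiplied by 2 for the two CO~2~ per acetate.
Replicates are averaged within each of the three incubation time points
and the rate is the unweighted mean of time-point means — time points
weigh equally regardless of replicate count — with the sd of time-point
means as dispersion.

**Sulphate removal.** Consecutive concentration differences per
temperature, assigned to the interval midpoint (unbiased for a linear
decline); apparent negative removal is clamped to zero with the raw value
retained, and a standard error is propagated from replicate spread —
essential context for a >20 mM pool where a few percent measurement noise
corresponds to tens of nmol cm⁻³ d⁻¹ of spurious rate.

**Kinetics.** `ln k` is regressed on `1/T` over per-temperature maximum
rates; `Ea = -slope × R` (kJ mol⁻¹). Zero rates cannot be logged and are
excluded (counted, never pseudo-counted). Q~10~ uses
`exp((Ea/R)·ΔT/(T1·T2))` with the 10--20 °C convention (283.15/293.15 K)
by default. The two-regime fit searches candidate breaks exhaustively,
fitting both sides in ln space and minimizing total SSE (ties to the
lower temperature); `improvement` compares against the single-regime SSE.
Because the freely chosen split soaks up variance, null data yield
improvements of ~0.2--0.3 under noise — a decisive kink is >0.9, and the
caller, not the fitter, decides. In the analysis drivers, fits use the
rising limb of each profile excluding rates under 5 % of the maximum;
which span the original fits used is not recorded anywhere, so the span
is an explicit argument.

**Thermodynamics.** `ΔG'r = ΔG°'(T) + RT ln Q` with
`ΔG°'(T) = ΔG°'(T0)·(T/T0) + ΔH°·(1 − T/T0)` (integrated Gibbs--Helmholtz,
constant ΔH°). Activities: solutes mol L⁻¹, gases bar (dissolved
gas-equivalents converted through van't Hoff-corrected Henry constants),
water 1, H⁺ as `10^-(pH-7)` because the bundled ΔG°' values use the pH-7
reference. Activity coefficients are 1 — the method is a
concentration-quotient screening, and ionic-strength correction is out of
scope. The six bundled reactions are element-balanced (checked against a
bundled composition table); their ΔG°'/ΔH° constants are editable CSV
defaults compiled from standard anaerobe-energetics tables, since the
original constants are not reproducible from the study. Zero substrate
activity returns a flagged −∞ sentinel rather than a silently huge
driving force.

**Carbon balance.** Each process rate × a signed CO~2~ factor
reconstructed from stoichiometry (+2 full acetate oxidation to CO~2~ per
acetate for sulphate and metal reduction, +1 acetoclastic methanogenesis,
+0.25 methylotrophic methanogenesis, −1 hydrogenotrophic methanogenesis,
−2 acetogenesis, 0 hydrogenotrophic sulphate reduction); the factor table
is configuration and its completeness is enforced, never defaulted. Net
per cell is the exact signed sum; the summary splits means below/at-above
43 °C. Production shares divide gross positive contributions only. In
the default simulation the above-43 °C mean is *negative* (the hot zone
is net autotrophic once acetate oxidation ceases), which is an honest
property of the model, not of the field system.

**Partition.** Total acetate oxidation (CO~2~ units, halved to acetate
units) caps acetoclastic sulphate reduction at 1:1 stoichiometry; the
remainder of the sulphate removal rate is a *lower bound* on the
hydrogenotrophic (strictly, non-acetate) fraction. Pairing uses
per-temperature maxima by default (`timewise` matches times instead).
Two robustness rules guard the reported ≥50 % threshold temperature:
temperatures whose sulphate-removal maximum is under 2 propagated
standard errors are flagged `below_quantification` and skipped, and the
threshold must hold for 3 consecutive quantifiable grid temperatures.
Without them, clamped noise maxima on the large sulphate pool at
0--10 °C — where true rates are a few nmol cm⁻³ d⁻¹ — can exceed twice
the tiny acetate oxidation there and masquerade as a hydrogenotrophic
signal.

**Breakpoints.** `detect_breakpoint` is the same exhaustive two-segment
least squares in plain coordinates, used to objectify visually identified
critical temperatures in any temperature profile.

**Cells.** Copies divided by the domain divisor (a configuration value:
rrnDB averages drift across versions); sd propagates as sd/divisor with
the divisor treated as exact; archaeal share from mean cells.

## Numerical and design choices

* Temperature conversion `T(K) = T(°C) + 273.15` everywhere; files store
  °C, only kinetics/thermodynamics convert.
* Window response truncates to exactly zero beyond six sigma, so
  processes are identically silent far outside their windows.
* Max-rate ties keep the earliest time; breakpoint ties keep the lowest
  temperature.
* The observation layer draws from a local RNG stream seeded from the
  design, leaving the caller's RNG untouched; identical seeds give
  byte-identical tables.
* Default problem sizes: 81 temperatures × 1000 Euler steps for the
  full-gradient runs, four sampling days, triplicates; Monte-Carlo
  recovery studies use 200 replicates at 9--16 temperatures.
* A straight-line profile yields improvement 0 exactly (zero single-fit
  SSE); noisy null improvements are judged against the >0.99 achieved by
  genuine kinks.

## Known limitations

Tracer rates report the instantaneous rate at incubation start, so they
drift from interval-average rates where pools change quickly within a
sampling interval. Recovered activation energies are *effective* slopes:
the simulator's temperature response is Gaussian, not Arrhenius, so a fit
over a whole rising limb bakes the window shape into Ea. The Gibbs module
screens favourability; it does not resolve the small free-energy
differences that decide competition near thresholds. And the 43 °C
critical temperature of the shipped configuration is a property of the
calibrated catalogue — moving the windows moves it.
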