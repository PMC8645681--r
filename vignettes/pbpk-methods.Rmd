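---
title: "Model and methods: whole-body PBPK simulation of apatinib interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: whole-body PBPK simulation of apatinib interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science inside it: the
model structure and its assumptions, every tunable parameter that matters,
what the virtual-population generator does and does not emulate, the
numerical choices, and the design decisions taken where the problem was
genuinely open.

## The disposition model

Each virtual subject is a perfusion-limited whole-body model: 12 tissues
(adipose, bone, brain, gut, heart, kidney, liver, lung, muscle, skin,
spleen, pancreas) plus arterial and venous blood, with the lung in series
between the venous and arterial pools. Every tissue obeys

$$\frac{dA_t}{dt} = Q_t\left(C_{art} - \frac{C_t\,(B\!:\!P)}{K_{p,t}}\right)V\text{-basis},$$

i.e. venous equilibration at the tissue partition coefficient. The liver
receives hepatic arterial plus portal (gut, spleen, pancreas) inflow and
the absorbed drug stream; the kidney loses filtered drug; amounts are
tracked in mg so a global mass ledger (absorbed, gut-metabolized, fecal,
hepatically metabolized, renally excreted) closes at every reporting time.

Assumptions worth stating plainly: perfusion-limited (no
permeability-limited tissues), well-stirred liver, blood and plasma related
by a constant B/P, no transporters, no enterohepatic recycling, and the
perpetrator influences the victim only through enzyme amounts and apparent
Km — it is itself described by a closed-form one-compartment oral model,
not a full PBPK model.

## Tissue partitioning

Partition coefficients come from the Poulin–Theil tissue-composition
method. Our variant (the method's original form): for non-adipose tissues
the partition term uses $P = 10^{\log P}$ and the tissue unbound fraction
follows the dilution relation $f_{u,t} = 1/(1 + 0.5\,(1-f_u)/f_u)$; for
adipose the vegetable-oil surrogate $\log P_{vo:w} = 1.115\,\log P - 1.35$
is corrected by the neutral fraction at pH 7.4 and tissue binding is
neglected ($f_{u,t}=1$). The single empirical scalar 0.7 multiplies every
tissue. The tissue-composition table is a packaged, editable fixture of
literature-typical fractional water/neutral-lipid/phospholipid contents;
with it, the predicted steady-state volume of distribution for apatinib
evaluates to about 2.1 L/kg (computed by `vss_from_kp()` and checked in the
test suite against the 2.684 L/kg reference within ±25%). Whether a
logD-based adipose correction should be applied is genuinely open; we chose
the documented variant above and isolated it in one function
(`kp_poulin_theil()`).

## Absorption

The gut is nine compartments in series with fasted-state volumes, pH,
radii and transit times in the physiology fixture (gastric emptying
0.35 h, small-intestinal transit 3.0 h over six segments, caecum 4.5 h,
colon 13.5 h). Solid and dissolved drug transit as parallel first-order
chains; the last segment empties to feces.

The tablet's in vitro dissolution profile is not public, so dissolution is
a mechanistic surrogate: a Noyes–Whitney surface law
$r = k_d M_s^{2/3}(1 - C/S(\mathrm{pH}))$ with pH-dependent solubility
$S = \min(S_0 / f_{neutral}(\mathrm{pH}),\ S_{max})$ for the dibasic base.
Supersaturation created by transit (acidic stomach to near-neutral gut) is
left in solution — precipitation kinetics are out of scope; the cap
$S_{max}$ (1 mg/mL) bounds how much the acidic stomach can dissolve.
Users with a measured profile can load it (`load_dissolution_profile()`)
and calibrate $k_d$ to it in closed form
(`fit_dissolution_coefficient()`).

Uptake from each segment uses $k_a = 2\,P_{eff}/R$. $P_{eff}$ comes from
the measured Caco-2 permeability through a single-point linear anchor
(factor 11.7474) chosen so the packaged pair (6.81e-6 cm/s → 0.80e-4 cm/s)
is reproduced exactly; the multi-point regression behind commercial tools
is not disclosed, and a transparent one-point anchor is preferable to a
guessed curve. Colonic and caecal permeability scalars are small
(0.02/0.05), reflecting poor distal absorption of this low-permeability
base.

**Calibration of $S_0$ and $k_d$.** These two constants are the declared
biopharmaceutic calibration surface. They were fitted once against the
published predicted single-dose exposures at 750 and 250 mg
(AUC and Cmax), by a coarse grid search followed by local refinement, and
then frozen in `apatinib.yaml` ($S_0 = 0.18$ mg/mL, $k_d = 1.2$ on a
mg$^{1/3}$ basis). In this regime absorption is solubility/surface
limited: the dose-normalized absorbed fraction falls as the dose triples,
which is what makes the 750/250 mg AUC ratio sub-proportional (< 3). A
pure surface law bounds that ratio near 2.1; stronger saturation pushes it
toward 1. The packaged calibration yields ≈ 1.6, inside the published
acceptance band for both AUCs individually.

## Metabolism and excretion

In vitro Vmax/Km for CYP3A4, CYP3A5 and CYP2D6 scale to whole-liver rates
by MPPGL (42 mg/g) × liver weight (1650 g) × 60 × MW. The driving
concentration is the unbound liver water concentration
$C_u = C_{liver} f_u / K_{p,liver}$, used consistently everywhere. The
apparent in vitro Km is corrected for nonspecific microsomal binding,
$K_{m,u} = K_m \times f_{u,mic}$ with $f_{u,mic} = 0.45$ — a standard
IVIVE step, plausible for a log P 3.14 base at a few mg/mL incubation
protein, and part of the declared calibration surface: without it the
whole-body clearance is too low to reproduce the published
concentration–time shape. No intersystem (ISEF-type) scalar is applied to
Vmax. Renal elimination is filtration only, $CL_r = f_u \cdot GFR$, which
for apatinib is a few percent of total clearance.

Enterocyte CYP3A4 first-pass extraction is on by default: the absorbed
flux is reduced by $CL_{gut}/(CL_{gut}+Q_{villi})$ with a modest packaged
intrinsic clearance (0.9 L/h against 18 L/h mucosal flow), so the healthy
gut availability is ~0.95 but induction can widen first-pass loss.

## Interactions

Perpetrators are packaged fixtures (one YAML per drug) holding a
one-compartment oral PK model (ka, V/F, CL/F, fu), the trial regimen, and
interaction constants. None of these constants are printed in the source
study; they are literature-typical values and form the declared
calibration surface for the interaction panel. Mechanism assignment:
itraconazole, fluvoxamine and quinidine competitive; erythromycin,
verapamil and paroxetine mechanism-based inactivators; rifampin,
carbamazepine, efavirenz and phenytoin inducers (rifampin also weakly
competitive). Unbound plasma concentration drives liver and gut
interactions alike — a deliberate simplification that avoids inventing an
enterocyte exposure model. The itraconazole model ignores its inhibitory
metabolite. Enzyme turnover uses $k_{deg}$ = 0.0193 h⁻¹ for hepatic CYP3A,
0.0099 h⁻¹ for CYP2D6 and 0.030 h⁻¹ for gut CYP3A4, all configurable in
the physiology fixture.

## Virtual populations

The healthy Chinese adult mean physiology is one editable YAML fixture
(61.6 kg, cardiac output 312 L/h, GFR 105 mL/min, organ volumes and flow
fractions summing exactly to cardiac output). Between-subject variability
is log-normal with mean-preserving parameterization, seeded and
reproducible per (seed, subject index): CV 30% on clearance-related
parameters (MPPGL, enzyme abundances), 20% on volumes, flows, cardiac
output, liver size and GFR — the source study reports no variability
model, so these are package defaults, stated here and overridable in
`population_spec()`. After sampling, flows are renormalized to cardiac
output and body weight rescales with total sampled volume.

Disease stages apply packaged multiplier sets (Child–Pugh A/B/C: shrinking
liver, falling CYP3A4/2D6 abundance, falling albumin — which raises fu
through $f_u' = 1/(1+a(1-f_u)/f_u)$ — reduced hematocrit, hepatic flow and
GFR; moderate/severe renal impairment: GFR to ~43 and ~19 mL/min with a
mild secondary CYP3A4 reduction and albumin fall). The generator emulates
parameter-level physiological variability and disease shifts only; it does
not emulate age/sex covariance structure, genotype-resolved CYP3A5/2D6
phenotypes, portal-systemic shunting, ascites, or correlated organ
changes, so agreement of the simulated ratios with published values shows
consistency of the mechanistic core under these stylized populations, not
validation against real patient dispersion.

## Numerical choices

- Stiff integration (`deSolve::lsoda`), rtol 1e-6, atol 1e-9 mg; halving
  the tolerances moves AUC by far less than 0.1% (tested).
- The derivative is implemented twice: a compiled C function (default) and
  a pure-R reference; a test pins their trajectories together. The C core
  keeps a full 10×10-subject scenario suite in the minutes range on one
  CPU.
- Reporting grid 0.1 h; exposure summaries in the trial engine use 0.25 h,
  which changes AUC/Cmax by well under 1%.
- Oral doses are instantaneous stomach-solid additions; a dose scheduled at
  the integration start is placed directly in the initial state so the
  first reporting row already carries it.
- When a perpetrator run-in precedes the victim dose, only the
  enzyme-turnover subsystem is integrated over the run-in (every victim
  state is exactly zero until the dose), then the full system starts at the
  victim dose — exact and much faster.
- Gut states are clamped at zero inside the derivative; the surface law
  $M^{2/3}$ vanishes smoothly at zero solid.
- Single-dose observation window 96 h; AUC is AUC0–96 by linear trapezoid
  with no extrapolated tail (which AUC the published tables report is not
  stated; the truncation error at these half-lives is small and identical
  across paired arms).

## Open questions, decided

- **Salt or free-base dose**: doses are treated as labelled tablet
  strength with `salt_factor = 1` (free-base mass), overridable in the
  compound file.
- **Ratio convention**: exposure ratios are ratios of arithmetic means
  across all subjects; per-subject ratios are also emitted for dispersion
  since the arms are paired (same virtual subjects with and without
  perpetrator — mirroring the crossover designs and cancelling
  between-subject noise).
- **Trial sizes**: the acceptance script and the acceptance tests run the
  full 10 trials × 10 subjects design; unit and property tests use 2–6
  subjects, which is ample for paired ratios.

## Known limitations

Fixed mean gut geometry across populations; no fed-state physiology; no
precipitation or bile-micelle solubilization; perpetrator PK is not
dynamic PBPK (no perpetrator autoinduction, no inhibitory metabolites);
apatinib acting as a perpetrator on other substrates is out of scope; and
all perpetrator/physiology constants not printed in the source study are
literature-typical fixtures, so the interaction panel should be read as a
mechanistically constrained reconstruction, with every such constant
exposed in one editable file per drug.
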