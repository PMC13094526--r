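---
title: "Methods: decay-chain kinetics, PBPK modelling and nanoshell dosimetry in radnc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decay-chain kinetics, PBPK modelling and nanoshell dosimetry in radnc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radnc)
```

radnc models the quantitative life cycle of a radium-223 labeled,
ultrasmall gold-nanocluster radiopharmaceutical: the physics of the decay
chain it carries, the blood and whole-body kinetics of the carrier, and the
fate of the emitted energy around the nanoparticle. This vignette explains
each model, its assumptions and tunable parameters, the numerical choices,
and what the synthetic-data generators do and do not emulate.

## The Ra-223 decay chain

Ra-223 (half-life 11.4 d) decays through a short-lived series
(Rn-219, Po-215, Pb-211, Bi-211, Tl-207) to stable Pb-207, releasing four
alpha particles and two beta particles per parent decay. The sub-percent
Bi-211 beta branch is folded into the main path, so the chain is strictly
linear. `bateman_atoms()` evaluates the closed-form Bateman solution

$$N_i(t) = \sum_{j \le i} N_j(0) \Big(\prod_{k=j}^{i-1}\lambda_k\Big)
  \sum_{k=j}^{i} \frac{e^{-\lambda_k t}}
  {\prod_{l \ne k} (\lambda_l - \lambda_k)}$$

with $\lambda = \ln 2 / t_{1/2}$ and $\lambda = 0$ for the stable terminus.
The closed form is singular for equal decay constants; decay-constant pairs
closer than 1e-9 relative are perturbed by 1e-6 relative (with a warning) or,
on request, rejected. Because all daughters are much shorter-lived than the
parent, daughter activities converge to the parent activity (secular
equilibrium) within about ten Pb-211 half-lives; the test suite checks this
limit, atom conservation, and agreement with an independent stiff ODE
integration of the same rate equations.

Daughter half-lives, main-branch alpha energies and mean beta energies are
not quantities this package estimates; they are shipped as a versioned data
file (`chain-ra223.json`) assembled from standard nuclear-data compilations,
with the parent half-life set to the clinical product label value (11.4 d).
Recoil energies are not stored but computed at load time from two-body
kinematics, $E_{rec} = E_\alpha \, m_\alpha / m_{daughter}$ (mass numbers),
giving 104-140 keV across the chain - inside the 100-200 keV window that
makes chelator retention of Ra-223 daughters impossible and motivates
encapsulating the chain in a dense carrier.

## Two-compartment blood pharmacokinetics

Blood concentration after an intravenous bolus is modelled as
$C(t) = A e^{-\alpha t} + B e^{-\beta t}$ with $\alpha > \beta$, the standard
two-compartment disposition curve; $t_{1/2\alpha} = \ln 2/\alpha$ is the
distribution half-life and $t_{1/2\beta} = \ln 2/\beta$ the elimination
half-life. `fit_two_compartment()` uses:

* **Curve-stripping initialisation**: a log-linear fit of the last four
  points gives $(B, \beta)$; the stripped residual head gives $(A, \alpha)$.
  This is deterministic and standard, and makes the optimiser start inside
  the right basin.
* **Relative-error weighting** (1/y² weights) by default, because %ID/g
  series span two decades between 1 and 240 min; `weighting = "none"`
  switches to ordinary least squares. On noiseless model-generated data the
  optimum is the generating parameter set under any weighting.
* **Bounds**: rates in (1e-6, 10) per minute, optimised on the log scale;
  amplitudes positive by construction.
* **Labeling**: phases are relabeled after the fit so $\alpha \ge \beta$;
  if the fitted fast-phase amplitude is negligible (monoexponential data),
  the single real phase is reported as the distribution phase with B pinned
  at zero.

Exposure metrics follow the closed forms
$AUC_{0-\infty} = A/\alpha + B/\beta$ and $C_{max} = A + B$ for fits, and
trapezoidal AUC / observed maximum for discrete series.

## The eight-compartment PBPK model

The whole-body model has a single well-mixed blood pool and seven organs
(heart, liver, spleen, lung, kidney, tumor, rest), each split into a
vascular and a tissue sub-compartment. All organs sit in parallel off the
blood pool; there is no separate arterial/venous split and the lung is not
placed in series, a deliberate simplification consistent with treating blood
as one compartment. Exchange is membrane-limited - ultrasmall nanoclusters
are not freely partitioning solutes - with, for organ $i$ (amounts $A$ in
%ID, concentrations amount/volume):

$$\frac{dA_{vas,i}}{dt} = Q_i (C_{blood} - C_{vas,i})
  - PA_i \left(C_{vas,i} - C_{tis,i}/K_i\right)$$
$$\frac{dA_{tis,i}}{dt} = PA_i \left(C_{vas,i} - C_{tis,i}/K_i\right)
  - k_{seq,i} A_{tis,i}$$

Sequestered material ($k_{seq}$, representing reticuloendothelial trapping
in liver/spleen and receptor-mediated retention in tumor) accumulates in an
irreversible bound pool inside the tissue. Renal clearance acts on blood
concentration ($CL \cdot C_{blood}$) and routes to a cumulative urine sink;
there is no enterohepatic recirculation. Receptor targeting is modelled as a
linear multiplier on tumor PA and tumor sequestration
(`apply_tumor_enhancement()`), not as saturable binding - no receptor
density or affinity is available to parameterise saturation.

**Parameters and defaults.** The reference physiology is a 20 g
tumor-bearing mouse (organ volumes, flows, vascular fractions from standard
rodent compendia, shipped as `physiology-mouse20g.json`); volumes and flows
scale linearly with body weight. The default transport parameters
(`transport-default.json`) are order-of-magnitude values for an ultrasmall
renally cleared nanocluster: organ PA of 0.002-0.05 mL/min (far below
plasma flows, i.e. strongly membrane-limited), partition coefficients of
0.5-5, sequestration of 0.001-0.002 per minute in liver, spleen and tumor,
renal clearance 0.25 mL/min, tumor enhancement 3. They were chosen once so
that the forward simulation has the qualitative shape expected of this
probe class - renal-dominant elimination (about 96 %ID in urine at 24 h),
sustained tumor retention near 2 %ID/g, blood elimination half-life of
roughly an hour - and so that the fitting problem below is structurally
identifiable. They are generator defaults for synthetic studies, not fitted
claims about any measured probe.

**Numerics.** The stiff-capable `lsoda` integrator is used with rtol 1e-8
and atol 1e-10 %ID; the bolus is always applied at t = 0 regardless of the
requested output grid. Mass balance (all compartments plus urine equal the
dose) holds to better than 1e-6 %ID over 24 h across random parameter
draws. In the one-compartment limit (PA = 0, vanishing vascular fractions)
the blood curve matches $e^{-CL\,t/V_{blood}}$ to 1e-6 relative; with PA = 0
at default vascular fractions the blood+vascular system is linear and is
checked against an independent eigen-decomposition solution.

**Fitting and validation.** `fit_transport_params()` performs bounded
least squares on log-transformed parameters (default set: renal CL, liver,
kidney and tumor PA, tumor sequestration) against log-scale residuals over
all observed tissue series. A single Levenberg-Marquardt run can stop
prematurely in this landscape's curved valleys, so the optimiser is
restarted (trust region reset) until the deviance stops improving; on
noiseless self-generated data this recovers the generating parameters to
well below 1%. Parameters tied to organs absent from the data are flagged
non-identifiable rather than silently estimated. Model validation follows
the conventional fold-error criterion: predicted/observed exposure metrics
(AUC, Cmax) within 0.5-2.0, bounds inclusive.

**Virtual populations.** `population_simulate()` draws body weights
uniformly over the cohort range (default 15-25 g), scales the physiology
proportionally, jitters every transport parameter lognormally at the stated
interindividual CV, and reports per-tissue median and 2.5/97.5 percentile
curves (the 95% prediction interval). With 500 mice and CV 0.2 applied to
every transport parameter, the per-time median carries a Monte-Carlo
standard error of a few percent of its value, so median curves reproduce
across seeds to within roughly 10% on the measurable part of the curve and
tighten as the cohort grows.

## Nanoshell dosimetry

`run_experiment()` estimates where the chain's emitted energy ends up when
the source sits inside a gold (or water, as control) shell in tissue. The
geometry is a 1 nm spherical source at the center of a water phantom
(sphere of radius equal to the cubic phantom's half width, default 100 µm),
wrapped in a concentric shell. Per parent decay the sampler emits the four
main-branch alphas, their four kinematic recoil nuclei (anti-parallel to
the alphas, sharing their emission point), and the two betas at mean
spectral energy; positions are uniform in the source sphere and directions
isotropic.

Transport is straight-line continuous slowing down (CSDA): each particle
consumes residual range sequentially through source, shell and water, with
ranges given by power-law fits $R(E) = aE^p$ per particle kind and material
(`stopping-model.json`, calibrated against published alpha, heavy-ion and
electron range tables; anchors and residuals are recorded in the file).
There is no scattering, straggling, delta-ray or photon transport: the
headline quantities - bulk absorbed fractions and mean alpha range - are
CSDA-dominated, and the cost of this fidelity cut is quantified by the
factor-of-2 acceptance band against full condensed-history reference
values. Two consequences are worth noting. First, recoil transport is what
makes nm-scale shell absorption non-negligible: a 10 nm gold layer removes
well under a percent of each alpha's energy but a large fraction of each
~100 keV recoil's. Second, with fixed main-branch energies and no
straggling, alpha stopping radii are nearly deterministic; the Monte-Carlo
spread lives almost entirely in emission position and direction.

The source sphere is treated as gold-like when the shell is gold and
water-like otherwise; its self-absorption (a few keV per decay) is tallied
separately. The energy denominator for the shell fraction counts alpha +
recoil + beta energy; photons (~0.3 MeV per chain decay in the compilation
values shipped) are excluded by default because their interaction
probability in nm-µm gold is negligible, and can be added to the
denominator with `include_gamma_in_total = TRUE`. Radial water deposits are
histogrammed in 0.5 µm bins; energy conservation (source + shell + water +
escaped = emitted) holds to machine precision by construction, and only
betas - whose ranges exceed the phantom - escape. `alpha_range_summary()`
reports the mean and maximum alpha stopping radius; the mean is this
package's interpretation of the distance within which a high deposition
density is maintained.

**Problem sizes.** The headline shell fractions are computed at 1e5 decays
(1e6 transported particles); the relative standard error of the shell
fraction at that size is far below 2%. Thickness sweeps across the nine
shell thicknesses from 2 nm to 10 µm use 1e4 decays each, which resolves
the monotone thickness dependence and the gold-versus-water ordering
cleanly.

## Cluster energetics bookkeeping

The doping energetics of the cluster are pure arithmetic over supplied
total energies: formation energy
$\Delta E = E_{defect} - E_{perfect} + E_{removed} - E_{added}$ (negative
means doping is favorable), binding energy
$E_b = E_{frame} + E_{atom} - E_{doped}$ (larger means more stable), and
the HOMO-LUMO gap $E_{gap} = E_{LUMO} - E_{HOMO}$. The relative-energy
convention is the same linear combination as the formation energy with the
atomic reference energies taken from elemental ground-state structures;
`relative_energy()` exists as a named variant so both conventions have a
tested home, and their algebraic identity is noted in its documentation.
Because the two formulas are identical as linear combinations, they can
only yield different numbers through different reference-energy inputs;
the package evaluates both as written and leaves the choice of references
to the caller. All three operations are exact linear combinations,
reproducible to machine precision, with eV in and eV out.

## Synthetic data

The generators exist so every analysis stage is testable without external
data. `make_blood_dataset()` samples the twelve-point tail-vein schedule
(1-240 min); `make_biodistribution_dataset()` forward-simulates the PBPK
model and samples it at the imaging snapshot times (0.5, 1, 2, 3.5 h) plus
24 h; `make_cohort()` draws virtual mice. Measurement noise is
multiplicative lognormal - concentrations are positive and span decades -
with $\sigma = \sqrt{\ln(1 + cv^2)}$ so the empirical coefficient of
variation equals the nominal `cv` exactly; the default CV of 10% is a
declared assumption, not a measured value. Every dataset carries its
generating truth as an attribute, used only for scoring recovery.

What the generators deliberately do not emulate: inter-animal variability
in the blood datasets (one curve per dataset), detector dead-time or decay
correction of counts, PET partial-volume effects, and any tumor-growth
dynamics. Passing recovery tests on these synthetics therefore demonstrates
correctness of the estimators under the stated noise model, not robustness
to every artefact of real gamma-counter or PET data.

## Known limitations

* PBPK equations reconstruct the stated compartment structure; organ-level
  agreement with any particular measured dataset is a matter of fitting,
  not of the defaults.
* CSDA dosimetry underestimates lateral spread and straggling; sub-percent
  absorbed fractions carry a factor-of-2 systematic band relative to
  condensed-history transport.
* The decay chain is linear; the <1% Bi-211 branch and all photon physics
  are out of scope.
* Tumor targeting is linear in the enhancement factor; saturable binding is
  not modelled.
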