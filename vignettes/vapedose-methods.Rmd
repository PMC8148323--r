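---
title: "Modeling first- and secondhand THC vaping exposure with vapedose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling first- and secondhand THC vaping exposure with vapedose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vapedose)
```

## The problem

When cannabis e-liquid is vaped indoors, the vapor the user exhales becomes
a secondary emission source: a bystander in the same room is exposed by
inhalation and through the skin. `vapedose` is a desk-scale, reduced-order
simulation of that exposure chain for tetrahydrocannabinol (THC), from the
puff entering the user's mouth to the microgram doses a bystander receives:

1. **Puff topography** — transient flow waveforms for three puff styles:
   short (2.43 s), long (5.0 s) and post puff (1.34 s, high flow, forceful
   2.5 s exhalation), plus a sinusoidal 1.8 s exhalation and a periodic
   nasal breathing cycle for the bystander.
2. **Airway wall uptake** — a one-dimensional transient diffusion model of
   the airway wall as layered media (air–mucus–epithelium–sub-epithelium
   over a blood sink), with a double-film partition boundary condition at
   the air–mucus interface.
3. **Airway transport** — 1-D advection–dispersion of the vapor through a
   segmented conduit (mouth to bronchial generation 4), coupled to the
   wall model in every segment, producing the four-way mass budget:
   absorbed / exhaled / remaining in tract / transported to the lung.
4. **Room dispersion** — a ventilated-box model (well-mixed or two-zone)
   of the 3 × 3 × 3 m displacement-ventilated room with the two occupants
   1 m apart, giving the bystander's inhaled dose.
5. **Dermal uptake** — the same layered-diffusion machinery parameterized
   as skin (surface lipid / stratum corneum / viable epidermis) under a
   gas-side deposition velocity, for the face-only short-range scenario.
6. **Dose chain** — exact accounting from e-liquid assumptions
   (0.5 g oil, 80% THC, 100 puffs per fill) through the budget fractions
   to per-puff, per-session and bystander doses.

## The wall-uptake model and its numerics

Within each layer the concentration obeys transient diffusion,
$\partial C_i/\partial t = D_i\, \partial^2 C_i/\partial x^2$. At the
air–mucus interface two mass-transfer films meet: a gas-side film with
coefficient $k_g$ and a liquid-side film, with flux continuity and
partition equilibrium $C_\text{mucus} = K\, C_\text{air,wall}$ holding at
the interface. The base of the stack is a perfect sink (blood perfusion;
no systemic pharmacokinetics are modeled).

Numerically we transform to the partition-normalized potential
$\phi = C / K_\text{cum}$ (the cumulative partition coefficient relative
to air), which is continuous across layer interfaces. In $\phi$ the system
is a heat-equation analogue with capacity $K_\text{cum}$ and conductivity
$D\,K_\text{cum}$; we discretize with finite volumes (harmonic-mean
interface conductances) and integrate with backward Euler, which is
unconditionally stable and makes the discrete uptake ledger close to
machine precision. Two closed forms anchor the solver in the test suite:
the early-time semi-infinite flux $K C \sqrt{D/(\pi t)}$ (matched within
2%) and the steady series-resistance flux
$C / (1/k_g + \sum_i L_i / (D_i K_{\text{cum},i}))$ (matched within 0.5%).

The same solver, parameterized with skin layers and the deposition
velocity as the gas-side coefficient, is the dermal model.

## Chemical properties

The THC and nicotine property sets are declared modeling assumptions, all
overridable through the scenario configuration:

* Gas diffusivities come from the Fuller–Schettler–Giddings correlation
  (THC: 4.0 × 10⁻⁶ m²/s at 298 K).
* Both species are configured as high-solubility vapors (large mucus:air
  partition coefficients, 5 × 10⁴ for THC, 10⁵ for nicotine), which makes
  airway uptake gas-film-limited — the regime in which absorbed fractions
  of tens of percent per puff arise.
* THC, the larger molecule, gets lower condensed-phase diffusivities than
  nicotine in every layer; this is what leaves more THC than nicotine
  residing un-absorbed in the tract.

## Airway transport choices

The conduit replaces a CT-derived 3-D geometry: oral cavity, oropharynx
and larynx are flattened channels (the mouth is drawn during puffing, so
the wetted perimeter is large and the hydraulic diameter small), followed
by symmetric-morphometry trachea and pooled bronchial generations 1–4.
The default dead space is ≈ 95 mL. Turbulent and secondary-flow mixing is
folded into an axial dispersion coefficient
$D_\text{disp} = \alpha\,|u|\,d_h$ with $\alpha = 2$ by default; because
it scales with velocity, the high-flow post puff drives more vapor past
the distal boundary (toward the lung) than the short puff, while its short
duration leaves less time for wall absorption — the two qualitative
orderings the transport model must reproduce. The gas-side film
coefficient per segment uses a laminar Sherwood number (Sh = 3.66) on the
hydraulic diameter unless overridden.

Mass crossing the distal boundary accumulates in a well-mixed distal
reservoir (default 300 mL); during exhalation the reservoir returns its
contents to the lumen and the mouth outflow is tallied as exhaled mass.
Desorption of absorbed mass back into the lumen is disabled by default
(switchable). The published CFD budget fractions for this scenario family
(84.1 / 85.0 / 64.4% absorbed for short/long/post puffs, etc.) embed
jet-impingement and 3-D geometry effects that a 1-D model cannot localize;
they ship as `reference_budgets()` fixtures for the dose-chain accounting
and are **not** solver targets. The solver's own guarantees are the
property suite: mass closure within 0.5%, exact zero uptake for an
insoluble tracer, linearity in the inlet concentration, budget closure to
100 ± 0.1 pp, and < 0.5 pp budget shift under 2× grid/step refinement
(which fixes the default resolution at 10 cells per segment and
dt = 5 ms).

## Room model and the near-field calibration

The room is a ventilated box: volume 27 m³, outdoor-air flow 0.018 m³/s.
(Scenario descriptions of this room sometimes also quote 0.6 air changes
per hour, which is inconsistent with that flow — 0.018 m³/s implies
2.4 h⁻¹; `nominal_ach()` computes from the flow and warns on such
discrepancies rather than guessing.) In two-zone mode the bystander's
breathing zone is a small near-field volume (default 5 L around the face);
a `direct_transfer_fraction` of the exhaled mass is delivered straight
into it — the reduced-order stand-in for the exhaled jet that reaches the
bystander's face in about two seconds. Under displacement ventilation the
breathing zone is fed by clean supply air from below while vapor
accumulates in the stratified upper zone, so the near field flushes
one-way into the far field (default 1 L/s); with zero direct transfer
(soft exhalation) the bystander dose is exactly zero, reproducing the
finding that gentle exhalation makes secondhand exposure negligible.

The two free near-field parameters cannot be derived at this level of
reduction, so they are calibrated once, by the shipped
`scripts/calibrate_near_field.R`, against the reference secondhand
fractions of the post-puff worst case: the bystander inhales 5.9% and
dermally absorbs 2.6% of the exhaled mass over the 12 s window with three
nasal breaths (6 L/min, 4 s period). The calibration is two nested 1-D
root finds (both response curves are monotone) and lands at
`direct_transfer_fraction` ≈ 0.899 and a deposition velocity of
≈ 1.45 × 10⁻³ m/s — both physically plausible for a face-on jet. These
are frozen as package defaults and clearly labeled as calibrated: the
5.9% / 2.6% figures are reproduced by construction, not predicted.

## The dose chain and its rounding convention

The chain itself is exact arithmetic: a 0.5 g fill at 80% THC over 100
puffs gives 4 mg inhaled per puff; the post-puff budget (64.4% absorbed,
3.2% exhaled, 32.4% to lung/remaining) then yields 2.576 mg absorbed,
1.296 mg to lung or remaining and 0.128 mg exhaled per puff, and the
secondhand fractions of exhaled vapor (5.9% inhaled, 2.6% dermal) give
overall bystander fractions of 0.1888% and 0.0832% of the inhaled dose.
`rounding = "paper_sigfigs"` reproduces the printed-table convention:
masses to two significant figures except the exhaled mass to one
(0.128 → 0.1 mg), overall percentages to two decimals (0.19% / 0.08%),
session emission from the rounded exhaled mass (0.1 × 20 = 2 mg), and
bystander doses from the *rounded* overall percentages
(4000 µg × 0.19% = 7.6 µg, 4000 µg × 0.08% = 3.2 µg) — the one order of
operations that makes every printed number mutually consistent.

## Synthetic scenarios and parameter recovery

`random_species()` / `random_scenario()` generate seeded, bit-exactly
reproducible scenario ensembles whose property ranges bracket the THC and
nicotine defaults by a factor of ten on partition coefficients and
condensed-phase diffusivities; the property suite runs the full pipeline
across them. `recover_partition_coefficient()` is a self-consistency
harness: it refits the mucus:air partition coefficient from a simulated
wall-flux series by 1-D least squares, recovering it within 2% noise-free
and within 10% (median over 20 seeds) under 5% multiplicative noise —
and it flags, rather than silently returns, the deposition-limited regime
in which the flux carries no information about K.

What these synthetic tests show is internal consistency of the solvers
and the accounting; they do not validate the model against measured human
exposure, which would require the 3-D CFD, CT geometry and measured puff
curves that are outside this package's scope.

## A worked run

```{r, eval = FALSE}
manifest <- run_pipeline(default_scenario())
print(manifest)
print(manifest$dose_report)
```

The default scenario is the post-puff worst case; the manifest carries the
simulated airway budget, the room exposure series, the secondhand
percentages (5.9% / 2.6% of exhaled with the calibrated defaults) and the
full-precision dose report.

## Known limitations

* One puff only: no multi-puff sessions, breath holds beyond a zero-flow
  segment, or long-term plasma pharmacokinetics.
* Vapor phase only: no aerosol size dynamics or particle deposition.
* Isothermal: vapor and wall temperatures are scenario metadata, not
  transported quantities.
* The airway budget fractions are qualitative at this order of reduction;
  regional (per-segment) uptake is reported but not validated.
* The secondhand fractions are calibrated, not predicted; changing the
  room, separation distance or breathing pattern moves them and the
  calibration should be rerun.
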