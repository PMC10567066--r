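---
title: "Mass-action analysis of saturation solubility-pH data with aggregation and salting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-action analysis of saturation solubility-pH data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satsol)
```

## The problem

Bromothymol blue (BTB) is a practically insoluble diprotic acid (H~2~A,
intrinsic solubility a few ng/mL) whose classical saturation solubility-pH
measurements in 0.1 M and 1.0 M NaCl (20 °C, pH 0–5.4 adjusted with HCl)
show two anomalies: the apparent intrinsic solubility drops by more than
0.7 log unit per molar salt — several times larger than ordinary
salting-out — and the apparent first ionization constant differs by almost
half a log unit between the two media, although an activity correction
predicts a difference near 0.02. Both anomalies are resolved by a
mass-action model in which the neutral monomer self-associates into a very
stable uncharged dimer: the dimer, not the monomer, dominates the neutral
mass in saturated acidic solutions, so the apparent "pK~a1~" read off a
solubility profile is really the anion/dimer equilibrium, and the apparent
salting constant is inflated by the salt dependence of self-association.
`satsol` implements that analysis as a reusable, tested pipeline.

## The speciation model

In a saturated solution below pH 6 the relevant equilibria are

* dissolution of the free acid: H~2~A(s) ⇌ H~2~A, with intrinsic
  solubility S~0~ = [H~2~A] (parameter `pS0` = −log~10~ S~0~);
* ionization: H~2~A ⇌ H^+^ + HA^−^ (`pKa1`) and HA^−^ ⇌ H^+^ + A^2−^
  (`pKa2`);
* neutral dimerization: 2 H~2~A ⇌ H~4~A~2~, K~2~ = [H~4~A~2~]/[H~2~A]^2^
  (`logK2`);
* salt precipitation: NaHA(s) ⇌ Na^+^ + HA^−^, K~sp~ = [Na^+^][HA^−^]
  (`pKsp_NaHA`);
* optionally a mixed-charge dimer H~2~A·HA^−^ (`logK_H3A2`) and its sodium
  salt solid (`pKps_NaH3A2`), needed only by the dimer-free alternative
  model in 1.0 M NaCl.

The total solubility in monomer equivalents is

$$S_T = [\mathrm{H_2A}] + [\mathrm{HA^-}] + [\mathrm{A^{2-}}]
      + 2[\mathrm{H_4A_2}] + 2[\mathrm{H_3A_2^-}],$$

which, for a given controlling solid, is a closed-form function of the
constants and pH. With the free acid controlling,
$S_T = S_0\,(1 + K_{a1}/[\mathrm{H^+}] + K_{a1}K_{a2}/[\mathrm{H^+}]^2)
+ 2K_2S_0^2$; with NaHA(s) controlling, [HA^−^] = K~sp~/[Na^+^] anchors the
chain instead. Every candidate solid imposes an upper bound on the neutral
monomer concentration; the controlling solid is the one imposing the lowest
bound, which is also the phase assignment leaving no other candidate
supersaturated. At a crossover pH two bounds coincide and both solids
co-control (a zero-width point, by the usual Gibbs phase-rule convention
for solubility-pH profiles).

Two diagnostic properties of this model shape the data analysis. First, in
the rising region where HA^−^ dominates, d log S~T~/d pH → +1 whether the
neutral mass is monomeric or dimeric, and also if a *mixed* dimer
H~2~A·HA^−^ forms — but a hypothetical anion-only dimer (HA^−^)~2~ would
force slope +2. The observed +1 slope therefore discriminates the neutral
(or mixed) aggregate from anionic aggregates. Second, at the pH where the
anion holds half the dissolved mass and the dimer the other half,
pK~a1~ ≈ −log 2 + p~c~H~1/2~ + pS~0~ − log K~2~
(`halfpoint_pKa1_estimate`), which is how the classical "apparent pK~a1~"
values are reinterpreted.

## Scales, activity and salting corrections

All equilibrium constants are concentration quotients on the constant
ionic medium (CIM) scale, tagged with a reference ionic strength `I_ref`
(and `Cs_ref` for neutral-species salting). Mixing constants from
different reference states is refused unless converted.

**Charged species.** Local deviations from `I_ref` are corrected by a
Stokes–Robinson hydration model: the per-unit-charge log activity
coefficient is

$$g(I) = -\frac{A\sqrt I}{1 + B a \sqrt I} - \frac{h}{2}\log_{10} a_w
       - \log_{10}\!\big(1 - 0.018\,(h-2)\,I\big),$$

with Debye–Hückel `A`, `B` computed from the dielectric constant of water
at the working temperature (20 °C: A = 0.507, B = 0.328), ideal water
activity (ln a~w~ = −0.036 I), and molality approximated by molarity. A
reaction with net squared-charge change Δz² shifts by Δz²·[g(I~to~) −
g(I~from~)]. The published functional details of the original correction
scheme are not available, so the ion-size parameters come from standard
tabulations (HCl-like: å = 4.47 Å; NaCl: å = 4.0 Å, h = 3.5) and the
hydration number of the ionization-type set was calibrated once against
the single published anchor — pK~a1~ = −0.66 measured at I = 4.59 M maps
to −1.18 at I~ref~ = 1.0 M — giving h = 6.09. That calibration was fixed
before any other use of the module and is not a tuning knob. With h = 0
the scheme reduces to extended Debye–Hückel, and below I ≈ 10^−3^ M the
two agree to better than 0.005 log units. The correction is applied per
reaction type: ionizations (Δz² = 2 and 4) with the acid parameter set,
the salt solubility products (Δz² = 2) with the NaCl set; the mixed-dimer
formation H~2~A + HA^−^ ⇌ H~3~A~2~^−^ has Δz² = 0 and receives none.
Ionic strength at each point is made self-consistent with the speciation
by fixed-point iteration (relative tolerance 10^−8^, at most 200
iterations; since the dissolved compound is micromolar against a 0.1–1 M
background this converges in two or three passes). One caveat recorded
here deliberately: over the full 0–5 M range the ionization corrections
swing far more than the K~sp~ correction (hydration dominates), but at a
*single* intermediate point such as I = 0.5 M the pK~a~-type curve sits
near its minimum, so pointwise slope orderings there are not meaningful —
the package asserts the ordering on the total swing instead.

**Neutral species.** Salting is linear in salt concentration (Setschenow):
pS~0~ shifts by +k~s~·ΔC~s~, with k~s~ = 0.25 M^−1^ as the model-C default.
The dimer receives its own coefficient, defaulting to 2k~s~ on the
volume-proportionality argument, which makes log K~2~ salt-independent;
any other value is accepted. C~s~ is the added background salt (NaCl after
dilution). Counting the strong-acid titrant as salt — relevant below pH 0,
where HCl rivals the background — is available via
`activity_config(salt_source = "background_plus_titrant")` but is not the
default: the datasets this package targets stay at pH ≥ 0, and the
cross-medium salting analysis regresses apparent pS~0~ on the nominal
added-salt concentration. When the solute self-associates, the *empirical*
Setschenow constant from total solubilities exceeds the true k~s~; the
modified form attributes the excess to a self-interaction term,
k~self~ = [log(S~T(0)~/S~T(s)~) − k~s~C~s~]/(S~T(s)~ − S~T(0)~)
(`self_interaction_solve`). In the speciation model itself
self-interaction is represented explicitly by the dimer species, so no
separate k~self~ adjustment enters `solve_point`.

**Electrode standardization.** Operational readings map to the
concentration scale through paH = α + k·p~c~H + j~H~[H^+^] +
j~OH~[OH^−^]; the defaults α = j~OH~ = 0, k = 1 correspond to an
electrode calibrated on the concentration scale, leaving the acidic
junction term j~H~, which matters below pH 2 and can be refined as a
nuisance parameter. A positive j~H~ makes the map non-monotone far below
pH 0; the numerical inversion restricts itself to the physically relevant
monotone branch and rejects readings that fall off it.

## Refinement conventions

`refine()` minimizes the weighted sum of squares
Σ[(log S^obs^ − log S^calc^)/σ]² by Levenberg–Marquardt, with the assigned
per-point error defaulting to σ = 0.1 log unit. The goodness of fit is
GOF = √(χ²~min~/(n − m)); this per-degree-of-freedom convention is a
package choice (the normalization used in the original reports is not
published, so their printed GOF values are indicative, not targets).
Standard errors come from GOF²·(JᵀJ)^−1^ with a central-difference
Jacobian of the weighted residuals, and the full parameter correlation
matrix is returned; correlations beyond 0.999, or singular normal
equations, set explicit flags rather than being absorbed silently. Rows
are sorted canonically before fitting so permuting input rows leaves
estimates bit-identical. Convergence is declared on a relative χ² change
of 10^−10^ (the forward model contains an internal iteration, so
derivative-free finite differences with log-unit parameter scaling are
used throughout).

When pK~a1~ is refined jointly with pS~0~, log K~2~ and pK~sp~ the normal
equations are nearly singular — the data constrain only combinations of
the four. `block_diagonal_refine()` implements the classical workaround:
alternate refinement of the two groups until the GOF stops improving,
recording the trajectory. `gof_profile()` quantifies the underlying
indeterminacy: across fixed pK~a1~ ∈ [−2, 1] the attained GOF varies by
well under 10 % of its level on data of this design, which is the
quantitative form of the statement that a range of pK~a1~ values fits the
solubility data equally well. This is why the production strategy (model
C) fixes pK~a1~ at the independently measured, re-referenced value instead
of fitting it.

## Salting analysis and the Abraham prediction

After per-medium refinement with neutral salting disabled, the apparent
pS~0~ values regress linearly on C~s~ (`derive_true_salting`); the slope
is the true salting-out parameter. The package also evaluates the Abraham
linear free-energy prediction k~s~ = a~0~ + a~1~A + a~2~B + a~3~S +
a~4~E + a~5~V with two bundled coefficient sets (`abraham_coefficients`):
the published multi-linear-regression set and a PLS refit. For BTB's
descriptors these give 0.54 and 0.63 M^−1^ — roughly double the 0.25
recovered from the solubility analysis, a gap plausibly due to training
sets lacking strongly self-associating solutes. `pls_fit_coefficients()`
reproduces the refit machinery on a user-supplied table
(`mixOmics::pls`, regression mode, component count by 5-fold
cross-validation); the 142-row literature compilation is third-party data
and is not shipped — `generate_descriptor_table()` provides a synthetic
table with the same schema for testing, drawing descriptors uniformly
over ranges spanning the published chemical space (A ∈ [0, 1.5],
B ∈ [0, 2.5], S ∈ [0.3, 3], E ∈ [0, 3.5], V ∈ [0.3, 4.5]).

On the NaH~3~A~2~(s) solid of the dimer-free alternative model: its
solubility product is implemented as K~ps~ = [Na^+^][H~3~A~2~^−^],
dissolution to the intact mixed-dimer anion. The triple-product
convention [Na^+^][H~2~A][HA^−^] with the published constant never
becomes the controlling phase anywhere in pH 0–5, i.e. it could not play
the role that solid is invoked for (explaining the pH 2.5–3.5 region);
the chosen convention yields a NaH~3~A~2~-controlled window between the
free-acid and NaHA regimes, as required.

## The synthetic-data generator

The original data points exist only as a figure, so the pipeline's
acceptance surface is parameter recovery on synthetic data emulating the
experimental design: 20 °C; media of 0.1 and 1.0 M NaCl; pH adjusted with
12 M HCl (titrant volumes computed exactly, with dilution of the
background; the strong acid dominates the proton balance since the
compound is micromolar); 10 points over pH 0.5–5.4 in the low-salt medium
and 15 over pH 0.0–5.4 in the high-salt medium; independent Gaussian
noise of σ = 0.1 on log~10~ S~T~, matching the assigned per-point errors.
Points are evenly spaced in pH — the original placement is unknown, so
even coverage is a declared stand-in, not a claim about the original
design. Every draw is seeded and reproducible, the caller's RNG state is
left untouched, and the generating truth travels with each dataset.

What the generator does *not* emulate: equilibration kinetics (the 24 h
equilibration is assumed complete), pH-measurement error (noise enters
log S only; the electrode map is exact unless a true j~H~ is requested),
correlated or heteroscedastic residuals, impurity or polymorph effects,
and any spectroscopic observables. Passing recovery tests therefore shows
the estimator is consistent and well-calibrated under the stated error
model, not that the historical data are free of systematic error.

Monte-Carlo study sizes are fixed in the package's tests and acceptance
script at 50 seeds per experiment (10- or 15-point datasets, three free
constants), which puts the standard error of recovered means near 0.01
log units — comfortably below the published uncertainties they are
compared against.

## Numerical choices

* Concentration floor 10^−30^ M keeps logarithms finite for absent
  species; species fractions still sum to 1 within 10^−9^.
* Dimer stoichiometry is fixed at n = 2. The degree of neutral
  aggregation is not determinable from solubility-pH data alone (a
  tetramer or oligomer mixture fits equally well at these
  concentrations); higher orders would enter through the same interface.
* pK~a2~ is fixed at 7.12 by default but is an ordinary, refinable
  constant; it plays a minor role below pH 6.
* pK~w~ = 14.17 (20 °C) for the hydroxide inventory and the alkaline
  electrode term.
* Solid-phase ties are resolved by reporting both phases at the crossover
  point (saturation equalities enforced simultaneously over a zero-width
  pH point).
* A trial j~H~ during refinement can push readings off the invertible
  electrode branch; the residual function returns a large finite penalty
  there, steering the optimizer back instead of crashing.
* A free j~H~ with no data below pH 2 is held at zero with a warning (it
  carries no information there); `hold_jH_without_acid = FALSE` keeps it
  free for information-content analyses.

## Limitations

The model works with macroscopic constants only: tautomers, zwitterion
microspeciation and the sultone ring question are outside its reach, as
is any structure assignment for the dimer. Only a single 1:1 background
electrolyte (NaCl + HCl) is supported — no general mixing rules. Micelle
formation above pH 6 and anionic aggregation are not modeled; the pH
range of validity is roughly −1.5 to 6. The Stokes–Robinson scheme with
ideal water activity is an approximation adequate to I ≈ 5 M for 1:1
electrolytes, constrained here by a single published anchor
transformation; its extrapolation beyond NaCl/HCl media is untested.
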