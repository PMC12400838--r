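---
title: "A strain-resolved cross-bridge and energetics model of exercising human muscle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A strain-resolved cross-bridge and energetics model of exercising human muscle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclexb)
```

## The model

`musclexb` simulates force generation by human skeletal muscle during
repeated dynamic contractions (the motivating task is constant-power
plantar flexion at 0.75 Hz to task failure) and the intramuscular
metabolite dynamics that accompany it. Two coupled layers make up the
model.

**Cross-bridge layer.** Actin–myosin interactions cycle through five
states: a non-permissible state N (binding sites blocked by troponin), a
permissible state P, a loosely attached state A1, a strongly bound
pre-power-stroke state A2, and a strongly bound post-power-stroke
(ratcheted) state A3. N and P are scalar fractions; the attached states
carry densities $p_i(t, s)$ over the cross-bridge strain $s$ (um), giving
an advection–reaction population balance:

$$\partial_t p_i + \frac{dL}{dt}\,\partial_s p_i = (\text{reactions}),$$

with attachment as a delta source $k_a\,\delta(s)\,P$ at $s = 0$,
strain-dependent kernels $e^{-\alpha_1 s}$, $e^{+\alpha_1 s}$,
$e^{-\alpha_2 s}$ and $e^{\alpha_3 (s+s_3)^2}$ on the A1/A2/A3
transitions, and total probability
$N + P + \int (p_1 + p_2 + p_3)\,ds = 1$ conserved.

Neural drive enters through the per-cycle normalized iEMG:
$k_{np} = \beta\,\mathrm{iEMG}_j$, $k_{pn} = \beta\,(1-\mathrm{iEMG}_j)$,
so the troponin gate equilibrates at an open fraction equal to the iEMG.
Metabolites modulate the attached-state rates through binding
polynomials: phosphate gates detachment from and progression out of A1
($\tilde k_d = k_d \frac{[P_i]/K_{P_i}}{1 + [P_i]/K_{P_i}}$,
$\tilde k_1 = k_1 / (1 + [P_i]/K_{P_i})$), while ATP, ADP and protons
partition A3
($\tilde k_{-2} = k_{-2}\,\frac{[\mathrm{ADP}]/K_{\mathrm{ADP}}}{D}$,
$\tilde k_3 = k_3\,\frac{[\mathrm{ATP}]/K_{\mathrm{ATP}}}{D}$ with
$D = 1 + [\mathrm{ADP}]/K_{\mathrm{ADP}} + [\mathrm{ATP}]/K_{\mathrm{ATP}}
+ ([\mathrm{ADP}]/K_{\mathrm{ADP}})([\mathrm{H^+}]/K_{\mathrm{H^+}})$).
An alternative proton-release mechanism (`mechanism = "A2_release"`)
instead divides the ratcheting rate $k_2$ by
$1 + [\mathrm{H^+}]/K_{\mathrm{H^+}}$ and removes the proton term from
$D$; it is the model's hypothesis for how acidosis could inhibit force.

Force is the sum of a frictional term carried by the strongly bound
strains and a power-stroke term of the ratcheted state,

$$F_{XB} = k_{stiff,1}\Big(\int s\,p_2\,ds + \int s\,p_3\,ds\Big) +
k_{stiff,2}\,\Delta r \int p_3\,ds,$$

plus an optional parallel-elastic offset $F_{PEE}$ (default 0). Power is
`power_scale * F_total * |dL/dt|`.

**Energetics layer.** ATP, ADP, Pi, PCr and H$^+$ evolve by mass-action
fluxes: ATP hydrolysis tied one-to-one to the A3 $\to$ P transition flux
(scaled by a myosin-site concentration `c_XB` to mM/s), creatine kinase
in both directions ($k_{CKf}[\mathrm{PCr}][\mathrm{ADP}]$,
$k_{CKr}([\mathrm{PCr}]_0 - [\mathrm{PCr}])[\mathrm{ADP}]$), glycolysis
($k_{Gly}[\mathrm{ADP}][P_i]$), adenylate kinase
($k_{adk}[\mathrm{ADP}]^2$) and Pi dilution ($k_{Pi,dil}[P_i]$). Protons
carry a stoichiometric coefficient of 0.6 on hydrolysis (the
H$_2$PO$_4^-$/HPO$_4^{2-}$ split at physiological pH) and a buffering
term $\gamma\,(\mathrm{pH}(t) - \mathrm{pH}_{ref})$. ATP mirrors ADP
exactly, so the adenine pool is conserved by construction; free creatine
is defined as $[\mathrm{PCr}]_0 - [\mathrm{PCr}]$.

**Protocol.** Each 1.6-s cycle runs at constant per-cycle activation and
sliding speed; at cycle boundaries the attached mass folds back into P
($P(t_0) = \hat p_1 + \hat p_2 + \hat p_3 + P(t_f)$, densities reset)
while metabolites continue across the boundary unchanged. The first
cycle starts from all-N with resting metabolites. Clamp experiments
continue a finished run for 10% extra cycles with one species held at a
multiple of its end-of-run value and all metabolite derivatives zeroed.

## Units and defaults

Internally everything is mM / um / s. The published human parameter
table mixes units (uM for $K_{ATP}$ and $K_{H^+}$, nm for $s_3$);
`xb_params()` takes table units and converts once at construction.
Defaults equal the human estimates; the remaining constants are package
choices, documented here:

* `delta_r = 0.30` um — the effective power-stroke displacement is not
  tabulated. Under sustained shortening the frictional term
  $k_{stiff,1}\int s\,p\,ds$ is negative (attached bridges are dragged to
  negative strain before the detachment kernels release them, at a mean
  strain of about $-0.06$ um with the tabulated kinetics), so the sign
  and magnitude of net force hinge on $\Delta r$. The physical working
  stroke of a myosin head is ~5–10 nm, but $k_{stiff,2}\Delta r$ here is
  a fitted phenomenological product; 0.30 um makes the power-stroke term
  dominate friction by ~1.7x, which yields positive force at the
  required-force scale and reproduces the reported qualitative responses
  (strong phosphate inhibition, marginal ADP potentiation, near-neutral
  protons under the base mechanism, proton inhibition under the
  A2-release variant). Chosen once; configurable.
* `beta = 0.2` 1/s — the activation rate scale is the 23rd estimable
  parameter and is not tabulated. The troponin gate then equilibrates
  over ~3 cycles, reproducing the observed multi-cycle force build-up
  from the all-N start; a gate that is fast relative to the cycle would
  make the first-cycle force jump immediately to its quasi-steady value
  and would leave `beta` unidentifiable from cycle-level data.
* `c_XB = 0.4` mM — converts cycling flux (fraction of bridges per
  second) to mM/s of ATP turnover. Chosen so the default run reproduces
  the reported trajectory magnitudes: PCr largely depleted within
  ~100–150 s and Pi rising from ~4 mM into the 15–20 mM range.
* `gamma = 20` mM/s per pH unit — the buffering constant is cited from
  an external method without a value. The implemented buffering is a
  restoring flux (the rate printed with $\Delta\mathrm{pH} =
  \mathrm{pH}_{ref} - \mathrm{pH}(t)$ would be anti-restoring: an acid
  excursion would amplify itself), and at this default it keeps pH close
  to rest, so simulated pH excursions are much smaller than in vivo
  (~0.02 vs ~0.3 units). Only the qualitative shape (H$^+$ rises then
  plateaus) is asserted anywhere; reduce `gamma` to ~1.5 for realistic
  amplitudes at the cost of a stronger proton feedback on the A3
  polynomial.
* Resting state: ATP 8.2 mM (the conventional reference), Pi 4.0 mM and
  ADP 8 uM (mid-range of resting values), pH 7.05, PCr 33 mM. The last
  two are synthetic defaults, not measured values.
* `power_scale = 0.045` W per (mN/mm$^2$ um/s) — calibrated once so the
  default synthetic run's late-exercise power is ~5 W, the scale of the
  constant-power task; the normalizing "required force" is
  `target_power / (power_scale * dLdt)`.

## Numerics

The strain axis uses a uniform grid with a node exactly at $s = 0$
(where attachment deposits $k_a P/\Delta s$). Each step is operator
split:

1. *Reaction*, by backward (implicit) Euler. The per-node 3x3 systems
   are eliminated in closed form and the remaining N/P coupling reduces
   to one scalar equation, so the step is unconditionally stable against
   the stiff strain kernels (which reach $e^{100+}$ at the domain edges
   during wide parameter sweeps; kernel exponents are capped at 200 to
   keep the algebra finite) and transfers probability exactly — the
   conservation sum is preserved to round-off (~1e-11 over 240 cycles).
2. *Advection*, by first-order upwind differencing with zero inflow,
   under the CFL restriction $|v|\,\Delta t \le \Delta s$ (violations
   raise an error reporting the admissible step). Shortening (positive
   `dLdt`) drives attached-bridge strain negative; this is the standard
   convention and the only one under which the fitted kernels are
   meaningful — with the opposite sign the ratcheting kernel
   $e^{-\alpha_2 s}$ ($\alpha_2 = 171.8$/um) shuts the cycle off and ATP
   turnover collapses ~100-fold below what the measured PCr/Pi
   excursions require. Probability advected past the downwind boundary
   is folded into P (forced detachment); on the default grid this
   closure handles ~1e-250 of the mass, i.e. it never fires in practice.
3. *Metabolites*, by explicit Euler — except H$^+$, whose buffering term
   has an effective relaxation rate $\gamma/([\mathrm{H^+}]\ln 10)
   \approx 10^5$/s and is therefore advanced by a per-step Newton solve.

Defaults: grid $[-0.4, 0.1]$ um with 401 nodes ($\Delta s = 1.25$ nm)
and $\Delta t = 0.25$ ms. Halving $\Delta s$ changes end-of-run
cycle-mean force by ~0.09% and halving $\Delta t$ by ~0.24% on a
30-cycle fixture; widening the domain changes force by < 1e-6. Negative
densities from round-off are clamped to zero and folded into N; the
clamped mass is tracked and stays below 1e-9 per run.

The Monte-Carlo oracle (`mc_oracle()`) is an independent check, not a
solver: each of $n$ bridges holds a state and a strain, waits an
exponential holding time against the summed exit rates (frozen over one
step), picks its exit channel proportionally, and advects along
characteristics. Attached fractions agree with the PDE within binomial
standard errors at $10^5$ bridges.

## Estimation and sensitivity

The objective follows the published least-squares form: for each fitted
series (cycle-mean power, Pi, ADP, PCr; pH is excluded by default
because the study reserved it for validation),
$\sum_j (d_j - m_j)^2 / \max_j(d_j)$ — squared residuals normalized by
the series *maximum*, not its square. `fit_parameters()` runs bounded
Levenberg–Marquardt (minpack.lm) in log10 parameter space from seeded
uniform random starts and keeps the lowest objective; default bounds are
one decade either side of the start values, since the study does not
state its search space.

A practical caution established while validating the estimator on
self-generated data: over a *shortened* protocol the Pi-binding
parameters form a sloppy ridge. If only the first 60 cycles are
observed, Pi stays well below $K_{P_i}$ and PCr never reaches its
depletion elbow; scaling $k_d$ and $K_{P_i}$ together (with a partial
$k_{Gly}$ compensation) then changes the observable output by only
~0.2% RMS, and with 2% observation noise the maximum-likelihood estimate
sits a factor of 1.3–3 along that ridge across noise realizations while
fitting *better* than the generating truth. Over the full 240-cycle
protocol — where Pi rises to $\approx K_{P_i}$ and the PCr elbow is in
the data — the same fit recovers all five tested parameters to within a
few percent. Noise-free recovery is exact in both cases. The lesson for
design: the binding constants are identified by the late-exercise
saturation regime, not by trajectory density early on.

Sensitivities follow the normalized central difference
$S_i = \frac{F(x_i + dx) - F(x_i - dx)}{F(x^0)}\,\frac{x_i}{2\,dx}$ with
a 1% step, where $F$ is by default the end-of-exercise cycle-mean force;
the global analysis evaluates the same $S_i$ over Latin-hypercube
samples within ±10% of the optimum and reports the distributions.

Two behaviours of the default parameterization are worth knowing when
interpreting sensitivity and clamp results. First, the marginal ADP
potentiation of force is non-monotone in the operating ADP level: a
small rise (under 1%) when doubling from a moderate end-exercise
concentration (~0.02 mM), turning into an equally small decline when
doubling from 0.03 mM and above, where ADP saturation of the A3 binding
polynomial lengthens attached lifetimes enough for the frictional strain
term to win. Either way the effect is an order of magnitude below the
phosphate effect. Second, on the default fixtures the attachment rate
$k_a$ carries the largest cross-bridge force sensitivity, with the
detachment-step parameters $k_d$ and $K_{P_i}$ inside the top five; how
the top of that ranking orders depends on the operating point and on
the constants the source leaves unvalued ($\Delta r$, `beta`, the
parallel-elastic term), so only the qualitative membership — detachment
and attachment parameters dominating, with the phosphate dissociation
constant far ahead of the other binding constants — should be read as
robust.

## What the synthetic data do and do not emulate

`synthetic_spec()`/`gen_activation()`/`gen_observations()` generate a
monotone activation ramp (36% to 60% over 240 cycles, the measured group
average), optional clipped Gaussian cycle jitter, and noisy
pseudo-observations sampled every 10 s (the spectroscopy interval; the
time-to-cycle mapping uses 6.3 cycles per 10 s) with multiplicative
Gaussian noise (default 5% relative SD per series, standing in for the
unpublished between-subject variability). They emulate the *shapes* of
the measured trajectories — rapid PCr fall then plateau; Pi, ADP and
H$^+$ rise then plateau; constant task power — not their exact values:
no real iEMG waveforms, no raw spectra, no between-subject structure,
and a pH amplitude far below in vivo (see `gamma` above). Tests passing
on these data therefore validate the mechanics, conservation laws,
directions of effect and the estimation machinery — not quantitative
agreement with any subject.

## Reduced problem sizes

The test suite runs short protocols (typically 5–120 cycles) on a
201-node grid at $\Delta t$ = 1–2 ms, sizes at which every qualitative
property above is already stable; the conservation and counterfactual
checks use the full 240-cycle default. The recovery experiment fits the
full 240-cycle protocol (per-cycle observations, 20 starts) on a coarse
101-node, 4-ms solver configuration — self-consistent between generator
and fit, and fast enough for routine use.

## Known limitations

* No calcium handling: EMG is the activation proxy, as in the source
  model; proton or phosphate effects on calcium release are out of
  scope.
* Single well-mixed compartment; oxidative phosphorylation is absorbed
  into the glycolytic/dilution terms.
* The within-cycle velocity waveform is not known from the study; the
  default applies the average shortening speed through the whole cycle,
  and a `half_cycle` option (shorten during the active fraction,
  re-lengthen during relaxation) is provided for exploration.
* First-order upwind advection is diffusive; the default grid is fine
  enough that refining it moves force by < 0.1%, but very sharp kernels
  (alpha values ~10x the defaults) would warrant a finer grid.
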