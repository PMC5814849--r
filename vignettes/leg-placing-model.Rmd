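---
title: "Modelling leg placement of a DNA bipedal walker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling leg placement of a DNA bipedal walker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnawalker)
```

## The system and the reaction

A DNA bipedal walker strides along a rectangular DNA origami track.
Each step requires a *leg-placing* reaction: a fuel strand, already bound
to the next foothold (or to the lifted leg), must hybridise with the free
partner to connect leg and foothold. A second fuel molecule from solution
can instead bind the still-free leg or foothold, producing an irreversibly
*trapped* motor. Because trapping is absorbing, the long-time fate of every
motor is decided by a simple kinetic race between the intramolecular
stepping reaction (rate $k_s$, independent of fuel concentration) and
pseudo-first-order fuel binding (rate $k_\mathrm{FB}[\mathrm{F1}]$):

$$Y = \frac{k_s}{k_s + k_\mathrm{FB}[\mathrm{F1}]}.$$

`yield_from_rates()` implements this competition, `simulate_race()` is an
independent exponential-clock oracle for it, and
`stepping_rate_from_yield()` is its exact inverse, which is how stepping
rates are extracted from measured yields once $k_\mathrm{FB}$ is known
(default $2.3\times10^{5}\,\mathrm{M^{-1}s^{-1}}$, the experimentally
determined value for this walker).

An equivalent barrier form assumes both rates share a common attempt
prefactor, so only activation free energies matter:

$$Y \approx \frac{e^{-\Delta G_s^\ddagger/k_BT}}
{e^{-\Delta G_s^\ddagger/k_BT} + e^{-\Delta G_\mathrm{FB}^\ddagger([\mathrm{F1}])/k_BT}},
\qquad
\Delta G_\mathrm{FB}^\ddagger([\mathrm{F1}]) =
\Delta G_\mathrm{FB}^\ddagger(c_0) - \ln\frac{[\mathrm{F1}]}{c_0}.$$

All energies are in units of $k_BT$; temperature never appears explicitly.
The logarithmic concentration term, with the reference concentration
$c_0 = 1\,\mathrm{M}$ by convention, makes the barrier form reproduce the
rate form's linearity in $[\mathrm{F1}]$ exactly; the suite checks the two
pictures agree to at least ten significant digits under the mapping
$\Delta G = -\ln(k/A)$.

## The coarse mechanical model

The step-size dependence of $\Delta G_s^\ddagger$ is dominated by the
entropic cost of forming the *first* leg-placing base pair: the two
reactive ends, each tethered to its own anchor, must meet. We therefore
model the system before contact as two independent tethered chains over a
hard wall:

* **Duplex segments** are rigid rods at 0.34 nm/bp. Every duplex here is
  far below the ~50 nm persistence length of dsDNA. Contiguous duplexes
  that meet at a nick are treated as one coaxially stacked rod: nicked
  duplexes are predominantly stacked, and treating them as freely jointed
  makes the model arm much floppier than the real construct (with fully
  jointed nicks the 5-20 nm barrier span comes out near 4 $k_BT$, at odds
  with the nearly flat barrier this system shows; with stacked nicks it is
  below 2 $k_BT$).
* **Single-stranded segments** are freely-jointed chains with Kuhn length
  1.5 nm and contour 0.63 nm/nt. A partial terminal Kuhn link keeps its
  true (shorter) contour; a segment shorter than one Kuhn length is a
  single rigid link.
* **The origami** is reduced to a hard wall: a flat half-space, or, for
  the short axis (which prefers to curl), a cylinder whose circumference
  defaults to the 60 nm origami width, with the walker on the convex side.
  Anchoring is a free pivot: any orientation in the allowed half-space.
  Intra-chain excluded volume is ignored; at these contour lengths the
  wall is the dominant steric constraint.
* **Flexible points** are the three-way junction where the bound leg
  branches off the foothold stem, the single-stranded inter-leg hinge, and
  every ss segment.

The default geometry (`walker_default_design()`) fixes what the strand
designs fix - the fuel is held by an 18 bp duplex on the foothold and
binds the leg by 16 bp - and chooses the remaining stem/hinge/overhang
lengths once, such that the fully stretched distal-termini reach of the
two arms reproduces the ~40 nm maximum step this walker supports. Every
length is a config knob.

### Contact probability and the overlap integral

The transition state is reached when the two reactive ends approach within
the capture radius $\delta$ (default 1 nm, of order one base-pair bond).
Because the arms are independent before contact,

$$p(d) \approx \tfrac{4}{3}\pi\delta^3 \int \rho_A(\mathbf r)\,
\rho_B(\mathbf r)\,\mathrm d^3 r,$$

valid when the densities are smooth on the scale of $\delta$. The integral
is evaluated on a shared 1 nm voxel grid with each sampled cloud smoothed
by a 1 nm Gaussian kernel; this product form multiplies the two arms'
*marginal* rarities, so contacts down to $p \sim 10^{-11}$ are resolved
near maximal reach, where a direct pairwise hit counter would register
nothing. The direct counter (`method = "direct"`) is retained as a
cross-check wherever hits are common, and the suite requires the two
estimators to agree within three combined standard errors. Standard errors
of the overlap estimator come from a multinomial bootstrap of both voxel
histograms. The KDE product is biased for near-singular densities (e.g.
two bare rods, whose end densities are spherical shells), which is why the
closed-form rod checks in the suite use the direct counter; the default
arms' clouds are convolutions over several flexible links and are smooth
on a multi-nanometre scale, where the bias is well inside the sampling
noise.

Barrier differences then follow as
$\Delta\Delta G^\ddagger(d) = -\ln\,[p(d)/p(d_\mathrm{ref})]$,
and `predict_yield_curve()` anchors the absolute rate scale by
$k_s(d) = k_{s,\mathrm{ref}}\,e^{-\Delta\Delta G^\ddagger(d)}$. The
capture radius and kernel bandwidth cancel to first order in the ratio.
The reference step size defaults to 12 nm (the step at which the model is
pinned to the measured rate). The reference rate defaults to
$3\,\mathrm{s^{-1}}$, the geometric middle of the $1$-$10\,\mathrm{s^{-1}}$
range measured for short steps; both are config values because the
experimental anchor is known only to within that range.

Sampling is plain rejection: chains are grown with uniformly random joint
orientations and any conformation with a bead inside the wall is
discarded (on curved walls, midpoints of links longer than 2 nm are also
checked, since a chord between two admissible joints can cut the
surface). Acceptance rates for the default arms on the flat track are
20-50%, so $10^5$ accepted conformations per arm - the default problem
size, which resolves the full flat-track yield surface in a few seconds -
are cheap. Arm clouds are sampled once per arm and re-placed for every
separation (translation on the flat track, rotation about the cylinder
axis), which the wall constraint leaves exact; separations beyond the
analytic reach return an exact zero without sampling.

### The curled short axis

On the cylinder, separations are arc lengths, and beyond half the
circumference the shorter way around is used: footholds at a 45 nm
designed arc on a 60 nm circumference are only a 15 nm arc apart the other
way, so the contact probability does not vanish where the flat model is
far beyond reach. This reproduces the *mechanism* of the short-axis
plateau (a wrap-around route that keeps the yield alive at the largest
designed steps, where the flat track gives exactly zero) and the early
short-axis drop near half the circumference, where the two anchors are
maximally distant in space. It does **not** reproduce the plateau *level*:
a static, fully closed, untwisted tube makes the wrap-around route far
easier than the fluctuating, twisted, partially curled origami, so the
model's yield at the largest short-axis step approaches unity rather than
the ~10% plateau observed for the real track. Modelling partial or
fluctuating curl (or the origami's twist) is out of scope here; the
corresponding acceptance check is deliberately left failing rather than
weakened, and this is the model's main known limitation.

### The fuel hairpin

A transient hairpin in the fuel's free overhang sequesters part of the
overhang when folded. `apply_hairpin()` builds the two-state mixture
$p_\mathrm{eff}(d) = p_\mathrm{open}\,p_\mathrm{full}(d) +
(1-p_\mathrm{open})\,p_\mathrm{short}(d)$ with
$p_\mathrm{open} = 1/(1+e^{-\Delta G_\mathrm{hp}})$
($\Delta G_\mathrm{hp}$ = folding free energy in $k_BT$, negative =
folded favoured; the hairpin's stability is a config input, not computed
from sequence). In this coarse model the folded state mainly shortens the
fuel arm's reach, so the penalty appears at the *longest* steps. The
experimentally observed effect - a small yield dip specifically at the
shortest (~5 nm) steps, caused by the folded hairpin keeping the fuel end
away from the foothold attachment point - is a sub-arm positional effect
below the resolution of a distal-termini contact model, and the package
does not claim to reproduce it.

## The synthetic smFRET measurement

The measurement this package emulates is diffusion-based single-molecule
FRET: each motor transiting the confocal spot yields one burst whose
apparent FRET efficiency identifies its state, leg-placed or trapped. The
generator (`generate_bursts()`) draws each burst from a two-component
truncated-normal mixture on $[0,1]$ with the leg-placed fraction given by
the kinetic competition. Defaults put the leg-placed state on the low-FRET
side ($E_\mathrm{LP} = 0.2$, $E_\mathrm{Trap} = 0.8$, widths 0.1); the
assignment is a labelling convention (the estimator identifies components
by proximity to the configured leg-placed mean, so only consistent
labelling matters, not its direction). What the generator deliberately
omits: photon shot noise, gamma factor, background, bleed-through, burst
search, and any burst-size dependence of the efficiency width. Passing
parameter-recovery tests therefore demonstrates that the *analysis chain*
is correct and well calibrated for clearly separated populations; it does
not validate photon-level aspects of a real measurement, and with real
data the population widths and means would first be characterised from
control samples.

`estimate_fractions()` fits the mixture by EM. By default the two means
are held at their configured values (mirroring practice, where state means
come from controls) and only the mixing weight and widths are free;
`fix_means = FALSE` releases the means. Weighted-moment width updates are
slightly biased low under truncation, which is immaterial at the default
4-6 sd separation. Fits with fewer than 50 bursts are rejected outright
(EM instability), non-convergence after 500 iterations is flagged rather
than hidden, and the 95% interval is a percentile bootstrap over bursts
(200 resamples by default), clamped to contain the point estimate.

## Pipeline, determinism and numerical choices

The five stages (`run_simulate_fret()`, `run_fit_yields()`,
`run_extract_rates()`, `run_predict_mechanics()`, `run_compare()`) mirror
the analysis chain and are independently testable; a YAML config drives
all of them, with strict schema validation (unknown keys are rejected with
a did-you-mean suggestion naming the full key path). Rate extraction
refuses yields outside $(0.01, 0.99)$ - flagged unreliable instead of
inverted, since a one-sided race does not constrain the losing rate. The
comparison joins the two curves on the exact shared grid (a mismatch is an
error listing the offending pairs), reports per-pair residuals, the RMS
residual, and per-concentration crossover step sizes, defined as the
linearly interpolated $Y = 0.5$ point - the natural midpoint of the
competition, where $\Delta G_s^\ddagger \approx
\Delta G_\mathrm{FB}^\ddagger$ - reported only when the curve brackets it.

Every stochastic component takes its stream from the single config seed
via tagged sub-streams (`derive_seed()`), so two runs from the same config
are byte-identical, and every stochastic output carries its seed. The
synthetic experiment's default true stepping rates follow the measured
pattern (a few $\mathrm{s^{-1}}$ at 5-25 nm, collapsing by roughly five
orders of magnitude by 35 nm); default fuel concentrations span
1 nM-10 uM, the experimental range.

Problem sizes used by the shipped tests: $10^5$ accepted conformations per
arm for yield surfaces ($10^6$ for the near-reach confirmation), $10^5$
motors for race oracles, 2000-5000 bursts per condition for estimator
calibration and 3000 for end-to-end rate recovery - sizes at which every
three-sigma check has comfortable margin while the whole suite runs in
about a minute.

## Known limitations

* The model predicts *relative* barriers only; absolute rates enter
  through the single calibration point.
* The short-axis plateau level and the 5 nm hairpin dip are mechanisms
  below the resolution of the idealised track and distal-termini contact
  model (see above).
* Base-pair-resolution free-energy profiles (the downhill zipping after
  nucleation), origami twist, the leg-lifting reaction and fuel/antifuel
  dissociation are out of scope.
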