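---
title: "Models and methods behind micellekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind micellekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micellekit)
```

`micellekit` analyses the micelles formed by the short-chain phosphocholine
2C6PC (dihexanoylphosphatidylcholine) and its phospholipase-A2 digestion
products, 1-hexanoyl-lysophosphocholine (LYSO) and hexanoic acid (FA). It
has two halves that meet in the middle: a small-angle neutron scattering
(SANS) model of the micelle as a triaxial core-shell body, and trajectory
analytics that measure aggregation, shape and hydration of micelles in
molecular configurations. A synthetic-configuration generator supplies
ground-truth data so that every analytic can be validated without access to
beam time or multi-day simulations.

## The scattering model

A micelle is modelled as a "lozenge": a triaxial ellipsoid hydrophobic core
with semi-axes `core_polar <= core_minor <= core_major` (polar, minor
equatorial and major equatorial radii, in that order for a flattened,
elongated body) wrapped in a uniform hydrophilic shell of fixed thickness
(5 Angstrom by convention, following the fitted systems this package was
built around). With contrasts written against the solvent, the
single-orientation amplitude is

$$F(q,\theta,\varphi) = (\rho_c-\rho_s)\,V_c\,K(q r_c) +
  (\rho_s-\rho_w)\,V_t\,K(q r_t), \qquad
  K(u) = \frac{3(\sin u - u\cos u)}{u^3},$$

where $r(\theta,\varphi)$ is the effective radius of each ellipsoid along
the scattering vector. The measured form factor is the orientation average
$P(q) = \langle |F|^2 \rangle / V_t$ (times $10^{-4}$ so that SLDs in
$10^{-6}\,\mathrm{\AA}^{-2}$ give absolute intensities in cm$^{-1}$).

*Numerical choice.* The average is taken over one octant by a fixed-order
Gauss–Legendre product rule in $(\cos\theta, \varphi)$, order 76 per
dimension. Doubling the order changes $P(q)$ by less than $10^{-6}$
relative on $q \le 0.4\,\mathrm{\AA}^{-1}$, and in the spherical limit the
kernel agrees with the analytic core-shell sphere to $10^{-8}$. An
independent Monte-Carlo Debye-sum oracle (stratified points in the two
ellipsoidal domains, pair-distance histogram) agrees with the quadrature to
better than 1% across the instrument range; that check runs in the test
suite.

Concentrated micellar dispersions interact, so the intensity is

$$I(q) = s\,P(q)\,S(q) + b,$$

with $S(q)$ the closed-form Percus–Yevick hard-sphere structure factor
(scalar decoupling approximation) and $b$ a flat background. The
hard-sphere radius defaults to the volume-equivalent sphere radius of the
outer ellipsoid; the coupling convention and effective radius are design
choices (the decoupling form is standard practice) and both are
configurable.

Fitting (`fit_model()`) is bounded weighted least squares via
Levenberg–Marquardt, minimising $\sum((I_m - I_o)/\sigma)^2$; parameter
uncertainties come from the residual-variance-scaled covariance at the
optimum and the reduced chi-squared is reported. Fits are deterministic
given the initial values; `fit_series()` warm-starts successive time slices
from the previous optimum, the natural workflow for stopped-flow series.
`guinier_rg()` provides the model-free cross-check: a weighted linear fit
of $\ln(I-b)$ against $q^2$ on a window chosen iteratively so that
$qR_g \le 1.3$ by default.

### Derived micelle quantities

Tanford's empirical formulas give the chain geometry: extended length
$R_{tail} = 1.5 + 1.265\,n$ Angstrom and two-chain volume
$V_{tails} = 54.8 + 2 \times 26.9\,n$ cubic Angstrom for $n$ carbons per
chain. With the last five carbons of each hexanoyl chain assigned to the
core ($n = 5$): $R_{tail} = 7.8$ A (effectively 5.9–6.2 A for fluid
chains, 75–80% of extended) and $V_{tails} = 323.8$ A$^3$. The aggregation
number is then $N = \mathrm{round}(V_{core}/V_{tails})$, per-lipid areas
are the core and outer ellipsoid surface areas (numerical quadrature,
converged to $10^{-6}$) divided by $N$, and head-group hydration follows a
shell volume balance $(V_{shell} - N V_{head})/(N V_{water})$ with
configurable $V_{head} = 319$ A$^3$ and $V_{water} = 30$ A$^3$. The
hydration column is method-dependent — no single volume pair reproduces
every published value — and is labelled as such in reports. Applied to the
published fitted radii (printed, i.e. rounded, values), the derived $N$
matches the printed aggregation numbers within $\pm 2$ for all six
well-constrained rows and exactly for three of them; the residual spread is
consistent with rounding of the printed radii.

## Trajectory analytics

**Aggregation.** Two molecules are in contact when any pair of their tail
or terminal carbons lies within 4.5 Angstrom under the minimum-image
convention, and aggregates are single-linkage connected components. The
4.5 A hydrophobic-carbon criterion is the conventional choice for micelle
aggregation (the underlying study does not state its criterion) and is
exposed in configuration. The micelle of a frame is the largest component,
ties broken by lowest cluster id. Molecules in components smaller than 5
are counted as monomers — the analytics distinguish only monomer vs
micelle, so dimers and trimers default to the monomer side; the threshold
is configurable. Composition tables report mean ± sample standard
deviation over an analysis window, defaulting to the final half of the
frames (published analyses used the last 100–120 ns of 120–140 ns runs,
i.e. most of the trajectory after assembly; the window is a configuration
value).

**Shape.** Before any geometry, the micelle is made whole: each molecule is
unwrapped internally, then molecules are attached by a minimum-image walk
from a seed molecule — periodic wrapping would corrupt every second moment.
Descriptors are the mass-weighted radius of gyration, the maximum pairwise
extent, and the sorted principal moments $I_1 \le I_2 \le I_3$ of the
inertia tensor. Eccentricity is defined as $e = 1 - I_{min}/\bar I$. That
definition is not printed in the source study, but it reproduces the
published (ratio pair to eccentricity) mapping to two decimals for every
row of the published shape table, and it is the standard micelle-shape
convention; the identity is asserted in the acceptance tests. Shape
classification (sphere / prolate / oblate / triaxial) uses a tolerance of
0.05 on the moment ratios; the original classification criteria live in
unavailable supplementary material, so the tolerance rule is a declared
substitute and is configurable.

**Hydration.** RDFs use the standard estimator (minimum-image distances,
$4\pi r^2 dr$ shell normalisation, partner density $N_b/V$), with the
running coordination number accumulated bin-by-bin so that it equals the
brute-force neighbour count at every bin edge exactly. The first hydration
shell is bounded by the first local minimum of the smoothed g(r) after the
dominant peak (searched in 2–6 A). Water-contact tables count water
oxygens within a per-role cutoff — 3.5 A for N/P/O sites, 5.0 A for
carbons, following the first-minima logic (e.g. the O–O$_w$ minimum near
3.2 A) with per-role overrides — split by each molecule's monomer/micelle
state in that frame, since molecules exchange between the states.
Reported integers round half away from zero; unrounded means are retained.

## The synthetic-data generator

The generator *plants* structure rather than simulating it: its ground
truth is the point of the exercise. A micelle with a chosen per-species
composition is placed at the centre of a cubic periodic box:

* terminal carbons sample the core ellipsoid interior, PC2C6 and FA biased
  toward the centre, LYSO terminal carbons held at radii at least 0.6 of
  the core boundary (emulating the partial interdigitation of the
  single-chain lyso species);
* choline N and phosphate P sit at the outer (core + shell) surface for
  PC2C6 and LYSO, while the FA carboxyl oxygens sit just outside the core
  boundary, so FA is buried deeper than LYSO — the radial ordering the
  analytics should detect;
* chains are reduced to pseudo-atoms (ester and carbonyl oxygens plus four
  tail beads and a terminal bead per hexanoyl chain), each carrying the
  approximate summed mass of its group; every analytic consumes only
  tagged atoms, so full atomistic detail would add nothing testable;
* free monomers are placed at least 15 A from the micelle surface and
  from each other; water oxygens fill the rest at 0.0334 molecules/A$^3$
  (bulk water at 300 K) outside a 2.6 A exclusion shell around solute
  atoms.

Two numerical choices deserve note. First, the planted core sits at
liquid-like bead density, where naive whole-molecule rejection sampling
against the full 1.8 A steric floor stalls; members are therefore placed
against a looser 1.2 A floor and the assembly is relaxed by soft-sphere
push-off until the 1.8 A floor holds everywhere. Second, the generator
verifies that the planted members form a single connected tail-contact
network at 4.0 A — strictly inside the 4.5 A analysis cutoff — and
re-samples the construction otherwise, making the planted aggregation
number recoverable by construction. Every stochastic step draws from its
own stream derived from the spec seed, so configurations are
bit-reproducible.

The presets mirror the seven simulated digestion-series systems (total
compositions from the published composition table, e.g. C6 = 35 PC2C6,
C6-50 = 17/18/18). Within each preset most molecules are planted in the
micelle with a few free monomers of the more soluble species; the pure-LYSO
system plants no micelle at all, matching its observed failure to
aggregate. Core semi-axes default to the 150 mM fit (27.1/15.7/6.3 A).
Multi-frame trajectories add i.i.d. Gaussian jitter (0.5 A default) to
solute atoms and re-draw water, so ground truth holds in every frame.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: no physical dynamics or exchange kinetics (the
membership never changes between frames), no realistic chain conformations
or packing correlations, water as an ideal gas outside the exclusion
shells (no hydrogen-bond structure, so RDFs of planted systems lack
realistic peak shapes), and no instrument effects on synthetic SANS curves
(no resolution smearing or polydispersity — both are out of scope for the
fitting model too). Recovery of planted parameters validates the
*analytics*, not the physics of any particular simulation.

## Degenerate inputs and edge rules

Single-atom selections give Rg 0 with a warning; collinear point sets are
a degeneracy error for the inertia tensor. A one-frame composition window
reports a standard deviation of 0 with a warning. RDF ranges are capped at
half the smallest box edge. Species absent from a system appear as `NA`
(printed as a dash) in composition tables. Curves with non-increasing q
are sorted with a warning; rows with $q \le 0$ are dropped. Fits require
strictly positive uncertainties; a curve with any zero sigma is a
weighting error.

## Problem sizes used in the shipped tests

The validation suite runs on deliberately small instances: planted
micelles of 3–70 molecules, boxes of 40–90 A (up to roughly 20,000
waters when hydration is exercised), trajectories of 2–6 frames, SANS
curves of 60–120 points, 20-seed recovery ensembles, and Debye oracles
with ~6,000/16,000 stratified points per domain. These sizes were chosen
so the whole suite gives tight statistical margins (4–5 sigma on the
loosest stochastic assertion) while remaining quick to run on one CPU.

## Known limitations

The shell is uniform; anisotropic shells (thicker over the equator than
the poles) are not modelled. The structure-factor coupling ignores
orientation-structure correlations (scalar decoupling). The head-group
hydration derivation is a volume balance with assumed component volumes.
The generator's molecules are geometrically idealised (radially stretched
chains, pentagon-helix bead placement); their internal geometry should not
be over-interpreted. Binary trajectory formats (XTC/TRR/DCD) are not read;
PDB, GRO and extended XYZ are.
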