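---
title: "Models and methods: hydrogen bonding, dynamics and free energies of disaccharide-water mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sugarglass)
```

This vignette is the package's own account of the science it implements:
the models behind each analysis, the tunable parameters and why their
defaults are what they are, what the synthetic generators do and do not
emulate, and the numerical choices that a user re-implementing or
auditing the package would want spelled out.

Units are fixed package-wide to GROMACS conventions — nm, ps, kJ/mol, K,
degrees — with `kB = 0.0083144626` kJ/(mol·K). Atom indices are 0-based
inside the package and 1-based only at file boundaries (the GRO
convention). Only orthorhombic cells are supported; the studies this
package targets use cubic boxes with isotropic pressure coupling, and
triclinic input is rejected with a clear error rather than silently
mis-wrapped.

## The study design this package serves

A comparative simulation study of sucrose and trehalose in water
typically spans the full concentration range — here represented by the
`study_composition_counts()` series, sixteen (sugar, water) count pairs
from pure sugar to 99.44 wt% water with equal total mass — and two
equilibration protocols: mixtures simulated directly ("not preheated")
and mixtures first heated above the glass transition and cooled by
simulated annealing ("preheated"). The protocol is carried through the
package purely as a dataset label on trajectories and reports; no
annealing is ever simulated here. One published row of the series
(2 sugars / 3700 waters, labelled 99.95 wt%) is inconsistent with the
mass-fraction identity
`100·n_w·MW_w/(n_w·MW_w + n_s·MW_s)` (it recomputes to ≈ 98.98%); the
package treats it as a probable typo, excludes it from the default
series, and deliberately does not adjust the formula to match it.

## Hydrogen bonds

The criterion is geometric: donor oxygen and acceptor oxygen within
`dist_cutoff` and the H–D–A angle (at the donor, between the O–H bond
and the O···O axis) within `angle_cutoff`. The defaults 0.35 nm / 30°
are the convention of GROMACS-style analyses; because engines differ,
both are exposed in `hbond_criterion()` and in the study config. Each
D–H···A triple counts once, so a water donating both hydrogens
contributes two bonds.

Two normalisations mirror the two ways such data are plotted:
`per_total_oxygen` divides category counts by *all* oxygens in the
system (sugar plus water) — the right denominator for comparing systems
of very different size along a concentration axis — while per-group
tables (`group_hbond_profile()`) divide by the number of group
instances, the right scale for asking which hydroxyl or ether oxygen is
doing the binding. Bonds internal to the selected group are excluded,
and overlapping group definitions are rejected at topology construction
(group-based counting is ill-defined under overlap). For trehalose, the
molecule's C2 symmetry makes group pairs equivalent
(O2-H8/O11-H22, O3-H9/O10-H21, O4-H10/O9-H20, O5-H11/O8-H19, O1/O7);
symmetry classes are averaged into single rows — the class total divided
by the class size — and the operation is idempotent.

Detection uses an exact all-pairs scan up to 1000 atoms and a cell-list
neighbour search above; the cell list only restricts candidates (bins no
smaller than the cutoff, 27-neighbourhood lookup), so its accepted set is
bitwise identical to the brute-force path, and the tests assert exactly
that, as well as agreement with an independent 27-image brute-force
oracle on random boxes.

## Structure

RDFs are shell histograms of minimum-image pair distances normalised by
the per-frame ideal-gas expectation `P · (4/3)π(r₊³ − r₋³)/V` (with `P`
the number of counted ordered pairs), so an ideal gas gives g(r) = 1
identically; `r_max` may not exceed half the smallest box edge. Default
binning is 0.002 nm to 2 nm.

Contact maps condense many RDFs into 1–10 scores. Because by-eye scoring
is not reproducible, the package defines the mapping explicitly:
`1 + round(9·log10(gmax/g_floor)/log10(g_ceiling/g_floor))`, clipped to
[1, 10], with the floor at the homogeneous baseline g = 1 and the
ceiling at the largest maximum in the set (round-half-even, R's
`round`). Scores are therefore deterministic, order-independent, and
invariant under joint rescaling only when floor and ceiling are rescaled
alongside — a property the tests pin down. Published score maps built by
visual inspection are not expected to be reproduced number-for-number.

Dihedrals use minimum-image bond vectors and the standard atan2
construction with the IUPAC sign convention on (−180°, 180°]; a colinear
inner triplet makes the angle undefined, and such frames are skipped and
counted rather than poisoning the histogram. The exact atom quadruplets
that define glycosidic dihedrals in real force fields live in topology
files this package does not ship; quadruplets are therefore
configuration, with the model templates' backbone carbons as schematic
defaults. Radius of gyration is mass-weighted about the center of mass
after making the molecule whole by bond-graph traversal — PBC-split
molecules would corrupt both Rg and dihedrals.

## Rotational dynamics of OH groups

OH groups are written as O→H unit vectors; the package computes the
first-rank autocorrelation C(t) = ⟨u(t₀)·u(t₀+t)⟩ with every frame as a
time origin (FFT-based), and fits `exp(−t/τ)` over lags with C above
0.05 — a log-linear least-squares seed weighted by C², refined by one
nonlinear pass. τ is reported as the e-fold time of that fit; the common
"time to rotate by one radian" phrasing maps onto the same exponential
time constant. Whether first- or second-rank correlation functions (or
stretched exponentials) better describe real OH dynamics is not settled
by this choice: the rank and fit window are exposed, and a
non-decaying C(t) yields a flagged non-converged result rather than an
error. For isotropic rotational diffusion the ground truth is
C₁(t) = exp(−2·D_r·t), so τ = 1/(2·D_r); the tests require recovery
within 5% for D_r ∈ {0.01, 0.05, 0.2} rad²/ps.

The generator advances each vector by an *exact* rotation by angle
θ = |(δ₁, δ₂)| drawn in the tangent plane (δᵢ ~ N(0, 2·D_r·dt)). The
naive add-noise-and-renormalise update looks equivalent but biases the
decay rate by ≈ 5·D_r·dt relative — 10% at D_r·dt = 0.02 — which is
exactly the kind of estimator error the planted ground truth exists to
catch. Stability requires D_r·dt ≤ 0.1 (enforced); accuracy of the
planted decay wants D_r·dt ≤ 0.01.

## Free energies

**Langevin sandbox.** The free-energy stack is validated on overdamped
(Brownian) 1D dynamics with unit mass: friction in amu/ps, Gaussian
noise of per-step variance 2·k_BT·dt/friction, integrated with the
Leimkuhler–Matthews (BAOAB-limit) scheme, whose configurational averages
are second-order accurate in dt. Plain Euler–Maruyama inflates sampled
variances by the factor 2/(2 − k·dt/γ); at the step sizes that are
practical against the stiff quartic used below this alone breaks
Boltzmann-sampling checks, which is why the higher-order scheme is the
integrator and not an option. The standard sandbox potential is
`double_well(barrier = 10 kJ/mol, minima = c(0.4, 1.2) nm)` — a contact
well, a solvent-separated well and a ~4 k_BT barrier, with local
curvature ≈ 500 kJ/(mol·nm²) that dictates dt = 5·10⁻⁴ ps by the
stability criterion k·dt/γ ≪ 1.

**WHAM.** Binned self-consistent iteration with biases evaluated at bin
centers: `p_j = Σᵢ n_ij / Σᵢ Nᵢ e^{(f_i − b_ij)/k_BT}` and
`f_i = −k_BT log Σⱼ p_j e^{−b_ij/k_BT}`, iterated until the largest
change in any f_i falls below 10⁻⁸ kJ/mol (cap 10⁵ iterations, error on
exceedance), bin width 0.01 nm. Bins with fewer than `min_counts = 10`
pooled samples are dropped: a bin holding one or two samples carries
k_BT-scale noise in −k_BT·log n and is not a meaningful profile point.
The profile is zeroed at its largest-z reported bin. Window coverage is
checked and gaps are warned about with their location. At the study's
sandbox conditions (22 windows, k = 45 kJ/(mol·nm²), 2·10⁴ steps per
window) the recovered profile matches the analytic potential with RMSE
below 0.5 kJ/mol.

**Well-tempered metadynamics.** Deposits of width σ every `stride` steps
with height h₀·e^{−V_bias(z_t)/(k_B·ΔT)}, ΔT = (γ−1)·T, accumulated on a
grid (as PLUMED does) so the per-step cost is independent of the hill
count; each deposit is logged as PLUMED-style columns. Reconstruction is
F(z) = −γ/(γ−1)·V(z), shifted so min F = 0. At the study's hill
parameters (h₀ = 1.2 kJ/mol, σ = 0.05 nm, stride 500, γ = 50) the
tempering is weak — k_B·ΔT ≈ 121 kJ/mol dwarfs a 10 kJ/mol landscape —
so the endpoint estimate oscillates with roughly the hill height. The
`"time_average"` estimator (mean of the instantaneous surfaces over the
last half of the deposits, each aligned at its minimum) is the standard
converged-FES answer to that oscillation and is what the sandbox checks
use; the plain `"final"` sum remains the default and is what the exact
single-deposit value −(γ/(γ−1))·h₀ ≈ −1.2245 kJ/mol is asserted
against. A remaining σ-convolution bias (~½·V″σ² ≈ 0.6 kJ/mol at these
well curvatures) is intrinsic to the stated hill width. Whether recorded
HILLS heights are pre-scaled by the tempering factor differs between
engine versions; the reader takes a flag and records the interpretation
used.

**Binding free energy.** The ratio of Boltzmann integrals over bound and
unbound regions, trapezoidal quadrature, invariant under additive shifts
of w and stable under grid refinement (< 0.01 kJ/mol on halving the
step). No 4πz² volume Jacobian is applied by default — the convention
followed here defines the ratio directly on the 1D profile — but a flag
enables it for sensitivity checks. For real sugar-pair PMFs the
conventional boundary is 1.5 nm with pulls to 1.7 nm; for the symmetric
sandbox double well, whose quartic wall makes z > 1.45 nm unreachable,
the pipeline defaults the dividing surface to the barrier top between
the minima. The flat-profile closed form on [0.2, 1.7] nm with boundary
1.5, ΔG = −k_B·298·ln(1.3/0.2) ≈ −4.638 kJ/mol, is asserted to four
decimals.

**Averaging and depths.** Multi-pull averaging (the five-force-constant
convention: 45, 35, 55, 25, 15 kJ/(mol·nm²), one PMF per pull, then
`average_pmf()`) re-zeroes each profile at the plateau — the mean over
the last 5% of the z grid — interpolates to a common grid and reports
pointwise mean and spread. Pooling all windows into one WHAM is equally
available; both paths exist because either convention is defensible.
Depth reports take w at the first interior local minimum under the
plateau zero, rank labels deepest-first, and sum depths; monotone
profiles are flagged and excluded rather than silently contributing an
endpoint.

## The synthetic generators: what they do and do not emulate

Every generator is bit-reproducible under its seed, and all pipeline
randomness derives from one root seed through a per-stage FNV-1a split,
so study runs are deterministic end to end.

The model sugars are rigid 23-site templates — four backbone carbons,
two ring ether oxygens, a glycosidic ether and eight hydroxyls arranged
radially around two ring centers 0.6 nm apart — carrying the group label
set and, for trehalose, the symmetry classes. They are *not*
force-field-accurate conformers: they exist so that label-resolved
counting, symmetry averaging, selection and Rg/dihedral machinery can be
tested on realistic shapes. Mixtures place templates at random positions
and orientations with all inter-molecular atom distances ≥ 0.3 nm (the
random-placement rule of the study design). Because a random orientation
essentially never satisfies a 30° angular criterion, a configurable
fraction of molecules (defaults: 90% of waters, 35% of sugars, doubled
for clustered/preheated sugars) is instead placed as an *aligned donor*
to a randomly chosen placed oxygen at O···O ∈ [0.28, 0.32] nm — planted
bonds that any conventional criterion accepts. That yields
concentration trends with the right shape (water–water bonds growing
with water content, sugar–water peaking at intermediate concentrations,
more sugar–sugar bonding in clustered/preheated packings) while
remaining an emulation: there is no energetics, no dynamics and no
cooperativity in these configurations, so passing tests validate the
*estimators*, not any claim about real sugar solutions. The same applies
to the τ emulator, which maps water fraction linearly onto a rotational
diffusion coefficient between `D_r_dry = 0.02` and
`D_r_dilute = 0.2` rad²/ps (τ ≈ 25 → 2.5 ps) — chosen to give the
qualitative slow-down toward dry mixtures at desk-scale series lengths,
three orders of magnitude below the nanosecond correlation times of
real amorphous sugar matrices, which require the full force-field
trajectories this package does not run.

Problem sizes used by the tests and the acceptance script — 22 × 2·10⁴
umbrella steps, 10⁶ metadynamics steps, 200 vectors × 5000 rotational
steps, 1000 ideal-gas atoms × 100 frames, pipeline studies of a few
molecules over a handful of frames — were chosen as the smallest sizes
at which the stated tolerances are comfortably resolved.

## Interfaces and degenerate inputs

GRO files are parsed by fixed columns with line-numbered errors;
molecule kinds come from residue names through an overridable map. The
multi-frame trajectory format is an XYZ dialect whose comment line
carries `time=<ps> box=<lx>,<ly>,<lz>`; non-increasing times and missing
boxes are format errors. HILLS and umbrella series are whitespace-column
text round-tripped by `write_hills()`/`read_hills()` and
`write_umbrella_series()`/`read_umbrella_series()`; PMFs write as
XVG-compatible two-column text. Study configs are YAML or R lists,
schema-validated with unknown keys rejected by name; reports serialise
to JSON at double precision and round-trip through
`read_study_report()`. Degenerate inputs follow one rule: states a
caller can reasonably reach carry flags (non-converged τ, monotone
profiles excluded from depth sums, failed pipeline stages recorded while
others continue), while contract violations (empty trajectories,
mismatched grids, triclinic boxes, boundary outside a PMF grid) are
errors that name the offending quantity.

## Known limitations

- The estimators are validated on emulated data only; no force-field
  energetics, no NPT volume fluctuations, no bond constraints.
- Orthorhombic cells only; no XTC/TRR binary parsing.
- The metadynamics σ-convolution bias is not deconvolved; with stiff
  wells and σ = 0.05 nm, expect ~0.5 kJ/mol systematic softening at the
  well walls.
- The hydrogen-bond definition is purely geometric; energetic or
  quantum-chemical definitions, and bond lifetime kinetics, are out of
  scope.
- Per-group hydrogen-bond counting requires disjoint groups, mirroring
  the standard engine limitation; overlapping group schemes are
  rejected.
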