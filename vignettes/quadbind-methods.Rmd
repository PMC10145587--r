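---
title: "quadbind: restraint-based absolute binding free energies — models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{quadbind methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadbind)
```

## The problem

Absolute standard binding free energies of a ligand to a nucleic-acid
receptor — here the motivating system is a G-quadruplex (G4) formed by the
insulin-linked polymorphic region with tetracationic porphyrin ligands —
can be computed from biased simulations via a thermodynamic cycle:

1. **Restrain** the bound ligand's position and orientation with a
   Boresch-style six-degree-of-freedom harmonic restraint (one distance
   $r$, two angles $\theta, \Theta$, three dihedrals $\phi, \Phi, \Psi$
   over three receptor anchors $a,b,c$ and three ligand anchors $A,B,C$),
   switching the restraint on over a schedule of coupling values
   $\lambda \in [0,1]$. The free-energy cost $\Delta G_{restr}^{bound}$
   is estimated by the Bennett acceptance ratio (BAR).
2. **Pull** the restrained ligand along the anchor distance $R_{aA}$
   through a ladder of harmonic umbrella windows; the weighted histogram
   analysis method (WHAM) reconstructs the potential of mean force (PMF)
   $w(r)$, whose value at the dissociation plateau $r^*$ gives the depth
   term $-w(r^*)$.
3. **Integrate** the bound well: the volume term
   $-k_BT \ln \left[\int_{bound} e^{-w(r)/k_BT} dr \, (2\pi k_BT/k_r)^{-1/2}\right]$
   corrects for the width of the bound basin relative to the pulling
   restraint.
4. **Release** the restraints in bulk analytically at the 1 M standard
   state (rigid-rotor closed form), giving $\Delta G_{restr}^{bulk}$.

The total is
$$\Delta G^{\circ}_{bind} = -\Delta G_{restr}^{bound} - w(r^*)
 - k_BT\ln\!\left[\int_{bound} e^{-w(r)/k_BT} dr\,(2\pi k_BT/k_r)^{-1/2}\right]
 + \Delta G_{restr}^{bulk},$$
with uncertainties combined in quadrature. `quadbind` implements every
analysis step downstream of the molecular-dynamics engine, plus a
Metropolis Monte Carlo toy sampler that generates Boltzmann-distributed
synthetic data with known ground truth, so that every estimator can be
validated end to end without MD.

The methodological refinement the package also implements is
*RMSF-based restraint-atom selection*: for large flexible ligands
(a porphyrin carrying four glycol arms, say) restraint anchors are chosen
among heavy atoms of a user-declared rigid region ranked by
root-mean-square fluctuation — restraining the most mobile atoms *of the
rigid core* suppresses exactly the fluctuations that otherwise stall
convergence, while the flexible arms stay unrestrained.

## Units and constants

Coordinates are in ångström, energies in kcal/mol, angles in radians,
temperature in kelvin. Force constants are accepted in the units MD
packages print — kJ mol⁻¹ nm⁻² for distances (1 kJ mol⁻¹ nm⁻² =
0.0023901 kcal mol⁻¹ Å⁻²) and kJ mol⁻¹ rad⁻² for angles — and converted
on input. $k_B$ = 0.0019872041 kcal mol⁻¹ K⁻¹; the 1 M standard state
corresponds to 1660.54 Å³ per molecule. Published angular force-constant
units of the form "kJ rad⁻¹ mol⁻¹" are interpreted as the harmonic
constant kJ mol⁻¹ rad⁻².

## The toy sampler as the stated world

`sample_boltzmann()` is a Metropolis random-walk chain (uniform
proposals, exact stationary distribution $\propto e^{-(V+bias)/k_BT}$)
over four analytic potential families: flat (bounded), harmonic, double
well, and a continuous piecewise-linear PMF used to emulate realistic
dissociation profiles (deep minimum near 6.5 Å, shoulder, plateau beyond
20–25 Å). "Time" is the sample index. Defaults follow the conventional
umbrella protocol: 1 Å window spacing, 1000 kJ mol⁻¹ nm⁻² force
constant, 300 K, burn-in 10% of the chain, per-window sub-seeds derived
deterministically from one master seed. The chain core is compiled
(Rcpp) and draws from R's RNG, so `set.seed()` reproducibility holds
bit-for-bit.

What the generator emulates: Boltzmann statistics under harmonic biases
and linearly coupled restraints, window-to-window overlap, sampling
autocorrelation (through the random-walk kernel). What it does not
emulate: molecular force fields, solvent, kinetic trapping between
binding modes, or correlated multidimensional motions. A green test
therefore establishes estimator correctness — not force-field accuracy
or MD convergence on any real complex.

The λ-coupling generator restricts the toy restraint to a harmonic form,
because linear coupling $\lambda U_{restr}$ of a harmonic restraint is
itself exactly a harmonic bias, which the sampler supports natively.
The BAR module's contract is unaffected: it consumes arbitrary
energy-difference samples.

## BAR

`bar_pair()` solves Bennett's implicit self-consistency equation by
bisection (the imbalance function is monotone), to 10⁻⁸ kcal/mol by
default, and reports the asymptotic variance evaluated at the solution.
A block-averaging option coarsens the Fermi weights over contiguous
blocks before the variance is taken, for correlated input. This is a
deliberate substitution: the original protocol quotes errors "based on
the fluctuation of ∂H/∂λ" as implemented inside its MD package, a
formula that is not published; the asymptotic BAR variance with
quadrature chaining is the standard, reproducible alternative. Whether
the published errors include autocorrelation corrections is unknown and
not guessed.

Poor phase-space overlap is flagged when the forward-work and
negated-reverse-work samples share no range at all; the estimate is
still returned, with `overlap_warning = TRUE`.

## WHAM

`wham_solve()` iterates the standard self-consistency equations
directly, with three numerical choices worth recording:

- **Bin-averaged bias factors.** The bias Boltzmann factor
  $e^{-U_i(r)/k_BT}$ is averaged over each bin (11-point rule) rather
  than evaluated at the bin center. On steep PMF walls (tens of
  $k_BT$/Å in the double-well validation suite) center evaluation
  introduces a discretization bias of order $(s\Delta)^2$ that is
  visible at $n = 10^5$ samples per window; bin averaging removes the
  leading term.
- **Support trimming.** The dominant connected run of populated bins is
  analyzed; stray fragments carrying < 1% of the samples (single
  outlier excursions) are dropped, while genuine disconnection (> 1%
  stranded) raises an error naming the gap.
- **Per-bin errors.** The default is the Poisson counting error
  $k_BT/\sqrt{n_{eff}}$, with each window's counts deflated by the
  statistical inefficiency $g = 1 + 2\tau$ estimated from its
  autocorrelation. This neglects the uncertainty of the window offsets
  $F_i$ and under-reports by roughly 40% (measured against seed-to-seed
  scatter over 20 independent synthetic runs). For calibrated bars,
  `stderr_method = "bootstrap"` runs a moving-block bootstrap (block
  length ≈ 5g) over every window's series and re-solves WHAM per
  replicate; its calibration ratio against seed-to-seed scatter is
  ≈ 1.1. Validation tests use the bootstrap bars.

Analysis bin width defaults to 0.1 Å (ten bins per conventional 1 Å
window spacing). For validation against analytic potentials at large
$n$, widths follow an a-priori rule — about one third of the narrowest
window's Gaussian width, commensurate with any hard support bounds — so
that the residual discretization bias stays below the statistical error.
The oracle in those tests is the *binned* Boltzmann expectation (direct
quadrature of the generating potential over each bin), which is what a
histogram estimator converges to.

**Plateau detection.** $r^*$ is the smallest coordinate beyond the PMF
minimum from which the least-squares slope of $w$ over the next
`tail_span` (default 3 Å) stays below `slope_tol` (default
0.05 kcal mol⁻¹ Å⁻¹) all the way to the end of the profile. A
regression slope over the full span is used because bin-to-bin finite
differences are dominated by statistical noise at realistic error-bar
sizes.

**Depth errors by trajectory splitting.** `error_by_split()` repeats
the full WHAM + depth evaluation on the two halves and the four
quarters of every window's series and reports the larger of the two
standard deviations — the conservative convention for split-trajectory
error bars. On synthetic data its mean estimate brackets the true
seed-to-seed scatter within a factor of two.

**Bound region.** The published protocol writes the bound-state
integral without limits. `bound_volume_term()` defaults to integrating
from the profile start to the first coordinate past the minimum where
$w$ has risen to within 2 kcal/mol of $w(r^*)$; the region is
configurable. For a PMF exactly harmonic with curvature $k_r$ the term
vanishes by construction; with curvature $4k_r$ it equals
$+k_BT\ln 2$; both closed forms are tested.

## Restraint geometry and the bulk correction

The geometric definitions follow the Boresch convention:
$r = |aA|$, $\theta = \angle(b,a,A)$, $\Theta = \angle(a,A,B)$,
$\phi = dih(c,b,a,A)$, $\Phi = dih(b,a,A,B)$, $\Psi = dih(a,A,B,C)$,
with dihedrals via `atan2` and differences wrapped to $(-\pi,\pi]$.
Reference values are ensemble averages from unconstrained frames —
arithmetic means for $r,\theta,\Theta$ and circular means for the
dihedrals (a resultant length below 0.1 makes the circular mean
meaningless and is an error, not a guess).

The bulk standard-state correction is the rigid-rotor closed form
$$\Delta G_{restr}^{bulk} = k_BT \ln\!\left[
  \frac{8\pi^2 V_0}{r^{*2}\sin\theta_0\sin\Theta_0}
  \frac{\sqrt{k_r k_\theta k_\phi k_\Theta k_\Phi k_\Psi}}
       {(2\pi k_BT)^3}\right].$$
The source typesetting of this expression is ambiguous; the form above
is the standard one, and its sign convention (positive, entering the
total with $+$) is validated against the published worked example:
with all six constants at 1000 (MD units), $T = 300$ K, $r^* = 20$ Å
and unit reference-angle sines it evaluates to 9.513 kcal/mol against
the printed 9.43. Exact reproduction is impossible because the
reference angles $\theta_0, \Theta_0$ of the published systems were
never printed; the ≈ 0.08 kcal/mol gap is fully absorbed by
$\sin\theta_0\sin\Theta_0 \approx 0.87$, i.e. angles ≈ 70–110°, which
is geometrically plausible but unverifiable. For the same reason the
direction of the published 9.43 → 9.54 change between the two ligand
systems cannot be separated into its $r^*$ (20 → 22.5 Å contributes
$-2k_BT\ln(22.5/20) = -0.14$) and angle contributions.

## RMSF-based restraint selection

`kabsch_superpose()` (SVD, determinant-corrected proper rotations) fits
frames on a configurable selection — by default receptor heavy atoms,
which isolates ligand motion relative to its binding site when ligand
RMSF is the quantity of interest. `rmsf()` supports both a bound-frame
reference and the ensemble mean. `select_restraint_atoms()` then ranks
heavy atoms *inside a user-declared rigid region* by RMSF (descending
for the ligand triple) and scans ranked triples in lexicographic order,
accepting the first that satisfies a minimum pairwise separation
(default 2 Å) and internal angles within 20–160°; ties break by
(RMSF, atom name, residue id), making the selection deterministic.

Two points are package design choices rather than published rules: the
rigid region is user-declared (the original analysis identified it by
inspection; automating that would be invention), and the receptor
anchor triple is ranked by *ascending* RMSF — the published rule only
covers the ligand side, and stable receptor anchors are the natural
complement. The published protocol also gives no quantitative
threshold for "larger RMSF"; ranking plus geometric constraints is the
documented interpretation.

## Contact metrics

Hydrogen bonds use the printed geometric rule verbatim, as strict
inequalities: donor–acceptor distance below 3.5 Å AND
donor–hydrogen–acceptor angle above 150°, intermolecular pairs only
(molecules are partitioned by ATOM/HETATM record, falling back to
chains). Donors default to N/O heavy atoms with an attached hydrogen
(X–H bond < 1.25 Å within the residue); acceptors to N/O. The original
analysis used a visualization tool's defaults, which are re-specified
here explicitly and are overridable. No periodic imaging is applied —
frames are assumed whole.

An arm of a multi-armed ligand counts as groove-bound when the minimum
distance from its terminal ether oxygen to any quartet guanine nitrogen
is below 3.5 Å (strict).

## Error propagation and affinity conversion

Totals combine the four signed components; uncertainties add in
quadrature. Quadrature is a package decision — the published protocol
does not state its rule — validated by reproducing both published total
uncertainties (0.59 and 0.43 kcal/mol) from the printed component
errors. "Room temperature" is fixed at 300 K, the simulation
temperature. Association constants are $K_a = e^{-\Delta G/k_BT}$ per
1 M. One published rounding wrinkle: the printed total −11.50 kcal/mol
converts to 0.2389 nM⁻¹, while the published table prints 0.240 — the
published conversion evidently used the unrounded total (−11.504
reproduces 0.240 exactly). Tests therefore match that value to one unit
in its last printed digit. The other printed values (0.005 nM⁻¹; the
"ca. 50-fold" ratio, which evaluates to 49) reproduce directly. A
second published inconsistency is recorded here for completeness: the
running text quotes the weaker binder's total error as ±0.48 while the
table prints ±0.43; the package's worked examples follow the table.

## End-to-end validation

The `full-report` pipeline (BAR chain → WHAM → plateau → depth + volume
→ analytic bulk term → assembly) is validated on a synthetic complex
whose every term is known analytically: a piecewise PMF with a 9
kcal/mol well at 6.5 Å and a plateau beyond 20 Å, umbrella windows
every 1 Å at 1000 kJ mol⁻¹ nm⁻², and a harmonic restraint switched on
over λ ∈ {0, 0.25, 0.5, 0.75, 1}. The recovered ΔG°bind agrees with the
quadrature ground truth within three reported standard errors plus a
0.2 kcal/mol systematic allowance (binning and plateau placement). A
reassuring physical detail the synthetic system reproduces: a slightly
early $r^*$ estimate lowers $-w(r^*)$ but also lowers the bulk term,
so the total is less sensitive to $r^*$ than either term alone — the
same partial cancellation the published protocol relies on when it
calls the choice of $r^*$ "to some extent ambiguous".

## Known limitations

- One-dimensional PMFs only; no umbrella integration, no MBAR.
- The toy sampler is not an MD engine; agreement on synthetic data does
  not certify any force field or sampling protocol on real systems.
- Published headline MD observables (receptor RMSD ≈ 4.5 Å, 2–3
  groove-bound arms, the exact PMF curves) require the original
  trajectories and are represented here only by qualitative synthetic
  fixtures.
- Histogram WHAM carries an $O(\Delta^2)$ discretization bias on steep
  walls even after bin averaging; validation chooses bin widths
  accordingly, and users analyzing very stiff profiles should too.
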