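---
title: "Methods: polarized-charge MM/PBSA at desk scale"
author: "polarbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polarized-charge MM/PBSA at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the numerical choices behind them, what the synthetic fixtures
do and do not emulate, and the design decisions taken where more than one
defensible convention exists. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The binding free-energy model

`polarbind` implements the single-trajectory end-state decomposition

$$\Delta G_{bind} = \Delta E_{ele} + \Delta E_{vdW} + \Delta G_{pol}
  + \Delta G_{nonpol} - T\Delta S .$$

Complex, receptor and ligand coordinates are all taken from the same
trajectory frame, so every intramolecular bonded and nonbonded term cancels
exactly in the binding difference; the package therefore only ever computes
*intergroup* gas-phase terms (`groupInteraction()`), never intramolecular
ones. This is both the usual practice and a substantial variance reduction,
at the cost of ignoring ligand/receptor relaxation.

Sign conventions: the entropy column `TdS` produced by `runCondition()` is
the *binding-opposing* contribution, i.e. $-T\Delta S_{bind}$, which is
positive for an associating pair, and `total = sub_total + TdS`. Published
decomposition tables that print this column with a minus sign in some rows
while their totals require the positive value are treated as carrying a
typographical sign; `assembleTotal()` documents and applies the consistent
convention.

### Gas-phase terms

Coulomb sums use $k = 332.0636$ kcal·Å/(mol·e²) and no cutoff or screening.
Lennard-Jones parameters are stored AMBER-style as `rmin/2` and `epsilon`
with Lorentz–Berthelot combining ($r_{min,ij} = r_{min,i}/2 + r_{min,j}/2$,
$\varepsilon_{ij} = \sqrt{\varepsilon_i\varepsilon_j}$); conversion from a
$\sigma/\varepsilon$ convention is $r_{min} = 2^{1/6}\sigma$. No 1-4
scaling exists because no intramolecular nonbonded term is ever formed in
binding energies.

### Polar solvation

`solvePB()` discretizes $\nabla\cdot(\varepsilon\nabla\phi) = -4\pi k\rho$
(linear, zero ionic strength) on a node-centred grid with spacing exactly
`1/gridDensity`, trilinear charge spreading, face-centred dielectrics, and
Dirichlet boundary values from solvent-screened atomic monopoles. The
dielectric boundary is the solvent-excluded region built by probe
inflate/deflate on the grid: a point is interior if it lies in a van der
Waals sphere, or in the probe-inflated union with no solvent-accessible
exterior lattice node within one probe radius. Relaxation is red–black SOR
(compiled) with $\omega = 2/(1+\sin(\pi/\max(\text{dims})))$, converged on
the relative residual (default $10^{-6}$).

$\Delta G_{pol}$ is always the *two-solve* difference
$\tfrac12\sum_i q_i[\phi_{solv}-\phi_{ref}](r_i)$ on one grid with one
charge spreading, so the (large, spacing-dependent) grid self-energy
cancels identically; and in binding differences the complex, receptor and
ligand are solved on the complex's grid for the same reason. The test suite
validates the solver against the analytic Born ion
($\Delta G = -\tfrac{k}{2}(1-1/80)q^2/a = -81.98$ kcal/mol for
$q=1, a=2$ Å) within 5% at 4 grids/Å, with the error decreasing from 2 to
4 grids/Å, and checks Gauss's law on the induced surface charge
($\sum q_b \approx -q(1-1/80)$).

Defaults follow standard implicit-solvent practice: $\varepsilon_{in}=1$,
$\varepsilon_{out}=80$, probe 1.4 Å, 4 grids/Å, 10 Å padding. Tests and the
acceptance script run fixtures at 2 grids/Å with 4–5 Å padding — a
deliberate scale-down that keeps a full condition matrix in minutes; the
Born validations quantify the cost (≈4% at 2 grids/Å versus ≈0.3% at 4).

The fixtures carry their own Poisson–Boltzmann radii (Bondi-like values per
element); no claim is made about matching any particular published radii
set, and runs on real structures must document that choice.

### Nonpolar solvation

`sasa()` is Shrake–Rupley counting on deterministic Fibonacci sphere points
(default 960/atom; single-sphere closed form reproduced within 1%), and
`nonpolarEnergy()` applies $\gamma\,\mathrm{SASA} + \beta$ with
$\gamma = 0.00542$ kcal/(mol·Å²), $\beta = 0.92$ kcal/mol. The $\beta$
offsets cancel in complex − receptor − ligand differences, so binding uses
$\gamma\,\Delta\mathrm{SASA}$ only. Because the sphere points are fixed in
the lab frame, SASA is rotation-invariant only to sampling error (≈0.2% at
960 points) — relevant when comparing frames that differ by a global
rotation.

### Entropy

`minimizeStructure()` (L-BFGS-B with the analytic gradient of the toy force
field: harmonic bonds/angles plus all nonbonded pairs excluding 1-2/1-3)
precedes `normalModes()`: a central-difference Hessian of the analytic
gradient, mass-weighted, with the six rigid-body modes projected out, and
eigenvalues converted to cm⁻¹. `entropyTerms()` assembles Sackur–Tetrode
translation (1 atm standard state), classical rigid-rotor rotation
(symmetry number 1), and *quantum* harmonic-oscillator vibration — the
convention of normal-mode entropy modules in MM/PBSA codes. The diatomic
fixture validates the frequency against
$\nu = \frac{1}{2\pi c}\sqrt{k'/\mu}$ to 0.1% and the monatomic entropy
against the closed form to $10^{-6}$.

Entropy snapshots default to 20 evenly spaced over the analysis window; the
per-snapshot values are averaged with their standard deviation. At test
scale, minimizing the 71-atom complex costs ~15 s per snapshot in pure R,
so the suite and acceptance script use 1–2 entropy snapshots — a stated
scale-down, not a change of method.

## 2. The polarized-charge loop

`scfPPC()` derives conformation-specific polarized charges:

1. `fragmentSolute()` cuts the protein into residue fragments with
   conjugate caps (C, O of the preceding residue; N, H, CA of the
   following), the ligand being one capless fragment. Cap charges are
   fitted but discarded on assembly; cores partition the solute, and each
   fragment carries an integer net-charge target.
2. For each fragment, the external potential at its atom sites is the
   Coulomb field of all other fragments' current charges (Gauss–Seidel:
   fragments already refitted in the sweep contribute updated values) plus
   the solvent reaction field.
3. The surrogate electronic model responds, the responded fragment is
   RESP-fitted, and the core charges enter the global set.
4. The Poisson–Boltzmann equation is re-solved with the assembled set,
   refreshing the reaction field and its induced surface charges.
5. Iterate until the largest per-atom change drops below `tol`
   (default 10⁻³ e); convergence on the fixtures takes 4–6 iterations, the
   regime reported for the quantum-mechanical original. Oscillation
   (non-decreasing steps over three iterations) switches on 0.5 mixing.

### The surrogate electronic model

The quantum-chemistry fragment calculation is out of scope by design; its
interface is preserved so a QM backend could drop in. The surrogate is a
*bond charge-flow* linear response: for each covalent bond $i$–$j$ inside a
fragment, electron density flows along the bond toward higher external
potential, $f_{ij} = \alpha\,(V_i - V_j)$ subtracted from $q_i$ and added
to $q_j$. This kernel was chosen over a mean-centred per-atom response
after the latter proved to shuffle charge among buried amide atoms in ways
that could *weaken* a hydrogen bond's four-atom Coulomb statistic even as
the physical field strengthened — the charge-flow form is the
electronegativity-equalization picture of polarization, conserves each
fragment's total charge exactly (pairwise antisymmetry), and reproduces the
qualitative electronic response of hydrogen bonds: the donor H, sitting in
the negative potential of the acceptor O, becomes more positive; the
acceptor O deepens.

The default $\alpha = 0.001$ e²·Å/kcal was fixed a priori at the value
giving (i) charge shifts of a few hundredths of an e at hydrogen-bonding
atoms, the scale separating polarized from standard force-field charge
sets, and (ii) a fragment-coupling spectral radius comfortably below 1, so
the loop contracts in the 4–6-iteration regime; several-fold larger values
approach the stability boundary of any such self-consistent scheme.

Two numerical choices matter here. First, the solvent background entering
step 2 is the grid reaction-field potential interpolated at atom sites, not
a Coulomb sum over the discrete induced surface charges: the two represent
the same field (the Born-ion tests show the surface charges reproduce the
reaction potential within 5%), but voxel-placed point charges are
$1/r$-noisy within about two grid spacings of exposed atoms, exactly where
the response is evaluated. The discrete charges are still computed and
returned every cycle. Second, each fragment's *own* reference reaction
field is subtracted from the background it responds to (one per-fragment
solve at the reference charges, cached for the conformation): in the real
method the fragment's self-solvation is inside the quantum step, whose
chemical hardness resists charge inflation, and a bare linear kernel made
to respond to its own Born-like self-field double-counts it and inflates
the charges of solvent-exposed atoms.

### RESP

`respFit()` minimizes the squared ESP misfit on Connolly shells (1.4×,
1.6×, 1.8×, 2.0× van der Waals, Fibonacci points, nothing inside any
atom's 1.4× shell) plus a harmonic restraint $\lambda\sum(q-q_{ref})^2$
toward the reference charges, under a hard net-charge constraint eliminated
by block substitution (the raw KKT matrix mixes $O(\|A\|^2)$ and $O(1)$
rows and is numerically singular). The canonical hyperbolic restraint is
deliberately not implemented — the harmonic form keeps the fit one linear
solve — and $\lambda$ defaults to $5\times10^{-4}$.

## 3. Trajectory metrics and hydrogen bonds

`kabschSuperpose()` is the SVD least-squares superposition with the
determinant correction (proper rotations only). `rmsf()` superposes on the
iterated mean structure (superpose → average → re-superpose, two passes),
on the same selection being measured, with equal weights by default and
mass weighting by flag; per-residue reporting aggregates by RMS. The
reference convention for fluctuations (trajectory mean versus crystal
structure) is genuinely ambiguous in the literature; the iterated mean is
this package's documented choice.

Hydrogen bonds use the donor–acceptor heavy-atom distance (≤ 3.5 Å) with
the donor–H–acceptor angle (≥ 120°), both cutoffs inclusive (boundary
values count, with a $10^{-9}$ guard against last-digit rounding). The
bond-energy statistic is the vacuum Coulomb energy over the four
(C,O)×(N,H) pairs — even in the charges, $E(q) = E(-q)$ — and per-bond
mean energies average over *all* frames, bound or broken; whether published
per-bond averages condition on the bound state is unknowable from the
tables alone, and the all-frames mean is the stated convention here.
Native-bond fractions are block averages (default 100 frames) of the count
of native-frame bonds still present divided by the native total.

## 4. The synthetic world

The generators are pure functions of their arguments; a fixed seed gives
byte-identical files.

* `born_ion` — one +1 e ion of radius 2 Å: the analytic solvation case.
* `dimer` — a CO-like harmonic diatomic (k = 350 kcal/mol/Å², r₀ = 1.1 Å,
  ±0.5 e): closed-form minimization and normal-mode cases.
* `mini_helix` — an ideal α-helical backbone (φ = −57°, ψ = −47°, five
  atoms N/H/CA/C/O per residue) whose i→i+4 amide bonds (3.09 Å, 165° as
  built) form the intra-protein backbone network.
* `toy_complex` — a 12-residue extended peptide whose same-face amide
  groups anchor a small ligand placed to form exactly three receptor–ligand
  hydrogen bonds (2.90–2.91 Å, 180°): one receptor N–H donating to a ligand
  carbonyl and two ligand amides donating to receptor carbonyls — the
  serine/glycine-to-ligand motif of a thrombin-style site. Anchor residues
  are chosen by maximizing the alignment of outward amide vectors, with a
  clash guard; the generator fails loudly rather than emit bad geometry.

Charges are integer per fragment (backbone amide charges AMBER-like, split
so the C,O and N,H,CA groups each sum to zero, keeping conjugate-cap
fragments integer even at termini). Each fixture ships a `base` and a
`polarized` charge set; the polarized set scales the designed
hydrogen-bonding atoms by the factor 1.2 (a realistic ~20% amide
polarization) and renormalizes each fragment over its remaining atoms, so
every designed bond's four-atom energy scales by exactly 1.2² — the
construction guarantees strict strengthening.

Trajectories are the native structure plus iid Gaussian jitter (default
σ = 0.1 Å per coordinate, giving sub-Å backbone RMSD like a stable
simulation) with scripted rupture: from the scheduled frame on, the bond's
moving group (ligand-side atoms, or the acceptor C/O for intra-protein
bonds) is displaced 3 Å along the donor–acceptor axis — clearing the 3.5 Å
cutoff from a 2.9 Å native distance with margin, so occupancies equal the
schedule arithmetic exactly.

What a green test does *not* establish: the fixtures have no side chains,
no torsional force field, no real conformational dynamics, and no water
structure; jitter is uncorrelated, whereas real fluctuations are not. The
fixture totals are dominated by the entropy penalty because the toy ligand
is held by three hydrogen bonds alone. Agreement of the machinery with its
oracles here says nothing about force-field accuracy on a real complex —
that is precisely the question the full method exists to probe.

## 5. Degenerate inputs, tie-breaks, tolerances

* Collinear point sets make superposition ill-posed → error, not a silent
  reflection. The SVD determinant correction forbids improper rotations.
* Zero native hydrogen bonds under the criteria → error (a fraction would
  be 0/0).
* Snapshot extraction is endpoint-inclusive near-even spacing
  (`round(seq(first, last, length.out = n))`), deterministic; the default
  window is the final half of the trajectory ("after equilibrium").
* A condition run tolerates up to 5% failed snapshots (recorded), then
  fails.
* Waters and monatomic ions parse as segment `other` and are excluded from
  every energy term; residue numbering is never rewritten.
* PB non-convergence reports the residual; normal modes at a non-stationary
  point warn at 10× the minimizer tolerance and refuse saddle points
  (imaginary modes after projection).
* The per-residue polar/nonpolar attributions are linear
  (½·q·Δφ per atom, γ·ΔSASA per atom) and sum to the whole-system terms to
  well within the 2% attribution tolerance; gas-phase attributions sum
  exactly.

## 6. Known limitations

* Nonlinear PB, salt screening, multigrid acceleration and analytic
  molecular surfaces are out of scope; the voxelized solvent-excluded
  surface converges with grid density but is not an analytic SES.
* The entropy term uses the toy bonded force field; real normal-mode
  entropies require the full force field and minimized real geometries.
* The surrogate electronic model is a one-parameter linear response. It is
  an architecture stand-in with the right conservation laws and qualitative
  directions, not an electronic-structure method; quantitative charge
  magnitudes from it should not be interpreted.
* The command-line layer is a thin wrapper over the exported functions; the
  package API is the primary interface.
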