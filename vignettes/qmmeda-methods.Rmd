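---
title: "Decomposing solute-solvent interaction energies under QM/MM embedding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing solute-solvent interaction energies under QM/MM embedding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmmeda)
```

## The problem

How many explicit solvent molecules must be treated quantum mechanically
before a QM/MM description of a solvated ion reproduces the
solute-solvent interaction energy of a large-QM-region reference?  To
answer that question per *physical component* rather than only for the
total, `qmmeda` implements an energy decomposition analysis (EDA) that
remains well defined when part of the solvent is described by a molecular
mechanics (MM) point-charge or induced-dipole embedding.  Fragment A is the
solute; fragment B is the *entire* solvent - its closest waters treated
quantum mechanically and the remainder as MM sites merged into fragment B's
nuclear potential.

## The decomposition

For two closed-shell fragments at a fixed geometry, the interaction energy
is the counterpoise-corrected supermolecular difference

$$\Delta E = E_{AB} - E_A^{AB} - E_B^{AB},$$

where both fragment energies are computed in the full complex basis (ghost
functions on the absent fragment's atoms).  Three single-point SCF states
are computed: the complex, fragment A (with B's ghost basis, no MM), and
fragment B (with A's ghost basis and the MM potential).  From the fragment
occupied orbitals a *frozen antisymmetrised state* is built by symmetric
(Löwdin) orthogonalisation of the concatenated occupied blocks; its energy
under the full Hamiltonian defines the intermediate reference.  The
components are then

* **electrostatic**: the classical Coulomb interaction of the unperturbed
  fragment charge distributions - nuclear cross-repulsion, nuclear-electron
  attraction both ways, the Hartree cross-term, and (with an MM region) the
  solute-nuclei/MM term, with B's nuclear potential replaced by the merged
  QM/MM potential;
* **Pauli**: $E_{\mathrm{frozen}} - E_A - E_B - E_{\mathrm{elec}}$, the
  antisymmetrisation (exchange + repulsion) cost.  The two contributions are
  evaluated jointly as a determinant energy difference; no interfragment
  exchange density is materialised;
* **polarization**: $E_{AB} - E_{\mathrm{frozen}}$, the variational orbital
  relaxation from the frozen determinant (always $\le 0$).

The three components sum to $\Delta E$ *identically*; the residual against
the independently accumulated supermolecular difference is reported as
`closure_residual` and is at numerical round-off (well below
$10^{-3}$ kcal/mol) at the default SCF tolerances ($10^{-10}$ hartree,
$10^{-8}$ RMS density).

### Induction and dispersion

At second-order perturbation level, polarization separates exactly into
induction (response to the partner's static field) and dispersion
(correlated fluctuations).  `qmmeda` extracts induction from constrained
fragment relaxations: each fragment is re-solved in the *frozen*
electrostatic potential of its partner (nuclear attraction + Hartree
potential of the unperturbed partner density, plus the MM potential on the
solvent side).  With the fragment polarization densities
$\Delta\rho_{\mathrm{pol}}^{A,B}$ this yields the charge-induction energy

$$E_{\text{ch-ind}} = \int \Delta\rho_{\mathrm{pol}}^A\, \hat v_B
  + \int \Delta\rho_{\mathrm{pol}}^B\, \hat v_A,$$

and the induction energy as interaction plus internal deformation cost,
$E_{\mathrm{ind}} = E_{\text{ch-ind}} + E_{\mathrm{intra}}^A +
E_{\mathrm{intra}}^B$.  In the linear-response regime this equals
$\tfrac12 E_{\text{ch-ind}}$ - the classical result that half of the
induction energy is spent deforming the responding system.  Both routes are
evaluated; their discrepancy is serialised in `induction_diagnostics` and
flagged (not raised) beyond 1% or 0.05 kcal/mol, since strong interactions
take the split outside second order.  Dispersion is defined as the exact
remainder $E_{\mathrm{disp}} = E_{\mathrm{pol}} - E_{\mathrm{ind}}$; when
$|E_{\mathrm{ind}}| > |E_{\mathrm{pol}}|$ the second-order caveat is flagged
in the result metadata.  Positive induction values, which do occur for
small QM regions, are reported as-is.

Two design choices deserve emphasis:

* **Sum-over-states is not materialised.**  The perturbative first-order
  density split is realised at mean-field level by the constrained
  relaxations; no excited-configuration enumeration is performed.  The
  construction is validated against the closed-form classical limit
  ($-\tfrac12\alpha E^2$ for a polarizable fragment in a weak field, with
  the polarizability measured independently from the dipole response) and
  the half-rule.
* **Relaxation uses the fragment's own AO subspace.**  An unconstrained
  relaxation in the partner's frozen potential is variationally unstable:
  the partner's nuclear wells are not Pauli-protected (the frozen potential
  carries no exchange), so electrons would collapse onto the ghost basis
  functions sitting there.  Restricting the relaxation to the fragment's
  own basis functions keeps the response intrafragment, which is exactly
  the content of the perturbative density split.  The main EDA components
  remain fully ghost-padded (counterpoise-consistent); the monomer-basis
  choice affects only where the polarization energy is cut into induction
  and dispersion, and the remainder definition keeps their sum exact.

## QM/MM embedding

The MM region enters as a one-electron potential from fixed atomic charges;
induced atomic dipoles (a polarizable force field's output, frozen at their
simulation values) are represented as charge pairs $\pm|\mu|/d$ at
$R \pm (d/2)\hat\mu$.  The default separation is $d = 10^{-3}$ Å, validated
at EDA time against $0.1\times$ the shortest QM-MM distance; the pair
potential converges to the analytic point-dipole potential as $O(d^2)$.
The unphysical intra-pair self-energy is never evaluated - only MM-to-QM
potentials and nuclei-MM cross terms enter.  The MM region attaches to the
solvent fragment only: B's nuclear potential is merged with the MM
potential in every integral, and the solute-nuclei/MM Coulomb term is added
to the electrostatic component.  Mutual QM/MM repolarisation is out of
scope by construction: dipoles are inputs, not variables.  An empty MM
region is bit-identical to a pure-QM run.

## The electronic-structure backend

The package carries its own restricted Hartree-Fock engine: contracted
Cartesian Gaussians with $s$ and $p$ shells (built-in minimal STO-3G data
for H, He, Li, C, N, O, F, Na), McMurchie-Davidson one- and two-electron
integrals in C++, DIIS-accelerated SCF with automatic level-shift retries,
ghost atoms, fixed external one-electron potentials, and total-energy
evaluation of arbitrary densities.  The decomposition algebra is
method-agnostic at the single-determinant level, so the EDA applies
unchanged on top of this backend; hybrid-functional energetics would shift
component values but not any structural property the package asserts
(closure, limits, conservation laws).  The minimal basis keeps every
shipped fixture in the seconds-to-minutes range on one CPU.

Numerical conventions: geometry in Å, charges in e, internal math in atomic
units, reported energies in kcal/mol (1 hartree = 627.509474 kcal/mol);
classical point-charge energies use k = 332.0637 kcal Å mol$^{-1}$ e$^{-2}$.
SCF convergence defaults to $10^{-10}$ hartree / $10^{-8}$ RMS density so
that component sums close far below 0.01 kcal/mol.  Linear dependence is
guarded by a $10^{10}$ condition-number threshold on overlap matrices, and
the frozen-state construction rejects degenerate combined occupied spaces
at the same threshold.

## The QM-region workflow

`partition_closest_n()` ranks waters by the *minimum over the water's three
atoms* of the distance to the solute's center of mass (standard atomic
masses), assigns the closest $n$ to the QM region and the rest to the MM
region, breaking ties by input order.  The any-atom metric (rather than
oxygen-only) matches how QM-region radii are conventionally quoted for
water shells; the partition is invariant under rigid translations and the
QM radius is nondecreasing in $n$.

`run_scan()` repeats the full decomposition over a size ladder and tabulates
deviations from a reference size (largest by default); `converged_size()`
returns the smallest size whose deviations - for *all six tracked
components* (electrostatic, Pauli, polarization, total, dispersion,
induction) - stay inside ±1 kcal/mol *for every larger sampled size*.
First entry into the band does not count; series that never settle return
`NA`, the behaviour expected of hard cases such as anions.  Scan results
are cached by size and configuration so re-runs are incremental.

`sample_stats()` reports per-component ensemble mean, standard deviation
(sample convention, $n-1$ denominator - at the ensemble sizes typical of
this analysis, around 20 geometries, the choice is material, and it is
recorded in the output) and
RSTD $= 100\,\sigma/|\bar X|$ (missing, not infinite, for a zero mean).
`sample_mean_convergence()` tracks running means over index-equispaced
subsamples (for $n=100$, $k=20$ selects positions $1, 6, \ldots, 96$) and
flags the smallest subsample size within ±1 kcal/mol of the full-sample
mean; unlike `sample_stats()` it is order-sensitive by design.

## The synthetic-snapshot generator

`generate_synthetic_snapshot()` emulates what an MD snapshot delivers to
this analysis: a rigid solute template (ammonium, glycine zwitterion, or
formate) surrounded by rigid 3-site waters (r(OH) = 0.9572 Å, HOH = 104.52°)
placed on concentric shells (default first shell 3.0 Å, spacing 0.8 Å,
minimum intermolecular distance 2.0 Å) with each water's dipole aligned to
the local electrostatic field of the solute's template charges, a free
azimuthal angle, and a random tilt of up to ~40° standing in for thermal
disorder.  Waters carry TIP3P charges (O −0.834 e, H +0.417 e); with
`polarizable = TRUE` each atom also carries an induced dipole
$\mu_i = \alpha_i E(R_i)$ from the field of the solute template charges and
all other waters' fixed charges, with a single isotropic polarizability
(0.53 Å³ on oxygen, none on hydrogen).  Generation is exactly reproducible
from its seed and leaves the global RNG untouched.

What the generator does *not* emulate: thermal O-H stretch/bend disorder,
solute conformational flexibility, counterions, hydrogen-bond network
topology, and the self-consistent polarization of a real polarizable-FF
simulation.  Tests passing on these snapshots therefore demonstrate the
correctness of the decomposition machinery - closure, conservation laws,
classical limits, convergence logic - not the quantitative solvation
energetics of real trajectories, which additionally require a converged MD
ensemble and a larger basis.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely at minimal-basis
scale: the packaged hydrogen-bonded water dimer, He and Li⁺/F⁻ pairs,
H₂-in-a-field fixtures, and synthetic ammonium snapshots with up to 8
waters (2 QM), scanned over 1-8 QM waters.  These sizes were chosen so the
full decomposition - five SCF states per EDA call - completes in about a
second per snapshot while still exercising every code path, including
polarizable embedding and the scan/statistics machinery.

## Known limitations

* Closed-shell RHF only; no correlation, so absolute component values are
  qualitative at minimal-basis scale.  The dispersion remainder at the
  mean-field level contains exchange-polarization coupling rather than
  genuine London dispersion.
* Minimal-basis artifacts exist for anions: the ghost-padded F⁻ fragment
  needs level shifting, and a Li⁺/F⁻ complex at long range relaxes into a
  partial charge-transfer state because the anion HOMO sits above the
  cation LUMO in this basis.  Fragment-based quantities (the electrostatic
  component in particular) are unaffected.
* The induction/dispersion split is trustworthy only where second-order
  perturbation theory is; the route-discrepancy diagnostic quantifies that
  trust per run.
* One Slater determinant per fragment; no open shells, no analytic
  gradients, no exchange-vs-repulsion separation.
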