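---
title: "Modeling DNA-wrapped carbon nanotubes: construction, stability scans and synthetic STM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling DNA-wrapped carbon nanotubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`cntdna` models hybrids of single-stranded DNA (ssDNA) wrapped helically
around single-walled carbon nanotubes (CNTs), and the scanning-tunneling
microscopy (STM) observables of such hybrids. It covers four connected
pieces of methodology:

1. atomistic construction of an (n,m) nanotube and of an ssDNA strand
   replicated along a helix on its surface;
2. a simplified, fully documented molecular-mechanics potential used to
   locally optimize the hybrids and to compute DNA-tube binding energies;
3. a stability experiment: the binding energy as a function of the DNA
   wrapping angle, with fixed or free strand ends;
4. a synthetic-topography generator (tip convolution, instrument noise) and
   the Fourier analysis that extracts the DNA coiling period and wrapping
   angle from such images.

The synthetic-data generator is first-class: all quantitative claims the
test suite makes about image analysis are demonstrated on its output, where
the ground truth is known exactly.

# Tube construction

The tube is the graphene lattice rolled onto a cylinder. For chiral indices
$(n,m)$ with lattice constant $a = 0.246$ nm,

* chiral angle $\theta = \arctan\!\big(\sqrt3\, m /(2n+m)\big) \in [0^\circ, 30^\circ]$,
* diameter $d = a\sqrt{n^2+nm+m^2}/\pi$,
* translational period $T = \sqrt3\,\pi d / d_R$, $d_R = \gcd(2n+m,\,2m+n)$,
* $4(n^2+nm+m^2)/d_R$ atoms per translational cell.

Atoms are enumerated in exact integer arithmetic in the basis of the chiral
and translation vectors, so the per-cell atom count is exact by
construction; the tests additionally compare it against an independent
floating-point lattice enumeration. For the (6,5) tube this gives
$d = 0.747$ nm and $\theta = 27.0^\circ$; the value $d \approx 0.8$ nm
sometimes quoted for this tube is treated as a rounded report of the
computed diameter and no rescaling is attempted. Tube ends are open and
uncapped; an open chiral cut can leave one singly-bonded carbon per edge,
which is irrelevant here because the strand is kept away from the edges.

The tube axis is the $z$ axis, coordinates are in nanometres, and the tube
is frozen in every optimization (a rigid sp$^2$ lattice; the simplified
potential carries no intra-tube bonded terms, so tube elasticity is outside
the model). Its internal energy is a constant that cancels from every
binding-energy difference.

# Helical wrap construction

One nucleotide unit is a DNA base plus a phosphate-deoxyribose fragment,
built from idealized internal coordinates: aromatic rings as regular
0.139-nm polygons, standard exocyclic bond lengths, a puckered five-ring
sugar and a tetrahedral phosphate; hydrogens are included with approximate
positions. The base ring lies in the unit's local $x$-$y$ plane with its
centroid at the origin; the local $z$ axis is the base-plane normal and the
local $x$ axis is the strand direction. The base is rotated in its plane
about the glycosidic attachment point (a chi-like torsion, free in ssDNA)
so that its narrow dimension faces the strand direction; this is how
flat-lying bases accommodate a per-residue step smaller than the base
width, and without it neighbouring bases in the initial configurations
overlap sterically.

The initial unit is placed with its base centroid at radius $R = R_0 +
\Delta$ (tube radius plus the pi-stacking clearance, default $\Delta =
0.33$ nm), base normal radial, and head-tail axis at the construction angle
$\alpha$ in the tangent plane; the placement azimuth is drawn from a seeded
generator, retrying on (never observed in practice) steric overlap. Unit
$n$ is the replica of unit 0 shifted by $\Delta z = L\sin\alpha$ along the
axis and rotated about it by the accumulated helix angle $n\,\Delta z /(R
\tan\alpha)$, applied as a 2x2 rotation of the $x$-$y$ coordinates. For
mixed sequences each unit's base is substituted from its letter's template
inside the identical backbone frame before replication.

**The per-residue step L.** The construction leaves $L$ (the arc step per
nucleotide along the strand) free. The study conditions require a C-25-mer
to stay shorter than the three-repeat-unit (6,5) tube ($3T = 12.19$ nm)
over a construction grid reaching $80^\circ$, which bounds $L < 0.51$ nm;
the default is $L = 0.50$ nm, at the compact end of ssDNA per-residue
rises. $L$ remains a configuration parameter.

**Angle conventions.** The construction formulas make $\alpha$ the helix
angle measured from the circumferential direction ($\Delta z = L\sin\alpha$
grows toward the axial limit). Wrapping angles in the experimental
literature are quoted from the tube axis; the relation
$p = 2\pi R/\tan\beta$ between pitch $p$ and from-axis angle $\beta$, and
the chirality complement $90^\circ - 27^\circ = 63^\circ$, both live in the
from-axis convention. Every measurement and scan row therefore reports both
the from-circumference angle and its complement, and scan minima are keyed
by the realized from-axis angle.

Junctions between consecutive units carry three harmonic distance
restraints with rest lengths recorded from the as-constructed helix (so a
fresh helix is strain-free): the O3'-P bond and two 1-3 pairs (C3'-P and
O3'-O5') that encode the bond-angle stiffness of the phosphodiester
linkage.

# The simplified potential

The energy is

$$E = \sum_{\text{inter-group pairs}} 4\varepsilon_{ij}
      \Big[\big(\tfrac{\sigma_{ij}}{r}\big)^{12} -
           \big(\tfrac{\sigma_{ij}}{r}\big)^{6}\Big]\,S(r)
    + \sum_{\text{restraints}} k\,(r - r_0)^2 ,$$

with Lorentz-Berthelot combination over a standard organic-element
parameter set (C, N, O, P, H), a CHARMM-style switching function $S$
between 1.0 and 1.2 nm, intra-unit all-pair distance restraints to the
template geometry (near-rigid units), and the junction restraints above.
Pairs within a unit and across the bonded junction are excluded from the
non-bonded sum; tube-tube pairs likewise (rigid tube). Point charges are
available behind a flag but default to zero: the model runs in vacuo with
neutralized phosphates and attributes binding to pi-stacking dispersion.
Energies are in kcal/mol and reported in eV via 1 eV = 23.0605 kcal/mol.

A single global factor on the well depths sets the energy scale. It is
calibrated once so that one optimized cytosine unit adsorbs on the (6,5)
surface at 0.5-0.7 eV (the default factor 1.3 gives 0.66 eV), and is then
frozen for every experiment in the package; no per-result adjustment is
made anywhere.

Minimization is chunked L-BFGS on the free atoms with a Verlet pair list
(cutoff + 0.4 nm skin, refreshed when any atom moves half the skin), a
convergence criterion on the gradient infinity norm (default 0.001
kcal/(A mol)), a monotone energy trace, and a final exact (list-free)
energy evaluation. Frozen atoms (the tube; in fixed-end mode also the two
terminal units) are excluded from the parameter vector, hence preserved bit
for bit.

**Binding energy.** $E_b = E(\text{hybrid}) - E(\text{bare tube}) -
E(\text{isolated DNA})$, each term from its own optimization. The isolated
reference starts from the optimized hybrid geometry with the tube removed
and is re-optimized (optionally from several perturbed starts, keeping the
lowest). Negative $E_b$ means bound.

# The wrapping-angle stability scan

For each construction angle on the grid (default $10^\circ$-$80^\circ$ in
$5^\circ$ steps; angles whose strand would overrun the tube are skipped) a
hybrid is generated, optimized in fixed- or free-end mode, and measured:
per-nucleotide local wrapping angles from the base-centroid cylindrical
track, their mean and standard deviation, the coiling period from a robust
(Huber) fit of $z$ against unwrapped azimuth, and per-base clearances. The
centroid track is smoothed with a three-point moving average before the
local-angle differences; optimized bases rock about the strand axis by a
few hundredths of a nanometre, and without smoothing that single-base
jitter dominates the dispersion statistic that is meant to capture path
inhomogeneity. The azimuth and height of a symmetric average are unbiased
on a uniform helix; the radius entering the arc length is taken from the
raw centroids, so a freshly built helix measures back its construction
angle exactly.

Clearance is reported two ways: the centroid radius minus tube radius, and
the pi-contact distance (closest approach of the base ring system to the
surface). At a compact per-residue step optimized bases roll a little
about the strand axis, keeping edge contact at the stacking distance while
their centroids sit slightly higher.

Scan rows are keyed by the realized mean from-axis angle. The barrier is
the smaller of the two maximal binding-energy rises flanking the minimum
within 20 degrees of realized angle.

**Problem sizes.** The shipped experiments use the C-25-mer on the
three-unit (6,5) tube (1092 tube atoms, 750 DNA atoms), a 15-point angle
grid of which 12 angles fit the tube, 3000 optimizer iterations per scan
point and 4000 for the single-configuration binding-energy runs. These
sizes make a full fixed-plus-free scan pair plus the 20-mer binding run
complete in roughly ten minutes on one CPU.

# What the model reproduces, and what it does not

With the frozen defaults the package's own experiments give:

* a well-defined binding-energy minimum of the C-25 fixed-end scan at a
  realized wrapping angle of about 60 degrees from the tube axis, inside
  the reported 58-63 degree stability window, with weaker binding at
  smaller from-axis angles (the C-mer trend);
* fixed-end aggregate angle dispersion of about 11 degrees against about
  13 degrees for free ends, reproducing the direction and magnitude of the
  end-constraint effect;
* recovery of the coiling period (3.3 nm within a few percent) and of the
  wrapping angle (63 degrees within one degree) from synthetic tip-convolved,
  noisy topographies of a chirality-matched hybrid.

Known limitations, stated deliberately:

* The per-base binding magnitude comes out near -0.5 eV rather than the
  reported -0.8 eV. The calibration anchor (single-base adsorption at
  0.5-0.7 eV) caps the contact term, and the isolated-strand reference
  relaxes by 0.15-0.2 eV per base through base-base stacking once off the
  tube; the difference of those two honest numbers cannot reach -0.8 eV
  under this potential class. Raising the anchor would restore the
  magnitude but break the calibration rule, so the smaller value is
  reported as-is.
* The barrier flanking the minimum is of order 1 eV rather than 0.2-0.3
  eV: the simplified potential exaggerates the destabilization of the
  extreme angles (edge confinement at the near-axial end, coil crowding at
  the near-circumferential end), which steepens the flanks of the same,
  correctly located, minimum.
* A few mid-strand bases at kinks lift off the surface in converged
  optima, so the pi-contact interval 0.30-0.36 nm holds for the large
  majority but not strictly for every base.
* The tube is rigid and in vacuo; solvent, counterions, tube elasticity
  and hydrogen-bonded base-phosphate contacts at extreme angles are
  outside the model.

# Synthetic STM and its analysis

The pre-tip topography is the upper envelope of the substrate plane, the
resting tube cylinder and the strand: either the union of atom spheres (for
an atomistic hybrid) or a swept tube along a parametric helix. Parametric
renders record their ground truth (pitch, strand angle, axis direction) in
the image metadata, which only the tests read. The default effective
backbone radial distance for parametric renders is 1.05 nm: the value at
which a 63.4-degree from-axis angle and a 3.3-nm period are mutually
consistent through $p = 2\pi R/\tan\beta$ (partial detachment of annealed
strands makes the effective radius larger than the stacking-geometry
value; the pre-tip ridge modulation depth is correspondingly deeper than
the measured ~0.2 nm, which is a tip-limited observable).

Tip convolution is grayscale morphological dilation by the inverted tip
(cone with spherical apex; default 2 nm apex, 30 degree half-angle chosen
to reproduce the ~5 nm apparent width of a wrapped tube). Noise is seeded
Gaussian height noise (default RMS 0.02 nm). The analysis side mirrors the
experimental procedure: longitudinal sections through the estimated tube
axis (principal axis of the above-substrate mask), cropped to the
DNA-covered island; linear detrending; an FFT with at least eight-fold zero
padding; the period as the inverse of the (quadratically interpolated)
non-DC peak frequency; the 90-percent-of-peak band as the uncertainty
convention, plus the null-to-null width, which for a sine spanning $N$
periods is approximately $2\lambda/N$. Period histograms over an ensemble
of noisy renders use 0.3-nm bins, matching that three-coil uncertainty at
$\lambda = 3.3$ nm.

The strand orientation estimator reads the spectral ridge of a band around
the tube crest, resampled into axis coordinates: at the coil spatial
frequency, the complex phase of each lateral column encodes the axial
displacement of the stripe pattern, and the weighted phase gradient across
the band gives the stripe slope, hence the angle to the axis. A blunt tip
smears the near-crest slant into near-circular domes (the apex of each
coil bump dominates the dilation), so when a nominal tip model is supplied
the image is first tip-deconvolved by grayscale erosion - the standard
first-order surface reconstruction in scanning-probe microscopy - which
restores the elongation. On noise-free renders the estimator recovers the
ground-truth angle to within a degree; with the default tip and noise it
stays within about one degree of the truth.

Degenerate inputs are handled explicitly: constant profiles and smooth
bare cylinders yield a no-periodicity flag (peak below three times the
median spectral magnitude, or below an absolute floor), straight strands
an undefined period, and sections leaving the image are truncated with a
warning.

# Determinism and reproducibility

Every stochastic step (placement azimuth, reference-start perturbations,
image noise) draws from an isolated seeded generator that never touches
the session's random state. A pipeline run (`run_experiment()`) writes a
manifest with the full configuration and md5 checksums of every artifact;
re-running the same configuration reproduces the artifacts bit for bit.
`scripts/acceptance.R` re-derives the headline quantities from scratch for
any seed.
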