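---
title: "Structure-based clustering of pMHC TCR-interacting surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based clustering of pMHC TCR-interacting surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pMHCsurf)
```

## The problem

A T-cell receptor does not recognize a peptide; it recognizes the composite
surface that the peptide and its presenting MHC molecule expose to it. Two
peptides with almost no sequence in common can form pMHC complexes whose
TCR-interacting faces are nearly indistinguishable — and T cells do
cross-react between them — while a single prominent feature (say, an
arginine pointing at the TCR from peptide position P7) can dominate
recognition of an otherwise unremarkable complex. `pMHCsurf` quantifies this
intuition: it characterizes the TCR-interacting surface of each complex by
its electrostatic topography in one fixed orientation, turns each surface
into a region-based descriptor vector, and clusters complexes so that
cluster membership can be compared against experimentally observed
cross-reactivity networks.

The pipeline has five stages, each usable on its own:

1. **Structures** — read PDB files (or generate synthetic "toy grooves"),
   assign formal charges and radii, and superpose everything onto one
   reference so all surfaces share a canonical frame.
2. **Electrostatics** — evaluate the potential, in kT/e, either as a
   screened Coulomb sum (fast, the default) or by a finite-difference
   linearized Poisson–Boltzmann (PB) solve.
3. **Surface map** — rasterize the TCR-facing side top-down: a height
   field, the potential sampled *on* that surface, and an 8-bit
   red–white–blue rendering clamped at ±5 kT/e; then average each channel
   over a predetermined region grid to get one descriptor column per
   complex.
4. **Clustering** — correlation distance between descriptor columns, UPGMA
   (unweighted average linkage), and a multiscale bootstrap that attaches
   an approximately unbiased p-value (AU), an ordinary bootstrap
   probability (BP), and a delta-method standard error to every internal
   edge. Threshold cuts of this tree play the role of putative
   cross-reactivity thresholds.
5. **Cross-reactivity** — percent positional identity between peptides, and
   sensitivity/specificity of a tree partition against a network of
   observed reactive and tested-negative pairs.

## Model assumptions, and where they come from

**Canonical frame.** Surfaces are compared pixel-for-pixel, so every
complex must sit in the same pose. The frame is defined operationally: a
designated reference structure is constructed (toys) or chosen (real
complexes) with its groove floor in the z ≈ 0 plane, the peptide N→C axis
along +x, and the TCR side facing +z; every other complex is superposed
onto it by proper-rotation least squares (Kabsch) over a chosen fit set.
For real class I complexes the natural fit set is the heavy-chain Cα trace
(`selection = "A:1-182"`, `atomNames = "CA"`), which is conserved across
allotype-matched complexes; for toys the floor/rim lattice is identical by
construction, so superposition is exact. The frame contract is tested: the
rotation has determinant +1 to 1e−9, a random rigid motion is recovered to
< 1e−6 Å RMSD, and re-canonicalizing a canonical structure is a no-op.

**Charge model.** The default charge scheme is deliberately minimal:
integer formal charges at physiological pH (Asp/Glu −1 split over the
carboxylate oxygens, Lys +1 on NZ, Arg +1 split over NH1/NH2, His neutral,
charged termini), radii per element (C 1.70, N 1.55, O 1.52, S 1.80,
P 1.80 Å, default 1.70). This is sufficient to reproduce the red/blue
±5 kT/e patterning that drives the descriptors; a per-atom table can be
plugged in when a force-field charge set is preferred. Hydrogens are never
added: the model is heavy-atom only, as crystal structures are.

**Electrostatics.** Both modes work in dimensionless kT/e units through the
length `L = e²/(4πε₀kT)` (560.5 Å at 298.15 K), so a +1 e charge in water
(ε = 80) contributes 1 kT/e at 7.0 Å. Defaults: ε_in = 4, ε_out = 80,
ionic strength 0.145 M (κ⁻¹ = 8.07 Å at 298.15 K), all configurable. The
screened-Coulomb mode is the pipeline default because the clustering
consumes *relative* patterns across complexes computed identically, and it
keeps the full pipeline interactive. The PB mode solves
∇·(ε∇φ) − ε_out κ² h φ = −4πLρ on a cubic grid: molecular region = union
of van der Waals spheres (ε_in, ion-excluded), trilinear charge spreading,
Dirichlet boundaries from the screened-Coulomb far field, and SOR
iteration until the largest node update falls below 1e−5 kT/e (hard cap
10,000 sweeps, a convergence error otherwise). The solver is validated
against two closed forms at 0.5 Å spacing in the 4–12 Å shell: the Coulomb
solution in a homogeneous dielectric (within 2%) and the Debye–Hückel
ion-excluded sphere (within 3%).

One numerical point deserves a note. The screened-Coulomb boundary
condition underestimates the exact Debye–Hückel sphere far field by the
factor (1 + κa)e^(−κa) (≈ 2.8% for a 2 Å sphere at 0.145 M), and for the
screened operator that boundary error decays into the interior only over a
Debye length. The Debye–Hückel validation therefore uses 14 Å padding so
the boundary layer sits outside the measured shell; the default 10 Å
padding is fine for production use, where the boundary sits in the far
field of a roughly neutral molecule.

**Surface raster.** The projection is orthographic and top-down: per pixel
(0.5 Å default) the height is the top of the highest probe-inflated atom
sphere (probe 1.4 Å) over that pixel, and the potential is evaluated at
that surface point. Rendering follows the conventional potential ramp:
−5 kT/e → red (255,0,0), 0 → white, +5 → blue (0,0,255), linear in
between, clamped outside; fading channels are `round(255·(1−|φ|/5))` with
half-counts rounded away from zero so rasters are bit-identical across
platforms. Background pixels are white and excluded from averages.

**Regions and descriptors.** The region grid is the package's stand-in for
the "predetermined regions" of image-analysis protocols: by default 8 × 4
rectangles over a window of x ∈ [−16, 16], y ∈ [−10, 10] Å around the
groove center, indexed row-major from (x_min, y_min). Per region and
channel the descriptor is the mean over molecule pixels (empty regions
contribute the channel's neutral value: 255 for R/G/B, 0 for φ/height).
Default channels are {R, G, B}, mirroring an RGB-screenshot protocol;
{phi, height} are available because 8-bit RGB saturates beyond the clamp.
`maskRegions()` excludes regions, which is how sub-surface analyses are
done — e.g. restricting to the half of the groove facing one TCR domain,
or removing a single prominent charged spot to ask whether the remaining
surface would cluster a complex with its cross-reactive partners.

**Clustering with uncertainty.** Distance is 1 − Pearson correlation
between descriptor columns; the tree is UPGMA, with ties broken by the
smallest pair of minimal leaf indices so that the tree is a pure function
of the distance matrix. Support comes from the multiscale bootstrap:
feature rows are resampled with replacement at sample-size scales
r ∈ {0.5, …, 1.4} (the de facto standard ladder), `round(n_f · r)` rows
per replicate, 10,000 replicates per scale at production settings, and the
fraction of replicate trees containing each reference cluster gives
BP_r. The AU p-value extrapolates: z_r = Φ⁻¹(1 − BP_r) is fit by weighted
least squares to z_r = v√r + c/√r (inverse binomial variance through the
probit as weights), and AU = 1 − Φ(v − c), with the model-implied BP at
r = 1 being 1 − Φ(v + c) and se(AU) following from the WLS covariance by
the delta method. Counts of 0 or n_boot get the continuity correction
(count + ½)/(n_boot + 1) before the probit. An edge with fewer than three
scales strictly inside (0, 1) *before* correction cannot identify the
two-parameter model: it falls back to AU = BP with SE 0 when BP is
identically 0 or 1 (the cluster is certain under resampling) and SE NaN
otherwise, flagged `degenerate`. This mirrors the behavior of the standard
multiscale-bootstrap implementation; fitting corrected-constant edges
instead would assign AU ≈ 0.6 to clusters that appear in 100% of
replicates, which is clearly wrong.

On synthetic planted-cluster matrices at production settings, the
delta-method SEs of fitted edges concentrate around 0.01: decisive edges
(BP near 0 or 1) have much smaller SEs, while near-tied "noise" edges
inside a planted cluster sit at mid-range BP where the SE peaks, and can
exceed 0.01 by a few percent. The acceptance suite records this honestly
rather than relaxing the bound.

**Agreement scoring.** Structural similarity is undirected, so
`evaluatePartition()` ignores edge direction: sensitivity is the fraction
of observed cross-reactive pairs co-clustered, specificity the fraction of
tested-negative pairs separated, and violating pairs are listed by name —
in real networks such exceptions are where private T-cell specificities,
not structure, carry the explanation. Directionality (strong/weak,
reciprocation) is summarized but never scored.

## What the toy generator emulates — and what it does not

`makeToyGroove()` builds the minimal geometry with the same *kind* of
structure a class I pMHC shows the TCR: a neutral floor lattice (9 × 5 at
3.5 Å, z = 0) for the β-sheet, two rim rows above the outer floor rows
(z = 2 Å) carrying fixed alternating ±0.25 e charges for the conserved
helix context — identical across all toys, as the MHC is identical within
a restriction — and an 8-position peptide row (y = 0, z = 3 Å) whose
per-position charges are free in {−1, 0, +1}. A "spicy" position can be
raised to z = 6 Å, the toy analogue of a prominent TCR-exposed side chain.
Pseudo-atoms have radius 2 Å; with the 1.4 Å probe the projected surface
is fully connected at 0.5 Å pixels. Geometry is a pure function of the
spec: randomness enters only named, seeded family generators.

The toys are *not* physically realistic MHC grooves: no side-chain
conformations, no sequence-to-structure coupling, no solvent structure,
and peptide variation is a charge vector rather than chemistry. What
passing tests on toys demonstrate is that the pipeline machinery —
orientation, projection, descriptor extraction, clustering, support — is
correct and deterministic, and that known ground truth (planted families,
Hamming-distance orderings, vanilla-vs-spicy contrasts) is recovered. They
say nothing about how faithfully formal charges plus screened Coulomb
approximate a DelPhi-grade potential on real complexes; for real data the
PB mode and a proper charge table are the serious configuration.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `pixelSize` | 0.5 | Å | smooth descriptors at desk-scale cost |
| `probeRadius` | 1.4 | Å | water-probe convention |
| `clamp` | ±5 | kT/e | the conventional render range for pMHC surfaces |
| window | x ±16, y ±10 | Å | covers groove + rims of class I complexes |
| regions | 8 × 4 | — | resolves per-position features of an 8–9-mer |
| `epsIn` / `epsOut` | 4 / 80 | — | conventional PB practice |
| `ionicStrength` | 0.145 | mol/L | physiological saline |
| `gridSpacing` / `gridPadding` | 1.0 / 10 | Å | production PB default; halve spacing for validation work |
| `nBoot` | 10,000 | — | production support values; SE(AU) ≈ 0.01 |
| `scales` | 0.5–1.4 × 0.1 | — | standard multiscale ladder, includes r = 1 |
| distance clamp | 0.5 | Å | keeps within-atom samples finite, applied identically everywhere |

Problem sizes used by the shipped tests: PB validation on 49³–65³ grids;
bootstrap tests at 200–1,000 replicates per scale; the support-error
analysis at the full 10,000; toy families of 6 complexes at 0.5 Å pixels.

## Degenerate inputs and tie-breaks

Zero-variance descriptor columns (a complex whose surface is uniformly
white) make correlation undefined and are an error naming the complex, not
an NA. Bootstrap replicates that draw a zero-variance resample fall back
to distance 1 for the affected pairs. UPGMA ties merge the
lexicographically smallest representative pair; equal-distance chains
therefore merge left-to-right in label order. `cutDendrogram()` uses a
strict `< h` rule, so h = 0 yields all singletons and any h above the root
yields one cluster. Newick export uses the midpoint convention (leaf depth
= height/2) with optional "AU|BP" labels to two decimals on internal
nodes.

## Known limitations

- The canonical frame, charge scheme, and region grid are *declared*
  conventions: different choices give different descriptors. They are
  stated in the configuration (persisted verbatim next to every pipeline
  run) rather than hidden.
- RGB descriptors discard everything beyond ±5 kT/e; use the `phi` and
  `height` channels when saturation or topography matters.
- The PB dielectric map is a union of vdW spheres, not a reentrant
  molecular surface; this is monotone under refinement and identical
  across complexes, but not a solvation-grade surface.
- Percent identity is strict positional matching of equal-length peptides;
  no alignment, no chemical similarity.
- The bootstrap engine handles up to 64 complexes (leaf sets are
  bitmasks); far above any published cross-reactivity network, but a hard
  limit nonetheless.
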