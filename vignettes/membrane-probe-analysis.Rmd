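---
title: "Assessing membrane perturbation by a bilayer probe: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing membrane perturbation by a bilayer probe: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question

Fluorescent probes report on membrane order, polarity and phase — but only
if inserting the probe does not itself reorganise the bilayer it is
supposed to observe. `memprobe` implements the computational side of that
verification for an ESIPT (excited-state intramolecular proton transfer)
solvatochromic probe anchored in one leaflet of a model membrane: a
3-hydroxyflavone chromophore with a zwitterionic head and an 18-carbon
tail, studied in a fluid POPC bilayer (liquid-disordered, Ld) and an
ordered DPPC/cholesterol bilayer (liquid-ordered, Lo), with the probe
absent or present as its excited normal form N\* or proton-transfer
tautomer T\*.

The package compares systems on four axes:

1. **Geometry** — P–P bilayer thickness and area per lipid;
2. **Order** — per-carbon deuterium order parameter (S~CD~) profiles of
   the acyl chains, optionally restricted to phospholipids within a cutoff
   of the probe;
3. **Pseudo-semantic fluidity clustering** — per-frame S~CD~ profiles
   encoded as letter strings, compared by k-mer overlap, embedded in 2-D;
4. **Energetics and photometry** — Welch tests on per-frame binding-energy
   series, and the dual-band I^N\*^/I^T\*^ emission ratio from spectra and
   two-channel vesicle images.

Trajectories and binding energies are *inputs*: the package never runs
molecular dynamics. A synthetic-bilayer generator with exact ground truth
stands in for MD output so every estimator can be validated end to end.

# Bilayer geometry

**Thickness** is the difference between the mean z of upper-leaflet and
lower-leaflet phosphorus atoms. The bilayer normal is fixed as the z axis
throughout; readers and generators orient membranes accordingly, and no
normal estimation is attempted. Leaflets are assigned by the sign of each
lipid's P z-coordinate relative to the P midplane, with ties going to the
lower leaflet (deterministic and testable; a coplanar, degenerate bilayer
additionally warns).

**Area per lipid** (A~l~) is the lateral box area divided by the number of
phospholipids in a leaflet, computed per leaflet and averaged — averaging
rather than pooling keeps the estimate meaningful for asymmetric leaflets.
Cholesterol is excluded from the denominator. When the cholesterol mole
fraction exceeds 20%, the raw A~l~ must be reduced by 10–20%; because only
that range rule is available, the package reports a corrected *range*
`(0.80·A_l, 0.90·A_l)` rather than inventing a point estimate, and the
range collapses to the raw value at or below the threshold.

Aggregation over analysis frames reports means and sample SDs (zero for a
single frame). The analysis window follows the production cadence of the
underlying simulations: the last 5 ns of a trajectory, resampled as the 11
frames nearest an even grid over the window, endpoints included.
Nearest-to-grid matching (rather than exact time equality) makes the
selection robust to whatever cadence the trajectory writer used.

# Deuterium order parameters

The instantaneous order parameter of one C–H (C–D) bond is
$$S = \tfrac{1}{2}\,(3\cos^2\theta - 1),$$
with θ the angle between the bond and the bilayer normal. Profiles average
S over all bonds of a carbon, all selected lipids and all frames in scope.
Values are reported as |S~CD~| — the common plotting convention under
which ordered plateaus sit near 0.2–0.4 and the disordered terminal tail
approaches 0 — while the signed mean is retained in the result.

When a structure carries no hydrogens, C–H directions are reconstructed
from the carbon skeleton. For a saturated mid-chain carbon *i* the local
chain direction is **d** = C~i+1~ − C~i−1~, and the two H vectors are unit
vectors perpendicular to **d**, separated by the exact tetrahedral angle
acos(−1/3). Within the perpendicular frame the pair is centred on the
45-degree diagonal: with that phase the *pair-averaged* order parameter
equals the full azimuthal average for any chain tilt, so the
reconstruction introduces no orientation bias for mid-chain methylenes —
this is the property the explicit-H versus reconstruction agreement tests
rely on. Double-bond (sp2) carbons get the single in-plane vinyl vector
along the exterior bisector of the C–C=C angle; terminal methyls get three
vectors at tetrahedral angles from the last bond; the first carbon uses
its only neighbour. Terminal and sp2 reconstructions are geometric
approximations: their azimuthal placement is dictated by the backbone, so
cross-path comparisons are made on saturated mid-chain carbons.

Near-probe profiles re-select the lipid set *in every frame* (the 5 Å
shell around the probe changes as lipids move), using minimum-image
distances in x and y only — the bilayer spans z, which is treated as
non-periodic. Cholesterol never enters the selectable set: only
chain-bearing phospholipids contribute letters to the fluidity analysis.
Profiles can be computed per frame (the default input to the string
encoding, which needs one string per frame) or averaged over the window.

# Pseudo-semantic fluidity analysis

Each per-frame profile is turned into a string: one letter per carbon,
sn-1 chain first, carbons in increasing acyl index, with per-carbon values
averaged over the selected lipids before encoding (this yields exactly one
string per frame). The encoding uses uniform bins over [0, 0.52] mapped
onto A–Z: 26 bins of width 0.02 cover the range |S~CD~| occupies with a
resolution comparable to the scatter of real profiles. The binning is a
package choice — no canonical binning exists for this encoding — and is
fully configurable; values outside the range clamp with a warning, and the
top edge maps to the last letter.

Two strings are compared through their k-mer sets with k from 2 to 8. By
default all lengths pool into one set per string and similarity is the
Szymkiewicz–Simpson overlap coefficient
$$\mathrm{overlap}(A, B) = \frac{|A \cap B|}{\min(|A|, |B|)},$$
with distance 1 − overlap. A per-k variant (coefficient per length,
averaged) is provided because the pooling convention is genuinely
ambiguous; pooled is the default. Exact-duplicate string removal is
available as a preprocessing step but disabled by default. Note the
overlap distance satisfies symmetry and zero self-distance but *not* the
triangle inequality; it is documented as a dissimilarity, not asserted as
a metric.

The distance matrix is embedded in 2-D with t-SNE on the precomputed
distances (no re-featurisation), deterministically for a fixed seed;
defaults seed 42 and perplexity 10 suit the standard 66-item problem (6
systems × 11 frames). Cluster structure is quantified by the mean
silhouette width computed *on the distances*, not on the embedding,
grouped by membrane composition by default — the claim of interest is
whether probe-bearing systems stay with their parent membrane. A label
permutation baseline (silhouette near zero) guards against reading
structure into noise.

# Binding-energy statistics

Per-frame probe–membrane binding energies are consumed from CSV; the
package never computes them (that is the MD engine's job). Pairs of
systems are compared with the unequal-variance Welch t test, two-sided,
with Welch–Satterthwaite degrees of freedom — the safe default when the
two systems fluctuate differently. A comparison is called significant
when 1 − p *strictly* exceeds the confidence threshold, default 0.98
(the "over 98%" rule); p = 0.02 exactly is therefore not significant.

# Dual-band photometry

For spectra, the N\* and T\* band peaks are the maxima of a lightly
smoothed intensity (centred moving average, 5 grid points, partial
windows at the edges) within two disjoint wavelength windows, and the
ratio is I~N~/I~T~. Default windows are 460–540 nm (N\*) and 545–650 nm
(T\*), bracketing the observed N\* solvatochromic span (~475–551 nm) and
the confocal detection channels (477–527 and 550–600 nm). If the T\*
window holds no interior local maximum — the protic-solvent case where
the red-shifted N\* band swallows T\* into a single ~520 nm peak — the
result is flagged `single_band` instead of reporting a meaningless ratio.
Ties between equal maxima resolve to the shorter wavelength.

For images, the membrane mask is the set of pixels whose summed
two-channel intensity exceeds a fraction (default 0.2) of the pair's
maximum — the simplest scheme that isolates the bright membrane annulus
of an equatorial vesicle section without ring fitting. The per-pixel
N/T ratio map is reported together with its mask mean; masked pixels with
zero T are excluded and counted. Both the map and the mean are reported
because the spatial averaging convention of ratio imaging is not unique.

# The synthetic generator: what it emulates, and what it does not

`gen_bilayer()` builds a *kinematic stick model*, not a physical
conformer ensemble. Lipids sit on a jittered xy grid; P atoms sit at
±thickness/2 with 0.5 Å z-jitter; each chain grows through per-carbon
local direction vectors. The tilt distribution of each carbon is solved
numerically (quadrature + root finding) so that the expected |S~CD~| of
C–H bonds placed perpendicular to the local direction equals the
prescribed per-carbon target; bond azimuths are uniform, which is what
makes the explicit-hydrogen estimator exactly unbiased. Thickness and
area per lipid are exact by construction (to the P jitter), so geometry,
order recovery, leaflet assignment and the string pipeline can all be
validated against known ground truth.

Two presets provide the Ld/Lo contrast: "popc" (thickness 37.3 Å,
A~l~ 64.4 Å², plateau ≈ 0.21 with an sp2 dip at carbons 9–10 of the
18-carbon chain, tail decaying to ≈ 0.03) and "dppc-chol" (thickness
45.9 Å, A~l~ 49.6 Å², cholesterol fraction 0.32, plateau ≈ 0.35). A
probe, when requested, adds a small uniform shift to the targets — +0.03
for T\* in POPC, reflecting its ordering effect; +0.005–0.01 otherwise —
and places a placeholder residue (three head atoms under the upper P
plane at the anchoring depth, an 18-carbon tail spanning the leaflet).
Cholesterol enters as a fraction driving the A~l~ correction and the
ordered profile, not as explicit sterol atoms.

Real trajectories are temporally coherent: chain order relaxes slowly, so
consecutive frames are similar. The generator emulates this by giving
every carbon a persistent orientation state that is resampled with
probability 0.02 per frame. Together with the default 64 lipids per
leaflet (a standard membrane-patch size) this produces per-frame strings
that drift gradually within a system while remaining far from the other
composition — the regime in which per-frame clustering is meaningful at
all, and the regime the production analysis operates in. The default
tilt wobble is 5 degrees (SD) around the solved mean tilt.

What the generator does *not* emulate: excluded volume, water and ions,
headgroup structure, realistic dihedral statistics, probe photophysics,
undulations and area fluctuations. Consequently, passing recovery tests
demonstrates that the *estimators* are correct and unbiased on data with
known truth — not that the package's numbers would match a specific
force field's output. Absolute thickness/A~l~/S~CD~ values of real
simulations depend on the MD setup, which is out of scope by design.

# Numerical choices and degenerate inputs

* Leaflet tie (P exactly at the midplane) → lower leaflet, warning on a
  fully degenerate bilayer; no phosphorus atoms → error.
* Frame selection requires the trajectory to span the window; otherwise
  an insufficient-span error.
* Encoding clamps out-of-range values with a warning; empty profiles,
  empty k-mer sets, and strings shorter than k~min~ are errors.
* t-SNE requires `3·perplexity < n − 1`; the silhouette requires at
  least two groups; both misconfigurations error rather than degrade.
* Welch testing refuses two zero-variance series; identical series give
  t = 0, p = 1.
* The tetrahedral angle is `acos(-1/3)` exactly, not a rounded constant.
* All generators are bit-reproducible for a fixed seed, and the pipeline
  writes byte-identical outputs for identical configuration and seed
  (the manifest records parameters, seed and file hashes).

Validation problem sizes, chosen to give comfortable statistical margins:
profile recovery uses 5 000 lipids × 2 bonds ≈ 10⁴ samples per carbon
(binomial SE ≈ 0.003 against a ±0.01 check); the null calibration of the
98% rule uses 1 000 replicates of 11-frame arms (3 SE ≈ 0.013 around
0.02); clustering checks use the full 11-frame, two-preset design with a
20-permutation baseline.

# Known limitations

* The pooled-k overlap on 26-letter strings saturates near 1 for
  unrelated strings; distances are informative mainly through their
  contrast, which is why the silhouette (a contrast statistic) is the
  reported cluster-quality measure.
* Near-probe profiles average over few lipids (typically 4–10 within
  5 Å), so per-frame letters are noisier for probe systems than for
  whole-membrane profiles; the membrane-composition silhouette of the
  full six-system run is correspondingly lower than that of the
  membrane-only contrast.
* Terminal-carbon and sp2 reconstruction are geometric approximations;
  with explicit hydrogens available they are never used.
* PDB is the only trajectory format; binary formats (XTC/DCD) are out of
  scope, as are Voronoi area decompositions, electron-density thickness,
  NMR quadrupolar conversions and flip-flop kinetics.
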