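# memprobe

Does inserting a fluorescent probe perturb the membrane it reports on?
`memprobe` answers that question computationally for solvatochromic
bilayer probes — ESIPT fluorophores anchored in one leaflet whose
dual-band emission ratio reads out membrane polarity. It compares
probe-free and probe-bearing model membranes (fluid POPC vs ordered
DPPC/cholesterol) on the standard structural observables and on a
string-based fluidity clustering, with every estimator validated against
a synthetic bilayer generator of known ground truth. Trajectories and
binding energies are inputs; the package never runs molecular dynamics.

It is aimed at membrane biophysicists and probe developers who have
multi-model PDB snapshots of bilayer simulations (with or without a
guest molecule) and want a reproducible perturbation report.

## What it computes

* **Bilayer geometry** — P–P thickness (mean z of upper-leaflet
  phosphorus atoms minus the lower-leaflet mean) and area per lipid
  `A_l = Lx·Ly / N_lipids_per_leaflet`, averaged over leaflets, with the
  cholesterol rule: above 20% cholesterol the raw `A_l` is reported with
  a 10–20% reduction range.
* **Deuterium order parameters** — per-carbon
  `S_CD = ⟨(3 cos²θ − 1)/2⟩` for the angle θ between each C–H bond and
  the bilayer normal, reported as |S_CD|; explicit hydrogens when
  present, tetrahedral C–H reconstruction from the carbon skeleton when
  not; optionally restricted to phospholipids within 5 Å of the probe,
  re-selected every frame.
* **Pseudo-semantic fluidity clustering** — each per-frame profile is
  encoded as a letter string (uniform 0.02-wide bins on [0, 0.52] over
  A–Z, sn-1 then sn-2 carbons); strings are compared by the
  Szymkiewicz–Simpson overlap of their k-mer sets (k = 2–8, pooled),
  `overlap(A,B) = |A ∩ B| / min(|A|, |B|)`, distance `1 − overlap`;
  the distance matrix is embedded with t-SNE and scored by silhouette
  at the membrane-composition grouping.
* **Binding-energy statistics** — Welch two-sample t tests between
  per-frame energy series, significant when `1 − p` strictly exceeds
  0.98.
* **Dual-band photometry** — the I(N*)/I(T*) emission ratio from spectra
  (smoothed peak maxima in disjoint N*/T* windows, with a single-band
  flag for protic-solvent conditions) and from two-channel vesicle
  images (per-pixel N/T over a summed-intensity membrane mask).
* **Synthetic data** — bilayer trajectories with prescribed thickness,
  area per lipid and per-carbon |S_CD| targets (solved tilt
  distributions), plus Gaussian energy series, sum-of-Gaussian spectra
  and ring-shaped two-channel vesicle images.

## Worked example

Generate a fluid POPC-like bilayer, measure it, and run the six-system
comparison:

```r
library(memprobe)

sim <- gen_bilayer(bilayer_preset("popc", seed = 1))
bilayer_metrics(sim$trajectory, sim$topology)
#> Bilayer metrics over 11 frame(s)
#>   thickness: 37.31 +/- 0.11 A
#>   area per lipid: 64.40 +/- 0.00 A^2

scd_profile(sim$trajectory, sim$topology, "sn2")
#> SCD profile, chain sn2 (explicit H, all, averaged)
#>    C1    C2    C3    C4    C5    C6    C7    C8    C9   C10   C11   C12   C13
#> 0.203 0.197 0.188 0.194 0.210 0.200 0.197 0.177 0.045 0.146 0.118 0.124 0.121
#>   C14   C15   C16   C17   C18
#> 0.087 0.087 0.063 0.037 0.037

run_pipeline(default_six_systems(seed = 42), verbose = FALSE)
#> Pipeline report: 6 system(s), 66 encoded strings
#>   POPC             thickness  37.29 A   A_l  64.40 A^2
#>   POPC+N*          thickness  37.36 A   A_l  64.40 A^2
#>   POPC+T*          thickness  37.27 A   A_l  64.40 A^2
#>   DPPC-Chol        thickness  45.89 A   A_l  49.60 A^2
#>   DPPC-Chol+N*     thickness  45.88 A   A_l  49.60 A^2
#>   DPPC-Chol+T*     thickness  45.88 A   A_l  49.60 A^2
#>   silhouette (membrane grouping): 0.132
```

Reading the numbers: the thickness and area per lipid of the
probe-bearing systems match their probe-free parents (no geometric
perturbation); the sn-2 profile shows the ordered plateau (~0.2), the
sharp dip at the double-bond carbon 9 and the decay toward 0 in the
disordered tail; the pipeline emits 11 encoded strings per system (66
total) whose pairwise distances cluster by membrane composition. The
dual-band ratio of a two-peak spectrum:

```r
band_ratio(gen_spectrum(list(c(500, 2, 20), c(575, 1, 20))))
#> I(N*)/I(T*) = 1.997  (N* 500 nm, T* 575 nm)
```

`run_pipeline()` accepts real multi-model PDB trajectories (with a
lipid-topology JSON/YAML file) in place of presets, writes
`metrics.csv`, `scd.csv`, `strings.tsv`, `distances.csv`,
`embedding.csv`, `silhouette.json`, `ttests.json` and a `manifest.json`
recording every parameter, seed and file hash, and is byte-reproducible
for a fixed configuration and seed.

## Scope

The package analyses trajectories; it does not run MD engines, compute
binding energies, model ESIPT photophysics or flip-flop kinetics, read
binary trajectory formats, or perform Voronoi/electron-density variants
of the geometric observables.
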