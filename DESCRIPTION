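Package: memprobe
Title: Membrane Perturbation Analysis for Solvatochromic Bilayer Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how strongly a guest fluorophore perturbs model lipid
    bilayers. Computes bilayer thickness and area per lipid from multi-model
    PDB snapshots, per-carbon deuterium order parameters (SCD) globally or for
    phospholipids near the probe, and a pseudo-semantic fluidity analysis that
    letter-encodes SCD profiles, compares frames by k-mer overlap
    (Szymkiewicz-Simpson) distances, embeds them with t-SNE and scores cluster
    structure. Also includes Welch tests on per-frame binding-energy series,
    dual-band ESIPT ratiometry for emission spectra and two-channel vesicle
    images, and synthetic-bilayer generators with known ground truth for
    validating every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    cluster,
    jsonlite,
    png,
    Rtsne,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
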