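# memfish

Quantification of plasma-membrane mRNA localization from single-molecule
FISH (smFISH) image stacks.

In early *C. elegans* embryos, transcripts such as *erm-1* — which encodes a
membrane–actin linker with a lipid-binding FERM domain — concentrate at the
plasma membrane of blastomeres. Deciding whether a transcript is
membrane-localized, and how strongly, requires counting individual mRNA
molecules in 3D image stacks and comparing where they sit relative to the
cell cortex against what a randomly distributed sample would do. `memfish`
implements that full quantification pipeline at desk scale, together with a
ground-truthed synthetic embryo simulator, so every stage can be developed,
validated and taught without microscopy data.

## The statistic

Each detected molecule is assigned the distance *d* to the nearest membrane
of its cell (anisotropy-aware 3D Euclidean distance transform of the cell
label mask) and the normalized distance *d̂* = *d* / *d*<sub>max</sub>,
where *d*<sub>max</sub> is that cell's maximum interior distance — so *d̂* ∈
[0, 1] regardless of cell size. Molecules are binned in 10% increments of
*d̂*, and each bin's molecule fraction is divided by the fraction of the
cell volume in the corresponding concentric shell:

  f(b) = (n_b / N) / (V_b / V)

f(b) = 1 means the bin holds exactly as many molecules as a uniformly
random sample; f(1) ≫ 1 (the outermost 10% of normalized distance) means
membrane enrichment. Profiles conserve mass: Σ_b f(b)·(V_b/V) = 1 exactly.
An embryo is called **localized** when the pooled outermost-bin frequency
reaches a threshold (default 1.5). Groups of embryos are compared with
Welch two-sample t-tests.

Around this core the package provides:

* **`synthetic_embryo`** — `generate_geometry()`, `place_spots()`,
  `render_stack()`: packed-blastomere geometries (1/2/4/8 cells, optional
  coverslip flattening), membrane / uniform / clustered molecule placement
  with exact ground truth, and diffraction-limited rendering with
  Poisson + Gaussian noise.
* **spot detection** — `bandpass_filter()`, `detect_spots()`,
  `match_to_truth()`: difference-of-Gaussians matched filtering, 26-connected
  maxima with robust (MAD-based) thresholding, and per-candidate 3D Gaussian
  least-squares refinement with sub-voxel accuracy.
* **molecule counting** — `estimate_reference()`, `decompose_spots()`,
  `count_clusters()`: median/MAD reference single-molecule intensity with
  iterative cluster trimming, integer-count decomposition by Gaussian
  likelihood over k, single-linkage cluster counting.
* **enrichment** — `rasterize_annotation()`, `distance_field()`,
  `assign_and_profile()`, `membrane_fraction()`.
* **statistics** — `welch_test()`, `classify_localization()`,
  `condition_summary()`, `nuclear_rfu()`.
* **recoding** — `recode_cds()`, `identity_nt()`, `identity_aa()`,
  `longest_shared_run()`: synonymous re-coding that maximizes nucleotide
  divergence per codon under a codon-usage floor while preserving the
  protein exactly (for probe-distinguishable transgenes).
* **pipeline** — `run_simulate()`, `run_quantify()`, `run_report()` plus the
  `exec/memfish` command-line front-end (subcommands `simulate`, `detect`,
  `quantify`, `report`, `recode`).

## Worked example

Simulate a four-cell embryo with 90% of 600 molecules planted within 10% of
the normalized radius from the membrane, image it at SNR 8, and quantify:

```r
library(memfish)

geom    <- generate_geometry(stage = 4, shape = c(32, 192, 192),
                             voxel_size = c(0.2, 0.1, 0.1), seed = 1)
model   <- localization_model("membrane", membrane_fraction = 0.9)
truth   <- place_spots(geom, model, n_molecules = 600, seed = 1)
stack   <- render_stack(geom, truth, spot_amplitude = amplitude_for_snr(8),
                        noise = list(poisson = TRUE, gaussian_sd = 10), seed = 1)

spots   <- detect_spots(stack$channels$smfish, geom$voxel_size)
counted <- decompose_spots(spots, estimate_reference(spots))
field   <- distance_field(geom$labels, geom$voxel_size)
profile <- assign_and_profile(counted, field, geom$labels)
profile
#> enrichment_profile: 10 bins, 4 cells, 628 molecules (0 discarded)
#> pooled normalized frequency by bin:
#>      b1      b2      b3      b4      b5      b6      b7      b8      b9     b10
#> 4.16700 0.32050 0.07480 0.06295 0.10770 0.15610 0.10440 0.17470 0.16730 0.23490

membrane_fraction(profile)       # 0.879  (0.9 planted)
classify_localization(profile)   # "localized"
```

The outermost bin is 4.2-fold enriched over the random expectation of 1,
87.9% of the 628 counted molecules sit within 10% of the normalized radius
from the membrane (0.9 was planted; detection and counting recover it to
within a few percent), and the embryo is called localized. Comparing
outermost-bin frequencies between conditions:

```r
welch_test(c(3.1, 3.4, 2.9, 3.6), c(1.0, 1.1, 0.9, 1.05),
           labels = c("membrane", "uniform"))
#> Welch two-sample t-test: membrane vs uniform
#>   t = 13.88, df = 3.450, p = 0.0003782 ***
#>   means: 3.25 (n=4) vs 1.012 (n=4)
```

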