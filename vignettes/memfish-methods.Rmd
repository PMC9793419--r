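---
title: "memfish: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{memfish: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`memfish` quantifies where single mRNA molecules sit inside cells of early
embryos, from 3D smFISH image stacks, and classifies embryos as
membrane-localized or not. This vignette explains the underlying models,
every tunable parameter that matters, the numerical conventions, and the
choices we made where the design was genuinely open. Nothing here states an
empirical result that the package's test suite or `scripts/acceptance.R` do
not themselves compute.

## 1. The enrichment statistic

For a cell label volume (from manual outlines or the simulator), the
distance field assigns each interior voxel its Euclidean distance, in µm and
respecting anisotropic voxel spacing, to the nearest voxel that is not part
of the same cell — neighbouring cells' interiors count as boundary, so the
shared membrane between blastomeres behaves exactly like the outward-facing
cortex. The normalized distance divides by the cell's maximum interior
distance, an inradius proxy, so 0 is the membrane and 1 the deepest interior
point of *that* cell. Per-cell normalization makes bins comparable across
cells and embryos of different sizes; a `fixed_radius` mode is available
when an absolute scale is preferred.

Molecules are binned in `1/n_bins` increments of normalized distance
(default 10 bins; half-open bins, last bin closed) and the per-bin molecule
fraction is divided by that shell's volume fraction. The statistic is
self-normalizing: for every profile with at least one molecule,
`sum(norm_freq * volume_fraction) == 1` exactly, and a uniformly random
sample has expectation 1 in every bin. Decomposed molecule counts (not raw
spot counts) weight the bins, so an unresolved cluster of three molecules
counts as three.

**Spot-to-cell assignment.** A spot belongs to the cell whose label contains
its voxel. Spots on the membrane itself (label 0, e.g. a fit centre that
lands between two annotated outlines) are the signal of interest and must
not vanish silently: they adopt the nearest labelled voxel within one voxel
of their position; anything deeper in the background is dropped and tallied
in the profile's `n_discarded` attribute.

**Classification.** An embryo is `localized` when its pooled outermost-bin
frequency reaches `threshold` (default 1.5). The published calls this
operationalizes were made qualitatively; 1.5 sits midway between the random
baseline (1.0) and the weakest quantified enrichment classes (roughly
1.3–1.8-fold), and is configurable. Profiles with fewer than `min_spots`
molecules (default 50) return `indeterminate` rather than a call.

## 2. Distance-transform discretization

Two conventions are implemented in `distance_field()`:

* `"centers"` — plain voxel-centre transform: a voxel face-adjacent to
  background in z is one z-step away. Simple and cheap, but the half-voxel
  ambiguity of where the membrane sits biases voxel-counted shell volumes by
  several percent in the outer bins of a digital sphere.
* `"subvoxel"` (default) — the transform runs on a 2× supersampled grid
  (each voxel split into 8 subvoxels at half spacing, background/foreground
  inherited) and distances are averaged back per coarse voxel. This locates
  the membrane with sub-voxel accuracy: on a radius-30-voxel digital sphere
  the outermost three decile shells match the analytic concentric-shell
  volumes `(1-(b-1)/10)^3 - (1-b/10)^3` to within ~2% (tested), at the cost
  of an 8× larger transform, run per cell on bounding boxes.

Molecule normalized distances are read from the containing voxel (not
interpolated). This makes uniform placement over cell voxels *exactly*
consistent with voxel-counted shell volumes — the flat baseline then holds
by construction up to multinomial noise, which is the self-consistency the
simulator's ground truth guarantees.

## 3. The synthetic embryo simulator

The simulator stands in for micrographs; its defaults are the imaging
conditions of the experiments it emulates.

* **Geometry.** An eggshell ellipsoid is partitioned into 1/2/4/8 cells by a
  power diagram around canonical blastomere arrangements with seeded jitter
  and per-cell size weights. Power cells are convex, hence connected;
  sub-voxel slivers that break *digital* connectivity are migrated to an
  adjacent cell (`26`-connectivity is the package's foreground convention).
  `z_clip` optionally flattens the eggshell's top and bottom, emulating
  embryos compressed between slide and coverslip — the same flattening that
  leads analysts to exclude the uppermost and lowermost z-slices of real
  stacks. Nuclei sit at each cell's deepest interior point. Voxel spacing
  defaults to 0.2 µm axially (the acquisition z-step of the emulated
  stacks) and 0.1 µm laterally (60×/1.42 NA widefield camera sampling; the
  papers this emulates do not state the pixel pitch, so the standard
  DeltaVision value is used).
* **Placement.** `uniform` samples cell voxels with equal probability and
  jitters within the voxel. `membrane` makes a per-molecule
  Bernoulli(`membrane_fraction`) choice between the shell
  (normalized distance < `membrane_shell`, default 0.1) and the interior
  *complement*. Placing the remainder in the complement rather than the
  whole cell is deliberate: it makes `membrane_fraction` the directly
  observable shell fraction, so a planted 0.4 reads back as 0.4 (the
  "roughly 40% at the membrane" regime) instead of 0.4 + 0.6 × shell-volume
  fraction. `clustered` draws cluster centres by a hard-core rule (≥ 8
  `cluster_sigma` apart, rejection-sampled) — distinct condensates, as for
  P-granule-scale aggregates — and scatters members as an isotropic
  Gaussian truncated to the cell.
* **Rendering.** Each molecule contributes an anisotropic Gaussian at the
  PSF scale, default σ = (0.35, 0.13, 0.13) µm (z, y, x), a typical
  widefield 60×/1.42 NA scale; truncation at 4σ. Voxel `i` spans
  `[i, i+1) · voxel_size` with centre-of-voxel sampling. Noise is Poisson on
  the full expected count (signal + `background`, default 100 counts) plus
  Gaussian read noise (`gaussian_sd`, default 10). `amplitude_for_snr()`
  converts a target peak SNR into an amplitude against that noise floor.
  The membrane and DAPI channels are blurred boundary masks and nuclear
  ellipsoids — sufficient for masking workflows, with no pretence of
  optical realism (no aberrations, no autofluorescence, no deconvolution).

What passing tests on this simulator do **not** show: robustness to real
cortical autofluorescence, probe background, segmentation error in manual
outlines, or chromatic registration — real micrographs add all of these.

## 4. Spot detection and molecule counting

Detection is the standard matched-filter chain: difference-of-Gaussians
band-pass (small scale = PSF σ, large scale 3×, kernels normalized, reflect
boundaries — constants map to exactly zero), 26-connected local maxima,
then 3D Gaussian least-squares refinement (Levenberg–Marquardt via
`minpack.lm`) with separate σ\_xy and σ\_z and a constant local background,
in an odd window (default 7³ voxels, each axis ≥ 5).

* **Threshold.** Interactive per-image thresholding is not reproducible, so
  the threshold is expressed in robust noise SDs of the band-passed volume
  (`stats::mad`, 1.4826 scaling); default 5, which returns zero detections
  on pure-noise stacks.
* **Determinism.** Candidate order for minimum-separation pruning (default
  0.3 µm) is response, then raw intensity, then lexicographic voxel order.
* **Quality gates.** Fits are rejected when σ leaves `[0.5, 3] ×` the PSF
  prior, the centre leaves the window, or the amplitude is non-positive;
  windows clipped at the volume edge are flagged, not dropped. Detection is
  annotation-free: spots in excluded slices are still detected and only
  dropped downstream.

Counting converts detections into integer molecule numbers. The reference
single molecule is the median integrated intensity after iteratively
trimming values above twice the current median (removing clusters from the
reference), with the MAD of the retained spots as spread and median fit
sigmas as shape. Each spot then gets `argmax_k` of a Gaussian likelihood
with mean `k × ref` and SD `√k × spread` (spread floored at 5% of the
reference so a degenerate spread cannot pin every spot at k = 1), k from 1
to `k_max` (default 20), ties toward smaller k, counts never below 1. The
intensity-only model is a deliberate formalization — intensity carries
nearly all count information for unresolved clusters; spot shape is kept on
the reference as an extension hook. Cluster counting single-links spot
positions at `link_radius` (default 0.3 µm) and counts groups whose summed
molecule count reaches `min_molecules` (default 3).

## 5. Statistics

`welch_test()` implements the unequal-variance t statistic with
Welch–Satterthwaite degrees of freedom and a two-sided p; `stats::t.test`
serves as the independent oracle in the test suite, never as the
implementation. Stars follow the figure-legend convention (\*P<0.05 down to
\*\*\*\*P<0.00005); no multiple-testing correction is applied, matching the
reporting style the package mirrors. Identical groups are a well-defined
degenerate case (t = 0, p = 1); otherwise groups need n ≥ 2 and nonzero
variance. `nuclear_rfu()` builds the nuclear mask by Otsu thresholding the
DAPI channel inside the embryo mask (EBImage's Otsu on 256 levels) with
small components removed, and subtracts the mean intensity of the
background — the embryo-mask complement eroded by 2 voxels to avoid edge
bleed.

## 6. Synonymous recoding

`recode_cds()` replaces every codon by the synonymous codon with maximal
Hamming distance among those whose within-family usage weight is at least
`min_usage` (default 0.05) — divergent nucleotides under an expression
floor, the two constraints a probe-distinguishable but comparably expressed
transgene needs. Ties break toward higher usage, then alphabetically, so
the rule is fully deterministic (the `seed` argument is reserved). Stop
codons only ever exchange within the stop family. Amino-acid identity of
input and output is 100% for every valid CDS — this is an invariant of the
rule, enforced by construction and property-tested. The bundled usage table
is a representative genome-wide *C. elegans* compilation (approximate
per-1000 values; the recoder only consumes within-family relative weights,
and any user table with columns `codon, per_1000` can be supplied). The
actual published re-coded transgene was produced by a proprietary vendor
algorithm; this rule is our formalization, and its nucleotide identity on
any given gene is not expected to reproduce the vendor's figure.

## 7. Problem sizes and numerical notes

The test suite and acceptance script run entirely on simulated data at
sizes chosen to keep a laptop-class run comfortable while preserving the
regimes that matter:

* Baseline calibration uses a coverslip-flattened cell (`z_clip`) in which
  every decile shell holds ~9–11% of the cell volume, so 50,000 molecules
  resolve each bin frequency to ±0.05 with margin. In a digital sphere the
  innermost decile holds ~0.1% of the volume (50 expected molecules,
  ±14% Poisson noise), so per-bin flatness there is checked only on the
  outer shells — a counting-statistics floor, not an implementation limit.
* Detection-quality fixtures use 200 molecules in a cell large enough that
  under ~3% of molecules have a neighbour within the 0.6 µm separation
  limit; matching tolerance is 0.5 µm. The single-transcript-scale fixture
  (~2,400 molecules per four-cell embryo at 0.2/0.11 µm sampling) is the
  densest regime exercised, where residual recall loss is dominated by
  optically unresolvable pairs.
* End-to-end membrane-fraction recovery runs three planted fractions (0.2,
  0.4, 0.8) through rendering at SNR 5 and detection on a four-cell embryo;
  classification cohorts are 10 membrane-mode + 10 uniform-mode embryos at
  300 molecules each.

Degenerate inputs are first-class: empty volumes detect zero spots, empty
spot sets profile to zero-count bins and raise a clear error only where a
quantity is genuinely undefined (membrane fraction of an empty profile, RFU
without nuclear voxels, reference from zero spots), and cells that vanish
after slice exclusion name themselves in the error.

## 8. Known limitations

* Cell geometry is convex-ish by construction (power-diagram blastomeres);
  strongly non-convex real cells can make the per-cell maximum interior
  distance a coarse normalizer.
* The PSF is a separable Gaussian; no depth-dependent aberration, so axial
  localization accuracy on real widefield stacks will be worse than on
  renders.
* The intensity-only decomposition assumes cluster intensity scales
  linearly with molecule number (no quenching, no probe saturation).
* OME-TIFF metadata travels in a `.ome.xml` companion file rather than the
  TIFF ImageDescription tag (the available TIFF writer cannot embed one);
  readers that insist on in-file OME-XML will see a plain multi-page TIFF.
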