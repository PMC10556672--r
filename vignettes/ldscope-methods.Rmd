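---
title: "Quantifying lipid-droplet and plastid dynamics in Phaeodactylum tricornutum"
author: "ldscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lipid-droplet and plastid dynamics in Phaeodactylum tricornutum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Diatoms such as *Phaeodactylum tricornutum* respond to nitrogen starvation
by storing neutral lipids in cytoplasmic lipid droplets (LDs), partly at the
expense of the plastid's thylakoid membranes; on nitrogen resupply the LDs
are degraded again. Two well-studied ecotypes differ in strategy: Pt4 cells
concentrate most of their lipid in two large LDs, while Pt1 cells spread
the same investment over more, smaller droplets. Quantifying this requires
three kinds of measurement on microscopy data:

1. **Cell morphometry** from brightfield mosaics: thousands of fusiform
   (spindle-shaped) cells per sample are segmented by a supervised pixel
   classifier, screened with shape descriptors, and their volumes estimated
   with a prolate-spheroid model,
   $V = \frac{\pi}{6}\, W^2 L$,
   where $W$ is the minor axis of the fitted ellipse and $L$ the Feret
   (maximum caliper) diameter, both in micrometres.
2. **3D organelle modelling** from two-channel confocal z-stacks
   (chlorophyll autofluorescence for the thylakoid region, BODIPY 505/515
   for LDs): per-object volumes and barycenters, with touching LDs split by
   a watershed, and per-LD distance to the plastid barycenter
   $d = \sqrt{(x_{LD}-x_P)^2 + (y_{LD}-y_P)^2 + (z_{LD}-z_P)^2}$.
3. **Population statistics**: per-cell LD counts and volumes summarised as
   mean ± SD per ecotype and timepoint, one-way ANOVA with Fisher's LSD
   post-hoc rendered as compact letter displays, and between-ecotype
   t-tests rendered as asterisk codes.

Because the original image data are not deposited, the package ships a
synthetic scene generator with exact ground truth; every pipeline stage is
validated as a recovery problem on data whose answer is known.

## The synthetic generator

`scene_config()` fixes the study conditions. Defaults are the measured
population ranges: Pt1 width 3.5–4 µm and length 22.6–23.5 µm; Pt4 width
4–4.4 µm and length 27.7–28.6 µm; confocal voxels 0.072 × 0.072 × 0.1 µm
(the 0.1 µm z-step is the published acquisition setting; the xy size is a
documented default for a ×63 objective at zoom ×2.5, which the source
instrument metadata does not state). Brightfield pixels default to 0.23 µm,
typical of a ×50/0.5 tube-lens configuration.

**Cell outline.** The fusiform profile is a tapered spindle with half-width
$h(x) = w\,(1-(2x/L)^2)$. Only two properties of the outline matter
downstream — the fitted-ellipse minor axis and the Feret diameter — so the
generator calibrates $w$ analytically such that the second-moment fitted
ellipse of the drawn shape has minor axis exactly equal to the nominal
width: the profile's moments give minor $= 1.905\,w$, hence
$w = W/1.905$. Likewise the drawn tips extend slightly beyond
$\pm L/2$ so the half-coverage point of the digitised profile — hence the
measured Feret diameter — sits at the nominal length. The recorded truth
volume applies the prolate-spheroid model to the nominal $(W, L)$. Cells
are rendered dark on a light background with radial internal shading
(darker midline), so each cell spans a range of intensities as real
brightfield cells do.

**LD strategies.** Four placement strategies emulate the observed
populations: `basal_only` draws only small LDs (0.005–0.7 µm³, truncated
log-normal around 0.15 µm³, the N-replete state); `two_large_dominant`
places two large LDs holding 87–93% of the configured total plus a basal
set (Pt4-like, default total 8.7 µm³); `many_medium` draws 4–8
gamma-distributed volumes resampled until the two largest hold between 58%
and 72% — the observed Pt1 repartition (Pt1-like, default total 6.2 µm³); `fragmented_distant` scatters 10–14
small LDs, 80% of them beyond 5.2 µm from the plastid barycenter along the
cell arms (the post-resupply fragmentation scenario, default total 3 µm³).
Default totals follow the published group means at the corresponding
timepoints (D11 for the two accumulation strategies, h24-like for
fragmentation). LDs are placed inside the cell envelope with
non-overlapping rejection sampling; an impossible load (total LD volume
beyond a quarter of the envelope) is rejected with a message.

**Plastid.** A central bilobed region built from two overlapping prolate
lobes (semi-length 0.18 L, semi-width 0.55 µm, offset ±0.45 µm across the
cell axis), giving a D0-like thylakoid-region volume near 10–14 µm³ with
its barycenter on the cell's long axis.

**Optics and noise.** Channels are blurred with an anisotropic Gaussian
point-spread approximation (default σ = 0.1, 0.1, 0.15 µm) — the real
acquisitions were deconvolved upstream, so a full PSF model is out of
scope — and corrupted with Poisson counting noise (the detectors ran in
photon-counting mode), at a default peak of 80 counts plus a background of
0.8 × `noise_level` counts. `noise_level = 0` with `psf_sigma_um = 0`
yields deterministic, analytically checkable stacks. All outputs are
bit-reproducible from `seed`.

**What the generator does not emulate**: optical aberrations and depth
dependence of the PSF, chromatic offsets between channels, detector
afterpulsing, non-spherical LDs, cell-to-cell intensity variation, and the
triradiate/oval morphotypes. Passing recovery tests on these scenes shows
the measurement chain is unbiased under the stated image-formation model,
not that it is robust to every real-world artifact.

## Brightfield morphometry

Features per pixel: raw intensity, Sobel gradient magnitude, a
moving-maximum texture response (radius 2 px), and Gabor energy from a
four-orientation bank (σ = 3 px, wavelength 8 px) aggregated to its
maximum and mean — rotation-invariant responses, so a classifier trained
on a handful of cells generalises to orientations absent from the
training set. The source protocol names the three filter families but not
their parameters, so all are exposed as arguments. The classifier is a
bagged decision-tree ensemble (random forest, 40 trees) trained on sparse
annotations — by default 20% of the cells of one scene and an equal
number of background pixels: 40% of those in a band 3–6 px outside the
annotated cells (so the halo decision boundary is well determined), 20%
on distractor objects, the rest uniform over the background. The probability map is thresholded at 0.5 (the
protocol does not state a threshold; 0.5 is the natural choice for a
two-class probability) and connected components are measured:

* area = pixel count × pixel area; perimeter = traced-contour polygon
  length; circularity $= 4\pi A / P^2$;
* fitted ellipse = second-central-moment ellipse rescaled to match the
  pixel area (the source tool's semantics), with a 1/12 px² pixel-extent
  term so single-row objects stay non-degenerate;
* Feret diameter = maximum pairwise distance over the convex hull of the
  contour; AR = major/minor; roundness $= 4A/(\pi\,\mathrm{major}^2)$;
  solidity = area / convex-hull area with the hull taken over pixel
  corners (taking it over pixel centres would push solidity above 1);
* width = ellipse minor, length = Feret, volume = prolate-spheroid model.

The ecotype screens are applied conjunctively exactly as published: area
25–200 µm², circularity 0–0.4, then AR ≥ 3 / roundness ≤ 0.3 /
solidity ≥ 0.55 for Pt1 and AR ≥ 3.5 / roundness ≤ 0.3 / solidity ≥ 0.5
for Pt4. Touching cells are not split; merged blobs fail the shape screen,
mirroring the original macro. Classification is per image file.

## 3D object modelling

Each channel is preprocessed with its published parameter pair
(`smooth_um`/`background_um`: thylakoid 0.3/0.2; LD 0.1/0.2 for Pt1 and
0.1/0.4 for Pt4). Smoothing is an anisotropic Gaussian at the stated
physical scale. The background parameter's semantics in the original
commercial tool are proprietary; here the baseline is estimated by a much
broader Gaussian (10× the background scale, computed on a decimated grid
for speed) and subtracted with clipping at zero — the parameter is
preserved as the fine scale whose local contrast must survive, and a
constant stack maps exactly to zero.

Binarisation defaults to Otsu's threshold (the original level is
unstated). A fixed global threshold, however, biases voxel-count volumes
in a blur- and context-dependent way (small droplets inflate when the
threshold sits in their blur skirt and shrink under per-object half-peak
rules). `analyze_cell_stack()` therefore defaults to a **volume-matched
binarisation**: after a first Otsu pass identifies objects, the channel's
plateau amplitude $A$ is estimated from the brightest object's 95th
intensity percentile; regions are regrown down to a floor of 0.04 A so
each object's region captures its skirt; and each object keeps its
brightest $N$ voxels with $N = \sum I / A$ — its integrated intensity in
plateau units, which a Gaussian blur leaves invariant. Volumes remain
voxel counts times the voxel volume. Objects whose photometric volume
falls below `min_voxels` (default 4 voxels ≈ 0.002 µm³) are dropped as
sub-detection.

Touching objects are split by a seeded watershed on the anisotropic
Euclidean distance transform (26-connectivity; both written in C++ since
the installed image packages provide only 2D versions). Seeds are local
EDT maxima; seed clusters whose centre lies inside another's inscribed
sphere are merged, which suppresses spurious ridge maxima inside a single
convex object while keeping the two centres of moderately overlapping
spheres apart.

Objects whose barycenter falls outside the cell mask are removed (the mask
is an input — in the original workflow it was drawn from transmitted
light; in synthetic mode it is the generator's envelope). Barycenters are
geometric (unweighted) voxel-centre centroids in physical coordinates with
the origin at the stack corner; whether the original tool weighted by
intensity is unknowable, and the distance definition is agnostic to the
choice. The thylakoid region is the single largest connected chlorophyll
object per cell (the plastid is one bilobed body); its volume carries a
small positive bias from the 0.3 µm smoothing scale.

## LD metrics and reference arithmetic

Per cell: LD count, total LD volume, the fraction of total LD volume in
the two largest droplets (only for cells with ≥ 3 LDs, matching the
published restriction; the minimum is configurable), size classes with an
inclusive 0.7 µm³ boundary (the published range gives no boundary rule;
volumes below 0.005 µm³ are flagged sub-detection), and distance classes
with an inclusive 5 µm boundary.

The individual mean LD volume (`V_Lipid/LD`) is defined as the **ratio of
group means**, mean(total LD volume) / mean(LD count). This definition
reproduces the published per-group values from the published means in 11
of 12 ecotype × timepoint groups exactly at two decimals; the twelfth
(Pt4, D3) differs by 0.006, which is within the rounding already present
in the printed inputs. The mean of per-cell ratios does not reproduce the
printed values. No dispersion is attached to this ratio: none follows
from the per-cell data, and the provenance of the published ± for it is
not stated.

`reference_group_means()` ships the published group means (LD counts,
total LD volumes, cell volumes) as a plain data frame so the derived
report — LD share of cell volume, starvation volume changes, the
between-ecotype volume ratio — can be recomputed from first principles.

## Statistics

Normality is screened per group with Shapiro–Wilk (groups under n = 3 are
skipped with a note; analysis proceeds with a warning on failure, since
the published protocol states no fallback). The one-way ANOVA gates
pairwise Fisher LSD tests (pooled within-group variance, no multiplicity
correction — that is the published procedure) at α = 0.05; the letter
display is assembled from the maximal cliques of the non-significance
graph, ordered so 'a' contains the highest mean — two levels share a
letter exactly when their pairwise test is non-significant. Ecotype
comparisons default to the pooled-variance t-test (the published variant
is unstated; Welch is a switch) with asterisk bands `*` 0.01<p<0.05, `**`
0.001<p<0.01, `***` p<0.001; boundary values map to the weaker band since
the published bands are open intervals. Division rates are
$\log_2(n_2/n_1)/\Delta t$ — doublings per day.

## Pigments

Chlorophyll a and c₁+c₂ are computed from 90% acetone extract spectra with
the trichromatic equations (coefficients shipped in a YAML config so other
solvent systems can be swapped in):
chl a = 11.85 A₆₆₄ − 1.54 A₆₄₇ − 0.08 A₆₃₀;
chl c = 24.52 A₆₃₀ − 7.60 A₆₄₇ − 1.67 A₆₆₄ (µg/mL, 1 cm path).
A 750 nm turbidity correction is applied by default (standard practice,
toggleable). Per-cell content is concentration × extract volume /
(culture volume × cell density); the extract volume depends on the number
of lysis cycles and is therefore a required input. The synthetic spectrum
generator solves a 2×2 linear system so its Gaussian bands invert exactly
to the requested concentrations — a round-trip oracle for the equations.

## Problem sizes and numerical choices

The shipped tests run recovery at these scales: 200 planted brightfield
cells (8 scenes of 25, classifier trained on one scene), 30 confocal
stacks (10 per LD strategy), and 1000 null replicates for the ANOVA
calibration, chosen to give stable medians while keeping the default
suite quick on a single core. Connectivity is 26 in 3D and 8 in 2D
(configurable). Ties in the watershed flood are broken first-in-first-out.
The Feret computation reduces to convex-hull points, which is exact. The
2D fitted-ellipse test uses a half-integer-centred digitised ellipse: an
integer-centred one has degenerate tangency rows that inflate AR by ~6%
regardless of estimator.

## Known limitations

* Thylakoid volumes inherit a small positive bias from their 0.3 µm
  smoothing scale; the thylakoid is treated as exactly one object.
* Volume-matched binarisation assumes objects share a common plateau
  amplitude per channel (true for a saturating lipophilic dye; weaker for
  heterogeneous staining).
* Sub-voxel droplets (below ~4 voxels photometric volume) are reported as
  sub-detection, not quantified.
* The brightfield stage measures only the fusiform morphotype; merged
  cell clumps are discarded by the shape screen rather than split.
* Real-data mode expects TIFF + JSON-sidecar inputs produced by this
  package's writers (or matching their layout); proprietary microscope
  formats must be converted upstream.
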