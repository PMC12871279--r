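---
title: "merscape: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{merscape: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific model behind each processing stage,
the tunable parameters and their defaults, the numerical choices made
where the method description left them open, and what the synthetic
fixtures do and do not establish.

## The processing model

An imaging-based spatial transcriptomics section arrives as a table of
decoded transcripts: gene (or blank codeword), x/y/z in micrometres, and
a section id. The pipeline's job is to turn that table into a filtered
cell-by-gene matrix with per-cell geometry, and the package implements
the computational stages around two external, pluggable components (a
volumetric segmentation model and a deep-learning doublet scorer):

* **Density stain.** Cytoplasmic segmentation needs a cytosol channel.
  PolyT stains recapitulate somata poorly, so a stain-like image is
  synthesized from the transcripts themselves: a 3D histogram binned on
  the imaging (DAPI) grid, a Gaussian blur, and a 3D median filter.
  Defaults (`density_params()`): sigma_z = 1, sigma_xy = 3 voxels;
  median windows 2 (z) and 10 (x/y) voxels. Units are voxels at the
  binning resolution — the description does not say whether sigma and
  window are micrometres or pixels, and voxels keep the filters
  resolution-independent. Whether "2" and "10" denote full window
  widths or radii is equally open; the default reading is full widths,
  with `window_mode = "radius"` exposing the other. Even windows are
  rounded up to the next odd integer for centering (the verbatim values
  stay in the stored parameters), and both filters use reflect padding.
* **Tiling and stitching.** Sections are processed in overlapping
  350 x 350 um tiles (overlap width is not specified upstream; the
  default is 50 um, configurable) ordered row-major from the minimum
  corner. The later-processed tile is the "newer" one. When two cells
  from different tiles share transcripts in the overlap, let `s` be the
  shared fraction of the *smaller* cell's transcripts (ties by
  lexicographic id): if `s > 0.5` strictly, the smaller cell's id is
  replaced by the larger's; otherwise each contested transcript goes to
  the newer tile's cell. A transcript never ends up in two cells.
* **Builtin segmenter.** The production segmenter is an external
  volumetric Cellpose model. So the stage runs and is testable offline,
  the builtin stand-in thresholds the smoothed density (Otsu), takes
  the Euclidean distance transform of the foreground
  (Felzenszwalb-Huttenlocher separable passes), seeds on
  26-neighbourhood local maxima of the density, and floods a watershed
  over the distance transform in synchronous rounds (each unlabeled
  voxel adopts the label of its deepest labeled neighbour). This is a
  test stand-in: it separates touching blobs with distinct peaks but is
  no substitute for a trained model on real tissue.
* **Alpha-shape boundaries.** Cell boundaries are per-z-plane 2D alpha
  shapes of the cell's transcript positions. The alpha complex keeps
  Delaunay triangles with circumradius at most `r`; in the inverse
  convention used by the common alpha-shape tools (alpha = 1/r, larger
  alpha = tighter shape), the search finds the *maximum* alpha whose
  shape is a single closed polygon — implemented as a 30-iteration
  bisection for the minimal `r` over `[0, diameter]`, ties toward
  smaller alpha — and then multiplies alpha by 0.75, loosening the
  outline toward biologically plausible convexity. If the scaled alpha
  still yields several components the largest-area one is kept. Volume
  is the sum of plane areas times the z spacing; the reported 2D area
  is the maximum single-plane area (the plane is not specified
  upstream); the polygon centroid is area-weighted across planes.

## Filters

* **Low-quality cells** are removed when genes < 6, transcripts < 30,
  or blank fraction >= 2% (`qc_thresholds()`). The 2% line is stated
  without inclusivity; removal at exactly 2% is the package's reading.
  No volume floor is applied (the 3D segmentation's volume distribution
  shows no clear lower threshold) and no upper transcript cutoff
  (superseded by doublet detection). Transcript density is reported per
  um^3 — the only dimensionally consistent reading of a
  "transcripts/um" axis — and is undefined for zero-volume cells.
* **Doublets.** The score difference is `dif = doublet - singlet`, so
  doublet-like cells sit high; the threshold is
  `q0.9(dif) - q0.1(dif)` with linear-interpolation quantiles
  (`type = 7`, index `p (n-1)`) over the *predicted doublets*
  (`doublet_p >= singlet_p`; ties included so a fully degenerate dif
  distribution yields threshold 0 and no flags). Cells with dif
  strictly above the threshold are flagged. The upstream prose does not
  fix the sign of dif or the flagging side; `convention =
  "singlet_minus_doublet"` inverts both consistently (the flag set is
  identical). The builtin scorer simulates twice as many artificial
  doublets as cells (summed random pairs), embeds everything by PCA of
  library-size/log1p-normalized counts plus a standardized
  log-library-size axis (depth is the main doublet signal that
  normalization removes), and votes with k = 15 neighbours.
* **Mapping filter.** Per cell type, `double_mad()` computes separate
  MADs below and above the median (the median belongs to both sides,
  which stabilizes ties); the cutoff is `median - 3 x MAD_low` and
  values strictly below are removed, with a 1e-12 relative tolerance so
  a value exactly at the cutoff survives floating-point round-off.
  Bimodal distributions first discard the mode below the KDE local
  minimum. Bimodality requires: exactly two KDE modes (Gaussian kernel,
  Silverman bandwidth, 512-point grid over the data range — the
  upstream work used an external package; this recipe is fixed for
  reproducibility); the minor mode holding >= 10% of the density
  (split at the local minimum); the local minimum within
  `median +/- 0.05`; and a normalized peak-height difference < 0.05.
  The height-difference reading of "difference between the two mode
  peaks" is a design decision (peak *locations* within 0.05 would
  preclude a resolvable minimum between them). Note its consequence:
  only near-balanced mixtures qualify under the defaults, because a
  minority mode is both lower-peaked and leaves the median inside the
  major mode. The parameters are configurable where a laxer screen is
  wanted. One robustness guard is added beyond the stated criteria: the
  KDE height at the local minimum must fall below 90% of the smaller
  peak, because discretization wiggles at a flat mode top otherwise
  satisfy all three criteria on perfectly unimodal data.

## Spatial domains, registration, imputation scoring

* **Grids and stability.** Transcripts are aggregated into half-open
  30 um bins; grids are kept with >= 60 genes, >= 300 transcripts and
  < 3% blanks. The spatially aware embedding itself (a graph attention
  autoencoder in the upstream work) is consumed, not reimplemented; a
  PCA of normalized grid counts (`grid_pca_embedding()`) stands in so
  the stage runs end-to-end. Stability: 25 subsamples of 80% of nodes,
  Leiden (modularity objective, k = 15 neighbour graph) per resolution,
  all subsample pairs scored by ARI and AMI on shared nodes. The
  resolution sweep defaults to 0.2-2.0 in 0.1 steps (the upstream
  Methods and Results disagree on the lower end; the wider range is the
  default and the sweep is configurable). AMI is implemented from the
  expected-mutual-information formula (no R implementation is
  installed); ARI is cross-checked against igraph's implementation in
  the tests. Note that on perfectly separated domains exact unity of
  ARI/AMI holds at low-to-mid resolutions; far above 1, modularity's
  resolution limit fragments even ideal domains, which is a property of
  the objective, not an instability of the data.
* **Registration.** QuickNII anchors give `o`, `u`, `v` vectors mapping
  normalized image coordinates into the atlas
  (`o + x_norm u + y_norm v`, normalization by image width/height);
  VisuAlign landmark pairs drive a barycentric warp over the Delaunay
  triangulation of the source markers. Cells outside the triangulation
  use the affine extension of the nearest triangle (by edge distance) —
  dropping them is the configurable alternative. Annotation lookup
  floors coordinates to 25 um voxels; outside the volume is label 0.
  The synthetic alignment fixture plants an *affine* warp so that the
  piecewise-linear interpolation is exact everywhere and round trips
  can be asserted to 1e-9; a genuinely non-linear warp would only agree
  at the landmarks.
* **COVET / MSSI.** The niche of a cell is its k = 8 nearest spatial
  neighbours, excluding the focal cell (the usual convention, left
  unstated upstream; configurable), summarized as the gene-gene
  covariance of deviations from the *global* mean expression. The MSSI
  compares two spatial expression patterns without any cell matching:
  independent k = 8 kNN graphs, 4 coarsening steps of factor ~2
  (one-step neighbourhood blur, then greedy maximal matching in
  node-index order with mean pooling — the exact pooling operator of
  the original index is unspecified; this one is validated by the
  self-similarity and symmetry properties), and per scale the product
  of SSIM-style luminance and contrast terms with a distribution-based
  structure term: the Pearson correlation of 64-bin normalized
  histograms over the pooled value range. The stabilizing constants are
  `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with `L` the pooled dynamic
  range of *both* datasets — using the reference range alone would
  break the symmetry property `mssi(a,b) = mssi(b,a)`, which the
  package treats as non-negotiable. Because the structure term is
  distribution-based, it is permutation-invariant at the original
  scale; spatial signal enters through the blurred and coarsened
  scales.

## The synthetic world

`generate_section()` emulates a small MERSCOPE-like field of view:
somata as 3D Gaussian blobs of radius ~5 um (sd 0.8), 7 z-planes at
1.5 um spacing, ~200 transcripts per soma (Poisson), three divisions
with mutually exclusive marker blocks (80% marker mass, 20% shared
housekeeping genes), extracellular noise at 0.02 transcripts/um^2,
blank codewords at a 0.8% per-cell rate (so a few percent of cells
exceed the 2% blank threshold, matching a world where most cells sit
below 2% and all filters together remove well under 10%), doublets as
planted cell pairs under 5 um apart at a 3% rate (matching the reported
sparse doublet incidence), and an optional fraction of planted
low-quality cells that emit only a handful of transcripts from three
genes. All generators are pure functions of their seed and restore the
global RNG state.

What a green test does **not** establish: the builtin segmenter's
behaviour on real tissue (blobs are isotropic and background is clean),
the doublet scorer's performance against a trained VAE, mapping-score
distributions of a real taxonomy (the planted modes are Gaussian with
fixed sd 0.03), or registration through genuinely non-linear tissue
deformation. The fixtures establish the *logic*: conservation,
thresholds and boundary conditions, merge rules, analytic transforms,
and estimator properties (oracle equivalence, symmetry, equivariance,
self-similarity).

## Known limitations

* The builtin watershed operates in synchronous rounds rather than a
  strict global priority queue; at ridge voxels the label choice
  depends on the local distance-transform comparison only. At fixture
  scale this is indistinguishable from a strict flood.
* Heavy-edge matching on an unweighted kNN graph is an arbitrary
  maximal matching; node counts shrink by slightly less than half when
  isolated singletons remain.
* `write_cell_matrix()` follows the anndata on-disk layout closely
  enough for round-tripping and interoperability of the arrays, but
  categorical/sparse encodings of full-featured writers are not
  implemented.
* The quantile doublet threshold is aggressive when the predicted
  doublets' dif distribution is tight; this mirrors the stated rule
  rather than a package choice.
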