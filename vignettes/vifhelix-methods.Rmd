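---
title: "Determining the helical architecture of vimentin filaments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining the helical architecture of vimentin filaments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vifhelix)
```

# The problem

Vimentin intermediate filaments (VIFs) are built from elongated coiled-coil
tetramers that intertwine during polymerization. Unlike actin or
microtubules, their asymmetric unit is ~65 nm long and partly disordered,
so the filament's helical symmetry cannot be read off a single projection;
it has to be pieced together from the axial periodicities visible in the
power spectra of many filament images, cross-checked against an explicit
model of how tetramers can pack into protofibrils. This package implements
both halves of that argument — the spectral measurement and the lattice
model — plus a synthetic data generator that produces filament images and
volumes with known ground truth so every stage can be verified
quantitatively.

# Helical symmetry and its estimation

A helical polymer is described by the rise $h_r$ (axial translation per
asymmetric unit, here one tetramer) and twist (rotation per unit). With $n$
units per pitch $P$,

$$P = n \, h_r, \qquad \mathrm{twist} = 360^\circ / n .$$

`n` is real-valued; VIFs have $n \approx 4.88$, i.e. the packing is slightly
incommensurate with a five-fold rotation. Angles are stored in degrees and
lengths in Angstrom throughout; nm appears only in reports. The handedness
of the twist cannot be determined from projection power spectra, so the
package defaults to right-handed (`handedness = +1`) as an explicit,
arbitrary convention with a flag to flip it.

Three estimators are layered:

1. **Initial estimate** (`initial_symmetry_estimate`): a filament of $k$
   protofibrils with axial periodicity $T$ has twist $360/k$ and rise
   $T/k$. Five protofibrils with the classic ~210 A intermediate-filament
   periodicity give 72 deg / 42 A; with the ~185 A repeat measured on 2D
   class averages, 72 deg / 37 A.
2. **Meridional scan** (`scan_meridional_bessel`): the rise produces a
   meridional (Bessel order 0) reflection at $1/h_r$. One-pixel rows of the
   averaged power spectrum inside a search band (default 1/69 to 1/30 1/A)
   are compared against the template $J_0(2\pi R r)$ for an assumed
   filament radius $R$ (default 55 A). The row maximizing the match, with
   3-point parabolic sub-pixel refinement, gives $h_r$.
3. **Layer-line indexing** (`index_layer_lines`): the layer lines bundled
   around the pitch reflection ($P_i$) are paired in order with those
   around the meridional ($h_i$), and $n$ is fitted by the closed-form
   least squares $n = \sum P_i h_i / \sum h_i^2$, which is unique,
   deterministic and scale-equivariant. On the four measured pairs this
   yields $n = 4.8804$ and twist $360/n = 73.76^\circ$.

## Numerical choices in the scan

Two decisions in `scan_meridional_bessel` were genuinely open and are worth
recording. First, the row-versus-template comparison uses the *normalized*
(Pearson) correlation, which discriminates the meridional's centered peak
from off-meridional Bessel orders (which dip at the meridian) regardless of
intensity scale. Second, normalization alone is unsafe on nearly noiseless
spectra: a row containing only faint spectral leakage from a neighbouring
layer line can correlate almost perfectly with the template's central lobe.
Rows whose RMS amplitude is below a fraction (default 0.2) of the strongest
row in the band are therefore ineligible as the best row. With both rules
the scan identifies the correct row on noiseless tall spectra, on the
five-fold control, and across noisy seeds; with either rule alone it has
identifiable failure modes (amplitude weighting lets strong $J_1$ lines
win; bare correlation lets empty rows win).

`pick_layer_lines` integrates spectrum amplitude laterally over a window of
0.03 1/A about the meridian before peak-finding. The window is wide enough
to include the first maxima of Bessel orders up to ~5 at the protofibril
radius, so off-meridional layer lines register in the axial profile; a
narrow (few-pixel) window would see only meridional intensity.

# The lattice model

`build_tetramer` places four rod chains as two antiparallel, half-staggered
dimers with aligned 1B domains (the A11 tetramer). The calibration
constants (all overridable in `tetramer_geometry`) are:

* CTE-to-CTE span 650 A (~65 nm tetramer length);
* axial chain core coil1 (205 A) + L12 (10 A) + coil2 (210 A) = **425 A**;
* 1A-1B NTE tips protruding toward the lumen, 290 A apart in pairs;
* 1A-1B bundles at radius 28 A, 2A-2B bundles at 48 A (protofibril center
  38 A), bead envelope reaching the 55 A filament radius;
* heads as luminal bead strings at radius 8 A, tails at the CTEs directed
  toward the neighbouring protofibril.

The 425 A core is the load-bearing number: it equals exactly two
protofibril periods ($2 \times 5 \times 42.5$ A), so when
`assemble_filament` replicates the tetramer with the helical operator and
books tetramer $k$ into protofibril $k \bmod 5$, each protofibril's
cross-section is octameric (two 4-chain spans overlap at every height) and
the five-protofibril filament carries exactly 40 rod chains in its central
plateau. Chain spans are counted as half-open intervals $[z_{min},
z_{max})$ so end-to-end chains tile the axis without double counting. The
luminal NTE protrusion (residues 86-99) leaves the rod cylinder toward the
head attachment and is excluded from the span — the cross-section count is
a count of *rod* chains, matching how the 40 is defined; including the
protrusion would make the count oscillate between 8 and 10 per protofibril
for purely geometric reasons.

Consequences the model reproduces without further tuning:

* assembly pathway counts 4 → 6 → 8 chains (one, two, three tetramers of a
  protofibril), 15 tetramers minimal for a full filament, 5 for a
  unit-length filament, 3 per minimal protofibril (~110 nm between CTEs);
* conserved-1A (residues 100-125) and conserved-2B (380-411) segments of
  successive tetramers coincide axially, forming interlock sites on both
  sides of each protofibril spaced $5 \times 42.5 = 212.5$ A (~21 nm) — a
  pure symmetry consequence, independent of the tetramer geometry details;
* the NTE pair of each tetramer reaches 32.5 A past its predecessor's CTE
  (the A$_{CN}$ co-extension, inside the expected 30-40 A window);
* mass per length $4 \times 53.652\ \mathrm{kDa} / 4.25\ \mathrm{nm} =
  50.5$ kDa/nm. The monomer mass is the molecular weight of the
  466-residue human vimentin chain, carried as a package constant and
  distributed over beads in proportion to the residues each represents.

`minimal_tetramer_count("protofibril_repeat")` assembles a *single*
protofibril under the protofibril's own symmetry (rise 212.5 A, twist
$5 \times 73.7 \bmod 360 = 8.5^\circ$, `protofibril_params()`), which is
the natural description of an isolated strand; in the full filament the
same spacing arises automatically from tetramer bookkeeping.

# The synthetic data generator

The generator emulates, with known ground truth, the data the analysis
needs: noisy 2D projection segments with per-segment transform records,
3D density maps, missing-wedge-corrupted volumes, and bent filaments.

* **Beads are isotropic Gaussians** (sd 4 A). The analysis operates at
  ~7-20 A resolution, where blob rendering is adequate; no atomic detail
  is modelled, and the cross-beta structure of the luminal fiber is
  explicitly out of scope.
* **Projections** are analytic line integrals of the blobs over a slab
  (default thickness 220 A), sampled on a 3.44 A / 110 px grid — a typical
  binned tomography geometry. Each segment is rotated by a random in-plane
  angle and shifted by a random sub-box offset *in bead coordinates before
  rendering*, so the recorded transform reproduces the noiseless image
  exactly, with no interpolation error in the ground truth.
* **Noise** is additive white Gaussian, scaled to the noiseless signal
  RMS. There is no CTF, no dose weighting and no per-tilt image formation;
  the missing wedge is applied as an aggregate Fourier mask
  (tilt axis x, wedge in the $k_y$-$k_z$ plane, tilts within
  $[-60^\circ, 60^\circ]$ kept by default).
* **Bent filaments** transport a rotation-minimizing frame along an
  arc-length-parameterized spline; curvature radii below twice the
  filament radius are rejected.
* **Determinism**: every stochastic output is a function of (inputs,
  seed); the seed is recorded in the per-segment records.

Because the generator shares the package's own geometry, passing tests
demonstrate internal consistency of the method chain — simulation,
spectral measurement, indexing, counting — under controlled noise. They do
not certify performance on real micrographs, which add CTF, structured
background, filament polymorphism and classification errors that are
deliberately out of scope here.

## What the spectra of the synthetic filament contain

For the bead model, the meridional intensity at $1/h_r$ is carried by the
axially localized features (chain ends, NTE/head/tail beads): uniform bead
strings spanning an integer number of rises cancel exactly in the $1/h_r$
Fourier component. This mirrors the physical situation — meridional
reflections come from axially modulated density, not from the smooth rod
background. The pitch layer line at $1/207.5$ A is a Bessel order 1 line
and needs a tall spectrum to resolve; segment-sized boxes (110 px) resolve
the meridional band but not the pitch line, which is why the pipeline
composites segments into long filament images (the computational assembly
step) before picking layer lines. For an exactly five-fold control (twist
72 deg) the layer lines sit at $k/P$ with the meridional on the fifth —
the selection-rule check used in the tests.

# Computational filament assembly

`align_segments` assigns each segment a reference, an in-plane rotation
(discretized grid, default 2 deg) and integer shifts by FFT
cross-correlation; `composite_ca_filament` inverts each record and pastes
the class average back into the filament frame, averaging overlaps with
equal weight (unweighted mean; feathering was considered and rejected as
unnecessary for the equal-exposure synthetic data). Compositing precedes
straightening: `straighten_filament` resamples the image along the
arc-length parameterization of a spline through the centerline with unit
speed, so output height equals arc length and total intensity is conserved
to ~1%. All resampling is bilinear, and pixels with zero paste support are
flagged rather than interpolated.

`autocorrelation_repeat` measures axial periodicity on the unbiased,
variance-normalized autocorrelation (axial profile at zero lateral lag,
zero-padded to avoid circular wrap). The repeat is the *first* local
maximum reaching 90% of the strongest one — preferring the fundamental
over its multiples while remaining robust to a slightly attenuated first
peak.

# Cross-section analysis

`extract_cross_sections` integrates slabs (default 8.84 A, a typical
4x-binned tomogram voxel stack) perpendicular to the filament axis;
`count_protofibrils` integrates an annulus at the protofibril radius
(default 38 +/- 10 A) into an angular profile (2 deg bins, light circular
smoothing) and counts peaks with topographic prominence above 20% of the
profile's max-minus-median. On the central plateau of the default model,
sections count five protofibrils essentially always; near the filament
ends occupancy ramps down and counts drop, so analyses sample the plateau
— as cross-sections of real filaments are taken far from filament tips.

Sections one rise apart are related by one helical twist, so
`average_fixed_alignment` with rotations $-k \cdot \mathrm{twist}$ (no
alignment search) averages rise-spaced sections coherently. The angular
contrast of the protofibril pattern is quantified by
`angular_periodicity`: the circular autocorrelation of the annular profile
at the 72 deg lag. A $\pm 60^\circ$ missing wedge degrades this
periodicity in sections lying in wedge-affected planes — the package
demonstrates the artifact; learned missing-wedge restoration is not
implemented.

The peak-to-mean ratio (`contrast` field) is reported as well, but it is
the wrong statistic for wedge comparisons: the wedge suppresses the
annulus baseline, which *raises* max/mean even as the five-fold pattern
disintegrates. The periodicity statistic does not have this pathology.

# The end-to-end pipeline

`run_filament_pipeline` chains the stages: simulate a filament at the default
symmetry → project noisy segments → averaged power spectrum → segment-level
meridional scan → composite the segments into a long filament image → boxed
long-range spectrum → meridional scan and layer-line picks at high axial
resolution → index $P = n h$ → lattice queries (40 chains, minimal counts,
interlock spacing, A$_{CN}$) → cross-section protofibril count. A single
seed drives all randomness; two runs with the same seed produce
byte-identical reports. Default problem sizes (200 segments of a ~9000 A
filament, a 512-pixel long-range box, 50 cross-sections) keep a full run
around half a minute while leaving the meridional row quantization well
below the tolerance of the parameter recovery; the tests use the same
machinery at somewhat smaller sizes.

# Known limitations

* The bead model is piecewise-rigid: each tetramer is a rigid copy of the
  template, so protofibrils wind as polygonal, not smooth, helices (8.5
  deg per 212.5 A). At the resolutions analysed this is invisible.
* No CTF, no structured noise, no filament polymorphism, no classification
  errors: recovery rates measured here are upper bounds on real-data
  performance.
* The handedness of the twist is conventionally positive; nothing in the
  implemented measurements could determine it.
* `index_layer_lines` pairs the two layer-line sequences positionally; no
  combinatorial matching of line bundles is attempted, and higher Bessel
  orders are not indexed.
* The printed pitch (207.4 A) and $n \times h_r$ (207.5 A) differ in the
  last digit because the inputs are rounded to 0.1 A; the implementation
  never forces them equal.
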