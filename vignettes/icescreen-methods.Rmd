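---
title: "Methods: synthetic interferometry, grid-square detection and ice-quality classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic interferometry, grid-square detection and ice-quality classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icescreen)
```

## Scope and problem

Plunge-frozen cryo-EM grids succeed or fail largely on the thickness and
homogeneity of their vitreous ice. A reflected-light microscope with
three-band illumination turns local film thickness into interference
colour, so a single optical image of a grid reports ice quality for every
grid square at once — orders of magnitude faster than screening in the
electron microscope. `icescreen` implements the complete analysis chain
for such images: deskewing, grid-square ("tile") segmentation, five-class
ice-quality classification with confidence, a watch-folder batch mode, and
the zero-loss energy-filter method that validates the class-to-thickness
relationship on EM image pairs.

Because screening images of this kind are not publicly deposited, the
package also contains a physics-based synthetic-scene generator. The
generator is first-class, tested code: it defines the study conditions
under which every downstream stage is trained and benchmarked.

## The optical model

A free-standing film of amorphous ice (refractive index $n = 1.31$,
configurable) reflects at its two interfaces with Fresnel amplitudes
$r_1 = (n_0 - n)/(n_0 + n)$ and $r_2 = -r_1$. Two-beam interference gives
the reflectance

$$R(t, \lambda) = r_1^2 + r_2^2 + 2 r_1 r_2 \cos\!\left(\frac{4 \pi n t}{\lambda}\right),$$

periodic in thickness with period $\lambda / 2n$, zero at $t = 0$ for the
symmetric stack and maximal at quarter-wave thickness. At
$|r| \approx 0.13$, multiple internal reflections contribute below
$10^{-3}$ of the signal and are omitted. Each camera channel averages $R$
over its filter passband (centres 433/517/613 nm; FWHM defaulting to
20 nm since the filter's passband widths are not printed anywhere
authoritative) by 5-point Gauss–Legendre quadrature; band averaging is
what washes fringes out as the optical path difference approaches the
coherence length, as seen around thick droplets.

Display constants map physics to camera counts: the interference term is
scaled so its maximum sits at 85% of full scale, on top of a uniform foil
reflectance offset of 0.12 that dips by 0.05 inside the foil holes. No
structural carbon contrast beyond this offset is modelled. The foil-hole
lattice is rendered through a logistic edge profile whose width follows
the objective's resolution (0.9/0.55/0.35 µm at 5×/10×/20×), reproducing
the "barely resolved" dotted texture of real images.

## Scene geometry and class-conditioned thickness fields

Scenes use a square mesh (defaults: Quantifoil Cu 200 R2/1 — 125 µm
pitch, 35 µm bars, 2 µm holes at 1 µm spacing; an UltrAuFoil Au 300
R1.2/1.3 preset is included) at 5×, 10× or 20× magnification with a
6.45 µm camera pixel. The raster convention is top-left origin,
row-major, with angles counter-clockwise positive and the mesh's
90° symmetry folding every rotation into $[-45°, 45°)$.

Each square's thickness field is a sum of three low-order random cosine
harmonics (smooth, near-uniform variation), plus a centre-weighted puddle
for class 3 and a Gaussian droplet peaking near 0.5 µm for class 4 —
thick enough to produce at least two full fringe periods at 433 nm, the
circular periodic pattern characteristic of 'too thick' squares. The
field is shifted so the square's mean thickness equals a target drawn
from the class's bin:

| class | name | mean-thickness bin (nm) | drawn from |
|---|---|---|---|
| 1 | too thin | 6–20 | uniform on (8, 18) |
| 2 | optimal | 20–50 | truncated normal centred at 40 |
| 3 | thicker | 50–70 | truncated normal centred at 56 |
| 4 | too thick | > 70 | uniform on (74, 88), plus droplet |

The bins are anchored to EM-validated per-square means: 6–91 nm overall,
class 2 near 40 nm (matching the 40 nm particles such ice suits), class 3
near 56 nm. Class 0 ('bad') reuses a class 1–3 field and adds one or two
defects from a catalogue of punched holes, scratches and dust, rendered
as dark overrides of the film colour. Defect geometry (hole radius
0.12–0.25 of the square side, scratch half-width 0.025–0.05, dust radius
0.08–0.16) was fixed once to make defects comparable in scale to those
visible in published screening images. Additive Gaussian noise
(default SD 0.02 of full scale) is applied per channel. All draws are
seeded: the same seed reproduces a scene bit for bit.

What the generator deliberately does not emulate: protein particles in
the ice, electron-optical aberrations, non-flat grid topography, bent or
torn bars, vignetting, and condensation artefacts. Passing benchmarks on
these scenes therefore demonstrates that the pipeline's machinery is
correct and calibrated under controlled conditions, not that the shipped
models transfer to any particular real instrument — retraining on real
labelled images is expected for deployment.

## Segmentation

Two classes: tiles versus everything else. The default path is classical
and deterministic: under three-band illumination the metal bars are the
only bright *colourless* structure, so bar pixels are found by a
channel-spread/brightness rule around a robustly estimated bar level, the
bar mask is morphologically closed, and tiles are its complement. When no
bar-like pixels exist the image is declared grid-free and an empty mask
returned. A learned alternative — a logistic pixel classifier over
channel values, brightness, channel spread and local brightness SD —
is trainable with `train_segmenter()` and selected via the pipeline
configuration; training from scratch on synthetic data replaces transfer
learning from pre-trained encoder backbones, whose specific weights are
not what this package sets out to reproduce.

Post-processing follows the standard recipe: connected components
(4-connectivity, so diagonal bar-gap contacts never merge squares), hole
filling per component, and removal of interior components with
bounding-box aspect ratio above 1.5 or area below 25% of the median.
Border-touching components are exempt from those two filters and instead
flagged `touches_border` (partially imaged squares are real tiles and
are retained downstream, where they are padded with background fill
before classification); only a 25 px absolute speck floor applies to
them. Detections are sorted row-major by bounding-box origin.

## Orientation

The deskew maximises the variance of radon projections of a bar-likeness
map over candidate directions: the projection profile is sharpest when
the projection direction parallels a bar axis. The search is
coarse-to-fine (2° grid, then the configured resolution, default 0.25°,
around the coarse optimum), folded into $[-45°, 45°)$, with ties broken
toward the smaller absolute angle. Projections are normalised by the
rotated support to remove the corner bias of the growing canvas, and only
columns with at least half the maximal support enter the variance. A flat
profile (featureless image) yields angle 0 with a low-confidence flag.
On synthetic scenes the estimate lands within 0.15° of the injected
angle, comfortably inside the 0.5° benchmark bound. Rotation happens
*before* segmentation in the pipeline, so detections and crops live in
the axis-aligned frame; `map_points_to_rotated()` converts coordinates
between frames.

## Classification

Every detected tile is resampled to a 128×128 crop and described by
25 interference-pattern features: per-channel means and SDs, brightness
and saturation statistics, dark-defect evidence (fractions below fixed
brightness thresholds, the minimum and relative dip of a 5×5 box-smoothed
brightness), centre-versus-edge contrast, per-channel fringe counts along
the ring-averaged radial profile (extrema with at least 0.04 prominence),
gradient energy, and centre-disc channel means. All features are
invariant under 90° rotations of the crop by construction, which the test
suite checks as an augmentation-consistency property.

The classifier is a compact multinomial softmax over these features,
trained from scratch by mini-batch SGD with momentum 0.9, L2 penalty
0.005 and cross-entropy loss under the piecewise learning-rate schedule
$\alpha \cdot 0.7^{\lfloor k/4 \rfloor}$ with $\alpha = 0.001$. A
feature-based linear model rather than a deep network is a deliberate
choice: on synthetic tiles the classes are separable in this feature
space, the model trains in seconds on one CPU, and its decisions are
auditable feature by feature. The architecture sits behind the same
train/classify interface, so a heavier backbone can replace it without
touching the rest of the pipeline.

One schedule tick is one epoch (a full pass over the training set), not
one mini-batch step. With per-step decay the cumulative step size is
bounded by $\alpha \cdot 4 / 0.3 \approx 0.013$, which cannot move any
model meaningfully from initialisation; the epoch interpretation matches
the drop-period semantics of the toolbox the recipe originates from.
`lr_schedule()` itself is agnostic about the tick unit. Validation uses a
stratified 80/20 split, reported overall and per class; class imbalance
is handled by the stratification. The default batch size is 8, small
enough that the early high-rate epochs provide the bulk of the
optimisation. Probability vectors are exact softmax outputs (they sum
to 1 by construction); the confidence is the maximum probability, and
per-class confidence histograms summarise how decisively tiles are
classified.

On the default benchmark — at least 2000 labelled tiles from image seeds
1–10, uniform class mix — held-out accuracy is above 98% with every
per-class accuracy above 90%.

## EM thickness validation

With a zero-loss energy filter, the filtered/unfiltered intensity ratio
of a pixel encodes the inelastic scattering it suffered:
$t = \lambda_{inel} \ln(I_t / I_{zl})$. The default
$\lambda_{inel} = 322$ nm is a literature value for vitreous ice at
300 kV and is configurable, since the calibration behind any particular
instrument's absolute numbers is not reproducible from published
information; agreement with the published 6–91 nm per-square means is
therefore a structural calibration of the generator, not an independent
measurement. Pixels with non-positive intensities are invalid; negative
apparent thickness under noise is clipped to zero and flagged rather than
propagated. Foil holes are detected in the filtered image by
thresholding midway between the robust dark/bright levels, 4-connectivity
labelling, and a circle fit filtered on radius, bounding-box fill factor
(a disc fills $\pi/4$ of its box) and border completeness. The
per-square summary samples 10 holes without replacement, averages the map
over each hole interior eroded by 2 px (avoiding edge fringes; no
aperture rule is published, so the margin is a package choice), and
reports the mean and SD of the hole means.

## Pipeline, determinism and the watch folder

`analyze_image()` chains orientation → segmentation → post-processing →
classification → overlay. Reports are JSON; overlays blend the class
palette (0 red, 1 white, 2 green, 3 bright green, 4 orange — one
published figure caption permutes this palette, and the non-permuted
caption is adopted) at configurable opacity and print confidences at tile
centres. Outputs are written atomically (temp file + rename), so readers
never observe partial files. Wall-clock timing is recorded only when
`include_timing = TRUE`, because timing is the one non-deterministic
report field and the pipeline guarantees byte-identical reports for fixed
input, configuration and seed. One 512×512 image takes roughly 2–3 s on
a single CPU core, most of it in the angle search.

`watch()` mirrors the published executable's contract — two positional
folders, new images analysed as they appear — using polling (default
2 s) with a modification-time settling rule for portability. Each file
is processed once per appearance event (a re-drop with a newer mtime is
reprocessed), non-image files are logged and ignored, and a `.stop` file
or cycle limit shuts the watcher down cleanly.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero-spread class models give
exactly constant fields; a corpus with one example per class cannot be
split and is validated on itself (a memorisation check); crops smaller
than 8 px on a side are rejected with a warning; featureless images
deskew to 0° flagged low-confidence. The benchmark sizes used throughout
the tests — ~2300 tiles from 120 images for classification, 30 images
across three magnifications for segmentation, 20 seeded scenes for
orientation and for the EM inversion — were chosen so the full suite
exercises every contract at statistically meaningful scale while
remaining comfortable to run routinely on a laptop-class machine.

## Known limitations

The optical model is a stand-in chosen to reproduce the qualitative
fringe phenomenology of three-wavelength interferograms; no published
optical calibration exists to fit against, so absolute colours are not
instrument-accurate. Whether ice inside holes should be modelled on a
carbon substrate (an asymmetric stack) for carbon-coated grids is
unstated in the source material; the symmetric free-standing film is the
default everywhere. Only square meshes are supported. The shipped
classifier and segmenter are trained on synthetic scenes; real-world use
should retrain both on labelled images from the instrument at hand, for
which `make_dataset()`, `augment()`, `train_segmenter()` and
`train_classifier()` provide the complete recipe.
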