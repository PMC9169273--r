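---
title: "Depiction-feature fingerprints and the chemdepict generation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depiction-feature fingerprints and the chemdepict generation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemdepict)
```

## The problem

Optical chemical structure recognition (OCSR) models map raster images of
drawn molecules back to machine-readable structures. They are only as
robust as the diversity of their training images: depiction style varies
across publishers and drawing toolkits (bond widths, fonts, kekulisation
conventions, superatom abbreviations), and page-extracted depictions carry
non-structural elements — identity labels, rest-group definitions,
reaction arrows, atom numbering — plus scanning artefacts. `chemdepict`
synthesises such diversity deterministically from SMILES input.

## The fingerprint model

Every pseudo-random decision made while drawing is *flagged* into a
`FingerprintScheme` via `register_decision()`; the scheme is assembled
automatically, so changing the set of flagged decisions never requires
touching the fingerprint code. Each decision contributes an ordered set
of *building blocks*:

* a binary decision occupies one position, blocks `(0)` and `(1)`;
* a categorical decision with $k$ options occupies $k$ positions, blocks
  the $k$ one-hot $k$-tuples — multi-hot patterns are contradictory (a
  bond cannot be thin and bold at once) and are rejected with a
  diagnostic naming the offending decision;
* a numeric range occupies 3 positions, its value set split into three
  near-equal subranges treated as categories. Integer ranges partition
  the values with the remainder going to the last subrange
  (`1..7` → `[1,2] [3,4] [5,7]`); continuous ranges split at the
  terciles. The triple coarsening is what keeps the fingerprint space
  enumerable: without it the combinatorics explode.

The valid-fingerprint set is the cartesian product of the building blocks
in layout order, enumerated lexicographically with the first-registered
decision varying slowest, which makes enumeration order — and therefore
every manifest — deterministic. `count_valid_fingerprints()` is the
closed-form product; a property test asserts its equality with the
enumeration length on every scheme small enough to enumerate.

## Reference style profiles

Three style profiles emulate three distinct toolkit house styles by
parameter presets on a single backend. Published constraints fix the
decision *counts* (15 / 10 / 8) and the valid-fingerprint totals
(2,799,360 / 18,432 / 864) but not the per-decision breakdown, so the
composition here is one consistent solution, chosen once:

* `STYLE_A` — 8 binary + 6 ranged + 1 categorical-15:
  $2^8 \cdot 3^6 \cdot 15 = 2{,}799{,}360$
* `STYLE_B` — 7 binary + 2 ranged + 1 categorical-16:
  $2^7 \cdot 3^2 \cdot 16 = 18{,}432$
* `STYLE_C` — 5 binary + 3 ranged: $2^5 \cdot 3^3 = 864$

Decision names follow the standard depiction parameters. The tunables
that matter, with units and defaults:

| parameter | kind | domain | notes |
|---|---|---|---|
| `kekulised` | binary | 0/1 | alternating double bonds vs single bonds with an inner dashed aromatic line |
| `abbreviate_substructures` | binary | 0/1 | superatom contraction (tBu, OEt, ...) |
| `atom_numbering` | binary | 0/1 | small indices at each atom |
| `chirality_labels` | binary | 0/1 | "(R)"/"(S)" text at stereocentres |
| `bond_length` | ranged | 20–45 px | capped so the drawing fits 85% of the canvas |
| `line_thickness` | ranged | 1–4 px | bond stroke width |
| `font_size` | ranged | 8–24 px | atom-label glyph height |
| `rotation` | ranged | 0–359° | about the centroid |
| `label_distance` | ranged | 2–8 px | clearance disc around atom labels |
| `double_bond_gap` | ranged | 2–6 px | parallel-line separation |
| `font_type` | categorical | 15–16 variants | procedural weight/slant/width/spacing variants |

The augmentation scheme is 11 binary flags in a fixed canonical order
(annotations first, geometric, photometric, compression last), giving
$2^{11} = 2048$ fingerprints. Augmentation fingerprints record presence
only; operator parameters are drawn at application time from mild ranges
chosen once as OCSR-plausible: rotation ±5°, shear ±10°, salt-and-pepper
density 0.1–1% of pixels, brightness factor 0.7–1.3 with ±10% per-channel
jitter, JPEG quality 40–95, pixelation downscale 1.5–3×.

## Diversity picking

Fingerprints are bit vectors, so diversity uses the Tanimoto distance
$d(a,b) = 1 - |a \wedge b| / |a \vee b|$ (defined 0 for two empty
vectors) with greedy MaxMin (farthest-point) picking: first index uniform
by seed, every later pick maximises its minimum distance to the picked
set, ties to the lowest index. Both choices the method leaves open —
metric and tie rule — are fixed here for determinism. The greedy picker
is validated index-by-index against an independent brute-force
reimplementation and carries the classic factor-2 dispersion guarantee,
asserted against exhaustive optima on small pools.

`STYLE_A`'s 2.8M-fingerprint pool is too large to hold per call: above a
configurable cap (default $10^5$) a seeded uniform subsample of distinct
enumeration *ranks* is materialised lazily by mixed-radix decoding
(`fingerprint_from_rank()`), so the full pool never exists in memory.
This preserves the diversity intent at desk scale. When a style's demand
exceeds its whole pool (more than 864 `STYLE_C` images), the complete
diverse ordering is cycled rather than failing.

Dataset plans allocate styles by largest-remainder rounding — exact
integer counts (a 10,000-image plan is exactly 5,500/3,000/1,500 with
5,000 augmented) — whereas random (non-fingerprint) mode draws a style
per call, so realised fractions are binomial around the targets.

## Rendering backend

The environment offers no cheminformatics drawing engine, so the backend
is built from first principles and kept deliberately simple:

* **SMILES parsing** is a hand-written parser covering the organic
  subset, bracket atoms (isotope, chirality marks, H counts, charges),
  bonds, branches, ring closures (including `%nn`), and disconnected
  components. Heavy-atom counts are cross-checked in the test suite
  against an independent cheminformatics toolkit.
* **Coordinates** come from a Kamada–Kawai layout seeded with a circular
  initial placement — fully deterministic — normalised to unit median
  bond length; components are tiled side by side. Rings render as
  near-regular polygons. This is graph drawing, not chemical layout:
  fused-ring geometry is approximate, which is acceptable because
  faithfully reproducing any particular toolkit's look is a non-goal.
* **Kekulisation** assigns alternating double bonds by backtracking
  perfect matching over the aromatic atoms that need one (aromatic
  carbons; two-connected aromatic N without H). With `kekulised = 0`
  aromatic bonds are drawn as single lines with short inner dashes.
* **Superatom contraction** matches the built-in 25-entry abbreviation
  table (largest group first) by colour-constrained VF2 subgraph
  isomorphism plus post-filters: every matched atom except the
  attachment site must be internal, and the attachment must have an
  external neighbour — so methane never becomes "Me" and a lone benzene
  never becomes "Ph". Only groups of ≥ 2 heavy atoms are contracted.
* **Text** uses procedural bitmap fonts: 16 weight/slant/width/spacing
  variants of a built-in 5×7 core font. Real TTF fonts would be binary
  assets with no rasteriser in the environment; the procedural variants
  keep the categorical font decision meaningful and the tests hermetic.
* **Chirality labels** are "(R)" for `@@` and "(S)" for `@` — a display
  convention, *not* a CIP assignment (a documented limitation; the label
  is depiction noise, not ground truth).
* A **stub backend** draws a constant-cost deterministic placeholder and
  exists solely for pipeline/scaling tests.

PNG output is emitted by a minimal deterministic encoder (8-bit RGB,
filter 0, one zlib IDAT via `memCompress`) because no installed package
writes pixel arrays to PNG; determinism here is what makes manifests
byte-replayable.

## Annotations and augmentations

Labels follow three grammars — identity (`1`, `1a`, `1–4`, `1a–d`),
rest-group (`R1 = OMe` with variables R, R', X, Y, Z and the superatom
vocabulary) and reaction conditions (reagent, solvent, duration from
shipped vocabularies of 26 reagents and 12 solvents, rendered on 1–3
lines). Placement tries up to 50 random positions for a box that misses
the structure mask (non-background pixels of the pre-annotation render,
dilated by 2 px); an unplaceable label is skipped with a logged message
rather than overlapping. Arrow glyphs (6 procedural variants) are
scaled, rotated and pasted so that curved mechanism arrows *do* overlap
the structure and straight reaction arrows do *not*; if no position
satisfies the rule the glyph is progressively shrunk before giving up.

JPEG compression is reproduced as an 8×8 blockwise DCT quantisation
round-trip with the standard luminance table under the IJG quality
scaling. Entropy coding is lossless, so this is pixel-equivalent to a
real encode/decode; the environment has no JPEG codec, and implementing
the artefact-generating core directly keeps the operator deterministic.

Every image is generated at dimensions drawn uniformly from
$[\lceil 0.9m \rceil, \lfloor 1.1m \rfloor]$ per axis and resampled to
the target with a method drawn from {nearest, bilinear, bicubic, area,
lanczos} — five separable kernels implemented as weight matrices, with
kernel widening when minifying. Annotations and augmentations are applied
*before* the final resize (the ordering is not externally specified; this
choice means resampling artefacts also affect the annotations, as they
would on a scanned page).

## Seeds and reproducibility

A depictor state holds a base value and a counter; every random choice
consumes one evolved seed, computed by mixing the counter through a
31-bit avalanche bijection (xorshifts and odd multiplications mod
$2^{31}$, composed — each a bijection, so seed streams are provably
collision-free and fit R's 32-bit integer seeds). Batch generation
derives one seed per record from the same stream, so records are
independent: any manifest row regenerates its PNG byte-exactly in
isolation, and two configs differing only in the initial seed produce
different images.

## What the synthetic data does and does not emulate

The generator emulates: style variation across three coherent profiles,
superatom abbreviation, textual and arrow noise, mild geometric and
photometric perturbations, and resampling artefacts. It does **not**
emulate: chemically idiomatic 2D layout (templated rings, collision-free
substituent placement), real typefaces (including non-Latin glyphs),
hand-drawn or historical depictions, scanner paper texture, or
semantically meaningful mechanism arrows (arrows are noise by design). A
green test suite therefore establishes the combinatorial, statistical and
reproducibility contracts of the pipeline — not that a model trained on
these images transfers to any particular journal's style.

## Numerical choices and degenerate inputs

* Tie-breaks: MaxMin ties go to the lowest index; `which.max` semantics.
* The Tanimoto distance of two all-zero vectors is defined as 0.
* Largest-remainder rounding resolves fractional style counts; remainder
  ties go to the larger fractional part first.
* The empty scheme has exactly one (empty) fingerprint; enumeration
  refuses to materialise pools beyond an explicit guard.
* Degenerate placements (fully masked canvas, labels larger than the
  image) skip with a logged message and leave the image unchanged.
* Molecules with a single atom lay out at the origin; disconnected
  SMILES components are tiled horizontally.
* All 32-bit modular arithmetic is done in doubles via 16-bit half-words
  (exact below $2^{53}$), since R lacks unsigned integers.
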