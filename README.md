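# chemdepict

Randomised, reproducible chemical structure depiction generation for
training and benchmarking **optical chemical structure recognition (OCSR)**
systems.

Deep-learning OCSR models (CNN/transformer encoders decoding images of
drawn molecules back to SMILES) generalise only across depiction styles
they have seen, and real page-extracted depictions carry non-structural
noise — atom numbering, identity labels like "1a", "R = OMe" definitions,
reaction arrows — that the model must learn to ignore. `chemdepict`
generates such data at scale from plain SMILES input: every depiction is
drawn with pseudo-randomly chosen parameters under one of three style
profiles, optionally decorated with labels and arrows, perturbed with mild
image augmentations, and always rendered through a distort-then-resize
step that injects resampling artefacts.

## The model at the core: depiction-feature fingerprints

Random sampling of a high-dimensional, mostly categorical parameter space
does not guarantee even coverage. `chemdepict` therefore summarises every
flagged depiction decision in a **feature fingerprint** — a bit array in
which each decision owns a contiguous span:

| decision kind  | span width | building blocks                      |
|----------------|-----------|---------------------------------------|
| binary         | 1         | `(0)`, `(1)`                          |
| categorical, k | k         | the k one-hot k-tuples                |
| numeric range  | 3         | one-hot triples bound to 3 subranges  |

A numeric range such as the integers 1..6 is split into the subranges
[1,2], [3,4], [5,6]; the fingerprint pins the subrange and the concrete
value is drawn uniformly inside it at depiction time. The set of valid
fingerprints is the cartesian product of the building blocks, so for a
scheme with decisions d₁…dₖ the count is

    N = ∏ᵢ bᵢ ,   bᵢ = 2 (binary) | kᵢ (categorical) | 3 (ranged)

The three reference style profiles declare 15, 10 and 8 decisions and
yield exactly **2,799,360**, **18,432** and **864** valid fingerprints;
the 11 augmentation flags yield **2,048**. Diverse subsets are selected by
greedy **MaxMin (farthest-point) picking** under the Tanimoto distance
d(a,b) = 1 − |a∧b|/|a∨b|, which carries the classic 2-approximation
guarantee on the dispersion (min pairwise distance).

Everything is driven by a seeded, systematically evolved stream of
sub-seeds, so a dataset is byte-for-byte reproducible from (SMILES list,
initial seed, config), and any manifest record can be replayed into the
identical PNG.

## Worked example

```r
library(chemdepict)

print(style_profile("STYLE_A")$scheme)
#> FingerprintScheme 'STYLE_A': 15 decisions, 41 bits, 2,799,360 valid fingerprints

smiles <- "CN1C=NC2=C1C(=O)N(C(=O)N2C)C"   # caffeine

# one random depiction, no augmentations, 299 x 299
img <- random_depiction(smiles, c(299, 299), depictor_state(42))
dim(img); ink_pixels(img)
#> [1] 299 299   3
#> [1] 3796

# augmented variant (labels/arrows/noise on top of the same pipeline)
aug <- depict_augmented(smiles, c(299, 299), depictor_state(42))

# diverse fingerprint-picked batch
cfg <- generator_config(shape = c(128, 128), seed = 42, per_smiles = 2,
                        outdir = "demo_out", fingerprint_picking = TRUE,
                        pool_cap = 2000)
m <- batch_generate(c(smiles, "CC(C)(C)c1ccc(O)cc1", "C[C@H](N)C(=O)O"), cfg)
m[, c("index", "style", "seed", "resize_method", "filename", "status")]
#>   index   style       seed resize_method      filename status
#> 1     1 STYLE_A 1978767477       bicubic img_00001.png     ok
#> 2     2 STYLE_A 1045115690      bilinear img_00002.png     ok
#> 3     3 STYLE_A 1429408816       bicubic img_00003.png     ok
#> 4     4 STYLE_B  590609254      bilinear img_00004.png     ok
#> 5     5 STYLE_B  253874310       nearest img_00005.png     ok
#> 6     6 STYLE_C 1493163569       nearest img_00006.png     ok
```

The six records follow the default 55% / 30% / 15% style split by
largest-remainder rounding (here 3/2/1); each row's `seed` regenerates its
image bit-exactly via `replay_record()`. A 100-image plan allocates
exactly 55/30/15 with 50 augmented:

```r
p <- plan_dataset(100, seed = 1)
table(p$style); sum(!is.na(p$aug_fingerprint))
#> STYLE_A STYLE_B STYLE_C
#>      55      30      15
#> [1] 50
```

`demo_out/` then contains the PNGs plus `manifest.jsonl` (one
self-describing record per image) and `mapping.tsv` (filename ↔ SMILES,
ready for OCSR training).

## Command line

```sh
Rscript inst/cli/depict.R --input molecules.smi --size 299 --seed 42 \
    --proportions 0.55,0.30,0.15 --augmented-fraction 0.5 \
    --fingerprint-picking --outdir dataset/
```

`--shard i/k` processes every k-th molecule (parallelise by giving each
instance a different shard — and a different `--seed` if you want
different parameter sets).

## Documentation

The methods vignette (`vignettes/depiction-fingerprints.Rmd`) describes
the fingerprint model, the parameter ranges and their defaults, what the
synthetic depictions do and do not emulate, and the numerical design
choices. Function-level documentation lives in the roxygen comments.
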