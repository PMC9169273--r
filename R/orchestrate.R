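#' Seed evolution
#'
#' Every pseudo-random choice uses a fresh seed taken from a depictor
#' state and the state is then altered systematically: a counter is mixed
#' through a 32-bit avalanche bijection, so successive seeds are
#' collision-free over any practical count and states initialised with
#' different seeds behave as disjoint streams.
#'
#' @param seed initial integer seed.
#' @return a `depictor_state` (mutable environment with `base`, `counter`).
#' @export
depictor_state <- function(seed = 42L) {
  e <- new.env(parent = emptyenv())
  e$base <- mix31(abs(seed) %% TWO31)
  e$counter <- 0
  class(e) <- "depictor_state"
  e
}

GOLDEN32 <- 2654435769 # 0x9E3779B9, odd multiplier => injective counter map

#' Draw the next seed from a depictor state
#'
#' Advances the state in place and returns the seed (a non-negative
#' integer below 2^31, directly usable with [cd_rng()]).
#'
#' @param state a [depictor_state()].
#' @return single numeric seed.
#' @export
evolve_seed <- function(state) {
  stopifnot(inherits(state, "depictor_state"))
  state$counter <- state$counter + 1
  mix31((state$base + mul32(state$counter, GOLDEN32)) %% TWO31)
}

#' The first k seeds of a depictor state (pure helper)
#'
#' Vectorised replica of [evolve_seed()]'s sequence for a fresh state;
#' used for collision and stream-disjointness checks.
#'
#' @param seed initial seed.
#' @param k number of seeds.
#' @return numeric vector of length `k`.
#' @export
seed_sequence <- function(seed, k) {
  base <- mix31(abs(seed) %% TWO31)
  mix31((base + mul32(seq_len(k), GOLDEN32)) %% TWO31)
}

#' Generator configuration
#'
#' @param shape image `c(height, width)`, default 299 x 299.
#' @param proportions style/augmentation fractions
#'   (default [default_proportions()]: 55% / 30% / 15%, 50% augmented).
#' @param seed initial seed; with the same SMILES input and seed every
#'   output byte is reproducible.
#' @param fingerprint_picking use diverse MaxMin-picked fingerprints
#'   (TRUE) or per-call random parameter sampling (FALSE).
#' @param per_smiles depictions generated per input SMILES.
#' @param outdir output directory for batch generation.
#' @param backend `"vector"` (the real depiction backend) or `"stub"`
#'   (constant-cost deterministic placeholder for pipeline tests).
#' @param pool_cap fingerprint pool subsampling cap (see
#'   [fingerprint_pool()]).
#' @return a `GeneratorConfig` list.
#' @export
generator_config <- function(shape = c(299L, 299L),
                             proportions = default_proportions(),
                             seed = 42L, fingerprint_picking = FALSE,
                             per_smiles = 1L, outdir = "chemdepict_out",
                             backend = c("vector", "stub"),
                             pool_cap = 1e5) {
  backend <- match.arg(backend)
  pr <- normalize_proportions(proportions)
  if (any(shape < 32)) stop("image shape must be at least 32 x 32")
  structure(list(shape = as.integer(shape), proportions = pr,
                 seed = seed, fingerprint_picking = fingerprint_picking,
                 per_smiles = as.integer(per_smiles), outdir = outdir,
                 backend = backend, pool_cap = pool_cap),
            class = "GeneratorConfig")
}

#' Sample style profiles by the configured proportions
#'
#' The per-call weighted style draw used by [random_depiction()] (random
#' mode draws a style per call, so realised fractions are binomial around
#' the targets; fingerprint mode uses exact largest-remainder counts
#' instead, see [plan_dataset()]).
#'
#' @param n number of draws.
#' @param proportions style fractions (see [default_proportions()]).
#' @param state a [depictor_state()].
#' @return character vector of style ids.
#' @export
sample_styles <- function(n, proportions, state) {
  pr <- normalize_proportions(proportions)
  ids <- c("STYLE_A", "STYLE_B", "STYLE_C")
  p <- unlist(pr[ids])
  vapply(seq_len(n), function(i) {
    u <- rng_runif(cd_rng(evolve_seed(state)), 1L)
    ids[findInterval(u, cumsum(p), left.open = TRUE) + 1L]
  }, character(1))
}

## one depiction with everything recorded; the core of every entry point
depict_core <- function(smiles, shape, state, config, profiles,
                        augmented = FALSE, style_fp = NULL, aug_fp = NULL) {
  mol <- tryCatch(parse_structure(smiles),
                  error = function(e)
                    stop("cannot depict '", smiles, "': ",
                         conditionMessage(e), call. = FALSE))
  style_id <- if (!is.null(style_fp)) attr(style_fp, "style")
              else sample_styles(1L, config$proportions, state)
  profile <- profiles[[style_id]]
  arng <- cd_rng(evolve_seed(state))
  if (is.null(style_fp)) {
    assignment <- sample_assignment(profile$scheme, arng)
  } else {
    assignment <- fingerprint_to_assignment(profile$scheme,
                                            as.integer(style_fp), arng)
  }
  fp <- assignment_to_fingerprint(profile$scheme, assignment)
  drng <- cd_rng(evolve_seed(state))
  dims <- sample_distorted_dims(shape[1], shape[2], drng)
  method <- rng_pick(drng, resize_methods())
  rseed <- evolve_seed(state)
  img <- if (config$backend == "stub") render_stub(smiles, dims, rseed)
         else render(mol, profile, assignment, dims, cd_rng(rseed))
  ops <- character(0)
  if (augmented) {
    if (is.null(aug_fp)) aug_fp <- rng_bits(cd_rng(evolve_seed(state)), 11L)
    ops <- augmentations_from_fingerprint(as.integer(aug_fp))
    mask <- structure_mask(img)
    for (op in ops)
      img <- apply_augmentation(img, op, cd_rng(evolve_seed(state)),
                                mask = mask)
  }
  img <- resize_image(img, shape[1], shape[2], method)
  list(image = img, style = style_id,
       style_fingerprint = paste(fp, collapse = ""),
       aug_fingerprint = if (augmented) paste(as.integer(aug_fp),
                                              collapse = "") else NA_character_,
       dims = dims, method = method)
}

#' Depict a structure with random style and parameters
#'
#' Picks a style profile by the configured proportions, samples a full
#' depiction parameter assignment, renders at distorted dimensions and
#' resamples to the requested shape. Never applies augmentations.
#'
#' @param smiles SMILES string.
#' @param shape target `c(height, width)` (default 299 x 299).
#' @param state a [depictor_state()]; identical SMILES + initial seed
#'   give a bit-identical image.
#' @param config a [generator_config()].
#' @return raster array of the requested shape.
#' @export
random_depiction <- function(smiles, shape = c(299L, 299L),
                             state = depictor_state(42L),
                             config = generator_config(shape = shape)) {
  depict_core(smiles, shape, state, config, style_profiles(),
              augmented = FALSE)$image
}

#' Depict a structure with annotations and augmentations
#'
#' The [random_depiction()] pipeline plus a sampled 11-bit augmentation
#' fingerprint, decoded into operators and applied in canonical order
#' before the final resize.
#'
#' @inheritParams random_depiction
#' @return raster array of the requested shape.
#' @export
depict_augmented <- function(smiles, shape = c(299L, 299L),
                             state = depictor_state(42L),
                             config = generator_config(shape = shape)) {
  depict_core(smiles, shape, state, config, style_profiles(),
              augmented = TRUE)$image
}

#' Batch-generate a depiction dataset
#'
#' Writes `length(smiles) * per_smiles` PNG images plus a JSON-lines
#' manifest (`manifest.jsonl`) and a filename-to-SMILES TSV
#' (`mapping.tsv`) to `config$outdir`. With `fingerprint_picking` the
#' per-image style and augmentation fingerprints come from
#' [plan_dataset()] (exact largest-remainder style counts, MaxMin-diverse
#' fingerprints); otherwise styles and parameters are sampled per image.
#' Each image derives from its own per-record seed, so any manifest
#' record regenerates its image bit-exactly via [replay_record()].
#' Per-SMILES failures are logged and recorded; the batch continues.
#'
#' @param smiles character vector of SMILES (non-empty).
#' @param config a [generator_config()].
#' @return data.frame manifest, invisibly.
#' @export
batch_generate <- function(smiles, config = generator_config()) {
  stopifnot(length(smiles) >= 1L)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  n <- length(smiles) * config$per_smiles
  profiles <- style_profiles()
  plan <- NULL
  if (config$fingerprint_picking)
    plan <- plan_dataset(n, config$proportions, profiles,
                         seed = config$seed, pool_cap = config$pool_cap)
  seeds <- seed_sequence(config$seed, n)
  recs <- vector("list", n)
  i <- 0L
  for (s in smiles) for (k in seq_len(config$per_smiles)) {
    i <- i + 1L
    fname <- sprintf("img_%05d.png", i)
    rec <- tryCatch({
      out <- depict_record(s, seeds[i], config, profiles,
                           if (is.null(plan)) NULL else plan[i, ])
      write_png(out$image, file.path(config$outdir, fname))
      data.frame(index = i, smiles = s, style = out$style,
                 style_fingerprint = out$style_fingerprint,
                 aug_fingerprint = out$aug_fingerprint, seed = seeds[i],
                 resize_method = out$method, filename = fname,
                 status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) {
      message("record ", i, " ('", s, "') failed: ", conditionMessage(e))
      data.frame(index = i, smiles = s, style = NA_character_,
                 style_fingerprint = NA_character_,
                 aug_fingerprint = NA_character_, seed = seeds[i],
                 resize_method = NA_character_, filename = NA_character_,
                 status = paste("error:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    recs[[i]] <- rec
  }
  manifest <- do.call(rbind, recs)
  write_manifest(manifest, config)
  invisible(manifest)
}

## build one record's depiction from its per-record seed (+ optional plan row)
depict_record <- function(smiles, seed, config, profiles, plan_row = NULL) {
  state <- depictor_state(seed)
  if (is.null(plan_row)) {
    augmented <- rng_runif(cd_rng(evolve_seed(state)), 1L) <
      config$proportions$augmented
    depict_core(smiles, config$shape, state, config, profiles,
                augmented = augmented)
  } else {
    fp <- as.integer(strsplit(plan_row$style_fingerprint, "")[[1]])
    attr(fp, "style") <- plan_row$style
    aug_fp <- if (is.na(plan_row$aug_fingerprint)) NULL
              else as.integer(strsplit(plan_row$aug_fingerprint, "")[[1]])
    depict_core(smiles, config$shape, state, config, profiles,
                augmented = !is.null(aug_fp), style_fp = fp, aug_fp = aug_fp)
  }
}

#' Regenerate one manifest record's image bit-exactly
#'
#' @param record one manifest row (data.frame or list).
#' @param config the `GeneratorConfig` used for the batch.
#' @return raster array identical to the written PNG's pixels.
#' @export
replay_record <- function(record, config) {
  state <- depictor_state(record$seed)
  if (!is.na(record$aug_fingerprint) || config$fingerprint_picking) {
    if (config$fingerprint_picking) {
      fp <- as.integer(strsplit(record$style_fingerprint, "")[[1]])
      attr(fp, "style") <- record$style
      aug_fp <- if (is.na(record$aug_fingerprint)) NULL
                else as.integer(strsplit(record$aug_fingerprint, "")[[1]])
      return(depict_core(record$smiles, config$shape, state, config,
                         style_profiles(), augmented = !is.null(aug_fp),
                         style_fp = fp, aug_fp = aug_fp)$image)
    }
  }
  ## random mode: rerun the recorded seed's full decision stream
  augmented <- rng_runif(cd_rng(evolve_seed(state)), 1L) <
    config$proportions$augmented
  depict_core(record$smiles, config$shape, state, config, style_profiles(),
              augmented = augmented)$image
}

write_manifest <- function(manifest, config) {
  jl <- file.path(config$outdir, "manifest.jsonl")
  con <- file(jl, open = "wb") # binary: byte-identical across platforms
  on.exit(close(con))
  for (i in seq_len(nrow(manifest))) {
    rec <- as.list(manifest[i, ])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null",
                                digits = NA),
               con, sep = "\n")
  }
  ok <- manifest[manifest$status == "ok", , drop = FALSE]
  utils::write.table(ok[, c("filename", "smiles")],
                     file.path(config$outdir, "mapping.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(jl)
}

#' Command-line interface
#'
#' `Rscript -e 'chemdepict::cd_cli()' -- --input smiles.smi --outdir out`
#' (or via the script in `inst/cli/`). Options: `--input` (SMILES file,
#' one per line), `--size`, `--seed`, `--num-per-smiles`,
#' `--proportions a,b,c`, `--augmented-fraction`, `--fingerprint-picking`,
#' `--outdir`, `--shard i/k` (process every k-th SMILES starting at i).
#' Logs go to stderr; the exit status is nonzero only if every record
#' failed.
#'
#' @param args command-line arguments (default: from the command line).
#' @return the manifest, invisibly.
#' @export
cd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  spec <- list(
    optparse::make_option("--input", type = "character"),
    optparse::make_option("--size", type = "integer", default = 299L),
    optparse::make_option("--seed", type = "integer", default = 42L),
    optparse::make_option("--num-per-smiles", type = "integer", default = 1L,
                          dest = "per_smiles"),
    optparse::make_option("--proportions", type = "character",
                          default = "0.55,0.30,0.15"),
    optparse::make_option("--augmented-fraction", type = "double",
                          default = 0.5, dest = "augmented"),
    optparse::make_option("--fingerprint-picking", action = "store_true",
                          default = FALSE, dest = "fingerprint"),
    optparse::make_option("--backend", type = "character",
                          default = "vector"),
    optparse::make_option("--outdir", type = "character",
                          default = "chemdepict_out"),
    optparse::make_option("--shard", type = "character", default = NULL))
  opt <- optparse::parse_args(
    optparse::OptionParser(option_list = spec), args = args)
  if (is.null(opt$input)) stop("--input SMILES file is required")
  smiles <- readLines(opt$input, warn = FALSE)
  smiles <- sub("\t.*$", "", trimws(smiles))
  smiles <- smiles[nzchar(smiles)]
  if (!is.null(opt$shard)) {
    ik <- as.integer(strsplit(opt$shard, "/")[[1]])
    smiles <- smiles[seq_along(smiles) %% ik[2] == ik[1] %% ik[2]]
  }
  p <- as.numeric(strsplit(opt$proportions, ",")[[1]])
  cfg <- generator_config(
    shape = c(opt$size, opt$size),
    proportions = list(STYLE_A = p[1], STYLE_B = p[2], STYLE_C = p[3],
                       augmented = opt$augmented),
    seed = opt$seed, fingerprint_picking = opt$fingerprint,
    per_smiles = opt$per_smiles, outdir = opt$outdir,
    backend = opt$backend)
  manifest <- batch_generate(smiles, cfg)
  n_ok <- sum(manifest$status == "ok")
  message(n_ok, "/", nrow(manifest), " depictions written to ", cfg$outdir)
  if (n_ok == 0L) stop("all records failed")
  invisible(manifest)
}
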