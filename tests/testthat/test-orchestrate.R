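test_that("seed evolution is deterministic, collision-free and stream-disjoint", {
  s1 <- depictor_state(42); s2 <- depictor_state(42)
  expect_identical(vapply(1:1000, function(i) evolve_seed(s1), numeric(1)),
                   vapply(1:1000, function(i) evolve_seed(s2), numeric(1)))
  ## the pure helper replicates the stateful stream
  s3 <- depictor_state(7)
  expect_identical(vapply(1:50, function(i) evolve_seed(s3), numeric(1)),
                   seed_sequence(7, 50))
  ## 1e6 successive seeds: no duplicates (bijective counter mix)
  expect_false(anyDuplicated(seed_sequence(42, 1e6)) > 0)
  ## different initial seeds: first 100 seeds differ pairwise
  expect_true(all(seed_sequence(0, 100) != seed_sequence(1, 100)))
  expect_true(all(seed_sequence(42, 100) < 2^31))
})

test_that("random_depiction returns the requested shape reproducibly", {
  img <- random_depiction(caffeine_smiles(), c(299, 299), depictor_state(5))
  expect_equal(dim(img), c(299L, 299L, 3L))
  expect_gt(ink_pixels(img), 0)
  expect_identical(img,
                   random_depiction(caffeine_smiles(), c(299, 299),
                                    depictor_state(5)))
  expect_false(identical(img,
                         random_depiction(caffeine_smiles(), c(299, 299),
                                          depictor_state(6))))
  expect_error(random_depiction("not_a_smiles", c(64, 64),
                                depictor_state(1)), "not_a_smiles")
})

test_that("style draws follow the configured proportions", {
  styles <- sample_styles(4000, default_proportions(), depictor_state(3))
  frac <- table(factor(styles, c("STYLE_A", "STYLE_B", "STYLE_C"))) / 4000
  expect_equal(as.vector(frac), c(0.55, 0.30, 0.15), tolerance = 0.12)
  ## extreme proportions are honoured
  only_b <- sample_styles(50, list(STYLE_A = 0, STYLE_B = 1, STYLE_C = 0,
                                   augmented = 0.5), depictor_state(4))
  expect_true(all(only_b == "STYLE_B"))
})

test_that("depict_augmented keeps the shape and adds ink on average", {
  img <- depict_augmented(caffeine_smiles(), c(128, 128), depictor_state(11))
  expect_equal(dim(img), c(128L, 128L, 3L))
  expect_identical(img, depict_augmented(caffeine_smiles(), c(128, 128),
                                         depictor_state(11)))
  ## annotations add ink on average (scaled-down: 12 seed pairs)
  plain <- vapply(1:12, function(s)
    ink_pixels(random_depiction(caffeine_smiles(), c(96, 96),
                                depictor_state(s))), numeric(1))
  aug <- vapply(1:12, function(s)
    ink_pixels(depict_augmented(caffeine_smiles(), c(96, 96),
                                depictor_state(s))), numeric(1))
  expect_gte(mean(aug), mean(plain))
})

test_that("batch_generate writes images + manifest and replays bit-exactly", {
  outdir <- file.path(tempdir(), "cd_batch")
  unlink(outdir, recursive = TRUE)
  smiles <- c(caffeine_smiles(), "c1ccccc1O", "CC(C)(C)c1ccccc1",
              "C[C@H](N)C(=O)O", "CCOC(=O)c1ccccc1")
  cfg <- generator_config(shape = c(64, 64), seed = 21, per_smiles = 2,
                          outdir = outdir)
  manifest <- batch_generate(smiles, cfg)
  expect_equal(nrow(manifest), 10L)
  expect_true(all(manifest$status == "ok"))
  expect_equal(sort(list.files(outdir, pattern = "png$")),
               sort(manifest$filename))
  expect_false(anyDuplicated(manifest$filename) > 0)
  expect_true(file.exists(file.path(outdir, "manifest.jsonl")))
  expect_true(file.exists(file.path(outdir, "mapping.tsv")))
  map <- read.delim(file.path(outdir, "mapping.tsv"), header = FALSE)
  expect_equal(nrow(map), 10L)
  ## replaying a record regenerates its PNG byte-exactly
  for (i in c(1L, 6L)) {
    rec <- manifest[i, ]
    img <- replay_record(rec, cfg)
    f <- tempfile(fileext = ".png")
    write_png(img, f)
    orig <- file.path(outdir, rec$filename)
    expect_identical(readBin(f, "raw", file.size(f)),
                     readBin(orig, "raw", file.size(orig)))
  }
  ## a bad SMILES is logged and recorded, the batch continues
  cfg2 <- generator_config(shape = c(64, 64), seed = 1,
                           outdir = file.path(tempdir(), "cd_batch2"))
  expect_message(m2 <- batch_generate(c("CCO", "not_a_smiles"), cfg2),
                 "failed")
  expect_equal(m2$status[1], "ok")
  expect_match(m2$status[2], "error")
})

test_that("reruns are byte-identical; different seeds diverge", {
  out1 <- file.path(tempdir(), "cd_rep1")
  out2 <- file.path(tempdir(), "cd_rep2")
  out3 <- file.path(tempdir(), "cd_rep3")
  for (d in c(out1, out2, out3)) unlink(d, recursive = TRUE)
  smiles <- c(caffeine_smiles(), "c1ccncc1")
  m1 <- batch_generate(smiles, generator_config(shape = c(64, 64), seed = 9,
                                                outdir = out1))
  m2 <- batch_generate(smiles, generator_config(shape = c(64, 64), seed = 9,
                                                outdir = out2))
  m3 <- batch_generate(smiles, generator_config(shape = c(64, 64), seed = 10,
                                                outdir = out3))
  read_bytes <- function(d, f) readBin(file.path(d, f), "raw",
                                       file.size(file.path(d, f)))
  for (f in m1$filename)
    expect_identical(read_bytes(out1, f), read_bytes(out2, f))
  expect_identical(read_bytes(out1, "manifest.jsonl"),
                   read_bytes(out2, "manifest.jsonl"))
  ## different initial seeds -> different images
  differs <- vapply(m1$filename, function(f)
    !identical(read_bytes(out1, f), read_bytes(out3, f)), logical(1))
  expect_gte(mean(differs), 0.95)
})

test_that("fingerprint-picking batch uses the planned diverse fingerprints", {
  outdir <- file.path(tempdir(), "cd_fp")
  unlink(outdir, recursive = TRUE)
  cfg <- generator_config(shape = c(64, 64), seed = 13, per_smiles = 3,
                          outdir = outdir, fingerprint_picking = TRUE,
                          pool_cap = 1500)
  m <- batch_generate(c("CCO", "c1ccccc1"), cfg)
  expect_equal(nrow(m), 6L)
  expect_true(all(m$status == "ok"))
  plan <- plan_dataset(6, cfg$proportions, seed = 13, pool_cap = 1500)
  expect_equal(m$style, plan$style)
  expect_equal(m$style_fingerprint, plan$style_fingerprint)
  ## replay matches in fingerprint mode too
  rec <- m[1, ]
  img <- replay_record(rec, cfg)
  f <- tempfile(fileext = ".png")
  write_png(img, f)
  orig <- file.path(outdir, rec$filename)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(orig, "raw", file.size(orig)))
})

test_that("the CLI generates a dataset from a SMILES file", {
  smi <- tempfile(fileext = ".smi")
  writeLines(c("CCO", "c1ccccc1", "CC(=O)O"), smi)
  outdir <- file.path(tempdir(), "cd_cli_out")
  unlink(outdir, recursive = TRUE)
  m <- cd_cli(c("--input", smi, "--size", "64", "--seed", "3",
                "--outdir", outdir, "--backend", "stub"))
  expect_equal(nrow(m), 3L)
  expect_equal(sum(file.exists(file.path(outdir, m$filename))), 3L)
  ## sharding splits the input
  outdir2 <- file.path(tempdir(), "cd_cli_shard")
  unlink(outdir2, recursive = TRUE)
  m2 <- cd_cli(c("--input", smi, "--size", "64", "--seed", "3",
                 "--outdir", outdir2, "--backend", "stub", "--shard", "1/2"))
  expect_lt(nrow(m2), 3L)
})
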