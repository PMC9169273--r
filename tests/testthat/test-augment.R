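test_that("augmentation scheme has 11 binary flags and 2048 fingerprints", {
  sch <- augmentation_scheme()
  expect_equal(n_decisions(sch), 11L)
  expect_equal(sch$total_length, 11L)
  expect_equal(count_valid_fingerprints(sch), 2048)
  expect_equal(nrow(enumerate_valid_fingerprints(sch)), 2048L)
})

test_that("augmentations_from_fingerprint decodes flags in canonical order", {
  expect_equal(augmentations_from_fingerprint(rep(0L, 11)), character(0))
  expect_equal(augmentations_from_fingerprint(rep(1L, 11)),
               augmentation_ops())
  fp <- integer(11); fp[c(2, 8)] <- 1L
  expect_equal(augmentations_from_fingerprint(fp),
               c("straight_arrow", "salt_pepper"))
  expect_error(augmentations_from_fingerprint(rep(0L, 10)), "length 11")
  expect_error(augmentations_from_fingerprint(c(rep(0L, 10), 2L)), "0/1")
})

test_that("every operator preserves dimensions and is seed-deterministic", {
  img <- render(parse_structure("CCO"), style_profile("STYLE_C"),
                list(rotation = 15), c(96, 96))
  for (op in augmentation_ops()) {
    o1 <- apply_augmentation(img, op, cd_rng(11))
    o2 <- apply_augmentation(img, op, cd_rng(11))
    expect_equal(dim(o1), dim(img), info = op)
    expect_identical(o1, o2, info = op)
  }
  expect_error(apply_augmentation(img, "nonsense", cd_rng(1)), "unknown")
})

test_that("salt and pepper darkens the configured fraction of a white image", {
  img <- new_image(100, 100)
  out <- apply_augmentation(img, "salt_pepper", cd_rng(8))
  dark <- sum(out[, , 1] < 0.5)
  expect_gt(dark, 0)
  ## density range 0.1-1%, pepper is ~half the flipped pixels
  expect_lte(dark, 0.01 * 100 * 100)
  changed <- sum(out[, , 1] != 1)
  expect_gte(changed, floor(0.001 * 100 * 100) * 0)
  expect_lte(changed, 0.01 * 100 * 100)
})

test_that("rotation by the drawn angle then its negation is near-identity", {
  img <- render(parse_structure(caffeine_smiles()), style_profile("STYLE_C"),
                list(rotation = 0), c(128, 128))
  rot <- rotate_image(img, 4.2)
  back <- rotate_image(rot, -4.2)
  expect_lt(mean(abs(back - img)), 5 / 255)
})

test_that("brightness/colour and compression operators perturb mildly", {
  img <- render(parse_structure("c1ccccc1"), style_profile("STYLE_C"),
                list(rotation = 0), c(96, 96))
  bc <- apply_augmentation(img, "brightness_colour", cd_rng(3))
  expect_false(identical(bc, img))
  expect_true(all(bc >= 0 & bc <= 1))
  jp <- jpeg_artifact(img, 40)
  expect_false(identical(jp, img))
  ## lower quality -> larger deviation
  expect_gt(mean(abs(jpeg_artifact(img, 10) - img)),
            mean(abs(jpeg_artifact(img, 95) - img)))
  px <- apply_augmentation(img, "pixelation", cd_rng(4))
  expect_false(identical(px, img))
  expect_equal(dim(px), dim(img))
})

test_that("distorted dimensions are uniform over the +-10% integer range", {
  rng <- cd_rng(123)
  dims <- t(vapply(1:10000, function(i) sample_distorted_dims(299, 299, rng),
                   numeric(2)))
  expect_true(all(dims >= 270 & dims <= 328))
  expect_lt(min(dims[, 1]), 285)
  expect_gt(max(dims[, 1]), 313)
  expect_error(sample_distorted_dims(10, 299, cd_rng(1)), "at least 32")
})

test_that("distort_and_resize hits the exact target shape deterministically", {
  renderer <- function(h, w) render_stub("CCO", c(h, w), 5)
  r1 <- distort_and_resize(renderer, 299, 299, cd_rng(9))
  expect_equal(dim(r1$image), c(299L, 299L, 3L))
  expect_true(r1$method %in% resize_methods())
  r2 <- distort_and_resize(renderer, 299, 299, cd_rng(9))
  expect_identical(r1$dims, r2$dims)
  expect_identical(r1$method, r2$method)
  expect_identical(r1$image, r2$image)
  ## different shapes work, including non-square
  r3 <- distort_and_resize(renderer, 64, 120, cd_rng(2))
  expect_equal(dim(r3$image), c(64L, 120L, 3L))
})

test_that("resize methods all hit the requested shape", {
  img <- render_stub("CCC", c(77, 91), 1)
  for (m in resize_methods()) {
    out <- resize_image(img, 64, 64, m)
    expect_equal(dim(out), c(64L, 64L, 3L), info = m)
    expect_true(all(out >= 0 & out <= 1), info = m)
  }
})

test_that("augmentation pipeline from a fingerprint is byte-reproducible", {
  img <- render(parse_structure("CCO"), style_profile("STYLE_C"),
                list(rotation = 30), c(96, 96))
  fp <- c(0L, 0L, 1L, 0L, 0L, 1L, 0L, 1L, 1L, 1L, 0L)
  run <- function() {
    out <- img
    mask <- structure_mask(img)
    state <- depictor_state(77)
    for (op in augmentations_from_fingerprint(fp))
      out <- apply_augmentation(out, op, cd_rng(evolve_seed(state)), mask)
    out
  }
  expect_identical(run(), run())
})
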