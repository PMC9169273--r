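test_that("identity labels follow the four-pattern grammar", {
  rng <- cd_rng(1)
  texts <- vapply(1:1000, function(i) gen_identity_label(rng)$text,
                  character(1))
  expect_true(all(grepl(identity_label_regex(), texts)))
  ## all four forms occur
  expect_true(any(grepl("^[0-9]+$", texts)))
  expect_true(any(grepl("^[0-9]+[a-z]$", texts)))
  expect_true(any(grepl("^[0-9]+[-–][0-9]+$", texts)))
  expect_true(any(grepl("^[0-9]+[a-z][-–][a-z]$", texts)))
  expect_identical(gen_identity_label(cd_rng(9))$text,
                   gen_identity_label(cd_rng(9))$text)
})

test_that("rest group labels combine variables with shipped superatoms", {
  rng <- cd_rng(2)
  specs <- lapply(1:1000, function(i) gen_rest_group_label(rng))
  texts <- vapply(specs, `[[`, character(1), "text")
  expect_true(all(grepl(rest_group_label_regex(), texts)))
  vars <- sub("[1-9]? = .*$", "", texts)
  expect_true(all(vars %in% c("R", "R'", "X", "Y", "Z")))
  sups <- sub("^.* = ", "", texts)
  expect_true(all(sups %in% superatom_labels()))
  expect_identical(gen_rest_group_label(cd_rng(3))$text,
                   gen_rest_group_label(cd_rng(3))$text)
})

test_that("reaction condition labels are reagent, solvent, duration", {
  rng <- cd_rng(4)
  specs <- lapply(1:1000, function(i) gen_reaction_condition_label(rng))
  texts <- vapply(specs, `[[`, character(1), "text")
  expect_true(all(grepl(condition_label_regex(), texts)))
  parts <- strsplit(texts, ", ")
  expect_true(all(vapply(parts, `[`, character(1), 1) %in%
                    reagent_vocabulary()))
  expect_true(all(vapply(parts, `[`, character(1), 2) %in%
                    solvent_vocabulary()))
  expect_true(all(grepl("^[0-9]+ (h|min)$",
                        vapply(parts, `[`, character(1), 3))))
  expect_true(all(vapply(specs, `[[`, numeric(1), "lines") %in% 1:3))
  expect_identical(gen_reaction_condition_label(cd_rng(5))$text,
                   gen_reaction_condition_label(cd_rng(5))$text)
  expect_gte(length(reagent_vocabulary()), 20L)
  expect_gte(length(solvent_vocabulary()), 10L)
})

test_that("place_label adds ink off the structure mask and keeps dimensions", {
  img <- new_image(160, 160)
  lab <- gen_identity_label(cd_rng(1))
  mask <- matrix(FALSE, 160, 160)
  out <- place_label(img, lab, mask, cd_rng(2))
  expect_equal(dim(out), dim(img))
  expect_gt(ink_pixels(out), 0)
  ## fully masked image: unchanged + logged skip
  full <- matrix(TRUE, 160, 160)
  expect_message(out2 <- place_label(img, lab, full, cd_rng(2)), "skipped")
  expect_identical(unclass(out2)[seq_along(img)], as.vector(img))
  expect_false(attr(out2, "placement")$placed)
})

test_that("placed labels never intersect the structure mask", {
  base <- render(parse_structure(caffeine_smiles()), style_profile("STYLE_C"),
                 list(rotation = 0), c(160, 160))
  mask <- structure_mask(base)
  for (s in 1:200) {
    rng <- cd_rng(s)
    out <- place_label(base, gen_identity_label(rng), mask, rng)
    pl <- attr(out, "placement")
    if (!pl$placed) next
    box <- mask[pl$row:(pl$row + pl$height - 1),
                pl$col:(pl$col + pl$width - 1)]
    expect_false(any(box), label = paste("seed", s))
  }
})

test_that("arrow glyphs exist for both kinds and carry ink", {
  for (kind in c("straight", "curved")) for (v in 1:3) {
    g <- arrow_glyph(kind, v)
    expect_gt(sum(g), 20)
  }
})

test_that("arrow placement follows the overlap rule per kind", {
  base <- render(parse_structure(caffeine_smiles()), style_profile("STYLE_C"),
                 list(rotation = 0), c(200, 200))
  mask <- structure_mask(base)
  placed_c <- 0; placed_s <- 0
  for (s in 1:25) {
    rng <- cd_rng(s)
    outc <- place_arrow(base, "curved", mask, rng)
    pc <- attr(outc, "placement")
    if (pc$placed) {
      placed_c <- placed_c + 1
      expect_true(any(mask[pc$row:(pc$row + pc$height - 1),
                           pc$col:(pc$col + pc$width - 1)]))
    }
    rng2 <- cd_rng(s + 1000)
    outs <- place_arrow(base, "straight", mask, rng2)
    ps <- attr(outs, "placement")
    if (ps$placed) {
      placed_s <- placed_s + 1
      expect_false(any(mask[ps$row:(ps$row + ps$height - 1),
                            ps$col:(ps$col + ps$width - 1)]))
    }
  }
  expect_gt(placed_c, 15) # placement succeeds for most seeds
  expect_gt(placed_s, 15)
  ## determinism
  r1 <- place_arrow(base, "curved", mask, cd_rng(3))
  r2 <- place_arrow(base, "curved", mask, cd_rng(3))
  expect_identical(r1, r2)
})
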