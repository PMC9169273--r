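test_that("register_decision lays out spans per kind and rejects bad input", {
  sch <- fingerprint_scheme("t")
  sch <- register_decision(sch, parameter_decision("kekulised", "binary"))
  expect_equal(sch$total_length, 1L)
  expect_equal(sch$layout$start, 0L)
  sch <- register_decision(sch, parameter_decision(
    "bond_width", "categorical", options = c("thin", "medium", "bold")))
  expect_equal(sch$layout$start, c(0L, 1L))   # bond width on positions 1-3
  expect_equal(sch$layout$length, c(1L, 3L))
  expect_equal(sch$total_length, 4L)
  sch <- register_decision(sch, parameter_decision(
    "bond_len", "ranged", range = c(1, 6)))
  expect_equal(sch$total_length, 7L)          # ranged always takes 3 bits

  expect_error(register_decision(sch, parameter_decision("extra", "binary")) |>
                 register_decision(parameter_decision("extra", "binary")),
               "already registered")
  expect_error(parameter_decision("x", "categorical", options = "only"),
               ">= 2 options")
  expect_error(parameter_decision("x", "ranged", range = c(5, 5)),
               "empty range")
})

test_that("building blocks match their kind", {
  expect_equal(lapply(building_blocks(parameter_decision("b", "binary")),
                      `[[`, "bits"), list(0L, 1L))
  cat3 <- building_blocks(parameter_decision(
    "w", "categorical", options = c("thin", "medium", "bold")))
  expect_equal(lapply(cat3, `[[`, "bits"),
               list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L)))
  expect_equal(vapply(cat3, `[[`, character(1), "value"),
               c("thin", "medium", "bold"))
  rg <- building_blocks(parameter_decision("r", "ranged", range = c(1, 6)))
  expect_equal(lapply(rg, `[[`, "value"),
               list(c(1, 2), c(3, 4), c(5, 6)))
  ## remainder goes to the last subrange
  rg7 <- building_blocks(parameter_decision("r", "ranged", range = c(1, 7)))
  expect_equal(rg7[[3]]$value, c(5, 7))
})

test_that("worked example enumerates to exactly the six published tuples", {
  sch <- worked_example_scheme()
  expect_equal(count_valid_fingerprints(sch), 6)
  got <- enumerate_valid_fingerprints(sch)
  want <- rbind(c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1),
                c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 0, 0, 1))
  expect_setequal(apply(got, 1, paste, collapse = ""),
                  apply(want, 1, paste, collapse = ""))
})

test_that("enumeration equals the nested-loop oracle and count", {
  schemes <- list(
    worked_example_scheme(),
    { s <- fingerprint_scheme("2cat")
      s <- register_decision(s, parameter_decision(
        "c1", "categorical", options = letters[1:3]))
      register_decision(s, parameter_decision(
        "c2", "categorical", options = letters[4:6])) },
    { s <- fingerprint_scheme("mix")
      s <- register_decision(s, parameter_decision("b1", "binary"))
      s <- register_decision(s, parameter_decision(
        "r1", "ranged", range = c(0, 8)))
      register_decision(s, parameter_decision(
        "c1", "categorical", options = 1:4)) })
  for (sch in schemes) {
    got <- enumerate_valid_fingerprints(sch)
    expect_equal(nrow(got), count_valid_fingerprints(sch))
    expect_equal(got, unname(oracle_enumerate(sch)),
                 ignore_attr = TRUE)
    expect_false(anyDuplicated(apply(got, 1, paste, collapse = "")) > 0)
    for (i in seq_len(nrow(got)))
      expect_true(validate_fingerprint(sch, got[i, ]))
  }
  ## empty scheme: one empty fingerprint
  expect_equal(count_valid_fingerprints(fingerprint_scheme("e")), 1)
  expect_equal(nrow(enumerate_valid_fingerprints(fingerprint_scheme("e"))), 1L)
  ## guard refuses oversized enumerations
  expect_error(enumerate_valid_fingerprints(style_profile("STYLE_A")$scheme,
                                            guard = 1e4), "guard")
})

test_that("scheme construction is order-stable", {
  build <- function() {
    s <- fingerprint_scheme("s")
    s <- register_decision(s, parameter_decision("a", "binary"))
    s <- register_decision(s, parameter_decision(
      "b", "categorical", options = c("x", "y")))
    register_decision(s, parameter_decision("c", "ranged", range = c(1, 9)))
  }
  expect_identical(build()$layout, build()$layout)
})

test_that("sample_assignment is seed-deterministic, in-domain and uniform", {
  sch <- register_decision(
    register_decision(fingerprint_scheme("s"),
                      parameter_decision("r", "ranged", range = c(1, 6))),
    parameter_decision("c", "categorical", options = c("a", "b", "c")))
  a1 <- sample_assignment(sch, cd_rng(99))
  a2 <- sample_assignment(sch, cd_rng(99))
  expect_identical(a1, a2)
  rng <- cd_rng(5)
  draws <- replicate(600, sample_assignment(sch, rng), simplify = FALSE)
  rvals <- vapply(draws, `[[`, numeric(1), "r")
  expect_true(all(rvals %in% 1:6))
  ## 6000 categorical draws: each option within 5 sigma of n/3
  rng2 <- cd_rng(6)
  cvals <- vapply(1:6000, function(i)
    sample_assignment(sch, rng2)$c, character(1))
  sigma <- sqrt(6000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(table(cvals) - 2000) < 5 * sigma))
})

test_that("fingerprint_to_assignment decodes and rejects invalid spans", {
  sch <- worked_example_scheme()
  a <- fingerprint_to_assignment(sch, c(1L, 1L, 0L, 0L), cd_rng(1))
  expect_equal(a$kekulised, 1L)
  expect_equal(a$bond_width, "thin")
  expect_error(fingerprint_to_assignment(sch, c(1L, 1L, 0L, 1L), cd_rng(1)),
               "bond_width")
  expect_error(fingerprint_to_assignment(sch, c(1L, 0L, 0L, 0L), cd_rng(1)),
               "one-hot")
  ## ranged decode stays inside the hot subrange across many seeds
  rsch <- register_decision(fingerprint_scheme("r"),
                            parameter_decision("v", "ranged", range = c(1, 6)))
  vals <- vapply(1:1000, function(s)
    fingerprint_to_assignment(rsch, c(0L, 1L, 0L), cd_rng(s))$v, numeric(1))
  expect_true(all(vals %in% c(3, 4)))
})

test_that("assignment <-> fingerprint round-trips", {
  sch <- register_decision(
    register_decision(
      register_decision(fingerprint_scheme("s"),
                        parameter_decision("b", "binary")),
      parameter_decision("c", "categorical", options = c("p", "q", "r"))),
    parameter_decision("v", "ranged", range = c(1, 6)))
  ## ranged value 4 with splits [1,2],[3,4],[5,6] -> middle block hot
  fp <- assignment_to_fingerprint(sch, list(b = 1L, c = "q", v = 4))
  expect_equal(fp, c(1L, 0L, 1L, 0L, 0L, 1L, 0L))
  expect_error(assignment_to_fingerprint(sch, list(b = 1L, c = "zz", v = 4)),
               "not among options")
  expect_error(assignment_to_fingerprint(sch, list(b = 1L, c = "q", v = 9)),
               "outside range")
  rng <- cd_rng(3)
  for (i in 1:500) {
    a <- sample_assignment(sch, rng)
    back <- fingerprint_to_assignment(sch, assignment_to_fingerprint(sch, a),
                                      cd_rng(i))
    expect_identical(back$b, a$b)
    expect_identical(back$c, a$c)
  }
})

test_that("invalid one-bit perturbations of enumerated fingerprints are rejected", {
  sch <- worked_example_scheme()
  fps <- enumerate_valid_fingerprints(sch)
  for (i in seq_len(nrow(fps))) {
    fp <- fps[i, ]
    for (pos in 2:4) { # the categorical span
      bad <- fp
      bad[pos] <- 1L - bad[pos]
      expect_error(fingerprint_to_assignment(sch, bad, cd_rng(1)))
    }
  }
})

test_that("scheme JSON serialization round-trips", {
  for (id in c("STYLE_A", "STYLE_B", "STYLE_C")) {
    sch <- style_profile(id)$scheme
    back <- scheme_from_json(scheme_to_json(sch))
    expect_equal(back$layout, sch$layout)
    expect_equal(count_valid_fingerprints(back),
                 count_valid_fingerprints(sch))
  }
})
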