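#' Reference style profiles
#'
#' Three depiction style profiles emulate the house looks of three distinct
#' drawing toolkits by presets on one backend. Their fingerprint schemes
#' declare 15, 10 and 8 flagged decisions respectively, giving exactly
#' 2,799,360 / 18,432 / 864 valid depiction-feature fingerprints:
#'
#' * `STYLE_A`: 8 binary + 6 ranged + 1 categorical-15 (2^8 * 3^6 * 15)
#' * `STYLE_B`: 7 binary + 2 ranged + 1 categorical-16 (2^7 * 3^2 * 16)
#' * `STYLE_C`: 5 binary + 3 ranged (2^5 * 3^3)
#'
#' Decisions are named after the standard depiction parameters: bond
#' length, line thickness, kekulisation, font type and size, rotation,
#' label distance, substructure abbreviation, atom numbering, chirality
#' labels, etc. Parameters a scheme does not flag fall back to per-style
#' presets so every profile still renders completely.
#'
#' @param id one of `"STYLE_A"`, `"STYLE_B"`, `"STYLE_C"`.
#' @return a `StyleProfile`: list with `id`, `scheme` and `presets`.
#' @export
style_profile <- function(id = c("STYLE_A", "STYLE_B", "STYLE_C")) {
  id <- match.arg(id)
  bin <- function(name) parameter_decision(name, "binary")
  rng_ <- function(name, lo, hi, integer = TRUE)
    parameter_decision(name, "ranged", range = c(lo, hi), integer = integer)
  cat_ <- function(name, options) parameter_decision(name, "categorical",
                                                     options = options)
  sch <- fingerprint_scheme(id)
  add <- function(s, ds) { for (d in ds) s <- register_decision(s, d); s }
  if (id == "STYLE_A") {
    sch <- add(sch, list(
      bin("kekulised"), bin("abbreviate_substructures"), bin("atom_numbering"),
      bin("chirality_labels"), bin("explicit_terminal_carbons"),
      bin("label_halo"), bin("filled_wedges"), bin("shortened_double_bonds"),
      rng_("bond_length", 20, 45), rng_("line_thickness", 1, 4),
      rng_("font_size", 8, 24), rng_("rotation", 0, 359),
      rng_("label_distance", 2, 8), rng_("double_bond_gap", 2, 6),
      cat_("font_type", font_names()[1:15])))
    presets <- list()
  } else if (id == "STYLE_B") {
    sch <- add(sch, list(
      bin("kekulised"), bin("abbreviate_substructures"), bin("atom_numbering"),
      bin("chirality_labels"), bin("explicit_terminal_carbons"),
      bin("label_halo"), bin("filled_wedges"),
      rng_("rotation", 0, 359), rng_("line_thickness", 1, 3),
      cat_("font_type", font_names()[1:16])))
    presets <- list(bond_length = 32, font_size = 14, label_distance = 4,
                    double_bond_gap = 4, shortened_double_bonds = 1L)
  } else {
    sch <- add(sch, list(
      bin("kekulised"), bin("abbreviate_substructures"), bin("atom_numbering"),
      bin("chirality_labels"), bin("explicit_terminal_carbons"),
      rng_("rotation", 0, 359), rng_("line_thickness", 1, 3),
      rng_("font_size", 10, 20)))
    presets <- list(bond_length = 30, label_distance = 3, double_bond_gap = 3,
                    shortened_double_bonds = 0L, label_halo = 0L,
                    filled_wedges = 1L, font_type = "font01")
  }
  structure(list(id = id, scheme = sch, presets = presets),
            class = "StyleProfile")
}

#' All three reference style profiles
#' @return named list of `StyleProfile`s in canonical order.
#' @export
style_profiles <- function() {
  ids <- c("STYLE_A", "STYLE_B", "STYLE_C")
  stats::setNames(lapply(ids, style_profile), ids)
}

#' Complete an assignment with the profile's presets
#'
#' Fills in depiction parameters the profile's scheme does not flag, so
#' the renderer always sees a full parameter set.
#' @keywords internal
complete_assignment <- function(profile, assignment) {
  miss <- setdiff(names(profile$presets), names(assignment))
  c(assignment, profile$presets[miss])
}

#' @export
print.StyleProfile <- function(x, ...) {
  cat("StyleProfile", x$id, "\n")
  print(x$scheme)
  invisible(x)
}
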