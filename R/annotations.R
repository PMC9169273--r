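#' Non-structural annotation generators
#'
#' Real-world depictions carry text and arrows that an OCSR model must
#' learn to ignore: identity labels ("1a"), rest-group definitions
#' ("R = OMe"), reaction conditions ("NaOH, EtOH, 5 h"), curved mechanism
#' arrows (which overlap the structure by design) and straight reaction
#' arrows (which must not). All generators are pure functions of the rng
#' state.
#'
#' @name annotations
NULL

#' Reagent vocabulary for condition labels
#' @export
reagent_vocabulary <- function() {
  c("NaOH", "KOH", "HCl", "H2SO4", "NaBH4", "LiAlH4", "Pd/C", "H2",
    "K2CO3", "Cs2CO3", "NEt3", "DIPEA", "DBU", "TFA", "AcOH", "NaH",
    "nBuLi", "MeMgBr", "TsCl", "SOCl2", "DCC", "EDC", "NaN3", "KOtBu",
    "AlCl3", "PPh3")
}

#' Solvent vocabulary for condition labels
#' @export
solvent_vocabulary <- function() {
  c("EtOH", "MeOH", "THF", "DCM", "DMF", "DMSO", "toluene", "Et2O",
    "MeCN", "dioxane", "H2O", "EtOAc")
}

new_label <- function(kind, text, rng) {
  structure(list(kind = kind, text = text,
                 font = rng_pick(rng, font_names()),
                 size = rng_int(rng, 9L, 18L)),
            class = "LabelSpec")
}

#' Generate a chemical identity label
#'
#' One of four forms: a number ("1"), number-letter ("1a"),
#' number-number range ("1-4") or number-letter-letter range ("1a-d");
#' the dash is a hyphen or an en dash, numbers are 1-99.
#'
#' @param rng a [cd_rng()].
#' @return a `LabelSpec`.
#' @export
gen_identity_label <- function(rng) {
  form <- rng_int(rng, 1L, 4L)
  n <- rng_int(rng, 1L, 99L)
  dash <- rng_pick(rng, c("-", "–"))
  text <- switch(form,
    as.character(n),
    paste0(n, rng_pick(rng, letters)),
    paste0(n, dash, rng_int(rng, n + 1L, n + 9L)),
    { l1 <- rng_int(rng, 1L, 20L)
      paste0(n, letters[l1], dash, letters[l1 + rng_int(rng, 1L, 5L)]) })
  new_label("identity", text, rng)
}

#' Generate a rest-group label
#'
#' A rest-group variable (R, R', X, Y, Z), optionally indexed, equated to
#' a randomly picked superatom label: "R1 = OMe".
#'
#' @param rng a [cd_rng()].
#' @return a `LabelSpec`.
#' @export
gen_rest_group_label <- function(rng) {
  var <- rng_pick(rng, c("R", "R'", "X", "Y", "Z"))
  if (rng_bits(rng, 1L) == 1L) var <- paste0(var, rng_int(rng, 1L, 9L))
  text <- paste0(var, " = ", rng_pick(rng, superatom_labels()))
  new_label("rest_group", text, rng)
}

#' Generate a reaction-condition label
#'
#' Reagent, solvent and a duration ("<int> h" or "<int> min"),
#' comma-separated; rendered on 1-3 lines at placement time.
#'
#' @param rng a [cd_rng()].
#' @return a `LabelSpec` with a `lines` field in 1..3.
#' @export
gen_reaction_condition_label <- function(rng) {
  reagent <- rng_pick(rng, reagent_vocabulary())
  solvent <- rng_pick(rng, solvent_vocabulary())
  dur <- if (rng_bits(rng, 1L) == 1L) paste(rng_int(rng, 1L, 48L), "h")
         else paste(rng_int(rng, 5L, 120L), "min")
  lab <- new_label("reaction_condition",
                   paste(reagent, solvent, dur, sep = ", "), rng)
  lab$lines <- rng_int(rng, 1L, 3L)
  lab
}

#' Structure mask of a rendered depiction
#'
#' Non-background pixels dilated by 2 px; annotation placement treats
#' masked pixels as occupied.
#'
#' @param img raster array.
#' @return logical matrix.
#' @export
structure_mask <- function(img) dilate_mask(ink_mask(img), 2L)

## render a (possibly multi-line) label to a 0/1 ink matrix
label_raster <- function(spec) {
  nlines <- if (!is.null(spec$lines)) spec$lines else 1L
  parts <- strsplit(spec$text, ", ", fixed = TRUE)[[1]]
  if (nlines <= 1L || length(parts) == 1L) {
    lines <- spec$text
  } else {
    cut <- min(nlines, length(parts))
    grp <- sort(rep_len(seq_len(cut), length(parts)))
    lines <- vapply(split(parts, grp), paste, character(1), collapse = ", ")
  }
  rasters <- lapply(lines, font_raster, size = spec$size, font = spec$font)
  wmax <- max(vapply(rasters, ncol, integer(1)))
  gap <- max(2L, round(spec$size / 4))
  rows <- lapply(rasters, function(r) {
    pad <- wmax - ncol(r)
    cbind(r, matrix(0L, nrow(r), pad))
  })
  spacer <- matrix(0L, gap, wmax)
  out <- rows[[1]]
  for (r in rows[-1]) out <- rbind(out, spacer, r)
  out
}

#' Place a text label avoiding the structure
#'
#' Tries up to `attempts` random positions for the rendered label box
#' (with a 2 px pad) that do not intersect the structure mask. If no free
#' position is found the image is returned unchanged and a message is
#' logged to stderr. Image dimensions never change.
#'
#' @param img raster array.
#' @param spec a `LabelSpec`.
#' @param mask logical structure mask (see [structure_mask()]).
#' @param rng a [cd_rng()].
#' @param attempts placement attempt bound (default 50).
#' @return the annotated raster array.
#' @export
place_label <- function(img, spec, mask, rng, attempts = 50L) {
  m <- label_raster(spec)
  h <- img_height(img); w <- img_width(img)
  bh <- nrow(m) + 4L; bw <- ncol(m) + 4L
  if (bh > h || bw > w) {
    message("label '", spec$text, "' does not fit the canvas; skipped")
    return(img)
  }
  for (k in seq_len(attempts)) {
    r0 <- rng_int(rng, 1L, h - bh + 1L)
    c0 <- rng_int(rng, 1L, w - bw + 1L)
    if (!any(mask[r0:(r0 + bh - 1L), c0:(c0 + bw - 1L)])) {
      out <- draw_mask_img(img, m, r0 + 2L, c0 + 2L)
      attr(out, "placement") <- list(placed = TRUE, row = r0, col = c0,
                                     height = bh, width = bw)
      return(out)
    }
  }
  message("no free region for label '", spec$text, "' after ", attempts,
          " attempts; skipped")
  attr(img, "placement") <- list(placed = FALSE)
  img
}

## ---- arrows ----------------------------------------------------------------

#' Procedural arrow glyphs
#'
#' At least six glyph variants drawn in code (no binary assets): plain and
#' double-headed straight arrows, an equilibrium pair, a hooked arrow, and
#' single/double-headed curved (mechanism) arrows.
#'
#' @param kind `"straight"` or `"curved"`.
#' @param variant 1-3 within the kind.
#' @return 0/1 ink matrix.
#' @export
arrow_glyph <- function(kind = c("straight", "curved"), variant = 1L) {
  kind <- match.arg(kind)
  img <- new_image(48L, 120L)
  head <- function(img, x, y, ux, uy, s = 8) {
    nx <- -uy; ny <- ux
    draw_polygon_img(img, c(x, x - ux * s + nx * s / 2, x - ux * s - nx * s / 2),
                     c(y, y - uy * s + ny * s / 2, y - uy * s - ny * s / 2))
  }
  if (kind == "straight") {
    if (variant == 1L) {           # plain reaction arrow
      img <- draw_line_img(img, 10, 24, 108, 24, 2)
      img <- head(img, 112, 24, 1, 0)
    } else if (variant == 2L) {    # double-headed
      img <- draw_line_img(img, 12, 24, 106, 24, 2)
      img <- head(img, 112, 24, 1, 0)
      img <- head(img, 6, 24, -1, 0)
    } else {                       # equilibrium half-arrow pair
      img <- draw_line_img(img, 10, 18, 105, 18, 2)
      img <- draw_line_img(img, 105, 18, 97, 12, 2)
      img <- draw_line_img(img, 14, 30, 109, 30, 2)
      img <- draw_line_img(img, 14, 30, 22, 36, 2)
    }
  } else {
    ## quadratic bezier arc
    t <- seq(0, 1, length.out = 80)
    p0 <- c(12, 40); p1 <- c(60, if (variant == 3L) -14 else 0); p2 <- c(108, 40)
    bx <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
    by <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
    for (i in seq_len(length(t) - 1L))
      img <- draw_line_img(img, bx[i], by[i], bx[i + 1], by[i + 1], 2)
    d <- c(bx[80] - bx[79], by[80] - by[79])
    d <- d / sqrt(sum(d^2))
    img <- head(img, bx[80], by[80], d[1], d[2])
    if (variant == 2L) {           # double-headed mechanism arrow
      d0 <- c(bx[1] - bx[2], by[1] - by[2])
      d0 <- d0 / sqrt(sum(d0^2))
      img <- head(img, bx[1], by[1], d0[1], d0[2])
    }
  }
  ink_mask(img) * 1L
}

#' Place an arrow glyph
#'
#' Picks a glyph of the requested kind, randomly scales (0.35-0.8 of
#' canvas width) and rotates it, then pastes it at a position whose
#' bounding box *does* intersect the structure mask for curved mechanism
#' arrows, and *does not* for straight reaction arrows. A straight arrow
#' with no free region after `attempts` tries is skipped with a logged
#' message. Image dimensions never change.
#'
#' @param img raster array.
#' @param kind `"curved"` or `"straight"`.
#' @param mask logical structure mask.
#' @param rng a [cd_rng()].
#' @param attempts placement attempt bound (default 50).
#' @return the annotated raster array.
#' @export
place_arrow <- function(img, kind = c("curved", "straight"), mask, rng,
                        attempts = 50L) {
  kind <- match.arg(kind)
  h <- img_height(img); w <- img_width(img)
  glyph <- arrow_glyph(kind, rng_int(rng, 1L, 3L))
  base_w <- rng_runif(rng, 1L, 0.35, 0.8) * w
  ang <- rng_runif(rng, 1L, 0, 360)
  for (shrink in c(1, 0.7, 0.5, 0.35)) { # shrink when no position fits
    sc <- base_w * shrink / ncol(glyph)
    gh <- max(4L, round(nrow(glyph) * sc))
    gw <- max(4L, round(ncol(glyph) * sc))
    ri <- pmin(nrow(glyph), pmax(1L, ceiling(seq_len(gh) / gh * nrow(glyph))))
    ci <- pmin(ncol(glyph), pmax(1L, ceiling(seq_len(gw) / gw * ncol(glyph))))
    g <- rotate_mask(glyph[ri, ci, drop = FALSE], ang)
    gh <- nrow(g); gw <- ncol(g)
    if (gh > h || gw > w) next
    for (k in seq_len(attempts)) {
      r0 <- rng_int(rng, 1L, h - gh + 1L)
      c0 <- rng_int(rng, 1L, w - gw + 1L)
      overlaps <- any(mask[r0:(r0 + gh - 1L), c0:(c0 + gw - 1L)])
      if ((kind == "curved") == overlaps) {
        out <- draw_mask_img(img, g, r0, c0)
        attr(out, "placement") <- list(placed = TRUE, row = r0, col = c0,
                                       height = gh, width = gw)
        return(out)
      }
    }
  }
  message("no valid position for ", kind, " arrow after ", attempts,
          " attempts; skipped")
  attr(img, "placement") <- list(placed = FALSE)
  img
}

## rotate a 0/1 mask about its centre, output tightly cropped
rotate_mask <- function(m, degrees) {
  d <- max(nrow(m), ncol(m))
  pad <- ceiling(d * 1.5)
  big <- matrix(0L, pad, pad)
  r0 <- (pad - nrow(m)) %/% 2L; c0 <- (pad - ncol(m)) %/% 2L
  big[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- m
  arr <- array(rep(1 - big, 3L), dim = c(pad, pad, 3L))
  rot <- rotate_image(arr, degrees)
  out <- ink_mask(rot, 0.5) * 1L
  rows <- which(rowSums(out) > 0); cols <- which(colSums(out) > 0)
  if (length(rows) == 0L) return(matrix(0L, 1L, 1L))
  out[min(rows):max(rows), min(cols):max(cols), drop = FALSE]
}
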