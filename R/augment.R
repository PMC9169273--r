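#' The augmentation fingerprint scheme
#'
#' Eleven binary flags, one per augmentation operator, in canonical
#' order: annotations first (curved arrow, straight arrow, identity,
#' rest-group and condition labels), then geometric (rotation, shear),
#' photometric (salt-and-pepper, brightness/colour) and compression
#' artefacts (JPEG-style compression, pixelation). 2^11 = 2048 valid
#' fingerprints. Augmentation fingerprints record only presence/absence;
#' operator parameters are drawn at application time.
#'
#' @return a `FingerprintScheme` with 11 binary decisions.
#' @export
augmentation_scheme <- function() {
  sch <- fingerprint_scheme("AUG")
  for (nm in augmentation_ops())
    sch <- register_decision(sch, parameter_decision(nm, "binary"))
  sch
}

#' Canonical augmentation operator order
#' @export
augmentation_ops <- function() {
  c("curved_arrow", "straight_arrow", "identity_label", "rest_group_label",
    "condition_label", "rotation", "shear", "salt_pepper",
    "brightness_colour", "jpeg_compression", "pixelation")
}

#' Decode an augmentation fingerprint into an operator list
#'
#' @param fp 0/1 vector of length 11.
#' @return character vector of operator ids whose flag is set, in
#'   canonical order.
#' @export
augmentations_from_fingerprint <- function(fp) {
  ops <- augmentation_ops()
  if (length(fp) != length(ops))
    stop("augmentation fingerprint must have length ", length(ops),
         ", got ", length(fp))
  if (!all(fp %in% c(0L, 1L)))
    stop("augmentation fingerprint must be 0/1")
  ops[fp == 1L]
}

## mild parameter ranges per operator
.aug_ranges <- list(rotation = c(-5, 5), shear = c(-10, 10),
                    salt_pepper = c(0.001, 0.01),
                    brightness = c(0.7, 1.3), colour_jitter = c(0.9, 1.1),
                    jpeg_quality = c(40, 95), pixelation = c(1.5, 3))

#' Apply one augmentation operator
#'
#' Parameters are drawn from mild, OCSR-plausible ranges: rotation +-5
#' degrees, shear +-10 degrees, salt-and-pepper density 0.1-1% of pixels,
#' brightness factor 0.7-1.3 with +-10% per-channel colour jitter, JPEG
#' quality 40-95, pixelation downscale factor 1.5-3x. Output dimensions
#' always equal input dimensions; results are deterministic per seed.
#' Annotation operators delegate to the annotations module.
#'
#' @param img raster array.
#' @param op_id one of [augmentation_ops()].
#' @param rng a [cd_rng()].
#' @param mask optional structure mask for the annotation operators
#'   (default: [structure_mask()] of the current image).
#' @return augmented raster array, same dimensions.
#' @export
apply_augmentation <- function(img, op_id, rng, mask = NULL) {
  r <- .aug_ranges
  switch(op_id,
    curved_arrow = place_arrow(img, "curved",
                               if (is.null(mask)) structure_mask(img) else mask,
                               rng),
    straight_arrow = place_arrow(img, "straight",
                                 if (is.null(mask)) structure_mask(img) else mask,
                                 rng),
    identity_label = place_label(img, gen_identity_label(rng),
                                 if (is.null(mask)) structure_mask(img) else mask,
                                 rng),
    rest_group_label = place_label(img, gen_rest_group_label(rng),
                                   if (is.null(mask)) structure_mask(img) else mask,
                                   rng),
    condition_label = place_label(img, gen_reaction_condition_label(rng),
                                  if (is.null(mask)) structure_mask(img) else mask,
                                  rng),
    rotation = rotate_image(img, rng_runif(rng, 1L, r$rotation[1],
                                           r$rotation[2])),
    shear = shear_image(img, rng_runif(rng, 1L, r$shear[1], r$shear[2])),
    salt_pepper = salt_pepper(img, rng_runif(rng, 1L, r$salt_pepper[1],
                                             r$salt_pepper[2]), rng),
    brightness_colour = brightness_colour(
      img, rng_runif(rng, 1L, r$brightness[1], r$brightness[2]),
      rng_runif(rng, 3L, r$colour_jitter[1], r$colour_jitter[2])),
    jpeg_compression = jpeg_artifact(img, rng_int(rng, r$jpeg_quality[1],
                                                  r$jpeg_quality[2])),
    pixelation = pixelate(img, rng_runif(rng, 1L, r$pixelation[1],
                                         r$pixelation[2])),
    stop("unknown augmentation operator '", op_id, "'"))
}

salt_pepper <- function(img, density, rng) {
  h <- img_height(img); w <- img_width(img)
  npx <- round(density * h * w)
  if (npx == 0L) return(img)
  idx <- rng_pick(rng, seq_len(h * w), npx)
  val <- rng_bits(rng, npx)
  for (ch in 1:3) img[idx + (ch - 1L) * h * w] <- val
  img
}

brightness_colour <- function(img, factor, jitter) {
  for (ch in 1:3) img[, , ch] <- img[, , ch] * factor * jitter[ch]
  clamp01(img)
}

## 8x8 DCT-II matrix (orthonormal)
.dct8 <- local({
  D <- matrix(0, 8, 8)
  for (k in 0:7) for (n in 0:7)
    D[k + 1, n + 1] <- cos(pi / 8 * (n + 0.5) * k)
  D[1, ] <- D[1, ] / sqrt(2)
  D * 0.5
})

## standard JPEG luminance quantisation table (Annex K)
.jpeg_qtab <- matrix(c(
  16, 11, 10, 16, 24, 40, 51, 61,
  12, 12, 14, 19, 26, 58, 60, 55,
  14, 13, 16, 24, 40, 57, 69, 56,
  14, 17, 22, 29, 51, 87, 80, 62,
  18, 22, 37, 56, 68, 109, 103, 77,
  24, 35, 55, 64, 81, 104, 113, 92,
  49, 64, 78, 87, 103, 121, 120, 101,
  72, 92, 95, 98, 112, 100, 103, 99), 8, 8, byrow = TRUE)

#' JPEG-style compression artefacts
#'
#' Blockwise 8x8 DCT quantisation round-trip with the standard JPEG
#' luminance table scaled by the IJG quality formula. Entropy coding is
#' lossless, so this reproduces the pixel-level effect of a JPEG
#' encode/decode without a codec.
#'
#' @param img raster array.
#' @param quality integer 1-100.
#' @return raster array with compression artefacts, same dimensions.
#' @export
jpeg_artifact <- function(img, quality) {
  quality <- max(1, min(100, quality))
  s <- if (quality < 50) 5000 / quality else 200 - 2 * quality
  Q <- floor((.jpeg_qtab * s + 50) / 100)
  Q[Q < 1] <- 1
  h <- img_height(img); w <- img_width(img)
  hp <- ceiling(h / 8) * 8; wp <- ceiling(w / 8) * 8
  nbr <- hp / 8; nbc <- wp / 8
  ## block-diagonal DCT operators
  Br <- matrix(0, hp, hp); Bc <- matrix(0, wp, wp)
  for (b in seq_len(nbr)) Br[(b - 1) * 8 + 1:8, (b - 1) * 8 + 1:8] <- .dct8
  for (b in seq_len(nbc)) Bc[(b - 1) * 8 + 1:8, (b - 1) * 8 + 1:8] <- .dct8
  Qtile <- Q[rep(1:8, nbr), rep(1:8, nbc)]
  out <- img
  for (ch in 1:3) {
    x <- matrix(0, hp, wp)
    x[1:h, 1:w] <- img[, , ch] * 255 - 128
    if (hp > h) x[(h + 1):hp, 1:w] <- x[rep(h, hp - h), 1:w]
    if (wp > w) x[, (w + 1):wp] <- x[, rep(w, wp - w)]
    coef <- Br %*% x %*% t(Bc)
    coef <- round(coef / Qtile) * Qtile
    y <- t(Br) %*% coef %*% Bc
    out[, , ch] <- clamp01((y[1:h, 1:w] + 128) / 255)
  }
  out
}

pixelate <- function(img, factor) {
  h <- img_height(img); w <- img_width(img)
  small <- resize_image(img, max(1L, round(h / factor)),
                        max(1L, round(w / factor)), "area")
  resize_image(small, h, w, "nearest")
}

#' Sample distorted intermediate dimensions
#'
#' The distort-then-resize step first renders at `(m_dist, n_dist)` with
#' each dimension drawn uniformly from the integer range
#' `[ceiling(0.9 m), floor(1.1 m)]`, then resamples to `(m, n)`.
#'
#' @param m,n target dimensions (>= 32).
#' @param rng a [cd_rng()].
#' @return integer `c(m_dist, n_dist)`.
#' @export
sample_distorted_dims <- function(m, n, rng) {
  if (m < 32 || n < 32) stop("target shape must be at least 32 x 32")
  c(rng_int(rng, ceiling(0.9 * m), floor(1.1 * m)),
    rng_int(rng, ceiling(0.9 * n), floor(1.1 * n)))
}

#' Distort-then-resize
#'
#' Renders via `render_fun(height, width)` at randomly perturbed
#' dimensions and resamples to exactly `(m, n)` with a resizing method
#' drawn uniformly from [resize_methods()], injecting the artefacts of
#' different resamplers into the data.
#'
#' @param render_fun function of `(height, width)` returning a raster.
#' @param m,n target dimensions (>= 32).
#' @param rng a [cd_rng()].
#' @return list with `image` (exactly `m x n`), `dims` (the intermediate
#'   dimensions) and `method`.
#' @export
distort_and_resize <- function(render_fun, m, n, rng) {
  dims <- sample_distorted_dims(m, n, rng)
  method <- rng_pick(rng, resize_methods())
  img <- render_fun(dims[1], dims[2])
  list(image = resize_image(img, m, n, method), dims = dims, method = method)
}
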