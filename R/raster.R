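#' Raster images
#'
#' Images are plain numeric arrays `height x width x 3` (RGB) with values
#' in `[0, 1]`; grayscale content simply has equal channels. Row 1 is the
#' top scanline; `x` is the column coordinate, `y` the row coordinate.
#'
#' @param height,width positive pixel dimensions.
#' @param bg background intensity (default white = 1).
#' @return a raster array.
#' @export
new_image <- function(height, width, bg = 1) {
  stopifnot(height >= 1, width >= 1)
  array(bg, dim = c(height, width, 3L))
}

img_height <- function(img) dim(img)[1L]
img_width <- function(img) dim(img)[2L]

clamp01 <- function(x) { # keeps dim attributes, unlike pmin/pmax with scalars
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

## set pixels (rows, cols vectors, recycled against each other as pairs)
stamp_pixels <- function(img, rows, cols, col = c(0, 0, 0), alpha = 1) {
  keep <- rows >= 1 & rows <= img_height(img) &
          cols >= 1 & cols <= img_width(img)
  rows <- rows[keep]; cols <- cols[keep]
  if (length(rows) == 0L) return(img)
  h <- img_height(img); w <- img_width(img)
  for (ch in 1:3) {
    idx <- (ch - 1L) * h * w + (cols - 1L) * h + rows
    img[idx] <- (1 - alpha) * img[idx] + alpha * col[ch]
  }
  img
}

## pixel centres covered by a thick line segment
line_pixels <- function(x0, y0, x1, y1, width = 1) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  npt <- max(2L, ceiling(len / 0.35) + 1L)
  t <- seq(0, 1, length.out = npt)
  px <- x0 + t * (x1 - x0)
  py <- y0 + t * (y1 - y0)
  r <- max(width / 2, 0.5)
  ro <- ceiling(r)
  off <- expand.grid(dx = -ro:ro, dy = -ro:ro)
  off <- off[off$dx^2 + off$dy^2 <= r^2 + 0.25, ]
  cols <- round(rep(px, each = nrow(off)) + off$dx)
  rows <- round(rep(py, each = nrow(off)) + off$dy)
  uniq <- !duplicated(cols * 1e6 + rows)
  list(rows = rows[uniq], cols = cols[uniq])
}

draw_line_img <- function(img, x0, y0, x1, y1, width = 1, col = c(0, 0, 0)) {
  p <- line_pixels(x0, y0, x1, y1, width)
  stamp_pixels(img, p$rows, p$cols, col)
}

## filled convex polygon (wedge bonds, arrow heads)
draw_polygon_img <- function(img, xs, ys, col = c(0, 0, 0)) {
  rmin <- max(1L, floor(min(ys))); rmax <- min(img_height(img), ceiling(max(ys)))
  cmin <- max(1L, floor(min(xs))); cmax <- min(img_width(img), ceiling(max(xs)))
  if (rmin > rmax || cmin > cmax) return(img)
  grid <- expand.grid(r = rmin:rmax, c = cmin:cmax)
  inside <- point_in_polygon(grid$c, grid$r, xs, ys)
  stamp_pixels(img, grid$r[inside], grid$c[inside], col)
}

## even-odd rule, vectorised over query points
point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i] + 1e-12) + xs[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

## stamp a 0/1 ink matrix with its top-left at (row, col)
draw_mask_img <- function(img, mask, row, col, colr = c(0, 0, 0), alpha = 1) {
  w <- which(mask == 1, arr.ind = TRUE)
  if (nrow(w) == 0L) return(img)
  stamp_pixels(img, row + w[, 1L] - 1L, col + w[, 2L] - 1L, colr, alpha)
}

## white halo box then text; (x, y) is the text centre
draw_text_img <- function(img, text, x, y, size = 14, font = "font01",
                          col = c(0, 0, 0), halo = FALSE) {
  m <- font_raster(text, size, font)
  r0 <- round(y - nrow(m) / 2); c0 <- round(x - ncol(m) / 2)
  if (halo) {
    rows <- rep((r0 - 1):(r0 + nrow(m)), times = ncol(m) + 2)
    cols <- rep((c0 - 1):(c0 + ncol(m)), each = nrow(m) + 2)
    img <- stamp_pixels(img, rows, cols, c(1, 1, 1))
  }
  draw_mask_img(img, m, r0, c0, col)
}

## binary mask of non-background pixels
#' Ink mask of an image
#' @param img raster array.
#' @param threshold intensity below which a pixel counts as ink.
#' @return logical matrix `height x width`.
#' @export
ink_mask <- function(img, threshold = 0.95) {
  img[, , 1L] < threshold | img[, , 2L] < threshold | img[, , 3L] < threshold
}

#' Count ink pixels
#' @inheritParams ink_mask
#' @export
ink_pixels <- function(img, threshold = 0.95) sum(ink_mask(img, threshold))

## square dilation by r pixels via shifted OR
dilate_mask <- function(mask, r = 2L) {
  if (r <= 0L) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0L && dc == 0L) next
    rs <- max(1L, 1L + dr):min(h, h + dr)
    rt <- rs - dr
    cs <- max(1L, 1L + dc):min(w, w + dc)
    ct <- cs - dc
    out[rt, ct] <- out[rt, ct] | mask[rs, cs]
  }
  out
}

## ---- resampling ------------------------------------------------------------

resample_kernel <- function(method) {
  switch(method,
    nearest = list(fun = function(x) as.numeric(abs(x) <= 0.5), support = 0.5),
    bilinear = list(fun = function(x) pmax(0, 1 - abs(x)), support = 1),
    bicubic = list(fun = function(x) { # Keys, a = -0.5
      x <- abs(x)
      ifelse(x < 1, 1.5 * x^3 - 2.5 * x^2 + 1,
             ifelse(x < 2, -0.5 * x^3 + 2.5 * x^2 - 4 * x + 2, 0))
    }, support = 2),
    lanczos = list(fun = function(x) {
      out <- ifelse(abs(x) < 1e-9, 1,
                    3 * sin(pi * x) * sin(pi * x / 3) / (pi^2 * x^2))
      out[abs(x) >= 3] <- 0
      out
    }, support = 3),
    stop("unknown resampling method '", method, "'"))
}

## n_out x n_in row-normalised weight matrix; 'area' is box averaging
make_resample_matrix <- function(n_in, n_out, method) {
  if (method == "area") {
    W <- matrix(0, n_out, n_in)
    edges_out <- seq(0, n_in, length.out = n_out + 1)
    for (i in seq_len(n_out)) {
      lo <- edges_out[i]; hi <- edges_out[i + 1]
      j0 <- floor(lo) + 1; j1 <- ceiling(hi)
      for (j in j0:min(j1, n_in))
        W[i, j] <- max(0, min(hi, j) - max(lo, j - 1))
    }
    return(W / rowSums(W))
  }
  k <- resample_kernel(method)
  scale <- n_in / n_out
  spread <- if (scale > 1 && method != "nearest") scale else 1
  centers <- (seq_len(n_out) - 0.5) * scale - 0.5 # 0-based input coords
  W <- matrix(0, n_out, n_in)
  sup <- k$support * spread
  for (i in seq_len(n_out)) {
    j <- max(0, floor(centers[i] - sup)):min(n_in - 1, ceiling(centers[i] + sup))
    w <- k$fun((j - centers[i]) / spread)
    if (sum(w) <= 0) { j <- round(centers[i]); w <- 1 }
    W[i, j + 1] <- w / sum(w)
  }
  W
}

#' Resize a raster image
#'
#' Separable resampling with one of five methods: `nearest`, `bilinear`,
#' `bicubic` (Keys a = -0.5), `area` (box average) or `lanczos` (a = 3).
#' Kernels are widened when minifying (except nearest), as mainstream
#' image libraries do.
#'
#' @param img raster array.
#' @param height,width target dimensions.
#' @param method resampling method name.
#' @return resized raster array.
#' @export
resize_image <- function(img, height, width, method = "bilinear") {
  Wr <- make_resample_matrix(img_height(img), height, method)
  Wc <- make_resample_matrix(img_width(img), width, method)
  out <- array(0, dim = c(height, width, 3L))
  for (ch in 1:3) out[, , ch] <- clamp01(Wr %*% img[, , ch] %*% t(Wc))
  out
}

#' Resampling methods available to distort-then-resize
#' @export
resize_methods <- function() c("nearest", "bilinear", "bicubic", "area",
                               "lanczos")

## inverse-mapped affine transform about the image centre, bilinear gather
## A maps output (x, y) offsets (from centre) to input offsets
affine_sample <- function(img, A, fill = 1) {
  h <- img_height(img); w <- img_width(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  grid_c <- rep(seq_len(w), each = h) - cx
  grid_r <- rep(seq_len(h), times = w) - cy
  sx <- A[1, 1] * grid_c + A[1, 2] * grid_r + cx
  sy <- A[2, 1] * grid_c + A[2, 2] * grid_r + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  out <- array(fill, dim = dim(img))
  gather <- function(ch, xs, ys) {
    ok <- xs >= 1 & xs <= w & ys >= 1 & ys <= h
    v <- rep(fill, length(xs))
    v[ok] <- img[cbind(ys[ok], xs[ok], ch)]
    v
  }
  for (ch in 1:3) {
    v <- (1 - fx) * (1 - fy) * gather(ch, x0, y0) +
         fx * (1 - fy) * gather(ch, x0 + 1, y0) +
         (1 - fx) * fy * gather(ch, x0, y0 + 1) +
         fx * fy * gather(ch, x0 + 1, y0 + 1)
    out[, , ch] <- matrix(clamp01(v), h, w)
  }
  out
}

rotate_image <- function(img, degrees, fill = 1) {
  th <- degrees * pi / 180
  affine_sample(img, matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2),
                fill = fill)
}

shear_image <- function(img, degrees, fill = 1) {
  affine_sample(img, matrix(c(1, 0, tan(degrees * pi / 180), 1), 2, 2),
                fill = fill)
}
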