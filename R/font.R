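## Procedural bitmap fonts.
##
## No font rasteriser exists in the target environment, so text is drawn
## from a built-in 5x7 core font; the categorical "font_type" depiction
## decision selects one of 16 procedural variants (weight / slant /
## width / spacing transforms of the core glyphs).

.font5x7 <- local({
  g <- function(...) {
    rows <- c(...)
    m <- do.call(rbind, lapply(rows, function(r)
      as.integer(strsplit(r, "")[[1]] == "#")))
    m
  }
  list(
  "A" = g(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
  "B" = g("####.", "#...#", "#...#", "####.", "#...#", "#...#", "####."),
  "C" = g(".####", "#....", "#....", "#....", "#....", "#....", ".####"),
  "D" = g("####.", "#...#", "#...#", "#...#", "#...#", "#...#", "####."),
  "E" = g("#####", "#....", "#....", "####.", "#....", "#....", "#####"),
  "F" = g("#####", "#....", "#....", "####.", "#....", "#....", "#...."),
  "G" = g(".####", "#....", "#....", "#.###", "#...#", "#...#", ".###."),
  "H" = g("#...#", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
  "I" = g("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "#####"),
  "J" = g("..###", "...#.", "...#.", "...#.", "...#.", "#..#.", ".##.."),
  "K" = g("#...#", "#..#.", "#.#..", "##...", "#.#..", "#..#.", "#...#"),
  "L" = g("#....", "#....", "#....", "#....", "#....", "#....", "#####"),
  "M" = g("#...#", "##.##", "#.#.#", "#.#.#", "#...#", "#...#", "#...#"),
  "N" = g("#...#", "##..#", "#.#.#", "#..##", "#...#", "#...#", "#...#"),
  "O" = g(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  "P" = g("####.", "#...#", "#...#", "####.", "#....", "#....", "#...."),
  "Q" = g(".###.", "#...#", "#...#", "#...#", "#.#.#", "#..#.", ".##.#"),
  "R" = g("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#"),
  "S" = g(".####", "#....", "#....", ".###.", "....#", "....#", "####."),
  "T" = g("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
  "U" = g("#...#", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  "V" = g("#...#", "#...#", "#...#", "#...#", ".#.#.", ".#.#.", "..#.."),
  "W" = g("#...#", "#...#", "#...#", "#.#.#", "#.#.#", "##.##", "#...#"),
  "X" = g("#...#", "#...#", ".#.#.", "..#..", ".#.#.", "#...#", "#...#"),
  "Y" = g("#...#", "#...#", ".#.#.", "..#..", "..#..", "..#..", "..#.."),
  "Z" = g("#####", "....#", "...#.", "..#..", ".#...", "#....", "#####"),
  "a" = g(".....", ".....", ".###.", "....#", ".####", "#...#", ".####"),
  "b" = g("#....", "#....", "####.", "#...#", "#...#", "#...#", "####."),
  "c" = g(".....", ".....", ".####", "#....", "#....", "#....", ".####"),
  "d" = g("....#", "....#", ".####", "#...#", "#...#", "#...#", ".####"),
  "e" = g(".....", ".....", ".###.", "#...#", "#####", "#....", ".####"),
  "f" = g("..###", ".#...", "####.", ".#...", ".#...", ".#...", ".#..."),
  "g" = g(".....", ".####", "#...#", "#...#", ".####", "....#", ".###."),
  "h" = g("#....", "#....", "####.", "#...#", "#...#", "#...#", "#...#"),
  "i" = g("..#..", ".....", ".##..", "..#..", "..#..", "..#..", ".###."),
  "j" = g("...#.", ".....", "..##.", "...#.", "...#.", "#..#.", ".##.."),
  "k" = g("#....", "#....", "#..#.", "#.#..", "##...", "#.#..", "#..#."),
  "l" = g(".##..", "..#..", "..#..", "..#..", "..#..", "..#..", ".###."),
  "m" = g(".....", ".....", "##.#.", "#.#.#", "#.#.#", "#.#.#", "#.#.#"),
  "n" = g(".....", ".....", "####.", "#...#", "#...#", "#...#", "#...#"),
  "o" = g(".....", ".....", ".###.", "#...#", "#...#", "#...#", ".###."),
  "p" = g(".....", "####.", "#...#", "#...#", "####.", "#....", "#...."),
  "q" = g(".....", ".####", "#...#", "#...#", ".####", "....#", "....#"),
  "r" = g(".....", ".....", "#.###", "##...", "#....", "#....", "#...."),
  "s" = g(".....", ".....", ".####", "#....", ".###.", "....#", "####."),
  "t" = g(".#...", ".#...", "####.", ".#...", ".#...", ".#...", "..###"),
  "u" = g(".....", ".....", "#...#", "#...#", "#...#", "#...#", ".####"),
  "v" = g(".....", ".....", "#...#", "#...#", "#...#", ".#.#.", "..#.."),
  "w" = g(".....", ".....", "#...#", "#...#", "#.#.#", "#.#.#", ".#.#."),
  "x" = g(".....", ".....", "#...#", ".#.#.", "..#..", ".#.#.", "#...#"),
  "y" = g(".....", "#...#", "#...#", ".####", "....#", "#...#", ".###."),
  "z" = g(".....", ".....", "#####", "...#.", "..#..", ".#...", "#####"),
  "0" = g(".###.", "#...#", "#..##", "#.#.#", "##..#", "#...#", ".###."),
  "1" = g("..#..", ".##..", "..#..", "..#..", "..#..", "..#..", ".###."),
  "2" = g(".###.", "#...#", "....#", "...#.", "..#..", ".#...", "#####"),
  "3" = g(".###.", "#...#", "....#", "..##.", "....#", "#...#", ".###."),
  "4" = g("...#.", "..##.", ".#.#.", "#..#.", "#####", "...#.", "...#."),
  "5" = g("#####", "#....", "####.", "....#", "....#", "#...#", ".###."),
  "6" = g(".###.", "#....", "#....", "####.", "#...#", "#...#", ".###."),
  "7" = g("#####", "....#", "...#.", "..#..", ".#...", ".#...", ".#..."),
  "8" = g(".###.", "#...#", "#...#", ".###.", "#...#", "#...#", ".###."),
  "9" = g(".###.", "#...#", "#...#", ".####", "....#", "#...#", ".###."),
  " " = g(".....", ".....", ".....", ".....", ".....", ".....", "....."),
  "=" = g(".....", ".....", "#####", ".....", "#####", ".....", "....."),
  "-" = g(".....", ".....", ".....", "#####", ".....", ".....", "....."),
  "+" = g(".....", "..#..", "..#..", "#####", "..#..", "..#..", "....."),
  "," = g(".....", ".....", ".....", ".....", ".....", "..##.", ".##.."),
  "." = g(".....", ".....", ".....", ".....", ".....", ".##..", ".##.."),
  "(" = g("...#.", "..#..", ".#...", ".#...", ".#...", "..#..", "...#."),
  ")" = g(".#...", "..#..", "...#.", "...#.", "...#.", "..#..", ".#..."),
  "/" = g("....#", "...#.", "...#.", "..#..", ".#...", ".#...", "#...."),
  ":" = g(".....", ".##..", ".##..", ".....", ".##..", ".##..", "....."),
  "'" = g("..#..", "..#..", ".....", ".....", ".....", ".....", "....."),
  "%" = g("##..#", "##..#", "...#.", "..#..", ".#...", "#..##", "#..##"),
  "*" = g(".....", "#.#.#", ".###.", "#####", ".###.", "#.#.#", "....."),
  "#" = g(".#.#.", "#####", ".#.#.", ".#.#.", ".#.#.", "#####", ".#.#.")
  )
})

#' Names of the available procedural font variants
#' @return character vector `font01` ... `font16`.
#' @export
font_names <- function() sprintf("font%02d", 1:16)

## variant -> transform parameters of the core 5x7 font
font_params <- function(name) {
  i <- match(name, font_names())
  if (is.na(i)) i <- 1L
  list(bold = c(0,1,0,1,0,1,0,1,0,1,0,1,0,1,0,1)[i] == 1,
       slant = c(0,0,1,1,0,0,1,1,0,0,1,1,0,0,1,1)[i] == 1,
       xscale = c(1,1,1,1,1.4,1.4,1.4,1.4,0.8,0.8,0.8,0.8,1.2,1.2,1.2,1.2)[i],
       spacing = c(1,1,1,1,1,1,1,1,2,2,2,2,2,2,2,2)[i])
}

## render a text string as a 0/1 ink matrix at the given pixel height
font_raster <- function(text, size = 14, font = "font01") {
  fp <- font_params(font)
  chars <- strsplit(text, "")[[1]]
  chars[chars == "–"] <- "-" # en dash
  glyphs <- lapply(chars, function(ch) {
    m <- .font5x7[[ch]]
    if (is.null(m)) m <- .font5x7[["#"]] # unknown -> box-ish placeholder
    if (fp$bold) { # thicken horizontally
      m2 <- m
      m2[, -1] <- pmax(m[, -1], m[, -ncol(m)])
      m <- m2
    }
    m
  })
  sp <- matrix(0L, 7L, fp$spacing)
  rows <- Reduce(function(a, b) cbind(a, sp, b), glyphs)
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 7L)
  if (fp$slant) { # shear: shift upper rows right by up to 2 cols
    pad <- matrix(0L, 7L, 2L)
    rows <- cbind(rows, pad)
    for (r in 1:7) {
      off <- (7L - r) %/% 3L
      if (off > 0) rows[r, ] <- c(rep(0L, off),
                                  rows[r, seq_len(ncol(rows) - off)])
    }
  }
  ## scale to target pixel height (nearest neighbour)
  h <- max(4L, as.integer(round(size)))
  w <- max(1L, as.integer(round(ncol(rows) * (h / 7) * fp$xscale)))
  ri <- pmin(7L, pmax(1L, ceiling(seq_len(h) / h * 7)))
  ci <- pmin(ncol(rows), pmax(1L, ceiling(seq_len(w) / w * ncol(rows))))
  rows[ri, ci, drop = FALSE]
}
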