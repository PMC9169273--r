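#' Built-in superatom abbreviations
#'
#' Common substituent abbreviations used for substructure contraction and
#' as vocabulary for rest-group labels. Each entry pairs a display label
#' with a group SMILES whose `*` marks the attachment point. Only groups
#' with at least two heavy atoms are contracted in depictions (collapsing
#' a lone methyl is visually pointless); the full label vocabulary is
#' available to the annotation generators.
#'
#' @return data.frame with columns `name`, `smiles`, `atoms`.
#' @export
superatom_table <- function() {
  tab <- data.frame(
    name = c("Me", "Et", "nPr", "iPr", "nBu", "tBu", "Ph", "Bn", "Bz",
             "Ac", "OMe", "OEt", "CF3", "CCl3", "CN", "NO2", "CO2H",
             "CO2Me", "SO3H", "NMe2", "OBn", "OAc", "Boc", "Cbz", "TMS"),
    smiles = c("*C", "*CC", "*CCC", "*C(C)C", "*CCCC", "*C(C)(C)C",
               "*c1ccccc1", "*Cc1ccccc1", "*C(=O)c1ccccc1", "*C(=O)C",
               "*OC", "*OCC", "*C(F)(F)F", "*C(Cl)(Cl)Cl", "*C#N",
               "*N(=O)=O", "*C(=O)O", "*C(=O)OC", "*S(=O)(=O)O", "*N(C)C",
               "*OCc1ccccc1", "*OC(=O)C", "*C(=O)OC(C)(C)C",
               "*C(=O)OCc1ccccc1", "*[Si](C)(C)C"),
    stringsAsFactors = FALSE)
  tab$atoms <- vapply(tab$smiles, function(s)
    heavy_atom_count(parse_structure(s)) - 1L, integer(1), USE.NAMES = FALSE)
  tab
}

#' Superatom label vocabulary
#' @return character vector of abbreviation labels.
#' @export
superatom_labels <- function() superatom_table()$name

.element_code <- function(el, arom) {
  codes <- c("*" = 1, B = 2, C = 3, N = 4, O = 5, P = 6, S = 7, F = 8,
             Cl = 9, Br = 10, I = 11, Si = 12, H = 13)
  v <- codes[el]
  v[is.na(v)] <- 14
  as.numeric(v + ifelse(arom, 100, 0))
}

.colored_graph <- function(mol) {
  g <- mol_igraph(mol)
  igraph::V(g)$color <- .element_code(mol$atoms$element, mol$atoms$aromatic)
  if (nrow(mol$bonds))
    igraph::E(g)$color <- as.numeric(mol$bonds$order * 2)
  g
}

#' Contract matched superatom substructures into labelled pseudo-atoms
#'
#' Matches each multi-atom entry of [superatom_table()] (largest first)
#' against the molecule via colour-constrained VF2 subgraph isomorphism.
#' A match is accepted only if every matched atom except the attachment
#' site is fully internal (no bonds leaving the group) and the attachment
#' site has at least one external neighbour. Accepted, non-overlapping
#' matches are collapsed into a single pseudo-atom carrying the
#' abbreviation label. Molecules without matches are returned unchanged.
#'
#' @param mol a `MoleculeGraph`.
#' @param rng a [cd_rng()]; when several candidate matches overlap, the
#'   kept one is chosen by the rng (deterministic under a fixed seed).
#' @return the (possibly contracted) `MoleculeGraph`.
#' @export
abbreviate_substructures <- function(mol, rng = cd_rng(0)) {
  stopifnot(inherits(mol, "MoleculeGraph"))
  if (nrow(mol$bonds) == 0L) return(mol)
  tab <- superatom_table()
  tab <- tab[tab$atoms >= 2L, ]
  tab <- tab[order(tab$atoms, decreasing = TRUE), ]
  gt <- .colored_graph(mol)
  adj <- lapply(seq_len(nrow(mol$atoms)), function(i)
    c(mol$bonds$to[mol$bonds$from == i], mol$bonds$from[mol$bonds$to == i]))
  taken <- rep(FALSE, nrow(mol$atoms))
  hits <- list() # each: list(name, atoms, attach)
  for (p in seq_len(nrow(tab))) {
    pat <- parse_structure(tab$smiles[p])
    star <- which(pat$atoms$element == "*")
    att_pat <- setdiff(c(pat$bonds$to[pat$bonds$from == star],
                         pat$bonds$from[pat$bonds$to == star]), star)[1]
    keep <- setdiff(seq_len(nrow(pat$atoms)), star)
    sub <- subset_molecule(pat, keep)
    att_idx <- match(att_pat, keep)
    gp <- .colored_graph(sub)
    maps <- tryCatch(
      igraph::subgraph_isomorphisms(pattern = gp, target = gt,
                                    method = "vf2"),
      error = function(e) list())
    if (length(maps) == 0L) next
    cand <- list()
    seen <- character(0)
    for (m in maps) {
      tv <- as.integer(igraph::as_ids(m))
      key <- paste(sort(tv), collapse = ",")
      if (key %in% seen) next
      att_t <- tv[att_idx]
      others <- setdiff(tv, att_t)
      ## internality: non-attachment atoms must not bond outside the match
      if (any(vapply(others, function(a)
        length(setdiff(adj[[a]], tv)) > 0L, logical(1)))) next
      if (length(setdiff(adj[[att_t]], tv)) == 0L) next
      seen <- c(seen, key)
      cand[[length(cand) + 1L]] <- list(name = tab$name[p], atoms = tv,
                                        attach = att_t)
    }
    if (length(cand) > 1L)
      cand <- cand[rng_pick(rng, seq_along(cand), length(cand))]
    for (h in cand) {
      if (any(taken[h$atoms])) next
      taken[h$atoms] <- TRUE
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (length(hits) == 0L) return(mol)
  drop <- integer(0)
  for (h in hits) {
    mol$atoms$label[h$attach] <- h$name
    drop <- c(drop, setdiff(h$atoms, h$attach))
  }
  subset_molecule(mol, setdiff(seq_len(nrow(mol$atoms)), drop))
}

## keep the given atoms, reindex bonds
subset_molecule <- function(mol, keep) {
  idx <- match(seq_len(nrow(mol$atoms)), keep)
  b <- mol$bonds
  b <- b[b$from %in% keep & b$to %in% keep, , drop = FALSE]
  b$from <- idx[b$from]; b$to <- idx[b$to]
  structure(list(atoms = mol$atoms[keep, , drop = FALSE],
                 bonds = b, coords = NULL, smiles = mol$smiles),
            class = "MoleculeGraph")
}

## default depiction parameters used when an assignment omits a knob
.render_defaults <- list(
  kekulised = 1L, abbreviate_substructures = 0L, atom_numbering = 0L,
  chirality_labels = 0L, explicit_terminal_carbons = 0L, label_halo = 1L,
  filled_wedges = 1L, shortened_double_bonds = 1L, bond_length = 30,
  line_thickness = 1, font_size = 13, rotation = 0, label_distance = 3,
  double_bond_gap = 4, font_type = "font01")

#' Render a molecule to a raster image
#'
#' Draws the laid-out molecule honouring the depiction parameter
#' assignment: rotation (about the centroid), bond length and line
#' thickness, kekulisation (alternating double bonds vs single bonds with
#' an inner dashed aromatic line), double-bond gap and shortening, font
#' type/size and label halo, superatom abbreviation, atom numbering and
#' chirality labels, wedge style for stereocentres. The structure is
#' scaled to fit 85% of the canvas and centred. Rendering is
#' deterministic given (molecule, assignment, seed) and never mutates the
#' input molecule.
#'
#' @param molecule a `MoleculeGraph` from [parse_structure()].
#' @param style a `StyleProfile` (its presets complete the assignment),
#'   or NULL to use package defaults.
#' @param assignment named list of depiction parameter values.
#' @param shape integer `c(height, width)`.
#' @param rng a [cd_rng()] (reserved; the drawing itself is deterministic).
#' @return raster array of exactly the requested shape.
#' @export
render <- function(molecule, style = NULL, assignment = list(),
                   shape = c(299L, 299L), rng = cd_rng(0)) {
  stopifnot(inherits(molecule, "MoleculeGraph"))
  if (!is.null(style)) assignment <- complete_assignment(style, assignment)
  miss <- setdiff(names(.render_defaults), names(assignment))
  a <- c(assignment, .render_defaults[miss])
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  img <- new_image(h, w)
  res <- tryCatch(
    render_impl(molecule, a, h, w, img),
    error = function(e) {
      stop("render failed (style ", if (is.null(style)) "default"
           else style$id, "; assignment ",
           paste(names(a), unlist(lapply(a, paste, collapse = ":")),
                 sep = "=", collapse = ", "), "): ", conditionMessage(e))
    })
  res
}

render_impl <- function(molecule, a, h, w, img) {
  mol <- molecule
  if (isTRUE(a$abbreviate_substructures == 1L))
    mol <- abbreviate_substructures(mol)
  aromatic_dash <- any(mol$bonds$order == 1.5) && a$kekulised != 1L
  if (a$kekulised == 1L) mol <- kekulize(mol)
  mol <- layout_molecule(mol)
  xy <- mol$coords
  ## rotate about centroid
  th <- a$rotation * pi / 180
  ctr <- colMeans(xy)
  xy <- sweep(xy, 2, ctr)
  xy <- xy %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ## scale: requested bond length, capped so the drawing fits 85% of canvas
  span <- apply(xy, 2, function(v) diff(range(v)))
  margin <- a$font_size + 4
  s <- a$bond_length
  fit <- min((0.85 * w - 2 * margin) / max(span[1], 1e-6),
             (0.85 * h - 2 * margin) / max(span[2], 1e-6))
  s <- max(4, min(s, fit))
  px <- xy[, 1] * s + w / 2 - mean(xy[, 1]) * s
  py <- -xy[, 2] * s + h / 2 + mean(xy[, 2]) * s
  hs <- implicit_hydrogens(mol)
  deg <- tabulate(c(mol$bonds$from, mol$bonds$to), nbins = nrow(mol$atoms))
  labelled <- atom_labels(mol, a, hs, deg)
  lt <- a$line_thickness
  ## bonds
  if (nrow(mol$bonds)) for (bi in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$from[bi]; j <- mol$bonds$to[bi]
    x0 <- px[i]; y0 <- py[i]; x1 <- px[j]; y1 <- py[j]
    len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
    if (len < 1e-6) next
    ux <- (x1 - x0) / len; uy <- (y1 - y0) / len # along bond
    nx <- -uy; ny <- ux                          # normal
    ord <- mol$bonds$order[bi]
    wedge_from <- which(mol$atoms$chirality != "")
    if (i %in% wedge_from && bi == min(which(mol$bonds$from == i |
                                             mol$bonds$to == i))) {
      ## stereo bond from a chiral atom: wedge or hash
      ww <- max(3, 2.5 * lt)
      if (a$filled_wedges == 1L) {
        img <- draw_polygon_img(img, c(x0, x1 + nx * ww, x1 - nx * ww),
                                c(y0, y1 + ny * ww, y1 - ny * ww))
      } else {
        for (t in seq(0.15, 1, length.out = 6)) {
          hw <- ww * t
          img <- draw_line_img(img, x0 + ux * len * t + nx * hw,
                               y0 + uy * len * t + ny * hw,
                               x0 + ux * len * t - nx * hw,
                               y0 + uy * len * t - ny * hw, 1)
        }
      }
    } else if (ord >= 2) {
      g <- a$double_bond_gap / 2
      img <- draw_line_img(img, x0 + nx * g, y0 + ny * g,
                           x1 + nx * g, y1 + ny * g, lt)
      sh <- if (a$shortened_double_bonds == 1L) 0.15 else 0
      img <- draw_line_img(img,
                           x0 - nx * g + ux * len * sh,
                           y0 - ny * g + uy * len * sh,
                           x1 - nx * g - ux * len * sh,
                           y1 - ny * g - uy * len * sh, lt)
      if (ord == 3)
        img <- draw_line_img(img, x0 + nx * 2 * g, y0 + ny * 2 * g,
                             x1 + nx * 2 * g, y1 + ny * 2 * g, lt)
    } else {
      img <- draw_line_img(img, x0, y0, x1, y1, lt)
      if (ord == 1.5 && aromatic_dash) {
        ## inner dashed aromatic companion line
        g <- a$double_bond_gap
        for (t in seq(0.2, 0.8, length.out = 4)) {
          img <- draw_line_img(img,
                               x0 + ux * len * t + nx * g,
                               y0 + uy * len * t + ny * g,
                               x0 + ux * len * (t + 0.1) + nx * g,
                               y0 + uy * len * (t + 0.1) + ny * g,
                               max(1, lt - 1))
        }
      }
    }
  }
  ## atom labels (drawn after bonds; halo/disc clears the strike-through)
  for (i in which(labelled != "")) {
    rad <- a$label_distance + a$font_size * 0.45
    disc <- line_pixels(px[i], py[i], px[i], py[i], 2 * rad)
    img <- stamp_pixels(img, disc$rows, disc$cols, c(1, 1, 1))
    img <- draw_text_img(img, labelled[i], px[i], py[i], a$font_size,
                         a$font_type, halo = a$label_halo == 1L)
  }
  if (a$atom_numbering == 1L) {
    for (i in seq_len(nrow(mol$atoms))) {
      img <- draw_text_img(img, as.character(i),
                           px[i] + a$font_size * 0.6,
                           py[i] - a$font_size * 0.6,
                           max(6, round(a$font_size * 0.6)), a$font_type)
    }
  }
  if (a$chirality_labels == 1L) {
    for (i in which(mol$atoms$chirality != "")) {
      lab <- if (mol$atoms$chirality[i] == "@@") "(R)" else "(S)"
      img <- draw_text_img(img, lab, px[i] - a$font_size,
                           py[i] + a$font_size,
                           max(6, round(a$font_size * 0.7)), a$font_type)
    }
  }
  img
}

## display label per atom ("" = bare vertex)
atom_labels <- function(mol, a, hs, deg) {
  vapply(seq_len(nrow(mol$atoms)), function(i) {
    at <- mol$atoms[i, ]
    if (!is.na(at$label)) return(at$label)
    show <- at$element != "C" || at$charge != 0L ||
      (a$explicit_terminal_carbons == 1L && deg[i] <= 1L)
    if (!show) return("")
    lab <- at$element
    if (at$element == "C" && deg[i] <= 1L && a$explicit_terminal_carbons == 1L)
      lab <- if (hs[i] >= 3) "CH3" else lab
    else if (hs[i] == 1L) lab <- paste0(lab, "H")
    else if (hs[i] > 1L) lab <- paste0(lab, "H", hs[i])
    if (at$charge > 0L) lab <- paste0(lab, if (at$charge > 1L) at$charge else "", "+")
    if (at$charge < 0L) lab <- paste0(lab, if (at$charge < -1L) -at$charge else "", "-")
    lab
  }, character(1))
}

#' Trivially deterministic stub backend
#'
#' Draws a cheap deterministic placeholder pattern derived from a hash of
#' the SMILES string: no chemistry, constant cost. Used for fast
#' pipeline and scaling tests where the depiction content is irrelevant.
#'
#' @param smiles input string (not parsed).
#' @param shape integer `c(height, width)`.
#' @param seed integer; pattern varies with the seed.
#' @return raster array of the requested shape.
#' @export
render_stub <- function(smiles, shape = c(299L, 299L), seed = 0L) {
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  img <- new_image(h, w)
  hsh <- sum(utf8ToInt(smiles) * seq_along(utf8ToInt(smiles))) + seed
  rng <- cd_rng(mix32(hsh %% TWO32) %% 2147483647)
  n <- 6L
  xs <- rng_runif(rng, n, 0.15 * w, 0.85 * w)
  ys <- rng_runif(rng, n, 0.15 * h, 0.85 * h)
  for (i in seq_len(n - 1L))
    img <- draw_line_img(img, xs[i], ys[i], xs[i + 1L], ys[i + 1L], 1)
  img
}
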