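#' Parse a SMILES string into a molecule graph
#'
#' Supports the organic subset (B, C, N, O, P, S, F, Cl, Br, I and their
#' aromatic lowercase forms), bracket atoms with isotope, chirality marks
#' (`@`/`@@`), explicit hydrogen counts and charges, bonds
#' (`-`, `=`, `#`, `:`, `/`, `\`), branches, ring-closure digits
#' (including `%nn`), disconnected components (`.`) and the wildcard `*`
#' (used for superatom attachment points). Whitespace is stripped first.
#'
#' @param smiles non-empty SMILES string.
#' @return a `MoleculeGraph`: list with `atoms` (data.frame: element,
#'   aromatic, charge, hcount, chirality), `bonds` (data.frame: from, to,
#'   order, stereo) and `coords` (NULL until [layout_molecule()]).
#' @export
parse_structure <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop("SMILES input must be a single non-empty string")
  s <- gsub("[[:space:]]", "", smiles)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)

  atoms <- list()
  bonds <- list()
  add_atom <- function(element, aromatic = FALSE, charge = 0L,
                       hcount = NA_integer_, chirality = "") {
    atoms[[length(atoms) + 1L]] <<- list(element = element,
                                         aromatic = aromatic, charge = charge,
                                         hcount = hcount,
                                         chirality = chirality)
    length(atoms)
  }
  add_bond <- function(from, to, order, stereo = "none") {
    bonds[[length(bonds) + 1L]] <<- list(from = from, to = to, order = order,
                                         stereo = stereo)
  }

  prev <- NA_integer_      # atom the next bond attaches to
  pending <- NA_character_ # explicit bond symbol awaiting the next atom
  stack <- integer(0)      # open branch points
  rings <- list()          # ring-closure number -> c(atom, bond symbol)
  bad <- function(msg, at) stop("cannot parse SMILES '", smiles, "': ", msg,
                                " at position ", at)

  connect <- function(a, b, sym) {
    order <- 1; stereo <- "none"
    if (is.na(sym)) {
      if (atoms[[a]]$aromatic && atoms[[b]]$aromatic) order <- 1.5
    } else {
      order <- switch(sym, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5,
                      "/" = 1, "\\" = 1, bad(paste0("bond '", sym, "'"), NA))
    }
    add_bond(a, b, order, stereo)
  }

  organic2 <- c("Cl", "Br")
  organic1 <- c("B", "C", "N", "O", "P", "S", "F", "I")
  aromatic1 <- c("b", "c", "n", "o", "p", "s")

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    new_atom <- NA_integer_
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) bad("unclosed bracket atom", i)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Z][a-z]?|[a-z]|\\*)(@{0,2})(H[0-9]*)?([+-][0-9]*|\\++|-+)?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0L) bad(paste0("bracket atom [", body, "]"), i)
      el <- m[3]
      arom <- el %in% aromatic1
      if (arom) el <- toupper(el)
      hc <- if (m[5] == "") 0L
            else if (m[5] == "H") 1L else as.integer(sub("H", "", m[5]))
      chg <- 0L
      if (m[6] != "") {
        cs <- m[6]
        chg <- if (grepl("^[+-][0-9]+$", cs))
          as.integer(cs)
        else (nchar(cs)) * (if (substr(cs, 1, 1) == "+") 1L else -1L)
      }
      new_atom <- add_atom(el, arom, chg, hc, m[4])
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% organic2) {
      new_atom <- add_atom(paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else if (ch %in% organic1) {
      new_atom <- add_atom(ch)
      i <- i + 1L
    } else if (ch %in% aromatic1) {
      new_atom <- add_atom(toupper(ch), aromatic = TRUE)
      i <- i + 1L
    } else if (ch == "*") {
      new_atom <- add_atom("*")
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- ch
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) bad("branch before any atom", i)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) bad("unmatched ')'", i)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending <- NA_character_
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n) bad("truncated %nn ring closure", i)
        num <- paste(chars[(i + 1L):(i + 2L)], collapse = "")
        i <- i + 3L
      } else {
        num <- ch
        i <- i + 1L
      }
      if (is.na(prev)) bad("ring closure before any atom", i)
      key <- paste0("r", num)
      if (is.null(rings[[key]])) {
        rings[[key]] <- list(atom = prev, sym = pending)
      } else {
        sym <- if (!is.na(pending)) pending else rings[[key]]$sym
        connect(rings[[key]]$atom, prev, sym)
        rings[[key]] <- NULL
      }
      pending <- NA_character_
    } else {
      bad(paste0("unexpected character '", ch, "'"), i)
    }
    if (!is.na(new_atom)) {
      if (!is.na(prev)) connect(prev, new_atom, pending)
      pending <- NA_character_
      prev <- new_atom
    }
  }
  if (length(stack) > 0L) bad("unclosed branch", n)
  if (length(rings) > 0L) bad("unclosed ring bond", n)
  if (length(atoms) == 0L) bad("no atoms", 1L)

  atoms_df <- data.frame(
    element = vapply(atoms, `[[`, character(1), "element"),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
    charge = vapply(atoms, `[[`, integer(1), "charge"),
    hcount = vapply(atoms, `[[`, integer(1), "hcount"),
    chirality = vapply(atoms, `[[`, character(1), "chirality"),
    label = NA_character_,
    stringsAsFactors = FALSE)
  bonds_df <- if (length(bonds)) data.frame(
    from = vapply(bonds, `[[`, numeric(1), "from"),
    to = vapply(bonds, `[[`, numeric(1), "to"),
    order = vapply(bonds, `[[`, numeric(1), "order"),
    stereo = vapply(bonds, `[[`, character(1), "stereo"),
    stringsAsFactors = FALSE)
  else data.frame(from = numeric(0), to = numeric(0), order = numeric(0),
                  stereo = character(0), stringsAsFactors = FALSE)
  structure(list(atoms = atoms_df, bonds = bonds_df, coords = NULL,
                 smiles = smiles),
            class = "MoleculeGraph")
}

#' Number of heavy (non-hydrogen) atoms
#' @param mol a `MoleculeGraph`.
#' @export
heavy_atom_count <- function(mol) {
  stopifnot(inherits(mol, "MoleculeGraph"))
  sum(mol$atoms$element != "H")
}

#' @export
print.MoleculeGraph <- function(x, ...) {
  cat("MoleculeGraph:", nrow(x$atoms), "atoms,", nrow(x$bonds), "bonds",
      if (!is.null(x$coords)) "(laid out)" else "", "\n")
  invisible(x)
}

mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    if (nrow(mol$bonds)) mol$bonds[, c("from", "to")]
    else data.frame(from = numeric(0), to = numeric(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms))))
}

#' Deterministic 2D coordinates for a molecule
#'
#' Kamada-Kawai layout seeded from a circular initial placement (fully
#' deterministic), per connected component; components are tiled side by
#' side. Coordinates are normalised so the median bond length is 1.
#'
#' @param mol a `MoleculeGraph`.
#' @return the molecule with a `coords` matrix (one row per atom).
#' @export
layout_molecule <- function(mol) {
  stopifnot(inherits(mol, "MoleculeGraph"))
  na <- nrow(mol$atoms)
  if (na == 1L) {
    mol$coords <- matrix(0, 1L, 2L)
    return(mol)
  }
  g <- mol_igraph(mol)
  comp <- igraph::components(g)
  coords <- matrix(0, na, 2L)
  xoff <- 0
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    sg <- igraph::induced_subgraph(g, vs)
    xy <- if (length(vs) == 1L) matrix(0, 1L, 2L)
          else if (length(vs) == 2L) rbind(c(0, 0), c(1, 0))
          else igraph::layout_with_kk(sg, coords = igraph::layout_in_circle(sg))
    ## normalise this component's bond length to 1
    eb <- igraph::as_edgelist(sg, names = FALSE)
    if (nrow(eb) > 0L) {
      bl <- sqrt(rowSums((xy[eb[, 1L], , drop = FALSE] -
                          xy[eb[, 2L], , drop = FALSE])^2))
      med <- stats::median(bl)
      if (med > 0) xy <- xy / med
    }
    xy[, 1L] <- xy[, 1L] - min(xy[, 1L]) + xoff
    xy[, 2L] <- xy[, 2L] - mean(xy[, 2L])
    xoff <- max(xy[, 1L]) + 1.5
    coords[vs, ] <- xy
  }
  mol$coords <- coords
  mol
}

#' Kekulise aromatic bonds
#'
#' Assigns alternating single/double orders to aromatic (order 1.5) bonds
#' by backtracking perfect matching over the atoms that require one double
#' bond (aromatic carbons; aromatic nitrogens with no hydrogen and two
#' ring neighbours). Returns the molecule with aromatic bond orders
#' replaced by 1 or 2. Molecules without aromatic bonds are returned
#' unchanged.
#'
#' @param mol a `MoleculeGraph`.
#' @export
kekulize <- function(mol) {
  stopifnot(inherits(mol, "MoleculeGraph"))
  ar <- which(mol$bonds$order == 1.5)
  if (length(ar) == 0L) return(mol)
  deg <- tabulate(c(mol$bonds$from, mol$bonds$to), nbins = nrow(mol$atoms))
  needs <- with(mol$atoms, aromatic &
                  (element == "C" |
                   (element == "N" & (is.na(hcount) | hcount == 0L) &
                      charge == 0L & deg[seq_len(nrow(mol$atoms))] == 2L) |
                   (element == "P" & (is.na(hcount) | hcount == 0L))))
  need_atoms <- which(needs)
  ## adjacency over aromatic bonds restricted to atoms needing a double bond
  cand <- ar[mol$bonds$from[ar] %in% need_atoms &
               mol$bonds$to[ar] %in% need_atoms]
  matched <- rep(FALSE, nrow(mol$atoms))
  chosen <- logical(length(cand))
  try_match <- function(k) {
    if (k > length(need_atoms)) return(TRUE)
    a <- need_atoms[k]
    if (matched[a]) return(try_match(k + 1L))
    for (ci in seq_along(cand)) {
      b <- cand[ci]
      ends <- c(mol$bonds$from[b], mol$bonds$to[b])
      if (!(a %in% ends)) next
      other <- ends[ends != a]
      if (matched[other]) next
      matched[c(a, other)] <<- TRUE
      chosen[ci] <<- TRUE
      if (try_match(k + 1L)) return(TRUE)
      matched[c(a, other)] <<- FALSE
      chosen[ci] <<- FALSE
    }
    FALSE
  }
  ok <- try_match(1L)
  mol$bonds$order[ar] <- 1
  if (ok) mol$bonds$order[cand[chosen]] <- 2
  mol
}

#' Implicit hydrogen count per atom (for drawing labels like NH, OH)
#' @keywords internal
implicit_hydrogens <- function(mol) {
  valence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2, F = 1,
               Cl = 1, Br = 1, I = 1, Si = 4)
  vapply(seq_len(nrow(mol$atoms)), function(i) {
    a <- mol$atoms[i, ]
    if (!is.na(a$hcount)) return(as.integer(a$hcount))
    v <- valence[a$element]
    if (is.na(v)) return(0L)
    bi <- mol$bonds$from == i | mol$bonds$to == i
    used <- sum(ceiling(mol$bonds$order[bi]))
    max(0L, as.integer(v + a$charge - used))
  }, integer(1))
}
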