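#' Depiction parameter decisions and fingerprint schemes
#'
#' A depiction run makes a sequence of flagged pseudo-random decisions
#' (kekulise or not, which bond width, which font, ...). Each flagged
#' decision contributes a *building block* to a depiction-feature
#' fingerprint: a binary decision occupies one bit; a categorical decision
#' with k options occupies k one-hot bits; a numeric range is split into
#' three near-equal subranges treated as categories (3 one-hot bits).
#' A fingerprint scheme lays the decisions out on contiguous bit spans, and
#' the set of valid fingerprints is the cartesian product of the building
#' blocks in layout order.
#'
#' @name param_space
NULL

#' Create a parameter decision
#'
#' @param name unique identifier within a scheme.
#' @param kind one of `"binary"`, `"categorical"`, `"ranged"`.
#' @param options for categorical: ordered vector of >= 2 option values.
#' @param range for ranged: numeric `c(lower, upper)`, lower < upper.
#' @param integer for ranged: draw uniform integers (default) or uniform
#'   continuous values.
#' @return a `ParameterDecision`.
#' @export
parameter_decision <- function(name, kind = c("binary", "categorical", "ranged"),
                               options = NULL, range = NULL, integer = TRUE) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "categorical") {
    if (is.null(options) || length(options) < 2L)
      stop("categorical decision '", name, "' needs >= 2 options")
    if (anyDuplicated(options))
      stop("categorical decision '", name, "' has duplicate options")
  } else if (kind == "ranged") {
    if (is.null(range) || length(range) != 2L || !is.numeric(range))
      stop("ranged decision '", name, "' needs a numeric range c(lower, upper)")
    if (!(range[1] < range[2]))
      stop("ranged decision '", name, "' has empty range (lower >= upper)")
  } else {
    options <- NULL; range <- NULL
  }
  structure(list(name = name, kind = kind, options = options,
                 range = range, integer = isTRUE(integer)),
            class = "ParameterDecision")
}

#' Number of fingerprint positions a decision occupies
#' @keywords internal
decision_width <- function(d) {
  switch(d$kind, binary = 1L, categorical = length(d$options), ranged = 3L)
}

#' Number of building blocks of a decision
#' @keywords internal
decision_block_count <- function(d) {
  switch(d$kind, binary = 2L, categorical = length(d$options), ranged = 3L)
}

#' Split a numeric range into three near-equal subranges
#'
#' Integer ranges partition the value set; remainder elements go to the
#' last subrange (1..6 -> [1,2], [3,4], [5,6]; 1..7 -> [1,2], [3,4], [5,7]).
#' Continuous ranges split at the terciles.
#'
#' @param d a ranged `ParameterDecision`.
#' @return list of 3 numeric `c(lo, hi)` subranges.
#' @export
ranged_subranges <- function(d) {
  stopifnot(inherits(d, "ParameterDecision"), d$kind == "ranged")
  lo <- d$range[1]; hi <- d$range[2]
  if (d$integer) {
    lo <- ceiling(lo); hi <- floor(hi)
    n <- hi - lo + 1
    base <- n %/% 3
    b1 <- lo + base - 1
    b2 <- b1 + base
    list(c(lo, b1), c(b1 + 1, b2), c(b2 + 1, hi))
  } else {
    b <- lo + (hi - lo) * c(1, 2) / 3
    list(c(lo, b[1]), c(b[1], b[2]), c(b[2], hi))
  }
}

#' Building blocks of a decision
#'
#' The ordered list of bit patterns a decision may legally contribute:
#' binary -> `(0)`, `(1)`; categorical-k -> the k one-hot k-tuples;
#' ranged -> 3 one-hot triples, each bound to one subrange.
#'
#' @param decision a `ParameterDecision`.
#' @return list of blocks; each block has `bits` (integer vector) and
#'   `value` (bit for binary, option for categorical, subrange for ranged).
#' @export
building_blocks <- function(decision) {
  stopifnot(inherits(decision, "ParameterDecision"))
  switch(decision$kind,
    binary = list(list(bits = 0L, value = 0L), list(bits = 1L, value = 1L)),
    categorical = {
      k <- length(decision$options)
      lapply(seq_len(k), function(i) {
        b <- integer(k); b[i] <- 1L
        list(bits = b, value = decision$options[[i]])
      })
    },
    ranged = {
      subs <- ranged_subranges(decision)
      lapply(1:3, function(i) {
        b <- integer(3); b[i] <- 1L
        list(bits = b, value = subs[[i]])
      })
    })
}

#' Create an empty fingerprint scheme
#'
#' @param id scheme identifier (stored on fingerprints and manifests).
#' @return a `FingerprintScheme` with no decisions.
#' @export
fingerprint_scheme <- function(id = "scheme") {
  structure(list(id = id, decisions = list(),
                 layout = data.frame(name = character(), start = integer(),
                                     length = integer(),
                                     stringsAsFactors = FALSE),
                 total_length = 0L),
            class = "FingerprintScheme")
}

#' Flag a decision as fingerprint-relevant
#'
#' Appends the decision to the scheme and allocates its contiguous bit
#' span (1 bit for binary, k for categorical-k, 3 for ranged). Schemes are
#' built automatically this way: any pseudo-random choice that should be
#' reflected in the fingerprint is registered once and the layout follows.
#'
#' @param scheme a `FingerprintScheme`.
#' @param decision a `ParameterDecision` with a name not yet in the scheme.
#' @return the extended scheme.
#' @export
register_decision <- function(scheme, decision) {
  stopifnot(inherits(scheme, "FingerprintScheme"),
            inherits(decision, "ParameterDecision"))
  if (decision$name %in% scheme$layout$name)
    stop("decision '", decision$name, "' already registered in scheme '",
         scheme$id, "'")
  w <- decision_width(decision)
  scheme$decisions[[length(scheme$decisions) + 1L]] <- decision
  scheme$layout <- rbind(scheme$layout,
                         data.frame(name = decision$name,
                                    start = scheme$total_length,
                                    length = w, stringsAsFactors = FALSE))
  scheme$total_length <- scheme$total_length + w
  scheme
}

#' Number of decisions in a scheme
#' @param scheme a `FingerprintScheme`.
#' @export
n_decisions <- function(scheme) length(scheme$decisions)

#' Count all valid fingerprints of a scheme
#'
#' Product over decisions of building-block counts: 2 per binary, k per
#' categorical-k, 3 per ranged. Equals the number of rows that
#' [enumerate_valid_fingerprints()] would produce. The empty scheme has
#' exactly one (empty) fingerprint.
#'
#' @param scheme a `FingerprintScheme`.
#' @return a count (double, exact for any practical scheme).
#' @export
count_valid_fingerprints <- function(scheme) {
  stopifnot(inherits(scheme, "FingerprintScheme"))
  prod(vapply(scheme$decisions, decision_block_count, integer(1)))
}

#' Enumerate all valid fingerprints of a scheme
#'
#' Cartesian product of the building blocks, concatenated in layout order.
#' Ordering is deterministic and lexicographic over block indices with the
#' first-registered decision varying slowest.
#'
#' @param scheme a `FingerprintScheme`.
#' @param guard refuse enumeration when the count exceeds this (memory
#'   guard, default 1e6).
#' @return integer matrix, one fingerprint per row, `total_length` columns.
#' @export
enumerate_valid_fingerprints <- function(scheme, guard = 1e6) {
  stopifnot(inherits(scheme, "FingerprintScheme"))
  n <- count_valid_fingerprints(scheme)
  if (n > guard)
    stop("scheme '", scheme$id, "' has ", format(n, big.mark = ","),
         " valid fingerprints, exceeding the enumeration guard (", guard, ")")
  if (n_decisions(scheme) == 0L)
    return(matrix(integer(0), nrow = 1L, ncol = 0L))
  blocks <- lapply(scheme$decisions, building_blocks)
  counts <- vapply(blocks, length, integer(1))
  ## index grid: last decision varies fastest (first varies slowest)
  grid <- expand.grid(rev(lapply(counts, seq_len)), KEEP.OUT.ATTRS = FALSE)
  grid <- as.matrix(grid)[, rev(seq_len(ncol(grid))), drop = FALSE]
  out <- matrix(0L, nrow = nrow(grid), ncol = scheme$total_length)
  for (j in seq_along(blocks)) {
    span <- scheme$layout$start[j] + seq_len(scheme$layout$length[j])
    bits <- do.call(rbind, lapply(blocks[[j]], `[[`, "bits"))
    out[, span] <- bits[grid[, j], , drop = FALSE]
  }
  out
}

#' Validate a fingerprint against a scheme
#'
#' Checks length and the one-hot invariant of every categorical/ranged
#' span and the 0/1 domain of binary positions.
#'
#' @param scheme a `FingerprintScheme`.
#' @param fp integer bit vector.
#' @return invisibly TRUE; otherwise an error naming the offending decision.
#' @export
validate_fingerprint <- function(scheme, fp) {
  stopifnot(inherits(scheme, "FingerprintScheme"))
  if (length(fp) != scheme$total_length)
    stop("fingerprint has length ", length(fp), ", scheme '", scheme$id,
         "' expects ", scheme$total_length)
  if (!all(fp %in% c(0L, 1L)))
    stop("fingerprint contains values other than 0/1")
  for (j in seq_along(scheme$decisions)) {
    d <- scheme$decisions[[j]]
    span <- scheme$layout$start[j] + seq_len(scheme$layout$length[j])
    if (d$kind != "binary" && sum(fp[span]) != 1L)
      stop("decision '", d$name, "': span is not one-hot (",
           sum(fp[span]), " bits set); contradictory or missing feature value")
  }
  invisible(TRUE)
}

#' Draw a random parameter assignment
#'
#' Uniform independent draw per decision: binary bits are fair coins,
#' categorical options equiprobable, ranged values uniform over the whole
#' range (integers for integer ranges, continuous otherwise).
#'
#' @param scheme a `FingerprintScheme`.
#' @param rng a [cd_rng()].
#' @return named list mapping decision name to concrete value.
#' @export
sample_assignment <- function(scheme, rng) {
  stopifnot(inherits(scheme, "FingerprintScheme"))
  vals <- lapply(scheme$decisions, function(d) {
    switch(d$kind,
      binary = rng_bits(rng, 1L),
      categorical = rng_pick(rng, d$options)[[1]],
      ranged = if (d$integer) rng_int(rng, ceiling(d$range[1]), floor(d$range[2]))
               else rng_runif(rng, 1L, d$range[1], d$range[2]))
  })
  names(vals) <- vapply(scheme$decisions, `[[`, character(1), "name")
  vals
}

#' Decode a fingerprint into a concrete parameter assignment
#'
#' Binary spans give their bit, categorical spans their hot option. A
#' ranged span only pins a subrange; the concrete value is drawn uniformly
#' from that subrange (this is what keeps the fingerprint space finite).
#'
#' @param scheme a `FingerprintScheme`.
#' @param fp valid fingerprint bit vector.
#' @param rng a [cd_rng()] for the ranged subrange draws.
#' @return named list, as [sample_assignment()].
#' @export
fingerprint_to_assignment <- function(scheme, fp, rng) {
  validate_fingerprint(scheme, fp)
  vals <- vector("list", n_decisions(scheme))
  for (j in seq_along(scheme$decisions)) {
    d <- scheme$decisions[[j]]
    span <- scheme$layout$start[j] + seq_len(scheme$layout$length[j])
    bits <- fp[span]
    vals[[j]] <- switch(d$kind,
      binary = as.integer(bits),
      categorical = d$options[[which(bits == 1L)]],
      ranged = {
        sub <- ranged_subranges(d)[[which(bits == 1L)]]
        if (d$integer) rng_int(rng, sub[1], sub[2])
        else rng_runif(rng, 1L, sub[1], sub[2])
      })
  }
  names(vals) <- vapply(scheme$decisions, `[[`, character(1), "name")
  vals
}

#' Encode a parameter assignment as a fingerprint
#'
#' Inverse of [fingerprint_to_assignment()] up to subrange membership:
#' binary and categorical values round-trip exactly; a ranged value maps to
#' the one-hot block of the subrange containing it.
#'
#' @param scheme a `FingerprintScheme`.
#' @param assignment named list of values, one per decision.
#' @return integer bit vector of length `total_length`.
#' @export
assignment_to_fingerprint <- function(scheme, assignment) {
  stopifnot(inherits(scheme, "FingerprintScheme"))
  fp <- integer(scheme$total_length)
  for (j in seq_along(scheme$decisions)) {
    d <- scheme$decisions[[j]]
    if (!d$name %in% names(assignment))
      stop("assignment is missing decision '", d$name, "'")
    v <- assignment[[d$name]]
    span <- scheme$layout$start[j] + seq_len(scheme$layout$length[j])
    if (d$kind == "binary") {
      if (!v %in% c(0L, 1L))
        stop("decision '", d$name, "': binary value must be 0 or 1, got ", v)
      fp[span] <- as.integer(v)
    } else if (d$kind == "categorical") {
      i <- match(v, d$options)
      if (is.na(i))
        stop("decision '", d$name, "': value '", v, "' not among options")
      fp[span[i]] <- 1L
    } else {
      subs <- ranged_subranges(d)
      i <- which(vapply(subs, function(s) v >= s[1] & v <= s[2], logical(1)))[1]
      if (is.na(i))
        stop("decision '", d$name, "': value ", v, " outside range [",
             d$range[1], ", ", d$range[2], "]")
      fp[span[i]] <- 1L
    }
  }
  fp
}

## ---- serialization ---------------------------------------------------------

#' Serialize a scheme to JSON
#'
#' Self-describing document: decision list with kinds, options or ranges,
#' and the layout spans, so dataset manifests can be interpreted without
#' the generating code.
#'
#' @param scheme a `FingerprintScheme`.
#' @return a JSON string.
#' @export
scheme_to_json <- function(scheme) {
  stopifnot(inherits(scheme, "FingerprintScheme"))
  doc <- list(
    id = scheme$id,
    total_length = scheme$total_length,
    decisions = lapply(seq_along(scheme$decisions), function(j) {
      d <- scheme$decisions[[j]]
      list(name = d$name, kind = d$kind,
           options = d$options, range = d$range, integer = d$integer,
           start = scheme$layout$start[j], length = scheme$layout$length[j])
    }))
  jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA)
}

#' Rebuild a scheme from its JSON serialization
#' @param json JSON string from [scheme_to_json()].
#' @return a `FingerprintScheme`.
#' @export
scheme_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  sch <- fingerprint_scheme(doc$id)
  for (d in doc$decisions) {
    sch <- register_decision(sch, parameter_decision(
      d$name, d$kind,
      options = if (!is.null(d$options)) unlist(d$options),
      range = if (!is.null(d$range)) unlist(d$range),
      integer = isTRUE(d$integer)))
  }
  stopifnot(sch$total_length == doc$total_length)
  sch
}

#' @export
print.FingerprintScheme <- function(x, ...) {
  cat("FingerprintScheme '", x$id, "': ", n_decisions(x), " decisions, ",
      x$total_length, " bits, ",
      format(count_valid_fingerprints(x), big.mark = ","),
      " valid fingerprints\n", sep = "")
  invisible(x)
}
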