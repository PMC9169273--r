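# Independent oracles and fixture builders shared across test files.
# Oracles deliberately re-derive results with naive nested loops, never
# through the package's own code paths.

# the two-decision worked example: binary kekulisation + 3-way bond width
worked_example_scheme <- function() {
  sch <- fingerprint_scheme("worked")
  sch <- register_decision(sch, parameter_decision("kekulised", "binary"))
  register_decision(sch, parameter_decision(
    "bond_width", "categorical", options = c("thin", "medium", "bold")))
}

# brute-force cartesian product of building blocks via nested loops
oracle_enumerate <- function(scheme) {
  blocks <- lapply(scheme$decisions, building_blocks)
  rows <- list(integer(0))
  for (bl in blocks) {
    rows <- unlist(lapply(rows, function(r)
      lapply(bl, function(b) c(r, b$bits))), recursive = FALSE)
  }
  do.call(rbind, rows)
}

oracle_tanimoto <- function(a, b) {
  inter <- sum(a == 1 & b == 1)
  union <- sum(a == 1 | b == 1)
  if (union == 0) 0 else 1 - inter / union
}

# step-by-step greedy MaxMin re-implementation (same seed rule: first pick
# uniform via cd_rng; ties to lowest index), scanning all pairs naively
oracle_maxmin <- function(pool, k, seed) {
  n <- nrow(pool)
  first <- rng_int(cd_rng(seed), 1L, n)
  picked <- first
  while (length(picked) < k) {
    best_i <- NA; best_d <- -Inf
    for (i in seq_len(n)) {
      if (i %in% picked) next
      di <- min(vapply(picked, function(p)
        oracle_tanimoto(pool[i, ], pool[p, ]), numeric(1)))
      if (di > best_d + 1e-12) { best_d <- di; best_i <- i }
    }
    picked <- c(picked, best_i)
  }
  picked
}

# exhaustive optimum of the min pairwise distance over all k-subsets
oracle_best_dispersion <- function(pool, k) {
  n <- nrow(pool)
  best <- -Inf
  for (sub in utils::combn(n, k, simplify = FALSE)) {
    d <- min(apply(utils::combn(sub, 2), 2, function(pr)
      oracle_tanimoto(pool[pr[1], ], pool[pr[2], ])))
    best <- max(best, d)
  }
  best
}

min_pairwise_distance <- function(pool, idx) {
  min(apply(utils::combn(idx, 2), 2, function(pr)
    oracle_tanimoto(pool[pr[1], ], pool[pr[2], ])))
}

# label grammars (the round-trip validators for the annotation generators)
identity_label_regex <- function() {
  "^([1-9][0-9]?)$|^([1-9][0-9]?[a-z])$|^([1-9][0-9]?[-–][0-9]+)$|^([1-9][0-9]?[a-z][-–][a-z])$"
}
rest_group_label_regex <- function() {
  "^(R|R'|X|Y|Z)[1-9]? = [A-Za-z0-9]+$"
}
condition_label_regex <- function() {
  "^[^,]+, [^,]+, [0-9]+ (h|min)$"
}

caffeine_smiles <- function() "CN1C=NC2=C1C(=O)N(C(=O)N2C)C"
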