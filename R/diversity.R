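#' Diversity picking over fingerprint pools
#'
#' Random sampling of a high-dimensional one-hot feature space does not
#' guarantee even coverage. Instead, all valid fingerprints (or a seeded
#' subsample of a huge pool) are enumerated and a maximally diverse subset
#' is selected with the greedy MaxMin (farthest-point) algorithm under the
#' Tanimoto distance on bit vectors.
#'
#' @name diversity
NULL

#' Tanimoto (Jaccard) distance between two bit vectors
#'
#' `1 - |a AND b| / |a OR b|`; defined as 0 when both vectors are all-zero.
#'
#' @param a,b equal-length 0/1 vectors.
#' @return a real in `[0, 1]`.
#' @export
tanimoto_distance <- function(a, b) {
  if (length(a) != length(b))
    stop("bit vectors differ in length (", length(a), " vs ", length(b), ")")
  u <- sum(a | b)
  if (u == 0) return(0)
  1 - sum(a & b) / u
}


#' Greedy MaxMin (farthest-point) pick
#'
#' Picks `k` diverse rows of a fingerprint pool: the first index is chosen
#' uniformly by `seed`; each subsequent pick maximises its minimum Tanimoto
#' distance to the already-picked set. Ties break to the lowest index, so
#' the result is fully deterministic given the seed.
#'
#' @param pool 0/1 matrix, one fingerprint per row (non-empty).
#' @param k number of picks, `1 <= k <= nrow(pool)`.
#' @param seed integer seed for the first pick.
#' @return integer vector of `k` distinct row indices in pick order.
#' @export
maxmin_pick <- function(pool, k, seed) {
  if (is.null(dim(pool))) pool <- matrix(pool, nrow = 1L)
  n <- nrow(pool)
  if (n == 0L) stop("empty fingerprint pool")
  if (k < 1L || k > n) stop("k must be in [1, ", n, "], got ", k)
  storage.mode(pool) <- "double" # coerce once; %*% would copy per pick
  ones <- rowSums(pool)
  dist_to <- function(i) {
    inter <- as.vector(pool %*% pool[i, ])
    u <- ones + ones[i] - inter
    d <- 1 - inter / u
    d[u == 0] <- 0
    d
  }
  rng <- cd_rng(seed)
  picked <- integer(k)
  picked[1L] <- as.integer(rng_int(rng, 1L, n))
  if (k == 1L) return(picked)
  mind <- dist_to(picked[1L])
  for (i in 2:k) {
    mind[picked[1:(i - 1L)]] <- -1 # never repick
    nxt <- which.max(mind)         # which.max returns the first (lowest) max
    picked[i] <- nxt
    mind <- pmin(mind, dist_to(nxt))
  }
  picked
}

#' Enumerate a scheme's pool, subsampling huge spaces
#'
#' Pools up to `cap` fingerprints are enumerated exhaustively. Larger
#' spaces (e.g. STYLE_A's 2.8 million) are represented by a seeded uniform
#' subsample of `cap` distinct fingerprints, materialised lazily from
#' mixed-radix ranks so the full pool never exists in memory.
#'
#' @param scheme a `FingerprintScheme`.
#' @param cap maximum pool size held in memory (default 1e5).
#' @param seed integer seed for the subsample draw.
#' @return 0/1 matrix of fingerprints.
#' @export
fingerprint_pool <- function(scheme, cap = 1e5, seed = 0L) {
  n <- count_valid_fingerprints(scheme)
  if (n <= cap) return(enumerate_valid_fingerprints(scheme, guard = cap))
  rng <- cd_rng(seed)
  ## distinct ranks in [0, n): draw with margin, dedupe, top up if short
  ranks <- unique(floor(rng_runif(rng, ceiling(cap * 1.2)) * n))
  while (length(ranks) < cap)
    ranks <- unique(c(ranks, floor(rng_runif(rng, cap) * n)))
  ranks <- ranks[seq_len(cap)]
  fingerprint_from_rank(scheme, ranks)
}

#' Materialise fingerprints from their enumeration ranks
#'
#' Rank r (0-based) in the lexicographic enumeration order decodes as a
#' mixed-radix number over the per-decision block counts, first decision
#' most significant.
#'
#' @param scheme a `FingerprintScheme`.
#' @param ranks 0-based ranks, each in `[0, count_valid_fingerprints)`.
#' @return 0/1 matrix with `length(ranks)` rows.
#' @export
fingerprint_from_rank <- function(scheme, ranks) {
  blocks <- lapply(scheme$decisions, building_blocks)
  counts <- vapply(blocks, length, integer(1))
  k <- length(counts)
  out <- matrix(0L, nrow = length(ranks), ncol = scheme$total_length)
  r <- ranks
  for (j in rev(seq_len(k))) {
    idx <- r %% counts[j]
    r <- r %/% counts[j]
    span <- scheme$layout$start[j] + seq_len(scheme$layout$length[j])
    bits <- do.call(rbind, lapply(blocks[[j]], `[[`, "bits"))
    out[, span] <- bits[idx + 1L, , drop = FALSE]
  }
  out
}

#' Plan a fingerprint-picked dataset
#'
#' Allocates `n` images across style profiles by largest-remainder
#' rounding of the style fractions, MaxMin-picks that many diverse style
#' fingerprints per profile, and marks a largest-remainder-rounded share
#' as augmented, attaching a MaxMin-picked augmentation fingerprint each.
#' When a style's demand exceeds its pool (e.g. more than 864 STYLE_C
#' images), the full diverse ordering is cycled.
#'
#' @param n number of images to plan.
#' @param proportions list/vector with `STYLE_A`, `STYLE_B`, `STYLE_C`
#'   fractions summing to 1 and an `augmented` fraction in `[0, 1]`.
#'   Defaults: 0.55 / 0.30 / 0.15, augmented 0.5.
#' @param profiles named list of style profiles (default [style_profiles()]).
#' @param seed integer seed; the plan is byte-identical across runs for a
#'   fixed seed.
#' @param pool_cap subsampling cap passed to [fingerprint_pool()].
#' @return data.frame with one row per image: `style`, `style_fingerprint`
#'   (bit string), `aug_fingerprint` (bit string or NA).
#' @export
plan_dataset <- function(n, proportions = default_proportions(),
                         profiles = style_profiles(), seed = 0L,
                         pool_cap = 1e5) {
  pr <- normalize_proportions(proportions)
  if (n == 0L)
    return(data.frame(style = character(), style_fingerprint = character(),
                      aug_fingerprint = character(), stringsAsFactors = FALSE))
  style_ids <- names(profiles)
  counts <- largest_remainder(n, unlist(pr[style_ids]))
  n_aug <- largest_remainder(n, c(pr$augmented, 1 - pr$augmented))[1]
  style <- rep(style_ids, counts)
  fp_chr <- character(n)
  pos <- 0L
  for (s in seq_along(style_ids)) {
    ks <- counts[s]
    if (ks == 0L) next
    pool <- fingerprint_pool(profiles[[s]]$scheme, cap = pool_cap,
                             seed = mix32(xor32(seed, s)))
    ## when demand exceeds the pool (STYLE_C has only 864 fingerprints),
    ## the full diverse ordering is cycled
    idx <- rep_len(maxmin_pick(pool, min(ks, nrow(pool)),
                               seed = mix32(xor32(seed, 100 + s))), ks)
    fp_chr[pos + seq_len(ks)] <-
      apply(pool[idx, , drop = FALSE], 1L, paste, collapse = "")
    pos <- pos + ks
  }
  aug <- rep(NA_character_, n)
  if (n_aug > 0L) {
    apool <- enumerate_valid_fingerprints(augmentation_scheme())
    k_eff <- min(n_aug, nrow(apool))
    aidx <- maxmin_pick(apool, k_eff, seed = mix32(xor32(seed, 777)))
    aidx <- rep_len(aidx, n_aug) # reuse diverse picks when n_aug > pool
    which_aug <- seq_len(n_aug)  # deterministic: first n_aug records
    aug[which_aug] <- apply(apool[aidx, , drop = FALSE], 1L, paste,
                            collapse = "")
  }
  data.frame(style = style, style_fingerprint = fp_chr,
             aug_fingerprint = aug, stringsAsFactors = FALSE)
}

#' Default dataset proportions
#'
#' 55% / 30% / 15% across the three style profiles and 50% augmented.
#' @return named list of fractions.
#' @export
default_proportions <- function() {
  list(STYLE_A = 0.55, STYLE_B = 0.30, STYLE_C = 0.15, augmented = 0.5)
}

normalize_proportions <- function(p) {
  p <- as.list(p)
  need <- c("STYLE_A", "STYLE_B", "STYLE_C")
  if (!all(need %in% names(p)))
    stop("proportions must name STYLE_A, STYLE_B, STYLE_C")
  f <- unlist(p[need])
  if (any(f < 0 | f > 1) || abs(sum(f) - 1) > 1e-9)
    stop("style fractions must lie in [0,1] and sum to 1")
  if (is.null(p$augmented)) p$augmented <- 0.5
  if (p$augmented < 0 || p$augmented > 1)
    stop("augmented fraction must lie in [0,1]")
  p
}

#' Largest-remainder apportionment of n into integer counts
#' @keywords internal
largest_remainder <- function(n, fractions) {
  q <- n * fractions
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[o] <- base[o] + 1
  }
  as.integer(base)
}
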