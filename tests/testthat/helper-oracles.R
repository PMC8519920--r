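# Independent oracles used across the suite. These are deliberately written
# as plain, slow reference implementations, separate from the package's
# production code paths.

# Quadratic-time affine-gap overlap (semi-global) aligner, Gotoh scheme,
# gap of length L costs open + (L - 1) * ext, free end gaps on both ends.
oracle_overlap_score <- function(a, b, match = 5, mismatch = -4,
                                 open = 5, ext = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i - 1, j] - open, E[i - 1, j] - ext)
      F[i, j] <- max(H[i, j - 1] - open, F[i, j - 1] - ext)
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      H[i, j] <- max(H[i - 1, j - 1] + s, E[i, j], F[i, j])
    }
  }
  max(H[m + 1, ], H[, n + 1])
}

# Exhaustive alignment enumerator for tiny strings: every monotone path,
# affine internal gap costs, free end gaps via explicit start/end border
# choices. Exponential; lengths <= 5 only.
oracle_enumerated_score <- function(a, b, match = 5, mismatch = -4,
                                    open = 5, ext = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  core <- function(i, j, i2, j2, last) {
    if (i > i2 && j > j2) return(0)
    best <- -Inf
    if (i <= i2 && j <= j2) {
      s <- if (A[i] == B[j]) match else mismatch
      best <- max(best, s + core(i + 1, j + 1, i2, j2, "M"))
    }
    if (i <= i2) {
      g <- if (identical(last, "E")) ext else open
      best <- max(best, -g + core(i + 1, j, i2, j2, "E"))
    }
    if (j <= j2) {
      g <- if (identical(last, "F")) ext else open
      best <- max(best, -g + core(i, j + 1, i2, j2, "F"))
    }
    best
  }
  starts <- rbind(cbind(0:m, 0), cbind(0, 0:n))
  ends <- rbind(cbind(0:m, n), cbind(m, 0:n))
  best <- -Inf
  for (s in seq_len(nrow(starts))) {
    for (e in seq_len(nrow(ends))) {
      i1 <- starts[s, 1]; j1 <- starts[s, 2]
      i2 <- ends[e, 1]; j2 <- ends[e, 2]
      if (i2 < i1 || j2 < j1) next
      best <- max(best, core(i1 + 1, j1 + 1, i2, j2, "S"))
    }
  }
  best
}

# Brute-force longest common substring: enumerate all substrings of a.
oracle_lcs <- function(a, b) {
  m <- nchar(a)
  best <- 0L
  for (i in 1:m) {
    for (j in i:m) {
      if (j - i + 1L <= best) next
      if (grepl(substr(a, i, j), b, fixed = TRUE)) best <- j - i + 1L
    }
  }
  best
}

# Bisection solve of the two-state mass-action equilibrium.
oracle_equilibrium <- function(K, a0, b0 = a0, homodimer = FALSE) {
  if (K <= 0) return(0)
  if (homodimer) {
    f <- function(x) K * (a0 - 2 * x)^2 - x
    hi <- a0 / 2
  } else {
    f <- function(x) K * (a0 - x) * (b0 - x) - x
    hi <- min(a0, b0)
  }
  lo <- 0
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Textbook contingency-table metrics.
oracle_mcc <- function(tp, fp, fn, tn) {
  num <- tp * tn - fp * fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else num / den
}

oracle_auroc <- function(truth_pos, scores) {
  pos <- scores[truth_pos]; neg <- scores[!truth_pos]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Levenshtein distance (standard DP) for the mutation-contract checks.
oracle_edit_distance <- function(a, b) {
  drop(utils::adist(a, b))
}

random_pair_set <- function(n, len_range = 18:26) {
  a <- vapply(sample(len_range, n, TRUE), function(L)
    random_sequence(L), character(1))
  b <- vapply(sample(len_range, n, TRUE), function(L)
    random_sequence(L), character(1))
  list(a = a, b = b)
}

# small seeded dataset shared by the model/evaluation tests (built once per
# test run, at desk scale)
shared_small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- assemble_dataset(seed_count = 30, target_size = 1500,
                             rng_seed = 11)
      cache <<- stratified_split(ds, rng_seed = 12)
    }
    cache
  }
})
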