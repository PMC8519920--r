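#' DNA sequence validation
#'
#' Normalises a character vector to uppercase A/C/G/T and validates it.
#' Sequences are represented throughout the package as plain uppercase
#' character strings; this is the single entry point that enforces the
#' alphabet.
#'
#' @param x character vector of DNA sequences.
#' @return the validated, uppercased character vector.
#' @export
#' @examples
#' dna("acgt")
dna <- function(x) {
  if (!is.character(x)) stop("DNA sequences must be character strings")
  x <- toupper(x)
  if (any(nchar(x) < 1L)) stop("DNA sequences must have length >= 1")
  bad <- regexpr("[^ACGT]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid character '%s' at position %d of sequence %d",
                 substr(x[i], bad[i], bad[i]), bad[i], i))
  }
  x
}

#' Reverse complement
#'
#' Watson-Crick complement (A<->T, C<->G) of the reversed sequence. An
#' involution: applying it twice returns the input.
#'
#' @param seq character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("ACGT") # palindrome
reverse_complement <- function(seq) {
  seq <- dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Completion counts f[r + 1, base, run] = number of admissible suffixes of
# length r given the current last base and its run length (runs >= 3
# forbidden). Doubles are exact here: counts < 4^26 < 2^53.
run_constrained_counts <- function(len) {
  f <- array(0, dim = c(len + 1L, 4L, 2L))
  f[1L, , ] <- 1
  for (r in seq_len(len)) {
    for (b in 1:4) {
      for (run in 1:2) {
        tot <- 0
        for (nb in 1:4) {
          if (nb == b) {
            if (run < 2L) tot <- tot + f[r, nb, run + 1L]
          } else {
            tot <- tot + f[r, nb, 1L]
          }
        }
        f[r + 1L, b, run] <- tot
      }
    }
  }
  f
}

#' Random DNA sequence without long homopolymer runs
#'
#' Draws uniformly over all sequences of the given length in which no base
#' repeats three or more times in a row. Uniformity over the admissible set
#' is exact: bases are sampled sequentially with probabilities proportional
#' to the number of admissible completions.
#'
#' @param length sequence length (>= 1).
#' @param n number of sequences to draw.
#' @param rng_seed optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return character vector of `n` sequences.
#' @export
random_sequence <- function(length, n = 1L, rng_seed = NULL) {
  if (!is.numeric(length) || length < 1L) stop("length must be >= 1")
  length <- as.integer(length)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  bases <- c("A", "C", "G", "T")
  f <- run_constrained_counts(length)
  out <- character(n)
  for (s in seq_len(n)) {
    chars <- character(length)
    last <- 0L; run <- 0L
    for (pos in seq_len(length)) {
      r <- length - pos # remaining after this draw
      w <- numeric(4)
      for (b in 1:4) {
        if (b == last) {
          w[b] <- if (run < 2L) f[r + 1L, b, run + 1L] else 0
        } else {
          w[b] <- f[r + 1L, b, 1L]
        }
      }
      b <- sample.int(4L, 1L, prob = w)
      if (b == last) run <- run + 1L else { last <- b; run <- 1L }
      chars[pos] <- bases[b]
    }
    out[s] <- paste0(chars, collapse = "")
  }
  out
}

#' Mutation specification
#'
#' Describes a batch of mutation events applied to one sequence. Minor
#' mutations use a single kind applied once or twice; severe mutations draw
#' each event's kind from all three kinds and apply at least three events.
#'
#' @param kinds character subset of `c("insertion", "deletion",
#'   "substitution")`.
#' @param count number of mutation events (>= 1).
#' @param severity `"minor"` or `"severe"`.
#' @return a `mutation_spec` list.
#' @export
mutation_spec <- function(kinds, count, severity = c("minor", "severe")) {
  severity <- match.arg(severity)
  all_kinds <- c("insertion", "deletion", "substitution")
  if (!all(kinds %in% all_kinds)) stop("unknown mutation kind")
  count <- as.integer(count)
  if (count < 1L) stop("count must be >= 1")
  if (severity == "minor" && (length(kinds) != 1L || !count %in% 1:2))
    stop("minor mutations use exactly one kind, applied once or twice")
  if (severity == "severe" && (length(kinds) != 3L || count < 3L))
    stop("severe mutations use all three kinds and count >= 3")
  structure(list(kinds = kinds, count = count, severity = severity),
            class = "mutation_spec")
}

#' Draw a random mutation specification
#'
#' Minor specs pick one kind uniformly and a count from `{1, 2}`; severe
#' specs use all three kinds with a count uniform on `{3, ..., 8}`.
#'
#' @param severity `"minor"` or `"severe"`.
#' @return a [mutation_spec()].
#' @export
random_mutation_spec <- function(severity = c("minor", "severe")) {
  severity <- match.arg(severity)
  all_kinds <- c("insertion", "deletion", "substitution")
  if (severity == "minor") {
    mutation_spec(sample(all_kinds, 1L), sample(1:2, 1L), "minor")
  } else {
    mutation_spec(all_kinds, sample(3:8, 1L), "severe")
  }
}

#' Mutate a sequence
#'
#' Applies exactly `spec$count` mutation events. Each event's kind is drawn
#' uniformly from `spec$kinds`; positions are drawn uniformly without
#' replacement within each kind's batch. Substitutions never replace a base
#' with itself; insertions lengthen by one, deletions shorten by one.
#' Substitutions are applied first, then deletions, then insertions.
#'
#' @param seq a DNA sequence.
#' @param spec a [mutation_spec()].
#' @param rng_seed optional integer seed.
#' @return the mutated sequence.
#' @export
mutate_sequence <- function(seq, spec, rng_seed = NULL) {
  seq <- dna(seq)
  stopifnot(inherits(spec, "mutation_spec"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  kinds <- sample(spec$kinds, spec$count, replace = TRUE)
  n_del <- sum(kinds == "deletion")
  if (n_del >= nchar(seq)) stop("deletions would empty the sequence")
  chars <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  n_sub <- sum(kinds == "substitution")
  if (n_sub > 0L) {
    pos <- sample.int(length(chars), min(n_sub, length(chars)))
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
  }
  if (n_del > 0L) {
    pos <- sample.int(length(chars), n_del)
    chars <- chars[-pos]
  }
  n_ins <- sum(kinds == "insertion")
  if (n_ins > 0L) {
    # insertion slots: before position 1 .. after the last base
    pos <- sample.int(length(chars) + 1L, min(n_ins, length(chars) + 1L))
    for (p in sort(pos, decreasing = TRUE)) {
      chars <- append(chars, sample(bases, 1L), after = p - 1L)
    }
  }
  paste0(chars, collapse = "")
}

#' Expand a seed sequence into its mutant family
#'
#' Returns the seed, its reverse complement, and `n_minor + n_severe`
#' mutants, each derived (with equal probability) from the seed or from its
#' reverse complement; duplicates are removed. Pairings within such a family
#' span the full range of hybridisation yields.
#'
#' @param seed_seq a DNA sequence.
#' @param n_minor number of minor mutants.
#' @param n_severe number of severe mutants.
#' @param rng_seed optional integer seed.
#' @return character vector of unique family members (seed first), with an
#'   attribute `side` recording whether each member derives from the seed
#'   strand or from its reverse complement.
#' @export
expand_family <- function(seed_seq, n_minor, n_severe, rng_seed = NULL) {
  seed_seq <- dna(seed_seq)
  stopifnot(n_minor >= 0L, n_severe >= 0L)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  rc <- reverse_complement(seed_seq)
  severities <- c(rep("minor", n_minor), rep("severe", n_severe))
  mutants <- character(0)
  sides <- character(0)
  for (sev in severities) {
    from_seed <- runif(1) < 0.5
    base_seq <- if (from_seed) seed_seq else rc
    spec <- random_mutation_spec(sev)
    mutants <- c(mutants, mutate_sequence(base_seq, spec))
    sides <- c(sides, if (from_seed) "seed" else "rc")
  }
  out <- c(seed_seq, rc, mutants)
  side <- c("seed", "rc", sides)
  keep <- !duplicated(out)
  structure(out[keep], side = side[keep])
}

#' Read and write FASTA sequence sets
#'
#' Thin wrappers around Biostrings preserving sequence identifiers.
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- dna(as.character(x))
  names(out) <- names(x)
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of DNA sequences.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- dna(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' GC content percentage
#'
#' @param seq character vector of DNA sequences.
#' @return numeric vector, percent G+C in `[0, 100]`.
#' @export
gc_percent <- function(seq) {
  seq <- dna(seq)
  gc <- vapply(gregexpr("[GC]", seq),
               function(m) if (m[1] == -1L) 0L else length(m), integer(1))
  100 * gc / nchar(seq)
}
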