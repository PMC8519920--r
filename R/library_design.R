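#' Longest common substring length
#'
#' Length of the longest run of consecutive characters shared by two strings
#' (a substring, not a subsequence). Vectorised pairwise.
#'
#' @param a,b character vectors (recycled pairwise).
#' @return integer vector of LCS lengths.
#' @export
#' @examples
#' lcs_length("ACGT", "ACGT") # 4
#' lcs_length("AAAA", "CCCC") # 0
lcs_length <- function(a, b) {
  if (!is.character(a) || !is.character(b)) stop("inputs must be character")
  if (any(nchar(c(a, b)) < 1L)) stop("strings must be non-empty")
  n <- max(length(a), length(b))
  cpp_lcs_batch(rep_len(a, n), rep_len(b, n))
}

#' LCS filter parameters
#'
#' @param k minimum longest-common-substring length (default 5): two
#'   sequences must share at least `k` consecutive complementary bases to be
#'   considered able to anneal.
#' @param against `"revcomp"` (default) compares each sequence to the
#'   partner's reverse complement, the annealing-motivated convention;
#'   `"direct"` compares the raw strings.
#' @return an `lcs_params` list.
#' @export
lcs_params <- function(k = 5L, against = c("revcomp", "direct")) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  structure(list(k = k, against = match.arg(against)), class = "lcs_params")
}

seq_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, 1:(L - k + 1L), k:L)
}

#' Candidate cross-hybridising pairs via an exact k-mer join
#'
#' Emits every unordered pair of distinct sequences whose LCS against the
#' partner's reverse complement is at least `k`. Sharing an exact k-mer is
#' equivalent to an LCS of at least `k`, so an indexed k-mer join gives the
#' exact filter without the quadratic all-pairs scan. Self-pairs and
#' symmetric duplicates are removed, mirroring the two deduplication rules
#' of the clustering workflow.
#'
#' @param seqs named character vector of DNA sequences (unique ids).
#' @param params an [lcs_params()].
#' @return a `candidate_pairs` object: data.table with columns `id_a`,
#'   `id_b` (one row per unordered pair, `id_a < id_b` lexicographically),
#'   plus attributes `min_lcs` and `source`.
#' @export
candidate_pairs <- function(seqs, params = lcs_params()) {
  seqs <- dna(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (anyDuplicated(ids)) stop("sequence ids must be unique")
  k <- params$k
  targets <- if (params$against == "revcomp") reverse_complement(seqs) else seqs
  # k-mers of each raw sequence, joined against k-mers of each target
  km_a <- data.table::data.table(
    kmer = unlist(lapply(seqs, seq_kmers, k = k), use.names = FALSE),
    ia = rep(seq_along(seqs), vapply(seqs, function(s)
      max(nchar(s) - k + 1L, 0L), 1L)))
  km_b <- data.table::data.table(
    kmer = unlist(lapply(targets, seq_kmers, k = k), use.names = FALSE),
    ib = rep(seq_along(targets), vapply(targets, function(s)
      max(nchar(s) - k + 1L, 0L), 1L)))
  km_a <- unique(km_a); km_b <- unique(km_b)
  hits <- merge(km_a, km_b, by = "kmer", allow.cartesian = TRUE)
  pairs <- unique(hits[, c("ia", "ib")])
  pairs <- pairs[pairs$ia != pairs$ib, ] # drop self-pairs
  # one representative per unordered pair
  lo <- pmin(pairs$ia, pairs$ib); hi <- pmax(pairs$ia, pairs$ib)
  up <- unique(data.table::data.table(lo = lo, hi = hi))
  out <- data.table::data.table(id_a = ids[up$lo], id_b = ids[up$hi])
  data.table::setorder(out, id_a, id_b)
  structure(out, min_lcs = k, source = "builtin_kmer",
            class = c("candidate_pairs", class(out)))
}

#' Deduplicate a raw pair list
#'
#' Applies the two rules used on raw clustering hits: drop self-pairs
#' (identical ids) and keep one representative per unordered pair.
#' Idempotent.
#'
#' @param pairs data.frame with columns `id_a`, `id_b`.
#' @return deduplicated data.table with `id_a < id_b` per row.
#' @export
dedup_pairs <- function(pairs) {
  keep <- pairs$id_a != pairs$id_b
  lo <- pmin(pairs$id_a[keep], pairs$id_b[keep])
  hi <- pmax(pairs$id_a[keep], pairs$id_b[keep])
  out <- unique(data.table::data.table(id_a = lo, id_b = hi))
  data.table::setorder(out, id_a, id_b)
  out
}

# ---- MMseqs2 orchestration -------------------------------------------------

#' Build the MMseqs2 command lines for the LCS search
#'
#' Reproduces the nucleotide search protocol: `createdb --dbtype 2`, then
#' `search` with maximum sensitivity 7.5, k-mer size 5, exact k-mer
#' matching, no spaced k-mers, minimum sequence identity 0.25, alignment
#' mode 4 (ungapped), `-e inf`, minimum alignment length 5, the dnafull
#' substitution matrix, `--strand 0` (reverse-complement search) and
#' `--search-type 3`, followed by `createtsv`.
#'
#' @param fasta input FASTA path.
#' @param workdir working directory for databases and temporaries.
#' @param min_aln_len minimum alignment (shared substring) length.
#' @param max_seq_len maximum sequence length in the set.
#' @return list of character vectors, one per command.
#' @export
mmseqs2_commands <- function(fasta, workdir, min_aln_len = 5L,
                             max_seq_len = 26L) {
  db <- file.path(workdir, "db")
  aln <- file.path(workdir, "aln")
  tmp <- file.path(workdir, "tmp")
  tsv <- file.path(workdir, "hits.tsv")
  list(
    createdb = c("createdb", fasta, db, "--dbtype", "2"),
    search = c("search", db, db, aln, tmp,
               "-s", "7.5", "-k", "5",
               "--max-seqs", "10000",
               "--exact-kmer-matching", "1", "--spaced-kmer-mode", "0",
               "--min-seq-id", "0.25", "--alignment-mode", "4",
               "-e", "inf", "--min-aln-len", as.character(min_aln_len),
               "--sub-mat", "dnafull",
               "--max-seq-len", as.character(max_seq_len),
               "--strand", "0", "--search-type", "3"),
    createtsv = c("createtsv", db, db, aln, tsv))
}

#' Parse an MMseqs2 hit table into deduplicated candidate pairs
#'
#' @param path tab-separated hit table whose first two columns are query and
#'   target ids.
#' @param min_lcs recorded threshold for the resulting object.
#' @return a `candidate_pairs` object (source `"mmseqs2"`).
#' @export
parse_mmseqs2_hits <- function(path, min_lcs = 5L) {
  hits <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(hits) < 2L) stop("malformed MMseqs2 hit table: ", path)
  out <- dedup_pairs(data.frame(id_a = as.character(hits[[1]]),
                                id_b = as.character(hits[[2]]),
                                stringsAsFactors = FALSE))
  structure(out, min_lcs = as.integer(min_lcs), source = "mmseqs2",
            class = c("candidate_pairs", class(out)))
}

#' Candidate pairs via MMseqs2
#'
#' Runs the full createdb/search/createtsv protocol of
#' [mmseqs2_commands()] and applies the two deduplication rules. MMseqs2 is
#' a heuristic accelerator: at matching k its hits are expected to contain
#' the exact k-mer join's pairs, which is reported, not asserted.
#'
#' @param fasta FASTA file of candidate sequences.
#' @param workdir working directory (created if needed).
#' @param min_aln_len minimum alignment length (the LCS threshold).
#' @return a `candidate_pairs` object.
#' @export
mmseqs2_candidates <- function(fasta, workdir = tempfile("mmseqs"),
                               min_aln_len = 5L) {
  if (!file.exists(fasta)) stop("FASTA file not found: ", fasta)
  if (length(read_fasta(fasta)) == 0L) stop("empty FASTA: ", fasta)
  bin <- Sys.which("mmseqs")
  if (!nzchar(bin))
    stop("MMseqs2 ('mmseqs') not found on PATH. Install MMseqs2 or use ",
         "candidate_pairs(), the exact builtin k-mer filter.", call. = FALSE)
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  lens <- nchar(read_fasta(fasta))
  cmds <- mmseqs2_commands(fasta, workdir, min_aln_len, max(lens))
  for (cmd in cmds) {
    out <- suppressWarnings(system2(bin, cmd, stdout = TRUE, stderr = TRUE))
    status <- attr(out, "status") %||% 0L
    if (status != 0L)
      stop(sprintf("mmseqs %s exited with status %d:\n%s", cmd[1], status,
                   paste(utils::tail(out, 20), collapse = "\n")))
  }
  parse_mmseqs2_hits(file.path(workdir, "hits.tsv"), min_aln_len)
}

#' Screen candidate pairs and assemble an orthogonal-library report
#'
#' Batch-predicts the yield of every candidate pair with a trained
#' predictor, flags pairs at or above the threshold as cross-hybridisation
#' conflicts, computes per-sequence conflict degrees, and extracts a greedy
#' maximal conflict-free subset (iteratively dropping the
#' highest-conflict-degree sequence).
#'
#' @param candidates a `candidate_pairs` object.
#' @param seqs named character vector supplying the sequence for every id.
#' @param predictor a trained `trained_predictor` (or any function
#'   `f(a, b) -> yields`, e.g. a thermodynamic backend closure).
#' @param threshold predicted-yield conflict threshold (default 0.2).
#' @return a `design_report` list: `pairs` (id_a, id_b, lcs,
#'   predicted_yield, conflict), `conflict_degree` (named integer),
#'   `conflict_free` (character ids).
#' @export
design_report <- function(candidates, seqs, predictor, threshold = 0.2) {
  seqs <- dna(seqs)
  ids <- names(seqs)
  miss <- setdiff(unique(c(candidates$id_a, candidates$id_b)), ids)
  if (length(miss))
    stop("missing sequences for ids: ", paste(head(miss, 5), collapse = ", "))
  pairs <- as.data.frame(candidates)
  if (nrow(pairs) > 0L) {
    a <- seqs[pairs$id_a]; b <- seqs[pairs$id_b]
    pairs$lcs <- lcs_length(a, reverse_complement(b))
    pairs$predicted_yield <- if (is.function(predictor)) predictor(a, b)
                             else predict_yield(predictor, a, b)
    pairs$conflict <- pairs$predicted_yield >= threshold
  } else {
    pairs$lcs <- integer(0)
    pairs$predicted_yield <- numeric(0)
    pairs$conflict <- logical(0)
  }
  conf <- pairs[pairs$conflict, , drop = FALSE]
  degree <- setNames(integer(length(ids)), ids)
  tab <- table(c(conf$id_a, conf$id_b))
  degree[names(tab)] <- as.integer(tab)
  # greedy: drop the worst offender until no conflict edge remains
  alive <- setNames(rep(TRUE, length(ids)), ids)
  edges <- conf[, c("id_a", "id_b")]
  deg <- degree
  while (nrow(edges) > 0L) {
    worst <- names(which.max(deg))
    alive[worst] <- FALSE
    touched <- edges$id_a == worst | edges$id_b == worst
    for (v in c(edges$id_a[touched], edges$id_b[touched]))
      deg[v] <- deg[v] - 1L
    deg[worst] <- 0L
    edges <- edges[!touched, , drop = FALSE]
  }
  structure(list(pairs = pairs, conflict_degree = degree,
                 conflict_free = ids[alive], threshold = threshold),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf(paste0("<design_report> %d candidate pairs, %d conflicts ",
                     "(threshold %.2f), %d conflict-free sequences\n"),
              nrow(x$pairs), sum(x$pairs$conflict), x$threshold,
              length(x$conflict_free)))
  invisible(x)
}

#' Write a design pair list as TSV
#'
#' Schema: `id_a  id_b  lcs  predicted_yield  conflict`.
#'
#' @param report a `design_report`.
#' @param path output TSV path.
#' @export
write_design_tsv <- function(report, path) {
  out <- report$pairs
  out$predicted_yield <- sprintf("%.6f", out$predicted_yield)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
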