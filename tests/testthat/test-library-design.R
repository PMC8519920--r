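test_that("LCS length matches the brute-force substring enumerator", {
  expect_equal(lcs_length("ACGT", "ACGT"), 4L)
  expect_equal(lcs_length("AAAA", "CCCC"), 0L)
  set.seed(71)
  pr <- random_pair_set(500)
  got <- lcs_length(pr$a, pr$b)
  ref <- mapply(oracle_lcs, pr$a, pr$b)
  expect_equal(got, unname(as.integer(ref)))
  expect_error(lcs_length("", "ACGT"), "non-empty")
})

test_that("k-mer join equals the brute-force LCS filter", {
  set.seed(72)
  seqs <- setNames(random_sequence(20, n = 100), sprintf("seq%03d", 1:100))
  cands <- candidate_pairs(seqs, lcs_params(k = 5))
  # exhaustive 4,950-pair brute force
  idx <- utils::combn(100, 2)
  rc <- reverse_complement(seqs)
  keep <- lcs_length(seqs[idx[1, ]], rc[idx[2, ]]) >= 5
  ref <- data.frame(id_a = names(seqs)[idx[1, keep]],
                    id_b = names(seqs)[idx[2, keep]])
  got_key <- paste(cands$id_a, cands$id_b)
  ref_key <- paste(pmin(ref$id_a, ref$id_b), pmax(ref$id_a, ref$id_b))
  expect_setequal(got_key, ref_key)
  # the filter is symmetric: LCS(a, rc(b)) == LCS(b, rc(a))
  expect_equal(lcs_length(seqs[idx[1, ]], rc[idx[2, ]]),
               lcs_length(seqs[idx[2, ]], rc[idx[1, ]]))
})

test_that("k-mer join equivalence holds exhaustively at small scale", {
  # every set of 6 short sequences over a fixed seed batch
  set.seed(73)
  for (rep in 1:20) {
    seqs <- setNames(random_sequence(sample(8:10, 1), n = 6),
                     paste0("s", 1:6))
    k <- sample(2:4, 1)
    cands <- candidate_pairs(seqs, lcs_params(k = k))
    idx <- utils::combn(6, 2)
    rc <- reverse_complement(seqs)
    keep <- lcs_length(seqs[idx[1, ]], rc[idx[2, ]]) >= k
    expect_equal(nrow(cands), sum(keep), info = paste("k =", k))
  }
})

test_that("degenerate threshold k = 1 links all complementary-base pairs", {
  seqs <- c(s1 = "ACAC", s2 = "GTGT", s3 = "TTTT")
  cands <- candidate_pairs(seqs, lcs_params(k = 1))
  # s1 rc = GTGT shares bases with s2's ACAC rc... enumerate by brute force
  idx <- utils::combn(3, 2)
  rc <- reverse_complement(seqs)
  keep <- lcs_length(seqs[idx[1, ]], rc[idx[2, ]]) >= 1
  expect_equal(nrow(cands), sum(keep))
})

test_that("deduplication removes self-pairs and symmetric duplicates", {
  raw <- data.frame(id_a = c("seq10", "seq20", "seq7", "seq10"),
                    id_b = c("seq20", "seq10", "seq7", "seq20"))
  dd <- dedup_pairs(raw)
  expect_equal(nrow(dd), 1L)
  expect_equal(dd$id_a, "seq10")
  expect_equal(dd$id_b, "seq20")
  # idempotence
  expect_identical(dedup_pairs(dd), dd)
  # candidate sets carry no self-pairs or symmetric duplicates
  set.seed(74)
  seqs <- setNames(random_sequence(20, n = 40), paste0("q", 1:40))
  cands <- candidate_pairs(seqs, lcs_params(k = 4))
  expect_false(any(cands$id_a == cands$id_b))
  expect_false(any(duplicated(paste(pmin(cands$id_a, cands$id_b),
                                    pmax(cands$id_a, cands$id_b)))))
  expect_lte(nrow(cands), 40 * 39 / 2)
  expect_error(candidate_pairs(setNames(c("ACGT", "ACGT"), c("a", "a"))),
               "unique")
})

test_that("MMseqs2 command lines reproduce the printed search protocol", {
  cmds <- mmseqs2_commands("lib.fa", "wd")
  expect_equal(cmds$createdb[1], "createdb")
  expect_true(all(c("--dbtype", "2") %in% cmds$createdb))
  s <- cmds$search
  flag_val <- function(f) s[which(s == f) + 1]
  expect_equal(flag_val("-s"), "7.5")
  expect_equal(flag_val("-k"), "5")
  expect_equal(flag_val("--min-seq-id"), "0.25")
  expect_equal(flag_val("--alignment-mode"), "4")
  expect_equal(flag_val("-e"), "inf")
  expect_equal(flag_val("--min-aln-len"), "5")
  expect_equal(flag_val("--sub-mat"), "dnafull")
  expect_equal(flag_val("--strand"), "0")
  expect_equal(flag_val("--search-type"), "3")
  expect_equal(flag_val("--exact-kmer-matching"), "1")
  expect_equal(flag_val("--spaced-kmer-mode"), "0")
})

test_that("MMseqs2 hit tables parse and deduplicate", {
  hits <- tempfile(fileext = ".tsv")
  writeLines(c("seq10\tseq20\t0.5", "seq20\tseq10\t0.5",
               "seq7\tseq7\t1.0", "seq1\tseq2\t0.9"), hits)
  cands <- parse_mmseqs2_hits(hits)
  expect_equal(nrow(cands), 2L)
  expect_setequal(paste(cands$id_a, cands$id_b),
                  c("seq10 seq20", "seq1 seq2"))
  expect_equal(attr(cands, "source"), "mmseqs2")
})

test_that("a missing MMseqs2 binary raises a configuration error", {
  fa <- tempfile(fileext = ".fa")
  write_fasta(setNames(random_sequence(20, 3, rng_seed = 1),
                       paste0("s", 1:3)), fa)
  if (nzchar(Sys.which("mmseqs"))) {
    cands <- mmseqs2_candidates(fa)
    expect_s3_class(cands, "candidate_pairs")
  } else {
    expect_error(mmseqs2_candidates(fa), "not found on PATH")
  }
  expect_error(mmseqs2_candidates(tempfile(fileext = ".fa")), "not found")
})

test_that("design reports flag conflicts and extract a conflict-free subset", {
  set.seed(75)
  base <- random_sequence(20, n = 6)
  seqs <- setNames(c(base, reverse_complement(base[1])),
                   c(paste0("lib", 1:6), "anti1"))
  cands <- candidate_pairs(seqs, lcs_params(k = 5))
  thermo_pred <- function(a, b) builtin_yield(a, b)$yield_fraction
  rep_obj <- design_report(cands, seqs, thermo_pred, threshold = 0.2)
  # the engineered complement pair must be flagged as a conflict
  key <- paste(rep_obj$pairs$id_a, rep_obj$pairs$id_b)
  expect_true(("anti1 lib1" %in% key) || ("lib1 anti1" %in% key))
  conflicted <- rep_obj$pairs[rep_obj$pairs$conflict, ]
  expect_true(any(grepl("anti1", paste(conflicted$id_a, conflicted$id_b))))
  # the conflict-free subset contains no flagged pair
  cf <- rep_obj$conflict_free
  bad <- conflicted$id_a %in% cf & conflicted$id_b %in% cf
  expect_false(any(bad))
  # no candidates at all leaves every sequence conflict-free
  empty <- design_report(cands[0, ], seqs, thermo_pred)
  expect_setequal(empty$conflict_free, names(seqs))
  expect_error(design_report(cands, seqs[-1], thermo_pred), "missing")
  # TSV writer emits the declared schema
  path <- tempfile(fileext = ".tsv")
  write_design_tsv(rep_obj, path)
  expect_identical(strsplit(readLines(path, n = 1), "\t")[[1]],
                   c("id_a", "id_b", "lcs", "predicted_yield", "conflict"))
})
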