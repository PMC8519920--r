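#' Assemble a labelled multi-temperature hybridisation dataset
#'
#' Implements the mutation-driven generative procedure: random seed
#' sequences (lengths 18-26, no homopolymer runs of 3 or more) are expanded
#' into mutant families (minor and severe mutants of the seed and of its
#' reverse complement), all intra-family unordered pairings are formed,
#' a fraction of cross-family pairings is added, duplicate unordered pairs
#' are removed, equilibrium yields are computed at every requested
#' temperature, and each pair is labelled Low/High at the reference
#' temperature (yield below 0.2 is Low, otherwise High). The procedure
#' repeats, adding fresh seed families, until the target size and the
#' variety constraint (each of the three yield regions `< 0.1`, `[0.1,
#' 0.9)`, `>= 0.9` holding at least `min_region_frac` of records) are
#' achieved.
#'
#' @param seed_count seed sequences generated per iteration.
#' @param target_size minimum number of unique pairs.
#' @param temps temperatures (Celsius) at which yields are computed.
#' @param backend yield engine, `"builtin"` or `"nupack"`.
#' @param rng_seed integer seed; the run is reproducible bit-for-bit.
#' @param reference_temperature temperature used for labels.
#' @param n_minor,n_severe mutants per family.
#' @param same_fraction fraction of same-side (seed-side vs seed-side)
#'   intra-family pairs retained; these are similar rather than
#'   complementary strands and populate the low-yield region.
#' @param cross_fraction cross-family pairs added, as a fraction of the
#'   intra-family pair count.
#' @param length_range admissible sequence lengths; seeds are drawn inside
#'   it and mutants falling outside are discarded.
#' @param min_region_frac variety constraint per yield region.
#' @param initial_concentration molar strand concentration.
#' @param max_iterations non-termination guard.
#' @return a `hyb_dataset` list with elements `records` (data.frame:
#'   `pair_id`, `seq_a`, `seq_b`, one `yield_<T>` column per temperature,
#'   `label`, `split`) and `reference_temperature`.
#' @export
assemble_dataset <- function(seed_count = 40L, target_size = 1000L,
                             temps = DEFAULT_TEMPERATURES,
                             backend = c("builtin", "nupack"),
                             rng_seed = 1L,
                             reference_temperature = 57,
                             n_minor = 3L, n_severe = 2L,
                             same_fraction = 0.30,
                             cross_fraction = 0.15,
                             length_range = c(18L, 26L),
                             min_region_frac = 0.10,
                             initial_concentration = 1e-6,
                             max_iterations = 25L) {
  backend <- match.arg(backend)
  stopifnot(target_size >= 1L)
  if (!reference_temperature %in% temps)
    stop("reference_temperature must be one of temps")
  set.seed(rng_seed)
  pairs_a <- character(0); pairs_b <- character(0)
  for (iter in seq_len(max_iterations)) {
    lens <- sample(length_range[1]:length_range[2], seed_count,
                   replace = TRUE)
    seeds <- vapply(lens, function(L) random_sequence(L), character(1))
    fams <- lapply(seeds, expand_family, n_minor = n_minor,
                   n_severe = n_severe)
    # the dataset's sequences live in the primer length range: mutants
    # pushed outside it by indels are discarded
    fams <- lapply(fams, function(f) {
      keep <- nchar(f) >= length_range[1] & nchar(f) <= length_range[2]
      structure(f[keep], side = attr(f, "side")[keep])
    })
    # intra-family pairings: all cross-side pairs (the annealing-prone
    # combinations spanning high and intermediate yields) plus a subsample
    # of same-side pairs (similar strands, hence low yield)
    intra <- lapply(fams, function(f) {
      if (length(f) < 2L) return(NULL)
      side <- attr(f, "side")
      idx <- utils::combn(length(f), 2L)
      cross_side <- side[idx[1L, ]] != side[idx[2L, ]]
      same <- which(!cross_side)
      sel <- c(which(cross_side), same[runif(length(same)) < same_fraction])
      cbind(f[idx[1L, sel]], f[idx[2L, sel]])
    })
    intra <- do.call(rbind, intra)
    # cross-family pairings populate the low-yield region
    all_seqs <- unlist(fams, use.names = FALSE)
    fam_id <- rep(seq_along(fams), lengths(fams))
    n_cross <- ceiling(cross_fraction * nrow(intra))
    i <- sample.int(length(all_seqs), n_cross, replace = TRUE)
    j <- sample.int(length(all_seqs), n_cross, replace = TRUE)
    keep <- fam_id[i] != fam_id[j]
    cross <- cbind(all_seqs[i[keep]], all_seqs[j[keep]])
    new_pairs <- rbind(intra, cross)
    pairs_a <- c(pairs_a, new_pairs[, 1L])
    pairs_b <- c(pairs_b, new_pairs[, 2L])
    # unordered-pair dedup: hybridisation is symmetric
    swap <- pairs_a > pairs_b
    tmp <- pairs_a[swap]; pairs_a[swap] <- pairs_b[swap]; pairs_b[swap] <- tmp
    dup <- duplicated(paste(pairs_a, pairs_b, sep = "|"))
    pairs_a <- pairs_a[!dup]; pairs_b <- pairs_b[!dup]
    if (length(pairs_a) < target_size) next
    # variety check at the reference temperature
    cond <- thermo_conditions(reference_temperature, initial_concentration)
    y_ref <- compute_yield(pairs_a, pairs_b, cond, backend)$yield_fraction
    frac <- c(mean(y_ref < 0.1), mean(y_ref >= 0.1 & y_ref < 0.9),
              mean(y_ref >= 0.9))
    if (all(frac >= min_region_frac)) break
    if (iter == max_iterations)
      warning("variety constraint not met within max_iterations")
  }
  yields <- vapply(temps, function(tt) {
    cond <- thermo_conditions(tt, initial_concentration)
    compute_yield(pairs_a, pairs_b, cond, backend)$yield_fraction
  }, numeric(length(pairs_a)))
  yields <- matrix(yields, nrow = length(pairs_a),
                   dimnames = list(NULL, paste0("yield_", temps)))
  ref_col <- paste0("yield_", reference_temperature)
  records <- data.frame(pair_id = sprintf("pair%06d", seq_along(pairs_a)),
                        seq_a = pairs_a, seq_b = pairs_b,
                        yields,
                        label = binarise(yields[, ref_col]),
                        split = NA_character_,
                        stringsAsFactors = FALSE)
  structure(list(records = records,
                 reference_temperature = reference_temperature),
            class = "hyb_dataset")
}

#' @export
print.hyb_dataset <- function(x, ...) {
  cat(sprintf("<hyb_dataset> %d pairs, reference temperature %g C\n",
              nrow(x$records), x$reference_temperature))
  if (!all(is.na(x$records$split))) {
    cat("  splits:", paste(sprintf("%s=%d", names(table(x$records$split)),
                                   table(x$records$split)), collapse = " "),
        "\n")
  }
  invisible(x)
}

dataset_yield_column <- function(ds, temperature) {
  col <- paste0("yield_", temperature)
  if (!col %in% names(ds$records)) {
    avail <- sub("^yield_", "", grep("^yield_", names(ds$records), value = TRUE))
    stop(sprintf("no yields at %g C; available temperatures: %s",
                 temperature, paste(avail, collapse = ", ")))
  }
  ds$records[[col]]
}

#' Decile histogram of the yield distribution
#'
#' Bins yields into ten 0.1-wide groups and summarises the three-region
#' balance: low (`< 0.1`), high (`>= 0.9`) and in-between.
#'
#' @param ds a `hyb_dataset`.
#' @param temperature temperature whose yields are binned.
#' @return a `yield_histogram` list: `bin_edges`, `counts` (10 integers),
#'   `extreme_counts` (low/mid/high).
#' @export
yield_histogram <- function(ds, temperature = ds$reference_temperature) {
  y <- dataset_yield_column(ds, temperature)
  edges <- seq(0, 1, by = 0.1)
  bin <- pmin(findInterval(y, edges, rightmost.closed = FALSE), 10L)
  counts <- tabulate(bin, nbins = 10L)
  structure(list(bin_edges = edges, counts = counts,
                 extreme_counts = c(low = sum(y < 0.1),
                                    mid = sum(y >= 0.1 & y < 0.9),
                                    high = sum(y >= 0.9)),
                 temperature = temperature),
            class = "yield_histogram")
}

#' @export
print.yield_histogram <- function(x, ...) {
  cat(sprintf("<yield_histogram> %d records at %g C\n",
              sum(x$counts), x$temperature))
  cat("  counts:", paste(x$counts, collapse = " "), "\n")
  cat(sprintf("  low (<0.1): %d   mid: %d   high (>=0.9): %d\n",
              x$extreme_counts["low"], x$extreme_counts["mid"],
              x$extreme_counts["high"]))
  invisible(x)
}

#' Stratified train/validation/test split
#'
#' Assigns each record to train/validation/test, stratifying on the ten
#' decile bins of the yield at the reference temperature so all three splits
#' carry the full yield distribution. Allocation within each bin uses
#' largest-remainder rounding, so split proportions hold within one record
#' per stratum.
#'
#' @param ds a `hyb_dataset`.
#' @param fractions train/validation/test proportions summing to 1.
#' @param rng_seed integer seed.
#' @return the dataset with the `split` column filled.
#' @export
stratified_split <- function(ds, fractions = c(0.8, 0.1, 0.1),
                             rng_seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (length(fractions) != 3L) stop("fractions must be train/validation/test")
  set.seed(rng_seed)
  y <- dataset_yield_column(ds, ds$reference_temperature)
  bin <- pmin(findInterval(y, seq(0, 1, 0.1)), 10L)
  split <- character(nrow(ds$records))
  names(fractions) <- c("train", "validation", "test")
  for (b in unique(bin)) {
    idx <- sample(which(bin == b))
    n <- length(idx)
    exact <- fractions * n
    base <- floor(exact)
    rem <- n - sum(base)
    if (rem > 0) {
      order_frac <- order(exact - base, decreasing = TRUE)
      base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
    }
    lab <- rep(names(fractions), base)
    split[idx] <- lab
  }
  ds$records$split <- split
  ds
}

#' Read and write the dataset TSV
#'
#' Canonical on-disk schema: `pair_id seq_a seq_b yield_<T>... label split`
#' with a mandatory header; yields printed with six decimals. A `.gz` suffix
#' is read and written transparently.
#'
#' @param ds a `hyb_dataset`.
#' @param path TSV path.
#' @param reference_temperature reference temperature to restore on read.
#' @export
write_dataset <- function(ds, path) {
  rec <- ds$records
  ycols <- grep("^yield_", names(rec), value = TRUE)
  for (cc in ycols) rec[[cc]] <- sprintf("%.6f", rec[[cc]])
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(rec, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, reference_temperature = 57) {
  rec <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) stop("cannot read dataset TSV: ", conditionMessage(e)))
  required <- c("pair_id", "seq_a", "seq_b", "label", "split")
  miss <- setdiff(required, names(rec))
  if (length(miss))
    stop("dataset TSV is missing columns: ", paste(miss, collapse = ", "))
  ycols <- grep("^yield_", names(rec), value = TRUE)
  if (length(ycols) == 0L) stop("dataset TSV has no yield_<T> columns")
  for (cc in ycols) {
    v <- suppressWarnings(as.numeric(rec[[cc]]))
    bad <- which(is.na(v) & !is.na(rec[[cc]]))
    if (length(bad))
      stop(sprintf("malformed yield in column %s at line %d", cc, bad[1] + 1L))
    rec[[cc]] <- v
  }
  rec$split[rec$split == "NA" | rec$split == ""] <- NA_character_
  ref_col <- paste0("yield_", reference_temperature)
  if (!ref_col %in% ycols) {
    reference_temperature <- as.numeric(sub("^yield_", "", ycols[1]))
  }
  structure(list(records = rec,
                 reference_temperature = reference_temperature),
            class = "hyb_dataset")
}

#' Subset a dataset by split
#'
#' @param ds a `hyb_dataset`.
#' @param split one of `"train"`, `"validation"`, `"test"`.
#' @return the records data.frame for that split.
#' @export
dataset_split <- function(ds, split = c("train", "validation", "test")) {
  split <- match.arg(split)
  out <- ds$records[!is.na(ds$records$split) & ds$records$split == split, ]
  if (nrow(out) == 0L) stop("split '", split, "' is empty; run stratified_split()")
  out
}
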