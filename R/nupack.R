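# NUPACK 3 standalone-executable wrapper: each pair is written to a .in
# file, fed to `complexes` (complex size capped at 2), whose output feeds
# `concentrations`; the equilibrium duplex concentration is read from the
# .eq table. NUPACK is an optional external backend; the builtin
# nearest-neighbour engine keeps the package fully testable without it.

nupack_find <- function(exe) {
  hit <- Sys.which(exe)
  if (!nzchar(hit)) {
    stop(sprintf(paste0(
      "NUPACK executable '%s' not found on PATH. Install NUPACK 3 ",
      "(complexes/concentrations) or select backend = 'builtin'."), exe),
      call. = FALSE)
  }
  hit
}

#' Write a NUPACK 3 complexes input file pair
#'
#' Produces `<prefix>.in` (sequence count, sequences, max complex size 2)
#' and `<prefix>.con` (initial molar concentrations), the file dialect the
#' `complexes` and `concentrations` executables consume.
#'
#' @param a,b DNA sequences (a single pair; `a == b` analyses a homodimer
#'   system with one distinct strand).
#' @param prefix path prefix for the `.in`/`.con` files.
#' @param initial_concentration molar concentration per distinct strand.
#' @return the prefix, invisibly.
#' @export
write_nupack_input <- function(a, b, prefix,
                               initial_concentration = 1e-6) {
  a <- dna(a); b <- dna(b)
  seqs <- if (identical(a, b)) a else c(a, b)
  writeLines(c(length(seqs), seqs, "2"), paste0(prefix, ".in"))
  writeLines(format(rep(initial_concentration, length(seqs)),
                    scientific = TRUE),
             paste0(prefix, ".con"))
  invisible(prefix)
}

#' Parse a NUPACK 3 concentrations .eq table
#'
#' The .eq output lists one complex per line: complex id, strand
#' multiplicities (one column per distinct strand), free energy, and the
#' equilibrium molar concentration in the final column. Comment lines start
#' with `%`.
#'
#' @param path path to the `.eq` file.
#' @param n_strands number of distinct strands in the system (1 or 2).
#' @return data.frame with columns `complex_id`, multiplicity columns
#'   `n1`(, `n2`), `energy`, `concentration`.
#' @export
parse_nupack_eq <- function(path, n_strands) {
  lines <- readLines(path)
  lines <- trimws(lines[!startsWith(trimws(lines), "%") & nzchar(trimws(lines))])
  if (length(lines) == 0) stop("no complex rows found in NUPACK output: ", path)
  rows <- lapply(strsplit(lines, "[ \t]+"), as.numeric)
  ncol_exp <- 1 + n_strands + 2
  if (any(vapply(rows, length, 1L) < ncol_exp))
    stop("malformed NUPACK .eq row in ", path)
  m <- do.call(rbind, lapply(rows, function(r) r[seq_len(ncol_exp)]))
  out <- as.data.frame(m)
  names(out) <- c("complex_id", paste0("n", seq_len(n_strands)),
                  "energy", "concentration")
  out
}

#' Equilibrium yield via NUPACK 3
#'
#' Runs `complexes` then `concentrations` on a temporary job directory and
#' returns the duplex yield in the same shape as [builtin_yield()]. Requires
#' the NUPACK 3 executables on `PATH`.
#'
#' @param a,b a single pair of DNA sequences.
#' @param cond a [thermo_conditions()].
#' @param keep_files keep the job directory (for inspection).
#' @return one-row data.frame matching the [builtin_yield()] columns.
#' @export
nupack_yield <- function(a, b, cond = thermo_conditions(),
                         keep_files = FALSE) {
  a <- dna(a); b <- dna(b)
  if (length(a) != 1L || length(b) != 1L)
    stop("nupack_yield analyses one pair at a time")
  complexes_bin <- nupack_find("complexes")
  concentrations_bin <- nupack_find("concentrations")
  dir <- tempfile("nupack")
  dir.create(dir)
  if (!keep_files) on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  prefix <- file.path(dir, "job")
  write_nupack_input(a, b, prefix, cond$initial_concentration)
  run <- function(bin, args) {
    out <- suppressWarnings(system2(bin, args, stdout = TRUE, stderr = TRUE))
    status <- attr(out, "status") %||% 0L
    if (status != 0L)
      stop(sprintf("NUPACK '%s' exited with status %d:\n%s",
                   basename(bin), status, paste(out, collapse = "\n")))
    out
  }
  run(complexes_bin,
      c("-T", format(cond$temperature_celsius), "-material", "dna", prefix))
  run(concentrations_bin, prefix)
  n_strands <- if (identical(a, b)) 1L else 2L
  eq <- parse_nupack_eq(paste0(prefix, ".eq"), n_strands)
  homo <- identical(a, b)
  if (homo) {
    duplex <- sum(eq$concentration[eq$n1 == 2])
    mono_a <- sum(eq$concentration[eq$n1 == 1])
    mono_b <- mono_a
  } else {
    duplex <- sum(eq$concentration[eq$n1 == 1 & eq$n2 == 1])
    mono_a <- sum(eq$concentration[eq$n1 == 1 & eq$n2 == 0])
    mono_b <- sum(eq$concentration[eq$n1 == 0 & eq$n2 == 1])
  }
  data.frame(yield_fraction = pmin(pmax(duplex / cond$initial_concentration,
                                        0), 1),
             duplex_concentration = duplex,
             monomer_a = mono_a, monomer_b = mono_b,
             delta_G_at_T = NA_real_, K_eq = NA_real_,
             backend = "nupack", stringsAsFactors = FALSE)
}

#' Is NUPACK 3 available on PATH?
#' @export
nupack_available <- function() {
  nzchar(Sys.which("complexes")) && nzchar(Sys.which("concentrations"))
}
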