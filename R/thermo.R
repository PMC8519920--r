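#' Thermodynamic conditions
#'
#' Conditions under which equilibrium duplex yields are computed. The default
#' temperature is 57 degrees Celsius (the primer-design range consensus);
#' ground-truth datasets carry yields at 37, 42, 47, 52, 57 and 62 degrees.
#'
#' @param temperature_celsius temperature in Celsius, within `[0, 100]`.
#' @param initial_concentration initial concentration of each strand, mol/L.
#' @param sodium_molar monovalent salt concentration, mol/L (builtin
#'   nearest-neighbour backend only; parameters are tabulated at 1 M).
#' @return a `thermo_conditions` list.
#' @export
thermo_conditions <- function(temperature_celsius = 57,
                              initial_concentration = 1e-6,
                              sodium_molar = 1.0) {
  if (temperature_celsius < 0 || temperature_celsius > 100)
    stop("temperature must be within [0, 100] Celsius")
  if (initial_concentration <= 0 || sodium_molar <= 0)
    stop("concentrations must be > 0")
  structure(list(temperature_celsius = temperature_celsius,
                 initial_concentration = initial_concentration,
                 sodium_molar = sodium_molar),
            class = "thermo_conditions")
}

#' Default evaluation temperatures
#' @export
DEFAULT_TEMPERATURES <- c(37, 42, 47, 52, 57, 62)

# Gas constant, kcal/(mol K)
R_KCAL <- 1.9872e-3

# Unified nearest-neighbour parameters for DNA/DNA stacks at 1 M NaCl
# (delta-H kcal/mol, delta-S cal/(mol K)), keyed by the 5'->3' top-strand
# dinucleotide of a Watson-Crick stack; the table is closed under taking the
# reverse complement of the key, so either strand may be read as "top".
nn_stack_table <- function() {
  key <- c("AA", "AT", "TA", "CA", "GT", "CT", "GA", "CG", "GC", "GG")
  dh <- c(-7.9, -7.2, -7.2, -8.5, -8.4, -7.8, -8.2, -10.6, -9.8, -8.0)
  ds <- c(-22.2, -20.4, -21.3, -22.7, -22.4, -21.0, -22.2, -27.2, -24.4, -19.9)
  tab <- data.frame(key = key, dh = dh, ds = ds, stringsAsFactors = FALSE)
  # expand to all 16 dinucleotides via reverse-complement symmetry
  full <- rbind(tab, data.frame(key = reverse_complement(tab$key),
                                dh = tab$dh, ds = tab$ds))
  full <- full[!duplicated(full$key), ]
  full[order(full$key), ]
}

# 16-vectors indexed by 4*code(first) + code(second), code A=0 C=1 G=2 T=3.
nn_vectors <- function() {
  tab <- nn_stack_table()
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  idx <- 4L * code[substr(tab$key, 1, 1)] + code[substr(tab$key, 2, 2)] + 1L
  dh <- numeric(16); ds <- numeric(16)
  dh[idx] <- tab$dh; ds[idx] <- tab$ds
  list(dh = dh, ds = ds)
}

# Duplex initiation terms per terminal pair and the helix-break penalty
# (applied to delta-H so the destabilisation is temperature-independent
# on the free-energy scale).
NN_INIT <- list(at_dh = 2.3, at_ds = 4.1, gc_dh = 0.1, gc_ds = -2.8,
                sym_ds = -1.4, break_dh = 0.5)

#' Nearest-neighbour duplex energetics
#'
#' Aligns strand `a` against the reverse complement of strand `b` with the
#' semi-global affine-gap aligner and scores consecutive Watson-Crick pairs
#' as nearest-neighbour stacks (unified DNA parameters at 1 M NaCl), plus
#' duplex initiation terms at the terminal pairs and a fixed destabilisation
#' of `+0.5` kcal/mol per helix interruption. A salt correction
#' `0.368 (n_pairs - 1) ln[Na+]` cal/(mol K) is applied to the entropy.
#'
#' @param a,b character vectors of DNA sequences (recycled pairwise).
#' @param cond a [thermo_conditions()].
#' @param params an [alignment_params()] used for the annealing alignment.
#' @return a data.frame with columns `delta_H` (kcal/mol), `delta_S`
#'   (cal/(mol K)), `delta_G_at_T` (kcal/mol), `K_eq` (1/M), `n_pairs`,
#'   `n_helices`, `max_helix`, `alignment_score`.
#' @export
duplex_energy <- function(a, b, cond = thermo_conditions(),
                          params = alignment_params()) {
  a <- dna(a); b <- dna(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  # canonical orientation: the duplex of (a, b) is physically the duplex of
  # (b, a) and of (rc(b), rc(a)); optimal alignments can differ between
  # orientations through tie-breaking, so the energy is computed on the
  # lexicographically smallest representative, making the model exactly
  # symmetric under strand swap and joint reverse complement
  rca <- reverse_complement(a); rcb <- reverse_complement(b)
  variants <- cbind(paste(a, b), paste(b, a), paste(rca, rcb), paste(rcb, rca))
  pick <- max.col(-matrix(rank(variants), n, 4L), ties.method = "first")
  first <- function(v1, v2, v3, v4, k) {
    out <- v1; out[k == 2L] <- v2[k == 2L]
    out[k == 3L] <- v3[k == 3L]; out[k == 4L] <- v4[k == 4L]
    out
  }
  a_c <- first(a, b, rca, rcb, pick)
  b_c <- first(b, a, rcb, rca, pick)
  nn <- nn_vectors()
  res <- cpp_duplex_hs_batch(a_c, reverse_complement(b_c), nn$dh, nn$ds,
                             NN_INIT$at_dh, NN_INIT$at_ds,
                             NN_INIT$gc_dh, NN_INIT$gc_ds,
                             NN_INIT$break_dh,
                             params$match, params$mismatch,
                             params$gap_open, params$gap_extend)
  dh <- res$delta_H
  ds <- res$delta_S + 0.368 * pmax(res$n_pairs - 1, 0) * log(cond$sodium_molar)
  ds <- ds + ifelse(a == b, NN_INIT$sym_ds, 0)
  tk <- cond$temperature_celsius + 273.15
  dg <- dh - tk * ds / 1000
  k <- ifelse(res$n_pairs == 0, 0, exp(-dg / (R_KCAL * tk)))
  data.frame(delta_H = dh, delta_S = ds, delta_G_at_T = dg, K_eq = k,
             n_pairs = res$n_pairs, n_helices = res$n_helices,
             max_helix = res$max_helix, alignment_score = res$alignment_score)
}

# Stable small root of K x^2 - (K (a0 + b0) + 1) x + K a0 b0 = 0
# (heterodimer A + B <-> AB with K = x / ((a0 - x)(b0 - x))).
hetero_duplex_conc <- function(K, a0, b0) {
  s <- K * (a0 + b0) + 1
  disc <- s * s - 4 * K * K * a0 * b0
  2 * K * a0 * b0 / (s + sqrt(pmax(disc, 0)))
}

# Stable small root of 4 K x^2 - (4 K a0 + 1) x + K a0^2 = 0
# (homodimer 2A <-> A2 with K = x / (a0 - 2 x)^2).
homo_duplex_conc <- function(K, a0) {
  s <- 4 * K * a0 + 1
  disc <- s * s - 16 * K * K * a0 * a0
  2 * K * a0 * a0 / (s + sqrt(pmax(disc, 0)))
}

#' Builtin two-state equilibrium yield
#'
#' The package's self-contained ground-truth engine: a two-state
#' nearest-neighbour model in which a single duplex species is in equilibrium
#' with the two monomers. The duplex free energy comes from
#' [duplex_energy()]; the equilibrium duplex concentration is the closed-form
#' root of the mass-action quadratic (with a `-1.4` cal/(mol K) symmetry
#' entropy correction and factor-2 stoichiometry when `a == b`). Yield is the
#' duplex concentration divided by the initial single-strand concentration,
#' clamped to `[0, 1]`. This is an approximation, not a NUPACK replacement:
#' cross-backend agreement is reported, never asserted.
#'
#' @inheritParams duplex_energy
#' @return a data.frame with columns `yield_fraction`, `duplex_concentration`,
#'   `monomer_a`, `monomer_b`, `delta_G_at_T`, `K_eq`, `backend`.
#' @export
builtin_yield <- function(a, b, cond = thermo_conditions(),
                          params = alignment_params()) {
  en <- duplex_energy(a, b, cond, params)
  a <- dna(a); b <- dna(b)
  n <- nrow(en)
  a <- rep_len(a, n); b <- rep_len(b, n)
  c0 <- cond$initial_concentration
  homo <- a == b
  x <- ifelse(homo, homo_duplex_conc(en$K_eq, c0),
              hetero_duplex_conc(en$K_eq, c0, c0))
  mono_a <- ifelse(homo, c0 - 2 * x, c0 - x)
  mono_b <- ifelse(homo, mono_a, c0 - x)
  data.frame(yield_fraction = pmin(pmax(x / c0, 0), 1),
             duplex_concentration = x,
             monomer_a = mono_a, monomer_b = mono_b,
             delta_G_at_T = en$delta_G_at_T, K_eq = en$K_eq,
             backend = "builtin", stringsAsFactors = FALSE)
}

#' Equilibrium yield via a pluggable backend
#'
#' @inheritParams duplex_energy
#' @param backend `"builtin"` (default) or `"nupack"`.
#' @export
compute_yield <- function(a, b, cond = thermo_conditions(),
                          backend = c("builtin", "nupack"),
                          params = alignment_params()) {
  backend <- match.arg(backend)
  if (backend == "builtin") builtin_yield(a, b, cond, params)
  else nupack_yield(a, b, cond)
}

#' Yield across a temperature profile
#'
#' @inheritParams compute_yield
#' @param temps numeric vector of temperatures (Celsius), non-empty.
#' @return a data.frame with one row per temperature (column `temperature`
#'   prepended to the yield columns).
#' @export
yield_profile <- function(a, b, temps = DEFAULT_TEMPERATURES,
                          backend = c("builtin", "nupack"),
                          initial_concentration = 1e-6,
                          sodium_molar = 1.0) {
  backend <- match.arg(backend)
  if (length(temps) == 0) stop("temperature list must be non-empty")
  out <- lapply(temps, function(tt) {
    cond <- thermo_conditions(tt, initial_concentration, sodium_molar)
    compute_yield(a, b, cond, backend)
  })
  cbind(temperature = rep(temps, each = nrow(out[[1]])), do.call(rbind, out))
}
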