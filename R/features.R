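#' Alignment parameters
#'
#' Semi-global (free-end-gap) affine alignment parameters. Defaults follow
#' the standard DNA full matrix (match +5, mismatch -4) with gap open 5 and
#' gap extend 2; a gap of length L costs `open + (L - 1) * extend`.
#'
#' @param match match score.
#' @param mismatch mismatch score.
#' @param gap_open penalty for the first gapped position (>= 0).
#' @param gap_extend penalty per additional gapped position (>= 0).
#' @return an `alignment_params` list.
#' @export
alignment_params <- function(match = 5, mismatch = -4,
                             gap_open = 5, gap_extend = 2) {
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

#' Semi-global affine-gap alignment
#'
#' Pairwise overlap alignment: end gaps are free on both ends of both
#' sequences, internal gaps pay affine penalties. Vectorised over pairs when
#' `traceback = FALSE`.
#'
#' @param a,b character vectors of DNA sequences (recycled pairwise).
#' @param params an [alignment_params()].
#' @param traceback if `TRUE` (single pair only), also return the aligned
#'   strings with `-` gap characters.
#' @return numeric score vector, or (with traceback) a list with `score`,
#'   `aligned_a`, `aligned_b`.
#' @export
#' @examples
#' semi_global_align("ACGT", "ACGT") # 4 matches at +5 each
semi_global_align <- function(a, b, params = alignment_params(),
                              traceback = FALSE) {
  a <- dna(a); b <- dna(b)
  if (traceback) {
    if (length(a) != 1L || length(b) != 1L)
      stop("traceback is available for a single pair only")
    return(cpp_sg_align_one(a, b, params$match, params$mismatch,
                            params$gap_open, params$gap_extend))
  }
  n <- max(length(a), length(b))
  cpp_sg_align_scores(rep_len(a, n), rep_len(b, n),
                      params$match, params$mismatch,
                      params$gap_open, params$gap_extend)
}

#' Alignment score as an annealing proxy
#'
#' Aligns `a` against the reverse complement of `b`: a high score means the
#' two strands are near-complementary and expected to anneal. Symmetric in
#' `(a, b)`.
#'
#' @inheritParams semi_global_align
#' @return numeric score vector.
#' @export
align_for_annealing <- function(a, b, params = alignment_params()) {
  semi_global_align(a, reverse_complement(dna(b)), params)
}

# Loop penalty tables (kcal/mol at 37 C) for the builtin hairpin-folding
# model; sizes beyond the table extrapolate with the Jacobson-Stockmayer
# term 1.75 R T ln(size / last_tabulated). Loop terms are treated as purely
# entropic so they scale with temperature.
loop_dg37 <- function() {
  list(
    hairpin = c(NA, NA, 3.5, 3.5, 3.3, 4.0, 4.4, 4.6, 4.7, 4.9),
    bulge = c(4.0, 2.9, 3.1, 3.2, 3.3, 3.5, 3.7, 3.9, 4.1, 4.3),
    iloop = c(NA, 3.2, 3.6, 4.0, 4.4, 4.6, 4.8, 4.9, 5.0, 5.1)
  )
}

loop_dg_at <- function(tab, tk, max_size = 30) {
  out <- numeric(max_size)
  n0 <- length(tab)
  for (s in seq_len(max_size)) {
    g37 <- if (s <= n0) tab[s]
           else tab[n0] + 1.75 * R_KCAL * 310.15 * log(s / n0)
    if (is.na(g37)) g37 <- 1e9 # disallowed size
    # purely entropic: dG(T) = T/310.15 * dG37
    out[s] <- if (g37 >= 1e8) g37 else g37 * tk / 310.15
  }
  out
}

#' Single-strand folding minimum free energy
#'
#' Builtin approximate hairpin-folding MFE: a Zuker-style dynamic programme
#' over Watson-Crick pairs with nearest-neighbour stack energies and
#' hairpin/bulge/internal-loop penalties (loops treated as entropic;
#' minimum hairpin loop 3). A low MFE signals self-structure that competes
#' with hybridisation.
#'
#' @param seq character vector of DNA sequences.
#' @param temperature_celsius fold temperature.
#' @return numeric vector of MFE values (kcal/mol, `<= 0`).
#' @export
fold_mfe <- function(seq, temperature_celsius = 57) {
  seq <- dna(seq)
  tk <- temperature_celsius + 273.15
  nn <- nn_vectors()
  stack_dg <- nn$dh - tk * nn$ds / 1000
  loops <- loop_dg37()
  hp <- loop_dg_at(loops$hairpin, tk)
  bu <- loop_dg_at(loops$bulge, tk)
  il <- loop_dg_at(loops$iloop, tk)
  vapply(seq, function(s) cpp_hairpin_mfe(s, stack_dg, hp, bu, il),
         numeric(1), USE.NAMES = FALSE)
}

#' Extract the nine baseline features of a sequence pair
#'
#' For each pair: the annealing alignment score, then per sequence the
#' folding MFE, the equilibrium single-stranded monomer concentration and
#' homodimer concentration from a size-2 self-complex analysis at the
#' initial concentration, and the GC content percentage. Exactly nine
#' features.
#'
#' @param a,b character vectors of DNA sequences (recycled pairwise).
#' @param cond a [thermo_conditions()] for the thermodynamic features.
#' @param params an [alignment_params()].
#' @param backend `"builtin"` or `"nupack"` self-complex engine.
#' @return data.frame with columns `alignment_score`, `mfe_a`, `mfe_b`,
#'   `ss_conc_a`, `ss_conc_b`, `homodimer_conc_a`, `homodimer_conc_b`,
#'   `gc_a`, `gc_b`.
#' @export
extract_features <- function(a, b, cond = thermo_conditions(),
                             params = alignment_params(),
                             backend = "builtin") {
  a <- dna(a); b <- dna(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  score <- align_for_annealing(a, b, params)
  tt <- cond$temperature_celsius
  uniq <- unique(c(a, b))
  mfe_u <- fold_mfe(uniq, tt)
  self_u <- compute_yield_many_self(uniq, cond, backend, params)
  idx_a <- match(a, uniq); idx_b <- match(b, uniq)
  data.frame(alignment_score = score,
             mfe_a = mfe_u[idx_a], mfe_b = mfe_u[idx_b],
             ss_conc_a = self_u$monomer_a[idx_a],
             ss_conc_b = self_u$monomer_a[idx_b],
             homodimer_conc_a = self_u$duplex_concentration[idx_a],
             homodimer_conc_b = self_u$duplex_concentration[idx_b],
             gc_a = gc_percent(a), gc_b = gc_percent(b))
}

# self-complex (homodimer) analysis for a set of unique sequences
compute_yield_many_self <- function(seqs, cond, backend, params) {
  if (backend == "builtin") {
    builtin_yield(seqs, seqs, cond, params)
  } else {
    do.call(rbind, lapply(seqs, function(s) nupack_yield(s, s, cond)))
  }
}

#' Fit the four classical baseline classifiers
#'
#' Trains linear discriminant analysis, quadratic discriminant analysis, a
#' random forest and a single-hidden-layer neural network on a feature table
#' against the Low/High labels, using off-the-shelf implementations (MASS,
#' randomForest, nnet), and scores each with [classification_report()] on
#' held-out data.
#'
#' @param features data.frame of numeric features (training rows).
#' @param labels factor/character labels with levels Low/High.
#' @param test_features,test_labels evaluation set (defaults to training
#'   data when omitted).
#' @param algorithms subset of `c("LDA", "QDA", "RF", "NN")`.
#' @param rng_seed seed for the stochastic fitters.
#' @return named list of [classification_report()] results, one per
#'   algorithm, each with a `fit` attribute.
#' @export
fit_baselines <- function(features, labels,
                          test_features = features, test_labels = labels,
                          algorithms = c("LDA", "QDA", "RF", "NN"),
                          rng_seed = 1L) {
  algorithms <- match.arg(algorithms, c("LDA", "QDA", "RF", "NN"),
                          several.ok = TRUE)
  labels <- factor(labels, levels = c("Low", "High"))
  test_labels <- factor(test_labels, levels = c("Low", "High"))
  if (nlevels(droplevels(labels)) < 2L)
    stop("baseline training needs both Low and High labels present")
  features <- as.data.frame(features)
  test_features <- as.data.frame(test_features)
  # z-score on training statistics: the concentration features live on a
  # 1e-6 molar scale and would otherwise trip the discriminants' constant-
  # variable guards; zero-variance columns are dropped
  mu <- vapply(features, mean, numeric(1))
  sdv <- vapply(features, sd, numeric(1))
  keep <- which(sdv > 0)
  if (length(keep) == 0L) stop("all features are constant")
  scale_to <- function(df) {
    as.data.frame(Map(function(x, m, s) (x - m) / s,
                      df[keep], mu[keep], sdv[keep]))
  }
  features <- scale_to(features)
  test_features <- scale_to(test_features)
  # rank-revealing guard: the self-complex features are exactly collinear
  # by mass balance (monomer + 2 x homodimer = c0), which the discriminant
  # fits cannot tolerate; redundant columns are dropped via pivoted QR
  qx <- qr(as.matrix(features))
  if (qx$rank < ncol(features)) {
    piv <- qx$pivot[seq_len(qx$rank)]
    features <- features[, piv, drop = FALSE]
    test_features <- test_features[, piv, drop = FALSE]
  }
  set.seed(rng_seed)
  out <- list()
  prob_high <- function(fit, newdata, kind) {
    switch(kind,
      lda = , qda = predict(fit, newdata)$posterior[, "High"],
      rf = predict(fit, newdata, type = "prob")[, "High"],
      nn = as.numeric(predict(fit, newdata, type = "raw")))
  }
  for (alg in algorithms) {
    fit <- switch(alg,
      LDA = MASS::lda(features, grouping = labels),
      QDA = MASS::qda(features, grouping = labels),
      RF = randomForest::randomForest(features, y = labels, ntree = 200),
      NN = nnet::nnet(features, class.ind(labels)[, "High", drop = FALSE],
                      size = 16, decay = 1e-4, maxit = 200,
                      trace = FALSE, entropy = TRUE))
    kind <- switch(alg, LDA = "lda", QDA = "qda", RF = "rf", NN = "nn")
    p <- prob_high(fit, test_features, kind)
    rep <- classification_report(test_labels, p, threshold = 0.5)
    attr(rep, "fit") <- fit
    out[[alg]] <- rep
  }
  out
}

# one-hot class indicator (avoids depending on nnet's internal helper name)
class.ind <- function(f) {
  f <- factor(f)
  m <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}
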