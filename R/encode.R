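BASES <- c("A", "C", "G", "T")

#' Token vocabulary for the sequence-pair encoding
#'
#' Fixed map: the four bases, the begin marker `<b>`, the separator `<s>`
#' (also used as the terminator) and the padding token `<pad>`.
#' @export
TOKEN_VOCAB <- c(A = 1L, C = 2L, G = 3L, T = 4L,
                 `<b>` = 5L, `<s>` = 6L, `<pad>` = 7L)

#' One-hot image encoding of a sequence pair
#'
#' Encodes a pair as a 4 x n_max x 2 grid (height x width x channels):
#' channel 1 holds sequence A, channel 2 sequence B; each occupied column is
#' the one-hot encoding of that position's base in fixed row order A, C, G,
#' T; sequences are left-aligned and unused columns are all-zero.
#'
#' @param a,b DNA sequences (single pair).
#' @param n_max maximum sequence length (default 26).
#' @return numeric array of dim `c(4, n_max, 2)`.
#' @export
encode_image <- function(a, b, n_max = 26L) {
  a <- dna(a); b <- dna(b)
  if (nchar(a) > n_max || nchar(b) > n_max)
    stop(sprintf("sequence longer than n_max = %d", n_max))
  enc <- array(0, dim = c(4L, n_max, 2L))
  for (ch in 1:2) {
    s <- if (ch == 1L) a else b
    rows <- match(strsplit(s, "")[[1]], BASES)
    enc[cbind(rows, seq_along(rows), ch)] <- 1
  }
  enc
}

#' Decode a one-hot image back to the sequence pair
#'
#' @param enc an array produced by [encode_image()].
#' @return character vector `c(a, b)`.
#' @export
decode_image <- function(enc) {
  stopifnot(length(dim(enc)) == 3L, dim(enc)[1] == 4L, dim(enc)[3] == 2L)
  out <- character(2)
  for (ch in 1:2) {
    cols <- which(colSums(enc[, , ch]) > 0)
    rows <- apply(enc[, cols, ch, drop = FALSE], 2, which.max)
    out[ch] <- paste0(BASES[rows], collapse = "")
  }
  out
}

#' Encode a batch of pairs as a flattened image matrix
#'
#' Row-per-pair layout used by the convolutional models: each row is the
#' flattened `4 * n_max * 2` image with index `((channel-1) * n_max +
#' (column-1)) * 4 + row`.
#'
#' @param a,b character vectors of DNA sequences.
#' @param n_max maximum sequence length.
#' @return numeric matrix, `length(a)` rows.
#' @export
encode_image_batch <- function(a, b, n_max = 26L) {
  a <- dna(a); b <- dna(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(nchar(a) > n_max) || any(nchar(b) > n_max))
    stop(sprintf("sequence longer than n_max = %d", n_max))
  X <- matrix(0, n, 4L * n_max * 2L)
  fill <- function(seqs, ch) {
    sp <- strsplit(seqs, "")
    rows <- match(unlist(sp), BASES)
    cols <- unlist(lapply(sp, seq_along))
    pair <- rep(seq_len(n), nchar(seqs))
    j <- ((ch - 1L) * n_max + (cols - 1L)) * 4L + rows
    X[cbind(pair, j)] <<- 1
  }
  fill(a, 1L); fill(b, 2L)
  X
}

#' Token encoding of a sequence pair
#'
#' Concatenates the pair as `<b>, a..., <s>, b..., <s>`: the separator also
#' marks the end of the encoded pair. Indices follow [TOKEN_VOCAB].
#'
#' @param a,b DNA sequences (single pair).
#' @return integer vector of token indices.
#' @export
#' @examples
#' encode_tokens("ACG", "TT")
encode_tokens <- function(a, b) {
  a <- dna(a); b <- dna(b)
  unname(TOKEN_VOCAB[c("<b>", strsplit(a, "")[[1]], "<s>",
                       strsplit(b, "")[[1]], "<s>")])
}

#' Decode a token vector back to the sequence pair
#'
#' @param tokens integer token indices (padding tokens are ignored).
#' @return character vector `c(a, b)`.
#' @export
decode_tokens <- function(tokens) {
  tokens <- tokens[tokens != TOKEN_VOCAB["<pad>"]]
  if (tokens[1] != TOKEN_VOCAB["<b>"]) stop("token stream must start with <b>")
  sep <- which(tokens == TOKEN_VOCAB["<s>"])
  if (length(sep) != 2L || sep[2] != length(tokens))
    stop("token stream must contain exactly two separators, the last at the end")
  inv <- names(TOKEN_VOCAB)
  c(paste0(inv[tokens[seq(2L, sep[1] - 1L)]], collapse = ""),
    paste0(inv[tokens[seq(sep[1] + 1L, sep[2] - 1L)]], collapse = ""))
}

#' Encode a batch of pairs as a padded token matrix
#'
#' @param a,b character vectors of DNA sequences.
#' @param length_to optional fixed width; defaults to the longest encoding
#'   in the batch. Shorter encodings are right-padded with `<pad>`.
#' @return integer matrix, one row per pair.
#' @export
encode_token_batch <- function(a, b, length_to = NULL) {
  a <- dna(a); b <- dna(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  toks <- mapply(encode_tokens, a, b, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  L <- length_to %||% max(lengths(toks))
  if (any(lengths(toks) > L)) stop("encoding longer than length_to")
  out <- matrix(TOKEN_VOCAB[["<pad>"]], n, L)
  for (i in seq_len(n)) out[i, seq_along(toks[[i]])] <- toks[[i]]
  out
}
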