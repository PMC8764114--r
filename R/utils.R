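# Internal helpers shared across modules: the 20-letter amino-acid alphabet,
# integer encoding of alignments, and sparse one-hot expansions used to
# vectorize pair-frequency and Hamming computations.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
N_AA <- 20L
GAP <- "-"
# Ambiguity/nonstandard codes collapsed to gap so every downstream sum runs
# over exactly 20 states.
NONSTANDARD_AA <- c("B", "Z", "X", "U", "O", "J", "*")

#' @noRd
encode_msa <- function(msa) {
  enc <- match(msa$residues, AA_ALPHABET)
  if (anyNA(enc)) {
    bad <- unique(as.vector(msa$residues)[is.na(enc)])
    stop("alignment contains symbols outside the 20-letter alphabet: ",
         paste(bad, collapse = ", "),
         " (run preprocess_msa() first)", call. = FALSE)
  }
  matrix(enc, nrow = nrow(msa$residues))
}

# N x (20p) sparse indicator: entry (s, 20*(i-1)+k) = 1 iff sequence s has
# amino acid k at column i. crossprod() of this gives all pair counts at once.
#' @noRd
onehot_encoded <- function(enc) {
  n <- nrow(enc)
  p <- ncol(enc)
  j <- as.vector(sweep(enc, 2, (seq_len(p) - 1L) * N_AA, "+"))
  Matrix::sparseMatrix(i = rep.int(seq_len(n), p), j = j, x = 1,
                       dims = c(n, N_AA * p))
}

# (20p) x p block-membership indicator: column i groups the 20 states of
# alignment column i. Used to block-sum 20p x 20p count matrices into p x p.
#' @noRd
block_indicator <- function(p) {
  Matrix::sparseMatrix(i = seq_len(N_AA * p),
                       j = rep(seq_len(p), each = N_AA),
                       x = 1, dims = c(N_AA * p, p))
}

# sum over x of x*log(x) with 0*log(0) := 0, elementwise on a matrix
#' @noRd
xlogx <- function(x) {
  out <- x
  nz <- x > 0
  out[nz] <- x[nz] * log(x[nz])
  out
}

#' @noRd
check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  as.integer(seed)
}

# Per-call child seeds derived from a root seed via a counter, so bootstrap
# replicates are reproducible independently of evaluation order.
#' @noRd
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 7919 + counter * 104729) %% 2147483647)
}

#' @noRd
upper_tri_values <- function(m) m[upper.tri(m)]
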