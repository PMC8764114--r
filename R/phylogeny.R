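# phylogeny: Jukes-Cantor pairwise distances on amino-acid alignments and
# single-linkage clade partitions at a distance cutoff.

# Protein-alphabet (20-state) Jukes-Cantor correction of a mismatch fraction.
# Saturated pairs (p >= 19/20) are capped at JC_SATURATION_CAP.
JC_SATURATION_CAP <- 10

#' @noRd
jc_from_mismatch <- function(p_mismatch) {
  out <- numeric(length(p_mismatch))
  sat <- p_mismatch >= 19 / 20
  out[!sat] <- -(19 / 20) * log(1 - (20 / 19) * p_mismatch[!sat])
  out[sat] <- JC_SATURATION_CAP
  out
}

#' Jukes-Cantor distance matrix
#'
#' Pairwise distances `d = -(19/20) * log(1 - (20/19) * p)` where `p` is the
#' mismatch fraction over compared columns, using the 20-state generalization
#' of the Jukes-Cantor model for amino acids. On gapped alignments each pair
#' is compared over the columns where both sequences are ungapped; pairs with
#' no shared ungapped column get distance `Inf`. Saturated pairs
#' (`p >= 19/20`) are capped at 10 with a warning.
#'
#' @param msa An [new_msa()] object.
#' @param columns Optional integer vector restricting the comparison to a
#'   subset of alignment columns (used by MirrorTree filtering).
#' @return A symmetric N x N matrix of class `jc_dist` with zero diagonal and
#'   sequence ids as dimnames.
#' @export
jc_distance <- function(msa, columns = NULL) {
  stopifnot(inherits(msa, "msa"))
  res <- msa$residues
  if (!is.null(columns)) {
    stopifnot(all(columns >= 1L), all(columns <= ncol(res)))
    res <- res[, columns, drop = FALSE]
  }
  n <- nrow(res)
  p <- ncol(res)
  has_gap <- any(res == GAP)
  if (!has_gap) {
    enc <- match(res, AA_ALPHABET)
    if (anyNA(enc)) stop("unknown residue symbols; run preprocess_msa()",
                         call. = FALSE)
    enc <- matrix(enc, nrow = n)
    X <- onehot_encoded(enc)
    matches <- as.matrix(Matrix::tcrossprod(X))
    pm <- 1 - matches / p
  } else {
    ok <- res != GAP
    OK <- Matrix::Matrix(ok * 1, sparse = TRUE)
    shared <- as.matrix(Matrix::tcrossprod(OK))
    enc <- match(res, AA_ALPHABET)
    enc[is.na(enc)] <- 0L  # gaps encode as 0 -> excluded from one-hot
    enc <- matrix(enc, nrow = n)
    j <- as.vector(sweep(enc, 2, (seq_len(p) - 1L) * N_AA, "+"))
    sel <- as.vector(enc) > 0L
    X <- Matrix::sparseMatrix(i = rep.int(seq_len(n), p)[sel], j = j[sel],
                              x = 1, dims = c(n, N_AA * p))
    matches <- as.matrix(Matrix::tcrossprod(X))
    pm <- 1 - matches / shared
    pm[shared == 0] <- NA  # no comparable columns
  }
  sat <- pm >= 19 / 20
  sat[is.na(sat)] <- FALSE
  d <- matrix(0, n, n)
  d[!sat & !is.na(pm)] <- -(19 / 20) * log(1 - (20 / 19) * pm[!sat & !is.na(pm)])
  if (any(sat[upper.tri(sat)])) {
    warning(sum(sat[upper.tri(sat)]),
            " saturated sequence pairs capped at distance ", JC_SATURATION_CAP)
    d[sat] <- JC_SATURATION_CAP
  }
  d[is.na(pm)] <- Inf
  diag(d) <- 0
  dimnames(d) <- list(msa$ids, msa$ids)
  class(d) <- c("jc_dist", class(d))
  d
}

#' Partition sequences into clades at a distance cutoff
#'
#' Clades are the connected components of the graph with an edge between two
#' sequences iff their Jukes-Cantor distance is strictly below `d`
#' (single linkage). Labels are deterministic: the component containing the
#' lowest row index gets label 1, and so on.
#'
#' @param dm A distance matrix from [jc_distance()] (any symmetric numeric
#'   matrix with zero diagonal is accepted).
#' @param d Positive distance cutoff.
#' @return An object of class `clade_partition` with fields `cutoff_d`,
#'   `labels` (integer per sequence), `clade_sizes` and `n_clades`.
#' @export
partition_clades <- function(dm, d) {
  dm <- unclass(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (!is.numeric(d) || length(d) != 1L || d <= 0) {
    stop("cutoff d must be a single positive number", call. = FALSE)
  }
  n <- nrow(dm)
  # union-find over edges dm < d
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- which(dm < d & upper.tri(dm), arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, sort(unique(roots)))  # lowest member index -> label 1
  sizes <- tabulate(labels)
  structure(list(cutoff_d = d, labels = labels, clade_sizes = sizes,
                 n_clades = length(sizes), ids = rownames(dm)),
            class = "clade_partition")
}

#' @export
print.clade_partition <- function(x, ...) {
  cat(sprintf("<clade_partition> cutoff d = %g: %d clades over %d sequences\n",
              x$cutoff_d, x$n_clades, length(x$labels)))
  cat("clade sizes:", paste(x$clade_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Write a distance matrix as delimited text
#'
#' @param dm Matrix from [jc_distance()].
#' @param path Output TSV path (ids in header row and first column).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  utils::write.table(as.data.frame(unclass(dm)), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
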