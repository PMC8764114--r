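# covariation: per-column entropies, normalized mutual information, and the
# average product correction. All entropies are in nats.

#' Construct a covariation matrix object
#'
#' @param values Symmetric p x p numeric matrix.
#' @param metric One of `"nmi"`, `"di"`, `"frobenius"`.
#' @param corrections Ordered character vector of corrections applied, drawn
#'   from `"apc"` and `"nc@<d>"`.
#' @return The matrix with class `covariation_matrix` and metadata attributes.
#' @export
new_covariation_matrix <- function(values, metric, corrections = character()) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-8) {
    stop("covariation matrix must be symmetric", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  structure(values, metric = metric, corrections = corrections,
            class = c("covariation_matrix", "matrix", "array"))
}

#' @export
print.covariation_matrix <- function(x, ...) {
  corr <- attr(x, "corrections")
  cat(sprintf("<covariation_matrix> %d x %d, metric %s%s\n",
              nrow(x), ncol(x), attr(x, "metric"),
              if (length(corr)) paste0(", corrections: ",
                                       paste(corr, collapse = " -> "))
              else ""))
  invisible(x)
}

# Per-column and all-pairs joint entropies via one sparse crossprod.
# Returns list(H = per-column entropy, Hij = p x p joint entropy matrix).
#' @noRd
entropy_tables <- function(enc) {
  n <- nrow(enc)
  p <- ncol(enc)
  X <- onehot_encoded(enc)
  counts <- as.matrix(Matrix::crossprod(X))       # 20p x 20p pair counts
  G <- block_indicator(p)
  S <- as.matrix(Matrix::t(G) %*% xlogx(counts) %*% G)  # sum n*log(n) per block
  Hij <- log(n) - S / n
  marg <- Matrix::colSums(X)                      # 20p marginal counts
  Hi <- log(n) - as.vector(Matrix::t(G) %*% xlogx(marg)) / n
  Hi <- pmax(Hi, 0)
  Hij <- pmax(Hij, 0)
  diag(Hij) <- Hi
  list(H = Hi, Hij = Hij)
}

#' Per-column Shannon entropy
#'
#' Natural-log entropies of the empirical (unweighted) residue frequencies at
#' each alignment column; zero iff the column is constant.
#'
#' @param msa A gap-free [new_msa()] object.
#' @return Numeric vector of length p (nats), bounded by `log(20)`.
#' @export
entropy_profile <- function(msa) {
  stopifnot(inherits(msa, "msa"))
  entropy_tables(encode_msa(msa))$H
}

#' Joint Shannon entropy of two columns
#'
#' @param msa A gap-free [new_msa()] object.
#' @param i,j Column indices; `joint_entropy(msa, i, i)` equals the marginal
#'   entropy of column i.
#' @return Joint entropy in nats.
#' @export
joint_entropy <- function(msa, i, j) {
  stopifnot(inherits(msa, "msa"))
  enc <- encode_msa(msa)
  p <- ncol(enc)
  stopifnot(i >= 1L, i <= p, j >= 1L, j <= p)
  n <- nrow(enc)
  code <- if (i == j) enc[, i] else (enc[, i] - 1L) * N_AA + enc[, j]
  cnt <- tabulate(code, nbins = N_AA * N_AA)
  log(n) - sum(xlogx(cnt)) / n
}

# NMI assembled from entropy tables; pairs with zero joint entropy (both
# columns constant) are defined as 0.
#' @noRd
nmi_from_tables <- function(H, Hij) {
  MI <- outer(H, H, "+") - Hij
  MI <- pmax(MI, 0)  # clip negative rounding error
  nmi <- matrix(0, nrow(Hij), ncol(Hij))
  nz <- Hij > 0
  nmi[nz] <- MI[nz] / Hij[nz]
  pmin(pmax(nmi, 0), 1)
}

#' Normalized mutual information matrix
#'
#' Total covariation `C_T(i, j) = (H_i + H_j - H_ij) / H_ij`: mutual
#' information normalized by the joint entropy, which removes the dependence
#' of MI on per-column conservation. Values lie in \[0, 1\]; pairs where both
#' columns are constant (`H_ij = 0`) are set to 0.
#'
#' @param msa A gap-free [new_msa()] object.
#' @return A symmetric [new_covariation_matrix()] with metric `"nmi"`.
#' @export
nmi_matrix <- function(msa) {
  stopifnot(inherits(msa, "msa"))
  et <- entropy_tables(encode_msa(msa))
  new_covariation_matrix(nmi_from_tables(et$H, et$Hij), metric = "nmi")
}

#' Average product correction
#'
#' Subtracts `mean_i(C) * mean_j(C) / mean(C)` from each entry, where the row,
#' column and grand means are computed over off-diagonal entries only (the
#' diagonal is identically 1 for NMI and would bias the means). The background
#' removed by APC is the product signal attributable to the average
#' covariation each position carries.
#'
#' @param C A symmetric [new_covariation_matrix()] (or plain matrix).
#' @return The corrected matrix with `"apc"` appended to its corrections; the
#'   diagonal is set to 0.
#' @export
apc_correct <- function(C) {
  metric <- attr(C, "metric") %||% "unknown"
  corrections <- attr(C, "corrections") %||% character()
  m <- unclass(C)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  p <- nrow(m)
  off <- m
  diag(off) <- NA
  row_means <- rowMeans(off, na.rm = TRUE)
  grand <- mean(off, na.rm = TRUE)
  if (grand == 0) {
    warning("all-zero covariation matrix; APC skipped")
    return(new_covariation_matrix(m, metric, corrections))
  }
  corrected <- m - outer(row_means, row_means) / grand
  diag(corrected) <- 0
  new_covariation_matrix(corrected, metric, c(corrections, "apc"))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a covariation matrix as delimited text
#'
#' @param C Matrix from [nmi_matrix()], [mfdca()] or [nc_correct()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_covariation_matrix <- function(C, path) {
  utils::write.table(as.data.frame(unclass(C)), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
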