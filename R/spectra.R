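# sectors (part 1): eigendecomposition of the multi-cutoff supermatrix and of
# baseline covariation matrices, sector extraction from signed eigenvectors,
# sector pairing, spatial compactness, and meta-sector merging.

#' @noRd
new_eigen_spectrum <- function(values, vectors, source, cutoffs = NULL) {
  # orient each eigenvector so its maximum-|coefficient| entry is positive,
  # making sector signs reproducible across linear-algebra backends
  for (m in seq_len(ncol(vectors))) {
    v <- vectors[, m]
    if (v[which.max(abs(v))] < 0) vectors[, m] <- -v
  }
  structure(list(values = values, vectors = vectors, source = source,
                 cutoffs = cutoffs),
            class = "eigen_spectrum")
}

#' @export
print.eigen_spectrum <- function(x, ...) {
  cat(sprintf("<eigen_spectrum> %d eigenvectors of length %d (source: %s)\n",
              ncol(x$vectors), nrow(x$vectors), x$source))
  cat("top eigenvalues:",
      paste(signif(utils::head(x$values, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Eigenspectrum of the multi-cutoff nested-coevolution supermatrix
#'
#' Stacks the nested-coevolution matrices from several phylogenetic cutoffs
#' row-wise into a `(p * n_d) x p` supermatrix (optionally APC-correcting
#' each first), mean-centers its columns, and eigendecomposes the resulting
#' `p x p` population covariance — treating the `p * n_d` rows as
#' observations and the `p` columns as features. Using the supermatrix avoids committing to a
#' single cutoff. Eigenvalues are ordered descending; each eigenvector is
#' oriented so its largest-magnitude coefficient is positive.
#'
#' @param nc_results An `nc_result_set` from [nc_correct()] (or a list of
#'   `nc_result` objects / plain matrices of equal dimension).
#' @param apply_apc Apply [apc_correct()] to each matrix before stacking
#'   (default `TRUE`).
#' @return An object of class `eigen_spectrum` with fields `values`,
#'   `vectors` (p x p, one eigenvector per column), `source` and `cutoffs`.
#' @export
nc_supermatrix_spectrum <- function(nc_results, apply_apc = TRUE) {
  mats <- lapply(nc_results, function(r) {
    m <- if (inherits(r, "nc_result")) r$nc else r
    if (apply_apc) m <- apc_correct(m)
    unclass(m)
  })
  if (length(mats) == 0L) stop("need at least one NC matrix", call. = FALSE)
  p <- ncol(mats[[1L]])
  if (!all(vapply(mats, ncol, integer(1)) == p)) {
    stop("NC matrices have inconsistent dimensions", call. = FALSE)
  }
  cutoffs <- vapply(nc_results, function(r)
    if (inherits(r, "nc_result")) r$cutoff_d else NA_real_, numeric(1))
  supermatrix <- do.call(rbind, mats)
  centered <- scale(supermatrix, center = TRUE, scale = FALSE)
  # population covariance (divide by the row count, not n - 1): stacking
  # identical matrices then reproduces the single-matrix spectrum exactly
  covm <- crossprod(centered) / nrow(centered)
  eig <- eigen(covm, symmetric = TRUE)
  new_eigen_spectrum(eig$values, eig$vectors, "nc_supermatrix",
                     cutoffs = cutoffs)
}

#' Eigenspectrum of a single covariation matrix
#'
#' Direct eigendecomposition of a symmetric covariation matrix (typically
#' NMI with APC), with the same ordering and sign-orientation rules as
#' [nc_supermatrix_spectrum()]. This is the "baseline" sector source.
#'
#' @param C A symmetric [new_covariation_matrix()] or plain matrix.
#' @return An `eigen_spectrum` with source `"baseline"`.
#' @export
baseline_spectrum <- function(C) {
  m <- unclass(C)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-8) {
    stop("baseline_spectrum requires a symmetric matrix", call. = FALSE)
  }
  eig <- eigen((m + t(m)) / 2, symmetric = TRUE)
  new_eigen_spectrum(eig$values, eig$vectors, "baseline")
}

#' Extract a sector from one signed eigenvector
#'
#' The positive sector at size `size_cutoff` consists of the positions with
#' the largest coefficients of the eigenvector; the negative sector of those
#' with the most negative. Positions are ordered by descending (signed)
#' coefficient so that smaller size cutoffs are prefixes of larger ones.
#' Sectors with fewer than 4 positions are flagged `ignored` and should be
#' excluded from downstream analysis.
#'
#' @param spectrum An `eigen_spectrum`.
#' @param eig_index Which eigenvector (1 = largest eigenvalue).
#' @param sign `"positive"` or `"negative"`.
#' @param size_cutoff Number of positions in the sector.
#' @return An object of class `sector` with fields `positions` (ordered by
#'   descending |coefficient|), `coefficients` (full eigenvector, sign
#'   adjusted), `eigenvector_index`, `sign`, `size_cutoff`, `ignored`.
#' @export
extract_sector <- function(spectrum, eig_index, sign = c("positive", "negative"),
                           size_cutoff) {
  stopifnot(inherits(spectrum, "eigen_spectrum"))
  sign <- match.arg(sign)
  p <- nrow(spectrum$vectors)
  if (size_cutoff > p) stop("size_cutoff exceeds the number of positions",
                            call. = FALSE)
  if (size_cutoff < 1L) stop("size_cutoff must be >= 1", call. = FALSE)
  v <- spectrum$vectors[, eig_index]
  signed <- if (sign == "positive") v else -v
  positions <- order(-signed, seq_len(p))[seq_len(size_cutoff)]
  structure(list(positions = positions,
                 coefficients = signed,
                 eigenvector_index = as.integer(eig_index),
                 sign = sign,
                 size_cutoff = as.integer(size_cutoff),
                 ignored = size_cutoff < 4L,
                 source = spectrum$source),
            class = "sector")
}

#' @export
print.sector <- function(x, ...) {
  cat(sprintf("<sector> eigenvector %d (%s), %d positions%s: %s\n",
              x$eigenvector_index, x$sign, x$size_cutoff,
              if (x$ignored) " [ignored: < 4 residues]" else "",
              paste(x$positions, collapse = ", ")))
  invisible(x)
}

#' Extract the dominant signed sector of an eigenvector
#'
#' Each eigenvector defines two candidate sectors (most positive and most
#' negative coefficients). This helper returns the side that forms the more
#' coherent block of large coefficients: the one whose `size_cutoff`-th
#' ranked coefficient has the larger magnitude. Useful when only one side of
#' an eigenvector carries sector signal and the other is diffuse background.
#'
#' @inheritParams extract_sector
#' @return A `sector` (see [extract_sector()]).
#' @export
dominant_sector <- function(spectrum, eig_index, size_cutoff) {
  pos <- extract_sector(spectrum, eig_index, "positive", size_cutoff)
  neg <- extract_sector(spectrum, eig_index, "negative", size_cutoff)
  tail_mag <- function(s) abs(s$coefficients[s$positions[s$size_cutoff]])
  if (tail_mag(pos) >= tail_mag(neg)) pos else neg
}

#' Pair eigenvectors of two spectra
#'
#' Matches eigenvectors whose absolute dot product exceeds `min_dot`
#' (default 0.6), greedily, one-to-one, in order of descending |dot|. An
#' empty result means no counterpart exists above the threshold.
#'
#' @param nc_spec,base_spec Two `eigen_spectrum` objects over the same
#'   positions.
#' @param min_dot Minimum |dot product| for a pair (default 0.6).
#' @param max_rank Only the first `max_rank` eigenvectors of each spectrum
#'   are considered (default: all).
#' @return Data frame with columns `nc_index`, `base_index`, `dot`.
#' @export
pair_sectors <- function(nc_spec, base_spec, min_dot = 0.6, max_rank = NULL) {
  stopifnot(inherits(nc_spec, "eigen_spectrum"),
            inherits(base_spec, "eigen_spectrum"),
            nrow(nc_spec$vectors) == nrow(base_spec$vectors))
  V1 <- nc_spec$vectors
  V2 <- base_spec$vectors
  if (!is.null(max_rank)) {
    V1 <- V1[, seq_len(min(max_rank, ncol(V1))), drop = FALSE]
    V2 <- V2[, seq_len(min(max_rank, ncol(V2))), drop = FALSE]
  }
  dots <- crossprod(V1, V2)
  cand <- which(abs(dots) > min_dot, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(data.frame(nc_index = integer(), base_index = integer(),
                      dot = numeric()))
  }
  cand <- cand[order(-abs(dots[cand])), , drop = FALSE]
  used1 <- logical(ncol(V1))
  used2 <- logical(ncol(V2))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    a <- cand[r, 1L]; b <- cand[r, 2L]
    if (!used1[a] && !used2[b]) {
      keep[r] <- TRUE
      used1[a] <- TRUE
      used2[b] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(nc_index = cand[, 1L], base_index = cand[, 2L],
             dot = dots[cand])
}

#' Spatial compactness of a group of positions
#'
#' Mean over all unordered pairs of alpha-carbon Euclidean distances; lower
#' values mean a more spatially contiguous group on the structure.
#'
#' @param sector A `sector` object or an integer vector of MSA columns.
#' @param coords A [new_structure_coords()] object mapping every position.
#' @return Mean pairwise CA-CA distance in Angstrom.
#' @export
spatial_compactness <- function(sector, coords) {
  positions <- if (inherits(sector, "sector")) sector$positions else sector
  stopifnot(inherits(coords, "structure_coords"))
  idx <- match(positions, coords$columns)
  if (anyNA(idx)) {
    stop("positions not mapped in the structure: ",
         paste(positions[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (length(idx) < 2L) stop("need at least 2 positions", call. = FALSE)
  mean(stats::dist(coords$xyz[idx, , drop = FALSE]))
}

#' Merge phylogenetically similar sectors into meta-sectors
#'
#' Clusters sectors by average-linkage hierarchical clustering on
#' `1 - MirrorTree score`, sums the member eigenvectors within each cluster
#' (multiplied by +1 for positive and -1 for negative sectors), and treats
#' each summed vector as an eigenvector from which meta-sectors are extracted
#' at the requested size cutoff.
#'
#' @param sectors List of `sector` objects (each carrying its full
#'   eigenvector in `coefficients`).
#' @param score_matrix Symmetric matrix of sector-sector MirrorTree scores,
#'   in the same order as `sectors`.
#' @param n_clusters Number of meta-sectors to form.
#' @param size_cutoff Size of each extracted meta-sector (default: size of
#'   the first sector).
#' @return List of `sector` objects (source `"meta"`), one per cluster, with
#'   a `members` attribute giving the indices of the merged sectors.
#' @export
meta_sectors <- function(sectors, score_matrix, n_clusters,
                         size_cutoff = sectors[[1L]]$size_cutoff) {
  stopifnot(length(sectors) >= 1L)
  if (length(sectors) == 1L) return(sectors)
  score_matrix <- as.matrix(score_matrix)
  stopifnot(nrow(score_matrix) == length(sectors),
            ncol(score_matrix) == length(sectors))
  diss <- 1 - score_matrix
  diag(diss) <- 0
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(hc, k = n_clusters)
  p <- length(sectors[[1L]]$coefficients)
  lapply(sort(unique(cl)), function(k) {
    members <- which(cl == k)
    # coefficients are already sign-adjusted (+v for positive, -v for
    # negative sectors), so the signed merge is a plain sum
    summed <- rowSums(vapply(members, function(m)
      sectors[[m]]$coefficients, numeric(p)))
    positions <- order(-summed, seq_len(p))[seq_len(size_cutoff)]
    structure(list(positions = positions, coefficients = summed,
                   eigenvector_index = NA_integer_, sign = "positive",
                   size_cutoff = as.integer(size_cutoff),
                   ignored = size_cutoff < 4L, source = "meta",
                   members = members),
              class = "sector")
  })
}
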