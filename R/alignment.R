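# alignment_io: reading aligned FASTA, the preprocessing recipe
# (reference-distance pruning, deduplication, gap-column removal,
# nearest-neighbour gap fill), and breadth/depth subsampling.

#' Construct an MSA object
#'
#' Low-level constructor for the `msa` class used throughout the package: a
#' rectangular character matrix of aligned residues with unique sequence
#' identifiers and one designated reference (query) sequence.
#'
#' @param residues Character matrix (sequences x columns) of single-letter
#'   residue codes; `"-"` denotes a gap.
#' @param ids Character vector of unique sequence identifiers.
#' @param reference_index Row index of the reference sequence.
#' @param provenance Character vector logging preprocessing steps applied.
#' @return An object of class `msa` with fields `ids`, `residues`,
#'   `reference_index` and `provenance`.
#' @export
new_msa <- function(residues, ids, reference_index = 1L,
                    provenance = character()) {
  stopifnot(is.matrix(residues), is.character(residues))
  ids <- as.character(ids)
  if (length(ids) != nrow(residues)) {
    stop("length(ids) must equal nrow(residues)", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  reference_index <- as.integer(reference_index)
  if (reference_index < 1L || reference_index > nrow(residues)) {
    stop("reference_index out of range", call. = FALSE)
  }
  rownames(residues) <- ids
  structure(list(ids = ids, residues = residues,
                 reference_index = reference_index,
                 provenance = provenance),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns; reference: %s\n",
              nrow(x$residues), ncol(x$residues),
              x$ids[x$reference_index]))
  if (length(x$provenance)) {
    cat("provenance:\n")
    cat(paste0("  - ", x$provenance, "\n"), sep = "")
  }
  invisible(x)
}

#' @export
dim.msa <- function(x) dim(x$residues)

#' Read an aligned FASTA file
#'
#' Records must all have the same length (the file is an alignment, not raw
#' sequences). Both `-` and `.` are accepted as gap characters and lowercase
#' letters are converted to uppercase.
#'
#' @param path Path to an aligned FASTA file.
#' @param reference_id Identifier of the reference (query) sequence; must be
#'   present in the file.
#' @return An [new_msa()] object with rows in file order.
#' @export
read_alignment <- function(path, reference_id) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment file: ", path, call. = FALSE)
  lens <- Biostrings::width(set)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment (not all records equal length): ",
         paste(sprintf("%s=%d", names(set), lens), collapse = ", "),
         call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  residues <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                     nrow = length(seqs), byrow = TRUE)
  residues[residues == "."] <- GAP
  ref <- match(reference_id, ids)
  if (is.na(ref)) {
    stop("reference_id '", reference_id, "' not found in alignment",
         call. = FALSE)
  }
  new_msa(residues, ids, ref,
          provenance = sprintf("read %d x %d alignment from %s",
                               length(ids), ncol(residues), path))
}

#' Write an MSA to aligned FASTA
#'
#' @param msa An [new_msa()] object.
#' @param path Output file path; gaps are written as `-`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path) {
  seqs <- apply(msa$residues, 1L, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- msa$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Jukes-Cantor distance from each row to the reference, tolerating gaps:
# computed over columns where both sequences are non-gap; no shared columns
# gives Inf.
#' @noRd
jc_to_reference <- function(residues, ref_index) {
  ref <- residues[ref_index, ]
  ref_ok <- ref != GAP
  vapply(seq_len(nrow(residues)), function(s) {
    row <- residues[s, ]
    both <- ref_ok & row != GAP
    n <- sum(both)
    if (n == 0L) return(Inf)
    jc_from_mismatch(sum(row[both] != ref[both]) / n)
  }, numeric(1))
}

#' Preprocess an alignment
#'
#' Applies, in order: (1) pruning of sequences whose Jukes-Cantor distance to
#' the reference exceeds `max_ref_distance`; (2) removal of exact duplicate
#' sequences (first occurrence kept; the reference always survives);
#' (3) mapping of nonstandard residue codes (B, Z, X, U, O, J) to gap and
#' removal of columns with more than `max_gap_fraction` gaps; (4) filling of
#' each remaining gap with the residue at that column from the nearest
#' non-gapped sequence by Jukes-Cantor distance (ties broken by lowest row
#' index). Distances in steps (1) and (4) are computed over columns where both
#' sequences are ungapped. The result contains no gaps and the operation is
#' idempotent.
#'
#' @param msa An [new_msa()] object.
#' @param max_gap_fraction Columns with a gap fraction strictly greater than
#'   this are removed (default 0.25).
#' @param max_ref_distance Sequences farther than this Jukes-Cantor distance
#'   from the reference are pruned (default 1).
#' @return A gap-free `msa` with updated provenance.
#' @export
preprocess_msa <- function(msa, max_gap_fraction = 0.25, max_ref_distance = 1) {
  stopifnot(inherits(msa, "msa"))
  res <- msa$residues
  ids <- msa$ids
  ref <- msa$reference_index
  log <- msa$provenance

  # nonstandard residues -> gap (keeps the alphabet at exactly 20 states)
  n_nonstd <- sum(res %in% NONSTANDARD_AA)
  if (n_nonstd > 0L) {
    res[res %in% NONSTANDARD_AA] <- GAP
    log <- c(log, sprintf("mapped %d nonstandard residues to gap", n_nonstd))
  }

  # (1) prune sequences too far from the reference
  d_ref <- jc_to_reference(res, ref)
  keep <- d_ref <= max_ref_distance
  keep[ref] <- TRUE
  if (!all(keep)) {
    log <- c(log, sprintf("pruned %d sequences with JC distance > %g from reference",
                          sum(!keep), max_ref_distance))
    ref <- sum(keep[seq_len(ref)])
    res <- res[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  if (nrow(res) == 0L) stop("all sequences pruned", call. = FALSE)

  # (2) deduplicate on exact residue-string equality; the reference always
  # survives (its earlier duplicate is dropped instead)
  strings <- apply(res, 1L, paste, collapse = "")
  first <- match(strings, strings)
  keep <- first == seq_along(strings)
  if (!keep[ref]) {
    keep[first[ref]] <- FALSE
    keep[ref] <- TRUE
  }
  if (!all(keep)) {
    log <- c(log, sprintf("removed %d duplicate sequences", sum(!keep)))
    ref <- sum(keep[seq_len(ref)])
    res <- res[keep, , drop = FALSE]
    ids <- ids[keep]
  }

  # (3) drop gappy columns
  gap_frac <- colMeans(res == GAP)
  keep_col <- gap_frac <= max_gap_fraction
  if (!all(keep_col)) {
    log <- c(log, sprintf("removed %d columns with > %d%% gaps",
                          sum(!keep_col), round(100 * max_gap_fraction)))
    res <- res[, keep_col, drop = FALSE]
  }
  if (ncol(res) == 0L) stop("all columns removed as gappy", call. = FALSE)

  # (4) fill remaining gaps from the nearest sequence (pre-fill distances)
  gap_rows <- which(rowSums(res == GAP) > 0L)
  if (length(gap_rows)) {
    n_filled <- 0L
    orig <- res  # donors come from the pre-fill matrix
    for (s in gap_rows) {
      d <- jc_pair_distances_to(orig, s)
      donor_order <- order(d, seq_len(nrow(orig)))  # ties by lowest row index
      donor_order <- donor_order[donor_order != s]
      for (i in which(orig[s, ] == GAP)) {
        donors <- donor_order[orig[donor_order, i] != GAP]
        if (length(donors) == 0L) {
          stop("column ", i, " has no non-gap donor for sequence ", ids[s],
               call. = FALSE)
        }
        res[s, i] <- orig[donors[1L], i]
        n_filled <- n_filled + 1L
      }
    }
    log <- c(log, sprintf("filled %d gaps from nearest sequences", n_filled))
  }

  new_msa(res, ids, ref, provenance = log)
}

# gap-aware JC distances from row s to every row (used by gap fill)
#' @noRd
jc_pair_distances_to <- function(residues, s) {
  row <- residues[s, ]
  row_ok <- row != GAP
  vapply(seq_len(nrow(residues)), function(t) {
    other <- residues[t, ]
    both <- row_ok & other != GAP
    n <- sum(both)
    if (n == 0L) return(Inf)
    jc_from_mismatch(sum(row[both] != other[both]) / n)
  }, numeric(1))
}

#' Subsample an alignment by breadth or depth
#'
#' Breadth sampling takes a uniform random subset of sequences (the reference
#' is always retained); depth sampling takes the sequences closest to the
#' reference by Jukes-Cantor distance, emulating a narrowly sampled protein
#' family. Row order of the input is preserved.
#'
#' @param msa An [new_msa()] object.
#' @param fraction Proportion of sequences to keep, in (0, 1].
#' @param mode `"breadth"` (random) or `"depth"` (closest to reference).
#' @param seed Integer seed (used by breadth mode).
#' @return An `msa` with `round(fraction * N)` sequences.
#' @export
subsample_msa <- function(msa, fraction, mode = c("breadth", "depth"),
                          seed = 1L) {
  stopifnot(inherits(msa, "msa"))
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  n <- nrow(msa$residues)
  k <- round(fraction * n)
  if (k < 2L) stop("subsample would have fewer than 2 sequences", call. = FALSE)
  if (k == n) return(msa)
  ref <- msa$reference_index
  if (mode == "breadth") {
    set.seed(check_seed(seed))
    others <- setdiff(seq_len(n), ref)
    keep <- sort(c(ref, sample(others, k - 1L)))
  } else {
    d <- jc_to_reference(msa$residues, ref)
    keep <- sort(order(d, seq_len(n))[seq_len(k)])  # ref has d = 0
    if (!(ref %in% keep)) keep <- sort(c(ref, keep[-k]))
  }
  new_msa(msa$residues[keep, , drop = FALSE], msa$ids[keep],
          match(ref, keep),
          provenance = c(msa$provenance,
                         sprintf("%s subsample: %d of %d sequences (fraction %g, seed %d)",
                                 mode, k, n, fraction, seed)))
}
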