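# contacts: alpha-carbon coordinates from PDB files, distance-threshold
# contact maps, and top-k true-positive scoring of covariation matrices.

#' Construct a structure-coordinates object
#'
#' @param xyz Numeric matrix (n x 3) of alpha-carbon coordinates in Angstrom.
#' @param columns Integer vector of the MSA columns the rows map to.
#' @param n_col Total number of MSA columns (defaults to `max(columns)`).
#' @param provenance Free-text mapping provenance.
#' @return An object of class `structure_coords`.
#' @export
new_structure_coords <- function(xyz, columns, n_col = max(columns),
                                 provenance = character()) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) == length(columns),
            all(is.finite(xyz)))
  columns <- as.integer(columns)
  if (anyDuplicated(columns)) {
    stop("MSA column mapped twice: ",
         paste(unique(columns[duplicated(columns)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(columns < 1L) || any(columns > n_col)) {
    stop("mapped columns out of range", call. = FALSE)
  }
  ord <- order(columns)
  dimnames(xyz) <- NULL
  structure(list(xyz = xyz[ord, , drop = FALSE], columns = columns[ord],
                 n_col = as.integer(n_col), provenance = provenance),
            class = "structure_coords")
}

#' Read alpha-carbon coordinates from a PDB file
#'
#' Uses the first model only and, where alternate locations exist, the
#' highest-occupancy altloc. Residues without an alpha carbon or absent from
#' `column_map` are skipped with a message.
#'
#' @param pdb_path Path to a PDB file.
#' @param chain Chain identifier (e.g. `"A"`).
#' @param column_map Optional mapping from PDB residue numbers to MSA
#'   columns: a named integer vector (`names` = residue numbers) or `NULL`
#'   for the identity map.
#' @param n_col Total number of MSA columns; defaults to the largest mapped
#'   column.
#' @return A [new_structure_coords()] object.
#' @export
read_ca_coordinates <- function(pdb_path, chain, column_map = NULL,
                                n_col = NULL) {
  pdb <- bio3d::read.pdb(pdb_path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$chain == chain & at$elety == "CA" & at$type == "ATOM", ,
           drop = FALSE]
  if (nrow(at) == 0L) {
    if (!chain %in% unique(pdb$atom$chain)) {
      stop("chain '", chain, "' not present in ", pdb_path, call. = FALSE)
    }
    stop("no CA atoms in chain '", chain, "' of ", pdb_path, call. = FALSE)
  }
  # highest-occupancy altloc per residue, ties by record order
  at <- at[order(at$resno, -replace(at$o, is.na(at$o), 1)), , drop = FALSE]
  at <- at[!duplicated(at$resno), , drop = FALSE]
  if (is.null(column_map)) {
    cols <- at$resno
  } else {
    cols <- unname(column_map[as.character(at$resno)])
    skipped <- sum(is.na(cols))
    if (skipped > 0L) {
      message(skipped, " residues not in column_map; skipped")
      at <- at[!is.na(cols), , drop = FALSE]
      cols <- cols[!is.na(cols)]
    }
  }
  if (nrow(at) == 0L) stop("no residues mapped to MSA columns", call. = FALSE)
  new_structure_coords(as.matrix(at[, c("x", "y", "z")]), cols,
                       n_col = if (is.null(n_col)) max(cols) else n_col,
                       provenance = sprintf("%s chain %s (%d CA atoms)",
                                            pdb_path, chain, nrow(at)))
}

#' Alpha-carbon contact map
#'
#' A pair of MSA columns is a contact iff the CA-CA Euclidean distance is
#' strictly below `threshold` and the sequence separation exceeds `min_sep`
#' (pairs with `|i - j| <= min_sep` are always excluded). Columns without
#' coordinates are never contacts.
#'
#' @param coords A [new_structure_coords()] object.
#' @param threshold Distance threshold in Angstrom (default 5; 8 is the
#'   common alternative).
#' @param min_sep Minimum sequence separation in residues (default 5).
#' @return A symmetric logical p x p matrix of class `contact_map` with
#'   attributes `threshold`, `min_sep` and `mapped` (the mapped columns).
#' @export
contact_map <- function(coords, threshold = 5, min_sep = 5L) {
  stopifnot(inherits(coords, "structure_coords"))
  if (nrow(coords$xyz) < 2L) stop("need at least 2 mapped columns",
                                  call. = FALSE)
  p <- coords$n_col
  d <- as.matrix(stats::dist(coords$xyz))
  cm <- matrix(FALSE, p, p)
  cols <- coords$columns
  cm[cols, cols] <- d < threshold
  sep <- abs(outer(seq_len(p), seq_len(p), "-"))
  cm[sep <= min_sep] <- FALSE
  structure(cm, threshold = threshold, min_sep = as.integer(min_sep),
            mapped = cols, class = c("contact_map", "matrix", "array"))
}

#' Count true-positive contacts among the top-k covariation pairs
#'
#' Ranks eligible column pairs (`i < j`, separation greater than the contact
#' map's `min_sep`, both columns mapped in the structure) by covariation
#' score, descending, with ties broken lexicographically by `(i, j)`, and
#' counts how many of the first `k` are structural contacts. The chance
#' expectation is `k` times the contact density among eligible pairs.
#'
#' @param C A [new_covariation_matrix()] (or plain symmetric matrix).
#' @param cm A [contact_map()] of the same dimension.
#' @param k Number of top predictions to evaluate (default 50).
#' @return List with `true_positives`, `expected` (chance level), `k` and
#'   `n_eligible`.
#' @export
top_k_true_positives <- function(C, cm, k = 50L) {
  m <- unclass(C)
  cmv <- unclass(cm)
  stopifnot(nrow(m) == nrow(cmv), k >= 1L)
  p <- nrow(m)
  min_sep <- attr(cm, "min_sep")
  mapped <- attr(cm, "mapped") %||% seq_len(p)
  is_mapped <- seq_len(p) %in% mapped
  idx <- which(upper.tri(m), arr.ind = TRUE)
  elig <- (idx[, 2L] - idx[, 1L]) > min_sep &
    is_mapped[idx[, 1L]] & is_mapped[idx[, 2L]]
  idx <- idx[elig, , drop = FALSE]
  if (nrow(idx) < k) {
    stop("fewer than k = ", k, " eligible pairs (", nrow(idx), ")",
         call. = FALSE)
  }
  scores <- m[idx]
  ord <- order(-scores, idx[, 1L], idx[, 2L])
  top <- idx[ord[seq_len(k)], , drop = FALSE]
  n_contacts <- sum(cmv[idx])
  list(true_positives = sum(cmv[top]),
       expected = k * n_contacts / nrow(idx),
       k = as.integer(k),
       n_eligible = nrow(idx))
}
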