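# synthetic_data: clade-structured alignments with planted coevolution and
# phylogenetic confounds, Potts-sampled alignments, and toy CA-only
# structures with a spatially clustered planted sector — all with ground
# truth, so every analysis module is testable without external downloads.

#' @noRd
random_symbol <- function(n) sample.int(N_AA, n, replace = TRUE)

# mutate positions `idx` of integer vector `x` to random *different* symbols
#' @noRd
mutate_sites <- function(x, idx) {
  if (length(idx) == 0L) return(x)
  shift <- sample.int(N_AA - 1L, length(idx), replace = TRUE)
  x[idx] <- ((x[idx] - 1L + shift) %% N_AA) + 1L
  x
}

#' Simulate a clade-structured alignment with planted signals
#'
#' A star-of-clades model: a uniform random root sequence spawns `n_clades`
#' clade ancestors (per-site mutation probability `mu_inter`), and each
#' ancestor spawns `seqs_per_clade` leaves (per-site probability `mu_intra`).
#' Three kinds of structure can be planted:
#' \describe{
#'   \item{confound groups}{columns that mutate in lockstep at the
#'     clade-ancestor step (one Bernoulli draw per group per ancestor):
#'     strong inter-clade correlation with no intra-clade coupling — the
#'     phylogenetic confound that inflates raw covariation.}
#'   \item{coupled pairs}{true within-clade coevolution: when a leaf
#'     mutation hits one member of a pair, the partner is set to a
#'     pair-specific complementary symbol (a fixed random permutation of the
#'     alphabet) with probability `coupling_rho`.}
#'   \item{divergent columns}{columns whose clade-ancestor states follow an
#'     independent random partition of the sequences, giving a position group
#'     whose phylogeny disagrees with the rest of the protein (a planted
#'     low-MirrorTree sector).}
#' }
#'
#' @param n_clades Number of clades (default 4).
#' @param seqs_per_clade Leaves per clade (default 50).
#' @param p Alignment columns (default 50).
#' @param mu_inter Root-to-ancestor per-site mutation probability: a scalar,
#'   or a vector of length `n_clades` giving each clade its own divergence
#'   from the root (varied clade depths spread the inter-clade distances as
#'   in real families). Default 0.3, which keeps inter-clade Jukes-Cantor
#'   distances near 0.8, below the reference-pruning threshold of 1.
#' @param mu_intra Ancestor-to-leaf per-site mutation probability: a scalar,
#'   or a length-2 range from which each leaf draws its own rate uniformly
#'   (per-branch rate heterogeneity, which spreads pairwise distances
#'   continuously as in real families). Default 0.08.
#' @param coupled_pairs Two-column integer matrix (or list of length-2
#'   vectors) of coupled column pairs; may share columns (e.g. a ring).
#' @param coupling_rho Probability that a mutation at one pair member sets
#'   the partner to its complementary symbol (default 0.9).
#' @param confound_groups List of integer vectors of lockstep columns.
#' @param divergent_columns Integer vector of columns evolving on an
#'   independent clade pattern.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return List with `msa` (an [new_msa()]; reference = first leaf of clade
#'   1) and `truth` (class `synthetic_truth`: clade labels, planted pairs,
#'   confound groups, divergent columns and all parameters).
#' @export
simulate_clade_msa <- function(n_clades = 4L, seqs_per_clade = 50L, p = 50L,
                               mu_inter = 0.3, mu_intra = 0.08,
                               coupled_pairs = NULL, coupling_rho = 0.9,
                               confound_groups = NULL,
                               divergent_columns = NULL, seed = 1L) {
  stopifnot(all(mu_inter >= 0), all(mu_inter <= 1),
            length(mu_inter) %in% c(1L, n_clades),
            all(mu_intra >= 0), all(mu_intra <= 1),
            length(mu_intra) %in% c(1L, 2L),
            coupling_rho >= 0, coupling_rho <= 1)
  mu_inter <- rep_len(mu_inter, n_clades)
  if (!is.null(coupled_pairs)) {
    coupled_pairs <- if (is.list(coupled_pairs)) {
      do.call(rbind, coupled_pairs)
    } else {
      as.matrix(coupled_pairs)
    }
    stopifnot(ncol(coupled_pairs) == 2L,
              all(coupled_pairs >= 1L), all(coupled_pairs <= p))
  }
  confound_cols <- unlist(confound_groups)
  if (length(intersect(confound_cols, as.vector(coupled_pairs)))) {
    stop("coupled pairs and confound groups must use disjoint columns",
         call. = FALSE)
  }
  set.seed(check_seed(seed))
  n <- n_clades * seqs_per_clade

  root <- random_symbol(p)
  ordinary <- setdiff(seq_len(p), c(confound_cols, divergent_columns))

  # clade ancestors
  ancestors <- matrix(0L, n_clades, p)
  for (cc in seq_len(n_clades)) {
    anc <- root
    anc <- mutate_sites(anc,
                        ordinary[stats::runif(length(ordinary)) < mu_inter[cc]])
    for (grp in confound_groups) {
      if (stats::runif(1) < mu_inter[cc]) anc <- mutate_sites(anc, grp)
    }
    ancestors[cc, ] <- anc
  }

  # independent pseudo-clade ancestors for divergent columns
  if (length(divergent_columns)) {
    pseudo_labels <- sample.int(n_clades, n, replace = TRUE)
    pseudo_anc <- matrix(0L, n_clades, length(divergent_columns))
    for (cc in seq_len(n_clades)) {
      anc <- root[divergent_columns]
      idx <- which(stats::runif(length(divergent_columns)) < mu_inter[cc])
      anc <- mutate_sites(anc, idx)
      pseudo_anc[cc, ] <- anc
    }
  }

  # fixed complementary-symbol maps (one random permutation per pair)
  comp_maps <- NULL
  if (!is.null(coupled_pairs)) {
    comp_maps <- lapply(seq_len(nrow(coupled_pairs)),
                        function(k) sample.int(N_AA))
  }

  residues <- matrix(0L, n, p)
  labels <- rep(seq_len(n_clades), each = seqs_per_clade)
  leaf_rate <- if (length(mu_intra) == 2L) {
    stats::runif(n, mu_intra[1L], mu_intra[2L])
  } else {
    rep(mu_intra, n)
  }
  for (s in seq_len(n)) {
    leaf <- ancestors[labels[s], ]
    if (length(divergent_columns)) {
      leaf[divergent_columns] <- pseudo_anc[pseudo_labels[s], ]
    }
    mutated <- stats::runif(p) < leaf_rate[s]
    leaf <- mutate_sites(leaf, which(mutated))
    if (!is.null(coupled_pairs)) {
      for (k in seq_len(nrow(coupled_pairs))) {
        i <- coupled_pairs[k, 1L]
        j <- coupled_pairs[k, 2L]
        comp <- comp_maps[[k]]
        if (mutated[i] && stats::runif(1) < coupling_rho) {
          leaf[j] <- comp[leaf[i]]
        } else if (mutated[j] && stats::runif(1) < coupling_rho) {
          leaf[i] <- match(leaf[j], comp)
        }
      }
    }
    residues[s, ] <- leaf
  }

  ids <- sprintf("c%02d_s%03d", labels, seq_len(n))
  msa <- new_msa(matrix(AA_ALPHABET[residues], n, p), ids,
                 reference_index = 1L,
                 provenance = sprintf("simulate_clade_msa(seed = %d)", seed))
  truth <- structure(list(clade = labels,
                          planted_pairs = coupled_pairs,
                          coupling_rho = coupling_rho,
                          confound_groups = confound_groups,
                          divergent_columns = divergent_columns,
                          params = list(n_clades = n_clades,
                                        seqs_per_clade = seqs_per_clade,
                                        p = p, mu_inter = mu_inter,
                                        mu_intra = mu_intra),
                          seed = seed),
                     class = "synthetic_truth")
  list(msa = msa, truth = truth)
}

#' Permutation-based Potts coupling table
#'
#' Builds a 20 x 20 interaction matrix with `J(k, l) = strength` when
#' `l = (k mod 20) + 1` and 0 otherwise — a deterministic one-to-one
#' preferred-partner map.
#'
#' @param i,j Coupled columns.
#' @param strength Interaction strength in energy units (default 3).
#' @return List with fields `i`, `j`, `J` as consumed by
#'   [simulate_potts_msa()].
#' @export
potts_coupling <- function(i, j, strength = 3) {
  J <- matrix(0, N_AA, N_AA)
  J[cbind(seq_len(N_AA), (seq_len(N_AA) %% N_AA) + 1L)] <- strength
  list(i = as.integer(i), j = as.integer(j), J = J)
}

#' Gibbs-sample an alignment from an explicit pairwise (Potts) model
#'
#' Each sequence is an independent Gibbs chain over `p` sites with zero
#' fields and the pairwise interactions in `coupling_spec`; with an empty
#' spec the columns are exactly independent uniform draws. Used as the
#' ground-truth generator for validating [mfdca()].
#'
#' @param p Number of columns (default 25).
#' @param n_seqs Number of sequences (default 500).
#' @param coupling_spec List of couplings from [potts_coupling()].
#' @param n_sweeps Gibbs sweeps per sequence (default 100; must be >= 1).
#' @param seed Integer seed.
#' @return List with `msa` and `truth` (planted pairs and parameters).
#' @export
simulate_potts_msa <- function(p = 25L, n_seqs = 500L, coupling_spec = list(),
                               n_sweeps = 100L, seed = 1L) {
  if (n_sweeps < 1L) stop("n_sweeps must be >= 1", call. = FALSE)
  set.seed(check_seed(seed))
  state <- matrix(random_symbol(n_seqs * p), n_seqs, p)
  if (length(coupling_spec)) {
    partners <- vector("list", p)  # per site: list of (other, J, transpose?)
    for (cs in coupling_spec) {
      partners[[cs$i]] <- c(partners[[cs$i]],
                            list(list(other = cs$j, J = cs$J, t = FALSE)))
      partners[[cs$j]] <- c(partners[[cs$j]],
                            list(list(other = cs$i, J = cs$J, t = TRUE)))
    }
    cum <- upper.tri(matrix(0, N_AA, N_AA), diag = TRUE) * 1
    active <- which(vapply(partners, length, integer(1)) > 0L)
    for (sweep in seq_len(n_sweeps)) {
      for (site in active) {
        E <- matrix(0, n_seqs, N_AA)
        for (pa in partners[[site]]) {
          other_state <- state[, pa$other]
          E <- E + if (pa$t) pa$J[other_state, , drop = FALSE]
                   else t(pa$J)[other_state, , drop = FALSE]
        }
        P <- exp(E - apply(E, 1L, max))
        P <- P / rowSums(P)
        u <- stats::runif(n_seqs)
        state[, site] <- 1L + rowSums((P %*% cum) < u)
      }
    }
  }
  ids <- sprintf("potts_s%04d", seq_len(n_seqs))
  msa <- new_msa(matrix(AA_ALPHABET[state], n_seqs, p), ids, 1L,
                 provenance = sprintf("simulate_potts_msa(seed = %d)", seed))
  planted <- if (length(coupling_spec)) {
    do.call(rbind, lapply(coupling_spec, function(cs) c(cs$i, cs$j)))
  }
  truth <- structure(list(planted_pairs = planted,
                          params = list(p = p, n_seqs = n_seqs,
                                        n_sweeps = n_sweeps),
                          seed = seed),
                     class = "synthetic_truth")
  list(msa = msa, truth = truth)
}

#' Simulate a CA-only structure with a spatially clustered sector
#'
#' Builds an alpha-carbon trace as a random walk with exact 3.8-Angstrom
#' steps and excluded-volume rejection (no two CA atoms closer than
#' `min_clash`). Residues in `sector_positions` are constrained to lie
#' within a ball of radius `cluster_radius_A` centered at the first sector
#' residue; a look-ahead constraint keeps the chain close enough to re-enter
#' the ball in time, so consecutive distances stay exactly 3.8.
#'
#' @param p Number of residues.
#' @param sector_positions Columns forming the compact planted sector
#'   (possibly empty).
#' @param cluster_radius_A Ball radius in Angstrom (default 8; must be > 0).
#' @param seed Integer seed.
#' @param pdb_path Optional path; when given, a minimal CA-only PDB file is
#'   written (chain A, one ALA CA per residue).
#' @param min_clash Minimum allowed CA-CA distance (default 3.4).
#' @param max_tries Direction retries per step before the walk restarts.
#' @param max_restarts Walk restarts before giving up.
#' @return A [new_structure_coords()] object over columns `1:p`.
#' @export
simulate_structure <- function(p, sector_positions = integer(),
                               cluster_radius_A = 8, seed = 1L,
                               pdb_path = NULL, min_clash = 3.4,
                               max_tries = 300L, max_restarts = 50L) {
  if (cluster_radius_A <= 0) stop("cluster_radius_A must be > 0",
                                  call. = FALSE)
  sector_positions <- sort(as.integer(sector_positions))
  stopifnot(all(sector_positions >= 1L), all(sector_positions <= p))
  set.seed(check_seed(seed))
  step_len <- 3.8
  r <- cluster_radius_A

  rand_dir <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  for (restart in seq_len(max_restarts)) {
    xyz <- matrix(NA_real_, p, 3L)
    xyz[1L, ] <- c(0, 0, 0)
    center <- if (length(sector_positions) && sector_positions[1L] == 1L) {
      xyz[1L, ]
    } else {
      NULL
    }
    ok <- TRUE
    for (t in seq_len(p - 1L) + 1L) {
      in_sector <- t %in% sector_positions
      nxt <- sector_positions[sector_positions >= t]
      nxt <- if (length(nxt)) nxt[1L] else NA_integer_
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- xyz[t - 1L, ] + step_len * rand_dir()
        d2 <- rowSums((xyz[seq_len(t - 1L), , drop = FALSE] -
                         matrix(cand, t - 1L, 3L, byrow = TRUE))^2)
        if (min(d2) < min_clash^2) next
        if (!is.null(center) && !is.na(nxt)) {
          reach <- sqrt(sum((cand - center)^2))
          limit <- if (in_sector) r else r + step_len * (nxt - t)
          if (reach > limit) next
        }
        xyz[t, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) {
        ok <- FALSE
        break
      }
      if (is.null(center) && t %in% sector_positions) center <- xyz[t, ]
    }
    if (ok) {
      coords <- new_structure_coords(xyz, seq_len(p), n_col = p,
                                     provenance = sprintf(
                                       "simulate_structure(seed = %d, radius = %g)",
                                       seed, r))
      if (!is.null(pdb_path)) write_ca_pdb(coords, pdb_path)
      return(coords)
    }
  }
  stop("chain placement failed after ", max_restarts, " restarts (",
       max_tries, " tries per step)", call. = FALSE)
}

#' Write a CA-only PDB file
#'
#' Minimal fixed-width ATOM records (one alanine CA per residue, chain A),
#' sufficient for [read_ca_coordinates()] round-trips.
#'
#' @param coords A [new_structure_coords()] object.
#' @param path Output PDB path.
#' @param chain Chain identifier (default `"A"`).
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(coords, path, chain = "A") {
  stopifnot(inherits(coords, "structure_coords"))
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_along(coords$columns), chain, coords$columns,
    coords$xyz[, 1L], coords$xyz[, 2L], coords$xyz[, 3L])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Serialize a synthetic ground-truth object to JSON
#'
#' @param truth A `synthetic_truth` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
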