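# sectors (part 2): MirrorTree phylogenetic-similarity scores, random-group
# null distributions (uniform and entropy-biased), and deep-mutational-
# scanning enrichment overlays.

#' MirrorTree score between two position sets
#'
#' Computes Jukes-Cantor distance matrices on the alignment restricted to
#' each position set and returns the Pearson correlation of their
#' strictly-upper-triangle entries. With `positions_b = NULL` the second
#' operand is the whole alignment (sector-protein mode); with two explicit
#' sets it is the sector-sector mode. A score near 1 means the filtered
#' alignment carries the same phylogenetic signal as the comparison set; low
#' scores mark phylogenetically distinct position groups.
#'
#' @param msa A gap-free [new_msa()] object.
#' @param positions_a Integer vector of MSA columns (nonempty).
#' @param positions_b Second column set, or `NULL` for all columns.
#' @return An object of class `mirrortree_score` with fields `value`
#'   (Pearson r in \[-1, 1\], or `NA` when either distance vector has zero
#'   variance), `undefined` (logical flag for that case) and `operands`.
#' @export
mirrortree_score <- function(msa, positions_a, positions_b = NULL) {
  stopifnot(inherits(msa, "msa"), length(positions_a) >= 1L)
  da <- upper_tri_values(unclass(jc_distance(msa, columns = positions_a)))
  db <- upper_tri_values(unclass(jc_distance(msa, columns = positions_b)))
  operands <- if (is.null(positions_b)) "sector-protein" else "sector-sector"
  if (stats::sd(da) == 0 || stats::sd(db) == 0) {
    return(structure(list(value = NA_real_, undefined = TRUE,
                          operands = operands),
                     class = "mirrortree_score"))
  }
  structure(list(value = stats::cor(da, db), undefined = FALSE,
                 operands = operands),
            class = "mirrortree_score")
}

#' @export
print.mirrortree_score <- function(x, ...) {
  cat(sprintf("<mirrortree_score> %s: %s\n", x$operands,
              if (x$undefined) "undefined (zero-variance distances)"
              else signif(x$value, 4)))
  invisible(x)
}

# fast JC distance vector (upper triangle) for a column subset, given the
# pre-built one-hot matrix of the full alignment
#' @noRd
jc_upper_subset <- function(X, cols, p_total) {
  state_cols <- as.vector(outer(seq_len(N_AA), (cols - 1L) * N_AA, "+"))
  matches <- as.matrix(Matrix::tcrossprod(X[, state_cols, drop = FALSE]))
  pm <- 1 - matches / length(cols)
  jc_from_mismatch(upper_tri_values(pm))
}

#' Null distribution of sector diagnostics over random residue groups
#'
#' Samples `n_samples` groups of `size` positions (never touching `exclude`)
#' and computes, for each, the sector-protein MirrorTree score and — when a
#' structure is supplied — the spatial compactness. Uniform sampling by
#' default; when `entropy_target` is given, a Metropolis swap chain biases
#' groups so their mean per-column entropy approaches the target (used to
#' ask whether a sector is phylogenetically distinct beyond what its
#' conservation level alone predicts). Returns means, standard deviations
#' and 95% intervals, from which z-scores of observed sectors are formed as
#' `(observed - mean) / sd`.
#'
#' @param msa A gap-free [new_msa()] object.
#' @param size Group size (e.g. the sector size).
#' @param n_samples Number of random groups (default 1000).
#' @param seed Integer seed.
#' @param coords Optional [new_structure_coords()]; adds the compactness
#'   metric (groups are drawn from mapped columns only).
#' @param exclude Columns never sampled (e.g. the sector itself).
#' @param entropy_target Optional target mean entropy (nats); must lie in
#'   the attainable range of the candidate columns.
#' @param entropy_tol Width (nats) of the Gaussian acceptance window around
#'   `entropy_target` (default 0.05).
#' @param metrics Which diagnostics to evaluate per group: any of
#'   `"mirrortree"` and `"compactness"` (the latter requires `coords`).
#'   Defaults to both when a structure is supplied, otherwise MirrorTree
#'   only.
#' @return An object of class `random_group_null` with fields `samples`
#'   (data frame of per-group metrics), `groups` (matrix of sampled
#'   positions) and `summary` (per-metric mean, sd, ci_lower, ci_upper).
#' @export
random_group_null <- function(msa, size, n_samples = 1000L, seed = 1L,
                              coords = NULL, exclude = integer(),
                              entropy_target = NULL, entropy_tol = 0.05,
                              metrics = NULL) {
  stopifnot(inherits(msa, "msa"))
  if (is.null(metrics)) {
    metrics <- if (is.null(coords)) "mirrortree"
               else c("mirrortree", "compactness")
  }
  stopifnot(all(metrics %in% c("mirrortree", "compactness")))
  if ("compactness" %in% metrics && is.null(coords)) {
    stop("compactness metric requires coords", call. = FALSE)
  }
  p <- ncol(msa$residues)
  candidates <- setdiff(seq_len(p), exclude)
  if (!is.null(coords)) candidates <- intersect(candidates, coords$columns)
  if (size > length(candidates)) {
    stop("size exceeds the number of eligible columns (",
         length(candidates), ")", call. = FALSE)
  }
  set.seed(check_seed(seed))
  H <- entropy_profile(msa)

  if (is.null(entropy_target)) {
    groups <- t(replicate(n_samples, sample(candidates, size)))
  } else {
    hs <- sort(H[candidates])
    lo <- mean(hs[seq_len(size)])
    hi <- mean(hs[seq.int(length(hs) - size + 1L, length(hs))])
    if (entropy_target < lo || entropy_target > hi) {
      stop(sprintf("entropy_target %.3f outside attainable range [%.3f, %.3f]",
                   entropy_target, lo, hi), call. = FALSE)
    }
    groups <- entropy_biased_groups(candidates, H, size, n_samples,
                                    entropy_target, entropy_tol)
  }

  samples <- data.frame(mean_entropy = rowMeans(matrix(H[t(groups)],
                                                       ncol = size,
                                                       byrow = TRUE)))
  if ("mirrortree" %in% metrics) {
    X <- onehot_encoded(encode_msa(msa))
    d_all <- jc_upper_subset(X, seq_len(p), p)
    samples$mirrortree <- apply(groups, 1L, function(g) {
      dg <- jc_upper_subset(X, g, p)
      if (stats::sd(dg) == 0 || stats::sd(d_all) == 0) NA_real_
      else stats::cor(dg, d_all)
    })
  }
  if ("compactness" %in% metrics) {
    samples$compactness <- apply(groups, 1L, spatial_compactness,
                                 coords = coords)
  }
  summarize <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), sd = stats::sd(x),
      ci_lower = unname(stats::quantile(x, 0.025)),
      ci_upper = unname(stats::quantile(x, 0.975)))
  }
  structure(list(samples = samples, groups = groups,
                 summary = lapply(samples, summarize),
                 size = as.integer(size),
                 entropy_target = entropy_target),
            class = "random_group_null")
}

# Metropolis swap chain over size-subsets of `candidates`, targeting a group
# mean entropy near `target`; 10x burn-in sweeps, one sweep between samples.
#' @noRd
entropy_biased_groups <- function(candidates, H, size, n_samples, target,
                                  tol) {
  current <- sample(candidates, size)
  outside <- setdiff(candidates, current)
  cur_mean <- mean(H[current])
  log_dens <- function(m) -(m - target)^2 / (2 * tol^2)
  sweep_len <- size
  n_burn <- 10L * sweep_len
  groups <- matrix(0L, n_samples, size)
  total <- n_burn + n_samples * sweep_len
  taken <- 0L
  for (step in seq_len(total)) {
    i <- sample.int(size, 1L)
    j <- sample.int(length(outside), 1L)
    new_mean <- cur_mean + (H[outside[j]] - H[current[i]]) / size
    if (log(stats::runif(1)) < log_dens(new_mean) - log_dens(cur_mean)) {
      tmp <- current[i]
      current[i] <- outside[j]
      outside[j] <- tmp
      cur_mean <- new_mean
    }
    if (step > n_burn && (step - n_burn) %% sweep_len == 0L) {
      taken <- taken + 1L
      groups[taken, ] <- current
    }
  }
  groups
}

#' z-score of an observed diagnostic against a random-group null
#'
#' @param null A [random_group_null()] object.
#' @param metric `"mirrortree"`, `"compactness"` or `"mean_entropy"`.
#' @param observed Observed value for the sector.
#' @return `(observed - null mean) / null sd`.
#' @export
null_z <- function(null, metric, observed) {
  stopifnot(inherits(null, "random_group_null"))
  s <- null$summary[[metric]]
  if (is.null(s)) stop("metric '", metric, "' not in the null", call. = FALSE)
  (observed - s[["mean"]]) / s[["sd"]]
}

#' Read a deep-mutational-scanning score table
#'
#' Expects a delimited text file with header columns `position`, `mutant_aa`
#' and `score` (one row per position x mutation).
#'
#' @param path CSV file path.
#' @param sep Field separator (default comma).
#' @return Data frame with the three columns, `position` as integer.
#' @export
read_dms_table <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("position", "mutant_aa", "score")
  if (!all(need %in% names(tab))) {
    stop("DMS table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab$position <- as.integer(tab$position)
  tab
}

#' Mutational-enrichment statistics of a sector
#'
#' For each sector position, takes the minimum and maximum score over all
#' mutations (minimum = strongest deactivation, maximum = strongest
#' activation in a fitness-style screen), averages them over the sector, and
#' compares each mean to its distribution over random same-size position
#' groups drawn from the table.
#'
#' @param sector A `sector` object or integer vector of positions; every
#'   position must appear in the table.
#' @param dms_table Data frame from [read_dms_table()].
#' @param n_samples Number of random groups for the null (default 1000).
#' @param seed Integer seed.
#' @return List with `mean_min`, `mean_max`, `z_min`, `z_max`,
#'   `per_position` (data frame of per-position min/max) and `null`
#'   (per-statistic mean/sd).
#' @export
dms_enrichment <- function(sector, dms_table, n_samples = 1000L, seed = 1L) {
  positions <- if (inherits(sector, "sector")) sector$positions else sector
  pos_min <- tapply(dms_table$score, dms_table$position, min)
  pos_max <- tapply(dms_table$score, dms_table$position, max)
  avail <- as.integer(names(pos_min))
  missing <- setdiff(positions, avail)
  if (length(missing)) {
    stop("sector positions absent from the DMS table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- match(positions, avail)
  obs_min <- mean(pos_min[idx])
  obs_max <- mean(pos_max[idx])
  set.seed(check_seed(seed))
  k <- length(positions)
  null_min <- replicate(n_samples, mean(pos_min[sample.int(length(avail), k)]))
  null_max <- replicate(n_samples, mean(pos_max[sample.int(length(avail), k)]))
  list(mean_min = obs_min,
       mean_max = obs_max,
       z_min = (obs_min - mean(null_min)) / stats::sd(null_min),
       z_max = (obs_max - mean(null_max)) / stats::sd(null_max),
       per_position = data.frame(position = positions,
                                 min_score = unname(pos_min[idx]),
                                 max_score = unname(pos_max[idx])),
       null = list(min = c(mean = mean(null_min), sd = stats::sd(null_min)),
                   max = c(mean = mean(null_max), sd = stats::sd(null_max))))
}
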