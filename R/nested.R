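# nested_coevolution: within-clade resampling null models, the closed-form
# null for NMI, the nested-coevolution subtraction C_{S<=d} = C_T - C_{S>d},
# and bootstrap significance estimates.

#' Resample an alignment within clades
#'
#' For every sequence and every column independently, the output symbol is
#' drawn (with replacement) from the symbols at that column among the
#' sequences of the same clade. This destroys within-clade couplings between
#' columns while preserving each clade's per-column composition, i.e. the
#' phylogenetic structure at distances greater than the clade cutoff.
#'
#' @param msa An [new_msa()] object.
#' @param partition A [partition_clades()] result covering the same rows.
#' @param seed Integer seed.
#' @return An `msa` with identical ids and dimensions.
#' @export
resample_within_clades <- function(msa, partition, seed = 1L) {
  stopifnot(inherits(msa, "msa"), inherits(partition, "clade_partition"))
  res <- msa$residues
  n <- nrow(res)
  p <- ncol(res)
  if (length(partition$labels) != n) {
    stop("partition does not cover the alignment rows", call. = FALSE)
  }
  set.seed(check_seed(seed))
  out <- res
  for (c_lab in seq_len(partition$n_clades)) {
    rows <- which(partition$labels == c_lab)
    m <- length(rows)
    if (m == 1L) next  # only donor is self
    block <- res[rows, , drop = FALSE]
    donors <- sample.int(m, m * p, replace = TRUE)
    out[rows, ] <- matrix(block[donors + (rep(seq_len(p), each = m) - 1L) * m],
                          nrow = m)
  }
  new_msa(out, msa$ids, msa$reference_index,
          provenance = c(msa$provenance,
                         sprintf("within-clade resample (d = %g, seed %d)",
                                 partition$cutoff_d, seed)))
}

#' @noRd
metric_matrix <- function(msa, metric, pseudocount = 0.5,
                          reweight_threshold = 0.3) {
  switch(metric,
         nmi = nmi_matrix(msa),
         di = mfdca(msa, pseudocount, reweight_threshold)$di,
         frobenius = mfdca(msa, pseudocount, reweight_threshold)$frobenius,
         stop("unknown metric: ", metric, call. = FALSE))
}

#' Bootstrap estimate of the inter-clade covariation null
#'
#' Averages the chosen covariation metric over `n_bootstrap` within-clade
#' resampled alignments, giving the covariation expected when columns are
#' independent within clades (`C_{S>d}`). Also records, per pair, the
#' fraction of resampled alignments whose metric value is greater than or
#' equal to the observed one — an exceedance p-value whose resolution is
#' `1 / n_bootstrap`. For DI/Frobenius the DCA reweighting is recomputed on
#' every resampled alignment.
#'
#' @param msa A gap-free [new_msa()] object.
#' @param partition A [partition_clades()] result.
#' @param metric `"nmi"`, `"di"` or `"frobenius"`.
#' @param n_bootstrap Number of resampled alignments (>= 1).
#' @param seed Root seed; per-replicate seeds are derived by counter.
#' @param observed Optional precomputed total covariation matrix `C_T` (saves
#'   one metric evaluation).
#' @return List with `null_mean` (a [new_covariation_matrix()]),
#'   `significance` (p x p exceedance fractions) and `n_bootstrap`.
#' @export
bootstrap_null <- function(msa, partition, metric = c("nmi", "di", "frobenius"),
                           n_bootstrap = 100L, seed = 1L, observed = NULL) {
  metric <- match.arg(metric)
  if (n_bootstrap < 1L) stop("n_bootstrap must be >= 1", call. = FALSE)
  if (is.null(observed)) observed <- metric_matrix(msa, metric)
  p <- ncol(msa$residues)
  acc <- matrix(0, p, p)
  exceed <- matrix(0, p, p)
  for (b in seq_len(n_bootstrap)) {
    msa_b <- resample_within_clades(msa, partition, derive_seed(seed, b))
    cb <- unclass(metric_matrix(msa_b, metric))
    acc <- acc + cb
    exceed <- exceed + (cb >= unclass(observed))
  }
  list(null_mean = new_covariation_matrix(acc / n_bootstrap, metric),
       significance = exceed / n_bootstrap,
       n_bootstrap = n_bootstrap)
}

#' Closed-form inter-clade null for NMI
#'
#' Under the null hypothesis that columns are independent within clades, the
#' joint distribution of a column pair is the clade-size-weighted mixture of
#' the products of clade marginals:
#' `p_null(k, l) = sum_c n_c p_c(i = k) p_c(j = l) / sum_c n_c`.
#' Marginals (and hence `H_i`) are unchanged; the null NMI is assembled from
#' `(H_i, H_j, H_null_ij)`. With singleton clades this reproduces the
#' empirical joint exactly (null = total covariation); with a single
#' all-encompassing clade it reduces to the product of the overall marginals
#' (null NMI = 0 off-diagonal).
#'
#' @param msa A gap-free [new_msa()] object.
#' @param partition A [partition_clades()] result.
#' @return A [new_covariation_matrix()] with metric `"nmi"`; its diagonal is
#'   copied from the observed NMI diagonal so the nested-coevolution diagonal
#'   is zero.
#' @export
analytical_null_nmi <- function(msa, partition) {
  stopifnot(inherits(msa, "msa"), inherits(partition, "clade_partition"))
  enc <- encode_msa(msa)
  n <- nrow(enc)
  p <- ncol(enc)
  if (length(partition$labels) != n) {
    stop("partition does not cover the alignment rows", call. = FALSE)
  }
  X <- onehot_encoded(enc)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = partition$labels, x = 1,
                            dims = c(n, partition$n_clades))
  counts_c <- as.matrix(Matrix::crossprod(X, Z))        # 20p x C clade counts
  # null pair-count matrix: sum_c outer(m_c, m_c) / n_c
  K <- counts_c %*% (t(counts_c) / partition$clade_sizes)
  P <- K / n
  G <- block_indicator(p)
  S <- as.matrix(Matrix::t(G) %*% xlogx(P) %*% G)
  H_null <- pmax(-S, 0)
  marg <- Matrix::colSums(X)
  H <- pmax(log(n) - as.vector(Matrix::t(G) %*% xlogx(marg)) / n, 0)
  null <- nmi_from_tables(H, H_null)
  diag(null) <- as.numeric(H > 0)  # matches the observed NMI diagonal
  new_covariation_matrix(null, "nmi")
}

#' Nested-coevolution correction across phylogenetic cutoffs
#'
#' For each cutoff `d`, partitions the sequences into clades, estimates the
#' inter-clade null `C_{S>d}` (analytically for NMI, or by within-clade
#' bootstrap for any metric) and subtracts it from the total covariation:
#' `C_{S<=d} = C_T - C_{S>d}`. Positive entries mark covariation exceeding
#' what phylogeny alone explains at that timescale; negative entries (signal
#' below the null) are preserved, not clipped.
#'
#' @param msa A gap-free [new_msa()] object.
#' @param cutoffs Numeric vector of positive Jukes-Cantor cutoffs (default
#'   `c(0.2, 0.5, 0.8, 1.1)`).
#' @param metric `"nmi"`, `"di"` or `"frobenius"`.
#' @param null_mode `"analytical"` (NMI only) or `"bootstrap"`.
#' @param n_bootstrap Bootstrap replicates when `null_mode = "bootstrap"`.
#' @param seed Root seed for the bootstrap.
#' @param dm Optional precomputed [jc_distance()] matrix.
#' @return A list of class `nc_result_set`: one `nc_result` per cutoff, each
#'   with fields `cutoff_d`, `total`, `null_mean`, `nc`, `significance`
#'   (bootstrap mode only), `partition`, `null_mode`, `n_bootstrap`, `seed`.
#' @export
nc_correct <- function(msa, cutoffs = c(0.2, 0.5, 0.8, 1.1),
                       metric = c("nmi", "di", "frobenius"),
                       null_mode = c("analytical", "bootstrap"),
                       n_bootstrap = 100L, seed = 1L, dm = NULL) {
  metric <- match.arg(metric)
  null_mode <- match.arg(null_mode)
  if (length(cutoffs) == 0L || any(cutoffs <= 0)) {
    stop("cutoffs must be a nonempty vector of positive distances",
         call. = FALSE)
  }
  if (null_mode == "analytical" && metric != "nmi") {
    stop("no closed form for metric '", metric, "'; use null_mode = \"bootstrap\"",
         call. = FALSE)
  }
  if (is.null(dm)) dm <- jc_distance(msa)
  total <- metric_matrix(msa, metric)
  results <- lapply(cutoffs, function(d) {
    part <- partition_clades(dm, d)
    if (null_mode == "analytical") {
      null_mean <- analytical_null_nmi(msa, part)
      significance <- NULL
    } else {
      bn <- bootstrap_null(msa, part, metric, n_bootstrap, seed,
                           observed = total)
      null_mean <- bn$null_mean
      significance <- bn$significance
    }
    nc <- new_covariation_matrix(unclass(total) - unclass(null_mean),
                                 metric, corrections = sprintf("nc@%g", d))
    structure(list(cutoff_d = d, total = total, null_mean = null_mean,
                   nc = nc, significance = significance, partition = part,
                   null_mode = null_mode,
                   n_bootstrap = if (null_mode == "bootstrap") n_bootstrap else 0L,
                   seed = seed),
              class = "nc_result")
  })
  structure(results, class = "nc_result_set")
}

#' @export
print.nc_result <- function(x, ...) {
  cat(sprintf("<nc_result> cutoff d = %g (%d clades), metric %s, null: %s\n",
              x$cutoff_d, x$partition$n_clades, attr(x$total, "metric"),
              x$null_mode))
  invisible(x)
}

#' @export
print.nc_result_set <- function(x, ...) {
  cat(sprintf("<nc_result_set> %d cutoffs: %s\n", length(x),
              paste(vapply(x, function(r) r$cutoff_d, numeric(1)),
                    collapse = ", ")))
  invisible(x)
}
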