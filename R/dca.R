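# Mean-field direct coupling analysis: sequence reweighting, pseudocount
# regularization, naive mean-field inversion of the connected-correlation
# matrix, and the direct-information and Frobenius-norm coupling scores.

#' Mean-field direct coupling analysis
#'
#' Fits a global pairwise (Potts) model by naive mean-field inversion and
#' scores every column pair by direct information (DI) and by the Frobenius
#' norm of the zero-sum-gauge coupling block. Sequences closer than
#' `reweight_threshold` (Hamming fraction) are downweighted:
#' `w_s = 1 / |{t : hamming(s, t) < threshold}|`. Frequencies are regularized
#' as `f_tilde = (1 - lambda) * f_weighted + lambda / q` (pair counterpart
#' `lambda / q^2` off-diagonal) with `q = 20`. The correlation matrix is
#' inverted on a reduced alphabet (last symbol dropped); couplings are
#' re-expanded in the zero-sum gauge for the Frobenius score.
#'
#' @param msa A gap-free [new_msa()] object with at least 2 sequences.
#' @param pseudocount Relative pseudocount weight `lambda` in \[0, 1)
#'   (default 0.5).
#' @param reweight_threshold Hamming-fraction similarity threshold for
#'   reweighting (default 0.3).
#' @param di_tol,di_max_iter Convergence tolerance and iteration cap for the
#'   two-site compensating-field fixed point.
#' @return A list with components `di` and `frobenius` (both symmetric
#'   [new_covariation_matrix()] objects with zero diagonal), plus `weights`
#'   and `m_eff`.
#' @export
mfdca <- function(msa, pseudocount = 0.5, reweight_threshold = 0.3,
                  di_tol = 1e-6, di_max_iter = 200L) {
  stopifnot(inherits(msa, "msa"))
  enc <- encode_msa(msa)
  n <- nrow(enc)
  p <- ncol(enc)
  if (n < 2L) stop("mfdca requires at least 2 sequences", call. = FALSE)
  q <- N_AA
  lambda <- pseudocount
  stopifnot(lambda >= 0, lambda < 1)

  X <- onehot_encoded(enc)
  matches <- as.matrix(Matrix::tcrossprod(X))
  hamming <- 1 - matches / p
  w <- 1 / rowSums(hamming < reweight_threshold)  # self included (distance 0)
  m_eff <- sum(w)

  fi <- as.vector(Matrix::crossprod(X, w)) / m_eff            # 20p
  fij <- as.matrix(Matrix::crossprod(X, X * w)) / m_eff       # 20p x 20p

  fi_t <- (1 - lambda) * fi + lambda / q
  fij_t <- (1 - lambda) * fij + lambda / q^2
  # same-position blocks: f_ii(k, l) = fi(k) * delta_kl (with lambda / q)
  for (i in seq_len(p)) {
    idx <- (i - 1L) * q + seq_len(q)
    blk <- matrix(0, q, q)
    diag(blk) <- fi_t[idx]
    fij_t[idx, idx] <- blk
  }

  # connected correlations on the reduced alphabet (drop state q)
  keep <- which(rep(seq_len(q), p) != q)
  C <- fij_t[keep, keep] - tcrossprod(fi_t[keep])
  invC <- tryCatch(solve(C), error = function(e) {
    stop("singular correlation matrix in mean-field inversion; ",
         "raise the pseudocount (", conditionMessage(e), ")", call. = FALSE)
  })

  di <- matrix(0, p, p)
  fro <- matrix(0, p, p)
  qr_ <- q - 1L
  warn_nonconv <- 0L
  for (i in seq_len(p - 1L)) {
    ii <- (i - 1L) * qr_ + seq_len(qr_)
    pi_ <- fi_t[(i - 1L) * q + seq_len(q)]
    for (j in (i + 1L):p) {
      jj <- (j - 1L) * qr_ + seq_len(qr_)
      e_red <- -invC[ii, jj]
      e_full <- matrix(0, q, q)
      e_full[seq_len(qr_), seq_len(qr_)] <- e_red
      # Frobenius norm in the zero-sum gauge
      K <- e_full - outer(rowMeans(e_full), rep(1, q)) -
        outer(rep(1, q), colMeans(e_full)) + mean(e_full)
      fro[i, j] <- sqrt(sum(K^2))
      # DI from the two-site model with compensating fields
      W <- exp(e_full)
      pj_ <- fi_t[(j - 1L) * q + seq_len(q)]
      mu1 <- rep(1 / q, q)
      mu2 <- rep(1 / q, q)
      converged <- FALSE
      for (it in seq_len(di_max_iter)) {
        scra1 <- as.vector(W %*% mu2)
        scra2 <- as.vector(crossprod(W, mu1))
        new1 <- pi_ / scra1
        new1 <- new1 / sum(new1)
        new2 <- pj_ / scra2
        new2 <- new2 / sum(new2)
        delta <- max(abs(new1 - mu1), abs(new2 - mu2))
        mu1 <- new1
        mu2 <- new2
        if (delta < di_tol) {
          converged <- TRUE
          break
        }
      }
      if (!converged) warn_nonconv <- warn_nonconv + 1L
      pdir <- W * outer(mu1, mu2)
      pdir <- pdir / sum(pdir)
      ref <- outer(pi_, pj_)
      di[i, j] <- sum(pdir * log(pdir / ref))
    }
  }
  if (warn_nonconv > 0L) {
    warning(warn_nonconv, " pairs did not reach the DI fixed-point tolerance; ",
            "values taken at the last iterate")
  }
  di <- di + t(di)
  fro <- fro + t(fro)
  list(di = new_covariation_matrix(di, "di"),
       frobenius = new_covariation_matrix(fro, "frobenius"),
       weights = w, m_eff = m_eff)
}
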