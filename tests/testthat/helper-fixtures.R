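# Shared fixtures and independent oracle implementations. Oracles are
# deliberately naive (nested loops, direct formulas) so they stay independent
# of the vectorized code paths they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

msa_from_strings <- function(strings, ids = NULL, ref = 1L) {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_along(strings))
  residues <- do.call(rbind, strsplit(toupper(strings), ""))
  new_msa(residues, ids, ref)
}

random_msa <- function(n, p, seed) {
  set.seed(seed)
  new_msa(matrix(sample(AA20, n * p, replace = TRUE), n, p),
          sprintf("r%03d", seq_len(n)), 1L)
}

# brute-force Jukes-Cantor distance between two residue vectors (gap-aware)
oracle_jc <- function(a, b) {
  both <- a != "-" & b != "-"
  if (!any(both)) return(Inf)
  pm <- mean(a[both] != b[both])
  if (pm >= 19 / 20) return(10)
  -(19 / 20) * log(1 - (20 / 19) * pm)
}

oracle_jc_matrix <- function(msa, columns = NULL) {
  res <- msa$residues
  if (!is.null(columns)) res <- res[, columns, drop = FALSE]
  n <- nrow(res)
  d <- matrix(0, n, n)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      d[a, b] <- d[b, a] <- oracle_jc(res[a, ], res[b, ])
    }
  }
  d
}

# direct-formula entropy of a character vector
oracle_entropy <- function(x) {
  f <- table(x) / length(x)
  -sum(f * log(f))
}

# brute-force APC on a symmetric matrix, means over off-diagonal entries
oracle_apc <- function(m) {
  p <- nrow(m)
  rm <- vapply(seq_len(p), function(i) mean(m[i, -i]), numeric(1))
  gm <- mean(m[row(m) != col(m)])
  out <- m - outer(rm, rm) / gm
  diag(out) <- 0
  out
}

# enumerate the analytical null joint distribution of columns i, j directly
oracle_null_nmi_pair <- function(msa, labels, i, j) {
  res <- msa$residues
  n <- nrow(res)
  pnull <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  for (lab in unique(labels)) {
    rows <- which(labels == lab)
    pi_c <- table(factor(res[rows, i], levels = AA20)) / length(rows)
    pj_c <- table(factor(res[rows, j], levels = AA20)) / length(rows)
    pnull <- pnull + length(rows) * outer(as.numeric(pi_c), as.numeric(pj_c))
  }
  pnull <- pnull / n
  hnull <- -sum(pnull[pnull > 0] * log(pnull[pnull > 0]))
  hi <- oracle_entropy(res[, i])
  hj <- oracle_entropy(res[, j])
  if (hnull == 0) return(0)
  (hi + hj - hnull) / hnull
}

# brute-force scan for top-k true positives
oracle_top_k <- function(m, cm, k, min_sep) {
  p <- nrow(m)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (j - i > min_sep) {
        rows <- c(rows, i); cols <- c(cols, j); vals <- c(vals, m[i, j])
      }
    }
  }
  ord <- order(-vals, rows, cols)
  sum(cm[cbind(rows[ord[seq_len(k)]], cols[ord[seq_len(k)]])])
}

# deterministic 2-clade fixture used by several nested-coevolution tests
two_clade_fixture <- function(seed = 42) {
  simulate_clade_msa(n_clades = 2, seqs_per_clade = 100, p = 50, seed = seed)
}

# the 200-replicate bootstrap on the 2-clade fixture is shared between two
# acceptance checks; compute it once per test run
.fixture_cache <- new.env(parent = emptyenv())
fixture_bootstrap_200 <- function() {
  if (is.null(.fixture_cache$boot)) {
    sim <- two_clade_fixture()
    part <- partition_clades(jc_distance(sim$msa), 0.5)
    .fixture_cache$boot <- bootstrap_null(sim$msa, part, "nmi",
                                          n_bootstrap = 200, seed = 7)
  }
  .fixture_cache$boot
}
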