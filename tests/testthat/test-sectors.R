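# sectors: supermatrix spectra, sector extraction/pairing, compactness,
# MirrorTree, random-group nulls, meta-sectors, DMS enrichment

sym_fixture <- function(p, seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(p * p), p, p)
  (m + t(m)) / 2
}

pop_cov <- function(m) {
  c_ <- scale(m, center = TRUE, scale = FALSE)
  crossprod(c_) / nrow(c_)
}

test_that("identical stacked matrices reproduce the single-matrix spectrum", {
  m <- sym_fixture(8, 1)
  single <- eigen(pop_cov(m), symmetric = TRUE)
  spec <- nc_supermatrix_spectrum(list(m, m, m), apply_apc = FALSE)
  expect_equal(spec$values, single$values, tolerance = 1e-10)
  expect_equal(abs(spec$vectors), abs(single$vectors), tolerance = 1e-8)
})

test_that("supermatrix spectra satisfy the spectral identities", {
  mats <- lapply(1:3, function(s) sym_fixture(10, s))
  spec <- nc_supermatrix_spectrum(mats, apply_apc = FALSE)
  supermat <- do.call(rbind, mats)
  expect_equal(sum(spec$values), sum(diag(pop_cov(supermat))),
               tolerance = 1e-8)
  gram <- crossprod(spec$vectors)
  expect_equal(gram, diag(10), tolerance = 1e-8)
  # orientation: max-|coefficient| entry of every eigenvector is positive
  for (k in seq_len(10)) {
    v <- spec$vectors[, k]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_error(nc_supermatrix_spectrum(list(sym_fixture(4, 1),
                                            sym_fixture(5, 2))),
               "inconsistent")
})

test_that("baseline_spectrum matches eigen() and the shift identity", {
  m <- sym_fixture(5, 7)
  spec <- baseline_spectrum(m)
  ref <- eigen(m, symmetric = TRUE)
  expect_equal(spec$values, ref$values, tolerance = 1e-12)
  shifted <- baseline_spectrum(m + diag(5))
  expect_equal(shifted$values, spec$values + 1, tolerance = 1e-10)
  expect_equal(abs(shifted$vectors), abs(spec$vectors), tolerance = 1e-8)
  expect_error(baseline_spectrum(matrix(1:9, 3, 3)), "symmetric")
  # diagonal matrix: coordinate axes ordered by diagonal value
  dspec <- baseline_spectrum(diag(c(3, 9, 1)))
  expect_equal(dspec$values, c(9, 3, 1))
  expect_equal(abs(dspec$vectors[, 1]), c(0, 1, 0))
})

test_that("extract_sector selects extremes, orders by |coefficient|", {
  vecs <- diag(10)
  vecs[, 1] <- c(0.9, -0.8, 0.7, 0.1, -0.05, 0.02, 0, 0, 0, 0)
  vecs[, 1] <- vecs[, 1] / sqrt(sum(vecs[, 1]^2))
  spec <- structure(list(values = 10:1, vectors = vecs, source = "baseline"),
                    class = "eigen_spectrum")
  pos <- extract_sector(spec, 1, "positive", 2)
  expect_equal(pos$positions, c(1L, 3L))
  neg <- extract_sector(spec, 1, "negative", 1)
  expect_equal(neg$positions, 2L)
  expect_true(neg$ignored)          # < 4 residues
  big <- extract_sector(spec, 1, "positive", 5)
  expect_false(big$ignored)
  # prefix property: smaller cutoffs are prefixes of larger ones
  expect_equal(big$positions[1:2], pos$positions)
  expect_error(extract_sector(spec, 1, "positive", 11), "exceeds")
})

test_that("negating an eigenvector swaps the signed sectors", {
  m <- sym_fixture(12, 3)
  spec <- baseline_spectrum(m)
  flipped <- spec
  flipped$vectors[, 2] <- -flipped$vectors[, 2]
  a <- extract_sector(spec, 2, "positive", 5)
  b <- extract_sector(flipped, 2, "negative", 5)
  expect_equal(a$positions, b$positions)
})

test_that("pair_sectors matches identical, orthogonal and planted cases", {
  m <- sym_fixture(8, 5)
  spec <- baseline_spectrum(m)
  same <- pair_sectors(spec, spec)
  expect_equal(same$nc_index, same$base_index)
  expect_equal(same$dot, rep(1, 8), tolerance = 1e-10)

  # orthogonal complements never pair
  v <- eigen(m, symmetric = TRUE)$vectors
  specA <- structure(list(values = 8:1, vectors = v[, 1:4],
                          source = "baseline"), class = "eigen_spectrum")
  specB <- structure(list(values = 8:1, vectors = v[, 5:8],
                          source = "baseline"), class = "eigen_spectrum")
  expect_equal(nrow(pair_sectors(specA, specB)), 0L)

  # planted rotation: one shared direction with dot 0.8
  u1 <- v[, 1]
  u2 <- 0.8 * u1 + sqrt(1 - 0.8^2) * v[, 2]
  specC <- structure(list(values = 1, vectors = cbind(u2),
                          source = "baseline"), class = "eigen_spectrum")
  got <- pair_sectors(specA, specC)
  expect_equal(nrow(got), 1L)
  expect_equal(got$nc_index, 1L)
  expect_equal(abs(got$dot), 0.8, tolerance = 1e-10)
})

test_that("spatial_compactness equals the mean pairwise distance", {
  two <- new_structure_coords(rbind(c(0, 0, 0), c(10, 0, 0)), 1:2)
  expect_equal(spatial_compactness(1:2, two), 10)
  tri <- new_structure_coords(rbind(c(0, 0, 0), c(5, 0, 0),
                                    c(2.5, 5 * sqrt(3) / 2, 0)), 1:3)
  expect_equal(spatial_compactness(1:3, tri), 5, tolerance = 1e-12)
  # 15-residue random group vs brute-force pair loop
  coords <- simulate_structure(30, seed = 8)
  grp <- c(2, 5, 7, 11, 14, 15, 18, 20, 21, 23, 25, 26, 27, 29, 30)
  acc <- 0; npair <- 0
  for (a in seq_along(grp)[-length(grp)]) {
    for (b in (a + 1):length(grp)) {
      acc <- acc + sqrt(sum((coords$xyz[grp[a], ] - coords$xyz[grp[b], ])^2))
      npair <- npair + 1
    }
  }
  expect_equal(spatial_compactness(grp, coords), acc / npair,
               tolerance = 1e-12)
  expect_error(spatial_compactness(c(1, 99), coords), "not mapped")
})

test_that("mirrortree_score is exactly 1 for identical operands", {
  msa <- two_clade_fixture()$msa
  expect_equal(mirrortree_score(msa, 1:50, 1:50)$value, 1.0)
  expect_equal(mirrortree_score(msa, c(3, 7, 9), c(3, 7, 9))$value, 1.0)
  # ALL as second operand is the sector-protein mode
  s <- mirrortree_score(msa, 1:50)
  expect_equal(s$value, 1.0)
  expect_equal(s$operands, "sector-protein")
})

test_that("mirrortree_score matches a hand-built small-fixture computation", {
  msa <- msa_from_strings(c("AAAACC", "AAAADD", "VVAACC", "VVVVCC"))
  a <- 1:2
  b <- 3:4
  da <- oracle_jc_matrix(msa, a)[upper.tri(matrix(0, 4, 4))]
  db <- oracle_jc_matrix(msa, b)[upper.tri(matrix(0, 4, 4))]
  expect_equal(mirrortree_score(msa, a, b)$value, cor(da, db),
               tolerance = 1e-12)
})

test_that("zero-variance distances give a flagged missing score", {
  msa <- msa_from_strings(c("AAC", "AAD", "AAV"))
  s <- mirrortree_score(msa, 1:2, 3)   # columns 1-2 constant
  expect_true(s$undefined)
  expect_true(is.na(s$value))
})

test_that("random_group_null excludes forbidden columns and calibrates", {
  msa <- two_clade_fixture()$msa
  rg <- random_group_null(msa, size = 10, n_samples = 50, seed = 2,
                          exclude = 1:20)
  expect_true(all(rg$groups > 20))
  # a group drawn from the null itself should rarely look extreme
  z <- null_z(rg, "mirrortree", rg$samples$mirrortree[1])
  expect_lt(abs(z), 4)
  expect_true(all(c("mean", "sd", "ci_lower", "ci_upper") %in%
                    names(rg$summary$mirrortree)))
})

test_that("entropy-biased sampling drives group entropy to the target", {
  msa <- two_clade_fixture()$msa
  H <- entropy_profile(msa)
  target <- stats::median(H) + 0.1
  rg <- random_group_null(msa, size = 12, n_samples = 100, seed = 6,
                          entropy_target = target)
  uniform <- random_group_null(msa, size = 12, n_samples = 100, seed = 6)
  bias <- abs(mean(rg$samples$mean_entropy) - target)
  expect_lt(bias, abs(mean(uniform$samples$mean_entropy) - target))
  expect_lt(bias, 0.1)
  expect_error(random_group_null(msa, size = 12, n_samples = 10, seed = 1,
                                 entropy_target = 10),
               "attainable")
})

test_that("a planted compact sector has compactness z < -2", {
  sector <- 11:25
  coords <- simulate_structure(50, sector_positions = sector,
                               cluster_radius_A = 6, seed = 12)
  msa <- two_clade_fixture()$msa
  rg <- random_group_null(msa, size = 15, n_samples = 300, seed = 4,
                          coords = coords)
  z <- null_z(rg, "compactness", spatial_compactness(sector, coords))
  expect_lt(z, -2)
})

test_that("meta-sectors merge signed eigenvectors within clusters", {
  # two sectors with disjoint high-coefficient supports in one cluster,
  # a third (anti-correlated sector pair) kept apart by the score matrix
  p <- 20
  v1 <- c(rep(5, 5), rep(0.1, 15))
  v2 <- c(rep(0.1, 10), rep(5, 5), rep(0.1, 5))
  v3 <- rep(0.1, 20); v3[18:20] <- 4
  mk <- function(v, sign) structure(
    list(positions = order(-v)[1:5], coefficients = if (sign == "positive") v
         else -v,
         eigenvector_index = 1L, sign = sign, size_cutoff = 5L,
         ignored = FALSE, source = "nc_supermatrix"), class = "sector")
  s1 <- mk(v1, "positive")
  s2 <- mk(v2, "positive")
  s3 <- mk(-v3, "negative")   # negative sector: coefficients already -(-v3)
  score <- matrix(0.1, 3, 3)
  score[1, 2] <- score[2, 1] <- 0.95
  diag(score) <- 1
  merged <- meta_sectors(list(s1, s2, s3), score, n_clusters = 2,
                         size_cutoff = 10)
  sizes <- vapply(merged, function(s) length(s$positions), integer(1))
  expect_equal(sizes, c(10L, 10L))
  members <- lapply(merged, function(s) s$members)
  joint <- merged[[which(vapply(members, length, integer(1)) == 2)]]
  # union of the two top-5 supports fills the merged top-10
  expect_setequal(joint$positions, c(1:5, 11:15))
  # the negative sector contributed its negated eigenvector
  solo <- merged[[which(vapply(members, length, integer(1)) == 1)]]
  expect_true(all(18:20 %in% solo$positions[1:3]))
  # single sector passes through unchanged
  expect_identical(meta_sectors(list(s1), score[1, 1, drop = FALSE], 1),
                   list(s1))
})

test_that("dominant_sector picks the coherent signed side", {
  v <- c(rep(-0.25, 6), 0.3, rep(0.01, 13))  # block of 6 negatives, 1 spike
  spec <- structure(list(values = 1, vectors = cbind(v), source = "test"),
                    class = "eigen_spectrum")
  sec <- dominant_sector(spec, 1, 6)
  expect_equal(sec$sign, "negative")
  expect_setequal(sec$positions, 1:6)
})

test_that("dms_enrichment reproduces exhaustive per-position extremes", {
  tab <- data.frame(
    position = rep(1:3, each = 3),
    mutant_aa = rep(c("A", "C", "D"), 3),
    score = c(-1, 0.5, 2, -3, -0.5, 0.2, 1, 1.5, 0.7))
  res <- dms_enrichment(1:2, tab, n_samples = 200, seed = 1)
  expect_equal(res$per_position$min_score, c(-1, -3))
  expect_equal(res$per_position$max_score, c(2, 0.2))
  expect_equal(res$mean_min, -2)
  expect_equal(res$mean_max, 1.1)
  expect_error(dms_enrichment(c(1, 9), tab), "absent")
})

test_that("a sector planted on damaging positions has mean-min z < -2", {
  set.seed(30)
  positions <- 1:60
  sector <- 5:14
  tab <- do.call(rbind, lapply(positions, function(pos) {
    base <- if (pos %in% sector) -4 else 0
    data.frame(position = pos, mutant_aa = AA20[1:5],
               score = stats::rnorm(5, mean = base, sd = 0.5))
  }))
  res <- dms_enrichment(sector, tab, n_samples = 500, seed = 8)
  expect_lt(res$z_min, -2)
})
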