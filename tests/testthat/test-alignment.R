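# alignment_io: FASTA parsing, the preprocessing recipe, subsampling

test_that("read_alignment parses aligned FASTA, normalizes gaps and case", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEFGhikl", ">b", "ACD.FGHIKL", ">c", "ACD-FGHIKL"),
             path)
  msa <- read_alignment(path, "a")
  expect_s3_class(msa, "msa")
  expect_equal(dim(msa), c(3L, 10L))
  expect_equal(msa$ids, c("a", "b", "c"))
  expect_equal(unname(msa$residues[1, 7]), "H")  # lowercase uppercased
  expect_equal(unname(msa$residues[2, 4]), "-")  # '.' parsed as gap
  expect_identical(msa$residues[2, ], msa$residues[3, ])
  expect_equal(msa$reference_index, 1L)
})

test_that("read_alignment rejects ragged, empty and bad-reference inputs", {
  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEF", ">b", "ACDE"), ragged)
  expect_error(read_alignment(ragged, "a"), "ragged")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_error(read_alignment(empty, "a"), "empty")

  ok <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEF", ">b", "ACDEV"), ok)
  expect_error(read_alignment(ok, "zz"), "not found")
  expect_error(read_alignment(file.path(tempdir(), "nope.fa"), "a"),
               "not found")
})

test_that("duplicate identifiers are rejected at construction", {
  expect_error(
    new_msa(matrix("A", 2, 3), c("x", "x")),
    "duplicate"
  )
})

test_that("alignment round-trips through FASTA", {
  msa <- random_msa(8, 12, seed = 5)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(msa, path)
  back <- read_alignment(path, msa$ids[1])
  expect_identical(back$residues, msa$residues)
  expect_identical(back$ids, msa$ids)
})

test_that("preprocess_msa prunes distant sequences, dedups, fills gaps", {
  # s_far differs from the reference at 35/50 positions: JC distance > 1
  set.seed(1)
  ref <- sample(AA20, 50, replace = TRUE)
  near <- ref
  near[1:3] <- vapply(near[1:3], function(a) setdiff(AA20, a)[1], "")
  far <- ref
  far[1:35] <- vapply(far[1:35], function(a) setdiff(AA20, a)[2], "")
  expect_gt(oracle_jc(ref, far), 1)
  msa <- new_msa(rbind(ref, near, near, far),
                 c("ref", "near", "near_dup", "far"), 1L)
  clean <- preprocess_msa(msa)
  expect_false("far" %in% clean$ids)       # pruned: JC > 1 from reference
  expect_false("near_dup" %in% clean$ids)  # exact duplicate removed
  expect_equal(clean$ids, c("ref", "near"))
  expect_false(any(clean$residues == "-"))
})

test_that("gappy columns are removed at the 25% threshold (strict)", {
  # column 1: 26% gaps -> removed; column 2: exactly 25% -> kept and filled.
  # Columns 5-6 make every row unique and keep all rows near the reference.
  n <- 100
  res <- matrix(rep(c("A", "C", "D", "E", "F", "G"), each = n), n, 6)
  res[seq_len(26), 1] <- "-"
  res[seq_len(25), 2] <- "-"
  res[, 5] <- AA20[(seq_len(n) - 1) %/% 20 + 1]
  res[, 6] <- AA20[(seq_len(n) - 1) %% 20 + 1]
  msa <- new_msa(res, sprintf("q%03d", 1:n), 30L)
  clean <- preprocess_msa(msa)
  expect_equal(nrow(clean$residues), n)   # nothing pruned or deduplicated
  expect_equal(ncol(clean$residues), 5L)  # only the 26%-gap column dropped
  expect_false(any(clean$residues == "-"))
})

test_that("gaps are filled from the nearest sequence, ties to lowest row", {
  # column 2 has 25% gaps (kept, at the threshold); row g2 is the nearest
  # sequence to g1 over shared columns and donates its "W"
  res <- rbind(
    c("A", "-", "C", "C", "C", "C"),
    c("A", "W", "C", "C", "C", "C"),
    c("A", "Y", "C", "C", "C", "D"),
    c("A", "Y", "C", "C", "D", "D")
  )
  msa <- new_msa(res, c("g1", "g2", "g3", "g4"), 2L)
  clean <- preprocess_msa(msa)
  expect_equal(unname(clean$residues[clean$ids == "g1", 2]), "W")  # nearest donor
})

test_that("the reference survives deduplication", {
  res <- rbind(c("A", "C", "D"), c("A", "C", "D"), c("A", "C", "V"))
  msa <- new_msa(res, c("dup", "ref", "other"), 2L)
  clean <- preprocess_msa(msa)
  expect_true("ref" %in% clean$ids)
  expect_false("dup" %in% clean$ids)
  expect_equal(clean$ids[clean$reference_index], "ref")
})

test_that("nonstandard residues are mapped to gap and handled", {
  res <- rbind(c("A", "X", "D"), c("A", "C", "D"), c("A", "C", "V"))
  msa <- new_msa(res, c("a", "b", "c"), 2L)
  clean <- preprocess_msa(msa)
  expect_false(any(clean$residues %in% c("X", "B", "Z")))
  expect_false(any(clean$residues == "-"))
})

test_that("preprocess_msa is idempotent", {
  sim <- two_clade_fixture()
  once <- preprocess_msa(sim$msa)
  twice <- preprocess_msa(once)
  expect_identical(twice$residues, once$residues)
  expect_identical(twice$ids, once$ids)
})

test_that("subsample keeps everything at fraction 1 and is seed-stable", {
  msa <- two_clade_fixture()$msa
  expect_identical(subsample_msa(msa, 1.0, "breadth", seed = 3), msa)
  a <- subsample_msa(msa, 0.2, "breadth", seed = 9)
  b <- subsample_msa(msa, 0.2, "breadth", seed = 9)
  expect_identical(a$ids, b$ids)
  expect_true(msa$ids[msa$reference_index] %in% a$ids)
})

test_that("depth subsampling matches an independent full sort oracle", {
  msa <- two_clade_fixture()$msa
  k <- round(0.1 * nrow(msa$residues))
  got <- subsample_msa(msa, 0.1, "depth", seed = 1)
  d <- vapply(seq_len(nrow(msa$residues)), function(s)
    oracle_jc(msa$residues[s, ], msa$residues[msa$reference_index, ]),
    numeric(1))
  want <- sort(msa$ids[order(d, seq_along(d))[seq_len(k)]])
  expect_setequal(got$ids, want)
  expect_equal(nrow(got$residues), k)
})

test_that("depth subsamples sit closer to the reference than breadth", {
  msa <- two_clade_fixture()$msa
  ref_row <- msa$residues[msa$reference_index, ]
  maxd <- function(m) max(vapply(seq_len(nrow(m$residues)), function(s)
    oracle_jc(m$residues[s, ], ref_row), numeric(1)))
  depth <- subsample_msa(msa, 0.2, "depth", seed = 4)
  breadth <- subsample_msa(msa, 0.2, "breadth", seed = 4)
  expect_lt(maxd(depth), maxd(breadth))
})

test_that("degenerate subsamples are rejected", {
  msa <- random_msa(10, 8, seed = 2)
  expect_error(subsample_msa(msa, 0.05, "breadth"), "fewer than 2")
  expect_error(subsample_msa(msa, 0, "breadth"), "fraction")
})
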