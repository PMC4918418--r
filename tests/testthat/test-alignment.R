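test_that("FASTA alignments read, normalise and round-trip", {
  path <- write_temp_fasta(c("ACDE-", "ac.eF", "AZDE-"))
  aln <- read_alignment(path, "fasta")
  expect_equal(aln$n_sequences, 3)
  expect_equal(aln$n_columns, 5)
  expect_equal(aln$seqs[2, ], c("A", "C", "-", "E", "F"))  # upper, . -> gap
  expect_equal(aln$seqs[3, 2], "X")                        # unknown -> missing
  out <- tempfile(fileext = ".fasta")
  write_alignment(aln, out)
  expect_equal(read_alignment(out, "fasta")$seqs, aln$seqs)
  expect_error(read_alignment(write_temp_fasta(c("ACDE", "AC"))), "ragged")
  expect_error(read_alignment(tempfile()), "no such file")
})

test_that("Stockholm alignments parse with insert-state conventions", {
  path <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               "#=GF ID test",
               "seq1 ACD.e",
               "seq2 ac-EF",
               "",
               "seq1 GH",
               "seq2 gh",
               "//"), path)
  aln <- read_alignment(path, "stockholm")
  expect_equal(aln$n_sequences, 2)
  expect_equal(aln$n_columns, 7)            # interleaved blocks concatenated
  expect_equal(aln$seqs[1, ], c("A", "C", "D", "-", "E", "G", "H"))
  expect_equal(aln$seqs[2, 3], "-")
})

test_that("Henikoff weights match hand-computed cases", {
  # identical sequences: equal weights
  path <- write_temp_fasta(rep("ACDE", 4))
  expect_equal(henikoff_weights(read_alignment(path)), rep(0.25, 4))
  # single column A, A, B: r = 2 distinct, so weights (1/4, 1/4, 1/2)
  path2 <- write_temp_fasta(c("A", "A", "C"))
  expect_equal(henikoff_weights(read_alignment(path2)), c(0.25, 0.25, 0.5))
  # gaps contribute nothing
  path3 <- write_temp_fasta(c("A-", "A-", "C-"))
  expect_equal(henikoff_weights(read_alignment(path3)), c(0.25, 0.25, 0.5))
  expect_error(henikoff_weights(read_alignment(write_temp_fasta(c("--", "--")))),
               "degenerate")
})

test_that("package weights match a brute-force oracle; duplication lowers others", {
  # independent position-based weighting oracle, unnormalised
  raw_weights <- function(mat) {
    w <- numeric(nrow(mat))
    for (j in seq_len(ncol(mat))) {
      col <- mat[, j]
      counts <- table(col)
      r <- length(counts)
      w <- w + 1 / (r * as.numeric(counts[col]))
    }
    w
  }
  set.seed(31)
  for (rep in 1:5) {
    mat <- matrix(sample(c("A", "C", "D", "E", "F"), 50, TRUE), 5, 10)
    aln <- read_alignment(write_temp_fasta(apply(mat, 1, paste, collapse = "")))
    raw <- raw_weights(mat)
    expect_equal(henikoff_weights(aln), raw / sum(raw), tolerance = 1e-12)
    # duplicating sequence 5 never increases any other's unnormalised weight
    raw_dup <- raw_weights(mat[c(1:5, 5), ])
    expect_true(all(raw_dup[1:4] <= raw[1:4] + 1e-12))
  }
})

test_that("alignment size gates reject small alignments with a reason", {
  small <- read_alignment(write_temp_fasta(rep(strrep("A", 50), 150)))
  ps <- site_profiles(small)
  expect_equal(ps$rejected, "too few columns")
  expect_equal(nrow(ps$profiles), 0)
  shallow <- read_alignment(write_temp_fasta(rep(strrep("A", 150), 50)))
  expect_equal(site_profiles(shallow)$rejected, "too few sequences")
})

test_that("gap-heavy columns are excluded by weighted gap fraction", {
  # 10 sequences, equal weights; column 1: 6 gaps (60% > 50%), column 2 clean
  rows <- c(rep("-A", 6), rep("AA", 4))
  aln <- read_alignment(write_temp_fasta(rows))
  ps <- site_profiles(aln, weights = rep(0.1, 10), min_columns = 1,
                      min_sequences = 5)
  expect_equal(ps$kept_columns, 1L)  # 0-based: only the second column kept
  # a pure column is a delta profile
  expect_equal(unname(ps$profiles[1, "A"]), 1)
  expect_true(all(ps$profiles[1, -1] == 0))
})

test_that("weighted frequencies with equal weights equal plain frequencies", {
  set.seed(33)
  rows <- replicate(12, paste(sample(c("A", "C", "D"), 8, TRUE), collapse = ""))
  aln <- read_alignment(write_temp_fasta(rows))
  ps <- site_profiles(aln, weights = rep(1 / 12, 12), min_columns = 1,
                      min_sequences = 2)
  for (j in seq_along(ps$kept_columns)) {
    col <- aln$seqs[, ps$kept_columns[j] + 1L]
    expect_equal(unname(ps$profiles[j, "A"]), mean(col == "A"))
  }
})

test_that("profile estimation is consistent as depth grows", {
  set.seed(35)
  true_p <- random_profile()
  aa <- names(mm2$lambda)
  devs <- vapply(c(100, 1000, 10000), function(n) {
    draws <- sample(aa, n, TRUE, prob = true_p)
    rows <- vapply(draws, function(d) d, character(1))
    aln <- read_alignment(write_temp_fasta(rows))
    ps <- site_profiles(aln, weights = rep(1 / n, n), min_columns = 0.5,
                        min_sequences = 2)
    max(abs(ps$profiles[1, ] - true_p))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
})

test_that("frequency scatter reports per-pair correlations", {
  # X and Y split a fixed mass: perfect anticorrelation
  set.seed(37)
  a <- runif(20, 0.1, 0.6)
  P <- t(vapply(a, function(x) {
    p <- rep((1 - 0.7) / 18, 20)
    names(p) <- names(mm2$lambda)
    p["I"] <- x * 0.7; p["V"] <- (1 - x) * 0.7
    p / sum(p)
  }, numeric(20)))
  sc <- frequency_scatter(P, c("I", "V"))
  expect_equal(attr(sc, "correlation"), -1, tolerance = 1e-10)
  # iid profiles: negligible correlation
  P2 <- t(replicate(500, random_profile()))
  expect_lt(abs(attr(frequency_scatter(P2, c("L", "S")), "correlation")), 0.2)
  # co-enriched classes: positive correlation
  gp <- generate_profiles(400, seed = 41)
  expect_gt(attr(frequency_scatter(gp$profiles, c("I", "V")), "correlation"), 0)
  expect_error(frequency_scatter(P[1:2, ], c("I", "V")), "fewer than 3")
  expect_error(frequency_scatter(P, c("I", "I")), "distinct")
})
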