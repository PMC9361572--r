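test_that("codon site counts match neighbour enumeration", {
  # phenylalanine: only the third-position T->C change is synonymous
  expect_equal(count_codon_sites("TTT"), c(s = 1 / 3, n = 8 / 3))
  # tryptophan: every neighbour changes the amino acid or creates a stop
  expect_equal(count_codon_sites("TGG"), c(s = 0, n = 3))

  expect_error(count_codon_sites("TAA"), "stop")
  expect_error(count_codon_sites("NTT"), "codon")
})

test_that("site counts conserve s + n == 3 and match the oracle for all sense codons", {
  for (cd in oracle_sense_codons) {
    got <- count_codon_sites(cd)
    expect_equal(unname(sum(got)), 3, tolerance = 1e-12)
    expect_equal(got, oracle_sites(cd), tolerance = 1e-12)
  }
})

test_that("codon difference counts average over mutational pathways", {
  expect_equal(count_codon_differences("TTT", "TTC"), c(Sd = 1, Nd = 0))
  # TTT->GTA: path via GTT is (1 syn, 1 nonsyn), via TTA is (0 syn, 2 nonsyn)
  expect_equal(count_codon_differences("TTT", "GTA"), c(Sd = 0.5, Nd = 1.5))
  expect_equal(count_codon_differences("AAA", "AAA"), c(Sd = 0, Nd = 0))
  expect_error(count_codon_differences("TGA", "TGG"), "stop")
})

test_that("Sd + Nd equals the number of differing positions for random codon pairs", {
  set.seed(11)
  for (i in 1:200) {
    cd <- sample(oracle_sense_codons, 2)
    d <- count_codon_differences(cd[1], cd[2])
    k <- sum(strsplit(cd[1], "")[[1]] != strsplit(cd[2], "")[[1]])
    expect_equal(unname(sum(d)), k, tolerance = 1e-12)
    expect_equal(d, oracle_diffs(cd[1], cd[2]), tolerance = 1e-12)
  }
})

test_that("Jukes-Cantor correction is exact, saturating, and monotone", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.1), 0.1073256, tolerance = 1e-6)
  expect_true(is.nan(jukes_cantor(0.75)))
  expect_true(is.nan(jukes_cantor(0.9)))
  expect_error(jukes_cantor(-0.01), "non-negative")

  p <- seq(0, 0.74, by = 0.01)
  d <- jukes_cantor(p)
  expect_true(all(diff(d) > 0))   # strictly increasing
  expect_true(all(d >= p))        # correction never shrinks the distance
})

test_that("preprocessing strips terminal stops, drops gapped codons, rejects internal stops", {
  p1 <- preprocess_pair("ATGAAATAA", "ATGAAGTAA")
  expect_equal(p1$seq_a, "ATGAAA")
  expect_equal(p1$seq_b, "ATGAAG")
  expect_equal(p1$excluded_codons, 0L)

  p2 <- preprocess_pair("ATG---AAA", "ATGCCCAAA")
  expect_equal(nchar(p2$seq_a), 6L)
  expect_equal(p2$excluded_codons, 1L)

  expect_error(preprocess_pair("ATGTGAAAA", "ATGTGCAAA"),
               "stop codon in seq_a at codon 2")
  expect_error(preprocess_pair("ATGAAA", "ATGAAAA"), "equal length")
  expect_error(preprocess_pair("ATGA", "ATGC"), "divisible by 3")
})

test_that("identical sequences give Ks = Ka = 0 with undefined omega", {
  seq <- paste(rep("ATGAAACCCGGGTTTCTG", 6), collapse = "")
  r <- compute_kaks(preprocess_pair(seq, seq))
  expect_equal(r$Ks, 0)
  expect_equal(r$Ka, 0)
  expect_true(is.nan(r$omega))
  expect_false(r$too_short)
})

test_that("Ka/Ks is symmetric under argument swap", {
  set.seed(21)
  for (i in 1:25) {
    p <- random_codon_pair(40)
    a <- compute_kaks(preprocess_pair(p$seq_a, p$seq_b))
    b <- compute_kaks(preprocess_pair(p$seq_b, p$seq_a))
    expect_equal(a[c("S", "N", "Sd", "Nd", "Ks", "Ka")],
                 b[c("S", "N", "Sd", "Nd", "Ks", "Ka")], tolerance = 1e-12)
  }
})

test_that("site conservation S + N == 3L holds for random pairs", {
  set.seed(31)
  for (i in 1:50) {
    p <- random_codon_pair(35)
    r <- compute_kaks(preprocess_pair(p$seq_a, p$seq_b))
    expect_equal(r$S + r$N, 3 * r$n_codons, tolerance = 1e-9)
  }
})

test_that("short alignments are flagged and empty ones rejected", {
  expect_warning(r <- compute_kaks(preprocess_pair("ATGAAA", "ATGAAG")),
                 "retained codons")
  expect_true(r$too_short)
  expect_error(preprocess_pair("---", "---"), "retained|divisible")
})
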