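test_that("width-1 uniform model gives 4 atoms of probability 0.25", {
  # four distinct scores so the four atoms stay separate
  m <- motif_model("w1", matrix(c(0.4, 0.3, 0.2, 0.1), 1, 4))
  d <- exact_score_distribution(m)
  nz <- d$atom_prob[d$atom_prob > 0]
  expect_length(nz, 4L)
  expect_equal(unname(nz), rep(0.25, 4))
  expect_equal(sum(d$atom_prob), 1, tolerance = 1e-9)
})

test_that("DP distribution matches exhaustive enumeration (widths 2-8)", {
  for (s in 1:8) {
    w <- sample(2:8, 1)
    bg <- if (s %% 2) rep(0.25, 4) else
      with_seed(s, {x <- rgamma(4, 5); x / sum(x)})
    m <- random_model(w, seed = 200 + s, background = bg)
    d <- exact_score_distribution(m)
    oracle <- enumerate_score_dist(d, m$background)
    expect_lt(sum(abs(d$atom_prob - oracle)) / 2, 1e-9)
    # survival properties
    expect_equal(d$survival[1], 1, tolerance = 1e-9)
    expect_true(all(diff(d$survival) <= 1e-12))
  }
})

test_that("ideal full-site model: best-match p-value is 0.25^12", {
  m <- consensus_to_pssm("AGAACANNNTGTTCT", 0.997)
  d <- exact_score_distribution(m)
  expect_equal(min(d$survival), 0.25^12, tolerance = 0.01 * 0.25^12)
})

test_that("coarse granularity warns when a column collapses", {
  m <- consensus_to_pssm("ACGT", 0.9)
  w <- capture_warnings(exact_score_distribution(m, granularity = 1000))
  expect_true(any(grepl("collapses", w)))
})

test_that("pvalue_to_score_threshold: bounds, sentinel, monotonicity", {
  m <- consensus_to_pssm("AGAACANNNTGTTCT", 0.997)
  d <- exact_score_distribution(m)
  expect_equal(pvalue_to_score_threshold(d, 1), d$atom_score[1],
               ignore_attr = TRUE)
  # p just above the best-match p-value: only perfect windows pass
  thr <- pvalue_to_score_threshold(d, 0.25^12 * 1.01)
  expect_equal(unname(d$survival[attr(thr, "int") + 1L]), 0.25^12,
               tolerance = 1e-15)
  expect_true(is.infinite(pvalue_to_score_threshold(d, 0.25^12 / 2)))
  expect_error(pvalue_to_score_threshold(d, 0), "p must lie")
  expect_error(pvalue_to_score_threshold(d, 1.5), "p must lie")
  grid <- 10^seq(-7, 0, length.out = 20)  # all above the minimum p
  thrs <- vapply(grid, function(p)
    as.numeric(pvalue_to_score_threshold(d, p)), numeric(1))
  expect_true(all(diff(thrs) <= 0))  # non-increasing as p grows
})

test_that("planted ideal site is recovered at the planted offset", {
  seq <- with_seed(42, random_dna(1000, seed = 42))
  site <- "AGAACAGGGTGTTCT"
  seq <- paste0(substr(seq, 1, 500), site, substr(seq, 516, 1000))
  m <- consensus_to_pssm("AGAACANNNTGTTCT", 0.997)
  hits <- scan_sequences(c(chr1 = seq), m, p_value = 4.94e-5,
                         background = "uniform")
  planted <- hits[hits$start == 501L, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$end, 515L)
  expect_equal(planted$matched_seq, site)
  expect_lte(planted$p_value, 6e-8)
})

test_that("all-C sequence yields zero hits for the ideal model", {
  m <- consensus_to_pssm("AGAACANNNTGTTCT", 0.997)
  hits <- scan_sequences(c(c1 = strrep("C", 500)), m,
                         p_value = 4.94e-5, background = "uniform")
  expect_equal(nrow(hits), 0L)
})

test_that("strand symmetry: revcomp sequence mirrors hits", {
  half <- consensus_to_pssm("AGAACA", 0.9)  # non-palindromic
  seq <- random_dna(3000, seed = 11)
  L <- nchar(seq)
  fwd <- scan_sequences(c(s = seq), half, p_value = 1e-3,
                        background = "uniform")
  rev <- scan_sequences(
    c(s = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))), half, p_value = 1e-3,
    background = "uniform")
  expect_gt(nrow(fwd), 0L)
  expect_equal(nrow(fwd), nrow(rev))
  mirrored <- data.frame(start = L - rev$end + 1L, end = L - rev$start + 1L,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         score = rev$score)
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  orig <- fwd[order(fwd$start, fwd$strand), c("start", "end", "strand",
                                              "score")]
  expect_equal(orig$start, mirrored$start)
  expect_equal(orig$strand, mirrored$strand)
  expect_equal(orig$score, mirrored$score, tolerance = 1e-9)
})

test_that("scanner equals brute-force thresholding on random sequence", {
  m <- random_model(6, seed = 31, name = "b6")
  seq <- random_dna(10000, seed = 32)
  p <- 2e-3
  hits <- scan_sequences(c(s = seq), m, p_value = p,
                         background = "uniform")
  # brute force: score every window on both strands via the shared
  # integer grid, threshold by enumerated survival
  d <- exact_score_distribution(set_background(m, rep(0.25, 4)))
  surv <- d$survival
  codes <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  n <- length(codes) - 5L
  expected <- 0L
  for (w in seq_len(n)) {
    sub <- codes[w:(w + 5L)]
    s_plus <- sum(d$int_scores[cbind(1:6, sub)])
    if (surv[s_plus + 1L] <= p) expected <- expected + 1L
    rc <- rev(5L - sub)  # complement codes: A<->T (1<->4), C<->G (2<->3)
    s_minus <- sum(d$int_scores[cbind(1:6, rc)])
    if (surv[s_minus + 1L] <= p) expected <- expected + 1L
  }
  expect_equal(nrow(hits), expected)
})

test_that("palindromic models report each locus once, + strand only", {
  m <- consensus_to_pssm("AGAACANNNTGTTCT", 0.85)
  seq <- with_seed(55, {
    bg <- random_dna(5000, seed = 55)
    plant_full_sites(bg, c("1" = 3, "2" = 3), seed = 56)$sequence
  })
  hits <- scan_sequences(c(s = seq), m, p_value = 4.94e-5,
                         background = "uniform")
  expect_gt(nrow(hits), 0L)
  expect_true(all(hits$strand == "+"))
  expect_false(any(duplicated(hits[, c("seqid", "start", "model")])))
})

test_that("false-positive count on background matches expectation", {
  # palindromic model scanned on one strand: E[hits] ~= (L - W + 1) * p
  m <- consensus_to_pssm("AGAACANNNTGTTCT", 0.85)
  p <- 1e-3
  L <- 50000
  seq <- random_dna(L, seed = 77)
  hits <- scan_sequences(c(s = seq), m, p_value = p,
                         background = "uniform")
  d <- exact_score_distribution(set_background(m, rep(0.25, 4)))
  # expected count uses the attained p at the threshold (discrete null)
  thr <- pvalue_to_score_threshold(d, p)
  p_att <- d$survival[attr(thr, "int") + 1L]
  expected <- (L - 14) * p_att
  expect_lt(abs(nrow(hits) - expected), 4 * sqrt(expected))
})

test_that("windows with ambiguous bases are skipped, not scored", {
  m <- consensus_to_pssm("AGAACANNNTGTTCT", 0.997)
  seq <- paste0(strrep("T", 20), "AGAACANNNTGTTCT", strrep("T", 20))
  hits <- scan_sequences(c(s = seq), m, p_value = 1,
                         background = "uniform")
  expect_gt(nrow(hits), 0L)  # p = 1 reports every scorable window
  # the N spacer occupies positions 27-29: no reported window covers it
  expect_false(any(hits$start <= 29L & hits$end >= 27L))
})

test_that("model wider than sequence gives an empty result", {
  m <- consensus_to_pssm("AGAACANNNTGTTCT", 0.997)
  expect_equal(nrow(scan_sequences(c(s = "ACGT"), m, p_value = 1)), 0L)
})
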