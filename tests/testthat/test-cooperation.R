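klf_model <- function() consensus_to_pssm("GGGGCGGGG", 0.95, name = "KLF")

# anchors data.frame from a half-site planting truth table
truth_anchors <- function(truth) {
  data.frame(seqid = truth$seqid, start = truth$start, end = truth$end,
             strand = truth$strand, stringsAsFactors = FALSE)
}

test_that("constant planted gap puts all mass in one downstream bin", {
  bg <- gen_background(120000, seed = 301)
  pl <- plant_half_sites_and_cooperators(
    bg, 200, secondary_consensus = "GGGGCGGGG", gap_sampler = 15L,
    seed = 302)
  h <- spacing_histogram(truth_anchors(pl$truth), klf_model(),
                         c(chr_sim = pl$sequence))
  expect_equal(h$n_anchors, 200L)
  expect_gte(h$n_anchors_with_secondary, 195L)  # rare background overlaps
  bin <- 15 %/% 5 + 1
  expect_gte(h$counts["downstream", bin],
             0.97 * h$n_anchors_with_secondary)
  res <- spacing_enrichment(h)
  sig <- res$bins[res$bins$significant, ]
  expect_true(any(sig$side == "downstream" & sig$bin_start == 15))
  expect_equal(res$modal_gap, 17.5)
})

test_that("no secondary occurrences: all-zero flagged histogram", {
  bg <- gen_background(20000, seed = 310)
  pl <- plant_half_sites_and_cooperators(bg, 20, seed = 311)
  sec <- consensus_to_pssm("ATATATATATATATA", 0.997, name = "absent")
  h <- spacing_histogram(truth_anchors(pl$truth), sec,
                         c(chr_sim = pl$sequence), secondary_p = 1e-7)
  expect_equal(sum(h$counts), 0L)
  expect_equal(h$n_anchors_with_secondary, 0L)
  expect_true(h$flagged_empty)
  res <- spacing_enrichment(h)
  expect_false(any(res$bins$significant))
})

test_that("uniform gaps spread counts within multinomial bounds", {
  bg <- gen_background(200000, seed = 320)
  pl <- plant_half_sites_and_cooperators(
    bg, 320, secondary_consensus = "GGGGCGGGG",
    gap_sampler = function(n) sample(0:159, n, replace = TRUE),
    seed = 321)
  h <- spacing_histogram(truth_anchors(pl$truth), klf_model(),
                         c(chr_sim = pl$sequence))
  n <- sum(h$counts)
  expect_gte(n, 300L)
  exp_bin <- n / 32
  sigma <- sqrt(n * (1 / 32) * (31 / 32))
  expect_true(all(abs(h$counts["downstream", ] - exp_bin) <=
                    4 * sigma + 1))
})

test_that("binomial tail enrichment matches an independent summation", {
  # construct a histogram object directly to control counts exactly
  h <- structure(list(
    anchor_model = "ARE", secondary_model = "KLF", window = 160,
    bin_width = 5,
    counts = matrix(0L, 2, 32,
                    dimnames = list(c("upstream", "downstream"), NULL)),
    gaps = data.frame(), n_anchors = 100L,
    n_anchors_with_secondary = 100L, n_dropped_edge = 0L,
    flagged_empty = FALSE), class = "spacing_histogram")
  h$counts["downstream", 4] <- 40L
  h$counts["upstream", ] <- h$counts["upstream", ] + 0L
  h$counts["downstream", c(1:3, 5:32)] <- 2L
  n <- sum(h$counts)
  res <- spacing_enrichment(h)
  row <- res$bins[res$bins$side == "downstream" & res$bins$bin_start == 15, ]
  oracle <- sum(dbinom(40:n, n, 1 / 32))  # upper tail by summation
  expect_equal(row$p_raw, oracle, tolerance = 1e-12)
  expect_equal(row$p_corrected, min(1, oracle * 64), tolerance = 1e-12)
  expect_true(row$significant)
})

test_that("uniform counts and single observations are not significant", {
  h <- structure(list(
    anchor_model = "ARE", secondary_model = "KLF", window = 160,
    bin_width = 5,
    counts = matrix(3L, 2, 32,
                    dimnames = list(c("upstream", "downstream"), NULL)),
    gaps = data.frame(), n_anchors = 192L,
    n_anchors_with_secondary = 192L, n_dropped_edge = 0L,
    flagged_empty = FALSE), class = "spacing_histogram")
  expect_false(any(spacing_enrichment(h)$bins$significant))

  h$counts[] <- 0L; h$counts[2, 4] <- 1L
  h$n_anchors_with_secondary <- 1L
  expect_false(any(spacing_enrichment(h)$bins$significant))
})

test_that("window/bin preconditions and edge anchors", {
  bg <- gen_background(5000, seed = 330)
  pl <- plant_half_sites_and_cooperators(bg, 5, seed = 331,
                                         edge_margin = 200)
  a <- truth_anchors(pl$truth)
  expect_error(spacing_histogram(a, klf_model(),
                                 c(chr_sim = pl$sequence), window = 2,
                                 bin_width = 5), "at least bin_width")
  # anchor hard against the edge is dropped and counted
  a2 <- rbind(a, data.frame(seqid = "chr_sim", start = 3L, end = 8L,
                            strand = "+"))
  h <- spacing_histogram(a2, klf_model(), c(chr_sim = pl$sequence))
  expect_equal(h$n_dropped_edge, 1L)
})

test_that("each anchor contributes at most one count", {
  bg <- gen_background(60000, seed = 340)
  pl <- plant_half_sites_and_cooperators(
    bg, 60, secondary_consensus = "GGGGCGGGG",
    gap_sampler = function(n) sample(0:100, n, replace = TRUE),
    seed = 341)
  h <- spacing_histogram(truth_anchors(pl$truth), klf_model(),
                         c(chr_sim = pl$sequence))
  expect_lte(sum(h$counts), h$n_anchors)
  expect_equal(sum(h$counts), h$n_anchors_with_secondary)
})

test_that("compare_anchor_classes: planted shift, identity, antisymmetry", {
  bg1 <- gen_background(100000, seed = 350)
  full_like <- plant_half_sites_and_cooperators(
    bg1, 120, secondary_consensus = "GGGGCGGGG", gap_sampler = 45L,
    seed = 351)
  bg2 <- gen_background(100000, seed = 352)
  half_like <- plant_half_sites_and_cooperators(
    bg2, 120, secondary_consensus = "GGGGCGGGG", gap_sampler = 15L,
    seed = 353)
  hf <- spacing_histogram(truth_anchors(full_like$truth), klf_model(),
                          c(chr_sim = full_like$sequence))
  hh <- spacing_histogram(truth_anchors(half_like$truth), klf_model(),
                          c(chr_sim = half_like$sequence))
  cmp <- compare_anchor_classes(hf, hh)
  expect_lt(cmp$median_shift, 0)  # half - full < 0: half sites closer
  expect_equal(cmp$median_full, 45, tolerance = 3)
  expect_equal(cmp$median_half, 15, tolerance = 3)

  same <- compare_anchor_classes(hf, hf)
  expect_equal(same$modal_shift, 0)
  expect_equal(same$median_shift, 0)
  expect_gt(same$p_value, 0.99)

  swapped <- compare_anchor_classes(hh, hf)
  expect_equal(swapped$median_shift, -cmp$median_shift)

  hbad <- hh; hbad$window <- 80
  expect_error(compare_anchor_classes(hf, hbad), "mismatched")
})
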