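# Shared fixture builders and independent oracles.

# random probability matrix model (Dirichlet-ish rows via gamma draws)
random_model <- function(width, seed, name = paste0("rnd", width),
                         background = rep(0.25, 4), conc = 1) {
  with_seed(seed, {
    g <- matrix(rgamma(width * 4, shape = conc), width, 4)
    motif_model(name, g / rowSums(g), background)
  })
}

# Independent oracle: full null score distribution by exhaustive
# enumeration of all 4^W windows, using the distribution's own integer
# score grid (discretization is shared contract; the convolution is
# what is being checked).
enumerate_score_dist <- function(dist, background) {
  ints <- dist$int_scores
  W <- nrow(ints)
  grid <- as.matrix(expand.grid(rep(list(1:4), W)))
  scores <- integer(nrow(grid))
  probs <- rep(1, nrow(grid))
  for (j in seq_len(W)) {
    scores <- scores + ints[j, grid[, j]]
    probs <- probs * background[grid[, j]]
  }
  atom <- tapply(probs, scores, sum)
  full <- numeric(length(dist$atom_prob))
  full[as.integer(names(atom)) + 1L] <- atom
  full
}

# random ACGT string
random_dna <- function(n, seed) gen_background(n, seed = seed)

# canonical window with exactly m informative mismatches (first m
# informative positions mutated deterministically)
window_with_mismatches <- function(m, spacer = "GGG") {
  cons <- strsplit("AGAACAGGGTGTTCT", "")[[1]]
  cons[7:9] <- strsplit(spacer, "")[[1]]
  inf <- c(1:6, 10:15)
  if (m > 0) for (p in inf[seq_len(m)])
    cons[p] <- setdiff(c("A", "C", "G", "T"), cons[p])[1]
  paste(cons, collapse = "")
}

# tiny two-gene model on one chromosome for annotation tests:
# gene_plus: + strand 10001..20000, exons 10001-12000 / 18001-20000,
#            CDS 11001..19000  (5'UTR 10001-11000, 3'UTR 19001-20000)
# gene_minus: - strand 40001..50000, exons 40001-42000 / 48001-50000,
#            CDS 41001..49000
# gene_nc:   + strand 70001..72000, single exon, non-coding
tiny_gene_model <- function() {
  tx <- data.frame(
    chrom = "chrT",
    start = c(10001L, 40001L, 70001L),
    end = c(20000L, 50000L, 72000L),
    strand = c("+", "-", "+"),
    gene_id = c("gene_plus", "gene_minus", "gene_nc"),
    tx_id = c("tx_plus", "tx_minus", "tx_nc"),
    coding = c(TRUE, TRUE, FALSE),
    cds_start = c(11001L, 41001L, NA),
    cds_end = c(19000L, 49000L, NA),
    stringsAsFactors = FALSE)
  exons <- list(
    tx_plus = cbind(start = c(10001L, 18001L), end = c(12000L, 20000L)),
    tx_minus = cbind(start = c(40001L, 48001L), end = c(42000L, 50000L)),
    tx_nc = cbind(start = 70001L, end = 72000L))
  tierscan:::new_gene_model(tx, exons)
}

# minimal tiered-hit row(s) at given midpoints (width-15 full sites)
hit_at <- function(mid, tier = 1L, seqid = "chrT") {
  data.frame(seqid = seqid, start = mid - 7L, end = mid + 7L,
             strand = "+", tier = tier, core_mismatches = tier - 1L,
             left_mm = 0L, right_mm = tier - 1L,
             half_orientation = NA_character_, stringsAsFactors = FALSE)
}
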