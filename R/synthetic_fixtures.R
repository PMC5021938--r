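# Seeded synthetic data: zero-order background sequence with planted
# tiered AREs, half sites with cooperating motifs at controlled
# spacings, gene models, and response tables. Every generator is a pure
# function of (parameters, seed). Planting verifies that the classifier
# will recover exactly the planted tier: no overlapping window may
# classify to an equal or lower tier, so resolution cannot displace a
# planted site.

#' Generate zero-order background sequence
#'
#' I.i.d. letters drawn from `composition` (A,C,G,T); identical seed,
#' identical string.
#'
#' @param length sequence length in bp (> 0).
#' @param composition base frequencies summing to 1.
#' @param seed RNG seed (see [with_seed()]).
#' @return a single character string.
#' @export
gen_background <- function(length, composition = rep(0.25, 4),
                           seed = NULL) {
  if (!is.numeric(length) || length < 1) stop("length must be positive")
  composition <- check_background(composition)
  with_seed(seed,
    paste(sample(DNA4, length, replace = TRUE, prob = composition),
          collapse = ""))
}

# draw a candidate start respecting min_gap to occupied intervals
.draw_start <- function(L, width, occupied, min_gap, edge_margin,
                        max_tries = 1000L) {
  lo <- edge_margin + 1L
  hi <- L - width - edge_margin + 1L
  if (hi < lo) return(NA_integer_)
  for (t in seq_len(max_tries)) {
    s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    e <- s + width - 1L
    if (!nrow(occupied) ||
        all(s > occupied$end + min_gap | e < occupied$start - min_gap))
      return(s)
  }
  NA_integer_
}

# tiers of every 15-bp window overlapping [s, s+14] in chars
.overlap_window_tiers <- function(chars, s) {
  lo <- max(1L, s - 14L)
  hi <- min(length(chars) - 14L, s + 14L)
  if (hi < lo) return(integer(0))
  starts <- lo:hi
  codes <- match(chars[lo:(hi + 14L)], DNA4)
  mm <- .window_mismatches(codes)
  stats::setNames(ifelse(is.na(mm$total) | mm$total > 3L, NA_integer_,
                         as.integer(mm$total) + 1L), starts)
}

#' Plant full-site AREs of requested tiers into a sequence
#'
#' Each site is the canonical `AGAACA` + random spacer + `TGTTCT` with
#' exactly `tier - 1` informative positions mutated to a different base
#' (positions and bases uniform, seeded). Placement keeps a minimum gap
#' between sites and an edge margin, and re-draws until no 15-bp window
#' overlapping the planted site classifies to an equal or lower tier, so
#' the classifier provably reports the planted window at the planted
#' tier.
#'
#' @param sequence background string.
#' @param counts_per_tier named vector, names in `"1".."4"`, values =
#'   number of sites to plant per tier.
#' @param seed RNG seed.
#' @param min_gap minimum bp between planted intervals (default 30).
#' @param edge_margin keep-out distance from sequence ends (default 200,
#'   comfortably above the 160-bp cooperation window).
#' @param seqid sequence id recorded in the truth table.
#' @return list with `sequence` (mutated string) and `truth`
#'   data.frame (`seqid`, `start`, `end`, `strand`, `planted_tier`,
#'   `mismatch_positions`, `site_seq`).
#' @export
plant_full_sites <- function(sequence, counts_per_tier, seed = NULL,
                             min_gap = 30, edge_margin = 200,
                             seqid = "chr_sim") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  tiers <- as.integer(names(counts_per_tier))
  if (any(is.na(tiers)) || any(!tiers %in% 1:4))
    stop("counts_per_tier names must be tiers 1..4")
  with_seed(seed, {
    chars <- strsplit(toupper(sequence), "")[[1]]
    L <- length(chars)
    occupied <- data.frame(start = integer(0), end = integer(0))
    truth <- list()
    for (ti in seq_along(tiers)) {
      tier <- tiers[ti]
      for (k in seq_len(counts_per_tier[[ti]])) {
        placed <- FALSE
        for (try_loc in 1:200) {
          s <- .draw_start(L, 15L, occupied, min_gap, edge_margin)
          if (is.na(s))
            stop("insufficient room: could not place ", sum(counts_per_tier),
                 " sites of width 15 with min_gap ", min_gap,
                 " in ", L, " bp")
          old <- chars[s:(s + 14L)]
          for (try_site in 1:50) {
            site <- strsplit(ARE_CONSENSUS, "")[[1]]
            site[7:9] <- sample(DNA4, 3, replace = TRUE)
            mpos <- if (tier > 1L)
              sort(sample(ARE_INFORMATIVE, tier - 1L)) else integer(0)
            for (p in mpos) site[p] <- sample(setdiff(DNA4, site[p]), 1L)
            chars[s:(s + 14L)] <- site
            wt <- .overlap_window_tiers(chars, s)
            self <- names(wt) == as.character(s)
            ok <- !is.na(wt[self]) && wt[self] == tier &&
              all(is.na(wt[!self]) | wt[!self] > tier)
            if (ok) break
            chars[s:(s + 14L)] <- old
          }
          if (ok) {
            occupied <- rbind(occupied,
                              data.frame(start = s, end = s + 14L))
            truth[[length(truth) + 1L]] <- data.frame(
              seqid = seqid, start = s, end = s + 14L, strand = "+",
              planted_tier = tier,
              mismatch_positions = paste(mpos, collapse = ","),
              site_seq = paste(site, collapse = ""),
              stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("could not plant a tier-", tier,
               " site without creating a better overlapping match")
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(seqid = character(0), start = integer(0),
                 end = integer(0), strand = character(0),
                 planted_tier = integer(0),
                 mismatch_positions = character(0),
                 site_seq = character(0), stringsAsFactors = FALSE)
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    list(sequence = paste(chars, collapse = ""), truth = truth)
  })
}

#' Plant isolated half sites with optional cooperating motifs
#'
#' Plants perfect hexamers (`AGAACA` forward or `TGTTCT` reverse, random
#' orientation) whose neighbourhood is verified to contain no tier 1-4
#' full-site window (the complementary half is "destroyed": at least 4
#' informative mismatches in every overlapping 15-bp frame). When a
#' secondary consensus is given, it is planted at an edge-to-edge gap
#' drawn from `gap_sampler`, on the requested side relative to anchor
#' orientation.
#'
#' @param sequence background string.
#' @param n_half number of half sites to plant.
#' @param secondary_consensus A/C/G/T string of the cooperating motif,
#'   or `NULL` for none.
#' @param gap_sampler function `n -> n integer gaps` in `[0, window)`,
#'   or a single constant gap; ignored without a secondary.
#' @param seed RNG seed.
#' @param min_gap minimum bp between planted intervals (default 30).
#' @param edge_margin keep-out distance from ends (default 200).
#' @param side `"downstream"` (3' of the anchor, default), `"upstream"`,
#'   or `"random"`.
#' @param seqid sequence id for the truth table.
#' @return list with `sequence` and `truth` data.frame (`seqid`,
#'   `start`, `end`, `strand`, `orientation`, `planted_tier` (= 5),
#'   `gap`, `secondary_start`, `secondary_end`).
#' @export
plant_half_sites_and_cooperators <- function(sequence, n_half,
                                             secondary_consensus = NULL,
                                             gap_sampler = NULL,
                                             seed = NULL, min_gap = 30,
                                             edge_margin = 200,
                                             side = "downstream",
                                             seqid = "chr_sim") {
  stopifnot(is.character(sequence), length(sequence) == 1L, n_half >= 0)
  side <- match.arg(side, c("downstream", "upstream", "random"))
  if (!is.null(secondary_consensus)) {
    secondary_consensus <- toupper(secondary_consensus)
    if (!grepl("^[ACGT]+$", secondary_consensus))
      stop("secondary_consensus must be an A/C/G/T string for planting")
  }
  if (is.numeric(gap_sampler)) {
    const <- as.integer(gap_sampler)
    gap_sampler <- function(n) rep(const, n)
  }
  with_seed(seed, {
    chars <- strsplit(toupper(sequence), "")[[1]]
    L <- length(chars)
    occupied <- data.frame(start = integer(0), end = integer(0))
    truth <- list()
    sw <- if (is.null(secondary_consensus)) 0L
          else nchar(secondary_consensus)
    for (k in seq_len(n_half)) {
      placed <- FALSE
      for (try_loc in 1:500) {
        orient <- sample(c("forward", "reverse"), 1L)
        gap <- if (!is.null(secondary_consensus)) gap_sampler(1L) else NA
        this_side <- if (side == "random")
          sample(c("downstream", "upstream"), 1L) else side
        # downstream of a forward (+) anchor extends right
        right <- !is.null(secondary_consensus) &&
          ((orient == "forward") == (this_side == "downstream"))
        # reserve the combined anchor+secondary footprint
        ext_left <- if (!is.null(secondary_consensus) && !right)
          gap + sw else 0L
        ext_right <- if (!is.null(secondary_consensus) && right)
          gap + sw else 0L
        s <- .draw_start(L, 6L + ext_left + ext_right, occupied,
                         min_gap, edge_margin)
        if (is.na(s))
          stop("insufficient room for ", n_half, " half sites in ",
               L, " bp")
        a_start <- s + ext_left
        hex <- if (orient == "forward") ARE_HALF_FWD else ARE_HALF_REV
        old <- chars[s:(s + 5L + ext_left + ext_right)]
        chars[a_start:(a_start + 5L)] <- strsplit(hex, "")[[1]]
        sec_start <- NA_integer_
        if (!is.null(secondary_consensus)) {
          sec_start <- if (right) a_start + 6L + gap
                       else a_start - gap - sw
          chars[sec_start:(sec_start + sw - 1L)] <-
            strsplit(secondary_consensus, "")[[1]]
        }
        wt <- .overlap_window_tiers(chars, a_start)
        if (all(is.na(wt))) {
          occupied <- rbind(occupied, data.frame(
            start = s, end = s + 5L + ext_left + ext_right))
          truth[[length(truth) + 1L]] <- data.frame(
            seqid = seqid, start = a_start, end = a_start + 5L,
            strand = if (orient == "forward") "+" else "-",
            orientation = orient, planted_tier = 5L,
            gap = if (is.null(secondary_consensus)) NA_integer_
                  else as.integer(gap),
            secondary_start = sec_start,
            secondary_end = if (is.na(sec_start)) NA_integer_
                            else sec_start + sw - 1L,
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        chars[s:(s + 5L + ext_left + ext_right)] <- old
      }
      if (!placed)
        stop("could not plant an isolated half site after 500 draws")
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(seqid = character(0), start = integer(0),
                 end = integer(0), strand = character(0),
                 orientation = character(0), planted_tier = integer(0),
                 gap = integer(0), secondary_start = integer(0),
                 secondary_end = integer(0), stringsAsFactors = FALSE)
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    list(sequence = paste(chars, collapse = ""), truth = truth)
  })
}

#' Generate a synthetic gene model
#'
#' Non-overlapping multi-exon genes on both strands; roughly 90% coding
#' with a CDS strictly inside the outer exons (leaving UTRs), the rest
#' flagged non-coding.
#'
#' @param n_genes number of genes.
#' @param chrom_length chromosome length in bp.
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @param min_intergenic minimum gap between genes (default 2000 bp).
#' @return a `gene_model` (see [read_gene_model()]).
#' @export
gen_gene_model <- function(n_genes, chrom_length, seed = NULL,
                           chrom = "chr_sim", min_intergenic = 2000) {
  stopifnot(n_genes >= 1)
  with_seed(seed, {
    pos <- 5000L
    rows <- list(); exons <- list()
    for (i in seq_len(n_genes)) {
      glen <- sample(3000:15000, 1L)
      start <- pos + sample(min_intergenic:(min_intergenic + 5000), 1L)
      end <- start + glen - 1L
      if (end > chrom_length - 5000L)
        stop("insufficient room: ", n_genes, " genes do not fit in ",
             chrom_length, " bp")
      n_ex <- sample(2:5, 1L)
      cuts <- sort(sample(seq(start + 200L, end - 200L, by = 50L),
                          2L * (n_ex - 1L)))
      ex_start <- c(start, cuts[seq(2, length(cuts), by = 2)] + 1L)
      ex_end <- c(cuts[seq(1, length(cuts), by = 2)], end)
      strand <- sample(c("+", "-"), 1L)
      coding <- stats::runif(1) < 0.9
      tid <- sprintf("tx%04d", i)
      gid <- sprintf("gene%04d", i)
      cds_start <- cds_end <- NA_integer_
      if (coding) {
        cds_start <- ex_start[1] + sample(50:150, 1L)
        cds_end <- ex_end[n_ex] - sample(50:150, 1L)
      }
      rows[[i]] <- data.frame(
        chrom = chrom, start = start, end = end, strand = strand,
        gene_id = gid, tx_id = tid, coding = coding,
        cds_start = cds_start, cds_end = cds_end,
        stringsAsFactors = FALSE)
      exons[[tid]] <- cbind(start = ex_start, end = ex_end)
      pos <- end
    }
    new_gene_model(do.call(rbind, rows), exons)
  })
}

#' Generate a synthetic gene response table
#'
#' Each ARE-bearing gene is marked differentially expressed with the
#' probability of its tier (direction up/down with equal probability);
#' all other listed genes are `ns`.
#'
#' @param gene_tiers `data.frame` with `gene_id` and `tier` (one row per
#'   gene).
#' @param tier_to_de_prob numeric vector of length 5: DE probability per
#'   tier 1-5.
#' @param seed RNG seed.
#' @return response table `data.frame` (`gene_id`, `direction`) with
#'   attribute `provenance = "synthetic AR knockdown"`.
#' @export
gen_response_table <- function(gene_tiers, tier_to_de_prob, seed = NULL) {
  stopifnot(all(c("gene_id", "tier") %in% names(gene_tiers)),
            length(tier_to_de_prob) == 5L,
            all(tier_to_de_prob >= 0 & tier_to_de_prob <= 1))
  if (anyDuplicated(gene_tiers$gene_id))
    stop("gene_tiers must have one row per gene")
  with_seed(seed, {
    p <- tier_to_de_prob[gene_tiers$tier]
    de <- stats::runif(nrow(gene_tiers)) < p
    direction <- ifelse(de, sample(c("up", "down"), nrow(gene_tiers),
                                   replace = TRUE), "ns")
    structure(data.frame(gene_id = gene_tiers$gene_id,
                         direction = direction, stringsAsFactors = FALSE),
              provenance = "synthetic AR knockdown")
  })
}
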