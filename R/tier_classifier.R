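# Five-tier degeneracy classification of ARE sites.
#
# The canonical full site is the palindromic dihexamer AGAACAnnnTGTTCT:
# positions 1-6 and 10-15 are informative, the 3-bp spacer is free.
# Tier k (k = 1..4) = k-1 mismatches at informative positions; tier 5 =
# an isolated perfect hexamer (AGAACA forward or TGTTCT reverse) that is
# not part of any tier 1-4 full site.

ARE_CONSENSUS <- "AGAACANNNTGTTCT"
ARE_HALF_FWD <- "AGAACA"
ARE_HALF_REV <- "TGTTCT"
ARE_INFORMATIVE <- c(1:6, 10:15)
# consensus base codes (A=1,C=2,G=3,T=4); NA at the spacer
ARE_CONS_CODES <- c(1L, 3L, 1L, 1L, 2L, 1L, NA, NA, NA,
                    4L, 3L, 4L, 4L, 2L, 4L)

.check_windows <- function(windows) {
  if (!is.character(windows))
    stop("windows must be character strings")
  if (any(nchar(windows) != 15L))
    stop("full-site windows must be exactly 15 bp")
  if (any(!grepl("^[ACGT]+$", windows)))
    stop("windows must contain only A,C,G,T (ambiguous letters rejected)")
}

#' Mismatches of a 15-bp window against the canonical ARE
#'
#' Hamming distance to `AGAACAnnnTGTTCT` over the 12 informative
#' positions; the 3-bp spacer is ignored. Vectorized over windows.
#'
#' @param windows character vector of 15-bp A/C/G/T strings.
#' @return integer vector of mismatch counts (0-12).
#' @export
core_mismatches <- function(windows) {
  windows <- toupper(windows)
  .check_windows(windows)
  h <- hexamer_mismatches(windows)
  h$left + h$right
}

#' Per-hexamer mismatch breakdown
#'
#' @param windows character vector of 15-bp A/C/G/T strings.
#' @return `data.frame` with `left` (positions 1-6 vs `AGAACA`) and
#'   `right` (positions 10-15 vs `TGTTCT`) mismatch counts.
#' @export
hexamer_mismatches <- function(windows) {
  windows <- toupper(windows)
  .check_windows(windows)
  mat <- matrix(unlist(strsplit(windows, "")), ncol = 15L, byrow = TRUE)
  cons <- strsplit(ARE_CONSENSUS, "")[[1]]
  left <- rowSums(mat[, 1:6, drop = FALSE] !=
                    matrix(cons[1:6], nrow(mat), 6, byrow = TRUE))
  right <- rowSums(mat[, 10:15, drop = FALSE] !=
                     matrix(cons[10:15], nrow(mat), 6, byrow = TRUE))
  data.frame(left = as.integer(left), right = as.integer(right))
}

#' Classify a 15-bp window into full-site tiers 1-4
#'
#' `m` informative-position mismatches give tier `m + 1` for `m <= 3`;
#' four or more mismatches mean the window is not a full site (`NA`).
#'
#' @param windows character vector of 15-bp A/C/G/T strings.
#' @param mismatches_one_hexamer when `TRUE`, additionally require all
#'   mismatches to fall within a single hexamer (one perfect half).
#' @return integer vector of tiers (1-4) with `NA` for non-sites.
#' @export
classify_full_site <- function(windows, mismatches_one_hexamer = FALSE) {
  windows <- toupper(windows)
  .check_windows(windows)
  h <- hexamer_mismatches(windows)
  m <- h$left + h$right
  tier <- ifelse(m <= 3L, m + 1L, NA_integer_)
  if (mismatches_one_hexamer)
    tier[h$left > 0L & h$right > 0L] <- NA_integer_
  as.integer(tier)
}

#' Find perfect ARE half-site hexamers
#'
#' Reports every exact occurrence of `AGAACA` (forward orientation) and
#' `TGTTCT` (reverse orientation). These are candidates only; feed them
#' through [resolve_lowest_tier()] to suppress hexamers that belong to a
#' full site.
#'
#' @param sequences named character vector (A/C/G/T/N) or anything
#'   accepted by [scan_sequences()].
#' @return `data.frame` with `seqid`, `start`, `end` (1-based,
#'   inclusive), `orientation` (`"forward"`/`"reverse"`), `strand`.
#' @export
find_half_sites <- function(sequences) {
  seqs <- as_sequences(sequences)
  out <- list()
  for (sid in names(seqs)) {
    for (orient in c("forward", "reverse")) {
      pat <- if (orient == "forward") ARE_HALF_FWD else ARE_HALF_REV
      m <- gregexpr(pat, seqs[[sid]], fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      out[[length(out) + 1L]] <- data.frame(
        seqid = sid, start = as.integer(m), end = as.integer(m) + 5L,
        orientation = orient,
        strand = if (orient == "forward") "+" else "-",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), orientation = character(0),
                      strand = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  out <- out[order(out$seqid, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve overlapping candidates to the lowest possible tier
#'
#' Full-site windows are accepted greedily in (tier, start) order, so
#' overlapping windows keep the lower tier (ties: leftmost). Any hexamer
#' overlapping an accepted tier 1-4 window by at least one base pair is
#' absorbed into that full site; the remainder become tier 5. Each
#' genomic position therefore contributes to at most one reported site.
#'
#' @param full_hits `data.frame` with `seqid`, `start`, `tier`,
#'   `left_mm`, `right_mm` (and optionally `matched_seq`); 15-bp windows.
#' @param half_hits `data.frame` from [find_half_sites()].
#' @return `data.frame` of tiered hits: `seqid`, `start`, `end`,
#'   `strand`, `tier`, `core_mismatches`, `left_mm`, `right_mm`,
#'   `half_orientation`, sorted by `seqid` then `start`.
#' @export
resolve_lowest_tier <- function(full_hits, half_hits) {
  if (is.null(full_hits)) full_hits <- data.frame()
  if (is.null(half_hits)) half_hits <- data.frame()
  n_full <- nrow(full_hits); n_half <- nrow(half_hits)
  if (n_full && n_half &&
      !length(intersect(unique(full_hits$seqid), unique(half_hits$seqid))))
    stop("full_hits and half_hits share no sequence ids; ",
         "inputs appear to be on mismatched coordinate systems")
  acc <- list()
  ids <- union(if (n_full) unique(full_hits$seqid) else character(0),
               if (n_half) unique(half_hits$seqid) else character(0))
  for (sid in ids) {
    fh <- if (n_full) full_hits[full_hits$seqid == sid, , drop = FALSE]
          else full_hits
    kept_start <- integer(0)
    if (nrow(fh)) {
      fh <- fh[order(fh$tier, fh$start), , drop = FALSE]
      last_ends <- integer(0)
      for (i in seq_len(nrow(fh))) {
        s <- fh$start[i]
        if (!any(s <= last_ends & s + 14L >= kept_start)) {
          kept_start <- c(kept_start, s)
          last_ends <- c(last_ends, s + 14L)
          acc[[length(acc) + 1L]] <- data.frame(
            seqid = sid, start = s, end = s + 14L, strand = "+",
            tier = fh$tier[i], core_mismatches = fh$tier[i] - 1L,
            left_mm = fh$left_mm[i], right_mm = fh$right_mm[i],
            half_orientation = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
    hh <- if (n_half) half_hits[half_hits$seqid == sid, , drop = FALSE]
          else half_hits
    if (nrow(hh)) {
      if (length(kept_start)) {
        covered <- vapply(seq_len(nrow(hh)), function(i)
          any(hh$start[i] <= kept_start + 14L &
                hh$end[i] >= kept_start), logical(1))
        hh <- hh[!covered, , drop = FALSE]
      }
      if (nrow(hh))
        acc[[length(acc) + 1L]] <- data.frame(
          seqid = sid, start = hh$start, end = hh$end,
          strand = hh$strand, tier = 5L,
          core_mismatches = NA_integer_, left_mm = NA_integer_,
          right_mm = NA_integer_, half_orientation = hh$orientation,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(acc)) return(.empty_tiered())
  out <- do.call(rbind, acc)
  out <- out[order(out$seqid, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_tiered <- function() {
  data.frame(seqid = character(0), start = integer(0), end = integer(0),
             strand = character(0), tier = integer(0),
             core_mismatches = integer(0), left_mm = integer(0),
             right_mm = integer(0), half_orientation = character(0),
             stringsAsFactors = FALSE)
}

# sliding-window informative-position mismatch counts over coded bases;
# windows touching non-ACGT letters get NA
.window_mismatches <- function(codes) {
  n <- length(codes) - 15L + 1L
  if (n < 1L)
    return(list(total = numeric(0), left = numeric(0), right = numeric(0)))
  left <- right <- numeric(n)
  bad <- logical(n)
  for (j in 1:15) {
    v <- codes[j:(j + n - 1L)]
    bad <- bad | is.na(v)
    cc <- ARE_CONS_CODES[j]
    if (!is.na(cc)) {
      mm <- v != cc
      mm[is.na(mm)] <- FALSE
      if (j <= 6L) left <- left + mm else right <- right + mm
    }
  }
  left[bad] <- NA; right[bad] <- NA
  list(total = left + right, left = left, right = right)
}

#' Classify sequences into tiered ARE sites
#'
#' Slides a 15-bp window over each sequence, classifies full sites by
#' informative-position Hamming distance (the consensus is palindromic,
#' so one pass covers both strands), finds perfect half-site hexamers in
#' both orientations, and resolves overlaps with
#' [resolve_lowest_tier()]. Windows overlapping non-ACGT letters (e.g.
#' masked repeats) are skipped.
#'
#' @param sequences FASTA path, `DNAStringSet`, or named character vector.
#' @param mismatches_one_hexamer see [classify_full_site()].
#' @return a tiered-hit `data.frame` (see [resolve_lowest_tier()]).
#' @export
classify_sequences <- function(sequences, mismatches_one_hexamer = FALSE) {
  seqs <- as_sequences(sequences)
  full <- list()
  for (sid in names(seqs)) {
    codes <- dna_codes(seqs[[sid]])
    mm <- .window_mismatches(codes)
    keep <- which(!is.na(mm$total) & mm$total <= 3L)
    if (mismatches_one_hexamer && length(keep))
      keep <- keep[mm$left[keep] == 0L | mm$right[keep] == 0L]
    if (length(keep))
      full[[length(full) + 1L]] <- data.frame(
        seqid = sid, start = keep, tier = as.integer(mm$total[keep]) + 1L,
        left_mm = as.integer(mm$left[keep]),
        right_mm = as.integer(mm$right[keep]), stringsAsFactors = FALSE)
  }
  full <- if (length(full)) do.call(rbind, full) else NULL
  half <- find_half_sites(seqs)
  resolve_lowest_tier(full, half)
}

#' Exhaustive census of all dihexamer cores
#'
#' Enumerates all 4^12 assignments of the 12 informative positions (the
#' spacer is free and ignored), applies the full-site tier rules to
#' each, and tallies the mismatch classes. Also reports, over the full
#' 15-bp window, the minimum number of consensus-agreeing positions
#' among cores assigned to each tier (spacer positions carry no
#' consensus letter and never agree).
#'
#' @param chunk_size cores processed per vectorized chunk.
#' @return list: `counts_by_mismatch` (named, m = 0..12), `tier_counts`
#'   (tiers 1-4), `min_agreement_by_tier` (bases out of 15), and
#'   `max_full_site_mismatches` (largest m still assigned a tier).
#' @export
enumerate_core_census <- function(chunk_size = 2^20) {
  total <- 4^12
  cons <- ARE_CONS_CODES[ARE_INFORMATIVE] - 1L  # base-4 digits 0..3
  counts <- integer(13)
  min_agree <- rep(15L, 4)  # running minima per tier, over the 15-bp window
  lo <- 0
  while (lo < total) {
    n <- min(chunk_size, total - lo)
    idx <- lo + seq_len(n) - 1
    m <- integer(n)
    rem <- idx
    for (p in 1:12) {
      digit <- rem %% 4
      rem <- rem %/% 4
      m <- m + (digit != cons[p])
    }
    counts <- counts + tabulate(m + 1L, nbins = 13L)
    # tier rule: m mismatches -> tier m+1 for m <= 3; spacer positions
    # carry no consensus letter, so window agreement = 12 - m
    tier <- ifelse(m <= 3L, m + 1L, NA_integer_)
    for (k in 1:4) {
      agr <- 12L - m[!is.na(tier) & tier == k]
      if (length(agr)) min_agree[k] <- min(min_agree[k], agr)
    }
    lo <- lo + n
  }
  names(counts) <- as.character(0:12)
  list(counts_by_mismatch = counts,
       tier_counts = stats::setNames(counts[1:4], paste0("tier", 1:4)),
       min_agreement_by_tier = stats::setNames(min_agree,
                                               paste0("tier", 1:4)),
       max_full_site_mismatches = max(which(counts > 0 &
                                              (0:12) <= 3L)) - 1L)
}

#' Tier count summary
#'
#' @param hits a tiered-hit `data.frame`.
#' @return object of class `tier_summary`: `counts` and `fractions` per
#'   tier 1-5, `n_full` (tiers 1-4), `n_half` (tier 5), `n` total.
#'   Fractions are `NA` for empty input.
#' @export
tier_distribution <- function(hits) {
  counts <- vapply(1:5, function(k) sum(hits$tier == k), integer(1))
  names(counts) <- paste0("tier", 1:5)
  n <- sum(counts)
  fractions <- if (n > 0) counts / n else
    stats::setNames(rep(NA_real_, 5), names(counts))
  structure(list(counts = counts, fractions = fractions,
                 n_full = sum(counts[1:4]), n_half = counts[[5]], n = n),
            class = "tier_summary")
}

#' @export
print.tier_summary <- function(x, ...) {
  cat("ARE tier summary:", x$n, "sites (", x$n_full, "full,",
      x$n_half, "half )\n")
  df <- data.frame(tier = 1:5, count = as.integer(x$counts),
                   fraction = round(x$fractions, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write tiered hits as TSV with mismatch breakdown
#'
#' @param hits tiered-hit `data.frame`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tiered_tsv <- function(hits, path) {
  write_tsv(hits, path,
            comment = "coordinates: 1-based inclusive; tier 5 = half site")
}
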