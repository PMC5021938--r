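# Spaced-motif cooperation analysis: distances between anchor AREs and
# the best occurrence of a secondary transcription-factor motif within a
# +/- window, binned into a spacing histogram and tested per bin against
# a uniform-placement binomial null.

#' Spacing histogram between anchor AREs and a secondary motif
#'
#' The sequences are scanned once with the secondary model; for each
#' anchor the best-scoring secondary hit whose edge-to-edge gap lies in
#' `[0, window)` is located (gap 0 = adjacent; overlapping occurrences
#' are not counted). Each anchor contributes at most one count, to one
#' bin on one side. Sides are oriented by the anchor strand: downstream
#' is 3' of the anchor. Anchors with less than `window` bp of flanking
#' context are dropped and counted.
#'
#' @param anchors tiered-hit `data.frame` (needs `seqid`, `start`,
#'   `end`, `strand`).
#' @param secondary a [motif_model()] for the cooperating factor.
#' @param sequences sequences containing the anchors.
#' @param window one-sided window size in bp (default 160).
#' @param bin_width histogram bin width in bp (default 5).
#' @param secondary_p p-value threshold for secondary occurrences
#'   (default 1e-4).
#' @param gap_type `"edge"` (default, edge-to-edge) or `"center"`
#'   (center-to-center) gap definition.
#' @param background background passed to [scan_sequences()].
#' @return object of class `spacing_histogram`: `counts` (2 x n_bins
#'   matrix, rows upstream/downstream), `gaps` (per-anchor gap records),
#'   `n_anchors`, `n_anchors_with_secondary`, `n_dropped_edge`, and the
#'   settings.
#' @export
spacing_histogram <- function(anchors, secondary, sequences, window = 160,
                              bin_width = 5, secondary_p = 1e-4,
                              gap_type = c("edge", "center"),
                              background = "auto") {
  gap_type <- match.arg(gap_type)
  if (window < bin_width) stop("window must be at least bin_width")
  seqs <- as_sequences(sequences)
  n_bins <- as.integer(ceiling(window / bin_width))
  counts <- matrix(0L, 2, n_bins,
                   dimnames = list(c("upstream", "downstream"), NULL))
  empty <- function(n_anchors, dropped) structure(
    list(anchor_model = "ARE", secondary_model = secondary$name,
         window = window, bin_width = bin_width, counts = counts,
         gaps = data.frame(anchor = integer(0), gap = integer(0),
                           side = character(0), score = numeric(0)),
         n_anchors = n_anchors, n_anchors_with_secondary = 0L,
         n_dropped_edge = dropped, flagged_empty = TRUE),
    class = "spacing_histogram")
  if (is.null(anchors) || nrow(anchors) == 0L) return(empty(0L, 0L))
  seqlen <- nchar(seqs)[anchors$seqid]
  ok <- anchors$start - window >= 1L & anchors$end + window <= seqlen
  dropped <- sum(!ok)
  anchors <- anchors[ok, , drop = FALSE]
  if (!nrow(anchors)) return(empty(0L, dropped))
  sec_hits <- scan_sequences(seqs, secondary, p_value = secondary_p,
                             background = background)
  gaps <- list()
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    h <- sec_hits[sec_hits$seqid == a$seqid, , drop = FALSE]
    if (!nrow(h)) next
    if (gap_type == "edge") {
      right <- h$start > a$end
      left <- h$end < a$start
      gap <- ifelse(right, h$start - a$end - 1L,
                    ifelse(left, a$start - h$end - 1L, -1L))
    } else {
      am <- (a$start + a$end) / 2
      hm <- (h$start + h$end) / 2
      right <- hm > am
      left <- hm < am
      gap <- as.integer(round(abs(hm - am)))
      gap[!(right | left)] <- -1L
    }
    cand <- which(gap >= 0L & gap < window)
    if (!length(cand)) next
    best <- cand[order(-h$score[cand], gap[cand])][1]
    is_right <- if (gap_type == "edge") h$start[best] > a$end
                else (h$start[best] + h$end[best]) / 2 >
                     (a$start + a$end) / 2
    side <- if ((a$strand == "+") == is_right) "downstream" else "upstream"
    g <- gap[best]
    counts[side, g %/% bin_width + 1L] <- counts[side, g %/% bin_width + 1L] + 1L
    gaps[[length(gaps) + 1L]] <- data.frame(
      anchor = i, gap = g, side = side, score = h$score[best],
      stringsAsFactors = FALSE)
  }
  gaps <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(anchor = integer(0), gap = integer(0),
               side = character(0), score = numeric(0))
  structure(
    list(anchor_model = "ARE", secondary_model = secondary$name,
         window = window, bin_width = bin_width, counts = counts,
         gaps = gaps, n_anchors = nrow(anchors),
         n_anchors_with_secondary = nrow(gaps),
         n_dropped_edge = dropped, flagged_empty = nrow(gaps) == 0L),
    class = "spacing_histogram")
}

#' @export
print.spacing_histogram <- function(x, ...) {
  cat("spacing_histogram:", x$secondary_model, "around",
      x$n_anchors, "anchors;", x$n_anchors_with_secondary,
      "with a secondary within +/-", x$window, "bp (",
      x$n_dropped_edge, "anchors dropped at sequence edges)\n")
  invisible(x)
}

#' Test spacing bins for enrichment
#'
#' Each (side, bin) cell is tested with an upper-tail binomial test
#' against uniform placement of the `n` observed gaps over the bins of
#' one side (success probability `1 / n_bins`); Bonferroni correction
#' over bins x sides.
#'
#' @param hist a [spacing_histogram()].
#' @param alpha significance level on the corrected p-values.
#' @return object of class `cooperation_result`: `bins` data.frame
#'   (`side`, `bin_start`, `bin_end`, `count`, `p_raw`, `p_corrected`,
#'   `significant`), `modal_gap` (midpoint of the fullest bin, `NA` when
#'   empty), `n`, `alpha`.
#' @export
spacing_enrichment <- function(hist, alpha = 0.05) {
  stopifnot(inherits(hist, "spacing_histogram"))
  n_bins <- ncol(hist$counts)
  cells <- 2L * n_bins
  n <- sum(hist$counts)
  bins <- data.frame(
    side = rep(rownames(hist$counts), each = n_bins),
    bin_start = rep(seq(0, by = hist$bin_width, length.out = n_bins), 2),
    bin_end = rep(pmin(seq(hist$bin_width, by = hist$bin_width,
                           length.out = n_bins), hist$window), 2),
    count = c(hist$counts["upstream", ], hist$counts["downstream", ]),
    stringsAsFactors = FALSE)
  if (n == 0L) {
    bins$p_raw <- NA_real_; bins$p_corrected <- NA_real_
    bins$significant <- FALSE
    return(structure(list(bins = bins, modal_gap = NA_real_, n = 0L,
                          alpha = alpha), class = "cooperation_result"))
  }
  # null: uniform placement over bins, success prob 1/n_bins per side
  # (conservative when observations spread across both sides);
  # Bonferroni over bins x sides
  p0 <- 1 / n_bins
  bins$p_raw <- stats::pbinom(bins$count - 1L, n, p0, lower.tail = FALSE)
  bins$p_corrected <- pmin(1, bins$p_raw * cells)
  bins$significant <- bins$p_corrected < alpha
  pooled <- hist$counts["upstream", ] + hist$counts["downstream", ]
  mb <- which.max(pooled)
  modal_gap <- (mb - 1L) * hist$bin_width + hist$bin_width / 2
  structure(list(bins = bins, modal_gap = modal_gap, n = n,
                 alpha = alpha), class = "cooperation_result")
}

#' @export
print.cooperation_result <- function(x, ...) {
  sig <- x$bins[x$bins$significant %in% TRUE, , drop = FALSE]
  cat("cooperation_result: n =", x$n, "; modal gap", x$modal_gap,
      "bp;", nrow(sig), "significant bin(s) at corrected alpha",
      x$alpha, "\n")
  if (nrow(sig)) print(sig, row.names = FALSE)
  invisible(x)
}

#' Compare spacing between two anchor classes
#'
#' Reports modal and median gaps for each histogram, their differences
#' (second minus first), and a two-proportion test of the fraction of
#' anchors having a secondary within the window.
#'
#' @param hist_full spacing histogram for the first anchor class
#'   (e.g. full sites).
#' @param hist_half spacing histogram for the second class (e.g. half
#'   sites); must share secondary model, window and bin settings.
#' @return list with per-class modal/median gaps, `modal_shift` and
#'   `median_shift` (second minus first), fractions with a secondary,
#'   `fraction_difference`, and `p_value` of the two-proportion test.
#' @export
compare_anchor_classes <- function(hist_full, hist_half) {
  stopifnot(inherits(hist_full, "spacing_histogram"),
            inherits(hist_half, "spacing_histogram"))
  if (hist_full$secondary_model != hist_half$secondary_model ||
      hist_full$window != hist_half$window ||
      hist_full$bin_width != hist_half$bin_width)
    stop("histograms have mismatched secondary model or window settings")
  modal <- function(h) {
    if (!sum(h$counts)) return(NA_real_)
    pooled <- colSums(h$counts)
    (which.max(pooled) - 1L) * h$bin_width + h$bin_width / 2
  }
  med <- function(h) if (nrow(h$gaps)) stats::median(h$gaps$gap) else NA_real_
  frac <- function(h) if (h$n_anchors) h$n_anchors_with_secondary /
    h$n_anchors else NA_real_
  x <- c(hist_full$n_anchors_with_secondary,
         hist_half$n_anchors_with_secondary)
  n <- c(hist_full$n_anchors, hist_half$n_anchors)
  pv <- if (all(n > 0)) {
    if (x[1] / n[1] == x[2] / n[2]) 1  # degenerate (e.g. both 100%)
    else suppressWarnings(stats::prop.test(x, n)$p.value)
  } else NA_real_
  list(modal_full = modal(hist_full), modal_half = modal(hist_half),
       modal_shift = modal(hist_half) - modal(hist_full),
       median_full = med(hist_full), median_half = med(hist_half),
       median_shift = med(hist_half) - med(hist_full),
       fraction_full = frac(hist_full), fraction_half = frac(hist_half),
       fraction_difference = frac(hist_half) - frac(hist_full),
       p_value = pv)
}

#' Write a spacing histogram with enrichment results as TSV
#'
#' @param result a [spacing_enrichment()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_spacing_tsv <- function(result, path) {
  stopifnot(inherits(result, "cooperation_result"))
  write_tsv(result$bins, path,
            comment = "gap bins in bp, edge-to-edge, 0 = adjacent")
}
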