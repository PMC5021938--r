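# PSSM scanning with exact p-values under a zero-order background.
#
# Log-odds scores are discretized onto a common integer grid (step =
# largest per-column score range / 1000 by default). The null score
# distribution is obtained by dynamic programming: per-position score
# atoms weighted by the background are convolved across positions. A
# window's p-value is the survival function of its integer score, so
# scanner p-values and the distribution are exactly consistent.

# core DP over a log-odds matrix (W x 4) and background frequencies
.dp_score_dist <- function(log_odds, background, granularity = NULL) {
  W <- nrow(log_odds)
  colmin <- apply(log_odds, 1, min)
  colmax <- apply(log_odds, 1, max)
  if (is.null(granularity)) {
    rng <- max(colmax - colmin)
    eps <- if (rng <= 0) 1 else rng / 1000
  } else {
    if (!is.numeric(granularity) || granularity <= 0)
      stop("granularity must be positive")
    eps <- granularity
  }
  ints <- round(sweep(log_odds, 1, colmin, "-") / eps)
  storage.mode(ints) <- "integer"
  for (i in seq_len(W)) {
    if (length(unique(log_odds[i, ])) > 1L && length(unique(ints[i, ])) == 1L)
      warning("granularity ", format(eps), " collapses all distinct scores ",
              "in column ", i, "; p-values will be coarse", call. = FALSE)
  }
  K <- sum(apply(ints, 1, max))
  p <- 1
  for (i in seq_len(W)) {
    m <- max(ints[i, ])
    np <- numeric(length(p) + m)
    for (b in 1:4) {
      s <- ints[i, b]
      idx <- (s + 1L):(s + length(p))
      np[idx] <- np[idx] + p * background[b]
    }
    p <- np
  }
  stopifnot(length(p) == K + 1L)
  surv <- rev(cumsum(rev(p)))
  list(eps = eps, offset = sum(colmin), ints = ints,
       atom_prob = p, survival = surv)
}

#' Exact null score distribution of a motif model
#'
#' Computes the full distribution of the discretized log-odds score of a
#' random window drawn from the zero-order background, by convolving the
#' per-position score atoms. The survival function `P(S >= s)` defines
#' the scanner's p-values.
#'
#' @param model a [motif_model()].
#' @param granularity discretization step in bits; `NULL` (default) uses
#'   the largest per-column score range divided by 1000, giving a common
#'   integer grid with at most 1000 levels in the widest column. A step
#'   coarse enough to collapse all distinct scores of some column
#'   triggers a warning, not an error.
#' @return an object of class `score_distribution` with fields
#'   `model_name`, `granularity` (bits per integer step), `offset`
#'   (score in bits at integer 0), `int_scores` (W x 4 integer matrix),
#'   `atom_score` (bits), `atom_prob`, and `survival`.
#' @export
exact_score_distribution <- function(model, granularity = NULL) {
  stopifnot(inherits(model, "motif_model"))
  d <- .dp_score_dist(model$log_odds, model$background, granularity)
  structure(
    list(model_name = model$name, granularity = d$eps, offset = d$offset,
         int_scores = d$ints,
         atom_score = d$offset + d$eps * seq(0, length(d$atom_prob) - 1L),
         atom_prob = d$atom_prob, survival = d$survival),
    class = "score_distribution")
}

#' Minimal score whose p-value does not exceed p
#'
#' @param dist a [exact_score_distribution()] result.
#' @param p target p-value in (0, 1].
#' @return the smallest discretized score (bits) `s` with
#'   `P(S >= s) <= p`, or `Inf` when even the maximal score has p-value
#'   above `p` (no window can pass). The matching integer score is
#'   attached as attribute `"int"`.
#' @export
pvalue_to_score_threshold <- function(dist, p) {
  stopifnot(inherits(dist, "score_distribution"))
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1)
    stop("p must lie in (0, 1]")
  idx <- which(dist$survival <= p)
  if (!length(idx)) return(structure(Inf, int = NA_integer_))
  structure(dist$atom_score[idx[1]], int = idx[1] - 1L)
}

# sum of per-position integer (or real) scores for every window;
# windows touching non-ACGT letters come back NA
.window_scores <- function(codes, mat) {
  W <- nrow(mat)
  n <- length(codes) - W + 1L
  if (n < 1L) return(numeric(0))
  S <- numeric(n)
  for (j in seq_len(W)) S <- S + mat[j, codes[j:(j + n - 1L)]]
  S
}

# log-odds matrix scoring a minus-strand window read on the plus strand
.minus_strand_matrix <- function(mat) {
  out <- mat[rev(seq_len(nrow(mat))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(out) <- DNA4
  out
}

#' Scan sequences for motif occurrences with exact p-values
#'
#' Both strands are scanned; every window whose score p-value is at most
#' `p_value` is reported. For palindromic (self-reverse-complementary)
#' models the minus strand would duplicate every plus-strand hit, so only
#' the plus strand is reported. Windows containing non-ACGT letters are
#' skipped. Coordinates are 1-based inclusive; use [write_hits_bed()]
#' for 0-based half-open BED output.
#'
#' @param sequences FASTA path, `DNAStringSet`, or named character vector.
#' @param model a [motif_model()].
#' @param p_value report windows with p-value at or below this.
#' @param background `"auto"` (default: strand-symmetrized zero-order
#'   composition of the scanned sequences), `"uniform"`, `"model"` (keep
#'   the model's own background), or an explicit numeric 4-vector.
#' @param granularity passed to [exact_score_distribution()].
#' @return a `data.frame` of hits: `seqid`, `start`, `end`, `strand`,
#'   `score` (bits), `p_value`, `matched_seq` (as read on the hit
#'   strand), `model`, sorted by `seqid` then `start`.
#' @export
scan_sequences <- function(sequences, model, p_value = 1e-4,
                           background = "auto", granularity = NULL) {
  stopifnot(inherits(model, "motif_model"))
  if (!is.numeric(p_value) || p_value <= 0 || p_value > 1)
    stop("p_value must lie in (0, 1]")
  seqs <- as_sequences(sequences)
  bg <- scan_background(seqs, model, background)
  m <- set_background(model, bg)
  dist_plus <- exact_score_distribution(m, granularity)
  palin <- is_palindromic(m)
  lo_minus <- .minus_strand_matrix(m$log_odds)
  dist_minus <- if (palin) NULL else {
    d <- .dp_score_dist(lo_minus, bg, dist_plus$granularity)
    structure(list(model_name = m$name, granularity = d$eps,
                   offset = d$offset, int_scores = d$ints,
                   atom_score = d$offset + d$eps *
                     seq(0, length(d$atom_prob) - 1L),
                   atom_prob = d$atom_prob, survival = d$survival),
              class = "score_distribution")
  }
  hits <- list()
  for (sid in names(seqs)) {
    codes <- dna_codes(seqs[[sid]])
    h <- .scan_one(codes, seqs[[sid]], sid, m$log_odds, dist_plus,
                   p_value, "+", m$name)
    hits[[length(hits) + 1L]] <- h
    if (!palin) {
      h <- .scan_one(codes, seqs[[sid]], sid, lo_minus, dist_minus,
                     p_value, "-", m$name)
      hits[[length(hits) + 1L]] <- h
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out) || !nrow(out)) return(.empty_hits())
  out <- out[order(out$seqid, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_hits <- function() {
  data.frame(seqid = character(0), start = integer(0), end = integer(0),
             strand = character(0), score = numeric(0),
             p_value = numeric(0), matched_seq = character(0),
             model = character(0), stringsAsFactors = FALSE)
}

.scan_one <- function(codes, seq_chr, sid, lo, dist, p_value, strand,
                      model_name) {
  S_int <- .window_scores(codes, dist$int_scores)
  if (!length(S_int)) return(NULL)
  pv <- rep(NA_real_, length(S_int))
  ok <- !is.na(S_int)
  pv[ok] <- dist$survival[S_int[ok] + 1L]
  keep <- which(!is.na(pv) & pv <= p_value)
  if (!length(keep)) return(NULL)
  score <- .window_scores(codes, lo)[keep]
  W <- nrow(lo)
  ms <- substring(seq_chr, keep, keep + W - 1L)
  if (strand == "-") ms <- revcomp(ms)
  data.frame(seqid = sid, start = keep, end = keep + W - 1L,
             strand = strand, score = score, p_value = pv[keep],
             matched_seq = ms, model = model_name,
             stringsAsFactors = FALSE)
}

# resolve a background specification against the scanned sequences
scan_background <- function(seqs, model, background) {
  if (is.numeric(background)) return(check_background(background))
  background <- match.arg(background, c("auto", "uniform", "model"))
  switch(background,
    uniform = check_background(rep(0.25, 4)),
    model = model$background,
    auto = {
      tab <- table(factor(unlist(strsplit(paste(seqs, collapse = ""), "")),
                          levels = DNA4))
      f <- as.numeric(tab)
      if (sum(f) == 0) return(check_background(rep(0.25, 4)))
      f <- f / sum(f)
      # strand-symmetrize so one distribution serves both strands
      f <- (f + rev(f)) / 2
      check_background(f)
    })
}

#' Write motif hits as BED6
#'
#' Coordinates are converted to 0-based half-open. The score column is
#' `min(1000, round(-10 * log10 p))` for genome-browser compatibility;
#' the name column is `<model>` or `ARE_tier<k>` for tiered hits.
#'
#' @param hits a hit `data.frame` from [scan_sequences()] or
#'   [classify_sequences()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  name <- if ("tier" %in% names(hits)) paste0("ARE_tier", hits$tier)
          else hits$model
  score <- if ("p_value" %in% names(hits) && nrow(hits) &&
               !all(is.na(hits$p_value)))
    pmin(1000, round(-10 * log10(pmax(hits$p_value, 1e-300))))
  else rep(0L, nrow(hits))
  score[is.na(score)] <- 0L
  bed <- data.frame(chrom = hits$seqid, start = hits$start - 1L,
                    end = hits$end, name = name, score = score,
                    strand = hits$strand)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 0-based half-open (BED)", con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
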