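# Region-density statistics (sites per Mbp inside a region set versus
# its complement) and per-tier transcriptional hit rates against a
# differential-expression table.

#' Build a normalized region set
#'
#' Overlapping or book-ended intervals are merged; `total_length` is the
#' merged base-pair total.
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end` (1-based
#'   inclusive) or a `GRanges`.
#' @param name region-set label.
#' @return object of class `region_set`: merged `intervals` data.frame,
#'   `name`, `total_length` (bp).
#' @export
region_set <- function(intervals, name = "regions") {
  if (methods::is(intervals, "GRanges")) {
    intervals <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(intervals)),
      start = GenomicRanges::start(intervals),
      end = GenomicRanges::end(intervals), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start > intervals$end)) stop("interval with start > end")
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    intervals$chrom, IRanges::IRanges(intervals$start, intervals$end)))
  merged <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                       start = GenomicRanges::start(gr),
                       end = GenomicRanges::end(gr),
                       stringsAsFactors = FALSE)
  structure(list(name = name, intervals = merged,
                 total_length = sum(merged$end - merged$start + 1)),
            class = "region_set")
}

#' Read a BED file as a region set
#'
#' @param path BED path (0-based half-open on disk; converted).
#' @param name region-set label.
#' @return a [region_set()].
#' @export
read_bed_regions <- function(path, name = basename(path)) {
  g <- rtracklayer::import(path, format = "bed")
  region_set(g, name = name)
}

#' Read a two-column chrom.sizes file
#'
#' @param path TSV with chromosome name and length.
#' @return named numeric vector of chromosome sizes.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$size), df$chrom)
}

#' Site density inside a region set versus its complement
#'
#' Hits are partitioned by midpoint containment in the merged regions;
#' densities are reported in hits per Mbp and compared with
#' [density_test()]. The complement is the covered genome (all
#' chromosomes in `chrom_sizes`) minus the regions.
#'
#' @param hits tiered-hit `data.frame`.
#' @param regions a [region_set()].
#' @param chrom_sizes named vector of chromosome lengths covering every
#'   hit chromosome.
#' @return object of class `density_comparison`: `hits_in`, `hits_out`,
#'   `mbp_in`, `mbp_out`, `density_in`, `density_out`, `p_value`
#'   (two-sided exact binomial; `NA` with a flag when undefined).
#' @export
region_density <- function(hits, regions, chrom_sizes) {
  stopifnot(inherits(regions, "region_set"))
  if (!all(unique(hits$seqid) %in% names(chrom_sizes)))
    stop("chrom_sizes must cover all hit chromosomes")
  iv <- regions$intervals
  if (!all(iv$chrom %in% names(chrom_sizes)) ||
      any(iv$end > chrom_sizes[iv$chrom]) || any(iv$start < 1))
    stop("regions fall outside chromosome bounds")
  mid <- floor((hits$start + hits$end) / 2)
  inside <- vapply(seq_len(nrow(hits)), function(i)
    any(iv$chrom == hits$seqid[i] & iv$start <= mid[i] & iv$end >= mid[i]),
    logical(1))
  hits_in <- sum(inside)
  hits_out <- nrow(hits) - hits_in
  mbp_in <- regions$total_length / 1e6
  mbp_out <- (sum(chrom_sizes) - regions$total_length) / 1e6
  p <- if (mbp_out <= 0 || hits_in + hits_out == 0) NA_real_
       else density_test(hits_in, hits_out, mbp_in, mbp_out)
  structure(list(region_set = regions$name, hits_in = hits_in,
                 hits_out = hits_out, mbp_in = mbp_in, mbp_out = mbp_out,
                 density_in = if (mbp_in > 0) hits_in / mbp_in else NA_real_,
                 density_out = if (mbp_out > 0) hits_out / mbp_out
                               else NA_real_,
                 p_value = p,
                 flagged = mbp_out <= 0 || hits_in + hits_out == 0),
            class = "density_comparison")
}

#' @export
print.density_comparison <- function(x, ...) {
  cat(sprintf(
    "density_comparison '%s': %.1f/Mbp in (%d hits / %.2f Mbp) vs %.1f/Mbp out (%d hits / %.2f Mbp), p = %.3g\n",
    x$region_set, x$density_in, x$hits_in, x$mbp_in, x$density_out,
    x$hits_out, x$mbp_out, x$p_value))
  invisible(x)
}

#' Exact two-sided binomial density test
#'
#' Conditional on the total hit count `n = hits_in + hits_out`, tests
#' whether `hits_in` is consistent with success probability
#' `mbp_in / (mbp_in + mbp_out)` (uniform placement by length).
#'
#' @param hits_in,hits_out hit counts inside/outside the regions.
#' @param mbp_in,mbp_out region and complement lengths in Mbp.
#' @return two-sided p-value (`NA` with a warning when `n` is 0).
#' @export
density_test <- function(hits_in, hits_out, mbp_in, mbp_out) {
  stopifnot(hits_in >= 0, hits_out >= 0, mbp_in > 0, mbp_out > 0)
  n <- hits_in + hits_out
  if (n == 0) {
    warning("no hits: density test undefined")
    return(NA_real_)
  }
  stats::binom.test(hits_in, n, mbp_in / (mbp_in + mbp_out))$p.value
}

#' Read a gene response (differential expression) table
#'
#' @param path TSV with columns `gene_id` and `direction`
#'   (up/down/ns); extra columns are kept.
#' @return `data.frame` with validated `direction`.
#' @export
read_response_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("gene_id", "direction") %in% names(df)))
  if (!all(df$direction %in% c("up", "down", "ns")))
    stop("direction must be one of up/down/ns")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in response table")
  df
}

#' Per-tier transcriptional hit rate
#'
#' A gene counts for tier k when it has at least one tier-k hit
#' associated (independently per tier by default, so a gene may count in
#' several tiers). The hit rate is the fraction of those genes confirmed
#' as differentially expressed (direction up or down). A Spearman rank
#' correlation of hit rate against tier index quantifies the
#' degeneracy-response trend (negative = rates fall with degeneracy).
#'
#' @param annotated output of [annotate_hits()] (needs `tier`,
#'   `gene_id`), or any `data.frame` with those columns.
#' @param responses response table (`gene_id`, `direction`).
#' @param per_gene_best_tier when `TRUE`, count each gene only at its
#'   best (lowest) tier.
#' @return object of class `tier_hit_rate`: `table` data.frame (`tier`,
#'   `n_genes`, `n_confirmed`, `hit_rate`), `rho`, `rho_p` (Spearman,
#'   exact, over tiers with genes), `trend_p` (proportion trend test).
#' @export
tier_hit_rate <- function(annotated, responses,
                          per_gene_best_tier = FALSE) {
  stopifnot(all(c("tier", "gene_id") %in% names(annotated)))
  if (is.null(responses) || nrow(responses) == 0L) {
    warning("empty response table: all hit rates are 0")
    responses <- data.frame(gene_id = character(0),
                            direction = character(0))
  }
  confirmed_genes <- responses$gene_id[responses$direction %in%
                                         c("up", "down")]
  ann <- annotated[!is.na(annotated$gene_id), , drop = FALSE]
  if (per_gene_best_tier && nrow(ann)) {
    best <- tapply(ann$tier, ann$gene_id, min)
    ann <- data.frame(gene_id = names(best), tier = as.integer(best),
                      stringsAsFactors = FALSE)
  }
  tab <- lapply(1:5, function(k) {
    genes <- unique(ann$gene_id[ann$tier == k])
    conf <- sum(genes %in% confirmed_genes)
    data.frame(tier = k, n_genes = length(genes), n_confirmed = conf,
               hit_rate = if (length(genes)) conf / length(genes) else
                 NA_real_)
  })
  tab <- do.call(rbind, tab)
  have <- !is.na(tab$hit_rate)
  rho <- rho_p <- trend_p <- NA_real_
  if (sum(have) >= 3L) {
    ct <- suppressWarnings(stats::cor.test(tab$tier[have],
                                           tab$hit_rate[have],
                                           method = "spearman"))
    rho <- unname(ct$estimate); rho_p <- ct$p.value
    tp <- tryCatch(stats::prop.trend.test(tab$n_confirmed[have],
                                          tab$n_genes[have],
                                          score = tab$tier[have]),
                   error = function(e) NULL)
    if (!is.null(tp)) trend_p <- tp$p.value
  }
  structure(list(table = tab, rho = rho, rho_p = rho_p,
                 trend_p = trend_p), class = "tier_hit_rate")
}

#' @export
print.tier_hit_rate <- function(x, ...) {
  cat("tier_hit_rate (Spearman rho =", round(x$rho, 3), ", p =",
      signif(x$rho_p, 3), "; trend p =", signif(x$trend_p, 3), ")\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
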