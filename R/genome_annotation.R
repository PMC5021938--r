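# Gene-model reading and annotation of tiered hits into genomic
# categories: TSS > TTS > 5'UTR > 3'UTR > exon > intron > non-coding >
# intergenic (priority order; each hit gets exactly one category).

ANNOT_CATEGORIES <- c("TSS", "TTS", "5'UTR", "3'UTR", "exon", "intron",
                      "non-coding", "intergenic")

# gene_model object: list(transcripts = data.frame, exons = named list
# of 2-col matrices (start, end), 1-based inclusive)
new_gene_model <- function(transcripts, exons) {
  stopifnot(is.data.frame(transcripts),
            all(c("chrom", "start", "end", "strand", "gene_id", "tx_id",
                  "coding", "cds_start", "cds_end") %in% names(transcripts)),
            all(transcripts$tx_id %in% names(exons)))
  if (nrow(transcripts) == 0L) stop("gene model contains zero transcripts")
  if (any(transcripts$start >= transcripts$end + 1L))
    stop("transcript with start > end")
  for (i in seq_len(nrow(transcripts))) {
    ex <- exons[[transcripts$tx_id[i]]]
    if (any(ex[, 1] < transcripts$start[i]) ||
        any(ex[, 2] > transcripts$end[i]))
      stop("exons outside transcript bounds for ", transcripts$tx_id[i])
    if (transcripts$coding[i] &&
        (is.na(transcripts$cds_start[i]) ||
         transcripts$cds_start[i] < transcripts$start[i] ||
         transcripts$cds_end[i] > transcripts$end[i]))
      stop("CDS outside transcript bounds for ", transcripts$tx_id[i])
  }
  structure(list(transcripts = transcripts, exons = exons),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", nrow(x$transcripts), "transcripts on",
      length(unique(x$transcripts$chrom)), "sequence(s);",
      sum(x$transcripts$coding), "coding\n")
  invisible(x)
}

#' Read a gene model from BED12 or GTF
#'
#' BED12 blocks become exons; a non-empty thick interval defines the CDS
#' (zero-width thick means non-coding). GTF transcripts are assembled
#' from their `exon` and `CDS` features. All coordinates are converted
#' to 1-based inclusive.
#'
#' @param path file path.
#' @param format `"bed12"` or `"gtf"`; default guesses from the
#'   extension.
#' @return a `gene_model` object: `$transcripts` data.frame (`chrom`,
#'   `start`, `end`, `strand`, `gene_id`, `tx_id`, `coding`,
#'   `cds_start`, `cds_end`) and `$exons`, a per-transcript list of
#'   (start, end) matrices.
#' @export
read_gene_model <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(gtf|gff)(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed12"
  }
  format <- match.arg(tolower(format), c("bed12", "gtf"))
  if (format == "bed12") {
    g <- tryCatch(rtracklayer::import(path, format = "bed"),
                  error = function(e)
                    stop("malformed BED12 in ", path, ": ",
                         conditionMessage(e)))
    if (!length(g)) stop("zero transcripts in ", path)
    tx_id <- as.character(S4Vectors::mcols(g)$name)
    if (any(is.na(tx_id)) || anyDuplicated(tx_id))
      stop("BED12 name column must give unique transcript ids")
    thick <- S4Vectors::mcols(g)$thick
    coding <- !is.null(thick) & IRanges::width(thick) > 0L
    exons <- list()
    blocks <- S4Vectors::mcols(g)$blocks
    for (i in seq_along(g)) {
      b <- if (!is.null(blocks) && length(blocks[[i]])) blocks[[i]]
           else IRanges::IRanges(1L, IRanges::width(g)[i])
      # blocks are relative 1-based within the transcript
      abs_start <- GenomicRanges::start(g)[i] + IRanges::start(b) - 1L
      abs_end <- GenomicRanges::start(g)[i] + IRanges::end(b) - 1L
      exons[[tx_id[i]]] <- cbind(start = abs_start, end = abs_end)
    }
    transcripts <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g), end = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g)),
      gene_id = tx_id, tx_id = tx_id, coding = as.logical(coding),
      cds_start = ifelse(coding, IRanges::start(thick), NA_integer_),
      cds_end = ifelse(coding, IRanges::end(thick), NA_integer_),
      stringsAsFactors = FALSE)
  } else {
    g <- tryCatch(rtracklayer::import(path, format = "gtf"),
                  error = function(e)
                    stop("malformed GTF in ", path, ": ",
                         conditionMessage(e)))
    mc <- S4Vectors::mcols(g)
    ex <- g[mc$type == "exon"]
    if (!length(ex)) stop("zero transcripts (no exon features) in ", path)
    exl <- split(ex, as.character(S4Vectors::mcols(ex)$transcript_id))
    cds <- g[mc$type == "CDS"]
    cdsl <- split(cds, as.character(S4Vectors::mcols(cds)$transcript_id))
    tx_ids <- names(exl)
    rows <- list(); exons <- list()
    for (tid in tx_ids) {
      e <- exl[[tid]]
      exons[[tid]] <- cbind(start = GenomicRanges::start(e),
                            end = GenomicRanges::end(e))
      has_cds <- tid %in% names(cdsl)
      rows[[tid]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(e))[1],
        start = min(GenomicRanges::start(e)),
        end = max(GenomicRanges::end(e)),
        strand = as.character(GenomicRanges::strand(e))[1],
        gene_id = as.character(S4Vectors::mcols(e)$gene_id)[1],
        tx_id = tid, coding = has_cds,
        cds_start = if (has_cds) min(GenomicRanges::start(cdsl[[tid]]))
                    else NA_integer_,
        cds_end = if (has_cds) max(GenomicRanges::end(cdsl[[tid]]))
                  else NA_integer_,
        stringsAsFactors = FALSE)
    }
    transcripts <- do.call(rbind, rows)
    rownames(transcripts) <- NULL
  }
  new_gene_model(transcripts, exons)
}

#' Write a gene model as BED12
#'
#' @param gm a `gene_model`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gene_model_bed12 <- function(gm, path) {
  stopifnot(inherits(gm, "gene_model"))
  tx <- gm$transcripts
  lines <- character(nrow(tx))
  for (i in seq_len(nrow(tx))) {
    ex <- gm$exons[[tx$tx_id[i]]]
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    sizes <- ex[, 2] - ex[, 1] + 1L
    starts <- ex[, 1] - tx$start[i]
    thick <- if (tx$coding[i]) c(tx$cds_start[i] - 1L, tx$cds_end[i])
             else c(tx$start[i] - 1L, tx$start[i] - 1L)
    lines[i] <- paste(tx$chrom[i], tx$start[i] - 1L, tx$end[i],
                      tx$tx_id[i], 0, tx$strand[i], thick[1], thick[2],
                      0, nrow(ex), paste0(paste(sizes, collapse = ","), ","),
                      paste0(paste(starts, collapse = ","), ","),
                      sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

# per-category interval lists for one gene model (matrices per chrom)
.category_regions <- function(gm, tss_window, tts_window) {
  tx <- gm$transcripts
  plus <- tx$strand == "+"
  tss <- ifelse(plus, tx$start, tx$end)
  tts <- ifelse(plus, tx$end, tx$start)
  reg <- list()
  reg[["TSS"]] <- data.frame(
    chrom = tx$chrom,
    start = ifelse(plus, tss + tss_window[1], tss - tss_window[2]),
    end = ifelse(plus, tss + tss_window[2], tss - tss_window[1]))
  reg[["TTS"]] <- data.frame(
    chrom = tx$chrom,
    start = ifelse(plus, tts + tts_window[1], tts - tts_window[2]),
    end = ifelse(plus, tts + tts_window[2], tts - tts_window[1]))
  utr5 <- list(); utr3 <- list(); exn <- list(); intr <- list(); nc <- list()
  for (i in seq_len(nrow(tx))) {
    ex <- gm$exons[[tx$tx_id[i]]]
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    ch <- tx$chrom[i]
    if (nrow(ex) > 1L)
      intr[[length(intr) + 1L]] <- data.frame(
        chrom = ch, start = ex[-nrow(ex), 2] + 1L, end = ex[-1, 1] - 1L)
    if (!tx$coding[i]) {
      nc[[length(nc) + 1L]] <- data.frame(chrom = ch, start = ex[, 1],
                                          end = ex[, 2])
      next
    }
    exn[[length(exn) + 1L]] <- data.frame(chrom = ch, start = ex[, 1],
                                          end = ex[, 2])
    cs <- tx$cds_start[i]; ce <- tx$cds_end[i]
    lo <- ex[ex[, 1] < cs, , drop = FALSE]   # exonic bp left of CDS
    if (nrow(lo)) {
      lo[, 2] <- pmin(lo[, 2], cs - 1L)
      d <- data.frame(chrom = ch, start = lo[, 1], end = lo[, 2])
      if (tx$strand[i] == "+") utr5[[length(utr5) + 1L]] <- d
      else utr3[[length(utr3) + 1L]] <- d
    }
    hi <- ex[ex[, 2] > ce, , drop = FALSE]
    if (nrow(hi)) {
      hi[, 1] <- pmax(hi[, 1], ce + 1L)
      d <- data.frame(chrom = ch, start = hi[, 1], end = hi[, 2])
      if (tx$strand[i] == "+") utr3[[length(utr3) + 1L]] <- d
      else utr5[[length(utr5) + 1L]] <- d
    }
  }
  bindr <- function(l) if (length(l)) do.call(rbind, l) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  reg[["5'UTR"]] <- bindr(utr5)
  reg[["3'UTR"]] <- bindr(utr3)
  reg[["exon"]] <- bindr(exn)
  reg[["intron"]] <- bindr(intr)
  reg[["non-coding"]] <- bindr(nc)
  lapply(reg, function(d) d[d$end >= d$start, , drop = FALSE])
}

#' Annotate tiered hits against a gene model
#'
#' Each hit is represented by its midpoint and assigned exactly one
#' category by strand-aware priority TSS > TTS > 5'UTR > 3'UTR > exon >
#' intron > non-coding > intergenic. The nearest gene is chosen by
#' distance to the transcription start site; a hit is associated when
#' that distance is at most `max_assoc` or when it lies within the gene
#' body extended by `end_flank` on either side.
#'
#' @param hits tiered-hit `data.frame` (`seqid` interpreted as
#'   chromosome).
#' @param genes a `gene_model` from [read_gene_model()] or
#'   [gen_gene_model()].
#' @param tss_window promoter window relative to the TSS in transcript
#'   orientation, default `c(-1000, 100)` bp.
#' @param tts_window terminator window relative to the TTS, default
#'   `c(-100, 1000)` bp.
#' @param end_flank gene-body flank (bp) still associated with the gene,
#'   default 5000.
#' @param max_assoc maximum TSS distance (bp) for nearest-gene
#'   assignment, default 100000; beyond it `gene_id` is `NA`.
#' @return the input with columns `category` (factor), `gene_id`, and
#'   `distance_to_tss` (signed bp, positive downstream of the TSS in
#'   transcript orientation) appended.
#' @export
annotate_hits <- function(hits, genes, tss_window = c(-1000, 100),
                          tts_window = c(-100, 1000), end_flank = 5000,
                          max_assoc = 100000) {
  stopifnot(is.data.frame(hits))
  n <- nrow(hits)
  mid <- as.integer(floor((hits$start + hits$end) / 2))
  category <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  dist_tss <- rep(NA_integer_, n)
  if (!is.null(genes) && inherits(genes, "gene_model") &&
      nrow(genes$transcripts) > 0L && n > 0L) {
    reg <- .category_regions(genes, tss_window, tts_window)
    for (cat_name in names(reg)) {
      r <- reg[[cat_name]]
      if (!nrow(r)) next
      unset <- which(category == "intergenic")
      if (!length(unset)) break
      for (i in unset) {
        if (any(r$chrom == hits$seqid[i] & r$start <= mid[i] &
                  r$end >= mid[i]))
          category[i] <- cat_name
      }
    }
    tx <- genes$transcripts
    plus <- tx$strand == "+"
    tss <- ifelse(plus, tx$start, tx$end)
    sgn <- ifelse(plus, 1L, -1L)
    for (i in seq_len(n)) {
      on_chr <- which(tx$chrom == hits$seqid[i])
      if (!length(on_chr)) next
      d <- (mid[i] - tss[on_chr]) * sgn[on_chr]
      in_body <- mid[i] >= tx$start[on_chr] - end_flank &
        mid[i] <= tx$end[on_chr] + end_flank
      ok <- abs(d) <= max_assoc | in_body
      if (!any(ok)) next
      j <- on_chr[ok][which.min(abs(d[ok]))]
      gene_id[i] <- tx$gene_id[tx$tx_id == tx$tx_id[j]][1]
      dist_tss[i] <- d[ok][which.min(abs(d[ok]))]
    }
  }
  hits$category <- factor(category, levels = ANNOT_CATEGORIES)
  hits$gene_id <- gene_id
  hits$distance_to_tss <- dist_tss
  hits
}

#' Category counts and fractions of annotated hits
#'
#' @param annotated output of [annotate_hits()].
#' @param split_by_tier when `TRUE`, one row per (tier, category).
#' @return `data.frame` with `category`, `count`, `fraction` (and `tier`
#'   when split); fractions sum to 1 within each tier.
#' @export
category_fractions <- function(annotated, split_by_tier = FALSE) {
  if (!split_by_tier) {
    tab <- table(annotated$category)
    return(data.frame(category = names(tab), count = as.integer(tab),
                      fraction = if (sum(tab) > 0) as.numeric(tab / sum(tab))
                                 else NA_real_,
                      stringsAsFactors = FALSE))
  }
  out <- list()
  for (k in sort(unique(annotated$tier))) {
    sub <- annotated[annotated$tier == k, , drop = FALSE]
    tab <- table(sub$category)
    out[[length(out) + 1L]] <- data.frame(
      tier = k, category = names(tab), count = as.integer(tab),
      fraction = as.numeric(tab / max(1L, sum(tab))),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Compare a category fraction between half-site and full-site hits
#'
#' Two-proportion test (chi-squared with continuity correction) of the
#' fraction of hits in `category` between tier-5 half sites and tier
#' 1-4 full sites, e.g. the elevated TSS fraction of half sites.
#'
#' @param annotated output of [annotate_hits()].
#' @param category category name, default `"TSS"`.
#' @return list with per-class counts, fractions, the difference
#'   (half - full), and the test p-value.
#' @export
compare_category_fraction <- function(annotated, category = "TSS") {
  half <- annotated$tier == 5L
  x <- c(half = sum(annotated$category[half] == category),
         full = sum(annotated$category[!half] == category))
  n <- c(half = sum(half), full = sum(!half))
  frac <- ifelse(n > 0, x / n, NA_real_)
  pv <- if (all(n > 0)) suppressWarnings(
    stats::prop.test(x, n)$p.value) else NA_real_
  list(category = category, counts = x, n = n, fractions = frac,
       difference = unname(frac["half"] - frac["full"]), p_value = pv)
}
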