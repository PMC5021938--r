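# End-to-end pipeline binding the stages, plus a subcommand CLI.
# Config is a flat keyed list (JSON on disk); every run echoes its
# effective config and writes a manifest with per-output row counts.

default_config <- function() {
  list(
    fasta = NULL, out_dir = "tierscan_out", seed = 1L,
    # scanning
    motif = NULL, p_value = 4.94e-5, background = "auto",
    # classification
    mismatches_one_hexamer = FALSE,
    # annotation
    genes = NULL, gene_format = NULL,
    tss_upstream = 1000L, tss_downstream = 100L,
    tts_upstream = 100L, tts_downstream = 1000L,
    end_flank = 5000L, max_assoc = 100000L,
    # cooperation
    secondary = NULL, window = 160L, bin_width = 5L,
    secondary_p = 1e-4, alpha = 0.05,
    # density
    regions = NULL, chrom_sizes = NULL,
    # hit rate
    responses = NULL, per_gene_best_tier = FALSE)
}

#' Load and validate a run configuration
#'
#' @param config named list or path to a JSON file; unknown keys are
#'   rejected.
#' @return the full config list with defaults filled in.
#' @export
load_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(def, config)
}

#' Run the full ARE analysis pipeline
#'
#' Stages (each optional input gates its stage): classify sequences into
#' tiered sites; annotate against a gene model; spacing analysis against
#' a secondary motif; region-density comparison; tier hit rate against a
#' response table. Outputs (BED/TSV), an effective-config echo, and a
#' manifest with row counts are written to `out_dir`. Identical config
#' and seed reproduce identical outputs.
#'
#' @param config list or JSON path (see [load_config()]); `fasta` is
#'   required.
#' @return invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$fasta)) stop("config key 'fasta' is required")
  if (!file.exists(cfg$fasta)) stop("FASTA not found: ", cfg$fasta)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(file, rows) manifest[[length(manifest) + 1L]] <<-
    data.frame(file = file, rows = rows, stringsAsFactors = FALSE)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  seqs <- stage("read_fasta", as_sequences(cfg$fasta))
  results <- list(config = cfg)

  tiered <- stage("classify", classify_sequences(
    seqs, mismatches_one_hexamer = cfg$mismatches_one_hexamer))
  write_hits_bed(tiered, file.path(cfg$out_dir, "tiered_hits.bed"))
  write_tiered_tsv(tiered, file.path(cfg$out_dir, "tiered_hits.tsv"))
  note("tiered_hits.tsv", nrow(tiered))
  results$tiered <- tiered
  results$tier_summary <- tier_distribution(tiered)

  if (!is.null(cfg$motif)) {
    models <- stage("read_motif", read_meme(cfg$motif))
    scan_hits <- stage("scan", do.call(rbind, lapply(models, function(m)
      scan_sequences(seqs, m, p_value = cfg$p_value,
                     background = cfg$background))))
    write_tsv(scan_hits, file.path(cfg$out_dir, "scan_hits.tsv"),
              comment = "coordinates: 1-based inclusive")
    note("scan_hits.tsv", nrow(scan_hits))
    results$scan_hits <- scan_hits
  }

  if (!is.null(cfg$genes)) {
    gm <- stage("read_genes", read_gene_model(cfg$genes, cfg$gene_format))
    annotated <- stage("annotate", annotate_hits(
      tiered, gm,
      tss_window = c(-cfg$tss_upstream, cfg$tss_downstream),
      tts_window = c(-cfg$tts_upstream, cfg$tts_downstream),
      end_flank = cfg$end_flank, max_assoc = cfg$max_assoc))
    write_tsv(annotated, file.path(cfg$out_dir, "annotated_hits.tsv"),
              comment = "coordinates: 1-based inclusive")
    note("annotated_hits.tsv", nrow(annotated))
    results$annotated <- annotated
    if (!is.null(cfg$responses)) {
      resp <- stage("read_responses", read_response_table(cfg$responses))
      hr <- stage("hitrate", tier_hit_rate(
        annotated, resp, per_gene_best_tier = cfg$per_gene_best_tier))
      write_tsv(hr$table, file.path(cfg$out_dir, "tier_hit_rate.tsv"),
                comment = sprintf("spearman rho=%g p=%g", hr$rho,
                                  hr$rho_p))
      note("tier_hit_rate.tsv", nrow(hr$table))
      results$hit_rate <- hr
    }
  }

  if (!is.null(cfg$secondary)) {
    sec <- stage("read_secondary", read_meme(cfg$secondary)[[1]])
    full_anchors <- tiered[tiered$tier <= 4L, , drop = FALSE]
    half_anchors <- tiered[tiered$tier == 5L, , drop = FALSE]
    hf <- stage("spacing", spacing_histogram(
      full_anchors, sec, seqs, window = cfg$window,
      bin_width = cfg$bin_width, secondary_p = cfg$secondary_p))
    hh <- stage("spacing", spacing_histogram(
      half_anchors, sec, seqs, window = cfg$window,
      bin_width = cfg$bin_width, secondary_p = cfg$secondary_p))
    ef <- spacing_enrichment(hf, alpha = cfg$alpha)
    eh <- spacing_enrichment(hh, alpha = cfg$alpha)
    write_spacing_tsv(ef, file.path(cfg$out_dir, "spacing_full.tsv"))
    write_spacing_tsv(eh, file.path(cfg$out_dir, "spacing_half.tsv"))
    note("spacing_full.tsv", nrow(ef$bins))
    note("spacing_half.tsv", nrow(eh$bins))
    results$spacing <- list(full = ef, half = eh,
                            comparison = compare_anchor_classes(hf, hh))
  }

  if (!is.null(cfg$regions) && !is.null(cfg$chrom_sizes)) {
    regions <- stage("read_regions", read_bed_regions(cfg$regions))
    sizes <- stage("read_chrom_sizes", read_chrom_sizes(cfg$chrom_sizes))
    dc <- stage("density", region_density(tiered, regions, sizes))
    df <- data.frame(hits_in = dc$hits_in, hits_out = dc$hits_out,
                     mbp_in = dc$mbp_in, mbp_out = dc$mbp_out,
                     density_in = dc$density_in,
                     density_out = dc$density_out, p_value = dc$p_value)
    write_tsv(df, file.path(cfg$out_dir, "density.tsv"),
              comment = "hits per Mbp, exact two-sided binomial test")
    note("density.tsv", 1L)
    results$density <- dc
  }

  manifest <- do.call(rbind, manifest)
  write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"),
            comment = paste0("tierscan ",
                             as.character(utils::packageVersion("tierscan")),
                             " seed=", cfg$seed))
  results$manifest <- manifest
  invisible(results)
}

# ---- command line interface -------------------------------------------

.parse_cli_args <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    key <- gsub("-", "_", key)
    if (i == length(argv) || startsWith(argv[i + 1L], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- argv[i + 1L]
      i <- i + 2L
    }
  }
  out
}

.cli_num <- function(x, default) if (is.null(x)) default else as.numeric(x)

#' Command-line entry point
#'
#' Subcommands: `build-model`, `scan`, `classify`, `annotate`,
#' `spacing`, `density`, `hitrate`, `simulate`, `run`. Invoke from a
#' shell via the `inst/scripts/tierscan` launcher or
#' `Rscript -e 'tierscan::tierscan_main()' <subcommand> --...`.
#'
#' @param argv character vector of arguments (default: the command
#'   line).
#' @return exit status 0, invisibly.
#' @export
tierscan_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    cat("usage: tierscan <build-model|scan|classify|annotate|spacing|",
        "density|hitrate|simulate|run> [--options]\n", sep = "")
    return(invisible(0L))
  }
  cmd <- argv[1]
  opt <- .parse_cli_args(argv[-1])
  switch(cmd,
    "build-model" = {
      m <- consensus_to_pssm(opt$consensus,
                             match_prob = .cli_num(opt$match_prob, 0.997))
      write_meme(m, opt$out)
      cat("wrote model '", m$name, "' to ", opt$out, "\n", sep = "")
    },
    scan = {
      models <- if (file.exists(opt$motif)) read_meme(opt$motif)
                else list(consensus_to_pssm(opt$motif))
      bg <- if (is.null(opt$background)) "auto" else opt$background
      hits <- do.call(rbind, lapply(models, function(m)
        scan_sequences(opt$fasta, m,
                       p_value = .cli_num(opt$pvalue, 1e-4),
                       background = bg)))
      write_hits_bed(hits, paste0(opt$out, ".bed"))
      write_tsv(hits, paste0(opt$out, ".tsv"),
                comment = "coordinates: 1-based inclusive")
      cat(nrow(hits), "hits\n")
    },
    classify = {
      tiered <- classify_sequences(
        opt$fasta,
        mismatches_one_hexamer = isTRUE(opt$mismatches_one_hexamer))
      write_hits_bed(tiered, paste0(opt$out, ".bed"))
      write_tiered_tsv(tiered, paste0(opt$out, ".tsv"))
      print(tier_distribution(tiered))
    },
    annotate = {
      hits <- utils::read.table(opt$hits, header = TRUE, sep = "\t",
                                comment.char = "#",
                                stringsAsFactors = FALSE)
      gm <- read_gene_model(opt$genes, opt$format)
      ann <- annotate_hits(hits, gm)
      write_tsv(ann, opt$out, comment = "coordinates: 1-based inclusive")
      cat(nrow(ann), "annotated hits\n")
    },
    spacing = {
      anchors <- utils::read.table(opt$anchors, header = TRUE, sep = "\t",
                                   comment.char = "#",
                                   stringsAsFactors = FALSE)
      sec <- read_meme(opt$secondary)[[1]]
      h <- spacing_histogram(anchors, sec, opt$fasta,
                             window = .cli_num(opt$window, 160),
                             bin_width = .cli_num(opt$bin, 5))
      res <- spacing_enrichment(h)
      write_spacing_tsv(res, opt$out)
      print(res)
    },
    density = {
      hits <- utils::read.table(opt$hits, header = TRUE, sep = "\t",
                                comment.char = "#",
                                stringsAsFactors = FALSE)
      dc <- region_density(hits, read_bed_regions(opt$regions),
                           read_chrom_sizes(opt$chrom_sizes))
      print(dc)
    },
    hitrate = {
      ann <- utils::read.table(opt$annotated, header = TRUE, sep = "\t",
                               comment.char = "#",
                               stringsAsFactors = FALSE)
      hr <- tier_hit_rate(ann, read_response_table(opt$responses))
      print(hr)
    },
    simulate = {
      seed <- as.integer(.cli_num(opt$seed, 1))
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      sim <- simulate_preset(if (is.null(opt$preset)) "tiers"
                             else opt$preset, seed = seed)
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(stats::setNames(sim$sequence, "chr_sim")),
        file.path(opt$out, "genome.fa"))
      write_tsv(sim$truth, file.path(opt$out, "truth.tsv"),
                comment = "coordinates: 1-based inclusive")
      cat("simulated", nrow(sim$truth), "planted sites to", opt$out, "\n")
    },
    run = {
      run_pipeline(opt$config)
      cat("pipeline complete\n")
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}

#' Simulate a named fixture preset
#'
#' Presets: `"tiers"` (100-kb genome, 5 sites per tier 1-4 plus 10 half
#' sites) and `"cooperation"` (half sites with a KLF-like GC-box motif
#' planted at a constant 15-bp downstream gap).
#'
#' @param preset preset name.
#' @param seed RNG seed.
#' @return list with `sequence` and `truth`.
#' @export
simulate_preset <- function(preset = c("tiers", "cooperation"),
                            seed = 1L) {
  preset <- match.arg(preset)
  bg <- gen_background(1e5, seed = seed)
  if (preset == "tiers") {
    full <- plant_full_sites(bg, c("1" = 5, "2" = 5, "3" = 5, "4" = 5),
                             seed = seed + 1L)
    half <- plant_half_sites_and_cooperators(full$sequence, 10,
                                             seed = seed + 2L)
    truth <- rbind(
      full$truth[, c("seqid", "start", "end", "strand", "planted_tier")],
      half$truth[, c("seqid", "start", "end", "strand", "planted_tier")])
    list(sequence = half$sequence, truth = truth[order(truth$start), ])
  } else {
    half <- plant_half_sites_and_cooperators(
      bg, 50, secondary_consensus = "GGGGCGGGG", gap_sampler = 15L,
      seed = seed + 1L)
    list(sequence = half$sequence, truth = half$truth)
  }
}
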