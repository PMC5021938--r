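# MEME minimal motif format reader/writer. Only the minimal-format
# fields are handled: version line, ALPHABET, optional strands line,
# background letter frequencies, and letter-probability matrix blocks.

#' Write motif models in MEME minimal format
#'
#' @param models a [motif_model()] or a list of them.
#' @param path output path.
#' @param background background frequencies written to the header; by
#'   default the background of the first model.
#' @param digits decimal digits for probabilities (6 gives round-trip
#'   agreement within 1e-6).
#' @return the path, invisibly.
#' @export
write_meme <- function(models, path, background = NULL, digits = 6) {
  if (inherits(models, "motif_model")) models <- list(models)
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "motif_model")))
  if (is.null(background)) background <- models[[1]]$background
  background <- check_background(background)
  fmt <- paste0("%.", digits, "f")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf(paste0("%s ", fmt), DNA4, background),
                     collapse = " "), ""), con)
  for (m in models) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      m$width), con)
    for (i in seq_len(m$width))
      writeLines(paste(sprintf(fmt, m$probs[i, ]), collapse = "  "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motif models from a MEME minimal file
#'
#' Rows are renormalized to sum to one (the format stores rounded
#' probabilities). The file-level background is attached to every model.
#'
#' @param path MEME minimal format file.
#' @return a named list of [motif_model()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  if (!any(grepl("^MEME version", lines)))
    stop("not a MEME minimal file (missing 'MEME version' line): ", path)
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(lines[bg_at[1] + 1], "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    lets <- toks[is.na(vals)]
    nums <- vals[!is.na(vals)]
    if (length(lets) == 4L && length(nums) == 4L)
      background <- nums[match(DNA4, toupper(lets))]
    background <- background / sum(background)
  }
  motif_at <- grep("^MOTIF\\b", lines)
  if (!length(motif_at)) stop("no MOTIF blocks in ", path)
  models <- list()
  for (s in motif_at) {
    name <- strsplit(lines[s], "\\s+")[[1]][2]
    h <- s + which(grepl("^letter-probability matrix", lines[(s + 1):length(lines)]))[1]
    if (is.na(h)) stop("MOTIF ", name, ": missing letter-probability matrix")
    w <- suppressWarnings(as.integer(
      sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[h])))
    rows <- list(); i <- h + 1
    while (i <= length(lines) &&
           grepl("^[0-9.eE+-]", lines[i]) && nzchar(lines[i])) {
      rows[[length(rows) + 1L]] <-
        as.numeric(strsplit(lines[i], "\\s+")[[1]])
      i <- i + 1
    }
    probs <- do.call(rbind, rows)
    if (!is.na(w) && nrow(probs) != w)
      stop("MOTIF ", name, ": expected ", w, " rows, found ", nrow(probs))
    probs <- probs / rowSums(probs)
    models[[name]] <- motif_model(name, probs, background)
  }
  models
}
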