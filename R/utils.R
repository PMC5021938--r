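# Shared low-level helpers: seed scoping, DNA coding, sequence coercion.

DNA4 <- c("A", "C", "G", "T")

# IUPAC nucleotide codes -> allowed bases (alphabet order A,C,G,T)
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with `set.seed(seed)` in effect and restores the caller's
#' RNG state afterwards, so seeded generators do not perturb the global
#' random stream. A `NULL` seed evaluates `expr` unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# character string -> integer codes 1..4 (A,C,G,T); anything else -> NA
dna_codes <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  match(strsplit(toupper(x), "", fixed = TRUE)[[1]], DNA4)
}

# vectorized reverse complement of character sequences
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# complement of IUPAC letters (for consensus strings)
iupac_complement <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
}

# Coerce FASTA path / DNAStringSet / character vector to a named,
# uppercased character vector of sequences.
as_sequences <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    out <- as.character(x)
  } else if (is.character(x) && length(x) == 1L && file.exists(x) &&
             !grepl("^[ACGTNacgtn]+$", x)) {
    out <- as.character(Biostrings::readDNAStringSet(x))
  } else if (is.character(x)) {
    out <- x
  } else {
    stop("sequences must be a FASTA path, a DNAStringSet, or a character vector")
  }
  out <- toupper(out)
  if (is.null(names(out)) || any(names(out) == "")) {
    nm <- names(out)
    if (is.null(nm)) nm <- rep("", length(out))
    nm[nm == ""] <- paste0("seq", which(nm == ""))
    names(out) <- nm
  }
  # FASTA headers: keep first token only
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

# validate a 4-vector of base frequencies
check_background <- function(background) {
  if (!is.numeric(background) || length(background) != 4L)
    stop("background must be a numeric vector of 4 frequencies (A,C,G,T)")
  if (any(background < 0) || abs(sum(background) - 1) > 1e-9)
    stop("background frequencies must be non-negative and sum to 1")
  stats::setNames(as.numeric(background), DNA4)
}

# write a data.frame as TSV with an optional '#' header comment
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
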