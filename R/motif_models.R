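# Position-specific matrix models: construction, transformation, and
# serialization. A motif_model carries per-position base probabilities,
# a zero-order background, and the derived base-2 log-odds view.

PROB_FLOOR <- 1e-10  # keeps log-odds finite for degenerate inputs

#' Construct a motif model from explicit probabilities
#'
#' Low-level constructor used by [consensus_to_pssm()] and
#' [build_pssm_from_sites()]. Validates that each row of `probs` sums to
#' one, floors entries at a tiny positive value so base-2 log-odds stay
#' finite, and derives the consensus string and informative mask.
#'
#' @param name model identifier.
#' @param probs numeric matrix, width x 4, columns in order A,C,G,T.
#' @param background numeric vector of 4 zero-order base frequencies.
#' @param consensus optional IUPAC consensus to store verbatim; when
#'   `NULL` it is derived per position (most probable base, `N` when the
#'   maximum probability falls below `degeneracy_threshold`).
#' @param degeneracy_threshold maximum-probability cutoff below which a
#'   derived consensus position is written as `N`.
#' @return an object of class `motif_model` with fields `name`, `width`,
#'   `probs`, `background`, `log_odds`, `consensus`, `informative_mask`.
#' @export
motif_model <- function(name, probs, background = rep(0.25, 4),
                        consensus = NULL, degeneracy_threshold = 0.5) {
  background <- check_background(background)
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L || nrow(probs) < 1L)
    stop("probs must be a width x 4 matrix (columns A,C,G,T)")
  if (any(!is.finite(probs)) || any(probs < 0))
    stop("probs entries must be finite and non-negative")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-9))
    stop("every probs row must sum to 1 (worst deviation ",
         format(max(abs(rs - 1))), ")")
  probs[probs < PROB_FLOOR] <- PROB_FLOOR
  probs <- probs / rowSums(probs)
  colnames(probs) <- DNA4
  rownames(probs) <- NULL
  if (any(background <= 0))
    stop("background frequencies must be strictly positive for log-odds")
  log_odds <- log2(sweep(probs, 2, background, "/"))
  w <- nrow(probs)
  # informative = not (numerically) identical to the background row
  informative <- apply(abs(sweep(probs, 2, background, "-")), 1, max) > 1e-6
  if (is.null(consensus)) {
    best <- max.col(probs, ties.method = "first")
    letters <- DNA4[best]
    letters[probs[cbind(seq_len(w), best)] < degeneracy_threshold] <- "N"
    consensus <- paste(letters, collapse = "")
  } else {
    consensus <- toupper(consensus)
    if (nchar(consensus) != w)
      stop("consensus length does not match probs width")
    informative[strsplit(consensus, "")[[1]] == "N"] <- FALSE
  }
  structure(
    list(name = as.character(name), width = w, probs = probs,
         background = background, log_odds = log_odds,
         consensus = consensus, informative_mask = informative),
    class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("motif_model '", x$name, "' width ", x$width,
      "\n  consensus:  ", x$consensus,
      "\n  informative: ", paste(ifelse(x$informative_mask, "*", "."),
                                 collapse = ""),
      "\n  background: ", paste(sprintf("%s=%.3f", DNA4, x$background),
                                collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Build a PSSM from an IUPAC consensus string
#'
#' Single-letter positions give `match_prob` to that letter and split the
#' remainder equally across the other three; multi-letter IUPAC codes
#' split `match_prob` equally among allowed letters; `N` positions copy
#' the background row and are marked uninformative.
#'
#' @param consensus IUPAC string, e.g. `"AGAACANNNTGTTCT"`.
#' @param match_prob probability mass on the consensus letter(s); must
#'   exceed 0.25 or the model carries no information.
#' @param background zero-order base frequencies (A,C,G,T).
#' @param name model name; defaults to the consensus string.
#' @return a [motif_model()].
#' @examples
#' m <- consensus_to_pssm("AGAACANNNTGTTCT", match_prob = 0.997)
#' which(!m$informative_mask)  # the 3-bp spacer
#' @export
consensus_to_pssm <- function(consensus, match_prob = 0.997,
                              background = rep(0.25, 4),
                              name = consensus) {
  background <- check_background(background)
  if (!is.character(consensus) || length(consensus) != 1L ||
      nchar(consensus) < 1L)
    stop("consensus must be a non-empty string")
  consensus <- toupper(consensus)
  letters <- strsplit(consensus, "")[[1]]
  bad <- which(!letters %in% names(IUPAC_CODES))
  if (length(bad))
    stop("non-IUPAC character '", letters[bad[1]], "' at position ", bad[1])
  if (!is.numeric(match_prob) || match_prob <= 0.25 || match_prob > 1)
    stop("match_prob must lie in (0.25, 1]: ", match_prob,
         " would give an uninformative model")
  w <- length(letters)
  probs <- matrix(0, w, 4, dimnames = list(NULL, DNA4))
  for (i in seq_len(w)) {
    if (letters[i] == "N") {
      probs[i, ] <- background
    } else {
      allowed <- IUPAC_CODES[[letters[i]]]
      k <- length(allowed)
      probs[i, ] <- (1 - match_prob) / (4 - k)
      probs[i, allowed] <- match_prob / k
    }
  }
  m <- motif_model(name, probs, background, consensus = consensus)
  m$informative_mask <- letters != "N"
  m
}

#' Build a PSSM from aligned binding sites
#'
#' Estimates per-position probabilities from observed site counts with a
#' background-weighted pseudocount:
#' `p[i,b] = (count[i,b] + pseudocount * background[b]) / (n + pseudocount)`.
#'
#' @param sites character vector of equal-length A/C/G/T strings.
#' @param pseudocount total pseudocount mass (default 1, Laplace-style,
#'   split by background). With zero, unobserved bases are floored at a
#'   tiny probability so log-odds remain finite.
#' @param background zero-order base frequencies.
#' @param name model name.
#' @param degeneracy_threshold consensus positions with maximum
#'   probability below this are written `N`.
#' @return a [motif_model()].
#' @export
build_pssm_from_sites <- function(sites, pseudocount = 1,
                                  background = rep(0.25, 4),
                                  name = "sites_model",
                                  degeneracy_threshold = 0.5) {
  background <- check_background(background)
  if (!is.character(sites) || length(sites) < 1L)
    stop("at least one site is required")
  sites <- toupper(sites)
  w <- nchar(sites[1])
  if (any(nchar(sites) != w))
    stop("all sites must have identical length")
  if (any(!grepl("^[ACGT]+$", sites)))
    stop("sites are restricted to the alphabet A,C,G,T")
  if (!is.numeric(pseudocount) || pseudocount < 0)
    stop("pseudocount must be non-negative")
  mat <- matrix(unlist(strsplit(sites, "")), nrow = length(sites),
                byrow = TRUE)
  counts <- sapply(DNA4, function(b) colSums(mat == b))
  if (w == 1L) counts <- matrix(counts, 1, 4, dimnames = list(NULL, DNA4))
  n <- length(sites)
  probs <- (counts + pseudocount * rep(background, each = w)) /
    (n + pseudocount)
  # with pseudocount 0, unobserved bases get zero probability; the
  # constructor floors these at a tiny value so log-odds stay defined
  motif_model(name, probs, background,
              degeneracy_threshold = degeneracy_threshold)
}

#' Reverse complement of a motif model
#'
#' Rows are reversed and bases permuted A<->T, C<->G in both the
#' probability matrix and the background. Applying the operation twice
#' returns the original model. The palindromic ARE full-site model is its
#' own reverse complement.
#'
#' @param model a [motif_model()].
#' @return a [motif_model()].
#' @export
reverse_complement_model <- function(model) {
  stopifnot(inherits(model, "motif_model"))
  perm <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G
  probs <- model$probs[rev(seq_len(model$width)), perm, drop = FALSE]
  colnames(probs) <- DNA4
  bg <- stats::setNames(model$background[perm], DNA4)
  m <- motif_model(model$name, probs, bg,
                   consensus = iupac_complement(
                     paste(rev(strsplit(model$consensus, "")[[1]]),
                           collapse = "")))
  m$informative_mask <- rev(model$informative_mask)
  m
}

#' Is a model its own reverse complement?
#'
#' @param model a [motif_model()].
#' @param tol maximum per-entry probability difference tolerated.
#' @return logical.
#' @export
is_palindromic <- function(model, tol = 1e-6) {
  rc <- reverse_complement_model(model)
  max(abs(model$probs - rc$probs)) <= tol
}

#' Replace the background of a model, recomputing log-odds
#'
#' @param model a [motif_model()].
#' @param background new zero-order frequencies.
#' @return a [motif_model()] with identical probabilities.
#' @export
set_background <- function(model, background) {
  m <- motif_model(model$name, model$probs, check_background(background),
                   consensus = model$consensus)
  m$informative_mask <- model$informative_mask
  m
}

#' Per-position and total information content (bits)
#'
#' Uses the uniform-background convention `IC(i) = 2 + sum_b p log2 p`,
#' the scaling used in sequence-logo conservation displays.
#'
#' @param model a [motif_model()].
#' @return list with `per_position` (numeric, bits) and `total` (bits).
#' @export
information_content <- function(model) {
  stopifnot(inherits(model, "motif_model"))
  plogp <- model$probs * log2(model$probs)
  plogp[model$probs == 0] <- 0
  per <- 2 + rowSums(plogp)
  list(per_position = per, total = sum(per))
}

#' Serialize a motif model to JSON
#'
#' All fields are written; [model_from_json()] restores them.
#'
#' @param model a [motif_model()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
model_to_json <- function(model, path) {
  stopifnot(inherits(model, "motif_model"))
  x <- list(name = model$name, width = model$width,
            alphabet = DNA4,
            probs = unname(model$probs),
            background = unname(model$background),
            log_odds = unname(model$log_odds),
            consensus = model$consensus,
            informative_mask = model$informative_mask)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a motif model from its JSON dump
#'
#' @param path path written by [model_to_json()].
#' @return a [motif_model()].
#' @export
model_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- motif_model(x$name, x$probs, x$background, consensus = x$consensus)
  m$informative_mask <- as.logical(x$informative_mask)
  m
}
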