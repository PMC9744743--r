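## motif_scan: linear HS-binding motif detection in amino-acid sequences.
##
## Patterns are strings over {B, X}: B positions must hold a basic residue
## (Arg, Lys, His by default), X positions anything non-basic (default) or
## strictly neutral (strict mode, additionally excluding Asp/Glu).

#' Build a motif pattern set
#'
#' @param id Pattern identifiers (unique).
#' @param pattern Patterns over the alphabet `{B, X}`; hyphen separators as
#'   in `"BB-X-B"` are stripped.
#' @param source Provenance label, e.g. `"user"`.
#' @return Data frame of class `hs_patterns` with columns `id`, `pattern`,
#'   `source`.
#' @export
motif_patterns <- function(id, pattern, source = "user") {
  pattern <- gsub("-", "", toupper(pattern), fixed = TRUE)
  if (!length(pattern)) stop("empty pattern list", call. = FALSE)
  bad <- !grepl("^[BX]+$", pattern)
  if (any(bad)) {
    stop("patterns must use only B and X: ",
         paste(pattern[bad], collapse = ", "), call. = FALSE)
  }
  nb <- vapply(strsplit(pattern, ""), function(p) sum(p == "B"), integer(1))
  if (any(nb < 2)) {
    stop("every pattern needs at least 2 B positions", call. = FALSE)
  }
  if (anyDuplicated(id)) stop("pattern ids must be unique", call. = FALSE)
  out <- data.frame(id = as.character(id), pattern = pattern,
                    source = source, stringsAsFactors = FALSE)
  class(out) <- c("hs_patterns", "data.frame")
  out
}

#' Default HS-binding motif patterns
#'
#' The five canonical linear HS-binding patterns: the three classical
#' Cardin-Weintraub-style consensus motifs XBBXBX, BBBXXBB and BBXXXBB,
#' plus the short spaced pairs BBXB and BBXXB whose one- or two-residue gap
#' mirrors the ~5-10 Angstrom spacing of charged groups in folded sites.
#'
#' @return An `hs_patterns` data frame with 5 rows.
#' @export
default_pattern_set <- function() {
  rbind(
    motif_patterns(c("XBBXBX", "BBBXXBB", "BBXXXBB"),
                   c("XBBXBX", "BBBXXBB", "BBXXXBB"),
                   source = "consensus"),
    motif_patterns(c("BBXB", "BBXXB"), c("BBXB", "BBXXB"),
                   source = "spaced_pair")
  )
}

#' Scan a sequence for linear HS-binding motifs
#'
#' Reports all matches of all patterns at all offsets; overlapping matches
#' are all kept (downstream removal design needs the full set). Matching is
#' case-insensitive. The residue code `X` in a *sequence* never matches a B
#' position.
#'
#' @param sequence One-letter amino-acid string (may be empty).
#' @param patterns An `hs_patterns` data frame; default
#'   [default_pattern_set()].
#' @param b_alphabet Residues counted as basic (default R, K, H; drop `"H"`
#'   to ignore histidine, which is mostly uncharged at physiological pH).
#' @param x_semantics What a pattern `X` may match: `"nonbasic"` (default),
#'   `"neutral"` (strict mode, additionally excluding the acidic D and E)
#'   or `"any"`.
#' @param reverse Also scan the reversed sequence (default `FALSE`;
#'   motifs are treated as directional strings).
#' @return Data frame of class `hs_motif_hits`, ordered by (start,
#'   pattern id), with columns `start`, `end` (1-based inclusive positions),
#'   `pattern_id`, `matched_subsequence`, `basic_positions`
#'   (comma-separated) and `strand` (`"fwd"`/`"rev"`).
#' @examples
#' scan_linear_motifs("AKKAKA",
#'                    patterns = motif_patterns("XBBXBX", "XBBXBX"))
#' @export
scan_linear_motifs <- function(sequence, patterns = default_pattern_set(),
                               b_alphabet = c("R", "K", "H"),
                               x_semantics = c("nonbasic", "neutral", "any"),
                               reverse = FALSE) {
  x_semantics <- match.arg(x_semantics)
  if (is.null(patterns) || !nrow(patterns)) {
    stop("empty pattern list", call. = FALSE)
  }
  b_alphabet <- setdiff(toupper(b_alphabet), "X")
  scan_one <- function(seqstr, strand) {
    chars <- strsplit(toupper(seqstr), "")[[1]]
    n <- length(chars)
    basic <- chars %in% b_alphabet
    xok <- switch(x_semantics,
      nonbasic = !basic,
      neutral = !basic & !(chars %in% .ACIDIC_AA) &
        !(chars %in% .BASIC_AA),
      any = rep(TRUE, n))
    hits <- list()
    for (r in seq_len(nrow(patterns))) {
      pat <- strsplit(patterns$pattern[r], "")[[1]]
      L <- length(pat)
      if (L > n) next
      pb <- which(pat == "B")
      px <- which(pat == "X")
      offs <- seq_len(n - L + 1L)
      ok <- rep(TRUE, length(offs))
      for (k in pb) ok <- ok & basic[offs + k - 1L]
      for (k in px) ok <- ok & xok[offs + k - 1L]
      ko <- offs[ok]
      if (!length(ko)) next
      hits[[length(hits) + 1L]] <- data.frame(
        start = ko, end = ko + L - 1L,
        pattern_id = patterns$id[r],
        matched_subsequence = vapply(ko, function(o) {
          paste(chars[o:(o + L - 1L)], collapse = "")
        }, character(1)),
        basic_positions = vapply(ko, function(o) {
          paste(o + pb - 1L, collapse = ",")
        }, character(1)),
        strand = strand, stringsAsFactors = FALSE
      )
    }
    hits
  }
  hits <- scan_one(sequence, "fwd")
  if (reverse) {
    rev_seq <- paste(rev(strsplit(sequence, "")[[1]]), collapse = "")
    hits <- c(hits, scan_one(rev_seq, "rev"))
  }
  out <- if (length(hits)) do.call(rbind, hits) else data.frame(
    start = integer(), end = integer(), pattern_id = character(),
    matched_subsequence = character(), basic_positions = character(),
    strand = character(), stringsAsFactors = FALSE
  )
  out <- out[order(out$start, out$pattern_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hs_motif_hits", "data.frame")
  out
}

#' Scan every chain of a structure model for linear motifs
#'
#' Runs [scan_linear_motifs()] on the full per-chain sequence (modeled and
#' unmodeled residues) and reports positions in author numbering.
#'
#' @param model An `hs_structure`.
#' @inheritParams scan_linear_motifs
#' @return An `hs_motif_hits` data frame with an additional `chain` column;
#'   `start`, `end` and `basic_positions` are author residue numbers.
#'   Ordered by (chain, start, pattern id).
#' @export
scan_model_motifs <- function(model, patterns = default_pattern_set(),
                              b_alphabet = c("R", "K", "H"),
                              x_semantics = c("nonbasic", "neutral", "any"),
                              ...) {
  x_semantics <- match.arg(x_semantics)
  chains <- unique(model$residues$chain)
  out <- list()
  for (ch in chains) {
    res <- model$residues[model$residues$chain == ch, , drop = FALSE]
    hits <- scan_linear_motifs(paste(res$aa, collapse = ""),
                               patterns = patterns,
                               b_alphabet = b_alphabet,
                               x_semantics = x_semantics, ...)
    if (!nrow(hits)) next
    remap <- function(idx) res$resno[idx]
    hits$basic_positions <- vapply(strsplit(hits$basic_positions, ","),
      function(p) paste(remap(as.integer(p)), collapse = ","), character(1))
    hits$start <- remap(hits$start)
    hits$end <- remap(hits$end)
    hits <- cbind(chain = ch, hits, stringsAsFactors = FALSE)
    out[[ch]] <- hits
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    chain = character(), start = integer(), end = integer(),
    pattern_id = character(), matched_subsequence = character(),
    basic_positions = character(), strand = character(),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$chain, res$start, res$pattern_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("hs_motif_hits", "data.frame")
  res
}
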