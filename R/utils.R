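#' Reverse complement of DNA strings (IUPAC-aware)
#'
#' @param x Character vector of DNA strings (IUPAC codes allowed).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

comp_base <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
}

# TRUE where the IUPAC pattern character admits the observed character
# (non-empty intersection of degeneracy sets, so N matches anything on
# either side). Vectorised over equal-length character vectors of single
# characters.
iupac_compatible <- function(pattern_char, observed_char) {
  mapply(function(p, o) {
    sp <- IUPAC_SETS[[p]]
    so <- IUPAC_SETS[[o]]
    if (is.null(sp) || is.null(so)) return(FALSE)
    length(intersect(sp, so)) > 0L
  }, pattern_char, observed_char, USE.NAMES = FALSE)
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# sample random DNA with a given GC content
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abescan_log <- function(..., level = "INFO") {
  lv <- Sys.getenv("ABESCAN_LOG", "INFO")
  ranks <- c(DEBUG = 1, INFO = 2, WARN = 3, ERROR = 4)
  if (ranks[[level]] >= ranks[[lv %||% "INFO"]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}
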