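#' Reverse complement of DNA strings
#'
#' Vectorised over its argument. Only `A`, `C`, `G`, `T`, `N` are handled;
#' `N` complements to `N`.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAT"))
revcomp <- function(x) {
  stopifnot(is.character(x))
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' GC content of DNA strings, in percent
#'
#' @param x Character vector of DNA strings.
#' @return Numeric vector, percent G+C.
#' @export
gc_content <- function(x) {
  stopifnot(is.character(x))
  n <- nchar(x)
  gc <- nchar(gsub("[^GC]", "", x))
  100 * gc / n
}

## locale-independent stable ordering used everywhere a reproducible,
## byte-identical output depends on sort order
.ord <- function(...) order(..., method = "radix")

## single sequence (character) from a DNAStringSet element or character
.as_seq_string <- function(x) {
  if (inherits(x, "DNAString") || inherits(x, "DNAStringSet")) {
    x <- as.character(x)
  }
  stopifnot(is.character(x))
  toupper(unname(x))
}

## empty locus table with the canonical column set
.empty_loci <- function() {
  data.frame(
    seq_id = character(0), start = integer(0), end = integer(0),
    motif = character(0), canonical_motif = character(0),
    repeat_count = integer(0), tract_length = integer(0),
    length_class = character(0), composition = character(0),
    compound = logical(0), stringsAsFactors = FALSE
  )
}
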