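#' Classify a locus by annotation overlap
#'
#' Any overlap of at least 1 nt counts. Priority: CDS, then 5' UTR, then
#' 3' UTR, then intron (inside a gene/mRNA span but overlapping no CDS, UTR
#' or exon feature), then intergenic. Independent of feature-file ordering.
#'
#' @param locus One-row locus data frame (`seq_id`, `start`, `end`).
#' @param features Feature data frame from [read_gff3()].
#' @return A list of class `genomic_context`: `region` (one of `"CDS"`,
#'   `"UTR5"`, `"UTR3"`, `"INTRON"`, `"INTERGENIC"`) and `evidence`
#'   (`"annotation"` when a feature overlap decided the call, else
#'   `"none"`).
#' @export
classify_by_annotation <- function(locus, features) {
  stopifnot(nrow(locus) == 1L)
  f <- features[features$seq_id == locus$seq_id &
                  features$start <= locus$end &
                  features$end >= locus$start, , drop = FALSE]
  ctx <- function(region, evidence) {
    structure(list(region = region, evidence = evidence),
              class = "genomic_context")
  }
  if (nrow(f) == 0L) return(ctx("INTERGENIC", "none"))
  if (any(f$type == "CDS")) return(ctx("CDS", "annotation"))
  if (any(f$type == "five_prime_UTR")) return(ctx("UTR5", "annotation"))
  if (any(f$type == "three_prime_UTR")) return(ctx("UTR3", "annotation"))
  in_gene <- any(f$type %in% c("gene", "mRNA", "intron"))
  in_exon <- any(f$type == "exon")
  if (in_gene && !in_exon) return(ctx("INTRON", "annotation"))
  ## inside a gene but on an exon with no finer sub-annotation: falls
  ## through the priority list to intergenic
  ctx("INTERGENIC", "none")
}

## codon tables for the ORF scan
.STOPS <- c("TAA", "TAG", "TGA")

#' Longest open reading frame over six frames
#'
#' Scans both strands in all three frames for `ATG`-initiated reading
#' frames ending at the first in-frame stop codon (stop included in the
#' span). Only ORFs of at least `min_len` nt are reported; ties between
#' equal-length ORFs are broken in favour of the plus strand, then the
#' leftmost start.
#'
#' @param seq DNA string (character or [Biostrings::DNAString]).
#' @param min_len Minimum ORF length in nt including the stop codon
#'   (default 300).
#' @return A list `(start, end, strand, length)` in input coordinates, or
#'   `NULL` when no qualifying ORF exists.
#' @export
find_longest_orf <- function(seq, min_len = 300L) {
  s <- .as_seq_string(seq)
  n <- nchar(s)
  if (n < 30L) return(NULL)
  best <- NULL
  consider <- function(start, end, strand) {
    len <- end - start + 1L
    if (len < min_len) return()
    if (is.null(best) || len > best$length ||
        (len == best$length &&
           (strand == "+" && best$strand == "-" ||
              strand == best$strand && start < best$start))) {
      best <<- list(start = start, end = end, strand = strand, length = len)
    }
  }
  for (strand in c("+", "-")) {
    w <- if (strand == "+") s else revcomp(s)
    for (frame in 0:2) {
      starts <- seq(1L + frame, n - 2L, by = 3L)
      if (!length(starts)) next
      codons <- substring(w, starts, starts + 2L)
      is_atg <- codons == "ATG"
      is_stop <- codons %in% .STOPS
      if (!any(is_atg) || !any(is_stop)) next
      stop_idx <- which(is_stop)
      for (a in which(is_atg)) {
        nxt <- stop_idx[stop_idx > a]
        if (!length(nxt)) break_at <- NA_integer_ else break_at <- nxt[1L]
        if (is.na(break_at)) next
        ws <- starts[a]
        we <- starts[break_at] + 2L
        if (strand == "+") consider(ws, we, "+")
        else consider(n - we + 1L, n - ws + 1L, "-")
      }
    }
  }
  best
}

#' Classify a flanked locus with an ORF fallback
#'
#' With annotation, delegates to [classify_by_annotation()]. Without, the
#' template (flanks + tract) is scanned for its longest ORF: the locus is
#' called `CDS` (evidence `"orf"`) when the repeat tract lies inside that
#' ORF, `INTERGENIC` (evidence `"orf"`) when an ORF exists elsewhere on the
#' template, and `INTERGENIC` (evidence `"none"`) when no ORF is found.
#'
#' @param fl A [extract_flanks()] result.
#' @param features Optional feature data frame from [read_gff3()].
#' @param orf_min Minimum ORF length in nt for the fallback (default 300).
#' @return A `genomic_context` list as in [classify_by_annotation()].
#' @export
classify_with_fallback <- function(fl, features = NULL, orf_min = 300L) {
  stopifnot(inherits(fl, "flanked_locus"))
  if (!is.null(features)) {
    return(classify_by_annotation(fl$locus, features))
  }
  orf <- find_longest_orf(fl$template, min_len = orf_min)
  if (is.null(orf)) {
    return(structure(list(region = "INTERGENIC", evidence = "none"),
                     class = "genomic_context"))
  }
  ts <- nchar(fl$left_flank) + 1L
  te <- ts + nchar(fl$tract) - 1L
  region <- if (orf$start <= ts && orf$end >= te) "CDS" else "INTERGENIC"
  structure(list(region = region, evidence = "orf"),
            class = "genomic_context")
}

#' Tabulate genomic-context calls over a locus set
#'
#' @param loci Locus data frame.
#' @param features Optional feature data frame; when `NULL` every locus
#'   needs `genome` for the ORF fallback.
#' @param genome Genome used for flank extraction in fallback mode.
#' @param flank_size Flank length for fallback templates.
#' @param orf_min Minimum ORF length for the fallback.
#' @return Data frame of loci with added `context` and `context_evidence`
#'   columns; region counts partition the locus set.
#' @export
summarize_context <- function(loci, features = NULL, genome = NULL,
                              flank_size = 200L, orf_min = 300L) {
  ctx <- character(nrow(loci))
  ev <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    if (!is.null(features)) {
      c0 <- classify_by_annotation(loci[i, , drop = FALSE], features)
    } else {
      stopifnot(!is.null(genome))
      fl <- extract_flanks(loci[i, , drop = FALSE], genome, flank_size)
      c0 <- classify_with_fallback(fl, NULL, orf_min)
    }
    ctx[i] <- c0$region
    ev[i] <- c0$evidence
  }
  loci$context <- ctx
  loci$context_evidence <- ev
  loci
}
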