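#' Microsatellite scan configuration
#'
#' Minimum repeat counts follow the MISA-style thresholds used for
#' genome-wide SSR surveys: 12 repeats for mononucleotide motifs, 8 for di-,
#' 5 for tri- and tetra-, 4 for penta- and hexanucleotide motifs.
#'
#' @param min_repeats Integer vector of length 6: minimum repeat count for
#'   motif lengths 1..6.
#' @param max_interruption Maximum distance in nt between two simple SSRs
#'   merged into one compound SSR by [join_compound()].
#' @return An object of class `ssr_scan_config`.
#' @export
scan_config <- function(min_repeats = c(12L, 8L, 5L, 5L, 4L, 4L),
                        max_interruption = 100L) {
  min_repeats <- as.integer(min_repeats)
  stopifnot(length(min_repeats) == 6L, all(min_repeats >= 2L),
            max_interruption >= 0L)
  structure(list(min_repeats = min_repeats,
                 max_interruption = as.integer(max_interruption)),
            class = "ssr_scan_config")
}

## is a motif primitive (not the repetition of a shorter word)?
.is_primitive <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        strrep(substr(motif, 1L, d), k %/% d) == motif) return(FALSE)
  }
  TRUE
}

#' Canonical representative of a motif group
#'
#' Motifs equivalent under cyclic rotation and reverse complement (e.g.
#' `AAT`/`ATT`/`TAA`/...) are grouped for landscape statistics; the group
#' representative is the lexicographically smallest word among all cyclic
#' rotations of the motif and of its reverse complement. Idempotent.
#'
#' @param motif Character vector of primitive DNA motifs, length 1-6.
#' @return Character vector of canonical motifs.
#' @export
#' @examples
#' canonical_motif(c("TTA", "T", "GAT"))
canonical_motif <- function(motif) {
  stopifnot(is.character(motif), all(nchar(motif) >= 1L & nchar(motif) <= 6L))
  vapply(motif, function(m) {
    if (!.is_primitive(m)) stop("motif is not primitive: ", m)
    k <- nchar(m)
    rc <- revcomp(m)
    rots <- function(w) {
      vapply(seq_len(k) - 1L, function(i) {
        paste0(substr(w, i + 1L, k), substr(w, 1L, i))
      }, character(1))
    }
    min(c(rots(m), rots(rc)))
  }, character(1), USE.NAMES = FALSE)
}

#' Classify a motif by base composition
#'
#' @param motif Character vector of DNA motifs.
#' @return Character vector: `"AT_RICH"` when the A+T fraction exceeds 0.5,
#'   `"GC_RICH"` when below, `"BALANCED"` at exactly 0.5.
#' @export
classify_composition <- function(motif) {
  stopifnot(is.character(motif), all(nchar(motif) >= 1L))
  at <- nchar(gsub("[^AT]", "", motif)) / nchar(motif)
  ifelse(at > 0.5, "AT_RICH", ifelse(at < 0.5, "GC_RICH", "BALANCED"))
}

## scan one N-free window (raw bytes) for all motif lengths; offset is the
## 1-based position of the window start on the parent sequence
.scan_window <- function(bytes, offset, seq_id, cfg) {
  n <- length(bytes)
  rows <- list()
  for (k in 1:6) {
    min_rep <- cfg$min_repeats[k]
    if (n < k * min_rep) next
    eq <- bytes[seq_len(n - k)] == bytes[(k + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & (r$lengths + k) %/% k >= min_rep)
    for (h in hit) {
      s <- starts[h]
      count <- (r$lengths[h] + k) %/% k
      motif <- rawToChar(bytes[s:(s + k - 1L)])
      if (!.is_primitive(motif)) next
      tract <- count * k
      rows[[length(rows) + 1L]] <- list(
        seq_id = seq_id, start = offset + s - 1L,
        end = offset + s + tract - 2L, motif = motif,
        repeat_count = count, tract_length = tract)
    }
  }
  rows
}

#' Scan one sequence for perfect microsatellites
#'
#' Finds all maximal perfect tandem repeats of primitive motifs of length
#' 1-6 meeting the configured minimum repeat counts. A run is reported at
#' its smallest primitive motif length only (a poly-A run is mono-`A`, never
#' di-`AA`); the reported tract covers whole motif copies
#' (`tract_length == repeat_count * motif length`), starting at the leftmost
#' position, with trailing partial copies excluded. Runs of `N` split the
#' sequence into independent scanning windows, so no reported locus overlaps
#' an `N`.
#'
#' @param seq A single sequence: character string, [Biostrings::DNAString],
#'   or a length-1 [Biostrings::DNAStringSet].
#' @param cfg A [scan_config()].
#' @param seq_id Sequence id used in the output; defaults to the name of
#'   `seq` or `"seq1"`.
#' @return Locus data frame: `seq_id`, `start`, `end` (1-based inclusive),
#'   `motif`, `canonical_motif`, `repeat_count`, `tract_length`,
#'   `length_class` (`"I"` when tract > 20 nt else `"II"`), `composition`,
#'   `compound` (all `FALSE` here), sorted by position.
#' @export
scan_sequence <- function(seq, cfg = scan_config(), seq_id = NULL) {
  if (is.null(seq_id)) {
    seq_id <- if (!is.null(names(seq)) && length(names(seq))) names(seq)[1L]
              else "seq1"
  }
  s <- .as_seq_string(seq)
  stopifnot(length(s) == 1L)
  n <- nchar(s)
  if (n == 0L) return(.empty_loci())
  bytes <- charToRaw(s)
  isN <- bytes == charToRaw("N")
  rows <- list()
  if (any(isN)) {
    r <- rle(isN)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (w in which(!r$values)) {
      rows <- c(rows, .scan_window(bytes[starts[w]:ends[w]], starts[w],
                                   seq_id, cfg))
    }
  } else {
    rows <- .scan_window(bytes, 1L, seq_id, cfg)
  }
  if (!length(rows)) return(.empty_loci())
  out <- data.frame(
    seq_id = vapply(rows, `[[`, character(1), "seq_id"),
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    motif = vapply(rows, `[[`, character(1), "motif"),
    repeat_count = vapply(rows, `[[`, numeric(1), "repeat_count"),
    tract_length = vapply(rows, `[[`, numeric(1), "tract_length"),
    stringsAsFactors = FALSE
  )
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out$repeat_count <- as.integer(out$repeat_count)
  out$tract_length <- as.integer(out$tract_length)
  out$canonical_motif <- canonical_motif(out$motif)
  out$length_class <- ifelse(out$tract_length > 20L, "I", "II")
  out$composition <- classify_composition(out$motif)
  out$compound <- FALSE
  out <- out[, colnames(.empty_loci())]
  out <- out[.ord(out$seq_id, out$start, nchar(out$motif)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a whole genome for microsatellites
#'
#' @param genome A named [Biostrings::DNAStringSet] (e.g. from
#'   [read_fasta()]) or named character vector.
#' @param cfg A [scan_config()].
#' @return Locus data frame as in [scan_sequence()], over all sequences.
#' @export
scan_genome <- function(genome, cfg = scan_config()) {
  stopifnot(!is.null(names(genome)))
  parts <- lapply(names(genome), function(id) {
    scan_sequence(genome[[id]], cfg, seq_id = id)
  })
  out <- do.call(rbind, c(parts, list(.empty_loci())))
  rownames(out) <- NULL
  out
}

#' Merge nearby simple SSRs into compound loci
#'
#' Consecutive simple loci on the same sequence separated by at most
#' `cfg$max_interruption` nt are merged into one compound locus spanning
#' from the first to the last member; the member loci are carried in the
#' `members` list-column of the compound row. Isolated simple loci pass
#' through unchanged.
#'
#' @param loci Locus data frame sorted by (`seq_id`, `start`), e.g. from
#'   [scan_genome()].
#' @param cfg A [scan_config()].
#' @return Locus data frame with compound rows (`compound == TRUE`,
#'   `motif` the `-`-joined member motifs, `members` holding the member
#'   rows) replacing their members.
#' @export
join_compound <- function(loci, cfg = scan_config()) {
  if (nrow(loci) == 0L) {
    loci$members <- list()
    return(loci)
  }
  o <- .ord(loci$seq_id, loci$start)
  if (!identical(o, seq_len(nrow(loci)))) {
    stop("loci must be sorted by (seq_id, start)")
  }
  prev_end <- cummax_by_group(loci$end, loci$seq_id)
  gap <- loci$start - prev_end - 1L
  first_of_seq <- c(TRUE, loci$seq_id[-1L] != loci$seq_id[-nrow(loci)])
  new_grp <- first_of_seq | gap > cfg$max_interruption
  grp <- cumsum(new_grp)
  out <- lapply(split(seq_len(nrow(loci)), grp), function(idx) {
    sub <- loci[idx, , drop = FALSE]
    if (nrow(sub) == 1L) {
      sub$members <- list(NULL)
      return(sub)
    }
    span <- max(sub$end) - min(sub$start) + 1L
    row <- data.frame(
      seq_id = sub$seq_id[1L], start = min(sub$start), end = max(sub$end),
      motif = paste(sub$motif, collapse = "-"),
      canonical_motif = NA_character_,
      repeat_count = NA_integer_, tract_length = span,
      length_class = ifelse(span > 20L, "I", "II"),
      composition = NA_character_, compound = TRUE,
      stringsAsFactors = FALSE
    )
    row$members <- list(sub[, colnames(.empty_loci())])
    row
  })
  out <- do.call(rbind, out)
  out <- out[.ord(out$seq_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## running maximum of end coordinates within seq_id groups, lagged by one,
## used to measure the interruption between consecutive loci
cummax_by_group <- function(end, grp) {
  unlist(lapply(split(end, factor(grp, levels = unique(grp))), function(e) {
    if (length(e) == 1L) return(e)
    c(e[1L], cummax(e)[-length(e)])
  }), use.names = FALSE)
}

#' Summarize the microsatellite landscape of a genome
#'
#' @param loci Locus data frame (simple, or simple + compound after
#'   [join_compound()]).
#' @param genome The scanned genome (named [Biostrings::DNAStringSet] or
#'   character vector); its total length, including `N` runs, is the
#'   denominator for density and genome fraction.
#' @param count_compound `"single"` (default) counts each compound locus
#'   once in the total; `"members"` counts its member loci instead.
#' @return A list of class `ssr_landscape`: counts by motif length, length
#'   class, composition and canonical motif (simple loci), compound and
#'   total counts, `density_per_mbp`, `genome_fraction_pct`, and
#'   `total_assembly_length`.
#' @export
summarize_landscape <- function(loci, genome,
                                count_compound = c("single", "members")) {
  count_compound <- match.arg(count_compound)
  glen <- sum(nchar(.as_seq_string(genome)))
  ids <- names(genome)
  if (nrow(loci) && !all(loci$seq_id %in% ids)) {
    stop("locus references unknown seq_id: ",
         setdiff(loci$seq_id, ids)[1L])
  }
  simple <- loci[!loci$compound, , drop = FALSE]
  compound <- loci[loci$compound, , drop = FALSE]
  members <- if (nrow(compound)) do.call(rbind, compound$members)
             else .empty_loci()
  all_simple <- rbind(simple[, colnames(.empty_loci())],
                      members[, colnames(.empty_loci())])
  k <- nchar(all_simple$motif)
  by_len <- vapply(1:6, function(i) sum(k == i), numeric(1))
  names(by_len) <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  n_total <- nrow(simple) +
    if (count_compound == "single") nrow(compound) else nrow(members)
  tract_nt <- sum(all_simple$tract_length)
  structure(list(
    by_motif_length = by_len,
    by_length_class = c(I = sum(all_simple$length_class == "I"),
                        II = sum(all_simple$length_class == "II")),
    by_composition = c(
      AT_RICH = sum(all_simple$composition == "AT_RICH"),
      GC_RICH = sum(all_simple$composition == "GC_RICH"),
      BALANCED = sum(all_simple$composition == "BALANCED")),
    by_canonical_motif = sort(table(all_simple$canonical_motif),
                              decreasing = TRUE),
    n_simple = nrow(all_simple), n_compound = nrow(compound),
    n_total = n_total,
    density_per_mbp = if (glen > 0) 1e6 * n_total / glen else 0,
    genome_fraction_pct = if (glen > 0) 100 * tract_nt / glen else 0,
    total_assembly_length = glen,
    count_compound = count_compound
  ), class = "ssr_landscape")
}

#' @export
print.ssr_landscape <- function(x, ...) {
  cat("SSR landscape: ", x$n_total, " loci (", x$n_simple, " simple, ",
      x$n_compound, " compound) in ", x$total_assembly_length, " nt\n",
      "density ", format(x$density_per_mbp, digits = 4), " per Mbp; ",
      format(x$genome_fraction_pct, digits = 3), "% of the assembly\n",
      sep = "")
  invisible(x)
}
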