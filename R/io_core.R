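#' Read a multi-record genome FASTA file
#'
#' Sequences are uppercased on read. Only the alphabet `A`, `C`, `G`, `T`,
#' `N` is accepted; any other character is a hard error reporting the
#' offending record and position. Record ids are the first whitespace-
#' delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by sequence id, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA file '", path,
                                           "': ", conditionMessage(e)))
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id in ", path, ": ", dup[1L])
  seqs <- toupper(as.character(raw))
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid character '%s' at position %d of sequence '%s'",
                 substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

## feature types retained from GFF3
.GFF_TYPES <- c("gene", "mRNA", "CDS", "five_prime_UTR", "three_prime_UTR",
                "exon", "intron")

#' Read gene features from a GFF3 file
#'
#' Retains only the feature types used for genomic-context classification
#' (`gene`, `mRNA`, `CDS`, `five_prime_UTR`, `three_prime_UTR`, `exon`,
#' `intron`); other types are skipped and counted, not an error.
#' Coordinates stay 1-based inclusive as in GFF3.
#'
#' @param path Path to a GFF3 file.
#' @return A data frame with columns `seq_id`, `type`, `start`, `end`,
#'   `strand`; the number of skipped features is attached as attribute
#'   `"skipped"`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  keep <- type %in% .GFF_TYPES
  skipped <- sum(!keep)
  if (skipped > 0L) {
    message(skipped, " GFF3 feature(s) of unhandled types skipped")
  }
  gr <- gr[keep]
  out <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  attr(out, "skipped") <- skipped
  out
}

#' Read a diploid genotype table
#'
#' Expects a tab-separated file whose header row names the markers and whose
#' first column holds individual ids. A cell is `"a/b"` (two allele sizes in
#' bp), `"a"` (homozygote shorthand for `a/a`), or the missing-data code.
#'
#' @param path Path to a genotype TSV.
#' @param missing Missing-data code, default `"-"`.
#' @return An object of class `genotype_table`: a list with `individuals`,
#'   `loci`, and integer allele matrices `a1`, `a2` (individual x locus,
#'   `NA` for missing). Within each call `a1 <= a2`.
#' @export
read_genotypes <- function(path, missing = "-") {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L) {
    stop("ragged genotype table: rows have differing field counts (",
         paste(unique(nf), collapse = ", "), ")")
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("genotype table needs an id column and >=1 locus")
  individuals <- tab[[1L]]
  loci <- colnames(tab)[-1L]
  n <- length(individuals)
  L <- length(loci)
  a1 <- a2 <- matrix(NA_integer_, n, L, dimnames = list(individuals, loci))
  for (j in seq_len(L)) {
    cells <- tab[[j + 1L]]
    for (i in seq_len(n)) {
      cell <- trimws(cells[i])
      if (cell == missing || cell == "") next
      parts <- strsplit(cell, "/", fixed = TRUE)[[1L]]
      if (length(parts) == 1L) parts <- c(parts, parts)
      if (length(parts) != 2L || !all(grepl("^[0-9]+$", parts))) {
        stop(sprintf(
          "invalid genotype cell '%s' (individual '%s', locus '%s')",
          cell, individuals[i], loci[j]))
      }
      al <- sort(as.integer(parts))
      a1[i, j] <- al[1L]
      a2[i, j] <- al[2L]
    }
  }
  structure(list(individuals = individuals, loci = loci, a1 = a1, a2 = a2,
                 missing = missing),
            class = "genotype_table")
}

#' Write a genotype table
#'
#' Inverse of [read_genotypes()]: homozygotes are written `"a/a"`, missing
#' calls as the table's missing code.
#'
#' @param gt A `genotype_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  cells <- matrix(gt$missing, length(gt$individuals), length(gt$loci))
  ok <- !is.na(gt$a1)
  cells[ok] <- paste0(gt$a1[ok], "/", gt$a2[ok])
  out <- cbind(individual = gt$individuals, as.data.frame(cells))
  colnames(out) <- c("individual", gt$loci)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table: ", length(x$individuals), " individuals x ",
      length(x$loci), " loci (", sum(is.na(x$a1)), " missing calls)\n",
      sep = "")
  invisible(x)
}
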