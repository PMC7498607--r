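## motif-length labels for the EMM table
.SSR_TYPE <- c("mono", "di", "tri", "tetra", "penta", "hexa")

#' Build marker records for one genome
#'
#' Scans (or takes) loci, extracts flanks, designs up to three ranked
#' primer pairs per locus and assigns genomic context. Loci for which no
#' primer pair satisfies the constraints count as primer-modelling
#' failures. Marker ids follow the scheme `EMM-<genome>-<serial>` with
#' serials assigned in (seq_id, start) order over successful loci, so runs
#' on identical input are reproducible.
#'
#' @param genome Named [Biostrings::DNAStringSet] or character vector.
#' @param genome_name Short genome/landrace name used in marker ids.
#' @param loci Optional locus data frame; defaults to
#'   `join_compound(scan_genome(genome, scan_cfg), scan_cfg)`.
#' @param scan_cfg A [scan_config()].
#' @param design_cfg A [design_config()].
#' @param flank_size Flank length for design templates, nt.
#' @param features Optional GFF3 feature data frame for context
#'   annotation; without it the longest-ORF fallback is used.
#' @param orf_min Minimum ORF length for the fallback.
#' @return A list of class `marker_set`: `markers` (data frame, one row per
#'   successful locus, with primer/Tm/product columns for ranks 1-3, flank
#'   sequences, genome coordinates of the rank-1 primer footprints, and
#'   context), `n_loci`, `n_success`, `success_rate_pct`.
#' @export
build_markers <- function(genome, genome_name, loci = NULL,
                          scan_cfg = scan_config(),
                          design_cfg = design_config(), flank_size = 200L,
                          features = NULL, orf_min = 300L) {
  if (is.null(loci)) {
    loci <- join_compound(scan_genome(genome, scan_cfg), scan_cfg)
  }
  loci <- loci[.ord(loci$seq_id, loci$start), , drop = FALSE]
  rows <- list()
  serial <- 0L
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, , drop = FALSE]
    fl <- extract_flanks(locus, genome, flank_size)
    pp <- design_for_locus(fl, design_cfg)
    if (nrow(pp) == 0L) next
    serial <- serial + 1L
    ctx <- if (!is.null(features)) classify_by_annotation(locus, features)
           else classify_with_fallback(fl, NULL, orf_min)
    g0 <- fl$template_start - 1L
    slot <- function(col, r, fill) if (r <= nrow(pp)) pp[[col]][r] else fill
    row <- data.frame(
      marker_id = sprintf("EMM-%s-%05d", genome_name, serial),
      source_genome = genome_name,
      seq_id = locus$seq_id, start_1based = locus$start,
      end_1based = locus$end,
      ssr_type = if (isTRUE(locus$compound)) "compound"
                 else .SSR_TYPE[nchar(locus$motif)],
      motif = locus$motif,
      canonical_motif = ifelse(is.na(locus$canonical_motif), "",
                               locus$canonical_motif),
      class = locus$length_class,
      composition = ifelse(is.na(locus$composition), "",
                           locus$composition),
      context = ctx$region,
      stringsAsFactors = FALSE
    )
    for (r in 1:3) {
      row[[paste0("forward_", r)]] <- slot("forward", r, "")
      row[[paste0("reverse_", r)]] <- slot("reverse", r, "")
      tmf <- slot("tm_f", r, NA_real_)
      tmr <- slot("tm_r", r, NA_real_)
      ## pair annealing temperature: the limiting (lower) primer Tm
      row[[paste0("tm_", r)]] <- if (is.na(tmf)) NA_real_
                                 else round(min(tmf, tmr), 2)
      row[[paste0("product_size_", r)]] <- slot("product_size", r,
                                                NA_integer_)
    }
    row$expected_size <- pp$product_size[1L]
    row$penalty_1 <- round(pp$penalty[1L], 4)
    row$f1_gstart <- g0 + pp$f_start[1L]
    row$f1_gend <- g0 + pp$f_end[1L]
    row$r1_gstart <- g0 + pp$r_start[1L]
    row$r1_gend <- g0 + pp$r_end[1L]
    row$left_flank <- fl$left_flank
    row$right_flank <- fl$right_flank
    rows[[serial]] <- row
  }
  markers <- if (length(rows)) do.call(rbind, rows) else NULL
  structure(list(markers = markers, n_loci = nrow(loci), n_success = serial,
                 success_rate_pct = if (nrow(loci) > 0)
                   100 * serial / nrow(loci) else NA_real_,
                 genome_name = genome_name),
            class = "marker_set")
}

#' Remove redundant and non-specific markers
#'
#' Two removal rules, applied in order: (i) markers sharing an identical
#' (forward, reverse) rank-1 primer-sequence pair collapse to the first by
#' locus coordinate; (ii) markers whose rank-1 pair produces more than one
#' amplicon in their own source genome (duplicated regions) are removed.
#'
#' @param markers Marker data frame from [build_markers()] (single genome).
#' @param genome The source genome.
#' @param cfg An [epcr_config()].
#' @param rules Subset of `c("duplicate", "multihit")` to apply.
#' @return A list: `kept` (data frame), `removed_pct`,
#'   `n_removed_duplicate`, `n_removed_multihit`.
#' @export
filter_redundant <- function(markers, genome, cfg = epcr_config(),
                             rules = c("duplicate", "multihit")) {
  n0 <- nrow(markers)
  m <- markers[.ord(markers$seq_id, markers$start_1based), , drop = FALSE]
  n_dup <- 0L
  if ("duplicate" %in% rules) {
    key <- paste(m$forward_1, m$reverse_1)
    dup <- duplicated(key)
    n_dup <- sum(dup)
    m <- m[!dup, , drop = FALSE]
  }
  n_multi <- 0L
  if ("multihit" %in% rules && nrow(m)) {
    multi <- vapply(seq_len(nrow(m)), function(i) {
      nrow(amplify(list(forward = m$forward_1[i], reverse = m$reverse_1[i]),
                   genome, cfg)) > 1L
    }, logical(1))
    n_multi <- sum(multi)
    m <- m[!multi, , drop = FALSE]
  }
  m <- m[.ord(m$marker_id), , drop = FALSE]
  rownames(m) <- NULL
  list(kept = m, removed_pct = if (n0 > 0) 100 * (n_dup + n_multi) / n0
       else 0, n_removed_duplicate = n_dup, n_removed_multihit = n_multi)
}

#' Cluster markers across genomes to a non-redundant set
#'
#' Markers from different genomes with identical (forward, reverse) rank-1
#' primer sequences collapse to one record (the one with the smallest
#' marker id) that retains all source genomes; also reports Venn-style
#' membership counts per genome subset.
#'
#' @param per_genome_markers Named list of marker data frames (one per
#'   genome, each already internally de-duplicated).
#' @return A list: `markers` (non-redundant data frame, sorted by
#'   `marker_id`, with a `source_genomes` semicolon-list column) and `venn`
#'   (named integer vector, subset label -> marker count).
#' @export
cluster_across_genomes <- function(per_genome_markers) {
  all_m <- do.call(rbind, unname(per_genome_markers))
  if (is.null(all_m) || nrow(all_m) == 0L) {
    return(list(markers = all_m, venn = integer(0)))
  }
  key <- paste(all_m$forward_1, all_m$reverse_1)
  grp <- split(seq_len(nrow(all_m)), key)
  rows <- lapply(grp, function(idx) {
    sub <- all_m[idx, , drop = FALSE]
    rep_row <- sub[.ord(sub$marker_id)[1L], , drop = FALSE]
    rep_row$source_genomes <- paste(sort(unique(sub$source_genome),
                                         method = "radix"), collapse = ";")
    rep_row
  })
  out <- do.call(rbind, rows)
  out <- out[.ord(out$marker_id), , drop = FALSE]
  rownames(out) <- NULL
  venn <- table(out$source_genomes)
  venn <- setNames(as.integer(venn), names(venn))
  list(markers = out, venn = venn[.ord(names(venn))])
}

#' Call cross-taxa transferability and length polymorphism
#'
#' A marker is present in a taxon when the e-PCR matrix holds at least one
#' amplicon there; it is polymorphic when some pair of observed amplicon
#' lengths (the source marker's expected product size included) differs by
#' at least 6 bp.
#'
#' @param mat An [epcr_matrix()] result.
#' @param expected_sizes Named numeric vector: marker id -> expected
#'   product size in the source genome, bp.
#' @param polymorphism_min_bp Polymorphism call threshold, bp (default 6).
#' @return Data frame: `marker_id`, `n_taxa`, `taxa_present` (semicolon
#'   list), `size_min`, `size_max`, `polymorphic`.
#' @export
call_transfer_polymorphism <- function(mat, expected_sizes,
                                       polymorphism_min_bp = 6L) {
  stopifnot(inherits(mat, "epcr_matrix"))
  rows <- lapply(mat$markers, function(id) {
    h <- mat$hits[mat$hits$marker_id == id, , drop = FALSE]
    taxa <- sort(unique(h$taxon), method = "radix")
    sizes <- h$length
    if (!is.na(expected_sizes[id])) sizes <- c(sizes, expected_sizes[[id]])
    data.frame(
      marker_id = id, n_taxa = length(taxa),
      taxa_present = paste(taxa, collapse = ";"),
      size_min = if (length(sizes)) min(sizes) else NA_integer_,
      size_max = if (length(sizes)) max(sizes) else NA_integer_,
      polymorphic = length(sizes) > 0L &&
        max(sizes) - min(sizes) >= polymorphism_min_bp,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Markers transferable to every member of a clade
#'
#' @param calls Output of [call_transfer_polymorphism()].
#' @param clade Character vector of taxon names.
#' @return Logical vector along `calls`: present in every clade member.
#' @export
transferable_to_clade <- function(calls, clade) {
  vapply(strsplit(calls$taxa_present, ";", fixed = TRUE), function(tx) {
    all(clade %in% tx)
  }, logical(1))
}

#' Per-chromosome counts of transferable markers
#'
#' Each marker with exactly one amplicon in the target taxon is assigned to
#' that amplicon's chromosome; markers with several amplicons are flagged
#' unplaced and excluded from the counts.
#'
#' @param mat An [epcr_matrix()] result.
#' @param taxon Target taxon name (a chromosome-level assembly).
#' @return A list: `counts` (named integer vector per chromosome),
#'   `n_placed`, `n_unplaced`, `mean`, `sd` (across chromosomes with >= 1
#'   marker).
#' @export
comparative_map <- function(mat, taxon) {
  stopifnot(inherits(mat, "epcr_matrix"), taxon %in% mat$taxa)
  h <- mat$hits[mat$hits$taxon == taxon, , drop = FALSE]
  per <- table(h$marker_id)
  placed <- names(per)[per == 1L]
  unplaced <- names(per)[per > 1L]
  hp <- h[h$marker_id %in% placed, , drop = FALSE]
  counts <- table(hp$seq_id)
  counts <- setNames(as.integer(counts), names(counts))
  counts <- counts[.ord(names(counts))]
  list(counts = counts, n_placed = length(placed),
       n_unplaced = length(unplaced),
       mean = if (length(counts)) mean(counts) else NA_real_,
       sd = if (length(counts) > 1L) stats::sd(counts) else NA_real_)
}

## the exported flat-table column order
.EMM_COLS <- c("marker_id", "source_genome", "seq_id", "start_1based",
               "end_1based", "ssr_type", "motif", "canonical_motif",
               "class", "composition", "context",
               "forward_1", "forward_2", "forward_3",
               "reverse_1", "reverse_2", "reverse_3",
               "tm_1", "tm_2", "tm_3",
               "product_size_1", "product_size_2", "product_size_3",
               "transferable_taxa", "polymorphic",
               "left_flank", "right_flank")

#' Export the marker table
#'
#' Writes the final marker table in a fixed column order (see Details) as
#' TSV or CSV; the export is byte-deterministic for identical input.
#'
#' @details Columns: `marker_id`, `source_genome`, `seq_id`,
#'   `start_1based`, `end_1based`, `ssr_type`, `motif`, `canonical_motif`,
#'   `class`, `composition`, `context`, `forward_1..3`, `reverse_1..3`,
#'   `tm_1..3`, `product_size_1..3`, `transferable_taxa` (semicolon list),
#'   `polymorphic`, `left_flank`, `right_flank`.
#'
#' @param markers Final marker data frame (from [run_pipeline()], or
#'   [build_markers()] output merged with transferability calls).
#' @param path Output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_emm <- function(markers, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (!"transferable_taxa" %in% colnames(markers)) {
    markers$transferable_taxa <- ""
  }
  if (!"polymorphic" %in% colnames(markers)) markers$polymorphic <- NA
  miss <- setdiff(.EMM_COLS, colnames(markers))
  if (length(miss)) stop("marker table lacks columns: ",
                         paste(miss, collapse = ", "))
  out <- markers[.ord(markers$marker_id), .EMM_COLS, drop = FALSE]
  for (col in c("tm_1", "tm_2", "tm_3")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", sprintf("%.2f", out[[col]]))
  }
  out$polymorphic <- ifelse(is.na(out$polymorphic), "",
                            ifelse(out$polymorphic, "true", "false"))
  ok <- tryCatch({
    utils::write.table(out, path, sep = if (format == "tsv") "\t" else ",",
                       quote = FALSE, row.names = FALSE, eol = "\n")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write marker table: ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read back an exported marker table
#'
#' @param path Path written by [export_emm()].
#' @param format `"tsv"` or `"csv"`.
#' @return Data frame in the export column order.
#' @export
read_emm <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  out <- utils::read.table(path, header = TRUE,
                           sep = if (format == "tsv") "\t" else ",",
                           colClasses = "character", check.names = FALSE,
                           quote = "")
  for (col in c("start_1based", "end_1based", "product_size_1",
                "product_size_2", "product_size_3")) {
    out[[col]] <- suppressWarnings(as.integer(out[[col]]))
  }
  for (col in c("tm_1", "tm_2", "tm_3")) {
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }
  out$polymorphic <- ifelse(out$polymorphic == "", NA,
                            out$polymorphic == "true")
  out
}

#' Filter a marker table by the standard search fields
#'
#' @param markers Marker data frame (EMM-style).
#' @param ssr_type,ssr_class,composition,context Optional exact filters.
#' @param polymorphic Optional logical filter.
#' @param transferable_to Optional taxon name that must appear in
#'   `transferable_taxa`.
#' @param marker_id Optional id (or vector of ids).
#' @param motif Optional canonical motif.
#' @return The filtered data frame.
#' @export
query_emm <- function(markers, ssr_type = NULL, ssr_class = NULL,
                      composition = NULL, context = NULL,
                      polymorphic = NULL, transferable_to = NULL,
                      marker_id = NULL, motif = NULL) {
  keep <- rep(TRUE, nrow(markers))
  if (!is.null(ssr_type)) keep <- keep & markers$ssr_type %in% ssr_type
  if (!is.null(ssr_class)) keep <- keep & markers$class %in% ssr_class
  if (!is.null(composition)) keep <- keep & markers$composition %in%
      composition
  if (!is.null(context)) keep <- keep & markers$context %in% context
  if (!is.null(polymorphic)) keep <- keep &
      !is.na(markers$polymorphic) & markers$polymorphic == polymorphic
  if (!is.null(transferable_to)) {
    keep <- keep & vapply(strsplit(markers$transferable_taxa, ";",
                                   fixed = TRUE),
                          function(tx) transferable_to %in% tx, logical(1))
  }
  if (!is.null(marker_id)) keep <- keep & markers$marker_id %in% marker_id
  if (!is.null(motif)) keep <- keep & markers$canonical_motif %in% motif
  markers[keep, , drop = FALSE]
}

#' Run the full marker-development pipeline
#'
#' For every genome: scan for SSRs, merge compounds, design primers, and
#' remove redundant/non-specific markers; then cluster the per-genome sets
#' to one non-redundant panel, run in silico PCR of that panel against all
#' target genomes, and call transferability and length polymorphism. The
#' pipeline uses no random numbers: two runs on identical inputs give
#' byte-identical exported tables.
#'
#' @param genomes Named list of source genomes (named
#'   [Biostrings::DNAStringSet] or character vectors, or FASTA paths).
#' @param extra_taxa Optional named list of additional target genomes
#'   (e.g. related species) included in the e-PCR matrix but not mined for
#'   markers.
#' @param scan_cfg,design_cfg,epcr_cfg Configuration objects.
#' @param flank_size Flank length for design templates.
#' @param features Optional named list of GFF3 feature data frames per
#'   genome.
#' @return A list of class `ssr_pipeline`: `per_genome` (scan/design/
#'   redundancy statistics and kept markers), `markers` (final
#'   non-redundant table with `transferable_taxa` and `polymorphic`
#'   columns), `matrix` (the [epcr_matrix()]), `calls`, `venn`, `summary`
#'   (named numeric vector of headline statistics).
#' @export
run_pipeline <- function(genomes, extra_taxa = NULL,
                         scan_cfg = scan_config(),
                         design_cfg = design_config(),
                         epcr_cfg = epcr_config(), flank_size = 200L,
                         features = NULL) {
  stopifnot(!is.null(names(genomes)))
  genomes <- lapply(genomes, function(g) {
    if (is.character(g) && length(g) == 1L && file.exists(g)) read_fasta(g)
    else g
  })
  gnames <- sort(names(genomes), method = "radix")
  per_genome <- list()
  kept_list <- list()
  for (gn in gnames) {
    ms <- build_markers(genomes[[gn]], gn, scan_cfg = scan_cfg,
                        design_cfg = design_cfg, flank_size = flank_size,
                        features = features[[gn]])
    fr <- if (!is.null(ms$markers)) {
      filter_redundant(ms$markers, genomes[[gn]], epcr_cfg)
    } else {
      list(kept = NULL, removed_pct = 0, n_removed_duplicate = 0L,
           n_removed_multihit = 0L)
    }
    per_genome[[gn]] <- list(
      n_loci = ms$n_loci, n_success = ms$n_success,
      success_rate_pct = ms$success_rate_pct,
      removed_pct = fr$removed_pct,
      n_removed_duplicate = fr$n_removed_duplicate,
      n_removed_multihit = fr$n_removed_multihit,
      markers = fr$kept
    )
    kept_list[[gn]] <- fr$kept
  }
  cl <- cluster_across_genomes(kept_list)
  markers <- cl$markers
  targets <- c(genomes, extra_taxa)
  mat <- epcr_matrix(markers, targets, epcr_cfg)
  expected <- setNames(markers$expected_size, markers$marker_id)
  calls <- call_transfer_polymorphism(mat, expected)
  mi <- match(markers$marker_id, calls$marker_id)
  markers$polymorphic <- calls$polymorphic[mi]
  markers$transferable_taxa <- vapply(seq_along(mi), function(z) {
    tx <- strsplit(calls$taxa_present[mi[z]], ";", fixed = TRUE)[[1L]]
    paste(setdiff(tx, markers$source_genome[z]), collapse = ";")
  }, character(1))
  n_nr <- nrow(markers)
  shared <- sum(vapply(strsplit(markers$source_genomes, ";", fixed = TRUE),
                       length, integer(1)) >= 2L)
  all_src <- transferable_to_clade(calls, gnames)[mi]
  summary <- c(
    n_loci_total = sum(vapply(per_genome, `[[`, numeric(1), "n_loci")),
    n_markers_designed = sum(vapply(per_genome, `[[`, numeric(1),
                                    "n_success")),
    success_rate_pct = 100 *
      sum(vapply(per_genome, `[[`, numeric(1), "n_success")) /
      max(1, sum(vapply(per_genome, `[[`, numeric(1), "n_loci"))),
    redundant_pct = 100 * (1 - n_nr /
                             max(1, sum(vapply(per_genome, function(x) {
                               x$n_success
                             }, numeric(1))))),
    n_nonredundant = n_nr,
    shared_across_genomes_pct = if (n_nr > 0) 100 * shared / n_nr else 0,
    transferable_all_sources_pct = if (n_nr > 0) 100 * sum(all_src) / n_nr
                                   else 0,
    polymorphic_pct = if (n_nr > 0) 100 * mean(markers$polymorphic) else 0
  )
  structure(list(per_genome = per_genome, markers = markers, matrix = mat,
                 calls = calls, venn = cl$venn, summary = summary),
            class = "ssr_pipeline")
}

#' @export
print.ssr_pipeline <- function(x, ...) {
  cat("ssr_pipeline: ", length(x$per_genome), " genomes, ",
      nrow(x$markers), " non-redundant markers\n", sep = "")
  print(round(x$summary, 2))
  invisible(x)
}
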