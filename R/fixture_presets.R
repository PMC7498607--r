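## a 220 nt cassette flank guaranteed free of threshold-passing repeats and
## guarded at its junction with the repeat tract
.make_cassette_flank <- function(motif, side, cfg, len = 220L) {
  repeat {
    f <- .random_dna(len)
    if (nrow(scan_sequence(f, cfg)) > 0L) next
    k <- nchar(motif)
    if (side == "left") {
      mlast <- substr(motif, k, k)
      if (substr(f, len, len) == mlast) {
        substr(f, len, len) <- setdiff(c("A", "C", "G", "T"), mlast)[1L]
      }
    } else {
      mfirst <- substr(motif, 1L, 1L)
      if (substr(f, 1L, 1L) == mfirst) {
        substr(f, 1L, 1L) <- setdiff(c("A", "C", "G", "T"), mfirst)[1L]
      }
    }
    if (nrow(scan_sequence(f, cfg)) == 0L) return(f)
  }
}

#' The four-landraces synthetic study fixture
#'
#' A seeded, fully manifest-predicted miniature of a four-landrace marker
#' study: a base genome (`landrace_A`, two contigs) with 15 planted SSRs
#' covering all motif lengths, both length classes and all composition
#' classes, including one duplicated primer cassette (a redundancy/
#' non-specificity case); three derived landraces with tract expansions or
#' contractions (amplicon-length polymorphism at and below the 6 bp call
#' threshold) and primer-footprint substitutions (2 substitutions: still
#' amplifiable; 4: transfer lost); a chromosome-level `relative` genome
#' carrying two conserved marker cassettes with shifted tract lengths; a
#' GFF3-style feature table putting planted loci into CDS, intron and
#' 5' UTR context; and a two-population genotype panel simulated under
#' Hardy-Weinberg with strongly divergent allele frequencies at 8 of 15
#' loci.
#'
#' @param seed RNG seed controlling every random choice.
#' @return A list: `genomes` (named list of four landrace genomes),
#'   `relative` (3-chromosome genome), `features` (feature data frame for
#'   `landrace_A`), `genotypes` (list `gt`, `groups`, `freqs`), `manifest`
#'   (plants table, per-landrace edit lists and expected transfer/
#'   polymorphism behaviour of the edited markers), `base_markers` (the
#'   marker set designed on the base genome, used to position footprint
#'   edits).
#' @export
four_landrace_fixture <- function(seed = 42L) {
  cfg <- scan_config()
  set.seed(seed)
  spec <- data.frame(
    contig = c(rep(1L, 10L), rep(2L, 5L)),
    pos = c(300L + 1100L * 0:9, 300L + 1100L * 0:4),
    motif = c("AG", "AT", "AAT", "A", "ACG", "ACAT", "AACCT", "AACGTC",
              "AC", "AG", "AG", "CCG", "AT", "AAG", "AT"),
    repeats = c(12L, 9L, 8L, 14L, 7L, 6L, 5L, 4L, 10L, 12L,
                8L, 6L, 12L, 7L, 8L),
    stringsAsFactors = FALSE
  )
  cassette <- rep(TRUE, nrow(spec))
  cassette[14L] <- FALSE               # one plain plant, background flanks
  lf <- rf <- rep(NA_character_, nrow(spec))
  for (i in seq_len(nrow(spec))) {
    if (!cassette[i]) next
    if (i == 10L) {                    # verbatim duplicate of plant 1
      lf[i] <- lf[1L]
      rf[i] <- rf[1L]
      next
    }
    lf[i] <- .make_cassette_flank(spec$motif[i], "left", cfg)
    rf[i] <- .make_cassette_flank(spec$motif[i], "right", cfg)
  }
  spec$left_flank <- lf
  spec$right_flank <- rf
  base <- make_genome(contig_len = c(12000L, 8000L), plants = spec,
                      seed = seed + 10L, cfg = cfg)
  plants <- base$manifest$plants
  ## markers on the base genome locate the rank-1 primer footprints
  ms <- build_markers(base$genome, "landrace_A", scan_cfg = cfg)
  mk <- ms$markers
  plant_marker <- match(
    paste(base$manifest$contigs[plants$contig], plants$tract_start),
    paste(mk$seq_id, mk$start_1based))
  marker_of <- function(p) {
    if (is.na(plant_marker[p])) NULL else mk[plant_marker[p], , drop = FALSE]
  }
  fwd_subs <- function(p, k) {
    m <- marker_of(p)
    if (is.null(m)) return(NULL)
    ## substitutions sit in the 5' half of the forward footprint, clear of
    ## the exact 3' seed word
    data.frame(seq_id = m$seq_id,
               pos = m$f1_gstart + c(1L, 3L, 5L, 7L)[seq_len(k)],
               stringsAsFactors = FALSE)
  }
  edits <- list(
    landrace_B = list(
      tract = data.frame(plant = c(2L, 3L), delta_units = c(3L, 1L)),
      subs = fwd_subs(11L, 2L)
    ),
    landrace_C = list(
      tract = data.frame(plant = c(13L, 9L), delta_units = c(2L, -3L)),
      subs = fwd_subs(5L, 4L)
    ),
    landrace_D = list()
  )
  vars <- make_landraces(base$genome, base$manifest, edits)
  genomes <- c(list(landrace_A = base$genome), vars$genomes)
  ## relative: chromosome-level target carrying two conserved cassettes
  ## with shifted tract lengths (+2 tri units = +6 bp; +3 di units = +6 bp)
  rel_plants <- data.frame(
    contig = c(1L, 2L),
    pos = c(600L, 600L),
    motif = plants$motif[c(3L, 13L)],
    repeats = plants$repeats[c(3L, 13L)] + c(2L, 3L),
    left_flank = plants$left_flank[c(3L, 13L)],
    right_flank = plants$right_flank[c(3L, 13L)],
    stringsAsFactors = FALSE
  )
  rel <- make_genome(contig_len = c(2600L, 2600L, 2600L),
                     plants = rel_plants, seed = seed + 11L, cfg = cfg)
  relative <- rel$genome
  names(relative) <- c("chr1", "chr2", "chr3")
  ## feature table on landrace_A: plant 1 in CDS, plant 2 intronic,
  ## plant 4 in a 5' UTR
  t1 <- c(plants$tract_start[1L], plants$tract_end[1L])
  t2 <- c(plants$tract_start[2L], plants$tract_end[2L])
  t4 <- c(plants$tract_start[4L], plants$tract_end[4L])
  features <- data.frame(
    seq_id = "c1",
    type = c("gene", "mRNA", "exon", "CDS",
             "gene", "mRNA", "exon", "CDS",
             "gene", "five_prime_UTR"),
    start = c(t1[1L] - 100L, t1[1L] - 100L, t1[1L] - 50L, t1[1L] - 50L,
              t2[1L] - 300L, t2[1L] - 300L, t2[1L] - 300L, t2[1L] - 290L,
              t4[1L] - 50L, t4[1L] - 20L),
    end = c(t1[2L] + 100L, t1[2L] + 100L, t1[2L] + 50L, t1[2L] + 50L,
            t2[2L] + 300L, t2[2L] - 120L, t2[2L] - 150L, t2[2L] - 150L,
            t4[2L] + 200L, t4[2L] + 30L),
    strand = "+",
    stringsAsFactors = FALSE
  )
  ## two-population genotype panel: loci L01-L08 strongly divergent
  loci <- sprintf("L%02d", 1:15)
  freq_one <- function(alleles, p) setNames(p, alleles)
  freqs <- list(cultivated = list(), wild = list())
  for (j in 1:15) {
    if (j <= 8L) {
      freqs$cultivated[[loci[j]]] <- freq_one(c(200L, 204L) + 2L * j,
                                              c(0.5, 0.5))
      freqs$wild[[loci[j]]] <- freq_one(c(240L, 244L) + 2L * j, c(0.5, 0.5))
    } else {
      shared <- freq_one(c(180L, 184L, 188L) + 2L * j, c(0.3, 0.5, 0.2))
      freqs$cultivated[[loci[j]]] <- shared
      freqs$wild[[loci[j]]] <- shared
    }
  }
  gen <- make_genotypes(freqs, n_per_group = c(cultivated = 10L, wild = 8L),
                        seed = seed + 2L)
  manifest <- list(
    plants = plants, edits = edits,
    plant_marker = setNames(
      ifelse(is.na(plant_marker), NA_character_,
             mk$marker_id[plant_marker]),
      paste0("plant_", seq_len(nrow(plants)))),
    expected = list(
      ## marker of plant 11: 2 footprint substitutions in landrace_B,
      ## still amplifiable there; tract unchanged
      still_transferable = list(marker = mk$marker_id[plant_marker[11L]],
                                taxon = "landrace_B"),
      ## marker of plant 5: 4 footprint substitutions in landrace_C
      lost_transfer = list(marker = mk$marker_id[plant_marker[5L]],
                           taxon = "landrace_C"),
      ## tract edits: +-6 bp is polymorphic, +3/+4 bp is not
      polymorphic = c(mk$marker_id[plant_marker[2L]],
                      mk$marker_id[plant_marker[9L]]),
      not_polymorphic_small_shift = c(mk$marker_id[plant_marker[3L]],
                                      mk$marker_id[plant_marker[13L]])
    )
  )
  list(genomes = genomes, relative = relative, features = features,
       genotypes = c(gen, list(freqs = freqs)), manifest = manifest,
       base_markers = ms)
}
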