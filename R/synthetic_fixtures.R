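## random background sequence, uniform over ACGT
.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic genome with planted microsatellites
#'
#' Background sequence is i.i.d. uniform ACGT; each plant (a repeat tract,
#' optionally wrapped in fixed cassette flanks) is written verbatim over the
#' background at its position. Guard bases adjacent to each tract are forced
#' to break the repeat so the scanner reports exactly the planted
#' coordinates. The assembled genome is verified against the manifest with
#' [scan_genome()] and the background resampled (deterministically, from
#' the seeded RNG stream) until no spontaneous threshold-passing repeat
#' survives, so the manifest predicts the scanner output exactly.
#'
#' @param contig_len Integer vector of contig lengths (contigs are named
#'   `c1`, `c2`, ...).
#' @param plants Data frame: `contig` (index), `pos` (1-based block start),
#'   `motif`, `repeats`, and optional `left_flank`/`right_flank` cassette
#'   sequences (`NA` for plain plants).
#' @param seed RNG seed; the same seed always yields identical bytes.
#' @param cfg [scan_config()] used for verification.
#' @param margin Minimum clear distance in nt between plant blocks and from
#'   contig ends (default 250).
#' @return A list: `genome` (named [Biostrings::DNAStringSet]) and
#'   `manifest` (list with the augmented `plants` table: tract coordinates
#'   `tract_start`/`tract_end`, block span, and `detected` flags).
#' @export
make_genome <- function(contig_len, plants = NULL, seed = 1L,
                        cfg = scan_config(), margin = 250L) {
  set.seed(seed)
  n_contigs <- length(contig_len)
  ids <- paste0("c", seq_len(n_contigs))
  if (is.null(plants)) {
    plants <- data.frame(contig = integer(0), pos = integer(0),
                         motif = character(0), repeats = integer(0))
  }
  if (is.null(plants$left_flank)) {
    plants$left_flank <- rep(NA_character_, nrow(plants))
  }
  if (is.null(plants$right_flank)) {
    plants$right_flank <- rep(NA_character_, nrow(plants))
  }
  lf <- ifelse(is.na(plants$left_flank), "", plants$left_flank)
  rf <- ifelse(is.na(plants$right_flank), "", plants$right_flank)
  tract <- strrep(plants$motif, plants$repeats)
  block <- paste0(lf, tract, rf)
  plants$block_start <- plants$pos
  plants$block_end <- plants$pos + nchar(block) - 1L
  plants$tract_start <- plants$pos + nchar(lf)
  plants$tract_end <- plants$tract_start + nchar(tract) - 1L
  k <- nchar(plants$motif)
  plants$detected <- plants$repeats >= cfg$min_repeats[k]
  ## feasibility: margins to contig ends and between blocks
  for (ci in seq_len(n_contigs)) {
    p <- plants[plants$contig == ci, , drop = FALSE]
    if (!nrow(p)) next
    p <- p[order(p$pos), , drop = FALSE]
    if (p$block_start[1L] <= margin ||
        p$block_end[nrow(p)] > contig_len[ci] - margin ||
        (nrow(p) > 1L &&
           any(p$block_start[-1L] - p$block_end[-nrow(p)] - 1L < margin))) {
      stop("infeasible packing: plants need a ", margin,
           " nt clear margin on contig c", ci)
    }
  }
  expected <- plants[plants$detected, , drop = FALSE]
  expected <- data.frame(seq_id = ids[expected$contig],
                         start = expected$tract_start,
                         end = expected$tract_end,
                         motif = expected$motif,
                         repeat_count = expected$repeats,
                         stringsAsFactors = FALSE)
  expected <- expected[.ord(expected$seq_id, expected$start), , drop = FALSE]
  rownames(expected) <- NULL
  for (attempt in seq_len(50L)) {
    seqs <- vapply(seq_len(n_contigs), function(ci) {
      s <- .random_dna(contig_len[ci])
      p <- which(plants$contig == ci)
      for (z in p) {
        substr(s, plants$block_start[z], plants$block_end[z]) <- block[z]
        ## guard bases so the tract cannot extend into the neighbourhood
        kk <- k[z]
        mfirst <- substr(plants$motif[z], 1L, 1L)
        mlast <- substr(plants$motif[z], kk, kk)
        gl <- plants$tract_start[z] - 1L
        if (gl >= 1L && substr(s, gl, gl) == mlast) {
          substr(s, gl, gl) <- setdiff(c("A", "C", "G", "T"), mlast)[1L]
        }
        gr <- plants$tract_end[z] + 1L
        if (gr <= contig_len[ci] && substr(s, gr, gr) == mfirst) {
          substr(s, gr, gr) <- setdiff(c("A", "C", "G", "T"), mfirst)[1L]
        }
      }
      s
    }, character(1))
    names(seqs) <- ids
    genome <- Biostrings::DNAStringSet(seqs)
    got <- scan_genome(genome, cfg)
    got <- got[, c("seq_id", "start", "end", "motif", "repeat_count")]
    rownames(got) <- NULL
    if (identical(got, expected)) {
      return(list(genome = genome,
                  manifest = list(plants = plants, contig_len = contig_len,
                                  seed = seed, contigs = ids)))
    }
  }
  stop("could not build a clean background in 50 attempts; ",
       "a cassette flank may itself contain a threshold-passing repeat")
}

#' Derive variant genomes from a base genome
#'
#' Applies per-variant edits to the base genome: tract-length edits
#' (`delta_units` whole repeat units added to or removed from a planted
#' tract, changing the expected amplicon size by exactly
#' `delta_units * motif length` bp) and single-base substitutions (e.g.
#' inside a designed primer footprint; the replacement base is the
#' deterministic transversion A<->C, G<->T unless given).
#'
#' @param base Named [Biostrings::DNAStringSet] from [make_genome()].
#' @param manifest Manifest from [make_genome()].
#' @param edits Named list (one element per variant). Each element is a
#'   list with optional `tract` (data frame `plant` (row index in the
#'   manifest plants table), `delta_units`) and `subs` (data frame
#'   `seq_id`, `pos`, optional `base`), positions in base-genome
#'   coordinates. Substitutions must fall within 250 nt of a planted tract.
#' @return A list: `genomes` (named list of variant genomes) and
#'   `manifests` (per-variant plants tables with updated coordinates and
#'   repeat counts).
#' @export
make_landraces <- function(base, manifest, edits) {
  stopifnot(!is.null(names(edits)))
  plants <- manifest$plants
  ids <- manifest$contigs
  out_g <- list()
  out_m <- list()
  for (vn in names(edits)) {
    ed <- edits[[vn]]
    tr <- ed$tract
    if (is.null(tr)) tr <- data.frame(plant = integer(0),
                                      delta_units = integer(0))
    if (any(tr$plant < 1L | tr$plant > nrow(plants))) {
      stop("tract edit references an unknown plant")
    }
    subs <- ed$subs
    if (is.null(subs)) subs <- data.frame(seq_id = character(0),
                                          pos = integer(0))
    near <- vapply(seq_len(nrow(subs)), function(z) {
      any(ids[plants$contig] == subs$seq_id[z] &
            subs$pos[z] >= plants$tract_start - 250L &
            subs$pos[z] <= plants$tract_end + 250L)
    }, logical(1))
    if (!all(near)) stop("substitution edit outside any plant: ",
                         subs$seq_id[!near][1L], ":", subs$pos[!near][1L])
    seqs <- as.character(base)
    vp <- plants
    vp$repeats_new <- vp$repeats
    for (ci in seq_along(ids)) {
      s <- seqs[[ids[ci]]]
      ## substitutions first (do not shift coordinates)
      on_c <- which(subs$seq_id == ids[ci])
      for (z in on_c) {
        old <- substr(s, subs$pos[z], subs$pos[z])
        newb <- if (!is.null(subs$base) && !is.na(subs$base[z])) subs$base[z]
                else chartr("ACGT", "CATG", old)
        substr(s, subs$pos[z], subs$pos[z]) <- newb
      }
      ## tract edits right-to-left so earlier coordinates stay valid
      te <- tr[plants$contig[tr$plant] == ci, , drop = FALSE]
      te <- te[order(-plants$tract_start[te$plant]), , drop = FALSE]
      for (z in seq_len(nrow(te))) {
        pz <- te$plant[z]
        newr <- plants$repeats[pz] + te$delta_units[z]
        stopifnot(newr >= 1L)
        s <- paste0(substr(s, 1L, plants$tract_start[pz] - 1L),
                    strrep(plants$motif[pz], newr),
                    substr(s, plants$tract_end[pz] + 1L, nchar(s)))
        vp$repeats_new[pz] <- newr
      }
      seqs[[ids[ci]]] <- s
    }
    ## updated coordinates: cumulative shift of preceding tract edits
    vp$tract_start_new <- vp$tract_start
    vp$tract_end_new <- vp$tract_end
    for (ci in seq_along(ids)) {
      on_c <- which(vp$contig == ci)
      on_c <- on_c[order(vp$tract_start[on_c])]
      shift <- 0L
      for (pz in on_c) {
        vp$tract_start_new[pz] <- vp$tract_start[pz] + shift
        delta <- (vp$repeats_new[pz] - vp$repeats[pz]) * nchar(vp$motif[pz])
        shift <- shift + delta
        vp$tract_end_new[pz] <- vp$tract_end[pz] + shift
      }
    }
    out_g[[vn]] <- Biostrings::DNAStringSet(seqs)
    out_m[[vn]] <- vp
  }
  list(genomes = out_g, manifests = out_m)
}

#' Simulate diploid genotypes under Hardy-Weinberg equilibrium
#'
#' Draws two alleles independently from the group's allele-frequency vector
#' at every locus, for every individual.
#'
#' @param freqs Named list: group -> named list: locus -> named numeric
#'   vector of allele frequencies (names are allele sizes in bp; each
#'   vector sums to 1). All groups must share the same locus set.
#' @param n_per_group Named integer vector (or single integer recycled):
#'   individuals per group.
#' @param seed RNG seed.
#' @return A list: `gt` (a `genotype_table`) and `groups` (named character
#'   vector individual -> group).
#' @export
make_genotypes <- function(freqs, n_per_group, seed = 1L) {
  set.seed(seed)
  gs <- names(freqs)
  stopifnot(!is.null(gs))
  loci <- names(freqs[[1L]])
  for (g in gs) {
    stopifnot(identical(names(freqs[[g]]), loci))
    for (l in loci) {
      stopifnot(abs(sum(freqs[[g]][[l]]) - 1) < 1e-9)
    }
  }
  if (length(n_per_group) == 1L) {
    n_per_group <- setNames(rep(n_per_group, length(gs)), gs)
  }
  inds <- unlist(lapply(gs, function(g) {
    paste0(g, "_", seq_len(n_per_group[[g]]))
  }))
  groups <- setNames(rep(gs, times = n_per_group[gs]), inds)
  a1 <- a2 <- matrix(NA_integer_, length(inds), length(loci),
                     dimnames = list(inds, loci))
  for (j in seq_along(loci)) {
    for (i in seq_along(inds)) {
      p <- freqs[[groups[inds[i]]]][[loci[j]]]
      al <- sort(as.integer(sample(names(p), 2L, replace = TRUE, prob = p)))
      a1[i, j] <- al[1L]
      a2[i, j] <- al[2L]
    }
  }
  gt <- structure(list(individuals = inds, loci = loci, a1 = a1, a2 = a2,
                       missing = "-"),
                  class = "genotype_table")
  list(gt = gt, groups = groups)
}
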