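#' In silico PCR configuration
#'
#' Mismatch and gap budgets are per primer (not summed over the pair), in
#' the style of electronic-PCR tools; the defaults permit 3 mismatches and
#' 3 gaps. The primer's 3'-terminal base must match the target exactly.
#'
#' @param max_mismatches Maximum mismatches per primer site.
#' @param max_gaps Maximum gap (indel) columns per primer site.
#' @param min_product,max_product Product size bounds, bp.
#' @param seed_word Length of the exact 3'-terminal word a binding site
#'   must match perfectly (the word semantics of electronic-PCR tools);
#'   mismatches and gaps are permitted only 5' of this word. `1` relaxes
#'   the requirement to the terminal base alone. Must not exceed the
#'   primer length.
#' @return An object of class `epcr_config`.
#' @export
epcr_config <- function(max_mismatches = 3L, max_gaps = 3L,
                        min_product = 50L, max_product = 2000L,
                        seed_word = 7L) {
  stopifnot(max_mismatches >= 0L, max_gaps >= 0L,
            min_product <= max_product, seed_word >= 1L)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 max_gaps = as.integer(max_gaps),
                 min_product = as.integer(min_product),
                 max_product = as.integer(max_product),
                 seed_word = as.integer(seed_word)),
            class = "epcr_config")
}

## Semi-global site search of primer p against the plus strand of target
## t, seed-and-verify: the 3'-terminal seed word (cfg$seed_word bases)
## must match the target exactly, so candidate end positions are the
## (overlap-aware) exact occurrences of the seed; each candidate is then
## verified by a layered banded dynamic program aligning the primer's 5'
## core to the window directly upstream, where layer g holds the minimum
## number of mismatches over alignments using at most g gap columns. The
## seed requirement makes the candidate set complete, so no site within
## the budgets is lost. A column against N counts as a mismatch. Per end
## position the reported site is the alignment minimizing
## mismatches + gaps (ties to fewer gaps); gap-placement ties resolve to
## the alignment preferring base-to-base columns.
.scan_primer_plus <- function(p, t, cfg) {
  m <- nchar(p)
  n <- nchar(t)
  w <- min(cfg$seed_word, m)
  empty <- data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0), gaps = integer(0))
  if (n < m - cfg$max_gaps || m < 2L) return(empty)
  G <- cfg$max_gaps
  MM <- cfg$max_mismatches
  tb_all <- strsplit(t, "", fixed = TRUE)[[1L]]
  seed <- strsplit(substr(p, m - w + 1L, m), "", fixed = TRUE)[[1L]]
  ## overlap-aware exact seed occurrences: anchor[j] is TRUE when the seed
  ## ends at target position j
  anchor <- rep(TRUE, n)
  for (z in seq_len(w)) {
    anchor <- anchor & c(rep(FALSE, w - z),
                         (tb_all == seed[z])[seq_len(n - w + z)])
  }
  ends <- which(anchor)
  if (!length(ends)) return(empty)
  core <- substr(p, 1L, m - w)
  cl <- nchar(core)
  if (cl == 0L) {
    return(data.frame(start = ends - w + 1L, end = ends,
                      mismatches = 0L, gaps = 0L))
  }
  pb <- strsplit(core, "", fixed = TRUE)[[1L]]
  INF <- 1e6
  out_s <- out_e <- out_mm <- out_g <- integer(0)
  for (j in ends) {
    lo <- max(0L, j - w - cl - G)    # window = target positions lo+1..j-w
    L <- (j - w) - lo
    if (L <= 0L) {
      if (cl > G) next               # no room for the core at all
      L <- 0L
    }
    tb <- if (L > 0L) tb_all[(lo + 1L):(j - w)] else character(0)
    ## vectors indexed u+1 for window prefix u = 0..L; the core must end
    ## exactly at u = L (just before the seed)
    prevM <- rep(list(rep(0, L + 1L)), G + 1L)
    prevS <- rep(list(as.numeric(lo + seq_len(L + 1L))), G + 1L)
    for (i in seq_len(cl)) {
      costi <- if (L > 0L) as.numeric(tb != pb[i] | tb == "N") else numeric(0)
      curM <- vector("list", G + 1L)
      curS <- vector("list", G + 1L)
      for (gi in seq_len(G + 1L)) {
        best <- c(INF, if (L > 0L) prevM[[gi]][1:L] + costi)
        bestS <- c(INF, if (L > 0L) prevS[[gi]][1:L])
        if (gi > 1L) {
          del <- prevM[[gi - 1L]]
          upd <- del < best
          best[upd] <- del[upd]
          bestS[upd] <- prevS[[gi - 1L]][upd]
          ins <- c(INF, if (L > 0L) curM[[gi - 1L]][1:L])
          insS <- c(INF, if (L > 0L) curS[[gi - 1L]][1:L])
          upd <- ins < best
          best[upd] <- ins[upd]
          bestS[upd] <- insS[upd]
        }
        curM[[gi]] <- best
        curS[[gi]] <- bestS
      }
      prevM <- curM
      prevS <- curS
    }
    bestT <- INF
    bmm <- INF
    bg <- NA_integer_
    bs <- NA_real_
    seen <- INF
    for (gi in seq_len(G + 1L)) {
      vg <- prevM[[gi]][L + 1L]
      if (vg >= seen) next           # gi-1 is the true gap count here
      seen <- vg
      if (vg + (gi - 1L) < bestT) {
        bestT <- vg + (gi - 1L)
        bmm <- vg
        bg <- gi - 1L
        bs <- prevS[[gi]][L + 1L]
      }
    }
    if (bmm <= MM && is.finite(bs) && bs <= j) {
      out_s <- c(out_s, as.integer(bs))
      out_e <- c(out_e, j)
      out_mm <- c(out_mm, as.integer(bmm))
      out_g <- c(out_g, bg)
    }
  }
  if (!length(out_e)) return(empty)
  data.frame(start = out_s, end = out_e, mismatches = out_mm, gaps = out_g)
}

## suppress shadow sites: a single physical binding site aligns at several
## neighbouring end positions once gaps are allowed; among sites of one
## primer on one strand with overlapping footprints only the best
## (fewest mismatches + gaps, ties to fewer gaps, then leftmost) is kept
.suppress_overlaps <- function(sites) {
  if (nrow(sites) <= 1L) return(sites)
  o <- .ord(sites$mismatches + sites$gaps, sites$gaps, sites$start)
  sites <- sites[o, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(sites))) {
    if (!length(kept) ||
        !any(sites$start[i] <= sites$end[kept] &
               sites$end[i] >= sites$start[kept])) {
      kept <- c(kept, i)
    }
  }
  sites[kept, , drop = FALSE]
}

#' Find primer binding sites in a genome
#'
#' Reports every site, on either strand, where the primer aligns
#' semi-globally (primer fully aligned, target local) within the
#' per-primer mismatch and gap budgets and with an exactly matching
#' 3'-terminal base. For each candidate end position the best alignment
#' (fewest mismatches + gap columns within the gap budget, ties to fewer
#' gaps) defines the site's mismatch and gap counts, and among overlapping
#' alignments of one physical site only the best is reported.
#'
#' @param primer Primer sequence, 5' to 3'.
#' @param genome Named [Biostrings::DNAStringSet] or character vector.
#' @param cfg An [epcr_config()].
#' @return Data frame: `seq_id`, `strand` (`"+"`/`"-"`), `start`, `end`
#'   (1-based inclusive on the plus strand), `mismatches`, `gaps`.
#' @export
find_binding_sites <- function(primer, genome, cfg = epcr_config()) {
  stopifnot(is.character(primer), length(primer) == 1L,
            nchar(primer) >= cfg$seed_word)
  out <- lapply(names(genome), function(id) {
    t <- .as_seq_string(genome[[id]])
    n <- nchar(t)
    plus <- .suppress_overlaps(.scan_primer_plus(primer, t, cfg))
    minus <- .suppress_overlaps(.scan_primer_plus(primer, revcomp(t), cfg))
    parts <- list()
    if (nrow(plus)) {
      parts$p <- data.frame(seq_id = id, strand = "+", start = plus$start,
                            end = plus$end, mismatches = plus$mismatches,
                            gaps = plus$gaps, stringsAsFactors = FALSE)
    }
    if (nrow(minus)) {
      parts$m <- data.frame(seq_id = id, strand = "-",
                            start = n - minus$end + 1L,
                            end = n - minus$start + 1L,
                            mismatches = minus$mismatches,
                            gaps = minus$gaps, stringsAsFactors = FALSE)
    }
    do.call(rbind, parts)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(seq_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0), gaps = integer(0)))
  }
  out <- out[.ord(out$seq_id, out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict PCR amplicons for a primer pair
#'
#' Enumerates all convergent forward/reverse binding-site combinations on
#' one sequence within the product-size bounds. Amplicon length is the
#' 5'-to-5' span, inclusive, so a perfect self-amplification reproduces the
#' designed product size exactly.
#'
#' @param pair One-row data frame with `forward` and `reverse` primer
#'   sequences (e.g. from [design_for_locus()]), or a list with those
#'   elements.
#' @param genome Named [Biostrings::DNAStringSet] or character vector.
#' @param cfg An [epcr_config()].
#' @return Data frame sorted by position: `seq_id`, `start`, `end`,
#'   `length`, `orientation` (`"FR"`: forward on plus strand; `"RF"`: the
#'   symmetric orientation), `mm_f`, `gaps_f`, `mm_r`, `gaps_r`.
#' @export
amplify <- function(pair, genome, cfg = epcr_config()) {
  fwd <- pair$forward[1L]
  rev_ <- pair$reverse[1L]
  stopifnot(is.character(fwd), is.character(rev_))
  sf <- find_binding_sites(fwd, genome, cfg)
  sr <- find_binding_sites(rev_, genome, cfg)
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      orientation = character(0), mm_f = integer(0),
                      gaps_f = integer(0), mm_r = integer(0),
                      gaps_r = integer(0), stringsAsFactors = FALSE)
  combine <- function(f, r, orient) {
    if (nrow(f) == 0L || nrow(r) == 0L) return(empty)
    fi <- rep(seq_len(nrow(f)), times = nrow(r))
    ri <- rep(seq_len(nrow(r)), each = nrow(f))
    same <- f$seq_id[fi] == r$seq_id[ri]
    if (orient == "FR") {
      len <- r$end[ri] - f$start[fi] + 1L
      a_start <- f$start[fi]
      a_end <- r$end[ri]
    } else {
      len <- f$end[fi] - r$start[ri] + 1L
      a_start <- r$start[ri]
      a_end <- f$end[fi]
    }
    ok <- same & len >= max(cfg$min_product, nchar(fwd), nchar(rev_)) &
      len <= cfg$max_product
    if (!any(ok)) return(empty)
    data.frame(seq_id = f$seq_id[fi[ok]], start = a_start[ok],
               end = a_end[ok], length = len[ok], orientation = orient,
               mm_f = f$mismatches[fi[ok]], gaps_f = f$gaps[fi[ok]],
               mm_r = r$mismatches[ri[ok]], gaps_r = r$gaps[ri[ok]],
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    combine(sf[sf$strand == "+", , drop = FALSE],
            sr[sr$strand == "-", , drop = FALSE], "FR"),
    combine(sf[sf$strand == "-", , drop = FALSE],
            sr[sr$strand == "+", , drop = FALSE], "RF")
  )
  if (nrow(out) == 0L) return(empty)
  key <- paste(out$seq_id, out$start, out$end, out$orientation)
  out <- out[.ord(key, out$mm_f + out$gaps_f + out$mm_r + out$gaps_r), ,
             drop = FALSE]
  out <- out[!duplicated(key[.ord(key, out$mm_f + out$gaps_f + out$mm_r +
                                    out$gaps_r)]), , drop = FALSE]
  out <- out[.ord(out$seq_id, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' In silico PCR of a marker panel across taxa
#'
#' Runs [amplify()] for every (marker, taxon) combination, using each
#' marker's rank-1 primer pair. The result is a complete matrix in long
#' form; (marker, taxon) cells without an amplicon are simply absent from
#' `hits` but present in the `markers`/`taxa` grid. Iteration order is
#' deterministic: markers sorted by id, taxa by name.
#'
#' @param markers Marker data frame with columns `marker_id`, `forward_1`,
#'   `reverse_1` (e.g. from [build_markers()]).
#' @param genomes Named list of genomes (each a named
#'   [Biostrings::DNAStringSet]/character vector, or a FASTA path).
#' @param cfg An [epcr_config()].
#' @return An object of class `epcr_matrix`: list with `hits` (long data
#'   frame: `marker_id`, `taxon`, amplicon columns), `markers`, `taxa`.
#' @export
epcr_matrix <- function(markers, genomes, cfg = epcr_config()) {
  stopifnot(!is.null(names(genomes)))
  taxa <- sort(names(genomes), method = "radix")
  ids <- sort(markers$marker_id, method = "radix")
  mk <- markers[match(ids, markers$marker_id), , drop = FALSE]
  rows <- list()
  for (taxon in taxa) {
    g <- genomes[[taxon]]
    if (is.character(g) && length(g) == 1L && file.exists(g)) {
      g <- tryCatch(read_fasta(g),
                    error = function(e) stop("cannot read genome for taxon '",
                                             taxon, "': ",
                                             conditionMessage(e)))
    }
    if (is.null(names(g))) stop("unreadable genome for taxon: ", taxon)
    for (i in seq_len(nrow(mk))) {
      amp <- amplify(list(forward = mk$forward_1[i],
                          reverse = mk$reverse_1[i]), g, cfg)
      if (nrow(amp)) {
        rows[[length(rows) + 1L]] <-
          cbind(marker_id = mk$marker_id[i], taxon = taxon, amp,
                stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker_id = character(0), taxon = character(0),
               seq_id = character(0), start = integer(0), end = integer(0),
               length = integer(0), orientation = character(0),
               mm_f = integer(0), gaps_f = integer(0), mm_r = integer(0),
               gaps_r = integer(0), stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  structure(list(hits = hits, markers = ids, taxa = taxa),
            class = "epcr_matrix")
}

#' @export
print.epcr_matrix <- function(x, ...) {
  cat("epcr_matrix: ", length(x$markers), " markers x ", length(x$taxa),
      " taxa; ", nrow(x$hits), " amplicons\n", sep = "")
  invisible(x)
}
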