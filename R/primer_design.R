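## Nearest-neighbor duplex parameters (unified set, Allawi & SantaLucia
## 1997): dH in kcal/mol, dS in cal/(mol K), keyed by the top-strand
## dinucleotide; reverse-complement pairs share parameters.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
## duplex initiation per terminal base pair
.NN_INIT_DH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
.NN_INIT_DS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)
.GAS_R <- 1.987        # cal/(mol K)

#' Nearest-neighbor melting temperature of primers
#'
#' Two-state nearest-neighbor model with the unified duplex parameter set
#' and duplex initiation terms, salt-corrected by the entropic term
#' `0.368 (N-1) ln[Na+]`, at fixed standard conditions: 50 mM monovalent
#' salt and 50 nM total oligonucleotide (so the concentration term is
#' `CT/4`; primers are treated as non-self-complementary duplexes).
#' Deterministic; vectorised.
#'
#' @param primer Character vector of primer sequences, length >= 8, no `N`.
#' @param Na Monovalent cation concentration, mol/L.
#' @param ct Total oligonucleotide concentration, mol/L.
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @export
melting_temperature <- function(primer, Na = 0.05, ct = 5e-8) {
  stopifnot(is.character(primer))
  if (any(nchar(primer) < 8L)) stop("primer shorter than 8 nt")
  if (any(grepl("[^ACGT]", primer))) {
    stop("primer contains a non-ACGT character (N not allowed): ",
         primer[grepl("[^ACGT]", primer)][1L])
  }
  vapply(primer, function(p) {
    n <- nchar(p)
    dn <- substring(p, seq_len(n - 1L), 2:n)
    first <- substr(p, 1L, 1L)
    last <- substr(p, n, n)
    dh <- sum(.NN_DH[dn]) + .NN_INIT_DH[first] + .NN_INIT_DH[last]
    ds <- sum(.NN_DS[dn]) + .NN_INIT_DS[first] + .NN_INIT_DS[last]
    ds <- ds + 0.368 * (n - 1L) * log(Na)
    1000 * dh / (ds + .GAS_R * log(ct / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Primer design configuration
#'
#' Reproducible, documented stand-in for a Primer3-style parameter set:
#' primer length 18-27 nt (optimum 20), GC 40-60%, Tm 57-63 C (optimum 60),
#' pair Tm difference at most 3 C, product size 100-300 bp, at most 4
#' identical consecutive bases, and at most 3 self-complementary bases at
#' the 3' end.
#'
#' @param len_min,len_opt,len_max Primer length bounds, nt.
#' @param gc_min,gc_max GC bounds, percent.
#' @param tm_min,tm_opt,tm_max Melting-temperature bounds, Celsius.
#' @param max_tm_diff Maximum |Tm forward - Tm reverse| for a pair, Celsius.
#' @param product_min,product_max Product size bounds, bp.
#' @param max_homopolymer Longest allowed single-base run in a primer.
#' @param max_3prime_self_complement Longest allowed 3'-terminal stretch
#'   whose reverse complement occurs within the primer itself.
#' @return An object of class `primer_design_config`.
#' @export
design_config <- function(len_min = 18L, len_opt = 20L, len_max = 27L,
                          gc_min = 40, gc_max = 60,
                          tm_min = 57, tm_opt = 60, tm_max = 63,
                          max_tm_diff = 3,
                          product_min = 100L, product_max = 300L,
                          max_homopolymer = 4L,
                          max_3prime_self_complement = 3L) {
  stopifnot(len_min <= len_opt, len_opt <= len_max,
            gc_min <= gc_max, tm_min <= tm_opt, tm_opt <= tm_max,
            product_min <= product_max)
  structure(as.list(environment()), class = "primer_design_config")
}

#' Extract microsatellite flanking sequence
#'
#' Pulls up to `flank_size` nt either side of a locus. Flanks are truncated
#' at the sequence boundary and at the nearest run of `N` (an `N` never
#' enters a flank used for design); truncation is flagged.
#'
#' @param locus One-row locus data frame (from [scan_genome()]).
#' @param genome Named [Biostrings::DNAStringSet] or character vector.
#' @param flank_size Maximum flank length, nt (default 200).
#' @return An object of class `flanked_locus`: the locus row, `left_flank`,
#'   `right_flank`, `tract`, `template` (left + tract + right),
#'   `template_start` (genome coordinate of the template's first base), and
#'   truncation flags.
#' @export
extract_flanks <- function(locus, genome, flank_size = 200L) {
  stopifnot(nrow(locus) == 1L)
  if (!locus$seq_id %in% names(genome)) {
    stop("unknown seq_id: ", locus$seq_id)
  }
  s <- .as_seq_string(genome[[locus$seq_id]])
  n <- nchar(s)
  stopifnot(locus$start >= 1L, locus$end <= n)
  ls <- max(1L, locus$start - flank_size)
  left <- if (locus$start > 1L) substr(s, ls, locus$start - 1L) else ""
  ## stop the flank at the nearest N run
  nrun <- gregexpr("N", left, fixed = TRUE)[[1L]]
  if (nrun[1L] > 0L) {
    cut <- max(nrun)
    ls <- ls + cut
    left <- substr(left, cut + 1L, nchar(left))
  }
  re <- min(n, locus$end + flank_size)
  right <- if (locus$end < n) substr(s, locus$end + 1L, re) else ""
  nrun <- gregexpr("N", right, fixed = TRUE)[[1L]]
  if (nrun[1L] > 0L) {
    right <- substr(right, 1L, min(nrun) - 1L)
  }
  tract <- substr(s, locus$start, locus$end)
  structure(list(
    locus = locus, left_flank = left, right_flank = right, tract = tract,
    template = paste0(left, tract, right),
    template_start = locus$start - nchar(left),
    left_truncated = nchar(left) < flank_size,
    right_truncated = nchar(right) < flank_size
  ), class = "flanked_locus")
}

## longest 3'-terminal stretch whose reverse complement occurs elsewhere in
## the primer (a simple, auditable 3' self-complementarity measure)
.self_complement_3prime <- function(p) {
  n <- nchar(p)
  k <- 0L
  while (k < n) {
    suf <- substr(p, n - k, n)
    if (!grepl(revcomp(suf), p, fixed = TRUE)) break
    k <- k + 1L
  }
  k
}

#' Score a single primer candidate
#'
#' Hard rejection outside the length, GC and Tm bounds, for homopolymer runs
#' longer than allowed, or excessive 3' self-complementarity; otherwise a
#' deterministic penalty
#' `|len - len_opt| + |Tm - Tm_opt| + 0.5 |GC - 50|`.
#'
#' @param p Primer sequence (single string).
#' @param cfg A [design_config()].
#' @return A list: `accepted`, `reason` (`NA` when accepted), `tm`, `gc`,
#'   `penalty`.
#' @export
score_primer <- function(p, cfg = design_config()) {
  n <- nchar(p)
  res <- function(ok, reason = NA_character_, tm = NA_real_, gc = NA_real_,
                  penalty = NA_real_) {
    list(accepted = ok, reason = reason, tm = tm, gc = gc, penalty = penalty)
  }
  if (n < cfg$len_min || n > cfg$len_max) return(res(FALSE, "length"))
  if (grepl("N", p, fixed = TRUE)) return(res(FALSE, "ambiguous_base"))
  gc <- gc_content(p)
  if (gc < cfg$gc_min || gc > cfg$gc_max) return(res(FALSE, "gc"))
  if (grepl(sprintf("([ACGT])\\1{%d}", cfg$max_homopolymer), p, perl = TRUE)) {
    return(res(FALSE, "homopolymer"))
  }
  tm <- melting_temperature(p)
  if (tm < cfg$tm_min || tm > cfg$tm_max) return(res(FALSE, "tm"))
  if (.self_complement_3prime(p) > cfg$max_3prime_self_complement) {
    return(res(FALSE, "self_complement_3prime"))
  }
  pen <- abs(n - cfg$len_opt) + abs(tm - cfg$tm_opt) + 0.5 * abs(gc - 50)
  res(TRUE, tm = tm, gc = gc, penalty = pen)
}

## enumerate all accepted primer candidates that are substrings of `s`
## (already oriented 5'->3'); returns start/end positions on `s`.
## Thermodynamic and GC sums are computed once per flank via cumulative
## sums, so enumeration is linear in flank length per candidate length.
.enumerate_candidates <- function(s, cfg) {
  n <- nchar(s)
  empty <- data.frame(start = integer(0), end = integer(0), len = integer(0),
                      seq = character(0), tm = numeric(0), gc = numeric(0),
                      penalty = numeric(0))
  if (n < cfg$len_min || grepl("N", s, fixed = TRUE)) return(empty)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  dn <- paste0(chars[-n], chars[-1L])
  dh_cum <- c(0, cumsum(.NN_DH[dn]))
  ds_cum <- c(0, cumsum(.NN_DS[dn]))
  gc_cum <- c(0L, cumsum(chars %in% c("G", "C")))
  ## homopolymer runs too long for any primer
  r <- rle(chars)
  rend <- cumsum(r$lengths)
  rstart <- rend - r$lengths + 1L
  long_runs <- which(r$lengths > cfg$max_homopolymer)
  out <- vector("list", cfg$len_max - cfg$len_min + 1L)
  for (len in cfg$len_min:cfg$len_max) {
    if (len > n) break
    st <- seq_len(n - len + 1L)
    en <- st + len - 1L
    gc <- 100 * (gc_cum[en + 1L] - gc_cum[st]) / len
    dh <- dh_cum[en] - dh_cum[st] +
      .NN_INIT_DH[chars[st]] + .NN_INIT_DH[chars[en]]
    ds <- ds_cum[en] - ds_cum[st] +
      .NN_INIT_DS[chars[st]] + .NN_INIT_DS[chars[en]] +
      0.368 * (len - 1L) * log(0.05)
    tm <- 1000 * dh / (ds + .GAS_R * log(5e-8 / 4)) - 273.15
    ok <- gc >= cfg$gc_min & gc <= cfg$gc_max &
      tm >= cfg$tm_min & tm <= cfg$tm_max
    for (h in long_runs) {
      ## candidate contains a run longer than allowed iff the overlap of
      ## the run with the candidate window exceeds max_homopolymer
      ov <- pmin(en, rend[h]) - pmax(st, rstart[h]) + 1L
      ok <- ok & ov <= cfg$max_homopolymer
    }
    if (!any(ok)) next
    out[[len - cfg$len_min + 1L]] <- data.frame(
      start = st[ok], end = en[ok], len = len,
      seq = substring(s, st[ok], en[ok]), tm = tm[ok], gc = gc[ok],
      penalty = abs(len - cfg$len_opt) + abs(tm[ok] - cfg$tm_opt) +
        0.5 * abs(gc[ok] - 50)
    )
  }
  out <- do.call(rbind, c(out, list(empty)))
  if (nrow(out) == 0L) return(out)
  keep <- vapply(out$seq, function(p) {
    .self_complement_3prime(p) <= cfg$max_3prime_self_complement
  }, logical(1), USE.NAMES = FALSE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Design ranked primer pairs for a flanked locus
#'
#' Forward candidates are substrings of the left flank, reverse candidates
#' reverse complements of substrings of the right flank, so every pair spans
#' the full repeat tract. Pairs must satisfy the product size range and the
#' pair Tm-difference bound. Pairs are ranked by the sum of the two primer
#' penalties, ties broken by smaller product size and then leftmost forward
#' start; at most `max_pairs` are returned. An empty result means primer
#' modelling failed for the locus.
#'
#' @param fl A [extract_flanks()] result.
#' @param cfg A [design_config()].
#' @param max_pairs Maximum number of ranked pairs (default 3).
#' @return Data frame, one row per pair: `rank`, `forward`, `reverse`,
#'   `tm_f`, `tm_r`, `gc_f`, `gc_r`, `product_size`, `penalty`, plus
#'   template coordinates `f_start`, `f_end`, `r_start`, `r_end` (the
#'   reverse primer binds the minus strand over `r_start..r_end`).
#' @export
design_for_locus <- function(fl, cfg = design_config(), max_pairs = 3L) {
  stopifnot(inherits(fl, "flanked_locus"))
  empty <- data.frame(
    rank = integer(0), forward = character(0), reverse = character(0),
    tm_f = numeric(0), tm_r = numeric(0), gc_f = numeric(0),
    gc_r = numeric(0), product_size = integer(0), penalty = numeric(0),
    f_start = integer(0), f_end = integer(0), r_start = integer(0),
    r_end = integer(0), stringsAsFactors = FALSE)
  a <- nchar(fl$left_flank)
  tl <- nchar(fl$tract)
  b <- nchar(fl$right_flank)
  fwd <- .enumerate_candidates(fl$left_flank, cfg)
  rev_ <- .enumerate_candidates(revcomp(fl$right_flank), cfg)
  if (nrow(fwd) == 0L || nrow(rev_) == 0L) return(empty)
  ## candidate coordinates on the template: forward candidates already are;
  ## a reverse candidate [i, j] on revcomp(right) binds template positions
  ## a + tl + (b - j + 1) .. a + tl + (b - i + 1) on the minus strand
  rev_$t_start <- a + tl + (b - rev_$end + 1L)
  rev_$t_end <- a + tl + (b - rev_$start + 1L)
  ## keep sides tractable while staying deterministic
  cap <- 250L
  fwd <- fwd[.ord(fwd$penalty, fwd$start, fwd$len), , drop = FALSE]
  rev_ <- rev_[.ord(rev_$penalty, rev_$t_start, rev_$len), , drop = FALSE]
  if (nrow(fwd) > cap) fwd <- fwd[seq_len(cap), , drop = FALSE]
  if (nrow(rev_) > cap) rev_ <- rev_[seq_len(cap), , drop = FALSE]
  nf <- nrow(fwd)
  nr <- nrow(rev_)
  fi <- rep(seq_len(nf), times = nr)
  ri <- rep(seq_len(nr), each = nf)
  product <- rev_$t_end[ri] - fwd$start[fi] + 1L
  ok <- product >= cfg$product_min & product <= cfg$product_max &
    abs(fwd$tm[fi] - rev_$tm[ri]) <= cfg$max_tm_diff
  if (!any(ok)) return(empty)
  fi <- fi[ok]
  ri <- ri[ok]
  product <- product[ok]
  pen <- fwd$penalty[fi] + rev_$penalty[ri]
  o <- .ord(pen, product, fwd$start[fi], rev_$t_start[ri])
  o <- o[seq_len(min(max_pairs, length(o)))]
  data.frame(
    rank = seq_along(o),
    forward = fwd$seq[fi[o]], reverse = rev_$seq[ri[o]],
    tm_f = fwd$tm[fi[o]], tm_r = rev_$tm[ri[o]],
    gc_f = fwd$gc[fi[o]], gc_r = rev_$gc[ri[o]],
    product_size = product[o], penalty = pen[o],
    f_start = fwd$start[fi[o]], f_end = fwd$end[fi[o]],
    r_start = rev_$t_start[ri[o]], r_end = rev_$t_end[ri[o]],
    stringsAsFactors = FALSE
  )
}
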