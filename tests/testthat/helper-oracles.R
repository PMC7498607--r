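## Independent oracles used by the property tests. These deliberately take
## different computational routes from the package implementation.

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_is_primitive <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L &&
        paste(rep(substr(motif, 1L, d), k %/% d), collapse = "") == motif) {
      return(FALSE)
    }
  }
  TRUE
}

## regex-backreference SSR finder: a PCRE engine pass per motif length,
## entirely independent of the byte-comparison run-length scanner
oracle_scan <- function(s, cfg = ssrminer::scan_config()) {
  rows <- list()
  wins <- gregexpr("[^N]+", s, perl = TRUE)[[1L]]
  if (wins[1L] == -1L) return(NULL)
  for (widx in seq_along(wins)) {
    ws <- wins[widx]
    text <- substr(s, ws, ws + attr(wins, "match.length")[widx] - 1L)
    for (k in 1:6) {
      pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, cfg$min_repeats[k] - 1L)
      m <- gregexpr(pat, text, perl = TRUE)[[1L]]
      if (m[1L] == -1L) next
      for (idx in seq_along(m)) {
        st <- m[idx]
        len <- attr(m, "match.length")[idx]
        motif <- substr(text, st, st + k - 1L)
        if (!oracle_is_primitive(motif)) next
        count <- len %/% k
        rows[[length(rows) + 1L]] <- data.frame(
          start = ws + st - 1L, end = ws + st + count * k - 2L,
          motif = motif, repeat_count = count, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$start, nchar(out$motif)), , drop = FALSE]
}

## brute-force binding-site search on the plus strand of a target string:
## for every target end position carrying the exact 3' seed word, a dense
## per-end dynamic program over (gap layer, core position, window position)
## finds the minimum-mismatch alignment of the primer's 5' core
oracle_sites_plus <- function(primer, t, cfg) {
  m <- nchar(primer)
  n <- nchar(t)
  w <- min(cfg$seed_word, m)
  G <- cfg$max_gaps
  MM <- cfg$max_mismatches
  seed <- substr(primer, m - w + 1L, m)
  core <- substr(primer, 1L, m - w)
  cl <- nchar(core)
  cb <- if (cl) strsplit(core, "", fixed = TRUE)[[1L]] else character(0)
  rows <- list()
  for (j in seq_len(n)) {
    if (j < w || substr(t, j - w + 1L, j) != seed) next
    if (cl == 0L) {
      rows[[length(rows) + 1L]] <-
        data.frame(start = j - w + 1L, end = j, mismatches = 0L, gaps = 0L)
      next
    }
    lo <- max(0L, j - w - cl - G)
    L <- j - w - lo
    if (L == 0L && cl > G) next
    win <- substr(t, lo + 1L, j - w)
    wb <- if (L) strsplit(win, "", fixed = TRUE)[[1L]] else character(0)
    D <- array(Inf, dim = c(G + 1L, cl + 1L, L + 1L))
    S <- array(NA_real_, dim = c(G + 1L, cl + 1L, L + 1L))
    D[, 1L, ] <- 0
    for (u in 0:L) S[, 1L, u + 1L] <- lo + u + 1L
    for (i in seq_len(cl)) {
      for (u in 0:L) {
        for (g in 0:G) {
          v <- Inf
          sv <- NA_real_
          if (u >= 1L) {
            cost <- as.numeric(wb[u] != cb[i] | wb[u] == "N")
            v <- D[g + 1L, i, u] + cost
            sv <- S[g + 1L, i, u]
          }
          if (g >= 1L) {
            if (D[g, i, u + 1L] < v) {            # core base gapped
              v <- D[g, i, u + 1L]
              sv <- S[g, i, u + 1L]
            }
            if (u >= 1L && D[g, i + 1L, u] < v) { # target base gapped
              v <- D[g, i + 1L, u]
              sv <- S[g, i + 1L, u]
            }
          }
          D[g + 1L, i + 1L, u + 1L] <- v
          S[g + 1L, i + 1L, u + 1L] <- sv
        }
      }
    }
    vals <- D[, cl + 1L, L + 1L]
    starts <- S[, cl + 1L, L + 1L]
    best <- NULL
    seen <- Inf
    for (g in 0:G) {
      v <- vals[g + 1L]
      if (!is.finite(v) || v >= seen) next
      seen <- v
      if (is.null(best) || v + g < best$tot) {
        best <- list(mm = v, g = g, tot = v + g, start = starts[g + 1L])
      }
    }
    if (!is.null(best) && best$mm <= MM && is.finite(best$start) &&
        best$start <= j) {
      rows[[length(rows) + 1L]] <-
        data.frame(start = as.integer(best$start), end = j,
                   mismatches = as.integer(best$mm),
                   gaps = as.integer(best$g))
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

oracle_suppress <- function(sites) {
  if (is.null(sites) || nrow(sites) <= 1L) return(sites)
  o <- order(sites$mismatches + sites$gaps, sites$gaps, sites$start)
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

## both strands of one sequence, same output convention as
## find_binding_sites
oracle_binding_sites <- function(primer, t, cfg = ssrminer::epcr_config()) {
  n <- nchar(t)
  plus <- oracle_suppress(oracle_sites_plus(primer, t, cfg))
  minus <- oracle_suppress(oracle_sites_plus(primer, ssrminer::revcomp(t),
                                             cfg))
  rows <- list()
  if (!is.null(plus)) {
    rows$p <- data.frame(strand = "+", start = plus$start, end = plus$end,
                         mismatches = plus$mismatches, gaps = plus$gaps,
                         stringsAsFactors = FALSE)
  }
  if (!is.null(minus)) {
    rows$m <- data.frame(strand = "-", start = n - minus$end + 1L,
                         end = n - minus$start + 1L,
                         mismatches = minus$mismatches, gaps = minus$gaps,
                         stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

## naive six-frame ORF finder: scans every codon position directly
oracle_longest_orf <- function(s, min_len = 300L) {
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (strand in c("+", "-")) {
    w <- if (strand == "+") s else ssrminer::revcomp(s)
    for (off in 0:2) {
      pos <- 1L + off
      while (pos + 2L <= n) {
        if (substr(w, pos, pos + 2L) == "ATG") {
          q <- pos
          while (q + 2L <= n && !(substr(w, q, q + 2L) %in% stops)) {
            q <- q + 3L
          }
          if (q + 2L <= n) {
            len <- q + 2L - pos + 1L
            cand <- if (strand == "+") {
              list(start = pos, end = q + 2L, strand = "+", length = len)
            } else {
              list(start = n - (q + 2L) + 1L, end = n - pos + 1L,
                   strand = "-", length = len)
            }
            if (len >= min_len &&
                (is.null(best) || len > best$length ||
                   (len == best$length &&
                      (cand$strand == "+" && best$strand == "-" ||
                         cand$strand == best$strand &&
                           cand$start < best$start)))) {
              best <- cand
            }
          }
        }
        pos <- pos + 3L
      }
    }
  }
  best
}
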