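test_that("minimum repeat thresholds hold at and below threshold", {
  cfg <- scan_config()
  motifs <- c("A", "AG", "AAT", "ACAT", "AACCT", "AACGTC")
  for (k in 1:6) {
    thr <- cfg$min_repeats[k]
    ## a delimiter differing from both motif ends cannot extend the run
    d <- setdiff(c("A", "C", "G", "T"),
                 c(substr(motifs[k], 1L, 1L), substr(motifs[k], k, k)))[1L]
    at <- scan_sequence(paste0(d, strrep(motifs[k], thr), d))
    below <- scan_sequence(paste0(d, strrep(motifs[k], thr - 1L), d))
    expect_equal(nrow(at), 1L, info = paste("motif", motifs[k]))
    expect_equal(at$motif, motifs[k])
    expect_equal(at$repeat_count, thr)
    expect_equal(at$tract_length, thr * k)
    expect_equal(nrow(below), 0L, info = paste("motif", motifs[k]))
  }
})

test_that("length classes split at a 20 nt tract", {
  l1 <- scan_sequence(paste0("C", strrep("AG", 11L), "C"))  # 22 nt
  expect_equal(l1$length_class, "I")
  l2 <- scan_sequence(paste0("C", strrep("AG", 10L), "C"))  # 20 nt
  expect_equal(l2$length_class, "II")
})

test_that("runs report at the smallest primitive motif, floor repeats, leftmost", {
  ## poly-A is mono, never di-AA
  x <- scan_sequence(paste0("G", strrep("A", 16L), "G"))
  expect_equal(nrow(x), 1L)
  expect_equal(x$motif, "A")
  ## trailing partial copy excluded from count and tract
  y <- scan_sequence(paste0("G", strrep("AAT", 7L), "AA", "G"))
  expect_equal(y$repeat_count, 7L)
  expect_equal(y$tract_length, 21L)
  expect_equal(y$start, 2L)
})

test_that("a planted repeat in random sequence is found exactly", {
  set.seed(11)
  bg <- random_dna_str(10000L)
  s <- paste0(substr(bg, 1L, 5000L), "G", strrep("AAT", 7L), "G",
              substr(bg, 5001L, 10000L))
  got <- scan_sequence(s)
  want <- oracle_scan(s)
  expect_equal(got$start, want$start)
  expect_equal(got$motif, want$motif)
  expect_true(any(got$start == 5002L & got$motif == "AAT" &
                    got$repeat_count == 7L))
})

test_that("canonical_motif groups rotations and reverse complements", {
  expect_equal(canonical_motif("TTA"), "AAT")
  expect_equal(canonical_motif("T"), "A")
  ## enumerate all 6 candidates of GAT: rotations of GAT and of ATC
  expect_equal(canonical_motif("GAT"),
               min(c("GAT", "ATG", "TGA", "ATC", "TCA", "CAT")))
  expect_error(canonical_motif("ATAT"), "primitive")
})

test_that("composition classes follow the AT fraction", {
  expect_equal(classify_composition(c("AAT", "AC", "CCG")),
               c("AT_RICH", "BALANCED", "GC_RICH"))
})

test_that("compound joining respects the interruption distance", {
  loci <- scan_genome(c(s1 = paste0(strrep("AT", 8L), "GCG",
                                    strrep("GA", 8L))))
  j <- join_compound(loci)
  expect_equal(nrow(j), 1L)
  expect_true(j$compound)
  expect_equal(nrow(j$members[[1L]]), 2L)
  ## 150 nt apart stays separate at the default 100
  far <- scan_genome(c(s1 = paste0(strrep("AT", 8L), random_dna_str(150L),
                                   strrep("GGATC", 5L))))
  if (nrow(far) == 2L) {
    jf <- join_compound(far)
    expect_equal(sum(jf$compound), 0L)
  }
  ## max_interruption 0: only directly adjacent loci merge
  adj <- scan_genome(c(s1 = paste0(strrep("AT", 8L), strrep("GA", 8L))))
  j0 <- join_compound(adj, scan_config(max_interruption = 0L))
  expect_equal(nrow(j0), 1L)
  expect_true(j0$compound)
})

test_that("join_compound insists on sorted input", {
  loci <- scan_genome(c(s1 = paste0(strrep("AT", 8L), "GCG",
                                    strrep("GA", 8L))))
  expect_error(join_compound(loci[c(2L, 1L), ]), "sorted")
})

test_that("landscape summary arithmetic is exact", {
  g <- c(s1 = paste(rep("ACGTN", 200000L), collapse = ""))  # 1 Mbp
  loci <- data.frame(
    seq_id = "s1", start = c(1L, 100L, 200L, 300L),
    end = c(30L, 129L, 229L, 329L), motif = c("AT", "A", "AAT", "AC"),
    canonical_motif = c("AT", "A", "AAT", "AC"),
    repeat_count = c(15L, 30L, 10L, 15L),
    tract_length = c(30L, 30L, 30L, 30L),
    length_class = "I", composition = c("AT_RICH", "AT_RICH", "AT_RICH",
                                        "BALANCED"),
    compound = FALSE, stringsAsFactors = FALSE)
  ls <- summarize_landscape(loci, g)
  expect_equal(ls$density_per_mbp, 4)
  expect_equal(ls$genome_fraction_pct, 0.012)
  expect_equal(unname(ls$by_motif_length[c("mono", "di", "tri")]),
               c(1, 2, 1))
  expect_equal(ls$n_total, 4L)
  ## empty set
  ls0 <- summarize_landscape(loci[0L, ], g)
  expect_equal(ls0$n_total, 0L)
  expect_equal(ls0$density_per_mbp, 0)
  ## unknown seq_id is an error
  bad <- loci
  bad$seq_id[1L] <- "nope"
  expect_error(summarize_landscape(bad, g), "nope")
})

test_that("scan never reports loci overlapping N and splits on N runs", {
  s <- paste0(strrep("AT", 8L), "NN", strrep("AT", 8L))
  x <- scan_sequence(s)
  expect_equal(nrow(x), 2L)
  expect_true(all(x$end < 17L | x$start > 18L))
  ## a run interrupted by N on both sides of threshold
  y <- scan_sequence(paste0(strrep("A", 6L), "N", strrep("A", 6L)))
  expect_equal(nrow(y), 0L)
})

test_that("per-motif counts are internally consistent on the fixture", {
  fx <- get_fixture()
  loci <- scan_genome(fx$genomes$landrace_A)
  ls <- summarize_landscape(loci, fx$genomes$landrace_A)
  expect_equal(sum(ls$by_motif_length), ls$n_simple)
  expect_equal(sum(ls$by_composition), ls$n_simple)
  expect_equal(sum(ls$by_canonical_motif), ls$n_simple)
  expect_equal(unname(sum(ls$by_length_class)), ls$n_simple)
  ## the fixture manifest predicts the scan exactly
  plants <- fx$manifest$plants
  detected <- plants[plants$detected, ]
  expect_equal(nrow(loci), nrow(detected))
  expect_setequal(loci$tract_length,
                  detected$repeats * nchar(detected$motif))
})
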