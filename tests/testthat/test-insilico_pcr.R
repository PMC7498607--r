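## plant an edited copy of a primer into background sequence; edits hit the
## 5' core only, leaving the exact 3' seed word intact
plant_site <- function(primer, n_sub = 0L, n_del = 0L, n_ins = 0L,
                       bg_len = 120L) {
  site <- primer
  core_len <- nchar(primer) - epcr_config()$seed_word
  pos_pool <- seq(2L, core_len - 1L)
  edit_pos <- sort(sample(pos_pool, n_sub + n_del + n_ins))
  ch <- strsplit(site, "", fixed = TRUE)[[1L]]
  types <- sample(rep(c("S", "D", "I"), c(n_sub, n_del, n_ins)))
  out <- character(0)
  for (i in seq_along(ch)) {
    z <- match(i, edit_pos)
    if (!is.na(z)) {
      if (types[z] == "S") {
        out <- c(out, chartr("ACGT", "CATG", ch[i]))
      } else if (types[z] == "D") {
        ## drop the base
      } else {
        out <- c(out, ch[i], sample(c("A", "C", "G", "T"), 1L))
      }
    } else {
      out <- c(out, ch[i])
    }
  }
  paste0(random_dna_str(bg_len), paste(out, collapse = ""),
         random_dna_str(bg_len))
}

test_that("a verbatim primer is found with zero mismatches and gaps", {
  set.seed(17)
  p <- "TGACGTCCTAGGAACTGCAT"
  t <- setNames(paste0(random_dna_str(100L), p, random_dna_str(100L)), "c1")
  s <- find_binding_sites(p, t)
  hit <- s[s$strand == "+" & s$mismatches == 0L & s$gaps == 0L, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(c(hit$start, hit$end), c(101L, 120L))
})

test_that("mismatch and gap budgets bound site acceptance", {
  set.seed(19)
  p <- "TGACGTCCTAGGAACTGCAT"
  sub_at <- function(s, pos) {
    for (z in pos) substr(s, z, z) <- chartr("ACGT", "CATG",
                                             substr(s, z, z))
    s
  }
  plant <- function(site) {
    setNames(paste0(random_dna_str(100L), site, random_dna_str(100L)), "c1")
  }
  ## 3 substitutions: accepted; 4: rejected
  s3 <- find_binding_sites(p, plant(sub_at(p, c(2L, 5L, 8L))))
  expect_true(any(s3$mismatches == 3L & s3$gaps == 0L))
  s4 <- find_binding_sites(p, plant(sub_at(p, c(2L, 5L, 8L, 11L))))
  expect_equal(nrow(s4), 0L)
  ## contiguous deletions in a shift-resistant core on a uniform
  ## background: 3 missing bases cost exactly 3 gap columns, 4 is out
  p2 <- "ATAGATTGGTTAAAGGGGTA"
  bg <- strrep("C", 60L)
  del <- function(k) setNames(paste0(bg, substr(p2, 1L, 5L),
                                     substr(p2, 6L + k, 20L), bg), "c1")
  sg3 <- find_binding_sites(p2, del(3L))
  expect_true(any(sg3$gaps == 3L & sg3$mismatches == 0L))
  expect_equal(nrow(find_binding_sites(p2, del(4L))), 0L)
})

test_that("a site with 2 substitutions and 1 deletion is reported", {
  set.seed(23)
  p <- "TGACGTCCTAGGAACTGCAT"
  t <- setNames(plant_site(p, n_sub = 2L, n_del = 1L), "c1")
  s <- find_binding_sites(p, t)
  expect_gte(nrow(s), 1L)
  expect_true(any(s$mismatches <= 2L & s$gaps <= 1L))
})

test_that("sites are strand-symmetric", {
  set.seed(29)
  p <- "TGACGTCCTAGGAACTGCAT"
  t <- paste0(random_dna_str(150L), p, random_dna_str(80L),
              revcomp(p), random_dna_str(150L))
  fwd <- find_binding_sites(p, setNames(t, "c1"))
  rcv <- find_binding_sites(p, setNames(revcomp(t), "c1"))
  n <- nchar(t)
  mapped <- data.frame(strand = ifelse(rcv$strand == "+", "-", "+"),
                       start = n - rcv$end + 1L, end = n - rcv$start + 1L,
                       mismatches = rcv$mismatches, gaps = rcv$gaps)
  o1 <- order(fwd$start, fwd$strand)
  o2 <- order(mapped$start, mapped$strand)
  expect_equal(fwd[o1, c("strand", "start", "end", "mismatches", "gaps")],
               mapped[o2, c("strand", "start", "end", "mismatches",
                            "gaps")],
               ignore_attr = TRUE)
})

test_that("amplify honors product bounds and finds duplicated cassettes", {
  tg <- mk_template_genome("AG", 10L, seed = 7L)
  fl <- extract_flanks(tg$loci[1L, ], tg$genome, 200L)
  pp <- design_for_locus(fl)[1L, ]
  ## the same cassette planted twice, far enough apart that the cross
  ## product exceeds max_product, gives exactly two amplicons
  set.seed(31)
  t2 <- setNames(paste0(random_dna_str(300L), fl$template,
                        random_dna_str(2500L), fl$template,
                        random_dna_str(300L)), "c1")
  amp2 <- amplify(pp, t2)
  expect_equal(nrow(amp2), 2L)
  expect_equal(amp2$length, rep(pp$product_size, 2L))
  ## convergent sites 5 kb apart exceed max_product 2000
  half_l <- substr(fl$template, 1L, pp$f_end + 10L)
  half_r <- substr(fl$template, pp$r_start - 10L, nchar(fl$template))
  t5 <- setNames(paste0(random_dna_str(200L), half_l, random_dna_str(5000L),
                        half_r, random_dna_str(200L)), "c1")
  expect_equal(nrow(amplify(pp, t5)), 0L)
})

test_that("epcr_matrix is complete, deterministic and manifest-consistent", {
  fx <- get_fixture()
  pl <- get_pipeline()
  mat <- pl$matrix
  expect_s3_class(mat, "epcr_matrix")
  expect_equal(mat$taxa, sort(c(names(fx$genomes), "relative")))
  expect_true(all(mat$hits$marker_id %in% mat$markers))
  ## the destroyed-footprint marker has an empty cell in landrace_C
  lost <- fx$manifest$expected$lost_transfer
  cell <- mat$hits[mat$hits$marker_id == lost$marker &
                     mat$hits$taxon == lost$taxon, ]
  expect_equal(nrow(cell), 0L)
  ## the 2-substitution marker still amplifies its edited landrace
  ok <- fx$manifest$expected$still_transferable
  cell2 <- mat$hits[mat$hits$marker_id == ok$marker &
                      mat$hits$taxon == ok$taxon, ]
  expect_gte(nrow(cell2), 1L)
})
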