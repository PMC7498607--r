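test_that("duplicate primer pairs collapse to the first locus", {
  fx <- get_fixture()
  mk <- fx$base_markers$markers
  fr <- filter_redundant(mk, fx$genomes$landrace_A)
  ## the duplicated cassette (plants 1 and 10) loses both markers: one as
  ## an exact primer duplicate, the survivor as a multi-hit
  expect_equal(fr$n_removed_duplicate, 1L)
  expect_gte(fr$n_removed_multihit, 1L)
  dup_ids <- fx$manifest$plant_marker[c("plant_1", "plant_10")]
  expect_false(any(dup_ids %in% fr$kept$marker_id))
  expect_equal(fr$removed_pct,
               100 * (fr$n_removed_duplicate + fr$n_removed_multihit) /
                 nrow(mk))
  ## rule switches act independently
  fr_dup <- filter_redundant(mk, fx$genomes$landrace_A, rules = "duplicate")
  expect_equal(nrow(fr_dup$kept), nrow(mk) - 1L)
})

test_that("two markers with identical pairs give 50% removal", {
  fx <- get_fixture()
  mk <- fx$base_markers$markers
  dup_ids <- fx$manifest$plant_marker[c("plant_1", "plant_10")]
  two <- mk[mk$marker_id %in% dup_ids, ]
  fr <- filter_redundant(two, fx$genomes$landrace_A, rules = "duplicate")
  expect_equal(nrow(fr$kept), 1L)
  expect_equal(fr$removed_pct, 50)
  ## the kept one is the first by locus coordinate
  expect_equal(fr$kept$marker_id, unname(dup_ids["plant_1"]))
})

test_that("cross-genome clustering collapses identical pairs and sums Venn cells", {
  pl <- get_pipeline()
  markers <- pl$markers
  expect_equal(sum(pl$venn), nrow(markers))
  expect_false(any(duplicated(paste(markers$forward_1, markers$reverse_1))))
  ## unedited cassettes are shared by all four landraces
  all4 <- paste(sort(names(get_fixture()$genomes)), collapse = ";")
  expect_gte(unname(pl$venn[all4]), 8L)
  ## when all pairs are distinct, nothing collapses
  a <- get_fixture()$base_markers$markers[1:3, ]
  b <- a
  b$marker_id <- sub("landrace_A", "landrace_X", b$marker_id)
  b$source_genome <- "landrace_X"
  b$forward_1 <- substr(b$forward_1, 1L, nchar(b$forward_1) - 1L)
  cl <- cluster_across_genomes(list(A = a, X = b))
  expect_equal(nrow(cl$markers), 6L)
})

test_that("polymorphism calls use the 6 bp rule symmetrically", {
  mk_mat <- function(len) {
    structure(list(
      hits = data.frame(marker_id = "m1", taxon = "tx", seq_id = "c1",
                        start = 1L, end = len, length = len,
                        orientation = "FR", mm_f = 0L, gaps_f = 0L,
                        mm_r = 0L, gaps_r = 0L, stringsAsFactors = FALSE),
      markers = "m1", taxa = "tx"), class = "epcr_matrix")
  }
  expected <- c(m1 = 200)
  expect_true(call_transfer_polymorphism(mk_mat(206L),
                                         expected)$polymorphic)
  expect_false(call_transfer_polymorphism(mk_mat(205L),
                                          expected)$polymorphic)
  expect_true(call_transfer_polymorphism(mk_mat(194L),
                                         expected)$polymorphic)
})

test_that("manifest-predicted transfer and polymorphism calls hold", {
  fx <- get_fixture()
  ## landrace-only matrix isolates the tract edits from the relative genome
  pl4 <- run_pipeline(fx$genomes)
  calls <- pl4$calls
  ex <- fx$manifest$expected
  row_of <- function(id) calls[calls$marker_id == id, ]
  for (id in ex$polymorphic) {
    expect_true(row_of(id)$polymorphic, info = id)
  }
  for (id in ex$not_polymorphic_small_shift) {
    expect_false(row_of(id)$polymorphic, info = id)
  }
  expect_false(grepl(ex$lost_transfer$taxon,
                     row_of(ex$lost_transfer$marker)$taxa_present))
  expect_true(grepl(ex$still_transferable$taxon,
                    row_of(ex$still_transferable$marker)$taxa_present))
  ## transferability to the full landrace clade
  tr <- transferable_to_clade(calls, names(fx$genomes))
  expect_false(tr[calls$marker_id == ex$lost_transfer$marker])
})

test_that("comparative mapping counts unique placements only", {
  hits <- data.frame(
    marker_id = c("m1", "m2", "m3", "m4", "m5", "m5"),
    taxon = "rel",
    seq_id = c("chr1", "chr1", "chr1", "chr2", "chr1", "chr3"),
    start = 1L, end = 100L, length = 100L, orientation = "FR",
    mm_f = 0L, gaps_f = 0L, mm_r = 0L, gaps_r = 0L,
    stringsAsFactors = FALSE)
  mat <- structure(list(hits = hits, markers = paste0("m", 1:5),
                        taxa = "rel"), class = "epcr_matrix")
  cm <- comparative_map(mat, "rel")
  expect_equal(cm$counts, c(chr1 = 3L, chr2 = 1L))
  expect_equal(cm$mean, 2)
  expect_equal(cm$n_unplaced, 1L)
  ## the fixture's conserved cassettes land on their planted chromosomes
  cm_fx <- comparative_map(get_pipeline()$matrix, "relative")
  expect_equal(cm_fx$counts, c(chr1 = 1L, chr2 = 1L))
  expect_equal(cm_fx$n_unplaced, 0L)
})

test_that("the exported table round-trips and answers queries", {
  pl <- get_pipeline()
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_emm(pl$markers, f1)
  back <- read_emm(f1)
  expect_equal(nrow(back), nrow(pl$markers))
  expect_equal(back$marker_id,
               sort(pl$markers$marker_id, method = "radix"))
  ## a second write of the re-read table is byte-identical
  export_emm(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  ## query by class and polymorphism matches a manual filter
  q <- query_emm(back, ssr_class = "I", polymorphic = TRUE)
  expect_equal(nrow(q), sum(back$class == "I" & back$polymorphic %in% TRUE))
  expect_equal(nrow(query_emm(back, marker_id = back$marker_id[1L])), 1L)
})

test_that("two pipeline runs give byte-identical marker tables", {
  fx <- get_fixture()
  p1 <- run_pipeline(fx$genomes)
  p2 <- run_pipeline(fx$genomes)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  export_emm(p1$markers, f1)
  export_emm(p2$markers, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
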