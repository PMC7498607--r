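test_that("locus statistics match hand-evaluated formulas", {
  ## two alleles at p = q = 0.5: He = 0.5, PIC = 1 - 0.5 - 2(0.25)(0.25)
  gt <- mk_gt(list(c(200L, 206L), c(200L, 206L), c(200L, 200L),
                   c(206L, 206L)))
  s <- locus_stats(gt, "L1")
  expect_equal(s$He, 0.5)
  expect_equal(s$PIC, 0.375)
  expect_equal(s$Ho, 0.5)
  ## monomorphic locus
  gm <- mk_gt(list(c(100L, 100L), c(100L, 100L)))
  sm <- locus_stats(gm, "L1")
  expect_equal(c(sm$He, sm$Ho, sm$PIC), c(0, 0, 0))
  expect_true(is.na(sm$F))
  ## all individuals heterozygous at p = q = 0.5: Ho = 1, F = -1
  gh <- mk_gt(list(c(100L, 104L), c(100L, 104L), c(100L, 104L),
                   c(100L, 104L)))
  sh <- locus_stats(gh, "L1")
  expect_equal(sh$Ho, 1)
  expect_equal(sh$F, -1)
  ## an all-missing locus is an error
  ga <- mk_gt(list(c(100L, 104L)))
  ga$a1[1L, 1L] <- ga$a2[1L, 1L] <- NA_integer_
  expect_error(locus_stats(ga, "L1"), "missing")
})

test_that("PIC never exceeds He", {
  set.seed(47)
  for (i in 1:1000) {
    k <- sample(2:8, 1L)
    p <- runif(k)
    p <- p / sum(p)
    s2 <- sum(p^2)
    s4 <- sum(p^4)
    he <- 1 - s2
    pic <- 1 - s2 - (s2^2 - s4)
    expect_lte(pic, he + 1e-12)
  }
  ## and on simulated genotype data end to end
  fx <- get_fixture()
  ds <- diversity_stats(fx$genotypes$gt)
  expect_true(all(ds$PIC <= ds$He + 1e-12))
})

test_that("Nei distance matches a spreadsheet-style evaluation", {
  ## group A allele counts 7:3, group B 2:8 at one locus
  gt <- mk_gt(list(c(1L, 1L), c(1L, 1L), c(1L, 1L), c(1L, 2L), c(2L, 2L),
                   c(1L, 1L), c(2L, 2L), c(2L, 2L), c(2L, 2L), c(2L, 2L)))
  groups <- setNames(rep(c("A", "B"), each = 5L), gt$individuals)
  D <- nei_distance(gt, groups)
  jx <- 0.7^2 + 0.3^2
  jy <- 0.2^2 + 0.8^2
  jxy <- 0.7 * 0.2 + 0.3 * 0.8
  expect_equal(D["A", "B"], -log(jxy / sqrt(jx * jy)), tolerance = 1e-12)
  expect_equal(D["A", "A"], 0)
  expect_equal(D["A", "B"], D["B", "A"])
  ## identical frequencies give zero distance
  gt2 <- mk_gt(list(c(1L, 2L), c(1L, 2L), c(1L, 2L), c(1L, 2L)))
  g2 <- setNames(rep(c("A", "B"), each = 2L), gt2$individuals)
  expect_equal(nei_distance(gt2, g2)["A", "B"], 0)
  ## disjoint allele sets give the +Inf sentinel
  gt3 <- mk_gt(list(c(1L, 1L), c(1L, 1L), c(9L, 9L), c(9L, 9L)))
  g3 <- setNames(rep(c("A", "B"), each = 2L), gt3$individuals)
  expect_equal(nei_distance(gt3, g3)["A", "B"], Inf)
})

test_that("G_ST separates fixed groups and vanishes for identical ones", {
  gt3 <- mk_gt(list(c(1L, 1L), c(1L, 1L), c(9L, 9L), c(9L, 9L)))
  g3 <- setNames(rep(c("A", "B"), each = 2L), gt3$individuals)
  ## H_S = 0 and H_T = 0.5, so (H_T - H_S)/H_T = 1
  expect_equal(gst(gt3, g3), 1)
  gt2 <- mk_gt(list(c(1L, 2L), c(1L, 2L), c(1L, 2L), c(1L, 2L)))
  g2 <- setNames(rep(c("A", "B"), each = 2L), gt2$individuals)
  expect_equal(gst(gt2, g2), 0)
})

test_that("G_ST recovers the generating differentiation from simulation", {
  freqs <- list(
    A = list(L1 = c(`100` = 0.9, `104` = 0.1),
             L2 = c(`200` = 0.8, `204` = 0.2)),
    B = list(L1 = c(`100` = 0.1, `104` = 0.9),
             L2 = c(`200` = 0.2, `204` = 0.8)))
  sim <- make_genotypes(freqs, n_per_group = 400L, seed = 53L)
  ## theoretical value from the generating frequencies
  hs <- mean(c(1 - (0.9^2 + 0.1^2), 1 - (0.1^2 + 0.9^2),
               1 - (0.8^2 + 0.2^2), 1 - (0.2^2 + 0.8^2)))
  ht <- mean(c(1 - 2 * 0.5^2, 1 - 2 * 0.5^2))
  want <- (ht - hs) / ht
  expect_equal(gst(sim$gt, sim$groups), want, tolerance = 0.1)
})

test_that("neighbor joining reproduces three-point branch lengths", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3L, 3L,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2L]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2L, 2L)))
  Dn <- D
  Dn[1L, 2L] <- 99
  expect_error(nj_tree(Dn), "symmetric")
})

test_that("neighbor joining recovers random additive trees exactly", {
  set.seed(59)
  for (i in 1:15) {
    n <- sample(4:10, 1L)
    t0 <- ape::unroot(ape::rtree(n, br = function(k) runif(k, 0.1, 1)))
    D <- ape::cophenetic.phylo(t0)
    tr <- nj_tree(D)
    expect_equal(ape::dist.topo(t0, tr), 0, ignore_attr = TRUE)
    expect_equal(sum(tr$edge.length), sum(t0$edge.length),
                 tolerance = 1e-6)
  }
})

test_that("nj_tree agrees with an independent NJ implementation", {
  set.seed(61)
  for (i in 1:5) {
    n <- sample(5:9, 1L)
    D <- as.matrix(stats::dist(matrix(runif(n * 3L), n)))
    rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
    mine <- nj_tree(D)
    ref <- ape::nj(as.dist(D))
    expect_equal(ape::dist.topo(mine, ref), 0, ignore_attr = TRUE)
  }
})

test_that("bootstrap supports are seeded, reproducible and sane", {
  fx <- get_fixture()
  gt <- fx$genotypes$gt
  t1 <- bootstrap_nj(gt, reps = 50L, seed = 7L)
  t2 <- bootstrap_nj(gt, reps = 50L, seed = 7L)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_error(bootstrap_nj(gt, reps = 0L), "reps")
  ## one effective locus (duplicated so resampling is allowed): every
  ## replicate equals the full data, so every support is 100
  g1 <- mk_gt(list(c(1L, 1L, 1L, 1L), c(1L, 2L, 1L, 2L),
                   c(5L, 5L, 5L, 5L), c(5L, 6L, 5L, 6L)))
  tb <- bootstrap_nj(g1, reps = 20L, seed = 3L)
  s1 <- suppressWarnings(as.numeric(tb$node.label))
  expect_true(all(s1[!is.na(s1)] == 100))
})

test_that("allele frequencies are computed per group", {
  gt <- mk_gt(list(c(1L, 1L), c(1L, 2L), c(2L, 2L), c(2L, 2L)))
  groups <- setNames(rep(c("A", "B"), each = 2L), gt$individuals)
  fr <- allele_freqs(gt, "L1", groups)
  expect_equal(fr$A, c(`1` = 0.75, `2` = 0.25))
  expect_equal(fr$B, c(`2` = 1))
})
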