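## shared fixtures, built once per test run
.fx_env <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.fx_env$fx)) .fx_env$fx <- four_landrace_fixture(seed = 42L)
  .fx_env$fx
}

get_pipeline <- function() {
  if (is.null(.fx_env$pl)) {
    fx <- get_fixture()
    .fx_env$pl <- run_pipeline(fx$genomes,
                               extra_taxa = list(relative = fx$relative))
  }
  .fx_env$pl
}

## build a genotype_table directly from a list of (a1, a2) row vectors
mk_gt <- function(calls, loci = NULL, individuals = NULL) {
  n <- length(calls)
  L <- length(calls[[1L]]) / 2L
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  if (is.null(individuals)) individuals <- paste0("i", seq_len(n))
  a1 <- a2 <- matrix(NA_integer_, n, L, dimnames = list(individuals, loci))
  for (i in seq_len(n)) {
    x <- calls[[i]]
    for (j in seq_len(L)) {
      pair <- sort(c(x[2L * j - 1L], x[2L * j]))
      a1[i, j] <- pair[1L]
      a2[i, j] <- pair[2L]
    }
  }
  structure(list(individuals = individuals, loci = loci, a1 = a1, a2 = a2,
                 missing = "-"),
            class = "genotype_table")
}

## a clean design template: random flanks around a repeat tract, as a
## one-sequence genome plus its scanned locus
mk_template_genome <- function(motif = "AG", repeats = 10L, flank = 200L,
                               seed = 7L) {
  set.seed(seed)
  g <- setNames(paste0(random_dna_str(flank), strrep(motif, repeats),
                       random_dna_str(flank)), "c1")
  list(genome = g, loci = scan_genome(g))
}
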