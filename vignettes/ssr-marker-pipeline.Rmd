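---
title: "Genome-wide SSR mining and marker development with ssrminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide SSR mining and marker development with ssrminer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the method

Microsatellites (simple sequence repeats, SSRs) are tandem repeats of 1–6
nt motifs. Because their repeat counts mutate quickly, PCR primers placed
in the sequence flanking an SSR amplify products whose length varies
between individuals and between related taxa, which makes SSRs cheap,
co-dominant genetic markers scoreable on agarose gels. `ssrminer`
implements the complete marker-development workflow for assembled genomes:

1. **Repeat scanning** (`scan_genome()`): all maximal perfect tandem
   repeats of primitive motifs of length 1–6, with minimum repeat counts
   of 12 (mono-), 8 (di-), 5 (tri-/tetra-) and 4 (penta-/hexanucleotide)
   motifs — the thresholds conventionally used for genome-wide SSR
   surveys. Nearby repeats merge into compound loci (`join_compound()`,
   interruption ≤ 100 nt by default). Loci are classified by length
   (class I > 20 nt, class II ≤ 20 nt), by motif base composition
   (AT-rich / GC-rich / balanced), and by canonical motif group — the
   lexicographic minimum over all cyclic rotations of the motif and of its
   reverse complement, so e.g. AAT, ATT, TAA and TTA are one group.
2. **Primer design** (`design_for_locus()`): up to three ranked primer
   pairs per locus from the 200 nt flanks, under Primer3-style
   constraints: length 18/20/27 (min/opt/max), GC 40–60 %, Tm 57/60/63 °C,
   pair ΔTm ≤ 3 °C, product 100–300 bp, homopolymer ≤ 4, 3'
   self-complementarity ≤ 3. The penalty of an accepted primer is
   `|len − 20| + |Tm − 60| + 0.5·|GC − 50|`; pairs are ranked by the sum of
   the two penalties, ties broken by smaller product then leftmost forward
   start. Melting temperatures use the unified nearest-neighbor duplex
   parameters with duplex-initiation terms, a `0.368·(N−1)·ln[Na+]`
   entropic salt correction, 50 mM monovalent salt and 50 nM total oligo
   (the `CT/4` concentration term; primers are treated as
   non-self-complementary duplexes).
3. **In silico PCR** (`find_binding_sites()`, `amplify()`,
   `epcr_matrix()`): binding sites permit up to 3 mismatches and 3 gap
   columns *per primer*, with budgets checked independently. A site must
   match the primer's 3'-terminal `seed_word` (default 7 nt) exactly —
   the word semantics of electronic-PCR tools, and the source of their
   specificity; mismatches and gaps are only permitted 5' of that word.
   Setting `seed_word = 1` relaxes this to an exact terminal base.
   Amplicon length is the 5'-to-5' span inclusive, so a perfect
   self-amplification reproduces the designed product size exactly.
4. **Marker pipeline** (`run_pipeline()`): within-genome redundancy
   filtering (identical primer pairs collapse to the first locus;
   markers amplifying more than one product in their own genome are
   dropped as non-specific), cross-genome clustering of identical pairs
   with Venn-style membership counts, transferability calls (≥ 1
   amplicon in a taxon), length-polymorphism calls (amplicon sizes
   spanning ≥ 6 bp, the resolution of agarose gels), per-chromosome
   comparative mapping, and a flat, byte-deterministic marker-table
   export (`export_emm()`/`query_emm()`).
5. **Genomic context** (`classify_by_annotation()`,
   `classify_with_fallback()`): overlap with GFF3 features at priority
   CDS > 5' UTR > 3' UTR > intron > intergenic; without annotation, a
   six-frame longest-ORF scan of the flanking template (ATG start, stop
   included, minimum 300 nt) stands in for gene prediction.
6. **Diversity statistics** (`diversity_stats()`, `nei_distance()`,
   `gst()`, `bootstrap_nj()`): allele frequencies, expected
   heterozygosity `He = 1 − Σp²` (gene diversity, no small-sample
   correction — the convention of marker-assay software), observed
   heterozygosity, Botstein's PIC
   `1 − Σp² − Σ_{i<j} 2p_i²p_j²`, fixation index `F = 1 − Ho/He`,
   Nei's (1972) standard distance, multi-locus
   `G_ST = (H_T − H_S)/H_T`, and a hand-implemented Saitou–Nei
   neighbor-joining tree with locus-resampling bootstrap supports.

## Design choices

**Coordinates.** All coordinates are 1-based inclusive throughout,
matching GFF3, Biostrings and the R/Bioconductor ecosystem. A single
convention with no internal conversion point is safer in R than carrying a
0-based convention alongside 1-based dependencies.

**Scanner conventions.** A run divisible at several motif phases is
reported once, from its leftmost start; trailing partial motif copies are
excluded, so `tract_length = repeat_count × motif length` exactly. A run
is reported at its smallest primitive motif length only. Runs of `N`
split sequences into independent windows and never appear inside a tract
or a design flank. Whether a compound locus counts once or per member in
published-style totals is a genuine ambiguity of survey reports, so
`summarize_landscape(count_compound=)` exposes both conventions.

**Primer modelling.** "Primer3 with default parameters" is
under-determined across Primer3 versions, so the constraint set above is
fixed, documented and configurable (`design_config()`); exact Primer3
replication is a non-goal. The scorer is deliberately simple (no
thermodynamic dimer/hairpin model beyond the 3' self-complementarity
count) to stay auditable; candidate enumeration over a flank shares
cumulative ΔH/ΔS and GC sums, so scoring every admissible substring is
linear per candidate length.

**e-PCR site definition.** Budgets are per primer, never summed over the
pair. With a budget as permissive as 3 mismatches + 3 gaps on a ~20-mer, a
1-base 3' anchor would admit spurious sites throughout random sequence;
the exact 3' seed word is what gives e-PCR-class tools their specificity,
so it is part of the site definition here, not merely a speed-up. For
each candidate end the engine reports the alignment minimizing
mismatches + gap columns (ties to fewer gaps) and accepts the site only
if that optimum satisfies both budgets — consequently a site carrying 4
substitutions is rejected rather than rescued by trading a substitution
for two gap columns. Among overlapping alignments of one physical site
only the best is reported. Each indel column counts 1 gap and 0
mismatches; any column against `N` counts as a mismatch. Candidate ends
are the overlap-aware exact occurrences of the seed word, each verified
by a banded, gap-layered dynamic program over the adjacent window — a
lossless search given the seed rule, checked in the tests against an
independent per-end alignment oracle.

**Redundancy rules.** The two removal rules (exact duplicate primer
pairs; multi-product amplification in the source genome) are separately
switchable (`filter_redundant(rules=)`) because published redundancy
percentages rarely state which definition was used.

**NJ details.** Negative branch lengths are clamped to zero with the
deficit moved to the sister edge, preserving the pair distance sum; Q-
criterion ties break on the lexicographically smallest label pair, making
tree construction deterministic. Bootstrap supports resample loci with
replacement and count, for every internal bipartition of the full-data
tree, the fraction of replicate trees containing it. The individual-level
distance is the shared-allele dissimilarity (1 − proportion of shared
alleles, counting multiplicity, averaged over co-typed loci); group-level
Nei distance is kept separate. Nei's 1972 distance (not 1983) is
implemented.

**G_ST edge case.** For two equal-sized groups fixed for different
alleles, `H_S = 0` and `H_T = 0.5`, so `G_ST = 1` — full differentiation,
as the formula requires.

## The synthetic study and what it does (not) show

`four_landrace_fixture()` builds a seeded miniature of a four-landrace
marker study with exact ground truth: a two-contig base genome (12 kb +
8 kb) carrying 15 planted SSRs that cover all six motif lengths, both
length classes and all three composition classes; most plants are
"cassettes" whose 220 nt flanks are fixed sequence, so primers and
cross-genome identity are fully controlled. One cassette is planted twice
(exercising both redundancy rules), three derived landraces carry tract
expansions/contractions of ±1–3 repeat units (bracketing the 6 bp
polymorphism threshold) and 2 or 4 substitutions inside a designed
forward-primer footprint (bracketing the mismatch budget), a
chromosome-level "relative" genome carries two conserved cassettes with
+6 bp tract shifts, and an 18-individual, 15-locus genotype panel is
drawn under Hardy–Weinberg with two populations strongly divergent at 8
loci. Backgrounds are rejection-resampled until the scanner output equals
the manifest exactly, so every expected value in the tests comes from the
manifest, not from recorded snapshots.

The generator emulates what the method needs to be tested — planted
repeats, controlled flank identity, unit-sized length edits, HWE
genotypes — and deliberately not the texture of real assemblies:
no transposable elements or satellite arrays, no assembly gaps or
collapsed duplications beyond the planted ones, uniform base composition,
and far smaller scale. Green tests therefore certify the *algorithms*
(detection, design, site search, calls, statistics) and the pipeline's
determinism, not survey statistics of any real genome; genome-scale
numbers depend on the input assembly and on the compound-counting
convention.

Problem sizes were chosen so the whole suite runs on a desk machine:
20 kb per synthetic genome, scanner/e-PCR oracle equivalence on 200 × 5 kb
and 100 instances respectively, frequency recovery at n = 500, bootstrap
support at 200 replicates.

## Numerical notes and limitations

* Tm values agree with independent sums over the published
  nearest-neighbor table to < 1e-6 °C; self-complementary primers are
  treated like any other duplex (no symmetry correction).
* All orderings that affect output files use locale-independent radix
  sorting, and the pipeline consumes no random numbers, so two runs on
  identical inputs produce byte-identical marker tables.
* `He` uses no small-sample correction; a corrected estimator would be a
  one-line change in `locus_stats()` but would no longer match the
  marker-assay software convention.
* Nei distance between groups with no shared alleles is `+Inf`; the NJ
  tree should then be built on the individual-level shared-allele
  dissimilarity, which stays finite.
* The ORF fallback cannot distinguish UTRs or introns — without
  annotation those loci fall into `CDS` (tract inside the longest ORF) or
  `INTERGENIC`.
* Compound loci carry no canonical motif or composition class; they are
  excluded from per-motif counts and counted once (configurable) in
  totals.

## A worked run

```{r example}
library(ssrminer)

fx <- four_landrace_fixture(seed = 42)

## landscape of the base genome
loci <- scan_genome(fx$genomes$landrace_A)
summarize_landscape(join_compound(loci), fx$genomes$landrace_A)

## full pipeline across the four landraces plus the relative
pl <- run_pipeline(fx$genomes, extra_taxa = list(relative = fx$relative))
pl$summary
comparative_map(pl$matrix, "relative")
export_emm(pl$markers, "markers.tsv")

## diversity on the genotype panel
diversity_stats(fx$genotypes$gt)
gst(fx$genotypes$gt, fx$genotypes$groups)
tree <- bootstrap_nj(fx$genotypes$gt, reps = 200, seed = 43)
ape::write.tree(tree, "tree.nwk")
```
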