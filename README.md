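# ssrminer

Genome-wide microsatellite mining and SSR-marker development in R.

Microsatellites (simple sequence repeats, SSRs — tandem repeats of 1–6 nt
motifs) mutate in repeat count fast enough that PCR primers placed in the
flanking sequence yield length-polymorphic, co-dominant markers scoreable
on plain agarose gels. They remain the workhorse for diversity surveys,
genotyping and germplasm management in crops whose communities cannot
afford sequencing-based genotyping — the motivating case being clonally
propagated, under-studied food-security crops with many locally named
landraces. `ssrminer` turns assembled genomes into a curated marker panel
and computes the population-genetic statistics used to validate one.

## What it computes

* **Repeat scan** — all maximal perfect tandem repeats of primitive
  motifs, length 1–6, at the survey-standard minimum repeat counts
  (12/8/5/5/4/4 for mono→hexa); compound-SSR merging (interruption
  ≤ 100 nt); classification by length class (I > 20 nt ≥ II), base
  composition (AT-rich / GC-rich / balanced) and canonical motif group
  (lexicographic minimum over cyclic rotations and reverse complement,
  e.g. AAT/ATT/TTA → AAT); landscape summaries (density per Mbp, % of
  assembly, per-motif counts).
* **Primer design** — up to three ranked pairs per locus from the 200 nt
  flanks under Primer3-style bounds (18–27 nt, GC 40–60 %, Tm 57–63 °C
  by unified nearest-neighbor thermodynamics at 50 mM Na⁺ / 50 nM oligo,
  ΔTm ≤ 3 °C, product 100–300 bp), penalty
  `|len−20| + |Tm−60| + 0.5·|GC−50|`.
* **In silico PCR** — binding sites within 3 mismatches and 3 gap columns
  per primer (independent budgets), an exact 3'-terminal 7 nt word
  required (the e-PCR word semantics), amplicons as convergent site pairs
  within 50–2000 bp; complete marker × taxon matrices.
* **Marker pipeline** — redundancy filtering (duplicate primer pairs;
  multi-product markers), cross-genome clustering with Venn counts,
  transferability and ≥ 6 bp length-polymorphism calls, per-chromosome
  comparative mapping, and a byte-deterministic flat marker table
  (`EMM-<genome>-<serial>` ids) with query helpers.
* **Genomic context** — CDS / 5' UTR / 3' UTR / intron / intergenic from
  GFF3 (priority CDS > UTR5 > UTR3 > intron), or a six-frame longest-ORF
  fallback (ATG…stop, ≥ 300 nt) when no annotation exists.
* **Diversity statistics** — allele frequencies, He = 1 − Σp², Ho,
  Botstein's PIC = 1 − Σp² − Σ_{i<j}2p_i²p_j², F = 1 − Ho/He, Nei (1972)
  distance, multi-locus G_ST = (H_T − H_S)/H_T, and neighbor-joining
  trees (Saitou–Nei, deterministic tie-breaking, clamped negative edges)
  with locus-resampling bootstrap supports.
* **Synthetic fixtures** — seeded genome/landrace/genotype generators
  whose manifests predict every downstream result exactly, so the whole
  pipeline is testable offline (`four_landrace_fixture()`).

## A worked example

```r
library(ssrminer)

fx <- four_landrace_fixture(seed = 42)   # 4 landraces + relative + genotypes

loci <- scan_genome(fx$genomes$landrace_A)
summarize_landscape(join_compound(loci), fx$genomes$landrace_A)
#> SSR landscape: 15 loci (15 simple, 0 compound) in 20000 nt
#> density 750 per Mbp; 1.56% of the assembly

pl <- run_pipeline(fx$genomes, extra_taxa = list(relative = fx$relative))
pl
#> ssr_pipeline: 4 genomes, 15 non-redundant markers
#>                 n_loci_total           n_markers_designed
#>                        59.00                        59.00
#>             success_rate_pct                redundant_pct
#>                       100.00                        74.58
#>               n_nonredundant    shared_across_genomes_pct
#>                        15.00                        86.67
#> transferable_all_sources_pct              polymorphic_pct
#>                        93.33                        26.67
```

59 loci are scanned across the four landraces (the same 15 physical loci,
minus one tract contracted below threshold in one landrace), every locus
yields primers, and clustering the four per-genome sets collapses them to
15 unique markers — the duplicated-cassette marker is removed by the
redundancy filter on the way. 86.67 % of unique markers occur in two or
more landraces, 93.33 % amplify in all four, and 26.67 % are length-
polymorphic by the ≥ 6 bp rule (the planted ±3-repeat-unit edits; the
±≤2-unit edits stay monomorphic, as they should at agarose resolution).

```r
diversity_stats(fx$genotypes$gt)[1:3, ]
#>   locus_id n_alleles n_typed    He    Ho   PIC     F
#> 1      L01         4      18 0.690 0.389 0.638 0.436
#> 2      L02         4      18 0.731 0.556 0.683 0.241
#> 3      L03         4      18 0.745 0.389 0.698 0.478
gst(fx$genotypes$gt, fx$genotypes$groups)
#> [1] 0.2190853
tree <- bootstrap_nj(fx$genotypes$gt, reps = 200, seed = 43)
bipartition_support(tree, names(fx$genotypes$groups)[
  fx$genotypes$groups == "cultivated"])
#> [1] 99
```

PIC ≤ He at every locus (an algebraic identity), F > 0 reflects the
two-population structure inside the pooled panel, and the bipartition
separating the two simulated populations is supported in 99 % of
bootstrap replicates.

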