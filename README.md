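# proseqkit

An R toolkit for preparing and analysing multi-locus DNA polymorphism
datasets, aimed at molecular ecologists and evolutionary geneticists working
downstream of SNP calling. It covers the span from raw multisample VCFs to
publication statistics:

* **Dataset preparation** — VCF → per-contig FASTA alignments (IUPAC or
  split-haplotype pseudo-sequences), annotation import from GFF/BED/CSV,
  population-structure files, sequence transforms (reverse complement,
  trim, mask), translation, ORF search, site filtering (codon positions,
  gap/missing columns) and QC reports (premature stop codons, per-individual
  missingness).
* **Polymorphism analysis** — segregating sites *S*, nucleotide diversity π,
  Watterson's θ_W = S/a₁, Tajima's D = (π − θ_W)/√(e₁S + e₂S(S−1)),
  Kelly's Z_nS (mean r² over biallelic site pairs), silent/non-silent
  partition via Nei–Gojobori site counting, sliding windows over alignments
  or directly over a VCF stream.
* **Population subdivision** — shared/fixed/private site counts,
  Fst = 1 − Hw/Hb and Kst = 1 − Ks/Kt with permutation tests (exact by
  enumeration on small samples).
* **Phylogenies** — neighbour joining (Studier–Keppler) on raw difference
  counts, Jukes–Cantor or Kimura two-parameter distances, single dataset or
  project-wide.
* **Coalescent simulation** — structured coalescent with stepwise size
  changes, island-model migration and population joins; θ-mode or fixed-S
  infinite-sites mutations; Newick genealogies, simulated alignments, and
  empirical critical values (null-distribution quantiles) for
  Tajima's D, Z_nS, π or S.
* **Format exports** — PHYLIP, NEXUS, MEGA, Structure, SweepFinder and
  site-frequency-spectrum vectors.

## Worked example

The package ships a four-sequence alignment small enough to check by hand
(`s1=ACGT`, `s2=ACGA`, `s3=ATGA`, `s4=ATGA`; populations P1 = {s1,s2},
P2 = {s3,s4}):

```r
library(proseqkit)
w <- worked_alignment()
diversity(w$dataset)
#> <proseq_diversity> n=4 sites=4 S=2 pi=1.16667 theta_W=1.09091 D=0.5916 ZnS=0.3333 [per_site]

subdivision(w$dataset, w$popmap, "P1", "P2")
#> <proseq_subdivision> P1 (n=2) vs P2 (n=2)
#>   Hw=0.5000 Hb=1.5000 Fst=0.6667 | Ks=0.5000 Kt=1.1667 Kst=0.5714
#>   fixed=1 shared=0 private_1=1 private_2=0
```

The six pairwise difference counts are 1,2,2,1,1,0, so π per locus is
7/6 ≈ 1.1667; with S = 2 and a₁ = 11/6, θ_W = 12/11 ≈ 1.0909, and the
normalized difference gives Tajima's D ≈ 0.5916. Between populations, site 2
is a fixed difference (CC vs TT) and site 4 is private to P1, giving
Fst = 2/3 and Kst = 4/7. The permutation test enumerates the three distinct
2+2 splits, so the exact p-value for Kst is 1/3:

```r
permutation_test(w$dataset, w$popmap, "P1", "P2", "Kst")$p_value
#> [1] 0.3333333
```

A null distribution for Tajima's D matched to an observed S:

```r
rep <- simulate_critical_values(demography(10), L = 100, mode = "fixed_S",
                                S = 10, statistic = "TajimasD",
                                n_reps = 2000, seed = 1)
rep$quantiles   # empirical 2.5% / 97.5% critical values
```

## Command-line tools

Thin wrappers over the same functions are installed under the package's
`exec/` directory: `vcf2fasta` (VCF → per-contig FASTA), `vcfswpol`
(sliding-window polymorphism scan straight from a VCF, stdin-friendly) and
the `proseqkit` multi-tool (`stats`, `window`, `subdiv`, `filter`, `report`,
`convert`, `nj`, `simulate`). For example:

```sh
zcat calls.vcf.gz | Rscript $(Rscript -e 'cat(system.file("exec/vcfswpol", package="proseqkit"))') \
    -i --window 10000 --step 2500
```

emits a TSV with columns `chrom start end n_sites S pi theta tajD`. All
tools exit 0 on success, 1 on data errors, 2 on usage errors, and every
stochastic subcommand takes `--seed`.

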