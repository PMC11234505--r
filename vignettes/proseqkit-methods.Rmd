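---
title: "Methods and design notes for proseqkit"
author: "proseqkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for proseqkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proseqkit)
```

# Scope

proseqkit is a scriptable engine for preparing and analysing multi-locus DNA
polymorphism datasets: reconstructing alignments from multisample VCFs,
attaching coding annotation and population structure, computing diversity and
subdivision statistics (whole-locus or in sliding windows), building
neighbour-joining phylogenies, and running structured-coalescent simulations
to obtain bespoke critical values for test statistics. This vignette records
the statistical definitions the package implements, the design choices made
where several defensible options existed, and the limits of what the test
suite demonstrates.

# Data model and conventions

A **dataset** is a rectangular alignment of named sequences for one locus or
contig, held as a character matrix. The alphabet is `A C G T`, the IUPAC
ambiguity codes, `N` and `?` (missing) and `-` (gap); `U` is normalized to
`T` and case is folded on load. All internal coordinates are **0-based
half-open**; conversion to and from 1-based formats (GFF, CSV annotation,
VCF positions) happens only in the format readers and writers, so no other
code ever adjusts offsets. For every statistic, only `A/C/G/T` count as
observed alleles: gaps, missing symbols and ambiguity codes are treated as
missing data.

A **project** is an ordered collection of datasets plus a relational map
sequence → individual → population (the popmap). The auto-linker
(`link_sequences()`) matches individual names as case-insensitive substrings
of sequence names; the longest match wins, and a tie between equally long
matches leaves the sequence unlinked with a warning rather than guessing.
This rule is deterministic and auditable, which we prioritized over recall.

# Diversity statistics

For an alignment of $n$ sequences, `diversity()` reports:

* **Segregating sites** $S$: columns with at least two distinct non-missing
  nucleotides.
* **Nucleotide diversity** $\pi$: under the default `per_site` policy each
  site contributes the unbiased heterozygosity
  $h = \frac{m}{m-1}\bigl(1 - \sum_a p_a^2\bigr)$, where $m$ is the number
  of non-missing alleles at the site (sites with $m < 2$ are skipped), and
  $\pi_{locus} = \sum h$. On complete data this equals the mean pairwise
  difference count. Under the `complete` policy, every column containing any
  gap/missing/ambiguous symbol is discarded first and the nominal $n$ is
  used throughout.
* **Watterson's** $\theta_W = S / a_1$ with $a_1 = \sum_{i=1}^{n-1} 1/i$.
* **Tajima's** $D = (\pi_{locus} - \theta_W) / \sqrt{e_1 S + e_2 S(S-1)}$,
  with the standard coefficient set ($a_1, a_2, b_1, b_2, c_1, c_2, e_1,
  e_2$) evaluated at the nominal sample size $n$. The variance coefficients
  assume a single $n$, so the missing-data policy deliberately affects only
  $\pi$ and $S$, never the coefficients. $D$ is reported as `NA` when
  $S = 0$ or $n < 3$ rather than some sentinel number.
* **Kelly's** $Z_{nS}$: the mean of $r^2 = D_{AB}^2 / (p_A(1-p_A)p_B(1-p_B))$
  over all pairs of biallelic segregating sites with no missing data. Sites
  with three or more alleles, or with any missing residue, are excluded
  (the source definition is biallelic); `NA` when fewer than two usable
  sites remain.

Sliding windows (`sliding_window()`, and `vcf_sliding_window()` on the VCF
path) tile columns from 0 in steps of `step`. Every full window is emitted;
one final partial window is appended only when the full windows leave a tail
uncovered (on the VCF path, additionally only when it contains a record).
This makes window sets a pure function of `(L, window, step)` and avoids
emitting empty slivers already covered by the last full window.

## Silent and non-silent partition

When a dataset-scope coding region is present, `silent_nonsilent()` splits
columns by Nei–Gojobori counting on the per-column consensus codon: each
codon position contributes $f_{syn}$ = (number of the three possible
single-base changes that preserve the amino acid)/3 synonymous sites and
$1 - f_{syn}$ nonsynonymous sites. Mutations to stop codons change the
protein and therefore count as nonsynonymous (so TTT yields 1/3 synonymous
and 8/3 nonsynonymous sites). A polymorphic coding site is classified
synonymous only when *all* observed fully-resolved codon variants encode the
same amino acid. Silent statistics pool synonymous coding sites with all
non-coding columns; per-site denominators are the fractional site counts.
Codons containing a gap in any sequence are excluded from both classes and
counted, since a within-codon gap makes the reading frame of that column
set unreliable.

## Subdivision and permutation testing

For two populations, `subdivision()` derives everything from raw pairwise
difference counts: $H_w$ is the **unweighted** mean of the two
within-population means and $F_{st} = 1 - H_w/H_b$; $K_s$ is the
**sample-size-weighted** within-population diversity and
$K_{st} = 1 - K_s/K_t$. The two weightings follow the respective source
formulations; since the original program documents neither formula, the
choice is pinned here and in the function documentation. Biallelic
pooled-segregating sites are classified as fixed (populations share no
allele), shared (both polymorphic) or private; sites with more than two
alleles are excluded and counted.

`permutation_test()` permutes sequence→population labels holding sample
sizes fixed. Both statistics are symmetric under swapping the population
labels, so the label assignments are enumerated as *unordered* splits; when
the number of distinct splits is at most `n_perm` the test is exhaustive and
the p-value is the exact tail probability (the observed split included),
otherwise `n_perm` random permutations give
$p = (1 + \#\{perm \ge obs\})/(1 + n_perm)$. On the worked four-sequence
alignment there are three distinct 2+2 splits and the exact p-value is 1/3.

# VCF handling

`vcf_to_fasta()` rebuilds per-contig alignments. Indel and symbolic-allele
records are **skipped in place** (the position keeps the reference base and
a counter is reported) rather than aligned, so every output column stays
coordinate-compatible with the reference. Missing genotypes become `N`.
Heterozygotes become IUPAC codes in `iupac` mode; in `split_haplotypes`
mode unphased genotypes are split in listed allele order — deterministic and
reproducible, at the cost of realism for haplotype-level statistics (the
unphased-heterozygote count is reported so users can judge the caveat).
Without a reference the recorded positions form the columns, which is exact
for all-sites VCFs.

`vcf_sliding_window()` expands genotype columns into allele samples (two per
diploid). Sites with fewer than two non-missing alleles are ignored; sites
with more than two distinct alleles are excluded from $S/\pi/D$ and counted
separately, matching the biallelic assumptions of the downstream statistics.
With `all_sites = TRUE` the per-site denominator is the number of records in
the window; otherwise it is the window length in bp, which *undercounts*
diversity where coverage is incomplete — the denominator is emitted in the
`n_sites` column so users can re-normalize.

# Neighbour joining

`distance_matrix()` implements raw difference counts (per the program
lineage, a count, not per site), Jukes–Cantor
$d = -\tfrac34\ln(1 - \tfrac43 p)$ and Kimura two-parameter
$d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$ (transitions A↔G, C↔T).
Out-of-domain proportions produce an `NA` marker; `nj_tree()` refuses
matrices containing them, naming the offending pairs. `nj_tree()` uses the
Studier–Keppler update: join the pair minimizing
$Q(i,j) = (r-2)d(i,j) - R_i - R_j$, with ties broken by the lowest
(row, column) index pair so results are order-deterministic. Negative branch
lengths are clamped to zero with a surfaced count — on additive inputs the
tests assert zero clamps. The final three-taxon join emits a trifurcating
root (the tree is unrooted). NJ is exact on additive matrices, which the
suite exploits: random trees with positive branch lengths are converted to
path-length matrices and must be recovered to $10^{-9}$.

# Coalescent simulator

Time runs backwards in units of $2N_0$ generations. With $k_i$ lineages in
deme $i$ of relative size $\sigma_i$, coalescence occurs at rate
$k_i(k_i-1)/(2\sigma_i)$ per deme; under the island model each lineage
migrates at rate $M/2$ ($M = 4N_0m$) to a uniformly chosen other deme.
Piecewise-constant demography (epochs of relative sizes, population joins)
is handled by drawing candidate exponential waiting times and **clipping at
the next boundary**, where all rates are re-evaluated; by memorylessness of
the exponential this realizes the time-inhomogeneous process exactly for
piecewise-constant rates. A validator rejects non-terminating
configurations (several demes, zero migration, joins that do not funnel all
demes together).

Mutations are dropped under the infinite-sites model: Poisson with mean
$(\theta/2)\,\ell$ per branch of length $\ell$, or — for fixed-$S$
conditioning — exactly $S$ mutations placed with probability proportional to
branch length on the realized genealogy (the standard conditional
approximation to conditioning the full process on $S$). Each mutation gets a
distinct site among $L$; the ancestral base is uniform on the four
nucleotides and the derived base uniform on the remaining three, giving
ordinary nucleotide alignments that flow straight into `diversity()`.

Reproducibility contract: a single master seed generates one sub-seed per
replicate up front, so a full report is byte-identical under the same seed
and any single replicate can be replayed in isolation. Critical values are
order statistics at 1-based index $\lceil q R \rceil$ over the defined
replicate values; undefined replicate values (e.g. $D$ with $S=0$) are
dropped and counted.

Expected problem sizes: closed-form checks (mean TMRCA $2(1-1/n)$, mean
total length $2\sum 1/i$, $E[S] = \theta a_1$, $E[\pi_{locus}] = \theta$)
are run at 20,000 replicates and judged within three Monte-Carlo standard
errors; the demographic sign checks (recent expansion ⇒ mean $D < 0$,
recent decline ⇒ mean $D > 0$) use 10,000 replicates of 20 samples. These
sizes give comfortable statistical resolution while keeping the whole suite
in the minutes range on one core.

# Synthetic data generators

The test fixtures are generated in code. `make_alignment()` injects an exact
number of biallelic segregating sites (random column, random minor-allele
count) on a monomorphic random background, optionally adding fixed
differences between two halves and uniform missingness — it emulates
SNP-matrix-like polymorphism, **not** realistic coalescent correlation
structure, indel patterns, or mutation-model bias (simulated data with
genealogical structure comes from the coalescent module instead).
`make_toy_vcf()` emits an all-sites haploid VCF whose reference is the
alignment's first-observed allele per column, exercising the VCF path's
bookkeeping rather than a realistic caller's output; corner-case records
(indels, missing and unphased genotypes, multiallelic sites) are available
for parser tests. Passing tests on these fixtures therefore demonstrate
correctness of the statistical bookkeeping, not robustness to the full
messiness of real variant calls (quality fields, overlapping indels,
half-calls), which the package does not attempt to model.

# Numerical and degenerate-input choices

* Ratios with zero denominators ($F_{st}$ with $H_b = 0$, $K_{st}$ with
  $K_t = 0$, Tajima's $D$ with $S = 0$) return `NA`, never `Inf`.
* Permutation tie handling compares with a $10^{-12}$ slack so that
  permutations reproducing the observed arrangement count as "at least as
  extreme" despite floating-point noise.
* NJ tie-breaks and the unphased-haplotype splitting rule are deterministic
  by construction; every stochastic entry point takes a seed and restores
  the caller's RNG state afterwards.
* Coding regions shorter than one codon are accepted with a warning and
  simply yield empty translations; out-of-range annotation records are
  reported per record and skipped rather than aborting a whole import.

# Known limitations

* No recombination, selection, exponential growth or sequencing-error model
  in the simulator; demography is piecewise-constant sizes + island
  migration + joins.
* Statistics assume biallelic sites where the source definitions do;
  multiallelic sites are excluded and counted, not modelled.
* `vcf_to_fasta()` ignores genotype likelihoods and quality fields; users
  are expected to pre-filter VCFs.
* Datasets are assumed pre-aligned; there is no alignment or assembly step.
* The Fst/Kst pair is defined for two populations at a time; multi-way
  differentiation requires looping over pairs.
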