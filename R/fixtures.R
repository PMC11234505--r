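# Deterministic generators for test inputs: controlled random alignments,
# toy VCF + reference pairs, random additive trees/matrices, and the worked
# four-sequence example alignment used throughout the documentation.

#' The worked example alignment
#'
#' A four-sequence, four-site alignment (`s1=ACGT`, `s2=ACGA`, `s3=ATGA`,
#' `s4=ATGA`) with populations `P1 = {s1, s2}` and `P2 = {s3, s4}`, used as
#' a hand-checkable example across the package: it has S = 2, per-locus
#' pi = 7/6, Watterson's theta = 12/11, Tajima's D ~ 0.5916, ZnS = 1/3,
#' Fst = 2/3 and Kst = 4/7.
#'
#' @return list with elements `dataset` (a `proseq_dataset`) and `popmap`.
#' @export
worked_alignment <- function() {
  ds <- dataset(c(s1 = "ACGT", s2 = "ACGA", s3 = "ATGA", s4 = "ATGA"),
                id = "W")
  pm <- popmap(paste0("s", 1:4), paste0("ind", 1:4),
               c("P1", "P1", "P2", "P2"))
  list(dataset = ds, popmap = pm)
}

#' Generate a random alignment with controlled polymorphism
#'
#' Deterministic in `seed`. In exact mode the requested number of biallelic
#' segregating sites is injected at random columns (each with a random
#' minor-allele count), so the alignment has exactly `n_segregating`
#' segregating sites before missing data is added.
#'
#' @param seed integer seed.
#' @param n number of sequences.
#' @param L alignment length.
#' @param n_segregating exact number of segregating sites to inject
#'   (`<= L`).
#' @param missing_prob per-residue probability of replacement by `'N'`.
#' @param fixed_differences optional: number of population-fixed differences
#'   between the first and second half of the sequences (injected at
#'   additional columns).
#' @param names sequence names (default `s1..sn`).
#' @return a `proseq_dataset`.
#' @export
make_alignment <- function(seed, n, L, n_segregating = 0,
                           missing_prob = 0, fixed_differences = 0,
                           names = paste0("s", seq_len(n))) {
  if (n_segregating + fixed_differences > L) {
    stop("more injected sites than alignment columns")
  }
  with_seed(seed, {
    mat <- matrix(rep(sample(.NUC, L, replace = TRUE), each = n), nrow = n)
    rownames(mat) <- names
    cols <- sample.int(L, n_segregating + fixed_differences)
    seg_cols <- cols[seq_len(n_segregating)]
    for (j in seg_cols) {
      alt <- sample(setdiff(.NUC, mat[1, j]), 1)
      k <- sample.int(n - 1, 1)              # minor-allele count, 1..n-1
      mat[sample.int(n, k), j] <- alt
    }
    if (fixed_differences > 0) {
      half <- seq_len(n %/% 2)
      for (j in cols[n_segregating + seq_len(fixed_differences)]) {
        alt <- sample(setdiff(.NUC, mat[1, j]), 1)
        mat[half, j] <- mat[1, j]
        mat[-half, j] <- alt
      }
    }
    if (missing_prob > 0) {
      mask <- matrix(stats::runif(n * L) < missing_prob, n, L)
      mat[mask] <- "N"
    }
    dataset(mat, id = sprintf("sim_seed%d", seed))
  })
}

#' Build a toy multisample VCF (with reference) from an alignment
#'
#' Emits an all-sites, haploid, single-contig VCF whose samples are the
#' alignment's sequences and whose reference is the first sequence; feeding
#' the result back through [vcf_to_fasta()] reproduces the alignment.
#' Optional corner-case records (an indel, a missing genotype, an unphased
#' heterozygous diploid record, a multiallelic record) can be appended for
#' parser tests.
#'
#' @param ds a `proseq_dataset` over A/C/G/T (missing residues become `./.`
#'   genotypes).
#' @param chrom contig name.
#' @param add_indel append one indel record (after the last position).
#' @return list with `vcf` (character lines) and `ref` (FASTA lines).
#' @export
make_toy_vcf <- function(ds, chrom = "chr1", add_indel = FALSE) {
  m <- ds$mat
  L <- ncol(m)
  refseq <- vapply(seq_len(L), function(j) {
    nt <- m[, j][m[, j] %in% .NUC]
    if (length(nt) == 0) "A" else nt[1]
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", chrom, L),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(m)), collapse = "\t"))
  body <- vapply(seq_len(L), function(j) {
    col <- m[, j]
    alleles <- unique(col[col %in% .NUC])
    alleles <- c(refseq[j], setdiff(alleles, refseq[j]))
    alt <- if (length(alleles) > 1) paste(alleles[-1], collapse = ",") else "."
    gts <- vapply(col, function(b) {
      if (!b %in% .NUC) "." else as.character(match(b, alleles) - 1L)
    }, character(1))
    paste(c(chrom, j, ".", refseq[j], alt, ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, character(1))
  if (add_indel) {
    body <- c(body, paste(c(chrom, L + 1L, ".", "A", "AT", ".", "PASS", ".",
                            "GT", rep("0", nrow(m))), collapse = "\t"))
    refseq <- c(refseq, "A")
  }
  list(vcf = c(header, body),
       ref = c(paste0(">", chrom), paste(refseq, collapse = "")))
}

#' Random additive tree and its exact path-length matrix
#'
#' Generates a random binary tree with positive branch lengths and the
#' corresponding tip-to-tip path-length (additive) distance matrix, on which
#' neighbour joining is exact.
#'
#' @param seed integer seed.
#' @param n_tips number of tips, `>= 3`.
#' @return list with `tree` (a `phylo`) and `matrix` (labelled distance
#'   matrix).
#' @export
make_additive_matrix <- function(seed, n_tips) {
  stopifnot(n_tips >= 3)
  with_seed(seed, {
    tr <- ape::rtree(n_tips, rooted = FALSE,
                     br = function(k) stats::runif(k, 0.1, 2))
    dm <- ape::cophenetic.phylo(tr)
    dm <- dm[tr$tip.label, tr$tip.label]
    list(tree = tr, matrix = dm)
  })
}
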