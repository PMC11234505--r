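test_that("auto-linking matches sequences to individuals by name substring", {
  ds <- dataset(c(ind1_locusA = "ACGT", ind2_locusA = "ACGA",
                  foo_x = "AAAA"), id = "locusA")
  pm <- link_sequences(project(list(ds)), c("ind1", "ind2"))
  expect_equal(individual_of(pm, c("ind1_locusA", "ind2_locusA")),
               c("ind1", "ind2"))
  expect_equal(attr(pm, "unlinked"), "foo_x")

  # longest match wins
  ds2 <- dataset(c(sample12_x = "ACGT"), id = "d")
  pm2 <- link_sequences(project(list(ds2)), c("sample1", "sample12"))
  expect_equal(individual_of(pm2, "sample12_x"), "sample12")

  expect_error(link_sequences(project(list(ds)), c("a", "a")), "duplicate")
})

test_that("ambiguous equally-long matches are left unlinked with a warning", {
  ds <- dataset(c(ab_cd = "ACGT"), id = "d")
  expect_warning(pm <- link_sequences(project(list(ds)), c("ab", "cd")),
                 "unlinked")
  expect_equal(attr(pm, "unlinked"), "ab_cd")
})

test_that("sequence transforms follow their definitions", {
  ds <- dataset(c(a = "ACGTN"))
  expect_equal(unname(as_strings(transform_dataset(ds, "reverse_complement"))),
               "NACGT")
  expect_equal(unname(as_strings(transform_dataset(dataset(c(a = "ACGT")),
                                                   "mask", 0, 2))), "NNGT")
  expect_error(transform_dataset(ds, "mask", 3, 9), "out of bounds")
})

test_that("trim remaps coding regions by interval clipping", {
  clip <- function(s, e, lo, hi) {  # independent interval-clipping oracle
    s2 <- max(s, lo); e2 <- min(e, hi)
    if (e2 <= s2) NULL else c(s2 - lo, e2 - lo)
  }
  ds <- dataset(c(a = "ACGT"), coding = list(coding_region(c(0, 4))))
  tr <- transform_dataset(ds, "trim", start = 1, end = 3)
  expect_equal(unname(as_strings(tr)), "CG")
  expect_equal(unname(tr$coding[[1]]$segments[1, ]), clip(0, 4, 1, 3))

  set.seed(11)
  for (rep in 1:20) {
    L <- sample(10:40, 1)
    s <- sample(0:(L - 2), 1); e <- sample((s + 1):L, 1)
    lo <- sample(0:(L - 2), 1); hi <- sample((lo + 1):L, 1)
    ds <- dataset(stats::setNames(paste(sample(c("A", "C", "G", "T"), L,
                                               TRUE), collapse = ""), "x"))
    ds <- suppressWarnings(add_coding_region(ds, coding_region(c(s, e))))
    tr <- suppressWarnings(transform_dataset(ds, "trim", start = lo, end = hi))
    expected <- clip(s, e, lo, hi)
    if (is.null(expected)) {
      expect_length(tr$coding, 0)
    } else {
      expect_equal(unname(tr$coding[[1]]$segments[1, ]), expected)
    }
  }
})

test_that("double reverse complement is the identity", {
  for (seed in 1:10) {
    ds <- random_nuc_alignment(seed, n = 5, L = 30, missing_prob = 0.05)
    back <- transform_dataset(transform_dataset(ds, "reverse_complement"),
                              "reverse_complement")
    expect_identical(back$mat, ds$mat)
  }
})

test_that("translation handles strand, frame, ambiguity and stops", {
  expect_equal(unname(translate(dataset(c(s = "ATGAAATAA")),
                                coding_region(c(0, 9)))), "MK*")
  expect_equal(unname(translate(dataset(c(s = "ATGAANTAA")),
                                coding_region(c(0, 9)))), "MX*")
  # minus strand: reverse complement of TTACATCAT is ATGATGTAA -> MM*
  expect_equal(unname(translate(dataset(c(s = "TTACATCAT")),
                                coding_region(c(0, 9), strand = "-"))), "MM*")
  # frame offset drops leading bases; trailing incomplete codon dropped
  expect_equal(unname(translate(dataset(c(s = "CATGAAATA")),
                                coding_region(c(0, 9), frame = 1))), "MK")
})

test_that("ORF search agrees with a brute-force 6-frame scan", {
  out <- find_orfs("ATGAAATAA", 2)
  expect_equal(nrow(out), 1)
  expect_equal(out$frame, 1)
  expect_equal(c(out$start, out$end), c(0, 9))
  expect_equal(nrow(find_orfs("CCCCCC", 1)), 0)

  set.seed(4)
  for (rep in 1:15) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    minaa <- sample(1:5, 1)
    expect_equal(find_orfs(s, minaa), oracle_orfs(s, minaa))
  }
})

test_that("site filtering drops the right columns", {
  ds <- dataset(c(a = "AC-T", b = "ACGT"))
  expect_equal(unname(as_strings(filter_sites(ds, drop_gap_sites = TRUE))),
               c("ACT", "ACT"))

  cds <- dataset(c(a = "ATGAAATAA", b = "ATGAAATAA"),
                 coding = list(coding_region(c(0, 9))))
  kept <- filter_sites(cds, drop_codon_positions = c(1, 2))
  expect_equal(n_sites(kept), 3)

  expect_error(filter_sites(dataset(c(a = "ACGT", b = "ACGT")),
                            drop_codon_positions = 3),
               "coding region")
  # all filters off is the identity
  expect_identical(filter_sites(ds)$mat, ds$mat)
})

test_that("site filtering equals an independent per-column predicate scan", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(3:8, 1); L <- sample(12:60, 1)
    ds <- random_nuc_alignment(rep + 100, n, L, missing_prob = 0.08)
    m <- ds$mat
    m[1, sample(L, 2)] <- "-"
    ds <- dataset(m, id = ds$id)
    out <- filter_sites(ds, drop_gap_sites = TRUE, drop_missing_sites = TRUE)
    keep <- vapply(seq_len(L), function(j) {
      col <- ds$mat[, j]
      !any(col == "-") && !any(col %in% c("N", "?"))
    }, logical(1))
    expect_identical(out$mat, ds$mat[, keep, drop = FALSE])
    expect_lte(n_sites(out), n_sites(ds))
  }
})

test_that("codon-position filter keeps floor(L/3) third positions", {
  for (ncod in c(3, 5, 8)) {
    L <- ncod * 3
    seqs <- paste(rep("ATG", ncod), collapse = "")
    ds <- dataset(c(a = seqs, b = seqs),
                  coding = list(coding_region(c(0, L))))
    expect_equal(n_sites(filter_sites(ds, drop_codon_positions = c(1, 2))),
                 L %/% 3)
  }
})

test_that("QC report flags premature stops and counts missingness", {
  good <- dataset(c(a = "ATGAAATAA"), id = "good",
                  coding = list(coding_region(c(0, 9))))
  bad <- dataset(c(a = "ATGTAATAA"), id = "bad",
                 coding = list(coding_region(c(0, 9))))
  qc <- qc_report(project(list(good, bad)))
  expect_equal(qc$coding_regions$has_premature_stop,
               c(FALSE, TRUE))
  expect_equal(qc$coding_regions$length_mod3, c(0L, 0L))

  ds <- dataset(c(x1 = "ANNN", x2 = "ACGT"), id = "d")
  pm <- popmap(c("x1", "x2"), c("ind1", "ind1"), c("P", "P"))
  qc2 <- qc_report(project(list(ds), pm))
  expect_equal(qc2$individuals$fraction_missing[
    qc2$individuals$individual == "ind1"], 3 / 8)
})

test_that("QC fractions are invariant under sequence reordering", {
  ds <- random_nuc_alignment(77, 6, 40, missing_prob = 0.1)
  perm <- sample(n_seqs(ds))
  ds2 <- dataset(ds$mat[perm, , drop = FALSE], id = ds$id)
  q1 <- qc_report(project(list(ds)))$datasets
  q2 <- qc_report(project(list(ds2)))$datasets
  expect_equal(q1$fraction_missing, q2$fraction_missing)
  expect_equal(q1$n_segregating, q2$n_segregating)
})
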