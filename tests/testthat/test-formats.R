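test_that("FASTA and FASTQ alignments are read and validated", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">b", "ACGA"), fa)
  ds <- read_alignment(fa)
  expect_equal(n_seqs(ds), 2)
  expect_equal(n_sites(ds), 4)

  fq <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
  dq <- read_alignment(fq)
  expect_equal(unname(as_strings(dq)), "ACGT")
  # mean-quality filter drops low-quality records
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGA", "+", "!!!!"), fq)
  expect_equal(n_seqs(read_alignment(fq, min_mean_quality = 20)), 1)

  writeLines(c(">a", "ACGT", ">b", "AC"), fa)
  expect_error(read_alignment(fa), "unequal")
  padded <- read_alignment(fa, pad_with_missing = TRUE)
  expect_equal(unname(as_strings(padded)), c("ACGT", "ACNN"))

  writeLines(c(">a", "ACGT", ">a", "ACGA"), fa)
  expect_error(read_alignment(fa), "duplicate")
  writeLines(character(0), fa)
  expect_error(read_alignment(fa), "empty")
})

test_that("U is normalized to T and case is folded on load", {
  ds <- dataset(c(a = "acgu"))
  expect_equal(unname(as_strings(ds)), "ACGT")
  expect_error(dataset(c(a = "ACGZ")), "invalid residue")
})

test_that("annotation coordinate conventions convert to 0-based half-open", {
  gff <- tempfile(fileext = ".gff")
  writeLines(c("##gff-version 3",
               paste("locus1", "src", "CDS", "1", "9", ".", "+", "0",
                     "ID=cds1", sep = "\t")), gff)
  a <- read_annotation(gff)
  expect_equal(c(a$start, a$end), c(0, 9))

  bed <- tempfile(fileext = ".bed")
  writeLines("locus1\t0\t9\tfeat1\t0\t+", bed)
  b <- read_annotation(bed)
  expect_equal(c(b$start, b$end), c(0, 9))

  csv <- tempfile(fileext = ".csv")
  writeLines(c("target,start,end,strand,frame", "locus1,4,9,+,0"), csv)
  cc <- read_annotation(csv)
  expect_equal(c(cc$start, cc$end), c(3, 9))
})

test_that("multi-segment CDS records sharing an ID are spliced when bound", {
  gff <- tempfile(fileext = ".gff")
  writeLines(c("##gff-version 3",
               paste("locus1", "src", "CDS", "1", "3", ".", "+", "0",
                     "ID=cdsA", sep = "\t"),
               paste("locus1", "src", "CDS", "7", "9", ".", "+", "0",
                     "ID=cdsA", sep = "\t")), gff)
  ds <- dataset(c(s = "ATGCCCTAA"), id = "locus1")
  ds <- bind_annotation(ds, read_annotation(gff))
  expect_length(ds$coding, 1)
  expect_equal(nrow(ds$coding[[1]]$segments), 2)
  expect_equal(unname(translate(ds, ds$coding[[1]])), "M*")
  # out-of-range records are reported, not fatal
  writeLines(c("##gff-version 3",
               paste("locus1", "src", "CDS", "1", "99", ".", "+", "0",
                     "ID=far", sep = "\t")), gff)
  expect_warning(out <- bind_annotation(ds, read_annotation(gff)), "skipped")
  expect_length(out$coding, 1)
})

test_that("popmap files round-trip and report parse errors with line numbers", {
  f <- tempfile(fileext = ".s2i")
  writeLines("s1\tind1\tpopA", f)
  pm <- read_popmap(f)
  expect_equal(population_of(pm, "s1"), "popA")

  writeLines(c("# only", "# comments"), f)
  expect_equal(nrow(read_popmap(f)), 0)

  writeLines("s1\tind1", f)
  expect_error(read_popmap(f), "line 1")

  big <- popmap(sprintf("seq%03d", 1:100), sprintf("ind%03d", 1:100),
                sprintf("pop%d", (0:99) %/% 10 + 1))
  write_popmap(big, f)
  back <- read_popmap(f)
  expect_equal(as.data.frame(back), as.data.frame(big))
})

test_that("newick parsing handles the brackets format, errors and round-trips", {
  trees <- parse_newick("((A,B),C);")
  expect_length(trees, 1)
  expect_setequal(trees[[1]]$tip.label, c("A", "B", "C"))

  expect_identical(write_newick(parse_newick("((A:1,B:2):0.5,C:3);")[[1]]),
                   "((A:1,B:2):0.5,C:3);")
  expect_error(parse_newick("((A,B;"), "parse error")
  expect_length(parse_newick("((A,B),C);((A,C),B);"), 2)
})

test_that("newick round-trip preserves topology and branch lengths", {
  skip_if_not_installed("phangorn")
  set.seed(31)
  for (ntip in c(5, 16, 64)) {
    tr <- ape::rtree(ntip)
    back <- parse_newick(write_newick(tr))[[1]]
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(back)), 0)
    expect_equal(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label],
                 ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
                 tolerance = 1e-8)
  }
})

test_that("fasta write-read is the identity on random alignments", {
  for (seed in 1:5) {
    ds <- random_nuc_alignment(seed, n = 6, L = 150, missing_prob = 0.05)
    f <- tempfile(fileext = ".fa")
    write_alignment(ds, f)
    expect_identical(read_alignment(f, id = ds$id)$mat, ds$mat)
  }
})

test_that("exports follow the documented dialects on the worked alignment", {
  ds <- worked$dataset
  ph <- export_dataset(ds, "phylip")
  expect_equal(ph[1], "4 4")
  expect_match(ph[2], "^s1 ACGT$")

  nx <- export_dataset(ds, "nexus")
  expect_true(any(grepl("NTAX=4 NCHAR=4", nx)))

  mg <- export_dataset(ds, "mega")
  expect_equal(mg[1], "#mega")
  expect_true("#s1" %in% mg)

  st <- export_dataset(ds, "structure")
  expect_equal(st[1], "s1 2 4")

  sw <- export_dataset(ds, "sweepfinder", folded = TRUE)
  expect_equal(sw[1], "position\tx\tn\tfolded")
  expect_equal(sw[-1], c("2\t2\t4\t1", "4\t1\t4\t1"))

  sfs <- export_dataset(ds, "sfs", folded = TRUE)
  expect_equal(sfs, "0 1 1")

  expect_error(export_dataset(dataset(c(a = "AAAA", b = "AAAA")),
                              "structure"), "biallelic")
  expect_error(export_dataset(ds, "sfs", folded = FALSE), "outgroup")
})

test_that("unfolded exports polarize by the outgroup", {
  ds <- dataset(c(s1 = "AAT", s2 = "AAT", s3 = "ACT", og = "ACA"))
  # site 2: og allele C; derived A has count 2 of 3. site 3: og A, derived T x3
  # is not segregating within the ingroup -> only site 2 both biallelic
  sw <- export_dataset(ds, "sweepfinder", folded = FALSE, outgroup = "og")
  expect_equal(sw[-1], "2\t2\t3\t0")
  sfs <- export_dataset(ds, "sfs", folded = FALSE, outgroup = "og")
  expect_equal(sfs, "0 0 1 0")
})

test_that("SFS vector sums to the number of exported SNPs", {
  for (seed in 1:5) {
    ds <- random_nuc_alignment(seed + 40, n = 8, L = 60, nseg = 10)
    sfs <- as.integer(strsplit(export_dataset(ds, "sfs", folded = TRUE),
                               " ")[[1]])
    snp <- sum(apply(ds$mat, 2, function(col) {
      length(unique(col[col %in% NUC])) == 2
    }))
    expect_equal(sum(sfs), snp)
  }
})

test_that("project manifests list member alignments", {
  d <- tempfile(); dir.create(d)
  write_alignment(worked$dataset, file.path(d, "W.fa"))
  write_alignment(random_nuc_alignment(2, 4, 10), file.path(d, "x.fa"))
  manifest <- file.path(d, "project.txt")
  writeLines(c("# project members", "W.fa", "x.fa"), manifest)
  prj <- read_project(manifest)
  expect_length(prj$datasets, 2)
  expect_equal(prj$datasets[[1]]$mat, worked$dataset$mat)
})
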