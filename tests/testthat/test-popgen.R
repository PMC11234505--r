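test_that("diversity reproduces the hand-enumerated worked-alignment values", {
  golden <- read_golden()
  d <- diversity(worked$dataset)
  expect_equal(d$S, unname(golden["S"]))
  expect_equal(d$pi_per_locus, unname(golden["pi_locus"]), tolerance = 1e-9)
  expect_equal(d$theta_w_per_locus, unname(golden["theta_w_locus"]),
               tolerance = 1e-9)
  expect_equal(d$tajimas_D, unname(golden["tajimas_D"]), tolerance = 1e-7)
  expect_equal(d$znS, unname(golden["znS"]), tolerance = 1e-9)
  # both missing-data policies agree on a complete alignment
  dc <- diversity(worked$dataset, "complete")
  expect_equal(dc$pi_per_locus, d$pi_per_locus)
})

test_that("diversity handles degenerate inputs", {
  mono <- dataset(c(a = "AAAA", b = "AAAA", c = "AAAA"))
  d <- diversity(mono)
  expect_equal(d$S, 0)
  expect_equal(d$pi_per_locus, 0)
  expect_true(is.na(d$tajimas_D))
  expect_error(diversity(dataset(c(a = "ACGT"))), "2 sequences")

  # duplicating every sequence cannot create segregating sites
  m <- worked$dataset$mat[rep(1:4, 2), , drop = FALSE]
  rownames(m) <- paste0("s", 1:8)
  expect_equal(diversity(dataset(m))$S, 2)
})

test_that("pi and S match brute-force oracles on random alignments", {
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(3:12, 1); L <- sample(20:120, 1)
    ds <- random_nuc_alignment(rep + 300, n, L)
    d <- diversity(ds)
    expect_equal(d$pi_per_locus, oracle_pi(ds$mat), tolerance = 1e-10)
    expect_equal(d$S, oracle_S(ds$mat))
  }
})

test_that("Tajima's D sign equals sign(pi - theta) whenever defined", {
  set.seed(6)
  for (rep in 1:20) {
    ds <- random_nuc_alignment(rep + 500, sample(4:10, 1), 80)
    d <- diversity(ds)
    if (!is.na(d$tajimas_D) && d$pi_per_locus != d$theta_w_per_locus) {
      expect_equal(sign(d$tajimas_D),
                   sign(d$pi_per_locus - d$theta_w_per_locus))
    }
  }
})

test_that("per-site policy uses non-missing allele counts", {
  # column 1: A A N N -> m=2, monomorphic; column 2: A C N C -> m=3, h=4/3*...
  ds <- dataset(c(a = "AA", b = "AC", c = "NN", d = "NC"))
  d <- diversity(ds, "per_site")
  expect_equal(d$S, 1)
  expect_equal(d$pi_per_locus, 3 / 2 * (1 - (1 / 9 + 4 / 9)), tolerance = 1e-12)
  dc <- diversity(ds, "complete")
  expect_equal(dc$sites_used, 0)
  expect_equal(dc$pi_per_locus, 0)
})

test_that("sliding windows tile the alignment as documented", {
  ds <- random_nuc_alignment(8, 4, 10)
  sw <- sliding_window(ds, 4, 3)
  expect_equal(sw$start, c(0, 3, 6))
  expect_equal(sw$end, c(4, 7, 10))

  uni <- dataset(c(a = strrep("A", 12), b = strrep("A", 12)))
  expect_true(all(sliding_window(uni, 4, 4)$S == 0))

  # uncovered tail yields one final partial window
  ds11 <- random_nuc_alignment(9, 4, 11)
  sw11 <- sliding_window(ds11, 4, 3)
  expect_equal(sw11$start, c(0, 3, 6, 9))
  expect_equal(sw11$end[4], 11)

  expect_warning(sw1 <- sliding_window(ds, 99, 1), "single")
  expect_equal(nrow(sw1), 1)
})

test_that("window statistics equal direct recomputation on the slice", {
  ds <- random_nuc_alignment(10, 6, 60, nseg = 12)
  sw <- sliding_window(ds, 20, 10)
  for (i in seq_len(nrow(sw))) {
    slice <- ds$mat[, (sw$start[i] + 1):sw$end[i], drop = FALSE]
    d <- diversity(slice)
    expect_equal(sw$S[i], d$S)
    expect_equal(sw$pi_per_site[i], d$pi_per_locus / ncol(slice))
  }
})

test_that("pi rises across the boundary between monomorphic and polymorphic halves", {
  mono <- matrix("A", 6, 30, dimnames = list(paste0("s", 1:6), NULL))
  poly <- random_nuc_alignment(13, 6, 30, nseg = 15)$mat
  ds <- dataset(cbind(mono, poly))
  sw <- sliding_window(ds, 30, 15)
  # windows [0,30) all-mono, [15,45) mixed, [30,60) all-poly
  expect_equal(sw$pi_per_site[1], 0)
  expect_true(all(diff(sw$pi_per_site) >= 0))
  expect_gt(sw$pi_per_site[3], 0)
})

test_that("Nei-Gojobori site counts and site classes are correct", {
  # consensus codon TTT: 1/3 synonymous sites (third position), 8/3 nonsyn
  ds <- dataset(c(a = "TTT", b = "TTT"), coding = list(coding_region(c(0, 3))))
  sn <- silent_nonsilent(ds)
  expect_equal(sn$counts$syn_sites, 1 / 3, tolerance = 1e-12)
  expect_equal(sn$counts$nonsyn_sites, 8 / 3, tolerance = 1e-12)

  # third-position TTT<->TTC polymorphism is synonymous (both Phe)
  syn <- dataset(c(a = "TTT", b = "TTC"), coding = list(coding_region(c(0, 3))))
  out <- silent_nonsilent(syn)
  expect_equal(out$silent$S, 1)
  expect_equal(out$nonsilent$S, 0)

  # ATG<->ACG is nonsynonymous (Met -> Thr)
  nonsyn <- dataset(c(a = "ATG", b = "ACG"),
                    coding = list(coding_region(c(0, 3))))
  out2 <- silent_nonsilent(nonsyn)
  expect_equal(out2$nonsilent$S, 1)
  expect_equal(out2$silent$S, 0)
})

test_that("silent and nonsilent fractional site counts sum per codon", {
  set.seed(14)
  for (rep in 1:8) {
    ncod <- sample(3:8, 1)
    ds <- random_nuc_alignment(rep + 700, 4, ncod * 3 + 4)
    ds <- add_coding_region(ds, coding_region(c(0, ncod * 3)))
    sn <- silent_nonsilent(ds)
    # no gaps injected, so every coding column counts
    expect_equal(sn$counts$syn_sites + sn$counts$nonsyn_sites,
                 ncod * 3, tolerance = 1e-9)
    expect_equal(sn$counts$noncoding_sites, 4)
  }
})

test_that("codon columns containing gaps are excluded and counted", {
  ds <- dataset(c(a = "AT-AAA", b = "ATGAAA"),
                coding = list(coding_region(c(0, 6))))
  sn <- silent_nonsilent(ds)
  expect_equal(sn$counts$excluded_codons, 1)
  expect_equal(sn$counts$syn_sites + sn$counts$nonsyn_sites, 3)
})

test_that("subdivision reproduces the worked-alignment values", {
  golden <- read_golden()
  sb <- subdivision(worked$dataset, worked$popmap, "P1", "P2")
  expect_equal(sb$Hw, 0.5)
  expect_equal(sb$Hb, 1.5)
  expect_equal(sb$Fst, unname(golden["Fst"]), tolerance = 1e-9)
  expect_equal(sb$Ks, 0.5)
  expect_equal(sb$Kt, 7 / 6, tolerance = 1e-12)
  expect_equal(sb$Kst, unname(golden["Kst"]), tolerance = 1e-9)
  expect_equal(sb$n_fixed, unname(golden["n_fixed"]))
  expect_equal(sb$n_shared, unname(golden["n_shared"]))
  expect_equal(sb$n_private_1, unname(golden["n_private_1"]))
  expect_equal(sb$n_private_2, unname(golden["n_private_2"]))
})

test_that("subdivision handles degenerate and symmetric cases", {
  ident <- dataset(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"))
  pm <- popmap(letters[1:4], letters[1:4], c("X", "X", "Y", "Y"))
  sb <- subdivision(ident, pm, "X", "Y")
  expect_true(is.na(sb$Fst))

  # swapping population labels flips only the private counts
  s1 <- subdivision(worked$dataset, worked$popmap, "P1", "P2")
  s2 <- subdivision(worked$dataset, worked$popmap, "P2", "P1")
  expect_equal(s1$Fst, s2$Fst)
  expect_equal(s1$Kst, s2$Kst)
  expect_equal(s1$n_private_1, s2$n_private_2)

  expect_error(subdivision(worked$dataset, worked$popmap, "P1", "nope"),
               ">= 2 sequences")
})

test_that("random halves of a panmictic sample give Fst centred near zero", {
  set.seed(15)
  ds <- random_nuc_alignment(16, 10, 100, nseg = 20)
  nm <- seq_names(ds)
  fsts <- replicate(60, {
    split <- sample(10, 5)
    pop <- rep("B", 10); pop[split] <- "A"
    sb <- subdivision(ds, popmap(nm, nm, pop), "A", "B")
    sb$Fst
  })
  expect_lt(abs(mean(fsts, na.rm = TRUE)), 0.15)
})

test_that("exhaustive permutation p-values equal enumeration tail probabilities", {
  pt <- permutation_test(worked$dataset, worked$popmap, "P1", "P2", "Kst",
                         n_perm = 999)
  expect_equal(pt$method, "exhaustive")
  expect_equal(pt$n_used, 3)
  # independent enumeration through subdivision() relabelings
  or <- oracle_perm_p(worked$dataset, 2)
  obs <- subdivision(worked$dataset, worked$popmap, "P1", "P2")$Kst
  expect_equal(pt$p_value, mean(or$values >= obs - 1e-12))

  # exhaustive mode ignores the seed
  p1 <- permutation_test(worked$dataset, worked$popmap, "P1", "P2",
                         n_perm = 999, seed = 1)$p_value
  p2 <- permutation_test(worked$dataset, worked$popmap, "P1", "P2",
                         n_perm = 999, seed = 999)$p_value
  expect_identical(p1, p2)
})

test_that("permutation test reports undefined observed statistics", {
  ident <- dataset(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"))
  pm <- popmap(letters[1:4], letters[1:4], c("X", "X", "Y", "Y"))
  pt <- permutation_test(ident, pm, "X", "Y")
  expect_true(is.na(pt$p_value))
  expect_match(pt$status, "undefined")
})

test_that("clearly diverged populations give the minimal sampled p-value", {
  ds <- make_alignment(17, 20, 120, n_segregating = 5, fixed_differences = 50)
  nm <- seq_names(ds)
  pm <- popmap(nm, nm, rep(c("A", "B"), each = 10))
  pt <- permutation_test(ds, pm, "A", "B", "Kst", n_perm = 199, seed = 2)
  expect_equal(pt$method, "sampled")
  expect_equal(pt$p_value, 1 / 200)
})
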