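# Diversity and subdivision statistics. Throughout, only A/C/G/T are treated
# as observed alleles: gaps, 'N', '?' and IUPAC ambiguity codes are missing
# for statistical purposes.

.NUC <- c("A", "C", "G", "T")

# Evaluate an expression with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards. seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Tajima (1989) variance coefficients
#'
#' The constants a1, a2, b1, b2, c1, c2, e1, e2 used to normalize the
#' difference between nucleotide diversity and Watterson's theta.
#'
#' @param n sample size (number of sequences), `>= 2`.
#' @return named numeric vector.
#' @export
tajima_coefficients <- function(n) {
  stopifnot(n >= 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  c(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

# Per-site allele counts: 4 x L matrix of A/C/G/T counts per column.
allele_counts <- function(m) {
  out <- matrix(0L, 4L, ncol(m), dimnames = list(.NUC, NULL))
  for (b in .NUC) out[b, ] <- colSums(m == b)
  out
}

# Unbiased per-site heterozygosity h = m/(m-1) (1 - sum p^2) from a count
# vector; NA when fewer than 2 non-missing alleles.
site_h <- function(cnt) {
  m <- sum(cnt)
  if (m < 2) return(NA_real_)
  p <- cnt / m
  m / (m - 1) * (1 - sum(p^2))
}

#' DNA polymorphism summary statistics
#'
#' Computes the segregating-site count S, nucleotide diversity pi (per locus
#' and per site), Watterson's theta, Tajima's D and Kelly's ZnS for one
#' alignment.
#'
#' Under `missing_policy = "complete"` every column containing a gap,
#' missing symbol or ambiguity code is discarded and statistics use the
#' nominal sample size n. Under `"per_site"` each site is summarized from its
#' non-missing alleles: site heterozygosity `h = m/(m-1) (1 - sum p_a^2)`
#' with `m` non-missing alleles (sites with `m < 2` are skipped) and
#' `pi_locus = sum h`. In both policies S counts sites with at least two
#' distinct non-missing nucleotides, `theta_W = S / a1` with
#' `a1 = sum_{i=1}^{n-1} 1/i`, and Tajima's
#' `D = (pi_locus - theta_locus) / sqrt(e1 S + e2 S (S-1))` with the variance
#' coefficients evaluated at the nominal n. D is `NA` when `S = 0` or
#' `n < 3`. ZnS is the mean of `r^2` over all pairs of biallelic segregating
#' sites with no missing data, `NA` when fewer than two such sites exist.
#'
#' @param ds a `proseq_dataset` (or residue character matrix).
#' @param missing_policy `"per_site"` (default) or `"complete"`.
#' @return an object of class `proseq_diversity`: list with elements `n`,
#'   `sites_used`, `S`, `pi_per_locus`, `pi_per_site`, `theta_w_per_locus`,
#'   `theta_w_per_site`, `tajimas_D`, `znS`, `missing_policy`.
#' @examples
#' ds <- dataset(c(s1 = "ACGT", s2 = "ACGA", s3 = "ATGA", s4 = "ATGA"))
#' diversity(ds)
#' @export
diversity <- function(ds, missing_policy = c("per_site", "complete")) {
  missing_policy <- match.arg(missing_policy)
  m <- if (inherits(ds, "proseq_dataset")) ds$mat else ds
  n <- nrow(m)
  if (n < 2) stop("diversity requires at least 2 sequences")

  cnt <- allele_counts(m)

  if (missing_policy == "complete") {
    clean <- colSums(cnt) == n
    cnt_used <- cnt[, clean, drop = FALSE]
    sites_used <- sum(clean)
  } else {
    usable <- colSums(cnt) >= 2
    cnt_used <- cnt[, usable, drop = FALSE]
    sites_used <- sum(usable)
  }

  if (ncol(cnt_used)) {
    S <- sum(colSums(cnt_used > 0) >= 2)
    mm <- colSums(cnt_used)
    p2 <- colSums((cnt_used / rep(mm, each = 4))^2)
    pi_locus <- sum((mm / (mm - 1) * (1 - p2))[mm >= 2])
  } else {
    S <- 0L; pi_locus <- 0
  }

  coefs <- tajima_coefficients(n)
  theta_locus <- S / coefs[["a1"]]

  D <- NA_real_
  if (S > 0 && n >= 3) {
    v <- coefs[["e1"]] * S + coefs[["e2"]] * S * (S - 1)
    D <- (pi_locus - theta_locus) / sqrt(v)
  }

  znS <- kelly_znS(m, cnt)

  structure(list(
    n = n, sites_used = sites_used, S = as.integer(S),
    pi_per_locus = pi_locus,
    pi_per_site = if (sites_used > 0) pi_locus / sites_used else NA_real_,
    theta_w_per_locus = theta_locus,
    theta_w_per_site = if (sites_used > 0) theta_locus / sites_used else NA_real_,
    tajimas_D = D, znS = znS, missing_policy = missing_policy),
    class = "proseq_diversity")
}

#' @export
print.proseq_diversity <- function(x, ...) {
  cat(sprintf(paste0("<proseq_diversity> n=%d sites=%d S=%d pi=%.5f ",
                     "theta_W=%.5f D=%s ZnS=%s [%s]\n"),
              x$n, x$sites_used, x$S, x$pi_per_locus, x$theta_w_per_locus,
              ifelse(is.na(x$tajimas_D), "NA", sprintf("%.4f", x$tajimas_D)),
              ifelse(is.na(x$znS), "NA", sprintf("%.4f", x$znS)),
              x$missing_policy))
  invisible(x)
}

# Kelly's ZnS: mean r^2 over all pairs of biallelic segregating sites with no
# missing data (every sequence carries A/C/G/T at both sites).
kelly_znS <- function(m, cnt = allele_counts(m)) {
  n <- nrow(m)
  idx <- which(colSums(cnt) == n & colSums(cnt > 0) == 2)
  if (length(idx) < 2) return(NA_real_)
  # indicator of the alphabetically first allele at each usable site
  first <- .NUC[apply(cnt[, idx, drop = FALSE] > 0, 2, which.max)]
  X <- m[, idx, drop = FALSE] == rep(first, each = n)
  p <- colMeans(X)
  pAB <- crossprod(X) / n
  Dab <- pAB - outer(p, p)
  denom <- outer(p * (1 - p), p * (1 - p))
  r2 <- Dab^2 / denom
  mean(r2[upper.tri(r2)])
}

#' Sliding-window polymorphism scan over an alignment
#'
#' Windows tile the alignment columns from 0 in steps of `step`; every full
#' window (`start + window <= L`) is emitted, plus one final partial window
#' when the full windows leave a tail of columns uncovered. Statistics are
#' those of [diversity()] on the column slice.
#'
#' @param ds a `proseq_dataset`.
#' @param window,step window width and step in alignment columns,
#'   `window >= step >= 1`.
#' @param missing_policy passed to [diversity()].
#' @return data.frame with columns `start`, `end`, `midpoint`, `n_sites`,
#'   `S`, `pi_per_site`, `theta_per_site`, `tajimas_D`.
#' @export
sliding_window <- function(ds, window, step,
                           missing_policy = c("per_site", "complete")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(step >= 1, window >= step)
  L <- n_sites(ds)
  if (window > L) {
    warning("window larger than alignment; using a single full-length window")
    window <- L
  }
  bounds <- window_bounds(L, window, step)
  rows <- lapply(seq_len(nrow(bounds)), function(i) {
    s <- unname(bounds[i, 1]); e <- unname(bounds[i, 2])
    d <- diversity(ds$mat[, seq.int(s + 1L, e), drop = FALSE], missing_policy)
    data.frame(start = s, end = e, midpoint = (s + e) / 2,
               n_sites = e - s, S = d$S,
               pi_per_site = d$pi_per_locus / (e - s),
               theta_per_site = d$theta_w_per_locus / (e - s),
               tajimas_D = d$tajimas_D)
  })
  do.call(rbind, rows)
}

# Tiling shared by alignment and VCF scans: all full windows, plus one final
# partial window only when the tail [.,L) is not already covered.
window_bounds <- function(L, window, step) {
  starts <- seq.int(0L, max(0L, L - 1L), by = step)
  full <- starts[starts + window <= L]
  if (length(full) == 0) full <- 0L
  ends <- pmin(full + window, L)
  last_end <- max(ends)
  if (last_end < L) {
    nxt <- full[length(full)] + step
    full <- c(full, nxt)
    ends <- c(ends, L)
  }
  cbind(start = full, end = ends)
}

#' Population subdivision statistics for a pair of populations
#'
#' Computes Hudson-style differentiation summaries from pairwise sequence
#' difference counts: `Hw` (unweighted mean of the two within-population
#' means), `Hb` (between-population mean), `Fst = 1 - Hw/Hb`; `Ks`
#' (sample-size-weighted within diversity), `Kt` (pooled mean pairwise
#' differences), `Kst = 1 - Ks/Kt`; and the classification of biallelic
#' pooled-segregating sites into fixed, shared and private categories.
#' Pairwise differences are counted over sites where both sequences carry an
#' unambiguous nucleotide.
#'
#' @param ds a `proseq_dataset`.
#' @param pm a `proseq_popmap`.
#' @param pop_a,pop_b population names, each with `>= 2` sequences in `ds`.
#' @return an object of class `proseq_subdivision`: list with `Hw`, `Hb`,
#'   `Fst`, `Ks`, `Kt`, `Kst`, `n_fixed`, `n_shared`, `n_private_1`,
#'   `n_private_2`, `n_multiallelic_excluded`, `pops`, `n_a`, `n_b`.
#' @examples
#' ds <- dataset(c(s1 = "ACGT", s2 = "ACGA", s3 = "ATGA", s4 = "ATGA"))
#' pm <- popmap(c("s1", "s2", "s3", "s4"), paste0("i", 1:4),
#'              c("P1", "P1", "P2", "P2"))
#' subdivision(ds, pm, "P1", "P2")
#' @export
subdivision <- function(ds, pm, pop_a, pop_b) {
  pops <- population_of(pm, seq_names(ds))
  ia <- which(pops == pop_a); ib <- which(pops == pop_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("each population needs >= 2 sequences in the dataset")
  }
  m <- ds$mat[c(ia, ib), , drop = FALSE]
  na <- length(ia); nb <- length(ib); n <- na + nb
  a_idx <- seq_len(na); b_idx <- na + seq_len(nb)

  dmat <- pairwise_diff_matrix(m)
  mean_pairs <- function(idx) {
    if (length(idx) < 2) return(NA_real_)
    mean(dmat[t(utils::combn(idx, 2))])
  }
  Ka <- mean_pairs(a_idx); Kb <- mean_pairs(b_idx)
  Hw <- (Ka + Kb) / 2
  Hb <- mean(dmat[a_idx, b_idx])
  Fst <- if (Hb > 0) 1 - Hw / Hb else NA_real_
  Ks <- (na * Ka + nb * Kb) / n
  Kt <- mean_pairs(seq_len(n))
  Kst <- if (Kt > 0) 1 - Ks / Kt else NA_real_

  n_fixed <- n_shared <- n_priv1 <- n_priv2 <- n_multi <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    obs <- col[col %in% .NUC]
    al <- unique(obs)
    if (length(al) < 2) next
    if (length(al) > 2) { n_multi <- n_multi + 1L; next }
    aa <- unique(col[a_idx][col[a_idx] %in% .NUC])
    ab <- unique(col[b_idx][col[b_idx] %in% .NUC])
    poly_a <- length(aa) >= 2; poly_b <- length(ab) >= 2
    if (length(intersect(aa, ab)) == 0 && length(aa) && length(ab)) {
      n_fixed <- n_fixed + 1L
    } else if (poly_a && poly_b) {
      n_shared <- n_shared + 1L
    } else if (poly_a) {
      n_priv1 <- n_priv1 + 1L
    } else if (poly_b) {
      n_priv2 <- n_priv2 + 1L
    }
  }

  structure(list(Hw = Hw, Hb = Hb, Fst = Fst, Ks = Ks, Kt = Kt, Kst = Kst,
                 n_fixed = n_fixed, n_shared = n_shared,
                 n_private_1 = n_priv1, n_private_2 = n_priv2,
                 n_multiallelic_excluded = n_multi,
                 pops = c(pop_a, pop_b), n_a = na, n_b = nb),
            class = "proseq_subdivision")
}

#' @export
print.proseq_subdivision <- function(x, ...) {
  cat(sprintf("<proseq_subdivision> %s (n=%d) vs %s (n=%d)\n",
              x$pops[1], x$n_a, x$pops[2], x$n_b))
  cat(sprintf("  Hw=%.4f Hb=%.4f Fst=%s | Ks=%.4f Kt=%.4f Kst=%s\n",
              x$Hw, x$Hb, ifelse(is.na(x$Fst), "NA", sprintf("%.4f", x$Fst)),
              x$Ks, x$Kt, ifelse(is.na(x$Kst), "NA", sprintf("%.4f", x$Kst))))
  cat(sprintf("  fixed=%d shared=%d private_1=%d private_2=%d\n",
              x$n_fixed, x$n_shared, x$n_private_1, x$n_private_2))
  invisible(x)
}

# n x n matrix of pairwise raw difference counts over sites where both
# sequences carry an unambiguous nucleotide.
pairwise_diff_matrix <- function(m) {
  n <- nrow(m)
  isnuc <- matrix(m %in% .NUC, nrow = n)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      both <- isnuc[i, ] & isnuc[j, ]
      d[i, j] <- d[j, i] <- sum(m[i, both] != m[j, both])
    }
  }
  d
}

#' Permutation test for population differentiation
#'
#' Tests the observed Kst or Fst between two populations by randomly
#' reassigning sequences to populations holding the sample sizes fixed. When
#' the number of distinct (unordered) splits is at most `n_perm`, all splits
#' are enumerated and the p-value is the exact tail probability (fraction of
#' splits, the observed one included, whose statistic is at least the
#' observed value); otherwise `n_perm` random permutations are drawn and
#' `p = (1 + #(permuted >= observed)) / (1 + n_perm)`.
#'
#' @param ds a `proseq_dataset`.
#' @param pm a `proseq_popmap`.
#' @param pop_a,pop_b population names.
#' @param statistic `"Kst"` (default) or `"Fst"`.
#' @param n_perm number of random permutations, `>= 1`.
#' @param seed optional integer fixing the shuffle stream (ignored when the
#'   test is exhaustive).
#' @return list with `p_value`, `observed`, `statistic`, `method`
#'   (`"exhaustive"` or `"sampled"`), `n_used` (splits enumerated or
#'   permutations drawn) and `status` (`"ok"` or an explanation when the
#'   observed statistic is undefined).
#' @export
permutation_test <- function(ds, pm, pop_a, pop_b,
                             statistic = c("Kst", "Fst"),
                             n_perm = 999L, seed = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(n_perm >= 1)
  pops <- population_of(pm, seq_names(ds))
  idx <- which(pops %in% c(pop_a, pop_b))
  sub <- ds$mat[idx, , drop = FALSE]
  grp <- pops[idx]
  na <- sum(grp == pop_a); nb <- sum(grp == pop_b)
  if (na < 2 || nb < 2) stop("each population needs >= 2 sequences")
  n <- na + nb

  # Permutations only relabel sequences, so the pairwise-difference matrix is
  # computed once and the statistic re-derived from it per split.
  dmat <- pairwise_diff_matrix(sub)
  Kt <- mean(dmat[t(utils::combn(n, 2))])
  stat_for <- function(a_rows) {
    b_rows <- setdiff(seq_len(n), a_rows)
    Ka <- mean(dmat[t(utils::combn(a_rows, 2))])
    Kb <- mean(dmat[t(utils::combn(b_rows, 2))])
    if (statistic == "Kst") {
      if (Kt == 0) return(NA_real_)
      1 - ((na * Ka + nb * Kb) / n) / Kt
    } else {
      Hb <- mean(dmat[a_rows, b_rows])
      if (Hb == 0) return(NA_real_)
      1 - ((Ka + Kb) / 2) / Hb
    }
  }

  obs <- stat_for(which(grp == pop_a))
  if (is.na(obs)) {
    return(list(p_value = NA_real_, observed = NA_real_, statistic = statistic,
                method = "none", n_used = 0L,
                status = "observed statistic undefined"))
  }

  n_ordered <- choose(n, na)
  n_distinct <- if (na == nb) n_ordered / 2 else n_ordered

  if (n_distinct <= n_perm) {
    splits <- utils::combn(n, na, simplify = FALSE)
    if (na == nb) splits <- Filter(function(s) 1L %in% s, splits)
    vals <- vapply(splits, stat_for, numeric(1))
    p <- mean(vals >= obs - 1e-12, na.rm = TRUE)
    method <- "exhaustive"; n_used <- length(splits)
  } else {
    vals <- with_seed(seed, vapply(seq_len(n_perm), function(r) {
      stat_for(sample.int(n, na))
    }, numeric(1)))
    p <- (1 + sum(vals >= obs - 1e-12, na.rm = TRUE)) / (1 + n_perm)
    method <- "sampled"; n_used <- as.integer(n_perm)
  }
  list(p_value = p, observed = obs, statistic = statistic, method = method,
       n_used = n_used, status = "ok")
}
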