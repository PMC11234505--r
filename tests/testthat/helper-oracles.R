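# Independent brute-force oracles used to check the package's statistics.
# These deliberately use the plainest possible implementations.

NUC <- c("A", "C", "G", "T")

# mean pairwise difference count and per-pair matrix, counting sites where
# both sequences carry an unambiguous nucleotide
oracle_pairdiffs <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      cnt <- 0
      for (s in seq_len(ncol(m))) {
        if (m[i, s] %in% NUC && m[j, s] %in% NUC && m[i, s] != m[j, s]) {
          cnt <- cnt + 1
        }
      }
      d[i, j] <- d[j, i] <- cnt
    }
  }
  d
}

oracle_pi <- function(m) {
  d <- oracle_pairdiffs(m)
  mean(d[upper.tri(d)])
}

oracle_S <- function(m) {
  s <- 0
  for (j in seq_len(ncol(m))) {
    if (length(unique(m[, j][m[, j] %in% NUC])) >= 2) s <- s + 1
  }
  s
}

# literal 6-frame ORF scan: try every position as a start codon
oracle_orfs <- function(seq, min_aa) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ch <- strsplit(toupper(seq), "")[[1]]
  L <- length(ch)
  rc <- rev(unname(comp[ch])); rc[is.na(rc)] <- "N"
  stops <- c("TAA", "TAG", "TGA")
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") ch else rc
    for (p0 in 0:(L - 3)) {
      if (paste(s[p0 + 1:3], collapse = "") != "ATG") next
      q <- p0 + 3
      found <- NA
      while (q + 3 <= L) {
        if (paste(s[q + 1:3], collapse = "") %in% stops) { found <- q; break }
        q <- q + 3
      }
      if (is.na(found)) next
      n_aa <- (found - p0) / 3
      if (n_aa < min_aa) next
      st <- p0; en <- found + 3
      if (strand == "-") { tmp <- st; st <- L - en; en <- L - tmp }
      res[[length(res) + 1]] <- data.frame(
        frame = (if (strand == "-") -1 else 1) * (p0 %% 3 + 1),
        start = st, end = en, length_aa = n_aa)
    }
  }
  if (!length(res)) {
    return(data.frame(frame = integer(), start = integer(),
                      end = integer(), length_aa = integer()))
  }
  df <- do.call(rbind, res)
  df <- df[order(df$frame, df$start), ]
  row.names(df) <- NULL
  df
}

# exhaustive Kst tail probability over all unordered equal-size splits,
# computed through subdivision() on explicit relabelings (a code path
# independent of permutation_test's internal statistic)
oracle_perm_p <- function(ds, na, statistic = "Kst") {
  n <- n_seqs(ds)
  nm <- seq_names(ds)
  splits <- utils::combn(n, na, simplify = FALSE)
  if (na == n - na) splits <- Filter(function(s) 1 %in% s, splits)
  vals <- sapply(splits, function(s) {
    pop <- rep("B", n); pop[s] <- "A"
    pm <- popmap(nm, nm, pop)
    sb <- subdivision(ds, pm, "A", "B")
    if (statistic == "Kst") sb$Kst else sb$Fst
  })
  obs <- vals[[1]]  # identity split must be supplied first by caller ordering
  list(values = vals, splits = splits)
}

random_nuc_alignment <- function(seed, n, L, nseg = NULL, missing_prob = 0) {
  if (is.null(nseg)) nseg <- sample.int(min(L, 12), 1)
  make_alignment(seed, n, L, n_segregating = nseg, missing_prob = missing_prob)
}

worked <- worked_alignment()

read_golden <- function() {
  path <- system.file("extdata", "worked_W_golden.tsv", package = "proseqkit")
  g <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  stats::setNames(g$value, g$statistic)
}
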