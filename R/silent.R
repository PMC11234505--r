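# Silent / non-silent partition of polymorphism statistics.
#
# Site counting follows Nei-Gojobori on the per-column consensus codon: each
# of a codon's three positions contributes f_syn = (number of the 3 possible
# single-base changes that preserve the amino acid) / 3 synonymous sites and
# 1 - f_syn nonsynonymous sites. Changes to stop codons are amino-acid
# changing and count as nonsynonymous. Polymorphic coding sites are
# classified synonymous when all observed (fully resolved) codon variants
# encode the same amino acid, nonsynonymous otherwise. Silent statistics pool
# synonymous coding sites with all non-coding sites.

# Fraction of the 3 single-base changes at codon position pos (1..3) that are
# synonymous for `codon`.
codon_fsyn <- function(codon, pos, code) {
  ref_aa <- code[[codon]]
  alts <- setdiff(.NUC, substr(codon, pos, pos))
  syn <- vapply(alts, function(b) {
    mut <- codon
    substr(mut, pos, pos) <- b
    identical(code[[mut]], ref_aa)
  }, logical(1))
  mean(syn)
}

#' Diversity statistics partitioned into silent and non-silent sites
#'
#' Uses the dataset-scope coding regions to split alignment columns into
#' silent (synonymous coding plus all non-coding) and non-silent
#' (nonsynonymous coding) classes, then computes S, pi, Watterson's theta and
#' Tajima's D per class. Per-site values divide by the fractional
#' Nei-Gojobori site counts (plus the non-coding column count for the silent
#' class). Codons containing a gap in any sequence are excluded from both
#' classes and counted.
#'
#' @param ds a `proseq_dataset` with at least one dataset-scope coding
#'   region.
#' @param missing_policy passed through to the per-class statistics.
#' @param code_table NCBI genetic-code table id.
#' @return list with elements `silent` and `nonsilent` (each a
#'   `proseq_diversity`) and `counts` (fractional site counts and exclusion
#'   tallies).
#' @export
silent_nonsilent <- function(ds, missing_policy = c("per_site", "complete"),
                             code_table = "1") {
  missing_policy <- match.arg(missing_policy)
  regions <- Filter(function(cr) is.na(cr$scope), ds$coding)
  if (length(regions) == 0) {
    stop("silent_nonsilent requires a dataset-scope coding region")
  }
  code <- as.list(get_code_table(code_table))
  m <- ds$mat
  n <- nrow(m); L <- ncol(m)

  site_class <- rep("noncoding", L)      # per alignment column
  syn_count <- 0; nonsyn_count <- 0; excluded_codons <- 0L
  covered <- rep(FALSE, L)

  for (cr in regions) {
    cols <- coding_columns(cr)           # translation order, 0-based
    n_codons <- length(cols) %/% 3L
    for (k in seq_len(n_codons)) {
      ccols <- cols[(3 * k - 2):(3 * k)] + 1L
      if (any(covered[ccols])) next      # first region wins on overlap
      covered[ccols] <- TRUE
      sub <- m[, ccols, drop = FALSE]
      if (cr$strand == "-") sub[] <- .PQ_COMPLEMENT[sub]
      if (any(sub == .PQ_GAP)) {
        excluded_codons <- excluded_codons + 1L
        site_class[ccols] <- "excluded"
        next
      }
      # consensus codon: per-position majority nucleotide (ties alphabetical)
      cons <- vapply(1:3, function(p) {
        cnt <- table(factor(sub[, p][sub[, p] %in% .NUC], levels = .NUC))
        if (sum(cnt) == 0) return(NA_character_)
        names(cnt)[which.max(cnt)]
      }, character(1))
      if (anyNA(cons)) { site_class[ccols] <- "excluded"; next }
      cons_codon <- paste(cons, collapse = "")
      fsyn <- vapply(1:3, codon_fsyn, numeric(1), codon = cons_codon,
                     code = code)
      syn_count <- syn_count + sum(fsyn)
      nonsyn_count <- nonsyn_count + sum(1 - fsyn)

      codons <- apply(sub, 1, paste, collapse = "")
      resolved <- unique(codons[!grepl("[^ACGT]", codons)])
      aas <- unlist(code[resolved])
      all_same_aa <- length(unique(aas)) <= 1
      for (p in 1:3) {
        colv <- sub[, p]
        if (length(unique(colv[colv %in% .NUC])) >= 2) {
          site_class[ccols[p]] <- if (all_same_aa) "syn" else "nonsyn"
        } else {
          site_class[ccols[p]] <- "mono_coding"
        }
      }
    }
    if (length(cols) %% 3L) {            # trailing incomplete codon
      tail_cols <- cols[(3 * n_codons + 1):length(cols)] + 1L
      site_class[tail_cols[!covered[tail_cols]]] <- "excluded"
      covered[tail_cols] <- TRUE
    }
  }

  n_noncoding <- sum(site_class == "noncoding")
  silent_cols <- which(site_class %in% c("syn", "noncoding"))
  nonsilent_cols <- which(site_class %in% c("nonsyn", "mono_coding"))

  class_stats <- function(cols, denom) {
    sub <- m[, cols, drop = FALSE]
    d <- diversity(sub, missing_policy)
    d$pi_per_site <- if (denom > 0) d$pi_per_locus / denom else NA_real_
    d$theta_w_per_site <- if (denom > 0) d$theta_w_per_locus / denom else NA_real_
    d$sites_used <- denom
    d
  }
  list(
    silent = class_stats(silent_cols, syn_count + n_noncoding),
    nonsilent = class_stats(nonsilent_cols, nonsyn_count),
    counts = list(syn_sites = syn_count, nonsyn_sites = nonsyn_count,
                  noncoding_sites = n_noncoding,
                  excluded_codons = excluded_codons))
}
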