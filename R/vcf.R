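# VCF consumption: alignment reconstruction (vcf2fasta) and sliding-window
# polymorphism scans computed directly from genotype columns (vcfSWpol).

# Load a VCF from a path ('-' = stdin), gzipped or plain, into a vcfR object.
read_vcf_input <- function(vcf) {
  if (inherits(vcf, "vcfR")) return(vcf)
  path <- vcf
  if (identical(path, "-")) {
    tmp <- tempfile(fileext = ".vcf")
    writeLines(readLines("stdin"), tmp)
    path <- tmp
  }
  vcfR::read.vcfR(path, verbose = FALSE)
}

# Parse one genotype string into allele indices; "." entries become NA.
# attr "phased" records whether the genotype used '|'.
split_gt <- function(gt) {
  if (is.na(gt) || gt == ".") return(structure(NA_integer_, phased = FALSE))
  core <- sub(":.*$", "", gt)
  phased <- grepl("|", core, fixed = TRUE)
  al <- strsplit(core, "[/|]")[[1]]
  structure(suppressWarnings(as.integer(al)), phased = phased)
}

is_snp_alleles <- function(alleles) {
  all(nchar(alleles) == 1) && all(alleles %in% .NUC)
}

#' Reconstruct per-contig alignments from a multisample VCF
#'
#' Substitutes sample alleles into the reference (or into the recorded
#' positions when the VCF covers all sites and no reference is given),
#' producing one alignment per contig. SNP records substitute alleles;
#' missing genotypes become `'N'`; indel and symbolic-allele records are
#' skipped (the position keeps the reference base) and counted. In `iupac`
#' mode each sample yields one sequence, heterozygous genotypes becoming
#' IUPAC ambiguity codes; in `split_haplotypes` mode each diploid sample
#' yields `<sample>_1` and `<sample>_2`, using phase when available and the
#' listed allele order (counted as a warning) when unphased.
#'
#' @param vcf path to a VCF file (`"-"` for stdin; `.gz` accepted) or a
#'   `vcfR` object.
#' @param reference optional reference FASTA path, or a named character
#'   vector of contig sequences. Required for variant-only VCFs.
#' @param mode `"iupac"` or `"split_haplotypes"`.
#' @param contigs optional character vector restricting output contigs.
#' @return named list of `proseq_dataset` (one per contig) with attributes
#'   `skipped_indels` and `unphased_het` (counts).
#' @export
vcf_to_fasta <- function(vcf, reference = NULL,
                         mode = c("iupac", "split_haplotypes"),
                         contigs = NULL) {
  mode <- match.arg(mode)
  v <- read_vcf_input(vcf)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(v@gt)[-1]

  refseqs <- NULL
  if (!is.null(reference)) {
    refseqs <- if (is.character(reference) && length(reference) == 1 &&
                   file.exists(reference)) {
      as_strings(read_alignment(reference, format = "fasta",
                                pad_with_missing = TRUE))
    } else {
      stats::setNames(normalize_residues(reference), names(reference))
    }
  }

  chroms <- unique(fix[, "CHROM"])
  if (!is.null(contigs)) chroms <- intersect(chroms, contigs)
  skipped <- 0L; unphased <- 0L
  out <- list()

  for (chrom in chroms) {
    rows <- which(fix[, "CHROM"] == chrom)
    pos <- as.integer(fix[rows, "POS"])
    if (is.unsorted(pos)) {
      o <- order(pos); rows <- rows[o]; pos <- pos[o]
    }
    if (!is.null(refseqs)) {
      if (!chrom %in% names(refseqs)) {
        stop("contig '", chrom, "' absent from the reference")
      }
      refchars <- strsplit(refseqs[[chrom]], "")[[1]]
      colof <- seq_along(refchars)             # position -> column (identity)
      Lc <- length(refchars)
      base <- refchars
    } else {
      upos <- sort(unique(pos))
      colof <- stats::setNames(seq_along(upos), upos)
      Lc <- length(upos)
      base <- fix[rows, "REF"][match(upos, pos)]
      base[nchar(base) != 1 | !base %in% .NUC] <- "N"
    }

    # ploidy: maximum number of alleles seen in any genotype on this contig
    ploidy <- 1L
    gts <- gt[rows, , drop = FALSE]
    parsed <- lapply(seq_along(rows), function(k) {
      lapply(gts[k, ], split_gt)
    })
    ploidy <- max(vapply(parsed, function(p) max(lengths(p)), integer(1)))

    n_out <- if (mode == "iupac") length(samples) else length(samples) * ploidy
    mat <- matrix(rep(base, each = n_out), nrow = n_out)
    rn <- if (mode == "iupac") samples else {
      if (ploidy == 1) samples else
        as.vector(t(outer(samples, seq_len(ploidy), paste, sep = "_")))
    }
    rownames(mat) <- rn

    for (k in seq_along(rows)) {
      r <- rows[k]
      alleles <- c(fix[r, "REF"], strsplit(fix[r, "ALT"], ",")[[1]])
      alleles <- alleles[!is.na(alleles) & alleles != "."]
      p <- pos[k]
      if (!is.null(refseqs)) {
        if (p > Lc) stop(sprintf("%s:%d beyond reference length %d", chrom, p, Lc))
        if (toupper(fix[r, "REF"]) != refchars[p] && is_snp_alleles(alleles[1])) {
          stop(sprintf("REF mismatch at %s:%d (VCF %s, reference %s)",
                       chrom, p, fix[r, "REF"], refchars[p]))
        }
      }
      if (!is_snp_alleles(alleles)) { skipped <- skipped + 1L; next }
      j <- if (!is.null(refseqs)) p else colof[[as.character(p)]]
      for (si in seq_along(samples)) {
        g <- parsed[[k]][[si]]
        obs <- alleles[g + 1L]                 # NA index -> NA base
        if (mode == "iupac") {
          mat[si, j] <- if (anyNA(obs)) "N" else {
            key <- paste(sort(unique(obs)), collapse = "")
            .PQ_AMBIG[[key]]
          }
        } else {
          if (length(obs) < ploidy) obs <- rep(obs, length.out = ploidy)
          if (length(unique(obs[!is.na(obs)])) > 1 && !attr(g, "phased")) {
            unphased <- unphased + 1L
          }
          for (h in seq_len(ploidy)) {
            ri <- (si - 1L) * ploidy + h
            mat[ri, j] <- if (is.na(obs[h])) "N" else obs[h]
          }
        }
      }
    }
    out[[chrom]] <- dataset(mat, id = chrom)
  }
  attr(out, "skipped_indels") <- skipped
  attr(out, "unphased_het") <- unphased
  out
}

#' Sliding-window polymorphism statistics directly from a VCF
#'
#' Windows tile each contig from position 0 in steps of `step_bp`; every full
#' window is emitted and one final partial window is appended when it
#' contains at least one record and the full windows do not cover the contig
#' tail. Genotype columns are expanded to allele samples (e.g. two per
#' diploid sample); records with fewer than two non-missing alleles are
#' ignored, and records with more than two distinct alleles are excluded
#' from S/pi/D (counted in `n_multiallelic`). With `all_sites = TRUE` the
#' per-site denominator is the number of records in the window; otherwise it
#' is the window length in bp (an undercount where coverage is incomplete).
#'
#' @param vcf path to a (sorted) VCF or a `vcfR` object.
#' @param window_bp,step_bp window and step size in bp,
#'   `window_bp >= step_bp >= 1`.
#' @param all_sites whether the VCF has a record for every position.
#' @return data.frame with columns `chrom`, `start`, `end`, `n_sites`, `S`,
#'   `pi`, `theta`, `tajD`, `n_multiallelic`.
#' @export
vcf_sliding_window <- function(vcf, window_bp, step_bp, all_sites = FALSE) {
  stopifnot(step_bp >= 1, window_bp >= step_bp)
  v <- read_vcf_input(vcf)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")

  # sortedness check (per contig, first violation reported)
  chrom_col <- fix[, "CHROM"]; pos_all <- as.integer(fix[, "POS"])
  for (chrom in unique(chrom_col)) {
    p <- pos_all[chrom_col == chrom]
    if (is.unsorted(p)) {
      stop("input VCF not sorted by position within contig ", chrom)
    }
  }

  contig_len <- vcf_contig_lengths(v)
  out <- list()
  for (chrom in unique(chrom_col)) {
    rows <- which(chrom_col == chrom)
    pos <- pos_all[rows]
    L <- if (chrom %in% names(contig_len)) contig_len[[chrom]] else max(pos)

    # per-record allele-index samples
    allele_samples <- lapply(rows, function(r) {
      unlist(lapply(gt[r, ], function(g) {
        a <- split_gt(g)
        attributes(a) <- NULL
        a
      }))
    })
    nhap <- max(lengths(allele_samples))

    bounds <- window_bounds(L, window_bp, step_bp)
    for (i in seq_len(nrow(bounds))) {
      s <- bounds[i, 1]; e <- bounds[i, 2]
      inwin <- which(pos > s & pos <= e)
      partial <- (e - s) < window_bp
      if (partial && length(inwin) == 0) next
      S <- 0L; pi_locus <- 0; nmulti <- 0L
      for (k in inwin) {
        a <- allele_samples[[k]]
        a <- a[!is.na(a)]
        if (length(a) < 2) next
        nall <- length(unique(a))
        if (nall > 2) { nmulti <- nmulti + 1L; next }
        if (nall == 2) {
          S <- S + 1L
          cnt <- table(a)
          pi_locus <- pi_locus + site_h(as.integer(cnt))
        }
      }
      denom <- if (all_sites) length(inwin) else (e - s)
      a1 <- sum(1 / seq_len(max(nhap - 1, 1)))
      theta_locus <- S / a1
      tajD <- NA_real_
      if (S > 0 && nhap >= 3) {
        cf <- tajima_coefficients(nhap)
        tajD <- (pi_locus - theta_locus) /
          sqrt(cf[["e1"]] * S + cf[["e2"]] * S * (S - 1))
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = s, end = e, n_sites = denom, S = S,
        pi = if (denom > 0) pi_locus / denom else NA_real_,
        theta = if (denom > 0) theta_locus / denom else NA_real_,
        tajD = tajD, n_multiallelic = nmulti, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

# Contig lengths from ##contig header lines, when present.
vcf_contig_lengths <- function(v) {
  meta <- v@meta
  cl <- meta[grepl("^##contig=", meta)]
  if (length(cl) == 0) return(stats::setNames(integer(0), character(0)))
  ids <- sub('.*ID=([^,>]+).*', "\\1", cl)
  lens <- suppressWarnings(as.integer(sub('.*length=([0-9]+).*', "\\1", cl)))
  keep <- !is.na(lens)
  stats::setNames(lens[keep], ids[keep])
}
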