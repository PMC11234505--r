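# Exporters to downstream population-genetic program formats. Each returns
# the file content as a character vector of lines; export_dataset() optionally
# writes it.

# Biallelic SNP columns: exactly two distinct unambiguous nucleotides among
# the (non-missing) residues of the column.
biallelic_columns <- function(m) {
  which(apply(m, 2, function(col) {
    length(unique(col[col %in% .NUC])) == 2
  }))
}

#' Export an alignment to a downstream program format
#'
#' Supported formats: `phylip` (relaxed names by default, strict 10-character
#' names with `strict_names = TRUE`), `nexus` (DATA block), `mega`,
#' `structure` (one row per sequence, one column per biallelic SNP, alleles
#' coded A=1, C=2, G=3, T=4, missing -9), `sweepfinder` (TSV
#' `position x n folded` per biallelic SNP; `x` is the derived allele count
#' in unfolded mode — which requires `outgroup` — or the minor allele count
#' in folded mode; `n` is the non-missing allele count) and `sfs` (a single
#' site-frequency-spectrum vector: length `n+1` unfolded, `floor(n/2)+1`
#' folded).
#'
#' @param ds a `proseq_dataset`.
#' @param format one of `"phylip"`, `"nexus"`, `"mega"`, `"structure"`,
#'   `"sweepfinder"`, `"sfs"`.
#' @param path optional output file.
#' @param folded for sweepfinder/sfs: fold the spectrum (default `TRUE` when
#'   no outgroup is given).
#' @param outgroup sequence name used to orient derived alleles (required
#'   unfolded; the outgroup is excluded from the sample).
#' @param strict_names phylip: truncate/pad names to 10 characters.
#' @return character vector of output lines (invisibly when `path` given).
#' @examples
#' ds <- dataset(c(s1 = "ACGT", s2 = "ACGA", s3 = "ATGA", s4 = "ATGA"))
#' export_dataset(ds, "phylip")
#' @export
export_dataset <- function(ds, format, path = NULL, folded = is.null(outgroup),
                           outgroup = NULL, strict_names = FALSE) {
  format <- match.arg(format, c("phylip", "nexus", "mega", "structure",
                                "sweepfinder", "sfs"))
  m <- ds$mat
  lines <- switch(format,
    phylip = {
      nm <- seq_names(ds)
      if (strict_names) nm <- formatC(substr(nm, 1, 10), width = -10)
      c(sprintf("%d %d", n_seqs(ds), n_sites(ds)),
        sprintf("%s %s", nm, as_strings(ds)))
    },
    nexus = {
      c("#NEXUS", "BEGIN DATA;",
        sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", n_seqs(ds), n_sites(ds)),
        "  FORMAT DATATYPE=DNA MISSING=? GAP=-;", "  MATRIX",
        sprintf("    %s %s", seq_names(ds), as_strings(ds)),
        "  ;", "END;")
    },
    mega = {
      c("#mega", sprintf("!Title %s;", ds$id), "",
        as.vector(rbind(paste0("#", seq_names(ds)), as_strings(ds))))
    },
    structure = {
      snp <- biallelic_columns(m)
      if (length(snp) == 0) {
        stop("structure export requires >= 1 biallelic segregating site")
      }
      codemap <- c(A = 1L, C = 2L, G = 3L, T = 4L)
      rows <- vapply(seq_len(nrow(m)), function(i) {
        codes <- codemap[m[i, snp]]
        codes[is.na(codes)] <- -9L
        paste(c(rownames(m)[i], codes), collapse = " ")
      }, character(1))
      rows
    },
    sweepfinder = {
      tab <- sfs_table(m, folded = folded, outgroup = outgroup)
      c("position\tx\tn\tfolded",
        sprintf("%d\t%d\t%d\t%d", tab$position, tab$x, tab$n,
                as.integer(tab$folded)))
    },
    sfs = {
      tab <- sfs_table(m, folded = folded, outgroup = outgroup)
      nsam <- if (is.null(outgroup)) nrow(m) else nrow(m) - 1L
      k <- if (folded) nsam %/% 2L + 1L else nsam + 1L
      spec <- tabulate(tab$x + 1L, nbins = k)
      paste(spec, collapse = " ")
    })
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# Per-SNP allele-count table used by sweepfinder and sfs exports. Unfolded
# mode polarizes by the outgroup allele and skips sites where the outgroup is
# missing or carries a third allele.
sfs_table <- function(m, folded = TRUE, outgroup = NULL) {
  if (!folded && is.null(outgroup)) {
    stop("unfolded export requires a designated outgroup sequence")
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% rownames(m)) stop("outgroup '", outgroup, "' not found")
    og <- m[outgroup, ]
    m <- m[setdiff(rownames(m), outgroup), , drop = FALSE]
  }
  snp <- biallelic_columns(m)
  if (length(snp) == 0) {
    stop("export requires >= 1 biallelic segregating site")
  }
  rows <- lapply(snp, function(j) {
    col <- m[, j][m[, j] %in% .NUC]
    al <- sort(unique(col))
    cnt <- c(sum(col == al[1]), sum(col == al[2]))
    if (folded) {
      x <- min(cnt)
    } else {
      anc <- og[j]
      if (!anc %in% al) return(NULL)   # outgroup missing or third allele
      x <- cnt[al != anc]
    }
    data.frame(position = j, x = x, n = length(col), folded = folded)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) stop("no polarizable SNPs for unfolded export")
  do.call(rbind, rows)
}
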