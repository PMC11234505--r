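# Codon translation with degenerate-codon handling. Codons containing gaps,
# missing symbols or ambiguity codes translate to 'X'; stops to '*'.

get_code_table <- function(code_table = "1") {
  Biostrings::getGeneticCode(as.character(code_table))
}

translate_codons <- function(nt, code) {
  n_codon <- nchar(nt) %/% 3L          # trailing incomplete codon dropped
  if (n_codon == 0) return("")
  codons <- substring(nt, 3L * (seq_len(n_codon) - 1L) + 1L,
                      3L * seq_len(n_codon))
  aa <- code[codons]
  aa[is.na(aa)] <- "X"                 # any non-ACGT base in the codon
  paste(aa, collapse = "")
}

# Spliced, strand-adjusted, frame-shifted nucleotide string of `region` for
# every sequence in the dataset (or just the scoped sequence).
region_nt <- function(ds, region) {
  cols <- coding_columns(region) + 1L
  rows <- if (is.na(region$scope)) seq_len(n_seqs(ds)) else
    match(region$scope, seq_names(ds))
  out <- apply(ds$mat[rows, cols, drop = FALSE], 1, function(ch) {
    if (region$strand == "-") ch <- .PQ_COMPLEMENT[ch]
    paste(ch, collapse = "")
  })
  stats::setNames(out, seq_names(ds)[rows])
}

translate_region <- function(ds, region, code_table = "1") {
  code <- get_code_table(code_table)
  vapply(region_nt(ds, region), translate_codons, character(1), code = code)
}

#' Translate a coding region
#'
#' Translates the spliced, strand-adjusted, frame-shifted coding sequence of
#' every targeted sequence. Codons containing gap, missing or ambiguity
#' symbols yield `'X'`; stop codons yield `'*'`; a trailing incomplete codon
#' is dropped.
#'
#' @param ds a `proseq_dataset`.
#' @param region a `proseq_coding_region` valid for `ds`.
#' @param code_table NCBI genetic-code table id (default `"1"`, the standard
#'   code).
#' @return named character vector of protein strings (one per sequence, or a
#'   single element for a sequence-scoped region).
#' @examples
#' ds <- dataset(c(s1 = "ATGAAATAA"))
#' translate(ds, coding_region(c(0, 9)))  # "MK*"
#' @export
translate <- function(ds, region, code_table = "1") {
  L <- n_sites(ds)
  if (any(region$segments[, 1] < 0) || any(region$segments[, 2] > L)) {
    stop(sprintf("coding region outside alignment [0,%d)", L))
  }
  translate_region(ds, region, code_table)
}

#' Find open reading frames
#'
#' Scans all six reading frames for ATG-initiated, stop-terminated open
#' reading frames of at least `min_length_aa` codons (the stop codon is not
#' counted towards the length). Coordinates are reported on the forward
#' strand, 0-based half-open, spanning start codon through stop codon.
#'
#' @param sequence a residue string (gaps/missing allowed; codons containing
#'   them cannot form starts or stops).
#' @param min_length_aa minimum ORF length in amino acids, `>= 1`.
#' @param code_table NCBI genetic-code table id.
#' @return data.frame with columns `frame` (`+1,+2,+3,-1,-2,-3`), `start`,
#'   `end`, `length_aa`.
#' @examples
#' find_orfs("ATGAAATAA", min_length_aa = 2)
#' @export
find_orfs <- function(sequence, min_length_aa = 1L, code_table = "1") {
  stopifnot(min_length_aa >= 1)
  sequence <- normalize_residues(sequence)
  code <- get_code_table(code_table)
  stops <- names(code)[code == "*"]
  L <- nchar(sequence)
  rc <- paste(rev(.PQ_COMPLEMENT[strsplit(sequence, "")[[1]]]), collapse = "")

  scan_strand <- function(s, minus) {
    hits <- list()
    for (off in 0:2) {
      n_codon <- (nchar(s) - off) %/% 3L
      if (n_codon < 1) next
      codons <- substring(s, off + 3L * (seq_len(n_codon) - 1L) + 1L,
                          off + 3L * seq_len(n_codon))
      stop_at <- which(codons %in% stops)
      for (i in which(codons == "ATG")) {
        j <- stop_at[stop_at > i][1]     # first in-frame stop downstream
        if (is.na(j) || (j - i) < min_length_aa) next
        s0 <- off + 3L * (i - 1L)        # 0-based on scanned strand
        e0 <- off + 3L * j               # end of stop codon
        if (minus) { tmp <- s0; s0 <- L - e0; e0 <- L - tmp }
        hits[[length(hits) + 1L]] <- data.frame(
          frame = if (minus) -(off + 1L) else (off + 1L),
          start = s0, end = e0, length_aa = j - i)
      }
    }
    hits
  }

  out <- c(scan_strand(sequence, FALSE), scan_strand(rc, TRUE))
  if (length(out) == 0) {
    return(data.frame(frame = integer(), start = integer(), end = integer(),
                      length_aa = integer()))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$frame, df$start), , drop = FALSE]
  row.names(df) <- NULL
  df
}
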