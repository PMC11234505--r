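#' Read a sequence alignment from FASTA or FASTQ
#'
#' Sequences are validated against the package alphabet (nucleotides, IUPAC
#' ambiguity codes, `N`, `?`, `-`), uppercased, and `U` is normalized to `T`.
#' FASTQ quality strings are used only for the optional mean-quality filter
#' and then discarded. Header names are truncated at the first whitespace.
#'
#' @param path input file path.
#' @param format `"fasta"` or `"fastq"` (default guessed from the extension).
#' @param pad_with_missing when `TRUE`, shorter sequences are right-padded
#'   with `'N'` to the longest length instead of raising an error.
#' @param min_mean_quality optional FASTQ filter: records whose mean Phred
#'   quality is below this value are dropped.
#' @param id dataset id (defaults to the file name without extension).
#' @return a `proseq_dataset`.
#' @export
read_alignment <- function(path, format = NULL, pad_with_missing = FALSE,
                           min_mean_quality = NULL, id = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  format <- match.arg(format, c("fasta", "fastq"))
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))

  if (format == "fastq") {
    ss <- Biostrings::readBStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
    if (length(ss) == 0) stop("empty sequence file: ", path)
    if (!is.null(min_mean_quality)) {
      qual <- S4Vectors::mcols(ss)$qualities
      meanq <- vapply(as.character(qual), function(q) {
        mean(utf8ToInt(q) - 33L)
      }, numeric(1), USE.NAMES = FALSE)
      ss <- ss[meanq >= min_mean_quality]
      if (length(ss) == 0) stop("no record passes the mean-quality filter")
    }
  } else {
    ss <- Biostrings::readBStringSet(path, format = "fasta")
    if (length(ss) == 0) stop("empty sequence file: ", path)
  }

  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence names in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    if (!pad_with_missing) {
      stop("unequal sequence lengths in ", path,
           " (set pad_with_missing = TRUE to right-pad with 'N')")
    }
    seqs <- vapply(seqs, function(s) {
      paste0(s, strrep("N", max(lens) - nchar(s)))
    }, character(1))
  }
  dataset(seqs, id = id)
}

#' Write a dataset as FASTA
#'
#' @param ds a `proseq_dataset`.
#' @param path output file path.
#' @param width line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(ds, path, width = 70L) {
  seqs <- as_strings(ds)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    if (nchar(s) == 0) next
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read and write a project manifest
#'
#' The manifest is a plain-text file listing member alignment files, one path
#' per line; `'#'` starts a comment and blank lines are ignored. Relative
#' paths are resolved against the manifest's directory.
#'
#' @param path manifest file path.
#' @param popmap_path optional path to a population-structure file read with
#'   [read_popmap()].
#' @return a `proseq_project`.
#' @export
read_project <- function(path, popmap_path = NULL) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  base <- dirname(path)
  files <- ifelse(grepl("^/", lines), lines, file.path(base, lines))
  datasets <- lapply(files, read_alignment)
  pm <- if (is.null(popmap_path)) popmap() else read_popmap(popmap_path)
  project(datasets, pm)
}
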