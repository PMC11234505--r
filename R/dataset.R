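#' @keywords internal
"_PACKAGE"

# Sequence alphabet: nucleotides, IUPAC ambiguity codes, missing ('N','?')
# and gap ('-'). 'U' is normalized to 'T' on load; case is normalized to upper.
.PQ_IUPAC <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V")
.PQ_ALPHABET <- c(.PQ_IUPAC, "N", "?", "-")
.PQ_MISSING <- c("N", "?")
.PQ_GAP <- "-"

.PQ_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                    R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                    B = "V", D = "H", H = "D", V = "B",
                    N = "N", `?` = "?", `-` = "-")

# IUPAC code for an unordered set of nucleotides (used by vcf_to_fasta).
.PQ_AMBIG <- c(AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
               A = "A", C = "C", G = "G", T = "T")

#' Normalize residue characters
#'
#' Uppercases, maps U to T, and validates against the package alphabet.
#'
#' @param x character vector of residue strings.
#' @return character vector of normalized residue strings.
#' @keywords internal
#' @noRd
normalize_residues <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- setdiff(unique(strsplit(paste(x, collapse = ""), "")[[1]]),
                 .PQ_ALPHABET)
  if (length(bad) > 0) {
    stop("invalid residue symbol(s): ", paste(bad, collapse = " "),
         call. = FALSE)
  }
  x
}

#' Create an alignment dataset
#'
#' A dataset is a rectangular alignment of named sequences for one locus or
#' contig, optionally annotated with coding regions. Internally it is stored
#' as a character matrix (one row per sequence, one column per alignment
#' site); all coordinates are 0-based half-open.
#'
#' @param seqs named character vector of residue strings (equal lengths), or
#'   a character matrix with one row per sequence and rownames set.
#' @param id dataset identifier.
#' @param coding list of coding regions created by [coding_region()].
#' @return an object of class `proseq_dataset`.
#' @examples
#' ds <- dataset(c(s1 = "ACGT", s2 = "ACGA"), id = "locus1")
#' n_sites(ds)
#' @export
dataset <- function(seqs, id = "dataset1", coding = list()) {
  if (is.matrix(seqs)) {
    m <- seqs
    if (is.null(rownames(m))) stop("sequence matrix must have rownames")
    m[] <- normalize_residues(m)
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
      stop("sequences must be named")
    }
    seqs <- normalize_residues(seqs)
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1) {
      stop("sequences have unequal lengths: ",
           paste(unique(lens), collapse = ", "))
    }
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- names(seqs)
    if (length(seqs) == 1 && lens == 0) m <- matrix("", 1, 0,
                                                    dimnames = list(names(seqs)))
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate sequence names: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  ds <- structure(list(id = id, mat = m, coding = list()),
                  class = "proseq_dataset")
  for (cr in coding) ds <- add_coding_region(ds, cr)
  ds
}

#' @export
print.proseq_dataset <- function(x, ...) {
  cat(sprintf("<proseq_dataset '%s'> %d sequences x %d sites, %d coding region(s)\n",
              x$id, nrow(x$mat), ncol(x$mat), length(x$coding)))
  invisible(x)
}

#' Number of sequences / alignment sites
#' @param ds a `proseq_dataset`.
#' @return integer count.
#' @export
n_seqs <- function(ds) nrow(ds$mat)

#' @rdname n_seqs
#' @export
n_sites <- function(ds) ncol(ds$mat)

#' Sequence names of a dataset
#' @param ds a `proseq_dataset`.
#' @return character vector.
#' @export
seq_names <- function(ds) rownames(ds$mat)

#' Extract sequences as residue strings
#' @param ds a `proseq_dataset`.
#' @return named character vector.
#' @export
as_strings <- function(ds) {
  stats::setNames(apply(ds$mat, 1, paste, collapse = ""), rownames(ds$mat))
}

#' Define a coding region
#'
#' Coding regions use internal 0-based half-open coordinates. A region may be
#' spliced (several segments), lie on either strand, start translation at a
#' frame offset, and apply to the whole dataset or a single named sequence.
#'
#' @param segments two-column matrix (or vector of length 2) of
#'   `(start, end)` 0-based half-open intervals, non-overlapping.
#' @param strand `"+"` or `"-"`.
#' @param frame frame offset in `{0, 1, 2}`: number of leading bases of the
#'   spliced, strand-oriented sequence skipped before the first codon.
#' @param scope `NA` for a dataset-wide region, or a sequence name.
#' @return an object of class `proseq_coding_region`.
#' @export
coding_region <- function(segments, strand = "+", frame = 0L, scope = NA_character_) {
  if (!is.matrix(segments)) segments <- matrix(segments, ncol = 2, byrow = TRUE)
  storage.mode(segments) <- "integer"
  segments <- segments[order(segments[, 1]), , drop = FALSE]
  if (any(segments[, 2] <= segments[, 1])) stop("empty coding segment")
  if (nrow(segments) > 1 &&
      any(segments[-1, 1] < segments[-nrow(segments), 2])) {
    stop("coding segments overlap")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  structure(list(segments = segments, strand = strand,
                 frame = as.integer(frame), scope = scope),
            class = "proseq_coding_region")
}

#' Attach a coding region to a dataset
#'
#' @param ds a `proseq_dataset`.
#' @param region a `proseq_coding_region`.
#' @return the dataset with the region appended. Regions whose spliced length
#'   is below one codon are accepted but flagged with a warning.
#' @export
add_coding_region <- function(ds, region) {
  stopifnot(inherits(region, "proseq_coding_region"))
  L <- n_sites(ds)
  if (any(region$segments[, 1] < 0) || any(region$segments[, 2] > L)) {
    stop(sprintf("coding region outside alignment [0,%d)", L))
  }
  if (!is.na(region$scope) && !region$scope %in% seq_names(ds)) {
    stop("coding region scope '", region$scope, "' not a sequence in dataset")
  }
  if (spliced_length(region) - region$frame < 3) {
    warning("coding region shorter than one codon; not translatable")
  }
  ds$coding <- c(ds$coding, list(region))
  ds
}

#' Total spliced length of a coding region
#' @param region a `proseq_coding_region`.
#' @return integer number of bases.
#' @export
spliced_length <- function(region) sum(region$segments[, 2] - region$segments[, 1])

# 0-based alignment columns of the region in translation (5'->3') order.
# For '-' strand regions this is right-to-left over the segments.
coding_columns <- function(region) {
  cols <- unlist(lapply(seq_len(nrow(region$segments)), function(i) {
    seq.int(region$segments[i, 1], region$segments[i, 2] - 1L)
  }))
  if (region$strand == "-") cols <- rev(cols)
  if (region$frame > 0) cols <- cols[-seq_len(region$frame)]
  cols
}

#' Create a population map
#'
#' Relational map sequence -> individual -> population. Sequences absent from
#' the map resolve to the individual/population `"unassigned"`.
#'
#' @param sequence,individual,population equal-length character vectors, or a
#'   3-column data.frame passed as `sequence`.
#' @return an object of class `proseq_popmap` (a data.frame).
#' @examples
#' pm <- popmap(c("s1", "s2"), c("i1", "i2"), c("P1", "P2"))
#' @export
popmap <- function(sequence = character(), individual = character(),
                   population = character()) {
  if (is.data.frame(sequence)) {
    df <- sequence
    names(df) <- c("sequence", "individual", "population")
  } else {
    df <- data.frame(sequence = as.character(sequence),
                     individual = as.character(individual),
                     population = as.character(population),
                     stringsAsFactors = FALSE)
  }
  if (anyDuplicated(df$sequence)) {
    stop("sequence(s) mapped more than once: ",
         paste(unique(df$sequence[duplicated(df$sequence)]), collapse = ", "))
  }
  ind2pop <- unique(df[, c("individual", "population")])
  if (anyDuplicated(ind2pop$individual)) {
    stop("individual(s) assigned to more than one population")
  }
  class(df) <- c("proseq_popmap", "data.frame")
  df
}

#' Population of each sequence name
#' @param pm a `proseq_popmap`.
#' @param seqnames character vector of sequence names.
#' @return character vector of population names (`"unassigned"` for unmapped).
#' @export
population_of <- function(pm, seqnames) {
  i <- match(seqnames, pm$sequence)
  out <- pm$population[i]
  out[is.na(i)] <- "unassigned"
  out
}

#' Individual of each sequence name
#' @inheritParams population_of
#' @return character vector of individual names (`"unassigned"` for unmapped).
#' @export
individual_of <- function(pm, seqnames) {
  i <- match(seqnames, pm$sequence)
  out <- pm$individual[i]
  out[is.na(i)] <- "unassigned"
  out
}

#' Create a multi-dataset project
#'
#' @param datasets list of `proseq_dataset` objects with unique ids.
#' @param popmap a `proseq_popmap` (may be empty).
#' @return an object of class `proseq_project`.
#' @export
project <- function(datasets = list(), popmap = proseqkit::popmap()) {
  ids <- vapply(datasets, function(d) d$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate dataset ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(datasets) <- ids
  structure(list(datasets = datasets, popmap = popmap),
            class = "proseq_project")
}

#' @export
print.proseq_project <- function(x, ...) {
  cat(sprintf("<proseq_project> %d dataset(s), %d popmap entries\n",
              length(x$datasets), nrow(x$popmap)))
  invisible(x)
}
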