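#' Automatically link sequences to individuals by name similarity
#'
#' Each sequence whose name contains an individual name as a case-insensitive
#' substring is linked to that individual; when several individual names
#' match, the longest match wins; ties between equally long matches leave the
#' sequence unlinked (with a warning). Unmatched sequences are reported in the
#' `unlinked` attribute.
#'
#' @param prj a `proseq_project` (or a single `proseq_dataset`).
#' @param individuals character vector of unique, non-empty individual names.
#' @param populations optional character vector (same length) assigning each
#'   individual to a population; defaults to `"unassigned"`.
#' @return a `proseq_popmap` with attribute `unlinked` listing sequence names
#'   that could not be linked.
#' @examples
#' ds <- dataset(c(ind1_locusA = "ACGT", ind2_locusA = "ACGA"))
#' link_sequences(project(list(ds)), c("ind1", "ind2"))
#' @export
link_sequences <- function(prj, individuals,
                           populations = rep("unassigned", length(individuals))) {
  if (inherits(prj, "proseq_dataset")) prj <- project(list(prj))
  if (any(!nzchar(individuals))) stop("individual names must be non-empty")
  if (anyDuplicated(individuals)) stop("duplicate individual names")
  stopifnot(length(populations) == length(individuals))

  seqs <- unique(unlist(lapply(prj$datasets, seq_names)))
  lseqs <- tolower(seqs)
  linds <- tolower(individuals)

  hit <- character(0); hit_seq <- character(0); unlinked <- character(0)
  ties <- 0L
  for (i in seq_along(seqs)) {
    m <- which(vapply(linds, function(p) grepl(p, lseqs[i], fixed = TRUE),
                      logical(1)))
    if (length(m) == 0) { unlinked <- c(unlinked, seqs[i]); next }
    len <- nchar(individuals[m])
    best <- m[len == max(len)]
    if (length(best) > 1) {          # ambiguous: equally long matches
      ties <- ties + 1L
      unlinked <- c(unlinked, seqs[i])
      next
    }
    hit_seq <- c(hit_seq, seqs[i]); hit <- c(hit, individuals[best])
  }
  if (ties > 0) warning(ties, " sequence name(s) matched several individuals ",
                        "equally well; left unlinked")
  pm <- popmap(hit_seq, hit, populations[match(hit, individuals)])
  attr(pm, "unlinked") <- unlinked
  pm
}

#' Transform an alignment
#'
#' Sequence-editing operations returning a transformed copy of the dataset:
#' reverse complementation (IUPAC-aware), case changes, trimming to a column
#' interval, and masking an interval with a symbol. Coding regions are
#' remapped for `trim` and `reverse_complement` (regions falling entirely
#' outside a trim are dropped).
#'
#' @param ds a `proseq_dataset`.
#' @param mode one of `"reverse_complement"`, `"upper"`, `"lower"`, `"trim"`,
#'   `"mask"`.
#' @param start,end 0-based half-open column interval (for trim/mask).
#' @param symbol masking symbol (for mask), default `"N"`.
#' @param targets `"all"` or a character vector of sequence names; coding
#'   regions are only remapped for whole-dataset transforms.
#' @return a transformed `proseq_dataset`.
#' @examples
#' ds <- dataset(c(s1 = "ACGTN"))
#' as_strings(transform_dataset(ds, "reverse_complement"))
#' @export
transform_dataset <- function(ds, mode, start = NULL, end = NULL,
                              symbol = "N", targets = "all") {
  mode <- match.arg(mode, c("reverse_complement", "upper", "lower",
                            "trim", "mask"))
  L <- n_sites(ds)
  rows <- if (identical(targets, "all")) seq_len(n_seqs(ds)) else {
    miss <- setdiff(targets, seq_names(ds))
    if (length(miss)) stop("unknown sequence(s): ", paste(miss, collapse = ", "))
    match(targets, seq_names(ds))
  }
  all_rows <- identical(targets, "all")

  if (mode %in% c("trim", "mask")) {
    if (is.null(start) || is.null(end)) stop(mode, " requires start and end")
    if (start < 0 || end > L || start >= end) {
      stop(sprintf("interval [%d,%d) out of bounds for alignment of length %d",
                   start, end, L))
    }
  }

  m <- ds$mat
  out_coding <- ds$coding
  switch(mode,
    reverse_complement = {
      m[rows, ] <- matrix(.PQ_COMPLEMENT[m[rows, , drop = FALSE]],
                          nrow = length(rows))
      m[rows, ] <- m[rows, rev(seq_len(L)), drop = FALSE]
      if (all_rows) {
        out_coding <- lapply(ds$coding, function(cr) {
          seg <- cbind(L - cr$segments[, 2], L - cr$segments[, 1])
          coding_region(seg, strand = if (cr$strand == "+") "-" else "+",
                        frame = cr$frame, scope = cr$scope)
        })
      } else if (length(ds$coding)) {
        warning("coding regions not remapped for partial reverse complement")
      }
    },
    upper = { m[rows, ] <- toupper(m[rows, , drop = FALSE]) },
    lower = { m[rows, ] <- tolower(m[rows, , drop = FALSE]) },
    trim = {
      keep <- seq.int(start + 1L, end)
      m <- m[, keep, drop = FALSE]
      out_coding <- list()
      for (cr in ds$coding) {
        seg <- cbind(pmax(cr$segments[, 1], start) - start,
                     pmin(cr$segments[, 2], end) - start)
        seg <- seg[seg[, 2] > seg[, 1], , drop = FALSE]
        if (nrow(seg) == 0) next
        out_coding <- c(out_coding,
                        list(coding_region(seg, cr$strand, cr$frame, cr$scope)))
      }
    },
    mask = {
      symbol <- normalize_residues(symbol)
      m[rows, seq.int(start + 1L, end)] <- symbol
    })

  res <- ds
  res$mat <- m
  res$coding <- list()
  for (cr in out_coding) res <- suppressWarnings(add_coding_region(res, cr))
  res
}

#' Filter alignment columns
#'
#' Drops columns by codon position and/or by gap or missing-data content. A
#' column is a gap site if any sequence carries `'-'`, and a missing site if
#' any sequence carries `'N'` or `'?'`. Codon positions (1, 2, 3) are derived
#' from the dataset-scope coding regions' frame and strand; columns outside
#' every coding region are unaffected by the codon-position filter.
#'
#' @param ds a `proseq_dataset`.
#' @param drop_codon_positions integer subset of `c(1, 2, 3)`.
#' @param drop_gap_sites,drop_missing_sites logical flags.
#' @return a filtered `proseq_dataset` (coding regions are dropped from the
#'   result when columns were removed, since their coordinates no longer
#'   apply; they are kept intact if the filter removed nothing).
#' @export
filter_sites <- function(ds, drop_codon_positions = integer(),
                         drop_gap_sites = FALSE, drop_missing_sites = FALSE) {
  L <- n_sites(ds)
  drop_codon_positions <- as.integer(drop_codon_positions)
  if (length(drop_codon_positions) &&
      !all(drop_codon_positions %in% 1:3)) {
    stop("drop_codon_positions must be a subset of 1:3")
  }
  keep <- rep(TRUE, L)

  if (length(drop_codon_positions)) {
    dswide <- Filter(function(cr) is.na(cr$scope), ds$coding)
    if (length(dswide) == 0) {
      stop("codon-position filtering requires a dataset-scope coding region")
    }
    codon_pos <- rep(NA_integer_, L)
    for (cr in dswide) {
      cols <- coding_columns(cr)
      pos <- ((seq_along(cols) - 1L) %% 3L) + 1L
      ncomplete <- 3L * (length(cols) %/% 3L)
      codon_pos[cols[seq_len(ncomplete)] + 1L] <- pos[seq_len(ncomplete)]
    }
    keep <- keep & !(codon_pos %in% drop_codon_positions)
  }
  if (drop_gap_sites && L > 0) {
    keep <- keep & !apply(ds$mat == .PQ_GAP, 2, any)
  }
  if (drop_missing_sites && L > 0) {
    keep <- keep & !apply(matrix(ds$mat %in% .PQ_MISSING, nrow = nrow(ds$mat)),
                          2, any)
  }

  if (all(keep)) return(ds)
  res <- ds
  res$mat <- ds$mat[, keep, drop = FALSE]
  res$coding <- list()
  res
}

#' Quality-control report for a project
#'
#' Produces three tables: per-dataset summaries (size, segregating sites,
#' missingness), per-coding-region checks (premature stop codons found in any
#' sequence's translation, spliced length modulo 3), and per-individual
#' missing-data fractions (gaps plus missing symbols over all residues of the
#' sequences assigned to the individual).
#'
#' @param prj a `proseq_project` (or single `proseq_dataset`).
#' @return a list of class `proseq_qc` with data.frames `datasets`,
#'   `coding_regions`, `individuals`.
#' @export
qc_report <- function(prj) {
  if (inherits(prj, "proseq_dataset")) prj <- project(list(prj))

  ds_rows <- lapply(prj$datasets, function(ds) {
    bad <- ds$mat %in% c(.PQ_MISSING, .PQ_GAP)
    data.frame(id = ds$id, n_sequences = n_seqs(ds), length = n_sites(ds),
               n_segregating = count_segregating(ds$mat),
               fraction_missing = if (length(ds$mat)) mean(bad) else 0,
               stringsAsFactors = FALSE)
  })

  cr_rows <- list()
  for (ds in prj$datasets) {
    for (ri in seq_along(ds$coding)) {
      cr <- ds$coding[[ri]]
      aa <- translate_region(ds, cr)
      internal_stop <- any(vapply(aa, function(p) {
        np <- nchar(p)
        np > 1 && grepl("*", substr(p, 1, np - 1), fixed = TRUE)
      }, logical(1)))
      cr_rows[[length(cr_rows) + 1L]] <- data.frame(
        dataset = ds$id, region = ri,
        has_premature_stop = internal_stop,
        length_mod3 = (spliced_length(cr) - cr$frame) %% 3L,
        stringsAsFactors = FALSE)
    }
  }

  ind_tot <- list(); ind_bad <- list()
  for (ds in prj$datasets) {
    inds <- individual_of(prj$popmap, seq_names(ds))
    for (r in seq_len(n_seqs(ds))) {
      key <- inds[r]
      ind_tot[[key]] <- (ind_tot[[key]] %||% 0) + n_sites(ds)
      ind_bad[[key]] <- (ind_bad[[key]] %||% 0) +
        sum(ds$mat[r, ] %in% c(.PQ_MISSING, .PQ_GAP))
    }
  }
  ind_df <- data.frame(
    individual = names(ind_tot),
    fraction_missing = vapply(names(ind_tot), function(k) {
      if (ind_tot[[k]] == 0) 0 else ind_bad[[k]] / ind_tot[[k]]
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  ind_df <- ind_df[order(ind_df$individual), , drop = FALSE]
  row.names(ind_df) <- NULL

  structure(list(
    datasets = do.call(rbind, c(ds_rows, list(make.row.names = FALSE))),
    coding_regions = if (length(cr_rows))
      do.call(rbind, cr_rows) else
      data.frame(dataset = character(), region = integer(),
                 has_premature_stop = logical(), length_mod3 = integer()),
    individuals = ind_df), class = "proseq_qc")
}

#' @export
print.proseq_qc <- function(x, ...) {
  cat("<proseq_qc>\n-- datasets --\n"); print(x$datasets)
  cat("-- coding regions --\n"); print(x$coding_regions)
  cat("-- individuals --\n"); print(x$individuals)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Segregating-site count of a residue matrix: columns with >= 2 distinct
# non-missing, non-gap nucleotide symbols (ambiguity codes are ignored).
count_segregating <- function(m) {
  if (length(m) == 0) return(0L)
  sum(apply(m, 2, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2
  }))
}
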