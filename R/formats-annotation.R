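#' Read coding/feature annotation from GFF, BED or CSV
#'
#' All coordinates are converted to the package's internal 0-based half-open
#' convention on read (GFF and the CSV dialect are 1-based inclusive, BED is
#' already 0-based half-open). The CSV dialect has the header
#' `target,start,end,strand,frame`. Multi-interval GFF features sharing an
#' `ID` (spliced CDS) share a `group` key and are spliced in coordinate
#' order when bound.
#'
#' @param path annotation file.
#' @param format `"gff"`, `"bed"` or `"csv"` (guessed from the extension by
#'   default).
#' @return data.frame with columns `target`, `feature_type`, `start`, `end`,
#'   `strand`, `frame`, `group`.
#' @export
read_annotation <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     gff = , gff3 = , gtf = "gff",
                     bed = "bed", csv = "csv",
                     stop("cannot guess annotation format of ", path))
  }
  format <- match.arg(format, c("gff", "bed", "csv"))

  if (format == "gff") {
    gr <- rtracklayer::import(path, format = "gff3")
    md <- S4Vectors::mcols(gr)
    ids <- if ("ID" %in% names(md) && any(!is.na(md$ID))) {
      ifelse(is.na(md$ID), paste0("feature", seq_along(gr)), md$ID)
    } else paste0("feature", seq_along(gr))
    frame <- if ("phase" %in% names(md)) {
      ph <- suppressWarnings(as.integer(as.character(md$phase)))
      ifelse(is.na(ph), 0L, ph)
    } else 0L
    df <- data.frame(
      target = as.character(GenomicRanges::seqnames(gr)),
      feature_type = as.character(md$type),
      start = BiocGenerics::start(gr) - 1L,   # GRanges is 1-based inclusive
      end = BiocGenerics::end(gr),
      strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-", "-", "+"),
      frame = frame, group = ids, stringsAsFactors = FALSE)
  } else if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    md <- S4Vectors::mcols(gr)
    nm <- if ("name" %in% names(md) && any(!is.na(md$name))) {
      ifelse(is.na(md$name), paste0("feature", seq_along(gr)), md$name)
    } else paste0("feature", seq_along(gr))
    df <- data.frame(
      target = as.character(GenomicRanges::seqnames(gr)),
      feature_type = "CDS",
      start = BiocGenerics::start(gr) - 1L,
      end = BiocGenerics::end(gr),
      strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-", "-", "+"),
      frame = 0L, group = nm, stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("target", "start", "end", "strand", "frame")
    if (!all(need %in% names(raw))) {
      stop("CSV annotation requires header: ", paste(need, collapse = ","))
    }
    df <- data.frame(
      target = as.character(raw$target), feature_type = "CDS",
      start = as.integer(raw$start) - 1L,   # 1-based inclusive dialect
      end = as.integer(raw$end),
      strand = ifelse(raw$strand == "-", "-", "+"),
      frame = as.integer(raw$frame),
      group = paste0("csv", seq_len(nrow(raw))), stringsAsFactors = FALSE)
  }
  df
}

#' Bind CDS annotation records to a dataset
#'
#' Only records with `feature_type == "CDS"` whose target matches the dataset
#' id or one of its sequence names become coding regions; other feature types
#' are ignored. Records sharing a `group` key are spliced into one region in
#' coordinate order. Records out of range are reported (a warning per
#' record) and skipped, not fatal.
#'
#' @param ds a `proseq_dataset`.
#' @param ann annotation data.frame from [read_annotation()].
#' @return the dataset with coding regions attached.
#' @export
bind_annotation <- function(ds, ann) {
  cds <- ann[ann$feature_type == "CDS" &
             (ann$target == ds$id | ann$target %in% seq_names(ds)), ,
             drop = FALSE]
  if (nrow(cds) == 0) return(ds)
  for (g in unique(cds$group)) {
    rows <- cds[cds$group == g, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    scope <- if (rows$target[1] %in% seq_names(ds)) rows$target[1]
             else NA_character_
    res <- try(add_coding_region(ds, coding_region(
      as.matrix(rows[, c("start", "end")]),
      strand = rows$strand[1], frame = rows$frame[1], scope = scope)),
      silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("annotation group '", g, "' skipped: ",
              conditionMessage(attr(res, "condition")))
    } else ds <- res
  }
  ds
}
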