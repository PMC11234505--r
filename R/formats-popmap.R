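#' Read and write population-structure files
#'
#' The population-structure (s2i) dialect is tab-delimited with three
#' columns, `sequence<TAB>individual<TAB>population`; `'#'` starts a comment
#' and blank lines are ignored. Writing then reading reproduces the map
#' exactly (up to comments).
#'
#' @param path file path.
#' @return a `proseq_popmap`.
#' @export
read_popmap <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) return(popmap())
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 3)) {
    bad <- keep[which(nfield != 3)[1]]
    stop(sprintf("popmap parse error at line %d: expected 3 tab-delimited fields, got %d",
                 bad, nfield[which(nfield != 3)[1]]))
  }
  m <- do.call(rbind, parts)
  popmap(trimws(m[, 1]), trimws(m[, 2]), trimws(m[, 3]))
}

#' @rdname read_popmap
#' @param pm a `proseq_popmap`.
#' @export
write_popmap <- function(pm, path) {
  writeLines(c("# sequence\tindividual\tpopulation",
               sprintf("%s\t%s\t%s", pm$sequence, pm$individual,
                       pm$population)), path)
  invisible(path)
}
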