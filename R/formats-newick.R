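#' Parse Newick text into trees
#'
#' Accepts a file path or raw Newick text holding one or more
#' `';'`-terminated trees ("brackets" format, e.g. `((A,B),C);`). Internal
#' labels, branch lengths and quoted labels are supported. Unbalanced
#' parentheses or dangling tokens raise a parse error naming the offending
#' tree and character position.
#'
#' @param x path to a Newick file, or a character scalar of Newick text.
#' @return a list of `phylo` trees (class `multiPhylo`).
#' @examples
#' parse_newick("((A:1,B:2):0.5,C:3);")
#' @export
parse_newick <- function(x) {
  text <- if (length(x) == 1 && !grepl("[();]", x) && file.exists(x)) {
    paste(readLines(x), collapse = "\n")
  } else paste(x, collapse = "\n")

  chunks <- newick_chunks(text)
  if (length(chunks) == 0) stop("no Newick tree found")
  trees <- lapply(seq_along(chunks), function(i) {
    tr <- tryCatch(ape::read.tree(text = chunks[i]),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tr)) stop(sprintf("Newick parse error in tree %d: %s",
                                  i, chunks[i]))
    tr
  })
  class(trees) <- "multiPhylo"
  trees
}

# Split Newick text into ';'-terminated chunks, validating parenthesis
# balance outside quoted labels; positions reported on error.
newick_chunks <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L; in_quote <- FALSE; buf <- character(0); chunks <- character(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (!in_quote) {
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") {
        depth <- depth - 1L
        if (depth < 0) stop("Newick parse error: unmatched ')' at position ", i)
      }
      if (ch == ";") {
        if (depth != 0) {
          stop("Newick parse error: unbalanced parentheses before ';' at position ", i)
        }
        chunks <- c(chunks, paste0(trimws(paste(buf, collapse = "")), ";"))
        buf <- character(0)
        next
      }
    }
    buf <- c(buf, ch)
  }
  if (nzchar(trimws(paste(buf, collapse = "")))) {
    stop("Newick parse error: dangling text after last ';' (missing terminator?)")
  }
  chunks
}

#' Serialize trees to Newick text
#'
#' @param trees a `phylo`, `multiPhylo`, or list of `phylo` trees.
#' @param path optional output file (one tree per line).
#' @param digits significant digits for branch lengths.
#' @return character vector of Newick strings (invisibly when `path` is
#'   given).
#' @export
write_newick <- function(trees, path = NULL, digits = 10) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  out <- vapply(trees, function(tr) {
    ape::write.tree(tr, digits = digits)
  }, character(1))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
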