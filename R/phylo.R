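#' Pairwise distance matrix of an alignment
#'
#' Computes per-pair distances under three models: `diffs` (raw number of
#' nucleotide differences, not per site), `jc` (Jukes-Cantor,
#' `d = -3/4 ln(1 - 4p/3)`) and `k2p` (Kimura two-parameter,
#' `d = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q)` with P the transition and Q the
#' transversion proportion; transitions are A<->G and C<->T). Sites with
#' gaps, missing symbols or ambiguity codes are treated as missing; with
#' `deletion = "pairwise"` each pair uses the sites where both members are
#' unambiguous, with `"complete"` only globally clean columns are used.
#' Pairs whose proportions fall outside the logarithm domain get `NA`.
#'
#' @param ds a `proseq_dataset` (or residue matrix).
#' @param model `"diffs"`, `"jc"` or `"k2p"`.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return a symmetric numeric matrix with zero diagonal and sequence-name
#'   dimnames; attribute `n_undefined` counts NA pairs.
#' @examples
#' ds <- dataset(c(a = "ACGT", b = "ACGA", c = "ATGA"))
#' distance_matrix(ds, "jc")
#' @export
distance_matrix <- function(ds, model = c("diffs", "jc", "k2p"),
                            deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  m <- if (inherits(ds, "proseq_dataset")) ds$mat else ds
  n <- nrow(m)
  if (n < 2) stop("distance matrix requires >= 2 sequences")
  isnuc <- matrix(m %in% .NUC, nrow = n)
  if (deletion == "complete") {
    clean <- colSums(isnuc) == n
    m <- m[, clean, drop = FALSE]
    isnuc <- isnuc[, clean, drop = FALSE]
  }
  is_transition <- function(a, b) {
    (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  }
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  undef <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      ok <- isnuc[i, ] & isnuc[j, ]
      nsite <- sum(ok)
      if (nsite == 0) {
        stop(sprintf("no comparable site for pair (%s, %s)",
                     rownames(m)[i], rownames(m)[j]))
      }
      a <- m[i, ok]; b <- m[j, ok]
      mismatch <- a != b
      val <- switch(model,
        diffs = sum(mismatch),
        jc = {
          p <- mean(mismatch)
          if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
        },
        k2p = {
          P <- mean(mismatch & is_transition(a, b))
          Q <- mean(mismatch & !is_transition(a, b))
          if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) NA_real_
          else -1 / 2 * log(1 - 2 * P - Q) - 1 / 4 * log(1 - 2 * Q)
        })
      if (is.na(val)) undef <- undef + 1L
      d[i, j] <- d[j, i] <- val
    }
  }
  attr(d, "n_undefined") <- undef
  attr(d, "model") <- model
  d
}

#' Neighbour-Joining tree from a distance matrix
#'
#' Studier-Keppler formulation: at each step the pair minimizing
#' `Q(i,j) = (r-2) d(i,j) - R_i - R_j` (R = row sums, r = current number of
#' taxa) is joined, with branch lengths
#' `v_i = d(i,j)/2 + (R_i - R_j)/(2(r-2))` and `v_j = d(i,j) - v_i`. Ties
#' are broken by the lowest (row, column) index pair; negative branch
#' lengths are clamped to zero (count in attribute `n_clamped`). The final
#' three-taxon join yields an unrooted tree emitted with a trifurcating
#' root.
#'
#' @param d symmetric distance matrix with dimnames (no NA entries).
#' @return a `phylo` tree with attribute `n_clamped`.
#' @examples
#' dm <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
#'              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' nj_tree(dm)
#' @export
nj_tree <- function(d) {
  if (anyNA(d)) {
    bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    stop("undefined distance for pair(s): ",
         paste(sprintf("(%s,%s)", rownames(d)[bad[, 1]],
                       colnames(d)[bad[, 2]]), collapse = ", "))
  }
  n <- nrow(d)
  if (n < 3) stop("neighbour joining requires >= 3 taxa")
  labels <- rownames(d)
  # each active cluster carries its Newick subtree string
  nodes <- as.list(labels)
  act <- d
  clamped <- 0L
  fmt <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)

  while (nrow(act) > 3) {
    r <- nrow(act)
    R <- rowSums(act)
    Q <- (r - 2) * act - outer(R, R, `+`)
    diag(Q) <- Inf
    # lowest (row, col) among ties of the minimum, scanning i < j
    best <- c(NA_integer_, NA_integer_); qmin <- Inf
    for (i in seq_len(r - 1)) {
      for (j in seq.int(i + 1, r)) {
        if (Q[i, j] < qmin - 1e-12) { qmin <- Q[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    vi <- act[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- act[i, j] - vi
    if (vi < 0) { vi <- 0; clamped <- clamped + 1L }
    if (vj < 0) { vj <- 0; clamped <- clamped + 1L }
    new_lab <- paste0("(", nodes[[i]], ":", fmt(vi), ",",
                      nodes[[j]], ":", fmt(vj), ")")
    du <- (act[i, ] + act[j, ] - act[i, j]) / 2
    du <- du[-c(i, j)]
    act <- act[-c(i, j), -c(i, j), drop = FALSE]
    act <- rbind(cbind(act, du), c(du, 0))
    nodes <- c(nodes[-c(i, j)], list(new_lab))
  }

  v1 <- (act[1, 2] + act[1, 3] - act[2, 3]) / 2
  v2 <- (act[1, 2] + act[2, 3] - act[1, 3]) / 2
  v3 <- (act[1, 3] + act[2, 3] - act[1, 2]) / 2
  v <- c(v1, v2, v3)
  neg <- v < 0
  clamped <- clamped + sum(neg)
  v[neg] <- 0
  nwk <- paste0("(", nodes[[1]], ":", fmt(v[1]), ",",
                nodes[[2]], ":", fmt(v[2]), ",",
                nodes[[3]], ":", fmt(v[3]), ");")
  tr <- ape::read.tree(text = nwk)
  attr(tr, "n_clamped") <- clamped
  tr
}

#' Neighbour-Joining trees for every dataset in a project
#'
#' Runs [distance_matrix()] + [nj_tree()] per dataset with per-dataset error
#' capture: a failing dataset yields an error record instead of aborting the
#' run.
#'
#' @param prj a `proseq_project`.
#' @param model,deletion passed to [distance_matrix()].
#' @param path optional multi-tree Newick output file (one tree per line, in
#'   project order; failed datasets are skipped in the file).
#' @return list with `trees` (named list of `phylo`, in project order) and
#'   `errors` (data.frame `dataset`, `reason`).
#' @export
nj_all_datasets <- function(prj, model = c("diffs", "jc", "k2p"),
                            deletion = c("pairwise", "complete"),
                            path = NULL) {
  model <- match.arg(model); deletion <- match.arg(deletion)
  trees <- list(); errs <- list()
  for (ds in prj$datasets) {
    res <- tryCatch(nj_tree(distance_matrix(ds, model, deletion)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(
        dataset = ds$id, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      trees[[ds$id]] <- res
    }
  }
  if (!is.null(path)) write_newick(trees, path)
  list(trees = trees,
       errors = if (length(errs)) do.call(rbind, errs) else
         data.frame(dataset = character(), reason = character()))
}
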