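# Structured-coalescent simulator. Time runs backwards in units of 2N0
# generations; with k lineages in deme i of relative size sigma_i the
# coalescence rate is k(k-1)/(2 sigma_i) and each lineage migrates at rate
# M/2 to a uniformly chosen other deme (island model, M = 4 N0 m). Rates are
# piecewise constant between epoch/join boundaries; candidate event times are
# drawn exponentially and clipped at the next boundary, where all rates are
# re-evaluated — this implements the time-inhomogeneous process exactly for
# piecewise-constant rates (memorylessness of the exponential).

#' Define a demographic scenario
#'
#' @param samples_per_pop integer vector: sampled sequences per deme.
#' @param epochs data.frame with a `time` column (start of each epoch,
#'   strictly increasing from 0) and one `size<i>` column per deme giving
#'   relative deme sizes; default a single epoch of size 1.
#' @param migration scaled symmetric island-model migration rate `M = 4 N0 m`.
#' @param joins optional data.frame `time`, `source`, `dest`: at `time`, all
#'   lineages of deme `source` move into deme `dest` (backwards in time).
#' @return an object of class `proseq_demography`.
#' @examples
#' demography(c(5, 5), migration = 1)
#' @export
demography <- function(samples_per_pop, epochs = NULL, migration = 0,
                       joins = NULL) {
  n_pops <- length(samples_per_pop)
  stopifnot(n_pops >= 1, all(samples_per_pop >= 0), sum(samples_per_pop) >= 2)
  if (is.null(epochs)) {
    epochs <- data.frame(time = 0)
    for (i in seq_len(n_pops)) epochs[[paste0("size", i)]] <- 1
  }
  stopifnot(identical(epochs$time[1], 0) || epochs$time[1] == 0)
  if (is.unsorted(epochs$time, strictly = TRUE)) {
    stop("epoch times must be strictly increasing from 0")
  }
  sizes <- as.matrix(epochs[, paste0("size", seq_len(n_pops)), drop = FALSE])
  if (any(sizes <= 0)) stop("relative sizes must be positive")
  if (!is.null(joins)) {
    stopifnot(all(c("time", "source", "dest") %in% names(joins)))
    joins <- joins[order(joins$time), , drop = FALSE]
  }
  if (n_pops > 1 && migration == 0) {
    # with no migration, joins must funnel every deme into one
    alive <- seq_len(n_pops)
    if (!is.null(joins)) {
      for (r in seq_len(nrow(joins))) {
        alive <- setdiff(alive, joins$source[r])
      }
    }
    if (length(alive) > 1) {
      stop("with several demes and zero migration, join events must merge ",
           "all demes or the process never reaches a common ancestor")
    }
  }
  structure(list(n_pops = n_pops, samples_per_pop = as.integer(samples_per_pop),
                 epoch_times = epochs$time, sizes = sizes,
                 migration = migration, joins = joins),
            class = "proseq_demography")
}

#' Simulate one coalescent genealogy
#'
#' Runs the structured-coalescent event loop under a demographic scenario
#' until a single ancestral lineage remains.
#'
#' @param dem a `proseq_demography`.
#' @return an object of class `proseq_genealogy`: a rooted binary ultrametric
#'   tree over the samples with node times in coalescent units; tip labels
#'   are `p<deme>_<i>`.
#' @examples
#' set.seed(1)
#' g <- simulate_genealogy(demography(4))
#' g$tmrca
#' @export
simulate_genealogy <- function(dem) {
  n <- sum(dem$samples_per_pop)
  n_nodes <- 2L * n - 1L
  parent <- rep(NA_integer_, n_nodes)
  children <- matrix(NA_integer_, n_nodes, 2)
  node_time <- numeric(n_nodes)
  tip_pop <- rep(seq_len(dem$n_pops), dem$samples_per_pop)
  tip_label <- unlist(lapply(seq_len(dem$n_pops), function(i) {
    paste0("p", i, "_", seq_len(dem$samples_per_pop[i]))
  }))

  active <- seq_len(n)                   # node ids of live lineages
  lin_pop <- tip_pop
  next_node <- n + 1L
  t <- 0

  boundaries <- sort(unique(c(dem$epoch_times[-1],
                              if (!is.null(dem$joins)) dem$joins$time)))
  done_joins <- logical(if (is.null(dem$joins)) 0 else nrow(dem$joins))

  current_sizes <- function(t) {
    e <- findInterval(t, dem$epoch_times)
    dem$sizes[max(e, 1L), ]
  }

  while (length(active) > 1) {
    sig <- current_sizes(t)
    k <- tabulate(lin_pop, dem$n_pops)
    coal_rate <- k * (k - 1) / (2 * sig)
    mig_rate_tot <- if (dem$n_pops > 1) sum(k) * dem$migration / 2 else 0
    lambda <- sum(coal_rate) + mig_rate_tot
    nb <- boundaries[boundaries > t]
    nxt <- if (length(nb)) nb[1] else Inf

    dt <- if (lambda > 0) stats::rexp(1, lambda) else Inf
    if (t + dt >= nxt) {
      t <- nxt
      if (!is.null(dem$joins)) {
        due <- which(!done_joins & dem$joins$time <= t)
        for (r in due) {
          lin_pop[lin_pop == dem$joins$source[r]] <- dem$joins$dest[r]
          done_joins[r] <- TRUE
        }
      }
      if (is.infinite(nxt)) stop("non-terminating demography (zero total rate)")
      next
    }
    t <- t + dt
    u <- stats::runif(1) * lambda
    if (u < sum(coal_rate)) {
      pop <- which(u < cumsum(coal_rate))[1]
      pair <- sample(which(lin_pop == pop), 2L)
      node <- next_node; next_node <- next_node + 1L
      node_time[node] <- t
      children[node, ] <- active[pair]
      parent[active[pair]] <- node
      keep <- setdiff(seq_along(active), pair)
      active <- c(active[keep], node)
      lin_pop <- c(lin_pop[keep], pop)
    } else {
      li <- sample(length(active), 1L)
      targets <- setdiff(seq_len(dem$n_pops), lin_pop[li])
      lin_pop[li] <- if (length(targets) == 1) targets else sample(targets, 1L)
    }
  }

  structure(list(n = n, parent = parent, children = children,
                 node_time = node_time, tip_label = tip_label,
                 tip_pop = tip_pop, root = n_nodes,
                 tmrca = node_time[n_nodes],
                 total_length = sum(node_time[parent[-n_nodes]] -
                                      node_time[-n_nodes])),
            class = "proseq_genealogy")
}

#' @export
print.proseq_genealogy <- function(x, ...) {
  cat(sprintf("<proseq_genealogy> %d tips, TMRCA=%.4f, total length=%.4f\n",
              x$n, x$tmrca, x$total_length))
  invisible(x)
}

#' Serialize a genealogy to Newick
#'
#' @param gen a `proseq_genealogy`.
#' @param digits significant digits for branch lengths.
#' @return a Newick string (rooted, binary, ultrametric).
#' @export
genealogy_newick <- function(gen, digits = 12) {
  build <- function(v) {
    if (v <= gen$n) return(gen$tip_label[v])
    ch <- gen$children[v, ]
    bl <- gen$node_time[v] - gen$node_time[ch]
    paste0("(", build(ch[1]), ":", format(bl[1], digits = digits),
           ",", build(ch[2]), ":", format(bl[2], digits = digits), ")")
  }
  paste0(build(gen$root), ";")
}

#' Convert a genealogy to an ape `phylo` tree
#' @param gen a `proseq_genealogy`.
#' @return a `phylo` object.
#' @export
genealogy_phylo <- function(gen) {
  ape::read.tree(text = genealogy_newick(gen))
}

# 0/1 membership: which tips descend from each node (n_nodes x n matrix).
tipsets <- function(gen) {
  n_nodes <- 2L * gen$n - 1L
  ts <- matrix(FALSE, n_nodes, gen$n)
  ts[cbind(seq_len(gen$n), seq_len(gen$n))] <- TRUE
  for (v in seq.int(gen$n + 1L, n_nodes)) {
    ch <- gen$children[v, ]
    ts[v, ] <- ts[ch[1], ] | ts[ch[2], ]
  }
  ts
}

#' Drop mutations on a genealogy (infinite-sites)
#'
#' Places mutations on branches — Poisson with mean `theta/2 * length` per
#' branch in `theta` mode, or exactly `S` mutations with probability
#' proportional to branch length in `fixed_S` mode — then assigns each
#' mutation a distinct site among `L` positions. The ancestral base at every
#' site is uniform on A/C/G/T and the derived base uniform on the remaining
#' three; tips below the mutated branch inherit the derived state.
#'
#' @param gen a `proseq_genealogy`.
#' @param L number of sites in the simulated alignment.
#' @param mode `"theta"` or `"fixed_S"`.
#' @param theta population mutation rate per locus (theta mode).
#' @param S number of segregating sites to place (fixed_S mode, `S <= L`).
#' @param id dataset id.
#' @return a `proseq_dataset` of `n` sequences and `L` sites.
#' @export
drop_mutations <- function(gen, L, mode = c("theta", "fixed_S"),
                           theta = NULL, S = NULL, id = "sim") {
  mode <- match.arg(mode)
  branch_nodes <- setdiff(seq_len(2L * gen$n - 1L), gen$root)
  bl <- gen$node_time[gen$parent[branch_nodes]] - gen$node_time[branch_nodes]

  if (mode == "theta") {
    stopifnot(!is.null(theta), theta > 0)
    nmut <- stats::rpois(length(bl), theta / 2 * bl)
    mut_branch <- rep(branch_nodes, nmut)
    if (length(mut_branch) > L) {
      stop("more mutations (", length(mut_branch), ") than sites (", L,
           "); increase L for an infinite-sites alignment")
    }
  } else {
    stopifnot(!is.null(S), S >= 0, S <= L)
    mut_branch <- branch_nodes[sample.int(length(bl), S, replace = TRUE,
                                          prob = bl)]
  }

  nm <- length(mut_branch)
  anc <- sample(.NUC, L, replace = TRUE)
  mat <- matrix(rep(anc, each = gen$n), nrow = gen$n)
  rownames(mat) <- gen$tip_label
  if (nm > 0) {
    sites <- sample.int(L, nm)
    ts <- tipsets(gen)
    for (i in seq_len(nm)) {
      derived <- sample(setdiff(.NUC, anc[sites[i]]), 1L)
      mat[ts[mut_branch[i], ], sites[i]] <- derived
    }
  }
  dataset(mat, id = id)
}

#' Simulate empirical critical values for a statistic
#'
#' Repeatedly simulates genealogies under a demographic scenario, drops
#' mutations, evaluates the chosen statistic on each simulated alignment,
#' and returns empirical null-distribution quantiles (order statistics at
#' 1-based index `ceiling(q * R)` over the defined replicate values).
#' Replicate sub-seeds are drawn once from the master seed, so the report is
#' identical for identical seeds and replicate r is reproducible in
#' isolation.
#'
#' @param dem a `proseq_demography`.
#' @param statistic one of `"TajimasD"`, `"ZnS"`, `"pi"`, `"S"` (`pi` is the
#'   per-locus mean pairwise difference count).
#' @param n_reps number of replicates (a warning is issued below 100).
#' @param quantiles probabilities for the reported critical values.
#' @param seed master seed (integer).
#' @inheritParams drop_mutations
#' @return an object of class `proseq_simreport`: list with `values`,
#'   `quantiles`, `n_reps`, `n_defined`, `statistic`, `seed`.
#' @export
simulate_critical_values <- function(dem, L = 1000L,
                                     mode = c("theta", "fixed_S"),
                                     theta = NULL, S = NULL,
                                     statistic = c("TajimasD", "ZnS", "pi", "S"),
                                     n_reps = 1000L,
                                     quantiles = c(0.025, 0.975),
                                     seed = 1L) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  if (n_reps < 100) warning("fewer than 100 replicates: quantiles are coarse")
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_reps))

  vals <- vapply(seq_len(n_reps), function(r) {
    with_seed(rep_seeds[r], {
      gen <- simulate_genealogy(dem)
      ds <- drop_mutations(gen, L, mode, theta = theta, S = S)
      d <- diversity(ds)
      switch(statistic,
             TajimasD = d$tajimas_D, ZnS = d$znS,
             pi = d$pi_per_locus, S = as.numeric(d$S))
    })
  }, numeric(1))

  defined <- vals[!is.na(vals)]
  if (length(defined) == 0) {
    stop("statistic undefined in every replicate")
  }
  sorted <- sort(defined)
  qv <- stats::setNames(
    sorted[pmin(pmax(ceiling(quantiles * length(sorted)), 1L), length(sorted))],
    paste0("q", quantiles))
  structure(list(values = vals, quantiles = qv, n_reps = n_reps,
                 n_defined = length(defined), statistic = statistic,
                 seed = seed),
            class = "proseq_simreport")
}

#' @export
print.proseq_simreport <- function(x, ...) {
  cat(sprintf("<proseq_simreport> %s, %d reps (%d defined), seed %d\n",
              x$statistic, x$n_reps, x$n_defined, x$seed))
  print(x$quantiles)
  invisible(x)
}
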