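# Heterochronous coalescent simulation under piecewise-constant haploid
# demography, mutation dropping, and genealogy-level summary statistics.
#
# Coalescence rate for k active lineages in an epoch of haploid size N is
# k(k-1)/(2N) per generation; waiting times are truncated at epoch
# boundaries and at sample-activation times.

#' Serial sampling configuration
#'
#' Describes how many sequences are sampled in each dated layer and the locus
#' length. Defaults reproduce the study shape: 79 modern sequences at the
#' present (age 0), 39 historical sequences at age 5 generations, and a
#' 16,588 bp mitogenome-sized locus.
#'
#' @param layer Character vector of layer labels.
#' @param n Integer vector of per-layer sample counts (>= 1).
#' @param age Numeric vector of layer ages in generations before present.
#' @param locus_length Number of sites in the locus.
#' @return A tibble (class `sample_config`) with columns `layer`, `n`, `age`,
#'   sorted by increasing age, carrying `locus_length` as an attribute.
#' @export
#' @examples
#' sample_config()
sample_config <- function(layer = c("modern", "historical"),
                          n = c(79L, 39L),
                          age = c(0, 5),
                          locus_length = 16588L) {
  stopifnot(length(layer) == length(n), length(n) == length(age),
            all(n >= 1), all(age >= 0), length(layer) >= 1,
            !anyDuplicated(layer), locus_length >= 1)
  ord <- order(age)
  out <- tibble::tibble(layer = as.character(layer)[ord],
                        n = as.integer(n)[ord], age = as.numeric(age)[ord])
  attr(out, "locus_length") <- as.integer(locus_length)
  class(out) <- c("sample_config", class(out))
  out
}

#' @rdname sample_config
#' @param config A `sample_config`.
#' @export
locus_length <- function(config) {
  L <- attr(config, "locus_length", exact = TRUE)
  if (is.null(L)) stop("not a sample_config: no locus_length attribute")
  L
}

new_genealogy <- function(parent, time, tip_layer, layers, tip_label = NULL) {
  n <- length(tip_layer)
  if (is.null(tip_label)) {
    idx <- stats::ave(seq_along(tip_layer), tip_layer, FUN = seq_along)
    tip_label <- sprintf("%s_%03d", tip_layer, idx)
  }
  structure(list(n_tip = n, parent = parent, time = time,
                 tip_layer = tip_layer, tip_label = tip_label,
                 layers = layers),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat("<genealogy>", x$n_tip, "tips,",
      paste(x$layers$n, x$layers$layer, collapse = " + "),
      sprintf("; TMRCA %.4g generations\n", max(x$time)))
  invisible(x)
}

#' Simulate a serially sampled coalescent genealogy
#'
#' Lineages become active at their layer's age going backwards in time; while
#' k >= 2 lineages are active within an epoch of haploid size N the waiting
#' time to the next coalescence is exponential with rate k(k-1)/(2N),
#' truncated at epoch boundaries and at lineage-activation times. Always
#' terminates for finite sizes and returns a fully coalesced binary tree.
#'
#' @param scenario A `demographic_scenario` from [build_scenario()].
#' @param config A [sample_config()].
#' @return A `genealogy`: tips are numbered 1..n grouped by layer in
#'   increasing age order; internal nodes n+1..2n-1 in increasing coalescence
#'   time order, the root last. Node times are in generations before present.
#' @export
#' @examples
#' sc <- build_scenario("constant", list(ne_constant = 500, mu = 1e-8))
#' set.seed(1)
#' simulate_genealogy(sc, sample_config(n = c(5L, 3L)))
simulate_genealogy <- function(scenario, config) {
  stopifnot(inherits(scenario, "demographic_scenario"),
            inherits(config, "sample_config"))
  layers <- config
  n <- sum(layers$n)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  time <- numeric(n_nodes)
  nlay <- nrow(layers)
  tip_layer <- rep(layers$layer, layers$n)
  time[seq_len(n)] <- rep(layers$age, layers$n)
  counts <- matrix(0L, n_nodes, nlay)
  counts[cbind(seq_len(n), rep(seq_len(nlay), layers$n))] <- 1L
  if (n == 1) {
    g <- new_genealogy(parent, time, tip_layer, layers)
    g$layer_counts <- counts
    g$locus_length <- locus_length(config)
    return(g)
  }
  tip_ids <- split(seq_len(n), rep(seq_len(nlay), layers$n))
  ep_starts <- scenario$epochs$start
  ep_sizes <- scenario$epochs$size
  n_ep <- length(ep_starts)
  active <- integer(n)  # preallocated; first k entries are live
  k <- 0L
  li <- 1L
  t <- layers$age[1]
  ei <- 1L
  nxt <- n + 1L
  while (nxt <= n_nodes) {
    while (li <= nlay && layers$age[li] <= t) {
      ids <- tip_ids[[li]]
      active[k + seq_along(ids)] <- ids
      k <- k + length(ids)
      li <- li + 1L
    }
    next_act <- if (li <= nlay) layers$age[li] else Inf
    if (k < 2) {
      t <- next_act
      next
    }
    while (ei < n_ep && ep_starts[ei + 1L] <= t) ei <- ei + 1L
    bnd <- min(next_act, if (ei < n_ep) ep_starts[ei + 1L] else Inf)
    dt <- stats::rexp(1, k * (k - 1) / (2 * ep_sizes[ei]))
    if (t + dt < bnd) {
      t <- t + dt
      pick <- sample.int(k, 2L)
      a <- active[pick[1L]]
      b <- active[pick[2L]]
      parent[a] <- nxt
      parent[b] <- nxt
      time[nxt] <- t
      counts[nxt, ] <- counts[a, ] + counts[b, ]
      active[pick[1L]] <- nxt
      active[pick[2L]] <- active[k]
      k <- k - 1L
      nxt <- nxt + 1L
    } else {
      t <- bnd
    }
  }
  g <- new_genealogy(parent, time, tip_layer, layers)
  g$layer_counts <- counts
  g$locus_length <- locus_length(config)
  g
}

# edge (branch above node v) lengths for all non-root nodes
edge_lengths <- function(gen) {
  ch <- seq_len(2L * gen$n_tip - 2L)
  gen$time[gen$parent[ch]] - gen$time[ch]
}

#' Poisson mutation counts per branch
#'
#' Draws the number of mutations on the branch above each non-root node as
#' Poisson(mu * locus_length * branch length).
#'
#' @param gen A `genealogy`.
#' @param mu Per-site per-generation mutation rate (> 0).
#' @param locus_length Number of sites.
#' @return Integer vector indexed by child node (1..2n-2).
#' @export
mutate_edges <- function(gen, mu, locus_length = gen$locus_length) {
  stopifnot(inherits(gen, "genealogy"), mu > 0)
  if (gen$n_tip < 2) return(integer(0))
  stats::rpois(2L * gen$n_tip - 2L, mu * locus_length * edge_lengths(gen))
}

# descendant tip lists per node (children precede parents in node id order)
descendant_tips <- function(gen) {
  n <- gen$n_tip
  n_nodes <- 2L * n - 1L
  desc <- vector("list", n_nodes)
  desc[seq_len(n)] <- as.list(seq_len(n))
  if (n >= 2) {
    kids <- split(seq_len(n_nodes - 1L), gen$parent[seq_len(n_nodes - 1L)])
    for (m in (n + 1L):n_nodes) {
      k <- kids[[as.character(m)]]
      desc[[m]] <- c(desc[[k[1L]]], desc[[k[2L]]])
    }
  }
  desc
}

#' Drop mutations on a genealogy and build an alignment
#'
#' Under the default infinite-sites model every mutation occupies a fresh
#' site (the ancestral sequence is all-A; only variation is meaningful) and
#' an error is raised if the locus runs out of sites. Under the Jukes-Cantor
#' finite-sites model the ancestral sequence is uniform random, each mutation
#' hits a uniformly chosen site (with replacement) and changes the current
#' base to one of the three alternatives.
#'
#' @param gen A `genealogy`.
#' @param mu Per-site per-generation mutation rate.
#' @param locus_length Number of sites.
#' @param model `"infinite_sites"` (default) or `"jukes_cantor"`.
#' @param mut_counts Optional precomputed per-branch mutation counts from
#'   [mutate_edges()]; drawn internally when `NULL`.
#' @return A [temporal_alignment()].
#' @export
drop_mutations <- function(gen, mu, locus_length = gen$locus_length,
                           model = c("infinite_sites", "jukes_cantor"),
                           mut_counts = NULL) {
  stopifnot(inherits(gen, "genealogy"))
  model <- match.arg(model)
  n <- gen$n_tip
  L <- as.integer(locus_length)
  if (is.null(mut_counts)) mut_counts <- mutate_edges(gen, mu, L)
  bases <- c("A", "C", "G", "T")
  if (n < 2) {
    s <- if (model == "infinite_sites") rep("A", L) else
      sample(bases, L, replace = TRUE)
    seqs <- paste(s, collapse = "")
    names(seqs) <- gen$tip_label
    return(temporal_alignment(seqs, genealogy_meta(gen)))
  }
  if (model == "infinite_sites") {
    M <- sum(mut_counts)
    if (M > L) {
      stop("infinite-sites model needs ", M, " distinct sites but the locus ",
           "has only ", L, "; use model = \"jukes_cantor\"", call. = FALSE)
    }
    mat <- matrix("A", n, L)
    if (M > 0) {
      sites <- sample.int(L, M)
      derived <- sample(c("C", "G", "T"), M, replace = TRUE)
      desc <- descendant_tips(gen)
      pos <- 0L
      for (v in which(mut_counts > 0L)) {
        m <- mut_counts[v]
        idx <- pos + seq_len(m)
        rows <- desc[[v]]
        mat[rows, sites[idx]] <- rep(derived[idx], each = length(rows))
        pos <- pos + m
      }
    }
  } else {
    n_nodes <- 2L * n - 1L
    node_seq <- vector("list", n_nodes)
    node_seq[[n_nodes]] <- sample(bases, L, replace = TRUE)
    for (v in (n_nodes - 1L):1L) {
      s <- node_seq[[gen$parent[v]]]
      m <- mut_counts[v]
      if (m > 0L) {
        hit <- sample.int(L, m, replace = TRUE)
        for (j in seq_len(m)) {
          s[hit[j]] <- sample(setdiff(bases, s[hit[j]]), 1L)
        }
      }
      node_seq[[v]] <- s
    }
    mat <- do.call(rbind, node_seq[seq_len(n)])
  }
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- gen$tip_label
  temporal_alignment(seqs, genealogy_meta(gen))
}

genealogy_meta <- function(gen) {
  tibble::tibble(
    sample_id = gen$tip_label,
    layer = gen$tip_layer,
    age_generations = gen$layers$age[match(gen$tip_layer, gen$layers$layer)]
  )
}

#' Per-layer summary statistics straight from a genealogy
#'
#' Computes the (n, h, S, k, D) summary vector of each layer from the
#' genealogy topology and per-branch mutation counts under infinite-sites
#' bookkeeping, without materialising sequences: a branch with c carriers in
#' a layer of size n_l contributes its mutations to S when 0 < c < n_l and
#' c(n_l - c) pairwise differences per mutation. Haplotype classes are the
#' connected components after contracting mutation-free branches. Equals the
#' sequence route ([drop_mutations()] + [layer_stats()]) exactly for the same
#' mutation counts.
#'
#' @param gen A `genealogy` from [simulate_genealogy()].
#' @param mut_counts Per-branch mutation counts from [mutate_edges()].
#' @return Tibble with one row per layer (increasing age): `layer`, `age`,
#'   `n`, `h`, `S`, `k`, `D` (`D` is `NA` when `S` = 0).
#' @export
genealogy_features <- function(gen, mut_counts) {
  stopifnot(inherits(gen, "genealogy"))
  n <- gen$n_tip
  n_nodes <- 2L * n - 1L
  children <- seq_len(max(n_nodes - 1L, 0L))
  stopifnot(length(mut_counts) == length(children))
  # haplotype classes = components after contracting mutation-free edges;
  # children always have smaller ids than parents, so one top-down pass
  # labels every node with its highest mutation-free ancestor
  rep_node <- seq_len(n_nodes)
  for (v in rev(children)) {
    if (mut_counts[v] == 0L) rep_node[v] <- rep_node[gen$parent[v]]
  }
  tip_rep <- rep_node[seq_len(n)]
  lay <- gen$layers
  nlay <- nrow(lay)
  h <- S <- integer(nlay)
  k <- D <- numeric(nlay)
  for (l in seq_len(nlay)) {
    nl <- lay$n[l]
    ce <- gen$layer_counts[children, l]
    S[l] <- sum(mut_counts[ce > 0L & ce < nl])
    k[l] <- if (nl >= 2) sum(mut_counts * ce * (nl - ce)) / choose(nl, 2) else NA_real_
    h[l] <- length(unique(tip_rep[gen$tip_layer == lay$layer[l]]))
    D[l] <- if (nl >= 4 && S[l] >= 1) tajimas_d(nl, S[l], k[l]) else NA_real_
  }
  tibble::tibble(layer = lay$layer, age = lay$age, n = lay$n,
                 h = h, S = S, k = k, D = D)
}

#' Convert a genealogy to an ape phylogeny
#'
#' Branch lengths are in generations before present. Parses back (via
#' [ape::read.tree()]) to an identical topology and node times.
#'
#' @param x A `genealogy`.
#' @param ... Unused.
#' @return An [ape::as.phylo] `phylo` object.
#' @method as.phylo genealogy
#' @export
as.phylo.genealogy <- function(x, ...) {
  n <- x$n_tip
  if (n < 2) stop("ape cannot represent a single-tip tree", call. = FALSE)
  n_nodes <- 2L * n - 1L
  # internal nodes are in increasing time order; ape wants the root at n+1
  ape_id <- c(seq_len(n), rev(seq.int(n + 1L, n_nodes)))
  children <- seq_len(n_nodes - 1L)
  edge <- cbind(ape_id[x$parent[children]], ape_id[children])
  tr <- structure(list(edge = edge,
                       edge.length = edge_lengths(x),
                       tip.label = x$tip_label,
                       Nnode = n - 1L),
                  class = "phylo")
  stats::reorder(tr, "cladewise")
}

#' Newick export of a genealogy
#'
#' @param gen A `genealogy`.
#' @return A Newick string with branch lengths in generations. A single-tip
#'   genealogy is written as `"label;"`.
#' @export
to_newick <- function(gen) {
  stopifnot(inherits(gen, "genealogy"))
  if (gen$n_tip < 2) return(paste0(gen$tip_label, ";"))
  ape::write.tree(as.phylo(gen))
}
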