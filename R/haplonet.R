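# Haplotype collapsing, temporal sharing, and minimum-spanning networks
# (union of all minimum spanning trees over Hamming distances).

#' Collapse an alignment into haplotypes
#'
#' Haplotypes are equivalence classes of identical sequences over the
#' effective columns (complete-deletion policy shared with the diversity
#' statistics, avoiding wildcard-matching ambiguity from undetermined bases).
#'
#' @param aln A [temporal_alignment()].
#' @return A `haplotype_table` tibble: `haplotype` id, `sequence`
#'   (representative sequence over effective columns), one count column per
#'   layer (`n_<layer>`), `n_total`. Attribute `columns` stores the retained
#'   column indices.
#' @export
collapse_haplotypes <- function(aln) {
  mat <- aln_matrix(aln)
  keep <- effective_columns(mat, "complete_deletion")
  key <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  first <- !duplicated(key)
  ids <- match(key, key[first])
  layers <- alignment_layers(aln)
  out <- tibble::tibble(
    haplotype = sprintf("hap%02d", seq_len(sum(first))),
    sequence = key[first]
  )
  for (l in layers$layer) {
    out[[paste0("n_", l)]] <- as.integer(
      tabulate(ids[aln$meta$layer == l], nbins = sum(first)))
  }
  out$n_total <- as.integer(tabulate(ids, nbins = sum(first)))
  attr(out, "columns") <- keep
  attr(out, "layers") <- layers$layer
  class(out) <- c("haplotype_table", class(out))
  out
}

layer_count_cols <- function(ht) {
  layers <- attr(ht, "layers", exact = TRUE)
  if (is.null(layers)) {
    grep("^n_(?!total)", names(ht), perl = TRUE, value = TRUE)
  } else {
    paste0("n_", layers)
  }
}

#' Haplotypes shared across time layers
#'
#' @param ht A `haplotype_table` from [collapse_haplotypes()] covering at
#'   least two layers.
#' @return List with `n_shared` (count of haplotypes present in >= 2 layers)
#'   and `patterns` (tibble: haplotype, per-layer presence, `n_layers`).
#' @export
temporal_shared <- function(ht) {
  cols <- layer_count_cols(ht)
  if (length(cols) < 2) {
    stop("temporal sharing needs at least 2 layers", call. = FALSE)
  }
  pres <- as.matrix(ht[, cols]) > 0
  colnames(pres) <- sub("^n_", "in_", cols)
  patterns <- dplyr::bind_cols(ht["haplotype"], tibble::as_tibble(pres))
  patterns$n_layers <- rowSums(pres)
  list(n_shared = sum(patterns$n_layers >= 2), patterns = patterns)
}

#' Pairwise mutational steps between haplotypes
#'
#' Hamming distances between the representative sequences (over effective
#' columns).
#'
#' @param ht A `haplotype_table`.
#' @return Symmetric integer matrix with haplotype ids as dimnames.
#' @export
pairwise_steps <- function(ht) {
  chars <- do.call(rbind, strsplit(ht$sequence, "", fixed = TRUE))
  nh <- nrow(chars)
  d <- matrix(0L, nh, nh, dimnames = list(ht$haplotype, ht$haplotype))
  if (nh >= 2) {
    for (i in seq_len(nh - 1)) {
      for (j in (i + 1):nh) {
        d[i, j] <- d[j, i] <- sum(chars[i, ] != chars[j, ])
      }
    }
  }
  d
}

#' Minimum-spanning haplotype network
#'
#' The union of all minimum spanning trees of the complete haplotype graph
#' under Hamming distances: working through distance tiers in increasing
#' order (Kruskal-style), every tie edge joining two distinct components is
#' included before the components are merged. This spanning-network variant
#' retains alternative equally parsimonious connections that a single MST
#' would drop; inferred median (unsampled intermediate) haplotypes are not
#' added.
#'
#' @param ht A `haplotype_table` with >= 2 haplotypes.
#' @return A `haplotype_network`: list with `nodes` (the haplotype table) and
#'   `edges` (tibble `from`, `to`, `steps`, `in_msn` = TRUE).
#' @export
min_spanning_network <- function(ht) {
  if (nrow(ht) < 2) stop("need at least 2 haplotypes", call. = FALSE)
  d <- pairwise_steps(ht)
  nh <- nrow(ht)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  wt <- d[pairs]
  ord <- order(wt)
  comp <- seq_len(nh)
  edges <- list()
  for (tier in sort(unique(wt))) {
    in_tier <- ord[wt[ord] == tier]
    # include every tie edge joining distinct components at this tier ...
    joins <- in_tier[comp[pairs[in_tier, 1]] != comp[pairs[in_tier, 2]]]
    for (e in joins) {
      edges[[length(edges) + 1]] <- c(pairs[e, 1], pairs[e, 2], tier)
    }
    # ... then merge
    for (e in joins) {
      ca <- comp[pairs[e, 1]]
      cb <- comp[pairs[e, 2]]
      if (ca != cb) comp[comp == cb] <- ca
    }
    if (length(unique(comp)) == 1) break
  }
  em <- do.call(rbind, edges)
  net <- structure(
    list(nodes = ht,
         edges = tibble::tibble(from = ht$haplotype[em[, 1]],
                                to = ht$haplotype[em[, 2]],
                                steps = as.integer(em[, 3]),
                                in_msn = TRUE)),
    class = "haplotype_network")
  net
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("<haplotype_network>", nrow(x$nodes), "haplotypes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Convert a haplotype network to igraph
#'
#' @param net A `haplotype_network`.
#' @return An [igraph::graph_from_data_frame()] graph with per-layer counts
#'   as vertex attributes and `steps` as edge weight.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "haplotype_network"))
  verts <- as.data.frame(net$nodes[, c("haplotype",
                                       layer_count_cols(net$nodes),
                                       "n_total")])
  igraph::graph_from_data_frame(
    data.frame(from = net$edges$from, to = net$edges$to,
               weight = net$edges$steps),
    directed = FALSE, vertices = verts)
}

#' Export a haplotype network
#'
#' Writes the edge list as TSV and the graph as GraphML.
#'
#' @param net A `haplotype_network`.
#' @param edges_tsv,graphml Output paths (either may be `NULL` to skip).
#' @return Invisibly, the network.
#' @export
write_network <- function(net, edges_tsv = NULL, graphml = NULL) {
  if (!is.null(edges_tsv)) readr::write_tsv(net$edges, edges_tsv)
  if (!is.null(graphml)) {
    igraph::write_graph(as_igraph(net), graphml, format = "graphml")
  }
  invisible(net)
}
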