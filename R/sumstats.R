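# Per-layer diversity statistics (h, S, Hd, pi, k, Tajima's D, Fu's Fs) and
# the ABC summary-statistic vector.

# base counts per column for an A/C/G/T character matrix
base_counts <- function(mat) {
  vapply(c("A", "C", "G", "T"), function(b) colSums(mat == b),
         numeric(ncol(mat)))
}

#' Number of segregating sites
#'
#' Count of effective columns carrying at least two distinct bases.
#'
#' @param aln A [temporal_alignment()].
#' @param policy Missing-data policy, see [effective_columns()].
#' @return Integer count.
#' @export
segregating_sites <- function(aln, policy = "complete_deletion") {
  mat <- aln_matrix(aln)
  if (nrow(mat) < 2) stop("need at least 2 sequences", call. = FALSE)
  if (policy == "complete_deletion") {
    mat <- mat[, effective_columns(mat, policy), drop = FALSE]
    cnt <- base_counts(mat)
    sum(rowSums(cnt > 0) >= 2)
  } else {
    # a site segregates when >= 2 distinct determined bases occur
    cnt <- base_counts(mat)
    sum(rowSums(cnt > 0) >= 2)
  }
}

#' Mean pairwise differences
#'
#' Average over all n(n-1)/2 unordered sequence pairs of the number of
#' differing effective columns. Under the `pairwise` policy each pair is
#' compared over the columns where both sequences are determined.
#'
#' @inheritParams segregating_sites
#' @return `k`, the mean number of pairwise differences (in sites).
#' @export
mean_pairwise_differences <- function(aln, policy = "complete_deletion") {
  mat <- aln_matrix(aln)
  n <- nrow(mat)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  if (policy == "complete_deletion") {
    mat <- mat[, effective_columns(mat, policy), drop = FALSE]
    cnt <- base_counts(mat)
    # sum_b c_b (n - c_b) double-counts each differing unordered pair once
    sum(cnt * (n - cnt)) / 2 / choose(n, 2)
  } else {
    tot <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ok <- mat[i, ] != "N" & mat[j, ] != "N" & mat[i, ] != "-" & mat[j, ] != "-"
        tot <- tot + sum(mat[i, ok] != mat[j, ok])
      }
    }
    tot / choose(n, 2)
  }
}

#' Nucleotide diversity per site
#'
#' pi = k / L_eff, with the sampling standard error of Tajima (1983)/Nei
#' (1987, eq. 10.7) for a non-recombining locus:
#' V(pi) = pi (n+1) / (3 (n-1) L) + pi^2 2 (n^2 + n + 3) / (9 n (n-1)).
#'
#' @inheritParams segregating_sites
#' @return Tibble with `pi`, `pi_se`, `k`, `L_eff`.
#' @export
nucleotide_diversity <- function(aln, policy = "complete_deletion") {
  n <- length(aln$seq)
  L_eff <- if (policy == "complete_deletion") {
    length(effective_columns(aln, policy))
  } else {
    n_sites(aln)
  }
  k <- mean_pairwise_differences(aln, policy)
  pi <- k / L_eff
  v <- pi * (n + 1) / (3 * (n - 1) * L_eff) +
    pi^2 * 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  tibble::tibble(pi = pi, pi_se = sqrt(v), k = k, L_eff = L_eff)
}

#' Haplotype count and diversity
#'
#' Haplotypes are equivalence classes of identical sequences over the
#' effective columns. Hd = n (1 - sum p_i^2) / (n - 1) with p_i the haplotype
#' frequencies; its standard error follows Nei (1987, eq. 8.12):
#' V(Hd) = 2 / (n (n-1)) * (2 (n-2) (sum p^3 - (sum p^2)^2)
#'                          + sum p^2 - (sum p^2)^2).
#'
#' @inheritParams segregating_sites
#' @return Tibble with `h`, `Hd`, `Hd_se`.
#' @export
haplotype_stats <- function(aln, policy = "complete_deletion") {
  mat <- aln_matrix(aln)
  n <- nrow(mat)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  keep <- effective_columns(mat, "complete_deletion")
  key <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  p <- as.numeric(table(key)) / n
  sp2 <- sum(p^2)
  sp3 <- sum(p^3)
  hd <- n * (1 - sp2) / (n - 1)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (sp3 - sp2^2) + sp2 - sp2^2)
  tibble::tibble(h = length(p), Hd = hd, Hd_se = sqrt(max(v, 0)))
}

#' Tajima's D
#'
#' D = (k - S/a1) / sqrt(e1 S + e2 S (S - 1)) with the usual constants
#' (a1 = sum 1/i, a2 = sum 1/i^2 over i = 1..n-1; b1 = (n+1)/(3(n-1));
#' b2 = 2(n^2+n+3)/(9n(n-1)); c1 = b1 - 1/a1; c2 = b2 - (n+2)/(a1 n) +
#' a2/a1^2; e1 = c1/a1; e2 = c2/(a1^2 + a2)). Negative values indicate an
#' excess of rare variants (expansion or directional selection), positive
#' values a deficit (bottleneck or balancing selection).
#'
#' @param n Sample size (>= 4).
#' @param S Number of segregating sites.
#' @param k Mean pairwise differences.
#' @return D, or `NA` when S = 0 (the statistic is not computable; it is
#'   never coerced to 0 here).
#' @export
#' @examples
#' tajimas_d(39, 100, 9.787)
tajimas_d <- function(n, S, k) {
  stopifnot(n >= 4, S >= 0)
  if (S == 0) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Per-layer diversity statistics
#'
#' Computes, within each time layer separately (layers ordered by increasing
#' age), the sample size n, haplotype count h, segregating sites S, haplotype
#' diversity Hd (with SE), nucleotide diversity pi (with SE), mean pairwise
#' differences k, Tajima's D, Fu's Fs and the effective number of sites after
#' missing-data handling.
#'
#' @inheritParams segregating_sites
#' @param strict Error when a layer has fewer than 2 sequences (default);
#'   otherwise that layer is dropped with a warning.
#' @return A tibble of class `layer_stats`, one row per layer.
#' @export
layer_stats <- function(aln, policy = "complete_deletion", strict = TRUE) {
  lay <- alignment_layers(aln)
  small <- lay$layer[lay$n < 2]
  if (length(small) > 0) {
    if (strict) {
      stop("layer(s) with fewer than 2 sequences: ",
           paste(small, collapse = ", "), call. = FALSE)
    }
    warning("dropping layer(s) with fewer than 2 sequences: ",
            paste(small, collapse = ", "), call. = FALSE)
    lay <- lay[lay$n >= 2, ]
  }
  rows <- lapply(seq_len(nrow(lay)), function(i) {
    sub <- subset_layer(aln, lay$layer[i])
    n <- lay$n[i]
    hs <- haplotype_stats(sub, policy)
    nd <- nucleotide_diversity(sub, policy)
    S <- segregating_sites(sub, policy)
    D <- if (n >= 4) tajimas_d(n, S, nd$k) else NA_real_
    Fs <- if (nd$k > 0) fus_fs(n, hs$h, nd$k) else NA_real_
    tibble::tibble(layer = lay$layer[i], age = lay$age_generations[i], n = n,
                   h = hs$h, S = S, Hd = hs$Hd, Hd_se = hs$Hd_se,
                   pi = nd$pi, pi_se = nd$pi_se, k = nd$k, D = D, Fs = Fs,
                   L_eff = nd$L_eff)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("layer_stats", class(out))
  out
}

#' ABC summary-statistic vector
#'
#' The feature vector used for rejection and regression: haplotype count,
#' segregating sites, mean pairwise differences and Tajima's D within each
#' time layer, layers in increasing age order. An undefined D (S = 0) is
#' encoded as 0 with a warning so reference tables contain no missing cells.
#'
#' @param x A `temporal_alignment`, a [layer_stats()] tibble, or a
#'   [genealogy_features()] tibble.
#' @param quiet Suppress the undefined-D warning (used in bulk simulation).
#' @return Named numeric vector of length 4 x number of layers, e.g.
#'   `h_modern, S_modern, k_modern, D_modern, h_historical, ...`.
#' @export
abc_feature_vector <- function(x, quiet = FALSE) {
  st <- if (inherits(x, "temporal_alignment")) layer_stats(x) else x
  stopifnot(is.data.frame(st), all(c("layer", "h", "S", "k", "D") %in% names(st)))
  if ("age" %in% names(st)) st <- st[order(st$age), ]
  D <- st$D
  if (anyNA(D)) {
    if (!quiet) {
      warning("Tajima's D undefined (S = 0) in layer(s) ",
              paste(st$layer[is.na(D)], collapse = ", "),
              "; encoded as 0 in the feature vector", call. = FALSE)
    }
    D[is.na(D)] <- 0
  }
  out <- as.numeric(rbind(st$h, st$S, st$k, D))
  names(out) <- as.vector(outer(c("h", "S", "k", "D"), st$layer, paste, sep = "_"))
  out
}

#' Fold change in diversity between two layers
#'
#' Ratios of haplotype and nucleotide diversity of an older layer over a
#' newer one, the "x-fold loss" report.
#'
#' @param stats A [layer_stats()] tibble covering both layers.
#' @param older,newer Layer labels.
#' @return Tibble with columns `metric` ("Hd", "pi"), the two layer values,
#'   and `fold_loss` (older / newer). Division by zero yields `Inf` with a
#'   warning.
#' @export
fold_change_report <- function(stats, older = "historical", newer = "modern") {
  stopifnot(all(c(older, newer) %in% stats$layer))
  o <- stats[stats$layer == older, ]
  m <- stats[stats$layer == newer, ]
  vals_o <- c(Hd = o$Hd, pi = o$pi)
  vals_n <- c(Hd = m$Hd, pi = m$pi)
  if (any(vals_n == 0)) {
    warning("newer-layer diversity is zero; fold loss reported as Inf",
            call. = FALSE)
  }
  tibble::tibble(metric = c("Hd", "pi"),
                 older = unname(vals_o), newer = unname(vals_n),
                 fold_loss = unname(vals_o / vals_n))
}
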