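# Shared fixtures and independent oracles used across the test files.

# tiny alignment from explicit sequences
make_aln <- function(seqs, layer = rep("modern", length(seqs)),
                     age = rep(0, length(seqs))) {
  ids <- sprintf("s%02d", seq_along(seqs))
  names(seqs) <- ids
  temporal_alignment(seqs, tibble::tibble(sample_id = ids, layer = layer,
                                          age_generations = age))
}

# random alignment over A/C/G/T (optionally with N at a given rate)
random_aln <- function(n, L, n_rate = 0, layers = NULL) {
  seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                             collapse = ""))
  if (n_rate > 0) {
    seqs <- vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      ch[stats::runif(L) < n_rate] <- "N"
      paste(ch, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  if (is.null(layers)) layers <- rep("modern", n)
  ages <- as.numeric(factor(layers, levels = unique(layers))) - 1
  make_aln(seqs, layers, ages)
}

# brute-force mean pairwise differences (double loop over pairs and sites)
brute_k <- function(aln) {
  mat <- do.call(rbind, strsplit(aln$seq, ""))
  keep <- colSums(mat == "N" | mat == "-") == 0
  mat <- mat[, keep, drop = FALSE]
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) tot <- tot + sum(mat[i, ] != mat[j, ])
  }
  tot / choose(n, 2)
}

# naive Fu's Fs for small n: plain-double Stirling recurrence + direct
# rising-factorial form of the Ewens tail (safe up to n ~ 15)
naive_fs <- function(n, h, theta) {
  s <- matrix(0, n + 1, n + 1)
  s[1, 1] <- 1
  for (m in seq_len(n)) {
    for (j in seq_len(m)) {
      s[m + 1, j + 1] <- s[m, j] + (m - 1) * s[m, j + 1]
    }
  }
  rising <- prod(theta + 0:(n - 1))
  sp <- sum(s[n + 1, (h + 1):(n + 1)] * theta^(h:n)) / rising
  log(sp / (1 - sp))
}

# independent oracle: discrete-generation haploid Wright-Fisher with serial
# sampling at constant size N. Tracks, per surviving ancestral lineage, how
# many tips it subtends, so TMRCA, total branch length, S (infinite sites)
# and mean pairwise differences k can all be simulated without trees.
wf_oracle <- function(N, n0, n1 = 0, age1 = 0, muL = 0) {
  lineage <- sample.int(N, n0)
  cnt <- rep(1L, n0)
  ntot <- n0 + n1
  t <- 0L
  total_len <- 0
  S <- 0L
  ksum <- 0
  added <- n1 == 0
  repeat {
    if (!added && t == age1) {
      lineage <- c(lineage, sample.int(N, n1))
      cnt <- c(cnt, rep(1L, n1))
      agg <- rowsum(cnt, lineage)
      lineage <- as.integer(rownames(agg))
      cnt <- as.integer(agg)
      added <- TRUE
    }
    if (length(lineage) == 1 && added) break
    total_len <- total_len + length(lineage)
    if (muL > 0) {
      m <- stats::rpois(length(lineage), muL)
      S <- S + sum(m)
      ksum <- ksum + sum(m * cnt * (ntot - cnt))
    }
    parent <- sample.int(N, length(lineage), replace = TRUE)
    agg <- rowsum(cnt, parent)
    lineage <- as.integer(rownames(agg))
    cnt <- as.integer(agg)
    t <- t + 1L
  }
  list(tmrca = t, total_len = total_len, S = S, k = ksum / choose(ntot, 2))
}

# small reference table built from simple Gaussian pseudo-simulations, shaped
# like an abc_reference (for testing the ABC algebra without the coalescent)
toy_gaussian_ref <- function(n_sims, obs_noise_sd = 0.2,
                             lower = -10, upper = 10,
                             scenarios = "toy", shift = 0) {
  blocks <- lapply(seq_along(scenarios), function(i) {
    theta <- stats::runif(n_sims, lower, upper)
    xbar <- stats::rnorm(n_sims, theta + shift[min(i, length(shift))],
                         obs_noise_sd)
    tibble::tibble(scenario = scenarios[i], theta = theta, xbar = xbar)
  })
  table <- dplyr::bind_rows(blocks)
  pri <- tibble::tibble(parameter = "theta", lower = lower, upper = upper)
  ps <- structure(list(scenario = scenarios[1], priors = pri,
                       constraints = tibble::tibble(greater = character(),
                                                    lesser = character())),
                  class = "prior_set")
  priors <- stats::setNames(rep(list(ps), length(scenarios)), scenarios)
  structure(list(table = table, feature_names = "xbar",
                 scales = c(xbar = stats::sd(table$xbar)),
                 priors = priors, config = NULL, scale_method = "sd"),
            class = "abc_reference")
}
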