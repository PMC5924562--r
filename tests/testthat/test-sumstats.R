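test_that("effective columns drop exactly the undetermined sites", {
  aln <- make_aln(c("ACGTACGTAC", "ACGTACGTAC"))
  expect_equal(effective_columns(aln), 1:10)
  aln2 <- make_aln(c("ACGTACNTAC", "ACGTACGTAC"))
  expect_equal(effective_columns(aln2), (1:10)[-7])
  expect_equal(length(effective_columns(aln2, "pairwise")), 10)
  aln3 <- make_aln(c("NNN", "ANN"))
  expect_error(effective_columns(aln3), "no columns survive")
})

test_that("column survival under random N matches the independence product", {
  set.seed(41)
  n <- 8
  L <- 4000
  rate <- 0.02
  aln <- random_aln(n, L, n_rate = rate)
  surv <- length(effective_columns(aln)) / L
  p <- (1 - rate)^n
  se <- sqrt(p * (1 - p) / L)
  expect_lt(abs(surv - p), 4 * se)
})

test_that("segregating sites and pairwise differences on hand-built cases", {
  same <- make_aln(rep("ACGTACGT", 4))
  expect_equal(segregating_sites(same), 0)
  expect_equal(mean_pairwise_differences(same), 0)
  two <- make_aln(c(paste(rep("A", 100), collapse = ""),
                    paste(c(rep("A", 95), rep("C", 5)), collapse = "")))
  expect_equal(segregating_sites(two), 5)
  expect_equal(mean_pairwise_differences(two), 5)
  nd <- nucleotide_diversity(two)
  expect_equal(nd$pi, 0.05)
  expect_equal(nd$k, 5)
  expect_error(segregating_sites(make_aln("ACGT")), "at least 2")
})

test_that("mean pairwise differences equal the brute-force double loop", {
  set.seed(42)
  for (i in 1:5) {
    aln <- random_aln(20, 60, n_rate = ifelse(i > 3, 0.03, 0))
    expect_equal(mean_pairwise_differences(aln), brute_k(aln))
  }
})

test_that("pi * L_eff equals k exactly", {
  set.seed(43)
  aln <- random_aln(10, 80, n_rate = 0.02)
  nd <- nucleotide_diversity(aln)
  expect_equal(nd$pi * nd$L_eff, nd$k)
})

test_that("haplotype diversity follows Nei's estimator", {
  same <- make_aln(rep("ACGT", 5))
  hs <- haplotype_stats(same)
  expect_equal(hs$h, 1)
  expect_equal(hs$Hd, 0)
  # n = 4, two haplotypes 2 + 2: Hd = (4/3)(1 - 1/2)
  two <- make_aln(c("AAAA", "AAAA", "AAAC", "AAAC"))
  hs2 <- haplotype_stats(two)
  expect_equal(hs2$h, 2)
  expect_equal(hs2$Hd, 2 / 3)
  # hand-computed Nei variance for p = (1/2, 1/2), n = 4
  expect_equal(hs2$Hd_se, sqrt(1 / 6 * 0.25))
  # 33 singletons + 3 doubletons among 39: Hd ~ 0.996 (printed table value)
  base <- strrep("A", 40)
  mk <- function(i) {
    s <- strsplit(base, "")[[1]]
    s[i] <- "C"
    paste(s, collapse = "")
  }
  seqs <- c(vapply(1:33, mk, ""), rep(vapply(34:36, mk, ""), each = 2))
  hs3 <- haplotype_stats(make_aln(seqs))
  expect_equal(hs3$h, 36)
  expect_equal(hs3$Hd, (39 / 38) * (1 - 45 / 1521))
  expect_equal(round(hs3$Hd, 3), 0.996)
})

test_that("Tajima's D reproduces the printed per-layer values", {
  # historical row: n = 39, S = 100, k = pi * 16588
  expect_equal(tajimas_d(39, 100, 0.00059 * 16588), -2.15, tolerance = 0.01)
  # modern row: n = 79, S = 7; rounding of the printed pi explains the gap
  # to the printed -0.944
  expect_equal(tajimas_d(79, 7, 0.00005 * 16588), -1.01, tolerance = 0.01)
  expect_true(is.na(tajimas_d(39, 0, 0)))
})

test_that("exact Stirling numbers satisfy the classical identities", {
  s3 <- as.character(unsigned_stirling_first(3))
  expect_equal(s3, c("0", "2", "3", "1"))       # |s(3,2)| = 3
  s6 <- as.numeric(as.character(unsigned_stirling_first(6)))
  expect_equal(s6[2], factorial(5))             # |s(n,1)| = (n-1)!
  # rising factorial identity at theta = 2: sum_j |s(6,j)| 2^j = 2*3*...*7
  expect_equal(sum(s6 * 2^(0:6)), prod(2:7))
  # a value too large for doubles, against Python-bigint cross-check
  s79 <- as.character(unsigned_stirling_first(79))
  expect_gt(nchar(s79[2]), 100)                 # |s(79,1)| = 78! ~ 10^115
  expect_equal(s79[80], "1")
})

test_that("exact and log-space Fu's Fs agree and match naive enumeration", {
  expect_equal(fus_fs(3, 2, 1), log(2))
  for (case in list(c(8, 5, 2.3), c(12, 3, 0.7), c(10, 10, 1.5))) {
    expect_equal(fus_fs(case[1], case[2], case[3]),
                 naive_fs(case[1], case[2], case[3]), tolerance = 1e-9)
  }
  for (th in c(0.5, 2, 9.787, 40)) {
    expect_equal(fus_fs(79, 10, th), fus_fs(79, 10, th, method = "log"),
                 tolerance = 1e-6)
  }
  expect_equal(fus_fs(10, 1, 2), Inf)
  expect_warning(out <- fus_fs(10, 3, 0), "undefined")
  expect_true(is.na(out))
})

test_that("Ewens haplotype tail matches a Chinese-restaurant simulation", {
  set.seed(44)
  n <- 10
  theta <- 2
  reps <- 4e4
  K <- rowSums(matrix(runif(reps * n), reps, n) <
                 matrix(theta / (theta + 0:(n - 1)), reps, n, byrow = TRUE))
  p_mc <- mean(K >= 6)
  p_exact <- ewens_haplotype_tail(n, 6, theta)
  expect_lt(abs(p_mc - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / reps))
})

test_that("layer stats compose into the ABC feature vector", {
  set.seed(45)
  aln <- random_aln(12, 40, layers = rep(c("modern", "historical"), c(7, 5)))
  st <- layer_stats(aln)
  expect_equal(st$layer, c("modern", "historical"))
  expect_equal(st$n, c(7L, 5L))
  fv <- abc_feature_vector(st)
  expect_length(fv, 8)
  expect_equal(unname(fv[1:4]),
               c(st$h[1], st$S[1], st$k[1], st$D[1]))
  expect_equal(unname(fv[5:8]),
               c(st$h[2], st$S[2], st$k[2], st$D[2]))
  # monomorphic single layer encodes as (1, 0, 0, 0) with a warning on D
  mono <- make_aln(rep("ACGTACGT", 5))
  stm <- layer_stats(mono)
  expect_warning(fvm <- abc_feature_vector(stm), "encoded as 0")
  expect_equal(unname(fvm), c(1, 0, 0, 0))
  # a layer with one sequence is an error in strict mode
  odd <- random_aln(4, 20, layers = c("a", "a", "a", "b"))
  expect_error(layer_stats(odd), "fewer than 2")
})

test_that("fold-change report reproduces the ~30-fold and ~11.8-fold losses", {
  st <- tibble::tibble(layer = c("modern", "historical"),
                       Hd = c(0.0331, 0.996), pi = c(0.00005, 0.00059))
  fc <- fold_change_report(st)
  expect_equal(fc$fold_loss[fc$metric == "Hd"], 30.09, tolerance = 0.001)
  expect_equal(fc$fold_loss[fc$metric == "pi"], 11.8)
  eq <- tibble::tibble(layer = c("modern", "historical"),
                       Hd = c(0.5, 0.5), pi = c(0.001, 0.001))
  expect_equal(fold_change_report(eq)$fold_loss, c(1, 1))
  z <- tibble::tibble(layer = c("modern", "historical"),
                      Hd = c(0, 0.5), pi = c(0.001, 0.001))
  expect_warning(fcz <- fold_change_report(z), "Inf")
  expect_equal(fcz$fold_loss[1], Inf)
})

test_that("D and Fs match naive reference implementations on random data", {
  set.seed(46)
  for (i in 1:10) {
    aln <- random_aln(8 + i, 60)
    st <- layer_stats(aln)
    n <- st$n
    # independent transcription: Watterson-normalized frequency-spectrum form
    a1 <- sum(1 / seq_len(n - 1))
    a2 <- sum(1 / seq_len(n - 1)^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    D_ref <- (brute_k(aln) - st$S / a1) /
      sqrt(c1 / a1 * st$S + c2 / (a1^2 + a2) * st$S * (st$S - 1))
    expect_equal(st$D, D_ref, tolerance = 1e-9)
    if (n <= 15 && st$k > 0) {
      expect_equal(st$Fs, naive_fs(n, st$h, st$k), tolerance = 1e-6)
    }
  }
})
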