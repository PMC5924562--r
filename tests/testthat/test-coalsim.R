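const_scenario <- function(N) build_scenario("constant",
                                             list(ne_constant = N, mu = 1e-8))

test_that("a single sample yields a single-tip tree with zero branch length", {
  g <- simulate_genealogy(const_scenario(100),
                          sample_config(layer = "modern", n = 1L, age = 0,
                                        locus_length = 100L))
  expect_equal(g$n_tip, 1)
  expect_equal(max(g$time), 0)
  expect_equal(to_newick(g), "modern_001;")
})

test_that("coalescent events always number tips - 1", {
  set.seed(21)
  sc <- const_scenario(500)
  for (n in c(2L, 7L, 30L)) {
    g <- simulate_genealogy(sc, sample_config(layer = "x", n = n, age = 0,
                                              locus_length = 100L))
    expect_equal(sum(g$parent == 0), 1)          # one root
    expect_equal(length(g$time) - g$n_tip, n - 1) # internal nodes
    expect_true(all(g$time[g$parent[seq_len(2 * n - 2)]] >
                      g$time[seq_len(2 * n - 2)]))
  }
})

test_that("mean TMRCA matches the closed form 2N(1 - 1/n)", {
  set.seed(22)
  cfg <- sample_config(layer = "m", n = 10L, age = 0, locus_length = 100L)
  sc <- const_scenario(1000)
  tm <- replicate(2000, max(simulate_genealogy(sc, cfg)$time))
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 1800), 3 * se)
})

test_that("serial sampling: TMRCA exceeds the older tip's age and has mean a + N", {
  # with coalescence rate k(k-1)/(2N), two lineages coalesce at rate 1/N
  set.seed(23)
  cfg <- sample_config(layer = c("new", "old"), n = c(1L, 1L), age = c(0, 50),
                       locus_length = 100L)
  sc <- const_scenario(1000)
  tm <- replicate(2000, max(simulate_genealogy(sc, cfg)$time))
  expect_true(all(tm >= 50))
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 1050), 3 * se)
})

test_that("expected segregating sites follow Watterson's formula", {
  set.seed(24)
  n <- 10L
  N <- 500
  muL <- 0.003  # mu * L
  cfg <- sample_config(layer = "m", n = n, age = 0, locus_length = 1000L)
  sc <- const_scenario(N)
  S <- replicate(2000, sum(mutate_edges(simulate_genealogy(sc, cfg),
                                        mu = muL / 1000, locus_length = 1000L)))
  a1 <- sum(1 / seq_len(n - 1))
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - a1 * 2 * N * muL), 3 * se)
})

test_that("branch mutation counts are Poisson with rate mu L t", {
  # fixed two-tip genealogy, total length 10 generations
  g <- tempogen:::new_genealogy(
    parent = c(3L, 3L, 0L), time = c(0, 0, 5),
    tip_layer = c("m", "m"),
    layers = tibble::tibble(layer = "m", n = 2L, age = 0))
  set.seed(25)
  m <- replicate(4000, sum(mutate_edges(g, mu = 2e-4, locus_length = 1000L)))
  # Poisson(2e-4 * 1000 * 10) = Poisson(2): mean = variance
  expect_lt(abs(mean(m) - 2), 3 * sqrt(2 / 4000))
  expect_lt(abs(var(m) / mean(m) - 1), 0.1)
})

test_that("mutation dropping: zero-rate limit and infinite-sites exhaustion", {
  set.seed(26)
  cfg <- sample_config(layer = "m", n = 6L, age = 0, locus_length = 50L)
  g <- simulate_genealogy(const_scenario(200), cfg)
  aln <- drop_mutations(g, mu = 1e-15, locus_length = 50L)
  expect_equal(length(unique(aln$seq)), 1)
  expect_equal(segregating_sites(aln), 0)
  expect_error(drop_mutations(g, mu = 1, locus_length = 50L),
               "jukes_cantor")
})

test_that("jukes-cantor alignments have the right shape and alphabet", {
  set.seed(27)
  cfg <- sample_config(layer = "m", n = 5L, age = 0, locus_length = 200L)
  g <- simulate_genealogy(const_scenario(300), cfg)
  aln <- drop_mutations(g, mu = 1e-4, locus_length = 200L,
                        model = "jukes_cantor")
  expect_equal(length(aln$seq), 5)
  expect_true(all(nchar(aln$seq) == 200))
  expect_false(any(grepl("[^ACGT]", aln$seq)))
})

test_that("newick export round-trips topology and node times", {
  set.seed(28)
  # two tips coalescing: both branch lengths equal the TMRCA
  g2 <- tempogen:::new_genealogy(
    parent = c(3L, 3L, 0L), time = c(0, 0, 5),
    tip_layer = c("m", "m"),
    layers = tibble::tibble(layer = "m", n = 2L, age = 0))
  expect_equal(to_newick(g2), "(m_001:5,m_002:5);")
  # large simulated tree: pairwise tip divergence times preserved
  sc <- build_scenario("bottleneck_eu",
                       list(ne_modern = 50, ne_pre_european = 2e4,
                            ne_pre_glaciation = 5e3, t_bottleneck_eu = 5,
                            t_post_glaciation = 400, mu = 1e-8))
  g <- simulate_genealogy(sc, sample_config())
  expect_equal(g$n_tip, 118)
  d1 <- ape::cophenetic.phylo(as.phylo(g))
  d2 <- ape::cophenetic.phylo(ape::read.tree(text = to_newick(g)))
  expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-6)
})

test_that("genealogy feature path equals the sequence pipeline exactly", {
  set.seed(29)
  sc <- build_scenario("bottleneck_eu",
                       list(ne_modern = 50, ne_pre_european = 2e4,
                            ne_pre_glaciation = 5e3, t_bottleneck_eu = 5,
                            t_post_glaciation = 400, mu = 5e-8))
  cfg <- sample_config(n = c(12L, 8L), locus_length = 3000L)
  for (i in 1:15) {
    g <- simulate_genealogy(sc, cfg)
    mc <- mutate_edges(g, 5e-8, 3000L)
    fast <- genealogy_features(g, mc)
    st <- layer_stats(drop_mutations(g, 5e-8, 3000L, mut_counts = mc))
    expect_equal(fast$h, st$h)
    expect_equal(fast$S, st$S)
    expect_equal(fast$k, st$k, tolerance = 1e-12)
    expect_equal(fast$D, st$D, tolerance = 1e-12)
  }
})

test_that("simulated S on infinite sites equals the genealogy mutation count", {
  set.seed(30)
  cfg <- sample_config(layer = "m", n = 10L, age = 0, locus_length = 2000L)
  g <- simulate_genealogy(const_scenario(400), cfg)
  mc <- mutate_edges(g, 1e-5, 2000L)
  aln <- drop_mutations(g, 1e-5, 2000L, mut_counts = mc)
  expect_equal(segregating_sites(aln), sum(mc))
})

test_that("simulator agrees with an independent Wright-Fisher oracle (KS)", {
  set.seed(31)
  N <- 300
  reps <- 1500
  muL <- 0.01
  cfg <- sample_config(layer = c("new", "old"), n = c(4L, 2L), age = c(0, 10),
                       locus_length = 1000L)
  sc <- const_scenario(N)
  coal <- replicate(reps, {
    g <- simulate_genealogy(sc, cfg)
    mc <- mutate_edges(g, muL / 1000, 1000L)
    c(tmrca = max(g$time), S = sum(mc))
  })
  wf <- replicate(reps, {
    o <- wf_oracle(N, n0 = 4, n1 = 2, age1 = 10, muL = muL)
    c(tmrca = o$tmrca, S = o$S)
  })
  expect_gt(suppressWarnings(
    stats::ks.test(coal["tmrca", ], wf["tmrca", ]))$p.value, 0.01)
  expect_gt(suppressWarnings(
    stats::ks.test(coal["S", ], wf["S", ]))$p.value, 0.01)
})
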