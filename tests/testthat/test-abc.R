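tiny_cfg <- sample_config(n = c(12L, 8L), locus_length = 2000L)

test_that("reference tables have the right shape and are reproducible", {
  ref <- build_reference_table(c("bottleneck_eu", "bottleneck_pol"), 100,
                               config = tiny_cfg, seed = 71)
  expect_equal(nrow(ref$table), 200)
  expect_length(ref$feature_names, 8)
  expect_true(all(ref$scales > 0))
  ref2 <- build_reference_table(c("bottleneck_eu", "bottleneck_pol"), 100,
                                config = tiny_cfg, seed = 71)
  expect_identical(ref$table, ref2$table)
  # parameters the other scenario lacks are NA in its rows
  expect_true(all(is.na(
    ref$table$t_bottleneck_pol[ref$table$scenario == "bottleneck_eu"])))
})

test_that("normalized distances match the brute-force definition", {
  set.seed(72)
  ref <- toy_gaussian_ref(500)
  ref$feature_names <- "xbar"
  obs <- c(xbar = 1.3)
  d <- normalized_distance(obs, ref)
  expect_equal(d, abs(ref$table$xbar - 1.3) / ref$scales[["xbar"]])
  # a row equal to the observation is at distance zero
  ref$table$xbar[7] <- 1.3
  expect_equal(normalized_distance(obs, ref)[7], 0)
  # doubling every scale halves every distance
  ref2 <- ref
  ref2$scales <- ref$scales * 2
  expect_equal(normalized_distance(obs, ref2),
               normalized_distance(obs, ref) / 2)
  expect_error(normalized_distance(c(a = 1, b = 2), ref), "length")
})

test_that("multi-feature distances equal an explicit loop", {
  ref <- build_reference_table("bottleneck_eu", 100, config = tiny_cfg,
                               seed = 73)
  obs <- as.numeric(ref$table[1, ref$feature_names])
  names(obs) <- ref$feature_names
  d <- normalized_distance(obs, ref)
  expect_equal(d[1], 0)
  for (i in c(2, 17, 60)) {
    manual <- sqrt(sum(((obs - as.numeric(ref$table[i, ref$feature_names])) /
                          ref$scales)^2))
    expect_equal(d[i], manual, tolerance = 1e-12)
  }
})

test_that("rejection keeps the requested count with deterministic ties", {
  set.seed(74)
  ref <- toy_gaussian_ref(1000)
  d <- normalized_distance(c(xbar = 0), ref)
  acc <- abc_reject(ref, d, 0.01)
  expect_equal(nrow(acc), 10)
  expect_lte(max(acc$.distance), min(d[-attr(acc, "indices")]))
  expect_equal(nrow(abc_reject(ref, d, 1)), 1000)
})

test_that("regression adjustment recovers the conjugate Gaussian posterior", {
  # theta ~ U(-10, 10); feature = mean of 25 unit-variance draws;
  # posterior is N(xbar, 1/25) well inside the prior bounds
  set.seed(75)
  ref <- toy_gaussian_ref(20000, obs_noise_sd = 1 / 5)
  obs <- c(xbar = 1.7)
  d <- normalized_distance(obs, ref)
  acc <- abc_reject(ref, d, 0.01)
  adj <- loclinear_adjust(acc, obs, ref)
  post_mean <- sum(adj$theta * adj$.weight) / sum(adj$.weight)
  n_eff <- sum(adj$.weight)^2 / sum(adj$.weight^2)
  mc_se <- (1 / 5) / sqrt(n_eff)
  expect_lt(abs(post_mean - 1.7), 3 * mc_se)
  # rejection-only posterior agrees in the small-acceptance limit
  rej_mean <- sum(acc$theta * adj$.weight) / sum(adj$.weight)
  expect_lt(abs(rej_mean - 1.7), 0.1)
  # adjustment at the accepted sample's feature mean is ~ the identity when
  # the regression has nothing to explain (constant parameter)
  flat <- ref
  flat$table$theta <- 5
  accf <- abc_reject(flat, d, 0.01)
  adjf <- loclinear_adjust(accf, obs, flat)
  expect_equal(adjf$theta, rep(5, nrow(accf)), tolerance = 1e-6)
})

test_that("adjusted draws respect prior bounds", {
  set.seed(76)
  ref <- build_reference_table("bottleneck_eu", 400, config = tiny_cfg,
                               seed = 76)
  obs <- as.numeric(ref$table[5, ref$feature_names])
  names(obs) <- ref$feature_names
  d <- normalized_distance(obs, ref)
  acc <- abc_reject(ref, d, 0.25)
  adj <- loclinear_adjust(acc, obs, ref)
  expect_true(all(adj$t_bottleneck_eu >= 1 & adj$t_bottleneck_eu <= 10))
  expect_true(all(adj$mu >= 1e-8 & adj$mu <= 1e-7))
  expect_true(all(adj$ne_modern >= 1 & adj$ne_modern <= 200))
})

test_that("model choice is symmetric for identical scenarios and sums to 1", {
  set.seed(77)
  ref <- toy_gaussian_ref(4000, scenarios = c("a", "b"), shift = c(0, 0))
  obs <- c(xbar = 0.5)
  d <- normalized_distance(obs, ref)
  pr <- model_choice_logistic(ref, d, obs, accept_fraction = 0.05)
  expect_equal(sum(pr$probability), 1, tolerance = 1e-9)
  expect_lt(abs(pr$probability[1] - 0.5), 0.15)
})

test_that("model choice separates well-separated scenarios", {
  # a severe recent bottleneck empties the modern layer of variation, which
  # a constant-size history cannot do while keeping the old layer diverse
  set.seed(78)
  ref <- build_reference_table(c("constant", "bottleneck_eu"), 400,
                               config = tiny_cfg, seed = 78)
  pod <- tempogen:::simulate_feature_row(
    "bottleneck_eu",
    list(ne_modern = 5, ne_pre_european = 3e5, ne_pre_glaciation = 5e4,
         t_bottleneck_eu = 5, t_post_glaciation = 450, mu = 8e-8),
    tiny_cfg)
  d <- normalized_distance(pod, ref)
  pr <- model_choice_logistic(ref, d, pod, accept_fraction = 0.05)
  expect_gt(pr$probability[pr$scenario == "bottleneck_eu"], 0.9)
  # probabilities are invariant to a rescaling absorbed by the scales
  ref2 <- ref
  ref2$table[ref$feature_names] <- ref$table[ref$feature_names] * 10
  ref2$scales <- ref$scales * 10
  expect_equal(normalized_distance(pod * 10, ref2), d, tolerance = 1e-12)
})

test_that("posterior summaries: point mass, normal sample, mode containment", {
  expect_equal(posterior_summary(rep(3.3, 60)),
               tibble::tibble(mode = 3.3, hpd_lower = 3.3, hpd_upper = 3.3))
  set.seed(79)
  x <- rnorm(1e4)
  ps <- posterior_summary(x)
  expect_lt(abs(ps$mode), 0.1)
  expect_lt(abs(ps$hpd_lower + 1.645), 0.1)
  expect_lt(abs(ps$hpd_upper - 1.645), 0.1)
  pss <- posterior_summary(x, interval = "shortest")
  expect_lt(abs(pss$hpd_lower + 1.645), 0.15)
  expect_lt(abs(pss$hpd_upper - 1.645), 0.15)
  expect_true(ps$mode >= ps$hpd_lower && ps$mode <= ps$hpd_upper)
  expect_error(posterior_summary(rnorm(10)), "50")
})

test_that("rejection-only intervals are calibrated on the Gaussian toy model", {
  # prior-drawn pods + rejection ABC => nominal coverage by construction
  set.seed(80)
  ref <- toy_gaussian_ref(20000, obs_noise_sd = 1 / 5)
  hits <- 0
  n_pods <- 200
  for (i in seq_len(n_pods)) {
    truth <- runif(1, -8, 8)
    obs <- c(xbar = rnorm(1, truth, 1 / 5))
    d <- normalized_distance(obs, ref)
    acc <- abc_reject(ref, d, 0.01)
    ps <- posterior_summary(acc$theta,
                            tempogen:::epanechnikov_weights(acc$.distance),
                            lower = -10, upper = 10)
    hits <- hits + (truth >= ps$hpd_lower && truth <= ps$hpd_upper)
  }
  expect_lt(abs(hits / n_pods - 0.9), 3 * sqrt(0.9 * 0.1 / n_pods))
})

test_that("pod confusion rows sum to the pod count with errors in [0, 1]", {
  ref <- build_reference_table(c("bottleneck_eu", "bottleneck_pol"), 400,
                               config = tiny_cfg, seed = 81)
  pc <- pods_confusion(ref, 12, accept_fraction = 0.05, seed = 82)
  counts <- as.matrix(pc$confusion[, -1])
  expect_equal(unname(rowSums(counts)), rep(12, 2))
  expect_true(all(pc$errors$type_I >= 0 & pc$errors$type_I <= 1))
  expect_true(all(pc$errors$type_II >= 0 & pc$errors$type_II <= 1))
  expect_error(pods_confusion(ref, 5), "n_pods")
})

test_that("abc_fit returns tidy and glance summaries", {
  set.seed(83)
  ref <- build_reference_table(c("bottleneck_eu", "bottleneck_pol"), 300,
                               config = tiny_cfg, seed = 83)
  pod <- tempogen:::simulate_feature_row(
    "bottleneck_eu", as.list(draw_params(default_priors("bottleneck_eu"), 1)),
    tiny_cfg)
  fit <- abc_fit(ref, pod, accept_fraction = 0.2)
  expect_s3_class(fit, "abc_fit")
  expect_equal(sum(fit$model_probs$probability), 1, tolerance = 1e-9)
  td <- tidy(fit)
  expect_true(all(c("parameter", "mode", "hpd_lower", "hpd_upper") %in%
                    names(td)))
  expect_true(all(td$hpd_lower <= td$hpd_upper))
  gl <- glance(fit)
  expect_equal(gl$n_sims, 600)
  expect_equal(gl$accept_fraction, 0.2)
})
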