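# ABC rejection with local linear regression adjustment, logistic model
# choice, posterior summaries, and pod-based type I/II error rates.

# one prior-predictive simulation -> named feature vector (fast path:
# summary statistics computed from the genealogy, no sequences built)
simulate_feature_row <- function(scenario_id, params, config) {
  scen <- build_scenario(scenario_id, params)
  gen <- simulate_genealogy(scen, config)
  mc <- mutate_edges(gen, params$mu, locus_length(config))
  if (sum(mc) > locus_length(config)) {
    stop("infinite-sites model needs ", sum(mc), " distinct sites but the ",
         "locus has only ", locus_length(config), call. = FALSE)
  }
  abc_feature_vector(genealogy_features(gen, mc), quiet = TRUE)
}

#' Build an ABC reference table
#'
#' For each scenario, draws parameters from its priors, simulates a
#' study-shaped dataset and stores the summary-statistic vector (haplotype
#' count, segregating sites, mean pairwise differences and Tajima's D per
#' time layer). Per-feature scales for distance normalization are computed
#' across the pooled table.
#'
#' @param scenarios Character vector of scenario ids (see [scenario_ids()]).
#' @param n_sims_per_model Simulations per scenario (>= 100).
#' @param priors Optional named list of `prior_set`s; defaults to
#'   [default_priors()] per scenario.
#' @param config A [sample_config()].
#' @param scale_method `"sd"` (pooled standard deviation, default) or
#'   `"mad"` (median absolute deviation).
#' @param seed Optional integer seed.
#' @return An `abc_reference`: list with `table` (tibble: `scenario`, one
#'   column per parameter in the union of scenario parameters, one column per
#'   feature), `feature_names`, `scales` (named; zero-spread features get
#'   scale 1 with a warning), `priors`, `config`.
#' @export
build_reference_table <- function(scenarios, n_sims_per_model,
                                  priors = NULL,
                                  config = sample_config(),
                                  scale_method = c("sd", "mad"),
                                  seed = NULL) {
  scale_method <- match.arg(scale_method)
  stopifnot(length(scenarios) >= 1, n_sims_per_model >= 100)
  scenarios <- unique(scenarios)
  lapply(scenarios, check_scenario_id)
  if (is.null(priors)) {
    priors <- stats::setNames(lapply(scenarios, default_priors), scenarios)
  }
  stopifnot(all(scenarios %in% names(priors)))
  if (!is.null(seed)) set.seed(seed)
  blocks <- lapply(scenarios, function(s) {
    par_draws <- draw_params(priors[[s]], n_sims_per_model)
    feats <- NULL
    for (i in seq_len(n_sims_per_model)) {
      row <- simulate_feature_row(s, as.list(par_draws[i, ]), config)
      if (is.null(feats)) {
        feats <- matrix(NA_real_, n_sims_per_model, length(row),
                        dimnames = list(NULL, names(row)))
      }
      feats[i, ] <- row
    }
    dplyr::bind_cols(tibble::tibble(scenario = s), par_draws,
                     tibble::as_tibble(feats))
  })
  table <- dplyr::bind_rows(blocks)
  feature_names <- colnames(blocks[[1]])[
    seq(ncol(blocks[[1]]) - 4 * nrow(config) + 1, ncol(blocks[[1]]))]
  fmat <- as.matrix(table[, feature_names])
  scales <- if (scale_method == "sd") {
    apply(fmat, 2, stats::sd)
  } else {
    apply(fmat, 2, stats::mad)
  }
  if (any(scales == 0)) {
    warning("feature(s) with zero spread get scale 1: ",
            paste(feature_names[scales == 0], collapse = ", "), call. = FALSE)
    scales[scales == 0] <- 1
  }
  structure(list(table = table, feature_names = feature_names,
                 scales = scales, priors = priors, config = config,
                 scale_method = scale_method),
            class = "abc_reference")
}

#' @export
print.abc_reference <- function(x, ...) {
  cat("<abc_reference>", nrow(x$table), "simulations,",
      length(unique(x$table$scenario)), "scenario(s):",
      paste(unique(x$table$scenario), collapse = ", "), "\n")
  invisible(x)
}

ref_feature_matrix <- function(ref, rows = NULL) {
  m <- as.matrix(ref$table[, ref$feature_names])
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  m
}

check_observed <- function(observed, ref) {
  if (is.data.frame(observed)) observed <- abc_feature_vector(observed)
  if (length(observed) != length(ref$feature_names)) {
    stop("observed vector has length ", length(observed), " but the table ",
         "has ", length(ref$feature_names), " features", call. = FALSE)
  }
  if (!is.null(names(observed)) &&
      !identical(names(observed), ref$feature_names)) {
    observed <- observed[ref$feature_names]
    if (anyNA(observed)) stop("observed feature names do not match the table",
                              call. = FALSE)
  }
  as.numeric(observed)
}

#' Normalized Euclidean distances to a reference table
#'
#' d_i = sqrt(sum_j ((x_j - y_ij) / scale_j)^2) with the per-feature scales
#' stored in the table.
#'
#' @param observed Named feature vector (or [layer_stats()] tibble).
#' @param ref An `abc_reference`.
#' @return Numeric vector, one distance per table row.
#' @export
normalized_distance <- function(observed, ref) {
  obs <- check_observed(observed, ref)
  fmat <- ref_feature_matrix(ref)
  z <- sweep(fmat, 2, obs) / rep(ref$scales, each = nrow(fmat))
  sqrt(rowSums(z^2))
}

#' Rejection step
#'
#' Keeps the `ceiling(accept_fraction * nrow)` rows with the smallest
#' distances; ties at the threshold are broken by row order (deterministic).
#'
#' @param ref An `abc_reference`.
#' @param distances From [normalized_distance()].
#' @param accept_fraction Fraction of the table to retain (0 < f <= 1).
#' @return The accepted rows of the table with a `.distance` column, ordered
#'   by increasing distance.
#' @export
abc_reject <- function(ref, distances, accept_fraction = 0.01) {
  stopifnot(accept_fraction > 0, accept_fraction <= 1,
            length(distances) == nrow(ref$table))
  if (nrow(ref$table) == 0) stop("empty reference table", call. = FALSE)
  m <- ceiling(accept_fraction * nrow(ref$table))
  idx <- order(distances)[seq_len(m)]  # order() is stable: ties by row order
  out <- ref$table[idx, ]
  out$.distance <- distances[idx]
  attr(out, "indices") <- idx
  out
}

epanechnikov_weights <- function(d, bandwidth = max(d)) {
  if (bandwidth <= 0) return(rep(1, length(d)))
  pmax(1 - (d / bandwidth)^2, 0)
}

# clamped logit transform onto a prior-bounded support
to_logit <- function(x, lower, upper) {
  p <- pmin(pmax((x - lower) / (upper - lower), 1e-9), 1 - 1e-9)
  stats::qlogis(p)
}
from_logit <- function(z, lower, upper) lower + (upper - lower) * stats::plogis(z)

#' Local linear regression adjustment (Beaumont-style)
#'
#' Weighted linear regression of each accepted parameter on the normalized
#' summary statistics centred at the observed vector, with Epanechnikov
#' kernel weights on the distances (bandwidth = largest accepted distance).
#' The adjusted draw is the fitted value at the observed statistics plus the
#' residual. Prior-bounded parameters are regressed on a logit scale and
#' back-transformed, so adjusted draws always respect their prior bounds.
#'
#' @param accepted Accepted rows from [abc_reject()] (must contain a single
#'   scenario's rows; filter first if the table pools scenarios).
#' @param observed Observed feature vector.
#' @param ref The `abc_reference` the rows came from.
#' @return Tibble of adjusted parameter draws plus a `.weight` column. Falls
#'   back to the unadjusted draws with a warning when the weighted design is
#'   singular.
#' @export
loclinear_adjust <- function(accepted, observed, ref) {
  obs <- check_observed(observed, ref)
  scen <- unique(accepted$scenario)
  if (length(scen) != 1) {
    stop("accepted rows span several scenarios; adjust one scenario at a time",
         call. = FALSE)
  }
  par_names <- ref$priors[[scen]]$priors$parameter
  lower <- stats::setNames(ref$priors[[scen]]$priors$lower, par_names)
  upper <- stats::setNames(ref$priors[[scen]]$priors$upper, par_names)
  d <- accepted$.distance
  w <- epanechnikov_weights(d)
  if (all(w == 0)) w <- rep(1, length(w))
  X <- sweep(as.matrix(accepted[, ref$feature_names]), 2, obs) /
    rep(ref$scales, each = nrow(accepted))
  if (nrow(X) <= ncol(X) + 1) {
    stop("need more accepted rows than features + 1 for the regression",
         call. = FALSE)
  }
  design <- cbind(`(Intercept)` = 1, X)
  out <- accepted[, par_names]
  singular <- FALSE
  for (p in par_names) {
    z <- to_logit(accepted[[p]], lower[p], upper[p])
    fit <- stats::lm.wfit(design, z, w)
    if (fit$rank < ncol(design) || anyNA(fit$coefficients)) {
      singular <- TRUE
      next
    }
    beta <- fit$coefficients[-1]
    z_adj <- z - drop(X %*% beta)
    out[[p]] <- from_logit(z_adj, lower[p], upper[p])
  }
  if (singular) {
    warning("singular weighted design; returning unadjusted draws for some ",
            "parameter(s)", call. = FALSE)
  }
  out$.weight <- w
  out
}

#' Posterior probabilities of each scenario by kernel-weighted logistic
#' regression
#'
#' Multinomial logistic regression of the scenario label on the normalized
#' summary statistics (centred at the observed vector) over the accepted set,
#' weighted by the Epanechnikov kernel; the reported probabilities are the
#' fitted probabilities at the observed vector. When a single scenario
#' occupies all accepted rows it gets probability 1; when the regression
#' fails to converge the kernel-weighted acceptance frequencies are returned
#' with a warning.
#'
#' @param ref An `abc_reference` containing >= 2 scenarios.
#' @param distances From [normalized_distance()].
#' @param observed Observed feature vector.
#' @param accept_fraction Fraction retained for the regression.
#' @return Tibble with columns `scenario`, `probability` (sums to 1).
#' @export
model_choice_logistic <- function(ref, distances, observed,
                                  accept_fraction = 0.01) {
  obs <- check_observed(observed, ref)
  if (length(unique(ref$table$scenario)) < 2) {
    stop("model choice needs at least 2 scenarios in the reference table",
         call. = FALSE)
  }
  acc <- abc_reject(ref, distances, accept_fraction)
  labs <- factor(acc$scenario, levels = sort(unique(ref$table$scenario)))
  w <- epanechnikov_weights(acc$.distance)
  if (all(w == 0)) w <- rep(1, length(w))
  present <- levels(droplevels(labs))
  if (length(present) == 1) {
    return(tibble::tibble(scenario = levels(labs),
                          probability = as.numeric(levels(labs) == present)))
  }
  X <- sweep(as.matrix(acc[, ref$feature_names]), 2, obs) /
    rep(ref$scales, each = nrow(acc))
  df <- data.frame(.scenario = droplevels(labs), X, check.names = TRUE)
  probs <- tryCatch({
    fit <- nnet::multinom(.scenario ~ ., data = df, weights = w,
                          trace = FALSE, maxit = 500, MaxNWts = 5000)
    nd <- as.data.frame(as.list(stats::setNames(rep(0, ncol(X)),
                                                colnames(df)[-1])))
    pr <- stats::predict(fit, newdata = nd, type = "probs")
    if (is.null(dim(pr)) && length(pr) == 1) {
      # two classes: predict() returns P(second level)
      pr <- stats::setNames(c(1 - pr, pr), levels(df$.scenario))
    }
    pr
  }, error = function(e) {
    warning("logistic model choice failed (", conditionMessage(e),
            "); returning kernel-weighted acceptance frequencies",
            call. = FALSE)
    tapply(w, droplevels(labs), sum) / sum(w)
  })
  full <- stats::setNames(rep(0, nlevels(labs)), levels(labs))
  full[names(probs)] <- probs
  full <- full / sum(full)
  tibble::tibble(scenario = names(full), probability = as.numeric(full))
}

#' Weighted posterior mode and 90% credible bounds
#'
#' Mode of a weighted Gaussian kernel density estimate (Silverman's rule)
#' evaluated on the prior-bounded support, and a 90% credible interval
#' reported as the 5% and 95% bounds. The default `"central"` interval is the
#' pair of weighted 5%/95% quantiles (the convention behind DIYABC-style
#' posterior tables); `"shortest"` gives the highest-density interval, the
#' smallest interval containing the requested mass.
#'
#' @param samples Numeric vector (>= 50 values).
#' @param weights Optional non-negative weights.
#' @param lower,upper Support bounds for the density grid.
#' @param level Probability mass of the interval.
#' @param interval `"central"` (weighted quantiles, default) or `"shortest"`
#'   (highest-density).
#' @return Tibble with `mode`, `hpd_lower`, `hpd_upper`.
#' @export
posterior_summary <- function(samples, weights = NULL,
                              lower = -Inf, upper = Inf, level = 0.90,
                              interval = c("central", "shortest")) {
  interval <- match.arg(interval)
  if (length(samples) < 50) stop("need at least 50 samples", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(samples))
  stopifnot(length(weights) == length(samples), all(weights >= 0),
            sum(weights) > 0)
  w <- weights / sum(weights)
  if (diff(range(samples)) == 0) {
    return(tibble::tibble(mode = samples[1], hpd_lower = samples[1],
                          hpd_upper = samples[1]))
  }
  from <- max(lower, min(samples))
  to <- min(upper, max(samples))
  dens <- suppressWarnings(
    stats::density(samples, weights = w, from = from, to = to, n = 512))
  mode <- dens$x[which.max(dens$y)]
  ord <- order(samples)
  xs <- samples[ord]
  cw <- cumsum(w[ord])
  if (interval == "central") {
    p_lo <- (1 - level) / 2
    lo <- xs[min(findInterval(p_lo, cw, left.open = TRUE) + 1L, length(xs))]
    hi <- xs[min(findInterval(1 - p_lo, cw, left.open = TRUE) + 1L, length(xs))]
    return(tibble::tibble(mode = mode, hpd_lower = lo, hpd_upper = hi))
  }
  lo_cum <- c(0, cw[-length(cw)])
  # for each left end i, smallest j with mass(i..j) >= level
  js <- findInterval(lo_cum + level, cw, left.open = TRUE) + 1L
  valid <- js <= length(xs)
  if (!any(valid)) {
    return(tibble::tibble(mode = mode, hpd_lower = xs[1],
                          hpd_upper = xs[length(xs)]))
  }
  width <- xs[js[valid]] - xs[which(valid)]
  i <- which(valid)[which.min(width)]
  tibble::tibble(mode = mode, hpd_lower = xs[i], hpd_upper = xs[js[i]])
}

#' Fit ABC posteriors and model probabilities for an observed dataset
#'
#' Runs the full inference: normalized distances, logistic model choice
#' across scenarios (when the table holds more than one), rejection within
#' the focal scenario, local linear regression adjustment, and
#' mode/90%-HPD summaries per parameter.
#'
#' @param ref An `abc_reference`.
#' @param observed Observed feature vector or [layer_stats()] tibble.
#' @param accept_fraction Fraction retained (applied to the pooled table for
#'   model choice and to the focal scenario's rows for estimation).
#' @param scenario Focal scenario for parameter estimation; defaults to the
#'   highest-probability one.
#' @param adjust Apply the regression adjustment (default) or keep the plain
#'   rejection sample.
#' @param interval Credible-interval type, see [posterior_summary()].
#' @return An `abc_fit`: list with `model_probs`, `posterior` (per-parameter
#'   mode and HPD bounds), `samples` (adjusted draws + weights), `scenario`,
#'   `accept_fraction`, `n_sims`.
#' @export
abc_fit <- function(ref, observed, accept_fraction = 0.01,
                    scenario = NULL, adjust = TRUE,
                    interval = c("central", "shortest")) {
  interval <- match.arg(interval)
  obs <- check_observed(observed, ref)
  distances <- normalized_distance(obs, ref)
  scen_ids <- unique(ref$table$scenario)
  model_probs <- if (length(scen_ids) >= 2) {
    model_choice_logistic(ref, distances, obs, accept_fraction)
  } else {
    tibble::tibble(scenario = scen_ids, probability = 1)
  }
  if (is.null(scenario)) {
    scenario <- model_probs$scenario[which.max(model_probs$probability)]
  }
  stopifnot(scenario %in% scen_ids)
  sub_rows <- which(ref$table$scenario == scenario)
  sub_d <- distances[sub_rows]
  m <- ceiling(accept_fraction * length(sub_rows))
  keep <- order(sub_d)[seq_len(m)]
  accepted <- ref$table[sub_rows[keep], ]
  accepted$.distance <- sub_d[keep]
  samples <- if (adjust) {
    loclinear_adjust(accepted, obs, ref)
  } else {
    out <- accepted[, ref$priors[[scenario]]$priors$parameter]
    out$.weight <- epanechnikov_weights(accepted$.distance)
    if (all(out$.weight == 0)) out$.weight <- 1
    out
  }
  pri <- ref$priors[[scenario]]$priors
  posterior <- dplyr::bind_rows(lapply(seq_len(nrow(pri)), function(i) {
    p <- pri$parameter[i]
    dplyr::bind_cols(
      tibble::tibble(parameter = p, prior_lower = pri$lower[i],
                     prior_upper = pri$upper[i]),
      posterior_summary(samples[[p]], samples$.weight,
                        lower = pri$lower[i], upper = pri$upper[i],
                        interval = interval))
  }))
  structure(list(model_probs = model_probs, posterior = posterior,
                 samples = samples, scenario = scenario,
                 accept_fraction = accept_fraction, adjusted = adjust,
                 n_sims = nrow(ref$table)),
            class = "abc_fit")
}

#' @export
print.abc_fit <- function(x, ...) {
  cat("<abc_fit> focal scenario:", x$scenario,
      sprintf("(accepted %d of %d simulations%s)\n",
              nrow(x$samples), x$n_sims,
              if (x$adjusted) ", regression-adjusted" else ""))
  if (nrow(x$model_probs) > 1) print(x$model_probs)
  print(x$posterior)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ABC fit: per-parameter posterior summaries
#'
#' @param x An `abc_fit`.
#' @param ... Unused.
#' @return Tibble with `parameter`, prior bounds, posterior `mode`,
#'   `hpd_lower`, `hpd_upper`.
#' @export
tidy.abc_fit <- function(x, ...) x$posterior

#' Glance at an ABC fit
#'
#' @param x An `abc_fit`.
#' @param ... Unused.
#' @return One-row tibble: focal scenario, its posterior probability,
#'   acceptance settings and table size.
#' @export
glance.abc_fit <- function(x, ...) {
  pr <- x$model_probs$probability[x$model_probs$scenario == x$scenario]
  tibble::tibble(scenario = x$scenario, probability = pr,
                 accept_fraction = x$accept_fraction,
                 n_accepted = nrow(x$samples), n_sims = x$n_sims,
                 adjusted = x$adjusted)
}

#' Pod-based confusion matrix and type I/II error rates
#'
#' Generates pseudo-observed datasets (pods) under each scenario with fresh
#' prior draws, runs each through the full pipeline (summary statistics,
#' normalized distances, logistic model choice against the shared reference
#' table), assigns it to the highest-probability scenario, and reports per
#' focal scenario the type I error (own pods assigned elsewhere) and type II
#' error (other scenarios' pods assigned to it).
#'
#' @param ref An `abc_reference` with >= 2 scenarios.
#' @param n_pods_per_model Pods per scenario (>= 10).
#' @param accept_fraction Fraction retained for model choice.
#' @param seed Optional integer seed.
#' @return A `pods_confusion`: list with `confusion` (tibble of counts,
#'   `true_scenario` x `assigned_scenario`), `errors` (tibble `scenario`,
#'   `type_I`, `type_II`), `n_pods_per_model`.
#' @export
pods_confusion <- function(ref, n_pods_per_model, accept_fraction = 0.01,
                           seed = NULL) {
  stopifnot(inherits(ref, "abc_reference"), n_pods_per_model >= 10)
  scen_ids <- unique(ref$table$scenario)
  if (length(scen_ids) < 2) stop("need >= 2 scenarios", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  assigned <- list()
  for (s in scen_ids) {
    par_draws <- draw_params(ref$priors[[s]], n_pods_per_model)
    got <- character(n_pods_per_model)
    for (i in seq_len(n_pods_per_model)) {
      feats <- simulate_feature_row(s, as.list(par_draws[i, ]), ref$config)
      d <- normalized_distance(feats, ref)
      pr <- model_choice_logistic(ref, d, feats, accept_fraction)
      got[i] <- pr$scenario[which.max(pr$probability)]
    }
    assigned[[s]] <- got
  }
  confusion <- dplyr::bind_rows(lapply(scen_ids, function(s) {
    cnt <- table(factor(assigned[[s]], levels = scen_ids))
    dplyr::bind_cols(tibble::tibble(true_scenario = s),
                     tibble::as_tibble(as.list(cnt)))
  }))
  errors <- dplyr::bind_rows(lapply(scen_ids, function(s) {
    own <- assigned[[s]]
    others <- unlist(assigned[setdiff(scen_ids, s)], use.names = FALSE)
    tibble::tibble(scenario = s,
                   type_I = mean(own != s),
                   type_II = mean(others == s))
  }))
  structure(list(confusion = confusion, errors = errors,
                 n_pods_per_model = n_pods_per_model,
                 accept_fraction = accept_fraction),
            class = "pods_confusion")
}

#' @export
print.pods_confusion <- function(x, ...) {
  cat("<pods_confusion>", x$n_pods_per_model, "pods per scenario\n")
  print(x$confusion)
  print(x$errors)
  invisible(x)
}

#' Pod-based coverage of a parameter's credible interval
#'
#' Simulates pods under one scenario with known truth, estimates the
#' parameter by rejection + regression adjustment against the scenario's rows
#' of the reference table, and reports how often the 90% HPD interval covers
#' the truth (nominally ~90% for calibrated inference from prior-drawn pods).
#'
#' @param ref An `abc_reference` containing the scenario.
#' @param scenario Scenario id.
#' @param parameter Parameter name.
#' @param n_pods Number of pods.
#' @param accept_fraction Fraction of the scenario's rows retained.
#' @param adjust Regression-adjust (default) or rejection only.
#' @param interval Credible-interval type, see [posterior_summary()].
#' @param seed Optional integer seed.
#' @return Tibble with one row per pod: `truth`, `mode`, `hpd_lower`,
#'   `hpd_upper`, `covered`.
#' @export
pods_parameter_coverage <- function(ref, scenario, parameter, n_pods,
                                    accept_fraction = 0.01, adjust = TRUE,
                                    interval = "central", seed = NULL) {
  stopifnot(scenario %in% unique(ref$table$scenario),
            parameter %in% ref$priors[[scenario]]$priors$parameter)
  if (!is.null(seed)) set.seed(seed)
  sub_ref <- ref
  keep <- ref$table$scenario == scenario
  sub_ref$table <- ref$table[keep, ]
  par_draws <- draw_params(ref$priors[[scenario]], n_pods)
  rows <- lapply(seq_len(n_pods), function(i) {
    feats <- simulate_feature_row(scenario, as.list(par_draws[i, ]),
                                  ref$config)
    fit <- abc_fit(sub_ref, feats, accept_fraction = accept_fraction,
                   scenario = scenario, adjust = adjust, interval = interval)
    post <- fit$posterior[fit$posterior$parameter == parameter, ]
    truth <- par_draws[[parameter]][i]
    tibble::tibble(truth = truth, mode = post$mode,
                   hpd_lower = post$hpd_lower, hpd_upper = post$hpd_upper,
                   covered = truth >= post$hpd_lower & truth <= post$hpd_upper)
  })
  dplyr::bind_rows(rows)
}
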