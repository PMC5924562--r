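# End-to-end orchestration with reproducible configuration, staged logging,
# and standard-format outputs (TSV, JSON manifest, GraphML, FASTA).

#' Build a pipeline run configuration
#'
#' Either point `fasta`/`meta` at an observed alignment, or leave them `NULL`
#' to analyse a synthetic dataset generated from `synthetic_scenario`. The
#' configuration round-trips losslessly through YAML via [write_run_config()]
#' / [read_run_config()].
#'
#' @param fasta,meta Paths to the observed FASTA and metadata TSV, or `NULL`.
#' @param synthetic_scenario Scenario used to generate a synthetic dataset
#'   when no input files are given.
#' @param scenarios Scenario ids compared by ABC.
#' @param n_sims Simulations per scenario for the reference table.
#' @param accept_fraction ABC acceptance fraction.
#' @param n_pods Pods per scenario for the confusion analysis (0 skips it).
#' @param network Build the haplotype network stage.
#' @param seed Integer seed recorded in every output.
#' @param out_dir Output directory.
#' @param locus_length,n_historical,age_historical,n_modern Shape of the
#'   synthetic dataset (ignored when reading files).
#' @return A `run_config` list.
#' @export
run_config <- function(fasta = NULL, meta = NULL,
                       synthetic_scenario = "bottleneck_eu",
                       scenarios = c("bottleneck_eu", "bottleneck_pol"),
                       n_sims = 5000, accept_fraction = 0.02,
                       n_pods = 0, network = TRUE, seed = 1,
                       out_dir = tempfile("tempogen_run_"),
                       locus_length = 16588, n_historical = 39,
                       age_historical = 5, n_modern = 79) {
  cfg <- list(fasta = fasta, meta = meta,
              synthetic_scenario = synthetic_scenario,
              scenarios = scenarios, n_sims = n_sims,
              accept_fraction = accept_fraction, n_pods = n_pods,
              network = network, seed = as.integer(seed), out_dir = out_dir,
              locus_length = locus_length, n_historical = n_historical,
              age_historical = age_historical, n_modern = n_modern)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg[!vapply(cfg, is.null, logical(1))])
}

stage <- function(name, expr) {
  message("[tempogen] stage: ", name)
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  attr(out, "elapsed_s") <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  out
}

#' Run the full pipeline
#'
#' Stages: load or generate the dataset; per-layer diversity statistics and
#' fold-change report; haplotype network; ABC reference table, fit and model
#' probabilities; optional pod confusion. Writes a diversity TSV, a posterior
#' TSV (parameter, prior, mode, HPD bounds), model probabilities, network
#' exports, and a JSON run manifest recording the seed, configuration hash,
#' package version and per-stage timings. Any stage error halts the run with
#' a stage-named message; outputs of completed stages are retained.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`stats`, `fit`,
#'   `network`, `pods`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "tempogen",
                   version = as.character(utils::packageVersion("tempogen")),
                   seed = config$seed,
                   config = unclass(config),
                   config_hash = rlang::hash(unclass(config)),
                   started = format(Sys.time(), tz = "UTC"),
                   stages = list())
  timings <- list()

  aln <- stage("load_data", {
    if (!is.null(config$fasta)) {
      read_temporal_alignment(config$fasta, config$meta)
    } else {
      cfg <- sample_config(n = c(config$n_modern, config$n_historical),
                           age = c(0, config$age_historical),
                           locus_length = config$locus_length)
      ds <- generate_dataset(dataset_spec(config$synthetic_scenario,
                                          config = cfg))
      write_dataset(ds, config$out_dir, "synthetic")
      ds$alignment
    }
  })
  timings$load_data <- attr(aln, "elapsed_s")

  stats <- stage("stats", {
    st <- layer_stats(aln)
    readr::write_tsv(st, file.path(config$out_dir, "diversity_stats.tsv"))
    if (nrow(st) >= 2) {
      fc <- fold_change_report(st, older = st$layer[which.max(st$age)],
                               newer = st$layer[which.min(st$age)])
      readr::write_tsv(fc, file.path(config$out_dir, "fold_change.tsv"))
    }
    st
  })
  timings$stats <- attr(stats, "elapsed_s")

  net <- NULL
  if (isTRUE(config$network)) {
    net <- stage("network", {
      ht <- collapse_haplotypes(aln)
      readr::write_tsv(ht, file.path(config$out_dir, "haplotypes.tsv"))
      if (nrow(ht) >= 2) {
        nw <- min_spanning_network(ht)
        write_network(nw,
                      edges_tsv = file.path(config$out_dir, "network_edges.tsv"),
                      graphml = file.path(config$out_dir, "network.graphml"))
        nw
      } else {
        NULL
      }
    })
    timings$network <- attr(net, "elapsed_s")
  }

  cfg_layers <- alignment_layers(aln)
  sim_config <- sample_config(layer = cfg_layers$layer, n = cfg_layers$n,
                              age = cfg_layers$age_generations,
                              locus_length = n_sites(aln))
  ref <- stage("abc_table", {
    build_reference_table(config$scenarios, config$n_sims, config = sim_config)
  })
  timings$abc_table <- attr(ref, "elapsed_s")

  fit <- stage("abc_fit", {
    f <- abc_fit(ref, stats, accept_fraction = config$accept_fraction)
    readr::write_tsv(tidy(f), file.path(config$out_dir, "posterior.tsv"))
    readr::write_tsv(f$model_probs,
                     file.path(config$out_dir, "model_probabilities.tsv"))
    f
  })
  timings$abc_fit <- attr(fit, "elapsed_s")

  pods <- NULL
  if (config$n_pods >= 10 && length(config$scenarios) >= 2) {
    pods <- stage("pods", {
      pc <- pods_confusion(ref, config$n_pods,
                           accept_fraction = config$accept_fraction)
      readr::write_tsv(pc$confusion,
                       file.path(config$out_dir, "pods_confusion.tsv"))
      readr::write_tsv(pc$errors, file.path(config$out_dir, "pods_errors.tsv"))
      pc
    })
    timings$pods <- attr(pods, "elapsed_s")
  }

  manifest$stages <- timings
  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(stats = stats, network = net, fit = fit, pods = pods,
                 manifest = manifest))
}
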