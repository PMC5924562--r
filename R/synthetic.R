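# Study-shaped synthetic datasets: two dated layers, mitogenome-sized locus,
# missing-data injection mimicking low-coverage consensus calling; and pods
# (pseudo-observed datasets) for ABC validation.

#' Specification of a synthetic dataset
#'
#' Defaults emulate the study conditions: 39 historical sequences at age 5
#' generations, 79 modern sequences at age 0, a 16,588 bp haploid maternally
#' inherited locus, and 2% of bases per historical sequence replaced by N
#' (none in modern sequences), mimicking positions left undetermined by a
#' low-coverage majority-rule consensus.
#'
#' @param scenario One of [scenario_ids()].
#' @param params Optional named list of true parameters; when `NULL` they are
#'   drawn from `priors` at generation time.
#' @param priors A `prior_set`; defaults to [default_priors()] for the
#'   scenario.
#' @param config A [sample_config()].
#' @param missing_fraction Named per-layer probability that a base is
#'   replaced by N (independently per site); layers not named get 0.
#' @param model Mutation model passed to [drop_mutations()].
#' @return A `dataset_spec` list.
#' @export
dataset_spec <- function(scenario = "bottleneck_eu",
                         params = NULL,
                         priors = default_priors(scenario),
                         config = sample_config(),
                         missing_fraction = c(historical = 0.02, modern = 0),
                         model = "infinite_sites") {
  check_scenario_id(scenario)
  stopifnot(all(missing_fraction >= 0), all(missing_fraction < 1))
  structure(list(scenario = scenario, params = params, priors = priors,
                 config = config, missing_fraction = missing_fraction,
                 model = model),
            class = "dataset_spec")
}

inject_missing <- function(aln, missing_fraction) {
  if (all(missing_fraction == 0)) return(aln)
  L <- n_sites(aln)
  frac <- missing_fraction[aln$meta$layer]
  frac[is.na(frac)] <- 0
  seqs <- aln$seq
  for (i in seq_along(seqs)) {
    if (frac[i] > 0) {
      hit <- which(stats::runif(L) < frac[i])
      if (length(hit) > 0) {
        s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        s[hit] <- "N"
        seqs[i] <- paste(s, collapse = "")
      }
    }
  }
  temporal_alignment(seqs, aln$meta)
}

#' Generate one labelled synthetic dataset
#'
#' Simulates a genealogy and mutations under the spec's scenario, converts
#' them to a [temporal_alignment()], injects undetermined bases (N) at
#' uniformly chosen positions per sequence at the layer's missing fraction,
#' and records the generating truth for every free parameter.
#'
#' @param spec A [dataset_spec()].
#' @param seed Optional integer seed for reproducibility.
#' @return A `labeled_dataset`: list with `alignment`, `truth` (tibble
#'   `parameter`, `value`), `scenario`.
#' @export
generate_dataset <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "dataset_spec"))
  if (!is.null(seed)) set.seed(seed)
  params <- spec$params
  if (is.null(params)) params <- as.list(draw_params(spec$priors, 1))
  scen <- build_scenario(spec$scenario, params)
  gen <- simulate_genealogy(scen, spec$config)
  aln <- drop_mutations(gen, params$mu, locus_length(spec$config),
                        model = spec$model)
  aln <- inject_missing(aln, spec$missing_fraction)
  structure(list(alignment = aln,
                 truth = tibble::tibble(parameter = names(params),
                                        value = as.numeric(unlist(params))),
                 scenario = spec$scenario),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> scenario:", x$scenario, "\n")
  print(x$alignment)
  print(x$truth)
  invisible(x)
}

#' Generate pseudo-observed datasets (pods)
#'
#' Each pod draws fresh parameters from the scenario's priors (order
#' constraints enforced) and simulates a study-shaped dataset. Pods carry
#' their generating truth and are used to estimate type I/II error rates of
#' ABC model choice and coverage of parameter estimates. Pods carry no
#' missing data (they emulate the simulated, not the sequenced, side).
#'
#' @param scenario_id One of [scenario_ids()].
#' @param n_pods Number of pods (>= 1).
#' @param priors A `prior_set`.
#' @param config A [sample_config()].
#' @param model Mutation model.
#' @param seed Optional integer seed.
#' @return List of `labeled_dataset`.
#' @export
generate_pods <- function(scenario_id, n_pods,
                          priors = default_priors(scenario_id),
                          config = sample_config(),
                          model = "infinite_sites",
                          seed = NULL) {
  check_scenario_id(scenario_id)
  if (!(is.numeric(n_pods) && length(n_pods) == 1 && n_pods >= 1)) {
    stop("n_pods must be >= 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  spec <- dataset_spec(scenario_id, priors = priors, config = config,
                       missing_fraction = c(none = 0), model = model)
  lapply(seq_len(n_pods), function(i) generate_dataset(spec))
}

#' Write a labelled dataset to disk
#'
#' FASTA + metadata TSV (columns `sample_id`, `layer`, `age_generations`) +
#' a JSON sidecar holding the scenario id and true parameters.
#'
#' @param ds A `labeled_dataset`.
#' @param dir Output directory (created if needed).
#' @param stem File stem; writes `<stem>.fasta`, `<stem>_meta.tsv`,
#'   `<stem>_truth.json`.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_dataset <- function(ds, dir, stem = "dataset") {
  stopifnot(inherits(ds, "labeled_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, paste0(stem, ".fasta")),
             meta = file.path(dir, paste0(stem, "_meta.tsv")),
             truth = file.path(dir, paste0(stem, "_truth.json")))
  write_temporal_alignment(ds$alignment, paths["fasta"], paths["meta"])
  truth <- as.list(stats::setNames(ds$truth$value, ds$truth$parameter))
  jsonlite::write_json(c(list(scenario = ds$scenario), truth),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
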