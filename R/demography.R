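# Demographic scenarios: parameters, priors, order constraints, and
# piecewise-constant haploid size histories on a backwards-in-time
# generation axis (time 0 = the most recent sampling layer).

.param_priors <- tibble::tribble(
  ~parameter,           ~lower, ~upper,
  "ne_modern",               1,    200,
  "ne_pre_european",       5e3,    6e5,
  "ne_pre_human",          5e3,    6e5,
  "ne_pre_glaciation",     1e3,    3e5,
  "ne_constant",           1e3,    3e5,
  "t_bottleneck_eu",         1,     10,
  "t_bottleneck",            1,     30,
  "t_bottleneck_pol",       20,     30,
  "t_post_glaciation",     300,    600,
  "mu",                   1e-8,   1e-7
)

.scenario_defs <- list(
  constant = list(
    params = c("ne_constant", "mu"),
    constraints = NULL
  ),
  expansion = list(
    params = c("ne_pre_european", "ne_pre_glaciation", "t_post_glaciation", "mu"),
    constraints = list(c("ne_pre_european", "ne_pre_glaciation"))
  ),
  expansion_bottleneck = list(
    params = c("ne_modern", "ne_pre_european", "ne_pre_glaciation",
               "t_bottleneck", "t_post_glaciation", "mu"),
    constraints = list(c("ne_pre_european", "ne_pre_glaciation"))
  ),
  bottleneck_eu = list(
    params = c("ne_modern", "ne_pre_european", "ne_pre_glaciation",
               "t_bottleneck_eu", "t_post_glaciation", "mu"),
    constraints = list(c("ne_pre_european", "ne_pre_glaciation"))
  ),
  bottleneck_pol = list(
    params = c("ne_modern", "ne_pre_human", "ne_pre_glaciation",
               "t_bottleneck_pol", "t_post_glaciation", "mu"),
    constraints = list(c("ne_pre_human", "ne_pre_glaciation"))
  ),
  bottleneck_pol_eu = list(
    params = c("ne_modern", "ne_pre_human", "ne_pre_european",
               "ne_pre_glaciation", "t_bottleneck_eu", "t_bottleneck_pol",
               "t_post_glaciation", "mu"),
    constraints = list(c("ne_pre_human", "ne_pre_glaciation"),
                       c("ne_pre_human", "ne_pre_european"))
  )
)

#' Supported demographic scenario identifiers
#'
#' Six single-deme piecewise-constant scenarios for a maternally inherited
#' haploid locus: constant size; postglacial expansion; expansion followed by
#' one recent bottleneck; and three refined bottleneck models distinguishing a
#' recent ("European", 1-10 generations ago) bottleneck, an older
#' ("Polynesian", 20-30 generations ago) bottleneck, and their combination.
#'
#' @return Character vector of scenario ids.
#' @export
#' @examples
#' scenario_ids()
scenario_ids <- function() names(.scenario_defs)

check_scenario_id <- function(scenario_id) {
  if (!(is.character(scenario_id) && length(scenario_id) == 1 &&
        scenario_id %in% names(.scenario_defs))) {
    stop("unknown scenario id: ", paste(scenario_id, collapse = ", "),
         "; must be one of ", paste(names(.scenario_defs), collapse = ", "),
         call. = FALSE)
  }
  scenario_id
}

#' Default uniform priors and order constraints for a scenario
#'
#' Returns the wide uniform priors used for prior-predictive simulation,
#' together with the order constraints between effective sizes (e.g. the
#' pre-human size must exceed both the pre-glaciation and the pre-European
#' size in the double-bottleneck model). Times are in generations before
#' present, sizes are haploid effective sizes, and `mu` is a per-site
#' per-generation mutation rate.
#'
#' @param scenario_id One of [scenario_ids()].
#' @return A `prior_set`: list with `scenario`, `priors` (tibble with columns
#'   `parameter`, `lower`, `upper`) and `constraints` (tibble with columns
#'   `greater`, `lesser`; zero rows if none).
#' @export
#' @examples
#' default_priors("bottleneck_eu")
default_priors <- function(scenario_id) {
  check_scenario_id(scenario_id)
  def <- .scenario_defs[[scenario_id]]
  priors <- .param_priors[match(def$params, .param_priors$parameter), ]
  cons <- if (is.null(def$constraints)) {
    tibble::tibble(greater = character(), lesser = character())
  } else {
    tibble::tibble(
      greater = vapply(def$constraints, `[`, "", 1),
      lesser  = vapply(def$constraints, `[`, "", 2)
    )
  }
  new_prior_set(scenario_id, priors, cons)
}

new_prior_set <- function(scenario, priors, constraints) {
  stopifnot(all(priors$lower < priors$upper))
  bad <- setdiff(c(constraints$greater, constraints$lesser), priors$parameter)
  if (length(bad) > 0) {
    stop("constraints reference undeclared parameters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(scenario = scenario, priors = priors, constraints = constraints),
            class = "prior_set")
}

#' @export
print.prior_set <- function(x, ...) {
  cat("<prior_set> scenario:", x$scenario, "\n")
  print(x$priors)
  if (nrow(x$constraints) > 0) {
    cat("conditions:",
        paste(x$constraints$greater, ">", x$constraints$lesser, collapse = "; "),
        "\n")
  }
  invisible(x)
}

#' Draw scenario parameters from their priors
#'
#' Draws independently from each uniform prior and rejects draws violating
#' any order constraint (draw-and-reject, the DIYABC-style condition
#' mechanism), so accepted draws follow the prior truncated to the
#' constraint-satisfying region.
#'
#' @param priors A `prior_set` from [default_priors()].
#' @param n Number of accepted draws to return.
#' @param max_tries Error if more than this many consecutive raw draws are
#'   rejected (unsatisfiable constraints).
#' @return A tibble with `n` rows, one column per parameter.
#' @export
#' @examples
#' set.seed(1)
#' draw_params(default_priors("bottleneck_pol_eu"), n = 5)
draw_params <- function(priors, n = 1, max_tries = 1e6) {
  stopifnot(inherits(priors, "prior_set"), n >= 1)
  p <- priors$priors
  cons <- priors$constraints
  out <- matrix(NA_real_, nrow = 0, ncol = nrow(p))
  colnames(out) <- p$parameter
  rejected_run <- 0
  while (nrow(out) < n) {
    m <- max(n - nrow(out), 1) * 2L
    draws <- vapply(seq_len(nrow(p)),
                    function(j) stats::runif(m, p$lower[j], p$upper[j]),
                    numeric(m))
    draws <- matrix(draws, nrow = m, dimnames = list(NULL, p$parameter))
    ok <- rep(TRUE, m)
    for (i in seq_len(nrow(cons))) {
      ok <- ok & draws[, cons$greater[i]] > draws[, cons$lesser[i]]
    }
    if (!any(ok)) {
      rejected_run <- rejected_run + m
      if (rejected_run > max_tries) {
        stop("order constraints rejected more than ", max_tries,
             " consecutive draws; check prior bounds", call. = FALSE)
      }
      next
    }
    rejected_run <- 0
    out <- rbind(out, draws[ok, , drop = FALSE])
  }
  tibble::as_tibble(out[seq_len(n), , drop = FALSE])
}

# epoch layout per scenario: (start time, size expression) going backwards
.scenario_epochs <- list(
  constant = function(p) list(starts = 0, sizes = p[["ne_constant"]]),
  expansion = function(p) list(
    starts = c(0, p[["t_post_glaciation"]]),
    sizes  = c(p[["ne_pre_european"]], p[["ne_pre_glaciation"]])
  ),
  expansion_bottleneck = function(p) list(
    starts = c(0, p[["t_bottleneck"]], p[["t_post_glaciation"]]),
    sizes  = c(p[["ne_modern"]], p[["ne_pre_european"]], p[["ne_pre_glaciation"]])
  ),
  bottleneck_eu = function(p) list(
    starts = c(0, p[["t_bottleneck_eu"]], p[["t_post_glaciation"]]),
    sizes  = c(p[["ne_modern"]], p[["ne_pre_european"]], p[["ne_pre_glaciation"]])
  ),
  bottleneck_pol = function(p) list(
    starts = c(0, p[["t_bottleneck_pol"]], p[["t_post_glaciation"]]),
    sizes  = c(p[["ne_modern"]], p[["ne_pre_human"]], p[["ne_pre_glaciation"]])
  ),
  bottleneck_pol_eu = function(p) list(
    starts = c(0, p[["t_bottleneck_eu"]], p[["t_bottleneck_pol"]],
               p[["t_post_glaciation"]]),
    sizes  = c(p[["ne_modern"]], p[["ne_pre_european"]], p[["ne_pre_human"]],
               p[["ne_pre_glaciation"]])
  )
)

#' Build a piecewise-constant demographic scenario
#'
#' Converts named parameters into an ordered epoch table on a backwards-in-time
#' generation axis. Each epoch is (start time in generations before present,
#' haploid effective size); the size history is a right-continuous step
#' function of time, with instantaneous changes at epoch starts.
#'
#' @param scenario_id One of [scenario_ids()].
#' @param params Named list, one-row data frame, or named numeric vector
#'   holding every parameter the scenario needs (see [default_priors()]).
#' @param generation_time_years Years per generation, used only for reporting
#'   on a calendar axis. Default 25.
#' @return A `demographic_scenario`: list with `id`, `epochs` (tibble with
#'   columns `start`, `size`), `mu` (if supplied) and `generation_time_years`.
#' @export
#' @examples
#' build_scenario("constant", list(ne_constant = 1000, mu = 1e-8))
build_scenario <- function(scenario_id, params, generation_time_years = 25) {
  check_scenario_id(scenario_id)
  if (is.data.frame(params)) {
    stopifnot(nrow(params) == 1)
    params <- as.list(params)
  }
  params <- as.list(params)
  needed <- .scenario_defs[[scenario_id]]$params
  present <- vapply(needed, function(nm) {
    !is.null(params[[nm]]) && is.finite(params[[nm]])
  }, logical(1))
  missing <- needed[!present]
  if (length(missing) > 0) {
    stop("scenario '", scenario_id, "' is missing parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ep <- .scenario_epochs[[scenario_id]](params)
  if (any(ep$sizes <= 0)) stop("all effective sizes must be > 0", call. = FALSE)
  if (any(diff(ep$starts) <= 0)) {
    stop("epoch start times must be strictly increasing", call. = FALSE)
  }
  structure(
    list(
      id = scenario_id,
      epochs = tibble::tibble(start = ep$starts, size = ep$sizes),
      mu = if (!is.null(params$mu)) params$mu else NA_real_,
      generation_time_years = generation_time_years,
      params = params[needed]
    ),
    class = "demographic_scenario"
  )
}

#' @export
print.demographic_scenario <- function(x, ...) {
  cat("<demographic_scenario>", x$id,
      sprintf("(generation time %s y)\n", x$generation_time_years))
  print(x$epochs)
  if (!is.na(x$mu)) cat("mu:", format(x$mu), "per site per generation\n")
  invisible(x)
}

#' Effective size at a time before present
#'
#' Right-continuous step function: at an epoch start the new (older) epoch's
#' size applies.
#'
#' @param scenario A `demographic_scenario`.
#' @param t Numeric vector of times in generations before present (>= 0).
#' @return Numeric vector of haploid effective sizes.
#' @export
size_at <- function(scenario, t) {
  stopifnot(inherits(scenario, "demographic_scenario"), all(t >= 0))
  idx <- findInterval(t, scenario$epochs$start)
  scenario$epochs$size[idx]
}
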