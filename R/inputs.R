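# domain validators ----------------------------------------------------------

check_prob <- function(value, key) {
  if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
      value < 0 || value > 1) {
    stop(sprintf("'%s' must be a probability in [0, 1] (got %s)",
                 key, format(value)), call. = FALSE)
  }
  value
}

check_pos <- function(value, key, strict = TRUE) {
  ok <- is.numeric(value) && length(value) == 1 && !is.na(value) &&
    (if (strict) value > 0 else value >= 0)
  if (!ok) {
    stop(sprintf("'%s' must be %s (got %s)", key,
                 if (strict) "> 0" else ">= 0", format(value)), call. = FALSE)
  }
  value
}

fit_from_config <- function(lst, key) {
  if (is.null(lst$family)) stop(sprintf("'%s' needs a 'family' entry", key), call. = FALSE)
  parametric_fit(lst$family, lst[setdiff(names(lst), "family")])
}

expected_input_keys <- c(
  "horizon_years", "cycles_per_year", "discount_rate_costs",
  "discount_rate_qalys", "threshold", "os_hazard_ratio",
  "background_mortality_annual", "drug_discount_fraction",
  "adjuvant_drug_years", "pd_drug_years", "structure",
  "costs", "utilities", "dfs_fits", "pd_death_fit",
  "event_splits", "adverse_events")

cost_keys <- c("egfr_test_once", "osimertinib_annual", "ned_annual_yr1_3",
               "ned_annual_yr4_5", "ned_annual_after5", "pd_diagnosis_once",
               "osimertinib_pd_annual", "pd_annual", "cns_pos_once",
               "cns_mri_annual", "end_of_life_once")
utility_keys <- c("ned_placebo", "ned_osimertinib", "pd_cns_neg", "pd_cns_pos")
split_keys <- c("placebo_cns_pos", "placebo_cns_neg",
                "osimertinib_cns_pos", "osimertinib_cns_neg")

#' Assemble and validate the full economic parameter set
#'
#' Builds the `model_inputs` object from a named list (usually parsed from
#' the packaged YAML). Every numeric is validated against its domain;
#' unknown keys are rejected; a missing `cycles_per_year` defaults to 12
#' (monthly cycles) with a message. Recurrence fractions are derived from
#' the event splits by exact integer arithmetic at access time.
#'
#' @param config Named list of inputs; see the packaged
#'   `extdata/model_inputs.yaml` for the schema and base-case values.
#' @return An object of class `model_inputs`.
#' @seealso [load_config()], [default_model_inputs()]
#' @export
model_inputs <- function(config) {
  unknown <- setdiff(names(config), expected_input_keys)
  if (length(unknown) > 0) {
    stop("unknown model-input keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(expected_input_keys, names(config))
  if ("cycles_per_year" %in% missing) {
    message("'cycles_per_year' not supplied; defaulting to 12 (monthly cycles)")
    config$cycles_per_year <- 12
    missing <- setdiff(missing, "cycles_per_year")
  }
  if (length(missing) > 0) {
    stop("missing model-input keys: ", paste(missing, collapse = ", "), call. = FALSE)
  }

  check_pos(config$horizon_years, "horizon_years")
  check_pos(config$cycles_per_year, "cycles_per_year")
  n_cycles <- config$horizon_years * config$cycles_per_year
  if (abs(n_cycles - round(n_cycles)) > 1e-9) {
    stop("'horizon_years' must be an integer multiple of the cycle length", call. = FALSE)
  }
  for (key in c("discount_rate_costs", "discount_rate_qalys")) {
    v <- config[[key]]
    if (!is.numeric(v) || v < 0 || v >= 1) {
      stop(sprintf("'%s' must lie in [0, 1) (got %s)", key, format(v)), call. = FALSE)
    }
  }
  check_pos(config$threshold, "threshold")
  check_pos(config$os_hazard_ratio, "os_hazard_ratio")
  check_prob(config$background_mortality_annual, "background_mortality_annual")
  check_prob(config$drug_discount_fraction, "drug_discount_fraction")
  check_pos(config$adjuvant_drug_years, "adjuvant_drug_years")
  check_pos(config$pd_drug_years, "pd_drug_years")
  config$structure <- match.arg(config$structure, c("stratified", "competing"))

  for (key in cost_keys) {
    if (is.null(config$costs[[key]])) stop("missing cost entry '", key, "'", call. = FALSE)
    check_pos(config$costs[[key]], paste0("costs$", key), strict = FALSE)
  }
  extra <- setdiff(names(config$costs), cost_keys)
  if (length(extra) > 0) stop("unknown cost keys: ", paste(extra, collapse = ", "), call. = FALSE)

  for (key in utility_keys) {
    if (is.null(config$utilities[[key]])) stop("missing utility '", key, "'", call. = FALSE)
    check_prob(config$utilities[[key]], paste0("utilities$", key))
  }

  for (key in split_keys) {
    sp <- config$event_splits[[key]]
    if (is.null(sp)) stop("missing event split '", key, "'", call. = FALSE)
    if (sp$recurrences < 0 || sp$events <= 0 || sp$recurrences > sp$events) {
      stop(sprintf("event split '%s' must satisfy 0 <= recurrences <= events", key),
           call. = FALSE)
    }
  }

  ae <- do.call(rbind, lapply(config$adverse_events, function(row) {
    data.frame(name = row$name, stage = row$stage,
               probability = check_prob(row$probability, paste0("ae:", row$name)),
               disutility = row$disutility, cost = row$cost)
  }))
  if (any(ae$disutility > 0)) stop("adverse-event disutilities must be <= 0", call. = FALSE)
  if (!all(ae$stage %in% c("ned", "pd", "cns"))) {
    stop("adverse-event 'stage' must be one of ned, pd, cns", call. = FALSE)
  }

  inputs <- list(
    horizon_years = config$horizon_years,
    cycles_per_year = config$cycles_per_year,
    cycle_length = 1 / config$cycles_per_year,
    n_cycles = as.integer(round(n_cycles)),
    discount_rate_costs = config$discount_rate_costs,
    discount_rate_qalys = config$discount_rate_qalys,
    threshold = config$threshold,
    os_hazard_ratio = config$os_hazard_ratio,
    background_mortality_annual = config$background_mortality_annual,
    drug_discount_fraction = config$drug_discount_fraction,
    adjuvant_drug_years = config$adjuvant_drug_years,
    pd_drug_years = config$pd_drug_years,
    structure = config$structure,
    costs = config$costs[cost_keys],
    utilities = config$utilities[utility_keys],
    dfs_fits = lapply(config$dfs_fits[split_keys], fit_from_config, key = "dfs_fits"),
    pd_death_fit = fit_from_config(config$pd_death_fit, "pd_death_fit"),
    event_splits = config$event_splits[split_keys],
    adverse_events = ae
  )
  class(inputs) <- "model_inputs"
  inputs
}

#' Load model inputs from a YAML configuration file
#'
#' @param path Path to a YAML file following the packaged schema; `NULL`
#'   (the default) loads the packaged base-case inputs.
#' @return A validated [model_inputs()] object.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "model_inputs.yaml", package = "osicea",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  model_inputs(yaml::read_yaml(path))
}

#' @rdname load_config
#' @export
default_model_inputs <- function() load_config(NULL)

#' Recurrence fraction implied by an event split
#'
#' Fraction of disease-free survival events that were recurrences (rather
#' than deaths), computed by exact integer arithmetic from the recorded
#' counts.
#'
#' @param inputs A [model_inputs()] object.
#' @param arm `"placebo"` or `"osimertinib"`.
#' @param cns `"pos"` or `"neg"`.
#' @return A probability.
#' @export
recurrence_fraction <- function(inputs, arm, cns) {
  key <- paste0(match.arg(arm, c("placebo", "osimertinib")), "_cns_",
                match.arg(cns, c("pos", "neg")))
  sp <- inputs$event_splits[[key]]
  sp$recurrences / sp$events
}

#' Arm-level model specification
#'
#' Bundles everything arm-specific the cohort engine needs: the two
#' disease-free survival fits (CNS-positive / CNS-negative disease), the
#' recurrence-versus-death splits derived from the trial event counts, the
#' CNS-positive stratum weight (share of the arm's DFS events that were
#' CNS-positive, used by the stratified structure), the post-progression
#' survival fit, the overall-survival hazard ratio (1 for placebo), and
#' background mortality.
#'
#' @param inputs A [model_inputs()] object.
#' @param arm `"placebo"` or `"osimertinib"`.
#' @param os_hazard_ratio Override for the arm's post-progression hazard
#'   ratio (defaults to 1 for placebo and `inputs$os_hazard_ratio` for
#'   osimertinib).
#' @return An object of class `arm_spec`.
#' @export
arm_spec <- function(inputs, arm, os_hazard_ratio = NULL) {
  arm <- match.arg(arm, c("placebo", "osimertinib"))
  if (is.null(os_hazard_ratio)) {
    os_hazard_ratio <- if (arm == "placebo") 1 else inputs$os_hazard_ratio
  }
  check_pos(os_hazard_ratio, "os_hazard_ratio")
  ev_pos <- inputs$event_splits[[paste0(arm, "_cns_pos")]]$events
  ev_neg <- inputs$event_splits[[paste0(arm, "_cns_neg")]]$events
  structure(list(
    arm = arm,
    dfs_cns_pos = inputs$dfs_fits[[paste0(arm, "_cns_pos")]],
    dfs_cns_neg = inputs$dfs_fits[[paste0(arm, "_cns_neg")]],
    recurrence_fraction_cns_pos = recurrence_fraction(inputs, arm, "pos"),
    recurrence_fraction_cns_neg = recurrence_fraction(inputs, arm, "neg"),
    cns_pos_weight = ev_pos / (ev_pos + ev_neg),
    pd_death_fit = inputs$pd_death_fit,
    os_hazard_ratio = os_hazard_ratio,
    background_mortality_annual = inputs$background_mortality_annual
  ), class = "arm_spec")
}
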