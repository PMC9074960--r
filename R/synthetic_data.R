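#' Specify a right-censored survival simulation
#'
#' Describes a simulated trial arm: an event-time distribution from one of
#' the six supported families, an independent exponential censoring process,
#' and an administrative cutoff. Together with [simulate_ipd()] this gives
#' reconstruction and fitting a ground truth to be tested against.
#'
#' @param family One of [survival_families()].
#' @param params Named list/vector of distribution parameters (see
#'   [survival_families()] for conventions).
#' @param n Number of subjects (>= 1).
#' @param censor_rate Rate (per year) of the exponential random-censoring
#'   process; 0 disables random censoring.
#' @param admin_censor_time Administrative cutoff in years (> 0, may be `Inf`).
#' @param seed Integer seed; identical specs give identical samples.
#' @return An object of class `simulation_spec`.
#' @examples
#' spec <- simulation_spec("lognormal", list(meanlog = 1.11, sdlog = 1.44),
#'                         n = 100, seed = 1)
#' simulate_ipd(spec)
#' @export
simulation_spec <- function(family, params, n, censor_rate = 0,
                            admin_censor_time = Inf, seed = 1L) {
  family <- match.arg(family, survival_families())
  params <- check_family_params(family, params)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be at least 1", call. = FALSE)
  if (!is.finite(censor_rate) || censor_rate < 0) {
    stop("'censor_rate' must be a finite rate >= 0", call. = FALSE)
  }
  if (is.na(admin_censor_time) || admin_censor_time <= 0) {
    stop("'admin_censor_time' must be > 0", call. = FALSE)
  }
  structure(list(family = family, params = params, n = n,
                 censor_rate = censor_rate,
                 admin_censor_time = admin_censor_time,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# evaluate fun() under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, fun) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  fun()
}

#' Simulate right-censored individual patient data
#'
#' Draws `n` event times from the spec's family, censors each by the minimum
#' of an exponential censoring draw and the administrative cutoff, and
#' returns the observed `(time, event)` records. The event flag is true iff
#' the event draw is the smallest of the three.
#'
#' @param spec A [simulation_spec()].
#' @return An [ipd()] with `n` records.
#' @export
simulate_ipd <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, function() {
    t_event <- family_random(spec$family, spec$params, spec$n)
    t_cens <- if (spec$censor_rate > 0) {
      stats::rexp(spec$n, rate = spec$censor_rate)
    } else {
      rep(Inf, spec$n)
    }
    t_obs <- pmin(t_event, t_cens, spec$admin_censor_time)
    ipd(t_obs, t_event <= pmin(t_cens, spec$admin_censor_time))
  })
}

#' Digitized survival-curve coordinates
#'
#' An ordered set of `(time, survival)` coordinates as read off a published
#' Kaplan-Meier plot. Times must be strictly increasing and survival
#' non-increasing in `[0, 1]`.
#'
#' @param time Non-negative, strictly increasing times (years).
#' @param survival Survival probabilities, non-increasing, first value <= 1.
#' @return A data frame of class `digitized_curve`.
#' @export
digitized_curve <- function(time, survival) {
  time <- as.numeric(time); survival <- as.numeric(survival)
  if (length(time) < 1L) stop("a digitized curve needs at least one point", call. = FALSE)
  if (length(time) != length(survival)) stop("'time' and 'survival' lengths differ", call. = FALSE)
  if (any(time < 0) || any(diff(time) <= 0)) {
    stop("curve times must be >= 0 and strictly increasing", call. = FALSE)
  }
  if (any(survival < 0) || any(survival > 1) || survival[1] > 1) {
    stop("survival values must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(survival) > 1e-12)) {
    stop("survival must be non-increasing in time", call. = FALSE)
  }
  structure(data.frame(time = time, survival = survival),
            class = c("digitized_curve", "data.frame"))
}

#' Numbers-at-risk table
#'
#' The auxiliary input reconstruction needs: subject counts still at risk at
#' a set of (strictly increasing) times, optionally with the total event
#' count over the whole curve.
#'
#' @param time Non-negative, strictly increasing times (years).
#' @param n_at_risk Non-increasing, non-negative subject counts.
#' @param total_events Optional total number of events (integer).
#' @return A data frame of class `risk_table` with attribute `total_events`.
#' @export
risk_table <- function(time, n_at_risk, total_events = NULL) {
  time <- as.numeric(time); n_at_risk <- as.numeric(n_at_risk)
  if (length(time) != length(n_at_risk) || length(time) < 1L) {
    stop("'time' and 'n_at_risk' must be non-empty and of equal length", call. = FALSE)
  }
  if (any(time < 0) || any(diff(time) <= 0)) {
    stop("risk-table times must be >= 0 and strictly increasing", call. = FALSE)
  }
  if (any(n_at_risk < 0) || any(diff(n_at_risk) > 0)) {
    stop("'n_at_risk' must be non-negative and non-increasing", call. = FALSE)
  }
  out <- structure(data.frame(time = time, n_at_risk = n_at_risk),
                   class = c("risk_table", "data.frame"))
  attr(out, "total_events") <- if (is.null(total_events)) NULL else as.integer(total_events)
  out
}

#' Emulate digitization of a Kaplan-Meier plot
#'
#' Evaluates the Kaplan-Meier estimate of `x` on a fixed time grid and
#' builds the matching numbers-at-risk table, emulating what manual
#' digitization of a published figure produces. The risk table carries the
#' true total event count of `x`.
#'
#' @param x An [ipd()] object.
#' @param grid Strictly increasing evaluation times starting at >= 0.
#' @param risk_times Times at which numbers at risk are tabulated.
#' @return A list with elements `curve` ([digitized_curve()]) and
#'   `risk` ([risk_table()]).
#' @export
make_digitized_curve <- function(x, grid, risk_times) {
  stopifnot(inherits(x, "ipd"))
  if (length(grid) < 1L) stop("'grid' must contain at least one time", call. = FALSE)
  if (any(grid < 0) || any(diff(grid) <= 0)) {
    stop("'grid' must be strictly increasing, starting at >= 0", call. = FALSE)
  }
  km <- kaplan_meier(x)
  surv <- km_survival_at(km, grid)
  n_at_risk <- vapply(risk_times, function(rt) sum(x$time >= rt), numeric(1))
  list(curve = digitized_curve(grid, surv),
       risk = risk_table(risk_times, n_at_risk, total_events = sum(x$event)))
}

#' Write curve / risk-table CSVs
#'
#' Serializes to the two-column CSV dialects used throughout the package:
#' `(time, survival)` for curves and `(time, n_at_risk)` for risk tables.
#'
#' @param x A [digitized_curve()] or [risk_table()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- utils::read.csv(path)
  if (all(c("time", "survival") %in% names(df))) {
    digitized_curve(df$time, df$survival)
  } else if (all(c("time", "n_at_risk") %in% names(df))) {
    risk_table(df$time, df$n_at_risk)
  } else {
    stop("CSV is neither a curve (time,survival) nor a risk table (time,n_at_risk)",
         call. = FALSE)
  }
}
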