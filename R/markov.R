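im_states <- c("NED", "PD_CNSneg", "PD_CNSpos", "Death")

# Competing-risk allocation within one cycle: marginal per-cycle event
# probabilities are converted to hazards, summed, and the joint exit
# probability is shared out in proportion to the cause-specific hazards.
# `probs` is a list of equal-length numeric vectors (one per cause).
competing_allocation <- function(probs) {
  probs <- lapply(probs, function(p) pmin(pmax(p, 0), 1 - 1e-15))
  hz <- lapply(probs, function(p) -log1p(-p))
  H <- Reduce(`+`, hz)
  p_exit <- -expm1(-H)
  share <- lapply(hz, function(h) ifelse(H > 0, h / H, 0))
  lapply(share, function(s) s * p_exit)
}

per_cycle_background <- function(annual, delta) 1 - (1 - annual)^delta

#' Per-cycle transition matrix of the four-state model
#'
#' Builds the row-stochastic matrix over `NED`, `PD_CNSneg`, `PD_CNSpos`,
#' `Death` for one cycle. The NED row combines, as competing risks within
#' the cycle, the CNS-positive and CNS-negative disease-free survival event
#' probabilities (each split between its PD state and Death by the
#' recurrence fraction) plus background mortality. The PD rows apply the
#' post-progression mortality at `time_in_pd` — with the arm's
#' overall-survival hazard ratio — plus background mortality. Death is
#' absorbing.
#'
#' Because post-progression mortality depends on time since progression,
#' the matrix is parameterized by `time_in_pd`; the cohort engine expands
#' PD into time-in-state tunnels and applies the same probabilities
#' stage by stage.
#'
#' @param arm An [arm_spec()].
#' @param cycle_index Zero-based cycle index (model time `cycle_index *
#'   delta` at cycle start).
#' @param delta Cycle length in years.
#' @param time_in_pd Time since progression (years) used for the PD rows.
#' @return A 4x4 row-stochastic matrix.
#' @export
build_transition_matrix <- function(arm, cycle_index, delta, time_in_pd = 0) {
  stopifnot(inherits(arm, "arm_spec"), cycle_index >= 0, delta > 0)
  t0 <- cycle_index * delta
  p_bg <- per_cycle_background(arm$background_mortality_annual, delta)
  alloc <- competing_allocation(list(
    pos = cycle_transition_prob(arm$dfs_cns_pos, t0, delta),
    neg = cycle_transition_prob(arm$dfs_cns_neg, t0, delta),
    bg = p_bg))
  p_pd_death <- competing_allocation(list(
    pd = cycle_transition_prob(arm$pd_death_fit, time_in_pd, delta,
                               hazard_ratio = arm$os_hazard_ratio),
    bg = p_bg))
  pd_die <- p_pd_death$pd + p_pd_death$bg

  m <- matrix(0, 4, 4, dimnames = list(im_states, im_states))
  f_pos <- arm$recurrence_fraction_cns_pos
  f_neg <- arm$recurrence_fraction_cns_neg
  m["NED", "PD_CNSpos"] <- alloc$pos * f_pos
  m["NED", "PD_CNSneg"] <- alloc$neg * f_neg
  m["NED", "Death"] <- alloc$pos * (1 - f_pos) + alloc$neg * (1 - f_neg) + alloc$bg
  m["NED", "NED"] <- 1 - sum(m["NED", -1])
  m["PD_CNSneg", "Death"] <- pd_die
  m["PD_CNSneg", "PD_CNSneg"] <- 1 - pd_die
  m["PD_CNSpos", "Death"] <- pd_die
  m["PD_CNSpos", "PD_CNSpos"] <- 1 - pd_die
  m["Death", "Death"] <- 1
  if (any(m < -1e-12) || any(m > 1 + 1e-12)) {
    bad <- which(m < -1e-12 | m > 1 + 1e-12, arr.ind = TRUE)[1, ]
    stop(sprintf("transition probability outside [0,1] in cell [%s, %s]",
                 im_states[bad[1]], im_states[bad[2]]), call. = FALSE)
  }
  m
}

# One stratum (or the whole competing-risk cohort): a set of NED-exit
# processes feeding the PD tunnels. `processes` is a list with elements
# fit, fraction (recurrence fraction) and dest ("pos"/"neg").
run_stratum <- function(processes, arm, inputs, init = 1,
                        half_cycle_correction = TRUE) {
  delta <- inputs$cycle_length
  N <- inputs$n_cycles
  t_start <- (seq_len(N) - 1) * delta
  p_bg <- per_cycle_background(arm$background_mortality_annual, delta)

  probs <- lapply(processes, function(pr) cycle_transition_prob(pr$fit, t_start, delta))
  probs$bg <- rep(p_bg, N)
  alloc <- competing_allocation(probs)

  # tunnel-stage death probabilities: stage k covers time-in-state
  # (k-1)*delta .. k*delta
  u <- (seq_len(N) - 1) * delta
  pd_alloc <- competing_allocation(list(
    pd = cycle_transition_prob(arm$pd_death_fit, u, delta,
                               hazard_ratio = arm$os_hazard_ratio),
    bg = rep(p_bg, N)))
  pd_die <- pd_alloc$pd + pd_alloc$bg
  drug_stage <- u < inputs$pd_drug_years   # stages still inside the PD drug window

  ned <- init; pd_neg <- numeric(N); pd_pos <- numeric(N); death <- 0
  cols <- c("occ_ned", "occ_pd_neg", "occ_pd_pos", "occ_death",
            "avg_ned", "avg_pd_neg", "avg_pd_pos", "avg_pd_drug",
            "entrants_pd_neg", "entrants_pd_pos", "entrants_death")
  tr <- matrix(0, N, length(cols), dimnames = list(NULL, cols))

  for (t in seq_len(N)) {
    occ <- c(ned, sum(pd_neg), sum(pd_pos), death)
    if (abs(sum(occ) - init) > 1e-9) {
      stop("state occupancy not conserved at cycle ", t - 1, call. = FALSE)
    }
    # NED exits
    new_pos <- 0; new_neg <- 0; ned_death <- ned * alloc$bg[t]
    for (i in seq_along(processes)) {
      e <- ned * alloc[[i]][t]
      f <- processes[[i]]$fraction
      if (processes[[i]]$dest == "pos") new_pos <- new_pos + e * f
      else new_neg <- new_neg + e * f
      ned_death <- ned_death + e * (1 - f)
    }
    ned2 <- ned - new_pos - new_neg - ned_death
    # PD tunnels advance one stage, losing deaths
    pd_deaths <- sum(pd_neg * pd_die) + sum(pd_pos * pd_die)
    pd_neg2 <- c(new_neg, (pd_neg * (1 - pd_die))[-N])
    pd_pos2 <- c(new_pos, (pd_pos * (1 - pd_die))[-N])
    death2 <- death + ned_death + pd_deaths

    w <- if (half_cycle_correction) 0.5 else 1
    tr[t, ] <- c(occ,
                 w * ned + (1 - w) * ned2,
                 w * sum(pd_neg) + (1 - w) * sum(pd_neg2),
                 w * sum(pd_pos) + (1 - w) * sum(pd_pos2),
                 w * sum((pd_neg + pd_pos)[drug_stage]) +
                   (1 - w) * sum((pd_neg2 + pd_pos2)[drug_stage]),
                 new_neg, new_pos, ned_death + pd_deaths)
    ned <- ned2; pd_neg <- pd_neg2; pd_pos <- pd_pos2; death <- death2
  }
  list(trace = tr,
       final = c(NED = ned, PD_CNSneg = sum(pd_neg), PD_CNSpos = sum(pd_pos),
                 Death = death))
}

#' Run the cohort model for one arm
#'
#' Propagates a cohort (100% NED at time zero) through the four-state model
#' for `horizon / cycle_length` cycles. Post-progression mortality and the
#' two-year re-treatment window depend on time since progression, tracked
#' internally by expanding the PD states into cycle-indexed tunnel
#' sub-states; the returned trace aggregates them back to the four reported
#' states.
#'
#' Two NED-exit structures are supported:
#' * `"stratified"` (base case): the cohort is split at baseline into a
#'   CNS-positive-destined stratum (weight = share of the arm's DFS events
#'   that were CNS-positive) and a CNS-negative stratum, each leaving NED
#'   according to its own fitted DFS distribution.
#' * `"competing"`: both DFS event processes contend within each cycle as
#'   competing risks for the whole cohort.
#'
#' @param arm An [arm_spec()].
#' @param inputs A [model_inputs()] object.
#' @param structure NED-exit structure; defaults to `inputs$structure`.
#' @param half_cycle_correction Average start- and end-of-cycle occupancy
#'   for accruals (default `TRUE`); one-time transition-triggered costs are
#'   never half-cycle corrected.
#' @return A data frame of class `cohort_trace`: one row per cycle with
#'   start-of-cycle state occupancy (`occ_*`), accrual-weighted occupancy
#'   (`avg_*`, incl. `avg_pd_drug`, the PD occupancy still inside the
#'   re-treatment window), and per-cycle entrant masses (`entrants_*`).
#'   Attributes carry the arm, cycle length and final occupancy.
#' @export
run_cohort <- function(arm, inputs, structure = inputs$structure,
                       half_cycle_correction = TRUE) {
  stopifnot(inherits(arm, "arm_spec"), inherits(inputs, "model_inputs"))
  structure_ <- match.arg(structure, c("stratified", "competing"))
  if (structure_ == "competing") {
    res <- run_stratum(list(
      list(fit = arm$dfs_cns_pos, fraction = arm$recurrence_fraction_cns_pos, dest = "pos"),
      list(fit = arm$dfs_cns_neg, fraction = arm$recurrence_fraction_cns_neg, dest = "neg")),
      arm, inputs, init = 1, half_cycle_correction = half_cycle_correction)
    tr <- res$trace; final <- res$final
  } else {
    w <- arm$cns_pos_weight
    res_pos <- run_stratum(list(
      list(fit = arm$dfs_cns_pos, fraction = arm$recurrence_fraction_cns_pos, dest = "pos")),
      arm, inputs, init = 1, half_cycle_correction = half_cycle_correction)
    res_neg <- run_stratum(list(
      list(fit = arm$dfs_cns_neg, fraction = arm$recurrence_fraction_cns_neg, dest = "neg")),
      arm, inputs, init = 1, half_cycle_correction = half_cycle_correction)
    tr <- w * res_pos$trace + (1 - w) * res_neg$trace
    final <- w * res_pos$final + (1 - w) * res_neg$final
  }
  out <- as.data.frame(tr)
  out <- cbind(cycle = seq_len(nrow(out)) - 1L,
               time = (seq_len(nrow(out)) - 1L) * inputs$cycle_length, out)
  class(out) <- c("cohort_trace", "data.frame")
  attr(out, "arm") <- arm$arm
  attr(out, "delta") <- inputs$cycle_length
  attr(out, "structure") <- structure_
  attr(out, "final_occupancy") <- final
  out
}

# mid-cycle discount factors for a trace
mid_cycle_discount <- function(trace, rate) {
  delta <- attr(trace, "delta")
  (1 + rate)^(-(trace$time + delta / 2))
}

ae_one_time <- function(inputs, stage, what = c("cost", "disutility")) {
  what <- match.arg(what)
  ae <- inputs$adverse_events
  rows <- ae[ae$stage == stage, , drop = FALSE]
  sum(rows$probability * abs(rows[[what]]))
}

#' Accumulate discounted costs over a cohort trace
#'
#' Applies the cost schedule to a [run_cohort()] trace: tiered NED health
#' care and (osimertinib arm, first 3 model years) adjuvant drug cost on
#' NED occupancy; progression work-up, EGFR testing (placebo arm), CNS+
#' lump-sum and adverse-event costs on PD entrants; PD health care, MRI
#' surveillance (CNS+) and re-treatment drug cost (while inside the 2-year
#' window) on PD occupancy; end-of-life cost on every Death entrant. The
#' osimertinib arm's EGFR test and treatment-initiation adverse-event costs
#' fall at model start. Occupancy accruals use the trace's half-cycle
#' weighting; every cycle is discounted at the cost rate to its midpoint.
#' End-of-life costs are booked in the post-progression bucket regardless
#' of the state death occurred from.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param inputs A [model_inputs()] object (same cycle length as the trace).
#' @param arm The [arm_spec()] the trace was run with.
#' @return A list of class `cost_summary` with `pre_pd`, `post_pd`,
#'   `total` (discounted dollars) and the per-cycle discounted streams.
#' @export
accumulate_costs <- function(trace, inputs, arm) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(inputs, "model_inputs"))
  if (abs(attr(trace, "delta") - inputs$cycle_length) > 1e-12) {
    stop("trace and inputs disagree on cycle length", call. = FALSE)
  }
  delta <- inputs$cycle_length
  osi <- arm$arm == "osimertinib"
  cs <- inputs$costs
  drug <- cs$osimertinib_annual * (1 - inputs$drug_discount_fraction)
  drug_pd <- cs$osimertinib_pd_annual * (1 - inputs$drug_discount_fraction)
  df <- mid_cycle_discount(trace, inputs$discount_rate_costs)

  ned_tier <- ifelse(trace$time < 3, cs$ned_annual_yr1_3,
                     ifelse(trace$time < 5, cs$ned_annual_yr4_5, cs$ned_annual_after5))
  pre <- trace$avg_ned * ned_tier * delta
  if (osi) {
    on_drug <- trace$time < inputs$adjuvant_drug_years
    pre <- pre + trace$avg_ned * drug * delta * on_drug
  }
  pre <- pre * df

  entrants_pd <- trace$entrants_pd_neg + trace$entrants_pd_pos
  one_off <- entrants_pd * (cs$pd_diagnosis_once + ae_one_time(inputs, "pd", "cost")) +
    trace$entrants_pd_pos * cs$cns_pos_once +
    trace$entrants_death * cs$end_of_life_once
  if (!osi) one_off <- one_off + entrants_pd * cs$egfr_test_once
  post <- one_off +
    (trace$avg_pd_neg + trace$avg_pd_pos) * cs$pd_annual * delta +
    trace$avg_pd_pos * cs$cns_mri_annual * delta +
    trace$avg_pd_drug * drug_pd * delta
  post <- post * df

  start_cost <- if (osi) cs$egfr_test_once + ae_one_time(inputs, "ned", "cost") else 0
  structure(list(
    pre_pd = sum(pre) + start_cost,
    post_pd = sum(post),
    total = sum(pre) + start_cost + sum(post),
    per_cycle = data.frame(cycle = trace$cycle, time = trace$time,
                           disc_cost_pre_pd = pre, disc_cost_post_pd = post)
  ), class = "cost_summary")
}

#' Accumulate discounted quality-adjusted life years over a cohort trace
#'
#' Occupancy-weighted state utilities accrue per cycle (Death contributes
#' zero); probability-weighted adverse-event disutilities are one-time
#' decrements at treatment initiation (osimertinib arm, model start), at
#' progression (both arms, re-treatment exposure) and at CNS-positive
#' progression. Discounted at the QALY rate to each cycle midpoint.
#'
#' @inheritParams accumulate_costs
#' @return A list of class `qaly_summary` with `qalys` and the per-cycle
#'   discounted stream.
#' @export
accumulate_qalys <- function(trace, inputs, arm) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(inputs, "model_inputs"))
  if (abs(attr(trace, "delta") - inputs$cycle_length) > 1e-12) {
    stop("trace and inputs disagree on cycle length", call. = FALSE)
  }
  delta <- inputs$cycle_length
  u <- inputs$utilities
  u_ned <- if (arm$arm == "osimertinib") u$ned_osimertinib else u$ned_placebo
  df <- mid_cycle_discount(trace, inputs$discount_rate_qalys)

  accrual <- (trace$avg_ned * u_ned +
                trace$avg_pd_neg * u$pd_cns_neg +
                trace$avg_pd_pos * u$pd_cns_pos) * delta
  entrants_pd <- trace$entrants_pd_neg + trace$entrants_pd_pos
  decrement <- entrants_pd * ae_one_time(inputs, "pd", "disutility") +
    trace$entrants_pd_pos * ae_one_time(inputs, "cns", "disutility")
  stream <- (accrual - decrement) * df
  start_dec <- if (arm$arm == "osimertinib") ae_one_time(inputs, "ned", "disutility") else 0
  structure(list(
    qalys = sum(stream) - start_dec,
    per_cycle = data.frame(cycle = trace$cycle, time = trace$time,
                           disc_qaly = stream)
  ), class = "qaly_summary")
}
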