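#' Evaluate one arm of the model
#'
#' Runs the cohort trace and accumulates discounted costs and QALYs.
#'
#' @param arm An [arm_spec()].
#' @param inputs A [model_inputs()] object.
#' @inheritParams run_cohort
#' @return A list of class `arm_output`: `arm`, `trace`, `costs`
#'   ([accumulate_costs()]) and `qalys` ([accumulate_qalys()]).
#' @export
evaluate_arm <- function(arm, inputs, structure = inputs$structure,
                         half_cycle_correction = TRUE) {
  trace <- run_cohort(arm, inputs, structure = structure,
                      half_cycle_correction = half_cycle_correction)
  structure(list(arm = arm$arm, trace = trace,
                 costs = accumulate_costs(trace, inputs, arm),
                 qalys = accumulate_qalys(trace, inputs, arm)),
            class = "arm_output")
}

as_cost_qaly <- function(x) {
  if (inherits(x, "arm_output")) {
    list(cost = x$costs$total, qaly = x$qalys$qalys)
  } else if (is.list(x) && all(c("cost", "qaly") %in% names(x))) {
    x
  } else {
    stop("expected an 'arm_output' or a list(cost =, qaly =)", call. = FALSE)
  }
}

#' Incremental cost-effectiveness ratio
#'
#' `ICER = (C_cmp - C_ref) / (E_cmp - E_ref)` with the usual dominance
#' verdicts: *dominant* if the comparator saves money and gains QALYs,
#' *dominated* if it costs more and loses QALYs, otherwise cost-effective
#' iff the ICER does not exceed the willingness-to-pay threshold. A zero
#' QALY difference leaves the ICER undefined and the verdict follows the
#' sign of the cost difference.
#'
#' @param ref,cmp Reference and comparator arm outputs ([evaluate_arm()])
#'   or bare `list(cost =, qaly =)` pairs.
#' @param threshold Willingness to pay per QALY (dollars).
#' @return A list of class `cea_result` with the costs, QALYs, increments,
#'   `icer`, `threshold` and `verdict`.
#' @examples
#' compute_icer(list(cost = 502937, qaly = 4.169),
#'              list(cost = 800697, qaly = 5.108), threshold = 195000)
#' @export
compute_icer <- function(ref, cmp, threshold) {
  r <- as_cost_qaly(ref); c_ <- as_cost_qaly(cmp)
  check_pos(threshold, "threshold")
  delta_cost <- c_$cost - r$cost
  delta_qaly <- c_$qaly - r$qaly
  icer <- if (delta_qaly == 0) NA_real_ else delta_cost / delta_qaly
  verdict <- if (delta_cost < 0 && delta_qaly > 0) {
    "dominant"
  } else if (delta_cost > 0 && delta_qaly < 0) {
    "dominated"
  } else if (delta_qaly == 0) {
    if (delta_cost <= 0) "cost_effective" else "not_cost_effective"
  } else if (delta_qaly > 0) {
    if (icer <= threshold) "cost_effective" else "not_cost_effective"
  } else {
    # saves money and loses QALYs: cost-effective if the savings per QALY
    # forgone exceed the threshold
    if (icer >= threshold) "cost_effective" else "not_cost_effective"
  }
  structure(list(cost_ref = r$cost, cost_cmp = c_$cost,
                 qaly_ref = r$qaly, qaly_cmp = c_$qaly,
                 delta_cost = delta_cost, delta_qaly = delta_qaly,
                 icer = icer, threshold = threshold, verdict = verdict),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> dC $%.2f  dE %.4f QALY  ICER %s  [%s at $%s/QALY]\n",
              x$delta_cost, x$delta_qaly,
              if (is.na(x$icer)) "undefined" else sprintf("$%.2f/QALY", x$icer),
              x$verdict, format(x$threshold, big.mark = ",")))
  invisible(x)
}

#' Run the base case
#'
#' Evaluates both arms under identical inputs (apart from the arm-specific
#' fields) and computes the ICER of osimertinib versus placebo.
#'
#' @param inputs A [model_inputs()] object; defaults to the packaged
#'   base-case configuration.
#' @inheritParams run_cohort
#' @return A list of class `base_case`: `placebo`, `osimertinib`
#'   ([evaluate_arm()] outputs) and `cea` ([compute_icer()]).
#' @export
run_base_case <- function(inputs = default_model_inputs(),
                          structure = inputs$structure,
                          half_cycle_correction = TRUE) {
  pl <- evaluate_arm(arm_spec(inputs, "placebo"), inputs, structure,
                     half_cycle_correction)
  os <- evaluate_arm(arm_spec(inputs, "osimertinib"), inputs, structure,
                     half_cycle_correction)
  structure(list(placebo = pl, osimertinib = os,
                 cea = compute_icer(pl, os, inputs$threshold)),
            class = "base_case")
}

#' @export
print.base_case <- function(x, ...) {
  fmt <- function(a) sprintf("  %-12s pre-PD $%.0f  post-PD $%.0f  total $%.0f  QALYs %.3f\n",
                             a$arm, a$costs$pre_pd, a$costs$post_pd,
                             a$costs$total, a$qalys$qalys)
  cat("<base_case>\n"); cat(fmt(x$placebo)); cat(fmt(x$osimertinib))
  print(x$cea)
  invisible(x)
}

#' Deterministic sweep over the assumed overall-survival benefit
#'
#' Re-runs the model over a grid of post-progression mortality risk
#' reductions for osimertinib (hazard ratio `1 - reduction`) and reports
#' the ICER at each point, plus the grid interval (if any) in which the
#' ICER crosses the willingness-to-pay threshold.
#'
#' @param inputs A [model_inputs()] object.
#' @param reductions Risk-reduction grid in `[0, 0.45]`.
#' @return A data frame `(risk_reduction, hazard_ratio, delta_cost,
#'   delta_qaly, icer)` with attribute `crossing` — `c(lower, upper)` of
#'   the first grid interval bracketing the threshold, or `NULL`.
#' @export
os_benefit_sweep <- function(inputs = default_model_inputs(),
                             reductions = seq(0, 0.45, by = 0.05)) {
  if (any(reductions < 0) || any(reductions > 0.45)) {
    stop("'reductions' must lie within [0, 0.45]", call. = FALSE)
  }
  pl <- evaluate_arm(arm_spec(inputs, "placebo"), inputs)
  rows <- lapply(reductions, function(rr) {
    os <- evaluate_arm(arm_spec(inputs, "osimertinib", os_hazard_ratio = 1 - rr),
                       inputs)
    cea <- compute_icer(pl, os, inputs$threshold)
    data.frame(risk_reduction = rr, hazard_ratio = 1 - rr,
               delta_cost = cea$delta_cost, delta_qaly = cea$delta_qaly,
               icer = cea$icer)
  })
  out <- do.call(rbind, rows)
  crossing <- NULL
  above <- out$icer > inputs$threshold
  idx <- which(above[-nrow(out)] & !above[-1])
  if (length(idx) > 0) {
    crossing <- c(out$risk_reduction[idx[1]], out$risk_reduction[idx[1] + 1])
  } else if (!above[1]) {
    crossing <- c(0, 0)
  }
  attr(out, "crossing") <- crossing
  attr(out, "threshold") <- inputs$threshold
  out
}

#' Deterministic sweep over osimertinib price discounts
#'
#' Applies each price discount to *all* osimertinib cost lines (adjuvant
#' and post-progression re-treatment) and reports the resulting ICER.
#'
#' @param inputs A [model_inputs()] object.
#' @param discounts Price-discount fractions in `[0, 1]`.
#' @return A data frame `(discount, delta_cost, delta_qaly, icer)`.
#' @export
drug_discount_sweep <- function(inputs = default_model_inputs(),
                                discounts = c(0.10, 0.25, 0.50)) {
  if (any(discounts < 0) || any(discounts > 1)) {
    stop("'discounts' must lie within [0, 1]", call. = FALSE)
  }
  rows <- lapply(discounts, function(d) {
    inp <- inputs
    inp$drug_discount_fraction <- d
    bc <- run_base_case(inp)
    data.frame(discount = d, delta_cost = bc$cea$delta_cost,
               delta_qaly = bc$cea$delta_qaly, icer = bc$cea$icer)
  })
  do.call(rbind, rows)
}
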