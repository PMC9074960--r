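# rebuild the raw configuration list from a validated model_inputs object,
# so the PSA can perturb it and re-validate each draw
as_config <- function(inputs) {
  stopifnot(inherits(inputs, "model_inputs"))
  fit_cfg <- function(f) c(list(family = f$family), as.list(f$params))
  ae <- inputs$adverse_events
  list(
    horizon_years = inputs$horizon_years,
    cycles_per_year = inputs$cycles_per_year,
    discount_rate_costs = inputs$discount_rate_costs,
    discount_rate_qalys = inputs$discount_rate_qalys,
    threshold = inputs$threshold,
    os_hazard_ratio = inputs$os_hazard_ratio,
    background_mortality_annual = inputs$background_mortality_annual,
    drug_discount_fraction = inputs$drug_discount_fraction,
    adjuvant_drug_years = inputs$adjuvant_drug_years,
    pd_drug_years = inputs$pd_drug_years,
    structure = inputs$structure,
    costs = inputs$costs,
    utilities = inputs$utilities,
    dfs_fits = lapply(inputs$dfs_fits, fit_cfg),
    pd_death_fit = fit_cfg(inputs$pd_death_fit),
    event_splits = inputs$event_splits,
    adverse_events = lapply(seq_len(nrow(ae)), function(i) as.list(ae[i, ]))
  )
}

# moment-matched Beta draw; degenerate at the boundary or when sd is 0
rbeta_mm <- function(mean, sd) {
  if (sd <= 0 || mean <= 0 || mean >= 1) return(mean)
  v_max <- mean * (1 - mean)
  v <- min(sd^2, 0.9 * v_max)
  nu <- v_max / v - 1
  stats::rbeta(1, mean * nu, (1 - mean) * nu)
}

# moment-matched Gamma draw; degenerate at 0
rgamma_mm <- function(mean, sd) {
  if (sd <= 0 || mean <= 0) return(mean)
  shape <- (mean / sd)^2
  stats::rgamma(1, shape = shape, rate = shape / mean)
}

# multiplicative log-normal jitter with relative sd
rlnorm_rel <- function(mean, rel) {
  if (rel <= 0 || mean == 0) return(mean)
  mean * exp(stats::rnorm(1, 0, rel))
}

draw_config <- function(base, rel, sd_scale) {
  cfg <- base
  rp <- rel$probability * sd_scale
  rc <- rel$cost * sd_scale
  rl <- rel$location * sd_scale
  rs <- rel$positive * sd_scale

  cfg$utilities <- lapply(base$utilities, function(u) rbeta_mm(u, rp * u))
  cfg$costs <- lapply(base$costs, function(cst) rgamma_mm(cst, rc * cst))
  cfg$background_mortality_annual <-
    rbeta_mm(base$background_mortality_annual, rp * base$background_mortality_annual)
  cfg$os_hazard_ratio <- rlnorm_rel(base$os_hazard_ratio, rs)

  jitter_fit <- function(f) {
    for (p in names(f)[-1]) {
      f[[p]] <- if (p %in% c("meanlog", "mu")) {
        stats::rnorm(1, f[[p]], rl * abs(f[[p]]))
      } else {
        rlnorm_rel(f[[p]], rs)
      }
    }
    f
  }
  cfg$dfs_fits <- lapply(base$dfs_fits, jitter_fit)
  cfg$pd_death_fit <- jitter_fit(base$pd_death_fit)

  cfg$adverse_events <- lapply(base$adverse_events, function(row) {
    row$probability <- rbeta_mm(row$probability, rp * row$probability)
    row$cost <- rgamma_mm(row$cost, rc * row$cost)
    row
  })

  # recurrence fractions and CNS-stratum weights, re-expressed as
  # real-valued splits so derived quantities stay internally consistent
  for (arm in c("placebo", "osimertinib")) {
    kp <- paste0(arm, "_cns_pos"); kn <- paste0(arm, "_cns_neg")
    ep <- base$event_splits[[kp]]$events; en <- base$event_splits[[kn]]$events
    w <- rbeta_mm(ep / (ep + en), rp * ep / (ep + en))
    fp <- base$event_splits[[kp]]$recurrences / ep
    fn <- base$event_splits[[kn]]$recurrences / en
    fp <- rbeta_mm(fp, rp * fp); fn <- rbeta_mm(fn, rp * fn)
    cfg$event_splits[[kp]] <- list(recurrences = fp * w, events = w)
    cfg$event_splits[[kn]] <- list(recurrences = fn * (1 - w), events = 1 - w)
  }
  cfg
}

#' Probabilistic sensitivity analysis
#'
#' Re-runs the whole model `n` times with every input resampled from its
#' assigned distribution: Beta for probabilities and utilities
#' (moment-matched, default 20% relative standard error), Gamma for costs
#' (20%), Normal for log-time location parameters and log-Normal for
#' positive survival parameters and the overall-survival hazard ratio
#' (10%). Draws whose inputs fall outside a valid domain are rejected and
#' resampled, with a count kept. Reproducible under a fixed seed.
#'
#' @param inputs A [model_inputs()] object (the distribution means).
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param rel_se Relative standard errors by parameter class:
#'   `probability`, `cost`, `location`, `positive`.
#' @param sd_scale Global multiplier on all relative standard errors
#'   (useful for tight-distribution checks; 0 makes every draw the base
#'   case).
#' @return A list of class `psa_result`: `draws` (data frame with
#'   `delta_cost`, `delta_qaly`, `icer` per draw), `n`, `seed`,
#'   `n_rejected`, `base` (the deterministic [compute_icer()] at the
#'   distribution means) and `distribution_spec`.
#' @export
run_psa <- function(inputs = default_model_inputs(), n = 1000, seed = 1L,
                    rel_se = list(probability = 0.20, cost = 0.20,
                                  location = 0.10, positive = 0.10),
                    sd_scale = 1) {
  stopifnot(inherits(inputs, "model_inputs"), n >= 1)
  base_cfg <- as_config(inputs)
  base <- run_base_case(inputs)
  n_rejected <- 0L
  draws <- with_seed(seed, function() {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      for (attempt in 1:100) {
        cfg <- draw_config(base_cfg, rel_se, sd_scale)
        inp <- tryCatch(model_inputs(cfg), error = function(e) NULL)
        if (!is.null(inp)) break
        n_rejected <<- n_rejected + 1L
      }
      if (is.null(inp)) stop("could not draw valid PSA inputs after 100 attempts",
                             call. = FALSE)
      bc <- run_base_case(inp)
      out[[i]] <- data.frame(draw = i, delta_cost = bc$cea$delta_cost,
                             delta_qaly = bc$cea$delta_qaly, icer = bc$cea$icer)
    }
    do.call(rbind, out)
  })
  structure(list(draws = draws, n = n, seed = as.integer(seed),
                 n_rejected = n_rejected, base = base$cea,
                 distribution_spec = c(rel_se, sd_scale = sd_scale)),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  pos <- x$draws$delta_qaly > 0
  cat(sprintf("<psa_result> %d draws (seed %d, %d rejected)\n",
              x$n, x$seed, x$n_rejected))
  cat(sprintf("  mean dC $%.0f  mean dE %.4f  ICER of means $%.0f/QALY\n",
              mean(x$draws$delta_cost), mean(x$draws$delta_qaly),
              mean(x$draws$delta_cost) / mean(x$draws$delta_qaly)))
  cat(sprintf("  draws with dE <= 0 (excluded from summary ICERs): %d\n", sum(!pos)))
  invisible(x)
}
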