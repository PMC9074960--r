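test_that("transition matrices are row-stochastic with the prescribed structure", {
  inputs <- default_model_inputs()
  arm <- arm_spec(inputs, "placebo")
  for (cyc in c(0, 6, 60)) {
    m <- build_transition_matrix(arm, cyc, 1 / 12, time_in_pd = 0.5)
    expect_equal(unname(rowSums(m)), rep(1, 4))
    expect_true(all(m >= 0))
    expect_equal(unname(m["Death", ]), c(0, 0, 0, 1))  # absorbing
    expect_equal(m["PD_CNSneg", "Death"], m["PD_CNSpos", "Death"])
  }
})

test_that("degenerate hazards give the identity matrix; equal arms give equal PD rows", {
  inert <- model_inputs(inert_config())
  arm <- arm_spec(inert, "placebo")
  m <- build_transition_matrix(arm, 0, 1 / 12)
  expect_equal(unname(m), diag(4), tolerance = 1e-10)

  inputs <- default_model_inputs()
  pl <- arm_spec(inputs, "placebo")
  os_null <- arm_spec(inputs, "osimertinib", os_hazard_ratio = 1)
  m_pl <- build_transition_matrix(pl, 3, 1 / 12, time_in_pd = 1)
  m_os <- build_transition_matrix(os_null, 3, 1 / 12, time_in_pd = 1)
  expect_equal(m_os["PD_CNSneg", ], m_pl["PD_CNSneg", ])
})

test_that("the placebo NED row at cycle 0 matches a brute-force competing-risk oracle", {
  inputs <- default_model_inputs()
  arm <- arm_spec(inputs, "placebo")
  d <- 1 / 12
  # brute force from the log-normal CDFs and the hazard-additive split
  p_pos <- 1 - (1 - plnorm(d, 1.94, 1.22)) / 1
  p_neg <- 1 - (1 - plnorm(d, 1.11, 1.44)) / 1
  p_bg <- 1 - (1 - 0.012)^d
  h <- -log(1 - c(p_pos, p_neg, p_bg))
  p_exit <- 1 - exp(-sum(h))
  e <- p_exit * h / sum(h)
  m <- build_transition_matrix(arm, 0, d)
  expect_equal(m["NED", "PD_CNSpos"], e[1] * 33 / 39, tolerance = 1e-12)
  expect_equal(m["NED", "PD_CNSneg"], e[2] * 118 / 120, tolerance = 1e-12)
  expect_equal(m["NED", "Death"],
               e[1] * 6 / 39 + e[2] * 2 / 120 + e[3], tolerance = 1e-12)
})

test_that("a time-homogeneous cohort equals hand-multiplied matrix powers", {
  cfg <- base_config()
  ex <- function(rate) list(family = "exponential", rate = rate)
  cfg$dfs_fits <- list(placebo_cns_pos = ex(0.05), placebo_cns_neg = ex(0.2),
                       osimertinib_cns_pos = ex(0.05), osimertinib_cns_neg = ex(0.2))
  cfg$pd_death_fit <- ex(0.4)
  cfg$structure <- "competing"
  inputs <- model_inputs(cfg)
  arm <- arm_spec(inputs, "placebo")
  tr <- run_cohort(arm, inputs)
  P <- build_transition_matrix(arm, 0, inputs$cycle_length)
  v <- c(1, 0, 0, 0)
  for (k in c(1, 2, 24)) {
    vk <- v
    for (i in seq_len(k)) vk <- vk %*% P
    expect_equal(unname(as.numeric(tr[tr$cycle == k,
                                      c("occ_ned", "occ_pd_neg", "occ_pd_pos", "occ_death")])),
                 as.numeric(vk), tolerance = 1e-12)
  }
})

test_that("occupancy is conserved and death is monotone in both structures", {
  inputs <- default_model_inputs()
  for (structure in c("stratified", "competing")) {
    for (arm_name in c("placebo", "osimertinib")) {
      tr <- run_cohort(arm_spec(inputs, arm_name), inputs, structure = structure)
      s <- rowSums(tr[, c("occ_ned", "occ_pd_neg", "occ_pd_pos", "occ_death")])
      expect_lt(max(abs(s - 1)), 1e-10)
      expect_true(all(diff(tr$occ_death) >= -1e-15))
    }
  }
})

test_that("zero hazards freeze the cohort in NED", {
  inert <- model_inputs(inert_config())
  tr <- run_cohort(arm_spec(inert, "placebo"), inert)
  expect_equal(tr$occ_ned, rep(1, nrow(tr)), tolerance = 1e-9)
  expect_equal(max(tr$occ_death), 0, tolerance = 1e-9)
})

test_that("greater assumed survival benefit weakly increases osimertinib QALYs", {
  inputs <- default_model_inputs()
  q <- vapply(c(1, 0.95, 0.7), function(hr) {
    evaluate_arm(arm_spec(inputs, "osimertinib", os_hazard_ratio = hr), inputs)$qalys$qalys
  }, numeric(1))
  expect_true(all(diff(q) > 0))
})

test_that("base-case placebo deaths at the horizon exceed osimertinib deaths", {
  inputs <- default_model_inputs()
  fin_pl <- attr(run_cohort(arm_spec(inputs, "placebo"), inputs), "final_occupancy")
  fin_os <- attr(run_cohort(arm_spec(inputs, "osimertinib"), inputs), "final_occupancy")
  expect_gt(fin_pl[["Death"]], fin_os[["Death"]])
})

test_that("a patient who never progresses accrues only the tiered NED annuity", {
  inert <- model_inputs(inert_config())
  arm <- arm_spec(inert, "placebo")
  out <- evaluate_arm(arm, inert)
  d <- inert$cycle_length
  t0 <- (seq_len(inert$n_cycles) - 1) * d
  tier <- ifelse(t0 < 3, 1078.76, ifelse(t0 < 5, 539.38, 296.69))
  annuity <- sum(tier * d * 1.03^-(t0 + d / 2))
  expect_equal(out$costs$pre_pd, annuity, tolerance = 1e-8)
  expect_lt(out$costs$post_pd, 1e-3)
})

test_that("one undiscounted NED year yields the NED utility in QALYs", {
  cfg <- inert_config()
  cfg$horizon_years <- 1
  cfg$discount_rate_costs <- 0
  cfg$discount_rate_qalys <- 0
  inputs <- model_inputs(cfg)
  out <- evaluate_arm(arm_spec(inputs, "placebo"), inputs)
  expect_equal(out$qalys$qalys, 0.83, tolerance = 1e-9)
})

test_that("everyone dead from the outset accrues zero QALYs", {
  cfg <- base_config()
  # an overwhelming early event hazard with all events fatal
  cfg$dfs_fits <- lapply(cfg$dfs_fits, function(...) list(family = "exponential", rate = 1e4))
  for (k in names(cfg$event_splits)) cfg$event_splits[[k]]$recurrences <- 0
  inputs <- model_inputs(cfg)
  out <- evaluate_arm(arm_spec(inputs, "placebo"), inputs)
  # at most the half-cycle of the instantaneous emptying of NED accrues
  expect_lt(out$qalys$qalys, 0.83 / 12)
  expect_equal(out$trace$occ_death[-1], rep(1, inputs$n_cycles - 1), tolerance = 1e-9)
})

test_that("identical arm specifications are null-equivalent end to end", {
  cfg <- base_config()
  cfg$dfs_fits$osimertinib_cns_pos <- cfg$dfs_fits$placebo_cns_pos
  cfg$dfs_fits$osimertinib_cns_neg <- cfg$dfs_fits$placebo_cns_neg
  cfg$event_splits$osimertinib_cns_pos <- cfg$event_splits$placebo_cns_pos
  cfg$event_splits$osimertinib_cns_neg <- cfg$event_splits$placebo_cns_neg
  cfg$os_hazard_ratio <- 1
  cfg$utilities$ned_osimertinib <- cfg$utilities$ned_placebo
  # neutralize arm-asymmetric cost/disutility lines
  cfg$costs$osimertinib_annual <- 0
  cfg$costs$osimertinib_pd_annual <- 0
  cfg$costs$egfr_test_once <- 0
  cfg$adverse_events <- lapply(cfg$adverse_events,
                               function(r) { r$probability <- 0; r })
  inputs <- model_inputs(cfg)
  pl <- evaluate_arm(arm_spec(inputs, "placebo"), inputs)
  os <- evaluate_arm(arm_spec(inputs, "osimertinib"), inputs)
  expect_equal(as.data.frame(pl$trace), as.data.frame(os$trace),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(pl$costs$total, os$costs$total, tolerance = 1e-12)
  expect_equal(pl$qalys$qalys, os$qalys$qalys, tolerance = 1e-12)
})

test_that("removing discounting strictly increases both totals", {
  cfg <- base_config()
  cfg$discount_rate_costs <- 0
  cfg$discount_rate_qalys <- 0
  undisc <- run_base_case(model_inputs(cfg))
  base <- run_base_case(default_model_inputs())
  for (arm in c("placebo", "osimertinib")) {
    expect_gt(undisc[[arm]]$costs$total, base[[arm]]$costs$total)
    expect_gt(undisc[[arm]]$qalys$qalys, base[[arm]]$qalys$qalys)
  }
})

test_that("halving the cycle length moves totals by less than one percent", {
  cfg <- base_config()
  cfg$cycles_per_year <- 24
  fine <- run_base_case(model_inputs(cfg))
  base <- run_base_case(default_model_inputs())
  for (arm in c("placebo", "osimertinib")) {
    expect_lt(abs(fine[[arm]]$costs$total / base[[arm]]$costs$total - 1), 0.01)
    expect_lt(abs(fine[[arm]]$qalys$qalys / base[[arm]]$qalys$qalys - 1), 0.01)
  }
})
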