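test_that("exponential MLE equals events over total time", {
  fit <- fit_parametric(ipd(c(1, 1, 1, 1), c(1, 1, 1, 1)), "exponential")
  expect_equal(unname(fit$params["rate"]), 1, tolerance = 1e-4)
  expect_error(fit_parametric(ipd(c(1, 2), c(1, 0)), "exponential"), "2 events")
})

test_that("lognormal and gamma parameters are recovered from simulated data", {
  x <- simulate_ipd(simulation_spec("lognormal", list(meanlog = 1.11, sdlog = 1.44),
                                    n = 2000, censor_rate = 0.05,
                                    admin_censor_time = 15, seed = 3))
  fl <- fit_parametric(x, "lognormal")
  expect_lt(abs(fl$params["meanlog"] - 1.11), 0.1)
  expect_lt(abs(fl$params["sdlog"] - 1.44), 0.1)

  x <- simulate_ipd(simulation_spec("gamma", list(shape = 1.86, rate = 0.56),
                                    n = 2000, censor_rate = 0.05,
                                    admin_censor_time = 15, seed = 3))
  fg <- fit_parametric(x, "gamma")
  expect_lt(abs(fg$params["shape"] / 1.86 - 1), 0.1)
  expect_lt(abs(fg$params["rate"] / 0.56 - 1), 0.1)
})

test_that("fitted likelihood is never below the likelihood at the truth", {
  # MLE definition check, oracle likelihood computed directly from stats::
  loglik_lnorm <- function(x, mu, sg) {
    sum(stats::dlnorm(x$time[x$event == 1], mu, sg, log = TRUE)) +
      sum(stats::plnorm(x$time[x$event == 0], mu, sg, lower.tail = FALSE, log.p = TRUE))
  }
  for (sd in 1:5) {
    x <- simulate_ipd(simulation_spec("lognormal", list(meanlog = 1.11, sdlog = 1.44),
                                      n = 300, censor_rate = 0.1,
                                      admin_censor_time = 12, seed = sd))
    fit <- fit_parametric(x, "lognormal")
    expect_gte(fit$loglik, loglik_lnorm(x, 1.11, 1.44) - 1e-6)
    # stored criteria match their definitions exactly
    expect_equal(fit$aic, 2 * fit$k - 2 * fit$loglik)
    expect_equal(fit$bic, fit$k * log(fit$n_obs) - 2 * fit$loglik)
  }
})

test_that("model selection ranks by AIC, flags BIC, and reports disagreement", {
  x <- simulate_ipd(simulation_spec("lognormal", list(meanlog = 1.11, sdlog = 1.44),
                                    n = 5000, censor_rate = 0.05,
                                    admin_censor_time = 15, seed = 5))
  fits <- lapply(survival_families(), function(fam) fit_parametric(x, fam))
  sel <- select_model(fits)
  expect_equal(sel$aic, sort(sel$aic))
  # the consistent criterion recovers the generating family
  expect_equal(sel$family[sel$best_bic], "lognormal")
  # AIC's winner is the generating family or the generalized gamma that
  # nests it (in which case the fit must have collapsed onto it)
  expect_true(sel$family[1] %in% c("lognormal", "gengamma"))
  if (sel$family[1] == "gengamma") {
    gg <- attr(sel, "fits")[[1]]
    expect_lt(abs(gg$params[["Q"]]), 0.3)
    expect_lt(sel$aic[sel$family == "lognormal"] - sel$aic[1], 2)
  }

  # single fit selects itself
  single <- select_model(fits[[1]])
  expect_true(single$best_aic && single$best_bic)

  # equal log-likelihood: the smaller model wins both criteria
  f1 <- parametric_fit("exponential", c(rate = 1), loglik = -100, n_obs = 50)
  f2 <- parametric_fit("weibull", c(shape = 1, scale = 1), loglik = -100, n_obs = 50)
  sel2 <- select_model(list(f2, f1))
  expect_equal(sel2$family[1], "exponential")
  expect_equal(sel2$family[sel2$best_bic], "exponential")

  f3 <- parametric_fit("exponential", c(rate = 1), loglik = -90, n_obs = 60)
  expect_error(select_model(list(f1, f3)), "differing size")
})

test_that("the proportional-hazards diagnostic behaves as a test should", {
  # identical groups: hazard ratio 1
  a <- simulate_ipd(simulation_spec("exponential", list(rate = 1), n = 200, seed = 1))
  expect_equal(ph_check(a, a)$hazard_ratio, 1, tolerance = 1e-8)
  # type-I behaviour: proportional hazards held on most null draws
  held <- vapply(1:10, function(sd) {
    g1 <- simulate_ipd(simulation_spec("exponential", list(rate = 1), n = 150, seed = sd))
    g2 <- simulate_ipd(simulation_spec("exponential", list(rate = 1), n = 150, seed = sd + 100))
    ph_check(g1, g2)$verdict == "held"
  }, logical(1))
  expect_gte(sum(held), 8)
  # power: strongly time-varying hazard ratio (crossing curves) is flagged
  g1 <- simulate_ipd(simulation_spec("exponential", list(rate = 1), n = 400, seed = 2))
  g2 <- simulate_ipd(simulation_spec("weibull", list(shape = 3, scale = 1.1), n = 400, seed = 3))
  expect_equal(ph_check(g1, g2)$verdict, "violated")
  expect_error(ph_check(ipd(1, 0), ipd(2, 0)), "no events")
})

test_that("survival evaluation matches medians and an independent quadrature", {
  ln <- parametric_fit("lognormal", c(meanlog = 1.94, sdlog = 1.22))
  expect_equal(survival_at(ln, 0), 1)
  expect_equal(survival_at(ln, exp(1.94)), 0.5)
  expect_error(survival_at(ln, -1), ">= 0")
  gm <- pd_death()
  oracle <- 1 - stats::integrate(function(u) stats::dgamma(u, 1.86, rate = 0.56),
                                 0, 1, rel.tol = 1e-12)$value
  expect_equal(survival_at(gm, 1), oracle, tolerance = 1e-9)
  # non-increasing
  ts <- seq(0, 20, 0.5)
  expect_true(all(diff(survival_at(gm, ts)) <= 0))
})

test_that("per-cycle transition probabilities are conditional and telescope", {
  ex <- parametric_fit("exponential", c(rate = 0.7))
  # memorylessness: closed form independent of t
  expect_equal(cycle_transition_prob(ex, 0, 1 / 12), 1 - exp(-0.7 / 12))
  expect_equal(cycle_transition_prob(ex, 5, 1 / 12), 1 - exp(-0.7 / 12))
  # continuity: probability vanishes with the cycle length
  expect_lt(cycle_transition_prob(ex, 1, 1e-9), 1e-8)

  ln <- parametric_fit("lognormal", c(meanlog = 1.11, sdlog = 1.44))
  # direct CDF-ratio oracle
  oracle <- 1 - (1 - stats::plnorm(1 + 1 / 12, 1.11, 1.44)) /
    (1 - stats::plnorm(1, 1.11, 1.44))
  expect_equal(cycle_transition_prob(ln, 1, 1 / 12), oracle, tolerance = 1e-12)
  # telescoping product identity over sub-cycles
  for (t0 in c(0.5, 1, 3)) {
    p_big <- cycle_transition_prob(ln, t0, 1 / 12)
    p_sub <- cycle_transition_prob(ln, t0 + (0:11) / 144, 1 / 144)
    expect_equal(1 - prod(1 - p_sub), p_big, tolerance = 1e-10)
  }
  # hazard-ratio scaling acts on the cumulative hazard
  p_hr <- cycle_transition_prob(ln, 1, 1 / 12, hazard_ratio = 0.5)
  expect_equal(log(1 - p_hr), 0.5 * log(1 - cycle_transition_prob(ln, 1, 1 / 12)),
               tolerance = 1e-12)
})
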