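# shared fixtures, built in code

base_config <- function() {
  yaml::read_yaml(system.file("extdata", "model_inputs.yaml", package = "osicea"))
}

# inputs with every transition hazard effectively switched off
inert_config <- function() {
  cfg <- base_config()
  off <- list(family = "exponential", rate = 1e-12)
  cfg$dfs_fits <- lapply(cfg$dfs_fits, function(...) off)
  cfg$pd_death_fit <- off
  cfg$background_mortality_annual <- 0
  cfg
}

# the published parametric fits, as directly usable objects
placebo_dfs_pos <- function() parametric_fit("lognormal", c(meanlog = 1.94, sdlog = 1.22))
placebo_dfs_neg <- function() parametric_fit("lognormal", c(meanlog = 1.11, sdlog = 1.44))
pd_death <- function() parametric_fit("gamma", c(shape = 1.86, rate = 0.56))

# the 5-record hand dataset used for product-limit oracles
hand_ipd <- function() ipd(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))

km_at <- function(x, t) osicea:::km_survival_at(kaplan_meier(x), t)
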