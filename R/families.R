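#' Supported parametric survival families
#'
#' The six families used for disease-free and post-progression survival:
#' exponential, Weibull, gamma, log-normal, log-logistic, and generalized
#' gamma. All distributions are over event times in **years**.
#'
#' Parameter conventions (the classic traps, fixed here once):
#' * `lognormal`: `meanlog`, `sdlog` on the natural-log time scale.
#' * `gamma`: `shape`, `rate` (per year), so the mean is `shape/rate`.
#' * `weibull`: `shape`, `scale` (as in [stats::pweibull()]).
#' * `loglogistic`: `shape`, `scale` (as in [flexsurv::pllogis()]).
#' * `gengamma`: `mu` (log-time location), `sigma` (log-time scale, > 0),
#'   `Q` (shape) — the Prentice log-time parameterization used by flexsurv.
#'
#' @return `survival_families()` returns the character vector of family names.
#' @export
survival_families <- function() {
  c("exponential", "weibull", "gamma", "lognormal", "loglogistic", "gengamma")
}

# parameter names, in canonical order, per family
family_param_names <- function(family) {
  switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    gamma       = c("shape", "rate"),
    lognormal   = c("meanlog", "sdlog"),
    loglogistic = c("shape", "scale"),
    gengamma    = c("mu", "sigma", "Q"),
    stop("unknown survival family: ", family, call. = FALSE)
  )
}

# parameters that must be strictly positive ("mu"/"meanlog"/"Q" may be any real)
family_positive_params <- function(family) {
  setdiff(family_param_names(family), c("meanlog", "mu", "Q"))
}

check_family_params <- function(family, params) {
  family <- match.arg(family, survival_families())
  wanted <- family_param_names(family)
  if (!all(wanted %in% names(params))) {
    stop(sprintf("family '%s' requires parameters: %s (got: %s)",
                 family, paste(wanted, collapse = ", "),
                 paste(names(params), collapse = ", ")), call. = FALSE)
  }
  params <- unlist(params)[wanted]
  if (any(!is.finite(params))) {
    bad <- wanted[!is.finite(params)][1L]
    stop(sprintf("parameter '%s' of family '%s' is not finite", bad, family),
         call. = FALSE)
  }
  for (p in family_positive_params(family)) {
    if (params[[p]] <= 0) {
      stop(sprintf("parameter '%s' of family '%s' must be > 0 (got %g)",
                   p, family, params[[p]]), call. = FALSE)
    }
  }
  params
}

# S(t), vectorized over t
family_survival <- function(family, params, t) {
  p <- as.list(params)
  switch(family,
    exponential = stats::pexp(t, rate = p$rate, lower.tail = FALSE),
    weibull     = stats::pweibull(t, shape = p$shape, scale = p$scale, lower.tail = FALSE),
    gamma       = stats::pgamma(t, shape = p$shape, rate = p$rate, lower.tail = FALSE),
    lognormal   = stats::plnorm(t, meanlog = p$meanlog, sdlog = p$sdlog, lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = p$shape, scale = p$scale, lower.tail = FALSE),
    gengamma    = flexsurv::pgengamma(t, mu = p$mu, sigma = p$sigma, Q = p$Q, lower.tail = FALSE)
  )
}

# cumulative hazard H(t) = -log S(t), computed on the log scale for stability
family_cumhaz <- function(family, params, t) {
  p <- as.list(params)
  lsurv <- switch(family,
    exponential = stats::pexp(t, rate = p$rate, lower.tail = FALSE, log.p = TRUE),
    weibull     = stats::pweibull(t, shape = p$shape, scale = p$scale, lower.tail = FALSE, log.p = TRUE),
    gamma       = stats::pgamma(t, shape = p$shape, rate = p$rate, lower.tail = FALSE, log.p = TRUE),
    lognormal   = stats::plnorm(t, meanlog = p$meanlog, sdlog = p$sdlog, lower.tail = FALSE, log.p = TRUE),
    loglogistic = flexsurv::pllogis(t, shape = p$shape, scale = p$scale, lower.tail = FALSE, log.p = TRUE),
    gengamma    = flexsurv::pgengamma(t, mu = p$mu, sigma = p$sigma, Q = p$Q, lower.tail = FALSE, log.p = TRUE)
  )
  -lsurv
}

family_density <- function(family, params, t, log = FALSE) {
  p <- as.list(params)
  switch(family,
    exponential = stats::dexp(t, rate = p$rate, log = log),
    weibull     = stats::dweibull(t, shape = p$shape, scale = p$scale, log = log),
    gamma       = stats::dgamma(t, shape = p$shape, rate = p$rate, log = log),
    lognormal   = stats::dlnorm(t, meanlog = p$meanlog, sdlog = p$sdlog, log = log),
    loglogistic = flexsurv::dllogis(t, shape = p$shape, scale = p$scale, log = log),
    gengamma    = flexsurv::dgengamma(t, mu = p$mu, sigma = p$sigma, Q = p$Q, log = log)
  )
}

family_random <- function(family, params, n) {
  p <- as.list(params)
  switch(family,
    exponential = stats::rexp(n, rate = p$rate),
    weibull     = stats::rweibull(n, shape = p$shape, scale = p$scale),
    gamma       = stats::rgamma(n, shape = p$shape, rate = p$rate),
    lognormal   = stats::rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog),
    loglogistic = flexsurv::rllogis(n, shape = p$shape, scale = p$scale),
    gengamma    = flexsurv::rgengamma(n, mu = p$mu, sigma = p$sigma, Q = p$Q)
  )
}
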