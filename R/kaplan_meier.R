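#' Kaplan-Meier estimate of an individual patient dataset
#'
#' Product-limit step function with `survival(0) = 1`, used both as the
#' validation oracle for reconstruction round trips and as the backbone of
#' [make_digitized_curve()]. Estimation is delegated to
#' [survival::survfit()].
#'
#' @param x An [ipd()] object (non-empty).
#' @return A [digitized_curve()] holding the step-function coordinates:
#'   time 0 plus every distinct observed time, with the estimate evaluated
#'   just after each time.
#' @export
kaplan_meier <- function(x) {
  stopifnot(inherits(x, "ipd"))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(x), conf.type = "none")
  digitized_curve(c(0, fit$time), c(1, fit$surv))
}

# step-function evaluation of a KM curve at arbitrary times (right-continuous,
# last value carried forward)
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "digitized_curve"))
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, 1, curve$survival[pmax(idx, 1)])
}
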