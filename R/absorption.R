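# Extended-release oral input: Weibull dissolution into the gut lumen and
# first-order permeation into gut tissue.

#' Fraction of an extended-release dose dissolved at time t
#'
#' Weibull dissolution profile with the scale parameterized through the 50\%
#' dissolution time: F(t) = 0 for t <= t_lag and
#' F(t) = 1 - exp(-ln2 * ((t - t_lag)/t_diss50)^b) otherwise, so that
#' exactly half the dose is dissolved at `t_lag + t_diss50`.
#'
#' @param t time since dose intake, min (vectorized).
#' @param f a `formulation_spec`.
#' @return fraction dissolved in [0, 1].
#' @export
weibull_fraction <- function(t, f) {
  stopifnot(inherits(f, "formulation_spec"), all(t >= 0))
  out <- numeric(length(t))
  on <- t > f$t_lag
  out[on] <- 1 - exp(-log(2) * ((t[on] - f$t_lag) / f$t_diss50)^f$shape_b)
  out
}

#' Instantaneous dissolution rate of a dose
#'
#' Time derivative of the Weibull dissolution profile applied to the
#' administered amount; integrates to the administered amount over
#' [0, infinity).
#'
#' @param t time since dose intake, min (vectorized).
#' @param f a `formulation_spec`.
#' @param dose_umol administered amount, umol.
#' @return dissolution rate, umol/min.
#' @export
dissolution_rate <- function(t, f, dose_umol) {
  stopifnot(dose_umol >= 0)
  out <- numeric(length(t))
  on <- t > f$t_lag
  x <- pmax((t[on] - f$t_lag) / f$t_diss50, 1e-12)
  b <- f$shape_b
  out[on] <- dose_umol * log(2) * b / f$t_diss50 * x^(b - 1) *
    exp(-log(2) * x^b)
  out
}

#' First-order intestinal permeation rate constant
#'
#' Monotone heuristic mapping lipophilicity and molecular size to an
#' absorption rate constant: more lipophilic and smaller molecules permeate
#' faster.  The heuristic deliberately plays a minor kinetic role for
#' extended-release formulations, whose input is dissolution-rate limited
#' through the fitted Weibull parameters.
#'
#' @param logp octanol/water log partition coefficient.
#' @param mr molecular weight, g/mol.
#' @param ka_ref reference rate constant at logP 2.5 and Mr 250, 1/min.
#' @return absorption rate constant, 1/min, clamped to [0.005, 0.2].
#' @export
ka_from_properties <- function(logp, mr, ka_ref = 0.05) {
  ka <- ka_ref * sqrt(250 / mr) * 10^(0.15 * (logp - 2.5))
  min(max(ka, 0.005), 0.2)
}

#' Construct a dose event
#'
#' @param compound compound name.
#' @param amount dose, mg.
#' @param time h since simulation start.
#' @param formulation a `formulation_spec`, or the string `"iv_bolus"` for
#'   an instantaneous intravenous dose.
#' @return an object of class `dose_event`.
#' @export
dose_event <- function(compound, amount, time, formulation) {
  stopifnot(amount >= 0, time >= 0)
  if (!inherits(formulation, "formulation_spec") &&
      !identical(formulation, "iv_bolus"))
    stop("formulation must be a formulation_spec or \"iv_bolus\"",
         call. = FALSE)
  structure(list(compound = compound, amount = amount, time = time,
                 formulation = formulation), class = "dose_event")
}

#' Build a once-daily regimen
#'
#' @param compound compound name.
#' @param amount dose, mg.
#' @param start_day,end_day first and last dosing day (day 1 is the 24 h
#'   window starting at t = 0).
#' @param formulation a `formulation_spec` or `"iv_bolus"`.
#' @param time_of_day intake time within the day, h.
#' @return an object of class `regimen` (list of `dose_event`s sorted by
#'   time).
#' @export
regimen_qd <- function(compound, amount, start_day, end_day, formulation,
                       time_of_day = 0) {
  days <- seq(start_day, end_day)
  regimen(lapply(days, function(d)
    dose_event(compound, amount, (d - 1) * 24 + time_of_day, formulation)))
}

#' Build a twice-daily regimen
#'
#' @inheritParams regimen_qd
#' @param interval_h dosing interval, h (default 12).
#' @return a `regimen`.
#' @export
regimen_bid <- function(compound, amount, start_day, end_day, formulation,
                        interval_h = 12, time_of_day = 0) {
  days <- seq(start_day, end_day)
  evs <- list()
  for (d in days) {
    t0 <- (d - 1) * 24 + time_of_day
    evs <- c(evs, list(dose_event(compound, amount, t0, formulation),
                       dose_event(compound, amount, t0 + interval_h,
                                  formulation)))
  }
  regimen(evs)
}

#' Assemble dose events into a regimen
#'
#' @param events list of `dose_event` objects.
#' @return `regimen` object with events sorted by time.
#' @export
regimen <- function(events) {
  stopifnot(all(vapply(events, inherits, logical(1), "dose_event")))
  ord <- order(vapply(events, function(e) e$time, numeric(1)))
  structure(events[ord], class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cmp <- vapply(x, function(e) e$compound, character(1))
  cat(sprintf("<regimen> %d doses: %s\n", length(x),
              paste(sprintf("%s x%d", unique(cmp),
                            tabulate(factor(cmp, unique(cmp)))),
                    collapse = ", ")))
  invisible(x)
}
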