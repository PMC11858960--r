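# Encoded interaction study designs and the resulting exposure-change
# reports.
#
# Day indexing: day N is the 24 h window [24*(N-1), 24*N) h; troughs are
# read immediately before the subsequent dose (the last grid point of the
# day window).

#' Build a named study protocol
#'
#' Known designs:
#' \describe{
#'   \item{ddi_150 / ddi_300}{225 mg/day venlafaxine on days 1-18; 150 or
#'     300 mg/day bupropion added on days 5-18 (14 days of combination);
#'     exposures compared on day 4 (before the perpetrator) vs day 18.}
#'   \item{mddi}{225 mg/day venlafaxine on days 1-27; 300 mg/day bupropion
#'     days 7-27; 100 mg twice daily (12 h interval) of a strong CYP3A4
#'     inhibitor days 21-27; comparisons on days 4, 17 and 27.}
#'   \item{ven_itra}{as mddi but without bupropion: venlafaxine days 1-27
#'     plus the CYP3A4 inhibitor days 21-27; comparison days 4 and 27.}
#'   \item{ven_alone}{225 mg/day venlafaxine days 1-18, no comparison
#'     phase.}
#' }
#'
#' @param name protocol name.
#' @param registry registry providing formulations (and, for the mddi
#'   protocols, the generic CYP3A4 inhibitor; it is added automatically if
#'   absent).
#' @return an object of class `study_protocol`.
#' @export
build_protocol <- function(name = c("ddi_150", "ddi_300", "mddi",
                                    "ven_itra", "ven_alone"),
                           registry = load_registry()) {
  name <- match.arg(name)
  doses <- switch(name,
    ddi_150 = list(
      list(compound = "VEN", amount = 225, schedule = "qd",
           start_day = 1, end_day = 18),
      list(compound = "BUP", amount = 150, schedule = "qd",
           start_day = 5, end_day = 18)),
    ddi_300 = list(
      list(compound = "VEN", amount = 225, schedule = "qd",
           start_day = 1, end_day = 18),
      list(compound = "BUP", amount = 300, schedule = "qd",
           start_day = 5, end_day = 18)),
    mddi = list(
      list(compound = "VEN", amount = 225, schedule = "qd",
           start_day = 1, end_day = 27),
      list(compound = "BUP", amount = 300, schedule = "qd",
           start_day = 7, end_day = 27),
      list(compound = "CYP3A4I", amount = 100, schedule = "bid",
           start_day = 21, end_day = 27)),
    ven_itra = list(
      list(compound = "VEN", amount = 225, schedule = "qd",
           start_day = 1, end_day = 27),
      list(compound = "CYP3A4I", amount = 100, schedule = "bid",
           start_day = 21, end_day = 27)),
    ven_alone = list(
      list(compound = "VEN", amount = 225, schedule = "qd",
           start_day = 1, end_day = 18)))
  comparison <- switch(name,
    ddi_150 = , ddi_300 = list(baseline_day = 4, effect_day = 18,
                               compare_days = c(4, 18)),
    mddi = list(baseline_day = 4, effect_day = 27,
                compare_days = c(4, 17, 27)),
    ven_itra = list(baseline_day = 4, effect_day = 27,
                    compare_days = c(4, 27)),
    ven_alone = list(baseline_day = NA_integer_, effect_day = NA_integer_,
                     compare_days = integer(0)))
  t_end <- 24 * max(vapply(doses, function(d) d$end_day, numeric(1)))
  structure(c(list(name = name, doses = doses,
                   analytes = c("VEN", "ODV", "AM"),
                   t_end_h = t_end), comparison),
            class = "study_protocol")
}

#' Materialize the dose events of a protocol
#'
#' @param protocol a `study_protocol`.
#' @param registry registry providing formulations.
#' @return list of `regimen` objects.
#' @export
protocol_regimens <- function(protocol, registry) {
  lapply(protocol$doses, function(d) {
    f <- registry$formulations[[d$compound]]
    if (is.null(f))
      stop("no formulation registered for ", d$compound, call. = FALSE)
    if (d$schedule == "qd")
      regimen_qd(d$compound, d$amount, d$start_day, d$end_day, f)
    else regimen_bid(d$compound, d$amount, d$start_day, d$end_day, f)
  })
}

#' Simulation day at which a monitored trough is read
#'
#' The sampling time of a monitored trough is the number of days between
#' the last change in perpetrator dosing and the blood draw; samples taken
#' more than ten days after the last change are read on day 10 of
#' concomitant use, when the perpetrator and its metabolites have reached
#' steady state.
#'
#' @param days_since_last_change integer days (>= 1).
#' @return simulation day of concomitant use (capped at 10).
#' @export
trough_sampling_day <- function(days_since_last_change) {
  if (any(days_since_last_change < 1))
    stop("days since last change must be >= 1", call. = FALSE)
  pmin(days_since_last_change, 10)
}

#' Dose-normalize a trough concentration
#'
#' Linear-kinetics rescaling of a trough measured under an arbitrary
#' parent-drug dose to the harmonized 225 mg/day dose.
#'
#' @param c_tr trough concentration, ng/mL.
#' @param actual_ven_dose administered dose, mg/day (> 0).
#' @param target harmonized dose, mg/day.
#' @return normalized trough, ng/mL.
#' @export
normalize_dose <- function(c_tr, actual_ven_dose, target = 225) {
  if (any(actual_ven_dose <= 0)) stop("dose must be > 0", call. = FALSE)
  c_tr * target / actual_ven_dose
}

day_window <- function(day) c(24 * (day - 1), 24 * day)

#' Run a drug-drug interaction study on a virtual population
#'
#' Simulates every individual over the protocol, forms the pointwise-median
#' population profile per analyte (parent, metabolite and flow-weighted
#' active moiety), applies non-compartmental analysis on the comparison-day
#' windows of that median profile (the primary statistic; medians of the
#' individual AUCs are also reported), and derives relative exposure
#' changes, the metabolic-ratio change, the inhibition-strength class of
#' the parent fold-change and reference-range verdicts of the median
#' active-moiety trough.
#'
#' @param protocol a `study_protocol`.
#' @param population list of `individual`s (see [sample_population()]).
#' @param registry a calibrated `system_registry`.
#' @param seed integer recorded in the report for reproducibility.
#' @param dt_out_h output grid spacing, h.
#' @return an object of class `ddi_report`.
#' @export
run_ddi_study <- function(protocol, population, registry, seed = 1L,
                          dt_out_h = 0.25) {
  stopifnot(inherits(protocol, "study_protocol"), length(population) >= 1)
  if (any(vapply(protocol$doses, function(d) d$compound, character(1)) ==
          "CYP3A4I") && !"CYP3A4I" %in% names(registry$compounds))
    registry <- add_cyp3a4_inhibitor(registry)
  regs <- protocol_regimens(protocol, registry)
  dose_times <- sort(unique(vapply(flatten_regimens(regs),
                                   function(e) e$time, numeric(1))))

  profiles <- list(VEN = NULL, ODV = NULL, AM = NULL)
  ind_auc <- list()
  tt <- NULL
  for (i in seq_along(population)) {
    ind <- population[[i]]
    sys <- assemble(registry, ind)
    res <- tryCatch(
      simulate_system(sys, regs, t_end_h = protocol$t_end_h,
                      dt_out_h = dt_out_h),
      error = function(e) stop("individual ", ind$id %||% i,
                               ": ", conditionMessage(e), call. = FALSE))
    if (is.null(tt)) tt <- res$time_h
    am <- am_profile(res)
    profiles$VEN <- cbind(profiles$VEN, res$conc[, "VEN"])
    profiles$ODV <- cbind(profiles$ODV, res$conc[, "ODV"])
    profiles$AM <- cbind(profiles$AM, am)
    ind_auc[[i]] <- vapply(protocol$compare_days, function(d) {
      w <- day_window(d)
      c(VEN = nca(tt, res$conc[, "VEN"], w)$auc,
        ODV = nca(tt, res$conc[, "ODV"], w)$auc,
        AM = nca(tt, am, w)$auc)
    }, numeric(3))
  }
  med <- lapply(profiles, function(m) apply(m, 1, stats::median))

  analyte_nca <- function(day) {
    w <- day_window(day)
    lapply(med, function(p) nca(tt, p, w, dose_times_h = dose_times))
  }
  days <- protocol$compare_days
  nca_by_day <- lapply(days, analyte_nca)
  if (length(days)) names(nca_by_day) <- paste0("day", days)

  tab <- NULL; changes <- NULL
  if (length(days) >= 2) {
    base <- nca_by_day[[1]]
    for (di in seq_along(days)) {
      cur <- nca_by_day[[di]]
      for (an in names(cur)) {
        row <- data.frame(day = days[di], analyte = an,
                          auc = cur[[an]]$auc, cmax = cur[[an]]$cmax,
                          cmin = cur[[an]]$cmin,
                          ctrough = cur[[an]]$ctrough)
        row$auc_change_pct <- if (di == 1) 0 else
          relative_change(cur[[an]]$auc, base[[an]]$auc)
        tab <- rbind(tab, row)
      }
    }
    eff <- nca_by_day[[length(days)]]
    mr_base <- mr_auc(base$ODV$auc, base$VEN$auc)
    mr_eff <- mr_auc(eff$ODV$auc, eff$VEN$auc)
    ven_fold <- eff$VEN$auc / base$VEN$auc
    changes <- list(
      mr_auc_baseline = mr_base, mr_auc_effect = mr_eff,
      mr_auc_change_pct = relative_change(mr_eff, mr_base),
      ven_auc_fold = ven_fold,
      classification = classify_ddi(ven_fold),
      am_trough_baseline = base$AM$ctrough,
      am_trough_effect = eff$AM$ctrough,
      verdict_baseline = reference_range_verdict(base$AM$ctrough),
      verdict_effect = reference_range_verdict(eff$AM$ctrough))
  } else {
    w <- day_window(protocol$t_end_h / 24)
    tab <- do.call(rbind, lapply(names(med), function(an) {
      n <- nca(tt, med[[an]], w, dose_times_h = dose_times)
      data.frame(day = protocol$t_end_h / 24, analyte = an, auc = n$auc,
                 cmax = n$cmax, cmin = n$cmin, ctrough = n$ctrough,
                 auc_change_pct = NA_real_)
    }))
  }

  median_individual_auc <- if (length(days))
    apply(simplify2array(ind_auc), c(1, 2), stats::median) else NULL

  structure(list(protocol = protocol$name, seed = seed, n = length(population),
                 table = tab, changes = changes,
                 nca_by_day = nca_by_day,
                 median_individual_auc = median_individual_auc,
                 median_profiles = c(list(time_h = tt), med)),
            class = "ddi_report")
}

#' @export
print.ddi_report <- function(x, ...) {
  cat(sprintf("<ddi_report> protocol %s, n = %d individuals\n",
              x$protocol, x$n))
  if (!is.null(x$table)) {
    print(x$table, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$changes)) {
    ch <- x$changes
    cat(sprintf("  MR_AUC %s -> %s (%s%%); VEN fold %.2f (%s)\n",
                report_round(ch$mr_auc_baseline, "ratio"),
                report_round(ch$mr_auc_effect, "ratio"),
                report_round(ch$mr_auc_change_pct, "percent"),
                ch$ven_auc_fold, ch$classification))
    cat(sprintf("  median AM trough %.0f -> %.0f ng/mL (%s -> %s)\n",
                ch$am_trough_baseline, ch$am_trough_effect,
                ch$verdict_baseline, ch$verdict_effect))
  }
  invisible(x)
}
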