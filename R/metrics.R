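# Evaluation metrics: active moiety, prediction errors, metabolic ratio,
# non-compartmental analysis, fold-error and percentile coverage,
# inhibition-strength classification and reference-range verdicts.

#' Active-moiety concentration
#'
#' Combined mass concentration of the parent and its active metabolite,
#' computed as the flow-weighted mean of the molar plasma concentrations
#' over the arterial, bone, fat, muscle and skin compartments, converted to
#' mass units per compound and summed:
#' `c_AM = Mr_p * sum(fQ_i c_i,p)/sum(fQ_i) + Mr_m * sum(fQ_i c_i,m)/sum(fQ_i)`.
#'
#' The flow-weighted sum is normalized by the total flow so the result
#' carries concentration units and reduces to the common plasma
#' concentration when all organs agree; `am_raw_sum = TRUE` preserves the
#' unnormalized literal sum for sensitivity analysis.
#'
#' @param conc_parent,conc_metabolite named numeric vectors of per-organ
#'   plasma concentrations, uM; must share the organ set of `flows`.
#' @param flows named numeric vector of organ blood flows, L/min (> 0).
#' @param mr_parent,mr_metabolite molecular weights, g/mol.
#' @param am_raw_sum if `TRUE`, skip the flow normalization.
#' @return active-moiety concentration, ng/mL.
#' @export
active_moiety <- function(conc_parent, conc_metabolite, flows,
                          mr_parent = 277.4, mr_metabolite = 263.38,
                          am_raw_sum = FALSE) {
  if (!setequal(names(conc_parent), names(flows)) ||
      !setequal(names(conc_metabolite), names(flows)))
    stop("organ set mismatch between concentrations and flows",
         call. = FALSE)
  stopifnot(all(flows > 0))
  fq <- flows
  cp <- conc_parent[names(fq)]
  cm <- conc_metabolite[names(fq)]
  denom <- if (am_raw_sum) 1 else sum(fq)
  as.numeric(mr_parent * sum(fq * cp) / denom +
             mr_metabolite * sum(fq * cm) / denom)
}

#' Relative change in percent
#'
#' `100 * (a - b) / b`; used both as the prediction error of a simulated
#' against an observed value and as the before/after exposure change.
#'
#' @param a predicted (or after) value.
#' @param b observed (or before) reference value; must be nonzero.
#' @return percent change.
#' @export
relative_change <- function(a, b) {
  if (any(b == 0)) stop("zero reference in relative change", call. = FALSE)
  100 * (a - b) / b
}

#' Mean and mean absolute prediction error
#'
#' @param pe_list numeric vector of prediction errors, percent.
#' @return list with `mpe` (bias) and `mape` (precision), percent.
#' @export
summarize_pe <- function(pe_list) {
  if (length(pe_list) == 0) stop("empty prediction-error list", call. = FALSE)
  list(mpe = mean(pe_list), mape = mean(abs(pe_list)))
}

#' Metabolic ratio of exposures
#'
#' `MR_AUC = AUC_metabolite / AUC_parent`.
#'
#' @param auc_odv metabolite exposure.
#' @param auc_ven parent exposure; must be > 0.
#' @return dimensionless ratio.
#' @export
mr_auc <- function(auc_odv, auc_ven) {
  if (any(auc_ven <= 0)) stop("parent AUC must be > 0", call. = FALSE)
  auc_odv / auc_ven
}

#' Non-compartmental analysis of a concentration-time profile
#'
#' Linear-trapezoid AUC over an interval, with maximal/minimal
#' concentration, time of maximum and the trough concentration immediately
#' before the next dose.
#'
#' @param time_h,conc profile (h, any concentration unit); at least two
#'   samples inside the interval.
#' @param interval `(t0, t1)` in h, within the profile support.
#' @param dose_times_h dose times, h; the trough is read at the last sample
#'   at or before the first dose after `t1` (falls back to the interval end).
#' @return list of class `nca_result`: `auc` (conc x h), `cmax`, `cmin`,
#'   `ctrough`, `tmax` (h after interval start).
#' @export
nca <- function(time_h, conc, interval, dose_times_h = numeric(0)) {
  stopifnot(length(time_h) == length(conc), length(interval) == 2,
            interval[1] < interval[2])
  if (interval[1] < min(time_h) - 1e-9 || interval[2] > max(time_h) + 1e-9)
    stop("interval outside profile support", call. = FALSE)
  inside <- time_h >= interval[1] - 1e-9 & time_h <= interval[2] + 1e-9
  if (sum(inside) < 2) stop("need >= 2 samples in interval", call. = FALSE)
  tt <- time_h[inside]; cc <- conc[inside]
  auc <- sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
  cmax <- max(cc); cmin <- min(cc)
  tmax <- tt[which.max(cc)] - interval[1]
  nxt <- dose_times_h[dose_times_h > interval[2] - 1e-9]
  t_tr <- if (length(nxt)) min(nxt) else interval[2]
  ctrough <- cc[max(which(tt <= t_tr + 1e-9))]
  structure(list(auc = auc, cmax = cmax, cmin = cmin, ctrough = ctrough,
                 tmax = tmax), class = "nca_result")
}

#' Fraction of predictions within a fold-error range
#'
#' @param predicted,observed paired values; observed must be > 0.
#' @param fold fold limit (> 1); a pair counts when
#'   `1/fold <= predicted/observed <= fold`.
#' @return percent of pairs inside the range.
#' @export
fold_error_fraction <- function(predicted, observed, fold = 2) {
  stopifnot(length(predicted) == length(observed), fold > 1)
  if (any(observed <= 0)) stop("observed values must be > 0", call. = FALSE)
  r <- predicted / observed
  100 * mean(r >= 1 / fold & r <= fold)
}

#' Percent of observations inside the simulated 5th-95th percentile band
#'
#' Empirical quantiles use the linear-interpolation convention
#' (`stats::quantile` type 7); the interval is closed.
#'
#' @param observed numeric vector of observed values.
#' @param simulated numeric vector of simulated values (>= 20 required).
#' @param probs percentile pair (default `c(0.05, 0.95)`).
#' @return percent of observations within `[p5, p95]`.
#' @export
percentile_coverage <- function(observed, simulated,
                                probs = c(0.05, 0.95)) {
  if (length(simulated) < 20)
    stop("simulated sample too small (need >= 20)", call. = FALSE)
  q <- stats::quantile(simulated, probs, type = 7, names = FALSE)
  100 * mean(observed >= q[1] & observed <= q[2])
}

#' Classify inhibition strength from an exposure fold-ratio
#'
#' Regulatory convention for the extent of an interaction on the victim
#' drug: a fold-increase of at least 5 is strong, at least 2 moderate, at
#' least 1.25 weak, otherwise no interaction.  Boundaries are inclusive at
#' the lower edge of each class.
#'
#' @param auc_fold_ratio AUC ratio with/without the perpetrator (> 0).
#' @return one of `"none"`, `"weak"`, `"moderate"`, `"strong"`.
#' @export
classify_ddi <- function(auc_fold_ratio) {
  stopifnot(auc_fold_ratio > 0)
  if (auc_fold_ratio >= 5) "strong"
  else if (auc_fold_ratio >= 2) "moderate"
  else if (auc_fold_ratio >= 1.25) "weak"
  else "none"
}

#' Therapeutic reference-range verdict for an active-moiety trough
#'
#' The therapeutic reference range of the active moiety is 100-400 ng/mL
#' (bounds included); above 400 up to 800 ng/mL is supratherapeutic; above
#' 800 ng/mL is toxic.
#'
#' @param c_am_trough trough concentration, ng/mL (>= 0).
#' @return one of `"subtherapeutic"`, `"therapeutic"`,
#'   `"supratherapeutic"`, `"toxic"`.
#' @export
reference_range_verdict <- function(c_am_trough) {
  stopifnot(c_am_trough >= 0)
  if (c_am_trough < 100) "subtherapeutic"
  else if (c_am_trough <= 400) "therapeutic"
  else if (c_am_trough <= 800) "supratherapeutic"
  else "toxic"
}

#' Round report values the way the interaction tables print them
#'
#' Ratios to two decimals, percent changes to three significant figures.
#'
#' @param x value.
#' @param kind `"ratio"` or `"percent"`.
#' @return rounded value.
#' @export
report_round <- function(x, kind = c("ratio", "percent")) {
  kind <- match.arg(kind)
  if (kind == "ratio") round(x, 2) else signif(x, 3)
}
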