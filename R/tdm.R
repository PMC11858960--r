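# Synthetic therapeutic-drug-monitoring cohorts with known ground truth,
# the routine-data exclusion filters, and the observed-vs-simulated trough
# evaluation block.

STRONG_CYP2D6_OR_PPI <- c("paroxetine", "fluoxetine", "cinacalcet",
                          "omeprazole", "esomeprazole", "pantoprazole")
BENIGN_COMEDS <- c("", "mirtazapine", "lorazepam", "metformin", "ramipril")

EXCLUSION_RULES <- c("strong_cyp2d6_or_ppi_comedication",
                     "missing_demographics", "missing_concentration",
                     "immediate_release", "recent_dose_change",
                     "documentation_bias")

#' Define a synthetic monitored cohort
#'
#' @param stratum `"young"` or `"elderly"`.
#' @param n_150,n_300 records per perpetrator dose group (defaults follow
#'   the study collective: 35/22 young, 8/5 elderly).
#' @param gsd geometric standard deviation of the lognormal residual noise
#'   multiplying simulated troughs (default 1.8, reflecting wide observed
#'   trough spreads; 1 = no noise).
#' @param contamination named list of fractions of records violating one
#'   exclusion rule each; names from
#'   `c("strong_cyp2d6_or_ppi_comedication", "missing_demographics",
#'   "missing_concentration", "immediate_release", "recent_dose_change",
#'   "documentation_bias")`.
#' @param seed integer seed.
#' @return an object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(stratum = c("young", "elderly"),
                                  n_150 = NULL, n_300 = NULL, gsd = 1.8,
                                  contamination = list(), seed = 1L) {
  stratum <- match.arg(stratum)
  defaults <- if (stratum == "young") c(35L, 22L) else c(8L, 5L)
  n_150 <- as.integer(n_150 %||% defaults[1])
  n_300 <- as.integer(n_300 %||% defaults[2])
  stopifnot(n_150 >= 0, n_300 >= 0, gsd >= 1)
  if (length(contamination)) {
    stopifnot(all(names(contamination) %in% EXCLUSION_RULES),
              all(unlist(contamination) >= 0),
              all(unlist(contamination) <= 1))
  }
  structure(list(stratum = stratum, n_150 = n_150, n_300 = n_300,
                 gsd = gsd, contamination = contamination,
                 seed = as.integer(seed)), class = "synthetic_cohort_spec")
}

#' Generate a synthetic monitored-trough dataset
#'
#' Clean records carry the simulated trough concentrations of the assigned
#' virtual individual under the matching perpetrator protocol, read at the
#' capped sampling day (see [trough_sampling_day()]), scaled linearly to
#' the record's parent dose and multiplied by independent lognormal noise
#' per analyte.  Contaminated records each violate exactly one named
#' exclusion rule; the ground-truth log states which.
#'
#' @param spec a `synthetic_cohort_spec`.
#' @param registry a calibrated `system_registry`.
#' @param population list of `individual`s for the stratum; individuals are
#'   recycled over records.
#' @param dt_out_h simulation output grid, h.
#' @return list with `records` (data.frame, one row per record) and
#'   `ground_truth` (data.frame with the planted rule and noise-free
#'   troughs).
#' @export
generate_tdm_dataset <- function(spec, registry, population,
                                 dt_out_h = 0.5) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"), length(population) >= 1)
  n <- spec$n_150 + spec$n_300
  if (n == 0) return(list(records = data.frame(), ground_truth = data.frame()))
  rng <- set_local_seed(spec$seed)
  on.exit(restore_seed(rng))

  bup_dose <- c(rep(150, spec$n_150), rep(300, spec$n_300))
  ind_idx <- rep_len(seq_along(population), n)
  days_since <- sample(1:21, n, replace = TRUE)
  ven_dose <- sample(c(150, 225, 300), n, replace = TRUE,
                     prob = c(0.2, 0.6, 0.2))
  sdlog <- log(spec$gsd)
  noise_ven <- exp(stats::rnorm(n, 0, sdlog))
  noise_odv <- exp(stats::rnorm(n, 0, sdlog))

  # one simulation per (individual, perpetrator dose) pair serves all its
  # records: troughs at any concomitant-use day are on the same profile
  cache <- new.env(parent = emptyenv())
  trough_at <- function(idx, dose, day_conc) {
    key <- paste0(idx, "_", dose)
    if (is.null(cache[[key]])) {
      prot <- build_protocol(if (dose == 150) "ddi_150" else "ddi_300",
                             registry)
      sys <- assemble(registry, population[[idx]])
      cache[[key]] <- simulate_system(sys, protocol_regimens(prot, registry),
                                      t_end_h = prot$t_end_h,
                                      dt_out_h = dt_out_h)
    }
    res <- cache[[key]]
    t_tr <- 24 * (4 + day_conc)   # end of concomitant-use day `day_conc`
    i <- max(which(res$time_h <= t_tr + 1e-9))
    c(ven = unname(res$conc[i, "VEN"]), odv = unname(res$conc[i, "ODV"]))
  }

  # plant contamination: each affected record violates exactly one rule
  planted <- rep("none", n)
  if (length(spec$contamination)) {
    pool <- sample(n)
    for (rule in names(spec$contamination)) {
      k <- round(spec$contamination[[rule]] * n)
      if (k > 0) {
        take <- utils::head(pool, k)
        pool <- utils::tail(pool, -k)
        planted[take] <- rule
      }
    }
  }

  rec <- vector("list", n)
  truth <- vector("list", n)
  for (r in seq_len(n)) {
    ind <- population[[ind_idx[r]]]
    day_conc <- trough_sampling_day(days_since[r])
    tr <- trough_at(ind_idx[r], bup_dose[r], day_conc)
    scale <- ven_dose[r] / 225
    cv <- tr[["ven"]] * scale * noise_ven[r]
    co <- tr[["odv"]] * scale * noise_odv[r]
    row <- data.frame(
      patient_id = r, age = round(ind$age), sex = ind$sex,
      weight = round(ind$weight, 1), height = round(ind$height),
      ven_dose = ven_dose[r], bup_dose = bup_dose[r],
      days_since_bup_change = days_since[r],
      c_tr_ven = cv, c_tr_odv = co,
      comedications = sample(BENIGN_COMEDS, 1),
      formulation = "extended",
      days_since_ven_change = sample(3:30, 1),
      documentation_ok = TRUE, stringsAsFactors = FALSE)
    row <- switch(planted[r],
      strong_cyp2d6_or_ppi_comedication = {
        row$comedications <- sample(STRONG_CYP2D6_OR_PPI, 1); row },
      missing_demographics = { row$weight <- NA_real_; row },
      missing_concentration = {
        if (stats::runif(1) < 0.5) row$c_tr_ven <- NA_real_
        else row$c_tr_odv <- NA_real_
        row },
      immediate_release = { row$formulation <- "immediate"; row },
      recent_dose_change = { row$days_since_ven_change <- sample(0:2, 1); row },
      documentation_bias = { row$documentation_ok <- FALSE; row },
      row)
    rec[[r]] <- row
    truth[[r]] <- data.frame(patient_id = r, planted_rule = planted[r],
                             true_trough_ven = tr[["ven"]],
                             true_trough_odv = tr[["odv"]],
                             stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, rec), ground_truth = do.call(rbind, truth))
}

#' Apply the routine-data exclusion filters
#'
#' A record is rejected iff at least one rule is violated: comedication
#' with a strong CYP2D6 inhibitor (paroxetine, fluoxetine, cinacalcet) or a
#' CYP2C19-inhibiting proton-pump inhibitor ((es)omeprazole, pantoprazole);
#' missing demographics; missing parent or metabolite trough; an
#' immediate-release formulation; a parent dose change (or therapy start)
#' less than three days before sampling; or flagged documentation bias.
#' All violated rules are enumerated per record.
#'
#' @param records data.frame of monitored-trough records.
#' @return list with `kept` (data.frame), `rejected` (data.frame) and
#'   `reasons` (data.frame patient_id/rule, one row per violated rule).
#' @export
apply_exclusion_filters <- function(records) {
  if (nrow(records) == 0)
    return(list(kept = records, rejected = records,
                reasons = data.frame(patient_id = integer(0),
                                     rule = character(0))))
  reasons <- list()
  bad <- logical(nrow(records))
  note <- function(idx, rule) {
    if (any(idx)) {
      reasons[[length(reasons) + 1]] <<- data.frame(
        patient_id = records$patient_id[idx], rule = rule,
        stringsAsFactors = FALSE)
      bad[idx] <<- TRUE
    }
  }
  comeds <- strsplit(ifelse(is.na(records$comedications), "",
                            records$comedications), ",\\s*")
  hit <- vapply(comeds, function(x)
    length(intersect(tolower(trimws(x)), STRONG_CYP2D6_OR_PPI)) > 0,
    logical(1))
  note(hit, "strong_cyp2d6_or_ppi_comedication")
  note(is.na(records$age) | is.na(records$sex) | is.na(records$weight) |
       is.na(records$height), "missing_demographics")
  note(is.na(records$c_tr_ven) | is.na(records$c_tr_odv),
       "missing_concentration")
  note(records$formulation == "immediate", "immediate_release")
  note(records$days_since_ven_change < 3, "recent_dose_change")
  note(!records$documentation_ok, "documentation_bias")
  reasons <- if (length(reasons)) do.call(rbind, reasons)
             else data.frame(patient_id = integer(0), rule = character(0))
  list(kept = records[!bad, , drop = FALSE],
       rejected = records[bad, , drop = FALSE],
       reasons = reasons[order(reasons$patient_id), , drop = FALSE])
}

#' Simulated population trough sample for a dose group
#'
#' Trough concentrations (parent, metabolite, active-moiety sum and
#' metabolite/parent ratio) of every individual of a population under the
#' matching perpetrator protocol, read at day 10 of concomitant use.
#'
#' @param registry a calibrated `system_registry`.
#' @param population list of `individual`s.
#' @param bup_dose 150 or 300 (mg/day).
#' @param days_concomitant concomitant-use day of the trough (default 10).
#' @param dt_out_h output grid, h.
#' @return data.frame with columns ven, odv, am, mr (ng/mL and ratio).
#' @export
population_troughs <- function(registry, population, bup_dose = 300,
                               days_concomitant = 10, dt_out_h = 0.5) {
  prot <- build_protocol(if (bup_dose == 150) "ddi_150" else "ddi_300",
                         registry)
  t_tr <- 24 * (4 + days_concomitant)
  out <- lapply(population, function(ind) {
    sys <- assemble(registry, ind)
    res <- simulate_system(sys, protocol_regimens(prot, registry),
                           t_end_h = prot$t_end_h, dt_out_h = dt_out_h)
    i <- max(which(res$time_h <= t_tr + 1e-9))
    v <- res$conc[i, "VEN"]; o <- res$conc[i, "ODV"]
    data.frame(ven = v, odv = o, am = v + o, mr = o / v)
  })
  do.call(rbind, out)
}

med_range <- function(x) sprintf("%.3g (%.3g-%.3g)", stats::median(x),
                                 min(x), max(x))

#' Observed-vs-simulated trough evaluation block
#'
#' For the parent, metabolite, active-moiety sum and metabolite/parent
#' trough ratio of one stratum/dose cell: record count, percent of
#' dose-normalized observations inside the simulated 5th-95th percentile
#' band, observed and simulated medians with ranges, and the prediction
#' error of the medians.  The per-record ratio statistic is the median of
#' ratios (the ratio of medians is also returned).
#'
#' @param records kept (filtered) records of the cell.
#' @param simulated data.frame from [population_troughs()] (>= 20 rows for
#'   coverage).
#' @param normalize dose-normalize observed troughs to 225 mg/day first.
#' @return data.frame with one row per quantity (VEN, ODV, AM, MR).
#' @export
evaluate_tdm <- function(records, simulated, normalize = TRUE) {
  if (nrow(records) == 0) stop("empty evaluation cell", call. = FALSE)
  obs_ven <- if (normalize)
    normalize_dose(records$c_tr_ven, records$ven_dose) else records$c_tr_ven
  obs_odv <- if (normalize)
    normalize_dose(records$c_tr_odv, records$ven_dose) else records$c_tr_odv
  obs <- list(VEN = obs_ven, ODV = obs_odv, AM = obs_ven + obs_odv,
              MR = obs_odv / obs_ven)
  sim <- list(VEN = simulated$ven, ODV = simulated$odv, AM = simulated$am,
              MR = simulated$mr)
  out <- lapply(names(obs), function(an) {
    o <- obs[[an]]; s <- sim[[an]]
    data.frame(
      quantity = an, n = length(o),
      pct_in_5_95 = if (length(s) >= 20) percentile_coverage(o, s)
                    else NA_real_,
      data_median = stats::median(o),
      data_range = med_range(o),
      model_median = stats::median(s),
      model_range = med_range(s),
      pe_median_pct = relative_change(stats::median(s), stats::median(o)),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "mr_ratio_of_medians") <-
    stats::median(obs$ODV) / stats::median(obs$VEN)
  res
}
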