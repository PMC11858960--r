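# Virtual individuals and age-stratified populations: organ volumes, blood
# flows, glomerular filtration, demographic sampling.

# Reduced 12-compartment organ set.  The active-moiety equation needs
# arterial blood, bone, fat, muscle and skin explicitly; liver, kidney and
# gut are mechanistic; everything else is lumped into "rest".
ORGAN_SET <- c("arterial_blood", "venous_blood", "lung", "gut_lumen",
               "gut_tissue", "liver", "kidney", "muscle", "skin", "fat",
               "bone", "rest")

# Reference adult (male, 30 y, 73 kg, 176 cm): organ volumes (L) and
# fractional tissue blood flows, compiled from standard reference-human
# physiology tables.  Flow fractions refer to cardiac output and sum to 1
# over the perfused tissues (the lung carries total cardiac output).
REF_WEIGHT <- 73
REF_VOLUMES <- c(arterial_blood = 1.7, venous_blood = 3.9, lung = 0.5,
                 gut_lumen = 1.0, gut_tissue = 1.1, liver = 1.8,
                 kidney = 0.31, muscle = 29, skin = 3.3, fat = 13,
                 bone = 10, rest = 6.4)
REF_FLOW_FRACTIONS <- c(gut_tissue = 0.15, liver = 0.065, kidney = 0.19,
                        muscle = 0.17, skin = 0.05, fat = 0.05,
                        bone = 0.05, rest = 0.275)  # liver = hepatic artery
REF_CARDIAC_OUTPUT <- 5.6   # L/min
REF_GFR <- 110              # mL/min
REF_HEMATOCRIT <- c(m = 0.45, f = 0.40)

# Linear declines beyond age 40 (fraction per year); explicit stand-ins for
# the age physiology that drives higher exposure in the elderly.
AGE_DECLINE_GFR <- 0.007
AGE_DECLINE_CO <- 0.005

age_factor <- function(age, rate) max(0.2, 1 - rate * max(0, age - 40))

#' Build a virtual individual from demographics
#'
#' Scales a bundled reference-adult physiology (organ volumes, fractional
#' blood flows, glomerular filtration rate) to the requested demographics.
#' Volumes scale linearly with body weight; flows and GFR scale with
#' weight^0.75 by default (switchable to linear).  Beyond age 40, GFR and
#' cardiac output decline linearly at configurable rates (defaults 0.7\%/yr
#' and 0.5\%/yr); enzyme abundances are age-invariant.
#'
#' @param age years, in [18, 100].
#' @param sex `"m"` or `"f"`.
#' @param weight kg, in [30, 200].
#' @param height cm.
#' @param flow_scaling `"allometric"` (weight^0.75) or `"linear"`.
#' @return an object of class `individual` with organ volumes (L), blood
#'   flows (L/min), GFR (mL/min), hematocrit, BMI and unit enzyme-abundance
#'   scalars.
#' @export
reference_individual <- function(age = 30, sex = "m", weight = 73,
                                 height = 176,
                                 flow_scaling = c("allometric", "linear")) {
  flow_scaling <- match.arg(flow_scaling)
  if (age < 18 || age > 100) stop("age out of range [18, 100]", call. = FALSE)
  if (weight < 30 || weight > 200)
    stop("weight out of range [30, 200] kg", call. = FALSE)
  if (height < 120 || height > 230)
    stop("height out of range [120, 230] cm", call. = FALSE)
  if (!sex %in% c("m", "f")) stop("sex must be 'm' or 'f'", call. = FALSE)

  wratio <- weight / REF_WEIGHT
  fratio <- if (flow_scaling == "allometric") wratio^0.75 else wratio
  volumes <- REF_VOLUMES * wratio
  co <- REF_CARDIAC_OUTPUT * fratio * age_factor(age, AGE_DECLINE_CO)
  flows <- REF_FLOW_FRACTIONS * co
  gfr <- REF_GFR * fratio * age_factor(age, AGE_DECLINE_GFR)

  structure(list(
    age = age, sex = sex, weight = weight, height = height,
    bmi = weight / (height / 100)^2,
    organ_volumes = volumes, blood_flows = flows,
    cardiac_output = co, gfr = gfr,
    hematocrit = REF_HEMATOCRIT[[sex]],
    enzyme_abundance = stats::setNames(rep(1, length(KNOWN_ENZYMES)),
                                       KNOWN_ENZYMES),
    kcat_multipliers = NULL, renal_multipliers = NULL,
    flow_scaling = flow_scaling), class = "individual")
}

#' @export
print.individual <- function(x, ...) {
  cat(sprintf("<individual> %s, %g y, %g kg, %g cm (BMI %.2f), GFR %.1f mL/min\n",
              x$sex, x$age, x$weight, x$height, x$bmi, x$gfr))
  invisible(x)
}

#' Define a virtual population
#'
#' @param n number of individuals (>= 1).
#' @param age_range,weight_range,height_range `(min, max)` sampling limits.
#' @param fraction_female fraction of females in [0, 1].
#' @param seed integer seed; identical seeds reproduce the population.
#' @param median_anchor optional `individual` (or demographics list) always
#'   included as subject 1, so the simulation of the published median
#'   individual is reproducible.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n, age_range, weight_range, height_range,
                            fraction_female = 0.5, seed = 1L,
                            median_anchor = NULL) {
  stopifnot(n >= 1, length(age_range) == 2, age_range[1] <= age_range[2],
            weight_range[1] <= weight_range[2],
            height_range[1] <= height_range[2],
            fraction_female >= 0, fraction_female <= 1)
  structure(list(n = as.integer(n), age_range = age_range,
                 weight_range = weight_range, height_range = height_range,
                 fraction_female = fraction_female, seed = as.integer(seed),
                 median_anchor = median_anchor), class = "population_spec")
}

#' Age-stratum population specifications used in the interaction study
#'
#' Demographic medians and ranges of the two age strata of the monitored
#' patient collective: young (median 50 y, ranges 20-63 y, 52-140 kg,
#' 152-193 cm, 58.0\% female) and elderly (median 69 y, ranges 65-78 y,
#' 65-112 kg, 160-181 cm, 53.8\% female).
#'
#' @param stratum `"young"` or `"elderly"`.
#' @param n population size.
#' @param seed integer seed.
#' @return a `population_spec` with the stratum median as anchor.
#' @export
stratum_population_spec <- function(stratum = c("young", "elderly"),
                                    n = 100, seed = 1L) {
  stratum <- match.arg(stratum)
  if (stratum == "young") {
    population_spec(n, c(20, 63), c(52, 140), c(152, 193),
                    fraction_female = 0.58, seed = seed,
                    median_anchor = list(age = 50, sex = "f", weight = 90,
                                         height = 171))
  } else {
    population_spec(n, c(65, 78), c(65, 112), c(160, 181),
                    fraction_female = 0.538, seed = seed,
                    median_anchor = list(age = 69, sex = "f", weight = 78,
                                         height = 166))
  }
}

#' Sample a virtual population
#'
#' Draws `n` individuals with demographics uniform within the specified
#' ranges.  The number of females equals `round(n * fraction_female)`.  If a
#' median anchor is given it becomes subject 1.  When a registry is
#' supplied, per-individual kinetic variability is attached: lognormal
#' multipliers on each process turnover with CV equal to the reported
#' relative SD of its maximal velocity, and renal-clearance multipliers
#' (lognormal for SD-type spreads, uniform within range-type spreads).
#'
#' @param spec a `population_spec`.
#' @param registry optional `system_registry` enabling kinetic variability.
#' @return list of `individual` objects.
#' @export
sample_population <- function(spec, registry = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n
  rng_state <- set_local_seed(spec$seed)
  on.exit(restore_seed(rng_state))

  n_f <- round(n * spec$fraction_female)
  ages <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  weights <- stats::runif(n, spec$weight_range[1], spec$weight_range[2])
  heights <- stats::runif(n, spec$height_range[1], spec$height_range[2])

  if (!is.null(spec$median_anchor)) {
    a <- spec$median_anchor
    ages[1] <- a$age; weights[1] <- a$weight; heights[1] <- a$height
    # the anchor's sex counts toward the female quota so the sampled
    # fraction stays exactly round(n * fraction_female)
    rest_f <- max(0, min(n - 1L, n_f - as.integer(a$sex == "f")))
    sexes <- c(a$sex, sample(c(rep("f", rest_f),
                               rep("m", n - 1L - rest_f))))
  } else {
    sexes <- sample(c(rep("f", n_f), rep("m", n - n_f)))
  }

  pop <- vector("list", n)
  for (i in seq_len(n)) {
    ind <- reference_individual(age = ages[i], sex = sexes[i],
                                weight = weights[i], height = heights[i])
    ind$id <- i
    if (!is.null(registry)) {
      km <- numeric(length(registry$processes))
      for (k in seq_along(registry$processes)) {
        p <- registry$processes[[k]]
        cv <- if (!is.na(p$vmax_sd) && !is.na(p$vmax_reported) &&
                  p$vmax_reported > 0) p$vmax_sd / p$vmax_reported else 0
        km[k] <- if (cv > 0) stats::rlnorm(1, -0.5 * log(1 + cv^2),
                                           sqrt(log(1 + cv^2))) else 1
      }
      ind$kcat_multipliers <- km
      rm_ <- vapply(registry$renal, function(r) {
        if (!is.na(r$sd) && r$value > 0) {
          cv <- r$sd / r$value
          stats::rlnorm(1, -0.5 * log(1 + cv^2), sqrt(log(1 + cv^2)))
        } else if (!is.na(r$min) && !is.na(r$max) && r$value > 0) {
          stats::runif(1, r$min, r$max) / r$value
        } else 1
      }, numeric(1))
      ind$renal_multipliers <- rm_
    }
    pop[[i]] <- ind
  }
  pop
}

# run expressions under a local, restorable RNG state
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Tabulate a population as a data frame
#'
#' One row per individual: id, demographics, GFR and cardiac output;
#' suitable for CSV export.
#'
#' @param population list of `individual` objects.
#' @return a data.frame.
#' @export
population_table <- function(population) {
  do.call(rbind, lapply(population, function(ind)
    data.frame(id = ind$id %||% NA_integer_, age = ind$age, sex = ind$sex,
               weight = ind$weight, height = ind$height, bmi = ind$bmi,
               gfr = ind$gfr, cardiac_output = ind$cardiac_output)))
}
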