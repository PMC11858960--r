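# Drug-system registry: compound, formulation, process, inhibition and renal
# clearance parameters, assembled from a JSON configuration.

KNOWN_ENZYMES <- c("CYP2D6", "CYP2C9", "CYP2C19", "CYP3A4", "CYP2B6",
                   "HSD11B1", "UGT1A1", "UGT2B7", "UGT1A9")
PARTITION_METHODS <- c("berezhkovskiy", "schmitt", "rodgers_rowland",
                       "charge_dependent_schmitt")

stop_field <- function(field, msg) {
  stop(sprintf("invalid registry field '%s': %s", field, msg), call. = FALSE)
}

#' Construct a compound specification
#'
#' Holds the physicochemistry and plasma binding of one drug or metabolite:
#' molecular weight, lipophilicity, ionization, unbound fraction, aqueous
#' solubility (only needed for orally dosed compounds) and the tissue
#' partition-coefficient method used for it.
#'
#' @param name compound identifier.
#' @param mr molecular weight, g/mol.
#' @param logp octanol/water log partition coefficient.
#' @param pka_entries list of `list(value =, kind =)` with kind `"base"` or
#'   `"acid"`; may be empty for neutral species.
#' @param fu_plasma unbound fraction in plasma, in (0, 1].
#' @param solubility aqueous solubility at pH 7, mg/mL, or `NA` for
#'   metabolites that are never dosed orally.
#' @param partition_method one of `"berezhkovskiy"`, `"schmitt"`,
#'   `"rodgers_rowland"`, `"charge_dependent_schmitt"`.
#' @param blood_plasma_ratio blood:plasma concentration ratio (default 1).
#' @param cell_permeability optional tag recording a permeability model
#'   choice (e.g. `"charge_dependent_schmitt"`); informational only.
#' @return an object of class `compound_spec`.
#' @export
compound_spec <- function(name, mr, logp, pka_entries = list(), fu_plasma,
                          solubility = NA_real_,
                          partition_method = "berezhkovskiy",
                          blood_plasma_ratio = 1,
                          cell_permeability = NULL) {
  if (!is.character(name) || nchar(name) == 0L) stop_field("name", "empty")
  if (!is.numeric(mr) || mr <= 0) stop_field("mr", "must be > 0")
  if (!is.numeric(fu_plasma) || fu_plasma <= 0 || fu_plasma > 1)
    stop_field("fu_plasma", "must be in (0, 1]")
  if (!is.na(solubility) && solubility <= 0)
    stop_field("solubility", "must be > 0 when present")
  if (!partition_method %in% PARTITION_METHODS)
    stop_field("partition_method",
               paste("must be one of", paste(PARTITION_METHODS, collapse = ", ")))
  for (p in pka_entries) {
    if (!is.list(p) || is.null(p$value) || is.null(p$kind) ||
        !p$kind %in% c("base", "acid"))
      stop_field("pka_entries", "each entry needs value and kind base/acid")
  }
  structure(list(name = name, mr = mr, logp = logp,
                 pka_entries = pka_entries, fu_plasma = fu_plasma,
                 solubility = solubility,
                 partition_method = partition_method,
                 blood_plasma_ratio = blood_plasma_ratio,
                 cell_permeability = cell_permeability),
            class = "compound_spec")
}

#' Construct an extended-release formulation specification
#'
#' Parameters of the Weibull dissolution profile of an oral
#' extended-release formulation.
#'
#' @param t_diss50 time to 50\% dissolution, min.
#' @param t_lag lag time before dissolution starts, min.
#' @param shape_b Weibull shape parameter (dimensionless).
#' @return an object of class `formulation_spec`.
#' @export
formulation_spec <- function(t_diss50, t_lag = 0, shape_b) {
  if (!is.numeric(t_diss50) || t_diss50 <= 0) stop_field("t_diss50", "must be > 0")
  if (!is.numeric(t_lag) || t_lag < 0) stop_field("t_lag", "must be >= 0")
  if (!is.numeric(shape_b) || shape_b <= 0) stop_field("shape_b", "must be > 0")
  structure(list(t_diss50 = t_diss50, t_lag = t_lag, shape_b = shape_b),
            class = "formulation_spec")
}

#' Construct an enzymatic process specification
#'
#' One hepatic elimination or metabolite-formation step.  Kinetics are
#' either saturable (`kcat` per enzyme amount with Michaelis constant `km`)
#' or linear (`clint`, first-order in the unbound liver concentration);
#' exactly one form must be given.  `kcat = 0` encodes a poor-metabolizer
#' process.
#'
#' @param enzyme enzyme identifier (e.g. `"CYP2D6"`).
#' @param substrate,product compound names; product `"SINK"` marks
#'   elimination to undefined metabolites.
#' @param kcat turnover number, 1/min (with `km`).
#' @param km Michaelis constant, uM.
#' @param clint intrinsic clearance, 1/min (alternative to kcat/km).
#' @param kcat_by_phenotype optional named list of kcat values per CYP2D6
#'   phenotype (`nd`, `em`, `pm`).
#' @param vmax_reported,vmax_unit,vmax_sd,km_sd literature maximal velocity
#'   with its unit tag and spreads; kept for provenance and relative
#'   inter-individual variability, not used directly by the engine.
#' @return an object of class `process_spec`.
#' @export
process_spec <- function(enzyme, substrate, product, kcat = NULL, km = NULL,
                         clint = NULL, kcat_by_phenotype = NULL,
                         vmax_reported = NA_real_, vmax_unit = NA_character_,
                         vmax_sd = NA_real_, km_sd = NA_real_) {
  if (!enzyme %in% KNOWN_ENZYMES)
    stop_field("enzyme", paste("unknown enzyme", enzyme))
  has_mm <- !is.null(kcat) && !is.null(km)
  has_lin <- !is.null(clint)
  if (has_mm == has_lin)
    stop_field("kinetics", "exactly one of (kcat, km) or clint must be set")
  if (has_mm) {
    if (km <= 0) stop_field("km", "must be > 0")
    if (kcat < 0) stop_field("kcat", "must be >= 0")
  } else if (clint < 0) stop_field("clint", "must be >= 0")
  structure(list(enzyme = enzyme, substrate = substrate, product = product,
                 kcat = kcat, km = km, clint = clint,
                 kcat_by_phenotype = kcat_by_phenotype,
                 vmax_reported = vmax_reported, vmax_unit = vmax_unit,
                 vmax_sd = vmax_sd, km_sd = km_sd),
            class = "process_spec")
}

#' Construct a competitive inhibition specification
#'
#' @param inhibitor compound name.
#' @param enzyme inhibited enzyme.
#' @param ki competitive inhibition constant, uM.
#' @param mechanism only `"competitive"` is supported.
#' @return an object of class `inhibition_spec`.
#' @export
inhibition_spec <- function(inhibitor, enzyme, ki, mechanism = "competitive") {
  if (!enzyme %in% KNOWN_ENZYMES)
    stop_field("enzyme", paste("unknown enzyme", enzyme))
  if (!identical(mechanism, "competitive"))
    stop_field("mechanism", "only competitive inhibition is supported")
  if (!is.numeric(ki) || ki <= 0) stop_field("ki", "must be > 0")
  structure(list(inhibitor = inhibitor, enzyme = enzyme, ki = ki,
                 mechanism = mechanism),
            class = "inhibition_spec")
}

#' Construct a renal clearance specification
#'
#' Specific renal plasma clearance in L/h per kg body weight (the unit
#' contract is configurable through the registry `units` block), with a
#' spread given either as a standard deviation or as a (min, max) range.
#'
#' @param value central renal clearance value, L/h/kg.
#' @param sd standard deviation (alternative to range).
#' @param min,max range limits (alternative to sd).
#' @return an object of class `renal_spec`.
#' @export
renal_spec <- function(value, sd = NA_real_, min = NA_real_, max = NA_real_) {
  if (!is.numeric(value) || value < 0) stop_field("renal value", "must be >= 0")
  if (!is.na(min) && !is.na(max) && min > max)
    stop_field("renal range", "min must be <= max")
  structure(list(value = value, sd = sd, min = min, max = max),
            class = "renal_spec")
}

#' Load a drug-system registry from a configuration
#'
#' Reads and validates the full drug system: compounds, formulations,
#' enzymatic processes, competitive inhibition entries, renal clearances,
#' enzyme reference abundances and the CYP2D6 phenotype switch.  The shipped
#' default configuration (`venlafaxine_bupropion.json`) encodes the
#' six-compound venlafaxine/bupropion system: venlafaxine is O-demethylated
#' to O-desmethylvenlafaxine by CYP2D6/2C9/2C19 and cleared to undefined
#' metabolites by CYP3A4/2C9/2C19; bupropion forms hydroxybupropion (CYP2B6)
#' and threo-/erythrohydrobupropion (11beta-HSD1), all of which inhibit
#' CYP2D6 competitively.
#'
#' @param config_source path to a JSON file, or an already-parsed list with
#'   the same structure.  Defaults to the shipped system.
#' @param cyp2d6_phenotype optional override of the configured CYP2D6
#'   phenotype: `"nd"` (not determined), `"em"` (extensive metabolizer) or
#'   `"pm"` (poor metabolizer, turnover zero).
#' @return an object of class `system_registry`.
#' @export
load_registry <- function(config_source = default_config_path(),
                          cyp2d6_phenotype = NULL) {
  cfg <- if (is.character(config_source)) {
    jsonlite::read_json(config_source, simplifyVector = FALSE)
  } else if (is.list(config_source)) config_source else
    stop("config_source must be a file path or a list", call. = FALSE)

  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  compounds <- lapply(names(cfg$compounds), function(nm) {
    cc <- cfg$compounds[[nm]]
    compound_spec(name = nm, mr = num(cc$mr), logp = num(cc$logp),
                  pka_entries = lapply(cc$pka_entries, function(p)
                    list(value = num(p$value), kind = p$kind)),
                  fu_plasma = num(cc$fu_plasma),
                  solubility = num(cc$solubility),
                  partition_method = cc$partition_method,
                  blood_plasma_ratio = if (is.null(cc$blood_plasma_ratio)) 1
                                       else num(cc$blood_plasma_ratio),
                  cell_permeability = cc$cell_permeability)
  })
  names(compounds) <- names(cfg$compounds)

  formulations <- lapply(cfg$formulations, function(f)
    formulation_spec(t_diss50 = num(f$t_diss50),
                     t_lag = if (is.null(f$t_lag)) 0 else num(f$t_lag),
                     shape_b = num(f$shape_b)))

  processes <- lapply(cfg$processes, function(p)
    process_spec(enzyme = p$enzyme, substrate = p$substrate,
                 product = p$product,
                 kcat = if (is.null(p$kcat)) NULL else num(p$kcat),
                 km = if (is.null(p$km)) NULL else num(p$km),
                 clint = if (is.null(p$clint)) NULL else num(p$clint),
                 kcat_by_phenotype = if (is.null(p$kcat_by_phenotype)) NULL
                   else lapply(p$kcat_by_phenotype, as.numeric),
                 vmax_reported = num(p$vmax_reported),
                 vmax_unit = if (is.null(p$vmax_unit)) NA_character_
                             else p$vmax_unit,
                 vmax_sd = num(p$vmax_sd), km_sd = num(p$km_sd)))

  inhibitions <- lapply(cfg$inhibitions, function(i)
    inhibition_spec(inhibitor = i$inhibitor, enzyme = i$enzyme,
                    ki = num(i$ki),
                    mechanism = if (is.null(i$mechanism)) "competitive"
                                else i$mechanism))

  renal <- lapply(cfg$renal, function(r)
    renal_spec(value = num(r$value), sd = num(r$sd),
               min = num(r$min), max = num(r$max)))

  phen <- cyp2d6_phenotype %||% cfg$cyp2d6_phenotype %||% "nd"
  if (!phen %in% c("nd", "em", "pm"))
    stop_field("cyp2d6_phenotype", "must be nd, em or pm")

  abund <- lapply(cfg$enzyme_reference_abundance, as.numeric)

  reg <- structure(list(
    compounds = compounds, formulations = formulations,
    processes = processes, inhibitions = inhibitions, renal = renal,
    cyp2d6_phenotype = phen,
    enzyme_reference_abundance = abund,
    inhibitor_potency = if (is.null(cfg$inhibitor_potency)) 1
                        else num(cfg$inhibitor_potency),
    units = cfg$units), class = "system_registry")
  validate_registry(reg)
  reg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to the shipped default drug-system configuration
#' @return file path of the packaged JSON configuration.
#' @export
default_config_path <- function() {
  system.file("extdata", "venlafaxine_bupropion.json", package = "venbupddi",
              mustWork = TRUE)
}

validate_registry <- function(reg) {
  cn <- names(reg$compounds)
  for (p in reg$processes) {
    if (!p$substrate %in% cn)
      stop_field("process substrate", paste("dangling reference", p$substrate))
    if (!identical(p$product, "SINK") && !p$product %in% cn)
      stop_field("process product", paste("dangling reference", p$product))
  }
  for (i in reg$inhibitions)
    if (!i$inhibitor %in% cn)
      stop_field("inhibitor", paste("dangling reference", i$inhibitor))
  for (nm in names(reg$renal))
    if (!nm %in% cn)
      stop_field("renal", paste("dangling reference", nm))
  for (nm in names(reg$formulations))
    if (!nm %in% cn)
      stop_field("formulation", paste("dangling reference", nm))
  invisible(reg)
}

#' CYP2D6 turnover number by phenotype for venlafaxine O-demethylation
#'
#' Returns the configured catalytic rate constant of the CYP2D6-mediated
#' venlafaxine to O-desmethylvenlafaxine process for a phenotype:
#' 29.16 1/min when the phenotype is not determined (the value used for
#' populations of unknown genotype), 64.8 1/min for extensive metabolizers
#' and 0 for poor metabolizers (no CYP2D6 capacity).
#'
#' @param phenotype `"nd"`, `"em"` or `"pm"`.
#' @param registry registry supplying the phenotype table (default: shipped
#'   system).
#' @return turnover number, 1/min.
#' @export
phenotype_kcat <- function(phenotype, registry = NULL) {
  if (!is.character(phenotype) || !phenotype %in% c("nd", "em", "pm"))
    stop("unknown CYP2D6 phenotype: ", phenotype, call. = FALSE)
  if (is.null(registry)) registry <- default_registry_cached()
  for (p in registry$processes) {
    if (!is.null(p$kcat_by_phenotype))
      return(as.numeric(p$kcat_by_phenotype[[phenotype]]))
  }
  stop("registry has no phenotype-dependent process", call. = FALSE)
}

the_registry_cache <- new.env(parent = emptyenv())
default_registry_cached <- function() {
  if (is.null(the_registry_cache$reg))
    the_registry_cache$reg <- load_registry()
  the_registry_cache$reg
}

#' Effective turnover of a process under the registry phenotype
#' @noRd
effective_kcat <- function(process, phenotype) {
  if (!is.null(process$kcat_by_phenotype))
    as.numeric(process$kcat_by_phenotype[[phenotype]])
  else process$kcat
}

#' Write a registry back to a JSON configuration
#'
#' Serializes all numeric fields without rounding, so that
#' `load_registry(write_registry(reg, f))` round-trips bit-exactly.
#'
#' @param registry a `system_registry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, function(v) is.null(v) ||
                (length(v) == 1L && is.atomic(v) && is.na(v)), logical(1))]
  }
  out <- list(
    units = registry$units,
    cyp2d6_phenotype = registry$cyp2d6_phenotype,
    compounds = lapply(registry$compounds, function(cc) {
      s <- strip(cc); s$name <- NULL; s
    }),
    formulations = lapply(registry$formulations, strip),
    processes = lapply(registry$processes, strip),
    inhibitions = lapply(registry$inhibitions, strip),
    renal = lapply(registry$renal, strip),
    enzyme_reference_abundance = registry$enzyme_reference_abundance,
    inhibitor_potency = registry$inhibitor_potency)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.system_registry <- function(x, ...) {
  cat("<system_registry>\n")
  cat("  compounds:   ", paste(names(x$compounds), collapse = ", "), "\n")
  cat("  processes:   ", length(x$processes), "enzymatic\n")
  cat("  inhibitions: ", length(x$inhibitions), "competitive\n")
  cat("  CYP2D6 phenotype:", x$cyp2d6_phenotype, "\n")
  invisible(x)
}

#' Add a generic strong CYP3A4 inhibitor to a registry
#'
#' Registers a seventh, user-parameterized compound acting as a competitive
#' CYP3A4 inhibitor, for what-if simulations of a triple interaction on top
#' of the venlafaxine/bupropion pair.  The defaults are placeholder,
#' literature-style values for an azole-like inhibitor; they are not
#' validated against any observed concentrations and results obtained with
#' them are qualitative what-if output only.
#'
#' @param registry a `system_registry`.
#' @param name compound name (default `"CYP3A4I"`).
#' @param mr,logp,fu_plasma,pka_value physicochemistry of the inhibitor.
#' @param ki competitive inhibition constant on CYP3A4, uM (unbound).
#' @param clint linear hepatic intrinsic clearance, 1/min.
#' @param renal renal clearance, L/h/kg.
#' @param t_diss50,shape_b Weibull dissolution parameters of its oral form.
#' @return the extended registry.
#' @export
add_cyp3a4_inhibitor <- function(registry, name = "CYP3A4I",
                                 mr = 705.64, logp = 4.0, fu_plasma = 0.02,
                                 pka_value = 3.7, ki = 0.02, clint = 0.05,
                                 renal = 0.001, t_diss50 = 120,
                                 shape_b = 1.2) {
  registry$compounds[[name]] <- compound_spec(
    name = name, mr = mr, logp = logp,
    pka_entries = list(list(value = pka_value, kind = "base")),
    fu_plasma = fu_plasma, solubility = 10,
    partition_method = "berezhkovskiy")
  registry$formulations[[name]] <- formulation_spec(
    t_diss50 = t_diss50, t_lag = 0, shape_b = shape_b)
  registry$processes[[length(registry$processes) + 1L]] <- process_spec(
    enzyme = "CYP3A4", substrate = name, product = "SINK", clint = clint)
  registry$inhibitions[[length(registry$inhibitions) + 1L]] <-
    inhibition_spec(inhibitor = name, enzyme = "CYP3A4", ki = ki)
  registry$renal[[name]] <- renal_spec(value = renal)
  validate_registry(registry)
  registry
}
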