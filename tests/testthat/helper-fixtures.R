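# Shared fixtures.  Expensive objects (the calibrated system) are cached in
# the package's session cache through calibrated_default_system().

`%||%` <- function(a, b) if (is.null(a)) b else a

fix_registry <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) reg <<- load_registry()
    reg
  }
})

fix_individual <- function() reference_individual()

# minimal single-compound registry without any elimination, for pure
# transport/conservation checks
bare_config <- function(clint = NULL, renal = NULL) {
  cfg <- list(
    compounds = list(X = list(
      mr = 250, logp = 2, pka_entries = list(list(value = 9, kind = "base")),
      fu_plasma = 0.5, solubility = 100,
      partition_method = "berezhkovskiy")),
    formulations = list(X = list(t_diss50 = 100, t_lag = 10, shape_b = 1.3)),
    processes = list(), inhibitions = list(), renal = list(),
    enzyme_reference_abundance = list(UGT1A1 = 1.0))
  if (!is.null(clint))
    cfg$processes <- list(list(enzyme = "UGT1A1", substrate = "X",
                               product = "SINK", clint = clint))
  if (!is.null(renal)) cfg$renal <- list(X = list(value = renal))
  cfg
}

unit_partitions <- function(registry) {
  organs <- setdiff(tissue_composition_table()$organ, "plasma")
  matrix(1, length(organs), length(registry$compounds),
         dimnames = list(organs, names(registry$compounds)))
}

mini_pop <- function(n = 3, seed = 11, registry = fix_registry()) {
  sample_population(stratum_population_spec("young", n = n, seed = seed),
                    registry)
}
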