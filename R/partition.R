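# Tissue:plasma partition coefficients from physicochemistry and tissue
# composition, by three published calculation families (Berezhkovskiy /
# Poulin-Theil, Schmitt, Rodgers & Rowland).  All methods are implemented in
# ratio form (tissue affinity over plasma affinity) so that a hypothetical
# pure-water tissue against pure-water plasma gives Kp = 1.

#' Reference tissue composition table
#'
#' Fractional tissue composition of the perfused organs and plasma: total
#' water, extracellular and intracellular water, neutral lipid, neutral
#' phospholipid and acidic phospholipid content (mg/g), compiled from
#' standard published reference tables for human tissues.
#'
#' @return data.frame with one row per organ plus a `plasma` row.
#' @export
tissue_composition_table <- function() {
  tab <- data.frame(
    organ = c("plasma", "lung", "gut_tissue", "liver", "kidney", "muscle",
              "skin", "fat", "bone", "rest"),
    f_water = c(0.945, 0.811, 0.718, 0.751, 0.783, 0.760, 0.718, 0.180,
                0.446, 0.750),
    f_ew    = c(0.945, 0.336, 0.282, 0.161, 0.273, 0.118, 0.382, 0.135,
                0.100, 0.250),
    f_iw    = c(0.000, 0.446, 0.475, 0.573, 0.483, 0.630, 0.291, 0.017,
                0.346, 0.500),
    f_nl    = c(0.0035, 0.0030, 0.0487, 0.0348, 0.0207, 0.0238, 0.0284,
                0.7920, 0.0174, 0.0400),
    f_ph    = c(0.00225, 0.0090, 0.0163, 0.0252, 0.0162, 0.0072, 0.0111,
                0.0020, 0.0011, 0.0100),
    ap      = c(0.04, 0.50, 2.41, 4.56, 5.03, 2.42, 1.32, 0.40, 0.67, 2.00))
  tab
}

pH_PLASMA <- 7.4
pH_IW <- 7.0

# fraction of the neutral microspecies at a given pH
neutral_fraction <- function(pka_entries, ph) {
  f <- 1
  for (p in pka_entries) {
    f <- f * if (p$kind == "base") 1 / (1 + 10^(p$value - ph))
             else 1 / (1 + 10^(ph - p$value))
  }
  f
}

# strongest basic pKa, or NA for compounds with no basic group
strongest_base_pka <- function(pka_entries) {
  v <- vapply(Filter(function(p) p$kind == "base", pka_entries),
              function(p) p$value, numeric(1))
  if (length(v)) max(v) else NA_real_
}

# tissue unbound fraction correction shared by the lipid-composition methods
fu_tissue <- function(fu) 1 / (1 + (1 - fu) / fu * 0.5)

kp_berezhkovskiy <- function(cmp, tis, pla) {
  # lipid partitioning of the neutral microspecies only: the effective
  # lipid affinity is the ionization-corrected distribution coefficient at
  # plasma pH (D = P * fn), not the intrinsic P of the neutral form
  D <- 10^cmp$logp * neutral_fraction(cmp$pka_entries, pH_PLASMA)
  lip <- function(r) D * (r$f_nl + 0.3 * r$f_ph) + (r$f_water + 0.7 * r$f_ph)
  lip(tis) / lip(pla) * cmp$fu_plasma / fu_tissue(cmp$fu_plasma)
}

kp_schmitt <- function(cmp, tis, pla) {
  P <- 10^cmp$logp
  # membrane affinity: neutral species partitions with P, charged species
  # with a 20-fold lower affinity; ionization taken at intracellular pH for
  # the tissue and plasma pH for plasma
  kmem <- function(ph) {
    fn <- neutral_fraction(cmp$pka_entries, ph)
    P * (fn + 0.05 * (1 - fn))
  }
  aff <- function(r, ph) r$f_water + kmem(ph) * (r$f_nl + r$f_ph)
  aff(tis, pH_IW) / aff(pla, pH_PLASMA) *
    cmp$fu_plasma / fu_tissue(cmp$fu_plasma)
}

kp_rodgers_rowland <- function(cmp, tis, pla) {
  P <- 10^cmp$logp
  pka <- strongest_base_pka(cmp$pka_entries)
  X <- if (is.na(pka)) 0 else 10^(pka - pH_IW)
  Y <- if (is.na(pka)) 0 else 10^(pka - pH_PLASMA)
  # association to acidic phospholipids, heuristic proportional to
  # lipophilicity (blood-cell binding data are not part of the inputs)
  ka_ap <- max(1, P) * 1e-3
  kpu <- tis$f_ew + (1 + X) / (1 + Y) * tis$f_iw +
    ka_ap * tis$ap * X / (1 + Y) +
    (P * tis$f_nl + (0.3 * P + 0.7) * tis$f_ph) / (1 + Y)
  kpu_pla <- pla$f_ew + pla$f_iw +
    (P * pla$f_nl + (0.3 * P + 0.7) * pla$f_ph) / (1 + Y)
  kpu / kpu_pla * cmp$fu_plasma
}

#' Tissue:plasma partition coefficients for one compound
#'
#' Computes the partition coefficient of every perfused organ from the
#' compound's lipophilicity, ionization and plasma binding together with a
#' tissue composition table, using the method named in the compound
#' specification.  `"charge_dependent_schmitt"` is accepted as a
#' permeability tag and computes coefficients with the Berezhkovskiy
#' composition method while recording the tag.
#'
#' @param compound a `compound_spec`.
#' @param tissue_table composition table (default:
#'   [tissue_composition_table()]); must contain a `plasma` row and one row
#'   per perfused organ.
#' @param method optional override of the compound's configured method.
#' @return named numeric vector of Kp values per organ, with the method
#'   recorded in attributes.
#' @export
partition_coefficients <- function(compound,
                                   tissue_table = tissue_composition_table(),
                                   method = NULL) {
  method <- method %||% compound$partition_method
  if (!method %in% PARTITION_METHODS)
    stop("unknown partition method: ", method, call. = FALSE)
  eff <- if (method == "charge_dependent_schmitt") "berezhkovskiy" else method
  pla <- tissue_table[tissue_table$organ == "plasma", ]
  if (nrow(pla) != 1L) stop("tissue table must contain a plasma row")
  organs <- setdiff(tissue_table$organ, "plasma")
  fn <- switch(eff, berezhkovskiy = kp_berezhkovskiy,
               schmitt = kp_schmitt, rodgers_rowland = kp_rodgers_rowland)
  kp <- vapply(organs, function(o)
    fn(compound, tissue_table[tissue_table$organ == o, ], pla), numeric(1))
  kp <- pmax(kp, 1e-6)
  attr(kp, "method") <- method
  attr(kp, "permeability_tag") <-
    if (method == "charge_dependent_schmitt" ||
        identical(compound$cell_permeability, "charge_dependent_schmitt"))
      "charge_dependent_schmitt" else "standard"
  kp
}

#' Partition coefficients for every compound in a registry
#'
#' @param registry a `system_registry`.
#' @param tissue_table composition table.
#' @return matrix organs x compounds of Kp values.
#' @export
partition_set <- function(registry,
                          tissue_table = tissue_composition_table()) {
  organs <- setdiff(tissue_table$organ, "plasma")
  out <- sapply(registry$compounds, function(cmp)
    as.numeric(partition_coefficients(cmp, tissue_table)))
  rownames(out) <- organs
  stopifnot(all(out > 0))
  out
}
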