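# Result serialization, run configuration and reproducibility manifests.

#' Tidy CSV export of a simulation result
#'
#' One row per (time, compound): venous plasma concentration in ng/mL.
#'
#' @param result a `simulation_result`.
#' @param path output CSV path.
#' @param compartments also write per-organ plasma concentrations (uM).
#' @return `path`, invisibly.
#' @export
write_simulation_csv <- function(result, path, compartments = FALSE) {
  cn <- colnames(result$conc)
  df <- do.call(rbind, lapply(cn, function(cmp)
    data.frame(time_h = result$time_h, compound = cmp,
               compartment = "venous_plasma",
               conc_ng_per_ml = result$conc[, cmp])))
  if (compartments) {
    for (cmp in cn) for (org in dimnames(result$organ_conc_um)[[2]]) {
      df <- rbind(df, data.frame(
        time_h = result$time_h, compound = cmp, compartment = org,
        conc_ng_per_ml = result$organ_conc_um[, org, cmp] *
          result$system$mr[[cmp]]))
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' JSON summary of a simulation result
#'
#' Last-day exposure metrics (AUC, Cmax, Cmin) per compound plus cumulative
#' urine fractions and mass-balance diagnostics.
#'
#' @param result a `simulation_result`.
#' @param path output JSON path.
#' @return the summary list, invisibly.
#' @export
write_simulation_summary <- function(result, path) {
  t_end <- max(result$time_h)
  w <- c(t_end - 24, t_end)
  per_compound <- lapply(colnames(result$conc), function(cmp) {
    n <- nca(result$time_h, result$conc[, cmp], w)
    list(auc_last_day_ng_h_ml = n$auc, cmax_ng_ml = n$cmax,
         cmin_ng_ml = n$cmin,
         urine_pct_of_dose = unname(result$urine_pct[cmp]))
  })
  names(per_compound) <- colnames(result$conc)
  out <- list(compounds = per_compound,
              mass_balance_rel_error = result$mass_balance_rel_error)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Export an interaction report as CSV and JSON
#'
#' @param report a `ddi_report`.
#' @param dir output directory (created if needed).
#' @param stem file name stem.
#' @return paths of the written files, invisibly.
#' @export
write_ddi_report <- function(report, dir, stem = report$protocol) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, "_exposure.csv"))
  utils::write.csv(report$table, csv, row.names = FALSE)
  js <- file.path(dir, paste0(stem, "_report.json"))
  jsonlite::write_json(
    list(protocol = report$protocol, seed = report$seed, n = report$n,
         changes = report$changes, table = report$table),
    js, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(csv = csv, json = js))
}

#' Reproducibility manifest of a run
#'
#' Records the configuration hash, seed and package version needed to
#' reproduce a run's outputs byte-identically.
#'
#' @param config_path path of the drug-system configuration used.
#' @param seed integer seed of the run.
#' @param extra optional named list merged into the manifest.
#' @return manifest list.
#' @export
run_manifest <- function(config_path = default_config_path(), seed,
                         extra = list()) {
  c(list(config = basename(config_path),
         config_md5 = unname(tools::md5sum(config_path)),
         seed = as.integer(seed),
         package_version =
           as.character(utils::packageVersion("venbupddi"))),
    extra)
}

#' Write a manifest next to run outputs
#'
#' @param manifest list from [run_manifest()].
#' @param dir output directory.
#' @return path, invisibly.
#' @export
write_manifest <- function(manifest, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
  invisible(p)
}
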