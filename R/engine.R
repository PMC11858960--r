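# Whole-body PBPK ODE system: assembly of the multi-compound flow-limited
# model and its numerical integration through a compiled right-hand side.
#
# Internal units: amounts umol, concentrations uM, time min, flows L/min.
# Doses are converted mg -> umol through the molecular weight at intake and
# reported concentrations converted back to ng/mL (uM * Mr = ng/mL).

ENGINE_ORGANS <- c("arterial_blood", "venous_blood", "lung", "gut_lumen",
                   "gut_tissue", "liver", "kidney", "muscle", "skin", "fat",
                   "bone", "rest")
ENGINE_TISSUES <- c("gut_tissue", "liver", "kidney", "muscle", "skin",
                    "fat", "bone", "rest")
# inhibition pools supported by the engine
INHIBITION_GROUPS <- c(CYP2D6 = 1, CYP3A4 = 2)

#' Michaelis-Menten rate under competitive inhibition
#'
#' Rate of one enzymatic process:
#' `v = kcat * e_amount * cu / (km * (1 + sum(iu/ki)) + cu)`, i.e.
#' competitive inhibitors scale the apparent Michaelis constant by
#' `1 + sum(iu/ki)`.
#'
#' @param cu unbound substrate concentration, uM.
#' @param kcat turnover number, 1/min.
#' @param e_amount enzyme amount, umol.
#' @param km Michaelis constant, uM.
#' @param inhibitors list of `c(iu =, ki =)` pairs (unbound inhibitor
#'   concentration and inhibition constant, both uM); may be empty.
#' @return reaction rate, umol/min.
#' @export
mm_inhibited_rate <- function(cu, kcat, e_amount, km, inhibitors = list()) {
  stopifnot(cu >= 0, kcat >= 0, e_amount >= 0, km > 0)
  s <- 0
  for (i in inhibitors) s <- s + i[["iu"]] / i[["ki"]]
  kcat * e_amount * cu / (km * (1 + s) + cu)
}

#' Assemble the whole-body ODE system
#'
#' Combines a validated drug-system registry, a virtual individual and a
#' tissue partition set into the flow-limited multi-compound mass-balance
#' system: every non-eliminating organ obeys
#' `V_i dC_i/dt = Q_i (C_art - C_i / Kp_i)`; the liver carries all
#' enzymatic sinks and metabolite sources (1:1 molar stoichiometry) with
#' unbound concentrations driving metabolism and inhibition; the kidney
#' clears unbound drug into a cumulative urine container; the gut receives
#' Weibull-dissolved drug from the lumen and drains into the portal
#' inflow of the liver.
#'
#' Enzyme amounts are `reference abundance (umol/L liver) * liver volume *
#' abundance scalar`; the scalars (and a single global inhibitor-potency
#' multiplier on all CYP2D6 1/Ki terms) are the calibration degrees of
#' freedom, see [calibrate()].
#'
#' @param registry a `system_registry`.
#' @param individual an `individual`.
#' @param partitions optional Kp matrix from [partition_set()].
#' @param ka_override optional named vector of absorption rate constants
#'   (1/min) by compound.
#' @return an object of class `pbpk_system`.
#' @export
assemble <- function(registry, individual, partitions = NULL,
                     ka_override = NULL) {
  stopifnot(inherits(registry, "system_registry"),
            inherits(individual, "individual"))
  if (is.null(partitions)) partitions <- partition_set(registry)
  cn <- names(registry$compounds)
  nc <- length(cn)

  V <- individual$organ_volumes[ENGINE_ORGANS]
  Q <- individual$blood_flows[ENGINE_TISSUES]
  CO <- individual$cardiac_output
  if (abs(sum(Q) - CO) > 1e-6 * CO)
    stop("flow balance violated: organ flows do not sum to cardiac output",
         call. = FALSE)

  Kp <- partitions[ENGINE_TISSUES, cn, drop = FALSE]
  fu <- vapply(registry$compounds, function(x) x$fu_plasma, numeric(1))
  mr <- vapply(registry$compounds, function(x) x$mr, numeric(1))
  ka <- vapply(registry$compounds, function(x)
    ka_from_properties(x$logp, x$mr), numeric(1))
  if (!is.null(ka_override))
    ka[names(ka_override)] <- ka_override
  # lumen solubility cap in uM (mg/mL -> uM: 1e6/Mr)
  sol <- vapply(registry$compounds, function(x)
    if (is.na(x$solubility)) -1 else x$solubility * 1e6 / x$mr, numeric(1))

  # renal clearance contract (configurable through the config units block):
  # default "L_h_kg" reads the value as specific renal plasma clearance in
  # L/h per kg body weight; the alternative "per_L_kidney_min" reads it as
  # clearance per liter kidney volume (1/min), CL = value * V_kidney.
  # Both are scaled by the individual's GFR relative to a same-weight
  # reference adult, with per-individual variability multipliers applied
  # when present.
  gfr_ref <- REF_GFR * (individual$weight / REF_WEIGHT)^0.75
  renal_unit <- registry$units$renal_clearance %||% "L_h_kg"
  clr <- numeric(nc); names(clr) <- cn
  for (nm in names(registry$renal)) {
    m <- 1
    if (!is.null(individual$renal_multipliers) &&
        nm %in% names(individual$renal_multipliers))
      m <- individual$renal_multipliers[[nm]]
    base <- if (identical(renal_unit, "per_L_kidney_min"))
      registry$renal[[nm]]$value * V[["kidney"]]
    else registry$renal[[nm]]$value * individual$weight / 60
    clr[nm] <- base * (individual$gfr / gfr_ref) * m
  }

  # processes -> engine table
  phen <- registry$cyp2d6_phenotype
  nproc <- length(registry$processes)
  ptab <- matrix(0, nproc, 5)
  vliv <- V[["liver"]]
  for (k in seq_len(nproc)) {
    p <- registry$processes[[k]]
    s <- match(p$substrate, cn)
    q <- if (identical(p$product, "SINK")) 0L else match(p$product, cn)
    # processes added after the population was sampled (e.g. an appended
    # perpetrator compound) default to a unit variability multiplier
    mult <- if (!is.null(individual$kcat_multipliers) &&
                k <= length(individual$kcat_multipliers))
      individual$kcat_multipliers[k] else 1
    ab <- individual$enzyme_abundance[[p$enzyme]] %||% 1
    ref <- registry$enzyme_reference_abundance[[p$enzyme]] %||% 0.1
    grp <- INHIBITION_GROUPS[p$enzyme]
    grp <- if (is.na(grp)) 0 else grp
    if (!is.null(p$clint)) {
      # linear: v = clint * Vliv * Cu, per unit reference abundance
      vmax <- p$clint * vliv * ref * ab * mult
      ptab[k, ] <- c(s, q, vmax, -1, 0)
    } else {
      e_amount <- ref * vliv * ab          # umol enzyme in liver
      vmax <- effective_kcat(p, phen) * e_amount * mult
      ptab[k, ] <- c(s, q, vmax, p$km, grp)
    }
  }

  # inhibition entries; the global potency multiplier scales all CYP2D6
  # 1/Ki terms identically, preserving the configured rank order
  itab <- if (length(registry$inhibitions))
    do.call(rbind, lapply(registry$inhibitions, function(i) {
      g <- INHIBITION_GROUPS[i$enzyme]
      ki_eff <- if (!is.na(g) && g == 1) i$ki / registry$inhibitor_potency
                else i$ki
      c(match(i$inhibitor, cn), ki_eff, ifelse(is.na(g), 0, g))
    }))
  else matrix(0, 0, 3)

  structure(list(
    registry = registry, individual = individual,
    compounds = cn, n_compounds = nc, mr = mr, fu = fu, ka = ka,
    solubility_um = sol, clr = clr, V = V, Q = Q, CO = CO, Kp = Kp,
    process_table = ptab, inhibition_table = itab),
    class = "pbpk_system")
}

#' @export
print.pbpk_system <- function(x, ...) {
  cat(sprintf("<pbpk_system> %d compounds x %d compartments, %d processes\n",
              x$n_compounds, length(ENGINE_ORGANS), nrow(x$process_table)))
  invisible(x)
}

# flatten system + doses into the packed parameter vector of the C code
pack_parameters <- function(system, dose_table) {
  nd <- nrow(dose_table)
  np <- nrow(system$process_table)
  ni <- nrow(system$inhibition_table)
  pv <- c(0, system$n_compounds, np, nd, ni, system$CO,
          system$V[["gut_lumen"]],
          as.numeric(system$V), as.numeric(system$Q),
          as.numeric(system$fu), as.numeric(system$ka),
          as.numeric(system$clr), as.numeric(system$solubility_um),
          as.numeric(system$Kp),
          as.numeric(t(system$process_table)),
          as.numeric(t(system$inhibition_table)),
          if (nd > 0) as.numeric(t(dose_table)) else numeric(0))
  pv[1] <- length(pv)
  pv
}

#' Integrate the PBPK system over a dosing history
#'
#' Runs the stiff-capable solver (lsoda) over the full protocol and returns
#' plasma concentration-time profiles at the venous sampling site (ng/mL
#' and uM), per-organ plasma concentrations, cumulative urine excretion and
#' solver/mass-balance diagnostics.  Oral doses enter through the Weibull
#' dissolution forcing; intravenous boluses are applied as instantaneous
#' additions to venous blood.
#'
#' @param system a `pbpk_system` from [assemble()].
#' @param regimens a `regimen`, a list of regimens, or a list of
#'   `dose_event`s.
#' @param t_end_h simulation end, h.
#' @param rtol,atol solver tolerances (defaults 1e-6, 1e-9 umol).
#' @param dt_out_h output grid spacing, h (default 0.25).
#' @return an object of class `simulation_result` with elements `time_h`,
#'   `conc` (ng/mL, time x compound), `conc_um`, `organ_conc_um` (time x
#'   organ x compound plasma concentrations), `urine_pct` (cumulative \% of
#'   administered dose in urine per compound), `mass_balance_rel_error`,
#'   `metabolized_umol`, `dosed_umol`.
#' @export
simulate_system <- function(system, regimens, t_end_h, rtol = 1e-6,
                            atol = 1e-9, dt_out_h = 0.25) {
  stopifnot(inherits(system, "pbpk_system"), t_end_h > 0)
  events <- flatten_regimens(regimens)
  cn <- system$compounds
  nc <- system$n_compounds
  np <- nrow(system$process_table)

  oral <- list(); iv <- list()
  for (e in events) {
    if (!e$compound %in% cn)
      stop("dose for unregistered compound: ", e$compound, call. = FALSE)
    if (identical(e$formulation, "iv_bolus")) iv <- c(iv, list(e))
    else oral <- c(oral, list(e))
  }
  amount_umol <- function(e) e$amount * 1000 / system$mr[[e$compound]]
  dose_table <- if (length(oral)) do.call(rbind, lapply(oral, function(e)
    c(match(e$compound, cn), amount_umol(e), e$time * 60,
      e$formulation$t_diss50, e$formulation$shape_b, e$formulation$t_lag)))
    else matrix(0, 0, 6)

  ny <- 12 * nc + nc + np
  y0 <- rep(0, ny)
  evdf <- NULL
  if (length(iv)) {
    ven_idx <- function(j) 12 * (j - 1) + 2
    evdf <- data.frame(
      var = vapply(iv, function(e) ven_idx(match(e$compound, cn)), numeric(1)),
      time = vapply(iv, function(e) e$time * 60, numeric(1)),
      value = vapply(iv, function(e) amount_umol(e), numeric(1)),
      method = "add")
    at0 <- evdf$time == 0
    if (any(at0)) {  # t = 0 boluses go into the initial state
      for (r in which(at0)) y0[evdf$var[r]] <- y0[evdf$var[r]] + evdf$value[r]
      evdf <- evdf[!at0, , drop = FALSE]
      if (nrow(evdf) == 0L) evdf <- NULL
    }
  }

  pv <- pack_parameters(system, dose_table)
  times <- seq(0, t_end_h * 60, by = dt_out_h * 60)
  dose_min <- if (nrow(dose_table)) dose_table[, 3] else numeric(0)
  times <- sort(unique(c(times, dose_min[dose_min <= t_end_h * 60])))

  .C("venbup_set_parms", as.integer(length(pv)), as.double(pv),
     PACKAGE = "venbupddi")
  out <- deSolve::lsoda(y0, times, func = "venbup_derivs", parms = NULL,
                        dllname = "venbupddi", rtol = rtol, atol = atol,
                        events = if (is.null(evdf)) NULL
                                 else list(data = evdf))
  diag <- attributes(out)
  if (anyNA(out))
    stop("ODE solver failure: NA in solution (istate = ",
         diag$istate[1], ")", call. = FALSE)

  tt <- out[, 1] / 60
  Y <- out[, -1, drop = FALSE]
  organ_conc <- array(0, dim = c(length(tt), 12, nc),
                      dimnames = list(NULL, ENGINE_ORGANS, cn))
  Vv <- as.numeric(system$V)
  for (j in seq_len(nc)) {
    block <- Y[, 12 * (j - 1) + (1:12), drop = FALSE]
    conc <- sweep(block, 2, Vv, "/")
    # tissues report emergent venous plasma concentration (amount/(V*Kp))
    conc[, 5:12] <- sweep(conc[, 5:12, drop = FALSE], 2,
                          system$Kp[, j], "/")
    # the solver can leave concentrations a rounding error below zero
    organ_conc[, , j] <- pmax(conc, 0)
  }
  conc_um <- organ_conc[, "venous_blood", , drop = TRUE]
  if (is.null(dim(conc_um))) conc_um <- matrix(conc_um, ncol = nc,
                                               dimnames = list(NULL, cn))
  conc_ngml <- sweep(conc_um, 2, system$mr, "*")

  dosed <- stats::setNames(numeric(nc), cn)
  for (e in events) dosed[e$compound] <- dosed[e$compound] + amount_umol(e)
  urine <- Y[, 12 * nc + (1:nc), drop = FALSE]
  colnames(urine) <- cn
  urine_pct <- 100 * urine[nrow(urine), ] / pmax(dosed, .Machine$double.eps)
  urine_pct[dosed == 0] <- 0

  # mass balance at the final time: everything administered must be in the
  # body, in urine, metabolized to sink, or still undissolved in the gut
  met <- Y[nrow(Y), 12 * nc + nc + seq_len(np)]
  sink_met <- sum(met[system$process_table[, 2] == 0])
  in_body <- sum(Y[nrow(Y), 1:(12 * nc)])
  undiss <- 0
  if (nrow(dose_table)) {
    tfin <- t_end_h * 60
    for (r in seq_len(nrow(dose_table))) {
      d <- dose_table[r, ]
      f <- formulation_spec(d[4], d[6], d[5])
      undiss <- undiss + d[2] * (1 - weibull_fraction(max(tfin - d[3], 0), f))
    }
  }
  tot_in <- sum(dosed)
  mb <- if (tot_in > 0)
    (in_body + sum(urine[nrow(urine), ]) + sink_met + undiss - tot_in) / tot_in
  else 0

  structure(list(
    time_h = tt, conc = conc_ngml, conc_um = conc_um,
    organ_conc_um = organ_conc, urine_pct = urine_pct,
    metabolized_umol = stats::setNames(met, NULL), dosed_umol = dosed,
    mass_balance_rel_error = mb,
    diagnostics = list(istate = diag$istate, rtol = rtol, atol = atol),
    system = system), class = "simulation_result")
}

flatten_regimens <- function(regimens) {
  if (inherits(regimens, "regimen")) return(unclass(regimens))
  if (inherits(regimens, "dose_event")) return(list(regimens))
  out <- list()
  for (r in regimens) {
    if (inherits(r, "regimen")) out <- c(out, unclass(r))
    else if (inherits(r, "dose_event")) out <- c(out, list(r))
    else stop("regimens must contain regimen or dose_event objects",
              call. = FALSE)
  }
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d time points, %d compounds, %.1f h\n",
              length(x$time_h), ncol(x$conc), max(x$time_h)))
  cat(sprintf("  mass balance rel. error: %.2e\n", x$mass_balance_rel_error))
  invisible(x)
}

#' Active-moiety concentration profile of a simulation
#'
#' Applies the flow-weighted active-moiety combination (see
#' [active_moiety()]) over the arterial, bone, fat, muscle and skin plasma
#' concentrations at every output time.
#'
#' @param result a `simulation_result`.
#' @param parent,metabolite compound names forming the active moiety.
#' @return numeric vector, ng/mL, same length as `result$time_h`.
#' @export
am_profile <- function(result, parent = "VEN", metabolite = "ODV") {
  sys <- result$system
  organs <- c("arterial_blood", "bone", "fat", "muscle", "skin")
  fq <- c(sys$CO, sys$Q[["bone"]], sys$Q[["fat"]], sys$Q[["muscle"]],
          sys$Q[["skin"]])
  cp <- result$organ_conc_um[, organs, parent]
  cm <- result$organ_conc_um[, organs, metabolite]
  mrp <- sys$mr[[parent]]; mrm <- sys$mr[[metabolite]]
  as.numeric(cp %*% fq / sum(fq) * mrp + cm %*% fq / sum(fq) * mrm)
}
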