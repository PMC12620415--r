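#' Right-heart-catheter record
#'
#' Bundles one patient's RHC measurements — the targets the Windkessel tuning
#' must reproduce. Pressures in mmHg, cardiac output in L/min, heart rate in
#' beats/min, PVR in Wood units (optional; recomputed from the pressure
#' gradient and CO when absent).
#'
#' @param mPAP,sPAP,dPAP Mean / systolic / diastolic pulmonary artery
#'   pressure, mmHg; must satisfy `dPAP <= mPAP <= sPAP`.
#' @param PAWP Pulmonary artery wedge pressure, mmHg; the downstream
#'   reference pressure of the pulmonary circuit.
#' @param CO Cardiac output, L/min (> 0).
#' @param HR Heart rate, beats/min (> 0).
#' @param RAP Right atrial pressure, mmHg. Carried for completeness; the 0D
#'   solver does not use it.
#' @param PVR Pulmonary vascular resistance, Wood units. Optional; when
#'   supplied it must agree with `(mPAP - PAWP)/CO` within 25% (guard against
#'   inconsistent records).
#'
#' @return A one-row tibble of class `rhc_record`.
#' @export
#' @examples
#' rhc_record(mPAP = 18, sPAP = 28, dPAP = 12, PAWP = 10, CO = 5.2, HR = 75)
rhc_record <- function(mPAP, sPAP = NA_real_, dPAP = NA_real_, PAWP,
                       CO, HR = 75, RAP = NA_real_, PVR = NA_real_) {
  if (!is.finite(mPAP) || !is.finite(PAWP) || !is.finite(CO) || !is.finite(HR)) {
    stop("mPAP, PAWP, CO and HR are required and must be finite", call. = FALSE)
  }
  if (CO <= 0) stop("CO must be positive", call. = FALSE)
  if (HR <= 0) stop("HR must be positive", call. = FALSE)
  if (is.finite(sPAP) && is.finite(dPAP) && !(dPAP <= mPAP && mPAP <= sPAP)) {
    stop("pressures must satisfy dPAP <= mPAP <= sPAP", call. = FALSE)
  }
  if (is.finite(PVR)) {
    derived <- (mPAP - PAWP) / CO
    if (abs(PVR - derived) / PVR >= 0.25) {
      stop(
        "supplied PVR (", PVR, " WU) inconsistent with (mPAP - PAWP)/CO (",
        round(derived, 2), " WU)",
        call. = FALSE
      )
    }
  }
  out <- tibble::tibble(
    mPAP = mPAP, sPAP = sPAP, dPAP = dPAP, PAWP = PAWP,
    RAP = RAP, CO = CO, HR = HR, PVR = PVR
  )
  class(out) <- c("rhc_record", class(out))
  out
}

#' Total pulmonary vascular resistance in CGS units
#'
#' Computes `(mPAP - PAWP)/CO` and converts to dyn.s/cm^5
#' (1 Wood unit = 80 dyn.s/cm^5).
#'
#' @param rhc An [rhc_record()] (or any one-row data frame with `mPAP`,
#'   `PAWP`, `CO` columns).
#' @return Total PVR in dyn.s/cm^5.
#' @export
#' @examples
#' total_pvr(rhc_record(mPAP = 21, sPAP = 30, dPAP = 15, PAWP = 11, CO = 5)) # 160
total_pvr <- function(rhc) {
  if (rhc$CO <= 0) stop("CO must be positive", call. = FALSE)
  if (rhc$PAWP >= rhc$mPAP) {
    stop("invalid record: PAWP must be below mPAP", call. = FALSE)
  }
  wu_to_cgs((rhc$mPAP - rhc$PAWP) / rhc$CO)
}

#' Distribute total resistance over outlets by a diameter power law
#'
#' Each outlet's resistance is inversely proportional to its diameter raised
#' to `exponent` (default 2.25, accounting for microcirculatory elements):
#' `R_i = R_total * sum_j(D_j^e) / D_i^e`. The parallel combination of the
#' returned resistances equals `R_total` exactly.
#'
#' @param outlet_diameters Positive diameters in cm, in outlet order.
#' @param R_total Total resistance to distribute, dyn.s/cm^5 (> 0).
#' @param exponent Diameter power-law exponent. `0` gives an equal split.
#' @return Vector of outlet resistances, dyn.s/cm^5.
#' @export
#' @examples
#' distribute_resistance(c(2, 1), 1) # parallel sum recombines to 1
distribute_resistance <- function(outlet_diameters, R_total, exponent = 2.25) {
  if (length(outlet_diameters) == 0) {
    stop("`outlet_diameters` must be non-empty", call. = FALSE)
  }
  if (any(outlet_diameters <= 0)) {
    stop("all outlet diameters must be positive", call. = FALSE)
  }
  if (!is.numeric(R_total) || R_total <= 0) {
    stop("`R_total` must be positive", call. = FALSE)
  }
  w <- outlet_diameters^exponent
  R_total * sum(w) / w
}

#' Distribute total compliance over outlets proportionally to diameter squared
#'
#' `C_i = C_total * D_i^2 / sum_j(D_j^2)`; the outlet compliances sum to
#' `C_total`.
#'
#' @param outlet_diameters Positive diameters in cm, in outlet order.
#' @param C_total Total compliance, cm^5/dyn (> 0).
#' @return Vector of outlet compliances, cm^5/dyn.
#' @export
#' @examples
#' distribute_compliance(c(2, 1), 5) # c(4, 1)
distribute_compliance <- function(outlet_diameters, C_total) {
  if (length(outlet_diameters) == 0) {
    stop("`outlet_diameters` must be non-empty", call. = FALSE)
  }
  if (any(outlet_diameters <= 0)) {
    stop("all outlet diameters must be positive", call. = FALSE)
  }
  if (!is.numeric(C_total) || C_total <= 0) {
    stop("`C_total` must be positive", call. = FALSE)
  }
  w <- outlet_diameters^2
  C_total * w / sum(w)
}

#' Assemble a three-element Windkessel parameter set
#'
#' Splits each outlet's total resistance into a proximal part `Rp` (fraction
#' `rp_fraction`) and a distal part `Rd`, pairs it with the outlet compliance,
#' and records the distal reference pressure behind every `Rd`.
#'
#' @param R_i,C_i Outlet resistance and compliance vectors, aligned with
#'   [outlets()] ordering.
#' @param outlet_ids Outlet segment ids, same order.
#' @param rp_fraction Proximal share of the outlet resistance, in [0, 1).
#'   Default 0.1, a common impedance-matching heuristic.
#' @param distal_pressure Distal reference pressure, mmHg (stored in CGS).
#'
#' @return A tibble of class `rcr_set` with columns `outlet_id, Rp, C, Rd`
#'   (CGS units) and attribute `distal_pressure` (dyn/cm^2).
#' @export
assemble_rcr <- function(R_i, C_i, outlet_ids = paste0("o", seq_along(R_i)),
                         rp_fraction = 0.1, distal_pressure = 0) {
  if (length(R_i) != length(C_i) || length(R_i) != length(outlet_ids)) {
    stop("R_i, C_i and outlet_ids must have equal lengths", call. = FALSE)
  }
  if (!is.numeric(rp_fraction) || rp_fraction < 0 || rp_fraction >= 1) {
    stop("`rp_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (any(R_i <= 0) || any(C_i <= 0)) {
    stop("resistances and compliances must be positive", call. = FALSE)
  }
  out <- tibble::tibble(
    outlet_id = as.character(outlet_ids),
    Rp = rp_fraction * R_i,
    C = C_i,
    Rd = (1 - rp_fraction) * R_i
  )
  attr(out, "distal_pressure") <- mmhg_to_cgs(distal_pressure)
  class(out) <- c("rcr_set", class(out))
  out
}

#' Read and write Windkessel parameter sets
#'
#' Tabular text, one row per outlet `{outlet_id, Rp, C, Rd}`, CGS units, with
#' `#`-prefixed header comments recording the distal pressure and (when
#' produced by [tune_rcr()]) the tuning targets and convergence.
#'
#' @param rcr An `rcr_set` (see [assemble_rcr()]).
#' @param path File path.
#' @param comments Extra `#` header lines to record (character vector).
#' @return `read_rcr()` returns an `rcr_set`; `write_rcr()` returns `path`
#'   invisibly.
#' @export
write_rcr <- function(rcr, path, comments = character(0)) {
  header <- c(
    paste0("# distal_pressure_dyn_cm2: ", format(attr(rcr, "distal_pressure"), digits = 17)),
    if (length(comments)) paste0("# ", comments)
  )
  writeLines(header, path)
  readr::write_csv(tibble::as_tibble(unclass(rcr)), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_rcr
#' @export
read_rcr <- function(path) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  pd_line <- grep("^# distal_pressure_dyn_cm2:", header, value = TRUE)
  if (length(pd_line) != 1) {
    stop("RCR file missing `distal_pressure_dyn_cm2` header", call. = FALSE)
  }
  pd <- as.numeric(sub("^# distal_pressure_dyn_cm2:\\s*", "", pd_line))
  df <- readr::read_csv(I(lines[!grepl("^#", lines)]),
    col_types = readr::cols(
      outlet_id = readr::col_character(),
      Rp = readr::col_double(),
      C = readr::col_double(),
      Rd = readr::col_double()
    )
  )
  attr(df, "distal_pressure") <- pd
  class(df) <- c("rcr_set", class(df))
  df
}

#' Tune Windkessel parameters to right-heart-catheter targets
#'
#' Iteratively adjusts the total outlet resistance and compliance until the
#' simulated mean pulmonary artery pressure and pulse pressure match the
#' patient's RHC record. Resistance is apportioned over outlets by the
#' inverse-diameter power law ([distribute_resistance()]), compliance
#' proportionally to diameter squared ([distribute_compliance()]); cardiac
#' output is matched by construction because the inflow waveform is imposed.
#'
#' Between solves, the total resistance is rescaled by
#' `(mPAP_target - PAWP)/(mPAP_sim - PAWP)` and the total compliance by
#' `pulse_pressure_sim / pulse_pressure_target` — a damped fixed-point
#' iteration (the map is nearly linear in both scale factors; the damping
#' factor starts at 1 and is halved whenever an update overshoots and
#' reverses sign).
#'
#' Initial guesses: `R_total` from [total_pvr()]; `C_total` = stroke volume /
#' pulse pressure; when sPAP/dPAP are missing, `C_total` is set so the RC
#' time constant is 0.5 s and only mPAP is tuned.
#'
#' @param tree An [arterial_tree].
#' @param rhc An [rhc_record()].
#' @param blood A [blood_model()].
#' @param tolerance Relative tolerance on each target. Default 0.02.
#' @param max_iterations Maximum tuning iterations. Default 20.
#' @param rp_fraction Proximal resistance share; see [assemble_rcr()].
#' @param exponent Resistance distribution exponent. Default 2.25.
#' @param systolic_fraction,n_samples Inflow waveform shape parameters; see
#'   [make_inflow()].
#' @param solver Named list of [solve_hemodynamics()] control options
#'   (`dt`, `min_cycles`, `max_cycles`, `periodicity_tol`).
#'
#' @return A list of class `rcr_tuning` with elements `rcr` (the tuned
#'   `rcr_set`), `report` (a one-row tibble: `iterations`, `achieved_mPAP`,
#'   `achieved_pulse_pressure` (mmHg), `rel_err_mPAP`,
#'   `rel_err_pulse_pressure`, `converged`) and `solution` (the final
#'   [solve_hemodynamics()] result).
#' @export
tune_rcr <- function(tree, rhc, blood = blood_model(),
                     tolerance = 0.02, max_iterations = 20,
                     rp_fraction = 0.1, exponent = 2.25,
                     systolic_fraction = 0.35, n_samples = 1000,
                     solver = list()) {
  leaf <- outlets(tree)
  inflow <- make_inflow(rhc$CO, rhc$HR,
    systolic_fraction = systolic_fraction,
    n_samples = n_samples
  )
  mPAP_t <- rhc$mPAP
  pp_t <- if (is.finite(rhc$sPAP) && is.finite(rhc$dPAP)) rhc$sPAP - rhc$dPAP else NA_real_
  tune_pp <- is.finite(pp_t) && pp_t > 0

  R_total <- total_pvr(rhc)
  if (tune_pp) {
    stroke_volume <- lmin_to_cgs(rhc$CO) * (60 / rhc$HR) # cm^3 per beat
    C_total <- stroke_volume / mmhg_to_cgs(pp_t)
  } else {
    C_total <- 0.5 / R_total # RC time constant 0.5 s
  }

  damp_R <- 1
  damp_C <- 1
  prev_fR <- NA_real_
  prev_fC <- NA_real_
  rcr <- NULL
  sol <- NULL
  achieved <- c(mPAP = NA_real_, pp = NA_real_)
  converged <- FALSE
  iter <- 0

  for (iter in seq_len(max_iterations)) {
    R_i <- distribute_resistance(leaf$diameter_cm, R_total, exponent)
    C_i <- distribute_compliance(leaf$diameter_cm, C_total)
    rcr <- assemble_rcr(R_i, C_i,
      outlet_ids = leaf$id,
      rp_fraction = rp_fraction, distal_pressure = rhc$PAWP
    )
    sol <- do.call(
      solve_hemodynamics,
      c(list(tree = tree, rcr = rcr, inflow = inflow, blood = blood), solver)
    )
    press <- summarize_pressures(sol)
    achieved <- c(mPAP = press$mPAP, pp = press$sPAP - press$dPAP)

    err_m <- abs(achieved[["mPAP"]] - mPAP_t) / mPAP_t
    err_p <- if (tune_pp) abs(achieved[["pp"]] - pp_t) / pp_t else 0
    if (err_m <= tolerance && err_p <= tolerance) {
      converged <- TRUE
      break
    }

    fR <- (mPAP_t - rhc$PAWP) / (achieved[["mPAP"]] - rhc$PAWP)
    if (!is.finite(fR) || fR <= 0) {
      stop("tuning update unstable: simulated mPAP at or below PAWP", call. = FALSE)
    }
    if (is.finite(prev_fR) && sign(log(fR)) * sign(log(prev_fR)) < 0) {
      damp_R <- damp_R / 2
    }
    prev_fR <- fR
    R_total <- R_total * fR^damp_R

    if (tune_pp) {
      fC <- achieved[["pp"]] / pp_t
      if (!is.finite(fC) || fC <= 0) {
        stop("tuning update unstable: non-positive simulated pulse pressure", call. = FALSE)
      }
      if (is.finite(prev_fC) && sign(log(fC)) * sign(log(prev_fC)) < 0) {
        damp_C <- damp_C / 2
      }
      prev_fC <- fC
      C_total <- C_total * fC^damp_C
    }
  }

  report <- tibble::tibble(
    iterations = iter,
    achieved_mPAP = achieved[["mPAP"]],
    achieved_pulse_pressure = achieved[["pp"]],
    rel_err_mPAP = abs(achieved[["mPAP"]] - mPAP_t) / mPAP_t,
    rel_err_pulse_pressure = if (tune_pp) abs(achieved[["pp"]] - pp_t) / pp_t else NA_real_,
    converged = converged
  )
  structure(list(rcr = rcr, report = report, solution = sol), class = "rcr_tuning")
}
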