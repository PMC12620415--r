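#' Wall shear stress waveform from a flow waveform
#'
#' Quasi-steady Poiseuille wall shear stress, `tau(t) = 4 mu Q(t) / (pi r^3)`
#' (viscosity in poise, radius in cm), signed with the flow. The signed 1D
#' shear stands in for the 3D wall shear stress vector; its absolute value is
#' the magnitude.
#'
#' @param flow Flow samples, cm^3/s (may be negative during backflow).
#' @param diameter Lumen diameter, cm (> 0).
#' @param blood A [blood_model()].
#' @return Shear stress samples, dyn/cm^2.
#' @export
#' @examples
#' wss_waveform(83.333, 2.3, blood_model()) # ~2.44 dyn/cm^2
wss_waveform <- function(flow, diameter, blood = blood_model()) {
  if (any(diameter <= 0)) stop("`diameter` must be positive", call. = FALSE)
  r <- diameter / 2
  4 * blood$viscosity_poise * flow / (pi * r^3)
}

#' Time-averaged wall shear stress
#'
#' Cycle average of the shear magnitude, `(1/T) integral |tau| dt`, computed
#' by the trapezoidal rule on the periodic extension — for a uniform
#' half-open grid this is the arithmetic mean of `|tau|`.
#'
#' @param tau Signed shear samples over exactly one period (uniform grid).
#' @param period Cycle period, s (kept for interface symmetry; the uniform
#'   periodic average does not depend on it).
#' @return TAWSS, dyn/cm^2 (non-negative).
#' @export
tawss <- function(tau, period = NULL) {
  if (length(tau) == 0) stop("`tau` must be non-empty", call. = FALSE)
  mean(abs(tau))
}

#' Oscillatory shear index
#'
#' `OSI = 0.5 (1 - |integral tau dt| / integral |tau| dt)`, in [0, 0.5]:
#' 0 for unidirectional shear, 0.5 for fully oscillatory zero-mean shear.
#' The degenerate no-flow case (`integral |tau| = 0`) returns 0.
#'
#' @inheritParams tawss
#' @return OSI, dimensionless in [0, 0.5].
#' @export
osi <- function(tau, period = NULL) {
  if (length(tau) == 0) stop("`tau` must be non-empty", call. = FALSE)
  denom <- mean(abs(tau))
  if (denom == 0) {
    return(0)
  }
  0.5 * (1 - abs(mean(tau)) / denom)
}

#' Per-segment shear metrics from a hemodynamic solution
#'
#' Computes the Poiseuille shear waveform for every segment of the solved
#' tree and summarizes it as TAWSS and OSI over the final cycle.
#'
#' @param solution A `hemo_solution` from [solve_hemodynamics()].
#' @param tree The [arterial_tree] that was solved (supplies diameters).
#' @param blood A [blood_model()].
#' @return A tibble with columns `segment_id`, `TAWSS`, `OSI`.
#' @export
compute_shear <- function(solution, tree, blood = blood_model()) {
  d <- tree$diameter_cm[match(solution$segment_ids, tree$id)]
  if (any(is.na(d))) stop("solution segments not found in tree", call. = FALSE)
  purrr::map_dfr(seq_along(solution$segment_ids), function(i) {
    tau <- wss_waveform(solution$flow[i, ], d[i], blood)
    tibble::tibble(
      segment_id = solution$segment_ids[i],
      TAWSS = tawss(tau, solution$period),
      OSI = osi(tau, solution$period)
    )
  })
}

#' Aggregate segment shear metrics to one proximal value per patient
#'
#' Luminal-surface-area-weighted mean of TAWSS and OSI over the proximal
#' scope segments (weight = pi * diameter * length per segment). The default
#' scope {MPA, LPA, RPA} matches the proximal pulmonary arteries the
#' biomarker is defined on.
#'
#' @param records Per-segment metrics from [compute_shear()].
#' @param tree The [arterial_tree] (supplies names and dimensions).
#' @param scope Character vector of segment names to aggregate over.
#' @return A one-row tibble with `TAWSS_proximal`, `OSI_proximal`.
#' @export
aggregate_proximal <- function(records, tree, scope = c("MPA", "LPA", "RPA")) {
  seg <- tree[tree$name %in% scope, ]
  seg <- dplyr::inner_join(
    tibble::as_tibble(seg)[, c("id", "diameter_cm", "length_cm")],
    records,
    by = c(id = "segment_id")
  )
  if (nrow(seg) == 0) {
    stop("no segments of the tree match the aggregation scope", call. = FALSE)
  }
  w <- pi * seg$diameter_cm * seg$length_cm
  tibble::tibble(
    TAWSS_proximal = sum(w * seg$TAWSS) / sum(w),
    OSI_proximal = sum(w * seg$OSI) / sum(w)
  )
}
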