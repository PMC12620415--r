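#' Construct a flow waveform
#'
#' A flow waveform is a tibble with columns `time_s` (uniform half-open grid
#' over one period, starting at 0) and `flow_cm3_s`, plus a `period`
#' attribute. The grid mean of `flow_cm3_s` is the imposed cardiac output.
#'
#' @param times Uniform, strictly increasing time grid over `[0, period)`, s.
#' @param flow Flow samples, cm^3/s.
#' @param period Cycle period, s.
#' @return A tibble of class `flow_waveform`.
#' @export
flow_waveform <- function(times, flow, period) {
  if (length(times) != length(flow) || length(times) < 2) {
    stop("`times` and `flow` must have equal length >= 2", call. = FALSE)
  }
  dt <- diff(times)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9 * dt[1]) {
    stop("`times` must be strictly increasing and uniformly spaced", call. = FALSE)
  }
  if (abs(times[1]) > 1e-12 || times[length(times)] >= period) {
    stop("`times` must cover the half-open interval [0, period)", call. = FALSE)
  }
  out <- tibble::tibble(time_s = times, flow_cm3_s = flow)
  attr(out, "period") <- period
  class(out) <- c("flow_waveform", class(out))
  out
}

#' Pulsatile inflow waveform from cardiac output and heart rate
#'
#' Builds the imposed root inflow: a half-sine systolic ejection followed by
#' zero diastolic flow, `Q(t) = Q_peak sin(pi t / T_s)` for `t < T_s` with
#' `T_s = systolic_fraction * T`, and `Q_peak = CO_cgs * pi * T / (2 T_s)` so
#' the cycle mean equals the cardiac output. The sampled waveform is rescaled
#' so its grid mean equals the cardiac output exactly.
#'
#' @param CO Cardiac output, L/min (> 0).
#' @param HR Heart rate, beats/min (> 0); the period is `60/HR` s.
#' @param systolic_fraction Fraction of the cycle in systole, in (0, 1).
#'   Default 0.35.
#' @param n_samples Samples per cycle. Default 1000.
#' @return A [flow_waveform()].
#' @export
#' @examples
#' wf <- make_inflow(5, 60)
#' mean(wf$flow_cm3_s) * 60 / 16.6667 / 60 # back to ~5 L/min
make_inflow <- function(CO, HR, systolic_fraction = 0.35, n_samples = 1000) {
  if (!is.numeric(CO) || CO <= 0) stop("`CO` must be positive", call. = FALSE)
  if (!is.numeric(HR) || HR <= 0) stop("`HR` must be positive", call. = FALSE)
  if (!is.numeric(systolic_fraction) || systolic_fraction <= 0 || systolic_fraction >= 1) {
    stop("`systolic_fraction` must be in (0, 1)", call. = FALSE)
  }
  period <- 60 / HR
  t_sys <- systolic_fraction * period
  co_cgs <- lmin_to_cgs(CO)
  q_peak <- co_cgs * pi * period / (2 * t_sys)
  times <- seq(0, period, length.out = n_samples + 1)[1:n_samples]
  flow <- ifelse(times < t_sys, q_peak * sin(pi * times / t_sys), 0)
  flow <- flow * co_cgs / mean(flow) # exact grid-mean cardiac output
  flow_waveform(times, flow, period)
}

#' Poiseuille resistance of a vessel segment
#'
#' `R = 8 mu L / (pi r^4)` with the viscosity in poise, length and radius in
#' cm — the fully developed laminar-flow resistance standing in for the 3D
#' viscous pressure loss of the segment.
#'
#' @param blood A [blood_model()].
#' @param length Segment length, cm (>= 0; 0 gives a zero-resistance stub).
#' @param diameter Lumen diameter, cm (> 0).
#' @return Resistance in dyn.s/cm^5.
#' @export
#' @examples
#' segment_resistance(blood_model(), length = 5, diameter = 2) # 1.4/pi
segment_resistance <- function(blood, length, diameter) {
  if (any(diameter <= 0)) stop("`diameter` must be positive", call. = FALSE)
  if (any(length < 0)) stop("`length` must be non-negative", call. = FALSE)
  r <- diameter / 2
  8 * blood$viscosity_poise * length / (pi * r^4)
}

# Affine reduction of the resistive tree.
#
# With fixed segment and proximal-outlet resistances, every nodal pressure
# and segment flow is affine in (Q_in, P_c): upward Thevenin collapse gives
# the root input impedance and source weights; the downward pass yields, for
# each segment, flow = alpha * Q_in + beta . P_c and inlet pressure =
# a * Q_in + b . P_c (pressures relative to the capacitor vector P_c).
network_maps <- function(tree, rcr, blood) {
  leaf_ids <- outlets(tree)$id
  if (!setequal(leaf_ids, rcr$outlet_id)) {
    stop("RCR set must cover exactly the tree outlets", call. = FALSE)
  }
  n_out <- length(leaf_ids)
  ids <- tree$id
  n_seg <- length(ids)
  idx <- stats::setNames(seq_len(n_seg), ids)
  rseg <- segment_resistance(blood, tree$length_cm, tree$diameter_cm)
  rp <- rcr$Rp[match(leaf_ids, rcr$outlet_id)]

  children_of <- split(tree$id, tree$parent_id)
  req <- numeric(n_seg)
  W <- matrix(0, n_seg, n_out)
  up <- function(id) {
    i <- idx[[id]]
    kids <- children_of[[id]]
    if (is.null(kids)) {
      k <- match(id, leaf_ids)
      req[i] <<- rseg[i] + rp[k]
      W[i, k] <<- 1
    } else {
      for (k in kids) up(k)
      g <- 1 / req[idx[kids]]
      rpar <- 1 / sum(g)
      wpar <- colSums(W[idx[kids], , drop = FALSE] * g) * rpar
      req[i] <<- rseg[i] + rpar
      W[i, ] <<- wpar
    }
    invisible(NULL)
  }
  root <- root_id(tree)
  up(root)

  alpha <- numeric(n_seg)
  beta <- matrix(0, n_seg, n_out)
  a_in <- numeric(n_seg)
  b_in <- matrix(0, n_seg, n_out)
  down <- function(id, a_node, b_node) {
    # (a_node, b_node): pressure at this segment's inlet node
    i <- idx[[id]]
    a_in[i] <<- a_node
    b_in[i, ] <<- b_node
    a_out <- a_node - alpha[i] * rseg[i]
    b_out <- b_node - beta[i, ] * rseg[i]
    kids <- children_of[[id]]
    if (!is.null(kids)) {
      for (k in kids) {
        j <- idx[[k]]
        alpha[j] <<- a_out / req[j]
        beta[j, ] <<- (b_out - W[j, ]) / req[j]
        down(k, a_out, b_out)
      }
    }
    invisible(NULL)
  }
  ir <- idx[[root]]
  alpha[ir] <- 1
  down(root, req[ir], W[ir, ])

  leaf_rows <- idx[leaf_ids]
  list(
    ids = ids, root = root, leaf_ids = leaf_ids,
    req_root = req[ir], w_root = W[ir, ],
    alpha = alpha, beta = beta, a_in = a_in, b_in = b_in,
    S = alpha[leaf_rows], M = beta[leaf_rows, , drop = FALSE]
  )
}

#' Solve pulsatile 0D hemodynamics on an arterial tree
#'
#' Solves the lumped-parameter circulation: a tree of Poiseuille segment
#' resistances driven by an imposed root inflow, terminated at every outlet
#' by a three-element Windkessel (proximal resistance in series with a
#' compliance/distal-resistance pair referenced to the distal pressure). At
#' each time step the resistive network is solved exactly for the current
#' capacitor pressures (the network is linear, so the nodal solve is a
#' precomputed affine map), and each capacitor is advanced by implicit Euler:
#' `dP_c/dt = (Q_outlet - (P_c - P_distal)/Rd) / C`.
#'
#' Cycles are repeated until the cycle-mean root pressure changes by less
#' than `periodicity_tol` (relative) between consecutive cycles, with at
#' least `min_cycles` cycles run; the returned waveforms are the final cycle.
#'
#' @param tree An [arterial_tree].
#' @param rcr An `rcr_set` covering exactly the tree outlets.
#' @param inflow A [flow_waveform()] (imposed root inflow).
#' @param blood A [blood_model()].
#' @param dt Time step, s. Default 1e-3.
#' @param min_cycles Minimum cardiac cycles (default 6).
#' @param max_cycles Maximum cycles before giving up on periodicity (20).
#' @param periodicity_tol Relative cycle-to-cycle change in mean root
#'   pressure accepted as periodic (default 0.005).
#'
#' @return A list of class `hemo_solution`: `times` (s, final cycle),
#'   `segment_ids`, `pressure` and `flow` matrices (segments x time, dyn/cm^2
#'   and cm^3/s; pressures at each segment's inlet node),
#'   `capacitor_pressure` (outlets x time), `outlet_ids`, `root_id`,
#'   `cycles_run`, `periodicity_error`, `converged`, `period`, `dt`.
#' @export
solve_hemodynamics <- function(tree, rcr, inflow, blood = blood_model(),
                               dt = 1e-3, min_cycles = 6, max_cycles = 20,
                               periodicity_tol = 0.005) {
  maps <- network_maps(tree, rcr, blood)
  period <- attr(inflow, "period")
  nt <- max(2L, round(period / dt))
  dt_eff <- period / nt
  ord <- match(maps$leaf_ids, rcr$outlet_id)
  Cv <- rcr$C[ord]
  Rd <- rcr$Rd[ord]
  if (any(!is.finite(Cv)) || any(Cv <= 0) || any(!is.finite(Rd)) || any(Rd <= 0)) {
    stop("solver instability: non-positive outlet C or Rd", call. = FALSE)
  }
  pd <- attr(rcr, "distal_pressure")
  if (is.null(pd) || !is.finite(pd)) pd <- 0

  # periodic interpolation of the imposed inflow onto the solver grid
  wf_t <- c(inflow$time_s, period)
  wf_q <- c(inflow$flow_cm3_s, inflow$flow_cm3_s[1])
  t_grid <- (seq_len(nt) * dt_eff) %% period
  q_grid <- stats::approx(wf_t, wf_q, xout = t_grid, rule = 2)$y

  n_out <- length(Cv)
  lhs <- diag(Cv / dt_eff + 1 / Rd, n_out) - maps$M
  lhs_inv <- solve(lhs)
  cdt <- Cv / dt_eff
  pdrd <- pd / Rd

  pc <- rep(pd, n_out)
  pc_mat <- matrix(0, n_out, nt)
  prev_mean <- NA_real_
  per_err <- NA_real_
  cycles <- 0L
  converged <- FALSE
  while (cycles < max_cycles) {
    cycles <- cycles + 1L
    for (k in seq_len(nt)) {
      pc <- drop(lhs_inv %*% (cdt * pc + maps$S * q_grid[k] + pdrd))
      pc_mat[, k] <- pc
    }
    if (any(!is.finite(pc))) {
      stop("solver instability: non-finite capacitor state in cycle ", cycles,
        call. = FALSE
      )
    }
    root_mean <- maps$req_root * mean(q_grid) + sum(maps$w_root * rowMeans(pc_mat))
    if (!is.na(prev_mean)) {
      per_err <- abs(root_mean - prev_mean) / max(abs(root_mean), .Machine$double.eps)
      if (cycles >= min_cycles && per_err < periodicity_tol) {
        converged <- TRUE
        break
      }
    }
    prev_mean <- root_mean
  }

  pressure <- outer(maps$a_in, q_grid) + maps$b_in %*% pc_mat
  flow <- outer(maps$alpha, q_grid) + maps$beta %*% pc_mat
  rownames(pressure) <- rownames(flow) <- maps$ids
  rownames(pc_mat) <- maps$leaf_ids

  structure(
    list(
      times = seq_len(nt) * dt_eff,
      segment_ids = maps$ids,
      pressure = pressure,
      flow = flow,
      capacitor_pressure = pc_mat,
      outlet_ids = maps$leaf_ids,
      root_id = maps$root,
      cycles_run = cycles,
      periodicity_error = per_err,
      converged = converged,
      period = period,
      dt = dt_eff
    ),
    class = "hemo_solution"
  )
}

#' Summarize root pulmonary artery pressures
#'
#' Systolic, diastolic and mean pressure of the root (MPA inlet) waveform on
#' the final cycle, converted to mmHg. The mean is the uniform-grid periodic
#' trapezoidal average.
#'
#' @param solution A `hemo_solution` from [solve_hemodynamics()].
#' @return A one-row tibble with `sPAP`, `dPAP`, `mPAP` (mmHg).
#' @export
summarize_pressures <- function(solution) {
  p <- solution$pressure[solution$root_id, ]
  tibble::tibble(
    sPAP = cgs_to_mmhg(max(p)),
    dPAP = cgs_to_mmhg(min(p)),
    mPAP = cgs_to_mmhg(mean(p))
  )
}

#' Tidy a hemodynamic solution into a long table
#'
#' @param x A `hemo_solution`.
#' @param ... Unused.
#' @return A tibble with columns `segment_id`, `time_s`, `pressure_dyn_cm2`,
#'   `flow_cm3_s` (final converged cycle).
#' @method tidy hemo_solution
#' @export
tidy.hemo_solution <- function(x, ...) {
  tibble::tibble(
    segment_id = rep(x$segment_ids, each = length(x$times)),
    time_s = rep(x$times, times = length(x$segment_ids)),
    pressure_dyn_cm2 = as.vector(t(x$pressure)),
    flow_cm3_s = as.vector(t(x$flow))
  )
}

#' @method glance hemo_solution
#' @export
glance.hemo_solution <- function(x, ...) {
  dplyr::bind_cols(
    summarize_pressures(x),
    tibble::tibble(
      cycles_run = x$cycles_run,
      periodicity_error = x$periodicity_error,
      converged = x$converged
    )
  )
}

#' Export a hemodynamic solution as tabular text
#'
#' Writes the long-format final-cycle waveforms with a `#` metadata block
#' recording cycles run, the periodicity error and the solver configuration.
#'
#' @param solution A `hemo_solution`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_solution <- function(solution, path) {
  meta <- c(
    paste0("# cycles_run: ", solution$cycles_run),
    paste0("# periodicity_error: ", format(solution$periodicity_error, digits = 6)),
    paste0("# converged: ", solution$converged),
    paste0("# period_s: ", format(solution$period, digits = 10)),
    paste0("# dt_s: ", format(solution$dt, digits = 10))
  )
  writeLines(meta, path)
  readr::write_csv(tidy.hemo_solution(solution), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Plot a hemodynamic solution
#'
#' Pressure (mmHg) and flow (cm^3/s) waveforms of the final cycle, one facet
#' per quantity, coloured by segment.
#'
#' @param object A `hemo_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hemo_solution
#' @export
autoplot.hemo_solution <- function(object, ...) {
  long <- tidy.hemo_solution(object)
  long <- dplyr::mutate(long, pressure_mmHg = cgs_to_mmhg(.data$pressure_dyn_cm2))
  long <- tidyr::pivot_longer(
    long[, c("segment_id", "time_s", "pressure_mmHg", "flow_cm3_s")],
    cols = c("pressure_mmHg", "flow_cm3_s"),
    names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value, colour = .data$segment_id)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL, colour = "segment") +
    ggplot2::theme_minimal()
}
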