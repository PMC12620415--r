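#' Calibrated study-group summaries
#'
#' Published group-level summaries (median, Q1, Q3) the synthetic cohort
#' generator is calibrated to: right-heart-catheter hemodynamics, MPA
#' diameter, proximal TAWSS and the V/Q mismatch score for the three study
#' groups — CTEPH (chronic thromboembolic pulmonary hypertension), CTEPD
#' (chronic thromboembolic disease with V/Q mismatch but no pulmonary
#' hypertension) and controls (no mismatch). Controls have no mismatch score.
#'
#' @return A named list (`CTEPH`, `CTEPD`, `CONTROL`); each element is a list
#'   of `c(median, q1, q3)` triplets: `tawss` (dyn/cm^2), `mpa_mm` (mm),
#'   `mismatch` (dimensionless, `NULL` for controls) and the RHC fields
#'   `sPAP`, `dPAP`, `mPAP`, `PAWP`, `RAP` (mmHg), `CO` (L/min), `PVR` (WU).
#' @export
group_summaries <- function() {
  list(
    CTEPH = list(
      tawss = c(16.5, 13.31, 20.44),
      mpa_mm = c(30.50, 26.75, 34.50),
      mismatch = c(0.40, 0.30, 0.40),
      sPAP = c(63.00, 54.50, 79.25),
      dPAP = c(17.00, 15.75, 25.25),
      mPAP = c(38.00, 29.75, 41.25),
      PAWP = c(9.00, 6.00, 11.00),
      RAP = c(6.00, 4.00, 9.00),
      CO = c(5.15, 4.56, 5.46),
      PVR = c(5.50, 4.35, 7.53)
    ),
    CTEPD = list(
      tawss = c(27.5, 24.00, 34.00),
      mpa_mm = c(25.00, 24.00, 27.75),
      mismatch = c(0.30, 0.21, 0.35),
      sPAP = c(25.55, 21.45, 28.35),
      dPAP = c(10.80, 7.55, 13.23),
      mPAP = c(15.57, 14.25, 16.91),
      PAWP = c(8.50, 7.00, 9.75),
      RAP = c(5.00, 2.50, 7.00),
      CO = c(5.67, 4.85, 6.55),
      PVR = c(1.38, 1.05, 1.51)
    ),
    CONTROL = list(
      tawss = c(42.0, 34.00, 48.50),
      mpa_mm = c(23.00, 21.00, 25.50),
      mismatch = NULL,
      sPAP = c(28.00, 28.00, 30.50),
      dPAP = c(12.00, 12.00, 14.00),
      mPAP = c(18.00, 17.33, 18.84),
      PAWP = c(10.00, 8.50, 10.00),
      RAP = c(9.00, 7.00, 13.00),
      CO = c(5.20, 4.70, 5.50),
      PVR = c(1.82, 1.42, 1.92)
    )
  )
}

#' Fit a lognormal distribution to a median and quartiles
#'
#' Quantile matching for positive, right-skewed clinical summaries reported
#' as median (IQR): `mu = ln(median)` and `sigma` is the average of the two
#' one-sided log-quartile distances divided by the standard normal 75th
#' percentile (0.6744898).
#'
#' @param median,q1,q3 Printed summary values with `0 < q1 <= median <= q3`.
#' @return Named vector `c(mu, sigma)` of log-scale parameters.
#' @export
#' @examples
#' fit_lognormal_quartiles(16.5, 13.31, 20.44)
fit_lognormal_quartiles <- function(median, q1, q3) {
  if (!(q1 > 0 && q1 <= median && median <= q3)) {
    stop("quartiles must satisfy 0 < q1 <= median <= q3", call. = FALSE)
  }
  z75 <- stats::qnorm(0.75)
  c(
    mu = log(median),
    sigma = mean(c(log(median / q1), log(q3 / median))) / z75
  )
}

#' Sample patient-level TAWSS for one study group
#'
#' Draws from the lognormal fitted to the group's printed TAWSS median and
#' quartiles; deterministic for a fixed seed.
#'
#' @param summary One element of [group_summaries()] (or any list with a
#'   `tawss = c(median, q1, q3)` entry).
#' @param n Number of patients (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of TAWSS draws, dyn/cm^2.
#' @export
sample_group_tawss <- function(summary, n, seed = 1L) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  par <- fit_lognormal_quartiles(summary$tawss[1], summary$tawss[2], summary$tawss[3])
  withr::with_seed(as.integer(seed), stats::rlnorm(n, par[["mu"]], par[["sigma"]]))
}

#' Sample right-heart-catheter records for one study group
#'
#' Each pressure/output field follows a lognormal quantile-matched to the
#' group's printed median and quartiles. Within a patient, the pressure
#' fields are coupled through a shared standard-normal severity factor
#' (loadings: 0.85 on sPAP/dPAP/mPAP, 0.7 on PAWP, 0 elsewhere) so that a
#' patient's systolic, diastolic, mean and wedge pressures rise and fall
#' together, as they do physiologically; the marginal distribution of every
#' field is unchanged by the coupling. Records are then post-adjusted to
#' full coherence: the (dPAP, mPAP, sPAP) triple is sorted, PAWP is capped
#' at 70% of mPAP, and PVR is recomputed as `(mPAP - PAWP)/CO`. Heart rate,
#' never printed, is uniform on [60, 90] beats/min.
#'
#' @inheritParams sample_group_tawss
#' @return A tibble with columns `mPAP, sPAP, dPAP, PAWP, RAP, CO, HR, PVR`.
#' @export
sample_group_rhc <- function(summary, n, seed = 1L) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    z_sev <- stats::rnorm(n)
    draw <- function(tri, loading = 0) {
      par <- fit_lognormal_quartiles(tri[1], tri[2], tri[3])
      z <- loading * z_sev + sqrt(1 - loading^2) * stats::rnorm(n)
      exp(par[["mu"]] + par[["sigma"]] * z)
    }
    sp <- draw(summary$sPAP, 0.85)
    dp <- draw(summary$dPAP, 0.85)
    mp <- draw(summary$mPAP, 0.85)
    pw <- draw(summary$PAWP, 0.7)
    ra <- draw(summary$RAP)
    co <- draw(summary$CO)
    hr <- stats::runif(n, 60, 90)
    tri <- cbind(dp, mp, sp)
    tri <- t(apply(tri, 1, sort))
    dp <- tri[, 1]
    mp <- tri[, 2]
    sp <- tri[, 3]
    pw <- pmin(pw, 0.7 * mp)
    tibble::tibble(
      mPAP = mp, sPAP = sp, dPAP = dp, PAWP = pw, RAP = ra,
      CO = co, HR = hr, PVR = (mp - pw) / co
    )
  })
}

#' Classify a hemodynamic record against the CTEPH criteria
#'
#' The CTEPH hemodynamic definition: mPAP > 20 mmHg, PVR > 2 Wood units and
#' PAWP < 15 mmHg, all strict. Boundary values are non-CTEPH-range.
#'
#' @param rhc A data frame with columns `mPAP`, `PVR`, `PAWP` (one row per
#'   record; vectorized).
#' @return Character vector, `"CTEPH-range"` or `"non-CTEPH-range"`.
#' @export
#' @examples
#' classify_patient(data.frame(mPAP = 38, PVR = 5.5, PAWP = 9))
classify_patient <- function(rhc) {
  ifelse(rhc$mPAP > 20 & rhc$PVR > 2 & rhc$PAWP < 15,
    "CTEPH-range", "non-CTEPH-range"
  )
}

#' Generate a synthetic three-group study cohort
#'
#' Builds the statistical substrate of the study: `sizes` patients in the
#' CTEPH, CTEPD and control groups, with group-calibrated hemodynamics, MPA
#' diameter, proximal TAWSS and OSI, and V/Q mismatch labels (CTEPH and
#' CTEPD are mismatch-positive; controls are not).
#'
#' Two modes:
#' * `"statistical"` — TAWSS is sampled directly from the lognormal fitted
#'   to each group's printed summary; OSI from a common narrow Beta
#'   distribution on [0, 0.5] with no group effect. This mode carries the
#'   quantitative calibration.
#' * `"mechanistic"` — each patient gets a Murray tree remodeled to their
#'   sampled MPA diameter (with seeded outlet occlusion for the disease
#'   groups), Windkessel parameters tuned to their sampled RHC record, a 0D
#'   solve, and area-weighted proximal TAWSS/OSI from the solved waveforms.
#'   Patients whose tuning fails to converge are dropped with a logged count.
#'
#' @param mode `"statistical"` or `"mechanistic"`.
#' @param sizes Integer vector of group sizes (CTEPH, CTEPD, CONTROL).
#'   Default `c(30, 30, 30)`, the study design.
#' @param seed Integer master seed; all per-group and per-patient seeds
#'   derive from it.
#' @param summaries Calibration summaries, default [group_summaries()].
#' @param osi_shape Beta shape parameters `c(a, b)` for the OSI generator
#'   (`OSI = 0.5 * Beta(a, b)`), identical across groups. Default `c(2, 8)`.
#' @param occlusion_fraction Named occlusion fractions per group for
#'   mechanistic mode. Default `c(CTEPH = 0.375, CTEPD = 0.25, CONTROL = 0)`.
#' @param n_generations Tree generations for mechanistic mode. Default 3.
#' @param solver,tuning Named lists of [solve_hemodynamics()] /
#'   [tune_rcr()] control options for mechanistic mode.
#'
#' @return A tibble of class `cohort_tbl` with columns `patient_id, group,
#'   mismatch_positive, mismatch_score, mPAP, sPAP, dPAP, PAWP, RAP, CO, HR,
#'   PVR, mpa_diameter_mm, TAWSS, OSI, mode, seed`; attributes `mode`,
#'   `seed`, and (mechanistic) `n_tuning_failures` plus a `tuning_reports`
#'   tibble with one row per attempted patient.
#' @export
generate_cohort <- function(mode = c("statistical", "mechanistic"),
                            sizes = c(30, 30, 30), seed = 1L,
                            summaries = group_summaries(),
                            osi_shape = c(2, 8),
                            occlusion_fraction = c(CTEPH = 0.375, CTEPD = 0.25, CONTROL = 0),
                            n_generations = 3,
                            solver = list(), tuning = list()) {
  mode <- match.arg(mode)
  groups <- c("CTEPH", "CTEPD", "CONTROL")
  if (length(sizes) != 3 || any(sizes < 1)) {
    stop("`sizes` must give three positive group sizes", call. = FALSE)
  }
  if (!all(groups %in% names(summaries))) {
    stop("`summaries` must contain CTEPH, CTEPD and CONTROL", call. = FALSE)
  }
  seed <- as.integer(seed)

  per_group <- purrr::map2(groups, sizes, function(g, n) {
    gseed <- seed * 7L + match(g, groups)
    s <- summaries[[g]]
    rhc <- sample_group_rhc(s, n, seed = gseed)
    mpa_mm <- withr::with_seed(gseed + 101L, {
      par <- fit_lognormal_quartiles(s$mpa_mm[1], s$mpa_mm[2], s$mpa_mm[3])
      stats::rlnorm(n, par[["mu"]], par[["sigma"]])
    })
    osi_draw <- withr::with_seed(
      gseed + 202L,
      0.5 * stats::rbeta(n, osi_shape[1], osi_shape[2])
    )
    score <- if (is.null(s$mismatch)) {
      rep(NA_real_, n)
    } else {
      withr::with_seed(gseed + 303L, {
        par <- fit_lognormal_quartiles(s$mismatch[1], s$mismatch[2], s$mismatch[3])
        stats::rlnorm(n, par[["mu"]], par[["sigma"]])
      })
    }
    dplyr::bind_cols(
      tibble::tibble(
        group = g,
        mismatch_positive = g != "CONTROL",
        mismatch_score = score
      ),
      rhc,
      tibble::tibble(mpa_diameter_mm = mpa_mm, OSI = osi_draw)
    )
  })
  cohort <- dplyr::bind_rows(per_group)
  cohort$patient_id <- sprintf("P%03d", seq_len(nrow(cohort)))

  n_fail <- 0L
  if (mode == "statistical") {
    tawss_by_group <- purrr::map2(groups, sizes, function(g, n) {
      sample_group_tawss(summaries[[g]], n, seed = seed * 7L + match(g, groups) + 404L)
    })
    cohort$TAWSS <- unlist(tawss_by_group)
  } else {
    blood <- blood_model()
    reports <- vector("list", nrow(cohort))
    results <- purrr::map(seq_len(nrow(cohort)), function(i) {
      row <- cohort[i, ]
      pseed <- seed * 1009L + i
      base <- generate_tree(3.0, n_generations = n_generations, seed = pseed)
      tree <- apply_disease_remodeling(
        base, row$group,
        mpa_diameter = row$mpa_diameter_mm / 10,
        occlusion_fraction = occlusion_fraction[[row$group]],
        seed = pseed
      )
      rhc <- rhc_record(
        mPAP = row$mPAP, sPAP = row$sPAP, dPAP = row$dPAP,
        PAWP = row$PAWP, CO = row$CO, HR = row$HR, RAP = row$RAP
      )
      fit <- do.call(tune_rcr, c(
        list(tree = tree, rhc = rhc, blood = blood, solver = solver),
        tuning
      ))
      reports[[i]] <<- dplyr::bind_cols(
        tibble::tibble(patient_id = row$patient_id), fit$report
      )
      if (!fit$report$converged) {
        return(NULL)
      }
      shear <- compute_shear(fit$solution, tree, blood)
      aggregate_proximal(shear, tree)
    })
    ok <- !purrr::map_lgl(results, is.null)
    n_fail <- sum(!ok)
    if (n_fail > 0) {
      message(
        n_fail, " patient(s) excluded: Windkessel tuning did not converge (",
        paste(cohort$patient_id[!ok], collapse = ", "), ")"
      )
    }
    tuning_reports <- dplyr::bind_rows(reports)
    cohort <- cohort[ok, ]
    agg <- dplyr::bind_rows(results[ok])
    cohort$TAWSS <- agg$TAWSS_proximal
    cohort$OSI <- agg$OSI_proximal
  }

  cohort$mode <- mode
  cohort$seed <- seed
  cohort <- cohort[, c(
    "patient_id", "group", "mismatch_positive", "mismatch_score",
    "mPAP", "sPAP", "dPAP", "PAWP", "RAP", "CO", "HR", "PVR",
    "mpa_diameter_mm", "TAWSS", "OSI", "mode", "seed"
  )]
  attr(cohort, "mode") <- mode
  attr(cohort, "seed") <- seed
  attr(cohort, "n_tuning_failures") <- n_fail
  if (mode == "mechanistic") attr(cohort, "tuning_reports") <- tuning_reports
  class(cohort) <- c("cohort_tbl", class(cohort))
  cohort
}

#' Read and write cohort tables
#'
#' Plain CSV with the full cohort column set; `write_cohort()` then
#' `read_cohort()` round-trips the table.
#'
#' @param cohort A `cohort_tbl` from [generate_cohort()].
#' @param path File path.
#' @return `read_cohort()` returns a `cohort_tbl`; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(tibble::as_tibble(unclass(cohort)), path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    group = readr::col_character(),
    mismatch_positive = readr::col_logical(),
    mode = readr::col_character(),
    seed = readr::col_integer(),
    .default = readr::col_double()
  ))
  class(df) <- c("cohort_tbl", class(df))
  df
}

#' Plot a cohort's shear metrics by group
#'
#' Boxplots of patient-level TAWSS (and OSI) by study group, with the fixed
#' diagnostic threshold overlaid on the TAWSS panel.
#'
#' @param object A `cohort_tbl`.
#' @param threshold TAWSS threshold to draw, dyn/cm^2 (default 27).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_tbl
#' @export
autoplot.cohort_tbl <- function(object, threshold = 27, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("group", "TAWSS", "OSI")],
    cols = c("TAWSS", "OSI"), names_to = "metric", values_to = "value"
  )
  df$group <- factor(df$group, levels = c("CTEPH", "CTEPD", "CONTROL"))
  hline <- tibble::tibble(metric = "TAWSS", y = threshold)
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$value, fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::geom_hline(
      data = hline, ggplot2::aes(yintercept = .data$y),
      linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "value (TAWSS: dyn/cm²)") +
    ggplot2::theme_minimal()
}
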