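#' Kruskal-Wallis test across study groups
#'
#' Tie-corrected Kruskal-Wallis H test (via [stats::kruskal.test()]) on a
#' value column split by a grouping column. The degenerate case where every
#' pooled value is identical returns `H = 0`, `p = 1`.
#'
#' @param data A data frame.
#' @param value,group Column names (tidy-eval) of the response and grouping
#'   variables.
#' @return A one-row tibble with `H`, `df`, `p`.
#' @export
#' @examples
#' kruskal_wallis(data.frame(v = 1:6, g = rep(c("a", "b", "c"), each = 2)), v, g)
kruskal_wallis <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  split_v <- split(v, g)
  if (length(split_v) < 2 || any(lengths(split_v) == 0)) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  if (length(unique(v)) == 1) {
    return(tibble::tibble(H = 0, df = length(split_v) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(v, factor(g))
  tibble::tibble(
    H = unname(kt$statistic),
    df = unname(kt$parameter),
    p = kt$p.value
  )
}

#' Dunn's post hoc pairwise test with Bonferroni correction
#'
#' Rank-based pairwise z tests on the pooled midranks, with the standard tie
#' correction: `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i +
#' 1/n_j))` where `T = sum(t^3 - t) / (12 (N - 1))` over tie groups.
#' Two-sided p-values from the standard normal; the Bonferroni adjustment
#' multiplies by the number of pairs, capped at 1.
#'
#' @inheritParams kruskal_wallis
#' @param adjustment `"bonferroni"` (default) or `"none"`.
#' @return A tibble with one row per group pair: `group1`, `group2`, `z`,
#'   `p_raw`, `p_adjusted`.
#' @export
dunn_test <- function(data, value, group, adjustment = c("bonferroni", "none")) {
  adjustment <- match.arg(adjustment)
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  if (nlevels(g) < 2 || any(table(g) == 0)) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  N <- length(v)
  r <- rank(v)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(levels(g), 2)
  n_pairs <- ncol(pairs)
  purrr::map_dfr(seq_len(n_pairs), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    se <- sqrt(s2 * (1 / n[[i]] + 1 / n[[j]]))
    z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    p_raw <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(
      group1 = i, group2 = j, z = z, p_raw = p_raw,
      p_adjusted = if (adjustment == "bonferroni") min(1, n_pairs * p_raw) else p_raw
    )
  })
}

#' Spearman rank correlation
#'
#' Tie-safe Spearman correlation (Pearson correlation of midranks) with an
#' asymptotic p-value via [stats::cor.test()].
#'
#' @param data A data frame.
#' @param x,y Column names (tidy-eval) of the two variables.
#' @return A one-row tibble with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  xv <- as.numeric(xv)
  yv <- as.numeric(yv)
  if (length(xv) != length(yv) || length(xv) < 3) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  if (stats::var(rank(xv)) == 0 || stats::var(rank(yv)) == 0) {
    stop("undefined correlation: zero rank variance", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(xv, yv, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, n = length(xv))
}

wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) {
    return(c(NA_real_, NA_real_))
  }
  # suppress the chi-square small-count warning; only the interval is used
  as.numeric(suppressWarnings(
    stats::prop.test(x, n, correct = FALSE, conf.level = conf)$conf.int
  ))
}

#' ROC analysis of a diagnostic score
#'
#' Builds the empirical ROC curve of a continuous score against a binary
#' condition label. With the default `orientation = "lower"` a patient is
#' called positive when their score falls *below* a threshold (appropriate
#' for TAWSS, which is reduced in disease); `"higher"` reverses the
#' direction. Thresholds are the midpoints between adjacent distinct scores
#' plus `-Inf`/`Inf` sentinels. The AUC is computed by the Mann-Whitney
#' identity (score ties between classes count 1/2), which equals the
#' trapezoidal area under the empirical curve.
#'
#' The Youden-optimal cutoff maximizes `J = sensitivity + specificity - 1`;
#' ties are broken toward higher specificity, then toward the lower
#' threshold. Sensitivity, specificity, PPV and NPV at the chosen cutoff are
#' reported with Wilson score 95% confidence intervals.
#'
#' @param data A data frame.
#' @param score,label Columns (tidy-eval): numeric score and logical (or
#'   0/1) condition indicator.
#' @param orientation `"lower"` (default; lower score = positive call) or
#'   `"higher"`.
#' @param threshold Optional fixed threshold at which to also evaluate the
#'   confusion metrics (in addition to the Youden cutoff).
#' @return A list of class `roc_result`: `curve` (tibble of `threshold`,
#'   `sensitivity`, `specificity`), `auc`, `optimal_cutoff`, `J_max`,
#'   `youden` and (if `threshold` given) `at_threshold` — each a
#'   [confusion_metrics()] row — plus `orientation`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(data, score, label, orientation = c("lower", "higher"),
                         threshold = NULL) {
  orientation <- match.arg(orientation)
  s <- dplyr::pull(data, {{ score }})
  y <- as.logical(dplyr::pull(data, {{ label }}))
  if (!any(y) || all(y)) {
    stop("both classes must be present", call. = FALSE)
  }
  pos <- s[y]
  neg <- s[!y]

  uq <- sort(unique(s))
  thresholds <- c(-Inf, (uq[-1] + uq[-length(uq)]) / 2, Inf)
  call_pos <- function(th) if (orientation == "lower") s < th else s > th
  curve <- purrr::map_dfr(thresholds, function(th) {
    pred <- call_pos(th)
    tibble::tibble(
      threshold = th,
      sensitivity = mean(pred[y]),
      specificity = mean(!pred[!y])
    )
  })

  # Mann-Whitney AUC: probability a positive scores on the diseased side of
  # a random negative, ties 1/2
  cmp <- outer(pos, neg, function(a, b) {
    if (orientation == "lower") (a < b) + 0.5 * (a == b) else (a > b) + 0.5 * (a == b)
  })
  auc <- mean(cmp)

  J <- curve$sensitivity + curve$specificity - 1
  J_max <- max(J)
  cand <- which(abs(J - J_max) < 1e-12)
  cand <- cand[order(-curve$specificity[cand], curve$threshold[cand])]
  best <- cand[1]
  optimal_cutoff <- curve$threshold[best]

  out <- list(
    curve = curve,
    auc = auc,
    optimal_cutoff = optimal_cutoff,
    J_max = J_max,
    youden = confusion_metrics(data, {{ score }}, {{ label }},
      threshold = optimal_cutoff, orientation = orientation
    ),
    orientation = orientation,
    n_pos = length(pos),
    n_neg = length(neg)
  )
  if (!is.null(threshold)) {
    out$at_threshold <- confusion_metrics(data, {{ score }}, {{ label }},
      threshold = threshold, orientation = orientation
    )
  }
  structure(out, class = "roc_result")
}

#' Diagnostic performance at a threshold
#'
#' The 2x2 confusion table and derived proportions — sensitivity,
#' specificity, positive and negative predictive value — with Wilson score
#' 95% confidence intervals. An empty denominator yields `NA` for the metric
#' and its interval.
#'
#' @inheritParams roc_analysis
#' @param threshold Decision threshold (same units as the score).
#' @return A one-row tibble: `threshold, TP, FP, TN, FN, sensitivity,
#'   specificity, ppv, npv` and `*_lo`/`*_hi` interval bounds.
#' @export
confusion_metrics <- function(data, score, label, threshold,
                              orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  s <- dplyr::pull(data, {{ score }})
  y <- as.logical(dplyr::pull(data, {{ label }}))
  if (!any(y) || all(y)) {
    stop("both classes must be present", call. = FALSE)
  }
  pred <- if (orientation == "lower") s < threshold else s > threshold
  TP <- sum(pred & y)
  FP <- sum(pred & !y)
  TN <- sum(!pred & !y)
  FN <- sum(!pred & y)
  prop <- function(x, n) if (n > 0) x / n else NA_real_
  ci <- function(x, n) if (n > 0) wilson_ci(x, n) else c(NA_real_, NA_real_)
  se_ci <- ci(TP, TP + FN)
  sp_ci <- ci(TN, TN + FP)
  ppv_ci <- ci(TP, TP + FP)
  npv_ci <- ci(TN, TN + FN)
  tibble::tibble(
    threshold = threshold, TP = TP, FP = FP, TN = TN, FN = FN,
    sensitivity = prop(TP, TP + FN),
    sensitivity_lo = se_ci[1], sensitivity_hi = se_ci[2],
    specificity = prop(TN, TN + FP),
    specificity_lo = sp_ci[1], specificity_hi = sp_ci[2],
    ppv = prop(TP, TP + FP), ppv_lo = ppv_ci[1], ppv_hi = ppv_ci[2],
    npv = prop(TN, TN + FN), npv_lo = npv_ci[1], npv_hi = npv_ci[2]
  )
}

#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(
    auc = x$auc,
    optimal_cutoff = x$optimal_cutoff,
    J_max = x$J_max,
    sensitivity = x$youden$sensitivity,
    specificity = x$youden$specificity,
    ppv = x$youden$ppv,
    npv = x$youden$npv,
    n_pos = x$n_pos,
    n_neg = x$n_neg
  )
}

#' Plot an ROC curve
#'
#' Empirical ROC curve with the chance diagonal and the Youden-optimal
#' operating point marked.
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  cur <- object$curve[order(1 - object$curve$specificity, object$curve$sensitivity), ]
  opt <- object$curve[object$curve$threshold == object$optimal_cutoff, ]
  ggplot2::ggplot(cur, ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = opt, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("AUC = %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Full diagnostic statistics for a cohort
#'
#' Runs the study's statistical stage on a cohort table: Kruskal-Wallis and
#' Dunn-Bonferroni comparisons of TAWSS and OSI across the three groups,
#' Spearman correlation between TAWSS and binary mismatch status, and ROC
#' analysis of TAWSS for predicting mismatch (lower TAWSS = positive call),
#' including the confusion metrics at a fixed threshold.
#'
#' @param cohort A `cohort_tbl` (or data frame with `group`,
#'   `mismatch_positive`, `TAWSS`, `OSI` columns).
#' @param threshold Fixed TAWSS decision threshold, dyn/cm^2. Default 27.0.
#' @return A list of class `cohort_diagnostics`: `tawss_test`,
#'   `tawss_pairwise`, `osi_test`, `osi_pairwise`, `spearman`, `roc`,
#'   `threshold`.
#' @export
diagnose_cohort <- function(cohort, threshold = 27.0) {
  structure(
    list(
      tawss_test = kruskal_wallis(cohort, TAWSS, group),
      tawss_pairwise = dunn_test(cohort, TAWSS, group),
      osi_test = kruskal_wallis(cohort, OSI, group),
      osi_pairwise = dunn_test(cohort, OSI, group),
      spearman = spearman_cor(
        dplyr::mutate(cohort, status = as.numeric(.data$mismatch_positive)),
        TAWSS, status
      ),
      roc = roc_analysis(cohort, TAWSS, mismatch_positive,
        orientation = "lower", threshold = threshold
      ),
      threshold = threshold
    ),
    class = "cohort_diagnostics"
  )
}

#' @method glance cohort_diagnostics
#' @export
glance.cohort_diagnostics <- function(x, ...) {
  tibble::tibble(
    H_tawss = x$tawss_test$H,
    p_tawss = x$tawss_test$p,
    H_osi = x$osi_test$H,
    p_osi = x$osi_test$p,
    rho = x$spearman$rho,
    auc = x$roc$auc,
    optimal_cutoff = x$roc$optimal_cutoff,
    sensitivity_at_threshold = x$roc$at_threshold$sensitivity,
    specificity_at_threshold = x$roc$at_threshold$specificity,
    threshold = x$threshold
  )
}

#' Export a diagnostics report
#'
#' Writes the full statistics as machine-readable JSON plus the ROC
#' coordinates as CSV alongside it (`<path>` and `<path>_roc.csv`).
#'
#' @param diag A `cohort_diagnostics` from [diagnose_cohort()].
#' @param path Output path for the JSON report.
#' @return `path`, invisibly.
#' @export
export_diagnostics <- function(diag, path) {
  report <- list(
    tawss = list(
      kruskal_wallis = as.list(diag$tawss_test),
      pairwise = diag$tawss_pairwise
    ),
    osi = list(
      kruskal_wallis = as.list(diag$osi_test),
      pairwise = diag$osi_pairwise
    ),
    spearman = as.list(diag$spearman),
    roc = list(
      auc = diag$roc$auc,
      optimal_cutoff = diag$roc$optimal_cutoff,
      J_max = diag$roc$J_max,
      youden = diag$roc$youden,
      at_threshold = diag$roc$at_threshold,
      threshold = diag$threshold
    )
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  roc_path <- paste0(sub("\\.json$", "", path), "_roc.csv")
  readr::write_csv(diag$roc$curve, roc_path)
  invisible(path)
}
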