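worked_groups <- data.frame(
  v = c(1, 2, 3, 4, 5, 6),
  g = rep(c("a", "b", "c"), each = 2)
)

test_that("Kruskal-Wallis matches the hand-ranked worked example", {
  kw <- kruskal_wallis(worked_groups, v, g)
  expect_equal(kw$H, 32 / 7, tolerance = 1e-12)
  expect_equal(kw$df, 2)
  # permuting group labels leaves H unchanged
  perm <- worked_groups
  perm$g <- factor(perm$g, levels = c("c", "a", "b"))
  expect_equal(kruskal_wallis(perm, v, g)$H, 32 / 7, tolerance = 1e-12)
  # degenerate all-identical data
  flat <- data.frame(v = rep(5, 9), g = rep(c("a", "b", "c"), 3))
  kw0 <- kruskal_wallis(flat, v, g)
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p, 1)
  expect_error(kruskal_wallis(data.frame(v = 1, g = "a"), v, g), "two")
})

test_that("Kruskal-Wallis is invariant under monotone transforms", {
  set.seed(31)
  d <- data.frame(v = stats::rlnorm(60), g = sample(c("a", "b", "c"), 60, TRUE))
  h0 <- kruskal_wallis(d, v, g)$H
  for (f in list(log, sqrt, function(x) x^3, function(x) 10 * x - 2)) {
    d2 <- transform(d, v = f(v))
    expect_equal(kruskal_wallis(d2, v, g)$H, h0, tolerance = 1e-10)
  }
})

test_that("Dunn's test reproduces the worked pairwise z and Bonferroni p", {
  dn <- dunn_test(worked_groups, v, g)
  ac <- dn[dn$group1 == "a" & dn$group2 == "c", ]
  expect_equal(abs(ac$z), 4 / sqrt(3.5), tolerance = 1e-12)
  expect_equal(ac$p_raw, 2 * stats::pnorm(-4 / sqrt(3.5)), tolerance = 1e-12)
  expect_equal(ac$p_adjusted, min(1, 3 * ac$p_raw), tolerance = 1e-12)
  expect_equal(ac$p_raw, 0.0325, tolerance = 1e-3)
  expect_equal(ac$p_adjusted, 0.0975, tolerance = 1e-3)
  # identical groups: z = 0, adjusted p = 1
  same <- data.frame(v = rep(c(1, 2), 3), g = rep(c("a", "b", "c"), each = 2))
  dn0 <- dunn_test(same, v, g)
  expect_true(all(abs(dn0$z) < 1e-12))
  expect_true(all(dn0$p_adjusted == 1))
})

test_that("Dunn z statistics are antisymmetric in the group order", {
  set.seed(32)
  d <- data.frame(v = stats::rnorm(45), g = rep(c("x", "y", "z"), each = 15))
  dn <- dunn_test(d, v, g)
  # reversing factor order flips the sign of each pairwise z
  d2 <- d
  d2$g <- factor(d2$g, levels = c("z", "y", "x"))
  dn2 <- dunn_test(d2, v, g)
  for (i in seq_len(nrow(dn))) {
    j <- which(dn2$group1 == dn$group2[i] & dn2$group2 == dn$group1[i])
    expect_equal(dn2$z[j], -dn$z[i], tolerance = 1e-12)
  }
})

test_that("Spearman correlation matches rank formulas and symmetries", {
  d <- data.frame(x = c(1, 2, 3), y = c(2, 1, 3))
  expect_equal(spearman_cor(d, x, y)$rho, 0.5, tolerance = 1e-12)
  inc <- data.frame(x = 1:10, y = (1:10)^3)
  expect_equal(spearman_cor(inc, x, y)$rho, 1)
  flip <- data.frame(x = 1:10, y = -(1:10)^3)
  expect_equal(spearman_cor(flip, x, y)$rho, -1)
  set.seed(33)
  r <- data.frame(x = stats::rnorm(40), y = stats::rnorm(40))
  expect_equal(
    spearman_cor(r, x, y)$rho,
    spearman_cor(data.frame(x = rank(r$x), y = rank(r$y)), x, y)$rho,
    tolerance = 1e-12
  )
  expect_error(spearman_cor(data.frame(x = rep(1, 5), y = 1:5), x, y), "rank variance")
})

test_that("ROC analysis matches enumerated examples with lower-is-positive", {
  perfect <- data.frame(s = c(1, 2, 3, 4), y = c(TRUE, TRUE, FALSE, FALSE))
  r1 <- roc_analysis(perfect, s, y)
  expect_equal(r1$auc, 1)
  expect_equal(r1$J_max, 1)

  mixed <- data.frame(s = c(1, 3, 2, 4), y = c(TRUE, TRUE, FALSE, FALSE))
  r2 <- roc_analysis(mixed, s, y)
  expect_equal(r2$auc, 0.75) # 3 of 4 (pos, neg) pairs correctly ordered
  expect_equal(r2$J_max, 0.5)
  expect_equal(r2$optimal_cutoff, 1.5) # tie broken toward higher specificity

  tied <- data.frame(s = rep(c(5, 7), 4), y = rep(c(TRUE, FALSE), each = 4))
  tied$s <- c(5, 7, 5, 7, 5, 7, 5, 7)
  r3 <- roc_analysis(tied, s, y)
  expect_equal(r3$auc, 0.5)
  expect_equal(r3$J_max, 0)

  expect_error(roc_analysis(data.frame(s = 1:4, y = rep(TRUE, 4)), s, y), "classes")
})

test_that("Mann-Whitney AUC equals the trapezoidal area and brute-force pairs", {
  set.seed(34)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    d <- data.frame(
      s = sample(stats::rnorm(n %/% 2 + 2), n, replace = TRUE),
      y = c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
    )
    r <- roc_analysis(d, s, y)
    # independent oracle 1: brute-force enumeration of all (pos, neg) pairs
    pos <- d$s[d$y]
    neg <- d$s[!d$y]
    brute <- 0
    for (p in pos) {
      for (q in neg) {
        brute <- brute + (p < q) + 0.5 * (p == q)
      }
    }
    brute <- brute / (length(pos) * length(neg))
    expect_equal(r$auc, brute, tolerance = 1e-12)
    # independent oracle 2: trapezoidal area under the empirical curve
    cur <- r$curve[order(1 - r$curve$specificity, r$curve$sensitivity), ]
    fpr <- 1 - cur$specificity
    trap <- sum(diff(fpr) * (utils::head(cur$sensitivity, -1) + utils::tail(cur$sensitivity, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(35)
  d <- data.frame(s = stats::rlnorm(80), y = sample(c(TRUE, FALSE), 80, TRUE))
  r <- roc_analysis(d, s, y)
  ref <- pROC::roc(response = d$y, predictor = d$s, direction = ">", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("confusion metrics reproduce the 2x2 table arithmetic with Wilson CIs", {
  # 60 positives (42 below / 18 above threshold), 30 negatives all above
  d <- data.frame(
    s = c(rep(10, 42), rep(30, 18), rep(30.5, 30)),
    y = c(rep(TRUE, 60), rep(FALSE, 30))
  )
  cm <- confusion_metrics(d, s, y, threshold = 27)
  expect_equal(cm[, c("TP", "FP", "TN", "FN")], tibble::tibble(TP = 42L, FP = 0L, TN = 30L, FN = 18L),
    ignore_attr = TRUE
  )
  expect_equal(cm$sensitivity, 0.70)
  expect_equal(cm$specificity, 1.00)
  expect_equal(cm$ppv, 1.00)
  expect_equal(cm$npv, 0.625)
  wil <- stats::prop.test(42, 60, correct = FALSE)$conf.int
  expect_equal(c(cm$sensitivity_lo, cm$sensitivity_hi), as.numeric(wil), tolerance = 1e-12)

  perfect <- data.frame(s = c(1, 1, 9, 9), y = c(TRUE, TRUE, FALSE, FALSE))
  cmp <- confusion_metrics(perfect, s, y, threshold = 5)
  expect_equal(c(cmp$sensitivity, cmp$specificity, cmp$ppv, cmp$npv), rep(1, 4))

  # threshold below all scores: nothing called positive
  low <- confusion_metrics(d, s, y, threshold = 0)
  expect_equal(low$sensitivity, 0)
  expect_equal(low$specificity, 1)
  expect_true(is.na(low$ppv)) # empty denominator reported as undefined
})

test_that("cohort diagnostics assemble all stages coherently", {
  coh <- generate_cohort("statistical", seed = 77)
  dg <- diagnose_cohort(coh)
  expect_s3_class(dg, "cohort_diagnostics")
  expect_lt(dg$tawss_test$p, 1e-6)
  expect_gt(dg$osi_test$p, 0.05) # OSI generator carries no group effect
  expect_lt(dg$spearman$rho, 0) # lower TAWSS accompanies mismatch
  expect_gt(dg$roc$auc, 0.8)
  expect_equal(nrow(dg$tawss_pairwise), 3)
  g <- glance(dg)
  expect_true(all(c("H_tawss", "auc", "rho", "sensitivity_at_threshold") %in% names(g)))
  path <- withr::local_tempfile(fileext = ".json")
  export_diagnostics(dg, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$roc$auc, dg$roc$auc, tolerance = 1e-9)
  expect_true(file.exists(paste0(sub("\\.json$", "", path), "_roc.csv")))
})
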