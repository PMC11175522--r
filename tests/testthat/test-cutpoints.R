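test_that("the Youden cut point lands at the midpoint of a clean separation", {
  scores <- c(0.80, 0.85, 0.90, 0.93, 0.95, 0.97)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  yc <- youden_cutpoint(scores, labels)
  expect_equal(yc$threshold, 0.915)
  expect_equal(yc$j, 1)
  expect_equal(yc$sensitivity, 1)
  expect_equal(yc$specificity, 1)
})

test_that("ties in J resolve to the smallest candidate threshold", {
  # interleaved labels give equal J = 0.5 at t = 1.5 and t = 3.5
  scores <- c(1, 2, 3, 4)
  labels <- c(TRUE, FALSE, TRUE, FALSE)
  yc <- youden_cutpoint(scores, labels)
  expect_equal(yc$threshold, 1.5)
  expect_equal(yc$j, 0.5)
  expect_equal(yc$threshold, youden_oracle_threshold(scores, labels)$threshold)
})

test_that("youden_cutpoint agrees with an exhaustive counting oracle", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    scores <- round(runif(n, 0.7, 1.1), sample(c(2, 3), 1))  # force ties often
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    got <- youden_cutpoint(scores, labels)
    want <- youden_oracle_threshold(scores, labels)
    expect_equal(got$j, want$j, tolerance = 1e-12)
    expect_equal(got$threshold, want$threshold, tolerance = 1e-12)
  }
})

test_that("single-class input is rejected", {
  expect_error(youden_cutpoint(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  expect_error(auc_mw(1:3, c(FALSE, FALSE, FALSE)), "both classes")
})

test_that("the Mann-Whitney AUC counts low-scoring positives, ties as half", {
  expect_equal(auc_mw(c(0.8, 0.9, 1.0, 1.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_mw(rep(0.9, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)), 0.5)
  expect_equal(auc_mw(c(0.8, 0.9, 0.85, 0.95), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
})

test_that("AUC is invariant under strictly monotone transforms of the scores", {
  set.seed(7)
  s <- runif(40); l <- runif(40) < 0.5
  l[1] <- TRUE; l[2] <- FALSE
  a0 <- auc_mw(s, l)
  expect_equal(auc_mw(qlogis(s / 2 + 0.25), l), a0)
  expect_equal(auc_mw(exp(3 * s), l), a0)
})

test_that("AUC matches pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    s <- round(runif(n), 2)
    l <- runif(n) < 0.5
    if (!any(l) || all(l)) next
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = l, predictor = s, direction = ">", quiet = TRUE)))
    expect_equal(auc_mw(s, l), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("region metrics implement the strict-below rule and flag undefined cells", {
  s <- c(0.8, 0.85, 0.95, 1.0)
  l <- c(TRUE, TRUE, FALSE, FALSE)
  m <- region_metrics(s, l, 0.9)
  expect_equal(unlist(m[c("auc", "accuracy", "sensitivity", "specificity")]),
               c(auc = 1, accuracy = 1, sensitivity = 1, specificity = 1))

  # threshold below all scores: nothing predicted positive
  m2 <- region_metrics(s, l, 0.5)
  expect_equal(m2$sensitivity, 0)
  expect_equal(m2$specificity, 1)

  # a score exactly at the threshold is predicted negative (strict below)
  m3 <- region_metrics(c(0.9, 1.0), c(TRUE, FALSE), 0.9)
  expect_equal(m3$sensitivity, 0)

  # single-class input flags rather than zero-fills
  m4 <- region_metrics(c(0.8, 0.9), c(TRUE, TRUE), 0.85)
  expect_true(all(c("specificity", "auc") %in% m4$undefined))
  expect_true(is.na(m4$auc))
  expect_equal(m4$sensitivity, 0.5)
})

test_that("metrics at the training-optimal threshold reproduce the fitted J", {
  set.seed(19)
  s <- rnorm(80, 0.95, 0.06)
  l <- runif(80) < plogis((0.92 - s) * 30)
  if (any(l) && !all(l)) {
    yc <- youden_cutpoint(s, l)
    m <- region_metrics(s, l, yc$threshold)
    expect_equal(m$sensitivity + m$specificity - 1, yc$j, tolerance = 1e-12)
  }
})

test_that("fitting errors name every single-class region", {
  tab <- simulate_tabular(tabular_sim_spec(n = 40, seed = 2))
  tab$infarcted[tab$region == "M3"] <- FALSE
  tab$infarcted[tab$region == "M6"] <- TRUE
  err <- tryCatch(aspects_cutpoints(tab), error = conditionMessage)
  expect_match(err, "M3")
  expect_match(err, "M6")
  expect_error(aspects_cutpoints(data.frame(region = "X", rhu = 1,
                                            infarcted = TRUE)),
               "unknown region")
})

test_that("the fitted model exposes coef/print/summary/predict", {
  tab <- simulate_tabular(tabular_sim_spec(n = 150, seed = 4))
  fit <- aspects_cutpoints(tab)
  expect_s3_class(fit, "aspects_cutpoints")
  cp <- coef(fit)
  expect_named(cp, ASPECTS_REGIONS)
  expect_true(all(cp > 0))
  expect_true(all(fit$cutpoints$youden_j >= 0 & fit$cutpoints$youden_j <= 1))
  expect_output(print(fit), "Youden")
  expect_output(print(summary(fit)), "cut points")

  # strict-below prediction, boundary excluded
  nd <- data.frame(region = c("M1", "M1", "M1"),
                   rhu = c(cp[["M1"]], cp[["M1"]] - 1e-9, 2))
  expect_identical(predict(fit, nd), c(FALSE, TRUE, FALSE))
  expect_error(predict(fit, data.frame(region = "Pons", rhu = 1)),
               "not in the fitted model")

  ta <- predict(fit, tab, type = "aspects")
  expect_identical(nrow(ta), length(unique(tab$patient_id)))
  expect_true(all(ta$threshold_aspects >= 0 & ta$threshold_aspects <= 10))
})

test_that("plot method draws without error", {
  tab <- simulate_tabular(tabular_sim_spec(n = 60, seed = 4))
  fit <- aspects_cutpoints(tab)
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f)
  expect_no_error(plot(fit, data = tab))
  grDevices::dev.off()
})

test_that("cross-validation partitions patients and is seed-deterministic", {
  tab <- simulate_tabular(tabular_sim_spec(n = 60, seed = 6))
  cv <- cross_validate(tab, k = 5, seed = 9)
  expect_identical(sort(names(cv$folds)), sort(unique(tab$patient_id)))
  expect_true(all(table(cv$folds) == 12))
  cv2 <- cross_validate(tab, k = 5, seed = 9)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$metrics, cv2$metrics)
  cv3 <- cross_validate(tab, k = 5, seed = 10)
  expect_false(identical(cv$folds, cv3$folds))
  expect_error(cross_validate(tab, k = 70), "exceeds the number of patients")
})

test_that("perfectly separable data cross-validates to AUC 1 with zero spread", {
  spec <- tabular_sim_spec(n = 60, mean_infarcted = 0.80, mean_normal = 1.10,
                           sd_infarcted = 0.01, sd_normal = 0.01,
                           prevalence = 0.5, seed = 13)
  cv <- cross_validate(simulate_tabular(spec), k = 5, seed = 1)
  agg <- cv$aggregate
  expect_equal(agg$mean[agg$metric == "auc"], 1)
  expect_equal(agg$sd[agg$metric == "auc"], 0)
})

test_that("under the null, cross-validated AUC is near one half", {
  spec <- tabular_sim_spec(n = 300, mean_infarcted = 0.95, mean_normal = 0.95,
                           sd_infarcted = 0.05, sd_normal = 0.05,
                           prevalence = 0.5, seed = 21)
  cv <- cross_validate(simulate_tabular(spec), k = 10, seed = 2)
  agg <- cv$aggregate
  m <- agg$mean[agg$metric == "auc"]
  se <- agg$sd[agg$metric == "auc"] / sqrt(agg$n_used[agg$metric == "auc"])
  expect_lt(abs(m - 0.5), 3.5 * se)
})

test_that("undefined fold cells are skipped and counted, not zero-filled", {
  spec <- tabular_sim_spec(n = 40, prevalence = c(
    Caudate = 0.02, InternalCapsule = 0.5, LentiformNucleus = 0.5,
    InsularCortex = 0.5, M1 = 0.5, M2 = 0.5, M3 = 0.5, M4 = 0.5,
    M5 = 0.5, M6 = 0.5), seed = 33)
  tab <- simulate_tabular(spec)
  # ensure the rare region has at least one positive so fit() is possible
  tab$infarcted[tab$region == "Caudate"][1] <- TRUE
  cv <- cross_validate(tab, k = 10, seed = 3)
  agg <- cv$aggregate
  expect_gt(agg$n_skipped[agg$metric == "auc"], 0)
  expect_equal(agg$n_used[agg$metric == "auc"] + agg$n_skipped[agg$metric == "auc"],
               nrow(cv$metrics))
  expect_false(anyNA(agg$mean))
})

test_that("model JSON serialization round-trips the cut points", {
  tab <- simulate_tabular(tabular_sim_spec(n = 80, seed = 14))
  fit <- aspects_cutpoints(tab)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(fit, f, seed = 42)
  back <- read_model(f)
  expect_equal(coef(back), coef(fit))
  payload <- jsonlite::read_json(f)
  expect_identical(payload$seed, 42L)
  expect_true(nzchar(payload$software_version))
})
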