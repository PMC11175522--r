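test_that("threshold-based ASPECTS is ten minus the predicted-infarct count", {
  none <- stats::setNames(rep(FALSE, 10), ASPECTS_REGIONS)
  expect_identical(threshold_aspects(none), 10L)
  expect_identical(threshold_aspects(!none), 0L)
  four <- none; four[c("M1", "M2", "M3", "Caudate")] <- TRUE
  expect_identical(threshold_aspects(four), 6L)
  expect_error(threshold_aspects(rep(FALSE, 9)), "exactly 10")
  expect_error(threshold_aspects(stats::setNames(rep(FALSE, 10),
                                                 c(ASPECTS_REGIONS[1:9], "M1"))),
               "duplicate")
})

test_that("Spearman is +/-1 for monotone relations and invariant to monotone maps", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  up <- spearman_ci(x, x^3 + 2, reps = 200, seed = 1)
  expect_equal(up$r_s, 1)
  down <- spearman_ci(x, -x, reps = 200, seed = 1)
  expect_equal(down$r_s, -1)

  set.seed(3)
  a <- rnorm(60); b <- a + rnorm(60)
  r1 <- spearman_ci(a, b, reps = 500, seed = 2)
  r2 <- spearman_ci(exp(a), b, reps = 500, seed = 2)
  expect_equal(r1$r_s, r2$r_s)
  expect_equal(r1$ci_low, r2$ci_low)  # bootstrap resamples ranks identically
  expect_lte(r1$ci_low, r1$r_s)
  expect_gte(r1$ci_high, r1$r_s)
  expect_error(spearman_ci(rep(1, 10), rnorm(10)), "constant")
})

test_that("the bootstrap CI covers the true rank correlation at roughly nominal rate", {
  set.seed(44)
  rho <- (6 / pi) * asin(0.5 / 2)  # Spearman of a bivariate normal with r = 0.5
  hits <- 0
  for (i in 1:40) {
    z <- rnorm(80)
    x <- z + rnorm(80)
    y <- z + rnorm(80)  # cor(x, y) = 0.5
    ci <- spearman_ci(x, y, reps = 400, seed = i)
    if (ci$ci_low <= rho && rho <= ci$ci_high) hits <- hits + 1
  }
  expect_gte(hits, 32)  # ~95% nominal; allow Monte-Carlo slack
})

test_that("comparing a predictor with itself gives p = 1", {
  set.seed(5)
  y <- rnorm(30); x <- y + rnorm(30)
  r <- compare_dependent_correlations(x, x, y, reps = 1000, seed = 1)
  expect_equal(r$p_value, 1)
  expect_equal(r$delta, 0)
})

test_that("too few replicates warn; constant inputs error", {
  set.seed(6)
  y <- rnorm(20); x1 <- y + rnorm(20); x2 <- y + rnorm(20)
  expect_warning(compare_dependent_correlations(x1, x2, y, reps = 500, seed = 1),
                 "1000")
  expect_error(compare_dependent_correlations(rep(1, 20), x2, y), "constant")
})

test_that("a clearly better predictor is detected by the bootstrap comparison", {
  set.seed(8)
  y <- rnorm(150)
  x1 <- y + 0.3 * rnorm(150)   # strongly correlated
  x2 <- rnorm(150)             # unrelated
  r <- compare_dependent_correlations(x1, x2, y, reps = 1000, seed = 2)
  expect_lt(r$p_value, 0.01)
  expect_gt(r$delta, 0.5)
})

test_that("DeLong on identical paired scores returns delta 0, p 1", {
  set.seed(9)
  s <- rnorm(40)
  l <- runif(40) < 0.5; l[1:2] <- c(TRUE, FALSE)
  r <- delong_test(s, s, l)
  expect_equal(r$delta, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$auc_a, r$auc_b)
})

test_that("DeLong structural components match a brute-force placement computation", {
  # small printed example: 4 positives, 4 negatives
  pos_a <- c(2.5, 3.1, 1.9, 4.0); neg_a <- c(1.0, 2.0, 3.0, 0.5)
  pos_b <- c(1.2, 2.2, 0.8, 3.5); neg_b <- c(1.1, 1.4, 2.1, 0.9)
  sa <- c(pos_a, neg_a); sb <- c(pos_b, neg_b)
  lab <- rep(c(TRUE, FALSE), each = 4)

  place <- function(pos, neg) {
    v10 <- sapply(pos, function(x) sum((x > neg) + 0.5 * (x == neg)) / length(neg))
    v01 <- sapply(neg, function(y) sum((pos > y) + 0.5 * (pos == y)) / length(pos))
    list(v10 = v10, v01 = v01)
  }
  pa <- place(pos_a, neg_a); pb <- place(pos_b, neg_b)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  var_d <- (var(pa$v10) + var(pb$v10) - 2 * cov(pa$v10, pb$v10)) / 4 +
           (var(pa$v01) + var(pb$v01) - 2 * cov(pa$v01, pb$v01)) / 4
  z <- (auc_a - auc_b) / sqrt(var_d)

  r <- delong_test(sa, sb, lab)
  expect_equal(r$auc_a, auc_a)
  expect_equal(r$auc_b, auc_b)
  expect_equal(r$se_delta, sqrt(var_d))
  expect_equal(r$p_value, 2 * pnorm(-abs(z)))
})

test_that("DeLong agrees with pROC across random paired instances", {
  skip_if_not_installed("pROC")
  set.seed(10)
  for (i in 1:30) {
    n <- sample(20:60, 1)
    l <- runif(n) < 0.5
    if (!any(l) || all(l)) next
    sa <- rnorm(n) + l
    sb <- 0.5 * sa + rnorm(n)
    ra <- pROC::roc(response = l, predictor = sa, direction = "<", quiet = TRUE)
    rb <- pROC::roc(response = l, predictor = sb, direction = "<", quiet = TRUE)
    ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    got <- delong_test(sa, sb, l)
    expect_equal(got$p_value, as.numeric(ref$p.value), tolerance = 1e-9)
    expect_equal(got$auc_a, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
  }
})

test_that("DeLong AUC equals the Mann-Whitney AUC across modules", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(15:50, 1)
    l <- runif(n) < 0.4
    if (!any(l) || all(l)) next
    s <- round(rnorm(n, 0.95, 0.05), 2)
    got <- delong_test(s, rnorm(n), l, direction = "low")
    expect_equal(got$auc_a, auc_mw(s, l), tolerance = 1e-12)
  }
})

test_that("outcome AUC orients low ASPECTS as high risk, with DeLong CI", {
  asp <- c(0, 0, 0, 10, 10, 10)
  poor <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  r <- outcome_auc(asp, poor)
  expect_equal(r$auc, 1)
  expect_equal(outcome_auc(rep(7, 6), poor)$auc, 0.5)
  expect_error(outcome_auc(asp, rep(TRUE, 6)), "both outcome classes")

  set.seed(12)
  asp2 <- sample(0:10, 500, replace = TRUE)
  poor2 <- runif(500) < 0.5  # independent of the score
  r2 <- outcome_auc(asp2, poor2)
  expect_lt(abs(r2$auc - 0.5), 0.07)
  expect_lte(r2$ci_low, r2$auc)
  expect_gte(r2$ci_high, r2$auc)
})
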