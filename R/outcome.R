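#' Threshold-based ASPECTS from predicted region labels
#'
#' @param predicted Logical vector of length 10 (one per ASPECTS region,
#'   optionally named by region), \code{TRUE} = predicted infarcted.
#' @return Integer 0-10: ten minus the number of predicted-infarcted regions.
#' @export
threshold_aspects <- function(predicted) {
  if (length(predicted) != 10L)
    stop("expected exactly 10 region predictions, got ", length(predicted),
         call. = FALSE)
  if (!is.null(names(predicted))) {
    if (anyDuplicated(names(predicted)))
      stop("duplicate region predictions", call. = FALSE)
    if (!setequal(names(predicted), ASPECTS_REGIONS))
      stop("predictions must cover the 10 ASPECTS regions exactly", call. = FALSE)
  }
  if (anyNA(predicted)) stop("missing predictions", call. = FALSE)
  10L - sum(as.logical(predicted))
}

#' Spearman correlation with a percentile-bootstrap confidence interval
#'
#' Rank correlation with average ranks for ties; the 95\% interval comes
#' from a patient-level percentile bootstrap rather than the Fisher-z
#' approximation, because the heavy ties in integer ASPECTS scores break
#' the normal approximation.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @param reps Bootstrap replicates (default 2000).
#' @param seed RNG seed.
#' @param conf Confidence level (default 0.95).
#' @return List with \code{r_s}, \code{ci_low}, \code{ci_high}, \code{n},
#'   \code{reps}, \code{seed}.
#' @export
spearman_ci <- function(x, y, reps = 2000, seed = 1, conf = 0.95) {
  check_paired(x, y, min_n = 3L)
  n <- length(x)
  r_s <- stats::cor(x, y, method = "spearman")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  boot <- vapply(seq_len(reps), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    stats::cor(x[i], y[i], method = "spearman")
  }, 0)
  boot <- boot[!is.na(boot)]  # resamples where one vector is constant
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  list(r_s = r_s, ci_low = qs[1], ci_high = qs[2], n = n, reps = reps,
       seed = seed)
}

check_paired <- function(..., min_n = 3L) {
  vs <- list(...)
  n <- unique(vapply(vs, length, 1L))
  if (length(n) != 1L) stop("vectors differ in length", call. = FALSE)
  if (n < min_n) stop("need at least ", min_n, " paired observations", call. = FALSE)
  for (v in vs) {
    if (anyNA(v)) stop("missing values in input", call. = FALSE)
    if (stats::sd(v) == 0) stop("constant input vector", call. = FALSE)
  }
  invisible(n)
}

#' Percentile-bootstrap comparison of two dependent overlapping correlations
#'
#' Tests H0: rho_S(x1, y) = rho_S(x2, y) for two predictors sharing one
#' outcome, by resampling patients with replacement, computing the
#' difference of the two Spearman correlations in each replicate, and
#' reading the two-sided p-value off the bootstrap distribution of the
#' difference: p = 2 min(P*(d < 0) + P*(d = 0)/2, P*(d > 0) + P*(d = 0)/2).
#'
#' @param x1,x2 Predictor vectors (e.g. two ASPECTS readings).
#' @param y Shared outcome vector.
#' @param reps Bootstrap replicates (default 2000; below 1000 a warning is
#'   issued).
#' @param seed RNG seed.
#' @return List with \code{p_value}, \code{r1}, \code{r2}, \code{delta}
#'   (observed difference), \code{n}, \code{reps}, \code{seed}.
#' @export
compare_dependent_correlations <- function(x1, x2, y, reps = 2000, seed = 1) {
  n <- check_paired(x1, x2, y, min_n = 10L)
  if (reps < 1000)
    warning("fewer than 1000 bootstrap replicates; the p-value will be coarse",
            call. = FALSE)
  r1 <- stats::cor(x1, y, method = "spearman")
  r2 <- stats::cor(x2, y, method = "spearman")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d <- vapply(seq_len(reps), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    stats::cor(x1[i], y[i], method = "spearman") -
      stats::cor(x2[i], y[i], method = "spearman")
  }, 0)
  d <- d[!is.na(d)]
  p_lo <- mean(d < 0) + mean(d == 0) / 2
  p <- 2 * min(p_lo, 1 - p_lo)
  list(p_value = min(p, 1), r1 = r1, r2 = r2, delta = r1 - r2, n = n,
       reps = reps, seed = seed)
}

# DeLong placement values for the orientation "high score = positive".
# Returns per-positive (v10) and per-negative (v01) placements and the AUC.
delong_placements <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), 0)
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two paired ROC AUCs
#'
#' Nonparametric covariance-based z-test for the difference of two AUCs
#' measured on the same patients, using DeLong placement values. Scores are
#' oriented so that a high score indicates the positive class (use
#' \code{direction = "low"} for scores where low values indicate disease,
#' e.g. raw rHU or ASPECTS). When the two score vectors are identical the
#' variance of the difference is zero; by convention the test then returns
#' delta = 0 and p = 1.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Logical, \code{TRUE} = positive class; both classes must be
#'   present.
#' @param direction \code{"high"} (default) or \code{"low"}: which end of
#'   the score scale indicates the positive class.
#' @param conf Confidence level for the per-AUC intervals (default 0.95).
#' @return List with \code{auc_a}, \code{auc_b}, their DeLong confidence
#'   intervals \code{ci_a}, \code{ci_b}, \code{delta}, \code{se_delta},
#'   \code{z}, \code{p_value}.
#' @export
delong_test <- function(scores_a, scores_b, labels, direction = c("high", "low"),
                        conf = 0.95) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  if (!any(labels) || all(labels))
    stop("both classes must be present", call. = FALSE)
  if (direction == "low") {
    scores_a <- -scores_a
    scores_b <- -scores_b
  }
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- sum(labels); n <- sum(!labels)
  if (m < 2 || n < 2)
    stop("the DeLong variance needs at least 2 cases in each class", call. = FALSE)
  # 2x2 covariance of (auc_a, auc_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  delta <- pa$auc - pb$auc
  var_d <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (var_d <= .Machine$double.eps) {
    p <- if (abs(delta) <= .Machine$double.eps) 1 else 0
    z <- if (p == 1) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(var_d)
    p <- 2 * stats::pnorm(-abs(z))
  }
  q <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- function(auc, v) pmin(1, pmax(0, auc + c(-1, 1) * q * sqrt(v)))
  list(auc_a = pa$auc, auc_b = pb$auc,
       ci_a = ci(pa$auc, S[1, 1]), ci_b = ci(pb$auc, S[2, 2]),
       delta = delta, se_delta = sqrt(max(var_d, 0)), z = z, p_value = p)
}

#' AUC of an ASPECTS score for predicting poor functional outcome
#'
#' The risk score is 10 - ASPECTS (a low ASPECTS means more affected
#' regions, hence higher risk), evaluated against the dichotomized outcome
#' (poor = 3-month mRS > 2) with the Mann-Whitney 1/2-tie rule and a DeLong
#' confidence interval.
#'
#' @param aspects Integer ASPECTS scores 0-10.
#' @param poor_outcome Logical, \code{TRUE} = poor outcome.
#' @param conf Confidence level (default 0.95).
#' @return List with \code{auc}, \code{ci_low}, \code{ci_high},
#'   \code{n_poor}, \code{n_good}.
#' @export
outcome_auc <- function(aspects, poor_outcome, conf = 0.95) {
  poor_outcome <- as.logical(poor_outcome)
  if (length(aspects) != length(poor_outcome))
    stop("scores and labels differ in length", call. = FALSE)
  if (!any(poor_outcome) || all(poor_outcome))
    stop("both outcome classes must be present", call. = FALSE)
  risk <- 10 - aspects
  p <- delong_placements(risk, poor_outcome)
  m <- sum(poor_outcome); n <- sum(!poor_outcome)
  v <- stats::var(p$v10) / m + stats::var(p$v01) / n
  q <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- pmin(1, pmax(0, p$auc + c(-1, 1) * q * sqrt(v)))
  list(auc = p$auc, ci_low = ci[1], ci_high = ci[2], n_poor = m, n_good = n)
}
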