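#' Youden-optimal cut point for a low-score-positive classifier
#'
#' Finds the threshold t maximizing the Youden index
#' J(t) = sensitivity(t) + specificity(t) - 1 under the decision rule
#' "predict positive iff score < t" (hypo-attenuation, i.e. a low rHU,
#' indicates infarction). Candidate thresholds are the midpoints between
#' consecutive distinct observed scores, plus -Inf and +Inf; when several
#' candidates achieve the maximal J, the smallest is returned, which makes
#' the estimate deterministic.
#'
#' @param scores Numeric scores (rHU values).
#' @param labels Logical, \code{TRUE} for the positive (infarcted) class.
#' @return List with \code{threshold}, \code{j}, and the training
#'   \code{sensitivity}/\code{specificity} at the optimum.
#' @export
youden_cutpoint <- function(scores, labels) {
  check_two_classes(scores, labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  us <- sort(unique(scores))
  cand <- c(-Inf, if (length(us) > 1) (us[-1] + us[-length(us)]) / 2, Inf)
  sens <- vapply(cand, function(t) mean(pos < t), 0)
  spec <- vapply(cand, function(t) mean(neg >= t), 0)
  j <- sens + spec - 1
  best <- which.max(j)  # first index = smallest threshold among ties
  list(threshold = cand[best], j = j[best],
       sensitivity = sens[best], specificity = spec[best])
}

#' Mann-Whitney area under the ROC curve, low score = positive
#'
#' Probability that a randomly chosen positive case has a lower score than a
#' randomly chosen negative case, ties counted one half. The orientation is
#' fixed (low rHU indicates disease); there is no automatic direction
#' flipping, so an AUC below 0.5 means the scores rank the classes the
#' wrong way.
#'
#' @param scores Numeric scores.
#' @param labels Logical, \code{TRUE} = positive class.
#' @return AUC in [0,1].
#' @export
auc_mw <- function(scores, labels) {
  check_two_classes(scores, labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  r <- rank(scores)
  (sum(r[!labels]) - n_neg * (n_neg + 1) / 2) / (n_pos * n_neg)
}

check_two_classes <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  if (anyNA(scores) || anyNA(labels))
    stop("missing values in scores or labels", call. = FALSE)
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both classes must be present", call. = FALSE)
  invisible(TRUE)
}

#' Confusion-matrix metrics at a fixed cut point
#'
#' Evaluates the strict-below rule (predict infarcted iff score < threshold)
#' and the threshold-free Mann-Whitney AUC. When a class is absent the
#' metrics that need it (sensitivity or specificity, and the AUC) are
#' returned as \code{NA} with the \code{undefined} field naming them, rather
#' than silently zero.
#'
#' @param scores Numeric scores.
#' @param labels Logical, \code{TRUE} = positive class.
#' @param threshold Decision threshold.
#' @return List with \code{auc}, \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, \code{n_positive}, \code{n_negative}, and
#'   \code{undefined} (character vector of unavailable metrics).
#' @export
region_metrics <- function(scores, labels, threshold) {
  if (length(scores) != length(labels) || !length(scores))
    stop("scores and labels must be non-empty and of equal length", call. = FALSE)
  labels <- as.logical(labels)
  pred <- scores < threshold
  tp <- sum(pred & labels); fn <- sum(!pred & labels)
  tn <- sum(!pred & !labels); fp <- sum(pred & !labels)
  n_pos <- tp + fn; n_neg <- tn + fp
  undefined <- character()
  sens <- if (n_pos > 0) tp / n_pos else { undefined <- c(undefined, "sensitivity"); NA_real_ }
  spec <- if (n_neg > 0) tn / n_neg else { undefined <- c(undefined, "specificity"); NA_real_ }
  auc <- if (n_pos > 0 && n_neg > 0) auc_mw(scores, labels) else {
    undefined <- c(undefined, "auc"); NA_real_
  }
  list(auc = auc, accuracy = (tp + tn) / (n_pos + n_neg),
       sensitivity = sens, specificity = spec,
       n_positive = n_pos, n_negative = n_neg, undefined = undefined)
}

#' Fit per-region Youden-optimal rHU cut points
#'
#' The core model: for each of the ten ASPECTS regions independently, the
#' rHU threshold maximizing the Youden index for predicting final
#' infarction is estimated from a training table of region measurements and
#' infarct labels.
#'
#' @param data Data frame with one row per patient x region.
#' @param score Name of the rHU column (default \code{"rhu"}).
#' @param label Name of the logical infarct column (default
#'   \code{"infarcted"}).
#' @param region Name of the region column (default \code{"region"}).
#' @return An object of class \code{aspects_cutpoints} with components
#'   \code{cutpoints} (data frame: region, cutpoint, youden_j, sensitivity,
#'   specificity, n, n_positive, n_negative) and \code{call}. Regions whose
#'   training data contain a single class raise an error naming them all.
#' @seealso \code{\link{predict.aspects_cutpoints}},
#'   \code{\link{cross_validate}}
#' @examples
#' tab <- simulate_tabular(tabular_sim_spec(n = 80, seed = 1))
#' fit <- aspects_cutpoints(tab)
#' coef(fit)
#' @export
aspects_cutpoints <- function(data, score = "rhu", label = "infarcted",
                              region = "region") {
  stopifnot(is.data.frame(data))
  for (col in c(score, label, region))
    if (!col %in% names(data)) stop("missing column: ", col, call. = FALSE)
  regions <- intersect(ASPECTS_REGIONS, unique(data[[region]]))
  unknown <- setdiff(unique(data[[region]]), ASPECTS_REGIONS)
  if (length(unknown))
    stop("unknown region(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  single <- character()
  rows <- list()
  for (r in regions) {
    d <- data[data[[region]] == r, ]
    lab <- as.logical(d[[label]])
    if (!any(lab) || all(lab)) { single <- c(single, r); next }
    yc <- youden_cutpoint(d[[score]], lab)
    rows[[r]] <- data.frame(region = r, cutpoint = yc$threshold,
                            youden_j = yc$j, sensitivity = yc$sensitivity,
                            specificity = yc$specificity, n = nrow(d),
                            n_positive = sum(lab), n_negative = sum(!lab),
                            stringsAsFactors = FALSE)
  }
  if (length(single))
    stop("single-class training data for region(s): ",
         paste(single, collapse = ", "), call. = FALSE)
  structure(list(cutpoints = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 score = score, label = label, region = region,
                 call = match.call()),
            class = "aspects_cutpoints")
}

#' @export
print.aspects_cutpoints <- function(x, digits = 3, ...) {
  cat("Per-region Youden-optimal rHU cut points\n\n")
  cp <- x$cutpoints
  cat(paste0(format(cp$region, width = 18), format(round(cp$cutpoint, digits)),
             "  (J = ", format(round(cp$youden_j, 2)), ", n = ", cp$n, ")",
             collapse = "\n"), "\n")
  invisible(x)
}

#' @export
coef.aspects_cutpoints <- function(object, ...) {
  stats::setNames(object$cutpoints$cutpoint, object$cutpoints$region)
}

#' @export
summary.aspects_cutpoints <- function(object, ...) {
  structure(list(cutpoints = object$cutpoints, call = object$call),
            class = "summary.aspects_cutpoints")
}

#' @export
print.summary.aspects_cutpoints <- function(x, ...) {
  cat("Call: "); print(x$call)
  cat("\nTraining cut points (predict infarction when rHU < cut point):\n")
  print(x$cutpoints, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predict infarction or threshold-based ASPECTS from fitted cut points
#'
#' Applies the strict-below rule: a region is predicted to be finally
#' infarcted when its rHU lies strictly below that region's cut point
#' (rHU exactly at the cut point is predicted non-infarcted).
#'
#' @param object Fitted \code{\link{aspects_cutpoints}} model.
#' @param newdata Data frame with region and rHU columns (same names as at
#'   fit time).
#' @param type \code{"infarct"} returns a logical per row; \code{"aspects"}
#'   aggregates to one threshold-based ASPECTS per patient and requires a
#'   \code{patient} column with all 10 regions per patient.
#' @param patient Name of the patient identifier column (for
#'   \code{type = "aspects"}).
#' @param ... Unused.
#' @return Logical vector, or a data frame \code{patient_id},
#'   \code{threshold_aspects}.
#' @export
predict.aspects_cutpoints <- function(object, newdata, type = c("infarct", "aspects"),
                                      patient = "patient_id", ...) {
  type <- match.arg(type)
  stopifnot(is.data.frame(newdata))
  cp <- coef(object)
  reg <- newdata[[object$region]]
  unknown <- setdiff(unique(reg), names(cp))
  if (length(unknown))
    stop("region(s) not in the fitted model: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pred <- newdata[[object$score]] < cp[reg]
  if (type == "infarct") return(unname(pred))
  if (!patient %in% names(newdata))
    stop("missing column: ", patient, call. = FALSE)
  ids <- unique(newdata[[patient]])
  out <- data.frame(patient_id = ids,
                    threshold_aspects = vapply(ids, function(p) {
                      i <- newdata[[patient]] == p
                      threshold_aspects(stats::setNames(pred[i], reg[i]))
                    }, 0L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Plot rHU distributions and fitted cut points
#'
#' One panel strip plot: rHU values by region, infarcted cases filled,
#' non-infarcted open, with the fitted cut point drawn per region.
#'
#' @param x Fitted \code{\link{aspects_cutpoints}} model.
#' @param data Optional training-style table to display; omit to plot just
#'   the cut points.
#' @param ... Passed to \code{plot}.
#' @export
plot.aspects_cutpoints <- function(x, data = NULL, ...) {
  cp <- x$cutpoints
  k <- nrow(cp)
  ylim <- range(cp$cutpoint[is.finite(cp$cutpoint)])
  if (!is.null(data)) ylim <- range(ylim, data[[x$score]])
  graphics::plot(NA, xlim = c(0.5, k + 0.5), ylim = ylim + c(-0.02, 0.02),
                 xaxt = "n", xlab = "", ylab = "rHU", ...)
  graphics::axis(1, at = seq_len(k), labels = cp$region, las = 2, cex.axis = 0.8)
  if (!is.null(data)) {
    for (i in seq_len(k)) {
      d <- data[data[[x$region]] == cp$region[i], ]
      lab <- as.logical(d[[x$label]])
      graphics::points(jitter(rep(i, nrow(d)), amount = 0.15), d[[x$score]],
                       pch = ifelse(lab, 16, 1),
                       col = ifelse(lab, "firebrick", "grey40"), cex = 0.6)
    }
  }
  graphics::segments(seq_len(k) - 0.35, cp$cutpoint, seq_len(k) + 0.35,
                     cp$cutpoint, lwd = 2, col = "dodgerblue3")
  invisible(x)
}

#' Evaluate a fitted model per region on a validation table
#'
#' @param object Fitted \code{\link{aspects_cutpoints}} model.
#' @param data Validation table (same columns as at fit time).
#' @return Data frame mirroring the per-region report: region, cutpoint,
#'   auc, accuracy, sensitivity, specificity, n_positive, n_negative.
#' @export
evaluate_cutpoints <- function(object, data) {
  stopifnot(inherits(object, "aspects_cutpoints"), is.data.frame(data))
  cp <- coef(object)
  rows <- lapply(names(cp), function(r) {
    d <- data[data[[object$region]] == r, ]
    if (!nrow(d)) return(NULL)
    m <- region_metrics(d[[object$score]], as.logical(d[[object$label]]), cp[[r]])
    data.frame(region = r, cutpoint = cp[[r]], auc = m$auc,
               accuracy = m$accuracy, sensitivity = m$sensitivity,
               specificity = m$specificity, n_positive = m$n_positive,
               n_negative = m$n_negative, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Patient-level k-fold cross-validation of the cut-point model
#'
#' Single-round k-fold cross-validation with unstratified random allocation
#' of patients (not rows) to folds. For each fold the cut points are fitted
#' on the other k-1 folds and evaluated on the held-out fold. Fold x region
#' cells where a metric is undefined (held-out fold missing a class, or the
#' region single-class in training so no cut point exists) are excluded
#' from the aggregate mean and SD and counted in \code{n_skipped}.
#'
#' @param data Training table, one row per patient x region.
#' @param k Number of folds (default 10).
#' @param seed RNG seed for fold allocation.
#' @param score,label,region,patient Column names.
#' @return Object of class \code{aspects_cv}: \code{folds} (patient ->
#'   fold), \code{metrics} (fold x region table), \code{aggregate}
#'   (mean/sd/n_used/n_skipped per metric), \code{k}, \code{seed}.
#' @export
cross_validate <- function(data, k = 10, seed = 1, score = "rhu",
                           label = "infarcted", region = "region",
                           patient = "patient_id") {
  stopifnot(is.data.frame(data))
  for (col in c(score, label, region, patient))
    if (!col %in% names(data)) stop("missing column: ", col, call. = FALSE)
  ids <- unique(data[[patient]])
  if (k > length(ids))
    stop("k = ", k, " exceeds the number of patients (", length(ids), ")",
         call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- stats::setNames(sample(rep_len(seq_len(k), length(ids))),
                          as.character(ids))
  row_fold <- fold[as.character(data[[patient]])]
  cells <- list()
  for (f in seq_len(k)) {
    train <- data[row_fold != f, ]
    test <- data[row_fold == f, ]
    for (r in intersect(ASPECTS_REGIONS, unique(test[[region]]))) {
      dtr <- train[train[[region]] == r, ]
      dte <- test[test[[region]] == r, ]
      lab_tr <- as.logical(dtr[[label]])
      if (!any(lab_tr) || all(lab_tr)) {
        cells[[length(cells) + 1L]] <- data.frame(
          fold = f, region = r, cutpoint = NA_real_, auc = NA_real_,
          accuracy = NA_real_, sensitivity = NA_real_, specificity = NA_real_,
          n_test = nrow(dte), stringsAsFactors = FALSE)
        next
      }
      t_r <- youden_cutpoint(dtr[[score]], lab_tr)$threshold
      m <- region_metrics(dte[[score]], as.logical(dte[[label]]), t_r)
      cells[[length(cells) + 1L]] <- data.frame(
        fold = f, region = r, cutpoint = t_r, auc = m$auc,
        accuracy = m$accuracy, sensitivity = m$sensitivity,
        specificity = m$specificity, n_test = nrow(dte),
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, c(cells, list(make.row.names = FALSE)))
  agg <- do.call(rbind, lapply(c("auc", "accuracy", "sensitivity", "specificity"),
    function(mn) {
      v <- metrics[[mn]]
      data.frame(metric = mn, mean = mean(v, na.rm = TRUE),
                 sd = stats::sd(v, na.rm = TRUE), n_used = sum(!is.na(v)),
                 n_skipped = sum(is.na(v)), stringsAsFactors = FALSE)
    }))
  structure(list(folds = fold, metrics = metrics, aggregate = agg,
                 k = k, seed = seed),
            class = "aspects_cv")
}

#' @export
print.aspects_cv <- function(x, ...) {
  cat("k-fold cross-validation (k = ", x$k, ", seed = ", x$seed,
      "), mean +/- SD over region x fold cells:\n", sep = "")
  a <- x$aggregate
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-12s %.2f +/- %.2f  (%d cells, %d undefined skipped)\n",
                a$metric[i], a$mean[i], a$sd[i], a$n_used[i], a$n_skipped[i]))
  invisible(x)
}

# Save/restore the global RNG state so seeded helpers do not clobber the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Serialize a fitted cut-point model to JSON
#'
#' @param object Fitted \code{\link{aspects_cutpoints}} model.
#' @param path Output JSON path.
#' @param seed Optional seed to record alongside the model.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(object, path, seed = NULL) {
  stopifnot(inherits(object, "aspects_cutpoints"))
  payload <- list(
    cutpoints = stats::setNames(as.list(object$cutpoints$cutpoint),
                                object$cutpoints$region),
    training_n = stats::setNames(as.list(object$cutpoints$n),
                                 object$cutpoints$region),
    youden_j = stats::setNames(as.list(object$cutpoints$youden_j),
                               object$cutpoints$region),
    software_version = as.character(utils::packageVersion("aspectscta")),
    seed = seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a serialized cut-point model
#'
#' @param path JSON path written by \code{\link{write_model}}.
#' @return An \code{aspects_cutpoints} object (training sensitivities and
#'   specificities are not serialized and come back as \code{NA}).
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  regions <- names(p$cutpoints)
  cp <- data.frame(region = regions, cutpoint = unlist(p$cutpoints),
                   youden_j = if (!is.null(p$youden_j)) unlist(p$youden_j)[regions] else NA_real_,
                   sensitivity = NA_real_, specificity = NA_real_,
                   n = if (!is.null(p$training_n)) unlist(p$training_n)[regions] else NA_integer_,
                   n_positive = NA_integer_, n_negative = NA_integer_,
                   stringsAsFactors = FALSE)
  rownames(cp) <- NULL
  structure(list(cutpoints = cp, score = "rhu", label = "infarcted",
                 region = "region", call = call("read_model", path)),
            class = "aspects_cutpoints")
}
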