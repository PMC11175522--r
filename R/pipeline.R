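#' Run configuration with the method's default parameters
#'
#' Collects the tunable parameters in one place; the defaults are the
#' method's operating point: inclusive 1-250 HU attenuation filter, 30\%
#' voxel-overlap rule, 10 cross-validation folds, 2000 bootstrap
#' replicates.
#'
#' @param hu_min,hu_max Inclusive HU filter bounds.
#' @param overlap_threshold Infarct overlap fraction.
#' @param k Cross-validation folds.
#' @param bootstrap_reps Bootstrap replicates.
#' @param seed RNG seed used for fold allocation and bootstraps.
#' @param paths Optional named list of input paths (atlas, manifests,
#'   tables), carried into reports.
#' @return A \code{run_config} list.
#' @export
run_config <- function(hu_min = 1, hu_max = 250, overlap_threshold = 0.30,
                       k = 10, bootstrap_reps = 2000, seed = 1L,
                       paths = list()) {
  structure(list(hu_min = hu_min, hu_max = hu_max,
                 overlap_threshold = overlap_threshold, k = as.integer(k),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed),
                 paths = paths,
                 software_version = as.character(utils::packageVersion("aspectscta"))),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#' @param path Config file (\code{.yaml}/\code{.yml} needs the yaml
#'   package; \code{.json} uses jsonlite).
#' @return A \code{run_config}.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  keep <- intersect(names(vals), names(formals(run_config)))
  do.call(run_config, vals[keep])
}

rbind_rows <- function(x) {
  x <- Filter(Negate(is.null), x)
  if (length(x)) do.call(rbind, c(x, list(make.row.names = FALSE))) else NULL
}

read_manifest <- function(manifest) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(manifest))
  if (!"patient_id" %in% names(manifest))
    stop("manifest needs a patient_id column", call. = FALSE)
  manifest
}

load_atlas_arg <- function(atlas) {
  if (inherits(atlas, "aspects_atlas")) atlas else load_atlas(atlas)
}

patient_transform <- function(row) {
  if (!is.null(row$transform_path) && !is.na(row$transform_path) &&
      nzchar(row$transform_path))
    read_affine(row$transform_path)
  else affine_transform(diag(4))
}

#' Batch rHU extraction over a patient manifest
#'
#' For every manifest row, reads the CTA, resamples the atlas into the
#' subject grid through the patient's template-to-subject transform, and
#' computes the ten occlusion-side rHU values. Per-patient failures are
#' caught, logged to stderr and reported; the run continues.
#'
#' @param manifest Data frame or CSV path with columns \code{patient_id},
#'   \code{cta_path}, \code{occlusion_side}, and optional
#'   \code{transform_path} (blank = identity).
#' @param atlas \code{aspects_atlas} or a path \code{\link{load_atlas}}
#'   accepts.
#' @param config A \code{\link{run_config}}.
#' @param output Optional CSV path for the measurement table.
#' @return List with \code{measurements} (the \code{\link{compute_rhu}}
#'   rows of all successful patients) and \code{failures} (data frame
#'   patient_id, error).
#' @export
run_extract <- function(manifest, atlas, config = run_config(), output = NULL) {
  manifest <- read_manifest(manifest)
  atlas <- load_atlas_arg(atlas)
  res <- list(); fail <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    out <- tryCatch({
      cta <- read_volume(row$cta_path)
      subj <- resample_atlas(atlas, cta, patient_transform(row))
      compute_rhu(cta, subj, row$occlusion_side, config$hu_min, config$hu_max,
                  patient_id = row$patient_id)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      message("extract: patient ", row$patient_id, " failed: ",
              conditionMessage(out))
      fail[[length(fail) + 1L]] <- data.frame(patient_id = row$patient_id,
                                              error = conditionMessage(out),
                                              stringsAsFactors = FALSE)
    } else res[[length(res) + 1L]] <- out
  }
  measurements <- rbind_rows(res)
  if (!is.null(output) && !is.null(measurements))
    utils::write.csv(measurements, output, row.names = FALSE)
  list(measurements = measurements, failures = rbind_rows(fail))
}

#' Batch infarct labeling over a patient manifest
#'
#' Resamples the atlas onto each patient's DWI grid, applies the overlap
#' rule against the lesion mask, and summarises per patient (DWI-ASPECTS
#' and final infarct volume in mL).
#'
#' @param manifest Data frame or CSV path with columns \code{patient_id},
#'   \code{dwi_lesion_path}, \code{occlusion_side}, optional
#'   \code{transform_path}.
#' @param atlas \code{aspects_atlas} or path.
#' @param config A \code{\link{run_config}}.
#' @param output Optional path prefix; writes \code{<output>_labels.csv}
#'   and \code{<output>_patients.csv}.
#' @return List with \code{labels} (region rows), \code{patients}
#'   (patient_id, occlusion_side, dwi_aspects, infarct_volume_ml) and
#'   \code{failures}.
#' @export
run_label <- function(manifest, atlas, config = run_config(), output = NULL) {
  manifest <- read_manifest(manifest)
  atlas <- load_atlas_arg(atlas)
  lab <- list(); pat <- list(); fail <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    out <- tryCatch({
      lesion <- read_volume(row$dwi_lesion_path)
      subj <- resample_atlas(atlas, lesion, patient_transform(row))
      labels <- label_regions(subj, lesion, row$occlusion_side,
                              config$overlap_threshold,
                              patient_id = row$patient_id)
      list(labels = labels,
           patient = data.frame(patient_id = row$patient_id,
                                occlusion_side = row$occlusion_side,
                                dwi_aspects = dwi_aspects(labels),
                                infarct_volume_ml = infarct_volume_ml(lesion),
                                stringsAsFactors = FALSE))
    }, error = function(e) e)
    if (inherits(out, "error")) {
      message("label: patient ", row$patient_id, " failed: ",
              conditionMessage(out))
      fail[[length(fail) + 1L]] <- data.frame(patient_id = row$patient_id,
                                              error = conditionMessage(out),
                                              stringsAsFactors = FALSE)
    } else {
      lab[[length(lab) + 1L]] <- out$labels
      pat[[length(pat) + 1L]] <- out$patient
    }
  }
  labels <- rbind_rows(lab)
  patients <- rbind_rows(pat)
  if (!is.null(output) && !is.null(labels)) {
    utils::write.csv(labels, paste0(output, "_labels.csv"), row.names = FALSE)
    utils::write.csv(patients, paste0(output, "_patients.csv"), row.names = FALSE)
  }
  list(labels = labels, patients = patients, failures = rbind_rows(fail))
}

#' Fit the cut-point model and cross-validate it
#'
#' @param table Merged training table (columns \code{patient_id},
#'   \code{region}, \code{rhu}, \code{infarcted}) or a CSV path.
#' @param config A \code{\link{run_config}} (supplies \code{k} and
#'   \code{seed}).
#' @param output Optional path prefix; writes \code{<output>_model.json} and
#'   \code{<output>_cv.csv}.
#' @return List with \code{model} (\code{\link{aspects_cutpoints}}) and
#'   \code{cv} (\code{\link{cross_validate}} report).
#' @export
run_train <- function(table, config = run_config(), output = NULL) {
  if (is.character(table)) table <- utils::read.csv(table, stringsAsFactors = FALSE)
  model <- aspects_cutpoints(table)
  cv <- cross_validate(table, k = config$k, seed = config$seed)
  if (!is.null(output)) {
    write_model(model, paste0(output, "_model.json"), seed = config$seed)
    utils::write.csv(cv$metrics, paste0(output, "_cv.csv"), row.names = FALSE)
  }
  list(model = model, cv = cv)
}

#' Evaluate a fitted model on a validation cohort
#'
#' Produces the per-region report (cut point, AUC, accuracy, sensitivity,
#' specificity, positive count) with a median [IQR] summary across regions,
#' the threshold-based ASPECTS per patient, and -- when the corresponding
#' patient-level columns are supplied -- Spearman correlations with
#' DWI-ASPECTS and final infarct volume, the percentile-bootstrap
#' comparison against a visual reading, and the poor-outcome AUC with
#' DeLong comparison. Analyses whose inputs are missing are skipped with a
#' logged notice, and the skipped section names are recorded in the report.
#'
#' @param model Fitted \code{\link{aspects_cutpoints}} or a model JSON path.
#' @param table Validation region table (or CSV path) with
#'   \code{patient_id}, \code{region}, \code{rhu}, \code{infarcted}.
#' @param patients Optional patient-level table (or CSV path) with
#'   \code{patient_id} and any of \code{dwi_aspects},
#'   \code{infarct_volume_ml}, \code{visual_aspects}, \code{mrs_3month} or
#'   \code{poor_outcome}.
#' @param config A \code{\link{run_config}} (bootstrap replicates, seed).
#' @param output Optional path prefix; writes \code{<output>_metrics.csv}
#'   and \code{<output>_stats.json}.
#' @return List of class \code{aspects_evaluation}: \code{region_metrics},
#'   \code{summary} (median/IQR per metric), \code{threshold_aspects},
#'   \code{correlations}, \code{comparisons}, \code{outcome},
#'   \code{skipped}, \code{config}.
#' @export
run_evaluate <- function(model, table, patients = NULL,
                         config = run_config(), output = NULL) {
  if (is.character(model)) model <- read_model(model)
  if (is.character(table)) table <- utils::read.csv(table, stringsAsFactors = FALSE)
  if (is.character(patients))
    patients <- utils::read.csv(patients, stringsAsFactors = FALSE)
  metrics <- evaluate_cutpoints(model, table)
  summ <- do.call(rbind, lapply(c("auc", "accuracy", "sensitivity", "specificity"),
    function(mn) {
      q <- stats::quantile(metrics[[mn]], c(0.25, 0.5, 0.75), na.rm = TRUE,
                           names = FALSE)
      data.frame(metric = mn, median = q[2], iqr_low = q[1], iqr_high = q[3],
                 stringsAsFactors = FALSE)
    }))
  ta <- predict(model, table, type = "aspects")
  skipped <- character()
  correlations <- list(); comparisons <- list(); outcome <- NULL
  has <- function(col) !is.null(patients) && col %in% names(patients) &&
    !all(is.na(patients[[col]]))
  if (!is.null(patients)) {
    p <- merge(ta, patients, by = "patient_id", sort = FALSE)
    if (has("dwi_aspects")) {
      correlations$dwi_aspects <- spearman_ci(p$threshold_aspects, p$dwi_aspects,
                                              config$bootstrap_reps, config$seed)
      if (has("visual_aspects"))
        comparisons$dwi_aspects <- compare_dependent_correlations(
          p$visual_aspects, p$threshold_aspects, p$dwi_aspects,
          config$bootstrap_reps, config$seed)
    } else skipped <- c(skipped, "correlation with DWI-ASPECTS")
    if (has("infarct_volume_ml")) {
      correlations$infarct_volume <- spearman_ci(
        p$threshold_aspects, p$infarct_volume_ml,
        config$bootstrap_reps, config$seed)
      if (has("visual_aspects"))
        comparisons$infarct_volume <- compare_dependent_correlations(
          p$visual_aspects, p$threshold_aspects, p$infarct_volume_ml,
          config$bootstrap_reps, config$seed)
    } else skipped <- c(skipped, "correlation with final infarct volume")
    poor <- if (has("poor_outcome")) p$poor_outcome
            else if (has("mrs_3month")) p$mrs_3month > 2
    if (!is.null(poor)) {
      outcome <- list(threshold = outcome_auc(p$threshold_aspects, poor))
      if (has("visual_aspects")) {
        outcome$visual <- outcome_auc(p$visual_aspects, poor)
        outcome$delong <- delong_test(10 - p$threshold_aspects,
                                      10 - p$visual_aspects, poor)
      }
    } else skipped <- c(skipped, "functional outcome")
  } else skipped <- c(skipped, "correlation with DWI-ASPECTS",
                      "correlation with final infarct volume",
                      "functional outcome")
  for (s in skipped) message("evaluate: skipped (missing inputs): ", s)
  report <- structure(list(region_metrics = metrics, summary = summ,
                           threshold_aspects = ta,
                           correlations = correlations,
                           comparisons = comparisons, outcome = outcome,
                           skipped = skipped, config = unclass(config)),
                      class = "aspects_evaluation")
  if (!is.null(output)) {
    utils::write.csv(metrics, paste0(output, "_metrics.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(summary = summ, correlations = correlations,
           comparisons = comparisons, outcome = outcome, skipped = skipped,
           config = unclass(config)),
      paste0(output, "_stats.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, null = "null", force = TRUE)
  }
  report
}

#' @export
print.aspects_evaluation <- function(x, ...) {
  cat("Per-region validation metrics:\n")
  print(x$region_metrics, row.names = FALSE, digits = 3)
  cat("\nMedian [IQR] across regions:\n")
  print(x$summary, row.names = FALSE, digits = 3)
  for (nm in names(x$correlations)) {
    ci <- x$correlations[[nm]]
    cat(sprintf("\nSpearman r_s vs %s: %.2f (95%% CI %.2f to %.2f, n = %d)",
                nm, ci$r_s, ci$ci_low, ci$ci_high, ci$n))
  }
  for (nm in names(x$comparisons))
    cat(sprintf("\nVisual vs threshold correlation with %s: p = %.2f",
                nm, x$comparisons[[nm]]$p_value))
  if (!is.null(x$outcome)) {
    o <- x$outcome$threshold
    cat(sprintf("\nPoor-outcome AUC (threshold-based): %.2f (95%% CI %.2f to %.2f)",
                o$auc, o$ci_low, o$ci_high))
    if (!is.null(x$outcome$delong))
      cat(sprintf("\nDeLong comparison vs visual: p = %.2f",
                  x$outcome$delong$p_value))
  }
  if (length(x$skipped))
    cat("\nSkipped: ", paste(x$skipped, collapse = "; "), sep = "")
  cat("\n")
  invisible(x)
}

#' Import an external measurement workbook or CSV with column mapping
#'
#' Mapping-driven importer for externally supplied per-region measurement
#' tables (e.g. a deposited spreadsheet whose exact column layout is not
#' fixed by this package). XLSX input requires the readxl package; CSV is
#' read with base R.
#'
#' @param path \code{.xlsx}/\code{.xls} or \code{.csv} file.
#' @param mapping Named character vector mapping standard names
#'   (\code{patient_id}, \code{region}, \code{rhu}, \code{infarcted}, and
#'   optionally patient-level columns) to source column names.
#' @param sheet Worksheet name or index for workbook input.
#' @param region_map Optional named vector translating source region
#'   spellings (e.g. \code{"Internal Capsular"}) to the package's region
#'   identifiers.
#' @return Data frame with the standard columns.
#' @export
import_measurements <- function(path, mapping, sheet = NULL, region_map = NULL) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("workbook import requires the readxl package", call. = FALSE)
    raw <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(unname(mapping), names(raw))
  if (length(missing))
    stop("source column(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- raw[unname(mapping)]
  names(out) <- names(mapping)
  if ("region" %in% names(out) && !is.null(region_map)) {
    hit <- out$region %in% names(region_map)
    out$region[hit] <- region_map[out$region[hit]]
  }
  if ("infarcted" %in% names(out)) out$infarcted <- as.logical(out$infarcted)
  out
}

#' Write a phantom cohort to disk for end-to-end runs
#'
#' Generates \code{n} phantom patients from a base \code{\link{phantom_spec}}
#' (per-patient seeds derived from the base seed), writes the CTA and DWI
#' lesion NIfTI volumes, the transform text files, the atlas, a manifest
#' CSV and the truth table.
#'
#' @param dir Output directory.
#' @param n Number of phantom patients.
#' @param base_spec Base \code{\link{phantom_spec}}; per-patient specs vary
#'   only in seed.
#' @return The manifest data frame (with a \code{truth_path} attribute),
#'   invisibly.
#' @export
run_simulate <- function(dir, n = 3, base_spec = phantom_spec(
                           multipliers = c(M1 = 0.85, Caudate = 0.9),
                           lesion_fractions = c(M1 = 0.5, Caudate = 0.4))) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_atlas(make_block_atlas(base_spec$grid_dim, base_spec$voxel_dims),
              file.path(dir, "atlas"))
  rows <- list(); truths <- list()
  for (i in seq_len(n)) {
    spec <- base_spec
    spec$seed <- base_spec$seed + i - 1L
    ph <- make_phantom_pair(spec)
    id <- sprintf("PH%02d", i)
    cta <- file.path(dir, paste0(id, "_cta.nii.gz"))
    dwi <- file.path(dir, paste0(id, "_dwi_lesion.nii.gz"))
    trf <- file.path(dir, paste0(id, "_transform.txt"))
    write_volume(ph$cta, cta)
    write_volume(ph$dwi_lesion, dwi)
    write_affine(ph$transform, trf)
    rows[[i]] <- data.frame(patient_id = id, cta_path = cta,
                            dwi_lesion_path = dwi, transform_path = trf,
                            occlusion_side = spec$occlusion_side,
                            stringsAsFactors = FALSE)
    truths[[i]] <- cbind(patient_id = id, ph$truth)
  }
  manifest <- do.call(rbind, rows)
  truth <- do.call(rbind, truths)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(base_spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(manifest, "truth_path") <- file.path(dir, "truth.csv")
  invisible(manifest)
}
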