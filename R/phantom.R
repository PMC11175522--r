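#' Specification for a paired CTA/DWI phantom
#'
#' Describes a synthetic head volume with a mirror-symmetric block atlas
#' (20 disjoint cuboids, 10 per hemisphere), planted ipsilateral
#' hypo-attenuation (one attenuation multiplier per region, so the true rHU
#' is known exactly), a DWI lesion mask filling a stated fraction of chosen
#' regions, optional small rigid misregistration, and Gaussian noise.
#'
#' @param grid_dim Volume dimensions in voxels (default c(40, 40, 26); at
#'   least c(28, 35, 24) so the block layout fits).
#' @param voxel_dims Voxel size in mm (default 2 mm isotropic).
#' @param bg_mean Background parenchyma attenuation in HU (default 40,
#'   typical supratentorial parenchyma on CTA source images).
#' @param noise_sd Gaussian noise SD in HU (default 2; 0 gives an exact
#'   phantom).
#' @param multipliers Named numeric vector, region -> ipsilateral
#'   attenuation multiplier (planted rHU); unnamed regions default to 1.
#' @param lesion_fractions Named numeric vector in [0,1], region -> fraction
#'   of that occlusion-side region filled by the DWI lesion.
#' @param rotation_deg,translation_mm Rigid misregistration of the subject
#'   volumes relative to template space: rotation about the z axis through
#'   the volume centre (<= 5 degrees) and translation (each axis <= 5 mm),
#'   capped so nearest-neighbour resampling stays sane at phantom
#'   resolution.
#' @param occlusion_side \code{"left"} or \code{"right"}.
#' @param mirror_noise Mirror the noise field across the midsagittal plane
#'   (makes a multiplier-free phantom exactly symmetric despite noise).
#' @param seed RNG seed; identical specs give bit-identical phantoms.
#' @return A \code{phantom_spec} list.
#' @export
phantom_spec <- function(grid_dim = c(40, 40, 26), voxel_dims = c(2, 2, 2),
                         bg_mean = 40, noise_sd = 2,
                         multipliers = numeric(), lesion_fractions = numeric(),
                         rotation_deg = 0, translation_mm = c(0, 0, 0),
                         occlusion_side = "left", mirror_noise = FALSE,
                         seed = 1L) {
  stopifnot(length(grid_dim) == 3L, length(voxel_dims) == 3L,
            all(voxel_dims > 0), noise_sd >= 0, bg_mean > 0)
  if (any(grid_dim < c(28, 35, 24)))
    stop("grid_dim too small for the block atlas layout (need >= 28 x 35 x 24)",
         call. = FALSE)
  bad <- setdiff(c(names(multipliers), names(lesion_fractions)), ASPECTS_REGIONS)
  if (length(bad))
    stop("unknown region(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(multipliers) && any(multipliers <= 0))
    stop("multipliers must be > 0", call. = FALSE)
  if (length(lesion_fractions) &&
      (any(lesion_fractions < 0) || any(lesion_fractions > 1)))
    stop("lesion fractions must lie in [0, 1]", call. = FALSE)
  if (abs(rotation_deg) > 5 || any(abs(translation_mm) > 5))
    stop("misregistration capped at 5 degrees / 5 mm", call. = FALSE)
  structure(list(grid_dim = as.integer(grid_dim), voxel_dims = voxel_dims,
                 bg_mean = bg_mean, noise_sd = noise_sd,
                 multipliers = multipliers, lesion_fractions = lesion_fractions,
                 rotation_deg = rotation_deg, translation_mm = translation_mm,
                 occlusion_side = match.arg(occlusion_side, c("left", "right")),
                 mirror_noise = mirror_noise, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Template affine: isotropic scaling with the world origin at the volume
# centre, so rigid misregistrations rotate about the centre.
phantom_affine <- function(grid_dim, voxel_dims) {
  a <- diag(c(voxel_dims, 1))
  a[1:3, 4] <- -voxel_dims * (grid_dim - 1) / 2
  a
}

#' Mirror-symmetric block atlas for phantoms
#'
#' Twenty disjoint cuboids (10 regions x 2 hemispheres) in a synthetic head
#' volume; the right-hemisphere blocks are exact voxel mirrors of the left
#' ones across the midsagittal plane. Geometry is irrelevant to the
#' arithmetic under test, so simple cuboids stand in for anatomical shapes.
#'
#' @param grid_dim,voxel_dims As in \code{\link{phantom_spec}}.
#' @return A validated \code{aspects_atlas} (template label
#'   \code{"phantom-block"}).
#' @export
make_block_atlas <- function(grid_dim = c(40, 40, 26), voxel_dims = c(2, 2, 2)) {
  grid_dim <- as.integer(grid_dim)
  aff <- phantom_affine(grid_dim, voxel_dims)
  masks <- list()
  for (i in seq_along(ASPECTS_REGIONS)) {
    row <- (i - 1L) %% 5L
    slab <- (i - 1L) %/% 5L
    xs <- 4:11                      # 1-based array indices, 8 voxels wide
    ys <- (3 + 7 * row):(7 + 7 * row)     # 5 voxels
    zs <- (3 + 12 * slab):(12 + 12 * slab)  # 10 voxels -> 400 voxels/region
    for (h in c("left", "right")) {
      a <- array(0, grid_dim)
      xi <- if (h == "left") xs else grid_dim[1] + 1L - xs
      a[xi, ys, zs] <- 1
      masks[[region_key(ASPECTS_REGIONS[i], h)]] <-
        volume3d(a, aff, voxel_dims)
    }
  }
  aspects_atlas(masks, template_name = "phantom-block")
}

misregistration_transform <- function(rotation_deg, translation_mm) {
  th <- rotation_deg * pi / 180
  Tm <- diag(4)
  Tm[1, 1] <- cos(th); Tm[1, 2] <- -sin(th)
  Tm[2, 1] <- sin(th); Tm[2, 2] <- cos(th)
  Tm[1:3, 4] <- translation_mm
  affine_transform(Tm)
}

#' Generate a paired CTA/DWI phantom with known ground truth
#'
#' Builds the block atlas, a CTA volume in which every occlusion-side
#' region's mean attenuation equals \code{bg_mean * multiplier} (planting
#' the true rHU), and a DWI lesion mask filling the stated fraction of each
#' lesion region. The subject volumes live on a grid whose affine is the
#' misregistration applied to the template affine; the correcting
#' template-world to subject-world transform is returned, so resampling the
#' template atlas through it reproduces the planted geometry.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return List with \code{cta}, \code{dwi_lesion} (both \code{volume3d} on
#'   the subject grid), \code{atlas} (template space), \code{truth} (data
#'   frame: region, true_rhu, lesion_fraction, infarcted), \code{transform}
#'   (\code{affine_transform}), and \code{spec}.
#' @export
make_phantom_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  atlas <- make_block_atlas(spec$grid_dim, spec$voxel_dims)
  Tm <- misregistration_transform(spec$rotation_deg, spec$translation_mm)
  subj_affine <- unclass(Tm) %*% phantom_affine(spec$grid_dim, spec$voxel_dims)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  cta <- array(spec$bg_mean, spec$grid_dim)
  if (spec$noise_sd > 0) {
    noise <- array(stats::rnorm(prod(spec$grid_dim), 0, spec$noise_sd),
                   spec$grid_dim)
    if (spec$mirror_noise) {
      half <- seq_len(floor(spec$grid_dim[1] / 2))
      noise[spec$grid_dim[1] + 1L - half, , ] <- noise[half, , ]
    }
    cta <- cta + noise
  }
  mult <- stats::setNames(rep(1, length(ASPECTS_REGIONS)), ASPECTS_REGIONS)
  mult[names(spec$multipliers)] <- spec$multipliers
  for (r in ASPECTS_REGIONS) {
    if (mult[[r]] == 1) next
    planted <- spec$bg_mean * mult[[r]]
    if (planted < 1 || planted > 250)
      warning("planted attenuation for ", r, " (", signif(planted, 4),
              " HU) lies outside the [1, 250] HU filter", call. = FALSE)
    m <- atlas$masks[[region_key(r, spec$occlusion_side)]]$data
    cta[m == 1] <- cta[m == 1] + spec$bg_mean * (mult[[r]] - 1)
  }

  lesion <- array(0, spec$grid_dim)
  frac <- stats::setNames(rep(0, length(ASPECTS_REGIONS)), ASPECTS_REGIONS)
  realized <- frac
  for (r in names(spec$lesion_fractions)) {
    idx <- which(atlas$masks[[region_key(r, spec$occlusion_side)]]$data == 1)
    n_sel <- round(spec$lesion_fractions[[r]] * length(idx))
    if (n_sel > 0) lesion[sort(idx)[seq_len(n_sel)]] <- 1
    frac[[r]] <- spec$lesion_fractions[[r]]
    realized[[r]] <- n_sel / length(idx)
  }
  n_reg <- vapply(ASPECTS_REGIONS, function(r)
    sum(atlas$masks[[region_key(r, spec$occlusion_side)]]$data), 0)
  truth <- data.frame(region = ASPECTS_REGIONS, true_rhu = unname(mult),
                      lesion_fraction = unname(realized),
                      infarcted = meets_overlap_threshold(
                        round(unname(realized) * n_reg), n_reg, 0.30),
                      stringsAsFactors = FALSE)
  list(cta = volume3d(cta, subj_affine, spec$voxel_dims),
       dwi_lesion = volume3d(lesion, subj_affine, spec$voxel_dims),
       atlas = atlas, truth = truth, transform = Tm, spec = spec)
}

#' Specification for a tabular rHU cohort simulation
#'
#' Emulates the statistical structure behind the per-region measurements:
#' for each patient and region an infarct label is drawn from the region's
#' prevalence, then an rHU value from the class-conditional Gaussian
#' (truncated at 0). Defaults reflect the modelled clinical setting: 368
#' patients (the training-cohort size), per-region prevalences equal to the
#' validation-cohort infarct frequencies, class means 0.87 (infarcted) and
#' 0.97 (non-infarcted), and a common SD of 0.13 so the binormal AUC is
#' about 0.71, matching the observed per-region discrimination.
#'
#' @param n Number of patients.
#' @param mean_infarcted,mean_normal Class-conditional rHU means.
#' @param sd_infarcted,sd_normal Class-conditional rHU SDs (> 0).
#' @param prevalence Named vector of per-region infarct prevalences in
#'   (0, 1); a scalar is recycled to all regions.
#' @param regions Regions to simulate (default all 10).
#' @param seed RNG seed.
#' @return A \code{tabular_sim_spec} list.
#' @export
tabular_sim_spec <- function(n = 368,
                             mean_infarcted = 0.87, mean_normal = 0.97,
                             sd_infarcted = 0.13, sd_normal = 0.13,
                             prevalence = c(Caudate = 0.36, InternalCapsule = 0.25,
                                            LentiformNucleus = 0.43,
                                            InsularCortex = 0.43, M1 = 0.15,
                                            M2 = 0.31, M3 = 0.12, M4 = 0.13,
                                            M5 = 0.16, M6 = 0.13),
                             regions = ASPECTS_REGIONS, seed = 1L) {
  regions <- match.arg(regions, ASPECTS_REGIONS, several.ok = TRUE)
  if (length(prevalence) == 1L && is.null(names(prevalence)))
    prevalence <- stats::setNames(rep(prevalence, length(regions)), regions)
  missing <- setdiff(regions, names(prevalence))
  if (length(missing))
    stop("prevalence missing for region(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(prevalence <= 0) || any(prevalence >= 1))
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  if (sd_infarcted <= 0 || sd_normal <= 0)
    stop("SDs must be > 0", call. = FALSE)
  structure(list(n = as.integer(n), mean_infarcted = mean_infarcted,
                 mean_normal = mean_normal, sd_infarcted = sd_infarcted,
                 sd_normal = sd_normal, prevalence = prevalence[regions],
                 regions = regions, seed = as.integer(seed)),
            class = "tabular_sim_spec")
}

#' Simulate a tabular rHU cohort with known labels
#'
#' @param spec A \code{\link{tabular_sim_spec}}.
#' @return Data frame with one row per patient x region: \code{patient_id},
#'   \code{region}, \code{rhu}, \code{infarcted}. Identical specs give
#'   bit-identical tables.
#' @export
simulate_tabular <- function(spec) {
  stopifnot(inherits(spec, "tabular_sim_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  ids <- sprintf("P%04d", seq_len(spec$n))
  out <- expand.grid(patient_id = ids, region = spec$regions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(match(out$patient_id, ids)), ]
  rownames(out) <- NULL
  out$infarcted <- stats::runif(nrow(out)) < spec$prevalence[out$region]
  mu <- ifelse(out$infarcted, spec$mean_infarcted, spec$mean_normal)
  sg <- ifelse(out$infarcted, spec$sd_infarcted, spec$sd_normal)
  rhu <- stats::rnorm(nrow(out), mu, sg)
  while (any(rhu <= 0))  # truncate the Gaussian at 0 by redrawing
    rhu[rhu <= 0] <- stats::rnorm(sum(rhu <= 0), mu[rhu <= 0], sg[rhu <= 0])
  out$rhu <- rhu
  out[, c("patient_id", "region", "rhu", "infarcted")]
}

#' Simulate a full cohort: region table plus patient-level metadata
#'
#' Extends \code{\link{simulate_tabular}} with the patient-level quantities
#' the outcome statistics consume: DWI-ASPECTS derived from the simulated
#' labels, a visual ASPECTS reading (DWI-ASPECTS plus reader noise, clamped
#' to 0-10), a log-normal final infarct volume increasing with the infarct
#' burden, and a 3-month mRS whose distribution shifts with the number of
#' infarcted regions (poor outcome = mRS > 2).
#'
#' @param spec A \code{\link{tabular_sim_spec}}.
#' @param reader_sd SD of the visual-reader noise in ASPECTS points
#'   (default 1.5).
#' @return List with \code{regions} (the simulate_tabular table) and
#'   \code{patients} (patient_id, occlusion_side, dwi_aspects,
#'   visual_aspects, infarct_volume_ml, mrs_3month, poor_outcome).
#' @export
simulate_cohort <- function(spec, reader_sd = 1.5) {
  tab <- simulate_tabular(spec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 1L)
  ids <- unique(tab$patient_id)
  n_inf <- vapply(ids, function(p) sum(tab$infarcted[tab$patient_id == p]), 0L)
  k <- length(spec$regions)
  dwi <- as.integer(10 - n_inf * (10 / k))  # scale when a region subset is simulated
  visual <- pmin(10L, pmax(0L, as.integer(round(dwi + stats::rnorm(length(ids), 0, reader_sd)))))
  vol <- exp(2.2 + 0.5 * n_inf + stats::rnorm(length(ids), 0, 0.9))
  poor <- stats::runif(length(ids)) < stats::plogis(-0.6 + 0.4 * n_inf)
  mrs <- ifelse(poor, sample(3:6, length(ids), replace = TRUE,
                             prob = c(0.35, 0.3, 0.2, 0.15)),
                sample(0:2, length(ids), replace = TRUE, prob = c(0.3, 0.35, 0.35)))
  patients <- data.frame(patient_id = ids,
                         occlusion_side = sample(c("left", "right"),
                                                 length(ids), replace = TRUE),
                         dwi_aspects = dwi, visual_aspects = visual,
                         infarct_volume_ml = vol, mrs_3month = as.integer(mrs),
                         poor_outcome = mrs > 2, stringsAsFactors = FALSE)
  rownames(patients) <- NULL
  list(regions = tab, patients = patients)
}
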