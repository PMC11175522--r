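test_that("identical specs generate bit-identical phantoms", {
  sp <- phantom_spec(noise_sd = 2, multipliers = c(M1 = 0.85), seed = 17)
  a <- make_phantom_pair(sp)
  b <- make_phantom_pair(sp)
  expect_identical(a$cta$data, b$cta$data)
  expect_identical(a$dwi_lesion$data, b$dwi_lesion$data)
  c <- make_phantom_pair(phantom_spec(noise_sd = 2, multipliers = c(M1 = 0.85),
                                      seed = 18))
  expect_false(identical(a$cta$data, c$cta$data))
})

test_that("the block atlas is mirror-symmetric to the voxel", {
  atlas <- make_block_atlas()
  nx <- dim(atlas$masks[[1]]$data)[1]
  for (r in c("Caudate", "M1", "M6")) {
    left <- atlas$masks[[paste0(r, "_left")]]$data
    right <- atlas$masks[[paste0(r, "_right")]]$data
    expect_identical(right[nx:1, , ], left)
  }
})

test_that("phantom spec enforces its own invariants", {
  expect_error(phantom_spec(multipliers = c(Pons = 0.9)), "unknown region")
  expect_error(phantom_spec(multipliers = c(M1 = -0.5)), "> 0")
  expect_error(phantom_spec(lesion_fractions = c(M1 = 1.2)), "\\[0, 1\\]")
  expect_error(phantom_spec(rotation_deg = 10), "capped")
  expect_error(phantom_spec(grid_dim = c(10, 10, 10)), "too small")
  expect_warning(make_phantom_pair(phantom_spec(noise_sd = 0,
                                                multipliers = c(M1 = 0.02))),
                 "outside the \\[1, 250\\]")
})

test_that("planted rHU and labels are reproduced exactly end-to-end at zero noise", {
  sp <- phantom_spec(noise_sd = 0,
                     multipliers = c(M1 = 0.85, Caudate = 0.9, M5 = 1.05),
                     lesion_fractions = c(M1 = 0.8, Caudate = 0.31, M4 = 0.29))
  ph <- make_phantom_pair(sp)
  subj_cta <- resample_atlas(ph$atlas, ph$cta, ph$transform)
  m <- compute_rhu(ph$cta, subj_cta, sp$occlusion_side)
  expect_equal(stats::setNames(m$rhu, m$region),
               stats::setNames(ph$truth$true_rhu, ph$truth$region))
  subj_dwi <- resample_atlas(ph$atlas, ph$dwi_lesion, ph$transform)
  lab <- label_regions(subj_dwi, ph$dwi_lesion, sp$occlusion_side)
  expect_identical(stats::setNames(lab$infarcted, lab$region),
                   stats::setNames(ph$truth$infarcted, ph$truth$region))
})

test_that("misregistered phantoms still recover planted values through the transform", {
  sp <- phantom_spec(noise_sd = 0, multipliers = c(M2 = 0.88),
                     rotation_deg = 4, translation_mm = c(3, -2, 1))
  ph <- make_phantom_pair(sp)
  subj <- resample_atlas(ph$atlas, ph$cta, ph$transform)
  m <- compute_rhu(ph$cta, subj, "left")
  expect_equal(m$rhu[m$region == "M2"], 0.88)
  expect_equal(m$rhu[m$region != "M2"], rep(1, 9))
})

test_that("lesion fractions straddling the 30% rule flip the planted label", {
  got <- sapply(c(0.29, 0.30, 0.31), function(f) {
    ph <- make_phantom_pair(phantom_spec(noise_sd = 0,
                                         lesion_fractions = c(M3 = f)))
    ph$truth$infarcted[ph$truth$region == "M3"]
  })
  expect_identical(got, c(FALSE, TRUE, TRUE))
})

test_that("tabular simulation honours its spec and is reproducible", {
  spec <- tabular_sim_spec(n = 200, seed = 99)
  tab <- simulate_tabular(spec)
  expect_identical(nrow(tab), 2000L)
  expect_identical(tab, simulate_tabular(spec))
  expect_true(all(tab$rhu > 0))
  m_inf <- mean(tab$rhu[tab$infarcted])
  m_non <- mean(tab$rhu[!tab$infarcted])
  expect_lt(abs(m_inf - 0.87), 0.02)
  expect_lt(abs(m_non - 0.97), 0.01)
  prev <- tapply(tab$infarcted, tab$region, mean)
  expect_lt(max(abs(prev[names(spec$prevalence)] - spec$prevalence)), 0.12)
  expect_error(tabular_sim_spec(prevalence = 0), "\\(0, 1\\)")
  expect_error(tabular_sim_spec(sd_infarcted = 0), "> 0")
})

test_that("zero-overlap class distributions make the fitted model perfect", {
  spec <- tabular_sim_spec(n = 80, mean_infarcted = 0.7, mean_normal = 1.2,
                           sd_infarcted = 0.02, sd_normal = 0.02,
                           prevalence = 0.5, seed = 3)
  tab <- simulate_tabular(spec)
  fit <- aspects_cutpoints(tab)
  ev <- evaluate_cutpoints(fit, tab)
  expect_true(all(ev$auc == 1))
  expect_true(all(ev$accuracy == 1))
})

test_that("identical class distributions give chance-level AUC", {
  spec <- tabular_sim_spec(n = 400, mean_infarcted = 0.95, mean_normal = 0.95,
                           sd_infarcted = 0.05, sd_normal = 0.05,
                           prevalence = 0.5, regions = "M1", seed = 5)
  tab <- simulate_tabular(spec)
  a <- auc_mw(tab$rhu, tab$infarcted)
  expect_lt(abs(a - 0.5), 0.08)
})

test_that("the cohort simulator produces consistent patient-level metadata", {
  co <- simulate_cohort(tabular_sim_spec(n = 120, seed = 7))
  p <- co$patients
  expect_identical(nrow(p), 120L)
  expect_identical(p$poor_outcome, p$mrs_3month > 2)
  expect_true(all(p$dwi_aspects >= 0 & p$dwi_aspects <= 10))
  expect_true(all(p$visual_aspects >= 0 & p$visual_aspects <= 10))
  expect_true(all(p$infarct_volume_ml > 0))
  n_inf <- tapply(co$regions$infarcted, co$regions$patient_id, sum)
  expect_identical(unname(10L - as.integer(n_inf[p$patient_id])), p$dwi_aspects)
  # visual reading tracks the DWI score
  expect_gt(cor(p$visual_aspects, p$dwi_aspects, method = "spearman"), 0.5)
})
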