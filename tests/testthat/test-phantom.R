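test_that("noiseless phantom reads exactly the requested clot densities", {
  ph <- simulate_phantom(c(62, 95, 68), noise_sd = 0)
  for (p in c("ncct", "cta", "ctv")) {
    vals <- unique(ph$volumes[[p]][ph$clot_mask])
    expect_length(vals, 1L)
  }
  expect_equal(unique(ph$volumes$ncct[ph$clot_mask]), 62)
  expect_equal(unique(ph$volumes$cta[ph$clot_mask]), 95)
  expect_equal(unique(ph$volumes$ctv[ph$clot_mask]), 68)
  # lumen and background are distinct from the clot
  lumen <- ph$volumes$cta[!ph$clot_mask]
  expect_true(any(lumen > 300))
})

test_that("phantom generation is deterministic for a fixed seed", {
  a <- simulate_phantom(c(62, 95, 68), noise_sd = 5, seed = 123)
  b <- simulate_phantom(c(62, 95, 68), noise_sd = 5, seed = 123)
  expect_identical(a$volumes, b$volumes)
  c_ <- simulate_phantom(c(62, 95, 68), noise_sd = 5, seed = 124)
  expect_false(identical(a$volumes$ncct, c_$volumes$ncct))
})

test_that("noisy clot voxel mean is within standard error of nominal", {
  ph <- simulate_phantom(c(62, 95, 68), noise_sd = 5, seed = 21)
  n_vox <- sum(ph$clot_mask)
  expect_gte(n_vox, 1000)
  se <- 5 / sqrt(n_vox)
  expect_lt(abs(mean(ph$volumes$ncct[ph$clot_mask]) - 62), 3.5 * se)
  expect_lt(abs(mean(ph$volumes$ncct[ph$clot_mask]) - 62), 0.5)
})

test_that("phantom rejects impossible geometry", {
  expect_error(simulate_phantom(c(62, 95, 68), clot_length = 2),
               "configuration error")
  expect_error(simulate_phantom(c(62, 95, 68), spacing = 0.1),
               "configuration error")
  expect_error(simulate_phantom(c(62, 95, 68), vessel_radius = 0.1),
               "configuration error")
})

test_that("three ROIs land at the thirds of a straight clot", {
  ph <- simulate_phantom(c(62, 95, 68), clot_length = 18, noise_sd = 0)
  rois <- place_rois(ph, n = 3, diameter = 1)
  expect_equal(nrow(rois), 3L)
  # clot occupies x in [5, 23] mm (18 mm clot, 5 mm margins)
  frac <- (sort(rois$x_mm) - 5) / 18
  expect_equal(frac, c(1, 3, 5) / 6, tolerance = 0.05)
  # non-overlapping: adjacent centres at least one diameter apart
  expect_true(all(diff(sort(rois$x_mm)) >= 1 - 1e-9))
})

test_that("a 3 mm clot exactly fits three 1 mm ROIs; shorter fails", {
  # thin distal vessel so the clot's long axis is its length
  ph <- simulate_phantom(c(62, 95, 68), clot_length = 3, vessel_radius = 1,
                         noise_sd = 0)
  rois <- place_rois(ph, n = 3, diameter = 1)
  expect_equal(nrow(rois), 3L)
  expect_true(all(diff(sort(rois$x_mm)) >= 1 - 1e-9))
  expect_error(place_rois(ph, n = 4, diameter = 1), "placement error")
  expect_error(place_rois(ph, n = 3, diameter = 1.5), "placement error")
})

test_that("ROI centres stay inside the mask of a curved clot", {
  ph <- simulate_phantom(c(62, 95, 68), clot_length = 24, curvature = 4,
                         noise_sd = 0)
  rois <- place_rois(ph, n = 3, diameter = 1)
  sp <- ph$spacing
  for (i in seq_len(nrow(rois))) {
    vox <- pmin(pmax(ceiling(c(rois$x_mm[i], rois$y_mm[i],
                               rois$z_mm[i]) / sp), 1L),
                dim(ph$clot_mask))
    expect_true(ph$clot_mask[vox[1], vox[2], vox[3]])
  }
})

test_that("measurement averages ROI means, not pooled voxels", {
  ph <- simulate_phantom(c(60, 60, 60), clot_length = 18, noise_sd = 0)
  rois <- place_rois(ph, n = 3, diameter = 1)
  # repaint the voxels of the third ROI sphere to 66 HU on NCCT
  sp <- ph$spacing
  dims <- dim(ph$volumes$ncct)
  cx <- (seq_len(dims[1]) - 0.5) * sp
  cy <- (seq_len(dims[2]) - 0.5) * sp
  cz <- (seq_len(dims[3]) - 0.5) * sp
  i3 <- which.max(rois$x_mm)
  d2 <- outer(outer((cx - rois$x_mm[i3])^2, (cy - rois$y_mm[i3])^2, "+"),
              (cz - rois$z_mm[i3])^2, "+")
  ph$volumes$ncct[d2 <= 0.5^2] <- 66
  m <- mean_roi_density(ph, rois)
  expect_equal(m$ncct_hu, (60 + 60 + 66) / 3)
  roi_means <- attr(m, "roi_means")
  expect_equal(sort(roi_means[, "ncct"]), c(60, 60, 66))
})

test_that("measured densities reproduce noiseless inputs and category", {
  tt <- table2_triplets()
  for (i in seq_len(nrow(tt))) {
    ph <- simulate_phantom(c(tt$ncct_hu[i], tt$cta_hu[i], tt$ctv_hu[i]),
                           noise_sd = 0)
    m <- mean_roi_density(ph, place_rois(ph))
    expect_equal(m$ncct_hu, tt$ncct_hu[i])
    expect_equal(m$cta_hu, tt$cta_hu[i])
    expect_equal(m$ctv_hu, tt$ctv_hu[i])
    lab <- classify_dynamic(compute_tai(m$ncct_hu, m$cta_hu, m$ctv_hu))
    expect_equal(as.character(lab), tt$group[i])
  }
})

test_that("noisy measurement stays within propagated standard error", {
  ph <- simulate_phantom(c(62, 95, 68), noise_sd = 5, seed = 77)
  rois <- place_rois(ph)
  m <- mean_roi_density(ph, rois)
  # each phase mean pools three ROIs of >= 7 voxels each (a 0.5 mm-radius
  # sphere on a 0.5 mm grid holds at least the centre and its 6 neighbours)
  se <- 5 / sqrt(3 * 7)
  expect_lt(abs(m$ncct_hu - 62), 3 * se)
  expect_lt(abs(m$cta_hu - 95), 3 * se)
  expect_lt(abs(m$ctv_hu - 68), 3 * se)
})

test_that("classification is robust to 5 HU noise away from boundaries", {
  # deltas (20, 35, 15): at least 10 HU from every decision boundary
  clot <- c(60, 80, 95)
  wrong <- 0L
  n_rep <- 500L
  for (s in seq_len(n_rep)) {
    ph <- simulate_phantom(clot, noise_sd = 5, seed = 1000L + s)
    m <- mean_roi_density(ph, place_rois(ph))
    lab <- classify_dynamic(compute_tai(m$ncct_hu, m$cta_hu, m$ctv_hu))
    if (as.character(lab) != "C_NW") wrong <- wrong + 1L
  }
  expect_lt(wrong / n_rep, 0.05)
})

test_that("phantom volumes survive a NIfTI round trip", {
  ph <- simulate_phantom(c(62, 95, 68), noise_sd = 3, seed = 5)
  dir <- withr::local_tempdir()
  paths <- write_phantom(ph, dir)
  back <- read_phantom(paths[["ncct"]], paths[["cta"]], paths[["ctv"]],
                       paths[["mask"]])
  expect_equal(back$spacing, ph$spacing, tolerance = 1e-6)
  expect_equal(dim(back$volumes$ncct), dim(ph$volumes$ncct))
  expect_equal(as.vector(back$volumes$cta), as.vector(ph$volumes$cta),
               tolerance = 1e-6)
  expect_identical(back$clot_mask, ph$clot_mask)

  m_disk <- measure_densities(paths[["ncct"]], paths[["cta"]],
                              paths[["ctv"]], paths[["mask"]])
  m_mem <- mean_roi_density(ph, place_rois(ph))
  expect_equal(m_disk$ncct_hu, m_mem$ncct_hu, tolerance = 1e-6)
  expect_equal(m_disk$cta_hu, m_mem$cta_hu, tolerance = 1e-6)
})

test_that("injected misregistration perturbs the contrast-phase reading", {
  clean <- simulate_phantom(c(62, 95, 68), noise_sd = 0)
  shifted <- simulate_phantom(c(62, 95, 68), noise_sd = 0,
                              misregistration = list(cta = c(30, 0, 0)))
  rois <- place_rois(clean)
  m_clean <- mean_roi_density(clean, rois)
  m_shift <- mean_roi_density(shifted, rois)
  expect_equal(m_clean$cta_hu, 95)
  expect_false(isTRUE(all.equal(m_shift$cta_hu, 95)))
  # the unshifted phases are untouched
  expect_equal(m_shift$ncct_hu, 62)
  expect_equal(m_shift$ctv_hu, 68)
})
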