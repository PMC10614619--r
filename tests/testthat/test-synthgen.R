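# Synthetic-scene generator: rendering rules, planted truth, determinism.

test_that("tubule rendering satisfies the circumference rule F_l = rho*pi*d", {
  # no blur, no noise: integrated cross-profile per nm equals rho*pi*d
  tub <- membrane_object("tubule",
                         centerline_nm = rbind(c(2000, 5000), c(18000, 5000)),
                         diameter_nm = 50, lipid_density = 10)
  sc <- render_scene(list(tub), optics_ideal(), c(100L, 200L), 100, "lipid")
  img <- unclass(sc$images$lipid)
  # column sums away from the ends = F_l * pixel_size
  for (col in c(60, 100, 140))
    expect_equal(sum(img[, col]), 10 * pi * 50 * 100, tolerance = 1e-6)
})

test_that("PSF blur preserves integrated cross-profile intensity for any
          sub-resolution diameter", {
  for (d in c(29, 55.4, 107)) {
    for (sigma in c(80, 120, 200)) {
      tub <- membrane_object("tubule",
                             centerline_nm = rbind(c(2000, 5000),
                                                   c(18000, 5000)),
                             diameter_nm = d, lipid_density = 5)
      opt <- optics_model(psf_sigma_nm = sigma, photons_per_unit = 0,
                          read_noise_sd = 0, background_level = 0)
      sc <- render_scene(list(tub), opt, c(100L, 200L), 100, "lipid")
      expect_equal(sum(unclass(sc$images$lipid)[, 100]), 5 * pi * d * 100,
                   tolerance = 1e-6, label = sprintf("d=%g sigma=%g", d, sigma))
    }
  }
})

test_that("flat film renders at lipid_density * pixel_area per pixel", {
  film <- membrane_object("flat_film", lipid_density = 5)
  sc <- render_scene(list(film), optics_ideal(), c(32L, 32L), 100, "lipid")
  expect_equal(mean(sc$images$lipid), 5 * 100^2)
  expect_true(all(abs(unclass(sc$images$lipid) - 50000) < 1e-9))
})

test_that("rendering is linear in lipid density (background excluded)", {
  mk <- function(rho) {
    obj <- membrane_object("tubule",
                           centerline_nm = rbind(c(1000, 2000), c(9000, 2500)),
                           diameter_nm = 80, lipid_density = rho)
    render_scene(list(obj), noiseless_optics(), c(50L, 100L), 100,
                 "lipid")$images$lipid
  }
  expect_equal(unclass(mk(10)), 2 * unclass(mk(5)), tolerance = 1e-12)
})

test_that("same seed gives bit-identical images; different seeds differ", {
  obj <- membrane_object("vesicle", center_nm = c(5000, 5000),
                         radius_nm = 1500)
  a <- render_scene(list(obj), optics_model(), c(64L, 64L), 100, "lipid",
                    seed = 11)
  b <- render_scene(list(obj), optics_model(), c(64L, 64L), 100, "lipid",
                    seed = 11)
  c <- render_scene(list(obj), optics_model(), c(64L, 64L), 100, "lipid",
                    seed = 12)
  expect_identical(unclass(a$images$lipid), unclass(b$images$lipid))
  expect_false(identical(unclass(a$images$lipid), unclass(c$images$lipid)))
})

test_that("empty object list renders a valid background-only scene and
          negative densities are rejected", {
  sc <- render_scene(list(), optics_model(), c(16L, 16L), 100, "lipid",
                     seed = 3)
  expect_true(all(unclass(sc$images$lipid) >= 0))
  expect_true(all(sc$truth$true_label_map == 0L))
  expect_error(membrane_object("vesicle", center_nm = c(0, 0),
                               radius_nm = 100, lipid_density = -1),
               "lipid_density")
  expect_error(membrane_object("tubule",
                               centerline_nm = rbind(c(0, 0), c(1, 1)),
                               diameter_nm = 50, protein_enrichment = -2),
               "protein_enrichment")
})

test_that("label map partitions the image and truth ratio is pixel-derived", {
  sc <- make_tubulation_scene(0.5, seed = 7)
  lab <- sc$truth$true_label_map
  expect_setequal(unique(as.vector(lab)), c(0L, 1L, 2L))
  expect_identical(sum(lab == 0L) + sum(lab == 1L) + sum(lab == 2L),
                   length(lab))
  # planted ratio is literally the label-map pixel count ratio
  expect_equal(sc$truth$true_tubulation_ratio,
               sum(lab == 1L) / (sum(lab == 1L) + sum(lab == 2L)))
  expect_lte(abs(sc$truth$true_tubulation_ratio - 0.5), 0.02)
})

test_that("tubulation boundary targets produce pure scenes", {
  s0 <- make_tubulation_scene(0, n_objects = 10L, seed = 1)
  expect_identical(s0$truth$true_tubulation_ratio, 0)
  expect_true(all(s0$truth$true_label_map != 1L))
  s1 <- make_tubulation_scene(1, n_objects = 10L, seed = 1)
  expect_identical(s1$truth$true_tubulation_ratio, 1)
  expect_true(all(s1$truth$true_label_map != 2L))
})

test_that("infeasible packings raise an explicit error", {
  expect_error(make_tubulation_scene(0.5, n_objects = 400L,
                                     image_shape = c(64L, 64L), seed = 1,
                                     max_tries = 20L),
               "infeasible|packing|place")
})

test_that("GUV + tubule scene passes planted values through and the lipid
          signal scales with diameter", {
  sc <- make_guv_tubule_scene(enrichment = 3, tubule_diameter_nm = 60,
                              seed = 2)
  expect_equal(sc$truth$true_sorting_ratio, 3)
  expect_equal(sc$truth$true_diameters_nm, 60)
  expect_error(make_guv_tubule_scene(enrichment = -1), "enrichment")
  # equal protein areal densities, diameters 55 and 90: lipid F_l ratio 90/55
  mk <- function(d) {
    s <- make_guv_tubule_scene(tubule_diameter_nm = d, enrichment = 1,
                               optics = noiseless_optics())
    pr <- extract_profile(s$lipid, s$truth$tubule_centerline_px, 2000)
    mean(pr$f_l)
  }
  expect_equal(mk(90) / mk(55), 90 / 55, tolerance = 1e-3)
})

test_that("scaffold scene plants per-segment truth in order", {
  segs <- data.frame(length_nm = c(4000, 3000, 4000),
                     diameter_nm = c(80, 55, 80),
                     protein_enrichment = c(1, 10, 1))
  sc <- make_scaffold_scene(segs, noiseless_optics(), seed = 1)
  expect_equal(sc$truth$segments$diameter_nm, c(80, 55, 80))
  expect_equal(sc$truth$segments$covered, c(FALSE, TRUE, FALSE))
  expect_equal(sc$truth$segments$end_nm - sc$truth$segments$start_nm,
               segs$length_nm)
  # lipid F_l steps by the diameter ratio at the boundary (noiseless)
  pr <- extract_profile(sc$lipid, sc$truth$tubule_centerline_px, 2000)
  mid <- function(a, b) mean(pr$f_l[pr$arc_nm > a & pr$arc_nm < b])
  expect_equal(mid(5000, 6500) / mid(1000, 3000), 55 / 80, tolerance = 0.01)
  expect_error(make_scaffold_scene(data.frame(length_nm = -5,
                                              diameter_nm = 50,
                                              protein_enrichment = 1)),
               "positive")
})

test_that("FRAP trace generator honours its closed form", {
  # mobile fraction 1: returns to prebleach as t -> Inf
  tr <- make_frap_trace(1, tau_s = 2, times_s = seq(0, 100), noise_sd = 0)
  expect_equal(tail(tr$intensity, 1), 100 + 10, tolerance = 1e-8)
  # mobile fraction 0: flat at the bleached level
  tr0 <- make_frap_trace(0, times_s = seq(0, 50), noise_sd = 0)
  post <- tr0$intensity[tr0$bleach_index:51]
  expect_true(all(abs(post - (100 * 0.2 + 10)) < 1e-9))
  # recovered fraction 0.5*(1 - e^-1) at t = tau after bleach
  tr5 <- make_frap_trace(0.5, tau_s = 5, times_s = seq(0, 30),
                         bleach_depth = 0.8, noise_sd = 0)
  t0 <- tr5$time_s[tr5$bleach_index]
  i_at_tau <- tr5$intensity[tr5$time_s == t0 + 5] - 10
  depth <- 100 - 20
  expect_equal((i_at_tau - 20) / depth, 0.5 * (1 - exp(-1)),
               tolerance = 1e-9)
  expect_error(make_frap_trace(0.5, times_s = c(0, 1, 1, 2)),
               "increasing")
})
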