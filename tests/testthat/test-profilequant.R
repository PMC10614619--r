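# Profile extraction, flat-film calibration, radius estimation, sorting
# ratio and scaffold-segment analysis.

test_that("profile over a constant image integrates to value x width", {
  img <- fluor_image(matrix(3, 60, 60), 100)
  pr <- extract_profile(img, rbind(c(20, 30), c(40, 30)), width_nm = 1000)
  # cross-section integral = c * width_px; background bands see the same
  # constant, so F_l is ~0 after correction
  expect_true(all(abs(pr$cross_sum - 3 * pr$width_px) < 1e-9))
  expect_true(all(abs(pr$f_l) < 1e-9))
  expect_equal(pr$background_per_px, 3)
  expect_error(extract_profile(img, rbind(c(2, 2), c(59, 59)), 2000),
               "exits")
})

test_that("profile along a noiseless tubule is uniform and recovers F_l", {
  sc <- straight_tubule_scene(60, noiseless_optics(100))
  pr <- extract_profile(sc$image, sc$centerline_px, width_nm = 2000)
  expect_lt(stats::sd(pr$f_l) / mean(pr$f_l), 0.01)
  expect_equal(mean(pr$f_l), 5 * pi * 60, tolerance = 1e-6)
  expect_equal(pr$background_per_px, 100, tolerance = 1e-9)
})

test_that("rho0 calibration inverts the rendering rule", {
  sc <- make_flat_film_scene(optics_ideal())
  cal <- estimate_rho0(sc$image, sc$truth$film_roi)
  expect_equal(cal$rho0, 5, tolerance = 1e-12)
  # a uniform offset is removed by the background ROI
  off <- fluor_image(unclass(sc$image) + 100, 100)
  cal2 <- estimate_rho0(off, sc$truth$film_roi,
                        background_roi = sc$truth$background_roi)
  expect_equal(cal2$rho0, 5, tolerance = 1e-12)
  # Poisson-noised film: within 1 percent by averaging
  scn <- make_flat_film_scene(optics_model(), seed = 8)
  caln <- estimate_rho0(scn$image, scn$truth$film_roi,
                        scn$truth$background_roi)
  expect_lt(abs(caln$rho0 - 5) / 5, 0.01)
  # all-background ROI fails loudly
  expect_error(estimate_rho0(scn$image, scn$truth$background_roi,
                             scn$truth$background_roi), "rho0")
})

test_that("estimate_radius implements r = F_l / (2 pi rho0) exactly", {
  cal <- structure(list(rho0 = 10, background = 0, pixel_size_nm = 100,
                        channel = "lipid", roi = NULL),
                   class = "flat_film_calibration")
  m <- estimate_radius(3141.59, cal)
  expect_equal(m$radius_nm, 3141.59 / (2 * pi * 10))
  expect_equal(m$radius_nm, 50, tolerance = 1e-4)
  expect_equal(m$diameter_nm, 2 * m$radius_nm)
  # linear in F_l, inverse in rho0
  expect_equal(estimate_radius(2 * 3141.59, cal)$radius_nm, 2 * m$radius_nm)
  cal2 <- cal; cal2$rho0 <- 20
  expect_equal(estimate_radius(3141.59, cal2)$radius_nm, m$radius_nm / 2)
  # degenerate and invalid inputs
  z <- estimate_radius(0, cal)
  expect_true(z$degenerate)
  expect_equal(z$radius_nm, 0)
  expect_error(estimate_radius(-1, cal), "non-negative")
  expect_error(estimate_radius(10, NULL), "calibration")
})

test_that("noiseless end-to-end radius inversion is within 1 percent", {
  sc <- straight_tubule_scene(60, noiseless_optics(50))
  film <- make_flat_film_scene(noiseless_optics(50))
  cal <- estimate_rho0(film$image, film$truth$film_roi,
                       film$truth$background_roi)
  m <- measure_tubule_diameter(sc$image, sc$centerline_px, cal)
  expect_equal(m$diameter_nm, 60, tolerance = 0.01)
})

test_that("sorting ratio arithmetic and failure diagnostics", {
  fake_pr <- function(fl) structure(list(arc_nm = seq_along(fl), f_l = fl,
                                         step_nm = 1),
                                    class = "line_profile")
  s <- sorting_ratio(fake_pr(200), fake_pr(100), fake_pr(2), fake_pr(1))
  expect_equal(s$sorting_ratio, 1)
  s3 <- sorting_ratio(fake_pr(300), fake_pr(100), fake_pr(1), fake_pr(1))
  expect_equal(s3$sorting_ratio, 3)
  expect_error(sorting_ratio(fake_pr(300), fake_pr(100), fake_pr(-1),
                             fake_pr(1)), "protein_guv")
})

test_that("sorting ratio is gain- and offset-invariant", {
  sc <- make_guv_tubule_scene(enrichment = 2, seed = 31)
  base <- guv_sorting_ratio(sc$lipid, sc$protein,
                            sc$truth$tubule_centerline_px,
                            sc$truth$guv_arc_px)
  # exact invariance under channel gain rescaling
  pro_scaled <- fluor_image(unclass(sc$protein) * 7.3, 100, "protein")
  lip_scaled <- fluor_image(unclass(sc$lipid) * 0.2, 100, "lipid")
  s2 <- guv_sorting_ratio(lip_scaled, pro_scaled,
                          sc$truth$tubule_centerline_px,
                          sc$truth$guv_arc_px)
  expect_equal(s2$sorting_ratio, base$sorting_ratio, tolerance = 1e-12)
  # offset invariance via flanking-band background subtraction (noiseless)
  scn <- make_guv_tubule_scene(enrichment = 2,
                               optics = noiseless_optics(0), seed = 1)
  s_off <- guv_sorting_ratio(
    fluor_image(unclass(scn$lipid) + 40, 100, "lipid"),
    fluor_image(unclass(scn$protein) + 90, 100, "protein"),
    scn$truth$tubule_centerline_px, scn$truth$guv_arc_px)
  s_ref <- guv_sorting_ratio(scn$lipid, scn$protein,
                             scn$truth$tubule_centerline_px,
                             scn$truth$guv_arc_px)
  expect_equal(s_off$sorting_ratio, s_ref$sorting_ratio, tolerance = 1e-6)
})

test_that("scaffold analysis recovers segments, diameters and flags", {
  sc <- make_scaffold_scene(data.frame(length_nm = c(5000, 3000),
                                       diameter_nm = c(80, 55),
                                       protein_enrichment = c(1, 10)),
                            noiseless_optics(0))
  film <- make_flat_film_scene(noiseless_optics(0))
  cal <- estimate_rho0(film$image, film$truth$film_roi,
                       film$truth$background_roi)
  seg <- analyze_scaffold_tubule(sc$lipid, sc$protein,
                                 sc$truth$tubule_centerline_px, cal)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$covered, c(FALSE, TRUE))
  expect_equal(seg$diameter_nm, c(80, 55), tolerance = 0.01)
  # ordered along the centerline
  expect_true(all(diff(seg$start_nm) > 0))
})

test_that("uniform protein cover yields a single uncovered segment", {
  sc <- make_scaffold_scene(data.frame(length_nm = 6000, diameter_nm = 70,
                                       protein_enrichment = 1),
                            noiseless_optics(0))
  seg <- analyze_scaffold_tubule(sc$lipid, sc$protein,
                                 sc$truth$tubule_centerline_px,
                                 shared_calibration())
  expect_equal(nrow(seg), 1L)
  expect_false(seg$covered)
})

test_that("swapped channels are rejected by the lipid-step guard", {
  sc <- make_scaffold_scene(data.frame(length_nm = c(5000, 3000),
                                       diameter_nm = c(80, 55),
                                       protein_enrichment = c(1, 10)),
                            noiseless_optics(0))
  expect_error(analyze_scaffold_tubule(sc$protein, sc$lipid,
                                       sc$truth$tubule_centerline_px,
                                       shared_calibration()),
               "swapped")
})

test_that("too-short centerlines are rejected", {
  sc <- make_scaffold_scene(data.frame(length_nm = 6000, diameter_nm = 70,
                                       protein_enrichment = 1),
                            noiseless_optics(0))
  short <- rbind(sc$truth$tubule_centerline_px[1, ],
                 sc$truth$tubule_centerline_px[1, ] + c(2, 0))
  expect_error(analyze_scaffold_tubule(sc$lipid, sc$protein, short,
                                       shared_calibration(),
                                       min_run_nm = 500),
               "shorter")
})
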