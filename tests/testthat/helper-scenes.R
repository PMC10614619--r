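# Shared fixtures, generated once per session and memoized.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

noiseless_optics <- function(background = 0)
  optics_model(psf_sigma_nm = 120, photons_per_unit = 0, read_noise_sd = 0,
               background_level = background)

# six seeded training scenes spanning the ratio range, plus a forest
training_scenes <- function() cached_fixture("train_scenes", {
  targets <- c(0.2, 0.4, 0.5, 0.6, 0.8, 0.5)
  lapply(seq_along(targets), function(i)
    make_tubulation_scene(targets[i], seed = 100 + i))
})

shared_model <- function() cached_fixture("model", {
  sc <- training_scenes()
  train_classifier(lapply(sc, `[[`, "image"),
                   lapply(sc, function(s) s$truth$true_label_map),
                   seed = 1L)
})

# one straight sub-resolution tubule, for calibration tests
straight_tubule_scene <- function(diameter_nm, optics = optics_model(),
                                  seed = NULL, lipid_density = 5,
                                  pixel_size_nm = 100) {
  tub <- membrane_object("tubule",
                         centerline_nm = rbind(c(2000, 5000),
                                               c(18000, 5000)),
                         diameter_nm = diameter_nm,
                         lipid_density = lipid_density)
  sc <- render_scene(list(tub), optics, c(100L, 200L), pixel_size_nm,
                     "lipid", seed = seed)
  list(image = sc$images$lipid, truth = sc$truth,
       centerline_px = rbind(c(40, 50), c(160, 50)))
}

shared_calibration <- function() cached_fixture("calib", {
  sc <- make_flat_film_scene(seed = 424242)
  estimate_rho0(sc$image, sc$truth$film_roi, sc$truth$background_roi)
})
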