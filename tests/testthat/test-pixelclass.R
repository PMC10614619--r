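# Feature bank, pixel classifier, object geometry and shape reassignment.

test_that("features of a constant image have zero derivatives", {
  img <- fluor_image(matrix(7, 20, 20), 100)
  fs <- compute_features(img, scales = c(1, 2))
  deriv <- grep("gradmag|laplacian|ridge", fs$names)
  expect_true(all(abs(fs$values[, deriv]) < 1e-9))
  expect_true(all(abs(fs$values[, grep("gauss", fs$names)] - 7) < 1e-9))
  expect_error(compute_features(img, scales = numeric()), "scale")
})

test_that("Gaussian feature of a single bright pixel matches direct
          convolution", {
  m <- matrix(0, 21, 21); m[11, 11] <- 1
  fs <- compute_features(fluor_image(m, 100), scales = 2)
  got <- matrix(fs$values[, "gauss_s2"], 21, 21)
  # independent oracle: direct summation with the same truncated kernel
  h <- ceiling(3 * 2)
  k <- exp(-((-h:h)^2) / (2 * 2^2)); k <- k / sum(k)
  expected <- outer(k, k)  # centred at [11, 11], no border effects here
  expect_equal(got[(11 - h):(11 + h), (11 - h):(11 + h)], expected,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("feature stack is mirror-symmetric (signless features)", {
  set.seed(5)
  m <- matrix(runif(400), 20, 20)
  fs <- compute_features(fluor_image(m, 100), scales = c(1, 2))
  fsm <- compute_features(fluor_image(m[, 20:1], 100), scales = c(1, 2))
  for (j in seq_len(ncol(fs$values))) {
    a <- matrix(fs$values[, j], 20, 20)
    b <- matrix(fsm$values[, j], 20, 20)[, 20:1]
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("training requires all three classes", {
  sc <- training_scenes()[[1]]
  lab <- sc$truth$true_label_map
  lab2 <- lab; lab2[lab2 == 1L] <- 2L  # drop the tubule class
  expect_error(train_classifier(sc$image, lab2, seed = 1),
               "tubule.*absent|absent.*tubule")
})

test_that("classifier is deterministic given the seed and accurate on its
          own noiseless training image", {
  sc <- make_tubulation_scene(0.5, optics = noiseless_optics(50), seed = 55)
  m1 <- train_classifier(sc$image, sc$truth$true_label_map, seed = 9,
                         ntree = 30L)
  m2 <- train_classifier(sc$image, sc$truth$true_label_map, seed = 9,
                         ntree = 30L)
  p1 <- predict_labels(m1, sc$image)
  p2 <- predict_labels(m2, sc$image)
  expect_identical(p1, p2)
  expect_gte(mean(p1 == sc$truth$true_label_map), 0.99)
})

test_that("held-out scenes are classified with >= 0.90 pixel accuracy", {
  model <- shared_model()
  for (s in c(901, 902)) {
    sc <- make_tubulation_scene(0.5, seed = s)
    acc <- mean(predict_labels(model, sc$image) == sc$truth$true_label_map)
    expect_gte(acc, 0.90)
  }
})

test_that("noiseless scenes match planted labels away from PSF borders", {
  model <- shared_model()
  sc <- make_tubulation_scene(0.5, optics = noiseless_optics(50), seed = 77)
  lab <- predict_labels(model, sc$image)
  truth <- sc$truth$true_label_map
  # exclude pixels within one PSF sigma (rounded up, px) of a class boundary
  b <- ceiling(120 / 100)
  bound <- truth != truth[c(1, seq_len(nrow(truth) - 1)), ] |
    truth != truth[, c(1, seq_len(ncol(truth) - 1))]
  excl <- matrix(FALSE, nrow(truth), ncol(truth))
  w <- which(bound, arr.ind = TRUE)
  for (k in seq_len(nrow(w))) {
    rr <- max(1, w[k, 1] - b):min(nrow(truth), w[k, 1] + b)
    cc <- max(1, w[k, 2] - b):min(ncol(truth), w[k, 2] + b)
    excl[rr, cc] <- TRUE
  }
  expect_gte(mean((lab == truth)[!excl]), 0.98)
})

test_that("a blank background image predicts all background", {
  model <- shared_model()
  blank <- render_scene(list(), optics_model(), c(64L, 64L), 100, "lipid",
                        seed = 1)$images$lipid
  lab <- predict_labels(model, blank)
  expect_gte(mean(lab == 0L), 0.999)
})

test_that("prediction commutes with 90-degree rotation away from borders", {
  model <- shared_model()
  sc <- make_tubulation_scene(0.5, seed = 404)
  img <- sc$image
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]  # counter-clockwise
  p <- predict_labels(model, img)
  pr <- predict_labels(model, fluor_image(rot90(unclass(img)), 100))
  inner <- 5:(nrow(img) - 5)
  agree <- mean(rot90(unclass(p))[inner, inner] == unclass(pr)[inner, inner])
  expect_gte(agree, 0.99)
})

test_that("extract_objects recovers disk and line geometry analytically", {
  lab <- matrix(0L, 60, 240)
  # 100-px-ish disk (radius 6) labelled vesicle
  for (r in 1:60) for (c in 1:30) {
    if ((r - 20)^2 + (c - 15)^2 <= 6^2) lab[r, c] <- 2L
  }
  # 3-px-wide, 200-px-long horizontal line labelled tubule
  lab[40:42, 21:220] <- 1L
  attr(lab, "pixel_size_nm") <- 100
  obj <- extract_objects(lab, 100)
  expect_equal(nrow(obj), 2L)
  disk <- obj[obj$class == "vesicle", ]
  line <- obj[obj$class == "tubule", ]
  expect_lt(disk$elongation, 1.1)
  expect_equal(disk$major_axis_nm, 2 * 6 * 100, tolerance = 0.1)
  expect_gte(line$elongation, 10)
  expect_equal(line$skeleton_length_nm, 200 * 100, tolerance = 0.05)
  expect_equal(line$mean_width_nm, 300, tolerance = 0.05)
  # empty map
  empty <- matrix(0L, 5, 5); attr(empty, "pixel_size_nm") <- 100
  expect_identical(nrow(extract_objects(empty, 100)), 0L)
})

test_that("speckles below min_object_area_px are dropped", {
  lab <- matrix(0L, 20, 20)
  lab[3, 3] <- 1L                  # 1-px speckle
  lab[10:15, 10:15] <- 2L          # 36-px object
  attr(lab, "pixel_size_nm") <- 100
  obj <- extract_objects(lab, 100, min_object_area_px = 10L)
  expect_equal(nrow(obj), 1L)
  expect_equal(obj$area_px, 36L)
})

test_that("shape reassignment is one-directional, idempotent and monotone", {
  objects <- data.frame(
    id = 1:4,
    class = c("tubule", "tubule", "vesicle", "tubule"),
    area_px = c(120, 300, 500, 30),
    area_nm2 = c(120, 300, 500, 30) * 1e4,
    major_axis_nm = c(1100, 8000, 4000, 500),
    minor_axis_nm = c(1000, 1000, 500, 450),
    elongation = c(1.05, 8, 8, 1.1),
    skeleton_length_nm = c(1000, 20000, 6000, 400),
    mean_width_nm = c(1200, 300, 800, 750),
    centroid_x_px = 0, centroid_y_px = 0)
  out <- reassign_by_shape(objects, shape_criteria())
  # round disk mislabelled tubule -> vesicle; good tubule stays;
  # elongated vesicle stays vesicle; small object -> vesicle
  expect_equal(out$class, c("vesicle", "tubule", "vesicle", "vesicle"))
  expect_identical(out$id, objects$id)          # order preserved
  out2 <- reassign_by_shape(out, shape_criteria())
  expect_equal(out2$class, out$class)           # idempotent
  expect_true(all(out$class %in% c("tubule", "vesicle")))
  # monotonicity: raising the elongation threshold never adds tubules
  n_tub <- vapply(c(1, 2, 3, 5, 9, 20), function(th)
    sum(reassign_by_shape(objects,
                          shape_criteria(min_tubule_elongation = th))$class ==
          "tubule"), 0L)
  expect_true(all(diff(n_tub) <= 0))
  expect_error(shape_criteria(min_tubule_elongation = -1), "positive")
})
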