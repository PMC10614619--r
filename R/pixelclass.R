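# Trainable pixel classification of fluorescence images into background,
# tubule and vesicle, in the spirit of the Trainable Weka Segmentation
# workflow: a multi-scale feature bank feeds a seeded random-forest pixel
# classifier, and connected components of the resulting label map are then
# re-examined with area/shape criteria (see reassign_by_shape).

FEATURE_PER_SCALE <- c("gauss", "gradmag", "laplacian", "hess_max",
                       "hess_min", "ridge")

#' Multi-scale per-pixel feature stack
#'
#' Computes, per scale sigma (in pixels): Gaussian smoothing, gradient
#' magnitude, Laplacian, the two Hessian eigenvalues (sorted), and the ridge
#' measure (difference of Hessian eigenvalues), plus the raw intensity.
#' Derivatives are taken on the Gaussian-smoothed image with central
#' differences; borders are handled by reflection padding, so the stack is
#' translation-equivariant away from borders and exactly equivariant under
#' 90-degree rotations and mirrorings.
#'
#' @param image a [fluor_image()] (or plain matrix).
#' @param scales vector of Gaussian scales sigma in pixels (>= 1 scale).
#' @return a `feature_stack`: list with `values` (n_pixels x n_features
#'   matrix, pixels in column-major order), `names`, `dim`, `scales`.
#' @export
compute_features <- function(image, scales = c(1, 2, 4)) {
  if (length(scales) < 1L) stop("need at least one scale")
  px <- as_matrix(image)
  nr <- nrow(px); nc <- ncol(px)
  dx <- c(-0.5, 0, 0.5)
  id <- 1
  feats <- list(raw = as.vector(px))
  for (s in scales) {
    g <- blur_image(px, s)
    gx <- cpp_conv_sep(g, 1, dx)
    gy <- cpp_conv_sep(g, dx, 1)
    gxx <- cpp_conv_sep(gx, 1, dx)
    gyy <- cpp_conv_sep(gy, dx, 1)
    gxy <- cpp_conv_sep(gx, dx, 1)
    tr2 <- (gxx + gyy) / 2
    disc <- sqrt(((gxx - gyy) / 2)^2 + gxy^2)
    feats[[paste0("gauss_s", s)]] <- as.vector(g)
    feats[[paste0("gradmag_s", s)]] <- as.vector(sqrt(gx^2 + gy^2))
    feats[[paste0("laplacian_s", s)]] <- as.vector(gxx + gyy)
    feats[[paste0("hess_max_s", s)]] <- as.vector(tr2 + disc)
    feats[[paste0("hess_min_s", s)]] <- as.vector(tr2 - disc)
    feats[[paste0("ridge_s", s)]] <- as.vector(2 * disc)
  }
  vals <- do.call(cbind, feats)
  if (any(!is.finite(vals))) stop("non-finite feature values")
  structure(list(values = vals, names = colnames(vals), dim = c(nr, nc),
                 scales = scales), class = "feature_stack")
}

CLASS_LEVELS <- c("background", "tubule", "vesicle")

#' Train a background/tubule/vesicle pixel classifier
#'
#' Fits a seeded random forest (the Weka plugin's default family) on a
#' stratified sample of labelled pixels from one or more training images.
#' Training is deterministic given `seed` and the training set.
#'
#' @param images list of [fluor_image()] (a single image is accepted).
#' @param truths list of label maps (integer matrices with values 0 =
#'   background, 1 = tubule, 2 = vesicle) matching `images`.
#' @param scales feature scales in pixels, see [compute_features()].
#' @param seed integer seed for sampling and forest growth.
#' @param n_per_class pixels sampled per class per image.
#' @param ntree,max_depth,min_node,mtry forest hyper-parameters; `mtry`
#'   defaults to the rounded square root of the feature count.
#' @return a `pixel_classifier`.
#' @export
train_classifier <- function(images, truths, scales = c(1, 2, 4), seed = 1L,
                             n_per_class = 2000L, ntree = 50L,
                             max_depth = 12L, min_node = 5L, mtry = NULL) {
  if (inherits(images, "fluor_image")) images <- list(images)
  if (is.matrix(truths)) truths <- list(truths)
  if (length(images) < 1L || length(images) != length(truths))
    stop("need matching non-empty lists of images and label maps")
  all_lab <- unlist(lapply(truths, as.vector))
  for (k in 0:2)
    if (!any(all_lab == k))
      stop("class '", CLASS_LEVELS[k + 1],
           "' absent from training labels; all three classes are required")
  set.seed(seed)
  Xs <- list(); ys <- list()
  for (i in seq_along(images)) {
    fs <- compute_features(images[[i]], scales)
    lab <- as.vector(unclass(truths[[i]]))
    for (k in 0:2) {
      idx <- which(lab == k)
      if (length(idx) == 0L) next
      take <- if (length(idx) > n_per_class)
        sample(idx, n_per_class) else idx
      Xs[[length(Xs) + 1L]] <- fs$values[take, , drop = FALSE]
      ys[[length(ys) + 1L]] <- rep.int(k, length(take))
    }
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys)
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(2L, round(sqrt(p)))
  forest <- cpp_rf_train(X, as.integer(y), as.integer(ntree),
                         as.integer(mtry), as.integer(max_depth),
                         as.integer(min_node), 3L)
  structure(list(forest = forest, scales = scales, seed = seed,
                 n_features = p, ntree = ntree,
                 n_train = nrow(X), classes = CLASS_LEVELS),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(paste0("<pixel_classifier> %d trees, %d features ",
                     "(scales %s), %d training pixels, seed %d\n"),
              x$ntree, x$n_features,
              paste(x$scales, collapse = "/"), x$n_train, x$seed))
  invisible(x)
}

#' Predict a 3-class label map for an image
#'
#' @param model a trained [train_classifier()] model.
#' @param image a [fluor_image()].
#' @return an integer `label_map` matrix (0 background, 1 tubule,
#'   2 vesicle) with the image's pixel size attached.
#' @export
predict_labels <- function(model, image) {
  if (!inherits(model, "pixel_classifier")) stop("model is not a pixel_classifier")
  fs <- compute_features(image, model$scales)
  if (ncol(fs$values) != model$n_features)
    stop("feature mismatch: image features (", ncol(fs$values),
         ") differ from training configuration (", model$n_features, ")")
  pred <- cpp_rf_predict(model$forest, fs$values, 3L)
  lab <- matrix(as.integer(pred), fs$dim[1], fs$dim[2])
  attr(lab, "pixel_size_nm") <- pixel_size(image)
  lab
}

#' Connected-component geometry of a label map
#'
#' Extracts one record per 8-connected foreground component (labels 1 or 2).
#' The component class is the majority pixel class.  Axis lengths follow the
#' image-moments ellipse convention (axis = 4 sqrt(eigenvalue of the pixel
#' covariance)), so a disk has elongation ~1.  The skeleton length is the
#' polyline length of the Zhang-Suen skeleton and the mean width is
#' area / skeleton length.
#'
#' @param labels a label map from [predict_labels()] (or a truth map).
#' @param pixel_size_nm pixel size; defaults to the map's attribute.
#' @param min_object_area_px components smaller than this are dropped
#'   (speckle filter).
#' @return data.frame with columns `id`, `class`, `area_px`, `area_nm2`,
#'   `major_axis_nm`, `minor_axis_nm`, `elongation`, `skeleton_length_nm`,
#'   `mean_width_nm`, `centroid_x_px`, `centroid_y_px`.
#' @export
extract_objects <- function(labels, pixel_size_nm = pixel_size(labels),
                            min_object_area_px = 10L) {
  lab <- unclass(labels)
  mask <- matrix(as.integer(lab > 0L), nrow(lab), ncol(lab))
  comp <- cpp_label_components(mask, TRUE)
  ncomp <- max(comp)
  out <- vector("list", ncomp)
  px <- pixel_size_nm
  for (i in seq_len(ncomp)) {
    idx <- which(comp == i)
    if (length(idx) < min_object_area_px) next
    rows <- (idx - 1L) %% nrow(lab) + 1L
    cols <- (idx - 1L) %/% nrow(lab) + 1L
    cls_px <- lab[idx]
    cls <- if (sum(cls_px == 1L) >= sum(cls_px == 2L)) "tubule" else "vesicle"
    # central second moments (+1/12 pixel-footprint term, as in ImageJ/skimage)
    mr <- mean(rows); mc <- mean(cols)
    crr <- mean((rows - mr)^2) + 1 / 12
    ccc <- mean((cols - mc)^2) + 1 / 12
    crc <- mean((rows - mr) * (cols - mc))
    tr2 <- (crr + ccc) / 2
    disc <- sqrt(((crr - ccc) / 2)^2 + crc^2)
    major <- 4 * sqrt(max(tr2 + disc, 0))
    minor <- 4 * sqrt(max(tr2 - disc, 1e-9))
    # skeleton of the component only
    sub <- matrix(0L, max(rows) - min(rows) + 3L, max(cols) - min(cols) + 3L)
    sub[cbind(rows - min(rows) + 2L, cols - min(cols) + 2L)] <- 1L
    sk <- cpp_thin(sub)
    sk_len_px <- skeleton_length_px(sk)
    area_px <- length(idx)
    out[[i]] <- data.frame(
      id = i, class = cls, area_px = area_px, area_nm2 = area_px * px^2,
      major_axis_nm = major * px, minor_axis_nm = minor * px,
      elongation = major / minor,
      skeleton_length_nm = sk_len_px * px,
      mean_width_nm = if (sk_len_px > 0) area_px * px / sk_len_px else NA_real_,
      centroid_x_px = mc - 1, centroid_y_px = mr - 1)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(id = integer(), class = character(),
                      area_px = integer(), area_nm2 = numeric(),
                      major_axis_nm = numeric(), minor_axis_nm = numeric(),
                      elongation = numeric(), skeleton_length_nm = numeric(),
                      mean_width_nm = numeric(), centroid_x_px = numeric(),
                      centroid_y_px = numeric())
  rownames(out) <- NULL
  out
}

# polyline length of a 1-px skeleton: orthogonal neighbour pairs count 1,
# diagonal pairs sqrt(2); isolated pixels contribute 1
skeleton_length_px <- function(sk) {
  idx <- which(sk == 1L)
  if (length(idx) == 0L) return(0)
  nr <- nrow(sk)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  on <- function(r, c) r >= 1 & r <= nr & c >= 1 & c <= ncol(sk) &
    sk[cbind(pmax(pmin(r, nr), 1), pmax(pmin(c, ncol(sk)), 1))] == 1L
  n_orth <- sum(on(rows + 1L, cols)) + sum(on(rows, cols + 1L))
  n_diag <- sum(on(rows + 1L, cols + 1L)) + sum(on(rows + 1L, cols - 1L))
  len <- n_orth + sqrt(2) * n_diag
  max(len, 1)
}

#' Area/shape criteria for tubule reclassification
#'
#' Thresholds used by [reassign_by_shape()] to find objects incorrectly
#' classified as tubules and reassign them as vesicles.  The defaults are
#' this package's documented choices (the original workflow's exact values
#' live only in its deposited code): an object stays a tubule only if it is
#' elongated, large enough, and thin on average.
#'
#' @param min_tubule_elongation minimum major/minor axis ratio.
#' @param min_tubule_area_px minimum component area in pixels.
#' @param max_tubule_mean_width_nm maximum mean width (area / skeleton
#'   length) in nm.
#' @param min_object_area_px speckle-filter threshold shared with
#'   [extract_objects()].
#' @return a `shape_criteria` list.
#' @export
shape_criteria <- function(min_tubule_elongation = 3,
                           min_tubule_area_px = 50,
                           max_tubule_mean_width_nm = 1000,
                           min_object_area_px = 10) {
  v <- c(min_tubule_elongation, min_tubule_area_px,
         max_tubule_mean_width_nm, min_object_area_px)
  if (any(v <= 0)) stop("all shape-criteria thresholds must be positive")
  structure(list(min_tubule_elongation = min_tubule_elongation,
                 min_tubule_area_px = min_tubule_area_px,
                 max_tubule_mean_width_nm = max_tubule_mean_width_nm,
                 min_object_area_px = min_object_area_px),
            class = "shape_criteria")
}

#' Reassign mislabelled tubules to vesicles by shape
#'
#' Any object classified as a tubule that fails *any* criterion (too round,
#' too small, or too wide on average) is reassigned as a vesicle.  The rule
#' is one-directional: vesicles are never promoted to tubules.  Order is
#' preserved and the operation is idempotent.
#'
#' @param objects data.frame from [extract_objects()].
#' @param criteria a [shape_criteria()].
#' @return the object table with updated `class` and a logical
#'   `reassigned` column.
#' @export
reassign_by_shape <- function(objects, criteria = shape_criteria()) {
  if (!inherits(criteria, "shape_criteria")) stop("invalid criteria")
  if (nrow(objects) == 0L) {
    objects$reassigned <- logical(0)
    return(objects)
  }
  fail <- objects$class == "tubule" &
    (objects$elongation < criteria$min_tubule_elongation |
       objects$area_px < criteria$min_tubule_area_px |
       (!is.na(objects$mean_width_nm) &
          objects$mean_width_nm > criteria$max_tubule_mean_width_nm))
  objects$class[fail] <- "vesicle"
  objects$reassigned <- fail
  objects
}
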