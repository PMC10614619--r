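# Synthetic fluorescence scenes with planted ground truth.
#
# The forward model renders membrane objects as fluorescence deposited on a
# pixel grid, blurs with an isotropic Gaussian PSF and adds Poisson shot
# noise (after photon conversion) followed by additive Gaussian read noise.
# Membrane accounting is per bilayer area: an areal dye density rho
# (units/nm^2) contributes
#   * flat film:  rho * pixel_size^2 per pixel footprint (one bilayer),
#   * tubule:     rho * pi * d per nm of centerline (the circumference of a
#                 cylinder of outer diameter d), deposited as a line source,
#   * vesicle:    rho * pixel_size^2 over the projected disk,
#   * GUV rim:    a thin-shell ring, rendered as a line source of effective
#                 linear density rho * pi * ring_width_nm.
# This is exactly the accounting the calibration r = F_l / (2 pi rho0)
# inverts.  Gaussian blur preserves integrals, so sub-resolution tubules
# keep their integrated cross-profile intensity per unit length.

#' Optical forward model parameters
#'
#' @param psf_sigma_nm Gaussian point-spread SD in nm (0 disables blur).
#' @param photons_per_unit photon conversion factor for shot noise
#'   (photons per fluorescence unit; 0 disables Poisson noise).
#' @param read_noise_sd additive Gaussian noise SD in fluorescence units.
#' @param background_level uniform background offset in fluorescence units.
#' @return an `optics_model` list.
#' @export
optics_model <- function(psf_sigma_nm = 120, photons_per_unit = 0.02,
                         read_noise_sd = 20, background_level = 50) {
  if (psf_sigma_nm < 0 || photons_per_unit < 0 || read_noise_sd < 0 ||
      background_level < 0)
    stop("optics parameters must be non-negative")
  structure(list(psf_sigma_nm = psf_sigma_nm,
                 photons_per_unit = photons_per_unit,
                 read_noise_sd = read_noise_sd,
                 background_level = background_level),
            class = "optics_model")
}

#' Noise-free optics (no blur, no noise, zero background)
#' @export
optics_ideal <- function() {
  optics_model(psf_sigma_nm = 0, photons_per_unit = 0, read_noise_sd = 0,
               background_level = 0)
}

#' Specification of one membrane object in a synthetic scene
#'
#' Geometry is given in nm in scene coordinates (x right, y down, origin at
#' the centre of pixel \[0, 0\]).
#'
#' @param kind `"vesicle"`, `"tubule"`, `"guv"` or `"flat_film"`.
#' @param center_nm length-2 (x, y) centre for vesicle/guv.
#' @param radius_nm disk/ring radius for vesicle/guv.
#' @param centerline_nm n x 2 matrix of (x, y) polyline vertices for a
#'   tubule.
#' @param diameter_nm outer diameter of a tubule (may be sub-resolution);
#'   for segmented tubules a vector with one value per centerline segment.
#' @param corners_nm c(x0, y0, x1, y1) rectangle for flat_film (NULL =
#'   whole frame).
#' @param lipid_density areal lipid fluorescence density (units/nm^2).
#' @param protein_enrichment protein-channel density factor relative to the
#'   scene's reference protein density; a vector for segmented tubules.
#' @param ring_width_nm effective edge-on membrane width of a GUV rim
#'   (appearance parameter; ratio-based measurements cancel it).
#' @return a `membrane_object` list.
#' @export
membrane_object <- function(kind, center_nm = NULL, radius_nm = NULL,
                            centerline_nm = NULL, diameter_nm = NULL,
                            corners_nm = NULL, lipid_density = 5,
                            protein_enrichment = 1, ring_width_nm = 200) {
  kind <- match.arg(kind, c("vesicle", "tubule", "guv", "flat_film"))
  if (lipid_density < 0) stop("lipid_density must be >= 0")
  if (any(protein_enrichment < 0)) stop("protein_enrichment must be >= 0")
  if (kind %in% c("vesicle", "guv")) {
    if (is.null(center_nm) || is.null(radius_nm) || radius_nm <= 0)
      stop(kind, " needs center_nm and positive radius_nm")
  }
  if (kind == "tubule") {
    if (is.null(centerline_nm) || is.null(diameter_nm) ||
        any(diameter_nm <= 0))
      stop("tubule needs centerline_nm and positive diameter_nm")
    centerline_nm <- as.matrix(centerline_nm)
    if (ncol(centerline_nm) != 2L || nrow(centerline_nm) < 2L)
      stop("centerline_nm must be an n x 2 matrix with n >= 2")
  }
  structure(list(kind = kind, center_nm = center_nm, radius_nm = radius_nm,
                 centerline_nm = centerline_nm, diameter_nm = diameter_nm,
                 corners_nm = corners_nm, lipid_density = lipid_density,
                 protein_enrichment = protein_enrichment,
                 ring_width_nm = ring_width_nm),
            class = "membrane_object")
}

gaussian_kernel <- function(sigma_px) {
  h <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-h:h)^2) / (2 * sigma_px^2))
  k / sum(k)
}

blur_image <- function(px, sigma_px) {
  if (sigma_px <= 0) return(px)
  k <- gaussian_kernel(sigma_px)
  cpp_conv_sep(px, k, k)
}

# resample a polyline (n x 2, nm) at fixed arc-length step; returns matrix of
# points and the segment index each point belongs to
resample_polyline <- function(poly, step) {
  seg_len <- sqrt(rowSums(diff(poly)^2))
  pts <- NULL; seg_id <- NULL; arc <- NULL
  s0 <- 0
  for (i in seq_along(seg_len)) {
    n <- max(1L, ceiling(seg_len[i] / step))
    tt <- (seq_len(n) - 0.5) / n
    p <- cbind(poly[i, 1] + tt * (poly[i + 1, 1] - poly[i, 1]),
               poly[i, 2] + tt * (poly[i + 1, 2] - poly[i, 2]))
    pts <- rbind(pts, p)
    seg_id <- c(seg_id, rep(i, n))
    arc <- c(arc, s0 + tt * seg_len[i])
    s0 <- s0 + seg_len[i]
  }
  list(points = pts, seg_id = seg_id, arc = arc,
       ds = rep(seg_len / pmax(1, ceiling(seg_len / step)),
                pmax(1L, ceiling(seg_len / step))),
       total = s0)
}

circle_polyline <- function(center, radius, n = max(64L, ceiling(2 * pi * radius / 50))) {
  th <- seq(0, 2 * pi, length.out = n + 1L)
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

# pixels (1-based matrix indices) covered by a disk
disk_mask_idx <- function(nr, nc, cx_px, cy_px, r_px) {
  rows <- max(1L, floor(cy_px + 1 - r_px)):min(nr, ceiling(cy_px + 1 + r_px))
  cols <- max(1L, floor(cx_px + 1 - r_px)):min(nc, ceiling(cx_px + 1 + r_px))
  g <- expand.grid(r = rows, c = cols)
  keep <- ((g$r - 1) - cy_px)^2 + ((g$c - 1) - cx_px)^2 <= r_px^2
  cbind(g$r[keep], g$c[keep])
}

# pixels within r_px of a sampled polyline (points in 0-based px coords)
polyline_mask_idx <- function(nr, nc, pts_px, r_px) {
  h <- ceiling(r_px)
  off <- expand.grid(dr = -h:h, dc = -h:h)
  off <- off[off$dr^2 + off$dc^2 <= (r_px + 0.5)^2, , drop = FALSE]
  rr <- as.vector(outer(round(pts_px[, 2]) + 1, off$dr, "+"))
  cc <- as.vector(outer(round(pts_px[, 1]) + 1, off$dc, "+"))
  keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  lin <- unique((cc[keep] - 1L) * nr + rr[keep])
  cbind((lin - 1L) %% nr + 1L, (lin - 1L) %/% nr + 1L)
}

#' Render a synthetic scene
#'
#' Renders a list of [membrane_object()]s into one noiseless geometric image
#' per channel, applies PSF blur, then background + Poisson/Gaussian noise,
#' and returns the per-channel [fluor_image()]s together with a `scene_truth`
#' record of every planted value.
#'
#' The protein channel is the lipid geometric signal of each object scaled by
#' `protein_density_ref / lipid_density x protein_enrichment`, i.e. protein
#' areal density is `protein_density_ref x protein_enrichment` on the same
#' membrane geometry.
#'
#' @param objects list of [membrane_object()]; may be empty.
#' @param optics an [optics_model()].
#' @param image_shape c(rows, cols) in pixels.
#' @param pixel_size_nm physical pixel size (nm).
#' @param channels subset of c("lipid", "protein").
#' @param seed integer RNG seed for the noise; same seed, same scene.
#' @param protein_density_ref reference protein areal density (units/nm^2)
#'   corresponding to enrichment 1.
#' @return list with elements `images` (named list of [fluor_image()]) and
#'   `truth` (`scene_truth`).
#' @export
render_scene <- function(objects, optics = optics_model(),
                         image_shape = c(256L, 256L), pixel_size_nm = 100,
                         channels = "lipid", seed = NULL,
                         protein_density_ref = 2) {
  stopifnot(all(channels %in% c("lipid", "protein")))
  if (!is.null(seed)) set.seed(seed)
  nr <- image_shape[1]; nc <- image_shape[2]
  px <- pixel_size_nm
  geom <- lapply(channels, function(ch) matrix(0, nr, nc))
  names(geom) <- channels
  labels <- matrix(0L, nr, nc)
  step <- px / 4
  diam_all <- numeric(0)

  for (obj in objects) {
    if (!inherits(obj, "membrane_object")) stop("objects must be membrane_object")
    dens <- c(lipid = obj$lipid_density,
              protein = protein_density_ref * obj$protein_enrichment[1])
    if (obj$kind == "flat_film") {
      co <- obj$corners_nm %||% c(0, 0, (nc - 1) * px, (nr - 1) * px)
      rows <- max(1L, round(co[2] / px) + 1L):min(nr, round(co[4] / px) + 1L)
      cols <- max(1L, round(co[1] / px) + 1L):min(nc, round(co[3] / px) + 1L)
      for (ch in channels)
        geom[[ch]][rows, cols] <- geom[[ch]][rows, cols] + dens[ch] * px^2
      labels[rows, cols] <- 2L
    } else if (obj$kind == "vesicle") {
      idx <- disk_mask_idx(nr, nc, obj$center_nm[1] / px,
                           obj$center_nm[2] / px, obj$radius_nm / px)
      for (ch in channels)
        geom[[ch]][idx] <- geom[[ch]][idx] + dens[ch] * px^2
      labels[idx] <- 2L
    } else if (obj$kind == "guv") {
      ring <- circle_polyline(obj$center_nm, obj$radius_nm)
      rs <- resample_polyline(ring, step)
      lambda <- dens * pi * obj$ring_width_nm   # per channel, units/nm
      for (ch in channels) {
        sp <- cpp_splat(nr, nc, rs$points[, 1] / px, rs$points[, 2] / px,
                        rep(lambda[ch], nrow(rs$points)) * rs$ds)
        geom[[ch]] <- geom[[ch]] + sp
      }
      idx <- polyline_mask_idx(nr, nc, rs$points / px,
                               max(obj$ring_width_nm / px / 2, 0.6))
      labels[idx] <- 2L
    } else {  # tubule
      rs <- resample_polyline(obj$centerline_nm, step)
      d_seg <- rep_len(obj$diameter_nm, nrow(obj$centerline_nm) - 1L)
      e_seg <- rep_len(obj$protein_enrichment, nrow(obj$centerline_nm) - 1L)
      d_pt <- d_seg[rs$seg_id]
      for (ch in channels) {
        rho <- if (ch == "lipid") obj$lipid_density else
          protein_density_ref * e_seg[rs$seg_id]
        w <- rho * pi * d_pt * rs$ds
        geom[[ch]] <- geom[[ch]] + cpp_splat(nr, nc, rs$points[, 1] / px,
                                             rs$points[, 2] / px, w)
      }
      idx <- polyline_mask_idx(nr, nc, rs$points / px,
                               max(max(d_seg) / px / 2, 0.6))
      labels[idx] <- 1L
      diam_all <- c(diam_all, d_seg[!duplicated(seq_along(d_seg))])
    }
  }

  sigma_px <- optics$psf_sigma_nm / px
  images <- lapply(channels, function(ch) {
    img <- blur_image(geom[[ch]], sigma_px) + optics$background_level
    if (optics$photons_per_unit > 0)
      img <- stats::rpois(length(img), pmax(img, 0) * optics$photons_per_unit) /
        optics$photons_per_unit
    if (optics$read_noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, optics$read_noise_sd)
    fluor_image(matrix(pmax(img, 0), nr, nc), px, ch)
  })
  names(images) <- channels

  attr(labels, "pixel_size_nm") <- px
  n_t <- sum(labels == 1L); n_v <- sum(labels == 2L)
  truth <- structure(list(
    objects = objects,
    true_label_map = labels,
    true_tubulation_ratio = if (n_t + n_v > 0) n_t / (n_t + n_v) else NA_real_,
    true_diameters_nm = diam_all,
    true_sorting_ratio = NA_real_,
    pixel_size_nm = px,
    optics = optics,
    seed = seed), class = "scene_truth")
  list(images = images, truth = truth)
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d object(s), tubulation ratio %s\n",
              length(x$objects),
              format(x$true_tubulation_ratio, digits = 3)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Scene factories emulating each experimental configuration
## ---------------------------------------------------------------------------

# a smooth random tubule centerline: heading random walk
random_tubule_centerline <- function(start_nm, length_nm, step_nm = 1000,
                                     wiggle = 0.35) {
  n <- max(2L, ceiling(length_nm / step_nm))
  heading <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(NA_real_, n + 1L, 2L)
  pts[1L, ] <- start_nm
  for (i in seq_len(n)) {
    heading <- heading + stats::rnorm(1, 0, wiggle)
    pts[i + 1L, ] <- pts[i, ] + step_nm * c(cos(heading), sin(heading))
  }
  pts
}

#' Synthetic liposome-tubulation field
#'
#' Places non-overlapping vesicle disks and curved thick tubules at random so
#' that the planted tubule-area fraction (by truth label pixels) is within
#' 0.02 of `target_ratio`, emulating a liposome field after a tubulation
#' reaction.
#'
#' @param target_ratio desired tubule-area fraction in \[0, 1\].
#' @param n_objects number of objects to place.
#' @param optics an [optics_model()].
#' @param image_shape c(rows, cols) pixels.
#' @param pixel_size_nm pixel size (nm).
#' @param seed RNG seed.
#' @param lipid_density areal dye density (units/nm^2).
#' @param max_tries placement retries per object before declaring the
#'   packing infeasible.
#' @return list(image = [fluor_image()], truth = `scene_truth`).
#' @export
make_tubulation_scene <- function(target_ratio, n_objects = 30L,
                                  optics = optics_model(),
                                  image_shape = c(256L, 256L),
                                  pixel_size_nm = 100, seed = NULL,
                                  lipid_density = 5, max_tries = 500L) {
  if (target_ratio < 0 || target_ratio > 1)
    stop("target_ratio must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  nr <- image_shape[1]; nc <- image_shape[2]; px <- pixel_size_nm
  occupied <- matrix(FALSE, nr, nc)
  objects <- list()
  area_t <- 0; area_v <- 0
  margin_px <- 3

  place_one <- function(kind) {
    for (try in seq_len(max_tries)) {
      shrink <- 0.99^(try - 1)   # crowded fields accept smaller objects
      if (kind == "vesicle") {
        r_nm <- stats::runif(1, 400, max(600, 1500 * shrink))
        cx <- stats::runif(1, r_nm + margin_px * px, (nc - 1) * px - r_nm - margin_px * px)
        cy <- stats::runif(1, r_nm + margin_px * px, (nr - 1) * px - r_nm - margin_px * px)
        idx <- disk_mask_idx(nr, nc, cx / px, cy / px, r_nm / px + margin_px)
        if (any(occupied[idx])) next
        obj <- membrane_object("vesicle", center_nm = c(cx, cy),
                               radius_nm = r_nm, lipid_density = lipid_density)
        core <- disk_mask_idx(nr, nc, cx / px, cy / px, r_nm / px)
        return(list(obj = obj, guard = idx, npx = nrow(core)))
      } else {
        len_nm <- stats::runif(1, 3000, max(4000, 10000 * shrink))
        start <- c(stats::runif(1, 0.1, 0.9) * (nc - 1) * px,
                   stats::runif(1, 0.1, 0.9) * (nr - 1) * px)
        cl <- random_tubule_centerline(start, len_nm)
        if (any(cl[, 1] < margin_px * px | cl[, 1] > (nc - 1 - margin_px) * px |
                cl[, 2] < margin_px * px | cl[, 2] > (nr - 1 - margin_px) * px))
          next
        d_nm <- 400
        rs <- resample_polyline(cl, px / 4)  # same step render_scene uses
        idx <- polyline_mask_idx(nr, nc, rs$points / px,
                                 d_nm / px / 2 + margin_px)
        if (any(occupied[idx])) next
        obj <- membrane_object("tubule", centerline_nm = cl,
                               diameter_nm = d_nm,
                               lipid_density = lipid_density)
        core <- polyline_mask_idx(nr, nc, rs$points / px,
                                  max(d_nm / px / 2, 0.6))
        return(list(obj = obj, guard = idx, npx = nrow(core)))
      }
    }
    NULL
  }

  want_kind <- function() {
    tot <- area_t + area_v
    if (target_ratio <= 0) return("vesicle")
    if (target_ratio >= 1) return("tubule")
    if (tot == 0) return(if (target_ratio >= 0.5) "tubule" else "vesicle")
    if (area_t / tot < target_ratio) "tubule" else "vesicle"
  }

  n_placed <- 0L
  budget <- n_objects + 4L * n_objects
  # the corrective phase aims at half the contract tolerance of 0.02
  while (n_placed < n_objects ||
         (target_ratio > 0 && target_ratio < 1 &&
          abs(area_t / (area_t + area_v) - target_ratio) > 0.01 &&
          n_placed < budget)) {
    res <- place_one(want_kind())
    if (is.null(res)) {
      if (n_placed < n_objects)
        stop("infeasible packing: could not place ", n_objects,
             " objects in a ", nr, "x", nc, " image")
      break
    }
    occupied[res$guard] <- TRUE
    objects[[length(objects) + 1L]] <- res$obj
    if (res$obj$kind == "tubule") area_t <- area_t + res$npx
    else area_v <- area_v + res$npx
    n_placed <- n_placed + 1L
  }
  if (target_ratio > 0 && target_ratio < 1 &&
      abs(area_t / (area_t + area_v) - target_ratio) > 0.02)
    stop("could not reach target tubulation ratio within tolerance 0.02")

  sc <- render_scene(objects, optics, image_shape, px, "lipid",
                     seed = if (is.null(seed)) NULL else seed + 10000L)
  list(image = sc$images$lipid, truth = sc$truth)
}

#' Synthetic GUV with a pulled membrane tubule (two channels)
#'
#' A GUV equatorial rim plus a straight sub-resolution tubule emanating from
#' it, with the protein channel enriched on the tubule by the planted
#' `enrichment` factor (the true sorting ratio).
#'
#' @param guv_radius_um GUV radius (micrometres).
#' @param tubule_diameter_nm planted outer diameter of the pulled tubule.
#' @param enrichment planted sorting ratio (protein density on the tubule
#'   relative to the GUV).
#' @param optics an [optics_model()].
#' @param pixel_size_nm pixel size (nm).
#' @param tubule_length_um tubule length.
#' @param seed RNG seed.
#' @param lipid_density areal lipid dye density (units/nm^2).
#' @return list(lipid, protein = [fluor_image()]s, truth = `scene_truth`);
#'   truth additionally carries `tubule_centerline_px` and `guv_arc_px`
#'   sampling polylines for profile extraction.
#' @export
make_guv_tubule_scene <- function(guv_radius_um = 8, tubule_diameter_nm = 60,
                                  enrichment = 1, optics = optics_model(),
                                  pixel_size_nm = 100, tubule_length_um = 10,
                                  seed = NULL, lipid_density = 5) {
  if (enrichment < 0) stop("enrichment must be >= 0")
  r_nm <- guv_radius_um * 1000
  if (tubule_diameter_nm >= r_nm / 10)
    stop("tubule_diameter_nm must be far below the GUV radius")
  px <- pixel_size_nm
  len_nm <- tubule_length_um * 1000
  pad <- 20 * px
  cx <- pad + r_nm; cy <- pad + r_nm
  x_end <- cx + r_nm + len_nm
  nc <- ceiling((x_end + pad) / px) + 1L
  nr <- ceiling((cy + r_nm + pad) / px) + 1L
  guv <- membrane_object("guv", center_nm = c(cx, cy), radius_nm = r_nm,
                         lipid_density = lipid_density,
                         protein_enrichment = 1)
  tub <- membrane_object("tubule",
                         centerline_nm = rbind(c(cx + r_nm, cy),
                                               c(cx + r_nm + len_nm, cy)),
                         diameter_nm = tubule_diameter_nm,
                         lipid_density = lipid_density,
                         protein_enrichment = enrichment)
  sc <- render_scene(list(guv, tub), optics, c(nr, nc), px,
                     channels = c("lipid", "protein"), seed = seed)
  truth <- sc$truth
  truth$true_sorting_ratio <- enrichment
  truth$true_diameters_nm <- tubule_diameter_nm
  # measurement polylines (0-based px): mid-portion of the tubule, and a GUV
  # arc on the far side from the attachment point
  x0 <- (cx + r_nm + 0.25 * len_nm) / px
  x1 <- (cx + r_nm + 0.85 * len_nm) / px
  truth$tubule_centerline_px <- cbind(c(x0, x1), c(cy / px, cy / px))
  th <- seq(140, 220, length.out = 33L) * pi / 180
  truth$guv_arc_px <- cbind((cx + r_nm * cos(th)) / px,
                            (cy + r_nm * sin(th)) / px)
  list(lipid = sc$images$lipid, protein = sc$images$protein, truth = truth)
}

#' Synthetic scaffold-covered tubule (two channels)
#'
#' One straight horizontal tubule whose outer diameter and protein
#' enrichment change stepwise per segment, emulating protein scaffolds that
#' constrict discrete stretches of a pulled membrane tube.  A segment is
#' flagged `covered` in the truth when its enrichment exceeds 2.
#'
#' @param segments data.frame (or list coercible to one) with columns
#'   `length_nm`, `diameter_nm`, `protein_enrichment`.
#' @param optics an [optics_model()].
#' @param pixel_size_nm pixel size (nm).
#' @param seed RNG seed.
#' @param lipid_density areal lipid dye density (units/nm^2).
#' @return list(lipid, protein, truth); truth carries a `segments`
#'   data.frame with planted start/end (nm along the tubule), diameters and
#'   covered flags, plus `tubule_centerline_px`.
#' @export
make_scaffold_scene <- function(segments, optics = optics_model(),
                                pixel_size_nm = 100, seed = NULL,
                                lipid_density = 5) {
  segments <- as.data.frame(segments)
  if (nrow(segments) < 1L) stop("need at least one segment")
  stopifnot(all(c("length_nm", "diameter_nm", "protein_enrichment") %in%
                  names(segments)))
  if (any(segments$length_nm <= 0)) stop("segment lengths must be positive")
  if (any(segments$diameter_nm <= 0)) stop("segment diameters must be positive")
  px <- pixel_size_nm
  pad <- 15 * px
  total <- sum(segments$length_nm)
  y <- pad + 10 * px
  xs <- c(0, cumsum(segments$length_nm)) + pad
  cl <- cbind(xs, y)
  nc <- ceiling((pad * 2 + total) / px) + 1L
  nr <- ceiling((2 * y) / px) + 1L
  tub <- membrane_object("tubule", centerline_nm = cl,
                         diameter_nm = segments$diameter_nm,
                         lipid_density = lipid_density,
                         protein_enrichment = segments$protein_enrichment)
  sc <- render_scene(list(tub), optics, c(nr, nc), px,
                     channels = c("lipid", "protein"), seed = seed)
  truth <- sc$truth
  truth$segments <- data.frame(
    start_nm = xs[-length(xs)] - pad,
    end_nm = xs[-1] - pad,
    diameter_nm = segments$diameter_nm,
    protein_enrichment = segments$protein_enrichment,
    covered = segments$protein_enrichment > 2)
  truth$true_diameters_nm <- segments$diameter_nm
  truth$tubule_centerline_px <- cbind(c(xs[1], xs[length(xs)]) / px,
                                      c(y, y) / px)
  list(lipid = sc$images$lipid, protein = sc$images$protein, truth = truth)
}

#' Synthetic flat-bilayer calibration film
#'
#' A uniform single-bilayer lipid film covering the central region of the
#' frame, used to calibrate the membrane fluorescence density rho0.
#'
#' @inheritParams make_scaffold_scene
#' @param image_shape c(rows, cols) pixels.
#' @return list(image, truth); truth carries `film_roi` and
#'   `background_roi` (row/col index lists) plus `true_rho0`.
#' @export
make_flat_film_scene <- function(optics = optics_model(),
                                 image_shape = c(160L, 160L),
                                 pixel_size_nm = 100, seed = NULL,
                                 lipid_density = 5) {
  nr <- image_shape[1]; nc <- image_shape[2]; px <- pixel_size_nm
  # film over left 60% of the frame, background band at the right edge
  film <- membrane_object("flat_film",
                          corners_nm = c(0, 0, (floor(nc * 0.6) - 1) * px,
                                         (nr - 1) * px),
                          lipid_density = lipid_density)
  sc <- render_scene(list(film), optics, image_shape, px, "lipid",
                     seed = seed)
  truth <- sc$truth
  truth$true_rho0 <- lipid_density
  inset <- max(4L, ceiling(3 * optics$psf_sigma_nm / px))
  truth$film_roi <- list(rows = (1L + inset):(nr - inset),
                         cols = (1L + inset):(floor(nc * 0.6) - inset))
  truth$background_roi <- list(rows = (1L + inset):(nr - inset),
                               cols = (floor(nc * 0.8)):(nc - 1L))
  list(image = sc$images$lipid, truth = truth)
}

#' Synthetic FRAP trace
#'
#' Emulates a photobleaching experiment: a constant prebleach plateau, a
#' bleach event after `n_prebleach` frames, then single-exponential recovery
#' towards `mobile_fraction` of the bleached depth, plus Gaussian noise.
#' The recovery clock starts at the first post-bleach frame.
#'
#' @param mobile_fraction fraction of the bleached signal that recovers
#'   (\[0, 1\]; ~1 for a fluid lipid, ~0 for a stably bound protein).
#' @param tau_s recovery time constant (s).
#' @param prebleach_level background-free prebleach signal.
#' @param bleach_depth fraction of signal removed by the bleach ((0, 1\]).
#' @param background constant background offset added to the trace.
#' @param noise_sd Gaussian noise SD.
#' @param times_s strictly increasing acquisition times (s).
#' @param seed RNG seed.
#' @param n_prebleach number of prebleach frames (>= 3).
#' @return a `frap_trace` (see [frap_trace()]).
#' @export
make_frap_trace <- function(mobile_fraction, tau_s = 5, prebleach_level = 100,
                            bleach_depth = 0.8, background = 10,
                            noise_sd = 0, times_s = seq(0, 120),
                            seed = NULL, n_prebleach = 3L) {
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop("mobile_fraction must be in [0, 1]")
  if (tau_s <= 0) stop("tau_s must be positive")
  if (bleach_depth <= 0 || bleach_depth > 1)
    stop("bleach_depth must be in (0, 1]")
  if (any(diff(times_s) <= 0)) stop("times_s must be strictly increasing")
  if (length(times_s) < n_prebleach + 2L)
    stop("times_s too short for the prebleach sequence")
  if (!is.null(seed)) set.seed(seed)
  bleach_index <- n_prebleach + 1L
  i_post <- prebleach_level * (1 - bleach_depth)
  t0 <- times_s[bleach_index]
  signal <- ifelse(seq_along(times_s) < bleach_index, prebleach_level,
                   i_post + mobile_fraction * (prebleach_level - i_post) *
                     (1 - exp(-(times_s - t0) / tau_s)))
  intensity <- signal + background
  if (noise_sd > 0)
    intensity <- intensity + stats::rnorm(length(times_s), 0, noise_sd)
  frap_trace(times_s, intensity, bleach_index = bleach_index,
             background = background)
}
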