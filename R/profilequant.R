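# Fluorescence-profile quantification: flat-film calibration of the
# membrane fluorescence density rho0, sub-resolution tubule radius from
# integrated fluorescence per unit length (r = F_l / (2 pi rho0)),
# curvature sorting ratios, and covered/uncovered scaffold-segment analysis.
#
# A sub-resolution tubule appears as a blurred line whose *integrated*
# cross-profile intensity, not its apparent width, encodes the diameter:
# the bilayer area per unit tubule length is the circumference 2 pi r, so
# F_l = rho0 * 2 pi r, with rho0 measured on a flat film that counts as a
# single bilayer.

#' Integrated line profile along a polyline
#'
#' Samples the image along `polyline` at `step_nm` intervals; at each
#' position the intensity is the integral across the perpendicular
#' cross-section (bilinear-interpolated pixel values, 0.5 px sampling,
#' spanning `width_nm`).  The per-sample background density is estimated as
#' the median of flanking bands just outside the integration width.
#'
#' @param image a [fluor_image()].
#' @param polyline n x 2 matrix of (x, y) vertices in 0-based pixel
#'   coordinates.
#' @param width_nm full integration width across the profile; should cover
#'   the whole blurred cross-section (>= 6 PSF sigmas recommended).
#' @param step_nm sampling step along the polyline (default: one pixel).
#' @param flank_width_nm width of each background band (default
#'   `width_nm / 2`).
#' @param flank_gap_nm gap between the integration width and the background
#'   bands.
#' @return a `line_profile`: list with `arc_nm`, `cross_sum` (integral
#'   across the section, pixel-value x px units), `f_l` (background-
#'   corrected fluorescence per nm of length), `background_per_px`,
#'   `width_px`, `step_nm`, `pixel_size_nm`, `channel`.
#' @export
extract_profile <- function(image, polyline, width_nm, step_nm = NULL,
                            flank_width_nm = width_nm / 2,
                            flank_gap_nm = 0) {
  stopifnot_image(image)
  px <- pixel_size(image)
  if (is.null(step_nm)) step_nm <- px
  if (width_nm <= 0 || step_nm <= 0) stop("width_nm and step_nm must be > 0")
  polyline <- as.matrix(polyline)
  rs <- resample_polyline(polyline * px, step_nm)   # work in nm
  pts <- rs$points / px                             # back to px coords
  # tangent per sample from its segment
  dirs <- diff(polyline)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  tang <- dirs[rs$seg_id, , drop = FALSE]
  norm <- cbind(-tang[, 2], tang[, 1])
  w2_px <- (width_nm / 2) / px
  dw <- 0.5
  off_in <- seq(-w2_px, w2_px, by = dw)
  fl0 <- (width_nm / 2 + flank_gap_nm) / px
  fl1 <- fl0 + flank_width_nm / px
  off_fl <- c(seq(-fl1, -fl0, by = dw), seq(fl0, fl1, by = dw))
  xs_all <- c(outer(norm[, 1], off_in) + pts[, 1])
  ys_all <- c(outer(norm[, 2], off_in) + pts[, 2])
  xf_all <- c(outer(norm[, 1], off_fl) + pts[, 1])
  yf_all <- c(outer(norm[, 2], off_fl) + pts[, 2])
  nrI <- nrow(image); ncI <- ncol(image)
  if (min(xs_all, xf_all) < 0 || max(xs_all, xf_all) > ncI - 1 ||
      min(ys_all, yf_all) < 0 || max(ys_all, yf_all) > nrI - 1)
    stop("profile (with its integration and flanking bands) exits the image")
  img <- as_matrix(image)
  n <- nrow(pts)
  vals <- matrix(cpp_bilinear(img, xs_all, ys_all), nrow = n)
  cross_sum <- rowSums(vals) * dw
  flank <- matrix(cpp_bilinear(img, xf_all, yf_all), nrow = n)
  bg <- stats::median(flank)                 # per-sample (per 0.5-px) density
  W_px <- length(off_in) * dw                # effective integration width
  f_l <- (cross_sum - bg * W_px) / px
  structure(list(arc_nm = rs$arc, cross_sum = cross_sum, f_l = f_l,
                 background_per_px = bg, width_px = W_px,
                 step_nm = step_nm, pixel_size_nm = px,
                 channel = attr(image, "channel")),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d positions over %.0f nm, channel '%s'\n",
              length(x$arc_nm), max(x$arc_nm), x$channel))
  cat(sprintf("  mean F_l %.4g units/nm (background %.4g/px)\n",
              mean(x$f_l), x$background_per_px))
  invisible(x)
}

#' Background-corrected integrated fluorescence of a profile
#'
#' Total background-corrected fluorescence summed over the profile, used as
#' the F terms of the sorting ratio.  Units are arbitrary but consistent
#' between profiles extracted with the same step, which is all a ratio of
#' ratios needs.
#'
#' @param profile a [extract_profile()] result.
#' @return scalar integrated fluorescence.
#' @export
integrated_fluorescence <- function(profile) {
  sum(profile$f_l) * profile$step_nm
}

#' Calibrate the membrane fluorescence density rho0 from a flat film
#'
#' rho0 = (mean film-ROI intensity - background) / pixel_size^2, treating
#' the film as a single bilayer.
#'
#' @param film_image a [fluor_image()] of a flat lipid film.
#' @param roi list(rows, cols) of 1-based indices fully on the film.
#' @param background_roi optional list(rows, cols) off-film; its mean is
#'   the background estimate.
#' @param background scalar background used when no `background_roi` is
#'   given (default 0).
#' @return a `flat_film_calibration`: list with `rho0` (units/nm^2),
#'   `background`, `pixel_size_nm`, `channel`, `roi`.
#' @export
estimate_rho0 <- function(film_image, roi, background_roi = NULL,
                          background = 0) {
  stopifnot_image(film_image)
  px <- pixel_size(film_image)
  m <- as_matrix(film_image)
  film_mean <- mean(m[roi$rows, roi$cols])
  if (!is.null(background_roi))
    background <- mean(m[background_roi$rows, background_roi$cols])
  rho0 <- (film_mean - background) / px^2
  if (!is.finite(rho0) || rho0 <= 0)
    stop("rho0 <= 0 after background subtraction; check the ROIs")
  structure(list(rho0 = rho0, background = background,
                 pixel_size_nm = px, channel = attr(film_image, "channel"),
                 roi = roi),
            class = "flat_film_calibration")
}

#' @export
print.flat_film_calibration <- function(x, ...) {
  cat(sprintf("<flat_film_calibration> rho0 = %.5g units/nm^2 (bg %.4g)\n",
              x$rho0, x$background))
  invisible(x)
}

#' Tubule radius from fluorescence per unit length
#'
#' r = F_l / (2 pi rho0): the tubule's bilayer area per unit length is its
#' circumference, so dividing the background-corrected fluorescence per nm
#' by the flat-film areal density and 2 pi yields the radius.
#'
#' @param F_l background-corrected total fluorescence per unit length
#'   (units/nm); must be >= 0.
#' @param calib a [estimate_rho0()] calibration.
#' @return a `tubule_measurement`: list with `F_l`, `radius_nm`,
#'   `diameter_nm`, `degenerate` (TRUE when F_l == 0), `segment_class`.
#' @export
estimate_radius <- function(F_l, calib) {
  if (!inherits(calib, "flat_film_calibration"))
    stop("calib must be a flat_film_calibration (missing rho0)")
  if (!is.finite(F_l) || F_l < 0) stop("F_l must be non-negative")
  r <- F_l / (2 * pi * calib$rho0)
  structure(list(F_l = F_l, radius_nm = r, diameter_nm = 2 * r,
                 degenerate = F_l == 0, segment_class = "n/a",
                 rho0 = calib$rho0),
            class = "tubule_measurement")
}

#' @export
print.tubule_measurement <- function(x, ...) {
  cat(sprintf("<tubule_measurement> F_l %.4g/nm -> r %.2f nm (d %.2f nm)%s\n",
              x$F_l, x$radius_nm, x$diameter_nm,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Measure a tubule's diameter from an image
#'
#' Convenience wrapper: extracts a profile along the supplied centerline,
#' averages the background-corrected fluorescence per unit length and
#' converts it with the flat-film calibration.
#'
#' @param image lipid-channel [fluor_image()].
#' @param centerline_px n x 2 polyline in 0-based pixel coordinates.
#' @param calib a [estimate_rho0()] calibration.
#' @param width_nm profile integration width.
#' @return a `tubule_measurement` (plus the `profile` attached).
#' @export
measure_tubule_diameter <- function(image, centerline_px, calib,
                                    width_nm = 2000) {
  pr <- extract_profile(image, centerline_px, width_nm)
  m <- estimate_radius(max(mean(pr$f_l), 0), calib)
  m$profile <- pr
  m
}

#' Curvature sorting ratio from two-channel profiles
#'
#' S = (F_protein / F_lipid) on the tubule divided by (F_protein / F_lipid)
#' on the GUV, with every F an integrated background-corrected profile
#' fluorescence.  No polarization correction is applied.
#'
#' @param tubule_protein,tubule_lipid,guv_protein,guv_lipid
#'   [extract_profile()] results for the respective channel and region.
#' @return a `sorting_ratio_result`: the four integrated fluorescences and
#'   `sorting_ratio`.
#' @export
sorting_ratio <- function(tubule_protein, tubule_lipid, guv_protein,
                          guv_lipid) {
  f <- c(protein_tubule = integrated_fluorescence(tubule_protein),
         lipid_tubule = integrated_fluorescence(tubule_lipid),
         protein_guv = integrated_fluorescence(guv_protein),
         lipid_guv = integrated_fluorescence(guv_lipid))
  bad <- names(f)[f <= 0]
  if (length(bad))
    stop("non-positive integrated fluorescence after background ",
         "correction in: ", paste(bad, collapse = ", "))
  s <- (f["protein_tubule"] / f["lipid_tubule"]) /
    (f["protein_guv"] / f["lipid_guv"])
  structure(list(F_protein_tubule = unname(f["protein_tubule"]),
                 F_lipid_tubule = unname(f["lipid_tubule"]),
                 F_protein_guv = unname(f["protein_guv"]),
                 F_lipid_guv = unname(f["lipid_guv"]),
                 sorting_ratio = unname(s)),
            class = "sorting_ratio_result")
}

#' @export
print.sorting_ratio_result <- function(x, ...) {
  cat(sprintf("<sorting_ratio_result> S = %.4f\n", x$sorting_ratio))
  invisible(x)
}

#' Sorting ratio of a GUV + pulled-tubule image pair
#'
#' Convenience wrapper extracting the four profiles (protein and lipid on
#' the tubule centerline and on a GUV rim arc) and forming the ratio.
#'
#' @param lipid,protein the two channel images.
#' @param tubule_polyline_px,guv_arc_px measurement polylines in 0-based
#'   pixel coordinates (e.g. from the synthetic scene truth).
#' @param width_nm profile integration width.
#' @return a `sorting_ratio_result`.
#' @export
guv_sorting_ratio <- function(lipid, protein, tubule_polyline_px,
                              guv_arc_px, width_nm = 2000) {
  sorting_ratio(
    tubule_protein = extract_profile(protein, tubule_polyline_px, width_nm),
    tubule_lipid = extract_profile(lipid, tubule_polyline_px, width_nm),
    guv_protein = extract_profile(protein, guv_arc_px, width_nm),
    guv_lipid = extract_profile(lipid, guv_arc_px, width_nm))
}

#' Covered/uncovered scaffold-segment analysis of one tubule
#'
#' Segments the protein profile along a tubule centerline into
#' scaffold-covered and uncovered runs by thresholding at
#' `covered_threshold` x the median protein intensity (runs shorter than
#' `min_run_nm` are merged into their neighbours), then converts the mean
#' lipid fluorescence per unit length of each run into a diameter via the
#' flat-film calibration.  Samples within `guard_nm` of a run boundary are
#' excluded from the mean so that PSF blur across the step does not bias
#' either side.
#'
#' @param lipid,protein the two channel images (lipid first).
#' @param centerline_px n x 2 polyline along the tubule (0-based px).
#' @param calib a [estimate_rho0()] calibration for the lipid channel.
#' @param covered_threshold multiple of the median protein profile
#'   intensity above which a position counts as covered.
#' @param min_run_nm minimum segment length; shorter runs are merged.
#' @param width_nm profile integration width.
#' @param guard_nm boundary exclusion zone for per-segment averaging.
#' @param max_lipid_step_factor sanity guard: if the lipid channel itself
#'   steps by more than this factor between segments, the channels were
#'   most likely swapped and an error is raised.
#' @return data.frame, ordered along the centerline: `segment`, `start_nm`,
#'   `end_nm`, `length_nm`, `covered`, `F_l`, `radius_nm`, `diameter_nm`.
#' @export
analyze_scaffold_tubule <- function(lipid, protein, centerline_px, calib,
                                    covered_threshold = 2, min_run_nm = 500,
                                    width_nm = 2000, guard_nm = 500,
                                    max_lipid_step_factor = 3) {
  pr_l <- extract_profile(lipid, centerline_px, width_nm)
  pr_p <- extract_profile(protein, centerline_px, width_nm)
  n <- length(pr_l$arc_nm)
  total_nm <- max(pr_l$arc_nm)
  if (total_nm < min_run_nm)
    stop("centerline shorter than the minimum run length")
  # misuse guard: the lipid signal tracks tubule circumference and varies
  # mildly between segments; a protein channel accidentally passed as lipid
  # shows scaffold-like steps (enrichment-fold).  Compare robust quantiles.
  ql <- stats::quantile(pr_l$f_l, c(0.05, 0.95), names = FALSE)
  if (ql[1] > 0 && ql[2] / ql[1] > max_lipid_step_factor)
    stop("lipid channel varies ", sprintf("%.1f", ql[2] / ql[1]),
         "-fold along the tubule (max_lipid_step_factor = ",
         max_lipid_step_factor, "); are the lipid and protein channels ",
         "swapped?")
  thr <- covered_threshold * stats::median(pmax(pr_p$f_l, 0))
  covered <- pr_p$f_l > thr
  # merge runs shorter than min_run_nm into their neighbours
  min_run_samples <- max(1L, ceiling(min_run_nm / pr_l$step_nm))
  repeat {
    r <- rle(covered)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_run_samples)
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    r$values[i] <- !r$values[i]
    covered <- inverse.rle(r)
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  guard_samples <- ceiling(guard_nm / pr_l$step_nm)
  seg <- lapply(seq_along(r$lengths), function(i) {
    lo <- starts[i]; hi <- ends[i]
    lo2 <- lo + guard_samples; hi2 <- hi - guard_samples
    if (lo2 > hi2) {  # segment too short to trim: use its middle third
      mid <- (lo + hi) / 2
      lo2 <- max(lo, floor(mid - r$lengths[i] / 6))
      hi2 <- min(hi, ceiling(mid + r$lengths[i] / 6))
    }
    fl <- mean(pr_l$f_l[lo2:hi2])
    m <- estimate_radius(max(fl, 0), calib)
    data.frame(segment = i,
               start_nm = pr_l$arc_nm[lo] - pr_l$step_nm / 2,
               end_nm = pr_l$arc_nm[hi] + pr_l$step_nm / 2,
               length_nm = r$lengths[i] * pr_l$step_nm,
               covered = r$values[i], F_l = m$F_l,
               radius_nm = m$radius_nm, diameter_nm = m$diameter_nm)
  })
  out <- do.call(rbind, seg)
  rownames(out) <- NULL
  out
}
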