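# Pipeline driver: configuration, batch execution and run manifest.

#' Pipeline configuration
#'
#' @param pixel_size_nm physical pixel size applied to inputs lacking
#'   embedded metadata.
#' @param channels named list mapping roles to channel labels; the two
#'   names must be distinct.
#' @param scales classifier feature scales (px).
#' @param criteria a [shape_criteria()].
#' @param calibration_file optional path to a rho0 calibration JSON.
#' @param seed integer seed echoed into every stochastic stage.
#' @param out_dir output directory.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size_nm, channels = list(lipid = "lipid",
                                                           protein = "protein"),
                            scales = c(1, 2, 4),
                            criteria = shape_criteria(),
                            calibration_file = NULL, seed = 1L,
                            out_dir = ".") {
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    stop("pixel_size_nm must be positive")
  if (anyDuplicated(unlist(channels)))
    stop("channel names must be distinct")
  structure(list(pixel_size_nm = pixel_size_nm, channels = channels,
                 scales = scales, criteria = criteria,
                 calibration_file = calibration_file,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected at validation time, before any computation.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("pixel_size_nm", "channels", "scales", "criteria",
             "calibration_file", "seed", "out_dir")
  extra <- setdiff(names(y), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  crit <- if (is.null(y$criteria)) shape_criteria() else
    do.call(shape_criteria, y$criteria)
  pipeline_config(pixel_size_nm = y$pixel_size_nm,
                  channels = y$channels %||% list(lipid = "lipid",
                                                  protein = "protein"),
                  scales = y$scales %||% c(1, 2, 4),
                  criteria = crit,
                  calibration_file = y$calibration_file,
                  seed = y$seed %||% 1L,
                  out_dir = y$out_dir %||% ".")
}

#' Save / load a flat-film calibration as JSON
#' @param calib a [estimate_rho0()] result.
#' @param path JSON file path.
#' @export
write_calibration <- function(calib, path) {
  jsonlite::write_json(unclass(calib[c("rho0", "background",
                                       "pixel_size_nm", "channel")]),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(rho0 = x$rho0, background = x$background,
                 pixel_size_nm = x$pixel_size_nm, channel = x$channel,
                 roi = NULL),
            class = "flat_film_calibration")
}

#' Run the segmentation -> objects -> tubulation pipeline on a batch
#'
#' For each input image: predict labels with the supplied classifier,
#' extract connected components, apply the shape criteria and compute the
#' tubulation ratio.  Per-image object CSVs, a ratio CSV and a JSON run
#' manifest (tool version, config hash, input hashes, seed) are written to
#' `config$out_dir`.  Identical config + inputs yield byte-identical CSVs.
#'
#' @param config a [pipeline_config()].
#' @param image_paths character vector of grayscale TIFF paths.
#' @param model a trained [train_classifier()] model.
#' @return list with `results` (data.frame of per-image ratios), `objects`
#'   (list of object tables), `manifest`, `files`.
#' @export
run_pipeline <- function(config, image_paths, model) {
  if (!inherits(config, "pipeline_config")) stop("invalid config")
  if (!length(image_paths)) stop("no input images")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  objects_all <- list()
  rows <- list()
  files <- character()
  for (i in seq_along(image_paths)) {
    p <- image_paths[i]
    res <- tryCatch({
      img <- read_image(p, pixel_size_nm = config$pixel_size_nm)
      lab <- predict_labels(model, img)
      obj <- extract_objects(lab, pixel_size(img),
                             config$criteria$min_object_area_px)
      obj <- reassign_by_shape(obj, config$criteria)
      tr <- tubulation_ratio(obj, image_id = basename(p))
      list(obj = obj, tr = tr)
    }, error = function(e)
      stop("pipeline stage failed for input '", basename(p), "': ",
           conditionMessage(e), call. = FALSE))
    objects_all[[i]] <- res$obj
    ocsv <- file.path(config$out_dir,
                      paste0(sub("\\.[^.]+$", "", basename(p)),
                             "_objects.csv"))
    utils::write.csv(res$obj, ocsv, row.names = FALSE)
    files <- c(files, ocsv)
    rows[[i]] <- data.frame(image_id = res$tr$image_id,
                            tubule_area_nm2 = res$tr$tubule_area_nm2,
                            vesicle_area_nm2 = res$tr$vesicle_area_nm2,
                            ratio = res$tr$ratio,
                            defined = res$tr$defined)
  }
  results <- do.call(rbind, rows)
  rcsv <- file.path(config$out_dir, "tubulation_ratios.csv")
  utils::write.csv(results, rcsv, row.names = FALSE)
  files <- c(files, rcsv)

  cfg_for_hash <- unclass(config)
  cfg_for_hash$out_dir <- NULL   # hash the analytic config, not where it goes
  cfg_json <- jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE,
                               force = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(as.character(cfg_json), tmp)
  manifest <- list(
    tool = "memtube",
    version = as.character(utils::packageVersion("memtube")),
    config_hash = unname(tools::md5sum(tmp)),
    input_hashes = as.list(tools::md5sum(image_paths)),
    seed = config$seed,
    timestamp = format(Sys.time(), tz = "UTC"))
  unlink(tmp)
  mjson <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, mjson, auto_unbox = TRUE)
  files <- c(files, mjson)
  list(results = results, objects = objects_all, manifest = manifest,
       files = files)
}

#' Write a synthetic scene to disk
#'
#' Per-channel 32-bit float TIFFs, the truth label map as an 8-bit TIFF,
#' and a sidecar JSON with the planted values.
#'
#' @param scene result of [render_scene()] or a scene factory (any list
#'   holding [fluor_image()]s plus `truth`).
#' @param dir output directory.
#' @param stem file-name stem.
#' @return the written paths, invisibly.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- scene$truth
  imgs <- if (!is.null(scene$images)) scene$images else
    Filter(function(x) inherits(x, "fluor_image"), scene)
  paths <- character()
  for (nm in names(imgs)) {
    p <- file.path(dir, sprintf("%s_%s.tif", stem, nm))
    write_image(imgs[[nm]], p)
    paths <- c(paths, p)
  }
  lp <- file.path(dir, sprintf("%s_truth_labels.tif", stem))
  write_label_map(truth$true_label_map, lp)
  paths <- c(paths, lp)
  tj <- file.path(dir, sprintf("%s_truth.json", stem))
  tr <- truth
  tr$true_label_map <- NULL
  tr$objects <- lapply(tr$objects, function(o) {
    o$centerline_nm <- if (!is.null(o$centerline_nm))
      apply(o$centerline_nm, 1, function(r) as.list(r), simplify = FALSE)
    o
  })
  jsonlite::write_json(tr, tj, auto_unbox = TRUE, force = TRUE,
                       digits = NA, null = "null")
  paths <- c(paths, tj)
  invisible(paths)
}
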