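# End-to-end pipeline: load -> normalize -> color features -> pixel
# classification -> mask cleanup -> watershed -> ME quantification.

#' Build a pipeline run configuration
#'
#' If `mean_nuclear_area_um2` is supplied, the macrovesicle cutoff is derived
#' from it via [macrovesicle_cutoff()], overriding `cutoff_um2`.
#'
#' @param magnification,sensor_pixel_size_um,resize_factor acquisition
#'   calibration (see [calibrated_image()]).
#' @param algorithm classifier id used when training is requested.
#' @param cutoff_um2 macrovesicle area cutoff, default 146.71 um^2.
#' @param mean_nuclear_area_um2 optional mean nuclear area; when set,
#'   `cutoff_um2 = macrovesicle_cutoff(mean_nuclear_area_um2)`.
#' @param n_threads workers for mask prediction.
#' @param seed integer seed for any stochastic step.
#' @param tissue_only use a tissue-only ME denominator (see
#'   [quantify_steatosis()]).
#' @param fill_holes,min_object_px mask cleanup settings
#'   ([postprocess_mask()]); `min_object_px = NULL` means "pixels equivalent
#'   to 5 um^2 at the current calibration".
#' @return a named list of class `run_config`.
#' @export
run_config <- function(magnification = 100,
                       sensor_pixel_size_um = 4.54,
                       resize_factor = 1.0,
                       algorithm = "nb",
                       cutoff_um2 = 146.71,
                       mean_nuclear_area_um2 = NULL,
                       n_threads = 1L,
                       seed = 0L,
                       tissue_only = FALSE,
                       fill_holes = TRUE,
                       min_object_px = NULL) {
  if (!is.null(mean_nuclear_area_um2))
    cutoff_um2 <- macrovesicle_cutoff(mean_nuclear_area_um2)
  structure(list(magnification = magnification,
                 sensor_pixel_size_um = sensor_pixel_size_um,
                 resize_factor = resize_factor, algorithm = algorithm,
                 cutoff_um2 = cutoff_um2,
                 mean_nuclear_area_um2 = mean_nuclear_area_um2,
                 n_threads = as.integer(n_threads), seed = as.integer(seed),
                 tissue_only = tissue_only, fill_holes = fill_holes,
                 min_object_px = min_object_px),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param config a [run_config()].
#' @param path YAML file path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  if (!file.exists(path)) stop_io("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[names(vals) %in% names(formals(run_config))])
}

#' Run the full steatosis quantification pipeline on one image
#'
#' Stages: load and calibrate the image, optionally match its histograms to a
#' reference, convert to CIE L*a*b*, classify every pixel with the trained
#' model, clean the mask, watershed-split confluent vacuoles, and quantify
#' the ME percentage. When `out_dir` is given, the report (JSON + CSV), mask
#' PNG, label TIFF, QC overlay PNG, and resolved configuration YAML are
#' written there.
#'
#' @param config a [run_config()].
#' @param image_path path to the image, or a ready [calibrated_image].
#' @param model a trained `pixel_classifier` or path to a saved model file.
#' @param reference optional [calibrated_image] used for histogram matching
#'   (`NULL` disables normalization; `"default"` uses the packaged synthetic
#'   reference).
#' @param out_dir optional output directory.
#' @param verbose log each stage with its wall time.
#' @return the `steatosis_report` (invisibly carries the binary `mask` and
#'   `label_image` as attributes).
#' @export
run_pipeline <- function(config, image_path, model, reference = NULL,
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(model))
    stop_domain(paste0("no model available: supply a trained classifier or ",
                       "a saved model path (train one with ",
                       "train_pixel_classifier() on labeled windows)"))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    if (verbose)
      message(sprintf("[%s] %.2f s", name, proc.time()[["elapsed"]] - t0))
    res
  }
  clf <- if (inherits(model, "pixel_classifier")) model
         else stage("load_model", load_model(model))
  img <- if (inherits(image_path, "calibrated_image")) image_path
         else stage("load_image", load_image(image_path, config$magnification,
                                             config$sensor_pixel_size_um,
                                             config$resize_factor))
  if (!is.null(reference)) {
    ref <- if (identical(reference, "default")) default_reference_image()
           else reference
    img <- stage("match_histogram", match_histogram(img, ref))
  }
  lab <- stage("rgb_to_cielab", rgb_to_cielab(img))
  mask <- stage("predict_mask",
                predict_mask(clf, img, lab, n_threads = config$n_threads))
  min_px <- if (is.null(config$min_object_px))
    default_min_object_px(img$microns_per_pixel) else config$min_object_px
  mask <- stage("postprocess_mask",
                postprocess_mask(mask, min_object_px = min_px,
                                 fill_holes = config$fill_holes))
  labels <- stage("watershed", watershed_separate(
    mask, microns_per_pixel = img$microns_per_pixel,
    cutoff_um2 = config$cutoff_um2))
  report <- stage("quantify", quantify_steatosis(
    labels, img, config$cutoff_um2, tissue_only = config$tissue_only))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(out_dir, "report.json"),
                 file.path(out_dir, "report.csv"))
    write_mask_png(mask, file.path(out_dir, "mask.png"))
    write_label_tiff(labels, file.path(out_dir, "labels.tif"))
    write_overlay_png(img, mask, file.path(out_dir, "overlay.png"))
    write_config_yaml(config, file.path(out_dir, "config_resolved.yaml"))
  }
  attr(report, "mask") <- mask
  attr(report, "label_image") <- labels
  report
}
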