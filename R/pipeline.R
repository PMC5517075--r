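#' Load the experiment recipes bundled with the package
#'
#' Recipes are YAML configurations for [run_experiment()], one per
#' quantification the package reproduces at desk scale (tube elongation
#' cohorts, vesicle cargo census, per-endosome colocalization, endosome
#' diameter recovery, nuclei counts, junction orientation, intensity
#' ratios). Every recipe fixes its seed, so runs are reproducible.
#'
#' @return A named list of validated recipe configurations.
#' @examples
#' names(bundled_recipes())
#' @export
bundled_recipes <- function() {
  dir <- system.file("recipes", package = "tubemorph")
  files <- list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE)
  recs <- lapply(files, read_recipe)
  stats::setNames(recs, vapply(recs, function(r) r$name, character(1)))
}

#' @rdname bundled_recipes
#' @param path Path of a recipe YAML file.
#' @export
read_recipe <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_recipe(cfg)
}

recipe_types <- c("tube_elongation", "vesicle_census", "coloc_overlap",
                  "diameter_recovery", "nuclei_count", "junction_orientation",
                  "intensity_ratio", "sar_afr")

recipe_param_keys <- list(
  tube_elongation = c("n_per_group", "control_tortuosity", "mutant_tortuosity",
                      "tortuosity_sd", "length_um", "diameter_um",
                      "control_label", "mutant_label", "trace"),
  vesicle_census = c("n_vesicles", "p_both", "p_ch1_only", "p_ch2_only",
                     "diameter_um_mean", "diameter_um_sd",
                     "within_vesicle_overlap", "min_separation_um",
                     "cargo_intensity", "field_um"),
  coloc_overlap = c("n_vesicles", "within_vesicle_overlap", "diameter_um_mean",
                    "diameter_um_sd", "min_separation_um", "cargo_intensity",
                    "ratio_cutoff", "field_um", "use_detections"),
  diameter_recovery = c("n_vesicles", "diameter_um_mean", "diameter_um_sd",
                        "min_separation_um", "cargo_intensity", "field_um",
                        "min_diameter_um", "max_diameter_um"),
  nuclei_count = c("planted_counts", "nucleus_diameter_um", "min_separation_um",
                   "group_label"),
  junction_orientation = c("n_cells", "axial_length_um",
                           "circumferential_length_um",
                           "orientation_jitter_deg", "tube_axis_deg"),
  intensity_ratio = c("n_replicates", "dt_intensity", "mt_intensity",
                      "dt_width_px", "mt_width_px"),
  sar_afr = c("cell_side_um", "sar_band_width_um", "sar_intensity",
              "afr_intensity", "band_width_px")
)

validate_recipe <- function(cfg) {
  top_keys <- c("name", "description", "mirrors", "type", "seed", "imaging",
                "params")
  unknown <- setdiff(names(cfg), top_keys)
  if (length(unknown)) {
    stop(sprintf("recipe '%s': unknown top-level key(s): %s",
                 cfg$name %||% "<unnamed>", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(cfg$name) || is.null(cfg$type)) {
    stop("recipe must have 'name' and 'type'", call. = FALSE)
  }
  if (!cfg$type %in% recipe_types) {
    stop(sprintf("recipe '%s': unknown stage type '%s'", cfg$name, cfg$type),
         call. = FALSE)
  }
  if (is.null(cfg$seed)) stop(sprintf("recipe '%s': seed is mandatory", cfg$name),
                              call. = FALSE)
  bad <- setdiff(names(cfg$params %||% list()), recipe_param_keys[[cfg$type]])
  if (length(bad)) {
    stop(sprintf("recipe '%s': unknown parameter(s) for type %s: %s",
                 cfg$name, cfg$type, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  bad_img <- setdiff(names(cfg$imaging %||% list()),
                     c("pixel_size_um", "psf_sigma_um", "poisson_noise",
                       "read_noise_sigma", "bit_depth"))
  if (length(bad_img)) {
    stop(sprintf("recipe '%s': unknown imaging key(s): %s", cfg$name,
                 paste(bad_img, collapse = ", ")), call. = FALSE)
  }
  cfg
}

recipe_imaging <- function(cfg, seed) {
  args <- cfg$imaging %||% list()
  args$seed <- seed
  do.call(imaging_params, args)
}

#' Run a recipe end to end: simulate, measure, report
#'
#' Executes one experiment configuration (see [bundled_recipes()]): phantoms
#' are generated with known ground truth, the relevant measurement operations
#' run on the rendered images, and the result is summarized into headline
#' values plus a [build_report()] table where a group comparison applies.
#' When `out_dir` is given, measurements, report and a provenance record
#' (config, config hash, seed, package version) are written there.
#'
#' @param config A recipe list (from [read_recipe()] / [bundled_recipes()])
#'   or the path of a recipe YAML file.
#' @param seed Optional seed overriding the recipe's own.
#' @param out_dir Optional output directory.
#' @return A list of class `experiment_result`: `name`, `type`, `values`
#'   (named numeric headline results), `measurements`, `report` (possibly
#'   NULL), `seed`.
#' @export
run_experiment <- function(config, seed = NULL, out_dir = NULL) {
  if (is.character(config)) config <- read_recipe(config)
  config <- validate_recipe(config)
  seed <- seed %||% config$seed
  runner <- switch(config$type,
    tube_elongation = run_tube_elongation,
    vesicle_census = run_vesicle_census,
    coloc_overlap = run_coloc_overlap,
    diameter_recovery = run_diameter_recovery,
    nuclei_count = run_nuclei_count,
    junction_orientation = run_junction_orientation,
    intensity_ratio = run_intensity_ratio,
    sar_afr = run_sar_afr)
  res <- tryCatch(
    runner(config$params %||% list(), config, seed),
    error = function(e) {
      stop(sprintf("stage '%s' (%s) failed: %s", config$name, config$type,
                   conditionMessage(e)), call. = FALSE)
    })
  out <- structure(c(list(name = config$name, type = config$type, seed = seed),
                     res),
                   class = "experiment_result")
  if (!is.null(out_dir)) write_experiment(out, config, out_dir)
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s (%s), seed %s\n", x$name, x$type, x$seed))
  v <- unlist(x$values)
  for (nm in names(v)) cat(sprintf("  %-28s %.6g\n", nm, v[[nm]]))
  invisible(x)
}

write_experiment <- function(res, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(res$measurements)) {
    utils::write.csv(res$measurements,
                     file.path(out_dir, paste0(res$name, "_measurements.csv")),
                     row.names = FALSE)
  }
  if (!is.null(res$report)) write_report(res$report, out_dir, res$name)
  prov <- list(name = res$name, type = res$type, seed = res$seed,
               values = res$values, config = config,
               config_hash = rlang::hash(config),
               package_version = as.character(utils::packageVersion("tubemorph")))
  jsonlite::write_json(prov, file.path(out_dir, paste0(res$name, "_result.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# --- stage runners -------------------------------------------------------

run_tube_elongation <- function(p, cfg, seed) {
  n <- p$n_per_group %||% 20
  labels <- c(p$control_label %||% "control", p$mutant_label %||% "mutant")
  targets <- c(p$control_tortuosity %||% 1.0, p$mutant_tortuosity %||% 1.226)
  sdv <- p$tortuosity_sd %||% 0.03
  trace <- p$trace %||% TRUE
  rows <- list()
  for (g in 1:2) {
    for (i in seq_len(n)) {
      s <- derive_seed(seed, paste0("tube-", g, "-", i))
      tort <- with_local_seed(s, max(1, stats::rnorm(1, targets[g], sdv)))
      img <- recipe_imaging(cfg, derive_seed(s, "img"))
      ph <- tube_phantom(length_um = p$length_um %||% 40,
                         diameter_um = p$diameter_um %||% 3,
                         tortuosity = tort, imaging = img)
      path <- if (isTRUE(trace)) {
        trace_centerline(ph$image, anchors = ph$truth$anchors_px)
      } else {
        roi_polyline(ph$truth$centerline)
      }
      r <- dt_ratio(path, ph$image$pixel_size_um)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = labels[g], phantom = i, planted_ratio = ph$truth$arc_chord_ratio,
        ratio = r$ratio, arc_length_um = r$arc_length_um,
        chord_length_um = r$chord_length_um)
    }
  }
  meas <- dplyr::bind_rows(rows)
  report <- build_report(meas[, c("group", "ratio")], group = "group",
                         reference = labels[1])
  means <- tapply(meas$ratio, meas$group, mean)[labels]
  pd <- percent_difference(means[[1]], means[[2]])
  list(values = list(mean_ratio_control = means[[1]],
                     mean_ratio_mutant = means[[2]],
                     percent_difference = pd,
                     percent_reduction = -pd,
                     p_value = report$comparisons$p_value[1]),
       measurements = meas, report = report)
}

run_vesicle_census <- function(p, cfg, seed) {
  img <- recipe_imaging(cfg, seed)
  ph <- vesicle_phantom(
    n_vesicles = p$n_vesicles %||% 194,
    diameter_um_mean = p$diameter_um_mean %||% 0.55,
    diameter_um_sd = p$diameter_um_sd %||% 0.05,
    p_both = p$p_both %||% 0.67, p_ch1_only = p$p_ch1_only %||% 0.15,
    p_ch2_only = p$p_ch2_only %||% 0.18,
    within_vesicle_overlap = p$within_vesicle_overlap %||% 0.60,
    cargo_intensity = p$cargo_intensity %||% 3000,
    min_separation_um = p$min_separation_um %||% 1.5,
    field_um = p$field_um, imaging = img)
  det <- detect_vesicles(ph$image)
  cen <- vesicle_census(det)
  planted <- vesicle_census(ph$truth$vesicles$cargo_class)
  list(values = list(
         pct_both = 100 * cen$p_both, pct_ch1_only = 100 * cen$p_ch1_only,
         pct_ch2_only = 100 * cen$p_ch2_only, n_detected = cen$n_total,
         planted_pct_both = 100 * planted$p_both,
         planted_pct_ch1_only = 100 * planted$p_ch1_only,
         planted_pct_ch2_only = 100 * planted$p_ch2_only),
       measurements = det, census = cen, planted_census = planted,
       truth = ph$truth, report = NULL)
}

run_coloc_overlap <- function(p, cfg, seed) {
  img <- recipe_imaging(cfg, seed)
  ph <- vesicle_phantom(
    n_vesicles = p$n_vesicles %||% 118, p_both = 1, p_ch1_only = 0,
    p_ch2_only = 0,
    within_vesicle_overlap = p$within_vesicle_overlap %||% 0.60,
    diameter_um_mean = p$diameter_um_mean %||% 0.55,
    diameter_um_sd = p$diameter_um_sd %||% 0.05,
    cargo_intensity = p$cargo_intensity %||% 3000,
    min_separation_um = p$min_separation_um %||% 1.5,
    field_um = p$field_um, imaging = img)
  objects <- if (isTRUE(p$use_detections %||% TRUE)) {
    detect_vesicles(ph$image)
  } else {
    ph$truth$vesicles
  }
  pc <- per_object_coloc(ph$image, "ch1", "ch2", objects,
                         coloc_params(ratio_cutoff = p$ratio_cutoff %||% 0.5))
  list(values = list(mean_coloc_fraction_pct = 100 * pc$mean_fraction,
                     n_objects = sum(!pc$per_object$flagged),
                     planted_overlap_pct = 100 * ph$truth$within_vesicle_overlap),
       measurements = pc$per_object, truth = ph$truth, report = NULL)
}

run_diameter_recovery <- function(p, cfg, seed) {
  img <- recipe_imaging(cfg, seed)
  ph <- vesicle_phantom(
    n_vesicles = p$n_vesicles %||% 30, p_both = 1, p_ch1_only = 0,
    p_ch2_only = 0, within_vesicle_overlap = 1,
    diameter_um_mean = p$diameter_um_mean %||% 0.55,
    diameter_um_sd = p$diameter_um_sd %||% 0.05,
    cargo_intensity = p$cargo_intensity %||% 3000,
    min_separation_um = p$min_separation_um %||%
      max(1.5, 2.5 * (p$diameter_um_mean %||% 0.55)),
    field_um = p$field_um, imaging = img)
  det <- detect_vesicles(ph$image,
                         min_diameter_um = p$min_diameter_um %||%
                           0.4 * (p$diameter_um_mean %||% 0.55),
                         max_diameter_um = p$max_diameter_um %||%
                           3 * (p$diameter_um_mean %||% 0.55),
                         psf_sigma_um = img$psf_sigma_um)
  list(values = list(mean_diameter_um = mean(det$diameter_um),
                     planted_mean_diameter_um = mean(ph$truth$vesicles$diameter_um),
                     n_detected = nrow(det)),
       measurements = det, truth = ph$truth, report = NULL)
}

run_nuclei_count <- function(p, cfg, seed) {
  counts <- unlist(p$planted_counts %||% c(25, 26, 25, 26))
  rows <- purrr::imap_dfr(counts, function(n, i) {
    img <- recipe_imaging(cfg, derive_seed(seed, paste0("field", i)))
    ph <- nuclei_phantom(n_nuclei = n,
                         nucleus_diameter_um = p$nucleus_diameter_um %||% 3,
                         min_separation_um = p$min_separation_um %||% 4.5,
                         imaging = img)
    tibble::tibble(field = i, planted = n, counted = count_nuclei(ph$image))
  })
  list(values = list(mean_count = mean(rows$counted),
                     planted_mean = mean(rows$planted),
                     n_exact = sum(rows$counted == rows$planted),
                     n_fields = nrow(rows)),
       measurements = rows, report = NULL)
}

run_junction_orientation <- function(p, cfg, seed) {
  img <- recipe_imaging(cfg, seed)
  ph <- junction_phantom(
    n_cells = p$n_cells %||% 25,
    axial_length_um = p$axial_length_um %||% 2,
    circumferential_length_um = p$circumferential_length_um %||% 1,
    orientation_jitter_deg = p$orientation_jitter_deg %||% 5,
    tube_axis_deg = p$tube_axis_deg %||% 0, imaging = img)
  segs <- measure_junctions(ph$truth$segments,
                            tube_axis_deg = p$tube_axis_deg %||% 0,
                            pixel_size_um = ph$image$pixel_size_um)
  sm <- summarize_junctions(segs)
  ax <- sm$summary$mean_length_um[sm$summary$class == "axial"]
  ci <- sm$summary$mean_length_um[sm$summary$class == "circumferential"]
  list(values = list(mean_axial_length_um = ax,
                     mean_circumferential_length_um = ci,
                     planted_axial_um = p$axial_length_um %||% 2,
                     planted_circumferential_um = p$circumferential_length_um %||% 1),
       measurements = segs, summary = sm, report = NULL)
}

run_intensity_ratio <- function(p, cfg, seed) {
  nrep <- p$n_replicates %||% 10
  dt_i <- p$dt_intensity %||% 1500
  mt_i <- p$mt_intensity %||% 1000
  dtw <- p$dt_width_px %||% 60
  mtw <- p$mt_width_px %||% 10
  truth_ratio <- NA_real_
  rows <- purrr::map_dfr(seq_len(nrep), function(i) {
    img_par <- recipe_imaging(cfg, derive_seed(seed, paste0("rep", i)))
    ph <- intensity_band_phantom(dt_intensity = dt_i, mt_intensity = mt_i,
                                 dt_width_px = dtw, mt_width_px = mtw,
                                 imaging = img_par)
    truth_ratio <<- ph$truth$dt_mt_true_ratio
    r <- dt_mt_ratio(ph$image, 1, ph$dt_roi, ph$mt_roi)
    dplyr::mutate(r, replicate = i)
  })
  list(values = list(mean_ratio = mean(rows$ratio),
                     true_generating_ratio = truth_ratio,
                     nominal_ratio = dt_i / mt_i),
       measurements = rows, report = NULL)
}

run_sar_afr <- function(p, cfg, seed) {
  img_par <- recipe_imaging(cfg, seed)
  side_px <- (p$cell_side_um %||% 5) / img_par$pixel_size_um
  poly <- roi_polygon(cbind(c(10, 10 + side_px, 10 + side_px, 10),
                            c(10, 10, 10 + side_px, 10 + side_px)))
  ph <- apical_cell_phantom(poly,
                            sar_band_width_um = p$sar_band_width_um %||% 0.3,
                            sar_intensity = p$sar_intensity %||% 2000,
                            afr_intensity = p$afr_intensity %||% 1000,
                            imaging = img_par)
  bw <- p$band_width_px %||%
    ((p$sar_band_width_um %||% 0.3) / img_par$pixel_size_um)
  r <- sar_afr_ratio(ph$image, 1, poly, band_width_px = bw)
  list(values = list(measured_ratio = r$ratio,
                     planted_ratio = ph$truth$sar_afr_true_ratio),
       measurements = r, truth = ph$truth, report = NULL)
}
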