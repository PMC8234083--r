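#' Default pipeline configuration
#'
#' Nested list of every stage's parameters with the package defaults filled
#' in. `phantom` holds the synthetic-tissue arguments (see
#' [phantom_config()]); per-image seeds are derived from the root `seed`.
#'
#' @return named list (see [validate_config()] for the schema).
#' @export
default_config <- function() {
  phantom_defaults <- formals(phantom_config)
  phantom_defaults$seed <- NULL
  phantom_defaults <- lapply(phantom_defaults, eval)
  list(seed = 1L,
       n_images = 6L,
       phantom = phantom_defaults,
       preprocess = list(ball_radius_um = 64, include_dapi = FALSE),
       segment = list(growth_um = 1, min_nucleus_area_um2 = 7,
                      max_nucleus_area_um2 = 120, smoothing_scale_um = 0.5,
                      watershed_tolerance = 1),
       phenotype = list(n_calibration_images = 3L,
                        double_positive = "exclude"),
       proximity = list(bin_edges_um = c(10, 30, 50, 100),
                        value = "normalized_intensity"),
       follicles = list(rule = "median"),
       survival = list(hazard_high = 1 / 1500, hazard_low = 1 / 500,
                       censor_time_days = 2200, cap_days = 1862),
       output = list(write_images = FALSE))
}

#' Validate and normalize a pipeline configuration
#'
#' Checks a (possibly partial) configuration against the schema of
#' [default_config()]: unknown keys are rejected before any execution,
#' missing keys are filled with defaults. Accepts a list or a YAML file path.
#'
#' @param config named list or path to a YAML file.
#' @return the normalized configuration (class `run_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- default_config()
  merge_level <- function(user, def, path) {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown))
      stop("unknown config key", if (length(unknown) > 1) "s", ": ",
           paste0(path, unknown, collapse = ", "))
    for (k in names(user)) {
      if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
        if (!is.list(user[[k]]))
          stop("config key '", path, k, "' must be a list")
        def[[k]] <- merge_level(user[[k]], def[[k]], paste0(path, k, "."))
      } else {
        def[[k]] <- user[[k]]
      }
    }
    def
  }
  out <- merge_level(config, defaults, "")
  if (out$n_images < 1) stop("'n_images' must be >= 1")
  bi <- out$phantom$base_intensities
  if (!is.null(names(bi))) out$phantom$base_intensities <- unlist(bi)
  structure(out, class = c("run_config", "list"))
}

#' Write a pipeline configuration to YAML losslessly
#'
#' Serializes at full numeric precision, with named vectors as maps, so
#' `validate_config(write_config(cfg, path))` reproduces the configuration.
#'
#' @param config a `run_config` (or plain list).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  if (!is.null(cfg$phantom$base_intensities))
    cfg$phantom$base_intensities <- as.list(cfg$phantom$base_intensities)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

# stable hash of a normalized config (used to key outputs to their settings)
.config_hash <- function(config, out_dir) {
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  unname(tools::md5sum(cfg_path))
}

#' Run the full phantom analysis pipeline
#'
#' simulate -> preprocess -> segment -> phenotype -> proximity -> follicles
#' -> survival, writing every tabular result as CSV under `out_dir` and a
#' JSON run manifest (config hash, stage outputs, excluded images).
#' Deterministic given `config$seed`: rerunning with the same configuration
#' produces byte-identical CSVs.
#'
#' Each phantom image plays the role of one sample: images are simulated and
#' rendered, marker channels are background-subtracted, nuclei segmented and
#' grown, cells phenotyped with thresholds calibrated on the first images,
#' proximity profiles pooled and compared across images, follicle
#' infiltration scored from the detected CD66b+ centroids and stratified,
#' and a survival cohort drawn with group-conditional hazards and compared
#' by log-rank.
#'
#' @param config a [validate_config()] result (or raw list / YAML path).
#' @param out_dir output directory (created if needed).
#' @param force rerun even if outputs with the same config hash exist.
#' @return the run manifest (list), invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir, force = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config, out_dir)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!force && file.exists(manifest_path)) {
    prev <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    if (identical(prev$config_hash, unname(hash)) &&
        all(file.exists(file.path(out_dir, prev$outputs)))) {
      message("outputs for this configuration already present; skipping ",
              "(use force = TRUE to rerun)")
      return(invisible(prev))
    }
  }
  seed <- config$seed
  marker <- config$phantom$marker_name
  params <- segmentation_params(
    growth_um = config$segment$growth_um,
    min_nucleus_area_um2 = config$segment$min_nucleus_area_um2,
    max_nucleus_area_um2 = config$segment$max_nucleus_area_um2,
    smoothing_scale_um = config$segment$smoothing_scale_um,
    watershed_tolerance = config$segment$watershed_tolerance)
  bins <- radial_bins(config$proximity$bin_edges_um)

  # simulate + per-image image analysis
  tables <- list(); infil <- list(); phantoms <- list()
  for (i in seq_len(config$n_images)) {
    img_id <- sprintf("phantom_%02d", i)
    pc <- do.call(phantom_config,
                  c(config$phantom,
                    list(seed = derive_seed(seed, "image", i))))
    ph <- render_image(generate_layout(pc))
    phantoms[[img_id]] <- ph
    if (isTRUE(config$output$write_images))
      write_stack_tiff(ph$image, file.path(out_dir, paste0(img_id, ".tif")))
    splits <- preprocess_stack(ph$image,
                               ball_radius_um = config$preprocess$ball_radius_um,
                               include_dapi = config$preprocess$include_dapi)
    labels <- segment_nuclei(ph$image$DAPI, params,
                             pixel_size_um = pc$pixel_size_um)
    grown <- grow_regions(labels, growth_um = params$growth_um,
                          pixel_size_um = pc$pixel_size_um)
    tables[[img_id]] <- extract_features(grown, splits,
                                         pixel_size_um = pc$pixel_size_um,
                                         image_id = img_id)
  }

  # phenotype: calibrate on the first images, classify all
  n_cal <- min(config$phenotype$n_calibration_images, length(tables))
  thr <- calibrate_thresholds(tables[seq_len(n_cal)])
  tables <- lapply(tables, classify_cells, thresholds = thr,
                   marker_channel = marker,
                   double_positive = config$phenotype$double_positive)
  cells <- do.call(rbind, tables)
  rownames(cells) <- NULL
  write_csv_out(cells, file.path(out_dir, "cells.csv"))

  # proximity profiles pooled across images
  geom <- list(width_um = config$phantom$field_width_um,
               height_um = config$phantom$field_height_um,
               pixel_size_um = config$phantom$pixel_size_um)
  prof <- profile_images(tables, bins, geom)
  profiles_df <- do.call(rbind, lapply(prof$profiles, as.data.frame))
  rownames(profiles_df) <- NULL
  write_csv_out(profiles_df, file.path(out_dir, "profiles.csv"))
  cmp <- if (length(prof$profiles) >= 2L)
    pool_and_compare(prof$profiles, value = config$proximity$value) else NULL
  if (!is.null(cmp)) {
    write_csv_out(cmp$pooled, file.path(out_dir, "profile_pooled.csv"))
    write_csv_out(cmp$pairwise, file.path(out_dir, "profile_pairwise.csv"))
  }

  # follicle infiltration per image-sample, then stratification
  for (img_id in names(tables)) {
    tab <- tables[[img_id]]
    pts <- tab[tab$is_CD66bpos, c("x_um", "y_um"), drop = FALSE]
    infil[[img_id]] <- count_in_follicles(pts,
                                          phantoms[[img_id]]$follicle_polygons,
                                          sample_id = img_id)
  }
  infil_df <- do.call(rbind, lapply(infil, as.data.frame))
  rownames(infil_df) <- NULL
  sample_means <- vapply(infil, function(x) attr(x, "sample_mean"), numeric(1))
  groups <- stratify_infiltration(sample_means, rule = config$follicles$rule)
  infil_df <- merge(infil_df,
                    groups[, c("sample_id", "group")], by = "sample_id")
  infil_df <- infil_df[order(infil_df$sample_id, infil_df$follicle_id), ]
  write_csv_out(infil_df, file.path(out_dir, "infiltration.csv"))

  # survival: group-conditional exponential times, capped, KM + log-rank
  set.seed(derive_seed(seed, "survival"))
  haz <- ifelse(groups$group == "high", config$survival$hazard_high,
                config$survival$hazard_low)
  t_event <- rexp(nrow(groups), rate = haz)
  surv <- data.frame(sample_id = groups$sample_id,
                     time_days = pmin(t_event, config$survival$censor_time_days),
                     event = as.integer(t_event <= config$survival$censor_time_days),
                     group = groups$group, stringsAsFactors = FALSE)
  surv <- cap_followup(surv, cap_days = config$survival$cap_days)
  write_csv_out(surv, file.path(out_dir, "survival.csv"))
  km <- km_estimate(surv)
  write_csv_out(as.data.frame(km), file.path(out_dir, "km.csv"))
  lr <- if (length(unique(surv$group)) >= 2L) logrank_test(surv) else NULL
  if (is.null(lr)) message("single survival group: log-rank skipped")

  outputs <- c("config.yaml", "cells.csv", "profiles.csv", "infiltration.csv",
               "survival.csv", "km.csv")
  if (!is.null(cmp))
    outputs <- c(outputs, "profile_pooled.csv", "profile_pairwise.csv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("lnspatial")),
    config_hash = unname(hash),
    seed = seed,
    n_images = config$n_images,
    outputs = outputs,
    excluded_images = as.list(prof$excluded),
    n_double_positive = sum(vapply(tables, function(t)
      attr(t, "n_double_positive") %||% 0L, numeric(1))),
    kruskal_p = if (!is.null(cmp)) cmp$kruskal$p.value else NA,
    logrank_p = if (!is.null(lr)) lr$p.value else NA,
    stratification_rule = attr(groups, "rule"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
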