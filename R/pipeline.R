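#' @title Batch pipeline: configuration, orchestration, manifest
#' @name pipeline
#' @description
#' Ties the stages into one reproducible workflow: catalog -> segment ->
#' traits -> dynamics -> [hairs] -> lifespan. A single YAML configuration
#' file carries every stage's parameters; outputs are CSV tables plus PNG
#' masks, and a plain-text run manifest records the package version, the
#' hash of the configuration actually used, and all seeds, which together
#' reproduce the run exactly.
NULL

#' Default pipeline configuration
#'
#' Nested list of every stage's parameters with their defaults; see the
#' configuration file written by [write_config()] for the flat reference.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    paths = list(input_dir = "", output_dir = "rhizotrack_out",
                 model_path = ""),
    catalog = list(naming_pattern = DEFAULT_NAMING_PATTERN,
                   pot_id = NULL, dpi = NULL,
                   frame_width_cm = 20, frame_height_cm = 34,
                   hair_dpi_threshold = HAIR_DPI_DEFAULT),
    geometry = list(DOF_cm = 0.25),
    segmentation = list(method = "classical", threshold = 0.5,
                        flatten_kernel_px = 41L, thr_offset = 0.12,
                        open_size = 3L, min_area_px = 20L),
    traits = list(prune_len_mm = 0.5),
    hairs = list(axis_min_width_mm = 0.08, hair_max_width_mm = 0.04,
                 hair_len_min_mm = 0.05, hair_len_max_mm = 1.5,
                 sample_k = 5L),
    lifespan = list(max_shift_px = 20L, min_corr = 0.2,
                    live_min_brightness = 0.6, tortuosity_threshold = 1.5,
                    min_area_px = 10L, roi_min_area_px = 25L,
                    roi_radius_px = 12L),
    simulate = list(frame_width_mm = 30, frame_height_mm = 45,
                    horizon_days = 12, day_start = 1L, day_step = 1L,
                    taproot_rate_mm_per_day = 3,
                    lateral1_rate_mm_per_day = 2,
                    lateral2_rate_mm_per_day = 1,
                    n_lateral1 = 6L, root_lifespan_mean_days = 6,
                    hair_density_per_mm = 0, dpi = 300L)
  )
}

#' Read / write a pipeline configuration (YAML)
#'
#' Configurations round-trip losslessly through serialization; unknown keys
#' are preserved.
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' @rdname read_config
#' @param config a configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Simulate a synthetic dataset on disk
#'
#' Generates a seeded synthetic root system from the `simulate` section of
#' the configuration and writes daily frames, truth masks and truth tables
#' into `dir`, in the naming convention [run_pipeline()] consumes.
#' Parameters are validated before any file is written.
#'
#' @param config a configuration list (see [default_config()]).
#' @param seed overrides `config$seed`.
#' @param dir output directory (defaults to `config$paths$input_dir`).
#' @return the [generate_series()] bundle, invisibly.
#' @export
simulate_dataset <- function(config = default_config(), seed = config$seed,
                             dir = config$paths$input_dir) {
  sc <- config$simulate
  params <- rsa_params(
    frame_width_mm = sc$frame_width_mm, frame_height_mm = sc$frame_height_mm,
    horizon_days = sc$horizon_days,
    taproot_rate_mm_per_day = sc$taproot_rate_mm_per_day,
    lateral1_rate_mm_per_day = sc$lateral1_rate_mm_per_day,
    lateral2_rate_mm_per_day = sc$lateral2_rate_mm_per_day,
    n_lateral1 = sc$n_lateral1,
    root_lifespan_mean_days = sc$root_lifespan_mean_days,
    hair_density_per_mm = sc$hair_density_per_mm)
  rc <- render_config(dpi = sc$dpi, seed = seed,
                      hair_dpi_threshold = config$catalog$hair_dpi_threshold)
  truth <- grow_root_system(params, seed = seed)
  days <- seq(sc$day_start, sc$horizon_days, by = sc$day_step)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  invisible(generate_series(truth, days, rc, dir = dir))
}

write_manifest <- function(path, entries) {
  writeLines(paste0(names(entries), "=", unlist(entries)), path)
  invisible(path)
}

#' Run the full phenotyping pipeline
#'
#' Executes catalog -> segment -> traits -> dynamics -> hairs -> lifespan on
#' the frames in `config$paths$input_dir`, writing all tables, masks and a
#' run manifest into `config$paths$output_dir`. The hair stage runs only on
#' hair-resolution series (and can be skipped explicitly); any stage error
#' aborts the run with the stage name while retaining partial outputs and a
#' manifest marking the failure.
#'
#' @param config a configuration list (see [default_config()] /
#'   [read_config()]).
#' @param skip character vector of stage names to skip
#'   (`"hairs"`, `"lifespan"`, `"dynamics"`).
#' @return named list of stage outputs, invisibly.
#' @export
run_pipeline <- function(config = default_config(), skip = character(0)) {
  out_dir <- config$paths$output_dir
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config_used.yaml")
  write_config(config, cfg_path)
  manifest <- list(package = "rhizotrack",
                   version = as.character(packageVersion("rhizotrack")),
                   config_hash = unname(tools::md5sum(cfg_path)),
                   seed = config$seed)
  manifest_path <- file.path(out_dir, "manifest.txt")
  results <- list()
  stage <- function(name, fun) {
    if (name %in% skip) {
      manifest[[paste0("stage_", name)]] <<- "skipped"
      return(invisible(NULL))
    }
    r <- tryCatch(fun(), error = function(e) {
      manifest[[paste0("stage_", name)]] <<- "failed"
      write_manifest(manifest_path, manifest)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest[[paste0("stage_", name)]] <<- "completed"
    results[[name]] <<- r
    r
  }

  series <- stage("catalog", function() {
    cc <- config$catalog
    s <- load_series(config$paths$input_dir, cc$naming_pattern,
                     pot_id = cc$pot_id, dpi = cc$dpi,
                     frame_width_cm = cc$frame_width_cm,
                     frame_height_cm = cc$frame_height_cm,
                     hair_dpi_threshold = cc$hair_dpi_threshold)
    write.csv(series_catalog(s), file.path(out_dir, "catalog.csv"),
              row.names = FALSE)
    s
  })

  masks <- stage("segment", function() {
    sg <- config$segmentation
    segment_one <- if (sg$method == "model") {
      model <- load_seg_model(config$paths$model_path)
      function(img) predict_mask(model, img, sg$threshold)
    } else {
      function(img) threshold_segment(img, sg$flatten_kernel_px,
                                      sg$thr_offset, sg$open_size,
                                      sg$min_area_px)
    }
    ms <- lapply(series$records, function(rec) {
      m <- segment_one(read_frame(rec))
      write_mask(m, file.path(out_dir, "masks",
                              sprintf("pot%02d_d%03d_%ddpi.png",
                                      rec$pot_id, rec$day, rec$dpi)))
      m
    })
    names(ms) <- as.character(series$days)
    ms
  })

  traits <- stage("traits", function() {
    geom <- frame_geometry(frame_area_cm2(series), config$geometry$DOF_cm)
    tt <- traits_for_series(series, masks, geom, config$traits$prune_len_mm)
    write.csv(tt, file.path(out_dir, "traits.csv"), row.names = FALSE)
    tt
  })

  stage("dynamics", function() {
    if (nrow(traits) < 2L) stop("need >= 2 frames for dynamics")
    dyn <- rld_ngr(traits)
    write.csv(dyn, file.path(out_dir, "dynamics.csv"), row.names = FALSE)
    dyn
  })

  hair_capable <- series$dpi >= config$catalog$hair_dpi_threshold
  if (!hair_capable && !("hairs" %in% skip)) skip <- c(skip, "hairs")
  stage("hairs", function() {
    hc <- config$hairs
    cal <- calibrate(series$dpi)
    hh <- do.call(rbind, lapply(seq_along(series$days), function(i) {
      hm <- tryCatch(
        detect_hairs(masks[[i]], cal, hc$axis_min_width_mm,
                     hc$hair_max_width_mm,
                     c(hc$hair_len_min_mm, hc$hair_len_max_mm),
                     config$catalog$hair_dpi_threshold),
        error = function(e) NULL)
      if (is.null(hm)) return(NULL)
      samp <- if (hm$n_hairs > 0)
        sample_hair_lengths(hm, hc$sample_k, config$seed)$sampled_mean_mm
      else NA_real_
      data.frame(day = series$days[i], n_hairs = hm$n_hairs,
                 axis_mm = hm$axis_length_mm,
                 density_per_mm = hm$density_per_mm,
                 mean_len_mm = hm$mean_length_mm,
                 sampled_mean_len_mm = samp)
    }))
    if (is.null(hh)) stop("no frame yielded a measurable root axis")
    write.csv(hh, file.path(out_dir, "hairs.csv"), row.names = FALSE)
    hh
  })

  stage("lifespan", function() {
    lc <- config$lifespan
    offs <- if (length(series$records) >= 2L)
      align_series(series, lc$max_shift_px, lc$min_corr)
    else data.frame(day = series$days, dr = 0L, dc = 0L, corr = 1)
    reg_masks <- lapply(seq_along(masks), function(i)
      shift_matrix(as_binary_mask(masks[[i]]), -offs$dr[i], -offs$dc[i]))
    rois <- propose_rois(reg_masks, lc$roi_min_area_px, lc$roi_radius_px)
    if (length(rois) == 0L) stop("no candidate subjects found")
    ev <- extract_events(series, masks, rois,
                         subject_type = "lateral_root", offsets = offs,
                         min_area_px = lc$min_area_px,
                         live_min_brightness = lc$live_min_brightness,
                         tortuosity_threshold = lc$tortuosity_threshold)
    write.csv(ev, file.path(out_dir, "events.csv"), row.names = FALSE)
    km <- kaplan_meier(ev)
    surv <- as.data.frame(km)
    surv$median <- rep(km_median(km), length.out = nrow(surv))
    write.csv(surv, file.path(out_dir, "survival.csv"), row.names = FALSE)
    list(events = ev, curve = km)
  })

  write_manifest(manifest_path, manifest)
  invisible(results)
}
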