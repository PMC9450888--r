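#' End-to-end pipeline: simulate, segment, register, classify, average
#'
#' [run_pipeline()] executes the full analysis on a synthetic scene from a
#' single config (a YAML file or an R list): scene generation, 2D/3D
#' nucleus segmentation with expansion factors, control-point registration,
#' spot detection + clustering + classification, class-5 averaging with
#' radial-profile measurements, and a run manifest with output checksums.
#' All randomness flows from the seeds in the config, so one manifest
#' reproduces identical outputs.
#'
#' @name pipeline
NULL

#' Demo pipeline configuration
#'
#' A small two-channel scene (a handful of structures per class) that runs
#' the whole pipeline in well under a minute.
#'
#' @param seed integer master seed.
#' @return config list accepted by [run_pipeline()].
#' @export
demo_pipeline_config <- function(seed = 1L) {
  list(
    seed = seed,
    simulate = list(
      n_structures_per_class = c(`1` = 1L, `2` = 1L, `3` = 1L, `4` = 1L,
                                 `5` = 2L)
    ),
    detect = list(
      spot_radius_nm = 400,
      quality_threshold = 100,
      link_radius_nm = 500,
      search_radius_nm = 2000
    ),
    register = list(train_fraction = 0.8),
    average = list(max_tilt_deg = 60, band_width_nm = 200,
                   crop_edge_um = 5, span_fraction = 0.5),
    expansion_factor = list(linear = 4, method = "macro")
  )
}

validate_pipeline_config <- function(config) {
  required <- c("seed", "detect")
  miss <- setdiff(required, names(config))
  if (length(miss))
    stop("config schema violation; missing keys: ",
         paste(miss, collapse = ", "), call. = FALSE)
  dkeys <- c("spot_radius_nm", "quality_threshold", "link_radius_nm",
             "search_radius_nm")
  dmiss <- setdiff(dkeys, names(config$detect))
  if (length(dmiss))
    stop("config schema violation; missing detect keys: ",
         paste(dmiss, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Detect, cluster and classify structures in a multi-channel scene
#'
#' The core analysis applied to one nucleus: per-channel LoG spot
#' detection, fixed-radius clustering of the site channel, attachment of
#' partner spots within the search radius, and rule-based classification.
#'
#' @param channels named list of [voxel_grid()]s; must contain `site`,
#'   other names are treated as partner channels (`dna` is ignored).
#' @param spot_radius_nm expected spot radius (scalar or named per
#'   channel).
#' @param quality_threshold detection threshold (scalar or named).
#' @param link_radius_nm site-spot linking radius.
#' @param search_radius_nm partner attachment radius.
#' @param rules class rule set (default chosen by channel count).
#' @return list: `spots` (per-channel list), `structures` (classified),
#'   `class_table`.
#' @export
analyse_scene <- function(channels, spot_radius_nm = 250,
                          quality_threshold = 40, link_radius_nm = 500,
                          search_radius_nm = 2000, rules = NULL) {
  stopifnot("site" %in% names(channels))
  use <- setdiff(names(channels), "dna")
  par_of <- function(p, ch) {
    if (length(p) == 1L && is.null(names(p))) p
    else if (ch %in% names(p)) p[[ch]] else p[[1]]
  }
  spots <- lapply(use, function(ch)
    detect_spots(channels[[ch]], par_of(spot_radius_nm, ch),
                 par_of(quality_threshold, ch)))
  names(spots) <- use
  partners <- spots[setdiff(use, "site")]
  cl <- cluster_site_spots(spots$site, link_radius_nm)
  structs <- assemble_structures(spots$site, cl, partners, search_radius_nm)
  if (is.null(rules)) {
    rules <- if (length(partners) >= 2) three_channel_rules()
             else two_channel_rules()
  }
  structs <- lapply(structs, classify_structure, rules = rules,
                    partner_channel = if ("partner" %in% names(partners))
                      "partner" else NULL)
  list(spots = spots, structures = structs,
       class_table = class_frequency_table(structs,
                                           sort(unique(rules$rules$class))))
}

write_csv_out <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline from a config
#'
#' Stages run in dependency order (simulate, segment, register, detect /
#' classify, average, report); a failure halts with a stage-named error.
#' Every table is written as CSV, measurements as JSON, and a manifest
#' records the config, seeds and MD5 checksums of all outputs.
#'
#' @param config config list or path to a YAML config (see
#'   [demo_pipeline_config()]).
#' @param out_dir output directory.
#' @return the run manifest (list), invisibly; written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = demo_pipeline_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # -- simulate ---------------------------------------------------------
  scene <- stage("simulate", {
    sim_args <- config$simulate %||% list()
    cfg <- do.call(simulation_config,
                   c(list(seed = config$seed), sim_args))
    generate_nucleus_scene(cfg)
  })
  gt_path <- file.path(out_dir, "ground_truth_spots.csv")
  outputs <- c(outputs, write_csv_out(scene$truth$spots, gt_path))

  # -- segment ----------------------------------------------------------
  seg <- stage("segment", {
    pre3 <- segment_nuclei_3d(scene$pre$dna)
    post3 <- segment_nuclei_3d(scene$post$dna)
    mid <- function(vg) {
      d <- dim(vg$data)
      voxel_grid(vg$data[, , ceiling(d[3] / 2)], vg$voxel_size[1:2],
                 channel = vg$channel)
    }
    pre2 <- segment_nuclei_2d(mid(scene$pre$dna), otsu_fallback = TRUE,
                              rolling_ball_radius_px = 0,
                              min_area_um2 = 1, max_area_um2 = 1e5)
    post2 <- segment_nuclei_2d(mid(scene$post$dna), otsu_fallback = TRUE,
                               rolling_ball_radius_px = 0,
                               min_area_um2 = 1, max_area_um2 = 1e5)
    list(
      factor_volume = expansion_factor_from_masks(pre3, post3, "volume"),
      factor_area = expansion_factor_from_masks(pre2, post2, "area")
    )
  })
  exp_json <- file.path(out_dir, "expansion.json")
  jsonlite::write_json(list(
    area_ratio = seg$factor_area$ratio,
    linear_factor_area = seg$factor_area$linear_factor,
    volume_ratio = seg$factor_volume$ratio,
    linear_factor_volume = seg$factor_volume$linear_factor
  ), exp_json, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, exp_json)

  # -- register ---------------------------------------------------------
  reg <- stage("register", {
    ts <- scene$truth$spots
    pts <- data.frame(id = seq_len(nrow(ts)),
                      pre_x = ts$x, pre_y = ts$y, pre_z = ts$z,
                      post_x = ts$post_x, post_y = ts$post_y,
                      post_z = ts$post_z)
    register_control_points(
      pts, train_fraction = config$register$train_fraction %||% 0.8,
      seed = config$seed)
  })
  reg_json <- file.path(out_dir, "registration.json")
  jsonlite::write_json(list(
    mse_train_nm = reg$mse_train, mse_validation_nm = reg$mse_validation,
    n_train = reg$n_train, n_validation = reg$n_validation,
    scale = reg$transform$scale, quaternion = reg$transform$quaternion,
    translation_nm = reg$transform$translation, split_seed = reg$seed
  ), reg_json, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, reg_json)

  # -- detect / classify -------------------------------------------------
  det <- config$detect
  res <- stage("classify", {
    analyse_scene(scene$post,
                  spot_radius_nm = det$spot_radius_nm,
                  quality_threshold = det$quality_threshold,
                  link_radius_nm = det$link_radius_nm,
                  search_radius_nm = det$search_radius_nm)
  })
  all_spots <- do.call(rbind, res$spots)
  outputs <- c(outputs,
               write_csv_out(all_spots, file.path(out_dir, "spots.csv")))
  st_df <- do.call(rbind, lapply(res$structures, function(s)
    data.frame(id = s$id, core_x_nm = s$core[1], core_y_nm = s$core[2],
               core_z_nm = s$core[3], n_site = s$counts[["site"]],
               n_partner = if ("partner" %in% names(s$members))
                 nrow(s$members$partner) else 0L,
               class = s$class_label)))
  outputs <- c(outputs,
               write_csv_out(st_df, file.path(out_dir, "structures.csv")))
  outputs <- c(outputs,
               write_csv_out(res$class_table,
                             file.path(out_dir, "class_frequencies.csv")))

  # -- average ----------------------------------------------------------
  avg_cfg <- config$average %||% list()
  avg_out <- stage("average", {
    c5 <- Filter(function(s) identical(s$class_label, 5L), res$structures)
    c5 <- select_in_plane(c5, avg_cfg$max_tilt_deg %||% 60,
                          avg_cfg$band_width_nm %||% 100)
    if (!length(c5)) return(NULL)
    crops <- lapply(c5, function(s) {
      lapply(scene$post[c("site", "partner")], crop_structure,
             core_nm = s$core, box_edge_um = avg_cfg$crop_edge_um %||% 5)
    })
    avg <- average_structures(crops, ids = vapply(c5, `[[`, 0L, "id"))
    bw <- avg_cfg$band_width_nm %||% 100
    prof_site <- radial_profile(avg, "site", bw)
    prof_partner <- radial_profile(avg, "partner", bw)
    p2p <- peak_to_peak(prof_partner)
    sg <- span_and_gap(prof_site, prof_partner,
                       avg_cfg$span_fraction %||% 0.5,
                       factor = config$expansion_factor$linear %||% 4)
    list(n = avg$n, profiles = list(site = prof_site,
                                    partner = prof_partner),
         peak_to_peak_nm = p2p$length$value, p2p_flag = p2p$flag,
         core_span_nm = sg$core_span$value,
         partner_span_nm = sg$partner_span$value, gap_nm = sg$gap$value)
  })
  if (!is.null(avg_out)) {
    prof_df <- rbind(
      cbind(channel = "site", avg_out$profiles$site),
      cbind(channel = "partner", avg_out$profiles$partner))
    outputs <- c(outputs, write_csv_out(
      prof_df, file.path(out_dir, "radial_profiles.csv")))
    meas_json <- file.path(out_dir, "measurements.json")
    f <- config$expansion_factor$linear %||% 4
    jsonlite::write_json(list(
      n_structures_averaged = avg_out$n,
      peak_to_peak_post_nm = avg_out$peak_to_peak_nm,
      peak_to_peak_pre_nm = avg_out$peak_to_peak_nm / f,
      core_span_post_nm = avg_out$core_span_nm,
      partner_span_post_nm = avg_out$partner_span_nm,
      gap_post_nm = avg_out$gap_nm,
      flag = avg_out$p2p_flag
    ), meas_json, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, meas_json)
  }

  # -- manifest ---------------------------------------------------------
  sums <- tools::md5sum(outputs)
  manifest <- list(
    config = config,
    seed = config$seed,
    planted = list(
      n_structures = length(scene$truth$structures),
      classes = vapply(scene$truth$structures, `[[`, 0L, "class")
    ),
    outputs = lapply(seq_along(outputs), function(i)
      list(file = basename(outputs[i]), md5 = unname(sums[i])))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Human-readable run report
#'
#' Renders a deterministic text summary (class frequencies, expansion
#' factors, registration errors, profile measurements) from a completed
#' run directory; every number is read back from a stage output file.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return the report text (character vector), invisibly; also written to
#'   `report.txt`.
#' @export
make_report <- function(out_dir) {
  man_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(man_path))
    stop("incomplete run: no manifest.json in ", out_dir, call. = FALSE)
  lines <- c("exmfoci pipeline report", "=======================")
  cf_path <- file.path(out_dir, "class_frequencies.csv")
  if (file.exists(cf_path)) {
    cf <- utils::read.csv(cf_path)
    lines <- c(lines, "", "Structure class frequencies:",
               sprintf("  class %s: %d", cf$class, cf$n),
               sprintf("  total: %d", sum(cf$n)))
  }
  exp_path <- file.path(out_dir, "expansion.json")
  if (file.exists(exp_path)) {
    ex <- jsonlite::read_json(exp_path)
    lines <- c(lines, "", sprintf(
      "Expansion: area ratio %.3g (linear %.3g), volume ratio %.3g (linear %.3g)",
      ex$area_ratio, ex$linear_factor_area, ex$volume_ratio,
      ex$linear_factor_volume))
  }
  reg_path <- file.path(out_dir, "registration.json")
  if (file.exists(reg_path)) {
    rg <- jsonlite::read_json(reg_path)
    lines <- c(lines, sprintf(
      "Registration: MSE %.4g nm train (n=%d) / %.4g nm validation (n=%d), scale %.4g",
      rg$mse_train_nm, rg$n_train, rg$mse_validation_nm, rg$n_validation,
      rg$scale))
  }
  meas_path <- file.path(out_dir, "measurements.json")
  if (file.exists(meas_path)) {
    ms <- jsonlite::read_json(meas_path)
    lines <- c(lines, sprintf(
      "Class-5 average (n=%d): peak-to-peak %.4g nm post (%.4g nm pre), core span %.4g nm, shell span %.4g nm, gap %.4g nm",
      ms$n_structures_averaged, ms$peak_to_peak_post_nm,
      ms$peak_to_peak_pre_nm, ms$core_span_post_nm, ms$partner_span_post_nm,
      ms$gap_post_nm))
  }
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(lines)
}
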