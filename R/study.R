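#' Per-condition generator settings for a simulated injury study
#'
#' The planted phenotypes mirror a focal contusion and its treatment:
#' control slices have a flat, low cell-death signal, spatially uniform
#' neurite density and mostly ramified cells; injured slices plant a strong
#' radially decaying cell-death signal, core neurite depletion and an
#' amoeboid shift in the core; the treated condition plants a partial
#' rescue of all three.
#'
#' @return named list of per-condition parameter lists
#'   (`pi_amplitude`, `density_factors`, `amoeboid_fraction_core`,
#'   `amoeboid_fraction_periphery`).
#' @export
condition_presets <- function() {
  list(
    "CTRL" = list(pi_amplitude = 80,
                  density_factors = c(lesion = 1, perilesion = 1,
                                      periphery = 1),
                  amoeboid_fraction_core = 0.2,
                  amoeboid_fraction_periphery = 0.2),
    "TBI" = list(pi_amplitude = 1000,
                 density_factors = c(lesion = 0.2, perilesion = 0.6,
                                     periphery = 1),
                 amoeboid_fraction_core = 0.8,
                 amoeboid_fraction_periphery = 0.2),
    "TBI+MSC-sec" = list(pi_amplitude = 550,
                         density_factors = c(lesion = 0.55,
                                             perilesion = 0.8,
                                             periphery = 1),
                         amoeboid_fraction_core = 0.5,
                         amoeboid_fraction_periphery = 0.2)
  )
}

#' Configuration of a simulated end-to-end study
#'
#' A run configuration is a plain list that round-trips losslessly through
#' YAML; [config_hash()] of the serialized form stamps every output for
#' provenance.
#'
#' @param conditions condition labels (subset of [condition_presets()]
#'   names, or all).
#' @param n_per_condition slices per condition.
#' @param stages character subset of `c("radial", "neurite", "glia",
#'   "expression")`.
#' @param seed base seed for the whole study.
#' @param pi_shape,pi_pixel_size PI channel image shape (px) and pixel size
#'   (um/px).
#' @param neurite_shape,neurite_pixel_size neurite channel geometry.
#' @param cell_shape,cell_pixel_size,cell_center,cell_count cell channel
#'   geometry and population size (`cell_center` is offset so that the
#'   field reaches the periphery area).
#' @param roi_size_px neurite ROI edge in px; `median_radius` the median
#'   filter radius used at this scaled-down geometry.
#' @param n_rings concentric rings for the radial profile.
#' @param genes,true_log2fc_tbi,true_log2fc_msc,n_expr,ct_noise_sd planted
#'   expression design.
#' @param out_dir optional output directory for CSVs.
#' @return list of class `run_config`.
#' @export
run_config <- function(conditions = c("CTRL", "TBI", "TBI+MSC-sec"),
                       n_per_condition = 3,
                       stages = c("radial", "neurite", "glia", "expression"),
                       seed = 1L,
                       pi_shape = c(400L, 400L), pi_pixel_size = 10,
                       neurite_shape = c(800L, 800L), neurite_pixel_size = 4,
                       cell_shape = c(1100L, 1100L), cell_pixel_size = 1,
                       cell_center = c(250, 250), cell_count = 150L,
                       roi_size_px = 56L, median_radius = 2L,
                       n_rings = 4L,
                       genes = c("MAP2", "BDNF", "GFAP", "CD11b"),
                       true_log2fc_tbi = c(MAP2 = -1.5, BDNF = -1.5,
                                           GFAP = 1, CD11b = 1),
                       true_log2fc_msc = c(MAP2 = -0.7, BDNF = -0.7,
                                           GFAP = 0.5, CD11b = 0.5),
                       n_expr = 6L, ct_noise_sd = 0.3,
                       out_dir = NULL) {
  stages <- match.arg(stages, c("radial", "neurite", "glia", "expression"),
                      several.ok = TRUE)
  bad <- setdiff(conditions, names(condition_presets()))
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  cfg <- list(conditions = conditions,
              n_per_condition = as.integer(n_per_condition),
              stages = stages, seed = as.integer(seed),
              pi_shape = as.integer(pi_shape), pi_pixel_size = pi_pixel_size,
              neurite_shape = as.integer(neurite_shape),
              neurite_pixel_size = neurite_pixel_size,
              cell_shape = as.integer(cell_shape),
              cell_pixel_size = cell_pixel_size,
              cell_center = as.numeric(cell_center),
              cell_count = as.integer(cell_count),
              roi_size_px = as.integer(roi_size_px),
              median_radius = as.integer(median_radius),
              n_rings = as.integer(n_rings),
              genes = genes,
              true_log2fc_tbi = as.list(true_log2fc_tbi),
              true_log2fc_msc = as.list(true_log2fc_msc),
              n_expr = as.integer(n_expr), ct_noise_sd = ct_noise_sd,
              out_dir = out_dir)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Hash of a run configuration
#'
#' MD5 of the YAML serialization; stamped into every output table so that
#' outputs from different configurations cannot be silently mixed.
#'
#' @param config a [run_config()].
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # output location does not identify the analysis
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(cfg, tf)
  unname(tools::md5sum(tf))
}

slice_seed <- function(base, cond_idx, rep_idx, channel_idx) {
  (base * 131L + cond_idx * 7919L + rep_idx * 104729L +
     channel_idx * 611L) %% 2147483000L
}

#' Run a simulated end-to-end study
#'
#' For each condition and replicate slice, generates the enabled channels
#' with the condition's planted phenotype and quantifies them: radial
#' cell-death profile and AUC; neurite skeleton metrics per concentric
#' area; per-region single-cell morphometry and percent stained area. One
#' planted Ct table per study feeds the delta-delta-Ct and group-test
#' stage. Rerunning with the same configuration and seed reproduces
#' identical outputs.
#'
#' @param config a [run_config()].
#' @return list of class `study_summary`: `metrics` (long data.frame:
#'   `condition`, `slice_id`, `stage`, `region`, `metric`, `value`,
#'   `config_hash`), `expression` (delta-delta-Ct table or NULL),
#'   `expression_tests`, `provenance`.
#' @export
run_study <- function(config) {
  presets <- condition_presets()
  hash <- config_hash(config)
  rows <- list()
  addrow <- function(cond, slice, stage, region, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      condition = cond, slice_id = slice, stage = stage, region = region,
      metric = metric, value = value, config_hash = hash)
  }
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    p <- presets[[cond]]
    for (ri in seq_len(config$n_per_condition)) {
      sid <- sprintf("%s-%02d", cond, ri)
      if ("radial" %in% config$stages) {
        spec <- slice_spec(image_shape = config$pi_shape,
                           pixel_size = config$pi_pixel_size,
                           pi_amplitude = p$pi_amplitude,
                           seed = slice_seed(config$seed, ci, ri, 1L))
        sim <- simulate_pi_channel(spec)
        geom <- lesion_geometry(spec$lesion_center, spec$pixel_size,
                                n_rings = config$n_rings)
        prof <- radial_profile(sim$image[, , 1], geom)
        for (k in seq_len(nrow(prof)))
          addrow(cond, sid, "radial",
                 as.character(assign_region(prof$mid_um[k])),
                 sprintf("ring%d_density", prof$ring[k]),
                 prof$normalized_density[k])
        addrow(cond, sid, "radial", "whole", "pi_auc", profile_auc(prof))
      }
      if ("neurite" %in% config$stages) {
        spec <- slice_spec(image_shape = config$neurite_shape,
                           pixel_size = config$neurite_pixel_size,
                           density_factors = p$density_factors,
                           seed = slice_seed(config$seed, ci, ri, 2L))
        sim <- simulate_neurite_channel(spec)
        geom <- lesion_geometry(spec$lesion_center, spec$pixel_size)
        rois <- place_rois(geom, spec$image_shape, config$roi_size_px)
        res <- neurite_pipeline(sim$image, rois, spec$pixel_size,
                                radius = config$median_radius)
        for (k in seq_len(nrow(res$per_area)))
          for (m in c("n_branches", "longest_branch_um", "network_density",
                      "total_length_um"))
            addrow(cond, sid, "neurite",
                   as.character(res$per_area$area[k]), m,
                   res$per_area[[m]][k])
      }
      if ("glia" %in% config$stages) {
        spec <- slice_spec(image_shape = config$cell_shape,
                           pixel_size = config$cell_pixel_size,
                           lesion_center = config$cell_center,
                           cell_count = config$cell_count,
                           amoeboid_fraction_core = p$amoeboid_fraction_core,
                           amoeboid_fraction_periphery =
                             p$amoeboid_fraction_periphery,
                           seed = slice_seed(config$seed, ci, ri, 3L))
        sim <- simulate_cell_channel(spec)
        sa <- stained_area_fraction(sim$image, n_planes = 1)
        addrow(cond, sid, "glia", "whole", "percent_stained",
               sa$mean_percent)
        cm <- cell_morphometry(sim$image, spec$pixel_size)
        if (nrow(cm$cells)) {
          d_um <- spec$pixel_size *
            sqrt((cm$cells$centroid_row - spec$lesion_center[1])^2 +
                 (cm$cells$centroid_col - spec$lesion_center[2])^2)
          reg <- assign_region(d_um)
          for (rg in levels(reg)) {
            sel <- reg == rg
            if (!any(sel)) next
            sm <- summarize_cells(cm$cells[sel, , drop = FALSE])
            for (m in c("mean_circularity", "mean_area_um2", "mean_feret_um",
                        "mean_perimeter_um"))
              addrow(cond, sid, "glia", rg, m, sm[[m]])
            addrow(cond, sid, "glia", rg, "n_cells", sm$n_cells)
          }
        }
      }
    }
  }
  expression <- NULL; expression_tests <- NULL
  if ("expression" %in% config$stages &&
      all(c("CTRL", "TBI") %in% config$conditions)) {
    treated2 <- if ("TBI+MSC-sec" %in% config$conditions)
      list(label = "TBI+MSC-sec", n = config$n_expr,
           log2fc = unlist(config$true_log2fc_msc)) else NULL
    ct <- simulate_ct_table(config$genes, config$n_expr, config$n_expr,
                            unlist(config$true_log2fc_tbi),
                            ct_noise_sd = config$ct_noise_sd,
                            seed = slice_seed(config$seed, 0L, 0L, 4L),
                            treated2 = treated2)
    expression <- delta_delta_ct(ct, ctrl_group = "CTRL")
    expression_tests <- lapply(split(expression, expression$gene),
                               function(g)
                                 compare_groups(g$log2fc, g$group))
  }
  metrics <- do.call(rbind, rows)
  out <- structure(
    list(metrics = metrics, expression = expression,
         expression_tests = expression_tests,
         provenance = list(config_hash = hash, seed = config$seed,
                           package_version =
                             as.character(utils::packageVersion("slicequant")))),
    class = "study_summary")
  if (!is.null(config$out_dir)) write_study(out, config$out_dir)
  out
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(study$metrics, file.path(out_dir, "metrics.csv"),
            row.names = FALSE)
  if (!is.null(study$expression))
    write.csv(cbind(study$expression,
                    config_hash = study$provenance$config_hash),
              file.path(out_dir, "expression_log2fc.csv"),
              row.names = FALSE)
  writeLines(yaml::as.yaml(study$provenance),
             file.path(out_dir, "provenance.yaml"))
  invisible(out_dir)
}

#' Condition-level summary of a simulated study
#'
#' Injured conditions are summarized per concentric region (mean over that
#' region's ROIs and slices); the control condition pools all regions (the
#' average-of-all-ROIs convention used when areas do not differ in
#' controls). Summaries refuse to mix metric tables carrying different
#' configuration hashes.
#'
#' @param metrics `metrics` table of a `study_summary` (tables from several
#'   studies may be concatenated if their hashes agree).
#' @param ctrl_condition label of the control condition.
#' @return data.frame: `condition`, `region`, `stage`, `metric`, `mean`,
#'   `n`.
#' @export
summarize_study <- function(metrics, ctrl_condition = "CTRL") {
  if (length(unique(metrics$config_hash)) > 1)
    stop("refusing to mix outputs from different configuration hashes")
  metrics$region_s <- ifelse(metrics$condition == ctrl_condition,
                             "all", as.character(metrics$region))
  ag <- aggregate(value ~ condition + region_s + stage + metric,
                  data = metrics, FUN = mean)
  n <- aggregate(value ~ condition + region_s + stage + metric,
                 data = metrics, FUN = length)
  ag$n <- n$value
  names(ag)[names(ag) == "region_s"] <- "region"
  names(ag)[names(ag) == "value"] <- "mean"
  ag[order(ag$stage, ag$metric, ag$condition, ag$region), ]
}
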