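#' Pipeline configuration
#'
#' Declares a reproducible multi-sample run: the sample manifest, the
#' per-stage parameters and the output directory. In `"phantom"` mode each
#' manifest row names a cohort preset; in `"volumes"` mode it points at a
#' TIFF volume written by [write_volume()]. A single global seed expands to
#' per-sample substreams as `seed * 1000 + row index`, so adding a sample
#' does not perturb the others (a `seed` column in the manifest overrides
#' the substream).
#'
#' @param samples Data frame with columns `sample_id`, `cohort`, and
#'   either `preset` (phantom mode) or `path` (volumes mode); optional
#'   `seed`.
#' @param input_mode `"phantom"` or `"volumes"`.
#' @param seg_params A [segmentation_params()].
#' @param prof_params A [profile_params()].
#' @param preset_args Named list of arguments forwarded to
#'   [cohort_preset()] (e.g. `lacuna_volume_scale`), phantom mode only.
#' @param base_config Base [phantom_config()] for phantom mode.
#' @param calibration TMD calibration passed to [tmd_calibrate()].
#' @param stages Character subset of `c("spatial", "mineral",
#'   "morphometry")`: which measurement stages to run after segmentation
#'   (canal segmentation runs whenever spatial or mineral stages need it).
#' @param out_dir Output directory for tables and the run manifest.
#' @param seed Global integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(samples, input_mode = c("phantom", "volumes"),
                            seg_params = segmentation_params(),
                            prof_params = profile_params(),
                            preset_args = list(),
                            base_config = phantom_config(),
                            calibration = "identity",
                            stages = c("spatial", "mineral", "morphometry"),
                            out_dir = tempfile("plr_run_"),
                            seed = 1L) {
  input_mode <- match.arg(input_mode)
  stages <- match.arg(stages, several.ok = TRUE)
  samples <- as.data.frame(samples)
  if (anyDuplicated(samples$sample_id))
    stop("pipeline_config: sample ids must be unique")
  need <- c("sample_id", "cohort", if (input_mode == "volumes") "path" else "preset")
  missing <- setdiff(need, names(samples))
  if (length(missing))
    stop(sprintf("pipeline_config: manifest lacks columns: %s",
                 paste(missing, collapse = ", ")))
  structure(list(samples = samples, input_mode = input_mode,
                 seg_params = seg_params, prof_params = prof_params,
                 preset_args = preset_args, base_config = base_config,
                 calibration = calibration, stages = stages,
                 out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

sample_seed <- function(global_seed, index, explicit = NULL) {
  if (!is.null(explicit) && !is.na(explicit)) return(as.integer(explicit))
  as.integer((as.numeric(global_seed) * 1000 + index) %% 2147483647)
}

# voxel-weighted aggregation of per-lacuna profile rows to
# (sample x quartile-or-all x bin)
aggregate_profiles <- function(per_lacuna, bin_width_um) {
  dt <- data.table::as.data.table(per_lacuna)
  all_rows <- dt[, list(mean_tmd = sum(mean_tmd * voxel_count) / sum(voxel_count),
                        voxel_count = sum(voxel_count),
                        n_lacunae = data.table::uniqueN(id)),
                 by = c("sample_id", "bin_index")]
  all_rows[, quartile := "all"]
  out <- all_rows
  if ("volume_quartile" %in% names(dt) && any(!is.na(dt$volume_quartile))) {
    qs <- dt[!is.na(volume_quartile),
             list(mean_tmd = sum(mean_tmd * voxel_count) / sum(voxel_count),
                  voxel_count = sum(voxel_count),
                  n_lacunae = data.table::uniqueN(id)),
             by = c("sample_id", "volume_quartile", "bin_index")]
    data.table::setnames(qs, "volume_quartile", "quartile")
    out <- rbind(all_rows, qs, fill = TRUE)
  }
  out[, `:=`(bin_lo_um = bin_index * bin_width_um,
             bin_hi_um = (bin_index + 1) * bin_width_um)]
  data.table::setorder(out, sample_id, quartile, bin_index)
  as.data.frame(out)
}

#' Run a single sample through segmentation and measurement
#'
#' The per-sample stage chain: bone mask, surfaces, lacunae, canals,
#' distance maps and surface assignment, morphometry, TMD calibration,
#' lacunar-edge distances and per-lacuna mineralization profiles.
#'
#' @param vol Attenuation [volume3d()].
#' @param sample_id,cohort Labels copied into the outputs.
#' @param seg_params,prof_params,calibration Stage parameters.
#' @param stages Which measurement stages to run (see [pipeline_config()]).
#' @return List: `lacunae` (augmented table), `morphometry` (or `NULL`),
#'   `profile_per_lacuna` (or `NULL`), `filter_counts`, `threshold`.
#' @export
analyze_sample <- function(vol, sample_id, cohort,
                           seg_params = segmentation_params(),
                           prof_params = profile_params(),
                           calibration = "identity",
                           stages = c("spatial", "mineral", "morphometry")) {
  do_spatial <- "spatial" %in% stages
  do_mineral <- "mineral" %in% stages
  do_morph <- "morphometry" %in% stages
  bone <- segment_bone(vol, seg_params)
  surfaces <- withCallingHandlers(
    identify_surfaces(bone, seg_params),
    warning = function(w) invokeRestart("muffleWarning"))
  med1 <- median_filter3(vol$data, seg_params$smoothing_kernel_k)
  lac <- segment_lacunae(vol, bone, seg_params, prefiltered = med1)
  canals <- if (do_spatial || do_mineral) {
    segment_canals(vol, bone, seg_params, surfaces = surfaces,
                   prefiltered = if (seg_params$canal_median_k ==
                                     seg_params$smoothing_kernel_k) med1)
  } else {
    volume3d(array(0L, dim(vol$data)), vol$spacing_um, "labels")
  }
  rm(med1)
  table <- lac$table
  table$sample_id <- sample_id
  table$cohort <- cohort
  have_canals <- any(canals$data > 0)
  if (do_spatial) {
    table <- suppressWarnings(assign_lacunae(
      table, lac$labels, surfaces$endosteum_mask, surfaces$periosteum_mask,
      canal_mask = if (have_canals) canals else NULL))
  }
  morph <- NULL
  if (do_morph) {
    morph <- cortical_morphometry(bone, lac$table, surfaces = surfaces,
                                  sample_id = sample_id)
    morph$cohort <- cohort
  }
  prof <- NULL
  if (do_mineral && nrow(lac$table) > 0) {
    tmd <- tmd_calibrate(vol, calibration)
    # bone tissue for profiling: thresholded bone voxels without voids
    thr <- attr(bone, "threshold")
    tissue <- volume3d(
      array(as.integer(bone$data > 0 & vol$data >= thr &
                         !(lac$labels$data > 0) & !(canals$data > 0)),
            dim(vol$data)), vol$spacing_um, "binary")
    edge <- lacunar_edge_distance(lac$labels, tissue)
    pr <- mineralization_profiles(tmd, edge, lac$table, tissue,
                                  canal_mask = canals, params = prof_params)
    prof <- pr$per_lacuna
    prof$sample_id <- sample_id
    prof$cohort <- cohort
  }
  list(lacunae = table, morphometry = morph, profile_per_lacuna = prof,
       filter_counts = lac$qc$counts, threshold = lac$qc$threshold)
}

#' Run the full multi-sample pipeline
#'
#' Generates or loads every sample, runs the per-sample chain, pools the
#' volume quartiles across samples and cohorts, summarizes distances by
#' quartile, runs the cohort statistics, and writes all tables plus a
#' machine-readable run manifest (config echo, seeds, per-stage filter
#' counts) to the output directory. Any stage error aborts with the stage
#' name and sample id; partial outputs are kept next to a `FAILED` marker.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the pooled tables (`lacunae`,
#'   `morphometry`, `profiles_per_sample`, `distance_summary`, `stats`,
#'   `manifest`) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  smp <- config$samples
  if (config$input_mode == "volumes") {
    missing <- !file.exists(smp$path)
    if (any(missing))
      stop(sprintf("run_pipeline: volume file missing for sample '%s': %s",
                   smp$sample_id[which(missing)[1]], smp$path[which(missing)[1]]))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fail <- function(stage, sample, e) {
    writeLines(sprintf("FAILED at stage '%s' for sample '%s': %s",
                       stage, sample, conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop(sprintf("run_pipeline: stage '%s' failed for sample '%s': %s",
                 stage, sample, conditionMessage(e)), call. = FALSE)
  }
  res <- vector("list", nrow(smp))
  for (i in seq_len(nrow(smp))) {
    sid <- smp$sample_id[i]
    vol <- tryCatch({
      if (config$input_mode == "phantom") {
        cfg <- do.call(cohort_preset,
                       c(list(name = smp$preset[i], base = config$base_config,
                              seed = sample_seed(config$seed, i, smp$seed[i])),
                         config$preset_args))
        generate_phantom(cfg)$attenuation
      } else {
        read_volume(smp$path[i])
      }
    }, error = function(e) fail("input", sid, e))
    res[[i]] <- tryCatch(
      analyze_sample(vol, sid, smp$cohort[i],
                     seg_params = config$seg_params,
                     prof_params = config$prof_params,
                     calibration = config$calibration,
                     stages = config$stages),
      error = function(e) fail("analyze", sid, e))
    rm(vol)
  }

  lacunae <- do.call(rbind, lapply(res, `[[`, "lacunae"))
  morph <- do.call(rbind, Filter(Negate(is.null),
                                 lapply(res, `[[`, "morphometry")))
  per_lac_prof <- do.call(rbind, Filter(Negate(is.null),
                                        lapply(res, `[[`, "profile_per_lacuna")))

  qt <- tryCatch(volume_quartiles(lacunae), error = function(e) fail("quartiles", "(pooled)", e))
  lacunae <- qt$table
  if (!is.null(per_lac_prof)) {
    per_lac_prof$volume_quartile <- NULL
    per_lac_prof <- merge(per_lac_prof,
                          lacunae[, c("sample_id", "id", "volume_quartile")],
                          by = c("sample_id", "id"))
    profiles_per_sample <- aggregate_profiles(per_lac_prof,
                                              config$prof_params$bin_width_um)
  } else {
    profiles_per_sample <- NULL
  }
  dist_summary <- if ("d_vasculature_um" %in% names(lacunae))
    mean_min_distance_by_quartile(lacunae) else NULL

  stats_out <- list()
  if (length(unique(lacunae$cohort)) >= 2) {
    stats_out$lacunar_volume <- suppressWarnings(
      mixed_model_compare(lacunae, outcome = "volume_um3",
                          group = "cohort", bone = "sample_id"))
    if ("d_vasculature_um" %in% names(lacunae))
      stats_out$d_vasculature <- suppressWarnings(
        mixed_model_compare(lacunae, outcome = "d_vasculature_um",
                            group = "cohort", bone = "sample_id"))
    if (length(unique(lacunae$cohort)) == 2 && !is.null(per_lac_prof)) {
      stats_out$profile_overall <- profile_compare(
        per_lac_prof, value = "mean_tmd", group = "cohort",
        bone = "sample_id", bin_width_um = config$prof_params$bin_width_um)
      q4 <- per_lac_prof[per_lac_prof$volume_quartile == "Q4", , drop = FALSE]
      if (nrow(q4)) {
        stats_out$profile_q4 <- profile_compare(
          q4, value = "mean_tmd", group = "cohort", bone = "sample_id",
          bin_width_um = config$prof_params$bin_width_um)
      }
    }
  }

  filter_counts <- do.call(rbind, lapply(seq_along(res), function(i) {
    data.frame(sample_id = smp$sample_id[i], t(res[[i]]$filter_counts))
  }))

  write_table(lacunae, file.path(config$out_dir, "lacunae.csv"))
  if (!is.null(morph))
    write_table(morph, file.path(config$out_dir, "morphometry.csv"))
  if (!is.null(profiles_per_sample))
    write_table(profiles_per_sample, file.path(config$out_dir, "profiles_per_sample.csv"))
  if (!is.null(dist_summary))
    write_table(dist_summary$per_cohort, file.path(config$out_dir, "distance_by_quartile.csv"))
  write_table(filter_counts, file.path(config$out_dir, "filter_counts.csv"))
  if (!is.null(stats_out$lacunar_volume))
    write_table(stats_out$lacunar_volume, file.path(config$out_dir, "stats_lacunar_volume.csv"))
  if (!is.null(stats_out$profile_q4)) {
    jsonlite::write_json(
      list(gate_significant = stats_out$profile_q4$gate_significant,
           significant_bins = stats_out$profile_q4$significant_bins,
           significant_ranges_um = stats_out$profile_q4$significant_ranges_um),
      file.path(config$out_dir, "significant_bins_q4.json"),
      auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("perilacunar")),
    r_version = R.version.string,
    seed = config$seed,
    input_mode = config$input_mode,
    samples = smp,
    quartile_boundaries_um3 = unname(qt$boundaries),
    filter_counts = filter_counts,
    seg_params = unclass(config$seg_params),
    prof_params = unclass(config$prof_params))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  invisible(list(lacunae = lacunae, morphometry = morph,
                 profiles_per_sample = profiles_per_sample,
                 profiles_per_lacuna = per_lac_prof,
                 distance_summary = dist_summary,
                 quartiles = qt, stats = stats_out,
                 filter_counts = filter_counts,
                 out_dir = config$out_dir))
}
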