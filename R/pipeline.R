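#' Analyze one clip: detect, track, summarize
#'
#' Runs the full video path on a single chamber clip: background
#' estimation, per-frame blob detection, Hungarian linking, and the chamber
#' endpoint summary.
#'
#' @param clip a `synthetic_clip` (or frame array plus explicit `imaging`).
#' @param imaging an [imaging_config()]; defaults to the clip's own
#'   calibration.
#' @param tracking a [tracking_config()].
#' @param time_h,chamber_id,n_animals metadata passed to
#'   [chamber_summary()].
#' @param jitter_floor_mm see [track_metrics()].
#' @return list with `detections`, `tracks`, `summary`.
#' @export
analyze_clip <- function(clip, imaging = NULL, tracking = tracking_config(),
                         time_h = 0, chamber_id = "chamber",
                         n_animals = NULL, jitter_floor_mm = 0.08) {
  if (is.null(imaging)) {
    if (!inherits(clip, "synthetic_clip")) {
      stop("'imaging' calibration is required for raw frame arrays",
           call. = FALSE)
    }
    imaging <- imaging_config(mm_per_px = clip$chamber$mm_per_px,
                              fps = clip$fps)
  }
  chamber <- if (inherits(clip, "synthetic_clip")) clip$chamber else {
    stop("'clip' must be a synthetic_clip; use detect_clip()/link_tracks() ",
         "directly for external frame stacks", call. = FALSE)
  }
  dets <- detect_clip(clip, imaging)
  tracks <- link_tracks(dets, tracking, imaging)
  summ <- chamber_summary(tracks, imaging, chamber, time_h = time_h,
                          chamber_id = chamber_id, n_animals = n_animals,
                          jitter_floor_mm = jitter_floor_mm,
                          body_length_mm = imaging$body_length_mm)
  list(detections = dets, tracks = tracks, summary = summ)
}

#' Analyze an assay dataset end to end
#'
#' Runs every chamber x timepoint through the endpoint extraction, either
#' on rendered clips (`mode = "video"`: detection and tracking) or directly
#' on ground-truth trajectories (`mode = "truth"`, the truth-bypass lane
#' that isolates endpoint and statistics correctness from tracker noise).
#' Treated groups are then normalized to the concurrent controls, response
#' syndromes classified, and ANOVA / t-test statistics computed. Chambers
#' with no reportable tracks are excluded with a warning.
#'
#' @param dataset an `assay_dataset` from [generate_assay()].
#' @param mode `"video"` or `"truth"`.
#' @param tracking a [tracking_config()].
#' @param metric endpoint used for normalization.
#' @param jitter_floor_mm see [track_metrics()].
#' @return list with `endpoints` (per chamber x timepoint),
#'   `normalized` (per concentration x timepoint, labelled), `stats`
#'   (ANOVA + t-tests), `immobilization` (counts per group suitable for
#'   [fit_hill()]).
#' @export
analyze_assay <- function(dataset, mode = c("truth", "video"),
                          tracking = tracking_config(),
                          metric = "total_distance_mm",
                          jitter_floor_mm = 0.08) {
  stopifnot(inherits(dataset, "assay_dataset"))
  mode <- match.arg(mode)
  design <- dataset$design
  chamber <- dataset$chamber_spec
  imaging <- imaging_config(mm_per_px = chamber$mm_per_px, fps = design$fps)
  ep <- list()
  for (rec in dataset$chambers) {
    tracks <- if (mode == "truth") {
      truth_tracks(rec$truths)
    } else {
      if (is.null(rec$clip)) {
        stop("dataset was generated without rendered clips; use mode = \"truth\" ",
             "or regenerate with render = TRUE", call. = FALSE)
      }
      link_tracks(detect_clip(rec$clip, imaging), tracking, imaging)
    }
    s <- chamber_summary(tracks, imaging, chamber, time_h = rec$time_h,
                         chamber_id = rec$chamber_id,
                         n_animals = design$animals_per_chamber,
                         jitter_floor_mm = jitter_floor_mm,
                         body_length_mm = imaging$body_length_mm)
    s$concentration <- rec$concentration
    s$replicate <- rec$replicate
    ep[[length(ep) + 1L]] <- s
  }
  endpoints <- do.call(rbind, ep)

  control <- endpoints[endpoints$concentration == 0, , drop = FALSE]
  normalized <- NULL
  for (cc in setdiff(sort(unique(endpoints$concentration)), 0)) {
    treated <- endpoints[endpoints$concentration == cc, , drop = FALSE]
    nr <- normalize_to_control(treated, control, metric = metric,
                               concentration = cc)
    nr <- classify_response(nr)
    normalized <- rbind(normalized, nr)
  }

  stats <- if (design$replicates >= 2) {
    behavioural_stats(endpoints, metric = metric)
  } else NULL

  imm <- unique(dataset$index[, c("chamber_id", "concentration", "replicate",
                                  "n_animals", "n_immobile")])
  immobilization <- dose_response_data(
    imm$concentration, imm$n_animals, imm$n_immobile,
    replicate = imm$replicate, units = design$units)

  list(endpoints = endpoints, normalized = normalized, stats = stats,
       immobilization = immobilization)
}

#' Write a simulated dataset to disk
#'
#' Materializes a synthetic assay as files: per chamber x timepoint a
#' directory of PNG frames (when rendered) plus a ground-truth CSV
#' (`animal_id`, `frame`, `t_s`, `x_mm`, `y_mm`, `phase`), one
#' immobilization CSV, and a JSON run manifest holding the config snapshot,
#' the seed and MD5 checksums of every written file, so a rerun with the
#' same manifest can be verified bit for bit.
#'
#' @param dataset an `assay_dataset` from [generate_assay()].
#' @param out_dir output directory (created if missing).
#' @return path of the manifest file, invisibly.
#' @export
simulate_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "assay_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (rec in dataset$chambers) {
    tag <- sprintf("%s_t%03dh", rec$chamber_id, round(rec$time_h))
    truth_df <- do.call(rbind, lapply(rec$truths, function(tr) {
      cbind(animal_id = tr$animal_id, tr$positions)
    }))
    truth_path <- file.path(out_dir, paste0(tag, "_truth.csv"))
    write.csv(truth_df, truth_path, row.names = FALSE)
    files <- c(files, truth_path)
    if (!is.null(rec$clip)) {
      fdir <- file.path(out_dir, paste0(tag, "_frames"))
      dir.create(fdir, showWarnings = FALSE)
      nf <- dim(rec$clip$frames)[3]
      for (f in seq_len(nf)) {
        fp <- file.path(fdir, sprintf("frame_%04d.png", f - 1L))
        png::writePNG(rec$clip$frames[, , f], fp)
        files <- c(files, fp)
      }
    }
  }
  imm_path <- file.path(out_dir, "immobilization.csv")
  write.csv(dataset$index, imm_path, row.names = FALSE)
  files <- c(files, imm_path)

  manifest <- list(
    package = "daphniachip",
    version = as.character(utils::packageVersion("daphniachip")),
    seed = dataset$seed,
    design = unclass(dataset$design),
    chamber = unclass(dataset$chamber_spec)[c("length_mm", "width_mm",
                                              "depth_mm", "mm_per_px")],
    files = lapply(files, function(f) {
      list(path = basename_rel(f, out_dir),
           md5 = unname(tools::md5sum(f)))
    })
  )
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(man_path)
}

basename_rel <- function(path, root) {
  sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", root), "/?"), "",
      path)
}

#' Analyze a dataset directory from disk
#'
#' Reads a directory written by [simulate_dataset()] and runs the analysis:
#' the video path on the PNG frame stacks when present, otherwise the
#' truth-bypass on the ground-truth CSVs.
#'
#' @param dir dataset directory containing `manifest.json`.
#' @param mode `"auto"` (video when frames exist), `"video"` or `"truth"`.
#' @param tracking a [tracking_config()].
#' @param jitter_floor_mm see [track_metrics()].
#' @param out_dir optional directory for result CSVs (`endpoints.csv`,
#'   `normalized.csv`).
#' @return as [analyze_assay()].
#' @export
analyze_dataset <- function(dir, mode = c("auto", "video", "truth"),
                            tracking = tracking_config(),
                            jitter_floor_mm = 0.08, out_dir = NULL) {
  mode <- match.arg(mode)
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) {
    stop("no manifest.json in ", dir, call. = FALSE)
  }
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  design <- do.call(assay_design, man$design[c("concentrations", "replicates",
                                               "animals_per_chamber",
                                               "sampling_times_h", "units",
                                               "duration_s", "fps", "name")])
  if (is.null(man$chamber$mm_per_px)) {
    stop("manifest lacks calibration (mm_per_px)", call. = FALSE)
  }
  chamber <- chamber_spec(man$chamber$length_mm, man$chamber$width_mm,
                          man$chamber$depth_mm, man$chamber$mm_per_px)
  imaging <- imaging_config(mm_per_px = chamber$mm_per_px, fps = design$fps)

  truth_files <- list.files(dir, pattern = "_truth\\.csv$", full.names = TRUE)
  ep <- list()
  for (tf in truth_files) {
    tag <- sub("_truth\\.csv$", "", basename(tf))
    fdir <- file.path(dir, paste0(tag, "_frames"))
    use_video <- mode == "video" || (mode == "auto" && dir.exists(fdir))
    if (use_video && !dir.exists(fdir)) {
      stop("no frames for ", tag, "; rerun with mode = \"truth\"", call. = FALSE)
    }
    tracks <- if (use_video) {
      fps_files <- sort(list.files(fdir, pattern = "\\.png$", full.names = TRUE))
      stack <- array(
        unlist(lapply(fps_files, function(p) png::readPNG(p))),
        dim = c(chamber$ny, chamber$nx, length(fps_files)))
      link_tracks(detect_clip(stack, imaging), tracking, imaging)
    } else {
      truth_df <- read.csv(tf)
      df_to_tracks(data.frame(track_id = truth_df$animal_id,
                              frame = truth_df$frame, t_s = truth_df$t_s,
                              x_mm = truth_df$x_mm, y_mm = truth_df$y_mm,
                              interpolated = FALSE))
    }
    meta <- parse_chamber_tag(tag)
    gi <- as.integer(meta$group)
    s <- chamber_summary(tracks, imaging, chamber, time_h = meta$time_h,
                         chamber_id = meta$chamber_id,
                         n_animals = design$animals_per_chamber,
                         jitter_floor_mm = jitter_floor_mm)
    s$concentration <- design$concentrations[gi]
    s$replicate <- meta$replicate
    ep[[length(ep) + 1L]] <- s
  }
  endpoints <- do.call(rbind, ep)

  control <- endpoints[endpoints$concentration == 0, , drop = FALSE]
  normalized <- NULL
  for (cc in setdiff(sort(unique(endpoints$concentration)), 0)) {
    nr <- normalize_to_control(endpoints[endpoints$concentration == cc, ],
                               control, concentration = cc)
    normalized <- rbind(normalized, classify_response(nr))
  }
  stats <- if (design$replicates >= 2) behavioural_stats(endpoints) else NULL

  imm <- read.csv(file.path(dir, "immobilization.csv"))
  imm <- unique(imm[, c("chamber_id", "concentration", "replicate",
                        "n_animals", "n_immobile")])
  immobilization <- dose_response_data(imm$concentration, imm$n_animals,
                                       imm$n_immobile,
                                       replicate = imm$replicate,
                                       units = design$units)
  out <- list(endpoints = endpoints, normalized = normalized, stats = stats,
              immobilization = immobilization)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(endpoints, file.path(out_dir, "endpoints.csv"), row.names = FALSE)
    write.csv(normalized, file.path(out_dir, "normalized.csv"), row.names = FALSE)
  }
  out
}

parse_chamber_tag <- function(tag) {
  m <- regmatches(tag, regexec("^g(\\d+)_r(\\d+)_t(\\d+)h$", tag))[[1]]
  if (length(m) != 4) stop("unrecognized chamber tag: ", tag, call. = FALSE)
  list(chamber_id = sprintf("g%s_r%s", m[2], m[3]),
       group = as.integer(m[2]), replicate = as.integer(m[3]),
       time_h = as.numeric(m[4]))
}

#' Paired control/treated behavioral recovery experiment
#'
#' The parameter-recovery harness for behavioral effects: for each seed,
#' simulates one control chamber and one treated chamber whose hop rate is
#' scaled by `multiplier`, measures the per-animal total distance through
#' the chosen lane (full video pipeline or truth bypass), and reports the
#' percentage change of the treated chamber relative to its paired control.
#' A multiplier of 0.4 emulates strong hypoactivity (expected change about
#' -60%); 1.25 emulates hyperactivity (about +25%).
#'
#' @param multiplier activity multiplier on the control hop rate (>= 0).
#' @param n_seeds number of paired replicates.
#' @param mode `"video"` (detect + track) or `"truth"` (ground-truth
#'   trajectories).
#' @param duration_s,fps clip length and frame rate.
#' @param n_animals animals per chamber.
#' @param params control [locomotion_params()].
#' @param chamber a [chamber_spec()].
#' @param noise_sd rendering noise (video mode).
#' @param jitter_floor_mm see [track_metrics()].
#' @param seed master seed.
#' @return data frame with one row per seed: `seed_index`, `control_mm`,
#'   `treated_mm`, `pct_change`.
#' @export
behavior_recovery_experiment <- function(multiplier, n_seeds = 50,
                                         mode = c("truth", "video"),
                                         duration_s = 15, fps = 10,
                                         n_animals = 5,
                                         params = locomotion_params(),
                                         chamber = chamber_spec(),
                                         noise_sd = 0.02,
                                         jitter_floor_mm = 0.08,
                                         seed = 1) {
  mode <- match.arg(mode)
  check_number(multiplier, "multiplier", min = 0)
  treated_params <- params
  treated_params$hop_rate_hz <- params$hop_rate_hz * multiplier
  if (treated_params$hop_rate_hz * treated_params$hop_duration_s >= 1) {
    treated_params$hop_duration_s <- 0.5 / treated_params$hop_rate_hz
  }
  imaging <- imaging_config(mm_per_px = chamber$mm_per_px, fps = fps)

  measure <- function(p, s) {
    truths <- lapply(seq_len(n_animals), function(a) {
      sample_trajectory(p, chamber, duration_s, fps,
                        seed = derive_seed(s, a), animal_id = a)
    })
    tracks <- if (mode == "truth") {
      truth_tracks(truths)
    } else {
      clip <- render_clip(truths, chamber, fps = fps, noise_sd = noise_sd,
                          seed = derive_seed(s, 999L))
      link_tracks(detect_clip(clip, imaging), tracking_config(), imaging)
    }
    if (!length(tracks)) return(NA_real_)
    dists <- vapply(tracks, function(tr) {
      track_metrics(tr, imaging, jitter_floor_mm)$total_distance_mm
    }, 1)
    sum(dists) / n_animals
  }

  rows <- lapply(seq_len(n_seeds), function(i) {
    s_ctrl <- derive_seed(seed, 2L * i)
    s_trt <- derive_seed(seed, 2L * i + 1L)
    ctrl <- measure(params, s_ctrl)
    trt <- measure(treated_params, s_trt)
    data.frame(seed_index = i, control_mm = ctrl, treated_mm = trt,
               pct_change = 100 * (trt - ctrl) / ctrl)
  })
  do.call(rbind, rows)
}

#' Hill EC50 parameter-recovery experiment
#'
#' Monte-Carlo recovery harness for the immobilization assay: for each
#' seed, binomial immobile counts are drawn from the Hill model at the
#' design's concentrations and fitted by binomial maximum likelihood; the
#' distribution of EC50 estimates quantifies the bias and spread the
#' chamber-scale design (e.g. 7 concentrations, 15 animals each) can
#' deliver.
#'
#' @param ec50,hill_slope generative Hill parameters.
#' @param concentrations assay concentrations (>= 4 positive).
#' @param n_per_conc animals per concentration.
#' @param n_seeds Monte-Carlo replicates.
#' @param seed master seed.
#' @return data frame with `seed_index`, `ec50_hat`, `hill_slope_hat`,
#'   `converged`.
#' @export
ec50_recovery_experiment <- function(ec50, hill_slope = 2, concentrations,
                                     n_per_conc = 15, n_seeds = 200,
                                     seed = 1) {
  effect <- toxicant_effect(ec50 = ec50, hill_slope = hill_slope)
  rows <- lapply(seq_len(n_seeds), function(i) {
    counts <- vapply(seq_along(concentrations), function(j) {
      sum(sample_immobilization(effect, concentrations[j], n_per_conc,
                                seed = derive_seed(seed, i * 100L + j)))
    }, 1)
    d <- dose_response_data(concentrations, rep(n_per_conc,
                                                length(concentrations)),
                            counts)
    f <- tryCatch(fit_hill(d), error = function(e) NULL)
    data.frame(
      seed_index = i,
      ec50_hat = if (is.null(f)) NA_real_ else f$ec50,
      hill_slope_hat = if (is.null(f)) NA_real_ else f$hill_slope,
      converged = if (is.null(f)) FALSE else f$converged)
  })
  do.call(rbind, rows)
}
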