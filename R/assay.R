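#' Assay design
#'
#' Layout of one dose-response experiment on the chamber array: the
#' concentration groups (which must include a concentration-0 control,
#' required later for normalization), replicate chambers per group, animals
#' per chamber, and the sampling schedule. The default layout mirrors the
#' chip: eight groups of three chambers = 24 chamber streams, five animals
#' each, 30 s clips at 30 fps.
#'
#' @param concentrations concentration per group; must include 0 (control).
#' @param replicates replicate chambers per group (>= 1).
#' @param animals_per_chamber animals loaded per chamber (>= 1).
#' @param sampling_times_h clip acquisition times in hours.
#' @param units concentration unit label.
#' @param duration_s,fps clip length and frame rate.
#' @param name free-text label.
#' @return object of class `assay_design`.
#' @export
assay_design <- function(concentrations = c(0, 0.01, 0.05, 0.1, 0.25, 0.5, 0.75, 1),
                         replicates = 3, animals_per_chamber = 5,
                         sampling_times_h = c(1, 24, 48), units = "mg/L",
                         duration_s = 30, fps = 30, name = "assay") {
  check_number(concentrations, "concentrations", min = 0,
               len = length(concentrations))
  check_number(replicates, "replicates", min = 1)
  check_number(animals_per_chamber, "animals_per_chamber", min = 1)
  check_number(sampling_times_h, "sampling_times_h", min = 0,
               len = length(sampling_times_h))
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  if (!any(concentrations == 0)) {
    stop("design must include a control group (concentration 0); ",
         "normalization requires concurrent controls", call. = FALSE)
  }
  if (anyDuplicated(concentrations)) {
    stop("'concentrations' must be distinct", call. = FALSE)
  }
  structure(list(
    concentrations = concentrations,
    replicates = as.integer(replicates),
    animals_per_chamber = as.integer(animals_per_chamber),
    sampling_times_h = sampling_times_h,
    units = units,
    duration_s = duration_s,
    fps = fps,
    name = name
  ), class = "assay_design")
}

#' Read an assay design from a YAML config
#'
#' Expected keys: `concentrations`, `replicates`, `animals_per_chamber`,
#' `sampling_times_h`, `units`, `duration_s`, `fps`, `name` (missing keys
#' fall back to the [assay_design()] defaults). Unknown keys are an error,
#' so typos in configs fail loudly.
#'
#' @param path YAML file path.
#' @return an `assay_design`.
#' @export
read_assay_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("concentrations", "replicates", "animals_per_chamber",
             "sampling_times_h", "units", "duration_s", "fps", "name")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ## YAML sequences of mixed int/float parse as lists; flatten numerics
  for (nm in c("concentrations", "sampling_times_h")) {
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- as.numeric(unlist(cfg[[nm]]))
  }
  do.call(assay_design, cfg)
}

#' Generate a synthetic assay dataset
#'
#' For every chamber x timepoint, simulates the ground truth of all animals
#' (with the dose-dependent hop rate from `effect$activity_curve` and
#' immobilization drawn from the Hill model) and optionally renders the
#' video clip. Immobilization outcomes are drawn once per chamber via
#' per-animal latent uniforms, so an animal immobile at one timepoint stays
#' immobile at later ones. Everything is deterministic given `seed`.
#'
#' @param design an [assay_design()].
#' @param effect a [toxicant_effect()].
#' @param params control [locomotion_params()].
#' @param chamber a [chamber_spec()].
#' @param seed explicit integer seed.
#' @param render logical; render video frames (`FALSE` keeps only ground
#'   truth, the fast path for statistics work).
#' @param noise_sd,blur_px rendering settings (see [render_clip()]).
#' @return object of class `assay_dataset`: list with `design`, `chambers`
#'   (one record per chamber x timepoint: `chamber_id`, `concentration`,
#'   `replicate`, `time_h`, `truths`, `immobile`, `clip`) and an `index`
#'   data frame.
#' @export
generate_assay <- function(design, effect, params = locomotion_params(),
                           chamber = chamber_spec(), seed = 1,
                           render = FALSE, noise_sd = 0.02, blur_px = 1) {
  stopifnot(inherits(design, "assay_design"), inherits(effect, "toxicant_effect"))
  seed <- check_seed(seed)
  recs <- list()
  idx <- list()
  counter <- 0L
  for (gi in seq_along(design$concentrations)) {
    conc <- design$concentrations[gi]
    for (ri in seq_len(design$replicates)) {
      chamber_id <- sprintf("g%02d_r%d", gi, ri)
      ## latent immobilization uniforms: one draw per animal per chamber
      counter <- counter + 1L
      u <- with_seed(derive_seed(seed, counter),
                     runif(design$animals_per_chamber))
      p_imm <- hill_probability(conc, effect$ec50, effect$hill_slope)
      immobile <- u < p_imm
      for (tt in design$sampling_times_h) {
        dosed <- apply_dose(params, effect, conc, tt)
        truths <- lapply(seq_len(design$animals_per_chamber), function(a) {
          counter_a <- counter * 1000L + match(tt, design$sampling_times_h) * 20L + a
          sample_trajectory(dosed, chamber, design$duration_s, design$fps,
                            seed = derive_seed(seed, counter_a),
                            immobile = immobile[a], animal_id = a)
        })
        clip <- if (render) {
          render_clip(truths, chamber, fps = design$fps, noise_sd = noise_sd,
                      blur_px = blur_px,
                      seed = derive_seed(seed, counter * 1000L + 999L))
        } else NULL
        recs[[length(recs) + 1L]] <- list(
          chamber_id = chamber_id, concentration = conc, replicate = ri,
          time_h = tt, truths = truths, immobile = immobile, clip = clip)
        idx[[length(idx) + 1L]] <- data.frame(
          chamber_id = chamber_id, concentration = conc, replicate = ri,
          time_h = tt, n_animals = design$animals_per_chamber,
          n_immobile = sum(immobile))
      }
    }
  }
  structure(list(
    design = design,
    chamber_spec = chamber,
    effect = effect,
    params = params,
    seed = seed,
    chambers = recs,
    index = do.call(rbind, idx)
  ), class = "assay_dataset")
}

#' @export
print.assay_dataset <- function(x, ...) {
  cat(sprintf("assay_dataset '%s': %d groups x %d replicates = %d chamber streams, %d timepoints\n",
              x$design$name, length(x$design$concentrations),
              x$design$replicates,
              length(x$design$concentrations) * x$design$replicates,
              length(x$design$sampling_times_h)))
  invisible(x)
}
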