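#' Configuration of the synthetic dynamic PET phantom
#'
#' Defines the study conditions a generated cohort emulates: an 80-min,
#' 34-frame acquisition; a ramped tri-exponential plasma input; tumor and
#' contralateral-brain tissue curves from nested compartment kinetics with
#' rate magnitudes anchored to the in-vivo group means (tumor 2TCM with
#' k1 ~ 0.41 +/- 0.18 mL/min, k2 ~ 2.29 +/- 0.80 /min, k3 ~ 0.13 /min,
#' contralateral low-binding 2TCM with k1 ~ 0.25, k3 ~ 0.04); count-like
#' frame-duration-dependent Gaussian noise; and bioluminescence
#' trajectories with a 5/22 responder rate in the treated arm and 0/9 in
#' controls.
#'
#' @param n_per_arm named integer vector of cohort sizes, default
#'   `c(treated = 22, control = 9)`.
#' @param n_responders named integer vector of responder counts per arm,
#'   default `c(treated = 5, control = 0)`.
#' @param model_order ground-truth tissue model order (default 2).
#' @param kinetics_tumor,kinetics_contra lists with `mean` and `sd` length-6
#'   rate vectors for the tissue parameter draws (truncated at the bounds).
#' @param aif an `aif_params` used for every subject (the study conditions
#'   fix one input-function shape; per-subject dose/weight vary).
#' @param framing framing blocks for [build_schedule()].
#' @param noise_c noise coefficient `c` of the per-frame standard deviation
#'   `sigma_i = c * sqrt(max(C_i, eps) / dt_i)` (dt in minutes). `NULL`
#'   (default) calibrates `c` per subject so the noise-free tumor curve has
#'   endpoint signal-to-noise `target_snr`.
#' @param target_snr endpoint SNR used when `noise_c` is `NULL`
#'   (default 10).
#' @param dose_bq_mean,dose_bq_sd injected dose distribution, Bq (default
#'   3.7 MBq +/- 0.37 MBq, i.e. 100 +/- 10 uCi).
#' @param weight_g_mean,weight_g_sd subject weight distribution, grams.
#' @param k1_uplift named vector: multiplicative day-4 to day-7 tumor `k1`
#'   change for responders and non-responders.
#' @param seed integer; fully determines every generated curve.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_per_arm = c(treated = 22, control = 9),
                           n_responders = c(treated = 5, control = 0),
                           model_order = 2,
                           kinetics_tumor = list(
                             mean = c(0.41, 2.29, 0.13, 0.02, 0, 0),
                             sd = c(0.18, 0.80, 0.05, 0.008, 0, 0)),
                           kinetics_contra = list(
                             mean = c(0.25, 1.2, 0.05, 0.02, 0, 0),
                             sd = c(0.10, 0.40, 0.015, 0.008, 0, 0)),
                           aif = default_phantom_aif(),
                           framing = default_framing(),
                           noise_c = NULL, target_snr = 10,
                           dose_bq_mean = 3.7e6, dose_bq_sd = 0.37e6,
                           weight_g_mean = 25, weight_g_sd = 2,
                           k1_uplift = c(responder = 2.5,
                                         `non-responder` = 1.15),
                           seed = 1L) {
  if (any(n_responders > n_per_arm[names(n_responders)]))
    stop("more responders than subjects in an arm")
  if (!model_order %in% 1:3) stop("model_order must be 1, 2 or 3")
  structure(list(n_per_arm = n_per_arm, n_responders = n_responders,
                 model_order = as.integer(model_order),
                 kinetics_tumor = kinetics_tumor,
                 kinetics_contra = kinetics_contra,
                 aif = aif, framing = framing,
                 schedule = build_schedule(framing),
                 noise_c = noise_c, target_snr = target_snr,
                 dose_bq_mean = dose_bq_mean, dose_bq_sd = dose_bq_sd,
                 weight_g_mean = weight_g_mean, weight_g_sd = weight_g_sd,
                 k1_uplift = k1_uplift, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Default phantom input-function parameters
#'
#' A ramped tri-exponential plasma curve in SUV units: a fast vascular
#' spike, an intermediate phase and a slow tail, with a 30-s injection
#' delay. Amplitudes are calibrated so the default tumor kinetics yield an
#' endpoint SUV in the 0.1-0.2 range typical of the tracer.
#'
#' @return An `aif_params`.
#' @export
default_phantom_aif <- function() {
  aif_params(t0_s = 30, A = 4.4, B = 0.6, C = 0.24,
             l1 = 2.8, l2 = 0.30, l3 = 0.0125, l4 = 8)
}

# Rate draw truncated to mean +/- 2 sd and clamped inside [lo, up], so a
# tail draw cannot produce a physiologically absurd subject.
draw_rates <- function(mean, sd, lo = 0, up = 5) {
  k <- rnorm(length(mean), mean, sd)
  k <- pmin(pmax(k, mean - 2 * sd), mean + 2 * sd)
  pmin(pmax(k, lo + ifelse(mean > 0, 1e-3, 0)), up)
}

#' Noise coefficient giving a target endpoint signal-to-noise ratio
#'
#' For the adopted noise model `sigma_i = c * sqrt(C_i / dt_i)`, the
#' endpoint SNR is `C_end / sigma_end`, so
#' `c = sqrt(C_end * dt_end) / snr`.
#'
#' @param noise_free_tac the noiseless tissue `tac`.
#' @param snr target endpoint signal-to-noise ratio.
#' @return the noise coefficient `c`.
#' @export
noise_coef_for_snr <- function(noise_free_tac, snr) {
  nf <- length(noise_free_tac$values)
  c_end <- noise_free_tac$values[nf]
  dt_end <- noise_free_tac$schedule$duration_s[nf] / 60
  sqrt(max(c_end, 1e-12) * dt_end) / snr
}

# Count-statistics-like frame noise, clipped at zero.
add_frame_noise <- function(values, duration_s, noise_c, eps = 1e-6) {
  if (noise_c == 0) return(values)
  sigma <- noise_c * sqrt(pmax(values, eps) / (duration_s / 60))
  pmax(values + rnorm(length(values), 0, sigma), 0)
}

#' Generate one phantom subject
#'
#' Draws ground-truth tumor and contralateral kinetics for the arm, builds
#' the noise-free forward curves for imaging sessions at days 4 and 7
#' (responder uplift applied to the day-7 tumor `k1`), adds
#' frame-duration-dependent Gaussian noise, and simulates dose, weight and
#' a bioluminescence trajectory consistent with the subject's response
#' label. All randomness comes from `seed`.
#'
#' @param config a `phantom_config`.
#' @param arm arm label present in `config$n_per_arm`.
#' @param response `"responder"` or `"non-responder"`.
#' @param seed integer seed for this subject.
#' @param id subject identifier.
#' @return A `phantom_subject` list with elements `id`, `arm`, `response`,
#'   `dose_bq`, `weight_g`, `truth` (per-session `kinetic_params`),
#'   `aif` (`aif_params`), `aif_tac`, `sessions` (per day: `tumor`,
#'   `contra`, `tumor_noise_free`, `contra_noise_free` `tac`s in SUV
#'   units), `noise_c`, `bli` (days, flux), `seed`.
#' @export
generate_subject <- function(config, arm, response = "non-responder",
                             seed = config$seed, id = "s1") {
  stopifnot(inherits(config, "phantom_config"))
  if (!arm %in% names(config$n_per_arm))
    stop("unknown arm label: ", arm)
  if (!response %in% c("responder", "non-responder"))
    stop("unknown response label: ", response)
  with_seed(seed, generate_subject_impl(config, arm, response, seed, id))
}

generate_subject_impl <- function(config, arm, response, seed, id) {
  schedule <- config$schedule
  ord <- config$model_order

  kt <- draw_rates(config$kinetics_tumor$mean, config$kinetics_tumor$sd)
  kc <- draw_rates(config$kinetics_contra$mean, config$kinetics_contra$sd)
  zero_from <- if (ord == 1) 3 else if (ord == 2) 5 else 7
  if (zero_from <= 6) {
    kt[zero_from:6] <- 0
    kc[zero_from:6] <- 0
  }
  uplift <- unname(config$k1_uplift[response])
  truth <- list(
    day4 = list(
      tumor = kinetic_params(ord, kt[1], kt[2], kt[3], kt[4], kt[5], kt[6]),
      contra = kinetic_params(ord, kc[1], kc[2], kc[3], kc[4], kc[5],
                              kc[6])),
    day7 = list(
      tumor = kinetic_params(ord, min(kt[1] * uplift, 5), kt[2], kt[3],
                             kt[4], kt[5], kt[6]),
      contra = kinetic_params(ord, kc[1], kc[2], kc[3], kc[4], kc[5],
                              kc[6])))

  dose <- max(rnorm(1, config$dose_bq_mean, config$dose_bq_sd),
              0.1 * config$dose_bq_mean)
  weight <- max(rnorm(1, config$weight_g_mean, config$weight_g_sd), 10)

  aif_tac <- generate_aif(config$aif, schedule)
  sessions <- lapply(truth, function(tr) {
    out <- list()
    for (roi in c("tumor", "contra")) {
      nf <- forward_model(tr[[roi]], config$aif, schedule)
      nf$roi <- roi
      nf$unit <- "SUV"
      noise_c <- if (is.null(config$noise_c))
        noise_coef_for_snr(nf, config$target_snr) else config$noise_c
      noisy <- nf
      noisy$values <- add_frame_noise(nf$values, schedule$duration_s,
                                      noise_c)
      out[[roi]] <- noisy
      out[[paste0(roi, "_noise_free")]] <- nf
      out[[paste0(roi, "_noise_c")]] <- noise_c
    }
    out
  })

  bli <- generate_bli_series(response, seed = NULL)  # continue subject RNG
  structure(list(id = id, arm = arm, response = response,
                 dose_bq = dose, weight_g = weight,
                 truth = truth, aif = config$aif, aif_tac = aif_tac,
                 sessions = sessions,
                 noise_c = sessions$day4$tumor_noise_c,
                 bli = bli, seed = seed),
            class = "phantom_subject")
}

#' Generate a bioluminescence trajectory for a response label
#'
#' Log-flux random walk sampled every 3 days from day 0 to day 30:
#' responders drift downward (and are guaranteed below a +20% day-30
#' increase), non-responders grow exponentially (guaranteed above it).
#'
#' @param response `"responder"` or `"non-responder"`.
#' @param seed integer seed, or `NULL` to draw from the current RNG state.
#' @param baseline_flux day-0 total flux, photons/s.
#' @param noise_sd per-step log-flux noise (0 gives a monotone responder
#'   series).
#' @return list with `days` and `flux`.
#' @export
generate_bli_series <- function(response, seed = 1L,
                                baseline_flux = 1e7, noise_sd = 0.1) {
  if (!response %in% c("responder", "non-responder"))
    stop("unknown response label: ", response)
  with_seed(seed, {
    days <- seq(0, 30, by = 3)
    drift <- if (response == "responder") -0.08 else 0.10  # /day, log scale
    steps <- drift * diff(days) + rnorm(length(days) - 1, 0, noise_sd)
    flux <- baseline_flux * exp(c(0, cumsum(steps)))
    n30 <- length(days)
    if (response == "responder" && flux[n30] >= 1.2 * baseline_flux)
      flux[-1] <- flux[-1] * (1.15 * baseline_flux / flux[n30])
    if (response == "non-responder" && flux[n30] < 1.2 * baseline_flux)
      flux[-1] <- flux[-1] * (1.5 * baseline_flux / flux[n30])
    list(days = days, flux = flux)
  })
}

#' Generate a full phantom cohort
#'
#' Subjects are generated arm by arm with per-subject seeds derived
#' deterministically from the configuration seed, responder labels
#' assigned to the first `n_responders` subjects of each arm (the draw
#' order is itself seeded, so reruns are bit-identical).
#'
#' @param config a `phantom_config`.
#' @return list of `phantom_subject`s.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  subjects <- list()
  idx <- 0L
  for (arm in names(config$n_per_arm)) {
    n <- config$n_per_arm[[arm]]
    nr <- if (arm %in% names(config$n_responders))
      config$n_responders[[arm]] else 0L
    for (i in seq_len(n)) {
      idx <- idx + 1L
      resp <- if (i <= nr) "responder" else "non-responder"
      subjects[[idx]] <- generate_subject(
        config, arm, resp, seed = config$seed + 1000L * idx,
        id = sprintf("%s_%02d", arm, i))
    }
  }
  subjects
}

#' Write a phantom cohort to disk
#'
#' Per subject: a TAC CSV (`frame_start_s`, `frame_duration_s`, `roi`,
#' `concentration_Bq_per_mL`; SUV-scale curves are converted with the
#' subject's dose and weight) per session, and a metadata JSON with dose,
#' weight, seed, response label and ground-truth rates.
#'
#' @param cohort list of `phantom_subject`s.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort) {
    factor <- s$dose_bq / s$weight_g  # SUV -> Bq/mL
    for (day in names(s$sessions)) {
      ses <- s$sessions[[day]]
      curves <- list(s$aif_tac)
      curves[[1]]$values <- curves[[1]]$values * factor
      for (roi in c("tumor", "contra")) {
        tc <- ses[[roi]]
        tc$values <- tc$values * factor
        tc$unit <- "Bq_mL"
        curves <- c(curves, list(tc))
      }
      write_tac_csv(curves, file.path(dir, sprintf("%s_%s_tac.csv",
                                                   s$id, day)))
    }
    meta <- list(id = s$id, arm = s$arm, response = s$response,
                 dose_Bq = s$dose_bq, weight_g = s$weight_g,
                 seed = s$seed,
                 ground_truth = lapply(s$truth, function(tr)
                   lapply(tr, function(p) as.list(p$k))),
                 bli = s$bli)
    jsonlite::write_json(meta, file.path(dir, paste0(s$id, "_meta.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Build a voxelized 4D image for a phantom subject
#'
#' Optional voxel-level fixture: a spherical tumor and a contralateral
#' sphere inside an ellipsoidal brain, each voxel carrying its ROI's
#' session curve (day 4), background zero. Returns the 4D image and an
#' integer label mask (1 = tumor, 2 = contralateral).
#'
#' @param subject a `phantom_subject`.
#' @param dims 3D grid size (default `c(16, 16, 8)`).
#' @param day session name (default `"day4"`).
#' @return list with `image` (4D array) and `mask` (3D integer array).
#' @export
generate_voxel_image <- function(subject, dims = c(16, 16, 8),
                                 day = "day4") {
  ses <- subject$sessions[[day]]
  nf <- length(ses$tumor$values)
  mask <- array(0L, dims)
  cen <- dims / 2
  r_t <- min(dims) / 5
  ax <- dims * 0.45
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      inside <- sum(((c(i, j, k) - cen) / ax)^2) <= 1
      if (!inside) next
      if (sqrt(sum((c(i, j, k) - cen * c(1.5, 1, 1))^2)) <= r_t)
        mask[i, j, k] <- 1L
      else if (sqrt(sum((c(i, j, k) - cen * c(0.5, 1, 1))^2)) <= r_t)
        mask[i, j, k] <- 2L
    }
  img <- array(0, c(dims, nf))
  for (f in seq_len(nf)) {
    sl <- array(0, dims)
    sl[mask == 1L] <- ses$tumor$values[f]
    sl[mask == 2L] <- ses$contra$values[f]
    img[, , , f] <- sl
  }
  list(image = img, mask = mask)
}
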