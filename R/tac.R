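#' Time-activity curve container
#'
#' A per-frame activity series for one ROI, carrying its frame schedule,
#' unit flag (`"Bq_mL"` or `"SUV"`), and decay-correction state so that
#' mixed-unit arithmetic can be refused downstream.
#'
#' @param schedule a `frame_schedule`.
#' @param values numeric vector, one value per frame.
#' @param roi ROI label, e.g. `"tumor"`, `"contralateral"`, `"heart"`.
#' @param unit `"Bq_mL"` or `"SUV"`.
#' @param decay_corrected logical; has the curve been decay-corrected?
#' @param reference_time_s decay-correction reference time (seconds from
#'   scan start), `NA` when uncorrected.
#' @return A `tac` object.
#' @export
tac <- function(schedule, values, roi = "roi", unit = c("Bq_mL", "SUV"),
                decay_corrected = FALSE, reference_time_s = NA_real_) {
  unit <- match.arg(unit)
  stopifnot(inherits(schedule, "frame_schedule"))
  values <- as.numeric(values)
  if (length(values) != attr(schedule, "n_frames"))
    stop("length of values (", length(values),
         ") does not match frame count (", attr(schedule, "n_frames"), ")")
  structure(list(schedule = schedule, values = values, roi = roi,
                 unit = unit, decay_corrected = isTRUE(decay_corrected),
                 reference_time_s = reference_time_s),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> roi=%s unit=%s decay_corrected=%s, %d frames\n",
              x$roi, x$unit, x$decay_corrected, length(x$values)))
  invisible(x)
}

#' Half-life of copper-64 in seconds (12.7006 h)
#' @export
CU64_HALF_LIFE_S <- 12.7006 * 3600

#' Decay-correct a time-activity curve
#'
#' Scales each frame value by `2^((t_mid - reference) / half_life)`,
#' referring the measured activity back to `reference_time_s` (typically
#' injection). Correcting an already-corrected curve is an error.
#'
#' @param x a `tac` in raw (uncorrected) activity units.
#' @param half_life_s isotope half-life in seconds; defaults to copper-64.
#' @param reference_time_s reference time in seconds from scan start.
#' @return The corrected `tac` with its decay flag set.
#' @export
decay_correct <- function(x, half_life_s = CU64_HALF_LIFE_S,
                          reference_time_s = 0) {
  stopifnot(inherits(x, "tac"))
  if (half_life_s <= 0) stop("half_life_s must be positive")
  if (x$decay_corrected) stop("curve is already decay-corrected")
  factor <- 2^((x$schedule$mid_s - reference_time_s) / half_life_s)
  x$values <- x$values * factor
  x$decay_corrected <- TRUE
  x$reference_time_s <- reference_time_s
  x
}

#' Convert a concentration curve to standardized uptake value
#'
#' SUV = concentration (Bq/mL) * weight (g) / injected dose (Bq), under the
#' 1 g = 1 mL tissue-density convention, so the result is dimensionless.
#' The input must already be decay-corrected, matching a dose that is
#' decay-corrected to injection.
#'
#' @param x a decay-corrected `tac` in Bq/mL.
#' @param dose_bq injected dose in Bq (decay-corrected to injection), > 0.
#' @param weight_g subject weight in grams, > 0.
#' @return A `tac` in SUV units.
#' @export
to_suv <- function(x, dose_bq, weight_g) {
  stopifnot(inherits(x, "tac"))
  if (!is.finite(dose_bq) || dose_bq <= 0) stop("dose_bq must be positive")
  if (!is.finite(weight_g) || weight_g <= 0) stop("weight_g must be positive")
  if (x$unit != "Bq_mL") stop("to_suv expects a Bq/mL curve")
  if (!x$decay_corrected) stop("decay-correct the curve before SUV conversion")
  x$values <- x$values * weight_g / dose_bq
  x$unit <- "SUV"
  x
}

#' Extract an ROI time-activity curve from a 4D image
#'
#' Per-frame mean over the voxels selected by a mask. Accepts in-memory
#' arrays or NIfTI file paths (read with RNifti); images are assumed
#' pre-aligned to the mask grid.
#'
#' @param image a 4D array (x, y, z, frame) or path to a 4D NIfTI file.
#' @param mask a 3D array (nonzero = inside) or path to a NIfTI mask; for an
#'   integer label map, supply `label` to pick one ROI.
#' @param schedule a `frame_schedule` whose frame count matches dim 4.
#' @param roi label stored on the returned curve.
#' @param label optional integer; voxels where `mask == label` are used
#'   (default: any nonzero voxel).
#' @param unit unit flag for the returned curve.
#' @return A `tac` of per-frame ROI means.
#' @export
extract_roi_tac <- function(image, mask, schedule, roi = "roi",
                            label = NULL, unit = "Bq_mL") {
  if (is.character(image)) image <- as.array(RNifti::readNifti(image))
  if (is.character(mask)) mask <- as.array(RNifti::readNifti(mask))
  image <- unclass(image); mask <- unclass(mask)
  if (length(dim(image)) != 4L) stop("image must be 4D (x, y, z, frame)")
  if (!identical(dim(image)[1:3], dim(mask)[1:3]))
    stop("image and mask grids differ")
  sel <- if (is.null(label)) mask != 0 else mask == label
  idx <- which(sel)
  if (length(idx) == 0L) stop("mask selects no voxels")
  nf <- dim(image)[4]
  if (nf != attr(schedule, "n_frames"))
    stop("image frame count does not match schedule")
  nvox <- prod(dim(image)[1:3])
  vals <- vapply(seq_len(nf),
                 function(f) mean(image[idx + (f - 1) * nvox]),
                 numeric(1))
  tac(schedule, vals, roi = roi, unit = unit)
}

#' Read / write time-activity curves as CSV
#'
#' Long format with columns `frame_start_s`, `frame_duration_s`, `roi`,
#' `concentration_Bq_per_mL` (or `suv` for SUV-unit curves).
#'
#' @param tacs a `tac` or list of `tac`s sharing one schedule.
#' @param path CSV file path.
#' @return `write_tac_csv` returns `path` invisibly; `read_tac_csv` returns
#'   a named list of `tac`s (one per ROI).
#' @export
write_tac_csv <- function(tacs, path) {
  if (inherits(tacs, "tac")) tacs <- list(tacs)
  rows <- do.call(rbind, lapply(tacs, function(x) {
    data.frame(frame_start_s = x$schedule$start_s,
               frame_duration_s = x$schedule$duration_s,
               roi = x$roi,
               value = x$values,
               unit = x$unit,
               decay_corrected = x$decay_corrected)
  }))
  names(rows)[names(rows) == "value"] <-
    if (all(vapply(tacs, function(x) x$unit, "") == "SUV"))
      "suv" else "concentration_Bq_per_mL"
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @export
read_tac_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  vcol <- intersect(c("concentration_Bq_per_mL", "suv"), names(d))[1]
  if (is.na(vcol)) stop("no value column found in ", path)
  out <- lapply(split(d, d$roi), function(g) {
    sch <- schedule_from_frames(g$frame_start_s, g$frame_duration_s)
    tac(sch, g[[vcol]], roi = g$roi[1],
        unit = if (vcol == "suv") "SUV" else "Bq_mL",
        decay_corrected = if ("decay_corrected" %in% names(g))
          g$decay_corrected[1] else FALSE)
  })
  out[unique(d$roi)]
}
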