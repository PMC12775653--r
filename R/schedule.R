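#' Build a dynamic PET frame schedule
#'
#' Constructs a contiguous frame schedule from a framing specification given
#' as (count, duration) blocks, e.g. the 80-min preclinical acquisition
#' `12 x 10 s, 6 x 30 s, 5 x 60 s, 10 x 300 s, 1 x 1200 s`.
#'
#' @param blocks list of length-2 numeric vectors `c(count, duration_s)`,
#'   or a 2-column matrix with one row per block.
#' @return A `frame_schedule` object: a data frame with columns `start_s`,
#'   `duration_s`, `mid_s` and attributes `n_frames`, `total_s`.
#' @examples
#' sch <- build_schedule(default_framing())
#' attr(sch, "total_s")  # 4800 s = 80 min
#' @export
build_schedule <- function(blocks) {
  if (is.matrix(blocks)) blocks <- split(blocks, row(blocks))
  if (length(blocks) == 0L) stop("framing specification is empty")
  counts <- vapply(blocks, function(b) b[[1]], numeric(1))
  durs <- vapply(blocks, function(b) b[[2]], numeric(1))
  if (any(counts < 1) || any(counts != round(counts)))
    stop("frame counts must be positive integers")
  if (any(durs <= 0)) stop("frame durations must be positive")
  duration_s <- rep(durs, times = counts)
  start_s <- cumsum(c(0, duration_s[-length(duration_s)]))
  sch <- data.frame(start_s = start_s, duration_s = duration_s,
                    mid_s = start_s + duration_s / 2)
  structure(sch, class = c("frame_schedule", "data.frame"),
            n_frames = nrow(sch), total_s = sum(duration_s))
}

#' Default framing specification of the 80-min dynamic acquisition
#'
#' The list-mode rebinning used throughout: 12 x 10 s, 6 x 30 s, 5 x 60 s,
#' 10 x 300 s, 1 x 1200 s (34 frames, 4800 s).
#'
#' @return list of `c(count, duration_s)` blocks for [build_schedule()].
#' @export
default_framing <- function() {
  list(c(12, 10), c(6, 30), c(5, 60), c(10, 300), c(1, 1200))
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.0f s total\n",
              attr(x, "n_frames"), attr(x, "total_s")))
  invisible(x)
}

#' Reconstruct a schedule from explicit frame starts and durations
#'
#' Used when parsing serialized schedules; validates contiguity.
#'
#' @param start_s,duration_s numeric vectors of equal length (seconds).
#' @return A `frame_schedule`.
#' @export
schedule_from_frames <- function(start_s, duration_s) {
  stopifnot(length(start_s) == length(duration_s), length(start_s) > 0)
  if (any(duration_s <= 0)) stop("frame durations must be positive")
  expected <- cumsum(c(start_s[1], duration_s[-length(duration_s)]))
  if (max(abs(start_s - expected)) > 1e-9)
    stop("frames are not contiguous")
  sch <- data.frame(start_s = start_s, duration_s = duration_s,
                    mid_s = start_s + duration_s / 2)
  structure(sch, class = c("frame_schedule", "data.frame"),
            n_frames = nrow(sch), total_s = sum(duration_s))
}

#' Serialize / parse a schedule as YAML
#'
#' @param schedule a `frame_schedule`.
#' @param path file path.
#' @return `write_schedule_yaml` returns `path` invisibly;
#'   `read_schedule_yaml` returns a `frame_schedule`.
#' @export
write_schedule_yaml <- function(schedule, path) {
  yaml::write_yaml(list(start_s = schedule$start_s,
                        duration_s = schedule$duration_s), path)
  invisible(path)
}

#' @rdname write_schedule_yaml
#' @export
read_schedule_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  schedule_from_frames(as.numeric(x$start_s), as.numeric(x$duration_s))
}
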