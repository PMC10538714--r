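#' @include AllClasses.R AllGenerics.R
NULL

#' Build a frame schedule from (count, duration) blocks
#'
#' Expands a compact binning specification such as
#' \code{list(c(12, 10), c(2, 30), c(1, 60), c(1, 360))} — the 16-frame
#' dynamic ammonia schedule, 600 s total — into an ordered
#' [FrameSchedule-class].
#'
#' @param spec list of length-2 numeric vectors \code{c(count, duration_s)},
#'   or a 2-column matrix with columns count, duration.
#' @return A [FrameSchedule-class] with \code{sum(counts)} frames.
#' @examples
#' sched <- makeFrameSchedule(list(c(12, 10), c(2, 30), c(1, 60), c(1, 360)))
#' length(frameDurations(sched))  # 16
#' totalDuration(sched)           # 600
#' @export
makeFrameSchedule <- function(spec) {
  if (is.matrix(spec)) spec <- split(spec, row(spec))
  if (!length(spec)) stop("'spec' must contain at least one block")
  durs <- unlist(lapply(spec, function(b) {
    if (length(b) != 2L) stop("each block must be c(count, duration_s)")
    count <- b[[1L]]; dur <- b[[2L]]
    if (!is.finite(count) || count < 1 || count != round(count))
      stop("block counts must be positive integers")
    if (!is.finite(dur) || dur <= 0)
      stop("frame durations must be positive")
    rep(dur, count)
  }))
  new("FrameSchedule", durations = durs)
}

#' Compress a frame schedule back to (count, duration) blocks
#'
#' Inverse of [makeFrameSchedule()]: runs of equal durations become
#' \code{c(count, duration)} blocks, so the canonical 16-frame schedule
#' round-trips to \code{list(c(12,10), c(2,30), c(1,60), c(1,360))}.
#'
#' @param schedule a [FrameSchedule-class].
#' @return list of \code{c(count, duration_s)} vectors.
#' @export
compressFrameSchedule <- function(schedule) {
  stopifnot(is(schedule, "FrameSchedule"))
  rl <- rle(schedule@durations)
  unname(Map(c, rl$lengths, rl$values))
}

#' The dynamic ammonia PET binning schedule
#'
#' The 16-frame list-mode binning used for dynamic ammonia perfusion
#' acquisitions: 12 x 10 s, 2 x 30 s, 1 x 60 s, 1 x 360 s (600 s total).
#'
#' @return A 16-frame [FrameSchedule-class].
#' @export
nh3FrameSchedule <- function()
  makeFrameSchedule(list(c(12, 10), c(2, 30), c(1, 60), c(1, 360)))

#' Bin list-mode events into a frame-rate curve
#'
#' Counts list-mode event timestamps into the frames of a schedule and
#' converts to rates (counts per second per frame). Event times at a frame
#' boundary belong to the later frame; events beyond the schedule's total
#' duration are ignored. Frame timestamps are midpoints by default.
#'
#' @param eventTimes numeric vector of event times in seconds, all >= 0.
#' @param schedule a [FrameSchedule-class].
#' @param timestamp \code{"mid"} (default) or \code{"start"}: where each
#'   frame's time coordinate is placed.
#' @return A frame-binned [TimeCurve-class] whose values are event rates
#'   (1/s); \code{sum(rate * duration)} equals the number of binned events.
#' @examples
#' binListMode(c(1, 2, 3), makeFrameSchedule(list(c(1, 10))))  # rate 0.3/s
#' @export
binListMode <- function(eventTimes, schedule, timestamp = c("mid", "start")) {
  stopifnot(is(schedule, "FrameSchedule"))
  timestamp <- match.arg(timestamp)
  if (any(eventTimes < 0)) stop("event times must be >= 0")
  edges <- c(0, frameEnds(schedule))
  counts <- if (length(eventTimes)) {
    # right-open frames [start, end); clamp nothing — beyond-schedule dropped
    idx <- findInterval(eventTimes, edges, rightmost.closed = FALSE)
    tabulate(idx[idx >= 1L & idx <= length(schedule@durations)],
             nbins = length(schedule@durations))
  } else rep(0L, length(schedule@durations))
  tt <- if (timestamp == "mid") frameMids(schedule) else frameStarts(schedule)
  TimeCurve(times = tt, values = counts / schedule@durations,
            durations = schedule@durations)
}
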