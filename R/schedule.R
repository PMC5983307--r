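#' Construct a frame schedule
#'
#' @param start,end frame start/end times in seconds from scan start.
#' @param lambda radiotracer decay constant (1/s); defaults to fluorine-18
#'   (half-life 6586 s).
#' @param tInj injection time (s from scan start).
#' @return a [FrameSchedule-class].
#' @examples
#' fs <- frameSchedule(c(0, 30, 60), c(30, 60, 120))
#' frameDurations(fs)
#' @export
frameSchedule <- function(start, end, lambda = log(2) / 6586, tInj = 0) {
  new("FrameSchedule", start = as.numeric(start), end = as.numeric(end),
      lambda = as.numeric(lambda), tInj = as.numeric(tInj))
}

#' The default dynamic FMISO acquisition schedule
#'
#' The frame sequence used throughout the package's simulations:
#' 1 x 30 s, 6 x 5 s, 6 x 20 s, 7 x 60 s, 10 x 120 s, 3 x 300 s, followed by
#' two additional 600 s frames at 2 h and 4 h post-injection.  The tracer is
#' injected 30 s into scanning, and the decay constant is fluorine-18's.
#'
#' @param lateFrames include the two late 600 s frames (default TRUE).
#' @return a [FrameSchedule-class] with 35 frames (33 without late frames).
#' @examples
#' nFrames(defaultFrameSchedule())
#' @export
defaultFrameSchedule <- function(lateFrames = TRUE) {
  durs <- c(30, rep(5, 6), rep(20, 6), rep(60, 7), rep(120, 10), rep(300, 3))
  start <- cumsum(c(0, durs[-length(durs)]))
  end <- cumsum(durs)
  tInj <- 30
  if (lateFrames) {
    late <- tInj + c(7200, 14400)       # 2 h and 4 h post-injection
    start <- c(start, late)
    end <- c(end, late + 600)
  }
  frameSchedule(start, end, lambda = log(2) / 6586, tInj = tInj)
}

## Uniform sampling grid covering the schedule, with every frame boundary
## on the grid (boundaries are integers in all schedules used here).
timeGridFor <- function(sched, dt = 1) {
  tmax <- max(sched@end)
  seq(0, tmax, by = dt)
}
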