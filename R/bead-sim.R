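## Stepping-bead trajectory simulation and CSV I/O.

#' Simulate a tethered-bead trajectory from a stepping motor
#'
#' The motor angle is a continuous-time jump process over `nDwells` equally
#' spaced dwell angles: dwell durations are exponential with mean
#' `meanDwellTime / deenergization`, and every step advances the angle by
#' `+2*pi/nDwells` (strictly unidirectional, as in a switch-deleted strain).
#' The observed angle adds independent elastic-linkage Gaussian noise per
#' sample; the bead position is the point of the projected orbit ellipse at
#' the observed angle plus independent localization noise on x and y.
#' Timestamps are uniform at the sample rate, and the result is reproducible
#' given the spec seed.
#'
#' @param spec a [BeadSimSpec-class].
#' @return A [BeadTrajectory-class]; the `truth` slot carries the spec, the
#'   jump times and the noise-free motor angle per sample.
#' @export
simulateBead <- function(spec) {
  stopifnot(is(spec, "BeadSimSpec"))
  N <- spec@nDwells
  times <- seq(0, spec@duration, by = 1 / spec@sampleRate)
  if (length(times) < 10 * N)
    warning("fewer than 10*N samples: dwell recovery is underpowered")
  meanDwell <- spec@meanDwellTime / spec@deenergization
  withr::with_seed(spec@seed, {
    expected <- spec@duration / meanDwell
    nDraw <- ceiling(expected + 6 * sqrt(expected + 1) + 50)
    jumps <- cumsum(stats::rexp(nDraw, rate = 1 / meanDwell))
    while (jumps[length(jumps)] < spec@duration) {
      jumps <- c(jumps, jumps[length(jumps)] +
                   cumsum(stats::rexp(nDraw, rate = 1 / meanDwell)))
    }
    stepAngle <- 2 * pi / N
    motor <- spec@phase + stepAngle * findInterval(times, jumps)
    obs <- motor + if (spec@linkageSd > 0)
      stats::rnorm(length(times), sd = spec@linkageSd) else 0
    e <- spec@ellipse
    px <- e[["a"]] * cos(obs)
    py <- e[["b"]] * sin(obs)
    ct <- cos(e[["theta"]]); st <- sin(e[["theta"]])
    x <- e[["cx"]] + px * ct - py * st
    y <- e[["cy"]] + px * st + py * ct
    if (spec@localizationSd > 0) {
      x <- x + stats::rnorm(length(times), sd = spec@localizationSd)
      y <- y + stats::rnorm(length(times), sd = spec@localizationSd)
    }
    BeadTrajectory(times, x, y,
                   condition = sprintf("deenergization=%g", spec@deenergization),
                   truth = list(spec = spec, jumpTimes = jumps,
                                motorAngle = motor))
  })
}

#' Write a bead trajectory to CSV
#'
#' Writes `time_s,x,y`; if the trajectory carries a simulation spec and
#' `specPath` is given, the spec is serialized alongside as a structured text
#' (YAML) config.
#'
#' @param traj a [BeadTrajectory-class].
#' @param path output CSV path.
#' @param specPath optional path for the serialized generating spec.
#' @return `path`, invisibly.
#' @export
writeBeadTrajectory <- function(traj, path, specPath = NULL) {
  stopifnot(is(traj, "BeadTrajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  if (!is.null(specPath) && !is.null(traj@truth$spec)) {
    s <- traj@truth$spec
    yaml::write_yaml(list(
      nDwells = s@nDwells, meanDwellTime = s@meanDwellTime,
      linkageSd = s@linkageSd, localizationSd = s@localizationSd,
      ellipse = as.list(s@ellipse), sampleRate = s@sampleRate,
      duration = s@duration, deenergization = s@deenergization,
      phase = s@phase, seed = s@seed), specPath)
  }
  invisible(path)
}

#' Read a bead trajectory from CSV
#'
#' Expects the `time_s,x,y` layout written by [writeBeadTrajectory()].
#'
#' @param path CSV path.
#' @param condition condition label to attach.
#' @return A [BeadTrajectory-class].
#' @export
readBeadTrajectory <- function(path, condition = "unlabelled") {
  d <- utils::read.csv(path)
  need <- c("time_s", "x", "y")
  if (!all(need %in% names(d)))
    stop("trajectory CSV needs columns: ", paste(need, collapse = ", "))
  BeadTrajectory(d$time_s, d$x, d$y, condition = condition)
}
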