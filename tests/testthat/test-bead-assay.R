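# Dwell-position recovery: ellipse fitting, angle extraction, circular KDE,
# occupancy-weighted spectra, step counting, and phase invariance.

test_that("ellipse fitting is exact on noise-free conics", {
  th <- seq(0, 2 * pi, length.out = 400)[-400]
  # circle
  fc <- fitEllipse(3 + 2 * cos(th), -1 + 2 * sin(th))
  expect_equal(unname(fc$center), c(3, -1), tolerance = 1e-9)
  expect_equal(unname(fc$axes), c(2, 2), tolerance = 1e-9)
  expect_lt(fc$rmsResidual, 1e-9)
  # ellipse with a = 2b, rotated and shifted
  a <- 4; b <- 2; phi <- 0.7
  px <- a * cos(th); py <- b * sin(th)
  x <- 1 + px * cos(phi) - py * sin(phi)
  y <- 2 + px * sin(phi) + py * cos(phi)
  fe <- fitEllipse(x, y)
  expect_equal(fe$axes[["a"]] / fe$axes[["b"]], 2, tolerance = 1e-6)
  expect_equal(unname(fe$center), c(1, 2), tolerance = 1e-8)
  expect_equal(fe$orientation, phi, tolerance = 1e-8)
})

test_that("ellipse fitting tolerates localization noise and rejects collinear data", {
  set.seed(14)
  th <- runif(600, 0, 2 * pi)
  r0 <- 2
  x <- r0 * cos(th) + rnorm(600, sd = 0.05 * r0)
  y <- r0 * sin(th) + rnorm(600, sd = 0.05 * r0)
  f <- fitEllipse(x, y)
  expect_lt(sqrt(sum(f$center^2)), 0.005 * r0)
  expect_error(fitEllipse(1:20, 2 * (1:20) + 3), "collinear")
})

test_that("angle extraction inverts the orbit ellipse before unwrapping", {
  t <- seq(0, 15, by = 0.01)
  omega <- 2 * pi * 0.8
  a <- 2; b <- 1; phi <- 0.3
  px <- a * cos(omega * t); py <- b * sin(omega * t)
  traj <- BeadTrajectory(t, 1 + px * cos(phi) - py * sin(phi),
                         2 + px * sin(phi) + py * cos(phi))
  # corrected: angular speed constant
  tr <- toAngularTrace(traj)
  expect_lt(diff(range(diff(tr@angle))), 1e-6)
  expect_equal(mean(diff(tr@angle)) / 0.01, omega, tolerance = 1e-6)
  expect_equal(revolutions(tr), 12, tolerance = 1e-6)
  # uncorrected: speed oscillates twice per revolution
  tu <- toAngularTrace(traj, correct = FALSE)
  sp <- diff(tu@angle)
  expect_gt(diff(range(sp)), 0.3 * mean(sp))
  osc <- Mod(fft(sp - mean(sp)))
  expect_equal(which.max(osc[2:500]) + 1L, 25L)  # 2 cycles/rev x 12 revs + 1
  # reverse rotation: negative revolutions
  trr <- suppressWarnings(toAngularTrace(
    BeadTrajectory(t, cos(-omega * t / 2), sin(-omega * t / 2))))
  expect_lt(revolutions(trr), 0)
})

test_that("few-revolution traces and centre samples are flagged", {
  t <- seq(0, 1, by = 0.01)
  traj <- BeadTrajectory(t, cos(2 * pi * t), sin(2 * pi * t))
  expect_warning(toAngularTrace(traj), "revolutions")
})

test_that("circular KDE is a normalized nonnegative density peaking at the data", {
  d <- circularKde(rep(1.3, 50), kappa = 200)
  expect_equal(d@theta[which.max(d@density)], 1.3, tolerance = 2 * pi / 2048)
  # circular mean of the density equals the repeated angle
  mu <- Arg(sum(d@density * exp(1i * d@theta)))
  expect_equal(mu, 1.3, tolerance = 1e-6)
  expect_true(all(d@density >= 0))
  expect_equal(sum(d@density) * 2 * pi / length(d@theta), 1, tolerance = 1e-9)
  expect_error(circularKde(1:5, kappa = -1), "kappa")
})

test_that("circular KDE of uniform angles converges to 1/(2*pi) at the root-n rate", {
  set.seed(101)
  errFor <- function(n) {
    d <- circularKde(runif(n, 0, 2 * pi))
    max(abs(d@density - 1 / (2 * pi))) * 2 * pi
  }
  e2e4 <- errFor(20000)
  expect_lt(e2e4, 0.3)
  expect_gt(errFor(2000) / e2e4, 1.5)        # ~sqrt(10) expected
})

test_that("KDE of a 26-dwell simulation shows 26 equally spaced maxima", {
  # noise-free: dwell angles on an exact grid, peaks to within one grid step
  d0 <- circularKde(toAngularTrace(simulateBead(
    BeadSimSpec(linkageSd = 0, localizationSd = 0, seed = 5L))))
  pk0 <- densityPeaks(d0)
  expect_length(pk0, 26)
  gaps0 <- diff(c(d0@theta[pk0], d0@theta[pk0[1]] + 2 * pi))
  expect_lt(max(abs(gaps0 - 2 * pi / 26)), 2 * pi / length(d0@theta) + 1e-12)
  # default noise, kernel matched to twice the dwell spacing
  d <- circularKde(toAngularTrace(simulateBead(BeadSimSpec(seed = 9L))),
                   kappa = kappaForFwhm(2 * pi / 52))
  pk <- densityPeaks(d)
  expect_length(pk, 26)
  gaps <- diff(c(d@theta[pk], d@theta[pk[1]] + 2 * pi))
  expect_lt(max(abs(gaps - 2 * pi / 26)), 0.05)
})

test_that("step spectra obey Fourier identities and occupancy weighting", {
  # uniform rotation sampled over whole revolutions: flat at numerical zero
  t <- (0:1999) / 200                        # 10 revolutions, 200 samples each
  tr <- new("AngularTrace", time = t, angle = 2 * pi * t,
            revolutions = 10)
  expect_lt(max(harmonicPower(stepSpectrum(tr))), 1e-16)

  # analytic density (1 + cos(26 theta)) / (2*pi): all power at m = 26
  G <- 2048
  th <- 2 * pi * (seq_len(G) - 1) / G
  dd <- new("DwellDensity", theta = th, density = (1 + cos(26 * th)) / (2 * pi),
            kappa = 1)
  sp <- stepSpectrum(dd)
  expect_equal(harmonics(sp)[which.max(harmonicPower(sp))], 26L)
  expect_equal(harmonicPower(sp)[26], 0.25, tolerance = 1e-9)
  expect_lt(max(harmonicPower(sp)[-26]), 1e-18)
})

test_that("trace combination weights by revolutions and duplication changes nothing", {
  trajA <- simulateBead(BeadSimSpec(seed = 6L))                 # ~57 revs
  trajB <- simulateBead(BeadSimSpec(duration = 3, seed = 7L))   # ~5.7 revs
  trA <- toAngularTrace(trajA)
  trB <- suppressWarnings(toAngularTrace(trajB))
  comb <- stepSpectrum(list(trA, trB))
  expect_equal(comb@weights[1] / comb@weights[2],
               revolutions(trA) / revolutions(trB), tolerance = 1e-9)
  expect_equal(harmonics(comb)[which.max(harmonicPower(comb))], 26L)
  dup <- stepSpectrum(list(trA, trA))
  expect_equal(harmonicPower(dup), harmonicPower(stepSpectrum(trA)),
               tolerance = 1e-12)
  # short traces are excluded with a warning
  trShort <- suppressWarnings(toAngularTrace(
    simulateBead(BeadSimSpec(duration = 0.8, seed = 8L))))
  expect_warning(stepSpectrum(list(trA, trShort)), "excluded")
})

test_that("step counting recovers simulated dwell numbers and refuses Brownian rotation", {
  expect_equal(countStepsPipeline(simulateBead(BeadSimSpec(seed = 5L)))$n, 26L)
  r13 <- countStepsPipeline(simulateBead(BeadSimSpec(nDwells = 13L, seed = 5L)))
  expect_equal(r13$n, 13L)
  expect_true(is.na(r13$subharmonicCandidate))
  # pure Brownian rotation (no dwells): no call
  set.seed(3)
  t <- seq(0, 30, by = 1 / 250)
  ang <- cumsum(c(0, rnorm(length(t) - 1, mean = 0.08, sd = 0.15)))
  tr <- new("AngularTrace", time = t, angle = ang,
            revolutions = (ang[length(ang)] - ang[1]) / (2 * pi))
  res <- countSteps(stepSpectrum(tr))
  expect_false(res$called)
  expect_true(is.na(res$n))
})

test_that("step counting validates its window and handles flat spectra", {
  sp <- new("StepSpectrum", harmonics = 1:64, power = rep(0, 64), weights = 1)
  res <- countSteps(sp)
  expect_false(res$called)
  expect_error(countSteps(sp, mMax = 100L), "within the spectrum")
})

test_that("rotating the bead data leaves the dwell spectrum unchanged and shifts phases", {
  spec <- BeadSimSpec(ellipse = c(a = 0.25, b = 0.25, cx = 0.5, cy = -0.3,
                                  theta = 0), seed = 12L)
  traj <- simulateBead(spec)
  phi <- 0.7
  rot <- BeadTrajectory(traj@time,
                        traj@x * cos(phi) - traj@y * sin(phi),
                        traj@x * sin(phi) + traj@y * cos(phi))
  # the corrected pipeline is fully equivariant: spectra agree to rounding
  p1 <- harmonicPower(stepSpectrum(toAngularTrace(traj)))
  p2 <- harmonicPower(stepSpectrum(toAngularTrace(rot)))
  expect_equal(p1, p2, tolerance = 1e-6)
  # with centre-only extraction the dwell phases shift by exactly phi
  d1 <- circularKde(toAngularTrace(traj, correct = FALSE))@density
  d2 <- circularKde(toAngularTrace(rot, correct = FALSE))@density
  cc <- Re(fft(fft(d2) * Conj(fft(d1)), inverse = TRUE))
  lag <- (which.max(cc) - 1) * 2 * pi / length(d1)
  shift <- min(abs(c(lag - phi, lag - phi - 2 * pi)))
  expect_lt(shift, 0.02)
})

test_that("phase invariance verdicts follow the pi/N criterion", {
  G <- 2048
  th <- 2 * pi * (seq_len(G) - 1) / G
  mk <- function(delta) new("DwellDensity", theta = th,
                            density = (1 + cos(26 * (th - delta))) / (2 * pi),
                            kappa = 1)
  same <- phaseInvariance(list(mk(0), mk(0)), n = 26)
  expect_equal(same$maxLag, 0, tolerance = 1e-9)
  expect_true(same$phaseInvariant)
  # rotation by 2*pi/52 = half a dwell spacing: verdict fails
  off <- phaseInvariance(list(mk(0), mk(2 * pi / 52)), n = 26)
  expect_equal(off$maxLag, pi / 26, tolerance = 1e-3)
  expect_false(off$phaseInvariant)
  expect_error(phaseInvariance(list(mk(0)), 26), "2")
})

test_that("de-energized and energized simulations share dwell phases", {
  d1 <- circularKde(toAngularTrace(simulateBead(
    BeadSimSpec(deenergization = 1, seed = 21L))))
  d02 <- circularKde(suppressWarnings(toAngularTrace(simulateBead(
    BeadSimSpec(deenergization = 0.2, seed = 22L)))))
  verdict <- phaseInvariance(list(d1, d02), n = 26)
  expect_true(verdict$phaseInvariant)
})

test_that("the full pipeline recovers N for N = 20..30 in at least 9 of 10 seeds", {
  for (N in 20:30) {
    hits <- 0L
    for (s in 1:10) {
      traj <- simulateBead(BeadSimSpec(nDwells = N, seed = 1000L + 37L * N + s))
      res <- countStepsPipeline(traj)
      if (!is.na(res$n) && res$n == N) hits <- hits + 1L
    }
    expect_gte(hits, 9L)
  }
})
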