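## Dwell-position recovery from bead trajectories: ellipse correction, angle
## extraction, circular KDE, occupancy-weighted power spectra, step counting,
## and phase-invariance across conditions.

#' Fit an ellipse to bead positions
#'
#' Direct algebraic least-squares conic fit constrained to an ellipse
#' (the numerically stable formulation of the classic direct ellipse fit),
#' with input centring/scaling for conditioning. Degenerate (collinear) data
#' are rejected.
#'
#' @param x a [BeadTrajectory-class], or numeric x coordinates.
#' @param y numeric y coordinates when `x` is numeric.
#' @return list with `center` (x, y), `axes` (semi-major a, semi-minor b),
#'   `orientation` (angle of the major axis, radians in (-pi/2, pi/2]),
#'   `rmsResidual` (RMS radial deviation in the unit-circle frame, scaled by
#'   the geometric-mean radius), and the `conic` coefficients
#'   (A, B, C, D, E, F).
#' @export
fitEllipse <- function(x, y = NULL) {
  if (is(x, "BeadTrajectory")) {
    y <- x@y
    x <- x@x
  }
  stopifnot(length(x) == length(y), length(x) >= 6L)
  mx <- mean(x); my <- mean(y)
  s <- mean(sqrt((x - mx)^2 + (y - my)^2))
  if (s == 0) stop("degenerate data: all points coincide")
  u <- (x - mx) / s
  w <- (y - my) / s
  ## collinearity check
  sv <- svd(cbind(u - mean(u), w - mean(w)))$d
  if (sv[2] < 1e-9 * sv[1])
    stop("degenerate (collinear) data: no ellipse fit possible")
  D1 <- cbind(u^2, u * w, w^2)
  D2 <- cbind(u, w, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  e <- eigen(M2)
  V <- Re(e$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  i <- which(cond > 0)
  if (!length(i)) stop("no ellipse solution found (degenerate data?)")
  a1 <- V[, i[1]]
  cf <- c(a1, as.vector(Tm %*% a1))          # A B C D E F, scaled frame
  ## back-transform to the original frame
  A <- cf[1] / s^2; B <- cf[2] / s^2; C <- cf[3] / s^2
  D <- cf[4] / s - (2 * cf[1] * mx + cf[2] * my) / s^2
  E <- cf[5] / s - (cf[2] * mx + 2 * cf[3] * my) / s^2
  F <- cf[6] + (cf[1] * mx^2 + cf[2] * mx * my + cf[3] * my^2) / s^2 -
    (cf[4] * mx + cf[5] * my) / s
  disc <- B^2 - 4 * A * C
  xc <- (2 * C * D - B * E) / disc
  yc <- (2 * A * E - B * D) / disc
  Fc <- A * xc^2 + B * xc * yc + C * yc^2 + D * xc + E * yc + F
  Mq <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eq <- eigen(Mq, symmetric = TRUE)
  semi <- sqrt(-Fc / eq$values)               # eigen returns decreasing values
  major <- which.max(semi)
  vMaj <- eq$vectors[, major]
  orientation <- atan2(vMaj[2], vMaj[1])
  if (orientation <= -pi / 2) orientation <- orientation + pi
  if (orientation > pi / 2) orientation <- orientation - pi
  axes <- c(a = max(semi), b = min(semi))
  ## residual: radial scatter about the unit circle in the ellipse frame
  ct <- cos(orientation); st <- sin(orientation)
  ux <- ((x - xc) * ct + (y - yc) * st) / axes[["a"]]
  uy <- (-(x - xc) * st + (y - yc) * ct) / axes[["b"]]
  rr <- sqrt(ux^2 + uy^2)
  list(center = c(x = xc, y = yc), axes = axes, orientation = orientation,
       rmsResidual = sqrt(mean((rr - 1)^2)) * sqrt(prod(axes)),
       conic = c(A = A, B = B, C = C, D = D, E = E, F = F))
}

## unwrap wrapped angles into a continuous trace
.unwrap <- function(theta) theta[1] + c(0, cumsum(.wrapPi(diff(theta))))

#' Extract the unwrapped rotation angle from a bead trajectory
#'
#' Points are mapped to the unit circle by inverting the orbit ellipse
#' (centre, orientation and axis scaling) before taking the angle, removing
#' the twice-per-revolution speed modulation an elliptical projection
#' imposes; the wrapped angles are then unwrapped. Set `correct = FALSE` to
#' skip the axis/orientation correction (centre subtraction only) for
#' sensitivity analyses.
#'
#' @param traj a [BeadTrajectory-class].
#' @param ellipse ellipse fit as returned by [fitEllipse()]; fitted from the
#'   trajectory when `NULL`.
#' @param correct apply the full ellipse correction (default TRUE).
#' @return An [AngularTrace-class].
#' @export
toAngularTrace <- function(traj, ellipse = NULL, correct = TRUE) {
  stopifnot(is(traj, "BeadTrajectory"))
  if (is.null(ellipse)) ellipse <- fitEllipse(traj)
  dx <- traj@x - ellipse$center[["x"]]
  dy <- traj@y - ellipse$center[["y"]]
  if (correct) {
    ct <- cos(ellipse$orientation); st <- sin(ellipse$orientation)
    ux <- (dx * ct + dy * st) / ellipse$axes[["a"]]
    uy <- (-dx * st + dy * ct) / ellipse$axes[["b"]]
  } else {
    ux <- dx; uy <- dy
  }
  rad <- sqrt(ux^2 + uy^2)
  nCentered <- sum(rad < 1e-12)
  if (nCentered > 0)
    warning(nCentered, " sample(s) at the exact orbit centre: angle undefined there")
  angle <- .unwrap(atan2(uy, ux))
  revs <- (angle[length(angle)] - angle[1]) / (2 * pi)
  if (abs(revs) < 10)
    warning(sprintf("only %.1f revolutions; >= 10 recommended for dwell analysis",
                    abs(revs)))
  new("AngularTrace", time = traj@time, angle = angle, revolutions = revs)
}

#' Von Mises kernel concentration for a target kernel width
#'
#' Returns the concentration kappa whose von Mises kernel has the requested
#' full width at half maximum. The package default resolves dwell structure
#' up to harmonic `mMax = 50` without oversmoothing:
#' `FWHM = (2*pi/mMax)/2`.
#'
#' @param fwhm kernel full width at half maximum, radians.
#' @return kappa (numeric).
#' @export
kappaForFwhm <- function(fwhm) {
  stopifnot(fwhm > 0, fwhm < pi)
  log(2) / (1 - cos(fwhm / 2))
}

#' Circular kernel density of dwell angle
#'
#' Von Mises kernel density over the wrapped angles of a trace, each sample
#' weighted by its time step (occupancy weighting), evaluated on a regular
#' grid over [0, 2*pi) and normalized to integrate to one. Computed with the
#' exponentially scaled Bessel normalization so large kappa stays stable.
#'
#' @param x an [AngularTrace-class] or numeric vector of angles (radians).
#' @param kappa von Mises concentration (> 0); default resolves dwell counts
#'   up to m = 50 (see [kappaForFwhm()]).
#' @param gridN grid size (default 2048).
#' @param weights optional sample weights; default is the per-sample time
#'   step for traces, uniform for raw angles.
#' @return A [DwellDensity-class].
#' @export
circularKde <- function(x, kappa = NULL, gridN = 2048L, weights = NULL) {
  if (is.null(kappa)) kappa <- kappaForFwhm((2 * pi / 50) / 2)
  if (!.isScalarNum(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (is(x, "AngularTrace")) {
    ang <- .wrap2pi(x@angle)
    if (is.null(weights)) {
      dt <- diff(x@time)
      weights <- c(dt[1], dt)               # occupancy per sample
    }
  } else {
    ang <- .wrap2pi(as.numeric(x))
  }
  nS <- length(ang)
  if (is.null(weights)) weights <- rep(1, nS)
  stopifnot(length(weights) == nS, all(weights >= 0))
  weights <- weights / sum(weights)
  grid <- 2 * pi * (seq_len(gridN) - 1) / gridN
  norm <- 2 * pi * besselI(kappa, 0, expon.scaled = TRUE)
  dens <- numeric(gridN)
  chunk <- 4096L
  for (i0 in seq(1L, nS, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, nS)
    K <- exp(kappa * (cos(outer(grid, ang[idx], "-")) - 1)) / norm
    dens <- dens + as.vector(K %*% weights[idx])
  }
  dens <- dens / (sum(dens) * 2 * pi / gridN)   # remove grid quadrature error
  new("DwellDensity", theta = grid, density = dens, kappa = kappa)
}

#' Occupancy-weighted dwell power spectrum
#'
#' For each trace, the Fourier power of its occupancy-weighted angular
#' density at integer harmonics m: `F_m = sum_i w_i exp(-i m theta_i)` with
#' time-step weights normalized per trace. Traces are combined as a weighted
#' mean with weight proportional to their revolution count (slow,
#' de-energized traces carry many samples per dwell but few revolutions, so
#' revolutions — not samples — measure how much independent dwell structure
#' a trace saw). Traces with fewer than 2 revolutions are excluded with a
#' warning; m = 0 is excluded by construction.
#'
#' Also accepts a [DwellDensity-class] (or list of them), whose grid density
#' is transformed directly — useful for analytic inputs.
#'
#' @param traces an [AngularTrace-class], a [DwellDensity-class], or a list
#'   of either (not mixed).
#' @param mMax largest harmonic (default 64).
#' @return A [StepSpectrum-class].
#' @export
stepSpectrum <- function(traces, mMax = 64L) {
  mMax <- as.integer(mMax)
  if (!is.list(traces)) traces <- list(traces)
  stopifnot(length(traces) >= 1L)
  m <- seq_len(mMax)
  if (is(traces[[1]], "DwellDensity")) {
    pows <- lapply(traces, function(d) {
      stopifnot(is(d, "DwellDensity"))
      dtheta <- 2 * pi / length(d@theta)
      Fm <- vapply(m, function(mm)
        sum(d@density * exp(-1i * mm * d@theta)) * dtheta, complex(1))
      Mod(Fm)^2
    })
    wts <- rep(1 / length(traces), length(traces))
  } else {
    keep <- vapply(traces, function(tr) abs(tr@revolutions) >= 2, logical(1))
    if (!all(keep))
      warning(sum(!keep), " trace(s) with < 2 revolutions excluded")
    traces <- traces[keep]
    if (!length(traces)) stop("no trace has >= 2 revolutions")
    pows <- lapply(traces, function(tr) {
      ang <- .wrap2pi(tr@angle)
      dt <- diff(tr@time)
      w <- c(dt[1], dt)
      w <- w / sum(w)
      E <- exp(-1i * outer(m, ang))
      Mod(as.vector(E %*% w))^2
    })
    revs <- vapply(traces, function(tr) abs(tr@revolutions), numeric(1))
    wts <- revs / sum(revs)
  }
  power <- Reduce(`+`, Map(`*`, pows, wts))
  new("StepSpectrum", harmonics = m, power = power, weights = wts)
}

#' Count dwell positions from a step spectrum
#'
#' The called dwell count is the argmax of power over harmonics in
#' `[mMin, mMax]`; confidence is the peak-to-median power ratio over the
#' window, and a flat spectrum yields "no call". Harmonic-alias guard: if the
#' subharmonic n/2 carries more power than n itself (possible only when n/2
#' lies below the search window), it is reported as a candidate in the
#' diagnostics.
#'
#' @param spectrum a [StepSpectrum-class].
#' @param mMin,mMax search window (defaults 10..50, bracketing the LP-ring
#'   periodicities with margin while excluding slow-drift harmonics).
#' @param confidenceThreshold minimum peak/median ratio for a call.
#' @return list with `n` (integer, `NA` if no call), `confidence`, `called`,
#'   `peak`, and `subharmonicCandidate` (integer or `NA`).
#' @export
countSteps <- function(spectrum, mMin = 10L, mMax = 50L,
                       confidenceThreshold = 15) {
  stopifnot(is(spectrum, "StepSpectrum"))
  mMin <- as.integer(mMin); mMax <- as.integer(mMax)
  h <- spectrum@harmonics
  if (mMin < min(h) || mMax > max(h))
    stop("search window must lie within the spectrum harmonics")
  sel <- h >= mMin & h <= mMax
  p <- spectrum@power[sel]
  hm <- h[sel]
  if (all(p == 0))
    return(list(n = NA_integer_, confidence = 0, called = FALSE,
                peak = NA_integer_, subharmonicCandidate = NA_integer_))
  i <- which.max(p)
  med <- stats::median(p)
  confidence <- if (med > 0) p[i] / med else Inf
  called <- confidence >= confidenceThreshold
  n <- hm[i]
  subCand <- NA_integer_
  if (n %% 2L == 0L) {
    half <- n %/% 2L
    if (half >= min(h) && spectrum@power[match(half, h)] > p[i])
      subCand <- half
  }
  list(n = if (called) n else NA_integer_, confidence = confidence,
       called = called, peak = n, subharmonicCandidate = subCand)
}

#' Phase invariance of dwell densities across conditions
#'
#' For each pair of densities, finds the circular lag maximizing the circular
#' cross-correlation (FFT-based, with parabolic sub-grid refinement), reduced
#' modulo the dwell spacing `2*pi/n` into `(-pi/n, pi/n]`. The verdict is
#' "phase-invariant" when every pairwise lag magnitude stays below `pi/n`
#' (strictly, with a half-grid-step guard against discretization), i.e. all
#' conditions share the same dwell phases for the called dwell count.
#'
#' @param densities list of >= 2 [DwellDensity-class] on the same grid.
#' @param n the called dwell count N.
#' @return list with `lags` (matrix of pairwise signed lags, radians),
#'   `maxLag`, and `phaseInvariant` (logical).
#' @export
phaseInvariance <- function(densities, n) {
  stopifnot(is.list(densities), length(densities) >= 2L, n >= 1)
  g <- densities[[1]]@theta
  for (d in densities)
    if (!isTRUE(all.equal(d@theta, g)))
      stop("densities must share the same angle grid")
  nG <- length(g)
  dtheta <- 2 * pi / nG
  nd <- length(densities)
  lags <- matrix(0, nd, nd)
  spacing <- 2 * pi / n
  for (i in seq_len(nd - 1)) for (j in (i + 1):nd) {
    F1 <- stats::fft(densities[[i]]@density)
    F2 <- stats::fft(densities[[j]]@density)
    cc <- Re(stats::fft(F1 * Conj(F2), inverse = TRUE)) / nG
    k <- which.max(cc)                       # 1-based; lag (k-1)*dtheta
    km <- if (k == 1) nG else k - 1
    kp <- if (k == nG) 1 else k + 1
    denom <- cc[km] - 2 * cc[k] + cc[kp]
    delta <- if (denom < 0) 0.5 * (cc[km] - cc[kp]) / denom else 0
    lag <- ((k - 1) + delta) * dtheta
    lag <- .wrapPi(lag)
    ## reduce modulo the dwell spacing into (-spacing/2, spacing/2]
    lag <- lag - spacing * round(lag / spacing)
    lags[i, j] <- lag
    lags[j, i] <- -lag
  }
  maxLag <- max(abs(lags))
  list(lags = lags, maxLag = maxLag,
       phaseInvariant = maxLag < pi / n - dtheta / 2)
}

#' Full bead dwell-count pipeline
#'
#' Convenience wrapper running ellipse fit, angle extraction,
#' occupancy-weighted spectrum and step counting on one or more trajectories.
#'
#' @param trajs a [BeadTrajectory-class] or list of them.
#' @param mMin,mMax step-count search window.
#' @param correct apply the ellipse correction (default TRUE).
#' @return the [countSteps()] result, with the spectrum attached as
#'   `spectrum` and the traces as `traces`.
#' @export
countStepsPipeline <- function(trajs, mMin = 10L, mMax = 50L, correct = TRUE) {
  if (!is.list(trajs)) trajs <- list(trajs)
  traces <- lapply(trajs, function(tr)
    suppressWarnings(toAngularTrace(tr, correct = correct)))
  spec <- stepSpectrum(traces)
  out <- countSteps(spec, mMin = mMin, mMax = mMax)
  out$spectrum <- spec
  out$traces <- traces
  out
}
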