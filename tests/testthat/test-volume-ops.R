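# Cylindrical-coordinate volume operations: resampling, lathing, Cn
# symmetrization, azimuthal spectra, radial profiles, filtering, FSC, MRC I/O.

test_that("cylindrical resampling of a radially symmetric tube is azimuthally flat", {
  v <- smoothTube(radius = 20, boxSize = 48L)
  cyl <- resampleCylindrical(v)
  vals <- cyl@values[5:18, , 16:32]
  spread <- apply(vals, c(1, 3), function(x) diff(range(x)))
  expect_lt(max(spread), 0.05 * max(densityGrid(v)))
})

test_that("an off-axis blob lands at its azimuth in the cylindrical map", {
  theta0 <- 2.1
  m <- PseudoAtomModel(data.frame(x = 30 * cos(theta0), y = 30 * sin(theta0),
                                  z = 0, amplitude = 1, sigma = 4, label = "A"))
  cyl <- resampleCylindrical(rasterize(m, 64L, 2))
  ring <- cyl@values[16, , 33]               # r = 30 Å, z = 0
  expect_lt(abs(cyl@theta[which.max(ring)] - theta0), 2 * pi / 256 + 1e-9)
})

test_that("cylindrical resampling validates theta count and flags out-of-box samples", {
  v <- smoothTube(radius = 20, boxSize = 48L)
  expect_error(resampleCylindrical(v, nTheta = 128L), "power of two")
  expect_error(resampleCylindrical(v, nTheta = 300L), "power of two")
  cyl <- resampleCylindrical(v, rMax = 70)   # beyond the 46 Å in-box radius
  expect_true(anyNA(cyl@values))
  expect_false(anyNA(cyl@values[cyl@r <= 46, , ]))
})

test_that("lathing removes azimuthal features and is idempotent", {
  v <- twoRingPhantom()
  l1 <- latheVolume(v)
  ann <- c(30, 52, 8, 32)
  spRaw <- azimuthalPowerSpectrum(resampleCylindrical(v), ann)
  spLat <- azimuthalPowerSpectrum(resampleCylindrical(l1), ann)
  flat <- function(s) s@totalPower / harmonicPower(s)[1]
  expect_lt(flat(spLat), 1e-3)
  expect_lt(flat(spLat), 0.01 * flat(spRaw))
  # idempotence within the stated interpolation tolerance (this fixture has
  # blob widths near one voxel, the sharpest case the package supports)
  l2 <- latheVolume(l1)
  d <- densityGrid(l2) - densityGrid(l1)
  expect_lt(max(abs(d)) / max(abs(densityGrid(v))), 0.08)
  expect_lt(sqrt(mean(d^2)) / sd(as.vector(densityGrid(v))), 0.08)
})

test_that("lathing equals the large-n limit of Cn symmetrization", {
  spec <- MotorPhantomSpec(list(
    TubeSpec(radius = 20, wallSigma = 4, zCenter = 0, zHalfWidth = 20),
    RingComponent(defaultProtomer(0.8),
                  RingLatticeSpec(9L, radius = 30, zCenter = 0, phase = 0.2))),
    boxSize = 48L, voxelSize = 2, noiseSd = 0)
  v <- makeMotorPhantom(spec)
  d <- densityGrid(latheVolume(v)) - densityGrid(symmetrizeVolume(v, 360L))
  expect_lt(max(abs(d)) / max(abs(densityGrid(v))), 0.06)
  expect_lt(sqrt(mean(d^2)) / sd(as.vector(densityGrid(v))), 0.03)
})

test_that("symmetrization: identity at n = 1, idempotent, faithful on a matching ring", {
  v <- makeMotorPhantom(singleRingPhantomSpec(17L, radius = 60, boxSize = 96L,
                                              protomerSize = 2))
  expect_identical(densityGrid(symmetrizeVolume(v, 1L)), densityGrid(v))
  expect_error(symmetrizeVolume(v, 0L), ">= 1")
  peak <- max(abs(densityGrid(v)))
  s1 <- symmetrizeVolume(v, 17L)
  expect_lt(max(abs(densityGrid(s1) - densityGrid(v))) / peak, 0.05)
  s2 <- symmetrizeVolume(s1, 17L)
  expect_lt(max(abs(densityGrid(s2) - densityGrid(s1))) / peak, 0.05)
})

test_that("symmetrization commutes with lathing", {
  v <- twoRingPhantom()
  a <- latheVolume(symmetrizeVolume(v, 9L))
  b <- symmetrizeVolume(latheVolume(v), 9L)
  expect_lt(sqrt(mean((densityGrid(a) - densityGrid(b))^2)) /
              sd(as.vector(densityGrid(v))), 0.03)
})

test_that("a painted cos(m*theta) pattern puts all azimuthal power at m", {
  nTheta <- 256L
  theta <- 2 * pi * (seq_len(nTheta) - 1) / nTheta
  nR <- 21L
  vals <- array(0, dim = c(nR, nTheta, 5L))
  for (i in 8:15) for (k in 1:5)
    vals[i, , k] <- cos(17 * theta)
  cmap <- new("CylindricalMap", values = vals, r = (seq_len(nR) - 1) * 2,
              theta = theta, z = (1:5) * 2, voxelSize = 2)
  sp <- azimuthalPowerSpectrum(cmap, c(14, 30, 0, 12))
  expect_equal(harmonics(sp)[which.max(harmonicPower(sp)[-1]) + 1L], 17L)
  expect_gt(harmonicPower(sp)[18], 0.999)    # m = 17 carries ~all power
})

test_that("degenerate annuli are rejected", {
  cyl <- resampleCylindrical(smoothTube(radius = 20, boxSize = 48L))
  expect_error(azimuthalPowerSpectrum(cyl, c(100, 120, 0, 10)), "empty")
  cylNA <- resampleCylindrical(smoothTube(radius = 20, boxSize = 48L), rMax = 70)
  expect_error(azimuthalPowerSpectrum(cylNA, c(40, 68, -10, 10)),
               "beyond the sampled region")
})

test_that("symmetry detection recovers every order n = 7..51 noise-free", {
  for (n in 7:51) {
    cyl <- resampleCylindrical(
      makeMotorPhantom(singleRingPhantomSpec(n, radius = 70, boxSize = 96L,
                                             protomerSize = 0.75)))
    det <- detectSymmetry(azimuthalPowerSpectrum(cyl, c(50, 90, -15, 15)),
                          mMin = 2L, mMax = 60L)
    expect_equal(det$n, as.integer(n), info = paste("order", n))
  }
})

test_that("noise-only volumes yield no symmetry call", {
  # annulus radii large enough that the azimuthal sampling is finer than the
  # voxel pitch across the whole search window (r >= mMax*voxel/pi)
  set.seed(12)
  v <- DensityVolume(array(rnorm(96^3), dim = rep(96, 3)), 2)
  det <- detectSymmetry(azimuthalPowerSpectrum(resampleCylindrical(v),
                                               c(40, 90, -20, 20)))
  expect_false(det$called)
  expect_true(is.na(det$n))
  expect_lt(det$confidence, 1.5)
})

test_that("symmetry-call ties break toward the smaller order and windows validate", {
  p <- numeric(129)
  p[c(21, 41) + 1L] <- 0.5                   # equal power at m = 21 and m = 41
  sp <- new("SymmetrySpectrum", harmonics = 0:128, power = abs(p),
            annulus = c(rMin = 0, rMax = 1, zMin = 0, zMax = 1),
            totalPower = 1)
  det <- detectSymmetry(sp, mMin = 10L, mMax = 50L, confidenceThreshold = 1)
  expect_equal(det$n, 21L)
  expect_error(detectSymmetry(sp, mMin = 1L), "mMin")
  expect_error(detectSymmetry(sp, mMax = 200L), "harmonic range")
})

test_that("radial profiles locate tube walls and stay flat on uniform maps", {
  prof <- radialProfile(smoothTube(radius = 40), zRange = c(-16, 16))
  est <- estimateFeatureRadius(prof, c(20, 70))
  expect_true(est$found)
  expect_lt(abs(est$radius - 40), 2)

  u <- DensityVolume(array(3.3, dim = rep(32, 3)), 2)
  pu <- radialProfile(u)
  expect_lt(diff(range(pu$density)), 1e-9)

  nested <- makeMotorPhantom(MotorPhantomSpec(list(
    TubeSpec(radius = 30, wallSigma = 4, zHalfWidth = 24),
    TubeSpec(radius = 60, wallSigma = 4, zHalfWidth = 24)),
    boxSize = 96L, voxelSize = 2, noiseSd = 0))
  pn <- radialProfile(nested, c(-16, 16))
  e1 <- estimateFeatureRadius(pn, c(15, 45))
  e2 <- estimateFeatureRadius(pn, c(45, 80))
  expect_lt(abs(e1$radius - 30), 2)
  expect_lt(abs(e2$radius - 60), 2)

  expect_false(estimateFeatureRadius(pn, c(70, 85))$found)
  expect_error(radialProfile(nested, c(200, 300)), "empty z range")
  expect_error(estimateFeatureRadius(pn, c(0, 1e4)), "inside the profile")
})

test_that("feature radius is invariant under imposed arbitrary symmetry orders", {
  v <- smoothTube(radius = 40)
  base <- estimateFeatureRadius(radialProfile(v, c(-16, 16)), c(20, 70))$radius
  for (n in c(17L, 33L)) {
    rn <- estimateFeatureRadius(
      radialProfile(symmetrizeVolume(v, n), c(-16, 16)), c(20, 70))$radius
    expect_lt(abs(rn - base), 2, label = sprintf("C%d radius shift", n))
  }
})

test_that("low-pass filtering preserves the mean, kills power beyond the cutoff, and keeps peak radii", {
  set.seed(4)
  v <- DensityVolume(array(rnorm(48^3, mean = 1), dim = rep(48, 3)), 2)
  lp <- lowpassVolume(v, 15)
  expect_equal(mean(densityGrid(lp)), mean(densityGrid(v)), tolerance = 1e-9)
  fr <- sqrt(ringstoich:::.freqSq3d(48L, 2))
  beyond <- fr > 1 / 15 + 1 / (48 * 2) / 2
  Pin <- Mod(fft(densityGrid(v)))^2
  Pout <- Mod(fft(densityGrid(lp)))^2
  expect_lt(sum(Pout[beyond]) / sum(Pin[beyond]), 0.01)

  tube <- smoothTube(radius = 40)
  r0 <- estimateFeatureRadius(radialProfile(tube, c(-16, 16)), c(20, 70))$radius
  r15 <- estimateFeatureRadius(radialProfile(lowpassVolume(tube, 15), c(-16, 16)),
                               c(20, 70))$radius
  expect_lt(abs(r15 - r0), 2)

  # fine-resolution limit: near identity on a smooth map
  sm <- rasterize(PseudoAtomModel(data.frame(x = 0, y = 0, z = 5, amplitude = 1,
                                             sigma = 6, label = "A")), 48L, 2)
  idty <- lowpassVolume(sm, 2 * 2 * 1.02)
  expect_lt(sqrt(mean((densityGrid(idty) - densityGrid(sm))^2)) /
              sd(as.vector(densityGrid(sm))), 0.01)
  expect_error(lowpassVolume(sm, 4), "Nyquist")
})

test_that("FSC identities: self-correlation 1, anti-correlation -1, symmetry, scale invariance", {
  v <- twoRingPhantom()
  neg <- DensityVolume(-densityGrid(v), voxelSize(v))
  scl <- DensityVolume(3.7 * densityGrid(v), voxelSize(v))
  self <- fscCurve(v, v)
  expect_true(all(abs(self@correlation - 1) < 1e-9))
  expect_true(all(abs(fscCurve(v, neg)@correlation + 1) < 1e-9))
  set.seed(2)
  noisy <- DensityVolume(densityGrid(v) + rnorm(96^3, sd = 0.2), 2)
  ab <- fscCurve(v, noisy)
  expect_equal(ab@correlation, fscCurve(noisy, v)@correlation, tolerance = 1e-12)
  expect_equal(ab@correlation, fscCurve(scl, noisy)@correlation, tolerance = 1e-9)
  expect_error(fscCurve(v, DensityVolume(array(0, dim = rep(32, 3)), 2)),
               "same grid")
})

test_that("FSC matches a brute-force per-shell oracle and crossings interpolate", {
  set.seed(9)
  n <- 24L
  a <- rasterize(PseudoAtomModel(data.frame(
    x = c(0, 5), y = c(3, -4), z = c(0, 2), amplitude = 1,
    sigma = c(3, 4), label = "A")), n, 2)
  b <- DensityVolume(densityGrid(a) + rnorm(n^3, sd = 0.05), 2)
  b <- lowpassVolume(b, 10)
  curve <- fscCurve(a, b)
  # independent oracle: loop over shells with an explicitly built index grid
  k1 <- ifelse(seq_len(n) - 1 <= n / 2, seq_len(n) - 1, seq_len(n) - 1 - n)
  kr <- array(0, dim = rep(n, 3))
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    kr[i, j, k] <- sqrt(k1[i]^2 + k1[j]^2 + k1[k]^2)
  Fa <- fft(densityGrid(a)); Fb <- fft(densityGrid(b))
  oracle <- sapply(0:(n / 2), function(s) {
    sel <- round(kr) == s
    Re(sum(Fa[sel] * Conj(Fb[sel]))) /
      sqrt(sum(Mod(Fa[sel])^2) * sum(Mod(Fb[sel])^2))
  })
  expect_equal(curve@correlation, oracle, tolerance = 1e-9)
  res <- resolutionAt(curve, 0.5)
  # oracle crossing by direct scan
  i <- which(oracle < 0.5 & c(1, head(oracle, -1)) >= 0.5)[1]
  oracleRes <- 1 / curve@frequency[i]
  expect_lt(abs(1 / res - 1 / oracleRes), curve@shellWidth)
  # identical maps never cross: reported at Nyquist
  rNy <- resolutionAt(fscCurve(a, a), 0.5)
  expect_equal(as.numeric(rNy), 2 * voxelSize(a))
  expect_false(attr(rNy, "crossed"))
})

test_that("MRC mode-2 maps round-trip with voxel size and origin", {
  set.seed(21)
  v <- DensityVolume(array(rnorm(24^3), dim = rep(24, 3)), 1.75)
  path <- tempfile(fileext = ".mrc")
  writeMRC(v, path)
  back <- readMRC(path)
  expect_equal(voxelSize(back), 1.75, tolerance = 1e-6)
  expect_equal(back@origin, v@origin, tolerance = 1e-4)
  expect_equal(densityGrid(back), densityGrid(v), tolerance = 1e-6)
  # header words: mode 2 at byte offset 12, little-endian
  con <- file(path, "rb"); hdr <- readBin(con, "integer", 4, 4,
                                          endian = "little"); close(con)
  expect_equal(hdr, c(24L, 24L, 24L, 2L))
  unlink(path)
})
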