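# Trajectory statistics: groove series, modes, normality, correlations,
# hydrogen bonds, RMSD.

test_that("a static trajectory gives zero-variance series equal to the
           static profile", {
  st <- synthTrajectory("GCATTACGCAT", nFrames = 10, seed = 51)  # sd 0
  gs <- grooveSeries(st$trajectory, burnIn = 0)
  static <- grooveProfile(st$trajectory@topology)
  for (j in seq_along(gs$positions)) {
    col <- gs$minor[, j]
    if (all(is.na(col))) next
    expect_lt(diff(range(col)), 1e-9)
    expect_equal(col[1], static@minor[j], tolerance = 1e-9)
  }
})

test_that("burn-in discards the stated fraction of frames", {
  st <- synthTrajectory("GCATTACGC", nFrames = 100, seed = 52,
                        sd = c(twist = 2))
  gs <- grooveSeries(st$trajectory, burnIn = 0.2)
  expect_equal(nrow(gs$minor), 80)
  expect_equal(gs$frames, 21:100)
})

test_that("series values equal direct per-frame profile computation", {
  st <- synthTrajectory("GCATTACGC", nFrames = 8, seed = 53,
                        sd = c(twist = 3, slide = 0.3))
  gs <- grooveSeries(st$trajectory, burnIn = 0)
  for (f in c(1, 4, 8)) {
    p <- grooveProfile(frameDuplex(st$trajectory, f))
    expect_equal(unname(gs$minor[f, ]), unname(p@minor), tolerance = 1e-12)
  }
})

test_that("summarizeSeries flags constant input and rejects tiny input", {
  s <- summarizeSeries(rep(3.5, 50))
  expect_equal(s@mode, 3.5)
  expect_equal(s@sd, 0)
  expect_equal(s@verdict, "undefined")
  expect_error(summarizeSeries(2), "at least 2")
})

test_that("Gaussian series: mode near the mean, normality not rejected", {
  # 0.05 is of the order of the KDE bandwidth at this n; the statistical
  # coverage of the mode estimator is checked over 100 seeds elsewhere
  set.seed(540)
  x <- rnorm(40000, 5, 0.5)
  s <- summarizeSeries(x)
  expect_lt(abs(s@mode - 5), 0.05)
  expect_equal(s@verdict, "gaussian")
  expect_equal(s@gaussMu, mean(x))
  expect_equal(s@gaussSigma, sd(x))
})

test_that("bimodal mixture: mode at the dominant component, normality
           rejected", {
  set.seed(55)
  x <- c(rnorm(28000, 4.5, 0.3), rnorm(12000, 7.0, 0.3))
  s <- summarizeSeries(x)
  expect_lt(abs(s@mode - 4.5), 0.05)
  expect_equal(s@verdict, "non-gaussian")
})

test_that("mode error decreases with sample size", {
  errs <- sapply(c(1e3, 1e4, 1e5), function(n) {
    set.seed(56)
    median(replicate(30, abs(summarizeSeries(rnorm(n, 5, 0.5))@mode - 5)))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("mostProbableProfile of a jittered trajectory matches the
           static profile", {
  st <- synthTrajectory(F28_SEQ, nFrames = 150, seed = 57,
                        sd = c(twist = 1.5, roll = 1.5, slide = 0.15))
  mp <- mostProbableProfile(st$trajectory, burnIn = 0.2)
  static <- windowStats(grooveProfile(st$trajectory@topology), c(-2, 2))
  expect_lt(abs(mp$window["meanMode"] - static["meanMinor"]), 0.2)
})

test_that("a single-frame trajectory reduces to the static profile", {
  d <- buildMeanDuplex("GCATTACGC")
  tr <- new("DuplexTrajectory", topology = d,
            coords = array(as.matrix(d@atoms[, c("x", "y", "z")]),
                           c(nrow(d@atoms), 3, 1)),
            frameInterval = 1)
  mp <- mostProbableProfile(tr, burnIn = 0)
  static <- grooveProfile(d)
  ok <- !is.na(static@minor)
  expect_equal(mp$profile$mode[ok], unname(static@minor[ok]),
               tolerance = 1e-9)
})

test_that("mixture trajectories recover the dominant state and fail
           normality", {
  cmp <- makeCompressedDuplex(F28_SEQ, 4.4)
  wide <- grooveDNA:::.meanStepsFor(strsplit(F28_SEQ, "")[[1]])
  st <- synthTrajectory(F28_SEQ, nFrames = 200, seed = 58,
                        mixture = list(steps = list(cmp$steps, wide),
                                       weights = c(0.7, 0.3)))
  gs <- grooveSeries(st$trajectory, burnIn = 0)
  center <- gs$minor[, gs$positions == 0]
  s <- summarizeSeries(center)
  expect_lt(abs(s@mode - cmp$achieved), max(s@bandwidth, 0.05))
  expect_equal(s@verdict, "non-gaussian")
  # generator truth: the two distinct step states map to two widths
  expect_equal(sort(unique(round(center, 6))), sort(unique(round(
    c(cmp$achieved, grooveWidthAt(grooveProfile(
      buildDuplex(F28_SEQ, NULL, wide)), 0)), 6))))
})

test_that("pearsonProfiles handles exact, mirrored and invalid input", {
  a <- c(4, 5, 6, 5, 4, 5, 7)
  expect_equal(pearsonProfiles(a, a), 1)
  expect_equal(pearsonProfiles(a, 2 * mean(a) - a), -1)
  expect_equal(pearsonProfiles(a, 3 * a + 2), 1)  # affine invariance
  expect_error(pearsonProfiles(a, rep(1, 7)), "zero variance")
  expect_error(pearsonProfiles(a[1:2], a[1:2]), "fewer than 3")
  expect_true(abs(pearsonProfiles(a, rev(a))) <= 1)
})

test_that("pearsonProfiles aligns data.frame profiles on shared positions", {
  pa <- data.frame(position = -3:3, mode = c(4, 5, 6, 5, 4, 5, 7))
  pb <- data.frame(position = -2:4, mode = c(5, 6, 5, 4, 5, 7, 8))
  r <- pearsonProfiles(pa, pb, range = c(-2, 2))
  direct <- cor(pa$mode[pa$position %in% -2:2],
                pb$mode[pb$position %in% -2:2])
  expect_equal(r, direct)
})

test_that("hydrogen-bond counts follow the pair chemistry", {
  d <- fixtureDuplex("F28-dI")  # contains A:T, I:C, C:I, G:C pairs
  tr <- new("DuplexTrajectory", topology = d,
            coords = array(as.matrix(d@atoms[, c("x", "y", "z")]),
                           c(nrow(d@atoms), 3, 2)),
            frameInterval = 1)
  hb <- hbondSeries(tr)
  types <- pairTypes(d)
  nExpected <- sum(ifelse(types %in% c("G:C", "C:G"), 3, 2))
  expect_equal(ncol(hb), nExpected)
  # static trajectory: constant series
  expect_equal(hb[1, ], hb[2, ])
  # direct coordinate oracle for one bond
  a <- d@atoms
  i <- which(a$strand == 1 & a$pair == 1 & a$atom == "O6")
  j <- which(a$strand == 2 & a$pair == 1 & a$atom == "N4")
  direct <- sqrt(sum((as.numeric(a[i, c("x", "y", "z")]) -
                      as.numeric(a[j, c("x", "y", "z")]))^2))
  expect_equal(unname(hb[1, "pair1.G:C.O6-N4"]), direct,
               tolerance = 1e-12)
  # ideal geometry: all bonds in the hydrogen-bonding range
  expect_true(all(hb > 2.6 & hb < 3.2))
})

test_that("RMSD series is zero for self and rigid motions", {
  set.seed(59)
  d <- buildMeanDuplex("GCATTACGC")
  xyz <- as.matrix(d@atoms[, c("x", "y", "z")])
  R <- randomRotation(); t <- rnorm(3, sd = 8)
  moved <- xyz %*% t(R) + matrix(t, nrow(xyz), 3, byrow = TRUE)
  coords <- array(NA_real_, c(nrow(xyz), 3, 2))
  coords[, , 1] <- xyz; coords[, , 2] <- moved
  tr <- new("DuplexTrajectory", topology = d, coords = coords,
            frameInterval = 1)
  r <- rmsdSeries(tr)
  expect_lt(r[1], 1e-9)
  expect_lt(r[2], 1e-9)
})

test_that("RMSD of known perturbations matches the bio3d oracle", {
  set.seed(60)
  d <- buildMeanDuplex("GCATTACGC")
  xyz <- as.matrix(d@atoms[, c("x", "y", "z")])
  pert <- xyz + matrix(rnorm(length(xyz), sd = 0.5), nrow(xyz))
  coords <- array(pert, c(nrow(xyz), 3, 1))
  tr <- new("DuplexTrajectory", topology = d, coords = coords,
            frameInterval = 1)
  ours <- rmsdSeries(tr)[1]
  oracle <- bio3d::rmsd(as.vector(t(xyz)), as.vector(t(pert)), fit = TRUE)
  expect_lt(abs(ours - oracle), 6e-4)  # bio3d rounds to 3 decimals
  expect_error(rmsdSeries(tr, selection = 1:2), "at least 3")
})

test_that("trajectory statistics are invariant under per-frame rigid
           motion", {
  st <- synthTrajectory("GCATTACGC", nFrames = 6, seed = 61,
                        sd = c(twist = 2))
  tr <- st$trajectory
  moved <- tr
  set.seed(62)
  for (f in seq_len(nFrames(tr))) {
    R <- randomRotation(); t <- rnorm(3, sd = 10)
    moved@coords[, , f] <- tr@coords[, , f] %*% t(R) +
      matrix(t, dim(tr@coords)[1], 3, byrow = TRUE)
  }
  g1 <- grooveSeries(tr, burnIn = 0)
  g2 <- grooveSeries(moved, burnIn = 0)
  expect_equal(g1$minor, g2$minor, tolerance = 1e-9)
  expect_equal(hbondSeries(tr), hbondSeries(moved), tolerance = 1e-9)
})

test_that("the MD protocol description covers the key settings", {
  txt <- paste(mdRunDescription(), collapse = " ")
  for (key in c("parmbsc0", "TIP3P", "300 K", "1.01325", "50 ns", "1 ps"))
    expect_match(txt, key, fixed = TRUE)
})
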