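# Base-frame fitting and helical-parameter analysis.

test_that("fitting the unmoved template gives an identity frame, RMSD 0", {
  for (b in c("A", "C", "G", "T", "I", "P")) {
    f <- fitBaseFrame(baseTemplates(b), b)
    expect_equal(f$frame$R, diag(3), tolerance = 1e-9)
    expect_equal(f$frame$o, c(0, 0, 0), tolerance = 1e-9)
    expect_lt(f$rmsd, 1e-9)
  }
})

test_that("a known rigid transform of the template is recovered exactly", {
  set.seed(11)
  for (k in 1:20) {
    b <- sample(c("A", "C", "G", "T", "I", "P"), 1)
    tpl <- baseTemplates(b)
    R0 <- randomRotation(); t0 <- rnorm(3, sd = 20)
    moved <- tpl
    xyz <- as.matrix(tpl[, c("x", "y", "z")]) %*% t(R0)
    moved$x <- xyz[, 1] + t0[1]; moved$y <- xyz[, 2] + t0[2]
    moved$z <- xyz[, 3] + t0[3]
    f <- fitBaseFrame(moved, b)
    expect_equal(f$frame$R, R0, tolerance = 1e-9)
    expect_equal(f$frame$o, t0, tolerance = 1e-9)
    expect_lt(f$rmsd, 1e-9)
  }
})

test_that("fit RMSD under coordinate noise matches an independent oracle", {
  # bio3d's superposition is the independent route; our Kabsch fit must
  # agree with it, and the reported RMSD must track the injected noise.
  set.seed(12)
  tpl <- baseTemplates("G")
  rmsds <- replicate(60, {
    noisy <- tpl
    noisy$x <- tpl$x + rnorm(nrow(tpl), sd = 0.1 / sqrt(3))
    noisy$y <- tpl$y + rnorm(nrow(tpl), sd = 0.1 / sqrt(3))
    noisy$z <- tpl$z + rnorm(nrow(tpl), sd = 0.1 / sqrt(3))
    ours <- fitBaseFrame(noisy, "G")$rmsd
    ref <- bio3d::rmsd(
      as.vector(t(as.matrix(tpl[, c("x", "y", "z")]))),
      as.vector(t(as.matrix(noisy[, c("x", "y", "z")]))),
      fit = TRUE)
    expect_lt(abs(ours - ref), 6e-4)  # bio3d rounds to 3 decimals
    ours
  })
  # displacement sd 0.1 A; fitting absorbs 6 of 3n dof
  n <- nrow(tpl)
  expectedRmsd <- 0.1 * sqrt((3 * n - 6) / (3 * n))
  expect_lt(abs(mean(rmsds) - expectedRmsd),
            3 * sd(rmsds) / sqrt(length(rmsds)) + 0.01)
})

test_that("fitBaseFrame errors with fewer than 3 matched atoms", {
  tpl <- baseTemplates("A")[1:2, ]
  expect_error(fitBaseFrame(tpl, "A"), "fewer than 3")
})

test_that("a pair of frames identical after y/z reversal has zero params", {
  R <- randomRotation(); o <- rnorm(3)
  f1 <- list(R = R, o = o)
  f2 <- list(R = R %*% diag(c(1, -1, -1)), o = o)
  bp <- basePairFrame(f1, f2)
  expect_equal(unname(bp$params), rep(0, 6), tolerance = 1e-9)
  expect_equal(bp$frame$R, R, tolerance = 1e-9)
})

test_that("propeller sign convention: -15 deg about the pair long axis", {
  f1 <- list(R = diag(3), o = c(0, 0, 0))
  rotY <- function(t) {
    t <- t * pi / 180
    matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  }
  f2 <- list(R = rotY(-15) %*% diag(c(1, -1, -1)), o = c(0, 0, 0))
  bp <- basePairFrame(f1, f2)
  expect_equal(unname(bp$params["propeller"]), -15, tolerance = 1e-9)
})

test_that("random intra-pair transforms round-trip through the pair frame", {
  set.seed(13)
  for (k in 1:50) {
    n <- 2
    intra <- randomIntraMatrix(1)
    d <- buildDuplex(sample(c("A", "C", "G", "T"), 1),
                     intra, matrix(numeric(0), 0, 6))
    an <- grooveDNA:::.analyzeDuplex(d)
    expect_equal(unname(an$intra[1, ]), unname(intra[1, ]),
                 tolerance = 1e-6)
  }
})

test_that("pure twist/rise step gives twist 36, rise 3.4, rest zero", {
  f1 <- list(R = diag(3), o = c(0, 0, 0))
  d <- buildDuplex("AT", NULL, matrix(c(0, 0, 3.4, 0, 0, 36), 1))
  an <- grooveDNA:::.analyzeDuplex(d)
  expect_equal(unname(an$steps[1, ]), c(0, 0, 3.4, 0, 0, 36),
               tolerance = 1e-9)
})

test_that("windowed means of a uniform duplex equal the input values", {
  steps <- matrix(rep(c(0.1, -0.3, 3.35, 1, 3, 34), each = 8), 8)
  d <- buildDuplex("AAAAAAAAA", NULL, steps)
  tb <- parameterTable(d)
  wm <- windowMeans(tb, c(-2, 2))
  expect_equal(unname(wm[c("shift", "slide", "rise", "tilt", "roll",
                           "twist")]),
               c(0.1, -0.3, 3.35, 1, 3, 34), tolerance = 1e-9)
  expect_equal(unname(wm[1:6]), rep(0, 6), tolerance = 1e-9)
})

test_that("windowed step means average the steps internal to the window", {
  # 5-bp window -> 4 internal steps
  set.seed(14)
  steps <- randomStepMatrix(9)
  d <- buildDuplex("ACGTACGTA", NULL, steps)
  tb <- parameterTable(d)
  wm <- windowMeans(tb, c(-2, 2))
  internal <- 3:6  # steps between pairs 3-4, 4-5, 5-6, 6-7 (positions -2..2)
  expect_equal(unname(wm["twist"]), mean(steps[internal, "twist"]),
               tolerance = 1e-6)
  expect_equal(unname(wm["roll"]), mean(steps[internal, "roll"]),
               tolerance = 1e-6)
})

test_that("mean roll over a window equals the generator's drawn mean", {
  set.seed(15)
  rolls <- rnorm(14, -2, 1)
  steps <- grooveDNA:::.meanStepsFor(strsplit(F28_SEQ, "")[[1]])
  steps[, "roll"] <- rolls
  d <- buildDuplex(F28_SEQ, NULL, steps)
  tb <- parameterTable(d)
  expect_equal(mean(tb$step$roll), mean(rolls), tolerance = 1e-6)
})

test_that("window outside the duplex raises an error", {
  d <- buildMeanDuplex("ACGTACG")
  expect_error(windowMeans(parameterTable(d), c(-10, 10)), "outside")
})

test_that("reverse-complement reading negates shift and tilt only", {
  set.seed(16)
  for (k in 1:5) {
    d <- randomDuplex("ACGTACGTACG")
    fwd <- grooveDNA:::.analyzeDuplex(d)$steps
    rev <- grooveDNA:::.analyzeDuplex(revcompDuplex(d))$steps
    revFlip <- rev[nrow(rev):1, ]
    expect_equal(unname(revFlip[, "shift"]), unname(-fwd[, "shift"]),
                 tolerance = 1e-6)
    expect_equal(unname(revFlip[, "tilt"]), unname(-fwd[, "tilt"]),
                 tolerance = 1e-6)
    for (p in c("slide", "rise", "roll", "twist"))
      expect_equal(unname(revFlip[, p]), unname(fwd[, p]),
                   tolerance = 1e-6)
  }
})

test_that("pair frames stay orthonormal with determinant +1", {
  set.seed(17)
  d <- randomDuplex("GCGCGCGC")
  an <- grooveDNA:::.analyzeDuplex(d)
  for (f in an$pairFrames) {
    expect_equal(crossprod(f$R), diag(3), tolerance = 1e-9)
    expect_equal(det(f$R), 1, tolerance = 1e-9)
  }
})
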