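# Shared builders for the test suite. Everything is generated in code;
# no stored fixtures.

F28_SEQ <- "GCTCAAGCGTTAGTC"
F1_SEQ <- "GCTCAAATTTTAGTC"

randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Random physically-plausible parameter matrices for an n-bp duplex.
randomStepMatrix <- function(n) {
  cbind(shift = runif(n - 1, -1, 1), slide = runif(n - 1, -1.5, 0.8),
        rise = runif(n - 1, 3.0, 3.8), tilt = runif(n - 1, -8, 8),
        roll = runif(n - 1, -8, 12), twist = runif(n - 1, 25, 45))
}

randomIntraMatrix <- function(n) {
  cbind(shear = runif(n, -0.5, 0.5), stretch = runif(n, -0.3, 0.3),
        stagger = runif(n, -0.5, 0.5), buckle = runif(n, -12, 12),
        propeller = runif(n, -18, 5), opening = runif(n, -6, 6))
}

randomDuplex <- function(sequence = "ACGTACGTAC") {
  n <- nchar(sequence)
  buildDuplex(sequence, randomIntraMatrix(n), randomStepMatrix(n))
}

# Apply a rigid motion (rotation + translation) to all atoms of a duplex.
rigidMove <- function(duplex, R = randomRotation(), t = rnorm(3, sd = 10)) {
  a <- duplex@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + t[1]; a$y <- xyz[, 2] + t[2]; a$z <- xyz[, 3] + t[3]
  duplex@atoms <- a
  duplex
}

# The same physical duplex read in the opposite orientation: strands
# swapped and pair order reversed (reverse-complement reading).
revcompDuplex <- function(duplex) {
  a <- duplex@atoms
  n <- nbp(duplex)
  a$strand <- 3L - a$strand
  a$pair <- n + 1L - a$pair
  a <- a[order(a$strand, ifelse(a$strand == 1L, a$pair, -a$pair)), ]
  p <- duplex@pairs
  p2 <- data.frame(pair = seq_len(n), base1 = rev(p$base2),
                   base2 = rev(p$base1))
  new("Duplex", atoms = a, pairs = p2)
}

# Brute-force groove widths: exhaustive scan over ALL cross-strand P-P
# pairs restricted to an offset window (independent of the package's
# vectorised path).
bruteGroove <- function(duplex, offsets, vdw = 5.8) {
  a <- duplex@atoms
  n <- nbp(duplex)
  getP <- function(s, i) {
    r <- a[a$strand == s & a$pair == i & a$atom == "P", c("x", "y", "z")]
    if (nrow(r) != 1) return(NULL)
    as.numeric(r)
  }
  out <- rep(NA_real_, n)
  for (pos in seq_len(n)) {
    best <- Inf
    for (i1 in seq_len(n)) for (o in offsets) {
      i2 <- i1 - o
      if (i2 < 1 || i2 > n) next
      if (abs((i1 + i2) / 2 - pos) > 0.5) next
      p1 <- getP(1L, i1); p2 <- getP(2L, i2)
      if (is.null(p1) || is.null(p2)) next
      best <- min(best, sqrt(sum((p1 - p2)^2)))
    }
    if (is.finite(best)) out[pos] <- best - vdw
  }
  out
}

# Brute-force clash scan with the same exclusion rules as findClashes.
bruteClashes <- function(duplex, tolerance = 0.4) {
  vd <- vdwRadii()
  a <- duplex@atoms
  a <- a[!(a$atom %in% c("OP1", "OP2", "O1P", "O2P", "C1'")), ]
  hb <- hbondSpec()
  ptype <- paste(duplex@pairs$base1, duplex@pairs$base2, sep = ":")
  hits <- 0L
  pairsSeen <- character(0)
  for (i in seq_len(nrow(a) - 1)) for (j in (i + 1):nrow(a)) {
    if (a$strand[i] == a$strand[j] && a$pair[i] == a$pair[j]) next
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
              (a$z[i] - a$z[j])^2)
    if (d >= vd[a$element[i]] + vd[a$element[j]] - tolerance) next
    if (a$pair[i] == a$pair[j] && a$strand[i] != a$strand[j]) {
      a1 <- if (a$strand[i] == 1) a$atom[i] else a$atom[j]
      a2 <- if (a$strand[i] == 1) a$atom[j] else a$atom[i]
      bonds <- hb[[ptype[a$pair[i]]]]
      if (any(vapply(bonds, function(b) b[1] == a1 && b[2] == a2,
                     logical(1)))) next
    }
    hits <- hits + 1L
    pairsSeen <- c(pairsSeen,
                   paste(a$strand[i], a$pair[i], a$atom[i],
                         a$strand[j], a$pair[j], a$atom[j]))
  }
  list(n = hits, keys = sort(pairsSeen))
}

clashKeys <- function(report) {
  sort(paste(report$strand1, report$pair1, report$atom1,
             report$strand2, report$pair2, report$atom2))
}
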