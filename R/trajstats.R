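# Distribution statistics over trajectory-derived series: groove widths
# per position, Watson-Crick hydrogen-bond lengths, superposed RMSD, and
# their summaries. Minor-groove width distributions over a trajectory can
# be strongly skewed or multimodal, in which case the most probable value
# (kernel-density mode) describes the system better than the mean; the
# summary reports both, together with a moment-matched Gaussian fit and a
# normality verdict.

#' Per-position groove-width series of a trajectory
#'
#' Applies [grooveProfile()] to every frame after discarding an initial
#' burn-in fraction (equilibration; default the first 20%).
#'
#' @param trajectory A [DuplexTrajectory-class].
#' @param convention A [GrooveConvention-class].
#' @param burnIn Fraction of initial frames discarded (default 0.2).
#' @param origin Pair index given position 0 (default: duplex center).
#' @return List with `minor` and `major` (matrices, kept frames x
#'   positions), `positions`, and `frames` (indices of the kept frames).
#' @export
grooveSeries <- function(trajectory, convention = grooveConvention(),
                         burnIn = 0.2, origin = NULL) {
  stopifnot(is(trajectory, "DuplexTrajectory"), burnIn >= 0, burnIn < 1)
  nf <- nFrames(trajectory)
  keep <- seq.int(floor(burnIn * nf) + 1L, nf)
  if (length(keep) < 1L) stop("no frames remain after burn-in")
  first <- grooveProfile(frameDuplex(trajectory, keep[1L]), convention,
                         origin)
  np <- length(first@positions)
  minor <- matrix(NA_real_, length(keep), np)
  major <- matrix(NA_real_, length(keep), np)
  minor[1L, ] <- first@minor; major[1L, ] <- first@major
  for (k in seq_along(keep)[-1L]) {
    p <- grooveProfile(frameDuplex(trajectory, keep[k]), convention, origin)
    minor[k, ] <- p@minor; major[k, ] <- p@major
  }
  colnames(minor) <- colnames(major) <- first@positions
  list(minor = minor, major = major, positions = first@positions,
       frames = keep)
}

#' Summarise one observable series
#'
#' Mean, spread, most probable value (Gaussian-kernel density maximum on a
#' fine grid, Silverman bandwidth), a moment-matched Gaussian fit and an
#' Anderson-Darling normality verdict.
#'
#' @param x Numeric series (length >= 2).
#' @param bandwidth KDE bandwidth; default Silverman's rule
#'   ([stats::bw.nrd0()]).
#' @param alpha Significance level for the normality verdict (default
#'   0.01).
#' @param gridStep Grid spacing for the density maximum (default 0.01, in
#'   the units of `x`).
#' @return A [SeriesSummary-class]. The verdict is `"undefined"` for
#'   constant series or fewer than 30 observations.
#' @export
#' @examples
#' s <- summarizeSeries(rnorm(1000, 5, 0.5))
#' s
summarizeSeries <- function(x, bandwidth = NULL, alpha = 0.01,
                            gridStep = 0.01) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) stop("series must have at least 2 finite values")
  m <- mean(x); s <- stats::sd(x)
  if (s < 1e-12) {
    return(new("SeriesSummary", n = n, mean = m, sd = 0, mode = m,
               bandwidth = 0, gaussMu = m, gaussSigma = 0,
               normalityP = NA_real_, normalityTest = "none",
               verdict = "undefined", alpha = alpha))
  }
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(x)
  lo <- min(x) - 3 * bandwidth; hi <- max(x) + 3 * bandwidth
  ngrid <- min(2L^15L, max(512L, ceiling((hi - lo) / gridStep) + 1L))
  den <- stats::density(x, bw = bandwidth, from = lo, to = hi, n = ngrid)
  mode <- den$x[which.max(den$y)]
  if (n >= 30L) {
    p <- nortest::ad.test(x)$p.value
    verdict <- if (p < alpha) "non-gaussian" else "gaussian"
    testName <- "Anderson-Darling"
  } else {
    p <- NA_real_; verdict <- "undefined"; testName <- "none"
  }
  new("SeriesSummary", n = n, mean = m, sd = s, mode = mode,
      bandwidth = bandwidth, gaussMu = m, gaussSigma = s,
      normalityP = p, normalityTest = testName, verdict = verdict,
      alpha = alpha)
}

#' Most-probable minor-groove-width profile of a trajectory
#'
#' Summarises the per-position minor-groove width series and reports the
#' kernel-density mode at every position, plus windowed mean/minimum of
#' the modes over a stated central range.
#'
#' @inheritParams grooveSeries
#' @param range Position window for the summary statistics (default
#'   -2..+2, the central 5 bp).
#' @param alpha Normality significance level passed to
#'   [summarizeSeries()].
#' @return List: `profile` (data.frame position, mode, bandwidth, mean,
#'   sd, normalityP, verdict), `window` (named numeric `meanMode`,
#'   `minMode` over the range), `series` (the [grooveSeries()] output).
#' @export
mostProbableProfile <- function(trajectory, convention = grooveConvention(),
                                burnIn = 0.2, origin = NULL,
                                range = c(-2, 2), alpha = 0.01) {
  gs <- grooveSeries(trajectory, convention, burnIn, origin)
  cols <- seq_along(gs$positions)
  sums <- lapply(cols, function(j) {
    v <- gs$minor[, j]
    v <- v[is.finite(v)]
    if (!length(v)) return(NULL)
    if (length(v) == 1L)  # single snapshot: the static profile itself
      return(new("SeriesSummary", n = 1L, mean = v, sd = 0, mode = v,
                 bandwidth = 0, gaussMu = v, gaussSigma = 0,
                 normalityP = NA_real_, normalityTest = "none",
                 verdict = "undefined", alpha = alpha))
    summarizeSeries(v, alpha = alpha)
  })
  profile <- data.frame(
    position = gs$positions,
    mode = vapply(sums, function(s) if (is.null(s)) NA_real_ else s@mode,
                  numeric(1L)),
    bandwidth = vapply(sums, function(s) if (is.null(s)) NA_real_
                       else s@bandwidth, numeric(1L)),
    mean = vapply(sums, function(s) if (is.null(s)) NA_real_ else s@mean,
                  numeric(1L)),
    sd = vapply(sums, function(s) if (is.null(s)) NA_real_ else s@sd,
                numeric(1L)),
    normalityP = vapply(sums, function(s) if (is.null(s)) NA_real_
                        else s@normalityP, numeric(1L)),
    verdict = vapply(sums, function(s) if (is.null(s)) "undefined"
                     else s@verdict, character(1L)))
  sel <- profile$position >= min(range) & profile$position <= max(range)
  modes <- profile$mode[sel]
  list(profile = profile,
       window = c(meanMode = mean(modes, na.rm = TRUE),
                  minMode = min(modes, na.rm = TRUE)),
       series = gs)
}

#' Pearson correlation of two groove-width profiles
#'
#' Product-moment correlation of two per-position width vectors over
#' their shared defined positions (optionally restricted to a range).
#' Used to quantify how closely one sequence's minor-groove shape tracks
#' another's.
#'
#' @param profileA,profileB Either numeric vectors of equal length, or
#'   data.frames with columns `position` and `mode` (as returned in
#'   `mostProbableProfile()$profile`).
#' @param range Optional length-2 position window (data.frame input only).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearsonProfiles <- function(profileA, profileB, range = NULL) {
  getvec <- function(p, shared) {
    if (is.data.frame(p)) p$mode[match(shared, p$position)]
    else as.numeric(p)
  }
  if (is.data.frame(profileA) && is.data.frame(profileB)) {
    shared <- intersect(profileA$position, profileB$position)
    if (!is.null(range))
      shared <- shared[shared >= min(range) & shared <= max(range)]
    a <- getvec(profileA, shared); b <- getvec(profileB, shared)
  } else {
    a <- as.numeric(profileA); b <- as.numeric(profileB)
    if (length(a) != length(b)) stop("profiles differ in length")
  }
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) stop("fewer than 3 shared defined positions")
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12)
    stop("zero variance in a profile: correlation undefined")
  stats::cor(a, b)
}

#' Watson-Crick hydrogen-bond length series
#'
#' Per-frame donor/acceptor heavy-atom distances for every Watson-Crick
#' hydrogen bond of the duplex (three per G:C pair, two per A:T, I:C and
#' 2-aminopurine:T pair; see [hbondSpec()]).
#'
#' @param trajectory A [DuplexTrajectory-class].
#' @return Matrix, frames x bonds; column names
#'   `"pair<i>.<type>.<atom1>-<atom2>"`.
#' @export
hbondSeries <- function(trajectory) {
  stopifnot(is(trajectory, "DuplexTrajectory"))
  topo <- trajectory@topology
  a <- topo@atoms
  types <- pairTypes(topo)
  idx1 <- integer(0L); idx2 <- integer(0L); labels <- character(0L)
  for (i in seq_len(nbp(topo))) {
    for (hb in .WC_HBONDS[[types[i]]]) {
      k1 <- which(a$strand == 1L & a$pair == i & a$atom == hb[1L])
      k2 <- which(a$strand == 2L & a$pair == i & a$atom == hb[2L])
      if (!length(k1) || !length(k2))
        stop(sprintf("pair %d (%s): missing atom %s", i, types[i],
                     if (!length(k1)) hb[1L] else hb[2L]))
      idx1 <- c(idx1, k1[1L]); idx2 <- c(idx2, k2[1L])
      labels <- c(labels, sprintf("pair%d.%s.%s-%s", i, types[i],
                                  hb[1L], hb[2L]))
    }
  }
  nf <- nFrames(trajectory)
  out <- matrix(NA_real_, nf, length(idx1), dimnames = list(NULL, labels))
  for (f in seq_len(nf)) {
    xyz <- trajectory@coords[, , f]
    out[f, ] <- sqrt(rowSums((xyz[idx1, , drop = FALSE] -
                              xyz[idx2, , drop = FALSE])^2))
  }
  out
}

#' Superposed RMSD series of a trajectory
#'
#' Per-frame root-mean-square deviation from a reference after
#' least-squares rigid superposition (rotation + translation, no
#' reflection), so global tumbling does not contribute.
#'
#' @param trajectory A [DuplexTrajectory-class].
#' @param reference A [Duplex-class] (default: the trajectory topology).
#' @param selection Optional integer or logical index into the atom table
#'   restricting the superposition (at least 3 atoms).
#' @return Numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsdSeries <- function(trajectory, reference = NULL, selection = NULL) {
  stopifnot(is(trajectory, "DuplexTrajectory"))
  topo <- trajectory@topology
  if (is.null(reference)) reference <- topo
  refxyz <- as.matrix(reference@atoms[, c("x", "y", "z")])
  if (is.null(selection)) selection <- seq_len(nrow(refxyz))
  refxyz <- refxyz[selection, , drop = FALSE]
  if (nrow(refxyz) < 3L) stop("selection must contain at least 3 atoms")
  vapply(seq_len(nFrames(trajectory)), function(f) {
    .kabsch(trajectory@coords[selection, , f, drop = TRUE], refxyz)$rmsd
  }, numeric(1L))
}

#' Engine-agnostic description of the reference MD protocol
#'
#' The package analyses trajectories but never drives an MD engine. This
#' helper returns a plain-text description of the simulation protocol the
#' trajectory statistics assume (force field, solvation, ensemble,
#' sampling), for use as documentation alongside any engine.
#'
#' @return Character vector, one line per protocol item.
#' @export
mdRunDescription <- function() {
  c("DNA oligomer in explicit solvent; parmbsc0 force field",
    "(ab initio charge set for inosine, which the force field lacks).",
    "TIP3P water box with ~16 A solvent margin around the DNA;",
    "Na+ counterions to global neutrality.",
    "Minimisation (conjugate gradient), solvent-only equilibration with",
    "the solute fixed, gradual heating to 300 K (50 K per 10 ps),",
    "100 ps equilibration, then production.",
    "Production: NPT, T = 300 K, P = 1.01325 bar, 50 ns,",
    "snapshots every 1 ps; analyse the final 40 ns (burn-in 0.2).")
}
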