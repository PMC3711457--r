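# Groove-width profiles by the phosphate-distance convention: the width
# at a position is the closest cross-strand P-P distance, restricted to a
# window of index offsets, minus the combined phosphate-group van der
# Waals radii (default 5.8 A). One convention serves crystal structures,
# rebuilt models and trajectory frames alike.

# Phosphorus coordinates per strand indexed by pair; NA rows where a
# residue (typically the 5'-terminal one) has no phosphate.
.phosphorusCoords <- function(duplex) {
  a <- duplex@atoms
  n <- nbp(duplex)
  out <- list(matrix(NA_real_, n, 3L), matrix(NA_real_, n, 3L))
  sel <- a$atom == "P"
  ap <- a[sel, ]
  for (k in seq_len(nrow(ap)))
    out[[ap$strand[k]]][ap$pair[k], ] <- c(ap$x[k], ap$y[k], ap$z[k])
  out
}

# Minimum width per reported position for one offset window.
.grooveSide <- function(P1, P2, offsets, positions, vdw) {
  n <- nrow(P1)
  cand <- expand.grid(i1 = seq_len(n), off = offsets)
  cand$i2 <- cand$i1 - cand$off
  cand <- cand[cand$i2 >= 1L & cand$i2 <= n, ]
  d <- sqrt(rowSums((P1[cand$i1, , drop = FALSE] -
                     P2[cand$i2, , drop = FALSE])^2))
  ok <- is.finite(d)
  cand <- cand[ok, ]; d <- d[ok]
  mid <- (cand$i1 + cand$i2) / 2
  vapply(seq_len(n), function(i) {
    use <- abs(mid - i) <= 0.5
    if (!any(use)) NA_real_ else min(d[use]) - vdw
  }, numeric(1L))
}

#' Minor and major groove width profile
#'
#' Computes per-position minor and major groove widths of a duplex by the
#' phosphate-distance convention (see [GrooveConvention-class]). Positions
#' near the ends where no spanning phosphate pair exists are `NA`, never
#' extrapolated.
#'
#' @param duplex A [Duplex-class] with at least 6 pairs.
#' @param convention A [GrooveConvention-class]; default [grooveConvention()].
#' @param origin Pair index given position 0 (default: duplex center).
#' @return A [GrooveProfile-class].
#' @seealso [windowStats()], [profileDelta()], [grooveWidthAt()].
#' @export
#' @examples
#' d <- buildMeanDuplex("GCTCAAGCGTTAGTC")
#' as.data.frame(grooveProfile(d))
grooveProfile <- function(duplex, convention = grooveConvention(),
                          origin = NULL) {
  stopifnot(is(duplex, "Duplex"), is(convention, "GrooveConvention"))
  n <- nbp(duplex)
  if (n < 6L) stop("duplex too short (< 6 bp): no interior groove definable")
  P <- .phosphorusCoords(duplex)
  if (all(!is.finite(P[[1L]])) || all(!is.finite(P[[2L]])))
    stop("a strand has no phosphates")
  pos <- pairPositions(duplex, origin)
  minor <- .grooveSide(P[[1L]], P[[2L]], convention@minorOffsets, pos,
                       convention@vdwSubtraction)
  major <- .grooveSide(P[[1L]], P[[2L]], convention@majorOffsets, pos,
                       convention@vdwSubtraction)
  new("GrooveProfile", positions = pos, minor = minor, major = major,
      convention = convention)
}

#' Groove width at a position
#'
#' @param profile A [GrooveProfile-class].
#' @param position Centered position (must exist in the profile).
#' @param groove `"minor"` (default) or `"major"`.
#' @return Width in Angstrom (possibly `NA` near the ends).
#' @export
grooveWidthAt <- function(profile, position, groove = c("minor", "major")) {
  groove <- match.arg(groove)
  i <- match(position, profile@positions)
  if (is.na(i)) stop("position ", position, " not in profile")
  slot(profile, groove)[i]
}

#' Windowed groove-width statistics
#'
#' Arithmetic mean and minimum of the defined minor and major widths over
#' an inclusive position window (e.g. the central 5 bp, -2..+2).
#'
#' @param profile A [GrooveProfile-class].
#' @param range Length-2 numeric position window.
#' @return Named numeric: `meanMinor`, `minMinor`, `meanMajor`, `minMajor`.
#' @export
windowStats <- function(profile, range = c(-2, 2)) {
  stopifnot(length(range) == 2L)
  sel <- profile@positions >= min(range) & profile@positions <= max(range)
  if (!any(sel)) stop("empty position range")
  mn <- profile@minor[sel]; mj <- profile@major[sel]
  if (all(is.na(mn)) || all(is.na(mj)))
    stop("no defined widths in the requested range")
  c(meanMinor = mean(mn, na.rm = TRUE), minMinor = min(mn, na.rm = TRUE),
    meanMajor = mean(mj, na.rm = TRUE), minMajor = min(mj, na.rm = TRUE))
}

#' Difference of groove statistics between two profiles
#'
#' Per-statistic differences (A minus B) of [windowStats()] over a shared
#' position window. Both profiles must use the same convention.
#'
#' @param profileA,profileB [GrooveProfile-class] objects.
#' @param range Length-2 numeric position window.
#' @return Named numeric of the four statistic differences.
#' @export
profileDelta <- function(profileA, profileB, range = c(-2, 2)) {
  ca <- profileA@convention; cb <- profileB@convention
  if (!isTRUE(all.equal(ca@vdwSubtraction, cb@vdwSubtraction)) ||
      !identical(ca@minorOffsets, cb@minorOffsets) ||
      !identical(ca@majorOffsets, cb@majorOffsets))
    stop("profiles use different groove conventions")
  windowStats(profileA, range) - windowStats(profileB, range)
}
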