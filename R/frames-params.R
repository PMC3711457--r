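# Base reference frames and helical parameters.
#
# A standard base template is superposed onto each observed base by
# least-squares rigid fitting; the transformed template frame is the base
# frame. Base-pair frames and the six intra-base-pair parameters come from
# combining the two base frames (the strand-2 frame has its y and z axes
# reversed first, reflecting the antiparallel strand orientation); the six
# base-pair-step parameters come from consecutive pair frames. Both
# decompositions use the mid-frame scheme in geometry.R, whose build
# direction is the exact inverse, so analysis and rebuilding round-trip to
# machine precision.

.INTRA_NAMES <- c("shear", "stretch", "stagger", "buckle", "propeller",
                  "opening")
.STEP_NAMES <- c("shift", "slide", "rise", "tilt", "roll", "twist")

#' Fit the standard reference frame to one base
#'
#' Least-squares rigid superposition (rotation + translation, no scaling
#' or reflection) of the standard base template onto the observed base
#' atoms, matched by atom name.
#'
#' @param atoms data.frame with columns `atom`, `x`, `y`, `z` for one
#'   nucleotide (extra atoms are ignored).
#' @param base Single-letter base code (A, C, G, T, I, P).
#' @return List with `frame` (list `R` 3x3 axes in columns, `o` origin) and
#'   `rmsd` (fit RMSD, Angstrom).
#' @export
#' @examples
#' tpl <- baseTemplates("A")
#' fitBaseFrame(tpl, "A")$rmsd   # 0: template fits itself exactly
fitBaseFrame <- function(atoms, base) {
  tpl <- baseTemplates(base)
  m <- match(tpl$atom, atoms$atom)
  keep <- !is.na(m)
  if (sum(keep) < 3L)
    stop("fewer than 3 template atoms matched for base ", base)
  x <- as.matrix(tpl[keep, c("x", "y", "z")])
  y <- as.matrix(atoms[m[keep], c("x", "y", "z")])
  k <- .kabsch(x, y)
  list(frame = list(R = k$R, o = as.vector(k$t)), rmsd = k$rmsd)
}

# Base frames for every nucleotide of a duplex.
# Returns list(frames = list [[strand]][[pair]], rmsd = matrix n x 2).
.duplexBaseFrames <- function(duplex) {
  a <- duplex@atoms
  p <- duplex@pairs
  n <- nrow(p)
  frames <- list(vector("list", n), vector("list", n))
  rmsd <- matrix(NA_real_, n, 2L)
  for (s in 1:2) for (i in seq_len(n)) {
    b <- if (s == 1L) p$base1[i] else p$base2[i]
    sel <- a$strand == s & a$pair == i
    f <- fitBaseFrame(a[sel, c("atom", "x", "y", "z")], b)
    frames[[s]][[i]] <- f$frame
    rmsd[i, s] <- f$rmsd
  }
  list(frames = frames, rmsd = rmsd)
}

#' Base-pair frame and intra-base-pair parameters
#'
#' Combines the two base frames of a Watson-Crick pair. The strand-2
#' frame's y and z axes are reversed first (antiparallel convention); the
#' pair frame is the mid-frame of the two, and the six intra-base-pair
#' parameters (shear, stretch, stagger in Angstrom; buckle, propeller,
#' opening in degrees) are the rigid-body parameters between them. Signs
#' are anchored so that rotating the strand-2 base by -15 degrees about
#' the pair long axis yields propeller -15 (A-tract propeller is negative).
#'
#' @param frame1,frame2 Base frames (`list(R, o)`) of the strand-1 and
#'   strand-2 bases.
#' @return List with `frame` (the pair frame) and `params` (named numeric,
#'   length 6).
#' @export
basePairFrame <- function(frame1, frame2) {
  .assertFrame(frame1); .assertFrame(frame2)
  f2s <- list(R = frame2$R %*% .FLIP, o = frame2$o)
  res <- .rigidAnalyze(frame1, f2s)
  params <- res$par
  names(params) <- .INTRA_NAMES
  list(frame = res$mid, params = params)
}

#' Base-pair-step parameters
#'
#' The six rigid-body parameters between two consecutive base-pair frames:
#' shift, slide, rise (Angstrom) and tilt, roll, twist (degrees), with
#' twist the rotation about the mid-step z axis (positive for right-handed
#' B-DNA) and (tilt, roll) the bending components about the mid-step x and
#' y axes.
#'
#' @param pairFrame1,pairFrame2 Consecutive pair frames (`list(R, o)`).
#' @return Named numeric vector of length 6.
#' @export
stepParams <- function(pairFrame1, pairFrame2) {
  .assertFrame(pairFrame1); .assertFrame(pairFrame2)
  par <- .rigidAnalyze(pairFrame1, pairFrame2)$par
  names(par) <- .STEP_NAMES
  par
}

# Full analysis of a duplex: base frames, pair frames, intra and step
# parameter matrices. Internal workhorse shared by parameterTable() and
# reconstructPartial().
.analyzeDuplex <- function(duplex) {
  bf <- .duplexBaseFrames(duplex)
  n <- nbp(duplex)
  pairFrames <- vector("list", n)
  intra <- matrix(NA_real_, n, 6L, dimnames = list(NULL, .INTRA_NAMES))
  for (i in seq_len(n)) {
    bp <- basePairFrame(bf$frames[[1L]][[i]], bf$frames[[2L]][[i]])
    pairFrames[[i]] <- bp$frame
    intra[i, ] <- bp$params
  }
  steps <- NULL
  if (n >= 2L) {
    steps <- matrix(NA_real_, n - 1L, 6L,
                    dimnames = list(NULL, .STEP_NAMES))
    for (i in seq_len(n - 1L))
      steps[i, ] <- stepParams(pairFrames[[i]], pairFrames[[i + 1L]])
  }
  list(pairFrames = pairFrames, intra = intra, steps = steps,
       fitRMSD = bf$rmsd)
}

#' Helical-parameter table of a duplex
#'
#' One record per base pair (intra-base-pair parameters) and one per step
#' (base-pair-step parameters), labelled by centered positions. Intra
#' records also carry the template fit RMSD of each base, which should be
#' small for well-resolved structures and is never silently dropped.
#'
#' @param duplex A [Duplex-class] with at least 2 pairs.
#' @param origin Pair index mapped to position 0 (see [pairPositions()]).
#' @return List of two data.frames, `intra` (columns `position`, `pair`,
#'   shear..opening, `fitRMSD1`, `fitRMSD2`) and `step` (columns
#'   `position` = midpoint of the flanking pair positions, `step` =
#'   dinucleotide on strand 1, shift..twist).
#' @seealso [windowMeans()] for windowed averages, [buildDuplex()] for the
#'   inverse operation.
#' @export
parameterTable <- function(duplex, origin = NULL) {
  if (nbp(duplex) < 2L) stop("duplex must have at least 2 pairs")
  an <- .analyzeDuplex(duplex)
  pos <- pairPositions(duplex, origin)
  intra <- data.frame(position = pos, pair = pairTypes(duplex),
                      as.data.frame(an$intra),
                      fitRMSD1 = an$fitRMSD[, 1L],
                      fitRMSD2 = an$fitRMSD[, 2L])
  b1 <- duplex@pairs$base1
  step <- data.frame(
    position = (pos[-1L] + pos[-length(pos)]) / 2,
    step = paste0(b1[-length(b1)], b1[-1L]),
    as.data.frame(an$steps))
  list(intra = intra, step = step)
}

#' Windowed means of a parameter table
#'
#' Averages helical parameters over a centered position window, e.g. the
#' central 5 bp (positions -2..+2). Intra-base-pair parameters average the
#' pairs inside the window; step parameters average the steps strictly
#' internal to it (both flanking pairs inside), i.e. 4 steps for a 5-bp
#' window.
#'
#' @param table Output of [parameterTable()].
#' @param range Length-2 numeric, inclusive position window.
#' @return Named numeric vector of the 12 windowed means.
#' @export
windowMeans <- function(table, range = c(-2, 2)) {
  stopifnot(length(range) == 2L)
  lo <- min(range); hi <- max(range)
  ip <- table$intra$position
  if (lo < min(ip) || hi > max(ip))
    stop("window outside the duplex position range")
  isel <- ip >= lo & ip <= hi
  ssel <- table$step$position > lo & table$step$position < hi
  c(colMeans(table$intra[isel, .INTRA_NAMES, drop = FALSE]),
    colMeans(table$step[ssel, .STEP_NAMES, drop = FALSE]))
}
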