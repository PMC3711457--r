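# S4 classes for the central data objects.

#' @import methods
NULL

.WC_PAIR_TYPES <- c("A:T", "T:A", "G:C", "C:G", "I:C", "C:I", "P:T", "T:P")

#' Duplex: a paired double-stranded DNA fragment with atomic coordinates
#'
#' The universal structural object of the package. Strand 2 is stored
#' antiparallel to strand 1, so pair index `i` of both strands forms
#' base pair `i`. Every pair must be of a Watson-Crick type supported by
#' the package chemistry: A:T, G:C, I:C (inosine) or P:T (2-aminopurine).
#'
#' @slot atoms data.frame with one row per heavy atom: `strand` (1 or 2),
#'   `pair` (pair index, 1-based from the strand-1 5' end), `chain`,
#'   `resno` (author numbering), `base` (single-letter code), `atom`
#'   (PDB-style name), `element`, `x`, `y`, `z` (Angstrom), `occ`.
#' @slot pairs data.frame: `pair`, `base1`, `base2`.
#' @export
setClass("Duplex", representation(atoms = "data.frame", pairs = "data.frame"))

setValidity("Duplex", function(object) {
  a <- object@atoms
  p <- object@pairs
  need <- c("strand", "pair", "chain", "resno", "base", "atom", "element",
            "x", "y", "z", "occ")
  if (!all(need %in% names(a)))
    return(paste("atoms table lacks columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(p) < 1L) return("duplex has no base pairs")
  if (!identical(sort(unique(a$pair)), seq_len(nrow(p))))
    return("atom pair indices do not cover 1..n_bp")
  if (!all(a$strand %in% c(1L, 2L))) return("strand must be 1 or 2")
  if (any(!is.finite(c(a$x, a$y, a$z)))) return("non-finite coordinates")
  if (any(a$occ < 0 | a$occ > 1)) return("occupancy outside [0, 1]")
  ptype <- paste(p$base1, p$base2, sep = ":")
  bad <- which(!ptype %in% .WC_PAIR_TYPES)
  if (length(bad))
    return(paste0("pair ", bad[1L], " (", ptype[bad[1L]],
                  ") is not a supported Watson-Crick pair type"))
  # every nucleotide must carry its ring atoms
  for (s in 1:2) for (i in seq_len(nrow(p))) {
    b <- if (s == 1L) p$base1[i] else p$base2[i]
    have <- a$atom[a$strand == s & a$pair == i]
    miss <- setdiff(.ringAtoms(b), have)
    if (length(miss))
      return(paste0("strand ", s, " pair ", i, " (", b, ") lacks ring atoms: ",
                    paste(miss, collapse = ", ")))
  }
  TRUE
})

#' DuplexTrajectory: ordered coordinate snapshots of one duplex
#'
#' @slot topology A [Duplex-class] providing atom identity and ordering.
#' @slot coords Numeric array `n_atoms x 3 x n_frames`; every frame uses
#'   the topology's atom ordering.
#' @slot frameInterval Time units per frame (arbitrary units; default ps).
#' @export
setClass("DuplexTrajectory",
         representation(topology = "Duplex", coords = "array",
                        frameInterval = "numeric"))

setValidity("DuplexTrajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2L] != 3L)
    return("coords must be an n_atoms x 3 x n_frames array")
  if (d[1L] != nrow(object@topology@atoms))
    return(sprintf("frame atom count (%d) differs from topology (%d)",
                   d[1L], nrow(object@topology@atoms)))
  if (d[3L] < 1L) return("trajectory has no frames")
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    return("frameInterval must be a positive scalar")
  TRUE
})

#' GrooveConvention: the phosphate-distance groove-width convention
#'
#' Groove width at a position is the smallest cross-strand P-P distance,
#' restricted to an offset window, minus the combined phosphate-group van
#' der Waals radii. The offset of a P pair is the strand-1 residue index
#' minus the strand-2 residue index (both counted along strand 1); the pair
#' is assigned to the midpoint of the two indices.
#'
#' @slot vdwSubtraction Total van der Waals subtraction in Angstrom
#'   (default 5.8, i.e. 2 x 2.9 per phosphate group).
#' @slot minorOffsets Integer window of cross-strand index offsets scanned
#'   for the minor groove.
#' @slot majorOffsets Same for the major groove (disjoint from minor).
#' @export
setClass("GrooveConvention",
         representation(vdwSubtraction = "numeric",
                        minorOffsets = "integer", majorOffsets = "integer"))

setValidity("GrooveConvention", function(object) {
  if (object@vdwSubtraction <= 0) return("vdwSubtraction must be positive")
  if (length(intersect(object@minorOffsets, object@majorOffsets)))
    return("minor and major offset windows must be disjoint")
  TRUE
})

#' GrooveProfile: per-position minor/major groove widths
#'
#' @slot positions Numeric centered positions (0 at the duplex center).
#' @slot minor,major Width in Angstrom per position; `NA` where a flanking
#'   phosphate does not exist (near the ends).
#' @slot convention The [GrooveConvention-class] used.
#' @export
setClass("GrooveProfile",
         representation(positions = "numeric", minor = "numeric",
                        major = "numeric", convention = "GrooveConvention"))

setValidity("GrooveProfile", function(object) {
  n <- length(object@positions)
  if (length(object@minor) != n || length(object@major) != n)
    return("minor/major must match positions in length")
  if (any(stats::na.omit(c(object@minor, object@major)) <
          -object@convention@vdwSubtraction - 1e-9))
    return("width below -vdwSubtraction implies a negative raw distance")
  TRUE
})

#' SeriesSummary: distribution summary of one groove-width series
#'
#' @slot n Number of observations.
#' @slot mean,sd Sample mean and standard deviation.
#' @slot mode Most probable value (kernel-density maximum).
#' @slot bandwidth KDE bandwidth used for the mode.
#' @slot gaussMu,gaussSigma Moment-matched Gaussian fit.
#' @slot normalityP Normality-test p-value (NA when undefined).
#' @slot normalityTest Name of the test used.
#' @slot verdict "gaussian", "non-gaussian" or "undefined".
#' @slot alpha Significance level for the verdict.
#' @export
setClass("SeriesSummary",
         representation(n = "integer", mean = "numeric", sd = "numeric",
                        mode = "numeric", bandwidth = "numeric",
                        gaussMu = "numeric", gaussSigma = "numeric",
                        normalityP = "numeric", normalityTest = "character",
                        verdict = "character", alpha = "numeric"))
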