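# Generics and simple methods (accessors, show, coercion).

#' Number of base pairs
#' @param x A [Duplex-class] or [DuplexTrajectory-class].
#' @return Integer pair count.
#' @export
setGeneric("nbp", function(x) standardGeneric("nbp"))

#' @rdname nbp
#' @export
setMethod("nbp", "Duplex", function(x) nrow(x@pairs))

#' @rdname nbp
#' @export
setMethod("nbp", "DuplexTrajectory", function(x) nbp(x@topology))

#' Number of trajectory frames
#' @param x A [DuplexTrajectory-class].
#' @return Integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "DuplexTrajectory", function(x) dim(x@coords)[3L])

#' Base sequence of a duplex strand
#' @param x A [Duplex-class].
#' @param strand 1 (default) or 2; strand 2 is returned 5' to 3'.
#' @return Single-letter base string (I = inosine, P = 2-aminopurine).
#' @export
setGeneric("duplexSequence", function(x, strand = 1L)
  standardGeneric("duplexSequence"))

#' @rdname duplexSequence
#' @export
setMethod("duplexSequence", "Duplex", function(x, strand = 1L) {
  if (strand == 1L) paste(x@pairs$base1, collapse = "")
  else paste(rev(x@pairs$base2), collapse = "")
})

#' Base-pair types of a duplex
#' @param x A [Duplex-class].
#' @return Character vector like `"A:T"`, one per pair.
#' @export
setGeneric("pairTypes", function(x) standardGeneric("pairTypes"))

#' @rdname pairTypes
#' @export
setMethod("pairTypes", "Duplex", function(x)
  paste(x@pairs$base1, x@pairs$base2, sep = ":"))

#' Atom table of a duplex
#' @param x A [Duplex-class].
#' @return data.frame of atoms (see [Duplex-class]).
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname atomTable
#' @export
setMethod("atomTable", "Duplex", function(x) x@atoms)

#' Centered position labels of a duplex
#'
#' Maps 1-based pair indices to the centered convention used for
#' binding-site analysis: position 0 at the duplex center for odd pair
#' counts, or at a user-chosen origin pair.
#'
#' @param x A [Duplex-class] or integer pair count.
#' @param origin Pair index assigned position 0. Default: the middle pair
#'   (requires an odd pair count unless `origin` is given).
#' @return Numeric vector of positions, one per pair.
#' @export
pairPositions <- function(x, origin = NULL) {
  n <- if (is(x, "Duplex")) nbp(x) else as.integer(x)
  if (is.null(origin)) {
    if (n %% 2L == 0L)
      stop("even pair count: specify the origin pair explicitly")
    origin <- (n + 1L) / 2L
  }
  if (origin < 1L || origin > n) stop("origin pair outside the duplex")
  seq_len(n) - origin
}

#' Extract one trajectory frame as a Duplex
#' @param x A [DuplexTrajectory-class].
#' @param i Frame index.
#' @return A [Duplex-class] with the topology's identity and frame `i`
#'   coordinates.
#' @export
frameDuplex <- function(x, i) {
  stopifnot(is(x, "DuplexTrajectory"))
  nf <- nFrames(x)
  if (i < 1L || i > nf) stop("frame index out of range: ", i)
  d <- x@topology
  d@atoms$x <- x@coords[, 1L, i]
  d@atoms$y <- x@coords[, 2L, i]
  d@atoms$z <- x@coords[, 3L, i]
  d
}

#' @describeIn Duplex-class Compact display.
#' @param object A `Duplex`.
#' @export
setMethod("show", "Duplex", function(object) {
  n <- nbp(object)
  cat("Duplex with", n, "base pairs,", nrow(object@atoms), "atoms\n")
  cat("  strand 1: 5'-", duplexSequence(object, 1L), "-3'\n", sep = "")
  cat("  strand 2: 3'-", paste(object@pairs$base2, collapse = ""),
      "-5'\n", sep = "")
})

#' @describeIn DuplexTrajectory-class Compact display.
#' @param object A `DuplexTrajectory`.
#' @export
setMethod("show", "DuplexTrajectory", function(object) {
  cat("DuplexTrajectory:", nFrames(object), "frames of a",
      nbp(object), "bp duplex (interval", object@frameInterval, ")\n")
})

#' @describeIn GrooveProfile-class Compact display.
#' @param object A `GrooveProfile`.
#' @export
setMethod("show", "GrooveProfile", function(object) {
  cat("GrooveProfile over", length(object@positions), "positions\n")
  print(utils::head(as.data.frame(object), 8L))
})

#' Coerce a GrooveProfile to a data.frame
#'
#' @param x A [GrooveProfile-class].
#' @param row.names,optional,... Ignored (S3 signature).
#' @return data.frame with columns `position`, `minor`, `major` (Angstrom).
#' @export
as.data.frame.GrooveProfile <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(position = x@positions, minor = x@minor, major = x@major)
}

#' @describeIn SeriesSummary-class Compact display.
#' @param object A `SeriesSummary`.
#' @export
setMethod("show", "SeriesSummary", function(object) {
  cat(sprintf(
    "SeriesSummary: n=%d mean=%.3f sd=%.3f mode=%.3f (bw %.3f)\n",
    object@n, object@mean, object@sd, object@mode, object@bandwidth))
  cat(sprintf("  Gaussian fit mu=%.3f sigma=%.3f; %s p=%.3g -> %s (alpha %.2g)\n",
              object@gaussMu, object@gaussSigma, object@normalityTest,
              object@normalityP, object@verdict, object@alpha))
})

#' @describeIn GrooveConvention-class Compact display.
#' @param object A `GrooveConvention`.
#' @export
setMethod("show", "GrooveConvention", function(object) {
  cat(sprintf("GrooveConvention: P-P minus %.2f A; minor offsets %s; major offsets %s\n",
              object@vdwSubtraction,
              paste(range(object@minorOffsets), collapse = ".."),
              paste(range(object@majorOffsets), collapse = "..")))
})

#' Construct a groove-width convention
#'
#' @param vdwSubtraction Total vdW subtraction (Angstrom); default 5.8
#'   (2.9 per phosphate group, the standard phosphate-group radius).
#' @param minorOffsets,majorOffsets Integer cross-strand index-offset
#'   windows scanned for each groove. The defaults (2..5 and -7..-2) match
#'   the geometry of B-form DNA, where the phosphates facing each other
#'   across the minor groove belong to pairs about 3-4 steps apart.
#' @return A [GrooveConvention-class].
#' @export
#' @examples
#' grooveConvention()
grooveConvention <- function(vdwSubtraction = 5.8,
                             minorOffsets = 2:5,
                             majorOffsets = -7:-2) {
  new("GrooveConvention", vdwSubtraction = vdwSubtraction,
      minorOffsets = as.integer(minorOffsets),
      majorOffsets = as.integer(majorOffsets))
}
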