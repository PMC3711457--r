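# Rebuilding duplex coordinates from helical parameters - the inverse of
# the frame analysis - including mean-parameter B-form models and partial
# reconstructions that keep only a subset of step parameters.

#' Mean dinucleotide step parameters
#'
#' Mean base-pair-step parameters of the 16 dinucleotide steps from the
#' crystallographic survey of protein-bound DNA (Olson and co-workers),
#' the standard source for sequence-dependent mean B-form geometry.
#' Complementary steps follow from the 10 unique values by negating tilt
#' and shift.
#'
#' @return data.frame with columns `step`, `shift`, `slide`, `rise`
#'   (Angstrom), `tilt`, `roll`, `twist` (degrees); 16 rows.
#' @export
#' @examples
#' meanStepTable()
meanStepTable <- function() {
  # twist tilt roll shift slide rise
  u <- rbind(AA = c(35.1, -1.4, 0.7, -0.03, -0.08, 3.27),
             AT = c(29.3, 0.0, 1.1, 0.00, -0.59, 3.31),
             AG = c(31.9, -1.7, 4.5, 0.09, -0.25, 3.34),
             AC = c(31.5, -0.1, 0.7, 0.13, -0.58, 3.36),
             GA = c(36.3, -1.5, 1.9, -0.28, 0.09, 3.37),
             GG = c(32.9, -0.1, 3.6, 0.05, -0.22, 3.42),
             GC = c(33.6, 0.0, 0.3, 0.00, -0.38, 3.40),
             TA = c(37.8, 0.0, 3.3, 0.00, 0.05, 3.42),
             CA = c(34.5, 0.5, 4.7, 0.09, 0.53, 3.33),
             CG = c(36.1, 0.0, 5.4, 0.00, 0.41, 3.39))
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  steps <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           paste0))
  out <- matrix(NA_real_, length(steps), 6L,
                dimnames = list(steps, c("shift", "slide", "rise",
                                         "tilt", "roll", "twist")))
  for (s in steps) {
    if (s %in% rownames(u)) {
      v <- u[s, ]
      out[s, ] <- c(v[4L], v[5L], v[6L], v[2L], v[3L], v[1L])
    } else {
      rc <- paste0(comp[substr(s, 2L, 2L)], comp[substr(s, 1L, 1L)])
      v <- u[rc, ]
      out[s, ] <- c(-v[4L], v[5L], v[6L], -v[2L], v[3L], v[1L])
    }
  }
  data.frame(step = steps, out, row.names = NULL)
}

# Mean step parameters for an arbitrary supported sequence; analog bases
# use the canonical purine they derive from (I -> G, P -> A), since the
# survey table is defined for canonical steps only.
.meanStepsFor <- function(bases) {
  tab <- meanStepTable()
  canon <- .STEP_CANONICAL[bases]
  if (any(is.na(canon)))
    stop("unknown base code: ", paste(bases[is.na(canon)], collapse = ","))
  key <- paste0(canon[-length(canon)], canon[-1L])
  m <- match(key, tab$step)
  if (any(is.na(m))) stop("unknown dinucleotide step: ", key[is.na(m)][1L])
  as.matrix(tab[m, .STEP_NAMES])
}

# Place all atoms of one nucleotide given its base frame.
.placeNucleotide <- function(base, frame, strand, pair, chain, resno,
                             backbone = TRUE) {
  tpl <- baseTemplates(base)
  if (backbone) tpl <- rbind(tpl, .BACKBONE_TEMPLATE)
  xyz <- as.matrix(tpl[, c("x", "y", "z")]) %*% t(frame$R)
  xyz <- sweep(xyz, 2L, frame$o, "+")
  data.frame(strand = strand, pair = pair, chain = chain, resno = resno,
             base = base, atom = tpl$atom,
             element = vapply(tpl$atom, .elementOf, ""),
             x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], occ = 1,
             row.names = NULL)
}

#' Build a duplex from helical parameters
#'
#' Generates base-pair frames by chaining the mid-frame step transforms
#' from an identity start, splits each pair into its two base frames by
#' the intra-base-pair parameters, and places idealized base atoms plus a
#' rigid phosphate group in every base frame. Re-analysing the result
#' returns the input parameters to numerical precision.
#'
#' @param sequence Strand-1 base string over A, C, G, T, I, P
#'   (P = 2-aminopurine); the second strand is the Watson-Crick complement
#'   unless `partner` is given.
#' @param intra `n x 6` matrix of intra-base-pair parameters
#'   (shear..opening), or `NULL` for all-zero.
#' @param steps `(n-1) x 6` matrix of step parameters (shift..twist).
#' @param partner Optional base string of the strand-2 partner at each
#'   pair position (aligned with `sequence`, i.e. 3' to 5' along strand
#'   2). Needed for analog-containing duplexes where the partner is not
#'   the canonical complement, e.g. a C:I pair.
#' @return A [Duplex-class].
#' @seealso [buildMeanDuplex()], [reconstructPartial()], [parameterTable()].
#' @export
#' @examples
#' d <- buildDuplex("ACGT", steps = matrix(rep(c(0, 0, 3.4, 0, 0, 36),
#'                                             each = 3), 3))
#' nbp(d)
buildDuplex <- function(sequence, intra = NULL, steps, partner = NULL) {
  bases <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(bases)
  if (n < 1L) stop("empty sequence")
  comp <- if (is.null(partner)) .WC_COMPLEMENT[bases]
          else strsplit(toupper(partner), "")[[1L]]
  if (length(comp) != n)
    stop("partner must align with sequence (one base per pair)")
  if (any(is.na(comp)))
    stop("unknown base code: ", paste(bases[is.na(comp)], collapse = ","))
  steps <- rbind(steps)
  if (n > 1L && (nrow(steps) != n - 1L || ncol(steps) != 6L))
    stop("steps must be a (length(sequence) - 1) x 6 matrix")
  if (is.null(intra)) intra <- matrix(0, n, 6L)
  intra <- rbind(intra)
  if (nrow(intra) != n || ncol(intra) != 6L)
    stop("intra must be a length(sequence) x 6 matrix")
  if (any(!is.finite(steps)) || any(!is.finite(intra)))
    stop("parameters must be finite")

  pairFrames <- vector("list", n)
  pairFrames[[1L]] <- list(R = diag(3L), o = c(0, 0, 0))
  if (n > 1L) for (i in seq_len(n - 1L))
    pairFrames[[i + 1L]] <- .rigidBuild(pairFrames[[i]],
                                        unname(steps[i, ]))$f2
  rows <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    sp <- .rigidSplit(pairFrames[[i]], unname(intra[i, ]))
    base2Frame <- list(R = sp$f2$R %*% .FLIP, o = sp$f2$o)
    rows[[i]] <- .placeNucleotide(bases[i], sp$f1, 1L, i, "A", i)
    rows[[n + i]] <- .placeNucleotide(comp[i], base2Frame, 2L, i, "B",
                                      n - i + 1L)
  }
  atoms <- do.call(rbind, rows)
  # order: strand 1 by pair 1..n, then strand 2 in its own 5'->3'
  # direction (pair n..1), matching how a PDB file lists the two chains
  atoms <- atoms[order(atoms$strand, ifelse(atoms$strand == 1L,
                                            atoms$pair, -atoms$pair)), ]
  rownames(atoms) <- NULL
  new("Duplex", atoms = atoms,
      pairs = data.frame(pair = seq_len(n), base1 = bases,
                         base2 = unname(comp)))
}

#' Build a mean-parameter B-form duplex
#'
#' [buildDuplex()] with per-step parameters taken from [meanStepTable()]
#' and zero intra-base-pair deformations: the "free DNA built from mean
#' parameters" model. Deterministic: the same sequence always yields the
#' same coordinates.
#'
#' @param sequence Strand-1 base string (A, C, G, T, I, P).
#' @return A [Duplex-class].
#' @export
#' @examples
#' d <- buildMeanDuplex("GCTCAAGCGTTAGTC")
#' grooveWidthAt(grooveProfile(d), 0)
buildMeanDuplex <- function(sequence) {
  bases <- strsplit(toupper(sequence), "")[[1L]]
  if (length(bases) < 2L) stop("sequence must have at least 2 bases")
  buildDuplex(sequence, NULL, .meanStepsFor(bases))
}

#' Rebuild a duplex keeping only a subset of its step parameters
#'
#' Extracts the step parameters of a reference duplex, keeps the named
#' subset, fills every other step parameter from a mean table (or fixed
#' constants) and all intra-base-pair parameters with zero, then rebuilds.
#' Used to ask which parameters suffice to reproduce a conformation, e.g.
#' whether twist, roll and slide alone carry minor-groove compression.
#'
#' @param reference A [Duplex-class].
#' @param keep Character subset of `c("shift","slide","rise","tilt",
#'   "roll","twist")`; may be empty.
#' @param fill Either `"mean"` (default; sequence-specific values from
#'   [meanStepTable()]) or a named numeric of per-parameter constants.
#' @return A [Duplex-class].
#' @export
reconstructPartial <- function(reference, keep = c("twist", "roll", "slide"),
                               fill = "mean") {
  if (nbp(reference) < 2L) stop("reference must have at least 2 pairs")
  keep <- as.character(keep)
  if (length(setdiff(keep, .STEP_NAMES)))
    stop("unknown step parameter: ",
         paste(setdiff(keep, .STEP_NAMES), collapse = ","))
  refSteps <- .analyzeDuplex(reference)$steps
  bases <- reference@pairs$base1
  filled <- if (identical(fill, "mean")) {
    .meanStepsFor(bases)
  } else {
    stopifnot(is.numeric(fill), all(.STEP_NAMES %in% names(fill)))
    matrix(fill[.STEP_NAMES], nrow(refSteps), 6L, byrow = TRUE,
           dimnames = list(NULL, .STEP_NAMES))
  }
  filled[, keep] <- refSteps[, keep]
  buildDuplex(paste(bases, collapse = ""), NULL, filled)
}
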