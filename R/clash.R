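# Steric-clash detection in duplex models, aimed at the exocyclic purine
# 2-amino (N2) group: in minor-groove-compressed models the N2 of guanine
# (or 2-aminopurine) collides with exocyclic groups of paired or
# diagonally apposed bases, while models built with inosine have no N2 at
# all. Heavy-atom radii with a tolerance stand in for the absent
# hydrogens, as in standard clash-score practice.

#' Find steric clashes in a duplex
#'
#' Reports every atom pair closer than the sum of the van der Waals radii
#' minus a tolerance, excluding same-residue pairs and the Watson-Crick
#' donor/acceptor pairs of each base pair (which legitimately sit closer
#' than vdW contact; see [hbondSpec()]). By default the scan covers base
#' heavy atoms and phosphorus, the atoms relevant to minor-groove
#' sterics.
#'
#' @param duplex A [Duplex-class].
#' @param vdw Named element radii (Angstrom); default [vdwRadii()].
#' @param tolerance Allowed overlap before a contact counts as a clash
#'   (Angstrom, default 0.4).
#' @param atoms `"base+P"` (default: base/exocyclic atoms plus P) or
#'   `"all"`.
#' @return data.frame with one row per clashing pair: strand/pair/base/atom
#'   of both partners, `distance`, `overlap` (= rA + rB - tolerance -
#'   distance, always positive) and `involvesN2`.
#' @export
#' @examples
#' findClashes(buildMeanDuplex("GCTCAAGCGTTAGTC"))   # clash-free B-DNA
findClashes <- function(duplex, vdw = vdwRadii(), tolerance = 0.4,
                        atoms = c("base+P", "all")) {
  stopifnot(is(duplex, "Duplex"), tolerance >= 0)
  atoms <- match.arg(atoms)
  a <- duplex@atoms
  if (atoms == "base+P")
    a <- a[!(a$atom %in% c("OP1", "OP2", "O1P", "O2P", "C1'")), ]
  r <- vdw[a$element]
  if (any(is.na(r)))
    stop("no vdW radius for element: ",
         paste(unique(a$element[is.na(r)]), collapse = ","))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  nd <- nrow(a)
  D <- as.matrix(stats::dist(xyz))
  cut <- outer(r, r, "+") - tolerance
  hit <- which(D < cut & upper.tri(D), arr.ind = TRUE)
  if (nrow(hit)) {
    i <- hit[, 1L]; j <- hit[, 2L]
    # drop same-residue pairs
    keep <- !(a$strand[i] == a$strand[j] & a$pair[i] == a$pair[j])
    # drop Watson-Crick donor/acceptor pairs of the same base pair
    samePair <- a$pair[i] == a$pair[j] & a$strand[i] != a$strand[j]
    if (any(samePair & keep)) {
      ptype <- paste(duplex@pairs$base1, duplex@pairs$base2, sep = ":")
      for (k in which(samePair & keep)) {
        a1 <- if (a$strand[i[k]] == 1L) a$atom[i[k]] else a$atom[j[k]]
        a2 <- if (a$strand[i[k]] == 1L) a$atom[j[k]] else a$atom[i[k]]
        hb <- .WC_HBONDS[[ptype[a$pair[i[k]]]]]
        if (any(vapply(hb, function(b)
          b[1L] == a1 && b[2L] == a2, logical(1L))))
          keep[k] <- FALSE
      }
    }
    i <- i[keep]; j <- j[keep]
  } else {
    i <- j <- integer(0L)
  }
  out <- data.frame(
    strand1 = a$strand[i], pair1 = a$pair[i], base1 = a$base[i],
    atom1 = a$atom[i],
    strand2 = a$strand[j], pair2 = a$pair[j], base2 = a$base[j],
    atom2 = a$atom[j],
    distance = if (length(i)) D[cbind(i, j)] else numeric(0L),
    overlap = if (length(i)) cut[cbind(i, j)] - D[cbind(i, j)]
              else numeric(0L))
  out$involvesN2 <- out$atom1 == "N2" | out$atom2 == "N2"
  out[order(out$pair1, out$pair2), , drop = FALSE]
}

#' Build a minor-groove-compressed model for 2-amino clash analysis
#'
#' Builds the named binding-site variant at the geometry of a
#' high-affinity bound site: center minor-groove width compressed to the
#' given target and A-tract-like negative propeller twist imposed over
#' the center. In such models every central purine 2-amino (N2) group
#' runs into steric clashes with exocyclic groups of paired or diagonally
#' apposed bases, whereas the inosine analog of the same sequence has no
#' N2 at all. Because amino-group contacts are hydrogen-mediated, scan
#' these models with `findClashes(model, tolerance = 0)`: the default
#' 0.4 Angstrom allowance compensates for ordinary apolar hydrogens and
#' would mask N-H-mediated overlap (see the methods vignette).
#'
#' @param fixture Fixture name (see [fixtureSequences()]) or a base
#'   string.
#' @param targetWidth Center minor-groove width target (Angstrom;
#'   default 3.9, the central mean of the high-affinity bound site).
#' @param propeller Central propeller twist (degrees; default -15).
#' @param partner Optional partner strand when `fixture` is a plain
#'   sequence.
#' @return A [Duplex-class].
#' @export
#' @examples
#' m <- compressedClashModel("F28")
#' sum(findClashes(m, tolerance = 0)$involvesN2) > 0
compressedClashModel <- function(fixture, targetWidth = 3.9,
                                 propeller = -15, partner = NULL) {
  fx <- fixtureSequences()
  i <- match(fixture, fx$name)
  seq15 <- if (!is.na(i)) fx$full15[i] else fixture
  if (!is.na(i)) partner <- fx$partner15[i]
  makeCompressedDuplex(seq15, targetWidth, partner = partner,
                       propeller = propeller)$duplex
}
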