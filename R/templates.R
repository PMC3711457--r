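# Embedded chemical reference data: idealized base geometries in the
# standard reference frame, the phosphate placement used when rebuilding
# coordinates, van der Waals radii, Watson-Crick hydrogen-bond atom pairs,
# and residue-name aliases for canonical and modified bases.

# Idealized heavy-atom coordinates of the four canonical bases (plus the
# glycosidic C1') in the standard base reference frame: x points from the
# minor- toward the major-groove edge, y toward the attached backbone, z
# completes a right-handed set. Units Angstrom.
.BASE_TEMPLATES <- local({
  mk <- function(...) {
    m <- matrix(c(...), ncol = 4L, byrow = TRUE)
    df <- data.frame(atom = m[, 1L],
                     x = as.numeric(m[, 2L]),
                     y = as.numeric(m[, 3L]),
                     z = as.numeric(m[, 4L]),
                     stringsAsFactors = FALSE)
    df
  }
  A <- mk("C1'", -2.479, 5.346, 0.000,
          "N9", -1.291, 4.498, 0.000,
          "C8",  0.024, 4.897, 0.000,
          "N7",  0.877, 3.902, 0.000,
          "C5",  0.071, 2.771, 0.000,
          "C6",  0.369, 1.398, 0.000,
          "N6",  1.611, 0.909, 0.000,
          "N1", -0.668, 0.532, 0.000,
          "C2", -1.912, 1.023, 0.000,
          "N3", -2.320, 2.290, 0.000,
          "C4", -1.267, 3.124, 0.000)
  G <- mk("C1'", -2.477, 5.399, 0.000,
          "N9", -1.289, 4.551, 0.000,
          "C8",  0.023, 4.962, 0.000,
          "N7",  0.870, 3.969, 0.000,
          "C5",  0.071, 2.833, 0.000,
          "C6",  0.424, 1.460, 0.000,
          "O6",  1.554, 0.955, 0.000,
          "N1", -0.700, 0.641, 0.000,
          "C2", -1.999, 1.087, 0.000,
          "N2", -2.949, 0.139, -0.001,
          "N3", -2.342, 2.364, 0.001,
          "C4", -1.265, 3.177, 0.000)
  C <- mk("C1'", -2.477, 5.402, 0.000,
          "N1", -1.285, 4.542, 0.000,
          "C2", -1.472, 3.158, 0.000,
          "O2", -2.628, 2.709, 0.001,
          "N3", -0.391, 2.344, 0.000,
          "C4",  0.837, 2.868, 0.000,
          "N4",  1.875, 2.027, 0.001,
          "C5",  1.056, 4.275, 0.000,
          "C6", -0.023, 5.068, 0.000)
  T <- mk("C1'", -2.481, 5.354, 0.000,
          "N1", -1.284, 4.500, 0.000,
          "C2", -1.462, 3.135, 0.000,
          "O2", -2.562, 2.608, 0.000,
          "N3", -0.298, 2.407, 0.000,
          "C4",  0.994, 2.897, 0.000,
          "O4",  1.944, 2.119, 0.000,
          "C5",  1.106, 4.338, 0.000,
          "C7",  2.466, 4.961, 0.001,
          "C6", -0.024, 5.057, 0.000)
  # Inosine: guanine without the exocyclic 2-amino group.
  I <- G[G$atom != "N2", ]
  rownames(I) <- NULL
  # 2-aminopurine: adenine without the 6-amino group, with an amino group
  # at the position guanine's N2 occupies (minor-groove edge).
  P <- A[A$atom != "N6", ]
  P <- rbind(P, data.frame(atom = "N2", x = -2.949, y = 0.139, z = -0.001))
  rownames(P) <- NULL
  list(A = A, G = G, C = C, T = T, I = I, P = P)
})

# Purine ring atoms carry N9/C8/N7 in addition to the six-membered ring.
.PURINES <- c("A", "G", "I", "P")
.RING_ATOMS <- list(
  purine = c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9"),
  pyrimidine = c("N1", "C2", "N3", "C4", "C5", "C6"))

.ringAtoms <- function(base) {
  if (base %in% .PURINES) .RING_ATOMS$purine else .RING_ATOMS$pyrimidine
}

# Watson-Crick complement (2-aminopurine pairs with thymine, inosine with
# cytosine).
.WC_COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G", I = "C", P = "T")

# Complement used for dinucleotide-step lookups: analog bases map onto the
# canonical purine they are derived from (I -> G, P -> A).
.STEP_CANONICAL <- c(A = "A", G = "G", C = "C", T = "T", I = "G", P = "A")

# Watson-Crick donor/acceptor heavy-atom pairs per pair type, strand1 atom
# first. Used both as the hydrogen-bond definition and as the clash
# exclusion list (these atoms legitimately sit closer than vdW contact).
.WC_HBONDS <- list(
  "A:T" = list(c("N6", "O4"), c("N1", "N3")),
  "T:A" = list(c("O4", "N6"), c("N3", "N1")),
  "G:C" = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2")),
  "C:G" = list(c("N4", "O6"), c("N3", "N1"), c("O2", "N2")),
  "I:C" = list(c("O6", "N4"), c("N1", "N3")),
  "C:I" = list(c("N4", "O6"), c("N3", "N1")),
  "P:T" = list(c("N1", "N3"), c("N2", "O2")),
  "T:P" = list(c("N3", "N1"), c("O2", "N2")))

# Phosphate-group placement in the base reference frame. The phosphorus
# sits on the fiber-model B-DNA helix of radius 8.91 A; its azimuth and
# axial offset are calibrated once so that an ideal 36 deg / 3.38 A helix
# reproduces canonical B-form groove widths under the P-P minus 5.8 A
# convention and a mean-parameter B-form model reproduces the published
# free-DNA center width (see the methods vignette). The two free oxygens
# are placed at tetrahedral geometry around P, pointing away from the
# helix interior.
.BACKBONE_TEMPLATE <- local({
  phi <- 80.609 * pi / 180
  p <- c(8.91 * cos(phi), 8.91 * sin(phi), -2.647)
  outward <- p / sqrt(sum(p[1:2]^2) + 0) # roughly radial
  o1 <- p + 1.48 * c(cos(phi + 0.45), sin(phi + 0.45), 0.55)
  o2 <- p + 1.48 * c(cos(phi - 0.45), sin(phi - 0.45), -0.55)
  data.frame(atom = c("P", "OP1", "OP2"),
             x = c(p[1L], o1[1L], o2[1L]),
             y = c(p[2L], o1[2L], o2[2L]),
             z = c(p[3L], o1[3L], o2[3L]),
             stringsAsFactors = FALSE)
})

.elementOf <- function(atom) {
  # PDB-style atom names used here start with the element symbol.
  substr(sub("^[0-9']*", "", atom), 1L, 1L)
}

#' Default van der Waals radii
#'
#' Heavy-atom van der Waals radii used by [findClashes()].
#'
#' @return Named numeric vector of radii in Angstrom (elements C, N, O, P).
#' @export
#' @examples
#' vdwRadii()
vdwRadii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, P = 1.80)
}

#' Residue-name aliases for base identification
#'
#' Maps PDB residue names to the single-letter base codes used throughout
#' the package: A, C, G, T, I (inosine) and P (2-aminopurine). Deposited
#' names for modified nucleotides vary between entries, so the table is
#' user-extensible.
#'
#' @param extra Named character vector of additional residue-name to
#'   base-code mappings, e.g. `c(XYZ = "P")`.
#' @return Named character vector mapping residue names to base codes.
#' @export
#' @examples
#' baseAliases()
#' baseAliases(c("2PR" = "P"))
baseAliases <- function(extra = NULL) {
  tab <- c(DA = "A", A = "A", ADE = "A",
           DG = "G", G = "G", GUA = "G",
           DC = "C", C = "C", CYT = "C",
           DT = "T", T = "T", THY = "T", DU = "T",
           DI = "I", I = "I", INO = "I",
           "2AP" = "P", AP2 = "P", P2A = "P", PRN = "P")
  if (!is.null(extra)) {
    stopifnot(is.character(extra), !is.null(names(extra)))
    tab[names(extra)] <- extra
  }
  tab
}

#' Standard base templates
#'
#' Idealized heavy-atom coordinates of each supported base (A, C, G, T,
#' inosine `I`, 2-aminopurine `P`) in the standard base reference frame.
#' The inosine template is the guanine template without N2; the
#' 2-aminopurine template is the adenine template without N6 and with an
#' N2 at the guanine N2 position.
#'
#' @param base Optional single base code; if omitted, all templates.
#' @return A data.frame (atom, x, y, z) or a named list of them.
#' @export
#' @examples
#' head(baseTemplates("G"))
baseTemplates <- function(base = NULL) {
  if (is.null(base)) return(.BASE_TEMPLATES)
  base <- toupper(base)
  if (!base %in% names(.BASE_TEMPLATES))
    stop("unknown base code: ", base)
  .BASE_TEMPLATES[[base]]
}

#' Watson-Crick hydrogen-bond atom pairs
#'
#' Donor/acceptor heavy-atom name pairs for each supported base-pair type:
#' three bonds for G:C, two for A:T, I:C and 2-aminopurine:T.
#'
#' @return Named list; each element is a list of length-2 character vectors
#'   (strand-1 atom, strand-2 atom).
#' @export
#' @examples
#' hbondSpec()[["G:C"]]
hbondSpec <- function() .WC_HBONDS
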