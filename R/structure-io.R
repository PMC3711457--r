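# Reading and writing atomic structures and multi-model trajectories.
# Parsing goes through bio3d; this layer identifies nucleotides (including
# modified bases via the alias table), assembles Watson-Crick-paired
# duplexes, and keeps protein chains available for distance measurements.

.RESNAME_OUT <- c(A = "DA", G = "DG", C = "DC", T = "DT", I = "DI",
                  P = "2AP")

# Highest-occupancy altloc per (chain, resno, insert, atom); ties keep the
# first encountered.
.resolveAltloc <- function(atom) {
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "|")
  ord <- order(factor(key, levels = unique(key)), -atom$o)
  atom <- atom[ord, ]
  atom[!duplicated(paste(atom$chain, atom$resno, atom$insert, atom$elety,
                         sep = "|")), ]
}

# A "strand": one nucleic chain as a data.frame of atoms with columns
# chain, resno, base, atom, element, x, y, z, occ, in residue file order.
.strandFromAtoms <- function(chainAtoms, aliases) {
  resno <- unique(chainAtoms$resno)
  rows <- lapply(resno, function(r) {
    res <- chainAtoms[chainAtoms$resno == r, ]
    resid <- res$resid[1L]
    base <- aliases[trimws(resid)]
    if (is.na(base))
      stop("unknown residue name: ", trimws(resid), " (chain ",
           res$chain[1L], " resno ", r, "); extend baseAliases()")
    data.frame(chain = res$chain, resno = r, base = unname(base),
               atom = res$elety,
               element = vapply(res$elety, .elementOf, ""),
               x = res$x, y = res$y, z = res$z,
               occ = ifelse(is.na(res$o), 1, res$o))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.nucResidue <- function(strand, k) {
  resno <- unique(strand$resno)
  strand[strand$resno == resno[k], ]
}

# Check one candidate Watson-Crick pair; returns TRUE or a reason string.
.checkPair <- function(nuc1, nuc2, c1Range = c(9.5, 11.5), maxAngle = 65,
                       hbMax = 3.5) {
  b1 <- nuc1$base[1L]; b2 <- nuc2$base[1L]
  if (!paste(b1, b2, sep = ":") %in% names(.WC_HBONDS))
    return(sprintf("bases %s/%s are not Watson-Crick complementary", b1, b2))
  c1a <- nuc1[nuc1$atom == "C1'", c("x", "y", "z")]
  c1b <- nuc2[nuc2$atom == "C1'", c("x", "y", "z")]
  if (nrow(c1a) != 1L || nrow(c1b) != 1L) return("missing C1' atom")
  d <- sqrt(sum((as.numeric(c1a) - as.numeric(c1b))^2))
  if (d < c1Range[1L] || d > c1Range[2L])
    return(sprintf("C1'-C1' distance %.1f A outside %.1f-%.1f", d,
                   c1Range[1L], c1Range[2L]))
  f1 <- tryCatch(fitBaseFrame(nuc1, b1), error = function(e) NULL)
  f2 <- tryCatch(fitBaseFrame(nuc2, b2), error = function(e) NULL)
  if (is.null(f1) || is.null(f2)) return("cannot fit a base frame")
  cosang <- abs(sum(f1$frame$R[, 3L] * f2$frame$R[, 3L]))
  if (acos(min(1, cosang)) > maxAngle * pi / 180)
    return("base planes inclined beyond the pairing limit")
  for (hb in .WC_HBONDS[[paste(b1, b2, sep = ":")]]) {
    aa <- nuc1[nuc1$atom == hb[1L], c("x", "y", "z")]
    bb <- nuc2[nuc2$atom == hb[2L], c("x", "y", "z")]
    if (nrow(aa) != 1L || nrow(bb) != 1L)
      return(sprintf("missing hydrogen-bond atom %s or %s", hb[1L], hb[2L]))
    if (sqrt(sum((as.numeric(aa) - as.numeric(bb))^2)) > hbMax)
      return(sprintf("hydrogen bond %s-%s longer than %.1f A", hb[1L],
                     hb[2L], hbMax))
  }
  TRUE
}

#' Pair two nucleic strands into a duplex
#'
#' Pairs residues by geometric Watson-Crick criteria: C1'-C1' distance
#' within 9.5-11.5 Angstrom, base planes inclined by at most 65 degrees,
#' and all Watson-Crick donor/acceptor heavy-atom distances below 3.5
#' Angstrom. Pairing must be sequential and antiparallel; either file
#' order of the second strand is accepted.
#'
#' @param strand1,strand2 Strand atom tables as produced by
#'   [readDuplexPDB()] (columns chain, resno, base, atom, element,
#'   x, y, z, occ).
#' @return A [Duplex-class]; strand 1 keeps its given order.
#' @export
pairStrands <- function(strand1, strand2) {
  n1 <- length(unique(strand1$resno))
  n2 <- length(unique(strand2$resno))
  if (n1 != n2)
    stop(sprintf("strands differ in length (%d vs %d residues)", n1, n2))
  tryOrder <- function(rev2) {
    idx2 <- if (rev2) rev(seq_len(n2)) else seq_len(n2)
    reasons <- character(n1)
    ok <- logical(n1)
    for (i in seq_len(n1)) {
      r <- .checkPair(.nucResidue(strand1, i), .nucResidue(strand2, idx2[i]))
      ok[i] <- isTRUE(r)
      if (!ok[i]) reasons[i] <- r
    }
    list(idx2 = idx2, ok = ok, reasons = reasons)
  }
  a <- tryOrder(TRUE)   # both strands listed 5'->3' (the usual case)
  b <- tryOrder(FALSE)  # second strand already listed 3'->5'
  best <- if (sum(a$ok) >= sum(b$ok)) a else b
  if (!all(best$ok)) {
    i <- which(!best$ok)[1L]
    nuc <- .nucResidue(strand1, i)
    stop(sprintf("residue %s %d cannot be paired: %s", nuc$chain[1L],
                 nuc$resno[1L], best$reasons[i]))
  }
  resno2 <- unique(strand2$resno)[best$idx2]
  rows <- vector("list", 2L * n1)
  pairs <- data.frame(pair = seq_len(n1), base1 = character(n1),
                      base2 = character(n1))
  for (i in seq_len(n1)) {
    nuc1 <- .nucResidue(strand1, i)
    nuc2 <- strand2[strand2$resno == resno2[i], ]
    pairs$base1[i] <- nuc1$base[1L]
    pairs$base2[i] <- nuc2$base[1L]
    rows[[i]] <- cbind(strand = 1L, pair = i, nuc1)
    rows[[n1 + i]] <- cbind(strand = 2L, pair = i, nuc2)
  }
  atoms <- do.call(rbind, rows)
  atoms <- atoms[order(atoms$strand, ifelse(atoms$strand == 1L,
                                            atoms$pair, -atoms$pair)), ]
  atoms <- atoms[, c("strand", "pair", "chain", "resno", "base", "atom",
                     "element", "x", "y", "z", "occ")]
  rownames(atoms) <- NULL
  new("Duplex", atoms = atoms, pairs = pairs)
}

#' Read a PDB structure into duplexes and protein chains
#'
#' Reads a PDB file (via bio3d), selects the highest-occupancy alternate
#' location of each atom, classifies chains as nucleic (majority of
#' residues carrying a C1' atom) or protein, identifies bases through the
#' alias table, and assembles Watson-Crick-paired [Duplex-class] objects.
#' Nucleic chains that cannot be paired are returned as single strands,
#' never silently dropped.
#'
#' @param file Path to a PDB file.
#' @param aliases Residue-name alias table; default [baseAliases()].
#' @return List with `duplexes` (list of [Duplex-class]), `singleStrands`
#'   (list of strand atom tables), `protein` (data.frame of protein-chain
#'   atoms, bio3d columns) and `atoms` (all atoms after altloc
#'   resolution).
#' @export
readDuplexPDB <- function(file, aliases = baseAliases()) {
  pdb <- tryCatch({
    out <- NULL
    utils::capture.output(out <- suppressWarnings(
      bio3d::read.pdb(file, rm.alt = FALSE, verbose = FALSE)))
    out
  }, error = function(e) stop("no atoms could be read from ", file,
                              " (", conditionMessage(e), ")"))
  atom <- pdb$atom
  if (is.null(atom) || nrow(atom) == 0L) stop("no atoms in ", file)
  if (is.null(atom$insert)) atom$insert <- ""
  atom$insert[is.na(atom$insert)] <- ""
  atom <- .resolveAltloc(atom)
  atom$chain[is.na(atom$chain)] <- " "
  chains <- split(atom, atom$chain)
  isNucleic <- vapply(chains, function(ch) {
    res <- split(ch, ch$resno)
    mean(vapply(res, function(r) "C1'" %in% r$elety, logical(1L))) > 0.5
  }, logical(1L))
  strands <- lapply(chains[isNucleic], .strandFromAtoms, aliases = aliases)
  duplexes <- list()
  singles <- list()
  remaining <- names(strands)
  while (length(remaining)) {
    id <- remaining[1L]
    remaining <- remaining[-1L]
    paired <- FALSE
    for (other in remaining) {
      d <- tryCatch(pairStrands(strands[[id]], strands[[other]]),
                    error = function(e) NULL)
      if (!is.null(d)) {
        duplexes[[length(duplexes) + 1L]] <- d
        remaining <- setdiff(remaining, other)
        paired <- TRUE
        break
      }
    }
    if (!paired) singles[[id]] <- strands[[id]]
  }
  protein <- do.call(rbind, chains[!isNucleic])
  list(duplexes = duplexes, singleStrands = singles,
       protein = if (is.null(protein)) atom[0L, ] else protein,
       atoms = atom)
}

# Fixed-width PDB ATOM records for one duplex (or one trajectory frame).
.pdbLines <- function(duplex, serialStart = 1L) {
  a <- duplex@atoms
  serial <- serialStart
  lines <- character(0L)
  for (s in 1:2) {
    sub <- a[a$strand == s, ]
    for (k in seq_len(nrow(sub))) {
      name <- sub$atom[k]
      name4 <- if (nchar(name) >= 4L) substr(name, 1L, 4L)
               else sprintf(" %-3s", name)
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, name4, .RESNAME_OUT[sub$base[k]], sub$chain[k],
        sub$resno[k], sub$x[k], sub$y[k], sub$z[k], sub$occ[k], 0,
        sub$element[k]))
      serial <- serial + 1L
    }
    lines <- c(lines, "TER")
  }
  list(lines = lines, nextSerial = serial)
}

#' Write a duplex as a PDB file
#'
#' @param duplex A [Duplex-class].
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
writeDuplexPDB <- function(duplex, file) {
  stopifnot(is(duplex, "Duplex"))
  writeLines(c(.pdbLines(duplex)$lines, "END"), file)
  invisible(file)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param trajectory A [DuplexTrajectory-class].
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
writeTrajectoryPDB <- function(trajectory, file) {
  stopifnot(is(trajectory, "DuplexTrajectory"))
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(trajectory))) {
    writeLines(sprintf("MODEL %8d", f), con)
    writeLines(.pdbLines(frameDuplex(trajectory, f))$lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Read a multi-model PDB trajectory
#'
#' Reads MODEL/ENDMDL-delimited frames and matches atoms to a topology
#' duplex by chain, residue number and atom name. Every frame must carry
#' the topology's atom count.
#'
#' @param file Path to a multi-model PDB file.
#' @param topology A [Duplex-class] defining atom identity and ordering.
#' @param frameInterval Time units per frame (default 1, arbitrary units).
#' @return A [DuplexTrajectory-class].
#' @export
readTrajectoryPDB <- function(file, topology, frameInterval = 1) {
  stopifnot(is(topology, "Duplex"))
  pdb <- tryCatch({
    out <- NULL
    utils::capture.output(out <- suppressWarnings(
      bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)))
    out
  }, error = function(e) stop("cannot read trajectory ", file, " (",
                              conditionMessage(e), ")"))
  natTopo <- nrow(topology@atoms)
  nat <- nrow(pdb$atom)
  if (nat != natTopo)
    stop(sprintf("frame 1: %d atoms, topology has %d", nat, natTopo))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  bad <- which(apply(xyz, 1L, function(r) any(!is.finite(r))))
  if (length(bad))
    stop(sprintf("frame %d: atom count or ordering differs from frame 1",
                 bad[1L]))
  keyT <- paste(topology@atoms$chain, topology@atoms$resno,
                topology@atoms$atom)
  keyF <- paste(pdb$atom$chain, pdb$atom$resno, pdb$atom$elety)
  m <- match(keyT, keyF)
  if (any(is.na(m)))
    stop("topology atom missing from trajectory: ", keyT[is.na(m)][1L])
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(natTopo, 3L, nf))
  for (f in seq_len(nf)) {
    fr <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    coords[, , f] <- fr[m, , drop = FALSE]
  }
  new("DuplexTrajectory", topology = topology, coords = coords,
      frameInterval = frameInterval)
}

#' Distance between two named atoms
#'
#' Euclidean separation between two atoms addressed by (chain, residue
#' number, atom name), e.g. the recognition-helix C-alpha atoms of a
#' protein dimer.
#'
#' @param x A [Duplex-class], the list returned by [readDuplexPDB()], or
#'   a bio3d-style atom data.frame.
#' @param a,b Selectors: `c(chain, resno, atomName)`.
#' @return Distance in Angstrom.
#' @export
#' @examples
#' d <- buildMeanDuplex("GCTCAAGCGTTAGTC")
#' measureSeparation(d, c("A", 1, "P"), c("B", 1, "P"))
measureSeparation <- function(x, a, b) {
  df <- if (is(x, "Duplex")) {
    data.frame(chain = x@atoms$chain, resno = x@atoms$resno,
               atom = x@atoms$atom, x = x@atoms$x, y = x@atoms$y,
               z = x@atoms$z)
  } else if (is.list(x) && !is.null(x$atoms) && !is.data.frame(x)) {
    data.frame(chain = x$atoms$chain, resno = x$atoms$resno,
               atom = x$atoms$elety, x = x$atoms$x, y = x$atoms$y,
               z = x$atoms$z)
  } else if (is.data.frame(x)) {
    data.frame(chain = x$chain, resno = x$resno,
               atom = if (!is.null(x$elety)) x$elety else x$atom,
               x = x$x, y = x$y, z = x$z)
  } else stop("unsupported structure object")
  pick <- function(sel) {
    hit <- df$chain == sel[1L] & df$resno == as.integer(sel[2L]) &
      df$atom == sel[3L]
    if (!any(hit))
      stop("atom not found: chain ", sel[1L], " resno ", sel[2L],
           " atom ", sel[3L])
    as.numeric(df[which(hit)[1L], c("x", "y", "z")])
  }
  sqrt(sum((pick(a) - pick(b))^2))
}
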