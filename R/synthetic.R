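# Synthetic-data generation with known ground truth: the named
# binding-site sequence variants, minor-groove-compressed duplexes, and
# stochastic trajectories with Gaussian or two-state mixture variation of
# the step parameters.

#' Binding-site sequence fixtures
#'
#' The seven binding-site variants used throughout: a high-affinity
#' A/T-centered site (F1), single and triple G/C substitutions (F27,
#' F28), the five-G/C variant (F29), and their inosine (dI) and
#' 2-aminopurine (2AP) analogs. The central 5-mers are the authoritative
#' sequences; the 15-mer flanks (G/C-edged, A/T-rich) are a synthetic
#' context shared by all variants, so that variants differ only at the
#' center.
#'
#' @return data.frame with columns `name`, `central5`, `full15` and
#'   `partner15` (the strand-2 base partnering each strand-1 position;
#'   in the analog variants every substituted G/C pair becomes I/C and
#'   every substituted pair of F28-2AP becomes 2-aminopurine:T, on
#'   whichever strand carried the purine). Single-letter codes;
#'   `I` = inosine, `P` = 2-aminopurine.
#' @export
#' @examples
#' fixtureSequences()
fixtureSequences <- function() {
  central <- c("F1" = "AATTT", "F27" = "AACTT", "F28" = "AGCGT",
               "F28-dI" = "AICIT", "F28-2AP" = "APTPT",
               "F29" = "GGCGC", "F29-dI" = "IICIC")
  centralPartner <- c("F1" = "TTAAA", "F27" = "TTGAA", "F28" = "TCGCA",
                      "F28-dI" = "TCICA", "F28-2AP" = "TTPTA",
                      "F29" = "CCGCG", "F29-dI" = "CCICI")
  data.frame(name = names(central),
             central5 = unname(central),
             full15 = paste0("GCTCA", unname(central), "TAGTC"),
             partner15 = paste0("CGAGT", unname(centralPartner), "ATCAG"),
             row.names = NULL)
}

#' Build the mean-parameter duplex of a named fixture
#'
#' @param name Fixture name (see [fixtureSequences()]).
#' @return A [Duplex-class] of the 15-mer built with [buildMeanDuplex()].
#' @export
fixtureDuplex <- function(name) {
  fx <- fixtureSequences()
  i <- match(name, fx$name)
  if (is.na(i)) stop("unknown fixture: ", name, "; see fixtureSequences()")
  bases <- strsplit(fx$full15[i], "")[[1L]]
  buildDuplex(fx$full15[i], NULL, .meanStepsFor(bases),
              partner = fx$partner15[i])
}

#' Export the sequence fixtures as FASTA
#'
#' Single-letter codes `I` (inosine) and `P` (2-aminopurine) extend the
#' DNA alphabet; a comment header declares them.
#'
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
exportFixturesFASTA <- function(file) {
  fx <- fixtureSequences()
  lines <- c(";; binding-site variants; alphabet ACGT plus I=inosine, P=2-aminopurine")
  for (i in seq_len(nrow(fx)))
    lines <- c(lines, paste0(">", fx$name[i], " central5=", fx$central5[i]),
               fx$full15[i])
  writeLines(lines, file)
  invisible(file)
}

# Smooth central perturbation applied to a step matrix: overtwist,
# negative roll, negative slide, weighted by a Gaussian envelope around
# the center - the parameter combination that carries minor-groove
# compression.
.compressSteps <- function(steps, lambda, sigma = 2) {
  ns <- nrow(steps)
  mid <- (ns + 1) / 2
  w <- exp(-((seq_len(ns) - mid)^2) / (2 * sigma^2))
  out <- steps
  out[, "twist"] <- out[, "twist"] + lambda * 4 * w
  out[, "roll"] <- out[, "roll"] - lambda * 5 * w
  out[, "slide"] <- out[, "slide"] - lambda * 0.6 * w
  out
}

#' Build a duplex with a centrally compressed minor groove
#'
#' Starting from the mean-parameter model of the sequence, applies a
#' smooth central perturbation of twist (+), roll (-) and slide (-) - the
#' parameters that carry minor-groove compression - and solves for the
#' perturbation amplitude that brings the center minor-groove width to
#' the target. Deterministic.
#'
#' @param sequence Strand-1 base string.
#' @param targetWidth Desired center minor-groove width (Angstrom); must
#'   be below the mean-parameter model's center width.
#' @param convention A [GrooveConvention-class].
#' @param tol Acceptable |achieved - target| (default 0.1 Angstrom).
#' @param lambdaMax Amplitude bound (default 3; about +12 deg twist,
#'   -15 deg roll, -1.8 A slide at the center).
#' @param partner Optional strand-2 partner string (see [buildDuplex()]).
#' @param propeller Propeller twist (degrees) imposed at the center with
#'   the same envelope (default 0).
#' @return List: `duplex`, `achieved` (center width, Angstrom), `lambda`
#'   (amplitude used), `steps` (the step-parameter matrix).
#' @export
#' @examples
#' cz <- makeCompressedDuplex("GCTCAAGCGTTAGTC", 4.4)
#' cz$achieved
makeCompressedDuplex <- function(sequence, targetWidth,
                                 convention = grooveConvention(),
                                 tol = 0.1, lambdaMax = 3, partner = NULL,
                                 propeller = 0) {
  bases <- strsplit(toupper(sequence), "")[[1L]]
  base <- .meanStepsFor(bases)
  n <- length(bases)
  intra <- matrix(0, n, 6L)
  intra[, 5L] <- propeller * exp(-((seq_len(n) - (n + 1) / 2)^2) / 8)
  widthAt <- function(lambda) {
    d <- buildDuplex(sequence, intra, .compressSteps(base, lambda),
                     partner = partner)
    list(w = grooveWidthAt(grooveProfile(d, convention), 0), d = d)
  }
  w0 <- widthAt(0)
  if (targetWidth > w0$w + tol)
    stop(sprintf(
      "target %.2f A above the mean-parameter center width %.2f A",
      targetWidth, w0$w))
  if (abs(w0$w - targetWidth) <= tol)
    return(list(duplex = w0$d, achieved = w0$w, lambda = 0,
                steps = base))
  lo <- 0; hi <- lambdaMax
  whi <- widthAt(hi)
  if (whi$w > targetWidth)
    stop(sprintf(
      "target %.2f A unreachable within bounds; best achieved %.2f A",
      targetWidth, whi$w))
  best <- NULL; bestL <- NA_real_
  for (k in 1:60) {
    midl <- (lo + hi) / 2
    wm <- widthAt(midl)
    if (is.null(best) ||
        abs(wm$w - targetWidth) < abs(best$w - targetWidth)) {
      best <- wm; bestL <- midl
    }
    if (wm$w > targetWidth) lo <- midl else hi <- midl
    if (abs(best$w - targetWidth) <= tol / 4) break
  }
  list(duplex = best$d, achieved = best$w, lambda = bestL,
       steps = .compressSteps(base, bestL))
}

#' Generate a synthetic duplex trajectory with known ground truth
#'
#' Each frame is rebuilt from the base step parameters plus either
#' independent Gaussian jitter per step parameter or a per-frame draw
#' from a two-state (or k-state) mixture of step-parameter matrices.
#' Frames are independent (no autocorrelation); the drawn parameters are
#' returned so every frame can be recomputed exactly.
#'
#' @param sequence Strand-1 base string.
#' @param nFrames Number of frames.
#' @param seed Integer seed; identical recipes reproduce bit-identical
#'   trajectories.
#' @param baseSteps Step matrix (default: [meanStepTable()] values for
#'   the sequence).
#' @param sd Named numeric of per-parameter Gaussian standard deviations
#'   (e.g. `c(twist = 3)`, degrees/Angstrom); unnamed parameters get 0.
#'   Ignored when `mixture` is given.
#' @param mixture Optional list with `steps` (list of step matrices, one
#'   per state) and `weights` (summing to 1): per-frame independent state
#'   draws.
#' @param frameInterval Time units per frame (default 1).
#' @param partner Optional strand-2 partner string (see [buildDuplex()]).
#' @return List: `trajectory` (a [DuplexTrajectory-class]) and `truth`
#'   (list with per-frame `steps`, the mixture `state` vector or `NULL`,
#'   and the generator settings).
#' @export
synthTrajectory <- function(sequence, nFrames, seed, baseSteps = NULL,
                            sd = NULL, mixture = NULL, frameInterval = 1,
                            partner = NULL) {
  bases <- strsplit(toupper(sequence), "")[[1L]]
  if (is.null(baseSteps)) baseSteps <- .meanStepsFor(bases)
  ns <- nrow(baseSteps)
  sdvec <- stats::setNames(numeric(6L), .STEP_NAMES)
  if (!is.null(sd)) {
    stopifnot(all(names(sd) %in% .STEP_NAMES), all(sd >= 0))
    sdvec[names(sd)] <- sd
  }
  if (!is.null(mixture)) {
    stopifnot(is.list(mixture$steps), length(mixture$weights) ==
                length(mixture$steps),
              abs(sum(mixture$weights) - 1) < 1e-9)
  }
  set.seed(seed)
  states <- if (is.null(mixture)) NULL
            else sample.int(length(mixture$steps), nFrames, replace = TRUE,
                            prob = mixture$weights)
  stepsList <- vector("list", nFrames)
  frames <- vector("list", nFrames)
  for (f in seq_len(nFrames)) {
    st <- if (is.null(mixture)) {
      baseSteps + matrix(stats::rnorm(ns * 6L), ns, 6L) %*% diag(sdvec)
    } else {
      mixture$steps[[states[f]]]
    }
    colnames(st) <- .STEP_NAMES
    stepsList[[f]] <- st
    frames[[f]] <- buildDuplex(paste(bases, collapse = ""), NULL, st,
                               partner = partner)
  }
  nat <- nrow(frames[[1L]]@atoms)
  coords <- array(NA_real_, c(nat, 3L, nFrames))
  for (f in seq_len(nFrames))
    coords[, , f] <- as.matrix(frames[[f]]@atoms[, c("x", "y", "z")])
  traj <- new("DuplexTrajectory", topology = frames[[1L]],
              coords = coords, frameInterval = frameInterval)
  list(trajectory = traj,
       truth = list(steps = stepsList, state = states, sd = sdvec,
                    baseSteps = baseSteps, seed = seed,
                    sequence = paste(bases, collapse = "")))
}
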