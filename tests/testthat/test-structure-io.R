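# PDB reading/writing, strand pairing, trajectories, distances.

test_that("write/read round trip preserves coordinates and identity", {
  set.seed(41)
  d <- randomDuplex("GCATTACGCAT")
  f <- tempfile(fileext = ".pdb")
  writeDuplexPDB(d, f)
  r <- readDuplexPDB(f)
  expect_length(r$duplexes, 1)
  d2 <- r$duplexes[[1]]
  expect_equal(duplexSequence(d2), duplexSequence(d))
  expect_equal(pairTypes(d2), pairTypes(d))
  expect_lt(max(abs(as.matrix(d2@atoms[, c("x", "y", "z")]) -
                    as.matrix(d@atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("modified bases survive the round trip via the alias table", {
  d <- fixtureDuplex("F28-dI")
  f <- tempfile(fileext = ".pdb")
  writeDuplexPDB(d, f)
  d2 <- readDuplexPDB(f)$duplexes[[1]]
  expect_equal(duplexSequence(d2), duplexSequence(d))
  d3 <- fixtureDuplex("F28-2AP")
  writeDuplexPDB(d3, f)
  d4 <- readDuplexPDB(f)$duplexes[[1]]
  expect_equal(pairTypes(d4), pairTypes(d3))
})

test_that("an empty or atom-free stream raises a 'no atoms' error", {
  f <- tempfile(fileext = ".pdb")
  writeLines(character(0), f)
  expect_error(readDuplexPDB(f), "no atoms")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(readDuplexPDB(f), "no atoms")
})

test_that("unknown nucleic residue names are reported by name", {
  d <- buildMeanDuplex("ACGTACG")
  f <- tempfile(fileext = ".pdb")
  writeDuplexPDB(d, f)
  txt <- readLines(f)
  txt <- sub(" DA ", " XXX", txt)  # corrupt every adenine residue name
  writeLines(txt, f)
  expect_error(readDuplexPDB(f), "XXX")
})

test_that("the highest-occupancy altloc is selected", {
  # hand-built two-atom altloc pair on a template duplex
  d <- buildMeanDuplex("ACGTACG")
  f <- tempfile(fileext = ".pdb")
  writeDuplexPDB(d, f)
  txt <- readLines(f)
  i <- grep("^ATOM.* P  ", txt)[1]
  lineA <- txt[i]
  substr(lineA, 17, 17) <- "A"
  substr(lineA, 57, 60) <- "0.40"
  lineB <- lineA
  substr(lineB, 17, 17) <- "B"
  substr(lineB, 57, 60) <- "0.60"
  substr(lineB, 31, 38) <- " 999.000"   # displaced coordinates
  writeLines(c(txt[seq_len(i - 1)], lineA, lineB,
               txt[seq.int(i + 1, length(txt))]), f)
  r <- readDuplexPDB(f)
  a <- r$duplexes[[1]]@atoms
  p1 <- a[a$strand == 1 & a$pair == 1 & a$atom == "P", ]
  expect_equal(p1$x, 999, tolerance = 1e-6)  # occupancy 0.60 wins
  expect_equal(p1$occ, 0.6, tolerance = 1e-6)
})

test_that("pairStrands pairs an ideal duplex regardless of file order", {
  d <- buildMeanDuplex(F28_SEQ)
  f <- tempfile(fileext = ".pdb")
  writeDuplexPDB(d, f)
  r <- readDuplexPDB(f)
  expect_equal(nbp(r$duplexes[[1]]), 15)
  # reverse the residue order of chain B in the file
  txt <- readLines(f)
  bLines <- which(substr(txt, 1, 4) == "ATOM" & substr(txt, 22, 22) == "B")
  blk <- txt[bLines]
  resno <- as.integer(substr(blk, 23, 26))
  txt[bLines] <- blk[order(-resno)]
  writeLines(txt, f)
  r2 <- readDuplexPDB(f)
  expect_length(r2$duplexes, 1)
  expect_equal(pairTypes(r2$duplexes[[1]]), pairTypes(d))
})

test_that("a displaced base is reported unpairable, not silently paired", {
  d <- buildMeanDuplex("ACGTACGT")
  a <- d@atoms
  move <- a$strand == 2 & a$pair == 4
  a$x[move] <- a$x[move] + 20
  s1 <- a[a$strand == 1, setdiff(names(a), c("strand", "pair"))]
  s2 <- a[a$strand == 2, setdiff(names(a), c("strand", "pair"))]
  expect_error(pairStrands(s1, s2), "cannot be paired")
  # and readDuplexPDB keeps the chains as single strands
  d@atoms <- a
  f <- tempfile(fileext = ".pdb")
  writeDuplexPDB(d, f)
  r <- readDuplexPDB(f)
  expect_length(r$duplexes, 0)
  expect_length(r$singleStrands, 2)
})

test_that("multi-model files round-trip frame by frame", {
  st <- synthTrajectory("GCATTACGC", nFrames = 20, seed = 42,
                        sd = c(twist = 3, roll = 2))
  f <- tempfile(fileext = ".pdb")
  writeTrajectoryPDB(st$trajectory, f)
  tr <- readTrajectoryPDB(f, st$trajectory@topology)
  expect_equal(nFrames(tr), 20)
  expect_lt(max(abs(tr@coords - st$trajectory@coords)), 1e-3)
})

test_that("a single-model file reads as a one-frame trajectory", {
  d <- buildMeanDuplex("GCATTACGC")
  f <- tempfile(fileext = ".pdb")
  writeDuplexPDB(d, f)
  tr <- readTrajectoryPDB(f, d)
  expect_equal(nFrames(tr), 1)
  expect_lt(max(abs(tr@coords[, , 1] -
                    as.matrix(d@atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("topology/frame atom mismatch raises an error", {
  st <- synthTrajectory("GCATTACGC", nFrames = 3, seed = 43)
  f <- tempfile(fileext = ".pdb")
  writeTrajectoryPDB(st$trajectory, f)
  wrongTopo <- buildMeanDuplex("GCATTACGCAT")
  expect_error(readTrajectoryPDB(f, wrongTopo), "atoms")
})

test_that("measureSeparation computes named-atom distances", {
  d <- buildMeanDuplex("GCATTACGC")
  expect_equal(measureSeparation(d, c("A", 1, "P"), c("A", 1, "P")), 0)
  a <- d@atoms
  i <- which(a$strand == 1 & a$pair == 1 & a$atom == "P")
  j <- which(a$strand == 1 & a$pair == 2 & a$atom == "P")
  direct <- sqrt(sum((as.numeric(a[i, c("x", "y", "z")]) -
                      as.numeric(a[j, c("x", "y", "z")]))^2))
  expect_equal(measureSeparation(d, c("A", 1, "P"), c("A", 2, "P")),
               direct, tolerance = 1e-12)
  df <- data.frame(chain = c("A", "A"), resno = c(1, 2),
                   atom = c("CA", "CA"), x = c(0, 3), y = c(0, 4),
                   z = c(0, 0))
  expect_equal(measureSeparation(df, c("A", 1, "CA"), c("A", 2, "CA")), 5)
  expect_error(measureSeparation(d, c("A", 1, "ZZ"), c("A", 2, "P")),
               "not found")
})
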