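test_that("threading is zero for a null map, linear in delta, correct sign", {
  m <- zeroGauge(randomModel(12, 5, seed = 31))
  aln <- randomAlignmentFor(m, 10, seed = 32)
  d0 <- dmapFromPairs(12, matrix(integer(), ncol = 2), numeric())
  expect_equal(threadEnergy(m, aln, d0), rep(0, 10))

  # single pair with delta = 1 and J(s_i, s_j) = -2: breaking a favourable
  # active-state contact costs +2
  h <- matrix(0, 12, 3)
  P <- 12 * 11 / 2
  J <- array(0, dim = c(P, 3, 3))
  J[pairIndex(2L, 9L, 12L), 1, 2] <- -2
  m1 <- pottsModel(h, J, alphabet = c("A", "C", "D"), gauge = "zero")
  s <- rep("D", 12); s[2] <- "A"; s[9] <- "C"
  d1 <- dmapFromPairs(12, c(2L, 9L), 1)
  expect_equal(threadEnergy(m1, paste(s, collapse = ""), d1), 2)

  d2 <- dmapFromPairs(12, c(2L, 9L), 2)
  expect_equal(threadEnergy(m1, paste(s, collapse = ""), d2), 4)
})

test_that("a raw-gauge model is transformed automatically with a warning", {
  m <- randomModel(12, 4, seed = 33)
  aln <- randomAlignmentFor(m, 5, seed = 34)
  dm <- randomDmap(12, seed = 35)
  expect_warning(e1 <- threadEnergy(m, aln, dm), "zero gauge")
  e2 <- threadEnergy(zeroGauge(m), aln, dm)
  expect_equal(e1, e2)
})

test_that("thread energies match the quadruple-loop oracle on small instances", {
  for (seed in 1:5) {
    L <- sample(8:10, 1)
    q <- sample(3:5, 1)
    m <- zeroGauge(randomModel(L, q, seed = 100 + seed))
    dm <- randomDmap(L, seed = 200 + seed)
    aln <- randomAlignmentFor(m, 6, seed = 300 + seed, gapFraction = 0.2)
    got <- threadEnergy(m, aln, dm)
    mat <- residueMatrix(aln)
    want <- vapply(seq_len(6), function(k) bruteThread(m, mat[k, ], dm),
                   numeric(1))
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("gap policy zero silences pairs containing a gap", {
  m <- zeroGauge(randomModel(12, 4, seed = 41))
  s <- rep(m@alphabet[1], 12); s[3] <- "-"
  dm <- dmapFromPairs(12, rbind(c(3L, 10L), c(2L, 11L)), c(1, 1))
  eModel <- threadEnergy(m, paste(s, collapse = ""), dm, gapPolicy = "model")
  eZero <- threadEnergy(m, paste(s, collapse = ""), dm, gapPolicy = "zero")
  # pair (2, 11) has no gap: shared contribution; (3, 10) only under "model"
  p2 <- pairIndex(2L, 11L, 12L)
  shared <- -m@J[p2, match(s[2], m@alphabet), match(s[11], m@alphabet)]
  expect_equal(eZero, shared)
  p1 <- pairIndex(3L, 10L, 12L)
  gapTerm <- -m@J[p1, match("-", m@alphabet), match(s[10], m@alphabet)]
  expect_equal(eModel, shared + gapTerm)
})

test_that("weighted bivariate marginals normalize to the class weight", {
  aln <- kinaseAlignment(c(a = "ACAC", b = "CCAC", c = "AAAC"))
  seqWeights(aln) <- c(1/2, 1/2, 1)
  f1 <- weightedBimarg(subsetAlignment(aln, 1), NULL, 1, 2)
  expect_equal(sum(f1), 1)
  expect_equal(f1["A", "C"], 1)
  f2 <- weightedBimarg(subsetAlignment(aln, 1:2), NULL, 1, 2)
  expect_equal(unname(f2["A", "C"]), 0.5)
  expect_equal(unname(f2["C", "C"]), 0.5)
  f3 <- weightedBimarg(aln, NULL, 1, 2)
  expect_equal(unname(f3["A", "C"]), 0.25)
  expect_equal(unname(f3["C", "C"]), 0.25)
  expect_equal(unname(f3["A", "A"]), 0.5)
  expect_equal(sum(f3), 1)
  expect_error(weightedBimarg(aln, "TK", 1, 2), "class")
})

test_that("divergence of a class with itself is exactly zero", {
  sc <- plantedScenario(L = 30, q = 5, nPlanted = 3, nPerClass = 40,
                        nStructures = 4, seed = 51)
  dm <- dmapFromPairs(30, as.matrix(sc$planted[, c("i", "j")]),
                      rep(1, nrow(sc$planted)))
  dv <- divergence(sc$model, sc$alignment, dm, dm,
                   classX = "STK", classY = "STK")
  expect_equal(dv@ddE, 0)
  expect_true(all(dv@ranked$ddE_ij == 0))
})

test_that("two single-sequence classes reproduce the hand difference", {
  h <- matrix(0, 12, 3)
  P <- 12 * 11 / 2
  J <- array(0, dim = c(P, 3, 3))
  p <- pairIndex(2L, 9L, 12L)
  J[p, 1, 2] <- -2   # (A, C)
  J[p, 2, 2] <- 1    # (C, C)
  m <- pottsModel(h, J, alphabet = c("A", "C", "D"), gauge = "zero")
  sX <- rep("D", 12); sX[2] <- "A"; sX[9] <- "C"
  sY <- rep("D", 12); sY[2] <- "C"; sY[9] <- "C"
  aln <- kinaseAlignment(rbind(sX, sY), ids = c("x", "y"))
  classLabels(aln) <- c("STK", "TK")
  dm <- dmapFromPairs(12, c(2L, 9L), 1)
  dv <- divergence(m, aln, dm, dm)
  expect_equal(dv@meanX, 2)    # -(-2) * 1
  expect_equal(dv@meanY, -1)   # -(1) * 1
  expect_equal(dv@ddE, 3)
  expect_equal(dv@ranked$ddE_ij, 3)
})

test_that("the pair decomposition is exact and both mean routes agree", {
  for (seed in c(61, 62)) {
    sc <- plantedScenario(L = 40, q = 6, nPlanted = 4, nPerClass = 80,
                          nStructures = 5, redundancy = 2,
                          missingFraction = 0.05, seed = seed)
    dv <- scenarioDivergence(sc)
    expect_lt(abs(sum(dv@pairMatrix[upper.tri(dv@pairMatrix)]) - dv@ddE), 1e-8)
    # independent route via weighted bivariate marginals
    dmaps <- list()
    for (cl in c("STK", "TK")) {
      both <- c(sc$structures[[cl]][["active_DFG_in"]],
                sc$structures[[cl]][["classical_DFG_out"]])
      w <- redundancyWeights(both)
      nA <- length(sc$structures[[cl]][["active_DFG_in"]])
      dmaps[[cl]] <- deltaContacts(
        ensembleFrequencies(sc$structures[[cl]][["active_DFG_in"]],
                            w[seq_len(nA)]),
        ensembleFrequencies(sc$structures[[cl]][["classical_DFG_out"]],
                            w[-seq_len(nA)]), quiet = TRUE)
    }
    mX <- meanEnergyFromBimarg(sc$model, sc$alignment, dmaps[["STK"]], "STK")
    mY <- meanEnergyFromBimarg(sc$model, sc$alignment, dmaps[["TK"]], "TK")
    expect_lt(abs(mX - dv@meanX), 1e-8)
    expect_lt(abs(mY - dv@meanY), 1e-8)
  }
})

test_that("sequence order does not affect the divergence", {
  sc <- plantedScenario(L = 30, q = 5, nPlanted = 3, nPerClass = 30,
                        nStructures = 4, seed = 71)
  dv1 <- scenarioDivergence(sc)
  set.seed(72)
  perm <- sample(nSequences(sc$alignment))
  sc$alignment <- subsetAlignment(sc$alignment, perm)
  dv2 <- scenarioDivergence(sc)
  expect_equal(dv2@ddE, dv1@ddE, tolerance = 1e-12)
  expect_equal(dv2@pairMatrix, dv1@pairMatrix, tolerance = 1e-12)
})

test_that("the ranked report is sorted with deterministic tie-breaks", {
  sc <- plantedScenario(L = 30, q = 5, nPlanted = 4, nPerClass = 40,
                        nStructures = 4, seed = 81)
  dv <- scenarioDivergence(sc)
  r <- dv@ranked
  expect_true(all(diff(r$ddE_ij) <= 1e-12))
  expect_equal(r$cumulative_fraction[nrow(r)], 1, tolerance = 1e-9)
  ties <- which(duplicated(r$ddE_ij) | duplicated(r$ddE_ij, fromLast = TRUE))
  if (length(ties) > 1)
    expect_true(all(diff(order(r$i[ties], r$j[ties])) > 0))
})
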