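test_that("FASTA parsing preserves records, folds case, rejects ragged input", {
  fa <- tempfile(fileext = ".fasta")
  write_fasta(fa, c(a = strrep("ACDEF", 10), b = strrep("ghikl", 10),
                    c = strrep("MN-P.", 10)))
  aln <- readAlignment(fa)
  expect_equal(nSequences(aln), 3L)
  expect_equal(alignmentWidth(aln), 50L)
  expect_equal(sequenceIds(aln), c("a", "b", "c"))
  # lowercase records parse to the same residues as uppercase ones
  expect_equal(unname(residueMatrix(aln)[2, 1:5]),
               c("G", "H", "I", "K", "L"))
  # "." gap normalized
  expect_true(all(residueMatrix(aln)[3, ] %in% aaAlphabet()))

  ragged <- tempfile(fileext = ".fasta")
  write_fasta(ragged, c(ok1 = strrep("A", 259), short = strrep("A", 258),
                        ok2 = strrep("C", 259)))
  expect_error(readAlignment(ragged), "short")
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(readAlignment(empty), "empty")
})

test_that("Stockholm alignments parse to the same residues as FASTA", {
  sto <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               "seqA   ACDEFGHIKL",
               "seqB   ACDE.GHIKL",
               "//"), sto)
  aln <- readAlignment(sto)
  expect_equal(nSequences(aln), 2L)
  expect_equal(unname(residueMatrix(aln)[2, 5]), "-")
})

test_that("nonstandard residue codes map to gap by default, error on request", {
  aln <- kinaseAlignment(c(s1 = "ACXBZ"))
  expect_equal(unname(residueMatrix(aln)[1, 3:5]), c("-", "-", "-"))
  expect_error(kinaseAlignment(c(s1 = "ACXBZ"), unknown = "error"),
               "nonstandard")
})

test_that("kinase classification follows the three-column rule", {
  base <- rep("G", 170)
  tk <- replace(base, c(126, 128, 165), c("A", "R", "W"))
  expect_equal(classifyKinase(tk), "TK")
  tk2 <- replace(base, c(126, 128, 165), c("R", "R", "W"))
  expect_equal(classifyKinase(tk2), "TK")
  stk <- replace(base, c(126, 128), c("K", "K"))
  expect_equal(classifyKinase(stk), "STK")
  # TK condition at 128 blocks the STK call even with Trp absent
  neither <- replace(base, c(126, 128, 165), c("K", "R", "F"))
  expect_equal(classifyKinase(neither), "other")
  gapped <- replace(base, c(126, 128, 165), c("-", "R", "W"))
  expect_equal(classifyKinase(gapped), "other")
  expect_error(classifyKinase(rep("A", 100)), "out of range")
})

test_that("classification depends only on the diagnostic columns", {
  set.seed(11)
  base <- rep("G", 170)
  for (sig in list(c("A", "R", "W"), c("K", "K", "G"), c("K", "R", "F"))) {
    s <- replace(base, c(126, 128, 165), sig)
    lab <- classifyKinase(s)
    for (rep_ in 1:20) {
      s2 <- s
      cols <- sample(setdiff(seq_len(170), c(126, 128, 165)), 30)
      s2[cols] <- sample(aaAlphabet(), 30, replace = TRUE)
      expect_equal(classifyKinase(s2), lab)
    }
  }
})

test_that("gatekeeper size classes match the printed sets, Asp resolves small", {
  expect_equal(gatekeeperClass("T"), "small")
  expect_equal(gatekeeperClass("M"), "large")
  expect_equal(gatekeeperClass(c("G", "V", "F", "E")),
               c("small", "small", "large", "large"))
  expect_equal(gatekeeperClass("D"), "small")   # volume 91 < 110
  expect_equal(gatekeeperClass("-"), "unclassifiable")
  expect_equal(gatekeeperClass("X"), "unclassifiable")
})

test_that("gap filtering retains at most maxGaps gaps and is idempotent", {
  mk <- function(ngap) paste0(strrep("-", ngap), strrep("A", 40 - ngap))
  aln <- kinaseAlignment(c(g32 = mk(32), g31 = mk(31), g0 = mk(0)))
  f <- filterGapped(aln, maxGaps = 31)
  expect_equal(sequenceIds(f), c("g31", "g0"))
  expect_equal(sequenceIds(filterGapped(f, 31)), sequenceIds(f))
  clean <- kinaseAlignment(c(a = strrep("A", 40), b = strrep("C", 40)))
  expect_equal(residueMatrix(filterGapped(clean)), residueMatrix(clean))
})

test_that("phylogenetic weights count identity neighbours within a class", {
  s <- strrep("ACDEFGHIKL", 4)
  far <- strrep("WYWYWYWYWY", 4)
  aln <- kinaseAlignment(c(a = s, b = s, c = s, d = far))
  w <- phyloWeights(aln, byClass = FALSE)
  expect_equal(unname(w), c(1/3, 1/3, 1/3, 1))
  expect_equal(sum(w), 2)  # N_eff: one cluster of 3 plus one singleton

  # all mutually distant: unit weights
  aln2 <- kinaseAlignment(c(a = strrep("A", 20), b = strrep("C", 20),
                            c = strrep("D", 20)))
  expect_equal(unname(phyloWeights(aln2, byClass = FALSE)), c(1, 1, 1))

  # 2 identical + 1 distant: brute-force expected (1/2, 1/2, 1)
  aln3 <- kinaseAlignment(c(x = s, y = s, z = far))
  expect_equal(unname(phyloWeights(aln3, byClass = FALSE)), c(0.5, 0.5, 1))
})

test_that("weights are permutation-equivariant and class N_eff sums to <= N", {
  set.seed(7)
  mat <- matrix(sample(c("A", "C", "D"), 12 * 30, replace = TRUE), 12)
  mat[7:9, ] <- mat[rep(7, 3), ]  # a redundant cluster
  aln <- kinaseAlignment(mat)
  classLabels(aln) <- rep(c("TK", "STK", "other"), each = 4)
  w <- phyloWeights(aln)
  perm <- sample(12)
  alnP <- subsetAlignment(aln, perm)
  expect_equal(unname(phyloWeights(alnP)), unname(w[perm]))
  aln <- addPhyloWeights(aln)
  expect_lte(sum(effectiveN(aln, byClass = TRUE)), nSequences(aln))
})

test_that("near-identical sequences at the 40 percent divergence boundary", {
  # 20 columns; 12 matches = 60% identity -> neighbours at the default
  a <- strrep("A", 20)
  b <- paste0(strrep("A", 12), strrep("C", 8))   # identity 0.60
  c_ <- paste0(strrep("A", 11), strrep("C", 9))  # identity 0.55
  aln <- kinaseAlignment(c(a = a, b = b, c = c_))
  w <- phyloWeights(aln, byClass = FALSE)
  expect_equal(unname(w[1]), 1/2)  # a ~ b but a !~ c
  # c neighbours b? identity(b, c) = 19/20 -> yes
  expect_equal(unname(w[3]), 1/2)
})

test_that("classification table reports gatekeeper and weight columns", {
  base <- strrep("G", 170)
  aln <- kinaseAlignment(c(k1 = base, k2 = base))
  aln <- classifyKinases(aln)
  aln <- addPhyloWeights(aln)
  tab <- classificationTable(aln, gatekeeperColumn = 10)
  expect_named(tab, c("id", "class", "n_gaps", "weight",
                      "gatekeeper_residue", "gatekeeper_class"))
  expect_equal(tab$gatekeeper_class, c("small", "small"))
  expect_equal(tab$weight, c(0.5, 0.5))
})
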