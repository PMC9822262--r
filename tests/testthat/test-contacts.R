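# Geometry fixtures: three residues with hand-placed side-chain atoms.
# Residues 1, 2, 3 map to MSA columns 10, 14, 40:
#   col 10 vs col 40 (separation 30): nearest atoms tunable
#   col 10 vs col 14 (separation 4): always excluded by the |i-j| > 4 rule
geomAtoms <- function(dx) {
  data.frame(
    resno = c(1L, 1L, 2L, 3L, 3L),
    resid = c("LEU", "LEU", "ALA", "PHE", "PHE"),
    elety = c("CB", "CG", "CB", "CB", "CG"),
    x = c(0, 1, 0.5, dx, dx + 3),
    y = 0, z = 0)
}
geomMap <- c(`1` = 10L, `2` = 14L, `3` = 40L)

test_that("contact cutoff is strict and the sequence-separation rule applies", {
  # nearest atoms at 5.99: contact
  cm <- contactMap(geomAtoms(1 + 5.99), geomMap)
  expect_equal(nrow(cm), 1L)
  expect_equal(unname(cm[1, ]), c(10L, 40L))
  # exactly 6.00: no contact (strict inequality)
  cm <- contactMap(geomAtoms(1 + 6.0), geomMap)
  expect_equal(nrow(cm), 0L)
  # residues 1 and 2 are 0.5 apart but |10 - 14| = 4: never a contact
  cm <- contactMap(geomAtoms(100), geomMap)
  expect_equal(nrow(cm), 0L)
})

test_that("contact maps are invariant to atom order and rigid motion", {
  at <- geomAtoms(1 + 5.5)
  ref <- contactMap(at, geomMap)
  shuffled <- at[c(4, 2, 5, 1, 3), ]
  expect_equal(contactMap(shuffled, geomMap), ref)
  # rotate 90 degrees about z and translate
  rot <- at
  rot$x2 <- -at$y + 7; rot$y <- at$x - 3; rot$x <- rot$x2; rot$x2 <- NULL
  rot$z <- at$z + 11
  expect_equal(contactMap(rot, geomMap), ref)
})

test_that("glycine contributes contacts through its C-alpha proxy only when enabled", {
  at <- data.frame(
    resno = c(1L, 2L),
    resid = c("GLY", "LEU"),
    elety = c("CA", "CB"),
    x = c(0, 3), y = 0, z = 0)
  map <- c(`1` = 1L, `2` = 20L)
  expect_equal(nrow(contactMap(at, map)), 1L)
  expect_equal(nrow(contactMap(at, map, glycineCA = FALSE)), 0L)
})

test_that("PDB files read through bio3d give the same contacts", {
  at <- geomAtoms(1 + 5.9)
  f <- tempfile(fileext = ".pdb")
  writeTinyPDB(f, at)
  sc <- readStructureContacts(f, chain = "A", columnMap = geomMap,
                              uniprotId = "P1", state = "active_DFG_in",
                              classLabel = "TK", L = 50)
  expect_s4_class(sc, "StructureContacts")
  expect_equal(unname(sc@contacts), matrix(c(10L, 40L), 1))
  expect_setequal(sc@resolved, c(10L, 14L, 40L))
})

test_that("redundancy weights are 1 over the UniProt count across both clusters", {
  mk <- function(id, uni, state) structureContacts(
    id, "A", uni, state, "TK", 50, matrix(integer(), ncol = 2), 1:50)
  ss <- list(mk("a1", "P1", "active_DFG_in"),
             mk("a2", "P1", "active_DFG_in"),
             mk("a3", "P1", "active_DFG_in"),
             mk("b1", "P1", "classical_DFG_out"),
             mk("a4", "P2", "active_DFG_in"))
  w <- redundancyWeights(ss)
  expect_equal(w, c(1/4, 1/4, 1/4, 1/4, 1))
  ss2 <- list(mk("x", "P1", "active_DFG_in"), mk("y", "P2", "active_DFG_in"))
  expect_equal(redundancyWeights(ss2), c(1, 1))
  ss3 <- list(mk("x", "P3", "active_DFG_in"), mk("y", "P3", "active_DFG_in"))
  expect_equal(redundancyWeights(ss3), c(1/2, 1/2))
  ss4 <- list(mk("x", "", "active_DFG_in"), mk("y", "", "active_DFG_in"))
  expect_warning(w4 <- redundancyWeights(ss4), "UniProt")
  expect_equal(w4, c(1, 1))
  expect_error(redundancyWeights(ss4, missingId = "error"), "UniProt")
})

test_that("ensemble frequencies implement the weighted per-pair average", {
  mk <- function(id, contacts, resolved = 1:50) structureContacts(
    id, "A", id, "active_DFG_in", "TK", 50, contacts, resolved)
  one <- mk("s1", matrix(c(10L, 40L), 1))
  e1 <- ensembleFrequencies(list(one))
  expect_equal(e1@cfreq[10, 40], 1)
  expect_equal(e1@cfreq[11, 40], 0)
  expect_true(is.na(e1@cfreq[10, 13]))  # |i-j| <= 4 outside the definition

  two <- list(mk("s1", matrix(c(10L, 40L), 1)),
              mk("s2", matrix(integer(), ncol = 2)))
  e2 <- ensembleFrequencies(two)
  expect_equal(e2@cfreq[10, 40], 0.5)

  # weights (1/2, 1/2, 1), contact only in the weight-1 chain:
  # c = 1 / (1/2 + 1/2 + 1) = 0.5
  three <- list(mk("s1", matrix(integer(), ncol = 2)),
                mk("s2", matrix(integer(), ncol = 2)),
                mk("s3", matrix(c(10L, 40L), 1)))
  e3 <- ensembleFrequencies(three, weights = c(1/2, 1/2, 1))
  expect_equal(e3@cfreq[10, 40], 0.5)
  expect_error(ensembleFrequencies(list()), "empty")
})

test_that("per-pair normalization excludes unresolved residues from both sums", {
  mk <- function(id, contacts, resolved) structureContacts(
    id, "A", id, "active_DFG_in", "TK", 50, contacts, resolved)
  # chain s2 does not resolve column 10, so the pair (10, 40) is supported
  # only by s1 where it is in contact: c = 1 under per-pair normalization
  ss <- list(mk("s1", matrix(c(10L, 40L), 1), 1:50),
             mk("s2", matrix(integer(), ncol = 2), setdiff(1:50, 10L)))
  e <- ensembleFrequencies(ss)
  expect_equal(e@cfreq[10, 40], 1)
  # global mode keeps the full denominator instead
  eg <- ensembleFrequencies(ss, normalization = "global")
  expect_equal(eg@cfreq[10, 40], 0.5)
  # a column resolved nowhere leaves its pairs without support
  ss2 <- list(mk("s1", matrix(integer(), ncol = 2), setdiff(1:50, 10L)))
  e2 <- ensembleFrequencies(ss2)
  expect_true(all(is.na(e2@cfreq[10, ])))
})

test_that("duplicating every chain with recomputed weights leaves c unchanged", {
  set.seed(21)
  base <- makeStructures("TK", "active_DFG_in", 4, 40,
                         plantedContacts = rbind(c(5L, 30L), c(10L, 22L)),
                         seed = 22)
  w <- redundancyWeights(base)
  e <- ensembleFrequencies(base, w)
  dup <- c(base, base, base)
  wd <- redundancyWeights(dup)
  expect_equal(wd, rep(w / 3, 3))
  ed <- ensembleFrequencies(dup, wd)
  expect_equal(ed@cfreq, e@cfreq)
})

test_that("delta maps difference active minus inactive with checks", {
  mk <- function(id, contacts, state, cl = "TK") structureContacts(
    id, "A", id, state, cl, 50, contacts, 1:50)
  act <- ensembleFrequencies(list(mk("a", matrix(c(10L, 40L), 1),
                                     "active_DFG_in")))
  ina <- ensembleFrequencies(list(mk("b", matrix(integer(), ncol = 2),
                                     "classical_DFG_out")))
  d <- deltaContacts(act, ina, quiet = TRUE)
  expect_equal(d@delta[10, 40], 1)   # contact lost on going to DFG-out
  expect_equal(d@delta[40, 10], 1)
  expect_equal(sum(d@delta != 0), 2)
  # identical ensembles: all-zero map
  d0 <- deltaContacts(act,
    ensembleFrequencies(list(mk("c", matrix(c(10L, 40L), 1),
                                "classical_DFG_out"))), quiet = TRUE)
  expect_true(all(d0@delta == 0))
  # swapping the roles negates every entry
  actSwap <- ensembleFrequencies(list(mk("d", matrix(integer(), ncol = 2),
                                         "active_DFG_in")))
  inaSwap <- ensembleFrequencies(list(mk("e", matrix(c(10L, 40L), 1),
                                         "classical_DFG_out")))
  dSwap <- deltaContacts(actSwap, inaSwap, quiet = TRUE)
  expect_equal(dSwap@delta, -d@delta)
  # mismatched class labels are a hard error
  inaSTK <- ensembleFrequencies(list(mk("f", matrix(integer(), ncol = 2),
                                        "classical_DFG_out", "STK")))
  expect_error(deltaContacts(act, inaSTK), "class")
  expect_error(deltaContacts(ina, act), "order")
})

test_that("ensemble tables round-trip frequencies and deltas", {
  mk <- function(id, contacts, state) structureContacts(
    id, "A", id, state, "TK", 30, contacts, 1:30)
  act <- ensembleFrequencies(list(mk("a", rbind(c(5L, 20L), c(6L, 25L)),
                                     "active_DFG_in")))
  ina <- ensembleFrequencies(list(mk("b", matrix(c(5L, 20L), 1),
                                     "classical_DFG_out")))
  f <- tempfile(fileext = ".tsv")
  df <- writeEnsembleTable(act, ina, f)
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(df))
  row <- back[back$i == 6 & back$j == 25, ]
  expect_equal(row$delta, 1)
  expect_equal(as.numeric(row$c_active), 1)
})
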