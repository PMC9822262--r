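#' @include threading.R contacts.R alignment.R
NULL

# Derive a bounded substream seed from a master seed and a stream index.
substreamSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103L + stream * 12345L) %% 2147483629)
}

# Admissible planted pairs: |i-j| > 4, spread across the alignment,
# deterministic given the RNG state.
choosePlantedPairs <- function(L, nPlanted) {
  cand <- which(upper.tri(matrix(0, L, L)) &
                (col(matrix(0, L, L)) - row(matrix(0, L, L)) > 4),
                arr.ind = TRUE)
  if (nPlanted > nrow(cand))
    stop(sprintf("cannot plant %d pairs: only %d pairs with |i-j| > 4 at L = %d",
                 nPlanted, nrow(cand), L))
  sel <- sample.int(nrow(cand), nPlanted)
  m <- cand[sel, , drop = FALSE]
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Ground-truth Potts model with planted conformation-sensitive couplings
#'
#' Background couplings and fields are small-magnitude Gaussian noise; a
#' chosen set of |i-j| > 4 pairs receives structured coupling blocks of
#' magnitude \code{contrast}: one designated state pair is strongly
#' favourable (coupling \code{-contrast}, a stabilizing coevolutionary
#' interaction in the active conformation) and one alternative state pair
#' is strongly unfavourable (\code{+contrast}).  The model is returned in
#' the zero gauge.  With \code{contrast = 0} the planted pairs are
#' statistically indistinguishable from background.
#'
#' @param L alignment width (>= 10).
#' @param q number of states (alphabet taken as the first q - 1 amino-acid
#'   letters of \code{c("A","R","K","W","G","E","D","T",...)} plus the gap,
#'   so the class-signature letters exist at any q >= 6).
#' @param nPlanted number of planted pairs.
#' @param contrast planted coupling magnitude (statistical-energy units).
#' @param seed integer RNG seed.
#' @param sdBackground background coupling noise sd (default 0.02).
#' @param sdField field noise sd (default 0.1).
#' @return list with \code{model} (zero-gauge \code{PottsModel}) and
#'   \code{planted}: data.frame i, j, aStar, bStar (favoured state pair),
#'   aAlt, bAlt (disfavoured state pair).
#' @export
makePotts <- function(L, q = 6L, nPlanted = 5L, contrast = 2, seed = 1L,
                      sdBackground = 0.02, sdField = 0.1) {
  stopifnot(L >= 10, q >= 4)
  set.seed(seed)
  letters21 <- c("A", "R", "K", "W", "G", "E", "D", "T", "S", "P", "V", "I",
                 "L", "M", "F", "Y", "N", "Q", "H", "C")
  alphabet <- c(letters21[seq_len(q - 1L)], "-")
  P <- L * (L - 1L) / 2L
  J <- array(rnorm(P * q * q, sd = sdBackground), dim = c(P, q, q))
  h <- matrix(rnorm(L * q, sd = sdField), L, q)
  planted <- choosePlantedPairs(L, nPlanted)
  aStar <- sample.int(q - 1L, nPlanted, replace = TRUE)
  bStar <- sample.int(q - 1L, nPlanted, replace = TRUE)
  aAlt <- (aStar %% (q - 1L)) + 1L
  bAlt <- (bStar %% (q - 1L)) + 1L
  for (k in seq_len(nPlanted)) {
    p <- pairIndex(planted[k, 1], planted[k, 2], L)
    J[p, aStar[k], bStar[k]] <- -contrast
    J[p, aAlt[k], bAlt[k]] <- contrast
  }
  model <- zeroGauge(pottsModel(h, J, alphabet = alphabet))
  list(model = model,
       planted = data.frame(i = planted[, 1], j = planted[, 2],
                            aStar = aStar, bStar = bStar,
                            aAlt = aAlt, bAlt = bAlt))
}

#' Synthetic structural ensemble as contact maps
#'
#' Generates \code{n} structure records for one class and state directly as
#' contact maps (no coordinates; the geometric contact operator is
#' exercised separately on coordinate fixtures).  Active-state maps contain
#' \code{plantedContacts}; maps of the other state have the \code{flipSet}
#' pairs toggled, so with no masking the contact difference is exactly +1
#' on flipped pairs and 0 elsewhere.  A shared background contact set
#' (present in both states) is added for realism.  \code{redundancy}
#' repeats pseudo-UniProt IDs to exercise the 1/u down-weighting;
#' \code{missingFraction} masks random columns per structure to exercise
#' per-pair normalization.
#'
#' @param classLabel "TK" or "STK".
#' @param state "active_DFG_in" or "classical_DFG_out".
#' @param n number of chains.
#' @param L alignment width.
#' @param plantedContacts integer matrix m x 2 of planted pairs.
#' @param flipSet integer matrix of pairs whose contact state differs
#'   between conformations (default: the planted pairs).
#' @param nBackground number of shared background contacts (default 15).
#' @param redundancy chains per pseudo-UniProt ID (default 1).
#' @param missingFraction fraction of columns masked per structure.
#' @param seed integer RNG seed.
#' @return list of \code{\linkS4class{StructureContacts}}.
#' @export
makeStructures <- function(classLabel, state, n, L, plantedContacts,
                           flipSet = plantedContacts, nBackground = 15L,
                           redundancy = 1L, missingFraction = 0, seed = 1L) {
  base <- matrix(as.integer(plantedContacts), ncol = 2)
  flip <- matrix(as.integer(flipSet), ncol = 2)
  # background contacts shared by both states of a class must not depend on
  # the per-call seed, otherwise they would differ between states and leak
  # into the contact difference; derive them from the class label and L
  set.seed(substreamSeed(sum(utf8ToInt(classLabel)) + L, 0L))
  bg <- choosePlantedPairs(L, nBackground)
  set.seed(seed)
  bg <- bg[!(paste(bg[, 1], bg[, 2]) %in%
             c(paste(base[, 1], base[, 2]), paste(flip[, 1], flip[, 2]))), ,
           drop = FALSE]
  active <- state == "active_DFG_in"
  contacts0 <- rbind(base, bg)
  if (!active) {
    keys <- paste(contacts0[, 1], contacts0[, 2])
    fkeys <- paste(flip[, 1], flip[, 2])
    drop <- keys %in% fkeys
    add <- flip[!(fkeys %in% keys), , drop = FALSE]
    contacts0 <- rbind(contacts0[!drop, , drop = FALSE], add)
  }
  uni <- rep(sprintf("UP%s%03d", substr(classLabel, 1, 1),
                     seq_len(ceiling(n / redundancy))),
             each = redundancy)[seq_len(n)]
  out <- vector("list", n)
  tag <- if (active) "act" else "out"
  for (k in seq_len(n)) {
    resolved <- seq_len(L)
    if (missingFraction > 0) {
      nm <- round(missingFraction * L)
      if (nm > 0) resolved <- sort(sample.int(L, L - nm))
    }
    keep <- contacts0[, 1] %in% resolved & contacts0[, 2] %in% resolved
    out[[k]] <- structureContacts(
      structureId = sprintf("%s_%s_%03d", classLabel, tag, k),
      chain = "A", uniprotId = uni[k], state = state,
      classLabel = classLabel, L = L,
      contacts = contacts0[keep, , drop = FALSE], resolved = resolved)
  }
  out
}

#' Two-class synthetic alignment with controllable marginal divergence
#'
#' Gibbs-samples sequences from the model, then (a) overwrites the
#' class-diagnostic columns with a TK signature for half the sequences and
#' an STK signature for the other half, so \code{\link{classifyKinase}}
#' recovers the intended labels for every sequence, and (b) biases the
#' planted pair columns: with probability \code{marginalShift} an STK
#' sequence gets the favoured state pair (strong negative coupling — an
#' active-state contact it will be penalized for breaking) and a TK
#' sequence gets the disfavoured alternative pair.  With
#' \code{marginalShift = 0} the classes are exchangeable apart from the
#' diagnostic columns.
#'
#' @param model a \code{PottsModel} from \code{\link{makePotts}}.
#' @param planted the planted-pair data.frame from \code{\link{makePotts}}.
#' @param nPerClass sequences per class.
#' @param diagnosticColumns three MSA columns carrying the class signature;
#'   they must avoid the planted pairs.
#' @param tkSignature,stkSignature length-3 residue vectors satisfying the
#'   TK and STK classification predicates (checked).
#' @param marginalShift bias probability in [0, 1].
#' @param seed integer RNG seed.
#' @param burnIn,thin Gibbs sampler controls.
#' @return a classified \code{KinaseAlignment} (STKs first), unit weights.
#' @export
makeTwoClassMSA <- function(model, planted, nPerClass,
                            diagnosticColumns = c(10L, 12L, 20L),
                            tkSignature = c("A", "R", "W"),
                            stkSignature = c("K", "K", "A"),
                            marginalShift = 0.8, seed = 1L,
                            burnIn = 100L, thin = 2L) {
  sig <- c(tkSignature, stkSignature)
  if (!all(sig %in% model@alphabet))
    stop("signature letters not in the model alphabet: ",
         paste(setdiff(sig, model@alphabet), collapse = ", "))
  if (classifyKinase(replace(rep("A", model@L), diagnosticColumns, tkSignature),
                     positions = diagnosticColumns) != "TK")
    stop("tkSignature does not satisfy the TK classification predicate")
  if (classifyKinase(replace(rep("A", model@L), diagnosticColumns, stkSignature),
                     positions = diagnosticColumns) != "STK")
    stop("stkSignature does not satisfy the STK classification predicate")
  aln <- gibbsSample(model, 2L * nPerClass, burnIn = burnIn, thin = thin,
                     seed = substreamSeed(seed, 2L))
  mat <- residueMatrix(aln)
  set.seed(substreamSeed(seed, 3L))
  stkRows <- seq_len(nPerClass)
  tkRows <- nPerClass + seq_len(nPerClass)
  alphabet <- model@alphabet
  for (k in seq_len(nrow(planted))) {
    i <- planted$i[k]; j <- planted$j[k]
    hit <- runif(nPerClass) < marginalShift
    mat[stkRows[hit], i] <- alphabet[planted$aStar[k]]
    mat[stkRows[hit], j] <- alphabet[planted$bStar[k]]
    hit <- runif(nPerClass) < marginalShift
    mat[tkRows[hit], i] <- alphabet[planted$aAlt[k]]
    mat[tkRows[hit], j] <- alphabet[planted$bAlt[k]]
  }
  # signatures last: classification must recover the intended labels even
  # if a planted pair happens to share a diagnostic column
  mat[stkRows, diagnosticColumns] <- matrix(stkSignature, nPerClass, 3,
                                            byrow = TRUE)
  mat[tkRows, diagnosticColumns] <- matrix(tkSignature, nPerClass, 3,
                                           byrow = TRUE)
  ids <- c(sprintf("STK%04d", seq_len(nPerClass)),
           sprintf("TK%04d", seq_len(nPerClass)))
  out <- kinaseAlignment(mat, ids = ids)
  classifyKinases(out, positions = diagnosticColumns)
}

#' A complete planted-divergence scenario
#'
#' Bundles the ground-truth model, the two-class alignment, and synthetic
#' structural ensembles for both classes and states, all derived from one
#' master seed through named substreams.  Regenerating with the same seed
#' reproduces every artifact exactly.  By construction the contact
#' difference is +1 exactly on the planted pairs and 0 elsewhere, STK
#' sequences are enriched in state pairs with strongly favourable
#' active-state couplings, and the expected class divergence
#' (STK minus TK) is positive.
#'
#' @param L,q,nPlanted,contrast see \code{\link{makePotts}}.
#' @param nPerClass sequences per class.
#' @param marginalShift planted-pair bias, see \code{\link{makeTwoClassMSA}}.
#' @param nStructures chains per class/state ensemble.
#' @param redundancy chains per pseudo-UniProt ID.
#' @param missingFraction masked-column fraction per structure.
#' @param seed master seed; all substreams derive from it.
#' @param weights if TRUE (default) phylogenetic weights are computed.
#' @return list with elements \code{model}, \code{planted},
#'   \code{alignment}, \code{structures} (nested list
#'   \code{[class][state]}), \code{expectedSign} (+1), \code{seed}.
#' @export
plantedScenario <- function(L = 60L, q = 6L, nPlanted = 5L, contrast = 2,
                            nPerClass = 500L, marginalShift = 0.8,
                            nStructures = 8L, redundancy = 1L,
                            missingFraction = 0, seed = 1L, weights = TRUE) {
  mp <- makePotts(L, q, nPlanted, contrast, seed = substreamSeed(seed, 1L))
  aln <- makeTwoClassMSA(mp$model, mp$planted, nPerClass,
                         marginalShift = marginalShift, seed = seed)
  if (weights) aln <- addPhyloWeights(aln)
  pc <- as.matrix(mp$planted[, c("i", "j")])
  structures <- list()
  stream <- 10L
  for (cl in c("STK", "TK")) {
    structures[[cl]] <- list()
    for (st in c("active_DFG_in", "classical_DFG_out")) {
      stream <- stream + 1L
      structures[[cl]][[st]] <- makeStructures(
        cl, st, nStructures, L, plantedContacts = pc,
        redundancy = redundancy, missingFraction = missingFraction,
        seed = substreamSeed(seed, stream))
    }
  }
  list(model = mp$model, planted = mp$planted, alignment = aln,
       structures = structures, expectedSign = 1, seed = seed)
}

#' Run the threading analysis on a planted scenario
#'
#' Computes redundancy weights and ensemble contact frequencies per class,
#' the class delta maps, and the full divergence decomposition (STK minus
#' TK).
#'
#' @param scenario output of \code{\link{plantedScenario}}.
#' @param gapPolicy see \code{\link{threadEnergy}}.
#' @return a \code{\linkS4class{DivergenceResult}}.
#' @export
scenarioDivergence <- function(scenario, gapPolicy = "model") {
  dmaps <- lapply(scenario$structures, function(byState) {
    both <- c(byState[["active_DFG_in"]], byState[["classical_DFG_out"]])
    w <- redundancyWeights(both)
    nA <- length(byState[["active_DFG_in"]])
    act <- ensembleFrequencies(byState[["active_DFG_in"]], w[seq_len(nA)])
    ina <- ensembleFrequencies(byState[["classical_DFG_out"]],
                               w[-seq_len(nA)])
    deltaContacts(act, ina, quiet = TRUE)
  })
  divergence(scenario$model, scenario$alignment,
             dmapX = dmaps[["STK"]], dmapY = dmaps[["TK"]],
             classX = "STK", classY = "TK", gapPolicy = gapPolicy)
}
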