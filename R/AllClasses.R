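#' @include kinthread-package.R
NULL

#' KinaseAlignment: a fixed-width alignment of kinase catalytic domains
#'
#' Holds N aligned sequences of identical width L over the 21-symbol
#' alphabet (20 amino acids + gap), together with per-sequence class labels
#' (\code{"TK"}, \code{"STK"} or \code{"other"}), phylogenetic down-weights
#' in (0, 1], and free-form metadata.  The effective number of sequences
#' N_eff is the sum of the weights.
#'
#' @slot ids character vector of sequence identifiers (unique).
#' @slot residues character matrix, N rows x L columns, uppercase symbols.
#' @slot classLabel character vector, one of \code{"TK"}, \code{"STK"},
#'   \code{"other"} per sequence.
#' @slot weight numeric vector in (0, 1].
#' @slot metadata character vector of free-form annotations.
#'
#' @exportClass KinaseAlignment
setClass("KinaseAlignment",
  representation(
    ids = "character",
    residues = "matrix",
    classLabel = "character",
    weight = "numeric",
    metadata = "character"
  )
)

setValidity("KinaseAlignment", function(object) {
  n <- length(object@ids)
  msgs <- character()
  if (nrow(object@residues) != n)
    msgs <- c(msgs, "number of rows in 'residues' must match 'ids'")
  if (anyDuplicated(object@ids))
    msgs <- c(msgs, "sequence ids must be unique")
  bad <- !(object@residues %in% aaAlphabet())
  if (any(bad))
    msgs <- c(msgs, sprintf("%d residue symbols outside the 21-letter alphabet", sum(bad)))
  if (length(object@classLabel) != n ||
      !all(object@classLabel %in% c("TK", "STK", "other")))
    msgs <- c(msgs, "classLabel must be TK/STK/other, one per sequence")
  if (length(object@weight) != n || any(object@weight <= 0) || any(object@weight > 1))
    msgs <- c(msgs, "weights must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' PottsModel: fields and couplings over L alignment columns
#'
#' The statistical energy of a sequence S is
#' \eqn{H(S) = \sum_{i<j} J_{ij}(s_i, s_j) + \sum_i h_i(s_i) + \mathrm{offset}},
#' with lower H more probable (\eqn{P(S) \propto e^{-H(S)}}).  Couplings are
#' stored for unordered pairs i < j in lexicographic order as a P x q x q
#' array with P = L(L-1)/2.  The \code{offset} slot carries the scalar
#' absorbed by gauge transformations so H is preserved exactly.
#'
#' @slot L integer, number of alignment columns.
#' @slot q integer, number of states (21 for the full alphabet).
#' @slot alphabet character vector of length q mapping states to symbols.
#' @slot h numeric matrix L x q of fields.
#' @slot J numeric array P x q x q of couplings, pairs lexicographic i < j.
#' @slot offset numeric scalar absorbed by gauge fixing (0 for raw models).
#' @slot gauge character, \code{"raw"} or \code{"zero"}.
#'
#' @exportClass PottsModel
setClass("PottsModel",
  representation(
    L = "integer",
    q = "integer",
    alphabet = "character",
    h = "matrix",
    J = "array",
    offset = "numeric",
    gauge = "character"
  )
)

setValidity("PottsModel", function(object) {
  L <- object@L; q <- object@q
  msgs <- character()
  P <- L * (L - 1L) / 2L
  if (length(object@alphabet) != q)
    msgs <- c(msgs, "alphabet length must equal q")
  if (anyDuplicated(object@alphabet))
    msgs <- c(msgs, "alphabet symbols must be unique")
  if (!all(dim(object@h) == c(L, q)))
    msgs <- c(msgs, "h must be L x q")
  if (!all(dim(object@J) == c(P, q, q)))
    msgs <- c(msgs, "J must be P x q x q with P = L(L-1)/2")
  if (length(object@offset) != 1L || !is.finite(object@offset))
    msgs <- c(msgs, "offset must be a finite scalar")
  if (!object@gauge %in% c("raw", "zero"))
    msgs <- c(msgs, "gauge must be 'raw' or 'zero'")
  if (length(msgs)) msgs else TRUE
})

#' StructureContacts: one chain's residue contacts in MSA column space
#'
#' A structure record reduced to what threading needs: the set of residue
#' pairs in contact (nearest side-chain heavy atoms under the distance
#' cutoff, MSA separation |i-j| > 4) and the set of MSA columns that are
#' resolved in the chain.  Produced either from coordinates via
#' \code{\link{contactMap}} or directly by the synthetic generator.
#'
#' @slot structureId character, e.g. PDB id.
#' @slot chain character chain identifier.
#' @slot uniprotId character accession ("" if unknown).
#' @slot state character, \code{"active_DFG_in"} or \code{"classical_DFG_out"}.
#' @slot classLabel character, \code{"TK"} or \code{"STK"}.
#' @slot L integer alignment width.
#' @slot contacts integer matrix m x 2 of column pairs, i < j, |i-j| > 4.
#' @slot resolved integer vector of resolved MSA columns.
#'
#' @exportClass StructureContacts
setClass("StructureContacts",
  representation(
    structureId = "character",
    chain = "character",
    uniprotId = "character",
    state = "character",
    classLabel = "character",
    L = "integer",
    contacts = "matrix",
    resolved = "integer"
  )
)

setValidity("StructureContacts", function(object) {
  msgs <- character()
  if (!object@state %in% c("active_DFG_in", "classical_DFG_out"))
    msgs <- c(msgs, "state must be active_DFG_in or classical_DFG_out")
  if (!object@classLabel %in% c("TK", "STK"))
    msgs <- c(msgs, "classLabel must be TK or STK")
  ct <- object@contacts
  if (ncol(ct) != 2L)
    msgs <- c(msgs, "contacts must have two columns")
  if (nrow(ct)) {
    if (any(ct[, 1] >= ct[, 2]))
      msgs <- c(msgs, "contact pairs must satisfy i < j")
    if (any(ct[, 2] - ct[, 1] <= 4L))
      msgs <- c(msgs, "contact pairs must satisfy |i - j| > 4")
    if (any(ct < 1L) || any(ct > object@L))
      msgs <- c(msgs, "contact columns out of range 1..L")
    if (!all(ct %in% object@resolved))
      msgs <- c(msgs, "contact columns must be resolved")
  }
  if (any(object@resolved < 1L) || any(object@resolved > object@L) ||
      anyDuplicated(object@resolved))
    msgs <- c(msgs, "resolved must be unique columns in 1..L")
  if (length(msgs)) msgs else TRUE
})

#' ConformationEnsemble: weighted contact frequencies for one state
#'
#' Per-pair weighted contact frequencies \eqn{c_{ij}} over the structures of
#' one conformational state (per class), with per-pair normalization: both
#' numerator and denominator run only over structures in which columns i and
#' j are both resolved.  Pairs with zero resolved support are NA in
#' \code{cfreq} and flagged in \code{support}.
#'
#' @slot classLabel character, "TK" or "STK".
#' @slot state character conformational state.
#' @slot cfreq numeric L x L symmetric matrix; NA where |i-j| <= 4 or no support.
#' @slot support numeric L x L matrix of summed weights backing each pair.
#' @slot nStructures integer number of contributing chains.
#'
#' @exportClass ConformationEnsemble
setClass("ConformationEnsemble",
  representation(
    classLabel = "character",
    state = "character",
    cfreq = "matrix",
    support = "matrix",
    nStructures = "integer"
  )
)

setValidity("ConformationEnsemble", function(object) {
  msgs <- character()
  cf <- object@cfreq
  if (nrow(cf) != ncol(cf))
    msgs <- c(msgs, "cfreq must be square")
  v <- cf[!is.na(cf)]
  if (length(v) && (any(v < 0) || any(v > 1)))
    msgs <- c(msgs, "contact frequencies must lie in [0, 1]")
  if (any(abs(cf - t(cf)) > 1e-12, na.rm = TRUE))
    msgs <- c(msgs, "cfreq must be symmetric")
  if (length(msgs)) msgs else TRUE
})

#' DeltaContactMap: contact-frequency difference active minus inactive
#'
#' Elementwise \eqn{\Delta c_{ij} = c^{A}_{ij} - c^{B}_{ij}} for one kinase
#' class, A the active DFG-in ensemble and B the classical DFG-out ensemble.
#' Undefined pairs (no resolved support in either ensemble) are set to 0 and
#' counted in \code{nUndefined}.
#'
#' @slot classLabel character class the map belongs to.
#' @slot delta numeric L x L matrix in [-1, 1]; 0 where |i-j| <= 4.
#' @slot orientation character, fixed "active_minus_inactive".
#' @slot nUndefined integer count of pairs with no support in either ensemble.
#'
#' @exportClass DeltaContactMap
setClass("DeltaContactMap",
  representation(
    classLabel = "character",
    delta = "matrix",
    orientation = "character",
    nUndefined = "integer"
  )
)

#' WelchResult: weighted Welch two-sample test
#'
#' @slot statistic numeric t statistic (sign matches meanX - meanY).
#' @slot df numeric Welch-Satterthwaite degrees of freedom.
#' @slot pValue numeric one-tailed p (upper tail of the t distribution).
#' @slot means numeric length-2, weighted means of X and Y.
#' @slot se numeric length-2, weighted standard errors of the two means.
#' @slot neff numeric length-2, effective sample sizes (sums of weights).
#'
#' @exportClass WelchResult
setClass("WelchResult",
  representation(
    statistic = "numeric",
    df = "numeric",
    pValue = "numeric",
    means = "numeric",
    se = "numeric",
    neff = "numeric"
  )
)

setValidity("WelchResult", function(object) {
  msgs <- character()
  if (object@df <= 0) msgs <- c(msgs, "degrees of freedom must be positive")
  if (object@pValue < 0 || object@pValue > 1) msgs <- c(msgs, "p must be in [0,1]")
  d <- object@means[1] - object@means[2]
  if (d != 0 && sign(object@statistic) != sign(d))
    msgs <- c(msgs, "t sign must match the sign of the mean difference")
  if (length(msgs)) msgs else TRUE
})

#' DivergenceResult: class divergence of threaded penalties
#'
#' Weighted class means of the threaded penalty, their difference
#' \eqn{\Delta\Delta E}, the exact residue-pair decomposition
#' \eqn{\Delta\Delta E_{ij}} (restricted to |i-j| > 4), a ranked pair report
#' with cumulative fractions, and the weighted Welch test on the two
#' per-sequence penalty samples.
#'
#' @slot classX,classY character class labels (difference is X minus Y).
#' @slot meanX,meanY numeric weighted mean penalties.
#' @slot ddE numeric meanX - meanY.
#' @slot pairMatrix numeric L x L matrix of pair contributions (upper use i<j).
#' @slot ranked data.frame with columns i, j, ddE_ij, cumulative_fraction.
#' @slot welch WelchResult for X vs Y, or NULL when a class is too small
#'   (effective size at or below 1) for the test.
#' @slot perSequence data.frame id, class, dE, weight.
#'
#' @exportClass DivergenceResult
setClass("DivergenceResult",
  representation(
    classX = "character",
    classY = "character",
    meanX = "numeric",
    meanY = "numeric",
    ddE = "numeric",
    pairMatrix = "matrix",
    ranked = "data.frame",
    welch = "ANY",
    perSequence = "data.frame"
  )
)
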