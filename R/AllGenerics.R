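#' @include AllClasses.R
NULL

#' Number of sequences in an alignment
#' @param x a \code{KinaseAlignment}.
#' @return integer.
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' Alignment width (number of MSA columns)
#' @param x a \code{KinaseAlignment} or \code{PottsModel}.
#' @return integer.
#' @export
setGeneric("alignmentWidth", function(x) standardGeneric("alignmentWidth"))

#' Sequence identifiers
#' @param x a \code{KinaseAlignment}.
#' @return character vector.
#' @export
setGeneric("sequenceIds", function(x) standardGeneric("sequenceIds"))

#' Residue matrix accessor
#' @param x a \code{KinaseAlignment}.
#' @return character matrix N x L.
#' @export
setGeneric("residueMatrix", function(x) standardGeneric("residueMatrix"))

#' Class labels accessor
#' @param x a \code{KinaseAlignment} (or other labelled object).
#' @return character vector.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Replace class labels
#' @param x a \code{KinaseAlignment}.
#' @param value character vector of labels.
#' @return the modified object.
#' @export
setGeneric("classLabels<-", function(x, value) standardGeneric("classLabels<-"))

#' Sequence weights accessor
#' @param x a \code{KinaseAlignment}.
#' @return numeric vector in (0, 1].
#' @export
setGeneric("seqWeights", function(x) standardGeneric("seqWeights"))

#' Replace sequence weights
#' @param x a \code{KinaseAlignment}.
#' @param value numeric vector in (0, 1].
#' @return the modified object.
#' @export
setGeneric("seqWeights<-", function(x, value) standardGeneric("seqWeights<-"))

#' Effective number of sequences (sum of phylogenetic weights)
#' @param x a \code{KinaseAlignment}.
#' @param byClass logical; if TRUE return one N_eff per class label.
#' @return numeric.
#' @export
setGeneric("effectiveN", function(x, byClass = FALSE) standardGeneric("effectiveN"))

#' Coupling block accessor
#' @param model a \code{PottsModel}.
#' @param i,j column indices (1-based, i != j).
#' @return q x q matrix J_ij; rows index the state at min(i,j)'s partner
#'   convention: the block returned always has rows = state at i, columns =
#'   state at j (transposed from storage when i > j).
#' @export
setGeneric("couplingBlock", function(model, i, j) standardGeneric("couplingBlock"))

setMethod("nSequences", "KinaseAlignment", function(x) length(x@ids))
setMethod("alignmentWidth", "KinaseAlignment", function(x) ncol(x@residues))
setMethod("alignmentWidth", "PottsModel", function(x) x@L)
setMethod("sequenceIds", "KinaseAlignment", function(x) x@ids)
setMethod("residueMatrix", "KinaseAlignment", function(x) x@residues)
setMethod("classLabels", "KinaseAlignment", function(x) x@classLabel)
setMethod("classLabels<-", "KinaseAlignment", function(x, value) {
  x@classLabel <- value
  validObject(x)
  x
})
setMethod("seqWeights", "KinaseAlignment", function(x) x@weight)
setMethod("seqWeights<-", "KinaseAlignment", function(x, value) {
  x@weight <- value
  validObject(x)
  x
})
setMethod("effectiveN", "KinaseAlignment", function(x, byClass = FALSE) {
  if (byClass) tapply(x@weight, x@classLabel, sum) else sum(x@weight)
})

setMethod("couplingBlock", "PottsModel", function(model, i, j) {
  stopifnot(i != j, i >= 1, j >= 1, i <= model@L, j <= model@L)
  if (i < j) {
    model@J[pairIndex(i, j, model@L), , ]
  } else {
    t(model@J[pairIndex(j, i, model@L), , ])
  }
})

setMethod("show", "KinaseAlignment", function(object) {
  cat("KinaseAlignment:", nSequences(object), "sequences x",
      alignmentWidth(object), "columns\n")
  tab <- table(object@classLabel)
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  N_eff = %.2f\n", sum(object@weight)))
})

setMethod("show", "PottsModel", function(object) {
  cat(sprintf("PottsModel: L = %d, q = %d, gauge = %s\n",
              object@L, object@q, object@gauge))
  cat(sprintf("  ||h|| = %.4g, ||J|| = %.4g, offset = %.4g\n",
              sqrt(sum(object@h^2)), sqrt(sum(object@J^2)), object@offset))
})

setMethod("show", "StructureContacts", function(object) {
  cat(sprintf("StructureContacts %s_%s [%s, %s]: %d contacts, %d resolved columns of %d\n",
              object@structureId, object@chain, object@classLabel, object@state,
              nrow(object@contacts), length(object@resolved), object@L))
})

setMethod("show", "ConformationEnsemble", function(object) {
  def <- sum(!is.na(object@cfreq[upper.tri(object@cfreq)]))
  cat(sprintf("ConformationEnsemble [%s, %s]: %d structures, %d supported pairs\n",
              object@classLabel, object@state, object@nStructures, def))
})

setMethod("show", "DeltaContactMap", function(object) {
  nz <- sum(object@delta[upper.tri(object@delta)] != 0)
  cat(sprintf("DeltaContactMap [%s, %s]: %d nonzero pairs, %d undefined\n",
              object@classLabel, object@orientation, nz, object@nUndefined))
})

#' Format a p-value the way tail probabilities below double precision are
#' reported
#' @param p numeric p-value.
#' @param floor smallest p reported exactly; smaller values print as a bound.
#' @return character.
#' @export
formatPValue <- function(p, floor = 1e-15) {
  if (p < floor) sprintf("< %g", floor) else sprintf("%.3g", p)
}

setMethod("show", "WelchResult", function(object) {
  cat(sprintf("Weighted Welch test: t = %.4g, nu = %.4g, one-tailed p %s\n",
              object@statistic, object@df,
              ifelse(object@pValue < 1e-15, formatPValue(object@pValue),
                     paste("=", formatPValue(object@pValue)))))
  cat(sprintf("  means: %.4g vs %.4g;  N_eff: %.2f vs %.2f\n",
              object@means[1], object@means[2], object@neff[1], object@neff[2]))
})

setMethod("show", "DivergenceResult", function(object) {
  cat(sprintf("DivergenceResult: <dE>_%s = %.4g, <dE>_%s = %.4g, ddE = %.4g\n",
              object@classX, object@meanX, object@classY, object@meanY, object@ddE))
  if (!is.null(object@welch)) {
    cat(sprintf("  Welch one-tailed p %s; top pairs:\n",
                ifelse(object@welch@pValue < 1e-15,
                       formatPValue(object@welch@pValue),
                       paste("=", formatPValue(object@welch@pValue)))))
  } else {
    cat("  Welch test unavailable (class too small); top pairs:\n")
  }
  print(utils::head(object@ranked, 5))
})
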