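#' @include potts.R
NULL

# Encode residues for threading.  Returns list(states, qEff, Jzero):
# states is an N x L integer matrix over 1..qEff where qEff = q + 1; the
# extra state is a zero-coupling sink used for (a) gap symbols when the
# model alphabet has no gap parameters and (b) the explicit gap state under
# gapPolicy = "zero".  Couplings touching the sink state contribute 0.
threadEncode <- function(model, residues, gapPolicy = c("model", "zero")) {
  gapPolicy <- match.arg(gapPolicy)
  q <- model@q
  idx <- match(residues, model@alphabet)
  isGap <- residues == "-"
  if (anyNA(idx[!isGap])) {
    bad <- which(is.na(idx) & !isGap)[1]
    col <- ((bad - 1) %/% nrow(residues)) + 1
    stop(sprintf("symbol '%s' at column %d is not in the model alphabet",
                 residues[bad], col))
  }
  sink <- q + 1L
  idx[is.na(idx)] <- sink                       # gaps absent from alphabet
  if (gapPolicy == "zero" && "-" %in% model@alphabet)
    idx[isGap] <- sink
  list(states = matrix(idx, nrow = nrow(residues)), qEff = sink)
}

# Coupling block for pair p extended with the zero sink row/column.
threadBlock <- function(model, p, qEff) {
  q <- model@q
  B <- matrix(0, qEff, qEff)
  B[seq_len(q), seq_len(q)] <- model@J[p, , ]
  B
}

# Nonzero |i-j| > 4 pairs of a delta map (upper triangle), as a data.frame
# with the lexicographic pair index attached.
deltaPairs <- function(dmap, L) {
  d <- dmap@delta
  ut <- which(upper.tri(d) & d != 0, arr.ind = TRUE)
  if (!nrow(ut))
    return(data.frame(i = integer(), j = integer(), delta = numeric(),
                      p = integer()))
  df <- data.frame(i = ut[, 1], j = ut[, 2], delta = d[ut])
  df$p <- pairIndex(df$i, df$j, L)
  df[order(df$p), ]
}

#' Threaded conformational penalty of sequences
#'
#' \eqn{\Delta E(S) = -\sum_{i<j, |i-j|>4} J_{ij}(s_i, s_j)\,\Delta c_{ij}}:
#' the statistical-energy cost for sequence S to move from the active
#' DFG-in ensemble to the classical DFG-out ensemble whose contact
#' difference is \code{dmap}.  Positive values are penalties.  The model
#' must be in the zero gauge (it is transformed automatically, with a
#' warning, if not), since the raw-gauge value depends on an arbitrary
#' convention.
#'
#' @param model a zero-gauge \code{PottsModel}.
#' @param seq a sequence (string or character vector), character matrix, or
#'   \code{KinaseAlignment}.
#' @param dmap a \code{\linkS4class{DeltaContactMap}}.
#' @param gapPolicy \code{"model"} (default): the gap is an ordinary Potts
#'   state with its own couplings when the model alphabet includes it;
#'   \code{"zero"}: pairs containing a gap contribute nothing.  When the
#'   model has no gap state, gap pairs contribute zero under either policy.
#' @return numeric vector of penalties (one per sequence).
#' @export
threadEnergy <- function(model, seq, dmap, gapPolicy = c("model", "zero")) {
  gapPolicy <- match.arg(gapPolicy)
  if (is(seq, "KinaseAlignment")) seq <- residueMatrix(seq)
  if (is.character(seq) && !is.matrix(seq)) {
    if (length(seq) == 1L && nchar(seq) > 1L)
      seq <- strsplit(seq, "", fixed = TRUE)[[1]]
    seq <- matrix(seq, nrow = 1)
  }
  if (ncol(seq) != model@L)
    stop(sprintf("sequence width %d does not match model L = %d",
                 ncol(seq), model@L))
  if (nrow(dmap@delta) != model@L)
    stop("delta map width does not match model L")
  if (model@gauge != "zero") {
    warning("model is not in the zero gauge; applying zeroGauge()")
    model <- zeroGauge(model)
  }
  enc <- threadEncode(model, seq, gapPolicy)
  S <- enc$states
  pr <- deltaPairs(dmap, model@L)
  E <- numeric(nrow(S))
  for (k in seq_len(nrow(pr))) {
    B <- threadBlock(model, pr$p[k], enc$qEff)
    E <- E - B[cbind(S[, pr$i[k]], S[, pr$j[k]])] * pr$delta[k]
  }
  E
}

#' Weighted bivariate marginal at a column pair
#'
#' \eqn{f_{\alpha\beta}^{ij}(X) = \sum_{s \in X} w_s [s_i = \alpha][s_j =
#' \beta] / \sum_{s \in X} w_s} over a stated alphabet.  Entries sum to 1
#' when every symbol at columns i and j is in the alphabet.
#'
#' @param x a weighted \code{KinaseAlignment}.
#' @param classLabel restrict to sequences with this class label (NULL = all).
#' @param i,j 1-based MSA columns.
#' @param alphabet state symbols (default the full 21-letter alphabet).
#' @return numeric q x q matrix, rows = state at i, columns = state at j.
#' @export
weightedBimarg <- function(x, classLabel = NULL, i, j,
                           alphabet = aaAlphabet()) {
  sel <- if (is.null(classLabel)) rep(TRUE, nSequences(x))
         else classLabels(x) == classLabel
  if (!any(sel)) stop("no sequences in class '", classLabel, "'")
  mat <- residueMatrix(x)[sel, , drop = FALSE]
  w <- seqWeights(x)[sel]
  q <- length(alphabet)
  si <- match(mat[, i], alphabet)
  sj <- match(mat[, j], alphabet)
  f <- matrix(0, q, q, dimnames = list(alphabet, alphabet))
  ok <- !is.na(si) & !is.na(sj)
  cell <- si[ok] + q * (sj[ok] - 1L)
  tab <- tapply(w[ok], cell, sum)
  f[as.integer(names(tab))] <- tab
  f / sum(w)
}

# Internal: weighted bivariate marginal over the threading state space
# (model alphabet + sink), normalized by the total class weight.
threadBimarg <- function(states, w, i, j, qEff) {
  f <- matrix(0, qEff, qEff)
  cell <- states[, i] + qEff * (states[, j] - 1L)
  tab <- tapply(w, cell, sum)
  f[as.integer(names(tab))] <- tab
  f / sum(w)
}

#' Class divergence of threaded penalties with exact pair decomposition
#'
#' Computes the weighted class means of the threaded penalty,
#' \eqn{\Delta\Delta E = \langle\Delta E\rangle_X - \langle\Delta
#' E\rangle_Y}, and its exact decomposition into residue-pair terms
#' \eqn{\Delta\Delta E_{ij} = -\sum_{\alpha\beta} J^{ij}_{\alpha\beta}
#' (f^{ij}_{\alpha\beta}(X)\,\Delta c_{ij}(X) -
#' f^{ij}_{\alpha\beta}(Y)\,\Delta c_{ij}(Y))}, using the same phylogenetic
#' weights for the means and the bivariate marginals so that
#' \eqn{\sum_{i<j}\Delta\Delta E_{ij} = \Delta\Delta E} holds as an
#' identity.  Class-specific delta maps are the default (each class is
#' threaded over its own ensembles); pass the same map twice for the
#' shared-map ablation.  The ranked report lists pairs by descending
#' contribution, ties broken by ascending (i, j).
#'
#' @param model a zero-gauge \code{PottsModel}.
#' @param x a classified, weighted \code{KinaseAlignment}.
#' @param dmapX,dmapY \code{DeltaContactMap}s for the two classes.
#' @param classX,classY class labels (default STK and TK, in which case the
#'   difference is STK minus TK).
#' @param gapPolicy see \code{\link{threadEnergy}}.
#' @return a \code{\linkS4class{DivergenceResult}}.
#' @export
divergence <- function(model, x, dmapX, dmapY, classX = "STK", classY = "TK",
                       gapPolicy = c("model", "zero")) {
  gapPolicy <- match.arg(gapPolicy)
  if (model@gauge != "zero") {
    warning("model is not in the zero gauge; applying zeroGauge()")
    model <- zeroGauge(model)
  }
  selX <- classLabels(x) == classX
  selY <- classLabels(x) == classY
  if (classX == classY) selY <- selX
  if (!any(selX)) stop("class '", classX, "' is empty")
  if (!any(selY)) stop("class '", classY, "' is empty")
  dEX <- threadEnergy(model, subsetAlignment(x, selX), dmapX, gapPolicy)
  dEY <- threadEnergy(model, subsetAlignment(x, selY), dmapY, gapPolicy)
  wX <- seqWeights(x)[selX]; wY <- seqWeights(x)[selY]
  meanX <- sum(wX * dEX) / sum(wX)
  meanY <- sum(wY * dEY) / sum(wY)
  ddE <- meanX - meanY

  encX <- threadEncode(model, residueMatrix(x)[selX, , drop = FALSE], gapPolicy)
  encY <- threadEncode(model, residueMatrix(x)[selY, , drop = FALSE], gapPolicy)
  prX <- deltaPairs(dmapX, model@L)
  prY <- deltaPairs(dmapY, model@L)
  allPairs <- unique(rbind(prX[c("i", "j", "p")], prY[c("i", "j", "p")]))
  allPairs <- allPairs[order(allPairs$p), ]
  L <- model@L
  pairMatrix <- matrix(0, L, L)
  dX <- dmapX@delta; dY <- dmapY@delta
  contrib <- numeric(nrow(allPairs))
  for (k in seq_len(nrow(allPairs))) {
    i <- allPairs$i[k]; j <- allPairs$j[k]; p <- allPairs$p[k]
    B <- threadBlock(model, p, encX$qEff)
    term <- 0
    if (dX[i, j] != 0)
      term <- term + sum(threadBimarg(encX$states, wX, i, j, encX$qEff) * B) * dX[i, j]
    if (dY[i, j] != 0)
      term <- term - sum(threadBimarg(encY$states, wY, i, j, encY$qEff) * B) * dY[i, j]
    contrib[k] <- -term
    pairMatrix[i, j] <- contrib[k]
    pairMatrix[j, i] <- contrib[k]
  }
  ord <- order(-contrib, allPairs$i, allPairs$j)
  ranked <- data.frame(i = allPairs$i[ord], j = allPairs$j[ord],
                       ddE_ij = contrib[ord])
  ranked$cumulative_fraction <- if (ddE != 0) cumsum(ranked$ddE_ij) / ddE
                                else NA_real_
  welch <- tryCatch(welchWeighted(dEX, wX, dEY, wY),
                    error = function(e) NULL)
  perSeq <- data.frame(
    id = c(sequenceIds(x)[selX], sequenceIds(x)[selY]),
    class = c(rep(classX, sum(selX)), rep(classY, sum(selY))),
    dE = c(dEX, dEY),
    weight = c(wX, wY),
    stringsAsFactors = FALSE)
  new("DivergenceResult", classX = classX, classY = classY,
      meanX = meanX, meanY = meanY, ddE = ddE,
      pairMatrix = pairMatrix, ranked = ranked, welch = welch,
      perSequence = perSeq)
}

#' Class mean of the threaded penalty via bivariate marginals
#'
#' Second, independent route to \eqn{\langle\Delta E\rangle_X}: the sum
#' over pairs of \eqn{-\sum_{\alpha\beta} f^{ij}_{\alpha\beta}(X)
#' J^{ij}_{\alpha\beta}\,\Delta c_{ij}(X)}.  Agrees with the weighted mean
#' of per-sequence penalties to numerical tolerance by construction.
#'
#' @inheritParams divergence
#' @param dmap the class's \code{DeltaContactMap}.
#' @param classLabel the class to average over.
#' @return numeric scalar.
#' @export
meanEnergyFromBimarg <- function(model, x, dmap, classLabel,
                                 gapPolicy = c("model", "zero")) {
  gapPolicy <- match.arg(gapPolicy)
  if (model@gauge != "zero") model <- zeroGauge(model)
  sel <- classLabels(x) == classLabel
  if (!any(sel)) stop("class '", classLabel, "' is empty")
  enc <- threadEncode(model, residueMatrix(x)[sel, , drop = FALSE], gapPolicy)
  w <- seqWeights(x)[sel]
  pr <- deltaPairs(dmap, model@L)
  total <- 0
  for (k in seq_len(nrow(pr))) {
    B <- threadBlock(model, pr$p[k], enc$qEff)
    f <- threadBimarg(enc$states, w, pr$i[k], pr$j[k], enc$qEff)
    total <- total - sum(f * B) * pr$delta[k]
  }
  total
}
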