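#' @include AllGenerics.R
NULL

#' Curated reorganization free-energy benchmark for ten human kinases
#'
#' Five serine/threonine kinases with large predicted DFG-out penalties and
#' five tyrosine kinases with small ones, assembled from published type-II
#' inhibitor panel data and absolute binding free-energy simulations.  For
#' each kinase: the type-II inhibitor hit count (inhibitors with K_d below
#' 10 micromolar in a kinome-wide panel), the Potts threaded-energy penalty
#' for the active DFG-in to classical DFG-out transition (statistical-energy
#' units), the reorganization free energy estimated as the mean excess of
#' experimental binding free energy over the simulated absolute binding
#' free energy across that kinase's type-II complexes (kcal/mol), and its
#' propagated uncertainty.
#'
#' This table anchors the calibration between the Potts statistical-energy
#' scale and physical free energies: the correlation of \code{potts_penalty}
#' with \code{dg_reorg} and the through-origin slope give the kcal/mol value
#' of one Potts unit.
#'
#' @return data.frame with columns \code{kinase}, \code{class},
#'   \code{hit_rate}, \code{potts_penalty}, \code{dg_reorg},
#'   \code{dg_reorg_err}.
#' @examples
#' tab <- kinaseReorgData()
#' fitThroughOrigin(tab$potts_penalty, tab$dg_reorg)
#' @export
kinaseReorgData <- function() {
  data.frame(
    kinase = c("MELK", "MAPK9", "CDK2", "IRAK4", "BRAF",
               "ABL1", "LCK", "TIE2", "NTRK2", "DDR1"),
    class = c(rep("STK", 5), rep("TK", 5)),
    hit_rate = c(3L, 5L, 2L, 0L, 7L, 10L, 11L, 6L, 6L, 11L),
    potts_penalty = c(5.9, 4.7, 5.3, 2.5, 4.0, -1.0, 0.5, 1.1, -1.0, 0.4),
    dg_reorg = c(5.6, 6.9, 7.7, 5.4, 6.5, 1.3, 1.0, -0.3, 1.7, 0.3),
    dg_reorg_err = c(0.2, 0.3, 0.2, 0.2, 0.1, 0.3, 0.3, 0.2, 0.1, 0.3),
    stringsAsFactors = FALSE
  )
}

#' Calibrate the Potts statistical-energy scale against free energies
#'
#' From paired (Potts penalty, reorganization free energy) values:
#' the Pearson correlation with its square, the least-squares slope through
#' the origin (kcal/mol per Potts unit), an unconstrained fit for
#' comparison, and the class means.
#'
#' @param tab data.frame like \code{\link{kinaseReorgData}()}.
#' @return list with \code{r}, \code{r2}, \code{slope_origin},
#'   \code{slope_free}, \code{intercept_free}, \code{class_means}, \code{n}.
#' @export
calibratePottsScale <- function(tab = kinaseReorgData()) {
  pc <- pearsonR2(tab$potts_penalty, tab$dg_reorg)
  fit <- stats::lm(dg_reorg ~ potts_penalty, data = tab)
  list(
    r = pc$r,
    r2 = pc$r2,
    slope_origin = fitThroughOrigin(tab$potts_penalty, tab$dg_reorg),
    slope_free = unname(stats::coef(fit)[2]),
    intercept_free = unname(stats::coef(fit)[1]),
    class_means = tapply(tab$dg_reorg, tab$class, mean),
    n = nrow(tab)
  )
}
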