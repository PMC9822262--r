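#' @include AllGenerics.R
NULL

#' Boltzmann constant in kcal/(mol K)
#' @export
KB_KCAL <- 0.0019872041

#' Standard binding free energy from a dissociation constant
#'
#' \eqn{\Delta G^\circ_{exp} = k_B T \ln(K_d / C_0)} with the standard
#' concentration \eqn{C_0 = 1} M.  IC50 values are treated identically to
#' K_d, a documented simplification.  Sub-molar constants give negative
#' free energies; the function is strictly increasing in \code{kd} and
#' exactly 0 at 1 M.
#'
#' @param kd dissociation constant(s) in molar; must be positive.
#' @param temperature in kelvin (default 298.15; the source measurements do
#'   not state a temperature, so room temperature is assumed).
#' @param kB Boltzmann constant in kcal/(mol K) (default \code{KB_KCAL}).
#' @return free energy in kcal/mol.
#' @export
kdToDeltaG <- function(kd, temperature = 298.15, kB = KB_KCAL) {
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("kd must be positive and finite")
  kB * temperature * log(kd)
}

#' Reorganization free energy
#'
#' \eqn{\Delta G_{reorg} = \Delta G^\circ_{exp} - \Delta G^{ABFE}_{bind}}:
#' the excess between the experimental standard binding free energy (which
#' implicitly pays for the active DFG-in to classical DFG-out
#' reorganization) and the absolute binding free energy computed against
#' the already-reorganized receptor.
#'
#' @param dgExp experimental standard binding free energy (kcal/mol).
#' @param dgBind absolute binding free energy to the DFG-out state (kcal/mol).
#' @return kcal/mol.
#' @export
dgReorg <- function(dgExp, dgBind) {
  dgExp - dgBind
}

#' Combine double-decoupling legs into an absolute binding free energy
#'
#' \eqn{\Delta G^\circ_{bind} = -\Delta G^{bound}_{restrain} + \Delta\Delta
#' G_{Coulomb} + \Delta\Delta G_{LJ} + \Delta G^{gas}_{restrain} + \Delta
#' G^{finite}_{elec}}; the finite-size electrostatic correction applies to
#' charged ligands and defaults to 0.
#'
#' @param restrainBound restraint free energy in the bound leg (kcal/mol).
#' @param coulomb Coulomb decoupling difference (kcal/mol).
#' @param lj Lennard-Jones decoupling difference (kcal/mol).
#' @param restrainGas gas-phase restraint release (kcal/mol).
#' @param finiteSize finite-size electrostatic correction (kcal/mol, default 0).
#' @return kcal/mol.
#' @export
ddmCombine <- function(restrainBound, coulomb, lj, restrainGas,
                       finiteSize = 0) {
  required <- c(restrainBound = missing(restrainBound),
                coulomb = missing(coulomb), lj = missing(lj),
                restrainGas = missing(restrainGas))
  if (any(required))
    stop("missing required decoupling legs: ",
         paste(names(required)[required], collapse = ", "))
  -restrainBound + coulomb + lj + restrainGas + finiteSize
}

#' Type-II inhibitor hit count for a kinase
#'
#' A "hit" is an inhibitor with \eqn{K_d \le} \code{threshold} (inclusive;
#' default 10 micromolar).  Ligands with missing affinity are excluded with
#' a message.
#'
#' @param kd numeric vector of dissociation constants in molar (NA allowed).
#' @param threshold hit threshold in molar (default \code{1e-5}).
#' @return integer hit count.
#' @export
hitRate <- function(kd, threshold = 1e-5) {
  miss <- is.na(kd)
  if (any(miss))
    message(sum(miss), " ligands without affinity excluded from the hit count")
  sum(kd[!miss] <= threshold)
}

# Weighted mean, weighted variance with the effective-sample-size
# denominator, and the standard error of the weighted mean.  One place so
# the estimator convention is isolated: s2 = sum(w (x - xbar)^2)/(Neff - 1),
# SE = s/sqrt(Neff), Neff = sum(w).
weightedMoments <- function(x, w) {
  neff <- sum(w)
  m <- sum(w * x) / neff
  s2 <- sum(w * (x - m)^2) / (neff - 1)
  list(mean = m, var = s2, se = sqrt(s2 / neff), neff = neff)
}

#' Weighted Welch two-sample test
#'
#' \eqn{t = (\bar x_w - \bar y_w)/\sqrt{s_X^2 + s_Y^2}} where \eqn{s} are
#' standard errors of the weighted means with effective counts \eqn{N_{eff}
#' = \sum w}; degrees of freedom by Welch–Satterthwaite, \eqn{\nu =
#' (s_X^2+s_Y^2)^2 / (s_X^4/\nu_X + s_Y^4/\nu_Y)} with \eqn{\nu_i = N_{eff,i}
#' - 1}; one-tailed p from the upper tail of the t distribution,
#' \eqn{p = 1 - F_t(t, \nu)}.  With unit weights this reduces exactly to
#' the textbook Welch test.
#'
#' @param x,y numeric samples.
#' @param wx,wy weights in (0, 1] (default unit weights).
#' @return a \code{\linkS4class{WelchResult}}.  p-values below 1e-15 are
#'   stored as computed but printed as a bound.
#' @export
welchWeighted <- function(x, wx = rep(1, length(x)),
                          y, wy = rep(1, length(y))) {
  mx <- weightedMoments(x, wx)
  my <- weightedMoments(y, wy)
  if (mx$neff <= 1 || my$neff <= 1)
    stop("effective sample size must exceed 1 in both samples")
  if (mx$var == 0 || my$var == 0)
    stop("degenerate (zero-variance) sample")
  tstat <- (mx$mean - my$mean) / sqrt(mx$se^2 + my$se^2)
  nu <- (mx$se^2 + my$se^2)^2 /
    (mx$se^4 / (mx$neff - 1) + my$se^4 / (my$neff - 1))
  p <- stats::pt(tstat, df = nu, lower.tail = FALSE)
  new("WelchResult", statistic = tstat, df = nu, pValue = p,
      means = c(mx$mean, my$mean), se = c(mx$se, my$se),
      neff = c(mx$neff, my$neff))
}

#' Pearson correlation and its square
#'
#' @param x,y numeric vectors, length >= 3, both with positive variance.
#' @return list with elements \code{r} and \code{r2}.
#' @export
pearsonR2 <- function(x, y) {
  if (length(x) < 3 || length(y) != length(x))
    stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  r <- cor(x, y)
  list(r = r, r2 = r^2)
}

#' Least-squares slope through the origin
#'
#' \eqn{\hat\beta = \sum x y / \sum x^2}.  Used to express one unit of
#' Potts statistical energy in kcal/mol of reorganization free energy.
#'
#' @param x,y numeric vectors; \code{x} must not be all zero.
#' @return numeric slope.
#' @export
fitThroughOrigin <- function(x, y) {
  if (sum(x^2) == 0) stop("all-zero x: slope undefined")
  sum(x * y) / sum(x^2)
}

#' Intercept of a slope-one regression (average reorganization penalty)
#'
#' Regressing \eqn{\Delta G_{exp}} on \eqn{\Delta G^{ABFE}_{bind}} with the
#' slope constrained to one estimates the intercept as
#' \eqn{\mathrm{mean}(y - x)} — the per-target average reorganization free
#' energy — with the standard error of \eqn{y - x} as its uncertainty.
#'
#' @param x \eqn{\Delta G^{ABFE}_{bind}} values (kcal/mol).
#' @param y \eqn{\Delta G_{exp}} values (kcal/mol).
#' @return list with \code{intercept} and \code{se} (NA for a single complex).
#' @export
fitSlopeOne <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- y - x
  list(intercept = mean(d),
       se = if (length(d) > 1) sd(d) / sqrt(length(d)) else NA_real_)
}

#' Weighted Welch test on the two classes of a divergence analysis
#'
#' Convenience wrapper: extracts the per-sequence penalties and weights of
#' classes X and Y from a \code{DivergenceResult} and re-runs
#' \code{\link{welchWeighted}} (X minus Y orientation).
#'
#' @param divResult a \code{\linkS4class{DivergenceResult}}.
#' @return a \code{\linkS4class{WelchResult}}.
#' @export
divergenceTest <- function(divResult) {
  ps <- divResult@perSequence
  if (divResult@classX == divResult@classY)
    stop("cannot test a class against itself")
  sx <- ps$class == divResult@classX
  welchWeighted(ps$dE[sx], ps$weight[sx], ps$dE[!sx], ps$weight[!sx])
}
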