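#' @include AllGenerics.R
NULL

#' Construct a PottsModel
#'
#' @param h numeric L x q matrix of fields.
#' @param J numeric P x q x q array of couplings (pairs lexicographic i < j)
#'   or NULL for an all-zero coupling set.
#' @param alphabet state symbols; defaults to the full 21-letter alphabet
#'   when q = 21, otherwise the first q symbols of it.
#' @param offset scalar energy offset (default 0).
#' @param gauge \code{"raw"} or \code{"zero"}.
#' @return A \code{\linkS4class{PottsModel}}.
#' @export
pottsModel <- function(h, J = NULL, alphabet = NULL, offset = 0, gauge = "raw") {
  L <- nrow(h); q <- ncol(h)
  P <- L * (L - 1L) / 2L
  if (is.null(J)) J <- array(0, dim = c(P, q, q))
  if (is.null(alphabet)) alphabet <- aaAlphabet()[seq_len(q)]
  new("PottsModel", L = as.integer(L), q = as.integer(q),
      alphabet = alphabet, h = h, J = J,
      offset = as.numeric(offset), gauge = gauge)
}

# Map a residue character matrix (or vector) to 1-based state indices under
# a model's alphabet.  Errors name the first offending column.
encodeStates <- function(residues, alphabet) {
  if (!is.matrix(residues)) residues <- matrix(residues, nrow = 1)
  idx <- match(residues, alphabet)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    col <- ((bad - 1) %/% nrow(residues)) + 1
    stop(sprintf("symbol '%s' at column %d is not in the model alphabet",
                 residues[bad], col))
  }
  matrix(idx, nrow = nrow(residues))
}

#' Potts statistical energy of sequences
#'
#' \eqn{H(S) = \sum_{i<j} J_{ij}(s_i, s_j) + \sum_i h_i(s_i) + \mathrm{offset}}.
#' Lower H is more probable (\eqn{P(S) \propto e^{-H(S)}}).  All column
#' pairs enter; the |i-j| > 4 sequence-separation rule belongs to contact
#' maps, not to the Hamiltonian.
#'
#' @param model a \code{PottsModel}.
#' @param seq a character vector/string of length L, a \code{KinaseAlignment},
#'   or a character matrix N x L.
#' @return numeric vector of energies (length N).
#' @export
hamiltonian <- function(model, seq) {
  if (is(seq, "KinaseAlignment")) seq <- residueMatrix(seq)
  if (is.character(seq) && !is.matrix(seq)) {
    if (length(seq) == 1L && nchar(seq) > 1L)
      seq <- strsplit(seq, "", fixed = TRUE)[[1]]
    seq <- matrix(seq, nrow = 1)
  }
  if (ncol(seq) != model@L)
    stop(sprintf("sequence width %d does not match model L = %d",
                 ncol(seq), model@L))
  S <- encodeStates(seq, model@alphabet)
  n <- nrow(S); L <- model@L; q <- model@q
  E <- rep(model@offset, n)
  for (i in seq_len(L)) E <- E + model@h[cbind(i, S[, i])]
  P <- L * (L - 1L) / 2L
  p <- 0L
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      p <- p + 1L
      E <- E + model@J[p + P * (S[, i] - 1L) + P * q * (S[, j] - 1L)]
    }
  }
  E
}

#' Transform a Potts model to the zero-sum gauge
#'
#' Each coupling block is replaced by
#' \eqn{J'_{ij}(\alpha,\beta) = J_{ij}(\alpha,\beta) - \bar J_{ij}(\alpha,\cdot)
#' - \bar J_{ij}(\cdot,\beta) + \bar J_{ij}(\cdot,\cdot)}, so all row and
#' column sums vanish; the removed row/column means are pushed into the
#' fields and the grand means into the scalar offset, and the fields are
#' then centred per column with their means also absorbed into the offset.
#' H(S) is preserved exactly for every sequence, and the transform is
#' idempotent.
#'
#' @param model a \code{PottsModel}.
#' @return the gauge-fixed \code{PottsModel} (gauge \code{"zero"}).
#' @export
zeroGauge <- function(model) {
  L <- model@L; q <- model@q
  J <- model@J
  h <- model@h
  offset <- model@offset
  P <- L * (L - 1L) / 2L
  # row means (over beta) per block/alpha, column means per block/beta
  rowMean <- apply(J, c(1, 2), mean)   # P x q : mean over beta
  colMean <- apply(J, c(1, 3), mean)   # P x q : mean over alpha
  grand <- rowMeans(rowMean)           # P
  Jp <- J
  for (a in seq_len(q)) Jp[, a, ] <- Jp[, a, ] - rowMean[, a]
  for (b in seq_len(q)) Jp[, , b] <- Jp[, , b] - colMean[, b]
  Jp <- sweep(Jp, 1, grand, "+")
  # redistribute: J = J' + rowMean_ij(alpha) + colMean_ij(beta) - grand_ij
  pi_ <- rep(seq_len(L - 1L), times = (L - 1L):1L)
  pj_ <- unlist(lapply(seq_len(L - 1L), function(i) (i + 1L):L))
  for (p in seq_len(P)) {
    h[pi_[p], ] <- h[pi_[p], ] + rowMean[p, ] - grand[p] / 2
    h[pj_[p], ] <- h[pj_[p], ] + colMean[p, ] - grand[p] / 2
  }
  # centre fields
  hm <- rowMeans(h)
  h <- h - hm
  offset <- offset + sum(hm)
  pottsModel(h, Jp, alphabet = model@alphabet, offset = offset, gauge = "zero")
}

#' Draw sequences from a Potts model by heat-bath Gibbs sampling
#'
#' A single sequential-scan heat-bath chain: after \code{burnIn} full
#' sweeps, one sequence is recorded every \code{thin} sweeps until \code{n}
#' samples are collected.  Identical seed and parameters give identical
#' output.
#'
#' @param model a \code{PottsModel}.
#' @param n number of sequences.
#' @param burnIn burn-in sweeps (default 200).
#' @param thin sweeps between recorded samples (default 5).
#' @param seed integer RNG seed.
#' @param ids optional sequence identifiers.
#' @return a \code{\linkS4class{KinaseAlignment}} over the model alphabet.
#' @export
gibbsSample <- function(model, n, burnIn = 200L, thin = 5L, seed = 1L,
                        ids = NULL) {
  stopifnot(n >= 1)
  set.seed(seed)
  s0 <- sample.int(model@q, model@L, replace = TRUE) - 1L
  S <- gibbs_sample_cpp(model@h, as.numeric(model@J), model@L, model@q,
                        as.integer(n), as.integer(burnIn), as.integer(thin),
                        as.integer(s0))
  mat <- matrix(model@alphabet[S], nrow = n)
  if (is.null(ids)) ids <- sprintf("sample%04d", seq_len(n))
  kinaseAlignment(mat, ids = ids)
}

#' Write a Potts model to the plain-text container format
#'
#' A single TSV with a header line \code{# potts L q alphabet}, followed by
#' one \code{h} row per (column, state) and one \code{J} row per (pair,
#' state, state) entry.  Zero J entries are omitted; the reader restores
#' them.  Round-trips exactly at full double precision.
#'
#' @param model a \code{PottsModel}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writePottsModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# potts\t%d\t%d\t%s\t%.17g\t%s", model@L, model@q,
                     paste(model@alphabet, collapse = ""), model@offset,
                     model@gauge), con)
  hidx <- which(model@h != 0, arr.ind = TRUE)
  if (nrow(hidx))
    writeLines(sprintf("h\t%d\t%d\t%.17g", hidx[, 1], hidx[, 2],
                       model@h[hidx]), con)
  jidx <- which(model@J != 0, arr.ind = TRUE)
  if (nrow(jidx))
    writeLines(sprintf("J\t%d\t%d\t%d\t%.17g", jidx[, 1], jidx[, 2],
                       jidx[, 3], model@J[jidx]), con)
  invisible(path)
}

#' Read a Potts model from the plain-text container format
#' @param path file written by \code{\link{writePottsModel}}.
#' @return a \code{\linkS4class{PottsModel}}.
#' @export
readPottsModel <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "# potts"))
    stop("not a Potts container file: ", path)
  hd <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  L <- as.integer(hd[2]); q <- as.integer(hd[3])
  alphabet <- strsplit(hd[4], "", fixed = TRUE)[[1]]
  offset <- as.numeric(hd[5]); gauge <- hd[6]
  P <- L * (L - 1L) / 2L
  h <- matrix(0, L, q)
  J <- array(0, dim = c(P, q, q))
  body <- lines[-1]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    kind <- vapply(parts, `[`, character(1), 1)
    hrows <- parts[kind == "h"]
    if (length(hrows)) {
      hm <- matrix(as.numeric(unlist(lapply(hrows, `[`, 2:4))), ncol = 3,
                   byrow = TRUE)
      h[hm[, 1:2]] <- hm[, 3]
    }
    jrows <- parts[kind == "J"]
    if (length(jrows)) {
      jm <- matrix(as.numeric(unlist(lapply(jrows, `[`, 2:5))), ncol = 4,
                   byrow = TRUE)
      J[jm[, 1:3]] <- jm[, 4]
    }
  }
  pottsModel(h, J, alphabet = alphabet, offset = offset, gauge = gauge)
}
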