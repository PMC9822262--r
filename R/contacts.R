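#' @include AllGenerics.R
NULL

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Build a StructureContacts record
#'
#' @param structureId,chain,uniprotId,state,classLabel metadata strings.
#' @param L alignment width.
#' @param contacts integer matrix m x 2 (i < j, |i-j| > 4) of MSA columns.
#' @param resolved integer vector of resolved MSA columns.
#' @return a \code{\linkS4class{StructureContacts}}.
#' @export
structureContacts <- function(structureId, chain, uniprotId, state,
                              classLabel, L, contacts, resolved) {
  contacts <- matrix(as.integer(contacts), ncol = 2)
  if (nrow(contacts)) {
    flip <- contacts[, 1] > contacts[, 2]
    contacts[flip, ] <- contacts[flip, 2:1]
    contacts <- unique(contacts)
    contacts <- contacts[order(contacts[, 1], contacts[, 2]), , drop = FALSE]
  }
  new("StructureContacts", structureId = structureId, chain = chain,
      uniprotId = uniprotId, state = state, classLabel = classLabel,
      L = as.integer(L), contacts = contacts,
      resolved = sort(as.integer(resolved)))
}

#' Contact map of a structure in MSA column space
#'
#' A pair of MSA columns (i, j) is in contact when the minimum Euclidean
#' distance between the side-chain heavy atoms of the two mapped residues
#' is strictly below \code{cutoff} and the column separation satisfies
#' |i - j| > \code{minSeparation}.  Side-chain atoms are heavy atoms beyond
#' the backbone (C-beta inclusive); glycine, which has no side-chain heavy
#' atom, uses C-alpha as a proxy when \code{glycineCA} is TRUE (default),
#' otherwise it can form no contacts.
#'
#' @param atoms data.frame with columns \code{resno} (author residue
#'   number), \code{elety} (atom name), \code{resid} (3-letter residue
#'   code, used for the glycine proxy), \code{x}, \code{y}, \code{z}.
#'   Hydrogens must already be absent or are ignored via \code{elety}
#'   starting with "H".
#' @param columnMap named integer vector: names are author residue numbers,
#'   values 1-based MSA columns (injective).
#' @param cutoff contact distance in Angstrom, strict inequality (default 6).
#' @param minSeparation minimum |i-j| exclusive (default 4: only pairs with
#'   |i-j| > 4 are kept).
#' @param glycineCA logical, glycine C-alpha proxy (default TRUE).
#' @return integer matrix m x 2 of contacting column pairs (i < j).
#' @export
contactMap <- function(atoms, columnMap, cutoff = 6, minSeparation = 4L,
                       glycineCA = TRUE) {
  if (anyDuplicated(columnMap))
    stop("columnMap must be injective into 1..L")
  atoms <- atoms[!grepl("^[0-9]*H", atoms$elety), , drop = FALSE]
  side <- !(atoms$elety %in% BACKBONE_ATOMS)
  if (glycineCA && "resid" %in% names(atoms))
    side <- side | (atoms$resid %in% c("GLY", "G") & atoms$elety == "CA")
  atoms <- atoms[side, , drop = FALSE]
  cols <- columnMap[as.character(atoms$resno)]
  keep <- !is.na(cols)
  atoms <- atoms[keep, , drop = FALSE]
  cols <- cols[keep]
  if (!nrow(atoms)) return(matrix(integer(), ncol = 2))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  ucols <- sort(unique(cols))
  pairs <- list()
  for (a in seq_along(ucols)) {
    for (b in seq_along(ucols)) {
      if (b <= a) next
      ci <- ucols[a]; cj <- ucols[b]
      if (cj - ci <= minSeparation) next
      dmin <- min(d[cols == ci, cols == cj])
      if (dmin < cutoff) pairs[[length(pairs) + 1L]] <- c(ci, cj)
    }
  }
  if (!length(pairs)) return(matrix(integer(), ncol = 2))
  do.call(rbind, pairs)
}

#' Read a chain from a PDB file into a StructureContacts record
#'
#' Parses coordinates with bio3d (model 1 only; for alternate locations the
#' highest-occupancy conformer is kept), extracts side-chain heavy atoms,
#' and evaluates \code{\link{contactMap}} under the supplied residue-to-MSA
#' column map.  Resolved columns are the mapped residues present in the
#' file with at least one (possibly proxy) side-chain heavy atom; residues
#' with none contribute no contacts.
#'
#' @param path PDB (or mmCIF, via bio3d) file path.
#' @param chain chain identifier.
#' @param columnMap named integer vector, author residue number -> MSA column.
#' @param uniprotId,state,classLabel metadata for the record.
#' @param L alignment width.
#' @param structureId defaults to the file base name.
#' @param ... passed to \code{\link{contactMap}}.
#' @return a \code{\linkS4class{StructureContacts}}.
#' @export
readStructureContacts <- function(path, chain, columnMap, uniprotId, state,
                                  classLabel, L,
                                  structureId = sub("\\.[^.]*$", "", basename(path)),
                                  ...) {
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    bio3d::read.cif(path) else bio3d::read.pdb(path, multi = FALSE)
  at <- pdb$atom
  at <- at[at$chain == chain & at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  at <- at[at$type == "ATOM", , drop = FALSE]
  # altloc: keep highest-occupancy conformer per residue/atom name
  if (!is.null(at$alt)) {
    blank <- is.na(at$alt) | at$alt %in% c("", " ")
    if (any(!blank)) {
      key <- paste(at$resno, at$elety)
      o <- order(key, -at$o)
      at <- at[o, , drop = FALSE]
      at <- at[!duplicated(paste(at$resno, at$elety)), , drop = FALSE]
    }
  }
  atoms <- data.frame(resno = at$resno, elety = at$elety, resid = at$resid,
                      x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  contacts <- contactMap(atoms, columnMap, ...)
  side <- atoms[!grepl("^[0-9]*H", atoms$elety), , drop = FALSE]
  hasSide <- !(side$elety %in% BACKBONE_ATOMS) |
    (side$resid %in% c("GLY") & side$elety == "CA")
  resolvedRes <- unique(side$resno[hasSide])
  resolved <- columnMap[as.character(resolvedRes)]
  resolved <- resolved[!is.na(resolved)]
  structureContacts(structureId, chain, uniprotId, state, classLabel, L,
                    contacts, resolved)
}

#' UniProt redundancy weights across both conformational clusters
#'
#' Each chain n gets weight \eqn{w_n = 1/u_n}, where \eqn{u_n} counts how
#' many chains in the combined active + inactive set share its UniProt ID.
#' Chains with a missing UniProt ID are, by default, treated as unique with
#' a warning.
#'
#' @param structures list of \code{StructureContacts} spanning both clusters.
#' @param missingId \code{"unique"} (default, warn) or \code{"error"}.
#' @return numeric vector of weights, one per structure.
#' @export
redundancyWeights <- function(structures, missingId = c("unique", "error")) {
  missingId <- match.arg(missingId)
  ids <- vapply(structures, function(s) s@uniprotId, character(1))
  miss <- is.na(ids) | ids == ""
  if (any(miss)) {
    if (missingId == "error") stop(sum(miss), " structures lack a UniProt ID")
    warning(sum(miss), " structures lack a UniProt ID; treated as unique")
    ids[miss] <- paste0(".anon", which(miss))
  }
  counts <- table(ids)
  1 / as.numeric(counts[ids])
}

#' Weighted contact frequencies of a conformational ensemble
#'
#' \eqn{c_{ij} = \sum_n w_n \delta_{ij}(n) / \sum_{n'} w_{n'}}, both sums
#' restricted to structures in which columns i and j are both resolved
#' (per-pair normalization): an unresolved residue is missing data, not a
#' non-contact.  Pairs with zero resolved support are NA in the frequency
#' matrix.  A \code{"global"} normalization mode keeps the full-weight
#' denominator instead.
#'
#' @param structures list of \code{StructureContacts}, all in \code{state}.
#' @param weights numeric vector from \code{\link{redundancyWeights}}
#'   (computed over both clusters); default all 1.
#' @param state the shared conformational state (checked).
#' @param normalization \code{"per-pair"} (default) or \code{"global"}.
#' @return a \code{\linkS4class{ConformationEnsemble}}.
#' @export
ensembleFrequencies <- function(structures, weights = NULL, state = NULL,
                                normalization = c("per-pair", "global")) {
  normalization <- match.arg(normalization)
  if (!length(structures)) stop("empty structure list")
  if (is.null(weights)) weights <- rep(1, length(structures))
  stopifnot(length(weights) == length(structures))
  states <- vapply(structures, function(s) s@state, character(1))
  if (is.null(state)) state <- states[1]
  if (!all(states == state))
    stop("all structures must share the state '", state, "'")
  classes <- vapply(structures, function(s) s@classLabel, character(1))
  L <- structures[[1]]@L
  num <- matrix(0, L, L)
  den <- matrix(0, L, L)
  for (k in seq_along(structures)) {
    s <- structures[[k]]
    r <- s@resolved
    ind <- numeric(L); ind[r] <- 1
    den <- den + weights[k] * tcrossprod(ind)
    if (nrow(s@contacts))
      num[s@contacts] <- num[s@contacts] + weights[k]
  }
  num <- num + t(num)  # symmetrize (contacts stored i < j)
  if (normalization == "global") den[] <- sum(weights)
  cf <- ifelse(den > 0, num / den, NA_real_)
  # pairs at |i-j| <= 4 are outside the contact definition
  idx <- abs(row(cf) - col(cf)) <= 4
  cf[idx] <- NA_real_
  den[idx] <- 0
  new("ConformationEnsemble",
      classLabel = unique(classes), state = state, cfreq = cf,
      support = den, nStructures = length(structures))
}

#' Contact-frequency difference map (active minus inactive)
#'
#' @param active ensemble in state \code{"active_DFG_in"}.
#' @param inactive ensemble in state \code{"classical_DFG_out"}.
#' @param quiet suppress the warning about undefined pairs.
#' @return a \code{\linkS4class{DeltaContactMap}}; pairs undefined in either
#'   ensemble contribute 0 with a warning.
#' @export
deltaContacts <- function(active, inactive, quiet = FALSE) {
  if (!identical(active@classLabel, inactive@classLabel))
    stop("class labels differ: ", active@classLabel, " vs ", inactive@classLabel)
  if (active@state != "active_DFG_in" || inactive@state != "classical_DFG_out")
    stop("deltaContacts expects (active_DFG_in, classical_DFG_out) in that order")
  a <- active@cfreq; b <- inactive@cfreq
  und <- (is.na(a) | is.na(b)) & abs(row(a) - col(a)) > 4
  nUnd <- sum(und[upper.tri(und)])
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  d <- a - b
  d[abs(row(d) - col(d)) <= 4] <- 0
  if (nUnd > 0 && !quiet)
    warning(nUnd, " pairs had no resolved support in one ensemble; treated as delta = 0")
  new("DeltaContactMap", classLabel = active@classLabel, delta = d,
      orientation = "active_minus_inactive", nUndefined = as.integer(nUnd))
}

#' Ensemble/difference table export
#'
#' Round-trippable TSV with one row per |i-j| > 4 pair that has support in
#' either ensemble: i, j, c_active, c_inactive, delta, n_support (summed
#' weights backing the pair across both ensembles).  Undefined frequencies
#' are written as ".".
#'
#' @param active,inactive \code{ConformationEnsemble} objects (same class).
#' @param path output TSV path.
#' @return invisibly, the data.frame written.
#' @export
writeEnsembleTable <- function(active, inactive, path) {
  a <- active@cfreq; b <- inactive@cfreq
  sup <- active@support + inactive@support
  ut <- which(upper.tri(a) & (col(a) - row(a) > 4) & sup > 0, arr.ind = TRUE)
  df <- data.frame(i = ut[, 1], j = ut[, 2],
                   c_active = a[ut], c_inactive = b[ut],
                   delta = ifelse(is.na(a[ut]), 0, a[ut]) -
                           ifelse(is.na(b[ut]), 0, b[ut]),
                   n_support = sup[ut])
  df <- df[order(df$i, df$j), ]
  out <- df
  out$c_active <- ifelse(is.na(df$c_active), ".", format(df$c_active, digits = 17))
  out$c_inactive <- ifelse(is.na(df$c_inactive), ".", format(df$c_inactive, digits = 17))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
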