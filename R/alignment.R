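#' @include AllGenerics.R
NULL

#' Construct a KinaseAlignment from raw character data
#'
#' @param seqs character vector of aligned sequences (equal width) or a
#'   character matrix N x L.
#' @param ids sequence identifiers; defaults to names of \code{seqs} or
#'   \code{seq1..seqN}.
#' @param unknown policy for nonstandard residue codes (X, B, Z, J, U, O):
#'   \code{"gap"} maps them to \code{"-"} (default), \code{"error"} aborts.
#' @param classLabel,weight,metadata optional per-sequence vectors.
#' @return A \code{\linkS4class{KinaseAlignment}}.
#' @export
kinaseAlignment <- function(seqs, ids = NULL, unknown = c("gap", "error"),
                            classLabel = NULL, weight = NULL, metadata = NULL) {
  unknown <- match.arg(unknown)
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (is.null(ids)) ids <- names(seqs)
    widths <- nchar(seqs)
    if (length(unique(widths)) > 1L) {
      w <- table(widths)
      ref <- as.integer(names(w)[which.max(w)])
      bad <- which(widths != ref)[1]
      stop(sprintf("ragged alignment: record '%s' has width %d, expected %d",
                   if (!is.null(ids)) ids[bad] else paste0("seq", bad),
                   widths[bad], ref))
    }
    mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), byrow = TRUE)
  }
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(mat)))
  mat <- toupper(mat)
  mat[mat == "."] <- "-"
  ns <- mat %in% NONSTANDARD_CODES
  if (any(ns)) {
    if (unknown == "error")
      stop(sprintf("%d nonstandard residue codes present (e.g. '%s')",
                   sum(ns), mat[ns][1]))
    mat[ns] <- "-"
  }
  bad <- !(mat %in% aaAlphabet())
  if (any(bad))
    stop(sprintf("unrecognized symbol '%s' in alignment", mat[bad][1]))
  n <- nrow(mat)
  rownames(mat) <- ids
  new("KinaseAlignment",
      ids = as.character(ids),
      residues = mat,
      classLabel = if (is.null(classLabel)) rep("other", n) else classLabel,
      weight = if (is.null(weight)) rep(1, n) else weight,
      metadata = if (is.null(metadata)) rep("", n) else metadata)
}

#' Read a fixed-width multiple sequence alignment
#'
#' FASTA and Stockholm are parsed with Biostrings; sequences are uppercased,
#' "." gaps normalized to "-", and nonstandard codes handled per
#' \code{unknown}.  All records must have identical width.
#'
#' @param path file path.
#' @param format \code{"fasta"} or \code{"stockholm"}; default guessed from
#'   the file extension (\code{.sto}/\code{.stk} = Stockholm).
#' @param unknown see \code{\link{kinaseAlignment}}.
#' @return A \code{\linkS4class{KinaseAlignment}}.
#' @export
readAlignment <- function(path, format = NULL, unknown = c("gap", "error")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty alignment file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.(sto|stk|stockholm)$", path, ignore.case = TRUE))
      "stockholm" else "fasta"
  }
  format <- match.arg(format, c("fasta", "stockholm"))
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path, format = "fasta")
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
    ss <- as(aln, "AAStringSet")
  }
  if (length(ss) == 0) stop("no sequence records in: ", path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  kinaseAlignment(seqs, unknown = unknown)
}

#' Write a KinaseAlignment as FASTA
#' @param x a \code{KinaseAlignment}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeAlignment <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seqs <- apply(residueMatrix(x), 1, paste, collapse = "")
  writeLines(paste0(">", sequenceIds(x), "\n", seqs), con)
  invisible(path)
}

#' Classify one aligned kinase sequence as TK, STK or other
#'
#' Tyrosine and serine/threonine kinases are distinguished by conserved
#' residues of their phosphoacceptor pockets at three MSA columns: the
#' HRD+2 position (Ala or Arg in TKs, Lys in STKs), the HRD+4 position
#' (Arg in TKs) and the APE-2 position (Trp in TKs).  A sequence is a TK
#' when it satisfies the TK condition at all three columns, an STK when it
#' has Lys at the first column and is non-overlapping with the TK condition
#' at the second (i.e. not Arg); anything else — including a gap at any
#' diagnostic column — is "other".
#'
#' @param seq character vector of aligned residues (or a single string).
#' @param positions 1-based diagnostic MSA columns, default \code{c(126, 128,
#'   165)} for the canonical 259-column kinase alignment.  Exposed so that
#'   reduced synthetic alignments can place their diagnostic columns
#'   elsewhere.
#' @return \code{"TK"}, \code{"STK"} or \code{"other"}.
#' @export
classifyKinase <- function(seq, positions = c(126L, 128L, 165L)) {
  if (length(seq) == 1L && nchar(seq) > 1L)
    seq <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(seq) < max(positions))
    stop(sprintf("sequence has %d columns; diagnostic column %d out of range",
                 length(seq), max(positions)))
  s <- toupper(seq[positions])
  if (any(s %in% c("-", ".")))
    return("other")
  if (s[1] %in% c("A", "R") && s[2] == "R" && s[3] == "W")
    return("TK")
  if (s[1] == "K" && s[2] != "R")
    return("STK")
  "other"
}

#' Classify every sequence in an alignment
#'
#' Applies \code{\link{classifyKinase}} row-wise and stores the labels, so
#' labels are always reproducible from the residues.
#'
#' @param x a \code{KinaseAlignment}.
#' @param positions diagnostic columns, see \code{\link{classifyKinase}}.
#' @return the alignment with updated class labels.
#' @export
classifyKinases <- function(x, positions = c(126L, 128L, 165L)) {
  labs <- apply(residueMatrix(x), 1, classifyKinase, positions = positions)
  classLabels(x) <- unname(labs)
  x
}

# Side-chain van der Waals volumes (A^3), standard literature values.
SIDECHAIN_VOLUME <- c(
  A = 67, R = 148, N = 96, D = 91, C = 86, E = 109, Q = 114, G = 48,
  H = 118, I = 124, L = 124, K = 135, M = 124, F = 135, P = 90, S = 73,
  T = 93, W = 163, Y = 141, V = 105
)

#' Classify a gatekeeper residue as small or large
#'
#' Small gatekeepers (side-chain volume < 110 cubic Angstrom) are Gly, Ala,
#' Ser, Pro, Thr, Cys, Val; large gatekeepers are Asn, His, Ile, Leu, Met,
#' Lys, Phe, Glu, Tyr, Gln, Trp, Arg.  Membership in these two sets decides
#' first; Asp, which appears in neither set, is resolved against the
#' bundled volume table (91 cubic Angstrom, hence small) at the same
#' threshold.  Gaps and unknown symbols are unclassifiable.
#'
#' @param residue one-letter amino-acid code (vectorized).
#' @param threshold volume threshold in cubic Angstrom (default 110).
#' @return character vector over \code{"small"}, \code{"large"},
#'   \code{"unclassifiable"}.
#' @export
gatekeeperClass <- function(residue, threshold = 110) {
  small <- c("G", "A", "S", "P", "T", "C", "V")
  large <- c("N", "H", "I", "L", "M", "K", "F", "E", "Y", "Q", "W", "R")
  residue <- toupper(residue)
  vapply(residue, function(r) {
    if (r %in% small) return("small")
    if (r %in% large) return("large")
    if (r %in% names(SIDECHAIN_VOLUME))
      return(if (SIDECHAIN_VOLUME[[r]] < threshold) "small" else "large")
    "unclassifiable"
  }, character(1), USE.NAMES = FALSE)
}

#' Per-sequence gap counts
#' @param x a \code{KinaseAlignment}.
#' @return integer vector.
#' @export
gapCounts <- function(x) {
  as.integer(rowSums(residueMatrix(x) == "-"))
}

#' Remove heavily gapped sequences
#'
#' Retains exactly the sequences whose gap count is at most \code{maxGaps}
#' (the canonical filter removes sequences with 32 or more gaps, i.e.
#' \code{maxGaps = 31}).  Order is preserved; idempotent.
#'
#' @param x a \code{KinaseAlignment}.
#' @param maxGaps maximum number of gap columns allowed (default 31).
#' @return the filtered alignment (possibly empty).
#' @export
filterGapped <- function(x, maxGaps = 31L) {
  keep <- gapCounts(x) <= maxGaps
  subsetAlignment(x, keep)
}

#' Subset an alignment by index or logical mask
#' @param x a \code{KinaseAlignment}.
#' @param idx integer or logical index.
#' @return a \code{KinaseAlignment}.
#' @export
subsetAlignment <- function(x, idx) {
  new("KinaseAlignment",
      ids = x@ids[idx],
      residues = x@residues[idx, , drop = FALSE],
      classLabel = x@classLabel[idx],
      weight = x@weight[idx],
      metadata = x@metadata[idx])
}

#' Combine two alignments of equal width
#' @param x,y \code{KinaseAlignment} objects with the same L.
#' @return a \code{KinaseAlignment}.
#' @export
bindAlignments <- function(x, y) {
  stopifnot(alignmentWidth(x) == alignmentWidth(y))
  new("KinaseAlignment",
      ids = c(x@ids, y@ids),
      residues = rbind(x@residues, y@residues),
      classLabel = c(x@classLabel, y@classLabel),
      weight = c(x@weight, y@weight),
      metadata = c(x@metadata, y@metadata))
}

# Pairwise identity-neighbour counts for a residue matrix: for each sequence,
# the number of sequences (itself included) whose Hamming identity over all
# L columns is >= minIdentity.  Gap is an ordinary symbol.  Exact all-pairs
# computation via one indicator cross-product per alphabet symbol.
identityNeighbourCounts <- function(mat, minIdentity) {
  n <- nrow(mat); L <- ncol(mat)
  matches <- matrix(0, n, n)
  for (a in unique(as.vector(mat))) {
    ind <- (mat == a) * 1
    matches <- matches + tcrossprod(ind)
  }
  as.integer(rowSums(matches / L >= minIdentity))
}

#' Phylogenetic down-weights at an identity threshold
#'
#' Each sequence s receives weight 1/n(s), where n(s) is the number of
#' sequences in the same class (s itself included) whose pairwise Hamming
#' identity over all L columns is at least \code{1 - divergenceThreshold}.
#' The gap symbol counts as an ordinary 21st symbol.  The effective number
#' of sequences in a class is the sum of its weights.  The neighbourhood is
#' computed by exact all-pairs comparison.
#'
#' @param x a \code{KinaseAlignment}.
#' @param divergenceThreshold neighbourhood radius as a divergence fraction;
#'   the default 0.40 makes sequences with identity of at least 0.60 neighbours.
#' @param byClass if TRUE (default) the neighbourhood is restricted to
#'   sequences with the same class label; classes must be assigned.
#' @return numeric vector of weights in (0, 1], named by sequence id.
#' @export
phyloWeights <- function(x, divergenceThreshold = 0.40, byClass = TRUE) {
  minIdentity <- 1 - divergenceThreshold
  mat <- residueMatrix(x)
  n <- nSequences(x)
  w <- numeric(n)
  groups <- if (byClass) split(seq_len(n), classLabels(x)) else list(seq_len(n))
  for (idx in groups) {
    counts <- identityNeighbourCounts(mat[idx, , drop = FALSE], minIdentity)
    w[idx] <- 1 / counts
  }
  stats::setNames(w, sequenceIds(x))
}

#' Attach phylogenetic weights to an alignment
#' @inheritParams phyloWeights
#' @return the alignment with its \code{weight} slot replaced.
#' @export
addPhyloWeights <- function(x, divergenceThreshold = 0.40, byClass = TRUE) {
  seqWeights(x) <- unname(phyloWeights(x, divergenceThreshold, byClass))
  x
}

#' Classification and weight summary table
#'
#' One row per sequence: id, class, gap count, gatekeeper residue and size
#' class (when a gatekeeper column is given), and phylogenetic weight.
#'
#' @param x a classified, weighted \code{KinaseAlignment}.
#' @param gatekeeperColumn optional 1-based MSA column of the gatekeeper.
#' @return data.frame.
#' @export
classificationTable <- function(x, gatekeeperColumn = NULL) {
  df <- data.frame(
    id = sequenceIds(x),
    class = classLabels(x),
    n_gaps = gapCounts(x),
    weight = seqWeights(x),
    stringsAsFactors = FALSE
  )
  if (!is.null(gatekeeperColumn)) {
    gk <- residueMatrix(x)[, gatekeeperColumn]
    df$gatekeeper_residue <- gk
    df$gatekeeper_class <- gatekeeperClass(gk)
  }
  df
}
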