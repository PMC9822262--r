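# Shared fixtures, all generated in code.

# Two-column, two-state toy model: h1 = (0.5, 0), h2 = (0, -1),
# J12(state1, state2) = 2.  H(A, R) = 0.5 - 1 + 2 = 1.5.
toyModel <- function() {
  h <- rbind(c(0.5, 0), c(0, -1))
  J <- array(0, dim = c(1, 2, 2))
  J[1, 1, 2] <- 2
  pottsModel(h, J, alphabet = c("A", "R"))
}

randomModel <- function(L, q, seed, sd = 0.5, gapped = TRUE) {
  set.seed(seed)
  alphabet <- if (gapped) c(aaAlphabet()[seq_len(q - 1)], "-")
              else aaAlphabet()[seq_len(q)]
  P <- L * (L - 1) / 2
  pottsModel(matrix(rnorm(L * q, sd = sd), L, q),
             array(rnorm(P * q * q, sd = sd), dim = c(P, q, q)),
             alphabet = alphabet)
}

randomAlignmentFor <- function(model, n, seed, gapFraction = 0.1) {
  set.seed(seed)
  letters <- model@alphabet
  mat <- matrix(sample(setdiff(letters, "-"), n * model@L, replace = TRUE),
                nrow = n)
  if (gapFraction > 0 && "-" %in% letters) {
    idx <- runif(length(mat)) < gapFraction
    mat[idx] <- "-"
  }
  kinaseAlignment(mat, ids = sprintf("r%03d", seq_len(n)))
}

# DeltaContactMap built directly from a pair list.
dmapFromPairs <- function(L, pairs, deltas, classLabel = "STK") {
  d <- matrix(0, L, L)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  for (k in seq_len(nrow(pairs))) {
    d[pairs[k, 1], pairs[k, 2]] <- deltas[k]
    d[pairs[k, 2], pairs[k, 1]] <- deltas[k]
  }
  new("DeltaContactMap", classLabel = classLabel, delta = d,
      orientation = "active_minus_inactive", nUndefined = 0L)
}

randomDmap <- function(L, seed, classLabel = "STK", density = 0.5) {
  set.seed(seed)
  d <- matrix(0, L, L)
  ut <- which(upper.tri(d) & col(d) - row(d) > 4, arr.ind = TRUE)
  keep <- which(runif(nrow(ut)) < density)
  d[ut[keep, , drop = FALSE]] <- runif(length(keep), -1, 1)
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  new("DeltaContactMap", classLabel = classLabel, delta = d,
      orientation = "active_minus_inactive", nUndefined = 0L)
}

# Independent quadruple-loop oracle for the threaded penalty, written
# directly against the slots, with gaps always contributing through the
# model's own gap state (gapPolicy = "model" semantics).
bruteThread <- function(model, seqChars, dmap) {
  L <- model@L
  total <- 0
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      if (j - i <= 4) next
      dc <- dmap@delta[i, j]
      if (dc == 0) next
      for (a in seq_len(model@q)) {
        for (b in seq_len(model@q)) {
          si <- match(seqChars[i], model@alphabet)
          sj <- match(seqChars[j], model@alphabet)
          if (!is.na(si) && !is.na(sj) && si == a && sj == b)
            total <- total - model@J[pairIndex(i, j, L), a, b] * dc
        }
      }
    }
  }
  total
}

# Minimal PDB writer for handcrafted coordinate fixtures.
# atoms: data.frame(resno, resid, elety, x, y, z)
writeTinyPDB <- function(path, atoms, chain = "A") {
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
    seq_len(nrow(atoms)),
    ifelse(nchar(atoms$elety) < 4, paste0(" ", atoms$elety), atoms$elety),
    atoms$resid, chain, atoms$resno, atoms$x, atoms$y, atoms$z,
    substr(atoms$elety, 1, 1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

write_fasta <- function(path, seqs, ids = names(seqs)) {
  writeLines(paste0(">", ids, "\n", seqs), path)
  invisible(path)
}
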