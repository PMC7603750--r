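# Independent brute-force oracles. These deliberately re-derive every
# quantity with plain dynamic programming / enumeration and share no
# code with the package implementation.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
          "K", "M", "F", "P", "S", "T", "W", "Y", "V")

randSeq <- function(n) paste(sample(AA20, n, replace = TRUE),
                             collapse = "")

# exhaustive affine-gap local alignment score (Gotoh, no pruning);
# gap of length L costs open + (L - 1) * ext
oracleLocalScore <- function(q, s, mat, open = 11, ext = 1) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) +
      mat[qc[i], sc[j]]
    X[i + 1, j + 1] <- max(M[i + 1, j] - open, X[i + 1, j] - ext)
    Y[i + 1, j + 1] <- max(M[i, j + 1] - open, Y[i, j + 1] - ext)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# exhaustive affine-gap global alignment score, terminal gaps penalized
oracleGlobalScore <- function(q, s, mat, open = 11, ext = 1) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in 1:m) X[1, j + 1] <- if (j == 1) -open else X[1, j] - ext
  for (i in 1:n) Y[i + 1, 1] <- if (i == 1) -open else Y[i, 1] - ext
  for (i in 1:n) for (j in 1:m) {
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + mat[qc[i], sc[j]]
    X[i + 1, j + 1] <- max(M[i + 1, j] - open, X[i + 1, j] - ext,
                           Y[i + 1, j] - open)
    Y[i + 1, j + 1] <- max(M[i, j + 1] - open, Y[i, j + 1] - ext,
                           X[i, j + 1] - open)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# exact Poisson-binomial upper tail by 2^n subset enumeration
enumPoisBinTail <- function(k, probs) {
  n <- length(probs)
  if (k == 0) return(1)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    if (sum(bits) >= k)
      total <- total + prod(ifelse(bits == 1, probs, 1 - probs))
  }
  total
}

# tiny in-memory database from named character vectors of sequences
makeDb <- function(...) {
  species <- list(...)
  sets <- lapply(species, function(seqs) Biostrings::AAStringSet(seqs))
  proteomeDbFromSets(sets)
}
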