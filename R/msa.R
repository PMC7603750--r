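#' @useDynLib CysConserve, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.rowsToMatrix <- function(rows) {
  do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
}

#' Align one sequence against an existing alignment (profile step)
#'
#' Global, end-to-end alignment of a new sequence against the current
#' profile using mean-pairwise column scores: a candidate residue scores
#' the average of its substitution scores against the residues already
#' in the column, with gap rows contributing 0. Gaps are affine
#' (\code{gapOpen + (L - 1) * gapExtend}), terminal gaps included.
#' Columns already in the profile are never removed, only new all-gap
#' (for the old rows) columns can be inserted: once a gap, always a gap.
#' For a single-row profile this reduces to exact pairwise global
#' alignment.
#'
#' @param rows named character vector of equal-length gapped rows.
#' @param seq ungapped residue string to insert.
#' @param label row name for the new sequence.
#' @param matrix substitution matrix.
#' @param gapOpen,gapExtend affine gap penalties.
#' @return named character vector of gapped rows (the grown alignment),
#'   with attribute \code{"score"} holding the profile alignment score.
#' @export
alignToProfile <- function(rows, seq, label, matrix, gapOpen = 11,
                           gapExtend = 1) {
  stopifnot(length(rows) >= 1L, nzchar(seq))
  mat <- .rowsToMatrix(rows)
  L1 <- ncol(mat)
  alpha <- rownames(matrix)
  # per-letter counts per column (gaps excluded)
  counts <- vapply(alpha, function(a) colSums(mat == a),
                   numeric(L1))            # L1 x nAlpha
  if (L1 == 1L) counts <- matrix(counts, nrow = 1L,
                                 dimnames = list(NULL, alpha))
  # column score of residue a vs column j = sum_l counts[j,l]*mat[a,l]/r
  colScore <- counts %*% t(matrix[alpha, alpha]) / nrow(mat) # L1 x nAlpha
  sc <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(sc, alpha)
  if (anyNA(idx)) stop("illegal residue in sequence", call. = FALSE)
  S <- t(colScore[, idx, drop = FALSE])    # L2 x L1
  res <- profile_align_path(S, gapOpen, gapExtend)
  ops <- res$path
  # reconstruct rows: op 0/1 consume a profile column, op 0/2 a residue
  profCol <- cumsum(ops != 2L)
  seqPos <- cumsum(ops != 1L)
  oldChars <- matrix("-", nrow = nrow(mat), ncol = length(ops))
  oldChars[, ops != 2L] <- mat[, profCol[ops != 2L], drop = FALSE]
  newChars <- rep("-", length(ops))
  newChars[ops != 1L] <- sc[seqPos[ops != 1L]]
  out <- c(apply(oldChars, 1L, paste, collapse = ""),
           paste(newChars, collapse = ""))
  names(out) <- c(names(rows), label)
  attr(out, "score") <- res$score
  out
}

#' Greedy progressive multiple alignment
#'
#' Query-anchored progressive alignment: starts from the query row and
#' inserts each homolog, in descending order of raw similarity score to
#' the query, via [alignToProfile()]. Row order is query first, then
#' insertion order; the procedure is fully deterministic. An empty
#' representative list yields a single-row (query-only) alignment with a
#' warning.
#'
#' @param query list with \code{id} and \code{sequence}.
#' @param representatives data.frame with columns \code{label} (row
#'   name, e.g. \code{species|accession}), \code{sequence} and
#'   \code{score} (raw similarity to the query); rows must already be
#'   sorted score-descending with ties in species panel order.
#' @param matrix substitution matrix.
#' @param gapOpen,gapExtend affine gap penalties.
#' @return named character vector of gapped rows, query first (named
#'   \code{"query|<id>"}).
#' @export
greedyMsa <- function(query, representatives, matrix, gapOpen = 11,
                      gapExtend = 1) {
  rows <- setNames(query$sequence, paste0("query|", query$id))
  if (is.null(representatives) || nrow(representatives) == 0L) {
    warning("no representatives; returning query-only alignment")
    return(rows)
  }
  ord <- order(-representatives$score)
  representatives <- representatives[ord, , drop = FALSE]
  for (i in seq_len(nrow(representatives))) {
    rows <- alignToProfile(rows, representatives$sequence[i],
                           representatives$label[i], matrix,
                           gapOpen, gapExtend)
  }
  attr(rows, "score") <- NULL
  rows
}

#' Map a query residue index to its alignment column
#'
#' @param msa named character vector of gapped rows, query first.
#' @param pos 1-based index into the ungapped query sequence.
#' @return 1-based column index holding the pos-th query residue.
#' @export
mapQueryPosition <- function(msa, pos) {
  qc <- strsplit(unname(msa[1]), "", fixed = TRUE)[[1]]
  resCols <- which(qc != "-")
  if (pos < 1L || pos > length(resCols))
    stop("position ", pos, " outside the query (length ",
         length(resCols), ")", call. = FALSE)
  resCols[pos]
}

#' Fraction of query residues identically conserved in one row
#'
#' The per-homolog ingredient of whole-protein conservation: the
#' fraction of query-residue columns where the row carries the identical
#' residue (a gap or a different residue counts as non-match).
#'
#' @param msa named character vector of gapped rows, query first.
#' @param row row index (> 1) or row name.
#' @return a value in [0, 1].
#' @export
identityToQuery <- function(msa, row) {
  qc <- strsplit(unname(msa[1]), "", fixed = TRUE)[[1]]
  rc <- strsplit(unname(msa[row]), "", fixed = TRUE)[[1]]
  qRes <- qc != "-"
  sum(qc[qRes] == rc[qRes]) / sum(qRes)
}

#' Remove gaps from an alignment row
#' @param row gapped string.
#' @export
ungapRow <- function(row) gsub("-", "", row, fixed = TRUE)
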