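#' Optimal local alignment of two protein sequences
#'
#' Exact Smith-Waterman with affine gaps (a gap of length L costs
#' \code{gapOpen + (L - 1) * gapExtend}), computed via
#' \link[Biostrings]{pairwiseAlignment}. When no cell scores positively
#' the result is an empty alignment with raw score 0.
#'
#' @param query,subject residue strings.
#' @param matrix substitution matrix from [substitutionMatrix()].
#' @param gapOpen,gapExtend affine gap penalties.
#' @return list with \code{rawScore}, \code{queryAligned},
#'   \code{subjectAligned}, 1-based inclusive \code{qstart}, \code{qend},
#'   \code{sstart}, \code{send}, and \code{identity} (matches over
#'   aligned columns; gap columns count in the denominator).
#' @examples
#' m <- substitutionMatrix()
#' smithWaterman("ACDE", "ACDE", m)$rawScore  # 4 + 9 + 6 + 5
#' @export
smithWaterman <- function(query, subject, matrix, gapOpen = 11,
                          gapExtend = 1) {
  if (!nzchar(query) || !nzchar(subject))
    stop("empty sequence", call. = FALSE)
  .assertResidues(query, "query"); .assertResidues(subject, "subject")
  pa <- Biostrings::pairwiseAlignment(
    pattern = query, subject = subject, type = "local",
    substitutionMatrix = matrix,
    gapOpening = gapOpen - gapExtend, gapExtension = gapExtend)
  s <- Biostrings::score(pa)
  qa <- as.character(Biostrings::alignedPattern(pa))
  sa <- as.character(Biostrings::alignedSubject(pa))
  if (s <= 0 || !nzchar(qa)) {
    return(list(rawScore = 0, queryAligned = "", subjectAligned = "",
                qstart = 0L, qend = 0L, sstart = 0L, send = 0L,
                identity = 0))
  }
  qc <- strsplit(qa, "")[[1]]; sc <- strsplit(sa, "")[[1]]
  list(rawScore = s, queryAligned = qa, subjectAligned = sa,
       qstart = Biostrings::start(Biostrings::pattern(pa)),
       qend = Biostrings::end(Biostrings::pattern(pa)),
       sstart = Biostrings::start(Biostrings::subject(pa)),
       send = Biostrings::end(Biostrings::subject(pa)),
       identity = sum(qc == sc & qc != "-") / length(qc))
}

#' Bit score and e-value from a raw alignment score
#'
#' Karlin-Altschul closed form: \eqn{E = K m n e^{-\lambda S}} and
#' \eqn{bits = (\lambda S - \ln K) / \ln 2}, with gapped-BLOSUM62
#' constants by default. Replaces the e-value a heuristic search engine
#' would report; it is strictly decreasing in the raw score and linear
#' in the database size.
#'
#' @param rawScore non-negative raw alignment score.
#' @param queryLen query length (m).
#' @param dbResidues total database residue count (n).
#' @param params a [SearchParams-class] supplying \code{lambda}, \code{K}.
#' @return list with \code{bitScore} and \code{evalue}.
#' @export
evalueFromScore <- function(rawScore, queryLen, dbResidues,
                            params = searchParams()) {
  stopifnot(rawScore >= 0, queryLen > 0, dbResidues > 0)
  lam <- params@lambda; K <- params@K
  list(bitScore = (lam * rawScore - log(K)) / log(2),
       evalue = K * queryLen * dbResidues * exp(-lam * rawScore))
}

# rank and filter a per-species candidate table:
# e-value cutoff, then relative raw-score band, then truncation
.selectHits <- function(df, params) {
  if (nrow(df) == 0L) return(df)
  df <- df[df$evalue <= params@evalueCutoff & df$rawScore > 0, ,
           drop = FALSE]
  if (nrow(df) == 0L) return(df)
  df <- df[order(-df$rawScore, df$evalue, df$accession), , drop = FALSE]
  best <- df$rawScore[1]
  df <- df[df$rawScore >= params@relScoreCutoff * best, , drop = FALSE]
  utils::head(df, params@maxHits)
}

.emptyHits <- function() {
  data.frame(accession = character(0), rawScore = numeric(0),
             bitScore = numeric(0), evalue = numeric(0),
             identity = numeric(0), queryAligned = character(0),
             subjectAligned = character(0), qstart = integer(0),
             qend = integer(0), sstart = integer(0), send = integer(0),
             stringsAsFactors = FALSE)
}

#' Search one species for homologs of a query
#'
#' Aligns the query locally against every sequence of the species,
#' converts raw scores to e-values over the whole database's residue
#' count, drops hits above the e-value cutoff, drops survivors scoring
#' below \code{relScoreCutoff} times the species' best raw score, and
#' keeps at most \code{maxHits} candidates (ties broken by e-value then
#' accession). An empty hit list is a valid outcome.
#'
#' @param query list or one-row data.frame with \code{id} and
#'   \code{sequence}.
#' @param db a [ProteomeDb-class].
#' @param species a panel species label.
#' @param matrix substitution matrix.
#' @param params a [SearchParams-class].
#' @return a [SpeciesHits-class] object.
#' @export
searchSpecies <- function(query, db, species, matrix,
                          params = searchParams()) {
  if (!(species %in% db@panel@species))
    stop("species '", species, "' not in panel", call. = FALSE)
  set <- db@sequences[[species]]
  if (length(set) == 0L)
    return(new("SpeciesHits", species = species, hits = .emptyHits()))
  bare <- set
  S4Vectors::mcols(bare) <- NULL
  scores <- Biostrings::pairwiseAlignment(
    pattern = bare, subject = query$sequence, type = "local",
    substitutionMatrix = matrix,
    gapOpening = params@gapOpen - params@gapExtend,
    gapExtension = params@gapExtend, scoreOnly = TRUE)
  scores <- pmax(scores, 0)
  ev <- evalueFromScore2(scores, nchar(query$sequence), dbResidues(db),
                         params)
  df <- data.frame(accession = names(set), rawScore = scores,
                   bitScore = ev$bitScore, evalue = ev$evalue,
                   stringsAsFactors = FALSE)
  df <- .selectHits(df, params)
  if (nrow(df) == 0L)
    return(new("SpeciesHits", species = species, hits = .emptyHits()))
  det <- lapply(df$accession, function(acc)
    smithWaterman(query$sequence, as.character(set[[acc]]), matrix,
                  params@gapOpen, params@gapExtend))
  df$identity <- vapply(det, `[[`, numeric(1), "identity")
  df$queryAligned <- vapply(det, `[[`, character(1), "queryAligned")
  df$subjectAligned <- vapply(det, `[[`, character(1), "subjectAligned")
  df$qstart <- vapply(det, `[[`, integer(1), "qstart")
  df$qend <- vapply(det, `[[`, integer(1), "qend")
  df$sstart <- vapply(det, `[[`, integer(1), "sstart")
  df$send <- vapply(det, `[[`, integer(1), "send")
  rownames(df) <- NULL
  new("SpeciesHits", species = species, hits = df)
}

# vectorized e-value helper
evalueFromScore2 <- function(scores, m, n, params) {
  lam <- params@lambda; K <- params@K
  list(bitScore = (lam * scores - log(K)) / log(2),
       evalue = K * m * n * exp(-lam * scores))
}

#' Search every panel species
#'
#' @inheritParams searchSpecies
#' @return named list of [SpeciesHits-class], in panel order.
#' @export
searchAllSpecies <- function(query, db, matrix, params = searchParams()) {
  out <- lapply(db@panel@species, function(sp)
    searchSpecies(query, db, sp, matrix, params))
  names(out) <- db@panel@species
  out
}

#' Build hit lists from tabular search-engine output
#'
#' Adapter for the standard 12-column tabular protein-search format
#' (qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore), so a heuristic engine can replace
#' the built-in aligner on large databases. The bit score stands in for
#' the raw score in ranking and the relative-score band; filtering is
#' otherwise identical to [searchSpecies()].
#'
#' @param file path to, or character lines of, the tabular output for
#'   ONE query.
#' @param db a [ProteomeDb-class]; subject accessions must resolve in it.
#' @param params a [SearchParams-class].
#' @return named list of [SpeciesHits-class], one per panel species.
#' @export
readTabularHits <- function(file, db, params = searchParams()) {
  lines <- if (length(file) == 1L && !grepl("\n|\t", file) &&
               file.exists(file)) readLines(file)
           else unlist(strsplit(file, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  acc2sp <- unlist(lapply(db@panel@species, function(sp)
    setNames(rep(sp, length(db@sequences[[sp]])),
             names(db@sequences[[sp]]))))
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    p <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(p) < 12L)
      stop("malformed tabular row at line ", i, call. = FALSE)
    acc <- p[2]
    if (!(acc %in% names(acc2sp)))
      stop("unknown accession '", acc, "' at line ", i, call. = FALSE)
    rows[[i]] <- data.frame(
      species = unname(acc2sp[acc]), accession = acc,
      rawScore = as.numeric(p[12]), bitScore = as.numeric(p[12]),
      evalue = as.numeric(p[11]), identity = as.numeric(p[3]) / 100,
      queryAligned = NA_character_, subjectAligned = NA_character_,
      qstart = as.integer(p[7]), qend = as.integer(p[8]),
      sstart = as.integer(p[9]), send = as.integer(p[10]),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  out <- lapply(db@panel@species, function(sp) {
    df <- if (is.null(tab)) .emptyHits()
          else tab[tab$species == sp, setdiff(names(tab), "species"),
                   drop = FALSE]
    df <- .selectHits(df, params)
    rownames(df) <- NULL
    new("SpeciesHits", species = sp, hits = df)
  })
  names(out) <- db@panel@species
  out
}
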