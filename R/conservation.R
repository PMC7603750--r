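#' Positions of a target amino acid in a sequence
#'
#' @param seq residue string.
#' @param targetAA single letter or vector/compound string of letters
#'   (e.g. \code{"C"} or \code{"CM"} for cysteine and methionine).
#' @return ascending 1-based positions of every occurrence (possibly
#'   empty).
#' @examples
#' findTargetPositions("MKCWC", "C")   # 3 5
#' @export
findTargetPositions <- function(seq, targetAA = "C") {
  letters <- unique(unlist(strsplit(targetAA, "", fixed = TRUE)))
  if (!all(letters %in% .AA_ALPHABET))
    stop("target letters must be amino-acid letters", call. = FALSE)
  which(strsplit(seq, "", fixed = TRUE)[[1]] %in% letters)
}

# character of 'subject' opposite query position 'pos' in the global
# pairwise alignment of query vs subject; returns the whole mapping so
# callers can cache it per candidate
.globalOpposite <- function(query, subject, matrix, gapOpen, gapExtend) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = subject, subject = query, type = "global",
    substitutionMatrix = matrix, gapOpening = gapOpen - gapExtend,
    gapExtension = gapExtend)
  qa <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sa[qa != "-"]   # indexed by query position
}

#' Choose per-species representatives for one query position
#'
#' Realizes the candidate-iteration rule: per species, the already
#' filtered candidates (relative-score band, at most \code{maxHits}) are
#' tried best-first; the first whose global pairwise alignment to the
#' query places the target amino acid opposite the query position
#' becomes the species representative. If no candidate detects the
#' residue the best-scoring candidate is kept (that species will count
#' as non-conserving); species with empty hit lists are excluded
#' entirely. The chosen representatives are then aligned by
#' [greedyMsa()].
#'
#' @param query list with \code{id} and \code{sequence}.
#' @param position 1-based query index; the residue there must be
#'   \code{targetAA}.
#' @param hits named list of [SpeciesHits-class] (one per species).
#' @param db a [ProteomeDb-class] used to look up candidate sequences.
#' @param matrix substitution matrix.
#' @param params a [SearchParams-class].
#' @param targetAA the residue letter being analysed.
#' @param cache optional environment reused across positions of the same
#'   query to memoize pairwise alignments and alignments of identical
#'   representative sets.
#' @return a [ResidueAssessment-class] object.
#' @export
assessPosition <- function(query, position, hits, db, matrix,
                           params = searchParams(), targetAA = "C",
                           cache = new.env(parent = emptyenv())) {
  qc <- substr(query$sequence, position, position)
  if (qc != targetAA)
    stop("query residue at position ", position, " is '", qc,
         "', not '", targetAA, "'", call. = FALSE)
  species <- names(hits)[vapply(hits, function(h) nrow(h@hits) > 0L,
                                logical(1))]
  repAcc <- character(0); repSeq <- character(0); repScore <- numeric(0)
  detected <- logical(0)
  for (sp in species) {
    h <- hits[[sp]]@hits
    found <- NA_integer_
    for (i in seq_len(nrow(h))) {
      key <- paste0("aln:", sp, ":", h$accession[i])
      opp <- cache[[key]]
      if (is.null(opp)) {
        opp <- .globalOpposite(query$sequence,
                               .dbSequence(db, sp, h$accession[i]),
                               matrix, params@gapOpen, params@gapExtend)
        cache[[key]] <- opp
      }
      if (opp[position] == targetAA) { found <- i; break }
    }
    pick <- if (is.na(found)) 1L else found
    repAcc <- c(repAcc, setNames(h$accession[pick], sp))
    repSeq <- c(repSeq, .dbSequence(db, sp, h$accession[pick]))
    repScore <- c(repScore, h$rawScore[pick])
    detected <- c(detected, setNames(!is.na(found), sp))
  }
  reps <- data.frame(label = paste(species, repAcc, sep = "|"),
                     sequence = repSeq, score = repScore,
                     stringsAsFactors = FALSE)
  msaKey <- paste0("msa:", paste(reps$label, collapse = ";"))
  msa <- cache[[msaKey]]
  if (is.null(msa)) {
    msa <- if (nrow(reps) == 0L)
      suppressWarnings(greedyMsa(query, reps, matrix,
                                 params@gapOpen, params@gapExtend))
    else greedyMsa(query, reps, matrix, params@gapOpen, params@gapExtend)
    cache[[msaKey]] <- msa
  }
  new("ResidueAssessment", position = as.integer(position),
      targetAA = targetAA, representatives = repAcc,
      detected = detected, msa = msa,
      column = as.integer(mapQueryPosition(msa, position)))
}

#' Per-species presence flags at the assessed column
#'
#' A species conserves the residue iff its representative row carries
#' the identical target letter exactly at the query position's alignment
#' column; a gap or any other residue (including conservative
#' substitutions) counts as absent. This final multiple-alignment
#' verdict overrides the pairwise detection used during candidate
#' selection.
#'
#' @param ras a [ResidueAssessment-class] object.
#' @return named logical vector, one flag per represented species.
#' @export
presenceFlags <- function(ras) {
  if (length(ras@representatives) == 0L)
    return(setNames(logical(0), character(0)))
  labels <- paste(names(ras@representatives), ras@representatives,
                  sep = "|")
  flags <- vapply(labels, function(lab) {
    substr(ras@msa[[lab]], ras@column, ras@column) == ras@targetAA
  }, logical(1))
  setNames(flags, names(ras@representatives))
}

#' Conservation score k/n
#'
#' The fraction of homolog-bearing species that retain the target
#' residue. Returned at full precision; the output layer rounds to two
#' decimals half-up.
#'
#' @param k number of conserving species.
#' @param n number of species with an accepted homolog.
#' @return k/n.
#' @examples
#' conservationScore(16, 18)            # 0.888...
#' formatScore(conservationScore(16, 18))  # "0.89"
#' @export
conservationScore <- function(k, n) {
  if (n < 1L)
    stop("undefined score: protein has no homolog species", call. = FALSE)
  if (k < 0L || k > n) stop("k must lie in [0, n]", call. = FALSE)
  k / n
}

#' Per-species null probabilities for the significance model
#'
#' The chance that a species would show the target residue at the
#' position absent selective constraint is modelled from the
#' whole-protein conservation: \eqn{q_s = 1 - identity_s}, clamped to
#' \eqn{[10^{-6}, 1 - 10^{-6}]}, where identity is the fraction of query
#' residues identically conserved in that species' representative row.
#'
#' @param ras a [ResidueAssessment-class] object.
#' @return named numeric vector of per-species probabilities.
#' @export
chanceProbabilities <- function(ras) {
  if (length(ras@representatives) == 0L)
    return(setNames(numeric(0), character(0)))
  labels <- paste(names(ras@representatives), ras@representatives,
                  sep = "|")
  q <- vapply(labels, function(lab)
    1 - identityToQuery(ras@msa, lab), numeric(1))
  q <- pmin(pmax(q, 1e-6), 1 - 1e-6)
  setNames(q, names(ras@representatives))
}

#' Upper tail of the Poisson-binomial distribution
#'
#' Exact P(X >= k) where X is the sum of independent Bernoulli variables
#' with the given success probabilities, computed by dynamic-programming
#' convolution in O(n^2). This is the conservation significance model:
#' under the null, each species independently shows the target residue
#' with its chance probability; a small tail probability means the
#' observed number of conserving species is unlikely by chance.
#'
#' @param k observed count (0 returns 1: the whole sample space).
#' @param probs vector of per-species probabilities.
#' @return P(X >= k) in (0, 1].
#' @examples
#' poissonBinomialTail(2, c(0.5, 0.5, 0.5))   # 0.5
#' @export
poissonBinomialTail <- function(k, probs) {
  n <- length(probs)
  stopifnot(k >= 0, k <= n, all(probs >= 0), all(probs <= 1))
  if (k == 0L) return(1)
  pmf <- 1
  for (q in probs) pmf <- c(pmf * (1 - q), 0) + c(0, pmf * q)
  min(1, max(sum(pmf[(k + 1L):(n + 1L)]), .Machine$double.xmin))
}

#' Classify a residue as putatively conserved
#'
#' @param p significance value.
#' @param alpha threshold (default 0.01); the boundary is inclusive.
#' @return TRUE iff \code{p <= alpha}.
#' @export
classifyConserved <- function(p, alpha = 0.01) {
  stopifnot(p > 0, p <= 1, alpha > 0, alpha < 1)
  p <= alpha
}

#' Analyse every target-residue position of one query protein
#'
#' End-to-end per-protein analysis: finds every occurrence of the target
#' letters, chooses species representatives per position (candidate
#' iteration), builds the per-position multiple alignment (cached when
#' positions share a representative set), derives presence flags,
#' conservation score, Poisson-binomial significance and the
#' conserved/not classification.
#'
#' @param query list or one-row data.frame with \code{id},
#'   \code{description} (optional) and \code{sequence}.
#' @param hits named list of [SpeciesHits-class] from
#'   [searchAllSpecies()] or [readTabularHits()].
#' @param db a [ProteomeDb-class].
#' @param matrix substitution matrix.
#' @param params a [SearchParams-class].
#' @param targetAA target letter(s), default \code{"C"}.
#' @param alpha significance threshold, default 0.01.
#' @return a [ProteinReport-class] object.
#' @export
analyzeProtein <- function(query, hits, db, matrix,
                           params = searchParams(), targetAA = "C",
                           alpha = 0.01) {
  letters <- unique(unlist(strsplit(targetAA, "", fixed = TRUE)))
  positions <- findTargetPositions(query$sequence, targetAA)
  nHom <- sum(vapply(hits, function(h) nrow(h@hits) > 0L, logical(1)))
  cache <- new.env(parent = emptyenv())
  assessments <- list(); presence <- list(); chance <- list()
  rows <- vector("list", length(positions))
  seqChars <- strsplit(query$sequence, "", fixed = TRUE)[[1]]
  for (i in seq_along(positions)) {
    pos <- positions[i]
    aa <- seqChars[pos]
    ras <- assessPosition(query, pos, hits, db, matrix, params,
                          targetAA = aa, cache = cache)
    flags <- presenceFlags(ras)
    q <- chanceProbabilities(ras)
    k <- sum(flags); n <- length(flags)
    score <- if (n > 0L) conservationScore(k, n) else NA_real_
    p <- if (n > 0L) poissonBinomialTail(k, q) else NA_real_
    rows[[i]] <- data.frame(
      position = pos, targetAA = aa, k = k, n = n, score = score,
      pValue = p,
      conserved = if (n > 0L) classifyConserved(p, alpha) else FALSE,
      stringsAsFactors = FALSE)
    assessments[[i]] <- ras
    presence[[i]] <- flags
    chance[[i]] <- q
  }
  res <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(position = integer(0), targetAA = character(0),
               k = integer(0), n = integer(0), score = numeric(0),
               pValue = numeric(0), conserved = logical(0))
  desc <- if (!is.null(query$description)) query$description else ""
  new("ProteinReport", id = query$id, description = desc,
      sequence = query$sequence, targetAA = paste(letters, collapse = ""),
      nHomologSpecies = as.integer(nHom), residues = res,
      presence = presence, chanceProbs = chance,
      assessments = assessments, alpha = alpha)
}

#' Summarize a protein report
#'
#' @param report a [ProteinReport-class] object.
#' @return list with \code{id}, \code{homologs}, \code{conservedCount},
#'   \code{totalCount} and the \code{"k of m"} display string.
#' @export
summarizeProtein <- function(report) {
  res <- report@residues
  list(id = report@id, homologs = report@nHomologSpecies,
       conservedCount = sum(res$conserved), totalCount = nrow(res),
       label = sprintf("%d of %d", sum(res$conserved), nrow(res)))
}
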