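#' @import methods
#' @importFrom stats setNames
NULL

# Residue alphabet: the 20 standard amino acids plus X (unknown).
# '*' is tolerated only as a terminal stop codon and stripped on input;
# '-' appears only inside alignments, never inside stored residues.
.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Ordered panel of species and their proteome FASTA files
#'
#' The panel fixes the species order for a whole run; every downstream
#' ordering (search, alignment rows, result rows, tree leaves) derives
#' from it, which is what makes the pipeline deterministic.
#'
#' @slot species character vector of unique species labels, in panel order.
#' @slot files named character vector mapping each species label to its
#'   proteome FASTA path (may be empty when the panel is built in memory).
#' @export
setClass("SpeciesPanel",
  representation(species = "character", files = "character"),
  validity = function(object) {
    if (length(object@species) == 0L) return("panel has no species")
    if (anyDuplicated(object@species)) return("duplicate species labels")
    if (length(object@files) > 0L &&
        !all(names(object@files) %in% object@species))
      return("files named for species not in the panel")
    TRUE
  })

#' Per-species proteome database
#'
#' @slot panel a [SpeciesPanel-class].
#' @slot sequences named list (one entry per panel species, in panel
#'   order) of \link[Biostrings]{AAStringSet} objects; names within a set
#'   are accessions, unique per species; descriptions are kept in
#'   \code{mcols(set)$description}.
#' @slot stats data.frame with one row per species: \code{species},
#'   \code{nSequences}, \code{nResidues}.
#' @export
setClass("ProteomeDb",
  representation(panel = "SpeciesPanel", sequences = "list",
                 stats = "data.frame"),
  validity = function(object) {
    if (!identical(names(object@sequences), object@panel@species))
      return("sequences must have one entry per panel species, in order")
    TRUE
  })

#' Homolog search and selection parameters
#'
#' Gap costs follow the affine convention where a gap of length L costs
#' \code{gapOpen + (L - 1) * gapExtend}. \code{lambda} and \code{K} are
#' Karlin-Altschul statistics for gapped BLOSUM62 used to convert raw
#' scores into bit scores and e-values.
#'
#' @slot gapOpen,gapExtend positive gap penalties (default 11 / 1).
#' @slot evalueCutoff hits with larger e-value are discarded (default 1e-5).
#' @slot maxHits at most this many candidates kept per species (default 9).
#' @slot relScoreCutoff keep only hits scoring at least this fraction of
#'   the species' best raw score (default 0.8).
#' @slot lambda,K gapped Karlin-Altschul constants (defaults 0.267, 0.041).
#' @export
setClass("SearchParams",
  representation(gapOpen = "numeric", gapExtend = "numeric",
                 evalueCutoff = "numeric", maxHits = "integer",
                 relScoreCutoff = "numeric", lambda = "numeric",
                 K = "numeric"),
  validity = function(object) {
    if (object@gapOpen <= 0 || object@gapExtend <= 0)
      return("gap penalties must be positive")
    if (object@maxHits < 1L) return("maxHits must be >= 1")
    if (object@relScoreCutoff <= 0 || object@relScoreCutoff > 1)
      return("relScoreCutoff must be in (0, 1]")
    TRUE
  })

#' Construct search parameters
#'
#' @param gapOpen,gapExtend affine gap penalties; a gap of length L costs
#'   \code{gapOpen + (L - 1) * gapExtend}.
#' @param evalueCutoff maximum e-value for a hit to be considered.
#' @param maxHits maximum candidates retained per species.
#' @param relScoreCutoff relative raw-score band: candidates below
#'   \code{relScoreCutoff * best} are dropped.
#' @param lambda,K Karlin-Altschul statistics for the e-value closed form.
#' @return a [SearchParams-class] object.
#' @examples
#' searchParams(maxHits = 9, relScoreCutoff = 0.8)
#' @export
searchParams <- function(gapOpen = 11, gapExtend = 1, evalueCutoff = 1e-5,
                         maxHits = 9L, relScoreCutoff = 0.8,
                         lambda = 0.267, K = 0.041) {
  new("SearchParams", gapOpen = gapOpen, gapExtend = gapExtend,
      evalueCutoff = evalueCutoff, maxHits = as.integer(maxHits),
      relScoreCutoff = relScoreCutoff, lambda = lambda, K = K)
}

#' Ranked homolog candidates for one species
#'
#' @slot species the species label.
#' @slot hits data.frame sorted best-first (raw score descending, e-value
#'   ascending, accession lexicographic) with columns \code{accession},
#'   \code{rawScore}, \code{bitScore}, \code{evalue}, \code{identity},
#'   \code{queryAligned}, \code{subjectAligned}, \code{qstart},
#'   \code{qend}, \code{sstart}, \code{send}. Zero rows is a valid
#'   outcome (species without a homolog).
#' @export
setClass("SpeciesHits",
  representation(species = "character", hits = "data.frame"),
  validity = function(object) {
    h <- object@hits
    if (nrow(h) > 1L && is.unsorted(-h$rawScore)) {
      return("hits must be sorted by raw score, best first")
    }
    TRUE
  })

#' Per-residue representative set and multiple alignment
#'
#' Produced by [assessPosition()]: for one occurrence of the target amino
#' acid in the query it records, per species, which candidate homolog was
#' chosen (iterating best-first through up to \code{maxHits} candidates
#' until one carries the residue), the resulting progressive multiple
#' alignment, and the alignment column of the query position.
#'
#' @slot position 1-based query residue index.
#' @slot targetAA the residue letter analysed at this position.
#' @slot representatives named character vector species -> accession.
#' @slot detected named logical, whether any candidate of that species
#'   carried the target residue opposite the query position in the
#'   pairwise global alignment used during candidate selection.
#' @slot msa named character vector of equal-length gapped rows; the
#'   query row is first and named \code{"query|<id>"}, homolog rows are
#'   named \code{"<species>|<accession>"}.
#' @slot column 1-based alignment column of the query position.
#' @export
setClass("ResidueAssessment",
  representation(position = "integer", targetAA = "character",
                 representatives = "character", detected = "logical",
                 msa = "character", column = "integer"))

#' Conservation report for one query protein
#'
#' @slot id,description,sequence the query entry.
#' @slot targetAA letters analysed.
#' @slot nHomologSpecies number of species with at least one accepted
#'   candidate homolog (residue-independent).
#' @slot residues data.frame with one row per analysed position:
#'   \code{position}, \code{targetAA}, \code{k} (conserving species),
#'   \code{n} (species with a homolog), \code{score} (k/n, full
#'   precision), \code{pValue}, \code{conserved}.
#' @slot presence list (per residue) of named logical species flags.
#' @slot chanceProbs list (per residue) of named per-species null
#'   probabilities used by the significance model.
#' @slot assessments list of [ResidueAssessment-class] objects.
#' @slot alpha significance level used for classification.
#' @export
setClass("ProteinReport",
  representation(id = "character", description = "character",
                 sequence = "character", targetAA = "character",
                 nHomologSpecies = "integer", residues = "data.frame",
                 presence = "list", chanceProbs = "list",
                 assessments = "list", alpha = "numeric"),
  validity = function(object) {
    r <- object@residues
    if (nrow(r) > 0L) {
      if (!isTRUE(all(r$k <= r$n))) return("k must not exceed n")
      bad <- abs(r$score * r$n - r$k) > 1e-9
      if (any(bad[!is.na(bad)])) return("score * n must equal k")
    }
    TRUE
  })

setMethod("show", "SpeciesPanel", function(object) {
  cat("SpeciesPanel with", length(object@species), "species:",
      paste(utils::head(object@species, 5), collapse = ", "),
      if (length(object@species) > 5) "..." else "", "\n")
})

setMethod("show", "ProteomeDb", function(object) {
  cat("ProteomeDb:", length(object@panel@species), "species,",
      sum(object@stats$nSequences), "sequences,",
      sum(object@stats$nResidues), "residues\n")
})

setMethod("show", "SpeciesHits", function(object) {
  cat("SpeciesHits for", object@species, "-", nrow(object@hits),
      "candidate(s)\n")
  if (nrow(object@hits) > 0)
    print(utils::head(object@hits[, c("accession", "rawScore", "evalue")]))
})

setMethod("show", "ResidueAssessment", function(object) {
  cat("ResidueAssessment:", object@targetAA, "at query position",
      object@position, "-", length(object@representatives),
      "species, alignment column", object@column, "\n")
})

setMethod("show", "ProteinReport", function(object) {
  cat("ProteinReport for", object@id, "\n")
  cat("  homolog species:", object@nHomologSpecies, "\n")
  cat("  residues analysed:", nrow(object@residues),
      "(", sum(object@residues$conserved), "putatively conserved )\n")
})

#' @describeIn SpeciesPanel-class species labels in panel order.
#' @param x object.
#' @export
panelSpecies <- function(x) {
  if (is(x, "ProteomeDb")) x@panel@species else x@species
}

#' Accessor: ranked hits table of a SpeciesHits object
#' @param x a [SpeciesHits-class] object.
#' @export
hitTable <- function(x) x@hits

#' Accessor: per-residue results table of a ProteinReport
#' @param x a [ProteinReport-class] object.
#' @export
residueResults <- function(x) x@residues

#' Accessor: gapped alignment rows of a ResidueAssessment
#' @param x a [ResidueAssessment-class] object.
#' @export
alignmentRows <- function(x) x@msa

.assertResidues <- function(s, what = "sequence") {
  bad <- regexpr(sprintf("[^%s]", paste(.AA_ALPHABET, collapse = "")), s)
  if (bad > 0L)
    stop(sprintf("illegal residue '%s' in %s at position %d",
                 substr(s, bad, bad), what, bad), call. = FALSE)
  invisible(TRUE)
}
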