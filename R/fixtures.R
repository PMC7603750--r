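#' Specification of a synthetic protein family
#'
#' Defines a controlled ortholog family with known conservation truth:
#' a random query protein, one ortholog per species derived by i.i.d.
#' per-site substitution at a per-species divergence rate, chosen
#' positions held fixed at a target residue, chosen species where that
#' residue is deliberately replaced, and optional paralogous decoy
#' sequences per species. Substitutions are uniform over the 19
#' non-identical standard residues and, by default, there are no indels,
#' which keeps the truth bookkeeping exact; a small optional indel rate
#' exercises gap handling.
#'
#' @param seed integer seed; the generator is the only randomized
#'   component of the package and is fully reproducible given the seed.
#' @param nSpecies number of species in the panel.
#' @param seqLength query length in residues.
#' @param divergence scalar or per-species vector in [0, 0.6]: expected
#'   substituted fraction per ortholog.
#' @param conservedPositions 1-based positions held at \code{targetAA}.
#' @param lossMap named list species -> subset of
#'   \code{conservedPositions} where the residue is replaced by a
#'   non-target residue.
#' @param targetAA the held residue letter, default \code{"C"}.
#' @param paralogCount decoy paralogs per species (default 0).
#' @param paralogCarryAA do decoys carry the target residue at conserved
#'   positions (default TRUE)?
#' @param paralogDivergenceFactor decoy divergence as a multiple of the
#'   species divergence (default 2: decoys rank below orthologs; values
#'   < 1 create decoys that outrank the ortholog, the stress case for
#'   the candidate-iteration rule).
#' @param indelRate per-site probability of a 1-residue indel in an
#'   ortholog, away from conserved positions (default 0).
#' @return a \code{FamilySpec} list, validated.
#' @export
familySpec <- function(seed, nSpecies, seqLength, divergence = 0.2,
                       conservedPositions = integer(0),
                       lossMap = list(), targetAA = "C",
                       paralogCount = 0L, paralogCarryAA = TRUE,
                       paralogDivergenceFactor = 2,
                       indelRate = 0) {
  species <- sprintf("sp%02d", seq_len(nSpecies))
  divergence <- rep_len(divergence, nSpecies)
  names(divergence) <- species
  stopifnot(all(divergence >= 0), all(divergence <= 0.6),
            seqLength >= 1L, indelRate >= 0, indelRate < 0.2)
  if (length(conservedPositions) > 0L &&
      (min(conservedPositions) < 1L ||
       max(conservedPositions) > seqLength))
    stop("conserved positions outside sequence length", call. = FALSE)
  for (sp in names(lossMap)) {
    if (!(sp %in% species))
      stop("loss species '", sp, "' not in panel", call. = FALSE)
    if (!all(lossMap[[sp]] %in% conservedPositions))
      stop("loss position not among conserved positions for '", sp,
           "'", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), species = species,
                 seqLength = as.integer(seqLength),
                 divergence = divergence,
                 conservedPositions = as.integer(conservedPositions),
                 lossMap = lossMap, targetAA = targetAA,
                 paralogCount = as.integer(paralogCount),
                 paralogCarryAA = paralogCarryAA,
                 paralogDivergenceFactor = paralogDivergenceFactor,
                 indelRate = indelRate),
            class = "FamilySpec")
}

.AA20 <- setdiff(.AA_ALPHABET, "X")

# substitute each site independently with probability 'rate', drawing
# uniformly from the 19 non-identical residues
.mutate <- function(chars, rate) {
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a)
      sample(setdiff(.AA20, a), 1L), character(1))
  }
  chars
}

#' Generate a synthetic protein family with known truth
#'
#' @param spec a \code{FamilySpec} from [familySpec()].
#' @return list with \code{db} (a [ProteomeDb-class]), \code{query}
#'   (list with \code{id}, \code{description}, \code{sequence}) and
#'   \code{truth} (data.frame per conserved position: \code{position},
#'   \code{k}, \code{n}, plus a logical presence matrix in
#'   \code{attr(truth, "presence")}).
#' @examples
#' fam <- generateFamily(familySpec(seed = 1, nSpecies = 4,
#'   seqLength = 60, divergence = 0.1, conservedPositions = c(10, 30)))
#' fam$truth
#' @export
generateFamily <- function(spec) {
  stopifnot(inherits(spec, "FamilySpec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(spec$seed)
  L <- spec$seqLength
  qc <- sample(.AA20, L, replace = TRUE)
  qc[spec$conservedPositions] <- spec$targetAA
  # avoid incidental target residues elsewhere, so found positions are
  # exactly the conserved ones and truth stays exact
  stray <- setdiff(which(qc == spec$targetAA), spec$conservedPositions)
  if (length(stray) > 0L)
    qc[stray] <- vapply(stray, function(i)
      sample(setdiff(.AA20, spec$targetAA), 1L), character(1))

  presence <- matrix(TRUE, nrow = length(spec$species),
                     ncol = length(spec$conservedPositions),
                     dimnames = list(spec$species,
                                     as.character(spec$conservedPositions)))
  sets <- list()
  for (sp in spec$species) {
    rate <- spec$divergence[[sp]]
    oc <- .mutate(qc, rate)
    oc[spec$conservedPositions] <- spec$targetAA
    lost <- spec$lossMap[[sp]]
    if (!is.null(lost) && length(lost) > 0L) {
      oc[lost] <- vapply(lost, function(i)
        sample(setdiff(.AA20, c(spec$targetAA, qc[i])), 1L),
        character(1))
      presence[sp, as.character(lost)] <- FALSE
    }
    # keep non-conserved sites free of the target letter so alignment
    # columns cannot pick up decoy occurrences
    strayO <- setdiff(which(oc == spec$targetAA),
                      spec$conservedPositions)
    if (length(strayO) > 0L)
      oc[strayO] <- vapply(strayO, function(i)
        sample(setdiff(.AA20, spec$targetAA), 1L), character(1))
    if (spec$indelRate > 0) {
      keep <- stats::runif(length(oc)) >= spec$indelRate
      keep[spec$conservedPositions] <- TRUE
      oc2 <- oc[keep]
      ins <- which(stats::runif(length(oc2)) < spec$indelRate)
      for (i in rev(ins)) {
        oc2 <- append(oc2, sample(setdiff(.AA20, spec$targetAA), 1L),
                      after = i)
      }
      oc <- oc2
    }
    seqs <- setNames(paste(oc, collapse = ""),
                     paste0(sp, "_orth"))
    if (spec$paralogCount > 0L) {
      for (pidx in seq_len(spec$paralogCount)) {
        prate <- min(rate * spec$paralogDivergenceFactor, 0.95)
        pc <- .mutate(qc, prate)
        # positions a decoy must NOT carry: every conserved position if
        # decoys are specified residue-free, plus the positions this
        # species lost (so decoys cannot rescue a deliberate loss and
        # the truth table stays exact)
        pLose <- if (spec$paralogCarryAA) lost
                 else spec$conservedPositions
        pKeep <- setdiff(spec$conservedPositions, pLose)
        pc[pKeep] <- spec$targetAA
        if (length(pLose) > 0L)
          pc[pLose] <- vapply(pLose, function(i)
            sample(setdiff(.AA20, spec$targetAA), 1L), character(1))
        strayP <- setdiff(which(pc == spec$targetAA),
                          spec$conservedPositions)
        if (length(strayP) > 0L)
          pc[strayP] <- vapply(strayP, function(i)
            sample(setdiff(.AA20, spec$targetAA), 1L), character(1))
        seqs <- c(seqs, setNames(paste(pc, collapse = ""),
                                 sprintf("%s_para%d", sp, pidx)))
      }
    }
    set <- Biostrings::AAStringSet(seqs)
    S4Vectors::mcols(set) <- S4Vectors::DataFrame(
      description = rep("synthetic", length(seqs)),
      species = rep(sp, length(seqs)))
    sets[[sp]] <- set
  }
  truth <- data.frame(
    position = spec$conservedPositions,
    k = if (length(spec$conservedPositions) > 0L)
      colSums(presence) else integer(0),
    n = rep(length(spec$species),
            length(spec$conservedPositions)),
    row.names = NULL)
  attr(truth, "presence") <- presence
  list(db = proteomeDbFromSets(sets),
       query = list(id = sprintf("QRY%d", spec$seed),
                    description = "synthetic query",
                    sequence = paste(qc, collapse = "")),
       truth = truth)
}

#' Expected conservation score from the truth table
#'
#' @param truth truth data.frame from [generateFamily()].
#' @param position a conserved position.
#' @return k/n for that position.
#' @export
expectedScore <- function(truth, position) {
  i <- match(position, truth$position)
  if (is.na(i)) stop("position ", position, " not in truth table",
                     call. = FALSE)
  truth$k[i] / truth$n[i]
}

#' Write a synthetic family to disk as FASTA + panel config
#'
#' Emits one FASTA per species, a \code{panel.tsv} config, a
#' \code{query.fasta} and a \code{query.tsv}, so fixtures are exercised
#' through the same file-based interface as real data.
#'
#' @param family result of [generateFamily()].
#' @param dir output directory (created).
#' @return list of written paths (\code{panel}, \code{queryFasta},
#'   \code{queryTable}).
#' @export
writeFamily <- function(family, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  db <- family$db
  panelLines <- character(0)
  for (sp in panelSpecies(db)) {
    f <- file.path(dir, paste0(sp, ".fasta"))
    set <- db@sequences[[sp]]
    writeLines(paste0(">", names(set), "\n",
                      as.character(set), collapse = "\n"), f)
    panelLines <- c(panelLines, paste(sp, paste0(sp, ".fasta"),
                                      sep = "\t"))
  }
  panelFile <- file.path(dir, "panel.tsv")
  writeLines(panelLines, panelFile)
  qf <- file.path(dir, "query.fasta")
  writeLines(c(paste0(">", family$query$id, " ",
                      family$query$description),
               family$query$sequence), qf)
  qt <- file.path(dir, "query.tsv")
  writeLines(paste(family$query$id, family$query$description,
                   sep = "\t"), qt)
  list(panel = panelFile, queryFasta = qf, queryTable = qt)
}
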