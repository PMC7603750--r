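#' Construct a species panel
#'
#' @param species character vector of species labels (order is the run
#'   order and controls all downstream output ordering).
#' @param files optional character vector of proteome FASTA paths, same
#'   length and order as \code{species}.
#' @return a [SpeciesPanel-class] object.
#' @export
speciesPanel <- function(species, files = character(0)) {
  if (length(files) > 0L) names(files) <- species
  new("SpeciesPanel", species = species, files = files)
}

#' Read a panel configuration file
#'
#' Plain text, one \code{label<TAB>path} pair per line; \code{#} starts
#' a comment. Relative FASTA paths are resolved against the config
#' file's directory.
#'
#' @param file path to the panel config.
#' @return a [SpeciesPanel-class] object.
#' @export
readSpeciesPanel <- function(file) {
  lines <- readLines(file)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("panel config is empty", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad))
    stop("malformed panel line: ", lines[bad][1], call. = FALSE)
  labels <- trimws(vapply(parts, `[`, character(1), 1L))
  paths <- trimws(vapply(parts, `[`, character(1), 2L))
  rel <- !grepl("^(/|[A-Za-z]:)", paths)
  paths[rel] <- file.path(dirname(file), paths[rel])
  speciesPanel(labels, paths)
}

#' Build the proteome database for a panel
#'
#' Parses every species' FASTA file, groups records by species (panel
#' order), rejects duplicate accessions within a species and records
#' per-species sequence and residue counts. A species whose file parses
#' to zero records triggers an error from the FASTA reader; a database
#' may also be assembled directly from in-memory sets with
#' [proteomeDbFromSets()].
#'
#' @param panel a [SpeciesPanel-class] whose \code{files} are populated.
#' @return a [ProteomeDb-class] object.
#' @export
buildProteomeDb <- function(panel) {
  stopifnot(is(panel, "SpeciesPanel"))
  if (length(panel@files) != length(panel@species))
    stop("panel has no source files", call. = FALSE)
  sets <- vector("list", length(panel@species))
  names(sets) <- panel@species
  for (sp in panel@species) {
    f <- panel@files[[sp]]
    if (!file.exists(f))
      stop("proteome file missing for species '", sp, "': ", f,
           call. = FALSE)
    sets[[sp]] <- readProteinFasta(f, species = sp)
  }
  proteomeDbFromSets(sets, panel = panel)
}

#' Assemble a proteome database from in-memory sequence sets
#'
#' @param sets named list of \link[Biostrings]{AAStringSet} objects, one
#'   per species; names define panel order when \code{panel} is missing.
#' @param panel optional [SpeciesPanel-class]; defaults to one built
#'   from \code{names(sets)}.
#' @return a [ProteomeDb-class] object.
#' @export
proteomeDbFromSets <- function(sets, panel = NULL) {
  if (is.null(panel)) panel <- speciesPanel(names(sets))
  sets <- sets[panel@species]
  for (sp in panel@species) {
    ids <- names(sets[[sp]])
    if (anyDuplicated(ids))
      stop("duplicate accession '", ids[duplicated(ids)][1],
           "' in species '", sp, "'", call. = FALSE)
  }
  stats <- data.frame(
    species = panel@species,
    nSequences = vapply(sets, length, 1L),
    nResidues = vapply(sets, function(s)
      sum(Biostrings::width(s)), 1L),
    row.names = NULL, stringsAsFactors = FALSE)
  new("ProteomeDb", panel = panel, sequences = sets, stats = stats)
}

#' Total residue count of a database (the e-value search space)
#' @param db a [ProteomeDb-class] object.
#' @export
dbResidues <- function(db) sum(db@stats$nResidues)

# look up one subject sequence as a plain character string
.dbSequence <- function(db, species, accession) {
  set <- db@sequences[[species]]
  if (is.null(set) || !(accession %in% names(set)))
    stop("accession '", accession, "' not found in species '", species,
         "'", call. = FALSE)
  as.character(set[[accession]])
}
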