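#' Read protein sequences from FASTA
#'
#' Wraps \link[Biostrings]{readAAStringSet} with the validation the
#' pipeline needs: sequences are uppercased, a single terminal stop
#' symbol (\code{*}) is stripped, residues are restricted to the 20
#' standard amino acids plus \code{X}, and accessions (the first
#' whitespace-delimited token of each header) must be unique within the
#' file. One file is one species: every record is tagged with the
#' caller-supplied species label.
#'
#' @param file path to a FASTA file, or a character vector of FASTA text
#'   lines (convenient in tests).
#' @param species species label attached to every record.
#' @return an \link[Biostrings]{AAStringSet} named by accession, with
#'   \code{mcols()} columns \code{description} and \code{species}.
#' @examples
#' aa <- readProteinFasta(c(">s1 desc", "MKC", "CW"), species = "demo")
#' as.character(aa[["s1"]])
#' @export
readProteinFasta <- function(file, species = "unknown") {
  txt <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
    readLines(file) else unlist(strsplit(file, "\n", fixed = TRUE))
  txt <- txt[nzchar(trimws(txt))]
  if (length(txt) == 0L || !startsWith(trimws(txt[1]), ">"))
    stop("no sequences: input is empty or not FASTA", call. = FALSE)
  .validateFastaText(txt)
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  set <- Biostrings::readAAStringSet(tmp)
  if (length(set) == 0L) stop("no sequences in FASTA input", call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate accession in species '", species, "': ",
         ids[duplicated(ids)][1], call. = FALSE)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i]))
      stop("empty sequence for record '", ids[i], "'", call. = FALSE)
    .assertResidues(seqs[i], what = sprintf("record '%s'", ids[i]))
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    description = desc, species = species)
  out
}

# the FASTA reader silently drops characters outside its alphabet, so
# the raw text is validated first and parse errors name the record and
# the position of the offending residue
.validateFastaText <- function(txt) {
  heads <- grep("^>", txt)
  for (i in seq_along(heads)) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(txt)
    seq <- toupper(paste(txt[seq(from, length.out = max(0, to - from + 1L))],
                         collapse = ""))
    seq <- sub("\\*$", "", seq)
    id <- sub("\\s.*$", "", sub("^>", "", txt[heads[i]]))
    .assertResidues(seq, what = sprintf("record '%s'", id))
  }
  invisible(TRUE)
}

#' Read a two-column query table
#'
#' Parses the tab-separated query list (identifier, optional free-text
#' description) and resolves every identifier against a supplied
#' id-to-sequence map, so queries are always provided as sequences and
#' never fetched remotely.
#'
#' @param file path to a TSV file, or a character vector of lines.
#' @param sequences named character vector or
#'   \link[Biostrings]{AAStringSet} mapping query ids to residues.
#' @return data.frame with columns \code{id}, \code{description},
#'   \code{sequence}, in file order.
#' @examples
#' readQueryTable("Q1\teRF1-1", sequences = c(Q1 = "MKCW"))
#' @export
readQueryTable <- function(file, sequences) {
  if (methods::is(sequences, "AAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  lines <- if (length(file) == 1L && !grepl("\n|\t", file) &&
               file.exists(file)) readLines(file)
           else unlist(strsplit(file, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, function(p) trimws(p[1]), character(1))
  desc <- vapply(parts, function(p)
    if (length(p) >= 2L) trimws(p[2]) else "", character(1))
  if (anyDuplicated(ids))
    stop("duplicate query id: ", ids[duplicated(ids)][1], call. = FALSE)
  unknown <- setdiff(ids, names(sequences))
  if (length(unknown) > 0L)
    stop("unknown query id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  data.frame(id = ids, description = desc,
             sequence = unname(sequences[ids]),
             stringsAsFactors = FALSE)
}

#' Load a substitution matrix
#'
#' \code{"BLOSUM62"} returns the standard BLOSUM62 table bundled with
#' Biostrings, restricted to the pipeline's alphabet (20 amino acids plus
#' X). Any other value is treated as a path to an NCBI-format matrix
#' file, which is checked for symmetry.
#'
#' @param name \code{"BLOSUM62"} or a file path.
#' @return symmetric integer matrix with identical row and column names.
#' @examples
#' m <- substitutionMatrix()
#' m["C", "C"]   # 9
#' @export
substitutionMatrix <- function(name = "BLOSUM62") {
  if (identical(name, "BLOSUM62")) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62[.AA_ALPHABET, .AA_ALPHABET]
    return(m)
  }
  if (!file.exists(name))
    stop("unknown substitution matrix: ", name, call. = FALSE)
  lines <- readLines(name)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  rows <- vapply(body, `[`, character(1), 1L)
  vals <- t(vapply(body, function(p) as.numeric(p[-1]),
                   numeric(length(cols))))
  dimnames(vals) <- list(rows, cols)
  if (!identical(sort(rows), sort(cols)))
    stop("matrix file rows and columns disagree", call. = FALSE)
  vals <- vals[cols, cols]
  if (!isTRUE(all.equal(vals, t(vals))))
    stop("substitution matrix is not symmetric", call. = FALSE)
  storage.mode(vals) <- "integer"
  vals
}

# round half away from zero at 'digits' decimals (so 0.885 -> 0.89),
# matching the published score formatting
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

formatScore <- function(x) sprintf("%.2f", roundHalfUp(x, 2L))

formatPValue <- function(p) {
  sprintf("%.2e", signif(p, 3))
}

#' Write the tab-separated results table
#'
#' One header line, then per protein a summary row (homolog-species
#' count and "k of m" putatively-conserved count) followed by one row
#' per analysed residue. Scores are printed with two decimals rounded
#' half-up; p-values in scientific notation with three significant
#' digits.
#'
#' @param reports list of [ProteinReport-class] objects (input order is
#'   preserved in the output).
#' @param file path or connection to write to.
#' @return invisibly, the character vector of written lines.
#' @export
writeResultsTable <- function(reports, file) {
  if (length(reports) == 0L) stop("no reports to write", call. = FALSE)
  if (methods::is(reports, "ProteinReport")) reports <- list(reports)
  header <- paste(c("name", "id", "homologs", "putatively_conserved",
                    "residue", "position", "score", "p_value",
                    "conserved"), collapse = "\t")
  lines <- header
  for (rep in reports) {
    res <- rep@residues
    name <- if (nzchar(rep@description)) rep@description else rep@id
    summary <- paste(c(name, rep@id, rep@nHomologSpecies,
                       sprintf("%d of %d", sum(res$conserved),
                               nrow(res)), "", "", "", "", ""),
                     collapse = "\t")
    lines <- c(lines, summary)
    if (nrow(res) > 0L) {
      for (i in seq_len(nrow(res))) {
        lines <- c(lines, paste(c(
          name, rep@id, "", "",
          paste0(res$targetAA[i], i), res$position[i],
          if (is.na(res$score[i])) "ERROR:no_homologs"
            else formatScore(res$score[i]),
          if (is.na(res$pValue[i])) "ERROR:no_homologs"
            else formatPValue(res$pValue[i]),
          if (res$conserved[i]) "yes" else "no"), collapse = "\t"))
      }
    }
  }
  writeLines(lines, file)
  invisible(lines)
}

#' Write the plain-text alignment dump
#'
#' One block per analysed residue: a \code{#} header naming the query,
#' target letter and position, then one \code{label<TAB>gapped-row} line
#' per alignment row.
#'
#' @param reports list of [ProteinReport-class] objects.
#' @param file path or connection.
#' @return invisibly, the written lines.
#' @export
writeAlignmentDump <- function(reports, file) {
  if (methods::is(reports, "ProteinReport")) reports <- list(reports)
  lines <- character(0)
  for (rep in reports) {
    for (a in rep@assessments) {
      lines <- c(lines,
                 sprintf("# %s %s%d column %d", rep@id, a@targetAA,
                         a@position, a@column),
                 paste(names(a@msa), a@msa, sep = "\t"), "")
    }
  }
  writeLines(lines, file)
  invisible(lines)
}
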