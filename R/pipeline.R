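#' Configuration for a pipeline run
#'
#' Collects every tunable of the end-to-end run. Flags of the
#' command-line front end map one-to-one onto these fields and override
#' them; the pipeline itself is fully deterministic, so no seed is
#' consumed.
#'
#' @param panelFile path to the species panel config
#'   (\code{label<TAB>fasta-path} lines).
#' @param queryFasta path to a FASTA of query sequences.
#' @param queryTable optional path to the 2-column TSV query list; ids
#'   must resolve in \code{queryFasta}.
#' @param hitsFrom optional path to 12-column tabular search output to
#'   use instead of the built-in aligner (single-query runs).
#' @param targetAA target amino-acid letter(s), default \code{"C"}.
#' @param alpha significance threshold, default 0.01.
#' @param matrix substitution matrix name or path, default
#'   \code{"BLOSUM62"}.
#' @param outDir output directory (created if needed).
#' @param gapOpen,gapExtend,evalueCutoff,maxHits,relScoreCutoff,lambda,K
#'   search parameters, see [searchParams()].
#' @return a \code{RunConfig} list.
#' @export
runConfig <- function(panelFile, queryFasta, queryTable = NULL,
                      hitsFrom = NULL, targetAA = "C", alpha = 0.01,
                      matrix = "BLOSUM62", outDir = "cysconserve_out",
                      gapOpen = 11, gapExtend = 1, evalueCutoff = 1e-5,
                      maxHits = 9L, relScoreCutoff = 0.8,
                      lambda = 0.267, K = 0.041) {
  structure(list(
    panelFile = panelFile, queryFasta = queryFasta,
    queryTable = queryTable, hitsFrom = hitsFrom, targetAA = targetAA,
    alpha = alpha, matrix = matrix, outDir = outDir,
    params = searchParams(gapOpen, gapExtend, evalueCutoff, maxHits,
                          relScoreCutoff, lambda, K)),
    class = "RunConfig")
}

.sanitizeId <- function(id) gsub("[^A-Za-z0-9._-]", "_", id)

#' Run the full conservation pipeline
#'
#' For each query: per-species homolog search (candidate selection with
#' the relative-score band and candidate cap), per-residue assessment
#' (candidate iteration, progressive multiple alignment, presence
#' flags), conservation score, Poisson-binomial significance and
#' classification, plus one presence-annotated neighbour-joining tree
#' per residue. Writes \code{results.tsv}, \code{alignments.txt},
#' \code{trees/<id>_<AA><pos>.nwk} and \code{run.log} under
#' \code{config$outDir}. A query with no homolog species is logged and
#' reported with an error marker; the run continues.
#'
#' @param config a \code{RunConfig} from [runConfig()].
#' @return invisibly, a summary list: \code{queries},
#'   \code{residuesAnalyzed}, \code{residuesConserved},
#'   \code{speciesMisses} (query/species pairs without a homolog),
#'   \code{reports}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$outDir, "trees"), showWarnings = FALSE)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  panel <- readSpeciesPanel(config$panelFile)
  db <- buildProteomeDb(panel)
  mat <- substitutionMatrix(config$matrix)
  note("panel: ", length(panelSpecies(db)), " species, ",
       dbResidues(db), " residues")

  qset <- readProteinFasta(config$queryFasta, species = "query")
  queries <- if (!is.null(config$queryTable)) {
    readQueryTable(config$queryTable, qset)
  } else {
    data.frame(id = names(qset),
               description = S4Vectors::mcols(qset)$description,
               sequence = as.character(qset), stringsAsFactors = FALSE)
  }
  note("queries: ", nrow(queries))

  reports <- vector("list", nrow(queries))
  misses <- 0L
  for (i in seq_len(nrow(queries))) {
    q <- as.list(queries[i, ])
    hits <- if (!is.null(config$hitsFrom)) {
      readTabularHits(config$hitsFrom, db, config$params)
    } else {
      searchAllSpecies(q, db, mat, config$params)
    }
    nohit <- names(hits)[vapply(hits, function(h) nrow(h@hits) == 0L,
                                logical(1))]
    misses <- misses + length(nohit)
    if (length(nohit) > 0L)
      note("query ", q$id, ": no homolog in ",
           paste(nohit, collapse = ", "))
    rep <- analyzeProtein(q, hits, db, mat, config$params,
                          targetAA = config$targetAA,
                          alpha = config$alpha)
    if (rep@nHomologSpecies == 0L)
      note("ERROR query ", q$id, ": no homolog species; ",
           "residues reported without scores")
    reports[[i]] <- rep
    for (a in rep@assessments) {
      if (length(a@msa) < 2L) next
      tree <- residueTree(a)
      nwk <- serializeNewick(tree)
      writeLines(nwk, file.path(config$outDir, "trees",
        sprintf("%s_%s%d.nwk", .sanitizeId(q$id), a@targetAA,
                a@position)))
    }
    note("query ", q$id, ": ", rep@nHomologSpecies,
         " homolog species, ", nrow(rep@residues),
         " residue(s) analysed, ", sum(rep@residues$conserved),
         " conserved")
  }
  writeResultsTable(reports, file.path(config$outDir, "results.tsv"))
  writeAlignmentDump(reports, file.path(config$outDir, "alignments.txt"))
  writeLines(log, file.path(config$outDir, "run.log"))
  summary <- list(
    queries = nrow(queries),
    residuesAnalyzed = sum(vapply(reports, function(r)
      nrow(r@residues), 1L)),
    residuesConserved = sum(vapply(reports, function(r)
      sum(r@residues$conserved), 1L)),
    speciesMisses = misses,
    reports = reports)
  invisible(summary)
}
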