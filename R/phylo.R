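#' Uncorrected p-distance matrix from an alignment
#'
#' Pairwise distance = mismatches / comparable columns, where comparable
#' means both rows carry a residue (columns with a gap in either row are
#' ignored). The homologs entering these alignments are pre-filtered for
#' high similarity, the regime where the uncorrected p-distance is
#' monotone with model-corrected distances.
#'
#' @param msa named character vector of gapped rows.
#' @return symmetric numeric matrix with zero diagonal, labelled by the
#'   alignment row names.
#' @export
pDistanceMatrix <- function(msa) {
  stopifnot(length(msa) >= 2L)
  m <- .rowsToMatrix(msa)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  res <- m != "-"
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- res[i, ] & res[j, ]
      if (!any(comp))
        stop("degenerate pair: rows '", names(msa)[i], "' and '",
             names(msa)[j], "' share no residue columns", call. = FALSE)
      d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / sum(comp)
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classic neighbour joining (Q-criterion pair selection with the
#' Studier-Keppler distance update), delegated to \link[ape]{nj};
#' negative branch-length estimates are clamped to zero with a warning.
#' For two taxa the distance is split evenly over the two pendant
#' branches, so the leaf-to-leaf path length equals the input distance.
#'
#' @param dm symmetric labelled distance matrix (or \code{dist}).
#' @return an \link[ape]{ape} \code{phylo} object (unrooted for >= 3
#'   leaves).
#' @export
neighborJoining <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  n <- nrow(dm)
  stopifnot(n >= 2L, isTRUE(all.equal(dm, t(dm))))
  if (n == 2L) {
    tree <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2L, 2L),
                 edge.length = rep(dm[1, 2] / 2, 2L),
                 tip.label = rownames(dm), Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }
  tree <- ape::nj(stats::as.dist(dm))
  if (any(tree$edge.length < 0)) {
    warning("negative neighbour-joining branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Per-residue tree with presence-annotated leaves
#'
#' Builds the neighbour-joining tree over the query and the residue's
#' species representatives from the alignment p-distances and appends a
#' presence marker to every leaf:
#' \code{species|accession|<AA><position>+} when the species conserves
#' the residue, \code{...-} otherwise; the query leaf is always marked
#' present.
#'
#' @param ras a [ResidueAssessment-class] object (needs >= 2 alignment
#'   rows, i.e. at least one representative).
#' @return a \code{phylo} object with annotated tip labels.
#' @export
residueTree <- function(ras) {
  if (length(ras@msa) < 2L)
    stop("cannot build a tree from a query-only alignment",
         call. = FALSE)
  flags <- presenceFlags(ras)
  marks <- setNames(ifelse(flags, "+", "-"),
                    paste(names(ras@representatives),
                          ras@representatives, sep = "|"))
  marks[names(ras@msa)[1]] <- "+"   # query leaf
  dm <- pDistanceMatrix(ras@msa)
  tree <- neighborJoining(dm)
  if (anyNA(marks[tree$tip.label]))
    stop("missing presence flag for leaf '",
         tree$tip.label[is.na(marks[tree$tip.label])][1], "'",
         call. = FALSE)
  tag <- sprintf("%s%d", ras@targetAA, ras@position)
  tree$tip.label <- paste0(tree$tip.label, "|", tag,
                           marks[tree$tip.label])
  tree
}

#' Serialize a tree to a Newick string
#'
#' @param tree a \code{phylo} object.
#' @return single Newick string terminated by \code{";"}, parseable by
#'   \link[ape]{read.tree}.
#' @export
serializeNewick <- function(tree) {
  ape::write.tree(tree)
}
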