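test_that("p-distance counts mismatches over mutually ungapped columns", {
  msa <- c(a = "MKCW", b = "MKCW", c = "MKAW")
  d <- pDistanceMatrix(msa)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0.25)
  expect_equal(d, t(d))
  expect_equal(diag(d), setNames(rep(0, 3), names(msa)))
  msa2 <- c(a = "MK--", b = "--CW")
  expect_error(pDistanceMatrix(msa2), "degenerate")
  msa3 <- c(a = "MK-W", b = "MKC-", c = "MKCW")
  expect_equal(pDistanceMatrix(msa3)["a", "b"], 0)  # only MK comparable
})

test_that("three-taxon neighbour joining solves the point formulas", {
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(d)
  pl <- ape::cophenetic.phylo(tr)
  expect_equal(pl["A", "B"], 2)
  expect_equal(pl["A", "C"], 3)
  expect_equal(pl["B", "C"], 3)
  # leaf branch lengths a=1, b=1, c=2
  tipEdge <- function(t, lab)
    t$edge.length[t$edge[, 2] == match(lab, t$tip.label)]
  expect_equal(tipEdge(tr, "A"), 1)
  expect_equal(tipEdge(tr, "B"), 1)
  expect_equal(tipEdge(tr, "C"), 2)
})

test_that("additive distances reproduce the generating tree", {
  set.seed(12)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    ref <- ape::rtree(n)
    d <- ape::cophenetic.phylo(ref)
    tr <- neighborJoining(d[ref$tip.label, ref$tip.label])
    expect_equal(ape::cophenetic.phylo(tr)[ref$tip.label, ref$tip.label],
                 d, tolerance = 1e-8)
    expect_equal(ape::dist.topo(ape::unroot(ref), tr), 0,
                 ignore_attr = TRUE)
  }
})

test_that("two taxa give a path of exactly the input distance", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  tr <- neighborJoining(d)
  expect_equal(sum(tr$edge.length), 0.4)
  expect_setequal(tr$tip.label, c("A", "B"))
})

test_that("negative branch estimates are clamped to zero", {
  d <- matrix(c(0, 1, 1, 1, 0, 4, 1, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_warning(tr <- neighborJoining(d), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("annotated residue trees serialize to parseable Newick", {
  msa <- c(`query|q1` = "MKCW", `spA|a1` = "MKCW", `spB|b1` = "MKAW",
           `spC|c1` = "MECW")
  ras <- new("ResidueAssessment", position = 3L, targetAA = "C",
             representatives = c(spA = "a1", spB = "b1", spC = "c1"),
             detected = c(spA = TRUE, spB = FALSE, spC = TRUE),
             msa = msa, column = 3L)
  tr <- residueTree(ras)
  nwk <- serializeNewick(tr)
  expect_match(nwk, ";$")
  back <- ape::read.tree(text = nwk)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_true("spB|b1|C3-" %in% back$tip.label)
  expect_true(all(grepl("[+-]$", back$tip.label)))
  expect_true(endsWith(back$tip.label[grep("query", back$tip.label)],
                       "+"))
  # serialize -> parse -> serialize is a fixed point
  expect_identical(serializeNewick(back), nwk)
  # all-present flags: every leaf ends with "+"
  ras2 <- ras
  ras2@msa["spB|b1"] <- "MKCW"
  expect_true(all(endsWith(residueTree(ras2)$tip.label, "+")))
})

test_that("tree leaves are exactly query plus representatives", {
  fam <- generateFamily(familySpec(seed = 2, nSpecies = 5,
    seqLength = 80, divergence = 0.1, conservedPositions = 40L))
  mat <- substitutionMatrix()
  hits <- searchAllSpecies(fam$query, fam$db, mat)
  rep <- analyzeProtein(fam$query, hits, fam$db, mat)
  tr <- residueTree(rep@assessments[[1]])
  want <- c(paste0("query|", fam$query$id),
            paste(names(rep@assessments[[1]]@representatives),
                  rep@assessments[[1]]@representatives, sep = "|"))
  expect_setequal(sub("\\|C40[+-]$", "", tr$tip.label), want)
})
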