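mat <- substitutionMatrix()

test_that("target positions are located for single and multiple letters", {
  expect_equal(findTargetPositions("MKCWC", "C"), c(3L, 5L))
  expect_equal(findTargetPositions("MKW", "C"), integer(0))
  expect_equal(findTargetPositions("CSTC", "CS"), c(1L, 2L, 4L))
  expect_error(findTargetPositions("MKC", "7"), "amino-acid")
})

# deterministic toy family: query with one Cys, species whose best hit
# lost it but whose runner-up (inside the score band) kept it
.buildIterationFixture <- function() {
  set.seed(21)
  qseq <- randSeq(50)
  ch <- strsplit(qseq, "")[[1]]
  ch[25] <- "C"
  ch[setdiff(which(ch == "C"), 25)] <- "A"
  qseq <- paste(ch, collapse = "")
  noC <- ch; noC[25] <- "A"
  withC4 <- ch
  withC4[c(3, 10, 40, 47)] <- vapply(withC4[c(3, 10, 40, 47)],
    function(a) sample(setdiff(AA20, c(a, "C")), 1), "")
  noC9 <- withC4; noC9[25] <- "S"
  db <- makeDb(
    spA = c(rank1_noC = paste(noC, collapse = ""),
            rank2_withC = paste(withC4, collapse = "")),
    spB = c(ok = qseq),
    spC = c(none1 = paste(noC9, collapse = ""),
            none2 = paste(noC, collapse = "")),
    spD = c(unrelated = randSeq(50)))
  list(query = list(id = "q1", description = "", sequence = qseq),
       db = db)
}

test_that("candidate iteration picks the first residue-bearing hit", {
  fx <- .buildIterationFixture()
  hits <- searchAllSpecies(fx$query, fx$db, mat)
  expect_equal(hitTable(hits$spA)$accession[1], "rank1_noC")
  ras <- assessPosition(fx$query, 25L, hits, fx$db, mat)
  expect_equal(unname(ras@representatives["spA"]), "rank2_withC")
  expect_true(unname(ras@detected["spA"]))
  flags <- presenceFlags(ras)
  expect_true(flags[["spA"]])
  expect_true(flags[["spB"]])
})

test_that("species with no residue-bearing candidate falls back to rank 1", {
  fx <- .buildIterationFixture()
  hits <- searchAllSpecies(fx$query, fx$db, mat)
  ras <- assessPosition(fx$query, 25L, hits, fx$db, mat)
  expect_false(unname(ras@detected["spC"]))
  expect_equal(unname(ras@representatives["spC"]),
               hitTable(hits$spC)$accession[1])
  expect_false(presenceFlags(ras)[["spC"]])
})

test_that("species with empty hit lists are excluded from n", {
  fx <- .buildIterationFixture()
  hits <- searchAllSpecies(fx$query, fx$db, mat)
  expect_equal(nrow(hitTable(hits$spD)), 0L)
  ras <- assessPosition(fx$query, 25L, hits, fx$db, mat)
  expect_false("spD" %in% names(ras@representatives))
  rep <- analyzeProtein(fx$query, hits, fx$db, mat)
  expect_equal(rep@nHomologSpecies, 3L)
  expect_equal(residueResults(rep)$n, 3L)
  expect_equal(residueResults(rep)$k, 2L)
})

test_that("conservation score is k/n with strict domain checks", {
  expect_equal(conservationScore(18, 18), 1.0)
  expect_equal(conservationScore(16, 18), 16 / 18)
  expect_equal(conservationScore(0, 7), 0.0)
  expect_error(conservationScore(1, 0), "no homolog")
  expect_error(conservationScore(5, 4), "\\[0, n\\]")
})

test_that("chance probabilities are clamped and anti-monotone in identity", {
  msa <- c(`query|q` = "MKCW", `spA|a` = "MKCW", `spB|b` = "MKCA",
           `spC|c` = "MACA")
  ras <- new("ResidueAssessment", position = 3L, targetAA = "C",
             representatives = c(spA = "a", spB = "b", spC = "c"),
             detected = c(spA = TRUE, spB = TRUE, spC = TRUE),
             msa = msa, column = 3L)
  q <- chanceProbabilities(ras)
  expect_equal(unname(q["spA"]), 1e-6)       # identical -> clamp floor
  expect_equal(unname(q["spB"]), 0.25)
  expect_equal(unname(q["spC"]), 0.50)
  expect_true(all(diff(unname(q)) > 0))
})

test_that("Poisson-binomial tail matches exhaustive enumeration", {
  expect_equal(poissonBinomialTail(0, c(0.3, 0.9)), 1.0)
  expect_equal(poissonBinomialTail(2, c(0.5, 0.5, 0.5)), 0.5)
  q <- rep(0.2, 6)
  expect_equal(poissonBinomialTail(6, q), 0.2^6)
  set.seed(33)
  for (i in 1:25) {
    n <- sample(1:10, 1)
    probs <- runif(n)
    k <- sample(0:n, 1)
    expect_equal(poissonBinomialTail(k, probs),
                 enumPoisBinTail(k, probs), tolerance = 1e-12)
  }
})

test_that("tail probability is non-increasing in k", {
  set.seed(34)
  probs <- runif(12)
  p <- vapply(0:12, poissonBinomialTail, 0, probs = probs)
  expect_true(all(diff(p) <= 1e-15))
  expect_equal(p[1], 1)
})

test_that("classification boundary is inclusive at alpha", {
  expect_true(classifyConserved(0.008, 0.01))
  expect_false(classifyConserved(0.0387, 0.01))
  expect_true(classifyConserved(0.01, 0.01))
  expect_error(classifyConserved(0, 0.01))
})

test_that("protein summary counts conserved residues", {
  fx <- .buildIterationFixture()
  hits <- searchAllSpecies(fx$query, fx$db, mat)
  rep <- analyzeProtein(fx$query, hits, fx$db, mat)
  s <- summarizeProtein(rep)
  expect_equal(s$totalCount, nrow(residueResults(rep)))
  expect_equal(s$conservedCount, sum(residueResults(rep)$conserved))
  expect_match(s$label, "^\\d+ of \\d+$")
  # invariant: score * n == k for every emitted row
  r <- residueResults(rep)
  expect_equal(r$score * r$n, as.numeric(r$k))
})
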