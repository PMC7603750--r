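test_that("FASTA parsing concatenates, uppercases and strips stops", {
  aa <- readProteinFasta(c(">s1 desc", "MKC", "CW"), species = "demo")
  expect_equal(length(aa), 1L)
  expect_equal(names(aa), "s1")
  expect_equal(as.character(aa[["s1"]]), "MKCCW")
  expect_equal(S4Vectors::mcols(aa)$description, "desc")

  aa2 <- readProteinFasta(c(">a", "mkc*", ">b", "ACD"), species = "x")
  expect_equal(as.character(aa2[["a"]]), "MKC")
  expect_equal(as.character(aa2[["b"]]), "ACD")
})

test_that("FASTA parsing rejects bad input with informative errors", {
  expect_error(readProteinFasta(c(">a", "MK7C")), "position 3")
  expect_error(readProteinFasta(character(0)), "no sequences")
  expect_error(readProteinFasta(c("MKC")), "no sequences")
  expect_error(readProteinFasta(c(">a", "MKC", ">a", "ACD")),
               "duplicate")
})

test_that("FASTA records round-trip through serialization", {
  set.seed(11)
  seqs <- setNames(vapply(1:5, function(i) randSeq(30), ""),
                   paste0("id", 1:5))
  f <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(seqs), "\n", seqs), f)
  aa <- readProteinFasta(f, species = "rt")
  expect_equal(setNames(as.character(aa), names(aa)), seqs)
})

test_that("query table resolves ids and keeps file order", {
  q <- readQueryTable("Q39097\teRF1-1", sequences = c(Q39097 = "MKCW"))
  expect_equal(nrow(q), 1L)
  expect_equal(q$description, "eRF1-1")
  expect_equal(q$sequence, "MKCW")

  q2 <- readQueryTable(c("X1", "X2\tnote"),
                       sequences = c(X1 = "MK", X2 = "CW"))
  expect_equal(q2$id, c("X1", "X2"))
  expect_equal(q2$description, c("", "note"))

  expect_error(readQueryTable("X1\tnote", sequences = c(Y = "MK")),
               "unknown query id")
  expect_error(readQueryTable(c("X1", "X1"), sequences = c(X1 = "MK")),
               "duplicate")
})

test_that("bundled BLOSUM62 has the standard values and shape", {
  m <- substitutionMatrix("BLOSUM62")
  expect_equal(m["C", "C"], 9)
  expect_equal(m["A", "R"], m["R", "A"])
  expect_true(isTRUE(all.equal(m, t(m))))
  expect_equal(sort(rownames(m)),
               sort(c(AA20, "X")))
  expect_true(all(m == round(m)))
  # diagonal dominates its row off-diagonals
  expect_true(all(diag(m)[AA20] >=
                  apply(m[AA20, AA20] - diag(diag(m[AA20, AA20])), 1,
                        max)))
})

test_that("matrix files are parsed and checked for symmetry", {
  f <- tempfile()
  writeLines(c("# tiny", "   A  C", "A  4  0", "C  0  9"), f)
  m <- substitutionMatrix(f)
  expect_equal(m["C", "C"], 9L)
  f2 <- tempfile()
  writeLines(c("   A  C", "A  4  1", "C  0  9"), f2)
  expect_error(substitutionMatrix(f2), "symmetric")
  expect_error(substitutionMatrix("NOSUCH62"), "unknown")
})

test_that("score formatting rounds half-up to two decimals", {
  expect_equal(CysConserve:::formatScore(16 / 18), "0.89")
  expect_equal(CysConserve:::formatScore(14 / 18), "0.78")
  expect_equal(CysConserve:::formatScore(10 / 19), "0.53")
  expect_equal(CysConserve:::formatScore(0.885), "0.89")
  expect_equal(CysConserve:::formatScore(1), "1.00")
})

test_that("results table layout carries positions, scores, p-values", {
  res <- data.frame(position = c(126L, 388L), targetAA = "C",
                    k = c(18L, 16L), n = 18L,
                    score = c(18 / 18, 16 / 18),
                    pValue = c(1.13e-13, 7.50e-10),
                    conserved = c(TRUE, TRUE))
  rep1 <- new("ProteinReport", id = "Q39097", description = "eRF1-1",
              sequence = "MKC", targetAA = "C",
              nHomologSpecies = 18L, residues = res,
              presence = list(), chanceProbs = list(),
              assessments = list(), alpha = 0.01)
  empty <- res[0, ]
  rep2 <- new("ProteinReport", id = "P2", description = "",
              sequence = "MK", targetAA = "C", nHomologSpecies = 3L,
              residues = empty, presence = list(),
              chanceProbs = list(), assessments = list(), alpha = 0.01)
  f <- tempfile()
  lines <- writeResultsTable(list(rep1, rep2), f)
  expect_equal(lines, readLines(f))
  r126 <- grep("\t126\t", lines, value = TRUE)
  expect_length(r126, 1L)
  cells <- strsplit(r126, "\t")[[1]]
  expect_true(all(c("126", "1.00", "1.13e-13") %in% cells))
  # summary rows in input order; empty protein prints "0 of 0"
  expect_true(grepl("\t18\t2 of 2\t", lines[2]))
  expect_true(any(grepl("\t3\t0 of 0\t", lines)))
  expect_lt(grep("Q39097", lines)[1], grep("\tP2\t", lines)[1])
})
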