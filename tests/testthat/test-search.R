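mat <- substitutionMatrix()

test_that("local alignment handles identity and hopeless pairs", {
  r <- smithWaterman("ACDE", "ACDE", mat)
  expect_equal(r$rawScore, mat["A", "A"] + mat["C", "C"] +
                 mat["D", "D"] + mat["E", "E"])
  expect_equal(r$identity, 1)
  r0 <- smithWaterman("CCC", "AAA", mat)
  expect_equal(r0$rawScore, 0)
  expect_equal(r0$queryAligned, "")
  expect_error(smithWaterman("", "AAA", mat), "empty")
})

test_that("local alignment is symmetric and matches the DP oracle", {
  set.seed(42)
  for (i in 1:60) {
    q <- randSeq(sample(2:8, 1)); s <- randSeq(sample(2:8, 1))
    o <- max(0, oracleLocalScore(q, s, mat))
    expect_equal(smithWaterman(q, s, mat)$rawScore, o,
                 info = paste(q, s))
    expect_equal(smithWaterman(s, q, mat)$rawScore, o)
  }
})

test_that("appending subject residues never lowers the local score", {
  set.seed(7)
  for (i in 1:20) {
    q <- randSeq(8); s <- randSeq(5)
    s1 <- smithWaterman(q, s, mat)$rawScore
    s2 <- smithWaterman(q, paste0(s, randSeq(3)), mat)$rawScore
    expect_gte(s2, s1)
  }
})

test_that("e-values follow the Karlin-Altschul closed form", {
  p <- searchParams()
  e0 <- evalueFromScore(0, 100, 1e4, p)
  expect_equal(e0$evalue, 0.041 * 100 * 1e4)
  e1 <- evalueFromScore(50, 100, 1e4, p)
  e2 <- evalueFromScore(50, 100, 2e4, p)
  expect_equal(e2$evalue / e1$evalue, 2)
  e <- evalueFromScore(100, 100, 10000, p)
  expect_equal(e$evalue, 0.041 * 1e6 * exp(-26.7))
  expect_equal(e$bitScore, (0.267 * 100 - log(0.041)) / log(2))
  # strictly decreasing in score
  expect_lt(e$evalue, e1$evalue)
})

test_that("species search applies the relative-score band and cap", {
  set.seed(3)
  q <- list(id = "q", sequence = randSeq(80))
  near <- function(rate) {
    ch <- strsplit(q$sequence, "")[[1]]
    idx <- sample(80, round(80 * rate))
    ch[idx] <- vapply(ch[idx], function(a)
      sample(setdiff(AA20, a), 1), "")
    paste(ch, collapse = "")
  }
  subjects <- c(h_best = q$sequence, h_mid = near(0.10),
                h_far = near(0.55))
  db <- makeDb(spA = subjects)
  sh <- searchSpecies(q, db, "spA", mat, searchParams())
  tab <- hitTable(sh)
  # independently recompute the selection rule
  raw <- vapply(subjects, function(s)
    smithWaterman(q$sequence, s, mat)$rawScore, 0)
  ev <- vapply(raw, function(s)
    evalueFromScore(s, 80, dbResidues(db))$evalue, 0)
  keep <- names(raw)[ev <= 1e-5 & raw >= 0.8 * max(raw[ev <= 1e-5])]
  expect_setequal(tab$accession, keep)
  expect_false(is.unsorted(-tab$rawScore))
  expect_true("h_best" %in% tab$accession)
  expect_false("h_far" %in% tab$accession)
})

test_that("at most maxHits survivors are kept", {
  set.seed(4)
  q <- list(id = "q", sequence = randSeq(60))
  subjects <- setNames(rep(q$sequence, 12), sprintf("h%02d", 1:12))
  db <- makeDb(spA = subjects)
  sh <- searchSpecies(q, db, "spA", mat)
  expect_equal(nrow(hitTable(sh)), 9L)
  # ties broken lexicographically by accession
  expect_equal(hitTable(sh)$accession, sprintf("h%02d", 1:9))
})

test_that("a species without credible hits yields an empty list", {
  set.seed(5)
  q <- list(id = "q", sequence = randSeq(60))
  db <- makeDb(spA = c(u1 = randSeq(60), u2 = randSeq(60)))
  sh <- searchSpecies(q, db, "spA", mat)
  expect_equal(nrow(hitTable(sh)), 0L)
})

test_that("hit ranking is invariant to input FASTA order", {
  set.seed(6)
  q <- list(id = "q", sequence = randSeq(70))
  ch <- strsplit(q$sequence, "")[[1]]
  make <- function(k) { c2 <- ch; c2[seq_len(k)] <- "A"
    paste(c2, collapse = "") }
  subjects <- c(x1 = make(1), x2 = make(2), x3 = make(3),
                x4 = make(4))
  db1 <- makeDb(spA = subjects)
  db2 <- makeDb(spA = rev(subjects))
  t1 <- hitTable(searchSpecies(q, db1, "spA", mat))
  t2 <- hitTable(searchSpecies(q, db2, "spA", mat))
  expect_equal(t1$accession, t2$accession)
  expect_equal(t1$rawScore, t2$rawScore)
})

test_that("tabular adapter filters like the built-in search", {
  db <- makeDb(spA = c(a1 = "MKCW", a2 = "MKAW"),
               spB = c(b1 = "MKCW"))
  row <- function(acc, ev, bits)
    paste("q", acc, "100.0", "4", "0", "0", "1", "4", "1", "4",
          ev, bits, sep = "\t")
  hits <- readTabularHits(c(row("a1", "1e-30", "80"),
                            row("a2", "1e-20", "60")), db)
  expect_equal(hitTable(hits$spA)$accession, "a1")  # 60 < 0.8 * 80
  expect_equal(nrow(hitTable(hits$spB)), 0L)
  empty <- readTabularHits(character(0), db)
  expect_true(all(vapply(empty, function(h) nrow(hitTable(h)) == 0L,
                         TRUE)))
  expect_error(readTabularHits(row("zz", "1e-30", "80"), db),
               "unknown accession 'zz' at line 1")
  expect_error(readTabularHits("q\tonly-three\tcols", db), "malformed")
})
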