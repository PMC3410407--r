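test_that("readFasta parses records, tags species, and validates input", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">p1 some description", "MKTT"), tf)
  p <- readFasta(tf, species = "synA")
  expect_equal(names(p), "p1")
  expect_equal(as.character(p[[1]]), "MKTT")
  expect_equal(S4Vectors::mcols(p)$species, "synA")
  expect_equal(S4Vectors::mcols(p)$description, "some description")

  writeLines(character(), tf)
  expect_length(readFasta(tf, species = "synA"), 0)

  writeLines(c(">p1", "MK", ">p1", "TT"), tf)
  expect_error(readFasta(tf, species = "s"), "duplicate.*p1")

  writeLines(c("MKTT", ">p1", "MK"), tf)
  expect_error(readFasta(tf, species = "s"), "line 1")

  writeLines(c(">p1", "MKJT"), tf)
  expect_error(readFasta(tf, species = "s"), "'J' in record 'p1' at position 3")

  writeLines(c(">g1", "ACGTN"), tf)
  expect_equal(as.character(readFasta(tf, species = "s", type = "dna")[[1]]),
               "ACGTN")
  writeLines(c(">g1", "ACGU"), tf)
  expect_error(readFasta(tf, species = "s", type = "dna"), "'U'")
})

test_that("FASTA round-trips byte-for-byte with 60-column wrapping", {
  set.seed(11)
  seqs <- setNames(vapply(c(10, 60, 61, 150), randomProtein, ""),
                   c("a", "b", "c", "d"))
  tf <- withr::local_tempfile(fileext = ".fa")
  writeFasta(seqs, tf)
  lines <- readLines(tf)
  expect_equal(lines[1], ">a")
  expect_equal(nchar(lines[lines != ">a" & lines != ">b" & lines != ">c" &
                             lines != ">d"][2]), 60)  # wrapped row
  back <- readFasta(tf, species = "s")
  expect_equal(as.character(back), seqs)
  ## writing what was read reproduces the file exactly
  tf2 <- withr::local_tempfile(fileext = ".fa")
  writeFasta(back, tf2)
  expect_identical(readLines(tf2), lines)
})

test_that("six-frame translation follows the standard code", {
  expect_equal(sixFrameTranslate("GGTTACGGT")[["+1"]], "GYG")
  fr <- sixFrameTranslate("ATG")
  expect_equal(fr[["+1"]], "M")
  expect_equal(fr[["-1"]], "H")   # revcomp CAT -> H
  ## N codons translate to X, stops to '*'
  expect_equal(sixFrameTranslate("TAAANG")[["+1"]], "*X")
  expect_error(sixFrameTranslate("AC"), "at least 3")
})

test_that("frame -1 equals forward translation of the reverse complement", {
  set.seed(21)
  for (rep in 1:20) {
    dna <- paste(sample(c("A", "C", "G", "T", "N"), sample(30:90, 1),
                        replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
                 collapse = "")
    fr <- sixFrameTranslate(dna)
    rc <- oracleRevComp(dna)
    expect_equal(fr[["-1"]], oracleTranslate(rc))
    expect_equal(fr[["-2"]], oracleTranslate(substring(rc, 2)))
    expect_equal(fr[["+1"]], oracleTranslate(dna))
    expect_equal(fr[["+3"]], oracleTranslate(substring(dna, 3)))
  }
})

test_that("findOrfs returns maximal stop-free runs", {
  expect_equal(findOrfs("MAA*GYGK", minLen = 1),
               data.frame(start = c(0L, 4L), end = c(3L, 8L)))
  expect_equal(nrow(findOrfs("***", minLen = 1)), 0)
  expect_equal(findOrfs("MAA*GYGK", minLen = 4),
               data.frame(start = 4L, end = 8L))
  ## reconstruction: segments plus removed stops reproduce the input
  set.seed(31)
  for (rep in 1:20) {
    pep <- paste(sample(c(AA20, "*"), 60, replace = TRUE,
                        prob = c(rep(1, 20), 6)), collapse = "")
    orfs <- findOrfs(pep, minLen = 1)
    rebuilt <- rep("*", nchar(pep))
    for (k in seq_len(nrow(orfs))) {
      seg <- strsplit(substring(pep, orfs$start[k] + 1, orfs$end[k]), "")[[1]]
      rebuilt[(orfs$start[k] + 1):orfs$end[k]] <- seg
    }
    expect_equal(paste(rebuilt, collapse = ""), pep)
  }
})

test_that("scanGyg finds selectivity-filter candidates in six-frame ORFs", {
  hit <- scanGyg(c(g1 = "GGTTACGGT"), minOrfLen = 3)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$frame, "+1")
  expect_equal(hit$gyg_offset, 0L)

  expect_equal(nrow(scanGyg(c(g1 = "TAATAATAATAA"), minOrfLen = 1)), 0)

  ## GYG encoded only on the reverse strand
  revOnly <- oracleRevComp("GCAGGTTACGGTGCG")
  hit2 <- scanGyg(setNames(revOnly, "g2"), minOrfLen = 3)
  expect_true(all(startsWith(hit2$frame, "-")))
  expect_gte(nrow(hit2), 1)
})

test_that("scanGyg equals a naive scan of all six translations", {
  set.seed(41)
  for (rep in 1:15) {
    dna <- paste(sample(c("A", "C", "G", "T"), 240, replace = TRUE),
                 collapse = "")
    got <- scanGyg(setNames(dna, "g"), minOrfLen = 5, contextWindow = 10)
    naive <- 0
    for (fr in c(0, 1, 2)) {
      for (s in c(dna, oracleRevComp(dna))) {
        pep <- oracleTranslate(substring(s, fr + 1))
        for (orf in strsplit(pep, "*", fixed = TRUE)[[1]]) {
          if (nchar(orf) >= 5) {
            naive <- naive + length(gregexpr("(?=GYG)", orf,
                                             perl = TRUE)[[1]]) *
              (gregexpr("(?=GYG)", orf, perl = TRUE)[[1]][1] != -1)
          }
        }
      }
    }
    expect_equal(nrow(got), naive)
  }
})

test_that("scanGyg coordinates re-translate to the reported context", {
  set.seed(51)
  total <- 0
  for (rep in 1:10) {
    dna <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")
    ## plant a GYG codon triplet at a random in-frame or out-of-frame spot
    at <- sample(1:(300 - 9), 1)
    substr(dna, at, at + 8) <- "GGATACGGA"
    hits <- scanGyg(setNames(dna, "g"), minOrfLen = 4, contextWindow = 7)
    total <- total + nrow(hits)
    for (k in seq_len(nrow(hits))) {
      slice <- substring(dna, hits$dna_start[k] + 1, hits$dna_end[k])
      pep <- if (startsWith(hits$frame[k], "+")) oracleTranslate(slice)
             else oracleTranslate(oracleRevComp(slice))
      expect_equal(pep, hits$context[k])
    }
  }
  expect_gt(total, 0)   # the property was actually exercised
})

test_that("scanGyg output is per-record and order-invariant", {
  set.seed(61)
  g1 <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
              collapse = "")
  g2 <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
              collapse = "")
  a <- scanGyg(c(x = g1, y = g2), minOrfLen = 4)
  b <- scanGyg(c(y = g2, x = g1), minOrfLen = 4)
  reorder <- function(d) {
    d <- d[order(d$genome_id, d$frame, d$orf_start, d$gyg_offset), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(reorder(a), reorder(b))
})
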