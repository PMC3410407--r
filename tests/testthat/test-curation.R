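## Build a protein with two copies of one motif instance at given 0-based
## offsets, on an alanine-free background so no accidental hits occur.
plantTwo <- function(instance, at1, at2, len) {
  s <- strsplit(paste(rep("W", len), collapse = ""), "")[[1]]
  for (at in c(at1, at2)) {
    s[(at + 1):(at + nchar(instance))] <- strsplit(instance, "")[[1]]
  }
  paste(s, collapse = "")
}

test_that("referenceSpan averages outermost motif spans", {
  lib <- motifLibrary()
  ## motif 1 instance TMTTVGYGD (9 residues)
  refs <- c(r1 = plantTwo("TMTTVGYGD", 10, 410, 500),
            r2 = plantTwo("TMTTVGYGD", 0, 691, 720))
  ## spans: (410+9)-10 = 409 and (691+9)-0 = 700
  expect_equal(referenceSpan(refs, lib, familyClass = "CHANNEL"),
               (409 + 700) / 2)
  expect_equal(referenceSpan(refs[1], lib, familyClass = "CHANNEL"), 409)
  ## a reference with fewer than two hits is excluded with a warning
  refs2 <- c(refs, r3 = "TMTTVGYGDWWWWWWWWWW")
  expect_warning(sp <- referenceSpan(refs2, lib, familyClass = "CHANNEL"),
                 "excluded")
  expect_equal(sp, (409 + 700) / 2)
  expect_error(referenceSpan(c(x = "WWWWWWWW"), lib, "CHANNEL"),
               "threshold undefined")
})

test_that("lengthFilter keeps the exact boundary", {
  cands <- c(short = randomProtein(419), exact = randomProtein(420),
             long = randomProtein(500))
  set.seed(91)
  out <- lengthFilter(cands, span = 600,
                      params = curationParams(lengthFraction = 0.7))
  expect_equal(sort(out$kept), c("exact", "long"))
  expect_equal(out$discarded, "short")
  ## partition property
  expect_setequal(c(out$kept, out$discarded), names(cands))
})

test_that("pairwiseScores implements percent identity over the shorter sequence", {
  expect_equal(pairwiseScores(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL"))$score,
               100)
  expect_equal(pairwiseScores(c(a = "ACDE", b = "ACDF"))$score, 75)
  set.seed(101)
  many <- setNames(vapply(rep(30, 6), randomProtein, ""), letters[1:6])
  e <- pairwiseScores(many)
  expect_equal(nrow(e), 6 * 5 / 2)
  expect_true(all(e$id_a < e$id_b))
})

test_that("pairwiseScores agrees with exhaustive alignment enumeration", {
  set.seed(111)
  sc <- ktfam:::alignmentScoring()
  for (rep in 1:8) {
    a <- randomProtein(sample(4:6, 1))
    b <- randomProtein(sample(4:6, 1))
    oracle <- oracleEnumAlign(a, b)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = sc$matrix, gapOpening = sc$gapOpening,
      gapExtension = sc$gapExtension, type = "global")
    expect_equal(Biostrings::score(aln), oracle$score, tolerance = 1e-8)
    expect_true(Biostrings::nmatch(aln) %in% oracle$identities)
    got <- pairwiseScores(setNames(c(a, b), c("a", "b")))$score
    expect_true(got %in% round(100 * oracle$identities / min(nchar(a),
                                                             nchar(b)), 2))
  }
})

test_that("pruneAndFragment removes weak edges, de-duplicates, and fragments", {
  p <- curationParams()
  ## single weak edge -> two singletons
  out <- pruneAndFragment(data.frame(id_a = "A", id_b = "B", score = 15),
                          c("A", "B"), p)
  expect_equal(out$components, list("A", "B"))

  ## chain with one weak link
  e <- data.frame(id_a = c("A", "B", "C"), id_b = c("B", "C", "D"),
                  score = c(50, 50, 10))
  out <- pruneAndFragment(e, c("A", "B", "C", "D"), p)
  expect_equal(out$components, list(c("A", "B", "C"), "D"))

  ## identical pair: larger id dropped entirely
  e <- data.frame(id_a = c("A", "A", "B"), id_b = c("B", "C", "C"),
                  score = c(100, 60, 60))
  out <- pruneAndFragment(e, c("A", "B", "C"), p)
  expect_equal(out$removedIdentical, "B")
  expect_equal(out$components, list(c("A", "C")))
})

test_that("selectGroup ranks components by reference similarity", {
  tpl <- familyTemplates()
  set.seed(121)
  fam <- evolveSequences(ape::read.tree(text = "(a:1,(b:1,c:1):1);"),
                         tpl$HAK, 0.05, seed = 5)
  decoys <- Biostrings::AAStringSet(
    c(d1 = randomProtein(700), d2 = randomProtein(700)))
  cands <- c(fam, decoys)
  refs <- familyReferences()$HAK
  out <- selectGroup(list(names(fam), names(decoys)), cands, refs)
  expect_setequal(out$selected, names(fam))
  expect_gt(out$referenceSimilarity[1], out$referenceSimilarity[2])

  ## ties broken by larger component
  same <- Biostrings::AAStringSet(
    setNames(rep(as.character(fam[[1]]), 5), paste0("s", 1:5)))
  out2 <- selectGroup(list(c("s1", "s2"), c("s3", "s4", "s5")), same, refs)
  expect_equal(out2$selected, c("s3", "s4", "s5"))

  expect_warning(out3 <- selectGroup(list(), cands, refs), "no components")
  expect_length(out3$selected, 0)
})

test_that("curateFamily is invariant under candidate input order", {
  tpl <- familyTemplates()
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  fam <- evolveSequences(tree, tpl$HKT, 0.05, seed = 6)
  short <- Biostrings::AAStringSet(c(tiny = randomProtein(80)))
  cands <- c(fam, short)
  refs <- familyReferences()$HKT
  r1 <- curateFamily(cands, refs, familyClass = "HKT")
  r2 <- curateFamily(rev(cands), refs, familyClass = "HKT")
  expect_setequal(r1$selected, names(fam))
  expect_equal(sort(r1$selected), sort(r2$selected))
  expect_equal(r1$discardedShort, "tiny")
  expect_equal(sort(unlist(r1$components)), sort(unlist(r2$components)))
})
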