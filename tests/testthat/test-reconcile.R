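st3 <- speciesTree3()   # ((A,B)AB,C)ABC

gt <- function(txt) ape::read.tree(text = txt)

test_that("lcaMap maps leaves and internal nodes by species LCA", {
  ## congruent gene tree: the natural isomorphism
  g <- gt("((A|1:1,B|1:1):1,C|1:1);")
  M <- lcaMap(g, st3)
  lab <- c(st3$tip.label, st3$node.label)
  expect_equal(lab[M[1:3]], c("A", "B", "C"))
  expect_equal(lab[M[4]], "ABC")   # root
  expect_equal(lab[M[5]], "AB")

  ## duplicated quartet: all internals map to the AB ancestor
  g2 <- gt("((A|1:1,B|1:1):1,(A|2:1,B|2:1):1);")
  M2 <- lcaMap(g2, st3)
  expect_equal(unique(lab[M2[5:7]]), "AB")

  expect_error(lcaMap(gt("(A|1:1,Z|1:1);"), st3), "unknown species 'Z'")
})

test_that("lcaMap agrees with brute-force path-intersection LCA", {
  set.seed(221)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    g <- ape::rtree(n)
    g$tip.label <- paste0(sample(c("A", "B", "C"), n, replace = TRUE),
                          "|g", seq_len(n))
    M <- lcaMap(g, st3)
    for (v in (n + 1):(n + g$Nnode)) {
      tipsBelow <- unlist(phangorn::Descendants(g, v, "tips"))
      spTips <- match(sub("\\|.*", "", g$tip.label[tipsBelow]),
                      st3$tip.label)
      oracle <- Reduce(function(a, b) oracleLca(st3, a, b), spTips)
      expect_equal(M[v], oracle)
    }
  }
})

test_that("annotateEvents flags duplications sharing a child image", {
  g <- gt("((A|1:1,B|1:1):1,C|1:1);")
  ev <- annotateEvents(lcaMap(g, st3), g)
  expect_equal(sum(ev == "DUPLICATION"), 0)

  g2 <- gt("((A|1:1,B|1:1):1,(A|2:1,B|2:1):1);")
  ev2 <- annotateEvents(lcaMap(g2, st3), g2)
  expect_equal(ev2[5], "DUPLICATION")          # root
  expect_equal(ev2[6:7], rep("SPECIATION", 2))

  g3 <- gt("(A|1:1,(A|2:1,B|1:1):1);")
  ev3 <- annotateEvents(lcaMap(g3, st3), g3)
  expect_equal(ev3[4], "DUPLICATION")          # root shares image AB
})

test_that("countLosses charges minimal losses on species edges", {
  g <- gt("((A|1:1,B|1:1):1,C|1:1);")
  M <- lcaMap(g, st3)
  out <- countLosses(M, annotateEvents(M, g), g, st3)
  expect_equal(out$lossCount, 0)

  g2 <- gt("(A|1:1,(A|2:1,B|1:1):1);")
  M2 <- lcaMap(g2, st3)
  rec <- reconcileTrees(g2, st3)
  expect_equal(rec@duplicationCount, 1L)
  expect_equal(rec@lossCount, 1L)
  expect_equal(rec@losses$species_edge, "B")   # one copy lost in B

  ## root constraint adds losses above the gene root
  recC <- reconcileTrees(g2, st3, rootConstraint = "ABC")
  expect_equal(recC@lossCount, 2L)
  expect_true("C" %in% recC@losses$species_edge)
})

test_that("rootByDL recovers the zero-cost rooting of congruent trees", {
  g <- ape::unroot(gt("((A|1:1,B|1:1):1,C|1:1);"))
  out <- rootByDL(g, st3)
  expect_equal(attr(out, "score"), 0)
  expect_equal(out@duplicationCount + out@lossCount, 0L)

  ## quartet: root on the central edge, one duplication, no losses
  g2 <- ape::unroot(gt("((A|1:1,B|1:1):1,(A|2:1,B|2:1):1);"))
  out2 <- rootByDL(g2, st3)
  expect_equal(attr(out2, "score"), 1)
  expect_equal(out2@duplicationCount, 1L)
  expect_equal(out2@lossCount, 0L)
})

test_that("rootByDL attains the minimum over independently rerooted trees", {
  set.seed(231)
  for (rep in 1:8) {
    n <- 6
    g <- ape::rtree(n, rooted = FALSE)
    g$tip.label <- paste0(sample(c("A", "B", "C"), n, replace = TRUE),
                          "|g", seq_len(n))
    out <- rootByDL(g, st3)
    ## oracle: reroot on every branch with phytools and reconcile
    scores <- vapply(seq_len(nrow(g$edge)), function(e) {
      rr <- phytools::reroot(g, g$edge[e, 2],
                             position = g$edge.length[e] / 2)
      rr <- ape::collapse.singles(rr)
      dlScore(reconcileTrees(rr, st3))
    }, numeric(1))
    expect_equal(attr(out, "score"), min(scores))
  }
})

test_that("DL reconciliation attains the exhaustive-history minimum (small)", {
  set.seed(241)
  shapes <- treeShapes(4)
  for (rep in 1:25) {
    shape <- shapes[[sample(length(shapes), 1)]]
    labs <- paste0(sample(c("A", "B", "C"), 4, replace = TRUE), "|g", 1:4)
    g <- gt(shapeToNewick(shape, labs))
    rec <- reconcileTrees(g, st3)
    expect_equal(dlScore(rec),
                 oracleDLmin(g, st3, leafMapFromLabels(g$tip.label)))
  }
})

test_that("ancestralCopies implements the copies-exiting convention", {
  g <- gt("((A|1:1,B|1:1):1,C|1:1);")
  rec <- reconcileTrees(g, st3)
  expect_equal(ancestralCopies(rec, "ABC"), 1L)
  expect_equal(ancestralCopies(rec, "AB"), 1L)

  g2 <- gt("((A|1:1,B|1:1):1,(A|2:1,B|2:1):1);")
  rec2 <- reconcileTrees(g2, st3)
  expect_equal(ancestralCopies(rec2, "AB"), 2L)
  expect_equal(ancestralCopies(rec2, "A"), 2L)   # leaf copy count
  expect_error(ancestralCopies(rec2, "ZZ"), "not found")
})

test_that("leaf copy counts are conserved", {
  set.seed(251)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    g <- ape::rtree(n)
    g$tip.label <- paste0(sample(c("A", "B", "C"), n, replace = TRUE),
                          "|g", seq_len(n))
    rec <- reconcileTrees(g, st3)
    counts <- vapply(c("A", "B", "C"), function(s) {
      ancestralCopies(rec, s)
    }, integer(1))
    expect_equal(sum(counts), n)
  }
})

test_that("grafting a species-specific leaf never decreases duplications", {
  set.seed(261)
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    g <- ape::rtree(n)
    g$tip.label <- paste0(sample(c("A", "B", "C"), n, replace = TRUE),
                          "|g", seq_len(n))
    rec <- reconcileTrees(g, st3)
    ## graft an extra C gene as sister of an existing C gene (or of a
    ## random tip when no C gene exists)
    cTips <- grep("^C\\|", g$tip.label)
    at <- if (length(cTips)) cTips[1] else 1
    g2 <- ape::bind.tree(g, gt("(C|x:1,C|y:1);"), where = at)
    g2$tip.label[g2$tip.label == "C|y"] <- paste0(
      sub("\\|.*", "", g$tip.label[at]), "|y")
    g2$tip.label[at + 1] <- g$tip.label[at]
    rec2 <- suppressWarnings(reconcileTrees(ape::collapse.singles(g2), st3))
    expect_gte(rec2@duplicationCount, rec@duplicationCount)
  }
})

test_that("fixture gene trees encode the stated group structures", {
  fx <- buildFixtureGeneTree("HKT")
  expect_length(fx$tree$tip.label, 16)   # 1 + 7 + 1 + 1 + 6 loci
  expect_equal(sum(fx$leafMap == "Osativa"), 7)

  fxS <- buildFixtureGeneTree("SHAKER")
  expect_equal(sum(fxS$leafMap == "Smoellendorffii"), 1)
  expect_true("Sel-moe-SmORK" %in% fxS$tree$tip.label)

  fxT <- buildFixtureGeneTree("TPK")
  recT <- reconcileTrees(fxT$tree, speciesTreeFixture(), fxT$leafMap)
  rootNode <- length(fxT$tree$tip.label) + 1L
  expect_equal(recT@events[rootNode], "DUPLICATION")
  stIdx <- ktfam:::treeIndex(recT@speciesTree)
  expect_equal(stIdx$labels[recT@mapping[rootNode]], "Embryophyta")

  expect_error(buildFixtureGeneTree("NOPE"), "unknown family")
})
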