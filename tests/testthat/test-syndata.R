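test_that("zero-rate simulation is congruent with the species tree", {
  cfg <- simulationConfig(dupRate = 0, lossRate = 0, seed = 3L)
  sim <- simulateFamily(cfg, "HKT")
  expect_equal(sim$nLeaves, 5L)
  expect_setequal(sim$leaves$species, cfg@speciesTree$tip.label)
  expect_equal(sim$dupCount, 0L)
  expect_equal(sim$lossCount, 0L)
  ## topology mirrors the species tree
  g <- sim$tree
  g$tip.label <- sim$leaves$species[match(g$tip.label, sim$leaves$label)]
  expect_equal(ape::dist.topo(ape::unroot(g),
                              ape::unroot(cfg@speciesTree)), 0,
               ignore_attr = TRUE)
  ## branch lengths sum to the species-tree depth on every root-leaf path
  gDepths <- ape::node.depth.edgelength(sim$tree)[1:5]
  sDepths <- ape::node.depth.edgelength(cfg@speciesTree)[
    match(g$tip.label, cfg@speciesTree$tip.label)]
  expect_equal(unname(gDepths), unname(sDepths))
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  cfg <- simulationConfig(dupRate = 0.3, lossRate = 0.1, seed = 7L)
  a <- simulateFamily(cfg, "HAK")
  b <- simulateFamily(cfg, "HAK")
  expect_identical(a$leaves, b$leaves)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  ## over 100 seeds, outcomes differ somewhere with overwhelming probability
  sig <- vapply(1:100, function(s) {
    sim <- suppressWarnings(
      simulateFamily(simulationConfig(dupRate = 0.3, lossRate = 0.1,
                                      seed = s), "HAK"))
    paste(sim$nLeaves, sim$dupCount, sim$lossCount)
  }, "")
  expect_gt(length(unique(sig)), 10)
})

test_that("duplication-only growth matches the birth-process expectation", {
  ## quick version of the calibration check (the acceptance suite runs the
  ## full 2000-replicate version): E[N(t)] = exp(lambda * t)
  lambda <- 0.4
  two <- ape::read.tree(text = "(A:1,B:1);")
  n <- vapply(1:400, function(s) {
    cfg <- simulationConfig(speciesTree = two, dupRate = lambda,
                            lossRate = 0, seed = s)
    sim <- simulateFamily(cfg, "F")
    sum(sim$leaves$species == "A")
  }, integer(1))
  se <- stats::sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - exp(lambda)), 4 * se)
})

test_that("evolveSequences respects branch lengths and motif constraints", {
  tpl <- familyTemplates()
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  ## zero rate: all identical to the template
  s0 <- evolveSequences(tree, tpl$HAK, substRate = 0, seed = 1)
  expect_true(all(as.character(s0) == tpl$HAK$sequence))
  ## members always carry the planted motifs at the planted offsets
  lib <- motifLibrary()
  s1 <- evolveSequences(tree, tpl$HAK, substRate = 0.1, seed = 2)
  for (i in seq_along(s1)) {
    for (k in seq_len(nrow(tpl$HAK$motifSpans))) {
      mid <- tpl$HAK$motifSpans$motif_id[k]
      hits <- scanMotif(as.character(s1[[i]]), lib[[mid]])
      expect_true(tpl$HAK$motifSpans$start[k] %in% hits$start)
    }
  }
  expect_false(all(as.character(s1) == tpl$HAK$sequence))
})

test_that("sister identity decreases with path length", {
  tpl <- familyTemplates()
  set.seed(271)
  paths <- c(0.4, 2, 6)
  ident <- vapply(paths, function(t) {
    tr <- ape::read.tree(text = sprintf("(a:%g,b:%g);", t / 2, t / 2))
    mean(vapply(1:12, function(s) {
      sq <- evolveSequences(tr, tpl$HKT, substRate = 0.1, seed = s)
      a <- strsplit(as.character(sq[[1]]), "")[[1]]
      b <- strsplit(as.character(sq[[2]]), "")[[1]]
      mean(a == b)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ident) < 0))
})

test_that("emitProteomes produces consistent ground truth", {
  cfg <- simulationConfig(decoysPerSpecies = 4L, seed = 11L)
  em <- emitProteomes(cfg)
  ids <- unlist(lapply(em$proteomes, names))
  ## every truth row exists in the FASTA set exactly once
  expect_setequal(em$truth$proteins$protein_id, ids)
  expect_equal(anyDuplicated(ids), 0)
  ## species metadata consistent with ids
  for (sp in names(em$proteomes)) {
    expect_true(all(S4Vectors::mcols(em$proteomes[[sp]])$species == sp))
    expect_true(all(startsWith(names(em$proteomes[[sp]]), paste0(sp, "|"))))
  }
  ## per-species copy numbers match the recorded gene trees
  for (fam in names(em$truth$families)) {
    ft <- em$truth$families[[fam]]
    expect_equal(sum(ft$copyNumber), ft$leaves$label |> length())
  }
  ## planted motif coordinates are valid hits in every family member
  lib <- motifLibrary()
  prot <- em$truth$proteins
  seqs <- setNames(unlist(lapply(em$proteomes, function(p) {
    as.character(p)
  })), ids)
  fams <- prot$protein_id[prot$label != "DECOY"]
  for (id in sample(fams, min(6, length(fams)))) {
    fam <- prot$label[prot$protein_id == id]
    spans <- em$truth$motifSpans[[fam]]
    for (k in seq_len(nrow(spans))) {
      hits <- scanMotif(seqs[[id]], lib[[spans$motif_id[k]]])
      expect_true(spans$start[k] %in% hits$start)
    }
  }
})

test_that("near-miss decoys never classify into their source family", {
  cfg <- simulationConfig(decoysPerSpecies = 8L, nearMissFraction = 0.5,
                          seed = 13L)
  em <- emitProteomes(cfg)
  prot <- em$truth$proteins
  near <- prot[prot$near_miss, ]
  expect_gt(nrow(near), 0)
  allSeqs <- Biostrings::AAStringSet(setNames(
    unlist(lapply(em$proteomes, as.character)),
    unlist(lapply(em$proteomes, names))))
  calls <- classifyProteins(allSeqs[near$protein_id])$calls
  pools <- ktfam:::assignPools(calls)
  for (k in seq_len(nrow(near))) {
    expect_false(identical(pools[k], near$source_family[k]))
  }
})

test_that("zero decoys and zero rates give exactly one protein per species", {
  tpl <- familyTemplates()["HKT"]
  cfg <- simulationConfig(dupRate = 0, lossRate = 0, decoysPerSpecies = 0L,
                          templates = tpl, seed = 17L)
  em <- emitProteomes(cfg)
  expect_true(all(vapply(em$proteomes, length, integer(1)) == 1L))
})
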