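#' Build a simulation configuration
#'
#' The defaults define the synthetic study conditions used throughout the
#' package: families evolve along the packaged five-species land-plant tree
#' (unit branch lengths) under a birth-death process with modest
#' duplication and loss, and sequences diverge slowly enough that
#' within-family identity stays well above the 20% curation threshold
#' (roughly 75-95% across the tree at the default substitution rate), while
#' different families remain unrelated.
#'
#' @param speciesTree rooted `ape::phylo` with branch lengths (default:
#'   packaged five-species tree).
#' @param dupRate,lossRate duplication/loss events per gene copy per unit
#'   branch length.
#' @param substRate substitutions per site per unit branch length.
#' @param templates named list of family templates
#'   (default [familyTemplates()]).
#' @param decoysPerSpecies random decoy proteins per species.
#' @param nearMissFraction fraction of decoys emitted as near-miss template
#'   copies.
#' @param terminalDupOnly restrict duplications to terminal branches
#'   (species-specific duplications; used in duplication-recovery
#'   experiments).
#' @param seed master seed.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(speciesTree = speciesTreeFixture(),
                             dupRate = 0.1, lossRate = 0.05,
                             substRate = 0.05,
                             templates = familyTemplates(),
                             decoysPerSpecies = 8L,
                             nearMissFraction = 0.25,
                             terminalDupOnly = FALSE, seed = 1L) {
  new("SimulationConfig", speciesTree = speciesTree, dupRate = dupRate,
      lossRate = lossRate, substRate = substRate, templates = templates,
      decoysPerSpecies = as.integer(decoysPerSpecies),
      nearMissFraction = nearMissFraction,
      terminalDupOnly = terminalDupOnly, seed = as.integer(seed))
}

#' Family template proteins with planted motif instances
#'
#' Deterministically generated template proteins, one per synthetic family:
#' HAK (all five HAK motifs), HKT (both HKT motifs), SHAKER (selectivity
#' filter, voltage-sensor-like and inner-helix motifs; one pore) and TPK
#' (two non-overlapping selectivity-filter instances; no voltage sensor).
#' Template backgrounds are random but scrubbed so that no window outside a
#' planted selectivity-filter span comes within two restricted-position
#' substitutions of matching motif 1 - drifted descendants therefore keep
#' their pore counts. Each template is validated on construction: scanning
#' it finds exactly the planted hits at the planted offsets.
#'
#' @return named list of templates; each has `sequence`, `family`,
#'   `motifSpans` (data.frame `motif_id`, `occurrence`, `start`, `end`,
#'   0-based half-open), `siteSets` (per-site allowed residue sets inside
#'   planted spans) and `defeatSet` (minimal motif instances to break for a
#'   near-miss decoy).
#' @export
familyTemplates <- function() {
  if (!is.null(templateCache$templates)) return(templateCache$templates)
  lib <- motifLibrary()
  plan <- list(
    HAK = list(len = 720L,
               plants = data.frame(motif_id = 6:10,
                                   start = c(40L, 160L, 300L, 450L, 600L)),
               defeat = 1:3),
    HKT = list(len = 520L,
               plants = data.frame(motif_id = c(4L, 5L),
                                   start = c(60L, 430L)),
               defeat = 1L),
    SHAKER = list(len = 820L,
                  plants = data.frame(motif_id = c(2L, 1L, 3L),
                                      start = c(120L, 560L, 700L)),
                  defeat = 2L),   # row 2 = the selectivity filter
    TPK = list(len = 360L,
               plants = data.frame(motif_id = c(1L, 1L),
                                   start = c(80L, 260L)),
               defeat = 1L))
  out <- withSeed(987654L, lapply(names(plan), function(fam) {
    makeTemplate(fam, plan[[fam]], lib)
  }))
  names(out) <- names(plan)
  templateCache$templates <- out
  out
}

templateCache <- new.env(parent = emptyenv())

## Generate one template: random background, planted motif instances (first
## allowed residue at restricted positions), motif-1 scrubbing, validation.
makeTemplate <- function(family, p, lib) {
  len <- p$len
  seqv <- sample(AA_STANDARD, len, replace = TRUE)
  spans <- p$plants
  spans$occurrence <- stats::ave(spans$motif_id, spans$motif_id,
                                 FUN = seq_along)
  siteSets <- vector("list", len)
  spans$end <- NA_integer_
  for (k in seq_len(nrow(spans))) {
    pat <- lib[[spans$motif_id[[k]]]]
    P <- length(pat@positions)
    spans$end[[k]] <- spans$start[[k]] + P
    for (j in seq_len(P)) {
      site <- spans$start[[k]] + j
      set <- pat@positions[[j]]
      if (!is.null(set)) {
        seqv[[site]] <- set[[1L]]
        siteSets[[site]] <- sort(set)
      }
    }
  }
  ## scrub: outside planted motif-1 spans, keep every window >= 3 restricted
  ## -position substitutions away from matching the selectivity filter
  m1 <- lib[[1L]]
  P1 <- length(m1@positions)
  pore <- spans[spans$motif_id == 1L, , drop = FALSE]
  overlapsPore <- function(w0) {
    any(w0 < pore$end & (w0 + P1) > pore$start)
  }
  planted <- which(!vapply(siteSets, is.null, logical(1)))
  for (iter in 1:200) {
    mm <- motifMismatches(seqv, m1)
    bad <- which(mm <= 2L) - 1L
    bad <- bad[!vapply(bad, overlapsPore, logical(1))]
    if (!length(bad)) break
    w0 <- bad[[1L]]
    free <- setdiff((w0 + 1L):(w0 + P1), planted)
    seqv[free] <- sample(AA_STANDARD, length(free), replace = TRUE)
  }
  template <- list(sequence = paste(seqv, collapse = ""), family = family,
                   motifSpans = spans[, c("motif_id", "occurrence",
                                          "start", "end")],
                   siteSets = siteSets, defeatSet = p$defeat)
  validateTemplate(template, lib)
  template
}

## Restricted-position mismatch count of every window against a pattern.
motifMismatches <- function(seqv, pattern) {
  codes <- match(seqv, AA_ALLOWED)
  P <- length(pattern@positions)
  W <- length(codes) - P + 1L
  mm <- rep(0L, W)
  for (j in seq_len(P)) {
    set <- pattern@positions[[j]]
    if (is.null(set)) next
    mm <- mm + !(codes[j:(j + W - 1L)] %in% match(set, AA_ALLOWED))
  }
  mm
}

## A template must scan positive at exactly its planted offsets for each
## planted motif.
validateTemplate <- function(template, lib = motifLibrary()) {
  for (k in seq_len(nrow(template$motifSpans))) {
    mid <- template$motifSpans$motif_id[[k]]
    hits <- scanMotif(template$sequence, lib[[mid]])
    if (!template$motifSpans$start[[k]] %in% hits$start) {
      stop(sprintf("template %s: planted motif %d not found at offset %d",
                   template$family, mid, template$motifSpans$start[[k]]))
    }
  }
  invisible(TRUE)
}

#' Simulate one gene family along the species tree
#'
#' Birth-death gene evolution: starting from one copy at the species-tree
#' root, each extant copy on a species branch duplicates with rate
#' `dupRate` and is lost with rate `lossRate` (exponential waiting times).
#' Surviving copies at the species leaves become genes, named
#' `Species|FAMILY|g<k>`. A fully extinct family is redrawn (up to 100
#' attempts, with a warning).
#'
#' @param config a [SimulationConfig-class].
#' @param family family name (used in gene ids and the seed substream).
#' @param seed optional override of the derived substream seed.
#' @return list: `tree` (`ape::phylo` with branch lengths, `NULL` when
#'   fewer than two genes survive), `leaves` (data.frame `label`,
#'   `species`), `dupCount` (duplications with two surviving descendants),
#'   `lossCount`, `dupEdges` (species edge label of each counted
#'   duplication), `attempts`.
#' @export
simulateFamily <- function(config, family = "FAM", seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (is.null(seed)) seed <- subSeed(config@seed, paste0("family-", family))
  withSeed(seed, {
    for (attempt in 1:100) {
      res <- simulateFamilyOnce(config, family)
      if (res$nLeaves > 0L) {
        res$attempts <- attempt
        if (attempt > 1L) {
          warning(sprintf("family %s extinct in %d attempt(s); redrawn",
                          family, attempt - 1L))
        }
        return(res)
      }
    }
    stop("family went extinct in 100 attempts; lower lossRate")
  })
}

simulateFamilyOnce <- function(config, family) {
  sIdx <- treeIndex(config@speciesTree)
  edgeLen <- config@speciesTree$edge.length
  if (is.null(edgeLen)) edgeLen <- rep(1, nrow(config@speciesTree$edge))
  edgeOf <- function(child) which(config@speciesTree$edge[, 2L] == child)
  counter <- new.env(parent = emptyenv())
  counter$k <- 0L
  counter$dups <- character()
  counter$losses <- 0L
  spLabel <- function(nd) sIdx$labels[[nd]]
  simFrom <- function(sNode) {
    if (sNode <= sIdx$n) {
      counter$k <- counter$k + 1L
      return(list(label = sprintf("%s|%s|g%d", spLabel(sNode), family,
                                  counter$k),
                  species = spLabel(sNode), len = 0))
    }
    kids <- lapply(sIdx$kids[[sNode]], function(ch) {
      simEdge(edgeLen[[edgeOf(ch)]], ch)
    })
    kids <- Filter(Negate(is.null), kids)
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1L]])
    list(children = kids, len = 0)
  }
  simEdge <- function(t, sChild) {
    dup <- if (config@terminalDupOnly && sChild > sIdx$n) 0 else config@dupRate
    rate <- dup + config@lossRate
    tau <- if (rate > 0) rexp(1L, rate) else Inf
    if (tau >= t) {
      sub <- simFrom(sChild)
      if (is.null(sub)) return(NULL)
      sub$len <- sub$len + t
      return(sub)
    }
    if (runif(1L) < dup / rate) {
      left <- simEdge(t - tau, sChild)
      right <- simEdge(t - tau, sChild)
      surv <- Filter(Negate(is.null), list(left, right))
      if (length(surv) == 0L) return(NULL)
      if (length(surv) == 1L) {
        sub <- surv[[1L]]
        sub$len <- sub$len + tau
        return(sub)
      }
      counter$dups <- c(counter$dups, spLabel(sChild))
      return(list(children = surv, len = tau))
    }
    counter$losses <- counter$losses + 1L
    NULL
  }
  top <- simFrom(sIdx$root)
  leaves <- collectLeaves(top)
  nl <- nrow(leaves)
  tree <- if (!is.null(top) && nl >= 2L) nestedToPhylo(top) else NULL
  list(tree = tree, leaves = leaves, nLeaves = nl,
       dupCount = length(counter$dups), lossCount = counter$losses,
       dupEdges = counter$dups,
       singleLeafDepth = if (nl == 1L) top$len else NA_real_)
}

collectLeaves <- function(x) {
  if (is.null(x)) {
    return(data.frame(label = character(), species = character()))
  }
  if (!is.null(x$label)) {
    return(data.frame(label = x$label, species = x$species))
  }
  do.call(rbind, lapply(x$children, collectLeaves))
}

## Convert the simulator's nested tree into an ape phylo (>= 2 leaves).
nestedToPhylo <- function(x) {
  env <- new.env(parent = emptyenv())
  env$tips <- character()
  env$edges <- list()
  env$lens <- numeric()
  nTips <- function(nd) {
    if (!is.null(nd$label)) 1L else sum(vapply(nd$children, nTips, integer(1)))
  }
  total <- nTips(x)
  env$nextNode <- total + 1L
  rec <- function(nd) {
    if (!is.null(nd$label)) {
      env$tips <- c(env$tips, nd$label)
      return(list(id = length(env$tips), len = nd$len))
    }
    my <- env$nextNode
    env$nextNode <- env$nextNode + 1L
    for (ch in nd$children) {
      r <- rec(ch)
      env$edges[[length(env$edges) + 1L]] <- c(my, r$id)
      env$lens[[length(env$lens) + 1L]] <- r$len
    }
    list(id = my, len = nd$len)
  }
  rec(x)
  phy <- list(edge = do.call(rbind, env$edges), tip.label = env$tips,
              edge.length = env$lens, Nnode = env$nextNode - total - 1L)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Evolve sequences along a gene tree from a family template
#'
#' Independent per-site substitution: on a branch of length t each site
#' mutates with probability `1 - exp(-substRate * t)`, drawing a uniform
#' different residue. Sites inside planted motif spans mutate only within
#' the motif's allowed set at that position (wildcard positions are
#' unrestricted), so every descendant still carries the family's motif
#' signature at the planted offsets.
#'
#' @param geneTree `ape::phylo` with branch lengths in species-tree units.
#' @param template one element of [familyTemplates()].
#' @param substRate substitutions per site per unit branch length.
#' @param seed integer seed.
#' @return `AAStringSet` named by gene-tree tip labels.
#' @export
evolveSequences <- function(geneTree, template, substRate, seed = 1L) {
  rootSeq <- chars(template$sequence)
  withSeed(seed, {
    idx <- treeIndex(geneTree)
    seqs <- vector("list", idx$N)
    seqs[[idx$root]] <- rootSeq
    ## preorder down the tree
    ord <- idx$root
    out <- list()
    while (length(ord)) {
      nd <- ord[[1L]]; ord <- ord[-1L]
      for (k in idx$kids[[nd]]) {
        e <- which(geneTree$edge[, 2L] == k)
        seqs[[k]] <- mutateSeq(seqs[[nd]], geneTree$edge.length[[e]],
                               substRate, template$siteSets)
        ord <- c(ord, k)
      }
    }
    res <- vapply(seq_len(idx$n), function(i) paste(seqs[[i]], collapse = ""),
                  character(1))
    Biostrings::AAStringSet(setNames(res, geneTree$tip.label))
  })
}

mutateSeq <- function(seqv, t, rate, siteSets) {
  p <- 1 - exp(-rate * t)
  if (p <= 0) return(seqv)
  hit <- which(runif(length(seqv)) < p)
  for (i in hit) {
    set <- siteSets[[i]]
    if (is.null(set)) {
      seqv[[i]] <- sample(setdiff(AA_STANDARD, seqv[[i]]), 1L)
    } else if (length(set) > 1L) {
      seqv[[i]] <- sample(setdiff(set, seqv[[i]]), 1L)
    } ## singleton sets are invariant
  }
  seqv
}

#' Emit synthetic proteomes with ground truth
#'
#' Simulates every family in the configuration, evolves member sequences,
#' adds uniform-random decoys with a length distribution matched to the
#' family templates, and near-miss decoys (template copies broken at one
#' restricted position per motif instance of a minimal rule-defeating set).
#' Ids encode species and truth linkage (`Species|FAMILY|g1`,
#' `Species|decoy|d1`, `Species|nearmiss|FAMILY|d2`).
#'
#' @param config a [SimulationConfig-class].
#' @return list with `proteomes` (named list of per-species `AAStringSet`s
#'   with species metadata) and `truth`: `proteins` (data.frame
#'   `protein_id`, `species`, `label` = family or `"DECOY"`, `near_miss`,
#'   `source_family`), `families` (per family: `tree`, `leaves`,
#'   `dupCount`, `lossCount`, `dupEdges`, `copyNumber` per species),
#'   `motifSpans` (planted coordinates, per family).
#' @export
emitProteomes <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  species <- config@speciesTree$tip.label
  seqsBySpecies <- setNames(vector("list", length(species)), species)
  truthRows <- list()
  famTruth <- list()
  for (fam in names(config@templates)) {
    tpl <- config@templates[[fam]]
    sim <- simulateFamily(config, fam)
    if (!is.null(sim$tree)) {
      seqs <- evolveSequences(sim$tree, tpl, config@substRate,
                              seed = subSeed(config@seed, paste0("seq-", fam)))
    } else if (sim$nLeaves == 1L) {
      seqs <- withSeed(subSeed(config@seed, paste0("seq-", fam)), {
        s <- mutateSeq(chars(tpl$sequence), sim$singleLeafDepth,
                       config@substRate, tpl$siteSets)
        Biostrings::AAStringSet(setNames(paste(s, collapse = ""),
                                         sim$leaves$label[[1L]]))
      })
    } else {
      seqs <- Biostrings::AAStringSet()
    }
    for (i in seq_along(seqs)) {
      sp <- sim$leaves$species[[match(names(seqs)[[i]], sim$leaves$label)]]
      seqsBySpecies[[sp]] <- c(seqsBySpecies[[sp]],
                               setNames(as.character(seqs[[i]]),
                                        names(seqs)[[i]]))
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        protein_id = names(seqs)[[i]], species = sp, label = fam,
        near_miss = FALSE, source_family = fam)
    }
    famTruth[[fam]] <- list(
      tree = sim$tree, leaves = sim$leaves, dupCount = sim$dupCount,
      lossCount = sim$lossCount, dupEdges = sim$dupEdges,
      copyNumber = vapply(species, function(sp) {
        sum(sim$leaves$species == sp)
      }, integer(1)))
  }
  ## decoys
  fams <- names(config@templates)
  lens <- vapply(config@templates, function(t) nchar(t$sequence), integer(1))
  nNear <- round(config@nearMissFraction * config@decoysPerSpecies)
  nRand <- config@decoysPerSpecies - nNear
  for (sp in species) {
    dseqs <- withSeed(subSeed(config@seed, paste0("decoy-", sp)), {
      out <- list()
      for (d in seq_len(nRand)) {
        L <- round(sample(lens, 1L) * runif(1L, 0.85, 1.15))
        out[[sprintf("%s|decoy|d%d", sp, d)]] <-
          paste(sample(AA_STANDARD, L, replace = TRUE), collapse = "")
      }
      for (d in seq_len(nNear)) {
        fam <- fams[[(d - 1L) %% length(fams) + 1L]]
        out[[sprintf("%s|nearmiss|%s|d%d", sp, fam, nRand + d)]] <-
          nearMissSequence(config@templates[[fam]])
      }
      out
    })
    for (id in names(dseqs)) {
      seqsBySpecies[[sp]] <- c(seqsBySpecies[[sp]], setNames(dseqs[[id]], id))
      isNear <- grepl("|nearmiss|", id, fixed = TRUE)
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        protein_id = id, species = sp, label = "DECOY", near_miss = isNear,
        source_family = if (isNear) strsplit(id, "|", fixed = TRUE)[[1L]][[3L]]
                        else NA_character_)
    }
  }
  proteomes <- lapply(species, function(sp) {
    x <- Biostrings::AAStringSet(seqsBySpecies[[sp]])
    S4Vectors::mcols(x) <- S4Vectors::DataFrame(
      species = rep(sp, length(x)),
      description = rep("", length(x)))
    x
  })
  names(proteomes) <- species
  list(proteomes = proteomes,
       truth = list(proteins = do.call(rbind, truthRows),
                    families = famTruth,
                    motifSpans = lapply(config@templates, `[[`, "motifSpans")))
}

## A near-miss decoy: template copy with one restricted position of each
## motif instance in the defeat set mutated outside its allowed set.
nearMissSequence <- function(template) {
  seqv <- chars(template$sequence)
  spans <- template$motifSpans
  for (k in template$defeatSet) {
    span <- (spans$start[[k]] + 1L):spans$end[[k]]
    restricted <- span[!vapply(template$siteSets[span], is.null, logical(1))]
    site <- restricted[[length(restricted)]]
    outside <- setdiff(AA_STANDARD, c(template$siteSets[[site]], seqv[[site]]))
    seqv[[site]] <- outside[[1L]]
  }
  paste(seqv, collapse = "")
}
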