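#' The packaged inventory tables
#'
#' Returns the inventory of K+ transporter and channel loci per species and
#' family (HAK, HKT, TPK, SHAKER and the non-Shaker voltage-gated channels
#' OTHER_VG, including the algal entries), as packaged plain-text fixtures.
#'
#' @param table optional table number 1-5 to subset.
#' @param family optional family to subset.
#' @return data.frame with columns `table`, `species`, `family`, `locus`,
#'   `name` and attribute `provenance = "FIXTURE"`.
#' @export
inventoryFixture <- function(table = NULL, family = NULL) {
  path <- system.file("extdata", "inventory_tables.tsv", package = "ktfam",
                      mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(table = "integer", species = "character",
                                   family = "character", locus = "character",
                                   name = "character"))
  if (!is.null(table)) tab <- tab[tab$table == table, , drop = FALSE]
  if (!is.null(family)) tab <- tab[tab$family == family, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "provenance") <- "FIXTURE"
  tab
}

#' Count inventory rows for a species/family cell
#'
#' @param table an inventory data.frame (fixture or computed) with `species`
#'   and `family` columns.
#' @param species species tag (e.g. `"Athaliana"`).
#' @param family family label (e.g. `"HAK"`).
#' @return integer count (0 for an empty table).
#' @examples
#' countInventory(inventoryFixture(), "Osativa", "HKT")  # 7
#' @export
countInventory <- function(table, species, family) {
  knownSp <- unique(table$species)
  if (nrow(table) > 0L && !species %in% knownSp) {
    stop(sprintf("unknown species '%s'; valid: %s", species,
                 paste(sort(knownSp), collapse = ", ")))
  }
  if (nrow(table) > 0L && !family %in% FAMILY_LEVELS) {
    stop(sprintf("unknown family '%s'; valid: %s", family,
                 paste(FAMILY_LEVELS, collapse = ", ")))
  }
  sum(table$species == species & table$family == family)
}

#' Compare two inventories
#'
#' @param computed,fixture inventory data.frames with `species`, `family`,
#'   `locus` columns.
#' @return data.frame per (species, family) occurring in either table:
#'   counts, number of shared loci, additions (in `computed` only) and
#'   omissions (in `fixture` only).
#' @export
compareInventories <- function(computed, fixture) {
  keys <- unique(rbind(computed[, c("species", "family")],
                       fixture[, c("species", "family")]))
  keys <- keys[order(keys$species, keys$family), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sp <- keys$species[[i]]; fam <- keys$family[[i]]
    a <- computed$locus[computed$species == sp & computed$family == fam]
    b <- fixture$locus[fixture$species == sp & fixture$family == fam]
    data.frame(species = sp, family = fam, n_computed = length(a),
               n_fixture = length(b), shared = length(intersect(a, b)),
               additions = length(setdiff(a, b)),
               omissions = length(setdiff(b, a)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- fixture gene trees -------------------------------------------------

## Fold a vector of labels into a nested ladder (caterpillar) list.
ladder <- function(labels) {
  if (length(labels) == 1L) return(labels[[1L]])
  list(labels[[1L]], ladder(labels[-1L]))
}

## Nested gene-subtree for one ortholog group: the species tree restricted
## to the represented species, with same-species loci as internal ladders.
groupNested <- function(speciesTree, bySpecies) {
  sIdx <- treeIndex(speciesTree)
  rec <- function(nd) {
    if (nd <= sIdx$n) {
      sp <- speciesTree$tip.label[[nd]]
      if (is.null(bySpecies[[sp]]) || !length(bySpecies[[sp]])) return(NULL)
      return(ladder(bySpecies[[sp]]))
    }
    parts <- Filter(Negate(is.null), lapply(sIdx$kids[[nd]], rec))
    if (length(parts) == 0L) return(NULL)
    if (length(parts) == 1L) return(parts[[1L]])
    parts
  }
  rec(sIdx$root)
}

nestedLabelsToPhylo <- function(x) {
  wrap <- function(y) {
    if (is.character(y)) return(list(label = y, len = 1))
    list(children = lapply(y, wrap), len = 1)
  }
  nestedToPhylo(wrap(x))
}

## Membership reconstruction of the ortholog-group structures stated for
## each family (memberships not stated in the source tables are allocated
## deterministically; see the methods vignette).
fixtureGroups <- function(family, tab) {
  split_by_species <- function(names) {
    sp <- tab$species[match(names, tab$name)]
    split(names, sp)[unique(sp)]
  }
  if (family == "HKT") {
    return(list(all = split_by_species(tab$name)))
  }
  if (family == "TPK") {
    gA <- c("Phy-pat-TPK01", "Phy-pat-TPK02",
            "Sel-moe-TPK1", "Sel-moe-TPK2",
            "Ory-sat-TPKa", "Ory-sat-TPKb",
            "Ara-tha-TPK1", "Ara-tha-TPK3", "Ara-tha-TPK2", "Ara-tha-KCO3",
            paste0("Pop-tri-TPK0", 1:5))
    gB <- setdiff(tab$name, gA)
    return(list(A = split_by_species(gA), B = split_by_species(gB)))
  }
  if (family == "SHAKER") {
    pp <- tab$name[tab$species == "Ppatens"]
    kout <- c("Sel-moe-SmORK", "Ara-tha-SKOR", "Ara-tha-GORK")
    kin <- setdiff(tab$name, c(pp, kout))
    return(list(PP = split_by_species(pp), KOUT = split_by_species(kout),
                KIN = split_by_species(kin)))
  }
  if (family == "HAK") {
    ## anchors stated in the source; the rest allocated round-robin
    anchor <- list(
      I = c("Ara-tha-HAK5", "Ara-tha-KUP/HAK/KT12", "Ory-sat-HAK1",
            "Ory-sat-HAK5", "Phy-pat-HAK1", "Sel-moe-HAK5", "Sel-moe-HAK8",
            "Sel-moe-HAK9"),
      II = c("Ory-sat-HAK10", "Phy-pat-HAK2"),
      III = character(),
      IV = c("Phy-pat-HAK13", "Sel-moe-HAK1", "Sel-moe-HAK11"),
      V = character(), VI = character())
    assigned <- unlist(anchor)
    groups <- anchor
    for (sp in unique(tab$species)) {
      rest <- setdiff(tab$name[tab$species == sp], assigned)
      if (sp == "Ppatens") {
        half <- ceiling(length(rest) / 2)
        groups$V <- c(groups$V, rest[seq_len(half)])
        groups$VI <- c(groups$VI, rest[-seq_len(half)])
      } else if (sp == "Smoellendorffii") {
        targets <- rep(c("II", "III"), length.out = length(rest))
        for (k in seq_along(rest)) {
          groups[[targets[[k]]]] <- c(groups[[targets[[k]]]], rest[[k]])
        }
      } else {
        targets <- rep(c("I", "II", "III", "IV"), length.out = length(rest))
        for (k in seq_along(rest)) {
          groups[[targets[[k]]]] <- c(groups[[targets[[k]]]], rest[[k]])
        }
      }
    }
    return(lapply(groups, split_by_species))
  }
  stop(sprintf("unknown family '%s'; valid: HAK, HKT, TPK, SHAKER", family))
}

#' Build a fixture gene tree from the packaged inventory
#'
#' Constructs, for one family, a rooted gene tree over the packaged
#' inventory loci that encodes the stated ortholog-group structure: within
#' each group the topology mirrors the species tree restricted to the
#' represented species (same-species loci as species-internal clades);
#' groups are joined per family - HKT as a single group, TPK as two groups
#' joined at the root, Shaker as the P. patens clade versus (Kout including
#' SmORK, angiosperm Kin), HAK as six groups joined in a chain. Unstated
#' within-group resolution and memberships are deterministic
#' reconstructions.
#'
#' @param family `"HAK"`, `"HKT"`, `"TPK"` or `"SHAKER"`.
#' @param speciesTree species tree (default the packaged fixture).
#' @return list with `tree` (rooted `ape::phylo`, unit branch lengths),
#'   `leafMap` (gene leaf -> species).
#' @export
buildFixtureGeneTree <- function(family, speciesTree = speciesTreeFixture()) {
  tab <- inventoryFixture(family = family)
  if (!nrow(tab)) stop(sprintf("unknown family '%s'", family))
  g <- fixtureGroups(family, tab)
  sub <- lapply(g, function(members) groupNested(speciesTree, members))
  nested <- switch(family,
    HKT = sub$all,
    TPK = list(sub$A, sub$B),
    SHAKER = list(sub$PP, list(sub$KOUT, sub$KIN)),
    HAK = list(sub$II, list(sub$V, list(sub$VI,
               list(sub$I, list(sub$III, sub$IV))))))
  tree <- nestedLabelsToPhylo(nested)
  leafMap <- setNames(tab$species[match(tree$tip.label, tab$name)],
                      tree$tip.label)
  list(tree = tree, leafMap = leafMap)
}
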