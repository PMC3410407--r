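#' Reference proteins for each synthetic family
#'
#' The packaged family templates double as the known reference transporters
#' that curation compares candidate groups against (the role the
#' characterised Arabidopsis family members play for real proteomes).
#'
#' @return named list of single-sequence `AAStringSet`s keyed by family.
#' @export
familyReferences <- function() {
  tpl <- familyTemplates()
  out <- lapply(names(tpl), function(fam) {
    Biostrings::AAStringSet(setNames(tpl[[fam]]$sequence,
                                     paste0("ref|", fam)))
  })
  names(out) <- names(tpl)
  out
}

## Motif class used for the reference span of each curated family.
familyMotifClass <- function(family) {
  switch(family, HAK = "HAK", HKT = "HKT", SHAKER = "CHANNEL",
         TPK = "CHANNEL", stop(sprintf("unknown family '%s'", family)))
}

## Assign classified proteins to curation pools. Tandem-pore candidates are
## any channel with >= 2 non-overlapping selectivity filters (robust to
## chance extra filter hits in drifted single-pore channels); remaining
## single-pore channels need voltage-sensor-like evidence (motif 2) to be
## Shaker candidates; the rest of the channel calls go to the OTHER_VG
## review list, mirroring the similarity-based (non-motif) identification
## of BK-like channels.
assignPools <- function(calls) {
  matched <- lapply(strsplit(calls$motif_ids_matched, ",", fixed = TRUE),
                    as.integer)
  hasM2 <- vapply(matched, function(m) 2L %in% m, logical(1))
  chan <- calls$family == "CHANNEL"
  pool <- rep(NA_character_, nrow(calls))
  pool[calls$family == "HAK"] <- "HAK"
  pool[calls$family == "HKT"] <- "HKT"
  pool[chan & calls$channel_pore_count >= 2L] <- "TPK"
  pool[chan & calls$channel_pore_count == 1L & hasM2] <- "SHAKER"
  pool[chan & is.na(pool)] <- "OTHER_VG"
  pool
}

#' Run the full inventory screen
#'
#' Orchestrates the pipeline on one or more proteomes: motif scan and
#' family classification, per-family semi-automatic curation, progressive
#' alignment with conserved-block filtering, identity-distance
#' neighbor-joining trees, and (when a species tree is given and at least
#' three members survive) duplication-loss rooting and reconciliation. The
#' computed inventory lists the selected members of each family plus their
#' identical duplicates removed during curation.
#'
#' @param proteomes a named list of `AAStringSet`s with species metadata
#'   (as from [readFasta()] or [emitProteomes()]), or a single such set.
#' @param references named list of reference `AAStringSet`s per family
#'   (default [familyReferences()]).
#' @param speciesTree optional rooted species tree for reconciliation.
#' @param motifs motif library.
#' @param rules classification rules.
#' @param params curation parameters.
#' @param blockParams block filter parameters.
#' @param bootstrapReplicates bootstrap replicates for family trees (0 =
#'   skip).
#' @param seed seed recorded in the manifest and used for bootstrap
#'   resampling.
#' @return list with `inventory` (data.frame `species`, `family`, `locus`,
#'   `name`, `via`, provenance `"COMPUTED"`), `calls`, `pools`, `families`
#'   (per family: curation report, `msa`, `filtered`, `distance`, `tree`,
#'   `recon`), `reviewOther` (channel calls routed to human review) and
#'   `manifest`.
#' @export
runScreen <- function(proteomes, references = familyReferences(),
                      speciesTree = NULL, motifs = motifLibrary(),
                      rules = defaultClassifyRules(),
                      params = curationParams(),
                      blockParams = blockFilterParams(),
                      bootstrapReplicates = 0L, seed = 1L) {
  if (is(proteomes, "XStringSet")) proteomes <- list(proteomes)
  all <- character()
  speciesOf <- character()
  for (p in proteomes) {
    sp <- S4Vectors::mcols(p)$species
    if (is.null(sp)) stop("proteomes must carry species metadata")
    all <- c(all, setNames(as.character(p), names(p)))
    speciesOf <- c(speciesOf, setNames(sp, names(p)))
  }
  combined <- Biostrings::AAStringSet(all)
  if (length(combined) == 0L) {
    return(list(inventory = emptyInventory(), calls = NULL, pools = NULL,
                families = list(), reviewOther = character(),
                manifest = list(seed = seed)))
  }
  cls <- classifyProteins(combined, motifs, rules)
  pools <- assignPools(cls$calls)
  invRows <- list()
  famOut <- list()
  for (fam in names(references)) {
    ids <- cls$calls$protein_id[!is.na(pools) & pools == fam]
    if (!length(ids)) next
    report <- curateFamily(combined[ids], references[[fam]], motifs,
                           familyClass = familyMotifClass(fam), params)
    members <- report$selected
    dups <- intersect(report$removedIdentical, ids)
    for (id in members) {
      invRows[[length(invRows) + 1L]] <- data.frame(
        species = speciesOf[[id]], family = fam, locus = id, name = id,
        via = "selected")
    }
    for (id in dups) {
      invRows[[length(invRows) + 1L]] <- data.frame(
        species = speciesOf[[id]], family = fam, locus = id, name = id,
        via = "identical_duplicate")
    }
    famRes <- list(report = report)
    if (length(members) >= 3L) {
      msa <- progressiveMsa(combined[members])
      bf <- blockFilter(msa, blockParams)
      useMsa <- if (ncol(bf$msa) >= 2L) bf$msa else msa
      D <- identityDistance(useMsa)
      tree <- njTree(D)
      if (bootstrapReplicates > 0L) {
        tree <- bootstrapSupport(useMsa, replicates = bootstrapReplicates,
                                 seed = seed, builder = "nj")
      }
      famRes$msa <- msa
      famRes$filtered <- bf
      famRes$distance <- D
      famRes$tree <- tree
      if (!is.null(speciesTree)) {
        lm <- setNames(speciesOf[members], members)
        famRes$recon <- rootByDL(tree, speciesTree, leafMap = lm)
      }
    }
    famOut[[fam]] <- famRes
  }
  inventory <- if (length(invRows)) do.call(rbind, invRows) else
    emptyInventory()
  inventory <- inventory[order(inventory$family, inventory$species,
                               inventory$locus), , drop = FALSE]
  rownames(inventory) <- NULL
  attr(inventory, "provenance") <- "COMPUTED"
  list(inventory = inventory, calls = cls$calls, pools = pools,
       families = famOut,
       reviewOther = cls$calls$protein_id[!is.na(pools) &
                                            pools == "OTHER_VG"],
       manifest = list(seed = seed, rules = rules, params = params,
                       blockParams = blockParams,
                       bootstrapReplicates = bootstrapReplicates,
                       nProteins = length(combined)))
}

emptyInventory <- function() {
  out <- data.frame(species = character(), family = character(),
                    locus = character(), name = character(),
                    via = character())
  attr(out, "provenance") <- "COMPUTED"
  out
}
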