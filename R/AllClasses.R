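#' MotifPattern: a compiled degenerate protein motif
#'
#' A positional representation of a degenerate motif written in the
#' `"[S,T]-x-x-T-x-G-[Y,F,L]-G-[D,E]"` dialect: positions are separated by
#' `-`; each position is either the wildcard `x`, a single residue letter, or
#' a bracketed set of allowed residues. Compiled patterns match a window of
#' exactly `length(positions)` residues, position by position. The wildcard
#' matches any letter including the unknown residue `X`; a restricted
#' position is never satisfied by `X`.
#'
#' @slot motifId integer identifier (1-10 for the packaged library).
#' @slot familyClass one of `"CHANNEL"`, `"HKT"`, `"HAK"` (or `""` for ad hoc
#'   patterns).
#' @slot positions list with one element per position: `NULL` for a wildcard,
#'   otherwise a character vector of allowed residues.
#' @slot sourceText the motif string as written; `renderMotif()` reproduces
#'   it.
#' @seealso [compileMotif()], [motifLibrary()], [scanMotif()]
#' @importClassesFrom Biostrings AAStringSet
#' @export
setClass("MotifPattern",
  representation(motifId = "integer", familyClass = "character",
                 positions = "list", sourceText = "character"),
  prototype(motifId = NA_integer_, familyClass = ""))

setValidity("MotifPattern", function(object) {
  msgs <- character()
  if (length(object@positions) < 1L) {
    msgs <- c(msgs, "pattern must have at least one position")
  }
  for (p in object@positions) {
    if (is.null(p)) next
    if (!is.character(p) || length(p) < 1L) {
      msgs <- c(msgs, "restricted positions must be non-empty character vectors")
    } else if (!all(p %in% AA_STANDARD)) {
      msgs <- c(msgs, sprintf("non-standard residue in position set: %s",
                              paste(setdiff(p, AA_STANDARD), collapse = ",")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Msa: a multiple protein sequence alignment
#'
#' Thin S4 container for an aligned block: an `AAStringSet` whose members all
#' have the same width, with `-` as the gap character. Removing the gaps from
#' a row reproduces the corresponding input sequence.
#'
#' @slot aln `Biostrings::AAStringSet` of equal-width aligned rows; names are
#'   the sequence ids.
#' @seealso [progressiveMsa()], [blockFilter()], [identityDistance()]
#' @export
setClass("Msa", representation(aln = "AAStringSet"))

setValidity("Msa", function(object) {
  w <- Biostrings::width(object@aln)
  if (length(w) == 0L) return(TRUE)
  msgs <- character()
  if (length(unique(w)) != 1L) msgs <- c(msgs, "all rows must have equal width")
  nm <- names(object@aln)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm))) {
    msgs <- c(msgs, "rows must carry unique non-empty names")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an Msa from aligned strings
#'
#' @param x named character vector of equal-length aligned strings (gaps as
#'   `-`), or an `AAStringSet`.
#' @return an [Msa-class] object.
#' @export
Msa <- function(x) {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  new("Msa", aln = x)
}

#' @describeIn Msa-class number of alignment columns.
#' @param x an `Msa`.
#' @export
setMethod("ncol", "Msa", function(x) {
  if (length(x@aln) == 0L) 0L else Biostrings::width(x@aln)[1L]
})

#' @describeIn Msa-class number of aligned sequences.
#' @export
setMethod("nrow", "Msa", function(x) length(x@aln))

#' @describeIn Msa-class sequence ids.
#' @export
setMethod("names", "Msa", function(x) names(x@aln))

#' @describeIn Msa-class rows as a character matrix (one residue per cell).
#' @param ... unused.
#' @export
setMethod("as.matrix", "Msa", function(x, ...) {
  if (length(x@aln) == 0L) {
    return(matrix(character(), nrow = 0L, ncol = 0L))
  }
  m <- do.call(rbind, strsplit(as.character(x@aln), "", fixed = TRUE))
  rownames(m) <- names(x@aln)
  m
})

#' @describeIn Msa-class aligned rows as a named character vector.
#' @export
setMethod("as.character", "Msa", function(x) {
  setNames(as.character(x@aln), names(x@aln))
})

setMethod("show", "Msa", function(object) {
  cat(sprintf("Msa with %d sequences x %d columns\n",
              nrow(object), ncol(object)))
})

#' ReconciliationResult: a reconciled gene tree
#'
#' Result of mapping a rooted gene tree onto a rooted species tree by lowest
#' common ancestor (LCA) reconciliation: every gene-tree node is mapped to
#' the species-tree node spanning its descendant species; an internal gene
#' node is a duplication iff it shares its image with one of its children;
#' losses are the minimal set consistent with that mapping, each placed on a
#' species-tree edge.
#'
#' @slot geneTree rooted `ape::phylo` gene tree.
#' @slot speciesTree rooted `ape::phylo` species tree (internal nodes
#'   labelled).
#' @slot mapping integer vector over gene-tree nodes (tips then internals,
#'   ape numbering) giving the species-tree node each maps to.
#' @slot events character vector over gene-tree nodes: `"LEAF"`,
#'   `"SPECIATION"` or `"DUPLICATION"`.
#' @slot duplicationCount,lossCount integer event totals.
#' @slot losses data.frame with columns `gene_node` (gene-tree child node of
#'   the edge charged) and `species_edge` (label of the species-tree child
#'   node identifying the edge the loss occurs on).
#' @slot leafMap named character vector: gene leaf label -> species label.
#' @seealso [reconcileTrees()], [ancestralCopies()], [rootByDL()]
#' @export
setClass("ReconciliationResult",
  representation(geneTree = "ANY", speciesTree = "ANY", mapping = "integer",
                 events = "character", duplicationCount = "integer",
                 lossCount = "integer", losses = "data.frame",
                 leafMap = "character"))

setMethod("show", "ReconciliationResult", function(object) {
  cat(sprintf(
    "ReconciliationResult: %d gene leaves on %d species; D = %d, L = %d\n",
    length(object@geneTree$tip.label), length(object@speciesTree$tip.label),
    object@duplicationCount, object@lossCount))
  if (nrow(object@losses)) {
    cat("losses on species edges:",
        paste(object@losses$species_edge, collapse = ", "), "\n")
  }
})

#' SimulationConfig: parameters of the synthetic proteome generator
#'
#' Bundles everything the birth-death gene family simulator needs: the
#' species tree along which families evolve, per-branch duplication and loss
#' rates, the per-site substitution rate, the family template proteins with
#' their planted motif instances, and decoy settings.
#'
#' @slot speciesTree rooted `ape::phylo` with branch lengths.
#' @slot dupRate,lossRate events per gene copy per unit branch length.
#' @slot substRate substitutions per site per unit branch length.
#' @slot templates named list of family templates as returned by
#'   [familyTemplates()].
#' @slot decoysPerSpecies number of random decoy proteins per species.
#' @slot nearMissFraction fraction of decoys built as near-miss template
#'   copies (one planted motif position mutated outside its allowed set).
#' @slot terminalDupOnly if `TRUE`, duplications occur on terminal (species
#'   leaf) branches only; used for duplication-count recovery experiments.
#' @slot seed master integer seed; all substreams derive from it.
#' @seealso [simulationConfig()], [emitProteomes()]
#' @export
setClass("SimulationConfig",
  representation(speciesTree = "ANY", dupRate = "numeric",
                 lossRate = "numeric", substRate = "numeric",
                 templates = "list", decoysPerSpecies = "integer",
                 nearMissFraction = "numeric", terminalDupOnly = "logical",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@dupRate < 0 || object@lossRate < 0 || object@substRate < 0) {
    msgs <- c(msgs, "rates must be nonnegative")
  }
  if (object@nearMissFraction < 0 || object@nearMissFraction > 1) {
    msgs <- c(msgs, "nearMissFraction must be in [0,1]")
  }
  if (object@decoysPerSpecies < 0L) {
    msgs <- c(msgs, "decoysPerSpecies must be nonnegative")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: %d species, families [%s]\n",
    "  dup %.3g, loss %.3g, subst %.3g per unit branch length; ",
    "%d decoys/species; seed %d\n"),
    length(object@speciesTree$tip.label),
    paste(names(object@templates), collapse = ", "),
    object@dupRate, object@lossRate, object@substRate,
    object@decoysPerSpecies, object@seed))
})
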