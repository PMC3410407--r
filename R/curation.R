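#' Curation parameters
#'
#' Defaults follow the screening protocol: candidates shorter than 70% of
#' the reference motif span are discarded; pairwise scores below 20 are
#' pruned; score-100 pairs (identical sequences) are de-duplicated.
#'
#' @param lengthFraction minimum candidate length as a fraction of the mean
#'   reference outermost-motif span (candidates strictly below are
#'   discarded; equality is kept).
#' @param minPairScore similarity edges strictly below this percent identity
#'   are deleted before fragmentation.
#' @param identicalScore pairs at exactly this score are treated as
#'   duplicate sequences; the lexicographically larger id is dropped.
#' @return a named list of parameters.
#' @export
curationParams <- function(lengthFraction = 0.70, minPairScore = 20,
                           identicalScore = 100) {
  stopifnot(lengthFraction > 0, lengthFraction <= 1,
            minPairScore >= 0, minPairScore < identicalScore,
            identicalScore <= 100)
  list(lengthFraction = lengthFraction, minPairScore = minPairScore,
       identicalScore = identicalScore)
}

#' Mean outermost-motif span of reference proteins
#'
#' For each reference protein, the span is the distance from the start of
#' its first motif hit to the end of its last motif hit, using the motifs of
#' one family class; the returned value is the arithmetic mean over
#' references with at least two hits. References with fewer than two hits
#' are excluded with a warning.
#'
#' @param references `AAStringSet` (or named character vector) of reference
#'   proteins (the known family members candidates are compared against).
#' @param motifs motif library, default [motifLibrary()].
#' @param familyClass restrict to motifs of this class (`"HAK"`, `"HKT"`,
#'   `"CHANNEL"`); `NULL` uses all ten motifs.
#' @return mean span in residues.
#' @export
referenceSpan <- function(references, motifs = motifLibrary(),
                          familyClass = NULL) {
  if (is.character(references)) references <- Biostrings::AAStringSet(references)
  if (!is.null(familyClass)) {
    motifs <- Filter(function(m) m@familyClass == familyClass, motifs)
  }
  spans <- rep(NA_real_, length(references))
  for (i in seq_along(references)) {
    codes <- aaCodes(as.character(references[[i]]))
    st <- integer(); en <- integer()
    for (m in motifs) {
      s <- motifStarts(codes, m)
      if (length(s)) {
        st <- c(st, s)
        en <- c(en, s + length(m@positions))
      }
    }
    if (length(st) >= 2L) spans[[i]] <- max(en) - min(st)
  }
  if (all(is.na(spans))) {
    stop("no reference protein has >= 2 motif hits; span threshold undefined")
  }
  if (anyNA(spans)) {
    warning(sprintf("%d reference protein(s) with < 2 motif hits excluded",
                    sum(is.na(spans))))
  }
  mean(spans, na.rm = TRUE)
}

#' Length-filter candidates against a reference span
#'
#' A candidate is kept iff its length is at least `lengthFraction * span`
#' (the boundary is kept: only candidates strictly below the threshold are
#' discarded).
#'
#' @param candidates `AAStringSet` or named character vector.
#' @param span reference span in residues (see [referenceSpan()]).
#' @param params see [curationParams()].
#' @return list with `kept` and `discarded` id vectors (a partition of the
#'   candidate ids).
#' @export
lengthFilter <- function(candidates, span, params = curationParams()) {
  stopifnot(span > 0)
  if (is.character(candidates)) candidates <- Biostrings::AAStringSet(candidates)
  len <- setNames(Biostrings::width(candidates), names(candidates))
  keep <- len >= params$lengthFraction * span
  list(kept = names(len)[keep], discarded = names(len)[!keep])
}

#' All-vs-all pairwise similarity scores
#'
#' The score of a pair is the percent identity of its optimal global
#' alignment under BLOSUM62 with affine gaps (opening 10, extension 0.5),
#' with the identity count divided by the length of the shorter sequence,
#' rounded to two decimals. This reconstructs the quick pairwise score of
#' classic alignment tools in a reproducible way.
#'
#' @param proteins `AAStringSet` or named character vector (>= 2 sequences).
#' @return data.frame of `n(n-1)/2` rows: `id_a`, `id_b`
#'   (lexicographically ordered within each pair), `score`.
#' @export
pairwiseScores <- function(proteins) {
  if (is.character(proteins)) proteins <- Biostrings::AAStringSet(proteins)
  ids <- names(proteins)
  stopifnot(length(ids) >= 2L, !is.null(ids))
  pairs <- utils::combn(sort(ids), 2L)
  data.frame(id_a = pairs[1L, ], id_b = pairs[2L, ],
             score = crossScores(proteins[pairs[1L, ]], proteins[pairs[2L, ]]))
}

## Vectorised pairwise percent-identity (PID over shorter sequence) between
## parallel string sets.
crossScores <- function(a, b) {
  sc <- alignmentScoring()
  aln <- Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = sc$matrix, gapOpening = sc$gapOpening,
    gapExtension = sc$gapExtension, type = "global")
  round(Biostrings::pid(aln, type = "PID3"), 2L)
}

#' Prune the similarity graph and fragment into groups
#'
#' Pairs at exactly `identicalScore` are duplicate sequences: the
#' lexicographically larger id of each such pair is removed from the
#' analysis entirely and recorded. Edges strictly below `minPairScore` are
#' then deleted, and the connected components of the remaining graph are the
#' candidate groups; ids with no surviving edge form singleton groups.
#'
#' @param edges data.frame from [pairwiseScores()].
#' @param ids all candidate ids the edges were computed over.
#' @param params see [curationParams()].
#' @return list with `components` (list of id vectors, each sorted;
#'   deterministic order), `removedIdentical` (dropped duplicate ids).
#' @export
pruneAndFragment <- function(edges, ids, params = curationParams()) {
  dup <- character()
  ident <- edges[edges$score == params$identicalScore, , drop = FALSE]
  if (nrow(ident)) {
    dup <- sort(unique(pmax(ident$id_a, ident$id_b)))
  }
  keepIds <- setdiff(ids, dup)
  e <- edges[edges$score >= params$minPairScore &
               edges$score != params$identicalScore &
               edges$id_a %in% keepIds & edges$id_b %in% keepIds, ,
             drop = FALSE]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(keepIds), name = sort(keepIds))
  if (nrow(e)) g <- igraph::add_edges(g, rbind(e$id_a, e$id_b))
  comp <- igraph::components(g)
  comps <- split(names(comp$membership), comp$membership)
  comps <- lapply(comps, sort)
  comps <- comps[order(vapply(comps, `[`, character(1), 1L))]
  names(comps) <- NULL
  list(components = comps, removedIdentical = dup)
}

#' Select the component most similar to the reference proteins
#'
#' Each component is scored by the mean pairwise similarity over all
#' (member, reference) pairs; the arg-max component is selected. Ties are
#' broken by larger component size, then by lexicographically smallest
#' member id.
#'
#' @param components list of id vectors (see [pruneAndFragment()]).
#' @param candidates `AAStringSet` holding the member sequences.
#' @param references `AAStringSet` of reference proteins.
#' @return list with `selected` (id vector, empty if no components),
#'   `referenceSimilarity` (per-component mean score).
#' @export
selectGroup <- function(components, candidates, references) {
  if (is.character(candidates)) candidates <- Biostrings::AAStringSet(candidates)
  if (is.character(references)) references <- Biostrings::AAStringSet(references)
  if (!length(components)) {
    warning("no components to select from")
    return(list(selected = character(), referenceSimilarity = numeric()))
  }
  sim <- vapply(components, function(members) {
    grid <- expand.grid(m = members, r = names(references),
                        stringsAsFactors = FALSE)
    mean(crossScores(candidates[grid$m], references[grid$r]))
  }, numeric(1))
  size <- lengths(components)
  firstId <- vapply(components, `[`, character(1), 1L)
  best <- order(-sim, -size, firstId)[[1L]]
  list(selected = components[[best]], referenceSimilarity = sim)
}

#' Run the full semi-automatic curation of one family
#'
#' Chains the curation steps the screening protocol applies to raw motif
#' candidates: length filter against the reference motif span, all-vs-all
#' pairwise scoring, de-duplication and edge pruning, fragmentation into
#' similarity components, and selection of the component most similar to
#' the references. The returned report keeps every intermediate decision so
#' the "semi-automatic" human step becomes an inspectable object.
#'
#' @param candidates `AAStringSet` of candidate proteins.
#' @param references `AAStringSet` of reference family members.
#' @param motifs motif library.
#' @param familyClass motif class used for the reference span.
#' @param params see [curationParams()].
#' @return list (curation report): `span`, `discardedShort`,
#'   `removedIdentical`, `components`, `selected`, `referenceSimilarity`.
#'   `selected` includes no duplicate ids; duplicates of selected members
#'   remain listed in `removedIdentical`.
#' @export
curateFamily <- function(candidates, references, motifs = motifLibrary(),
                         familyClass = NULL, params = curationParams()) {
  if (is.character(candidates)) candidates <- Biostrings::AAStringSet(candidates)
  if (is.character(references)) references <- Biostrings::AAStringSet(references)
  span <- referenceSpan(references, motifs, familyClass)
  lf <- lengthFilter(candidates, span, params)
  kept <- candidates[lf$kept]
  if (length(kept) == 0L) {
    return(list(span = span, discardedShort = lf$discarded,
                removedIdentical = character(), components = list(),
                selected = character(), referenceSimilarity = numeric()))
  }
  if (length(kept) == 1L) {
    comps <- list(names(kept))
    dup <- character()
  } else {
    edges <- pairwiseScores(kept)
    frag <- pruneAndFragment(edges, names(kept), params)
    comps <- frag$components
    dup <- frag$removedIdentical
  }
  sel <- selectGroup(comps, kept, references)
  list(span = span, discardedShort = lf$discarded, removedIdentical = dup,
       components = comps, selected = sel$selected,
       referenceSimilarity = sel$referenceSimilarity)
}
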