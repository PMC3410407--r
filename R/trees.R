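## Run code with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## UPGMA agglomeration with deterministic tie-breaking. Returns the merge
## schedule (consumed by the progressive aligner) and the rooted ultrametric
## tree. Cluster ids are the lexicographically smallest member label; among
## equally close pairs the lexicographically smallest (idA,idB) pair merges
## first.
upgmaMerges <- function(D) {
  ids <- rownames(D)
  stopifnot(!is.null(ids), nrow(D) >= 2L, isSymmetric(unname(D)))
  if (any(D < 0)) stop("distance matrix has negative entries")
  clId <- ids
  size <- setNames(rep(1L, length(ids)), ids)
  height <- setNames(rep(0, length(ids)), ids)
  sub <- setNames(ids, ids)
  D <- D[ids, ids, drop = FALSE]
  merges <- list()
  while (length(clId) > 1L) {
    best <- NULL
    for (i in seq_len(length(clId) - 1L)) {
      for (j in (i + 1L):length(clId)) {
        a <- clId[[i]]; b <- clId[[j]]
        p <- sort(c(a, b))
        cand <- list(d = D[a, b], p1 = p[[1L]], p2 = p[[2L]], i = i, j = j)
        if (is.null(best) || cand$d < best$d ||
            (cand$d == best$d && (cand$p1 < best$p1 ||
              (cand$p1 == best$p1 && cand$p2 < best$p2)))) {
          best <- cand
        }
      }
    }
    a <- clId[[best$i]]; b <- clId[[best$j]]
    h <- best$d / 2
    newId <- min(a, b)
    merges[[length(merges) + 1L]] <- list(a = a, b = b, id = newId, height = h)
    if (b < a) { tmp <- a; a <- b; b <- tmp }   # render smaller id first
    newSub <- sprintf("(%s:%.12g,%s:%.12g)", sub[[a]],
                      max(0, h - height[[a]]), sub[[b]],
                      max(0, h - height[[b]]))
    ## average linkage update
    others <- setdiff(clId, c(a, b))
    newD <- matrix(0, length(others) + 1L, length(others) + 1L,
                   dimnames = list(c(others, newId), c(others, newId)))
    if (length(others)) {
      newD[others, others] <- D[others, others]
      dn <- (size[[a]] * D[a, others] + size[[b]] * D[b, others]) /
        (size[[a]] + size[[b]])
      newD[newId, others] <- dn
      newD[others, newId] <- dn
    }
    size[[newId]] <- size[[a]] + size[[b]]
    height[[newId]] <- h
    sub[[newId]] <- newSub
    clId <- c(others, newId)
    D <- newD
  }
  tree <- ape::read.tree(text = paste0(sub[[clId]], ";"))
  list(merges = merges, tree = tree)
}

#' UPGMA tree from a distance matrix
#'
#' Standard average-linkage agglomeration producing a rooted ultrametric
#' tree; merge heights are nondecreasing and ties are broken by the
#' lexicographically smallest pair of cluster ids, so the result is fully
#' deterministic.
#'
#' @param D symmetric nonnegative distance matrix with dimnames.
#' @return a rooted `ape::phylo`.
#' @examples
#' D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' ape::write.tree(upgmaTree(D))  # ((A:1,B:1):2,C:3);
#' @export
upgmaTree <- function(D) upgmaMerges(D)$tree

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via `ape::nj`); negative branch lengths are
#' clamped to zero with a warning. Used as the desk-scale tree builder of
#' the pipeline; externally inferred trees can be supplied as newick via
#' [readNewickFile()] instead.
#'
#' @param D symmetric distance matrix with dimnames (>= 3 taxa).
#' @return an unrooted `ape::phylo`.
#' @export
njTree <- function(D) {
  stopifnot(nrow(D) >= 3L)
  tr <- ape::nj(stats::as.dist(D))
  if (any(tr$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Bootstrap support for a distance tree
#'
#' Resamples alignment columns with replacement (seeded), rebuilds the tree
#' per replicate with the same distance function and builder, and reports
#' for each internal bipartition of the reference tree the percentage of
#' replicates containing it.
#'
#' @param msa an [Msa-class].
#' @param replicates number of bootstrap replicates (default 1000).
#' @param seed integer seed; identical seeds give bit-identical supports.
#' @param builder `"nj"` or `"upgma"`.
#' @param distanceFn function mapping an `Msa` to a distance matrix
#'   (default [identityDistance()]).
#' @return the reference tree with `node.label` set to support percentages.
#' @export
bootstrapSupport <- function(msa, replicates = 1000L, seed = 1L,
                             builder = c("nj", "upgma"),
                             distanceFn = identityDistance) {
  builder <- match.arg(builder)
  stopifnot(replicates >= 1L)
  build <- function(m) {
    if (builder == "nj") njTree(distanceFn(m)) else upgmaTree(distanceFn(m))
  }
  ref <- build(msa)
  m <- as.matrix(msa)
  reps <- withSeed(seed, lapply(seq_len(replicates), function(b) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rows <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    suppressWarnings(build(Msa(rows)))
  }))
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- round(100 * counts / replicates, 1L)
  ref
}

#' Read / write newick trees
#'
#' Thin wrappers over `ape` newick I/O with the error contract the pipeline
#' relies on: unbalanced parentheses and duplicate leaf labels are rejected
#' with an informative message. Branch lengths round-trip to at least six
#' decimals and internal labels carry bootstrap supports.
#'
#' @param path file path (for `readNewickFile`, a file containing one tree).
#' @return `readNewickFile`: an `ape::phylo`.
#' @export
readNewickFile <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  parseNewick(txt)
}

#' @rdname readNewickFile
#' @param text a newick string.
#' @export
parseNewick <- function(text) {
  assertString(text, "text")
  cc <- chars(text)
  op <- sum(cc == "(")
  cl <- sum(cc == ")")
  if (op != cl) {
    stop(sprintf("newick parse error: %d '(' vs %d ')'", op, cl))
  }
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("newick parse error: unreadable tree")
  if (anyDuplicated(tr$tip.label)) {
    stop(sprintf("duplicate leaf label(s): %s",
                 paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                       collapse = ", ")))
  }
  tr
}

#' @rdname readNewickFile
#' @param tree an `ape::phylo`.
#' @export
writeNewickFile <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Canonical topology string of a rooted tree
#'
#' Label-sorted newick-like rendering of the topology (no branch lengths),
#' used for deterministic tie-breaking among equally parsimonious rootings.
#'
#' @param tree rooted `ape::phylo`.
#' @return a character string.
#' @export
canonicalNewick <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  rec <- function(node) {
    if (node <= n) return(tree$tip.label[[node]])
    parts <- sort(vapply(kids[[as.character(node)]], rec, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(n + 1L), ";")
}
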