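## Small structural index of a rooted phylo: parent vector, children list,
## depth (root = 0), and a node-label lookup table.
treeIndex <- function(phy) {
  n <- length(phy$tip.label)
  N <- n + phy$Nnode
  parent <- integer(N)
  kids <- vector("list", N)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; c <- phy$edge[e, 2L]
    parent[[c]] <- p
    kids[[p]] <- c(kids[[p]], c)
  }
  root <- n + 1L
  depth <- integer(N)
  todo <- root
  while (length(todo)) {
    nd <- todo[[1L]]; todo <- todo[-1L]
    for (k in kids[[nd]]) {
      depth[[k]] <- depth[[nd]] + 1L
      todo <- c(todo, k)
    }
  }
  labels <- c(phy$tip.label,
              if (!is.null(phy$node.label)) phy$node.label else
                rep("", phy$Nnode))
  list(n = n, N = N, root = root, parent = parent, kids = kids,
       depth = depth, labels = labels)
}

## Postorder sequence of node indices for a rooted phylo.
postorderNodes <- function(idx) {
  out <- integer(0)
  rec <- function(nd) {
    for (k in idx$kids[[nd]]) rec(k)
    out[[length(out) + 1L]] <<- nd
  }
  rec(idx$root)
  out
}

## LCA of two nodes by depth-aligned parent walking.
lcaNodes <- function(idx, a, b) {
  while (idx$depth[[a]] > idx$depth[[b]]) a <- idx$parent[[a]]
  while (idx$depth[[b]] > idx$depth[[a]]) b <- idx$parent[[b]]
  while (a != b) {
    a <- idx$parent[[a]]
    b <- idx$parent[[b]]
  }
  a
}

## TRUE iff `anc` is an ancestor-or-equal of `des`.
isAncestorOrEqual <- function(idx, anc, des) {
  while (idx$depth[[des]] > idx$depth[[anc]]) des <- idx$parent[[des]]
  des == anc
}

## Resolve a species-tree node given as label (tip or internal) or index.
resolveSpeciesNode <- function(sIdx, node) {
  if (is.numeric(node)) {
    node <- as.integer(node)
    if (node < 1L || node > sIdx$N) stop("species node index out of range")
    return(node)
  }
  hit <- which(sIdx$labels == node)
  if (length(hit) != 1L) {
    stop(sprintf("species node '%s' not found in species tree", node))
  }
  hit
}

#' Derive a gene-leaf to species map from labels
#'
#' Gene leaves named with the `Species|gene` convention map to the species
#' before the separator.
#'
#' @param labels gene leaf labels.
#' @param sep separator (default `"|"`).
#' @return named character vector: label -> species.
#' @export
leafMapFromLabels <- function(labels, sep = "|") {
  setNames(vapply(strsplit(labels, sep, fixed = TRUE), `[`, character(1), 1L),
           labels)
}

#' LCA mapping of a rooted gene tree onto a rooted species tree
#'
#' Each gene leaf maps to its species leaf; each internal gene node maps to
#' the species-tree lowest common ancestor of its children's images
#' (computed in one postorder pass).
#'
#' @param geneTree rooted `ape::phylo`.
#' @param speciesTree rooted `ape::phylo` with unique tip labels.
#' @param leafMap named character vector mapping every gene tip label to a
#'   species tip label (default: derived from `Species|gene` tip names).
#' @return integer vector over gene-tree nodes (ape numbering: tips
#'   `1..n`, then internals) of species-tree node indices.
#' @export
lcaMap <- function(geneTree, speciesTree,
                   leafMap = leafMapFromLabels(geneTree$tip.label)) {
  gIdx <- treeIndex(geneTree)
  sIdx <- treeIndex(speciesTree)
  M <- integer(gIdx$N)
  for (i in seq_len(gIdx$n)) {
    lab <- geneTree$tip.label[[i]]
    sp <- leafMap[[lab]]
    if (is.null(sp) || is.na(sp)) {
      stop(sprintf("gene leaf '%s' has no species mapping", lab))
    }
    hit <- which(speciesTree$tip.label == sp)
    if (length(hit) != 1L) {
      stop(sprintf("gene leaf '%s' maps to unknown species '%s'", lab, sp))
    }
    M[[i]] <- hit
  }
  for (nd in postorderNodes(gIdx)) {
    if (nd <= gIdx$n) next
    imgs <- M[gIdx$kids[[nd]]]
    acc <- imgs[[1L]]
    for (k in imgs[-1L]) acc <- lcaNodes(sIdx, acc, k)
    M[[nd]] <- acc
  }
  M
}

#' Annotate duplication/speciation events
#'
#' An internal gene node is a DUPLICATION iff it maps to the same species
#' node as at least one of its children; otherwise it is a SPECIATION.
#' Leaves are labelled LEAF.
#'
#' @param M mapping from [lcaMap()].
#' @param geneTree rooted `ape::phylo`.
#' @return character vector of events over gene-tree nodes.
#' @export
annotateEvents <- function(M, geneTree) {
  gIdx <- treeIndex(geneTree)
  events <- rep("LEAF", gIdx$N)
  for (nd in (gIdx$n + 1L):gIdx$N) {
    events[[nd]] <- if (any(M[gIdx$kids[[nd]]] == M[[nd]])) "DUPLICATION"
                    else "SPECIATION"
  }
  events
}

#' Count and place gene losses
#'
#' For each gene edge (u,v) the species path from M(u) down to M(v) implies
#' losses in the bypassed sibling lineages: k-1 losses when u is a
#' speciation and k when u is a duplication, where k is the number of
#' species edges on the path. Each loss is placed on the species edge it
#' occurs on (identified by the species child node the lost lineage would
#' have entered). When a species root constraint is supplied, losses implied
#' on the path from that node down to the image of the gene root are charged
#' as well (off by default).
#'
#' @param M mapping from [lcaMap()].
#' @param events events from [annotateEvents()].
#' @param geneTree,speciesTree rooted `ape::phylo` trees.
#' @param rootConstraint optional species node (label or index) pinning the
#'   family's origin.
#' @return list with `lossCount` and `losses` (data.frame `gene_node`,
#'   `species_edge`).
#' @export
countLosses <- function(M, events, geneTree, speciesTree,
                        rootConstraint = NULL) {
  gIdx <- treeIndex(geneTree)
  sIdx <- treeIndex(speciesTree)
  lossNode <- integer()
  lossEdge <- character()
  chargePath <- function(top, bottom, skipFirst, geneNode) {
    ## nodes on the species path top -> bottom, charging the off-path child
    ## edge at each charged node
    path <- bottom
    while (path[[1L]] != top) path <- c(sIdx$parent[[path[[1L]]]], path)
    k <- length(path) - 1L
    if (k < 1L) return(invisible())
    from <- if (skipFirst) 2L else 1L
    if (from > k) return(invisible())
    for (i in from:k) {
      nd <- path[[i]]
      off <- setdiff(sIdx$kids[[nd]], path[[i + 1L]])
      for (o in off) {
        lossNode[[length(lossNode) + 1L]] <<- geneNode
        lossEdge[[length(lossEdge) + 1L]] <<-
          if (nzchar(sIdx$labels[[o]])) sIdx$labels[[o]] else as.character(o)
      }
    }
  }
  for (e in seq_len(nrow(geneTree$edge))) {
    u <- geneTree$edge[e, 1L]; v <- geneTree$edge[e, 2L]
    if (M[[u]] == M[[v]]) next
    chargePath(M[[u]], M[[v]], skipFirst = events[[u]] == "SPECIATION", v)
  }
  if (!is.null(rootConstraint)) {
    s0 <- resolveSpeciesNode(sIdx, rootConstraint)
    rootImg <- M[[gIdx$root]]
    if (!isAncestorOrEqual(sIdx, s0, rootImg)) {
      stop("root constraint is not an ancestor of the gene root's image")
    }
    if (s0 != rootImg) chargePath(s0, rootImg, skipFirst = FALSE, gIdx$root)
  }
  list(lossCount = length(lossNode),
       losses = data.frame(gene_node = lossNode, species_edge = lossEdge))
}

#' Reconcile a rooted gene tree against a species tree
#'
#' Runs [lcaMap()], [annotateEvents()] and [countLosses()] and bundles the
#' result.
#'
#' @inheritParams countLosses
#' @inheritParams lcaMap
#' @return a [ReconciliationResult-class].
#' @examples
#' st <- parseNewick("(A:1,B:1);")
#' gt <- parseNewick("((A|g1:1,B|g1:1):1,(A|g2:1,B|g2:1):1);")
#' reconcileTrees(gt, st)  # one duplication at the AB ancestor, no losses
#' @export
reconcileTrees <- function(geneTree, speciesTree,
                           leafMap = leafMapFromLabels(geneTree$tip.label),
                           rootConstraint = NULL) {
  M <- lcaMap(geneTree, speciesTree, leafMap)
  events <- annotateEvents(M, geneTree)
  loss <- countLosses(M, events, geneTree, speciesTree, rootConstraint)
  new("ReconciliationResult", geneTree = geneTree, speciesTree = speciesTree,
      mapping = M, events = events,
      duplicationCount = sum(events == "DUPLICATION"),
      lossCount = as.integer(loss$lossCount), losses = loss$losses,
      leafMap = leafMap)
}

#' Duplication-loss score of a reconciliation
#'
#' @param recon a [ReconciliationResult-class].
#' @return duplications + losses.
#' @export
dlScore <- function(recon) recon@duplicationCount + recon@lossCount

#' Root a gene tree by duplication-loss parsimony
#'
#' Evaluates the duplication + loss score of every branch rooting of an
#' unrooted gene tree against the species tree and returns the reconciled
#' minimal-score rooting. Ties are broken by the rooting with the
#' lexicographically smallest canonical topology string; all tied rootings
#' are reported in the `tiedRootings` attribute.
#'
#' @param geneTree unrooted `ape::phylo` with >= 3 leaves (an already-rooted
#'   binary tree is accepted: its own rootings are enumerated).
#' @param speciesTree rooted `ape::phylo` species tree.
#' @inheritParams reconcileTrees
#' @return a [ReconciliationResult-class] for the best rooting, with
#'   attributes `score` and `tiedRootings`.
#' @export
rootByDL <- function(geneTree, speciesTree,
                     leafMap = leafMapFromLabels(geneTree$tip.label),
                     rootConstraint = NULL) {
  stopifnot(length(geneTree$tip.label) >= 3L)
  rootings <- enumerateRootings(geneTree)
  recons <- lapply(rootings, reconcileTrees, speciesTree = speciesTree,
                   leafMap = leafMap, rootConstraint = rootConstraint)
  scores <- vapply(recons, dlScore, numeric(1))
  best <- which(scores == min(scores))
  canon <- vapply(recons[best], function(r) canonicalNewick(r@geneTree),
                  character(1))
  ## identical canonical topologies (the two half-edges of the original
  ## root) collapse to one reported rooting
  pick <- best[order(canon)][[1L]]
  out <- recons[[pick]]
  attr(out, "score") <- scores[[pick]]
  attr(out, "tiedRootings") <- sort(unique(canon))
  out
}

## All rooted versions of a tree, one per branch of its unrooted topology.
enumerateRootings <- function(phy) {
  edges <- phy$edge
  len <- phy$edge.length
  if (is.null(len)) len <- rep(1, nrow(edges))
  n <- length(phy$tip.label)
  N <- n + phy$Nnode
  adj <- vector("list", N)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    adj[[a]] <- rbind(adj[[a]], c(b, len[[e]]))
    adj[[b]] <- rbind(adj[[b]], c(a, len[[e]]))
  }
  sub <- function(node, from) {
    nbr <- adj[[node]]
    ch <- nbr[nbr[, 1L] != from, , drop = FALSE]
    if (nrow(ch) == 0L) return(phy$tip.label[[node]])
    parts <- vapply(seq_len(nrow(ch)), function(k) {
      paste0(sub(ch[k, 1L], node), ":", format(ch[k, 2L], digits = 10))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  ## suppress the old root if it is a degree-2 node (rooted input): treat
  ## its two incident edges as one
  deg <- vapply(adj, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  root2 <- which(deg == 2L)
  lapply(seq_len(nrow(edges)), function(e) {
    a <- edges[e, 1L]; b <- edges[e, 2L]; l <- len[[e]]
    txt <- paste0("(", sub(a, b), ":", format(l / 2, digits = 10), ",",
                  sub(b, a), ":", format(l / 2, digits = 10), ");")
    tr <- ape::read.tree(text = txt)
    if (length(root2)) tr <- ape::collapse.singles(tr)
    tr
  })
}

#' Ancestral copy number at a species node
#'
#' Counts the gene copies present in an ancestral genome *after* the
#' duplications mapped to it ("copies exiting the node"): the gene edges
#' (u,v), including a virtual edge above the gene root, with M(u) a proper
#' ancestor of the node (or equal and u a duplication; the virtual root
#' parent counts as proper ancestor) and M(v) a proper descendant (or equal
#' and v a speciation or leaf). At a species leaf this equals the number of
#' that species' genes in the tree.
#'
#' @param recon a [ReconciliationResult-class].
#' @param speciesNode species-tree node label (tip or internal) or index.
#' @return integer copy number.
#' @export
ancestralCopies <- function(recon, speciesNode) {
  sIdx <- treeIndex(recon@speciesTree)
  s <- resolveSpeciesNode(sIdx, speciesNode)
  gIdx <- treeIndex(recon@geneTree)
  M <- recon@mapping
  events <- recon@events
  upOk <- function(u) {
    if (is.na(u)) return(TRUE)   # virtual root parent
    if (M[[u]] == s) return(events[[u]] == "DUPLICATION")
    isAncestorOrEqual(sIdx, M[[u]], s) && M[[u]] != s
  }
  downOk <- function(v) {
    if (M[[v]] == s) return(events[[v]] %in% c("SPECIATION", "LEAF"))
    isAncestorOrEqual(sIdx, s, M[[v]]) && M[[v]] != s
  }
  count <- 0L
  if (upOk(NA) && downOk(gIdx$root)) count <- count + 1L
  for (e in seq_len(nrow(recon@geneTree$edge))) {
    u <- recon@geneTree$edge[e, 1L]; v <- recon@geneTree$edge[e, 2L]
    if (upOk(u) && downOk(v)) count <- count + 1L
  }
  count
}

#' The packaged five-species land-plant tree
#'
#' Rooted topology `(Ppatens,(Smoellendorffii,(Osativa,(Athaliana,
#' Ptrichocarpa))))` with unit branch lengths and labelled internal nodes
#' (`Embryophyta`, `Tracheophyta`, `Angiospermae`, `Rosids`).
#'
#' @return an `ape::phylo`.
#' @export
speciesTreeFixture <- function() {
  readNewickFile(system.file("extdata", "species_tree.nwk",
                             package = "ktfam", mustWork = TRUE))
}
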