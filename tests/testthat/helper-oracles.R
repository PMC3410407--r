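## Independent oracles and generators used across the suite. These are kept
## deliberately separate in style and machinery from the package internals
## (plain loops, phangorn/ape utilities) so that agreement is meaningful.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomProtein <- function(n, withX = FALSE) {
  alpha <- if (withX) c(AA20, "X") else AA20
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}

## ---- translation oracle -------------------------------------------------

## Codon-by-codon translation using the standard code table, with a
## hand-rolled reverse complement.
oracleTranslate <- function(dna) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(dna) - nchar(dna) %% 3
  if (n < 3) return("")
  codons <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  aa <- ifelse(grepl("N", codons), "X", unname(code[codons]))
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

oracleRevComp <- function(dna) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", dna), "")[[1]]), collapse = "")
}

## ---- motif scan oracle --------------------------------------------------

## Check every window against every position set, one window at a time.
oracleScanStarts <- function(sequence, pattern) {
  ss <- strsplit(sequence, "")[[1]]
  P <- length(pattern@positions)
  if (length(ss) < P) return(integer())
  hits <- integer()
  for (w in seq_len(length(ss) - P + 1)) {
    ok <- TRUE
    for (j in seq_len(P)) {
      set <- pattern@positions[[j]]
      if (!is.null(set) && !(ss[w + j - 1] %in% set)) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, w - 1L)
  }
  hits
}

## ---- pairwise alignment oracle ------------------------------------------

## Exhaustive enumeration of global alignments under BLOSUM62 with affine
## gaps (gap of length k costs open + k * ext). Returns the optimal score
## and the identity counts achieved by optimal alignments.
oracleEnumAlign <- function(a, b, open = 10, ext = 0.5) {
  S <- ktfam:::blosum62Matrix()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- -Inf
  ids <- integer()
  rec <- function(i, j, prev, sc, nid) {
    if (i > na && j > nb) {
      if (sc > best + 1e-9) {
        best <<- sc; ids <<- nid
      } else if (abs(sc - best) <= 1e-9) {
        ids <<- union(ids, nid)
      }
      return(invisible())
    }
    if (i <= na && j <= nb) {
      rec(i + 1, j + 1, "d", sc + S[av[i], bv[j]], nid + (av[i] == bv[j]))
    }
    if (i <= na) {
      rec(i + 1, j, "u", sc - (if (identical(prev, "u")) ext else open + ext),
          nid)
    }
    if (j <= nb) {
      rec(i, j + 1, "l", sc - (if (identical(prev, "l")) ext else open + ext),
          nid)
    }
  }
  rec(1, 1, "none", 0, 0L)
  list(score = best, identities = ids)
}

## ---- block filter oracle ------------------------------------------------

## Step-by-step re-implementation with explicit index scans; operates on a
## character matrix, returns retained 0-based column indices.
oracleBlockFilter <- function(mat, maxRun = 20, minBlock = 2,
                              minCons = NULL, minFlank = NULL) {
  n <- nrow(mat); nc <- ncol(mat)
  if (is.null(minCons)) minCons <- ceiling(n / 2)
  if (is.null(minFlank)) minFlank <- ceiling(n / 2)
  maj <- integer(nc)
  for (c in seq_len(nc)) maj[c] <- max(table(mat[, c]))
  conserved <- maj >= minCons
  keep <- rep(TRUE, nc)
  c <- 1
  while (c <= nc) {
    if (!conserved[c]) {
      e <- c
      while (e < nc && !conserved[e + 1]) e <- e + 1
      if (e - c + 1 > maxRun) keep[c:e] <- FALSE
      c <- e + 1
    } else {
      c <- c + 1
    }
  }
  retained <- integer()
  c <- 1
  while (c <= nc) {
    if (keep[c]) {
      e <- c
      while (e < nc && keep[e + 1]) e <- e + 1
      seg <- c:e
      while (length(seg) && maj[seg[1]] < minFlank) seg <- seg[-1]
      while (length(seg) && maj[seg[length(seg)]] < minFlank) {
        seg <- seg[-length(seg)]
      }
      if (length(seg) >= minBlock) retained <- c(retained, seg)
      c <- e + 1
    } else {
      c <- c + 1
    }
  }
  retained - 1L
}

randomToyAlignment <- function(nrow = 4, ncol = 60, alpha = c("A", "C", "D",
                               "E", "-")) {
  ## biased columns so both conserved and nonconserved stretches occur
  m <- matrix("", nrow, ncol)
  for (c in seq_len(ncol)) {
    if (runif(1) < 0.5) {
      m[, c] <- sample(alpha, 1)
      flip <- runif(nrow) < 0.2
      m[flip, c] <- sample(alpha, sum(flip), replace = TRUE)
    } else {
      m[, c] <- sample(alpha, nrow, replace = TRUE)
    }
  }
  rownames(m) <- paste0("s", seq_len(nrow))
  m
}

matToMsa <- function(m) {
  Msa(setNames(apply(m, 1, paste, collapse = ""), rownames(m)))
}

## ---- tree generators ----------------------------------------------------

## Random ultrametric tree via sequential random joins at increasing
## heights; returns the cophenetic (ultrametric) distance matrix and tree.
randomUltrametric <- function(n) {
  labs <- paste0("t", seq_len(n))
  height <- setNames(rep(0, n), labs)
  sub <- setNames(labs, labs)
  active <- labs
  h <- 0
  while (length(active) > 1) {
    h <- h + runif(1, 0.5, 2)
    pick <- sample(active, 2)
    a <- pick[1]; b <- pick[2]
    nid <- a
    sub[nid] <- sprintf("(%s:%.15g,%s:%.15g)", sub[a], h - height[a],
                        sub[b], h - height[b])
    height[nid] <- h
    active <- c(setdiff(active, c(a, b)), nid)
  }
  tree <- ape::read.tree(text = paste0(sub[active], ";"))
  D <- ape::cophenetic.phylo(tree)
  list(tree = tree, D = D[labs, labs])
}

## Random unrooted binary tree with positive branch lengths; its path
## distances form an additive matrix.
randomAdditive <- function(n) {
  tree <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.5, 2))
  D <- ape::cophenetic.phylo(tree)
  list(tree = tree, D = D)
}

## ---- reconciliation oracles ---------------------------------------------

## Ancestors-or-self of a node, via phangorn.
ancSelf <- function(phy, nd) c(nd, phangorn::Ancestors(phy, nd, "all"))

## Brute-force LCA by ancestor-path intersection.
oracleLca <- function(phy, a, b) {
  common <- intersect(ancSelf(phy, a), ancSelf(phy, b))
  depths <- sapply(common, function(x) length(ancSelf(phy, x)))
  common[which.max(depths)]
}

## Minimal duplication + loss cost over ALL consistent mappings of the gene
## tree into the species tree (events and losses derived from each mapping).
oracleDLmin <- function(geneTree, speciesTree, leafMap) {
  nG <- length(geneTree$tip.label)
  NG <- nG + geneTree$Nnode
  kids <- vector("list", NG)
  for (e in seq_len(nrow(geneTree$edge))) {
    p <- geneTree$edge[e, 1]
    kids[[p]] <- c(kids[[p]], geneTree$edge[e, 2])
  }
  sDepth <- sapply(seq_len(length(speciesTree$tip.label) +
                             speciesTree$Nnode),
                   function(x) length(ancSelf(speciesTree, x)))
  M <- integer(NG)
  for (i in seq_len(nG)) {
    M[i] <- match(leafMap[[geneTree$tip.label[i]]], speciesTree$tip.label)
  }
  internals <- rev(sort(setdiff(seq_len(NG), seq_len(nG))))
  ## postorder: children of a node have larger preorder indices in ape's
  ## cladewise numbering is not guaranteed, so order by tree depth instead
  gDepth <- sapply(seq_len(NG), function(x) {
    length(phangorn::Ancestors(geneTree, x, "all"))
  })
  internals <- internals[order(gDepth[internals], decreasing = TRUE)]
  bestCost <- Inf
  cost <- function(M) {
    dup <- logical(NG)
    for (v in internals) {
      imgs <- M[kids[[v]]]
      lca <- Reduce(function(a, b) oracleLca(speciesTree, a, b), imgs)
      ## a node mapped above its children's LCA cannot be a clean
      ## speciation: both child lineages pass through one side
      dup[v] <- any(imgs == M[v]) || M[v] != lca
    }
    total <- sum(dup)
    for (e in seq_len(nrow(geneTree$edge))) {
      u <- geneTree$edge[e, 1]; v <- geneTree$edge[e, 2]
      k <- sDepth[M[v]] - sDepth[M[u]]
      total <- total + max(0, k - 1 + dup[u])
    }
    total
  }
  rec <- function(idx) {
    if (idx > length(internals)) {
      bestCost <<- min(bestCost, cost(M))
      return(invisible())
    }
    v <- internals[idx]
    allowed <- Reduce(intersect, lapply(kids[[v]], function(c) {
      ancSelf(speciesTree, M[c])
    }))
    for (m in allowed) {
      M[v] <<- m
      rec(idx + 1)
    }
  }
  rec(1)
  bestCost
}

## All rooted binary tree shapes with n leaves, as nested lists of leaf
## slot indices.
treeShapes <- function(n) {
  if (n == 1) return(list(1))
  out <- list()
  for (k in seq_len(floor(n / 2))) {
    left <- treeShapes(k)
    right <- treeShapes(n - k)
    for (l in left) {
      for (r in right) {
        out[[length(out) + 1]] <- list(shiftLeaves(l, 0), shiftLeaves(r, k))
      }
    }
  }
  out
}

shiftLeaves <- function(x, by) {
  if (is.numeric(x)) return(x + by)
  lapply(x, shiftLeaves, by = by)
}

shapeToNewick <- function(shape, labels) {
  rec <- function(x) {
    if (is.numeric(x)) return(labels[x])
    paste0("(", paste(vapply(x, rec, ""), collapse = ","), ")")
  }
  paste0(rec(shape), ";")
}

## ---- misc ---------------------------------------------------------------

speciesTree3 <- function() {
  ape::read.tree(text = "((A:1,B:1)AB:1,C:2)ABC;")
}
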