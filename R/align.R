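#' Block filter parameters
#'
#' Defaults reproduce the stated conserved-block filtering of the screening
#' study: the minimum number of sequences for a conserved position and for a
#' flanking position is half the number of sequences (read as the ceiling,
#' so well defined for odd n), the maximum run of contiguous non-conserved
#' positions is 20, the minimum block length is 2, and positions with gaps
#' are not treated differently from other positions.
#'
#' @param minConserved minimum row count of the majority symbol for a
#'   CONSERVED column; `NULL` = `ceiling(n/2)` at filter time.
#' @param minFlank minimum majority count for block-flank columns; `NULL` =
#'   `ceiling(n/2)`.
#' @param maxNonconservedRun maximal kept run of NONCONSERVED columns.
#' @param minBlockLen minimal kept block length.
#' @param gapsAllowed if `TRUE` the gap is counted as an ordinary 21st
#'   symbol when finding the majority symbol.
#' @return named parameter list.
#' @export
blockFilterParams <- function(minConserved = NULL, minFlank = NULL,
                              maxNonconservedRun = 20L, minBlockLen = 2L,
                              gapsAllowed = TRUE) {
  stopifnot(minBlockLen >= 1L, maxNonconservedRun >= 0L)
  list(minConserved = minConserved, minFlank = minFlank,
       maxNonconservedRun = as.integer(maxNonconservedRun),
       minBlockLen = as.integer(minBlockLen), gapsAllowed = gapsAllowed)
}

## Majority-symbol count per column (gap as ordinary symbol when allowed).
columnMajorityCounts <- function(msa, gapsAllowed = TRUE) {
  m <- as.matrix(msa)
  apply(m, 2L, function(col) {
    if (!gapsAllowed) col <- col[col != "-"]
    if (!length(col)) return(0L)
    max(table(col))
  })
}

#' Label alignment columns CONSERVED / NONCONSERVED
#'
#' A column is CONSERVED iff its most frequent symbol (counting the gap as
#' an ordinary symbol when `gapsAllowed`) occurs in at least `minConserved`
#' rows.
#'
#' @param msa an [Msa-class].
#' @param params see [blockFilterParams()].
#' @return character vector over columns, `"CONSERVED"`/`"NONCONSERVED"`.
#' @export
columnStatus <- function(msa, params = blockFilterParams()) {
  n <- nrow(msa)
  minCons <- if (is.null(params$minConserved)) ceiling(n / 2) else
    params$minConserved
  counts <- columnMajorityCounts(msa, params$gapsAllowed)
  ifelse(counts >= minCons, "CONSERVED", "NONCONSERVED")
}

#' Filter an alignment down to its conserved blocks
#'
#' Reproduces the stated block-filtering procedure: (1) columns are labelled
#' by [columnStatus()]; (2) every maximal NONCONSERVED run longer than
#' `maxNonconservedRun` is deleted; (3) each remaining segment is trimmed so
#' that it begins and ends on a column whose majority count reaches
#' `minFlank`; (4) segments shorter than `minBlockLen` are deleted.
#'
#' @param msa an [Msa-class].
#' @param params see [blockFilterParams()].
#' @return list with `msa` (filtered [Msa-class]; may have zero columns,
#'   with a warning) and `retained` (0-based indices of retained columns,
#'   strictly increasing).
#' @export
blockFilter <- function(msa, params = blockFilterParams()) {
  nc <- ncol(msa)
  n <- nrow(msa)
  minFlank <- if (is.null(params$minFlank)) ceiling(n / 2) else params$minFlank
  status <- columnStatus(msa, params)
  counts <- columnMajorityCounts(msa, params$gapsAllowed)

  ## step 2: drop long nonconserved runs, keeping segment structure
  r <- rle(status == "NONCONSERVED")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dropRun <- r$values & r$lengths > params$maxNonconservedRun
  keep <- rep(TRUE, nc)
  for (k in which(dropRun)) keep[starts[[k]]:ends[[k]]] <- FALSE

  ## segments = maximal runs of still-kept columns
  segments <- list()
  kr <- rle(keep)
  kEnds <- cumsum(kr$lengths)
  kStarts <- kEnds - kr$lengths + 1L
  for (k in which(kr$values)) {
    seg <- kStarts[[k]]:kEnds[[k]]
    ## step 3: trim to flank-qualifying boundary columns
    good <- counts[seg] >= minFlank
    if (!any(good)) next
    seg <- seg[min(which(good)):max(which(good))]
    ## step 4: minimum block length
    if (length(seg) >= params$minBlockLen) {
      segments[[length(segments) + 1L]] <- seg
    }
  }
  retained <- unlist(segments)
  if (is.null(retained)) retained <- integer()
  if (!length(retained)) {
    warning("block filter removed all columns")
    return(list(msa = Msa(setNames(rep("", nrow(msa)), names(msa))),
                retained = integer()))
  }
  m <- as.matrix(msa)[, retained, drop = FALSE]
  rows <- apply(m, 1L, paste, collapse = "")
  list(msa = Msa(setNames(rows, names(msa))), retained = retained - 1L)
}

#' Pairwise identity distances from an alignment
#'
#' `identity(i,j)` is the fraction of matching residues over the columns
#' where both rows are non-gap; the distance is `1 - identity`. Pairs with
#' zero comparable columns get distance 1 with a warning.
#'
#' @param msa an [Msa-class] with >= 2 rows.
#' @return a symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
identityDistance <- function(msa) {
  m <- as.matrix(msa)
  n <- nrow(m)
  stopifnot(n >= 2L)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  warned <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(comp)) {
        if (!warned) {
          warning("pair(s) with no comparable columns assigned distance 1")
          warned <- TRUE
        }
        dij <- 1
      } else {
        dij <- 1 - sum(m[i, comp] == m[j, comp]) / sum(comp)
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Progressive multiple alignment
#'
#' A deliberately simple progressive aligner adequate for the synthetic
#' proteomes this package simulates (which evolve without indels): the guide
#' tree is UPGMA on pairwise-identity distances, and profiles are merged by
#' global alignment with average-of-pairs BLOSUM62 column scoring and a
#' linear gap penalty. For real data, pass a pre-aligned FASTA through
#' [Msa()] instead (external-aligner hook).
#'
#' @param proteins `AAStringSet` or named character vector (>= 2 sequences).
#' @param gapPenalty linear per-column gap penalty used in profile merging.
#' @return an [Msa-class]; with two sequences this reduces to their pairwise
#'   global alignment.
#' @export
progressiveMsa <- function(proteins, gapPenalty = 8) {
  if (is.character(proteins)) proteins <- Biostrings::AAStringSet(proteins)
  ids <- names(proteins)
  stopifnot(length(ids) >= 2L, !is.null(ids))
  ## pairwise identity distances for the guide tree
  pairs <- utils::combn(ids, 2L)
  pid <- crossScores(proteins[pairs[1L, ]], proteins[pairs[2L, ]])
  D <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_len(ncol(pairs))) {
    D[pairs[1L, k], pairs[2L, k]] <- D[pairs[2L, k], pairs[1L, k]] <-
      1 - pid[[k]] / 100
  }
  merges <- upgmaMerges(D)$merges
  ## profiles: named character matrices (rows = sequences)
  profiles <- lapply(ids, function(id) {
    matrix(chars(as.character(proteins[[id]])), nrow = 1L,
           dimnames = list(id, NULL))
  })
  names(profiles) <- ids
  for (m in merges) {
    merged <- alignProfiles(profiles[[m$a]], profiles[[m$b]], gapPenalty)
    profiles[[m$a]] <- NULL
    profiles[[m$b]] <- NULL
    profiles[[m$id]] <- merged
  }
  prof <- profiles[[1L]]
  rows <- apply(prof, 1L, paste, collapse = "")
  Msa(rows[ids])   # restore input order
}

## Profile-profile global alignment (linear gaps). Columns are scored by the
## average BLOSUM62 score over residue pairs; a gap in an existing profile
## row scores `-gapPenalty` against any symbol, 0 against another gap.
alignProfiles <- function(A, B, gapPenalty) {
  S <- blosum62Matrix()
  syms <- c(AA_ALLOWED, "-")
  S2 <- matrix(-gapPenalty, length(syms), length(syms),
               dimnames = list(syms, syms))
  S2[AA_ALLOWED, AA_ALLOWED] <- S[AA_ALLOWED, AA_ALLOWED]
  S2["-", "-"] <- 0
  freq <- function(P) {
    apply(P, 2L, function(col) tabulate(match(col, syms), length(syms)))
  }
  FA <- freq(A); FB <- freq(B)
  CS <- t(FA) %*% S2[seq_along(syms), seq_along(syms)] %*% FB /
    (nrow(A) * nrow(B))
  nA <- ncol(A); nB <- ncol(B)
  M <- matrix(0, nA + 1L, nB + 1L)
  M[1L, ] <- (0:nB) * -gapPenalty
  M[, 1L] <- (0:nA) * -gapPenalty
  TB <- matrix(0L, nA + 1L, nB + 1L)  # 1 diag, 2 up (gap in B), 3 left
  TB[1L, -1L] <- 3L
  TB[-1L, 1L] <- 2L
  ## fill by anti-diagonals (vectorised; cells on a diagonal are independent)
  for (d in 2:(nA + nB)) {
    i <- max(1L, d - nB):min(nA, d - 1L)
    j <- d - i
    diag <- M[cbind(i, j)] + CS[cbind(i, j)]
    up <- M[cbind(i, j + 1L)] - gapPenalty
    left <- M[cbind(i + 1L, j)] - gapPenalty
    best <- pmax(diag, up, left)
    M[cbind(i + 1L, j + 1L)] <- best
    TB[cbind(i + 1L, j + 1L)] <- ifelse(best == diag, 1L,
                                        ifelse(best == up, 2L, 3L))
  }
  ## traceback (filled back to front)
  i <- nA; j <- nB
  L <- nA + nB
  colsA <- integer(L); colsB <- integer(L)   # 0 = gap column
  pos <- L + 1L
  while (i > 0L || j > 0L) {
    mv <- TB[i + 1L, j + 1L]
    pos <- pos - 1L
    if (mv == 1L) {
      colsA[[pos]] <- i; colsB[[pos]] <- j; i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      colsA[[pos]] <- i; colsB[[pos]] <- 0L; i <- i - 1L
    } else {
      colsA[[pos]] <- 0L; colsB[[pos]] <- j; j <- j - 1L
    }
  }
  colsA <- colsA[pos:L]; colsB <- colsB[pos:L]
  take <- function(P, cols) {
    out <- matrix("-", nrow(P), length(cols), dimnames = list(rownames(P), NULL))
    out[, cols != 0L] <- P[, cols[cols != 0L], drop = FALSE]
    out
  }
  rbind(take(A, colsA), take(B, colsB))
}
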