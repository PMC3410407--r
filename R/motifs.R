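#' Compile a degenerate motif string
#'
#' Motifs are written in the dash-separated dialect used for plant K+
#' transporter screening: each position is the wildcard `x`, a single
#' residue letter, or a bracketed comma-separated allowed set, e.g.
#' `"[S,T]-x-x-T-x-G-[Y,F,L]-G-[D,E]"`. Input is case-insensitive; the
#' compiled pattern renders back in canonical uppercase.
#'
#' @param sourceText the motif string.
#' @param motifId optional integer id stored on the pattern.
#' @param familyClass optional class tag (`"CHANNEL"`, `"HKT"`, `"HAK"`).
#' @return a [MotifPattern-class].
#' @examples
#' p <- compileMotif("[S,T]-x-x-T-x-G-[Y,F,L]-G-[D,E]")
#' renderMotif(p)
#' @export
compileMotif <- function(sourceText, motifId = NA_integer_, familyClass = "") {
  assertString(sourceText, "sourceText")
  toks <- strsplit(sourceText, "-", fixed = TRUE)[[1]]
  if (length(toks) == 0L) stop("empty motif")
  positions <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    tok <- trimws(toks[[i]])
    if (tok == "x" || tok == "X") {
      positions[i] <- list(NULL)
    } else if (grepl("^\\[.*\\]$", tok)) {
      inner <- substr(tok, 2L, nchar(tok) - 1L)
      letters <- toupper(trimws(strsplit(inner, ",", fixed = TRUE)[[1]]))
      letters <- letters[nzchar(letters)]
      if (length(letters) == 0L) {
        stop(sprintf("motif compile error at position %d: empty bracket", i))
      }
      bad <- setdiff(letters, AA_STANDARD)
      if (length(bad)) {
        stop(sprintf(
          "motif compile error at position %d: '%s' is not a standard amino acid",
          i, bad[[1]]))
      }
      positions[[i]] <- sort(unique(letters))
    } else if (nchar(tok) == 1L && toupper(tok) %in% AA_STANDARD) {
      positions[[i]] <- toupper(tok)
    } else {
      stop(sprintf("motif compile error at position %d: unknown token '%s'",
                   i, tok))
    }
  }
  ## keep the printed residue order for faithful rendering
  for (i in seq_along(toks)) {
    tok <- trimws(toks[[i]])
    if (grepl("^\\[.*\\]$", tok)) {
      inner <- toupper(gsub("\\s", "", substr(tok, 2L, nchar(tok) - 1L)))
      positions[[i]] <- strsplit(inner, ",", fixed = TRUE)[[1]]
    }
  }
  new("MotifPattern", motifId = as.integer(motifId),
      familyClass = familyClass, positions = positions,
      sourceText = toupper(gsub("\\s", "", sourceText)))
}

#' Render a compiled motif back to its source dialect
#'
#' @param pattern a [MotifPattern-class].
#' @return the canonical motif string; for packaged motifs this reproduces
#'   the library file character for character.
#' @export
renderMotif <- function(pattern) {
  stopifnot(is(pattern, "MotifPattern"))
  toks <- vapply(pattern@positions, function(p) {
    if (is.null(p)) "x"
    else if (length(p) == 1L) p
    else paste0("[", paste(p, collapse = ","), "]")
  }, character(1))
  paste(toks, collapse = "-")
}

#' The packaged ten-motif screening library
#'
#' Loads the ten class-specific degenerate motifs used to screen plant
#' proteomes for K+ transporters: motifs 1-3 mark K+ channels (motif 1 is
#' the selectivity-filter region, motif 2 is voltage-sensor-like, motif 3
#' inner-helix-like), motifs 4-5 mark HKT transporters, and motifs 6-10 mark
#' HAK transporters. The library ships as a plain-text file in the motif
#' dialect plus a manifest with ids and classes.
#'
#' @return list of [MotifPattern-class] objects, one per motif id 1-10.
#' @export
motifLibrary <- function() {
  path <- system.file("extdata", "motifs.tsv", package = "ktfam",
                      mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    compileMotif(tab$motif[[i]], motifId = tab$motif_id[[i]],
                 familyClass = tab$family_class[[i]])
  })
}

## Integer-code a protein sequence over the allowed alphabet.
aaCodes <- function(sequence) match(chars(sequence), AA_ALLOWED)

#' Scan a protein for a degenerate motif
#'
#' Reports every window of the sequence that satisfies the pattern position
#' by position. Overlapping hits are allowed. The wildcard matches any
#' letter including `X`; restricted positions are never satisfied by `X`.
#'
#' @param sequence a protein string, `AAString`, or a single element of an
#'   `AAStringSet`.
#' @param pattern a [MotifPattern-class].
#' @param proteinId id recorded in the output (defaults to `""`).
#' @return data.frame of hits sorted by start: `protein_id`, `motif_id`,
#'   `start`, `end` (0-based half-open), `matched`.
#' @examples
#' lib <- motifLibrary()
#' scanMotif("TMTTVGYGD", lib[[1]])  # one hit at start 0
#' @export
scanMotif <- function(sequence, pattern, proteinId = "") {
  stopifnot(is(pattern, "MotifPattern"))
  if (!is.character(sequence)) sequence <- as.character(sequence)
  starts <- motifStarts(aaCodes(sequence), pattern)
  P <- length(pattern@positions)
  data.frame(protein_id = rep(proteinId, length(starts)),
             motif_id = rep(pattern@motifId, length(starts)),
             start = starts, end = starts + P,
             matched = if (length(starts)) {
               substring(sequence, starts + 1L, starts + P)
             } else character())
}

## Vectorised window matcher on integer-coded residues; returns 0-based
## start offsets. One logical sweep per motif position.
motifStarts <- function(codes, pattern) {
  P <- length(pattern@positions)
  n <- length(codes)
  if (n < P) return(integer())
  W <- n - P + 1L
  ok <- rep(TRUE, W)
  for (j in seq_len(P)) {
    set <- pattern@positions[[j]]
    if (is.null(set)) next                      # wildcard: anything incl. X
    allowed <- match(set, AA_ALLOWED)           # X never in a restricted set
    ok <- ok & (codes[j:(j + W - 1L)] %in% allowed)
    if (!any(ok)) return(integer())
  }
  which(ok) - 1L
}

#' Default family classification rules
#'
#' The original screening protocol does not state how many motifs of a class had
#' to co-occur; these defaults are a documented reconstruction chosen so
#' that genuine family members classify while single-motif coincidences in
#' random sequence do not: HAK requires at least `hakMin` (3) of the five
#' HAK motifs, HKT requires both HKT motifs, CHANNEL requires the
#' selectivity-filter motif 1. Precedence HAK > HKT > CHANNEL applies only
#' when classes conflict.
#'
#' @param hakMin minimum number of distinct HAK motifs (6-10) for a HAK call.
#' @return a rules list consumed by [classifyProteins()].
#' @export
defaultClassifyRules <- function(hakMin = 3L) {
  list(hakMin = as.integer(hakMin), hakMotifs = 6:10, hktMotifs = c(4L, 5L),
       channelMotif = 1L)
}

#' Classify proteins into K+ transporter families by motif content
#'
#' Scans each protein with the full motif library and applies the class
#' rules. For CHANNEL calls the pore count is the number of non-overlapping
#' selectivity-filter (motif 1) hits, selected leftmost-greedily; one pore
#' gives subtype `SINGLE_PORE` (Shaker-like candidates), two gives
#' `TANDEM_PORE` (TPK candidates), more gives `MULTI`. Evidence from all ten
#' motifs is returned regardless of the final label.
#'
#' @param proteins an `AAStringSet` (e.g. from [readFasta()]) or named
#'   character vector.
#' @param motifs motif library, default [motifLibrary()].
#' @param rules classification rules, default [defaultClassifyRules()].
#' @return list with `calls`: data.frame (`protein_id`, `family`,
#'   `channel_pore_count`, `channel_subtype`, `motif_ids_matched`) and
#'   `hits`: data.frame of every motif hit in every protein.
#' @export
classifyProteins <- function(proteins, motifs = motifLibrary(),
                             rules = defaultClassifyRules()) {
  if (is.character(proteins)) proteins <- Biostrings::AAStringSet(proteins)
  ids <- names(proteins)
  if (length(proteins) == 0L) {
    return(list(calls = data.frame(protein_id = character(),
                                   family = character(),
                                   channel_pore_count = integer(),
                                   channel_subtype = character(),
                                   motif_ids_matched = character()),
                hits = data.frame(protein_id = character(),
                                  motif_id = integer(), start = integer(),
                                  end = integer(), matched = character())))
  }
  if (is.null(ids)) stop("proteins must be named")
  seqs <- as.character(proteins)
  allHits <- list()
  calls <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    codes <- aaCodes(seqs[[i]])
    hits <- lapply(motifs, function(m) {
      st <- motifStarts(codes, m)
      if (!length(st)) return(NULL)
      P <- length(m@positions)
      data.frame(protein_id = ids[[i]], motif_id = m@motifId, start = st,
                 end = st + P,
                 matched = substring(seqs[[i]], st + 1L, st + P))
    })
    hits <- do.call(rbind, hits)
    matched <- if (is.null(hits)) integer() else sort(unique(hits$motif_id))
    isHak <- sum(rules$hakMotifs %in% matched) >= rules$hakMin
    isHkt <- all(rules$hktMotifs %in% matched)
    isChan <- rules$channelMotif %in% matched
    family <- if (isHak) "HAK" else if (isHkt) "HKT"
              else if (isChan) "CHANNEL" else "UNCLASSIFIED"
    poreCount <- 0L
    if (family == "CHANNEL") {
      m1 <- hits[hits$motif_id == rules$channelMotif, , drop = FALSE]
      m1 <- m1[order(m1$start), , drop = FALSE]
      lastEnd <- -1L
      for (k in seq_len(nrow(m1))) {         # leftmost-greedy non-overlap
        if (m1$start[[k]] >= lastEnd) {
          poreCount <- poreCount + 1L
          lastEnd <- m1$end[[k]]
        }
      }
    }
    subtype <- if (poreCount == 1L) "SINGLE_PORE"
               else if (poreCount == 2L) "TANDEM_PORE"
               else if (poreCount > 2L) "MULTI" else "NA"
    calls[[i]] <- data.frame(
      protein_id = ids[[i]], family = family,
      channel_pore_count = poreCount, channel_subtype = subtype,
      motif_ids_matched = paste(matched, collapse = ","))
    if (!is.null(hits)) allHits[[length(allHits) + 1L]] <- hits
  }
  hits <- if (length(allHits)) do.call(rbind, allHits) else
    data.frame(protein_id = character(), motif_id = integer(),
               start = integer(), end = integer(), matched = character())
  rownames(hits) <- NULL
  list(calls = do.call(rbind, calls), hits = hits)
}
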