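#' Read a proteome or genome FASTA file
#'
#' Reads a multi-record FASTA file into a `Biostrings` string set, tagging
#' every record with a species label (kept in `mcols(x)$species`). Record ids
#' are the first whitespace-delimited token of each header; the remainder of
#' the header is kept as `mcols(x)$description`. Sequences are uppercased on
#' ingest and validated against the protein alphabet (20 standard residues
#' plus `X`) or the DNA alphabet (`ACGTN`).
#'
#' @param path path to a FASTA file.
#' @param species species tag attached to every record.
#' @param type `"protein"` (returns an `AAStringSet`) or `"dna"` (returns a
#'   `DNAStringSet`).
#' @return an `AAStringSet` or `DNAStringSet` with per-record `species` and
#'   `description` metadata columns. An empty file yields an empty set.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">p1 demo", "MKTT"), tf)
#' p <- readFasta(tf, species = "synA")
#' names(p)                        # "p1"
#' as.character(p[["p1"]])         # "MKTT"
#' @export
readFasta <- function(path, species, type = c("protein", "dna")) {
  type <- match.arg(type)
  assertString(path, "path")
  assertString(species, "species")
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  ids <- character()
  desc <- character()
  seqs <- character()
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) {
      header <- sub("^>", "", ln)
      tok <- strsplit(trimws(header), "\\s+")[[1]]
      if (length(tok) == 0L || !nzchar(tok[[1]])) {
        stop(sprintf("FASTA parse error at line %d: empty header", i))
      }
      ids <- c(ids, tok[[1]])
      desc <- c(desc, trimws(sub("^\\S+\\s*", "", trimws(header))))
      seqs <- c(seqs, "")
      cur <- length(seqs)
    } else if (nzchar(trimws(ln))) {
      if (is.null(cur)) {
        stop(sprintf("FASTA parse error at line %d: sequence before any header", i))
      }
      seqs[[cur]] <- paste0(seqs[[cur]], toupper(gsub("\\s", "", ln)))
    }
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate record id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (any(!nzchar(seqs))) {
    stop(sprintf("empty sequence for record(s): %s",
                 paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  allowed <- if (type == "protein") AA_ALLOWED else DNA_ALLOWED
  for (k in seq_along(seqs)) {
    cc <- chars(seqs[[k]])
    bad <- which(!cc %in% allowed)
    if (length(bad)) {
      stop(sprintf("disallowed character '%s' in record '%s' at position %d",
                   cc[bad[[1]]], ids[[k]], bad[[1]]))
    }
  }
  out <- if (type == "protein") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    species = rep(species, length(out)), description = desc)
  out
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param x an `AAStringSet`/`DNAStringSet` or named character vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Translate a genome record in all six reading frames
#'
#' Frames `+1/+2/+3` translate the forward strand starting at offsets 0, 1
#' and 2; frames `-1/-2/-3` translate the reverse complement at the same
#' offsets. The standard genetic code (translation table 1) is used, stop
#' codons are rendered as `*`, codons containing `N` translate to `X`, and
#' 1-2 trailing nucleotides of a frame are ignored.
#'
#' @param dna a single `DNAString`, a length-one `DNAStringSet`, or a DNA
#'   string.
#' @return named character vector of six peptides, names `"+1"`,...,`"-3"`.
#' @examples
#' sixFrameTranslate("GGTTACGGT")[["+1"]]  # "GYG"
#' @export
sixFrameTranslate <- function(dna) {
  if (is.character(dna)) dna <- Biostrings::DNAString(toupper(dna))
  if (is(dna, "DNAStringSet")) {
    stopifnot(length(dna) == 1L)
    dna <- dna[[1L]]
  }
  if (length(dna) < 3L) stop("sequence must be at least 3 nt long")
  rc <- Biostrings::reverseComplement(dna)
  oneFrame <- function(s, off) {
    n <- length(s) - off
    n <- n - n %% 3L
    if (n < 3L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(s, start = off + 1L, width = n),
      no.init.codon = TRUE, if.fuzzy.codon = "X"))
  }
  c("+1" = oneFrame(dna, 0L), "+2" = oneFrame(dna, 1L), "+3" = oneFrame(dna, 2L),
    "-1" = oneFrame(rc, 0L),  "-2" = oneFrame(rc, 1L),  "-3" = oneFrame(rc, 2L))
}

#' Find open reading frames in a frame translation
#'
#' ORFs are defined stop-to-stop: maximal runs of residues free of the stop
#' character `*`. No initiator methionine is required, so channel fragments
#' truncated by the frame boundaries are not missed. Segments shorter than
#' `minLen` are dropped.
#'
#' @param peptide a frame translation (may contain `*`).
#' @param minLen minimum ORF length in residues (default 50).
#' @return data.frame with 0-based half-open columns `start`, `end`, sorted
#'   by `start`.
#' @examples
#' findOrfs("MAA*GYGK", minLen = 1)  # segments [0,3) and [4,8)
#' @export
findOrfs <- function(peptide, minLen = 50L) {
  assertString(peptide, "peptide")
  stopifnot(minLen >= 1L)
  cc <- chars(peptide)
  isStop <- cc == "*"
  if (all(isStop)) return(data.frame(start = integer(), end = integer()))
  r <- rle(isStop)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !r$values & r$lengths >= minLen
  data.frame(start = starts[keep] - 1L, end = ends[keep])
}

#' Scan a genome for the G-Y-G selectivity filter in six-frame ORFs
#'
#' Exhaustiveness probe for potassium channel genes: every occurrence of the
#' canonical K+ selectivity-filter tripeptide G-Y-G inside every stop-free
#' ORF of every reading frame is reported, with forward-strand DNA
#' coordinates and a peptide context window for human inspection. No
#' automated channel call is made from DNA hits; the context window replaces
#' manual inspection of the filter surroundings.
#'
#' @param genomes a `DNAStringSet` (e.g. from [readFasta()]), `DNAString`,
#'   or named character vector of genome records.
#' @param minOrfLen minimum ORF length in residues (default 50).
#' @param contextWindow number of residues reported on each side of the
#'   G-Y-G (truncated at ORF bounds; default 40).
#' @return data.frame with one row per hit, ordered by record, frame and
#'   position: `genome_id`, `frame` (`"+1"`..`"-3"`), `orf_start`/`orf_end`
#'   (0-based half-open peptide coordinates within the frame translation),
#'   `gyg_offset` (0-based offset of G-Y-G within the ORF),
#'   `dna_start`/`dna_end` (0-based half-open forward-strand coordinates of
#'   the context peptide), `context` (the peptide window).
#' @examples
#' scanGyg(c(g1 = "GGTTACGGT"), minOrfLen = 3)
#' @export
scanGyg <- function(genomes, minOrfLen = 50L, contextWindow = 40L) {
  stopifnot(contextWindow >= 0L)
  if (is.character(genomes)) genomes <- Biostrings::DNAStringSet(toupper(genomes))
  if (is(genomes, "DNAString")) genomes <- Biostrings::DNAStringSet(genomes)
  if (is.null(names(genomes))) names(genomes) <- paste0("g", seq_along(genomes))
  out <- list()
  for (gi in seq_along(genomes)) {
    gid <- names(genomes)[[gi]]
    L <- Biostrings::width(genomes)[[gi]]
    if (L < 3L) next
    frames <- sixFrameTranslate(genomes[[gi]])
    for (fr in names(frames)) {
      pep <- frames[[fr]]
      if (!nzchar(pep)) next
      orfs <- findOrfs(pep, minLen = max(3L, minOrfLen))
      if (!nrow(orfs)) next
      off <- as.integer(substring(fr, 2L)) - 1L
      fwd <- startsWith(fr, "+")
      for (k in seq_len(nrow(orfs))) {
        orfSeq <- substring(pep, orfs$start[[k]] + 1L, orfs$end[[k]])
        hits <- gregexpr("(?=GYG)", orfSeq, perl = TRUE)[[1]]
        if (hits[[1]] == -1L) next
        for (h in as.integer(hits)) {
          gygOff <- h - 1L
          ctxStart <- max(0L, gygOff - contextWindow)
          ctxEnd <- min(orfs$end[[k]] - orfs$start[[k]], gygOff + 3L + contextWindow)
          context <- substring(orfSeq, ctxStart + 1L, ctxEnd)
          pepStart <- orfs$start[[k]] + ctxStart   # within frame translation
          pepEnd <- orfs$start[[k]] + ctxEnd
          if (fwd) {
            dnaStart <- off + 3L * pepStart
            dnaEnd <- off + 3L * pepEnd
          } else {
            dnaStart <- L - (off + 3L * pepEnd)
            dnaEnd <- L - (off + 3L * pepStart)
          }
          out[[length(out) + 1L]] <- data.frame(
            genome_id = gid, frame = fr,
            orf_start = orfs$start[[k]], orf_end = orfs$end[[k]],
            gyg_offset = gygOff, dna_start = dnaStart, dna_end = dnaEnd,
            context = context)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(genome_id = character(), frame = character(),
                      orf_start = integer(), orf_end = integer(),
                      gyg_offset = integer(), dna_start = integer(),
                      dna_end = integer(), context = character()))
  }
  res <- do.call(rbind, out)
  frameOrder <- c("+1", "+2", "+3", "-1", "-2", "-3")
  res <- res[order(match(res$genome_id, names(genomes)),
                   match(res$frame, frameOrder), res$orf_start,
                   res$gyg_offset), , drop = FALSE]
  rownames(res) <- NULL
  res
}
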