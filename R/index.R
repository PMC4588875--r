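## Lookup structures for placing 21-nt tags on the genome with at most one
## mismatch, and the transcript-level tag set used to recover tags spanning
## exon-exon junctions.
##
## The matcher uses the pigeonhole principle: a 21-mer with <= 1 mismatch
## must match exactly over positions 1..11 or over positions 12..21, so two
## trusted-band dictionary passes (Biostrings::matchPDict) enumerate every
## candidate; candidates are verified and de-duplicated.  The result is
## contract-identical to a brute-force Hamming scan over both strands.

#' Extend gene boundaries
#'
#' Widens each gene interval by `extension` nt on both sides (to capture
#' unannotated UTRs where many DGE tags fall), clamped to `[1,
#' chromosome length]`.
#'
#' @param annotation a `dge_annotation`.
#' @param extension nt added at each end (default 300).
#' @return data frame of class `extended_gene_intervals` with columns
#'   gene_id, chrom, start, end, strand.
#' @export
extend_gene_bounds <- function(annotation, extension = 300) {
  stopifnot(extension >= 0)
  cl <- annotation$chrom_lengths
  if (is.null(cl) || any(is.na(cl))) stop("chromosome lengths unknown")
  g <- annotation$genes
  if (!all(g$chrom %in% names(cl))) {
    stop("annotation references chromosomes with unknown length: ",
         paste(setdiff(g$chrom, names(cl)), collapse = ", "))
  }
  out <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                    start = pmax(1L, g$start - as.integer(extension)),
                    end = pmin(unname(cl[g$chrom]),
                               g$end + as.integer(extension)),
                    strand = g$strand, stringsAsFactors = FALSE)
  structure(out, class = c("extended_gene_intervals", "data.frame"),
            extension = extension, chrom_lengths = cl)
}

#' Build a one-mismatch tag index over a genome
#'
#' @param genome `DNAStringSet` of chromosome sequences (or named character
#'   vector).
#' @return object of class `tag_index`.
#' @export
build_tag_index <- function(genome) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (length(genome) == 0L) stop("genome is empty")
  names(genome) <- sub("\\s.*$", "", names(genome))
  structure(list(genome = genome,
                 rc = Biostrings::reverseComplement(genome),
                 chrom_lengths = setNames(Biostrings::width(genome),
                                          names(genome))),
            class = "tag_index")
}

count_mismatches <- function(a, b) {
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

## One trusted-band pass of all tags against one subject sequence.
## Returns data.frame(tag_i, start).
pdict_pass <- function(dict, subject, tb) {
  pd <- Biostrings::PDict(dict, tb.start = tb[1L], tb.end = tb[2L])
  m <- Biostrings::matchPDict(pd, subject, max.mismatch = 1L)
  cnt <- S4Vectors::elementNROWS(m)
  hit <- which(cnt > 0L)
  if (length(hit) == 0L) {
    return(data.frame(tag_i = integer(0), start = integer(0)))
  }
  data.frame(tag_i = rep(hit, cnt[hit]),
             start = unlist(lapply(hit, function(i) IRanges::start(m[[i]]))))
}

#' Place 21-nt tags on the genome with at most one mismatch
#'
#' Batch version of [match_tag()].  A placement `(chrom, pos, strand)` means
#' the tag, read 5' to 3', matches the given strand with its leftmost base
#' at plus-strand position `pos`.  The result is complete and exact for the
#' Hamming distance <= 1 contract, deterministically ordered by (tag, chrom,
#' position, strand).  Tags containing non-ACGT characters yield no
#' placements.
#'
#' @param tags character vector of 21-nt tags.
#' @param index a `tag_index`.
#' @param best_only keep only the best mismatch stratum per tag (exact hits
#'   suppress 1-mismatch hits); by default all hits within the bound are
#'   reported.
#' @return data frame with columns tag, chrom, pos, strand, mismatch.
#' @export
match_tags <- function(tags, index, best_only = FALSE) {
  stopifnot(inherits(index, "tag_index"))
  empty <- data.frame(tag = character(0), chrom = character(0),
                      pos = integer(0), strand = character(0),
                      mismatch = integer(0), stringsAsFactors = FALSE)
  if (length(tags) == 0L) return(empty)
  if (any(nchar(tags) != 21L)) stop("all tags must be 21 nt")
  tags <- unique(tags)
  ok <- !grepl("[^ACGT]", tags)
  valid <- tags[ok]
  if (length(valid) == 0L) return(empty)
  dict <- Biostrings::DNAStringSet(valid)
  out <- list()
  for (chrom in names(index$genome)) {
    L <- index$chrom_lengths[[chrom]]
    if (L < 21L) next
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") index$genome[[chrom]] else
        index$rc[[chrom]]
      h <- rbind(pdict_pass(dict, subject, c(1L, 11L)),
                 pdict_pass(dict, subject, c(12L, 21L)))
      if (nrow(h) == 0L) next
      h <- unique(h)
      subj_str <- as.character(subject)
      window <- substring(subj_str, h$start, h$start + 20L)
      mm <- count_mismatches(valid[h$tag_i], window)
      pos <- if (strand == "+") h$start else L - h$start - 19L
      out[[paste0(chrom, strand)]] <-
        data.frame(tag = valid[h$tag_i], chrom = chrom, pos = pos,
                   strand = strand, mismatch = mm,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (best_only && nrow(res) > 0L) {
    best <- tapply(res$mismatch, res$tag, min)
    res <- res[res$mismatch == best[res$tag], , drop = FALSE]
  }
  res[order(res$tag, res$chrom, res$pos, res$strand), , drop = FALSE]
}

#' Place a single tag on the genome
#'
#' @param tag a 21-nt tag.
#' @param index a `tag_index`.
#' @param best_only see [match_tags()].
#' @return data frame with columns chrom, pos, strand, mismatch.
#' @export
match_tag <- function(tag, index, best_only = FALSE) {
  stopifnot(length(tag) == 1L)
  res <- match_tags(tag, index, best_only = best_only)
  res$tag <- NULL
  rownames(res) <- NULL
  res
}

#' Build the transcript tag set
#'
#' Enumerates, for every spliced transcript, each CATG site with at least
#' 17 nt downstream within the transcript and records the resulting 21-mer
#' as a key to `(gene, transcript)`.  Tags spanning exon-exon junctions are
#' present here but absent from the genomic index, which is what allows the
#' assignment stage to recover them.
#'
#' @param annotation a `dge_annotation`.
#' @param genome matching `DNAStringSet`.
#' @return data frame of class `transcript_tag_set` with columns tag,
#'   gene_id, transcript_id.
#' @export
build_transcript_tag_set <- function(annotation, genome) {
  tx <- splice_transcripts(annotation, genome)
  gid <- attr(tx, "gene_id")
  rows <- list()
  for (i in seq_along(tx)) {
    s <- tx[[i]]
    m <- gregexpr("CATG", s, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) next
    m <- m[m <= nchar(s) - 20L]
    if (length(m) == 0L) next
    rows[[length(rows) + 1L]] <-
      data.frame(tag = unique(substring(s, m, m + 20L)),
                 gene_id = unname(gid[i]),
                 transcript_id = names(tx)[i],
                 stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0L) {
    data.frame(tag = character(0), gene_id = character(0),
               transcript_id = character(0), stringsAsFactors = FALSE)
  } else {
    unique(do.call(rbind, rows))
  }
  rownames(out) <- NULL
  structure(out, class = c("transcript_tag_set", "data.frame"))
}
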