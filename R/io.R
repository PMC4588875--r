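## File-format boundaries: FASTA via Biostrings, GFF3 via rtracklayer on the
## way in (hand-rendered 9-column text on the way out, so that identical seeds
## give byte-identical files), FASTQ as strict 4-line records.

#' Read a FASTQ file into a character vector of read sequences
#'
#' A strict reader for 4-line FASTQ records.  Any structural violation
#' (truncated record, missing `@`/`+` markers, quality string of the wrong
#' length) raises an error naming the 1-based record index, so that corrupt
#' library files fail loudly rather than silently losing reads.
#'
#' @param path FASTQ file.
#' @return character vector of read sequences, named by read id.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(setNames(character(0), character(0)))
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ record ", length(lines) %/% 4L + 1L,
         ": truncated record in '", path, "'")
  }
  idx <- seq(1L, length(lines), by = 4L)
  head_ok <- startsWith(lines[idx], "@")
  plus_ok <- startsWith(lines[idx + 2L], "+")
  len_ok <- nchar(lines[idx + 1L]) == nchar(lines[idx + 3L])
  bad <- which(!(head_ok & plus_ok & len_ok))
  if (length(bad) > 0L) {
    stop("malformed FASTQ record ", bad[1L], " in '", path, "'")
  }
  ids <- sub("\\s.*$", "", substring(lines[idx], 2L))
  setNames(toupper(lines[idx + 1L]), ids)
}

#' Write reads as 4-line FASTQ with a constant quality string
#'
#' The DGE filtering rules used here are sequence-based only, so simulated
#' libraries carry a flat Phred quality.
#'
#' @param seqs character vector of read sequences.
#' @param path output file.
#' @param ids read identifiers; defaults to `r000001, ...`.
#' @param qual_char single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, ids = NULL, qual_char = "I") {
  if (is.null(ids)) ids <- sprintf("r%06d", seq_along(seqs))
  n <- length(seqs)
  if (n == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- character(4L * n)
  out[seq(1L, by = 4L, length.out = n)] <- paste0("@", ids)
  out[seq(2L, by = 4L, length.out = n)] <- seqs
  out[seq(3L, by = 4L, length.out = n)] <- "+"
  out[seq(4L, by = 4L, length.out = n)] <- strrep(qual_char, nchar(seqs))
  writeLines(out, path)
  invisible(path)
}

#' Write a genome as FASTA
#' @param genome named character vector or `DNAStringSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return `DNAStringSet`.
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

gff3_attr <- function(...) {
  kv <- c(...)
  paste(paste0(names(kv), "=", kv), collapse = ";")
}

#' Write a gene annotation as GFF3
#'
#' Emits `gene`, `mRNA` and `exon` features with `ID`/`Parent` attributes and
#' `##sequence-region` pragmas, 1-based inclusive coordinates.
#'
#' @param annotation a `dge_annotation` object (see [read_annotation()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  g <- annotation$genes
  e <- annotation$exons
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d",
                     names(annotation$chrom_lengths),
                     annotation$chrom_lengths))
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    ex <- e[e$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    tid <- unique(ex$transcript_id)[1L]
    lines <- c(lines,
      paste(g$chrom[i], "cobdge", "gene", g$start[i], g$end[i], ".",
            g$strand[i], ".", gff3_attr(ID = gid), sep = "\t"),
      paste(g$chrom[i], "cobdge", "mRNA", g$start[i], g$end[i], ".",
            g$strand[i], ".", gff3_attr(ID = tid, Parent = gid), sep = "\t"),
      paste(ex$chrom, "cobdge", "exon", ex$start, ex$end, ".",
            ex$strand, ".", gff3_attr(Parent = tid), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build a gene annotation object
#'
#' The in-memory annotation used throughout the package: a `genes` table
#' (gene_id, chrom, start, end, strand; 1-based inclusive as in GFF3), an
#' `exons` table (gene_id, transcript_id, chrom, start, end, strand), and
#' known chromosome lengths.
#'
#' @param genes,exons data frames as described above.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return object of class `dge_annotation`.
#' @export
dge_annotation <- function(genes, exons, chrom_lengths) {
  stopifnot(all(genes$start <= genes$end),
            all(genes$strand %in% c("+", "-")),
            all(exons$start <= exons$end))
  if (!all(exons$gene_id %in% genes$gene_id)) {
    stop("exons reference unknown genes")
  }
  structure(list(genes = genes, exons = exons,
                 chrom_lengths = chrom_lengths),
            class = "dge_annotation")
}

#' @export
print.dge_annotation <- function(x, ...) {
  cat("dge_annotation:", nrow(x$genes), "genes,", nrow(x$exons), "exons on",
      length(x$chrom_lengths), "chromosome(s)\n")
  invisible(x)
}

#' Read a GFF3 gene annotation
#'
#' Uses `rtracklayer` to parse GFF3 and assembles the package's annotation
#' object from `gene`, `mRNA` and `exon` features.  Chromosome lengths are
#' taken from `genome` when given, otherwise from `##sequence-region`
#' pragmas.
#'
#' @param path GFF3 file.
#' @param genome optional `DNAStringSet` supplying chromosome lengths.
#' @return a `dge_annotation` object.
#' @export
read_annotation <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  gdf <- data.frame(
    gene_id = as.character(gr$ID[type == "gene"]),
    chrom = as.character(GenomicRanges::seqnames(gr))[type == "gene"],
    start = GenomicRanges::start(gr)[type == "gene"],
    end = GenomicRanges::end(gr)[type == "gene"],
    strand = as.character(GenomicRanges::strand(gr))[type == "gene"],
    stringsAsFactors = FALSE)
  tx <- type %in% c("mRNA", "transcript")
  tx_parent <- setNames(vapply(gr$Parent[tx], `[`, "", 1L),
                        as.character(gr$ID[tx]))
  is_ex <- type == "exon"
  ex_tid <- vapply(gr$Parent[is_ex], `[`, "", 1L)
  edf <- data.frame(
    gene_id = unname(tx_parent[ex_tid]),
    transcript_id = ex_tid,
    chrom = as.character(GenomicRanges::seqnames(gr))[is_ex],
    start = GenomicRanges::start(gr)[is_ex],
    end = GenomicRanges::end(gr)[is_ex],
    strand = as.character(GenomicRanges::strand(gr))[is_ex],
    stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    cl <- setNames(Biostrings::width(genome),
                   sub("\\s.*$", "", names(genome)))
  } else {
    prag <- grep("^##sequence-region", readLines(path), value = TRUE)
    if (length(prag) == 0L) stop("no chromosome lengths available: supply ",
                                 "'genome' or ##sequence-region pragmas")
    parts <- strsplit(prag, "\\s+")
    cl <- setNames(as.integer(vapply(parts, `[`, "", 4L)),
                   vapply(parts, `[`, "", 2L))
  }
  dge_annotation(gdf, edf, cl)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Spliced (mature) transcript sequences
#'
#' Concatenates each transcript's exons in genomic order and
#' reverse-complements minus-strand transcripts, yielding mRNA sequences in
#' sense orientation.
#'
#' @param annotation a `dge_annotation`.
#' @param genome `DNAStringSet` of chromosome sequences.
#' @return named character vector of transcript sequences; names are
#'   transcript ids, with gene ids in the `gene_id` attribute.
#' @export
splice_transcripts <- function(annotation, genome) {
  names(genome) <- sub("\\s.*$", "", names(genome))
  ex <- annotation$exons
  tids <- unique(ex$transcript_id)
  seqs <- character(length(tids))
  gids <- character(length(tids))
  chrom_str <- setNames(as.character(genome), names(genome))
  for (i in seq_along(tids)) {
    e <- ex[ex$transcript_id == tids[i], , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    s <- paste(substring(chrom_str[[e$chrom[1L]]], e$start, e$end),
               collapse = "")
    if (e$strand[1L] == "-") s <- revcomp(s)
    seqs[i] <- s
    gids[i] <- e$gene_id[1L]
  }
  structure(setNames(seqs, tids), gene_id = setNames(gids, tids))
}
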