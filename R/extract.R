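## Raw reads -> clean 21-nt tag tables.  Filtering rules: 3' adapter
## removal, electronic restoration of the leading CATG, exact length 21
## (CATG + 17 bp), no ambiguous base, per-library count >= 2.

#' Strip the 3' adapter from raw reads
#'
#' Finds the leftmost occurrence of the adapter's leading `seed_len`-mer in
#' each read and returns the preceding prefix.  A read is rejected (NA)
#' unless the resulting fragment is exactly `tag_len` nt.  When the seed is
#' not found, the first `tag_len` nt are taken if `allow_no_adapter` is TRUE
#' (rescuing reads whose adapter start was hit by a sequencing error),
#' otherwise the read is rejected.
#'
#' @param reads character vector of raw read sequences.
#' @param adapter adapter sequence (>= `seed_len` nt).
#' @param seed_len length of the adapter prefix used for exact detection.
#' @param allow_no_adapter take the leading `tag_len` nt when no adapter
#'   seed is found.
#' @param tag_len sequenced cDNA length downstream of the CATG site.
#' @return character vector of 17-nt fragments, NA where rejected.
#' @export
strip_adapter <- function(reads, adapter, seed_len = 7,
                          allow_no_adapter = TRUE, tag_len = 17) {
  if (missing(adapter) || is.null(adapter) || !nzchar(adapter)) {
    stop("adapter sequence must be a non-empty string")
  }
  if (nchar(adapter) < seed_len) {
    stop("adapter is shorter than the detection seed (", seed_len, " nt)")
  }
  seed <- substr(adapter, 1L, seed_len)
  pos <- regexpr(seed, reads, fixed = TRUE)
  frag <- rep(NA_character_, length(reads))
  found <- pos > 0L
  frag[found] <- substr(reads[found], 1L, pos[found] - 1L)
  if (allow_no_adapter) {
    rescue <- !found & nchar(reads) >= tag_len
    frag[rescue] <- substr(reads[rescue], 1L, tag_len)
  }
  frag[!is.na(frag) & nchar(frag) != tag_len] <- NA_character_
  frag
}

#' Extract a clean-tag table from a FASTQ library
#'
#' Applies the clean-read rules: each accepted 17-nt fragment is prefixed
#' with CATG to form a 21-nt tag; tags containing any non-ACGT character are
#' discarded; tags seen fewer than `min_count` times in the library are
#' discarded.  Totals of raw and surviving reads are recorded.
#'
#' @param fastq path to a FASTQ file, or a character vector of read
#'   sequences.
#' @param adapter 3' adapter sequence.
#' @param library_id label for the library.
#' @param min_count minimum per-library tag count (default 2).
#' @param allow_no_adapter,seed_len passed to [strip_adapter()].
#' @return object of class `clean_tag_table`: list with `library_id`,
#'   `counts` (named integer vector, tag -> count), `total_raw_reads`,
#'   `total_clean_reads`.
#' @export
extract_clean_tags <- function(fastq, adapter, library_id = "library",
                               min_count = 2, allow_no_adapter = TRUE,
                               seed_len = 7) {
  reads <- if (length(fastq) == 1L && file.exists(fastq)) {
    read_fastq(fastq)
  } else {
    as.character(fastq)
  }
  frag <- strip_adapter(reads, adapter, seed_len = seed_len,
                        allow_no_adapter = allow_no_adapter)
  tags <- paste0("CATG", frag[!is.na(frag)])
  tags <- tags[!grepl("[^ACGT]", tags)]
  tab <- table(tags)
  tab <- tab[tab >= min_count]
  counts <- setNames(as.integer(tab), names(tab) %||% character(0))
  if (length(counts) > 0L) counts <- counts[order(names(counts))]
  clean_tag_table(library_id, counts, total_raw_reads = length(reads))
}

#' Construct a clean-tag table
#'
#' @param library_id library label.
#' @param counts named integer vector mapping 21-nt tags to counts.
#' @param total_raw_reads raw reads the table was derived from.
#' @return object of class `clean_tag_table`.
#' @export
clean_tag_table <- function(library_id, counts, total_raw_reads) {
  if (length(counts) > 0) {
    stopifnot(all(nchar(names(counts)) == 21L),
              all(startsWith(names(counts), "CATG")),
              !any(grepl("N", names(counts), fixed = TRUE)),
              all(counts >= 1))
  }
  structure(list(library_id = library_id,
                 counts = counts,
                 total_raw_reads = as.numeric(total_raw_reads),
                 total_clean_reads = as.numeric(sum(counts))),
            class = "clean_tag_table")
}

#' @export
print.clean_tag_table <- function(x, ...) {
  cat(sprintf("clean_tag_table '%s': %d tags, %g clean / %g raw reads\n",
              x$library_id, length(x$counts), x$total_clean_reads,
              x$total_raw_reads))
  invisible(x)
}

#' Re-apply the minimum-count filter across libraries
#'
#' The default rule keeps tags with count >= 2 within each library.  The
#' alternative `pooled` scope (available without endorsement, since the
#' published rule reads "in a library") keeps tags whose summed count over
#' all libraries reaches the threshold; per-library counts of 1 then
#' survive when supported elsewhere.  Tables passed here should have been
#' extracted with `min_count = 1`.
#'
#' @param tables list of `clean_tag_table`.
#' @param min_count threshold.
#' @param scope `"per_library"` or `"pooled"`.
#' @return list of filtered `clean_tag_table`.
#' @export
apply_min_count <- function(tables, min_count = 2,
                            scope = c("per_library", "pooled")) {
  scope <- match.arg(scope)
  if (scope == "per_library") {
    lapply(tables, function(t) {
      keep <- t$counts >= min_count
      clean_tag_table(t$library_id, t$counts[keep], t$total_raw_reads)
    })
  } else {
    all_tags <- sort(unique(unlist(lapply(tables, function(t) names(t$counts)))))
    pooled <- setNames(numeric(length(all_tags)), all_tags)
    for (t in tables) pooled[names(t$counts)] <- pooled[names(t$counts)] + t$counts
    keep_tags <- names(pooled)[pooled >= min_count]
    lapply(tables, function(t) {
      keep <- names(t$counts) %in% keep_tags
      clean_tag_table(t$library_id, t$counts[keep], t$total_raw_reads)
    })
  }
}

#' Write / read a tag table as TSV
#'
#' @param x a `clean_tag_table`.
#' @param path output file.
#' @return `path` invisibly (write); a `clean_tag_table` (read).
#' @export
write_tag_table <- function(x, path) {
  df <- data.frame(tag = names(x$counts), count = unname(x$counts))
  attr <- sprintf("# library_id=%s total_raw_reads=%g", x$library_id,
                  x$total_raw_reads)
  con <- file(path, "w")
  writeLines(attr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_tag_table
#' @param library_id library label override for reading.
#' @export
read_tag_table <- function(path, library_id = NULL) {
  header <- readLines(path, n = 1L)
  raw <- NA_real_
  lid <- library_id
  if (startsWith(header, "#")) {
    m <- regmatches(header, regexec("library_id=(\\S+) total_raw_reads=(\\S+)",
                                    header))[[1L]]
    if (length(m) == 3L) {
      lid <- lid %||% m[2L]
      raw <- as.numeric(m[3L])
    }
    df <- read.delim(path, sep = "\t", skip = 1L, stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  }
  clean_tag_table(lid %||% basename(path),
                  setNames(as.integer(df$count), df$tag),
                  total_raw_reads = raw)
}
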