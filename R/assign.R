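## Tag -> gene assignment with the ambiguity rules: placements are mapped to
## genes whose 300-nt-extended interval contains the whole 21-mer on the
## same strand; tags with no genomic placement are looked up in the
## transcript tag set; 1-3 distinct genes share the tag count equally, more
## than 3 genes drop the tag, 0 genes leave it unmapped.

.assign_tag_set <- function(tags, index, extended, tx_tags, max_genes = 3) {
  stopifnot(inherits(extended, "extended_gene_intervals"))
  if (!all(unique(extended$chrom) %in% names(index$chrom_lengths))) {
    stop("annotation and index disagree on chromosome names: ",
         paste(setdiff(unique(extended$chrom), names(index$chrom_lengths)),
               collapse = ", "))
  }
  genes_by_tag <- setNames(vector("list", length(tags)), tags)
  source <- setNames(rep(NA_character_, length(tags)), tags)

  pl <- match_tags(tags, index)
  placed <- unique(pl$tag)
  if (nrow(pl) > 0L) {
    pl_gr <- GenomicRanges::GRanges(pl$chrom,
                                    IRanges::IRanges(pl$pos, pl$pos + 20L),
                                    strand = pl$strand)
    gene_gr <- GenomicRanges::GRanges(extended$chrom,
                                      IRanges::IRanges(extended$start,
                                                       extended$end),
                                      strand = extended$strand)
    ov <- GenomicRanges::findOverlaps(pl_gr, gene_gr, type = "within",
                                      ignore.strand = FALSE)
    hit_tag <- pl$tag[S4Vectors::queryHits(ov)]
    hit_gene <- extended$gene_id[S4Vectors::subjectHits(ov)]
    by_tag <- split(hit_gene, hit_tag)
    for (tg in names(by_tag)) {
      genes_by_tag[[tg]] <- sort(unique(by_tag[[tg]]))
      source[tg] <- "genome"
    }
    ## placements outside any gene still count as genomic: such tags are
    ## unmapped, not candidates for transcript recovery
    source[setdiff(placed, names(by_tag))] <- "genome"
  }

  unplaced <- setdiff(tags, placed)
  if (length(unplaced) > 0L && nrow(tx_tags) > 0L) {
    tx_hit <- tx_tags[tx_tags$tag %in% unplaced, , drop = FALSE]
    by_tag <- split(tx_hit$gene_id, tx_hit$tag)
    for (tg in names(by_tag)) {
      genes_by_tag[[tg]] <- sort(unique(by_tag[[tg]]))
      source[tg] <- "transcript"
    }
  }

  n_genes <- lengths(genes_by_tag)
  status <- ifelse(n_genes == 0L, "unmapped",
                   ifelse(n_genes > max_genes, "dropped_too_many_genes",
                          "assigned"))
  data.frame(tag = tags,
             status = status,
             source = ifelse(status == "assigned", unname(source[tags]),
                             NA_character_),
             n_genes = unname(n_genes),
             genes = I(unname(genes_by_tag)),
             fraction = ifelse(status == "assigned", 1 / n_genes, NA_real_),
             stringsAsFactors = FALSE)
}

#' Assign clean tags to genes
#'
#' @param clean_tags a `clean_tag_table`.
#' @param index a `tag_index` built from the same genome as the annotation.
#' @param extended `extended_gene_intervals` from [extend_gene_bounds()].
#' @param tx_tags `transcript_tag_set` from [build_transcript_tag_set()].
#' @param max_genes tags mapped to more than this many genes are dropped
#'   (default 3).
#' @return data frame of class `tag_assignment` with one row per tag:
#'   `tag`, `count`, `status` (assigned / dropped_too_many_genes /
#'   unmapped), `source` (genome / transcript), `n_genes`, `genes` (list
#'   column) and `fraction` (equal split, `1 / n_genes`).
#' @export
assign_tags <- function(clean_tags, index, extended, tx_tags,
                        max_genes = 3) {
  stopifnot(inherits(clean_tags, "clean_tag_table"))
  res <- .assign_tag_set(names(clean_tags$counts), index, extended, tx_tags,
                         max_genes = max_genes)
  res <- cbind(res[, "tag", drop = FALSE],
               count = unname(clean_tags$counts[res$tag]),
               res[, setdiff(names(res), "tag"), drop = FALSE])
  structure(res, class = c("tag_assignment", "data.frame"),
            library_id = clean_tags$library_id,
            total_raw_reads = clean_tags$total_raw_reads,
            total_clean_reads = clean_tags$total_clean_reads)
}

#' Summarize assignment outcomes for one library
#'
#' @param assignment a `tag_assignment`.
#' @return one-row data frame with the library's clean total and the tag
#'   counts falling into each outcome; these satisfy
#'   `clean = assigned + dropped + unmapped` exactly.
#' @export
assignment_summary <- function(assignment) {
  s <- function(st) as.numeric(sum(assignment$count[assignment$status == st]))
  data.frame(library_id = attr(assignment, "library_id") %||% NA_character_,
             total_raw_reads = attr(assignment, "total_raw_reads") %||%
               NA_real_,
             total_clean_reads = as.numeric(sum(assignment$count)),
             assigned = s("assigned"),
             dropped_too_many_genes = s("dropped_too_many_genes"),
             unmapped = s("unmapped"),
             stringsAsFactors = FALSE)
}

#' Build the gene x library count matrix
#'
#' Each gene's expression value is the sum over its sense-strand tags of
#' tag count x fraction (fractional counts for 2-3 gene tags).  Genes with
#' no tags are present with count 0.
#'
#' @param assignments list of `tag_assignment`, one per library.
#' @param gene_ids gene universe (row order of the result).
#' @return numeric matrix genes x libraries of class `count_matrix`, with
#'   attribute `lib_sizes` holding each library's total clean reads.
#' @export
quantify_genes <- function(assignments, gene_ids) {
  if (is.null(names(assignments))) {
    names(assignments) <- vapply(assignments, function(a) {
      attr(a, "library_id") %||% "library"
    }, "")
  }
  counts <- matrix(0, nrow = length(gene_ids), ncol = length(assignments),
                   dimnames = list(gene_ids, names(assignments)))
  for (j in seq_along(assignments)) {
    a <- assignments[[j]]
    a <- a[a$status == "assigned", , drop = FALSE]
    if (nrow(a) == 0L) next
    g <- unlist(a$genes, use.names = FALSE)
    w <- rep(a$count * a$fraction, a$n_genes)
    if (!all(g %in% gene_ids)) {
      stop("assignment references genes outside the given universe")
    }
    agg <- tapply(w, g, sum)
    counts[names(agg), j] <- counts[names(agg), j] + agg
  }
  structure(counts, class = c("count_matrix", class(counts)),
            lib_sizes = vapply(assignments, function(a) {
              attr(a, "total_clean_reads") %||% NA_real_
            }, 0))
}

#' TPTM normalization (transcripts per ten million reads)
#'
#' `TPTM = count / denominator * 1e7`.  The denominator defaults to each
#' library's total clean-read count (attribute `lib_sizes` of the count
#' matrix); the column totals of assigned counts can be used instead for
#' sensitivity analysis.
#'
#' @param counts genes x libraries matrix.
#' @param denominators per-library totals; default clean-read totals, then
#'   column sums.
#' @return TPTM matrix with attribute `denominators`.
#' @export
tptm_normalize <- function(counts, denominators = NULL) {
  denominators <- denominators %||% attr(counts, "lib_sizes") %||%
    colSums(counts)
  if (any(is.na(denominators))) denominators <- colSums(counts)
  bad <- which(denominators <= 0)
  if (length(bad) > 0L) {
    stop("zero TPTM denominator for library: ",
         paste(colnames(counts)[bad] %||% bad, collapse = ", "))
  }
  tptm <- sweep(unclass(counts), 2L, denominators, "/") * 1e7
  structure(tptm, denominators = setNames(denominators, colnames(counts)))
}

#' Call preferentially expressed genes between two groups
#'
#' A gene is preferentially expressed in group A if its group-level TPTM is
#' at least `min_tptm` in A and exactly zero in B (and symmetrically for
#' B).  Group-level TPTM is computed from summed counts over replicates
#' divided by summed denominators.  With `per_replicate = TRUE` every
#' replicate of the expressing group must individually reach `min_tptm`.
#'
#' @param counts genes x libraries count matrix.
#' @param design data frame with columns `sample`, `group` matching the
#'   matrix columns.
#' @param contrast length-2 character vector (group A, group B).
#' @param denominators per-library TPTM denominators (defaults as in
#'   [tptm_normalize()]).
#' @param min_tptm expression threshold (default 10 TPTM).
#' @param per_replicate require the threshold in every replicate.
#' @return data frame with columns `gene`, `direction` (`"A"`-side group
#'   label where expressed), `tptm_a`, `tptm_b`.
#' @export
call_preferential <- function(counts, design, contrast,
                              denominators = NULL, min_tptm = 10,
                              per_replicate = FALSE) {
  stopifnot(length(contrast) == 2, all(contrast %in% design$group))
  denominators <- denominators %||% attr(counts, "lib_sizes") %||%
    colSums(counts)
  if (any(is.na(denominators))) denominators <- colSums(counts)
  denominators <- setNames(as.numeric(denominators), colnames(counts))
  cols_a <- design$sample[design$group == contrast[1L]]
  cols_b <- design$sample[design$group == contrast[2L]]
  grp_tptm <- function(cols) {
    rowSums(counts[, cols, drop = FALSE]) / sum(denominators[cols]) * 1e7
  }
  ta <- grp_tptm(cols_a)
  tb <- grp_tptm(cols_b)
  rep_ok <- function(cols) {
    tp <- sweep(counts[, cols, drop = FALSE], 2L, denominators[cols],
                "/") * 1e7
    rowSums(tp >= min_tptm) == length(cols)
  }
  in_a <- ta >= min_tptm & tb == 0
  in_b <- tb >= min_tptm & ta == 0
  if (per_replicate) {
    in_a <- in_a & rep_ok(cols_a)
    in_b <- in_b & rep_ok(cols_b)
  }
  out <- rbind(
    data.frame(gene = rownames(counts)[in_a],
               direction = rep(contrast[1L], sum(in_a)),
               tptm_a = ta[in_a], tptm_b = tb[in_a],
               stringsAsFactors = FALSE),
    data.frame(gene = rownames(counts)[in_b],
               direction = rep(contrast[2L], sum(in_b)),
               tptm_a = ta[in_b], tptm_b = tb[in_b],
               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
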