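## Synthetic tag-seq study generator.  Emulates the structure of the real
## experiment (2 tissues x 2 nitrogen conditions x 3 replicates of
## NlaIII-anchored 17-bp tag libraries) on a toy genome with known truth, so
## that every downstream stage can be validated without any download.

#' Simulation configuration
#'
#' Builds and validates the configuration object that drives the synthetic
#' tag-seq generator.  The defaults describe the study design this package
#' is modelled on: four sample groups (cob/floret tissue under optimal and
#' low nitrogen) with three replicates each, negative-binomial count noise,
#' and 35-nt raw reads consisting of a 17-nt NlaIII tag followed by the 3'
#' sequencing adapter.
#'
#' @param n_genes number of genes.
#' @param gene_length range (min, max) of mature transcript length in nt;
#'   minimum 25 so that every transcript can host CATG + 17 nt.
#' @param intergenic_gap range of intergenic gap lengths in nt.
#' @param groups character vector of sample-group labels.
#' @param replicates_per_group libraries per group.
#' @param de_fraction proportion of genes differentially expressed between
#'   the two `contrast` groups.
#' @param fold_change true fold change (>= 1) of DE genes.
#' @param dispersion negative-binomial dispersion phi >= 0
#'   (variance = mu + phi * mu^2); 0 gives Poisson counts.
#' @param library_depth expected reads per library.
#' @param error_rate per-base substitution probability in raw reads.
#' @param adapter_seq 3' adapter sequence appended to each tag (no N).
#' @param read_length raw read length in nt.
#' @param seed integer seed; all randomness in the generator flows from it
#'   (per-stage sub-seeds are derived by fixed offsets).
#' @param contrast the two group labels carrying the DE/exclusive design;
#'   defaults to the first two `groups`.
#' @param exclusive_fraction proportion of genes made group-exclusive
#'   (abundance zero in one contrast group), to exercise the
#'   preferential-expression rule.
#' @param junction_fraction proportion of genes whose canonical tag spans an
#'   exon-exon junction (absent from the genome, recoverable only through
#'   the spliced transcript).
#' @param abundance_sdlog log-normal sd of relative gene abundances.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500,
                       gene_length = c(200, 600),
                       intergenic_gap = c(300, 800),
                       groups = c("cob_ON", "floret_ON",
                                  "cob_LN", "floret_LN"),
                       replicates_per_group = 3,
                       de_fraction = 0.1,
                       fold_change = 4,
                       dispersion = 0.1,
                       library_depth = 2e5,
                       error_rate = 0.005,
                       adapter_seq = "TCGTATGCCGTCTTCTGCTTG",
                       read_length = 35,
                       seed = 1,
                       contrast = NULL,
                       exclusive_fraction = 0.02,
                       junction_fraction = 0.1,
                       abundance_sdlog = 1) {
  contrast <- contrast %||% groups[1:2]
  cfg <- list(n_genes = as.integer(n_genes), gene_length = gene_length,
              intergenic_gap = intergenic_gap, groups = groups,
              replicates_per_group = as.integer(replicates_per_group),
              de_fraction = de_fraction, fold_change = fold_change,
              dispersion = dispersion, library_depth = library_depth,
              error_rate = error_rate, adapter_seq = adapter_seq,
              read_length = as.integer(read_length), seed = as.integer(seed),
              contrast = contrast, exclusive_fraction = exclusive_fraction,
              junction_fraction = junction_fraction,
              abundance_sdlog = abundance_sdlog)
  stopifnot(cfg$n_genes >= 1,
            length(gene_length) == 2, all(gene_length > 0),
            gene_length[1] <= gene_length[2],
            length(intergenic_gap) == 2, all(intergenic_gap > 0),
            intergenic_gap[1] <= intergenic_gap[2],
            length(groups) >= 1, !anyDuplicated(groups),
            replicates_per_group >= 1,
            de_fraction >= 0, de_fraction <= 1,
            fold_change >= 1,
            dispersion >= 0,
            library_depth > 0,
            error_rate >= 0, error_rate <= 1,
            read_length >= 17,
            exclusive_fraction >= 0, exclusive_fraction <= 1,
            junction_fraction >= 0, junction_fraction <= 1,
            all(contrast %in% groups), length(contrast) == 2)
  if (gene_length[1] < 25) {
    stop("gene_length must be at least 25 nt to host a CATG + 17 nt tag")
  }
  if (grepl("N", adapter_seq, fixed = TRUE) || nchar(adapter_seq) < 7) {
    stop("adapter_seq must be at least 7 nt and contain no N")
  }
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## 1-based start of the 3'-most CATG with >= 17 nt downstream, or NA.
canonical_catg_site <- function(seq) {
  m <- gregexpr("CATG", seq, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) return(NA_integer_)
  m <- m[m <= nchar(seq) - 20L]
  if (length(m) == 0L) NA_integer_ else max(m)
}

## Guarantee a canonical tag site and keep the sequenced 17-mer free of the
## adapter seed (adapter detection is sequence-based, so a tag containing the
## seed would be systematically lost at trimming -- excluded by construction).
plant_canonical_tag <- function(seq, adapter_seed) {
  len <- nchar(seq)
  for (i in 1:50) {
    p <- canonical_catg_site(seq)
    if (is.na(p)) {
      substr(seq, len - 20L, len - 17L) <- "CATG"
      next
    }
    tag17 <- substr(seq, p + 4L, p + 20L)
    if (!grepl(adapter_seed, tag17, fixed = TRUE)) return(seq)
    substr(seq, p + 4L, p + 20L) <- random_dna(17L)
  }
  stop("could not plant a canonical CATG tag site")  # nocov
}

#' Generate a toy genome and annotation
#'
#' Creates a single-chromosome genome of `n_genes` randomly stranded,
#' non-overlapping genes separated by intergenic gaps.  Every mature
#' transcript is guaranteed to contain a CATG site with at least 17 nt
#' downstream (the canonical DGE tag site, taken at the 3'-most such site).
#' A configurable fraction of genes receives a single intron placed inside
#' the canonical tag window, so that their tag spans an exon-exon junction
#' and can only be recovered through the spliced transcript.
#'
#' @param config a [sim_config()].
#' @return list with elements `genome` (`DNAStringSet`) and `annotation`
#'   (`dge_annotation`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  seed7 <- substr(config$adapter_seq, 1L, 7L)
  segs <- character(2L * n + 1L)
  segs[1L] <- random_dna(sample(config$intergenic_gap[1]:config$intergenic_gap[2], 1L))
  cursor <- nchar(segs[1L])
  genes <- vector("list", n)
  exons <- vector("list", n)
  for (i in seq_len(n)) {
    len <- sample(config$gene_length[1]:config$gene_length[2], 1L)
    tseq <- plant_canonical_tag(random_dna(len), seed7)
    strand <- sample(c("+", "-"), 1L)
    junction <- runif(1L) < config$junction_fraction
    if (junction) {
      p <- canonical_catg_site(tseq)
      d <- sample(5:12, 1L)              # split 5-12 nt into the 17-nt cDNA
      cut <- p + 3L + d                  # exon1 = 1..cut on the mRNA
      ilen <- sample(60:200, 1L)
      intron <- paste0("GT", random_dna(ilen - 4L), "AG")
      pre <- paste0(substr(tseq, 1L, cut), intron,
                    substr(tseq, cut + 1L, len))
      ex_tx <- rbind(c(1L, cut), c(cut + ilen + 1L, len + ilen))
    } else {
      pre <- tseq
      ex_tx <- rbind(c(1L, len))
    }
    glen <- nchar(pre)
    if (strand == "-") {
      pre <- revcomp(pre)
      ex_tx <- cbind(glen - ex_tx[, 2L] + 1L, glen - ex_tx[, 1L] + 1L)
      ex_tx <- ex_tx[order(ex_tx[, 1L]), , drop = FALSE]
    }
    gid <- sprintf("GENE%04d", i)
    gstart <- cursor + 1L
    genes[[i]] <- data.frame(gene_id = gid, chrom = "chr1",
                             start = gstart, end = cursor + glen,
                             strand = strand, stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(gene_id = gid,
                             transcript_id = paste0(gid, "_T01"),
                             chrom = "chr1",
                             start = gstart + ex_tx[, 1L] - 1L,
                             end = gstart + ex_tx[, 2L] - 1L,
                             strand = strand, stringsAsFactors = FALSE)
    segs[2L * i] <- pre
    gap <- random_dna(sample(config$intergenic_gap[1]:config$intergenic_gap[2], 1L))
    segs[2L * i + 1L] <- gap
    cursor <- cursor + glen + nchar(gap)
  }
  chrom <- paste(segs, collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(chrom, "chr1"))
  ann <- dge_annotation(do.call(rbind, genes), do.call(rbind, exons),
                        setNames(nchar(chrom), "chr1"))
  list(genome = genome, annotation = ann)
}

#' Assign ground-truth expression to a simulated annotation
#'
#' Draws log-normal relative abundances (normalized to sum to one within
#' each group), flags `floor(de_fraction * n_genes)` genes as differentially
#' expressed between the two contrast groups (half up, half down, ties to
#' up) with an exact `fold_change` ratio of group means, and makes a further
#' subset group-exclusive (abundance zero in one contrast group).  Non-DE
#' genes in the second contrast group are jointly rescaled so each group's
#' abundances still sum to one; flagged genes therefore keep their exact
#' fold while the background absorbs the compositional shift (which TMM
#' normalization is designed to remove downstream).
#'
#' @param annotation a `dge_annotation` from [generate_genome()].
#' @param config the same [sim_config()] used to generate it.
#' @param genome the matching `DNAStringSet`, used to derive each gene's
#'   canonical 21-nt tag; may be NULL for count-level studies that never
#'   touch read sequences (tags are then NA).
#' @return data frame of class `ground_truth` with one row per gene: the
#'   canonical tag, per-group relative abundances (`abund_<group>`), DE and
#'   exclusivity flags, and the true log2 fold change of the contrast.
#' @export
assign_expression_truth <- function(annotation, config, genome = NULL) {
  stopifnot(inherits(config, "sim_config"), nrow(annotation$genes) > 0)
  gene_ids <- annotation$genes$gene_id
  n <- length(gene_ids)
  if (!is.null(genome)) {
    tx <- splice_transcripts(annotation, genome)
    gid_by_tx <- attr(tx, "gene_id")
    sites <- vapply(tx, canonical_catg_site, 0L)
    tags <- substr(tx, sites, sites + 20L)
    tag_by_gene <- setNames(as.character(tags), unname(gid_by_tx))
  } else {
    tag_by_gene <- setNames(rep(NA_character_, n), gene_ids)
  }

  set.seed(config$seed + 1L)
  base <- rlnorm(n, meanlog = 0, sdlog = config$abundance_sdlog)
  base <- base / sum(base)

  n_de <- floor(config$de_fraction * n)
  n_up <- ceiling(n_de / 2)
  perm <- sample.int(n)
  de_idx <- perm[seq_len(n_de)]
  up_idx <- de_idx[seq_len(n_up)]
  down_idx <- setdiff(de_idx, up_idx)
  n_ex <- floor(config$exclusive_fraction * n)
  ex_idx <- perm[n_de + seq_len(min(n_ex, n - n_de))]
  ex_in_a <- ex_idx[seq_along(ex_idx) %% 2L == 1L]   # present in A, zero in B
  ex_in_b <- setdiff(ex_idx, ex_in_a)

  fc <- config$fold_change
  a <- base
  b <- base
  a[ex_in_b] <- 0
  b[ex_in_a] <- 0
  b[up_idx] <- base[up_idx] * fc
  b[down_idx] <- base[down_idx] / fc
  free <- setdiff(seq_len(n), de_idx)
  ka <- (1 - sum(a[de_idx])) / sum(a[free])
  kb <- (1 - sum(b[de_idx])) / sum(b[free])
  if (ka <= 0 || kb <= 0) {
    stop("DE abundance mass too large to renormalize; lower de_fraction ",
         "or fold_change")
  }
  a[free] <- a[free] * ka
  b[free] <- b[free] * kb

  direction <- rep(NA_character_, n)
  direction[up_idx] <- "up"
  direction[down_idx] <- "down"
  exclusive <- rep(NA_character_, n)
  exclusive[ex_in_a] <- config$contrast[1L]
  exclusive[ex_in_b] <- config$contrast[2L]
  lfc <- log2(b / a)

  truth <- data.frame(gene_id = gene_ids,
                      tag = unname(tag_by_gene[gene_ids]),
                      de_flag = seq_len(n) %in% de_idx,
                      de_direction = direction,
                      exclusive_in = exclusive,
                      true_log2fc = lfc,
                      stringsAsFactors = FALSE)
  for (g in config$groups) {
    truth[[paste0("abund_", g)]] <-
      if (g == config$contrast[2L]) b else a
  }
  structure(truth, class = c("ground_truth", "data.frame"),
            contrast = config$contrast)
}

draw_library_counts <- function(truth, group, config) {
  mu <- truth[[paste0("abund_", group)]] * config$library_depth
  if (config$dispersion == 0) {
    counts <- rpois(length(mu), mu)
  } else {
    counts <- rnbinom(length(mu), size = 1 / config$dispersion, mu = mu)
  }
  setNames(counts, truth$gene_id)
}

add_substitution_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  L <- nchar(reads[1L])
  hit <- which(runif(length(reads) * L) < rate)
  bases <- c("A", "C", "G", "T")
  for (h in hit) {
    i <- (h - 1L) %/% L + 1L
    pos <- (h - 1L) %% L + 1L
    cur <- substr(reads[i], pos, pos)
    substr(reads[i], pos, pos) <- sample(setdiff(bases, cur), 1L)
  }
  reads
}

#' Simulate one raw-read library
#'
#' Per-gene read counts are drawn from a negative binomial with mean
#' `abundance * library_depth` and dispersion `phi` (Poisson when `phi = 0`).
#' Each raw read is the 17-nt sequence 3' of the gene's canonical CATG site
#' (sense strand, without the leading CATG, which the extraction stage
#' restores electronically) followed by the adapter, truncated or padded to
#' `read_length`; substitution errors are applied per base.
#'
#' @param genome `DNAStringSet` (unused for read synthesis, kept to bind the
#'   library to the genome it was simulated from).
#' @param truth a `ground_truth` from [assign_expression_truth()].
#' @param group group label to simulate.
#' @param config the [sim_config()].
#' @param replicate replicate number within the group.
#' @param path optional FASTQ output path.
#' @return list with `counts` (named truth counts actually emitted),
#'   `reads` (character vector, or NULL if written to `path`) and `path`.
#' @export
simulate_library <- function(genome, truth, group, config, replicate = 1,
                             path = NULL) {
  stopifnot(group %in% config$groups, config$library_depth > 0)
  lib_idx <- (match(group, config$groups) - 1L) *
    config$replicates_per_group + replicate
  set.seed(config$seed + 10L + lib_idx)
  counts <- draw_library_counts(truth, group, config)
  tag17 <- substr(truth$tag, 5L, 21L)
  template <- substr(paste0(tag17, config$adapter_seq,
                            strrep("A", config$read_length)),
                     1L, config$read_length)
  reads <- rep(template, counts)
  reads <- add_substitution_errors(reads, config$error_rate)
  if (!is.null(path)) {
    write_fastq(reads, path)
    reads <- NULL
  }
  list(counts = counts, reads = reads, path = path)
}

#' Simulate a count matrix directly (no reads)
#'
#' Draws the same negative-binomial per-library gene counts as
#' [simulate_library()] but skips read synthesis; used for studies of the
#' statistical stages (normalization, dispersion, testing) where the
#' tag-level plumbing is not under test.
#'
#' @param truth a `ground_truth`.
#' @param config the [sim_config()].
#' @param groups groups to simulate (default all configured groups).
#' @return list with `counts` (genes x libraries matrix) and `design`
#'   (data frame sample/group).
#' @export
simulate_count_matrix <- function(truth, config, groups = config$groups) {
  set.seed(config$seed + 2L)
  cols <- list()
  design <- data.frame(sample = character(0), group = character(0))
  for (g in groups) {
    for (r in seq_len(config$replicates_per_group)) {
      nm <- sprintf("%s_r%d", g, r)
      cols[[nm]] <- draw_library_counts(truth, g, config)
      design <- rbind(design, data.frame(sample = nm, group = g))
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- truth$gene_id
  list(counts = counts, design = design)
}

#' Simulate a random gene-to-term annotation
#'
#' Random term membership over the simulated genes, for exercising the
#' enrichment stage.  Clearly synthetic: terms carry no biological meaning.
#'
#' @param gene_ids character vector of genes.
#' @param n_terms number of terms.
#' @param mean_size mean genes per term.
#' @param seed integer seed.
#' @return data frame with columns `term`, `gene`, `label`.
#' @export
simulate_term_annotation <- function(gene_ids, n_terms = 20, mean_size = 15,
                                     seed = 1) {
  set.seed(seed)
  rows <- list()
  for (t in seq_len(n_terms)) {
    size <- max(2L, rpois(1L, mean_size))
    size <- min(size, length(gene_ids))
    rows[[t]] <- data.frame(term = sprintf("TERM:%04d", t),
                            gene = sample(gene_ids, size),
                            label = sprintf("synthetic term %d", t),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate a complete tag-seq experiment on disk
#'
#' Writes `genome.fa`, `genes.gff3`, one FASTQ per library
#' (`reads_<group>_r<i>.fastq`), `design.tsv` (sample, group, fastq),
#' `truth_counts.tsv` (emitted per-gene read counts per library),
#' `truth_de.tsv` (the ground-truth table) and `term2gene.tsv`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return invisible list with the generated `genome`, `annotation`,
#'   `truth`, realized `counts`, `design` and all file `paths`.
#' @export
simulate_experiment <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome(config)
  truth <- assign_expression_truth(gen$annotation, config, gen$genome)
  paths <- list(genome = file.path(outdir, "genome.fa"),
                annotation = file.path(outdir, "genes.gff3"),
                design = file.path(outdir, "design.tsv"),
                truth_counts = file.path(outdir, "truth_counts.tsv"),
                truth_de = file.path(outdir, "truth_de.tsv"),
                terms = file.path(outdir, "term2gene.tsv"))
  write_genome(gen$genome, paths$genome)
  write_gff3(gen$annotation, paths$annotation)
  cols <- list()
  design <- data.frame(sample = character(0), group = character(0),
                       fastq = character(0), stringsAsFactors = FALSE)
  for (g in config$groups) {
    for (r in seq_len(config$replicates_per_group)) {
      nm <- sprintf("%s_r%d", g, r)
      fq <- file.path(outdir, sprintf("reads_%s.fastq", nm))
      lib <- simulate_library(gen$genome, truth, g, config, replicate = r,
                              path = fq)
      cols[[nm]] <- lib$counts
      design <- rbind(design, data.frame(sample = nm, group = g, fastq = fq,
                                         stringsAsFactors = FALSE))
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- truth$gene_id
  terms <- simulate_term_annotation(truth$gene_id, seed = config$seed + 3L)
  ## design.tsv stores fastq paths relative to its own directory, so a run
  ## directory is relocatable and byte-stable across machines
  design_out <- transform(design, fastq = basename(fastq))
  write_tsv(design_out, paths$design)
  write_tsv(data.frame(gene_id = rownames(counts), counts,
                       check.names = FALSE), paths$truth_counts)
  write_tsv(as.data.frame(truth), paths$truth_de)
  write_tsv(terms, paths$terms)
  invisible(list(genome = gen$genome, annotation = gen$annotation,
                 truth = truth, counts = counts, design = design,
                 terms = terms, paths = paths))
}
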