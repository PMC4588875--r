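## Small simulation configurations for fast unit tests.  Acceptance-level
## study conditions live in test-acceptance.R at their stated sizes.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 40, groups = c("cob_ON", "floret_ON"),
                   replicates_per_group = 2, library_depth = 1e4,
                   de_fraction = 0.2, exclusive_fraction = 0.05,
                   seed = 1)
  do.call(sim_config, utils::modifyList(defaults, args))
}

## A hand-built two-gene annotation on a known genome, for assignment and
## transcript-set unit tests.
make_toy_locus <- function() {
  set.seed(404)
  g1 <- paste0(random_tag(40), "CATG", random_tag(30))        # gene1 5..78
  g2 <- paste0(random_tag(10), "CATG", random_tag(40))        # gene2
  chrom <- paste0(random_tag(400), g1, random_tag(700), g2, random_tag(400))
  s1 <- 401L; e1 <- s1 + nchar(g1) - 1L
  s2 <- e1 + 701L; e2 <- s2 + nchar(g2) - 1L
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      start = c(s1, s2), end = c(e1, e2),
                      strand = c("+", "+"), stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("gA", "gB"),
                      transcript_id = c("gA_T01", "gB_T01"),
                      chrom = "chr1", start = c(s1, s2), end = c(e1, e2),
                      strand = "+", stringsAsFactors = FALSE)
  ann <- dge_annotation(genes, exons, c(chr1 = nchar(chrom)))
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  list(genome = genome, annotation = ann)
}
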