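test_that("gene boundary extension widens and clamps correctly", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(1000L, 100L), end = c(2000L, 400L),
                      strand = "+", stringsAsFactors = FALSE)
  exons <- transform(genes, transcript_id = paste0(gene_id, "_T01"))
  ann <- dge_annotation(genes, exons, c(chr1 = 100000L))
  ext <- extend_gene_bounds(ann, 300)
  expect_equal(ext$start, c(700L, 1L))      # g2 clamped at chromosome start
  expect_equal(ext$end, c(2300L, 700L))
  ident <- extend_gene_bounds(ann, 0)
  expect_equal(ident$start, genes$start)
  expect_equal(ident$end, genes$end)
  ## clamping at the chromosome end
  ann2 <- dge_annotation(genes, exons, c(chr1 = 2100L))
  expect_equal(extend_gene_bounds(ann2, 300)$end, c(2100L, 700L))
})

test_that("indexed matching equals the brute-force Hamming oracle", {
  set.seed(71)
  g <- random_tag(5000)
  genome <- c(chrZ = g)
  idx <- build_tag_index(genome)
  tags <- character(0)
  for (i in 1:30) {
    p <- sample(nchar(g) - 20L, 1)
    t0 <- substr(g, p, p + 20L)
    t1 <- t0
    j <- sample(21L, 1)
    substr(t1, j, j) <- sample(setdiff(c("A", "C", "G", "T"),
                                       substr(t0, j, j)), 1)
    t2 <- t1
    repeat {
      j2 <- sample(21L, 1)
      if (substr(t2, j2, j2) == substr(t0, j2, j2)) break
    }
    substr(t2, j2, j2) <- sample(setdiff(c("A", "C", "G", "T"),
                                         substr(t0, j2, j2)), 1)
    tags <- c(tags, t0, t1, t2, rc_str(t0))
  }
  tags <- unique(c(tags, replicate(80, random_tag())))
  mine <- match_tags(tags, idx)
  orc <- oracle_match_tags(tags, genome)
  expect_identical(placement_key(mine), placement_key(orc))
})

test_that("matching the reverse complement swaps strands and keeps positions", {
  set.seed(72)
  genome <- c(chr1 = random_tag(3000))
  idx <- build_tag_index(genome)
  for (i in 1:20) {
    p <- sample(2980L, 1)
    tag <- substr(genome[["chr1"]], p, p + 20L)
    fwd <- match_tag(tag, idx)
    rev <- match_tag(rc_str(tag), idx)
    expect_equal(sort(fwd$pos), sort(rev$pos))
    expect_identical(sort(fwd$pos[fwd$strand == "+"]),
                     sort(rev$pos[rev$strand == "-"]))
  }
})

test_that("single-tag matching honours the mismatch bound and input guards", {
  set.seed(73)
  g <- random_tag(1000)
  idx <- build_tag_index(c(c1 = g))
  p <- 333L
  tag <- substr(g, p, p + 20L)
  hit <- match_tag(tag, idx)
  expect_true(any(hit$pos == p & hit$strand == "+" & hit$mismatch == 0))
  tag1 <- tag
  substr(tag1, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(tag, 5, 5))[1]
  hit1 <- match_tag(tag1, idx)
  expect_true(any(hit1$pos == p & hit1$mismatch == 1))
  ## N-containing tags yield no placements; length is enforced
  expect_equal(nrow(match_tag("CATGNNNNNNNNNNNNNNNNN", idx)), 0L)
  expect_error(match_tag("CATG", idx), "21 nt")
})

test_that("best-only mode suppresses 1-mismatch hits when an exact hit exists", {
  ## genome contains the tag exactly once and a 1-mismatch copy elsewhere
  set.seed(74)
  tag <- random_tag()
  near <- tag
  substr(near, 11, 11) <- setdiff(c("A", "C", "G", "T"), substr(tag, 11, 11))[1]
  g <- paste0(random_tag(100), tag, random_tag(100), near, random_tag(100))
  idx <- build_tag_index(c(c1 = g))
  all_hits <- match_tag(tag, idx)
  best <- match_tag(tag, idx, best_only = TRUE)
  expect_gt(nrow(all_hits), nrow(best))
  expect_true(all(best$mismatch == 0))
})

test_that("the transcript tag set enumerates CATG-anchored 21-mers of spliced mRNA", {
  toy <- make_toy_locus()
  tts <- build_transcript_tag_set(toy$annotation, toy$genome)
  expect_true(all(startsWith(tts$tag, "CATG")))
  ## single-exon genes: the set equals genomic sense-strand CATG 21-mers
  tx <- splice_transcripts(toy$annotation, toy$genome)
  for (i in seq_along(tx)) {
    s <- tx[[i]]
    m <- gregexpr("CATG", s, fixed = TRUE)[[1L]]
    m <- m[m != -1L & m <= nchar(s) - 20L]
    want <- sort(unique(substring(s, m, m + 20L)))
    got <- sort(tts$tag[tts$transcript_id == names(tx)[i]])
    expect_identical(got, want)
  }
})

test_that("junction-spanning tags live in the transcript set but not the genome", {
  cfg <- sim_config(n_genes = 15, junction_fraction = 1, seed = 77,
                    groups = c("cob_ON", "floret_ON"),
                    replicates_per_group = 1)
  gen <- generate_genome(cfg)
  truth <- assign_expression_truth(gen$annotation, cfg, gen$genome)
  idx <- build_tag_index(gen$genome)
  tts <- build_transcript_tag_set(gen$annotation, gen$genome)
  expect_true(all(truth$tag %in% tts$tag))
  placed <- match_tags(truth$tag, idx)
  expect_equal(nrow(placed), 0L)
})

test_that("transcripts without a usable CATG contribute no tag keys", {
  chrom <- paste0(strrep("A", 50), "CATG", strrep("A", 5))  # < 17 nt downstream
  genes <- data.frame(gene_id = "g1", chrom = "c1", start = 1L,
                      end = nchar(chrom), strand = "+",
                      stringsAsFactors = FALSE)
  exons <- transform(genes, transcript_id = "g1_T01")
  ann <- dge_annotation(genes, exons, c(c1 = nchar(chrom)))
  tts <- build_transcript_tag_set(ann, c(c1 = chrom))
  expect_equal(nrow(tts), 0L)
})

test_that("annotation written as GFF3 reads back identically", {
  cfg <- tiny_config(seed = 12, n_genes = 20)
  gen <- generate_genome(cfg)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(gen$annotation, path)
  back <- read_annotation(path, genome = gen$genome)
  expect_equal(back$genes[order(back$genes$gene_id), ],
               gen$annotation$genes[order(gen$annotation$genes$gene_id), ],
               ignore_attr = TRUE)
  o1 <- order(back$exons$gene_id, back$exons$start)
  o2 <- order(gen$annotation$exons$gene_id, gen$annotation$exons$start)
  expect_equal(back$exons[o1, ], gen$annotation$exons[o2, ],
               ignore_attr = TRUE)
})
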