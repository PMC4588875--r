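## A hand-built locus where the multiplicity of each tag is known exactly.
make_multi_gene_fixture <- function() {
  set.seed(505)
  shared2 <- paste0("CATG", random_tag(17))   # planted in genes 1 and 2
  shared4 <- paste0("CATG", random_tag(17))   # planted in genes 3-6
  uniq <- paste0("CATG", random_tag(17))      # only in gene 1
  inter <- paste0("CATG", random_tag(17))     # intergenic only
  gap <- function() random_tag(800)           # > extension, keeps genes apart
  body <- function(...) paste0(...)
  bodies <- list(body(random_tag(30), uniq, random_tag(20), shared2,
                      random_tag(30)),
                 body(random_tag(40), shared2, random_tag(40)),
                 body(random_tag(35), shared4, random_tag(35)),
                 body(random_tag(35), shared4, random_tag(35)),
                 body(random_tag(35), shared4, random_tag(35)),
                 body(random_tag(35), shared4, random_tag(35)))
  segs <- c(gap())
  genes <- list(); exons <- list(); cursor <- nchar(segs[1])
  for (i in seq_along(bodies)) {
    s <- cursor + 1L; e <- cursor + nchar(bodies[[i]])
    gid <- paste0("g", i)
    genes[[i]] <- data.frame(gene_id = gid, chrom = "chr1", start = s,
                             end = e, strand = "+", stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(gene_id = gid, transcript_id = paste0(gid, "_T"),
                             chrom = "chr1", start = s, end = e,
                             strand = "+", stringsAsFactors = FALSE)
    segs <- c(segs, bodies[[i]], gap())
    cursor <- e + 800L
  }
  chrom <- paste(segs, collapse = "")
  ann <- dge_annotation(do.call(rbind, genes), do.call(rbind, exons),
                        c(chr1 = nchar(chrom)))
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  list(genome = genome, annotation = ann, tags = list(
    uniq = uniq, shared2 = shared2, shared4 = shared4, inter = inter))
}

test_that("tags are assigned with equal fractions and the >3-gene rule", {
  fx <- make_multi_gene_fixture()
  idx <- build_tag_index(fx$genome)
  ext <- extend_gene_bounds(fx$annotation, 300)
  tts <- build_transcript_tag_set(fx$annotation, fx$genome)
  absent <- paste0("CATG", strrep("AC", 8), "A")
  counts <- setNames(c(10L, 6L, 8L, 4L),
                     c(fx$tags$uniq, fx$tags$shared2, fx$tags$shared4,
                       absent))
  tab <- clean_tag_table("fx", counts, sum(counts))
  asn <- assign_tags(tab, idx, ext, tts)
  row <- function(tg) asn[asn$tag == tg, ]

  u <- row(fx$tags$uniq)
  expect_equal(u$status, "assigned")
  expect_equal(u$genes[[1]], "g1")
  expect_equal(u$fraction, 1)

  s2 <- row(fx$tags$shared2)
  expect_equal(s2$genes[[1]], c("g1", "g2"))
  expect_equal(s2$fraction, 0.5)

  s4 <- row(fx$tags$shared4)
  expect_equal(s4$status, "dropped_too_many_genes")
  expect_equal(row(absent)$status, "unmapped")

  ## conservation: clean total = assigned + dropped + unmapped, exactly
  sm <- assignment_summary(asn)
  expect_identical(sm$total_clean_reads,
                   sm$assigned + sm$dropped_too_many_genes + sm$unmapped)
  ## per-tag fractions sum to one
  ok <- asn$status == "assigned"
  expect_true(all(abs(asn$fraction[ok] * asn$n_genes[ok] - 1) < 1e-9))
})

test_that("quantification sums fractional tag counts per gene", {
  fx <- make_multi_gene_fixture()
  idx <- build_tag_index(fx$genome)
  ext <- extend_gene_bounds(fx$annotation, 300)
  tts <- build_transcript_tag_set(fx$annotation, fx$genome)
  counts <- setNames(c(10L, 6L), c(fx$tags$uniq, fx$tags$shared2))
  asn <- assign_tags(clean_tag_table("L1", counts, 16), idx, ext, tts)
  empty <- assign_tags(clean_tag_table("L2", setNames(integer(0),
                                                      character(0)), 0),
                       idx, ext, tts)
  m <- quantify_genes(list(L1 = asn, L2 = empty),
                      fx$annotation$genes$gene_id)
  expect_equal(m["g1", "L1"], 10 + 6 * 0.5)   # 13: full tag + half of shared
  expect_equal(m["g2", "L1"], 3)
  expect_equal(unname(m["g3", "L1"]), 0)
  expect_true(all(m[, "L2"] == 0))
})

test_that("TPTM is count over denominator times ten million", {
  m <- matrix(c(5, 0, 20, 10), 2, 2,
              dimnames = list(c("gA", "gB"), c("L1", "L2")))
  tptm <- tptm_normalize(m, denominators = c(1e4, 2e4))
  expect_equal(tptm["gA", "L1"], 5000)
  expect_equal(tptm["gB", "L1"], 0)
  ## scale invariance
  tptm2 <- tptm_normalize(2 * m, denominators = 2 * c(1e4, 2e4))
  expect_equal(unclass(tptm2), unclass(tptm), ignore_attr = TRUE)
  expect_error(tptm_normalize(m, denominators = c(0, 1e4)), "L1")
})

test_that("preferential expression needs >= 10 TPTM in one group and zero in the other", {
  design <- data.frame(sample = c("a1", "a2", "b1", "b2"),
                       group = c("A", "A", "B", "B"))
  den <- c(a1 = 5e6, a2 = 5e6, b1 = 5e6, b2 = 5e6)
  m <- rbind(called = c(8, 4, 0, 0),     # group TPTM A = 12, B = 0
             below = c(5, 4, 0, 0),      # A = 9 -> not called
             leaky = c(8, 4, 0.4, 0))    # B > 0 -> not called
  colnames(m) <- design$sample
  got <- call_preferential(m, design, c("A", "B"), denominators = den)
  expect_identical(got$gene, "called")
  expect_identical(got$direction, "A")
  ## the strict per-replicate mode also requires every replicate >= 10
  m2 <- rbind(pooled_only = c(11, 1, 0, 0),  # pooled 12, replicate 2 below
              both = c(11, 10, 0, 0))
  colnames(m2) <- design$sample
  strict <- call_preferential(m2, design, c("A", "B"), denominators = den,
                              per_replicate = TRUE)
  expect_identical(strict$gene, "both")
  loose <- call_preferential(m2, design, c("A", "B"), denominators = den)
  expect_setequal(loose$gene, c("pooled_only", "both"))
})

test_that("no-noise synthetic data is quantified back to truth counts", {
  cfg <- tiny_config(error_rate = 0, dispersion = 0, seed = 14,
                     library_depth = 2e4, junction_fraction = 0.2)
  gen <- generate_genome(cfg)
  truth <- assign_expression_truth(gen$annotation, cfg, gen$genome)
  idx <- build_tag_index(gen$genome)
  ext <- extend_gene_bounds(gen$annotation, 300)
  tts <- build_transcript_tag_set(gen$annotation, gen$genome)
  lib <- simulate_library(gen$genome, truth, "cob_ON", cfg)
  tab <- extract_clean_tags(lib$reads, cfg$adapter_seq, library_id = "L1")
  asn <- assign_tags(tab, idx, ext, tts)
  m <- quantify_genes(list(L1 = asn), truth$gene_id)
  unique_tags <- asn$tag[asn$status == "assigned" & asn$n_genes == 1]
  uniq_genes <- truth$gene_id[truth$tag %in% unique_tags]
  expect_gt(length(uniq_genes), 0)
  expect_equal(unname(m[uniq_genes, "L1"]),
               unname(lib$counts[uniq_genes]))
})

test_that("enlarging the extension only moves tags from unmapped to assigned", {
  cfg <- tiny_config(seed = 15, library_depth = 1e4)
  gen <- generate_genome(cfg)
  truth <- assign_expression_truth(gen$annotation, cfg, gen$genome)
  idx <- build_tag_index(gen$genome)
  tts <- build_transcript_tag_set(gen$annotation, gen$genome)
  lib <- simulate_library(gen$genome, truth, "cob_ON", cfg)
  tab <- extract_clean_tags(lib$reads, cfg$adapter_seq, library_id = "L1")
  ## Wider bounds can only recruit tags (unmapped -> assigned) or spread an
  ## already-assigned tag over more genes; the per-library assigned mass and
  ## the per-gene contributing tag sets are therefore non-decreasing, even
  ## though a single gene's fractional count may shrink when a neighbour
  ## starts sharing one of its tags.
  prev_mass <- -Inf
  prev_tags <- NULL
  for (e in c(0, 100, 300, 600)) {
    ext <- extend_gene_bounds(gen$annotation, e)
    asn <- assign_tags(tab, idx, ext, tts)
    mass <- sum(asn$count[asn$status == "assigned"])
    expect_gte(mass, prev_mass)
    ok <- asn$status == "assigned"
    tag_sets <- split(rep(asn$tag[ok], asn$n_genes[ok]),
                      unlist(asn$genes[ok]))
    if (!is.null(prev_tags)) {
      for (g in names(prev_tags)) {
        expect_true(all(prev_tags[[g]] %in% tag_sets[[g]]), label = g)
      }
    }
    prev_mass <- mass
    prev_tags <- tag_sets
  }
})
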