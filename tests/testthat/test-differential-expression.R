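test_that("TMM factors are unity for identical or size-scaled libraries", {
  set.seed(41)
  a <- rnbinom(500, mu = 40, size = 5) + 1
  expect_equal(unname(tmm_factors(cbind(a, a))), c(1, 1))
  expect_equal(unname(tmm_factors(cbind(a, 2 * a))), c(1, 1))
})

test_that("TMM handles composition shifts and matches an independent implementation", {
  skip_if_not_installed("edgeR")
  set.seed(42)
  counts <- matrix(rnbinom(3000, mu = 50, size = 5), ncol = 3)
  counts[1, 2] <- 60000                      # dominant transcript in library 2
  mine <- tmm_factors(counts)
  oracle <- edgeR::calcNormFactors(edgeR::DGEList(counts))$samples$norm.factors
  expect_lt(unname(mine[2]), 1)
  expect_equal(unname(mine), oracle, tolerance = 1e-6)
  expect_equal(exp(mean(log(mine))), 1)
  expect_error(tmm_factors(cbind(counts[, 1], 0 * counts[, 1])), "all-zero")
})

test_that("the conditional exact test agrees with direct enumeration", {
  cases <- expand.grid(a = c(0, 1, 3, 5, 10, 17), b = c(0, 2, 5, 10, 20),
                       phi = c(0, 0.05, 0.5))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      expect_equal(exact_nb_pvalue(a, b, 3, 3, phi),
                   oracle_cond_pvalue(a, b, 3, 3, phi), tolerance = 1e-12)
      expect_equal(exact_nb_pvalue(a, b, 1, 2, phi),
                   oracle_cond_pvalue(a, b, 1, 2, phi), tolerance = 1e-12)
    })
  }
  ## symmetric split at the mode has p = 1; empty data is vacuous
  expect_equal(exact_nb_pvalue(5, 5, 1, 1, 0), 1)
  expect_equal(exact_nb_pvalue(0, 0, 3, 3, 0.1), 1)
  ## extreme split, one library per group, Poisson limit
  expect_equal(exact_nb_pvalue(0, 10, 1, 1, 0),
               oracle_cond_pvalue(0, 10, 1, 1, 0))
  expect_error(exact_nb_pvalue(-1, 5, 1, 1, 0), "non-negative")
})

test_that("the doubling variant doubles the smaller conditional tail", {
  p <- exact_nb_pvalue(2, 10, 1, 1, 0, method = "doubling")
  lo <- sum(dbinom(0:2, 12, 0.5))
  expect_equal(p, 2 * lo)
})

test_that("swapping group labels preserves p and negates the fold change", {
  cfg <- tiny_config(seed = 16, library_depth = 2e4, replicates_per_group = 3)
  gen <- generate_genome(cfg)
  truth <- assign_expression_truth(gen$annotation, cfg)
  sim <- simulate_count_matrix(truth, cfg)
  fwd <- de_analysis(sim$counts, sim$design, cfg$contrast, dispersion = 0.1)
  rev <- de_analysis(sim$counts, sim$design, rev(cfg$contrast),
                     dispersion = 0.1)
  expect_equal(fwd$pvalue, rev$pvalue)
  expect_equal(fwd$log2fc, -rev$log2fc)
})

test_that("BH adjustment reproduces the step-up closed forms", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(43)
  p <- runif(100)
  perm <- sample(100)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("DE calls require both the FDR and fold-change gates", {
  res <- data.frame(fdr = c(0.01, 0.01, 0.06, 0.01),
                    log2fc = c(2, 0.5, 3, -1.5))
  got <- call_de(res, de_settings())$call
  expect_identical(got, c("up", "ns", "ns", "down"))
})

test_that("condition-specific genes follow the opposite-or-silent rule", {
  mk <- function(p, lfc) data.frame(gene = c("g1", "g2", "g3"),
                                    log2fc = lfc, pvalue = p,
                                    stringsAsFactors = FALSE)
  ln <- mk(c(0.005, 0.005, 0.005), c(1.2, 1.2, 1.2))
  lp <- mk(c(0.5, 0.001, 0.001), c(0.1, 1.4, -1.0))
  lk <- mk(c(0.8, 0.2, 0.2), c(-0.2, 0.3, 0.3))
  got <- ln_specific_genes(ln, lp, lk)
  ## g1: quiet in both refs; g2: same-direction response in LP -> excluded;
  ## g3: opposite in LP, quiet in LK -> included
  expect_setequal(got$gene, c("g1", "g3"))
  expect_identical(unique(got$direction), "up")
  bad <- mk(c(0.5, 0.5, 0.5), c(0, 0, 0)); bad$gene <- c("g1", "g2", "gX")
  expect_error(ln_specific_genes(ln, bad, lk), "universes")
})

test_that("Venn partitioning is plain set arithmetic per direction", {
  a <- data.frame(gene = c("a", "b", "c", "z"),
                  direction = c("up", "up", "up", "down"))
  b <- data.frame(gene = c("b", "c", "d"), direction = "up")
  got <- venn_partition(a, b)
  expect_equal(got[got$direction == "up", c("a_only", "shared", "b_only")],
               data.frame(a_only = 1L, shared = 2L, b_only = 1L),
               ignore_attr = TRUE)
  expect_equal(got[got$direction == "down", ]$a_only, 1L)
  same <- venn_partition(b, b)
  expect_equal(same[same$direction == "up", ]$shared, 3L)
  expect_equal(same[same$direction == "up", ]$a_only, 0L)
})

test_that("dispersion estimation returns zero for replicate-identical counts", {
  y <- matrix(rep(c(7, 7, 7), 5), ncol = 3, byrow = TRUE)
  est <- estimate_common_dispersion(y, c("A", "A", "A"),
                                    eff_sizes = c(1, 1, 1))
  expect_equal(est$phi, 0)
  expect_error(estimate_common_dispersion(y, c("A", "B", "C")),
               "replicates")
})

test_that("calls are invariant to a tenfold rescaling of counts and sizes", {
  cfg <- tiny_config(seed = 17, library_depth = 2e4, replicates_per_group = 3,
                     de_fraction = 0.2)
  gen <- generate_genome(cfg)
  truth <- assign_expression_truth(gen$annotation, cfg)
  sim <- simulate_count_matrix(truth, cfg)
  base <- de_analysis(sim$counts, sim$design, cfg$contrast, dispersion = 0.1)
  scaled <- de_analysis(sim$counts * 10, sim$design, cfg$contrast,
                        dispersion = 0.1,
                        lib_sizes = colSums(sim$counts) * 10)
  expect_identical(base$call, scaled$call)
})
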