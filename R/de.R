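## Differential expression for DGE count matrices: TMM normalization,
## conditional-ML common dispersion on equalized pseudo-counts, a
## conditional negative-binomial exact test (Poisson/binomial limit at
## phi = 0), Benjamini-Hochberg FDR, threshold-based calls, and the
## condition-specific / Venn set logic used for reporting.

#' Differential-expression settings
#'
#' @param fdr_threshold FDR cutoff for a DE call (default 0.05).
#' @param min_fold minimum fold change for a DE call (default 2).
#' @param ln_specific_p p-value threshold for the condition-specific rule
#'   (default 0.01).
#' @param trim_m,trim_a TMM two-sided trim fractions for M and A values.
#' @param pseudo_fraction prior added to group means when reporting fold
#'   changes, expressed per million of the common library size
#'   (default 0.5).
#' @param two_sided how two-sided exact p-values are formed:
#'   `"minlik"` sums all outcomes with probability at most that of the
#'   observed split; `"doubling"` doubles the smaller tail.
#' @return list of class `de_settings`.
#' @export
de_settings <- function(fdr_threshold = 0.05, min_fold = 2,
                        ln_specific_p = 0.01, trim_m = 0.30, trim_a = 0.05,
                        pseudo_fraction = 0.5,
                        two_sided = c("minlik", "doubling")) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1, min_fold >= 1,
            ln_specific_p > 0, ln_specific_p < 1,
            trim_m >= 0, trim_m < 0.5, trim_a >= 0, trim_a < 0.5,
            pseudo_fraction >= 0)
  structure(list(fdr_threshold = fdr_threshold, min_fold = min_fold,
                 ln_specific_p = ln_specific_p, trim_m = trim_m,
                 trim_a = trim_a, pseudo_fraction = pseudo_fraction,
                 two_sided = match.arg(two_sided)),
            class = "de_settings")
}

.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  o <- obs[keep]; r <- ref[keep]
  M <- log2((o / n_obs) / (r / n_ref))
  A <- (log2(o / n_obs) + log2(r / n_ref)) / 2
  v <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2) || all(v[keep2] == 0)) return(1)
  lf <- sum(M[keep2] / v[keep2]) / sum(1 / v[keep2])
  if (!is.finite(lf)) lf <- 0
  2^lf
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each library against the reference, log
#' ratios (M) and average log abundances (A) are computed on library-size
#' scaled counts over genes nonzero in both libraries, doubly trimmed
#' (`trim_m` of M, `trim_a` of A, two-sided), and combined by
#' inverse-variance (delta-method) weights.  Factors are rescaled to have
#' geometric mean one.  The reference defaults to the library whose upper
#' quartile of scaled counts is closest to the mean upper quartile.
#'
#' @param counts genes x libraries matrix (>= 2 libraries).
#' @param lib_sizes library sizes; default column sums.
#' @param ref_library reference column index or name; default chosen as
#'   above.
#' @param trim_m,trim_a two-sided trim fractions (defaults 0.30, 0.05).
#' @return named vector of normalization factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, lib_sizes = NULL, ref_library = NULL,
                        trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM requires at least two libraries")
  lib_sizes <- lib_sizes %||% colSums(counts)
  zero <- which(colSums(counts) == 0)
  if (length(zero) > 0L) {
    stop("library with all-zero counts: ",
         paste(colnames(counts)[zero] %||% zero, collapse = ", "))
  }
  f75 <- vapply(seq_len(ncol(counts)), function(k) {
    unname(quantile(counts[, k] / lib_sizes[k], 0.75))
  }, 0)
  if (is.null(ref_library)) {
    ref_library <- which.min(abs(f75 - mean(f75)))
  } else if (is.character(ref_library)) {
    ref_library <- match(ref_library, colnames(counts))
  }
  f <- vapply(seq_len(ncol(counts)), function(k) {
    if (k == ref_library) return(1)
    .tmm_pair(counts[, k], counts[, ref_library],
              lib_sizes[k], lib_sizes[ref_library], trim_m, trim_a)
  }, 0)
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Equalize libraries to a common effective size
#'
#' Linearly rescales each library's counts from its effective size
#' (library size x TMM factor) to the geometric mean of the effective
#' sizes, producing the pseudo-counts on which the dispersion estimator
#' and the exact test operate.
#'
#' @param counts genes x libraries matrix.
#' @param eff_sizes per-library effective sizes.
#' @return list with `pseudo` (matrix) and `common_size`.
#' @export
equalize_pseudo_counts <- function(counts, eff_sizes) {
  stopifnot(all(eff_sizes > 0), length(eff_sizes) == ncol(counts))
  common <- exp(mean(log(eff_sizes)))
  list(pseudo = sweep(as.matrix(counts), 2L, common / eff_sizes, "*"),
       common_size = common)
}

## Conditional log-likelihood of one group's counts given their sum, summed
## over genes.  y: genes x replicates.  At phi = 0 the NB collapses to
## Poisson and the conditional law is multinomial with equal cell
## probabilities.
cond_loglik_group <- function(y, phi) {
  n <- ncol(y)
  s <- rowSums(y)
  if (phi <= 0) {
    return(sum(lgamma(s + 1) - rowSums(lgamma(y + 1)) - s * log(n)))
  }
  r <- 1 / phi
  sum(rowSums(lgamma(y + r)) - n * lgamma(r) - rowSums(lgamma(y + 1)) -
        (lgamma(s + n * r) - lgamma(n * r) - lgamma(s + 1)))
}

#' Estimate the common negative-binomial dispersion
#'
#' Maximizes the conditional log-likelihood (conditioning on each gene's
#' within-group total, which removes the mean parameters) summed over all
#' groups with at least two replicates, on pseudo-counts equalized to a
#' common effective library size.  The search combines a log-spaced grid
#' over (0, `upper`] with golden-section refinement ([stats::optimize()]);
#' `phi = 0` is allowed and returned when the boundary dominates.
#'
#' @param counts genes x libraries matrix.
#' @param group group label per column.
#' @param eff_sizes effective library sizes; defaults to
#'   `colSums(counts) * tmm_factors(counts)`.
#' @param upper upper bound of the search interval (default 5).
#' @return list of class `dispersion_estimate`: `phi`, `method`.
#' @export
estimate_common_dispersion <- function(counts, group, eff_sizes = NULL,
                                       upper = 5) {
  counts <- as.matrix(counts)
  group <- as.character(group)
  stopifnot(length(group) == ncol(counts))
  reps <- table(group)
  if (!any(reps >= 2L)) {
    stop("no group has replicates: supply a dispersion value explicitly")
  }
  eff_sizes <- eff_sizes %||% (colSums(counts) * tmm_factors(counts))
  pseudo <- equalize_pseudo_counts(counts, eff_sizes)$pseudo
  grps <- names(reps)[reps >= 2L]
  ll <- function(phi) {
    sum(vapply(grps, function(g) {
      cond_loglik_group(pseudo[, group == g, drop = FALSE], phi)
    }, 0))
  }
  grid <- c(0, 10^seq(-4, log10(upper), length.out = 25))
  vals <- vapply(grid, ll, 0)
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  phi <- if (hi > lo) {
    opt <- optimize(ll, interval = c(lo, hi), maximum = TRUE,
                    tol = 1e-6)
    if (opt$objective > max(vals)) opt$maximum else grid[i]
  } else {
    grid[i]
  }
  if (ll(0) >= ll(phi)) phi <- 0
  structure(list(phi = phi, method = "conditional ML on pseudo-counts"),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("common dispersion phi = %.4g (%s)\n", x$phi, x$method))
  invisible(x)
}

#' Conditional exact p-value for one gene
#'
#' Conditions on the total `s = a + b` of the two group sums (of
#' equalized pseudo-counts from `n_a` and `n_b` libraries).  Under the
#' null the group-A sum follows the negative hypergeometric law induced by
#' NB(size `n_a / phi`) and NB(size `n_b / phi`) components, collapsing to
#' Binomial(`s`, `n_a / (n_a + n_b)`) when `phi = 0`.  The two-sided
#' p-value sums the probabilities of all splits at most as likely as the
#' observed one (`"minlik"`), or doubles the smaller tail (`"doubling"`).
#'
#' @param a,b observed group sums (non-negative; rounded to integers).
#' @param n_a,n_b number of libraries in each group.
#' @param phi common NB dispersion (>= 0).
#' @param method `"minlik"` (default) or `"doubling"`.
#' @return p-value in (0, 1].
#' @export
exact_nb_pvalue <- function(a, b, n_a, n_b, phi,
                            method = c("minlik", "doubling")) {
  method <- match.arg(method)
  if (a < 0 || b < 0) stop("counts must be non-negative")
  a <- round(a); b <- round(b)
  s <- a + b
  if (s == 0) return(1)
  x <- 0:s
  prop <- n_a / (n_a + n_b)
  if (phi <= 0) {
    lp <- dbinom(x, s, prop, log = TRUE)
  } else {
    mu_a <- s * prop
    lp <- dnbinom(x, size = n_a / phi, mu = mu_a, log = TRUE) +
      dnbinom(s - x, size = n_b / phi, mu = s - mu_a, log = TRUE)
    lp <- lp - logsumexp(lp)
  }
  if (method == "minlik") {
    p <- sum(exp(lp[lp <= lp[a + 1L] + 1e-9]))
  } else {
    p <- 2 * min(sum(exp(lp[x <= a])), sum(exp(lp[x >= a])))
  }
  min(p, 1)
}

#' Negative-binomial exact test per gene
#'
#' Scales both groups' counts to a common effective library size (rounded
#' pseudo-counts), sums within groups, and applies [exact_nb_pvalue()] to
#' each gene.
#'
#' @param counts_a,counts_b genes x replicates matrices for the two groups.
#' @param effective_lib_sizes effective sizes for the columns of
#'   `cbind(counts_a, counts_b)`.
#' @param phi common dispersion.
#' @param method two-sided rule, see [exact_nb_pvalue()].
#' @return numeric vector of p-values, one per gene.
#' @export
nb_exact_test <- function(counts_a, counts_b, effective_lib_sizes, phi,
                          method = c("minlik", "doubling")) {
  method <- match.arg(method)
  counts_a <- as.matrix(counts_a)
  counts_b <- as.matrix(counts_b)
  if (any(counts_a < 0) || any(counts_b < 0)) {
    stop("counts must be non-negative")
  }
  n_a <- ncol(counts_a); n_b <- ncol(counts_b)
  stopifnot(length(effective_lib_sizes) == n_a + n_b)
  eq <- equalize_pseudo_counts(cbind(counts_a, counts_b),
                               effective_lib_sizes)
  a <- round(rowSums(eq$pseudo[, seq_len(n_a), drop = FALSE]))
  b <- round(rowSums(eq$pseudo[, n_a + seq_len(n_b), drop = FALSE]))
  vapply(seq_along(a), function(i) {
    exact_nb_pvalue(a[i], b[i], n_a, n_b, phi, method = method)
  }, 0)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment across genes (or terms), via
#' [stats::p.adjust()].
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of FDR-adjusted values.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Apply DE call thresholds
#'
#' A gene is called `up` if FDR < `fdr_threshold` and log2 fold change
#' >= log2(`min_fold`); `down` with the opposite sign; `ns` otherwise.
#'
#' @param results data frame with columns `fdr` and `log2fc`.
#' @param settings a [de_settings()].
#' @return `results` with a `call` column added (up / down / ns).
#' @export
call_de <- function(results, settings = de_settings()) {
  lf <- log2(settings$min_fold)
  sig <- results$fdr < settings$fdr_threshold
  results$call <- ifelse(sig & results$log2fc >= lf, "up",
                         ifelse(sig & results$log2fc <= -lf, "down", "ns"))
  results
}

#' Differential expression for one contrast
#'
#' Runs the full DE stack on a count matrix: TMM factors over all
#' libraries, common-dispersion estimation across all replicated groups,
#' the conditional NB exact test on the contrast's two groups, BH
#' adjustment, fold changes on equalized group means with the configured
#' pseudo-fraction, and threshold calls.
#'
#' @param counts genes x libraries matrix (rownames = genes).
#' @param design data frame with columns `sample`, `group` matching the
#'   columns of `counts`.
#' @param contrast length-2 character vector `(A, B)`; fold changes and
#'   calls are B relative to A.
#' @param settings a [de_settings()].
#' @param lib_sizes library sizes (default: clean-read totals carried by
#'   the count matrix, then column sums).
#' @param dispersion optional fixed dispersion; estimated when NULL.
#' @return data frame of class `de_result`: gene, cpm_a, cpm_b, log2fc,
#'   pvalue, fdr, call; attributes carry the contrast, dispersion and TMM
#'   factors.
#' @export
de_analysis <- function(counts, design, contrast,
                        settings = de_settings(), lib_sizes = NULL,
                        dispersion = NULL) {
  stopifnot(length(contrast) == 2, all(contrast %in% design$group))
  lib_sizes <- lib_sizes %||% attr(counts, "lib_sizes")
  counts <- as.matrix(unclass(counts))
  if (is.null(colnames(counts))) colnames(counts) <- design$sample
  stopifnot(identical(colnames(counts), design$sample))
  lib_sizes <- lib_sizes %||% colSums(counts)
  lib_sizes <- as.numeric(lib_sizes)
  factors <- tmm_factors(counts, lib_sizes,
                         trim_m = settings$trim_m, trim_a = settings$trim_a)
  eff <- lib_sizes * factors
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(counts, design$group, eff)$phi
  }
  cols_a <- which(design$group == contrast[1L])
  cols_b <- which(design$group == contrast[2L])
  p <- nb_exact_test(counts[, cols_a, drop = FALSE],
                     counts[, cols_b, drop = FALSE],
                     eff[c(cols_a, cols_b)], dispersion,
                     method = settings$two_sided)
  eq <- equalize_pseudo_counts(counts[, c(cols_a, cols_b), drop = FALSE],
                               eff[c(cols_a, cols_b)])
  mu_a <- rowMeans(eq$pseudo[, seq_along(cols_a), drop = FALSE])
  mu_b <- rowMeans(eq$pseudo[, length(cols_a) + seq_along(cols_b),
                             drop = FALSE])
  prior <- settings$pseudo_fraction * eq$common_size / 1e6
  res <- data.frame(gene = rownames(counts),
                    cpm_a = mu_a / eq$common_size * 1e6,
                    cpm_b = mu_b / eq$common_size * 1e6,
                    log2fc = log2((mu_b + prior) / (mu_a + prior)),
                    pvalue = p,
                    fdr = bh_adjust(p),
                    stringsAsFactors = FALSE)
  res <- call_de(res, settings)
  rownames(res) <- NULL
  structure(res, class = c("de_result", "data.frame"),
            contrast = contrast, dispersion = dispersion,
            tmm_factors = factors, common_size = eq$common_size)
}

#' Genes specifically responsive to one condition
#'
#' A gene responds specifically to the focal condition (e.g. low nitrogen)
#' if it is significantly differential there (`pvalue < p_threshold`) and,
#' in each of the two reference conditions (e.g. low phosphorus, low
#' potassium), is either not differential at that threshold or changes in
#' the opposite direction.
#'
#' @param de_focal,de_ref1,de_ref2 `de_result` tables over the same gene
#'   universe.
#' @param p_threshold p-value threshold (default 0.01).
#' @return data frame with columns `gene`, `direction` of the focal
#'   response.
#' @export
ln_specific_genes <- function(de_focal, de_ref1, de_ref2,
                              p_threshold = 0.01) {
  for (o in list(de_ref1, de_ref2)) {
    if (!identical(sort(o$gene), sort(de_focal$gene))) {
      stop("mismatched gene universes between contrast tables")
    }
  }
  r1 <- de_ref1[match(de_focal$gene, de_ref1$gene), ]
  r2 <- de_ref2[match(de_focal$gene, de_ref2$gene), ]
  s <- sign(de_focal$log2fc)
  ok <- function(o) o$pvalue >= p_threshold | sign(o$log2fc) == -s
  keep <- de_focal$pvalue < p_threshold & ok(r1) & ok(r2)
  data.frame(gene = de_focal$gene[keep],
             direction = ifelse(s[keep] > 0, "up", "down"),
             stringsAsFactors = FALSE)
}

de_gene_list <- function(x) {
  if (inherits(x, "de_result")) {
    x <- data.frame(gene = x$gene[x$call != "ns"],
                    direction = x$call[x$call != "ns"],
                    stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "direction") %in% names(x)))
  x
}

#' Venn partition of two DE gene lists
#'
#' Counts, per direction, the genes exclusive to each list and shared
#' between them.
#'
#' @param list_a,list_b `de_result` tables (non-`ns` calls are used) or
#'   data frames with columns `gene`, `direction`.
#' @param directions directions to partition (default up and down).
#' @return data frame with columns `direction`, `a_only`, `shared`,
#'   `b_only`.
#' @export
venn_partition <- function(list_a, list_b, directions = c("up", "down")) {
  a <- de_gene_list(list_a)
  b <- de_gene_list(list_b)
  out <- lapply(directions, function(d) {
    ga <- unique(a$gene[a$direction == d])
    gb <- unique(b$gene[b$direction == d])
    data.frame(direction = d,
               a_only = length(setdiff(ga, gb)),
               shared = length(intersect(ga, gb)),
               b_only = length(setdiff(gb, ga)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
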