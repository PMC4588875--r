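## Classic Fisher (hypergeometric) term enrichment of a study gene set
## against a population.  No term-graph propagation: annotations are taken
## as given (pre-propagated input), and only over-representation is tested.

#' Fisher-test term enrichment
#'
#' For each term with at least one annotated gene in the population, tests
#' over-representation of the term among the study genes with the upper
#' hypergeometric tail `P[X >= k]` for a draw of `n` study genes from a
#' population of `N` containing `K` term members, followed by BH adjustment
#' across tested terms.
#'
#' @param study character vector of study genes (must be a subset of
#'   `population`).
#' @param population character vector of population (universe) genes.
#' @param terms data frame with columns `term`, `gene` and optionally
#'   `label`; annotations outside the population are ignored.
#' @param min_term_size skip terms with fewer population members.
#' @return data frame of class `enrichment_result`, ordered by p-value:
#'   term, label, study_hits (k), study_size (n), pop_hits (K), pop_size
#'   (N), fold_enrichment, pvalue, fdr.
#' @export
fisher_enrichment <- function(study, population, terms, min_term_size = 1) {
  study <- unique(study)
  population <- unique(population)
  extra <- setdiff(study, population)
  if (length(extra) > 0L) {
    stop("study genes missing from the population: ",
         paste(utils::head(extra, 10L), collapse = ", "))
  }
  stopifnot(all(c("term", "gene") %in% names(terms)))
  terms <- terms[terms$gene %in% population, , drop = FALSE]
  terms <- unique(terms[, intersect(c("term", "gene", "label"),
                                    names(terms)), drop = FALSE])
  N <- length(population)
  n <- length(study)
  by_term <- split(terms$gene, terms$term)
  labels <- if ("label" %in% names(terms)) {
    vapply(split(terms$label, terms$term), `[`, "", 1L)
  } else {
    setNames(names(by_term), names(by_term))
  }
  rows <- lapply(names(by_term), function(tm) {
    genes <- unique(by_term[[tm]])
    K <- length(genes)
    if (K < min_term_size) return(NULL)
    k <- length(intersect(genes, study))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, label = unname(labels[tm]), study_hits = k,
               study_size = n, pop_hits = K, pop_size = N,
               fold_enrichment = (k / n) / (K / N),
               pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), label = character(0),
                      study_hits = integer(0), study_size = integer(0),
                      pop_hits = integer(0), pop_size = integer(0),
                      fold_enrichment = numeric(0), pvalue = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out$fdr <- bh_adjust(out$pvalue)
  out <- out[order(out$pvalue, out$term), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}
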