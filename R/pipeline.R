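## End-to-end orchestration: extract -> index -> assign -> quantify -> TPTM
## -> DE -> preferential -> Venn -> condition-specific -> enrichment, with
## every table exported as headered TSV and a machine-readable YAML run
## manifest.  Progress is logged to stderr; stdout is left untouched.

parse_contrast <- function(x) {
  ## "B:A" reads as "B versus A": fold changes are B relative to A
  parts <- strsplit(x, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop("contrast must be of the form 'B:A': ", x)
  c(parts[2L], parts[1L])
}

#' Pipeline configuration
#'
#' Collects paths and per-stage settings for [run_pipeline()].  Contrasts
#' are written `"B:A"` (B versus A), e.g. `"cob_LN:cob_ON"` for the low-
#' versus optimal-nitrogen response in the cob.
#'
#' @param genome path to the reference FASTA.
#' @param annotation path to the gene annotation GFF3.
#' @param design path to a TSV with columns `sample`, `group`, `fastq`.
#' @param outdir output directory.
#' @param adapter 3' adapter sequence.
#' @param contrasts named character vector of `"B:A"` contrasts.
#' @param terms optional path to a term-to-gene TSV (`term`, `gene`,
#'   optional `label`) enabling enrichment of each contrast's DE genes.
#' @param venn optional length-2 vector of contrast names to partition.
#' @param specific optional length-3 vector of contrast names
#'   (focal, reference1, reference2) for the condition-specific rule.
#' @param min_count clean-tag minimum count (default 2).
#' @param min_count_scope `"per_library"` (default) or `"pooled"`.
#' @param extension gene-boundary extension in nt (default 300).
#' @param min_tptm preferential-expression threshold (default 10 TPTM).
#' @param allow_no_adapter see [strip_adapter()].
#' @param settings a [de_settings()].
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic; the seed governs upstream simulation).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, annotation, design, outdir,
                            adapter, contrasts, terms = NULL, venn = NULL,
                            specific = NULL, min_count = 2,
                            min_count_scope = "per_library",
                            extension = 300, min_tptm = 10,
                            allow_no_adapter = TRUE,
                            settings = de_settings(), seed = 1) {
  for (p in c(genome, annotation, design, terms)) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  if (is.null(names(contrasts)) || any(names(contrasts) == "")) {
    names(contrasts) <- gsub(":", "_vs_", contrasts, fixed = TRUE)
  }
  if (!is.null(venn)) stopifnot(length(venn) == 2, all(venn %in% names(contrasts)))
  if (!is.null(specific)) stopifnot(length(specific) == 3,
                                    all(specific %in% names(contrasts)))
  structure(list(genome = genome, annotation = annotation, design = design,
                 outdir = outdir, adapter = adapter, contrasts = contrasts,
                 terms = terms, venn = venn, specific = specific,
                 min_count = min_count, min_count_scope = min_count_scope,
                 extension = extension, min_tptm = min_tptm,
                 allow_no_adapter = allow_no_adapter, settings = settings,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; `settings` may be a
#' mapping of [de_settings()] arguments.  Relative paths are resolved
#' against the YAML file's directory.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p)) NULL
    else ifelse(startsWith(p, "/"), p, file.path(base, p))
  }
  settings <- do.call(de_settings, y$settings %||% list())
  contrasts <- unlist(y$contrasts)
  pipeline_config(genome = rel(y$genome), annotation = rel(y$annotation),
                  design = rel(y$design), outdir = rel(y$outdir),
                  adapter = y$adapter, contrasts = contrasts,
                  terms = rel(y$terms), venn = unlist(y$venn),
                  specific = unlist(y$specific),
                  min_count = y$min_count %||% 2,
                  min_count_scope = y$min_count_scope %||% "per_library",
                  extension = y$extension %||% 300,
                  min_tptm = y$min_tptm %||% 10,
                  allow_no_adapter = y$allow_no_adapter %||% TRUE,
                  settings = settings, seed = y$seed %||% 1)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full DGE pipeline
#'
#' Executes extraction, indexing, assignment, quantification, TPTM
#' normalization, differential expression for every configured contrast,
#' preferential-expression calling, optional Venn partitioning,
#' condition-specific gene selection and term enrichment, writing every
#' table under `config$outdir` and a `manifest.yaml` with per-stage
#' tallies.  Identical inputs produce byte-identical outputs.
#'
#' @param config a [pipeline_config()] or path to its YAML file.
#' @return invisible list with the in-memory results (`counts`, `tptm`,
#'   `de`, `preferential`, `venn`, `specific`, `enrichment`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  stage_log("load", "reading genome, annotation and design")
  genome <- read_genome(config$genome)
  ann <- read_annotation(config$annotation, genome = genome)
  design <- read_tsv(config$design)
  stopifnot(all(c("sample", "group", "fastq") %in% names(design)))

  stage_log("extract", "%d libraries", nrow(design))
  fq_dir <- dirname(config$design)
  tables <- lapply(seq_len(nrow(design)), function(i) {
    fq <- design$fastq[i]
    if (!file.exists(fq)) fq <- file.path(fq_dir, fq)
    extract_clean_tags(fq, config$adapter, library_id = design$sample[i],
                       min_count = if (config$min_count_scope == "pooled")
                         1 else config$min_count,
                       allow_no_adapter = config$allow_no_adapter)
  })
  if (config$min_count_scope == "pooled") {
    tables <- apply_min_count(tables, config$min_count, scope = "pooled")
  }
  names(tables) <- design$sample
  for (nm in names(tables)) {
    write_tag_table(tables[[nm]], file.path(out, sprintf("tags_%s.tsv", nm)))
  }

  stage_log("index", "building tag index and transcript tag set")
  index <- build_tag_index(genome)
  extended <- extend_gene_bounds(ann, config$extension)
  tx_tags <- build_transcript_tag_set(ann, genome)

  stage_log("assign", "assigning tags for %d libraries", length(tables))
  assignments <- lapply(tables, function(t) {
    assign_tags(t, index, extended, tx_tags)
  })
  summary <- do.call(rbind, lapply(assignments, assignment_summary))
  rownames(summary) <- NULL
  write_tsv(summary, file.path(out, "assignment_summary.tsv"))

  stage_log("quantify", "building count and TPTM matrices")
  counts <- quantify_genes(assignments, ann$genes$gene_id)
  tptm <- tptm_normalize(counts)
  write_tsv(data.frame(gene_id = rownames(counts), unclass(counts),
                       check.names = FALSE),
            file.path(out, "counts.tsv"))
  write_tsv(data.frame(gene_id = rownames(tptm), round(tptm, 4),
                       check.names = FALSE),
            file.path(out, "tptm.tsv"))

  de <- list()
  preferential <- list()
  for (nm in names(config$contrasts)) {
    ct <- parse_contrast(config$contrasts[[nm]])
    stage_log("de", "contrast %s (%s vs %s)", nm, ct[2L], ct[1L])
    de[[nm]] <- de_analysis(counts, design[, c("sample", "group")], ct,
                            settings = config$settings)
    write_tsv(as.data.frame(de[[nm]]),
              file.path(out, sprintf("de_%s.tsv", nm)))
    pref <- call_preferential(counts, design, ct,
                              min_tptm = config$min_tptm)
    preferential[[nm]] <- pref
    write_tsv(pref, file.path(out, sprintf("preferential_%s.tsv", nm)))
  }

  venn <- NULL
  if (!is.null(config$venn)) {
    stage_log("venn", "partition %s vs %s", config$venn[1L], config$venn[2L])
    venn <- venn_partition(de[[config$venn[1L]]], de[[config$venn[2L]]])
    write_tsv(venn, file.path(out, sprintf("venn_%s_%s.tsv",
                                           config$venn[1L], config$venn[2L])))
  }

  specific <- NULL
  if (!is.null(config$specific)) {
    stage_log("specific", "condition-specific genes (focal %s)",
              config$specific[1L])
    specific <- ln_specific_genes(de[[config$specific[1L]]],
                                  de[[config$specific[2L]]],
                                  de[[config$specific[3L]]],
                                  config$settings$ln_specific_p)
    write_tsv(specific, file.path(out, "ln_specific.tsv"))
  }

  enrichment <- list()
  if (!is.null(config$terms)) {
    terms <- read_tsv(config$terms)
    for (nm in names(de)) {
      study <- de[[nm]]$gene[de[[nm]]$call != "ns"]
      if (length(study) == 0L) next
      stage_log("enrich", "contrast %s: %d DE genes", nm, length(study))
      enrichment[[nm]] <- fisher_enrichment(study, rownames(counts), terms)
      write_tsv(as.data.frame(enrichment[[nm]]),
                file.path(out, sprintf("enrichment_%s.tsv", nm)))
    }
  }

  manifest <- list(
    package = "cobdge",
    version = as.character(packageVersion("cobdge")),
    seed = config$seed,
    n_genes = nrow(counts),
    libraries = lapply(seq_len(nrow(summary)), function(i) as.list(summary[i, ])),
    contrasts = lapply(names(de), function(nm) {
      list(name = nm,
           contrast = unname(config$contrasts[[nm]]),
           dispersion = attr(de[[nm]], "dispersion"),
           n_up = sum(de[[nm]]$call == "up"),
           n_down = sum(de[[nm]]$call == "down"),
           n_preferential = nrow(preferential[[nm]]))
    }))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  stage_log("done", "results in %s", out)
  invisible(list(counts = counts, tptm = tptm, assignments = assignments,
                 summary = summary, de = de, preferential = preferential,
                 venn = venn, specific = specific, enrichment = enrichment,
                 manifest = manifest))
}

#' Relative expression by the comparative CT method
#'
#' Computes `ddCT = (CT_target,sample - CT_reference,sample) -
#' (CT_target,calibrator - CT_reference,calibrator)` and returns the
#' relative expression ratio `2^(-ddCT)` of the target gene in the sample
#' versus the calibrator, normalized to the reference gene.
#'
#' @param ct_target_sample,ct_reference_sample CT values of target and
#'   reference gene in the sample of interest.
#' @param ct_target_calibrator,ct_reference_calibrator CT values in the
#'   calibrator sample.
#' @return relative expression ratio (vectorized).
#' @export
ddct_relative_expression <- function(ct_target_sample, ct_reference_sample,
                                     ct_target_calibrator,
                                     ct_reference_calibrator) {
  cts <- cbind(ct_target_sample, ct_reference_sample,
               ct_target_calibrator, ct_reference_calibrator)
  if (any(!is.finite(cts))) stop("all CT values must be finite")
  ddct <- (ct_target_sample - ct_reference_sample) -
    (ct_target_calibrator - ct_reference_calibrator)
  2^(-ddct)
}
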