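---
title: "Methods: tag-based digital gene expression with cobdge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-based digital gene expression with cobdge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobdge)
```

## The measurement and its assumptions

Digital gene expression (DGE, a SAGE descendant) profiles a transcriptome by
counting short restriction-anchored tags instead of sequencing whole cDNAs.
The chemistry modelled here anchors at NlaIII sites: the enzyme cuts cDNA at
`CATG`, and a type-IIS enzyme (MmeI) then releases the 17 bp immediately
downstream.  Each mRNA is therefore represented by a 21-nt identifier —
`CATG` plus 17 bp — derived from the 3'-most usable `CATG` of its sequence.
Raw reads carry only the 17 sequenced bases followed by the 3' adapter; the
anchoring `CATG` is restored electronically during extraction.

The package implements this measurement end-to-end for a two-tissue,
two-nutrient-condition maize ear design (cob and florets under optimal and
low nitrogen, three replicates each), but every stage is generic over the
design table it is given.

Core assumptions: one dominant tag site per transcript (3' bias of the
chemistry), sense-strand counting, no PCR-duplicate structure, and
count noise that is negative binomial across biological replicates.

## Pipeline stages and rules

1. **Clean-tag extraction** (`strip_adapter()`, `extract_clean_tags()`).
   The 3' adapter is located by exact match of its leading 7-mer; the read
   prefix must be exactly 17 nt.  Reads whose adapter seed is not found
   (e.g. hit by a sequencing error) contribute their first 17 nt by default
   (`allow_no_adapter = TRUE`); strict rejection is available.  After
   prefixing `CATG`, tags containing any ambiguous base are discarded, and
   tags seen fewer than twice within a library are discarded.  The
   min-count rule is applied per library; a pooled variant is provided
   (`apply_min_count(scope = "pooled")`) without endorsement, since the
   per-library reading matches how such filters are usually stated.
2. **Genomic placement** (`build_tag_index()`, `match_tags()`).  Tags are
   placed on both strands of the genome allowing at most one substitution.
   The matcher is a pigeonhole scheme — a 21-mer with at most one mismatch
   must be exact over positions 1–11 or 12–21, so two trusted-band
   dictionary passes (`Biostrings::matchPDict`) enumerate all candidates,
   which are then verified.  Tests hold it set-identical to an exhaustive
   Hamming scan.  Exact hits do *not* suppress 1-mismatch hits by default
   (only the bound is specified by the protocol); `best_only = TRUE`
   enables best-stratum placement for sensitivity analysis.
3. **Junction recovery** (`build_transcript_tag_set()`).  Tags without any
   genomic placement are looked up among the CATG-anchored 21-mers of
   spliced transcripts, recovering tags that straddle exon–exon junctions.
   Recovery is deliberately restricted to genomically unplaced tags,
   mirroring the two-pass mapping order of the original protocol.
4. **Assignment** (`assign_tags()`).  A placement is attributed to every
   gene whose interval — extended by 300 nt on both sides to capture
   unannotated UTRs, clamped to the chromosome — contains the whole 21-mer
   on the same strand.  Multiple placements inside one gene count once
   (the ambiguity unit is the gene, not the placement).  Tags hitting one
   to three genes are assigned with equal fractions `1/k`; more than three
   genes drops the tag; zero genes leaves it unmapped.  Per library,
   `clean = assigned + dropped + unmapped` holds exactly.
5. **Quantification and TPTM** (`quantify_genes()`, `tptm_normalize()`).
   A gene's expression is the fractional sum of its tag counts.  TPTM
   (transcripts per ten million) is `count / denominator * 1e7`; the
   denominator is the library's total clean reads by default.  Whether
   such pipelines use clean or assigned totals is ambiguous in practice;
   both are supported and the default is documented here.
6. **Preferential expression** (`call_preferential()`).  A gene is
   preferentially expressed in a group when its group-level TPTM (summed
   counts over summed denominators across replicates) reaches 10 while the
   other group is exactly zero.  "Sample" is interpreted as the pooled
   replicate group; a stricter per-replicate mode is available.
7. **Differential expression** (`de_analysis()` and friends) — next
   section.
8. **Set logic** (`ln_specific_genes()`, `venn_partition()`).  A gene
   responds specifically to the focal stress (here low nitrogen) when it
   is differential there at `p < 0.01` while, under each reference stress
   (low phosphorus, low potassium), it is either non-differential at that
   threshold or changes in the opposite direction.  This rule uses raw
   p-values, not FDR, matching how such screens are usually thresholded.
9. **Enrichment** (`fisher_enrichment()`).  Classic one-sided
   hypergeometric over-representation per term with BH correction across
   terms.  No ontology-graph propagation or decorrelation: annotations
   must arrive pre-propagated, and only enrichment (not depletion) is
   tested.

## The statistical model

**TMM normalization.**  For library *k* against reference *r*, with
library sizes \(N_k, N_r\) and counts \(y_{gk}\),
\(M_g = \log_2\frac{y_{gk}/N_k}{y_{gr}/N_r}\) and
\(A_g = \tfrac12\log_2\frac{y_{gk}}{N_k}\cdot\frac{y_{gr}}{N_r}\) are
computed over genes nonzero in both libraries; the most extreme 30 % of
M and 5 % of A are trimmed on each side, and the factor is the
inverse-variance-weighted mean of the surviving M values (delta-method
weights \((N_k-y_{gk})/(N_k y_{gk}) + (N_r-y_{gr})/(N_r y_{gr})\)),
exponentiated and rescaled to geometric mean one.  The reference library
is the one whose 75th count percentile (scaled) is closest to the mean.

**Dispersion.**  Counts are modelled as negative binomial with variance
\(\mu + \phi\mu^2\).  A single common \(\phi\) is estimated by maximizing
the conditional log-likelihood — conditioning each gene's within-group
counts on their sum removes the gene means — summed over all replicated
groups, after libraries are equalized to a common effective size (the
geometric mean of `lib size × TMM factor`) by linear pseudo-count
scaling.  Common dispersion only: with three replicates per group there
is little information for per-gene dispersion, and the tagwise/trended
elaborations of the framework this follows are out of scope.

**Exact test.**  For a two-group contrast the equalized pseudo-counts are
summed within groups (rounded to integers).  Conditional on the total
\(s = a + b\), the group-A sum follows the distribution induced by two
negative binomials with sizes \(n_A/\phi\) and \(n_B/\phi\) and a common
success parameter — a negative hypergeometric that is free of the mean —
collapsing to Binomial\((s, n_A/(n_A+n_B))\) at \(\phi = 0\).  The
two-sided p-value sums the probabilities of all splits with probability
at most that of the observed split (the usual convention for conditional
exact tests; tail-doubling is available via
`de_settings(two_sided = "doubling")`).

**Calls.**  BH-adjusted FDR < 0.05 and at least a 2-fold change
(\(|\log_2 FC| \ge 1\)).  Fold changes are computed on equalized group
means with a pseudo-fraction of 0.5 per million of the common library
size added to both groups, so genes absent in one condition report a
finite, shrunk fold change; the 2-fold gate applies to this shrunk value
for stability at low counts.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| extension | 300 | nt | UTR capture beyond annotated gene ends |
| min tag count | 2 | reads/library | removes singleton (mostly error) tags |
| max genes per tag | 3 | genes | beyond this a tag is uninformative |
| TPTM threshold | 10 | TPTM | presence/absence calling floor |
| FDR threshold | 0.05 | — | DE significance gate |
| min fold | 2 | ratio | DE effect-size gate |
| specific-response p | 0.01 | — | focal-stress specificity screen |
| TMM trims | 0.30 / 0.05 | fraction | M / A two-sided trimming |
| pseudo-fraction | 0.5 | per million | zero-safe fold changes |
| dispersion search | [0, 5] | — | grid + golden-section refinement |

## What the simulator emulates — and what it does not

`sim_config()` / `simulate_experiment()` generate a toy chromosome of
non-overlapping, randomly stranded genes with log-normal relative
abundances (`sdlog = 1`, a realistic skew for tag libraries), a 2×2×3
group design, negative-binomial counts (`phi = 0.1` by default — a
plausible biological-replicate value chosen as a stand-in, since no
empirical dispersion accompanies the design being emulated), per-base
substitution errors (0.005), and 35-nt reads of tag + adapter.  DE genes
are planted with an exact fold-change ratio between the two contrast
groups (half up, half down, ties to up); the non-DE background of the
second group is jointly rescaled so abundances still sum to one — the
compositional shift this creates is intentional, it is exactly what TMM
exists to remove.  A configurable fraction of genes is group-exclusive
(zero abundance in one contrast group) to exercise presence/absence
calling, and a fraction receives a single intron inside the canonical tag
window so their tag spans an exon–exon junction.

The canonical tag is taken at the 3'-most `CATG` with 17 nt downstream
(the convention of the chemistry); alternative-site usage is not
simulated.  The sequenced 17-mer is kept free of the adapter's 7-nt seed
by construction, because adapter detection is sequence-based and a tag
containing the seed would be systematically truncated — a real but
pathological corner that would otherwise contaminate exact-recovery
checks.  Not modelled: PCR duplication, positional quality decay
(quality strings are flat, and no quality filtering exists in the
pipeline), paired ends, isoform mixtures, and tags spanning more than
one junction.  Passing tests therefore demonstrate correctness of the
pipeline's logic and calibration of its statistics under NB noise — not
robustness to artefacts the generator does not produce.

All randomness flows from one integer seed; per-stage sub-seeds are
derived by fixed offsets, and identical configurations yield
byte-identical FASTA/GFF3/FASTQ/TSV outputs.

## Numerical choices

* Probability ties in the exact test are compared in log space with a
  `1e-9` slack, so analytically tied outcomes (e.g. symmetric splits) are
  not separated by floating-point noise; the enumeration oracle in the
  test suite uses the same rule and agrees to `<1e-10`.
* The dispersion likelihood is evaluated at `phi = 0` via its Poisson /
  multinomial limit, so the boundary is a first-class candidate rather
  than an asymptote.
* Pseudo-counts are left unrounded for the (gamma-function) dispersion
  likelihood but rounded for the exact test, which is defined on
  integers.
* Coordinates are 1-based inclusive at every file boundary (GFF3
  convention); reverse-strand placements are reported by the plus-strand
  start of the 21-mer window.
* Genes with zero counts are carried through every table; TPTM of 0 is 0,
  and a zero denominator is an error naming the library.

## Validation scales

The shipped test-suite exercises: matcher-versus-brute-force equality on
ten random 20–50 kb genomes with 1000 tags each (planted 0/1/2-mismatch
and reverse-complement cases); exact-count recovery of a noise-free
300-gene study; exact-test calibration and power on 2000-gene, 3 + 3,
200 k-read count studies over five seeds each (null p < 0.05 fraction,
FDR-call rate, sensitivity and empirical FDR at 4-fold); dispersion
recovery over ten seeds; and full-pipeline determinism.  These sizes
were chosen as the smallest at which the binomial noise of the measured
proportions is comfortably inside the asserted bands.

## Known limitations

* The conditional-ML dispersion and exact test approximate, but do not
  numerically replicate, any particular release of the established
  count-model packages; those serve as independent cross-checks in the
  test suite (TMM factors agree to ~1e-6 on shared fixtures).
* Antisense tags, isoform-level quantification and indel-tolerant
  placement are out of scope.
* Enrichment assumes pre-propagated annotations; results on raw
  (unpropagated) ontology files will under-count ancestral terms.
* The one-mismatch matcher is exhaustive and exact but plain-text scale:
  it is designed for the toy genomes of this package's studies, not for
  a 2-Gb crop genome.
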