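## Independent brute-force oracles used to validate the package's
## implementations.  These deliberately take a different algorithmic route
## from the code under test.

random_tag <- function(n = 21) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## All Hamming<=1 neighbors of a tag (the tag itself plus every single-base
## substitution), with their mismatch count.
tag_neighborhood <- function(tag) {
  ch <- strsplit(tag, "")[[1L]]
  vars <- unlist(lapply(seq_along(ch), function(i) {
    vapply(setdiff(c("A", "C", "G", "T"), ch[i]), function(b) {
      v <- ch; v[i] <- b; paste(v, collapse = "")
    }, "")
  }))
  data.frame(kmer = c(tag, vars),
             mismatch = c(0L, rep(1L, length(vars))),
             stringsAsFactors = FALSE)
}

## Brute-force <=1-mismatch scan over both strands of a genome, by
## exhaustive neighborhood enumeration merged against the full k-mer table
## -- independent of the pigeonhole matcher.
oracle_match_tags <- function(tags, genome) {
  genome <- setNames(as.character(genome), names(genome))
  tags <- unique(tags[!grepl("[^ACGT]", tags)])
  nb <- do.call(rbind, lapply(tags, function(tg) {
    cbind(tag = tg, tag_neighborhood(tg))
  }))
  out <- list()
  for (chrom in names(genome)) {
    g <- genome[[chrom]]
    L <- nchar(g)
    if (L < 21L) next
    pos <- 1:(L - 20L)
    rcg <- rc_str(g)
    kmers <- rbind(
      data.frame(kmer = substring(g, pos, pos + 20L), pos = pos,
                 strand = "+", stringsAsFactors = FALSE),
      data.frame(kmer = substring(rcg, pos, pos + 20L), pos = L - pos - 19L,
                 strand = "-", stringsAsFactors = FALSE))
    m <- merge(nb, kmers, by = "kmer")
    if (nrow(m) == 0L) next
    key <- paste(m$tag, m$pos, m$strand)
    mm <- tapply(m$mismatch, key, min)
    first <- m[match(names(mm), key), , drop = FALSE]
    out[[chrom]] <- data.frame(tag = first$tag, chrom = chrom,
                               pos = first$pos, strand = first$strand,
                               mismatch = as.integer(mm),
                               stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(tag = character(0), chrom = character(0),
                      pos = integer(0), strand = character(0),
                      mismatch = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$tag, res$chrom, res$pos, res$strand), , drop = FALSE]
}

placement_key <- function(d) {
  sort(paste(d$tag, d$chrom, d$pos, d$strand, d$mismatch))
}

## Direct enumeration of the conditional two-sided exact p-value from the
## negative-hypergeometric law written in binomial-coefficient form
## (lchoose), normalized explicitly -- no dnbinom/dbinom involved.
oracle_cond_pvalue <- function(a, b, n_a, n_b, phi) {
  s <- a + b
  if (s == 0) return(1)
  x <- 0:s
  if (phi <= 0) {
    lw <- lchoose(s, x) + x * log(n_a) + (s - x) * log(n_b) -
      s * log(n_a + n_b)
  } else {
    r_a <- n_a / phi
    r_b <- n_b / phi
    lw <- (lgamma(x + r_a) - lgamma(r_a) - lgamma(x + 1)) +
      (lgamma(s - x + r_b) - lgamma(r_b) - lgamma(s - x + 1))
    m <- max(lw)
    lw <- lw - (m + log(sum(exp(lw - m))))
  }
  min(1, sum(exp(lw[lw <= lw[a + 1L] + 1e-9])))
}

## Direct hypergeometric upper-tail summation via choose().
oracle_hyper_p <- function(k, K, n, N) {
  x <- k:min(n, K)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

## Leftmost position of `seed` in `read` by exhaustive substring scan.
oracle_seed_pos <- function(read, seed) {
  w <- nchar(seed)
  for (p in seq_len(max(0L, nchar(read) - w + 1L))) {
    if (substr(read, p, p + w - 1L) == seed) return(p)
  }
  NA_integer_
}
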