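# Independent brute-force oracles used to cross-check the implementation.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# naive sliding-window k-mer extraction: plain substring arithmetic,
# independent of the package's rolling-code path
oracle_extract <- function(seq, k) {
  seq <- chartr("acgtuU", "ACGTTT", seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1)
  wins <- substring(seq, starts, starts + k - 1)
  wins[!grepl("[^ACGT]", wins)]
}

# naive dictionary tally across reads, thresholded
oracle_count <- function(reads, k, min_count) {
  tab <- table(unlist(lapply(reads, oracle_extract, k = k)))
  tab <- tab[tab >= min_count]
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[sort(names(out), method = "radix")]
}

# closed-form simple-regression estimates via the normal equations
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# minimal abundance-table fixture builder: counts is a kmer x sample matrix
# of raw counts (NA = absent), samples a data frame (sample_id, cohort,
# tissue, total_bp)
fixture_table <- function(counts, samples, k = 25, min_count = 10) {
  catalogs <- lapply(seq_len(nrow(samples)), function(j) {
    s <- samples[j, ]
    cts <- counts[, j]
    cts <- cts[!is.na(cts)]
    kmerscreen:::new_sample_catalog(
      sample_meta(s$sample_id, s$cohort, s$tissue, s$total_bp),
      cts, k, min_count)
  })
  build_abundance_table(catalogs)
}

# arbitrary fixed-length k-mer labels for fixtures (valid DNA 25-mers)
fixture_kmers <- function(n, k = 25) {
  stopifnot(n <= 4^k)
  kmer_decode(seq_len(n) - 1, k)
}
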