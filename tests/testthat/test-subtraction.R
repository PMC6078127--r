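test_that("normalization is count-per-billion-bp and linear", {
  expect_equal(normalize_abundance(100, 2e9), 50)
  expect_equal(normalize_abundance(0, 1e9), 0)
  expect_equal(normalize_abundance(7, 1e9), 7)
  expect_error(normalize_abundance(5, 0), "positive")
  set.seed(1)
  cts <- sample(0:1e6, 20)
  bp <- runif(20, 1e8, 1e10)
  expect_equal(normalize_abundance(cts, bp) * bp / 1e9, cts)
  expect_equal(normalize_abundance(3 * cts, bp), 3 * normalize_abundance(cts, bp))
})

make_samples <- function() {
  data.frame(
    sample_id = c("t1", "t2", "n1", "n2", "n3"),
    cohort = c("tumor", "tumor", "normal", "normal", "normal"),
    tissue = c("", "", "liver", "liver", "lung"),
    total_bp = c(2e9, 1e9, 1e9, 4e9, 2e9),
    stringsAsFactors = FALSE)
}

test_that("abundance table imputes 0 for tumor and min_count for normals", {
  kms <- fixture_kmers(3)
  counts <- matrix(NA_real_, 3, 5, dimnames = list(kms, NULL))
  counts[1, ] <- c(100, 50, 20, 80, 40)   # everywhere
  counts[2, c(1, 2)] <- c(60, 30)         # tumor-only
  counts[3, 3] <- 15                      # one normal only
  tab <- fixture_table(counts, make_samples())
  ab <- tab$abundance
  # missing normal entries -> raw 10, normalized per that sample's effort
  expect_equal(ab[kms[2], "n1"], 10 * 1e9 / 1e9)
  expect_equal(ab[kms[2], "n2"], 10 * 1e9 / 4e9)
  # missing tumor entries -> 0
  expect_equal(ab[kms[3], "t1"], 0)
  expect_equal(ab[kms[3], "t2"], 0)
  # counted entries normalize as-is
  expect_equal(ab[kms[1], "t1"], 100 * 1e9 / 2e9)
  # a k-mer counted in no sample never enters the table
  expect_false("AAAAAAAAAAAAAAAAAAAAAAAAT" %in% rownames(ab))
  expect_equal(nrow(ab), 3)
})

test_that("abundance table rejects inconsistent catalog sets", {
  kms <- fixture_kmers(1)
  samples <- make_samples()
  counts <- matrix(20, 1, 5, dimnames = list(kms, NULL))
  cats <- lapply(1:5, function(j)
    kmerscreen:::new_sample_catalog(
      sample_meta(samples$sample_id[j], samples$cohort[j], samples$tissue[j],
                  samples$total_bp[j]),
      stats::setNames(20, kms), if (j == 1) 31L else 25L, 10L))
  expect_error(build_abundance_table(cats), "mix different k")
  cats2 <- lapply(c(1, 1), function(j)
    kmerscreen:::new_sample_catalog(
      sample_meta(samples$sample_id[j], samples$cohort[j], samples$tissue[j],
                  samples$total_bp[j]),
      stats::setNames(20, kms), 25L, 10L))
  expect_error(build_abundance_table(cats2), "duplicate sample_id")
})

test_that("tissue ratio is min(tumor)/max(normal) at full precision", {
  # published worked example: three tumor and six cerebral-cortex abundances
  tum <- c(28341, 349248, 54922)
  ctx <- c(34115, 1551, 16368, 54135, 167743, 2376)
  kms <- fixture_kmers(1)
  samples <- data.frame(
    sample_id = c(paste0("t", 1:3), paste0("n", 1:6)),
    cohort = c(rep("tumor", 3), rep("normal", 6)),
    tissue = c(rep("", 3), rep("cerebral cortex", 6)),
    total_bp = 1e9, stringsAsFactors = FALSE)
  counts <- matrix(c(tum, ctx), 1, 9, dimnames = list(kms, NULL))
  tab <- fixture_table(counts, samples)
  r <- tissue_ratio(kms, tab, "cerebral cortex")
  expect_equal(r, 28341 / 167743)
  expect_equal(truncate_ratio(r), 0.16)
  expect_error(tissue_ratio(kms, tab, "spleen"), "unknown tissue")
})

test_that("tissue ratio matches a brute-force min/max oracle and is monotone", {
  set.seed(11)
  for (i in 1:20) {
    tum <- runif(5, 1, 1e5)
    nrm <- runif(8, 1, 1e5)
    kms <- fixture_kmers(1)
    samples <- data.frame(
      sample_id = c(paste0("t", 1:5), paste0("n", 1:8)),
      cohort = c(rep("tumor", 5), rep("normal", 8)),
      tissue = c(rep("", 5), rep("x", 8)),
      total_bp = 1e9, stringsAsFactors = FALSE)
    counts <- matrix(c(tum, nrm), 1, 13, dimnames = list(kms, NULL))
    tab <- fixture_table(counts, samples)
    expect_equal(tissue_ratio(kms, tab, "x"), min(tum) / max(nrm))
    # raising a non-minimal tumor abundance leaves the ratio unchanged;
    # raising the normal maximum strictly lowers it
    j <- which.max(tum)
    counts2 <- counts; counts2[1, j] <- counts2[1, j] * 10
    expect_equal(tissue_ratio(kms, fixture_table(counts2, samples), "x"),
                 min(tum) / max(nrm))
    jm <- 5 + which.max(nrm)
    counts3 <- counts; counts3[1, jm] <- counts3[1, jm] * 2
    expect_lt(tissue_ratio(kms, fixture_table(counts3, samples), "x"),
              min(tum) / max(nrm))
  }
  # equal single tumor and normal abundance -> ratio 1
  kms <- fixture_kmers(1)
  samples <- data.frame(sample_id = c("t", "n"), cohort = c("tumor", "normal"),
                        tissue = c("", "x"), total_bp = 1e9,
                        stringsAsFactors = FALSE)
  counts <- matrix(c(77, 77), 1, 2, dimnames = list(kms, NULL))
  expect_equal(tissue_ratio(kms, fixture_table(counts, samples), "x"), 1)
})

# five tissues, one normal sample each, equal effort: a k-mer's ratio per
# tissue is tumor_count / normal_count
five_tissue_fixture <- function(tumor_count, normal_counts) {
  kms <- fixture_kmers(1)
  n <- length(normal_counts)
  samples <- data.frame(
    sample_id = c("t1", paste0("n", seq_len(n))),
    cohort = c("tumor", rep("normal", n)),
    tissue = c("", paste0("tissue", seq_len(n))),
    total_bp = 1e9, stringsAsFactors = FALSE)
  counts <- matrix(c(tumor_count, normal_counts), 1, n + 1,
                   dimnames = list(kms, NULL))
  fixture_table(counts, samples)
}

test_that("over-abundance flags use a strict > threshold", {
  tab <- five_tissue_fixture(500 * 20, c(20, 19.99999, 21, 1000, 20.004))
  prof <- overabundance_profile(fixture_kmers(1), tab, threshold = 500)
  # ratio exactly 500 is not over-abundant; 500.1-ish is
  expect_false(prof$overabundant[["tissue1"]])
  expect_true(prof$overabundant[["tissue2"]])
  expect_false(prof$overabundant[["tissue3"]])  # below 500
  expect_false(prof$overabundant[["tissue4"]])
  expect_false(prof$overabundant[["tissue5"]])
  expect_equal(prof$tissue_count, 1)
  expect_error(overabundance_profile(fixture_kmers(1), tab, threshold = 0),
               "positive")
})

test_that("tissue_count counts exactly the flagged tissues", {
  tab <- five_tissue_fixture(10000, c(1, 10, 19, 30, 100))
  # ratios: 10000, 1000, 526.3, 333.3, 100 -> 3 tissues above 500
  prof <- overabundance_profile(fixture_kmers(1), tab)
  expect_equal(prof$tissue_count, 3)
  expect_equal(sum(prof$overabundant), prof$tissue_count)
})

test_that("candidate filtering equals a brute-force pair scan and is order-invariant", {
  set.seed(23)
  n_km <- 40; n_tum <- 3; n_nrm <- 6
  kms <- fixture_kmers(n_km)
  samples <- data.frame(
    sample_id = c(paste0("t", 1:n_tum), paste0("n", 1:n_nrm)),
    cohort = c(rep("tumor", n_tum), rep("normal", n_nrm)),
    tissue = c(rep("", n_tum), rep(c("a", "b", "c"), each = 2)),
    total_bp = 1e9, stringsAsFactors = FALSE)
  counts <- matrix(sample(c(NA, 10:20000), n_km * (n_tum + n_nrm), TRUE),
                   n_km, n_tum + n_nrm, dimnames = list(kms, NULL))
  counts[sample(n_km, 5), 1:n_tum] <- 5e6  # force some extreme candidates
  tab <- fixture_table(counts, samples)
  got <- filter_candidates(tab, threshold = 500)

  # oracle: recompute every (kmer, tissue) ratio directly
  flag <- sapply(c("a", "b", "c"), function(ts)
    vapply(kms, function(km) tissue_ratio(km, tab, ts) > 500, logical(1)))
  keep <- rownames(flag)[rowSums(flag) > 0]
  expect_setequal(names(got), keep)
  for (km in names(got))
    expect_equal(got[[km]]$tissue_count, sum(flag[km, ]))
  # sorted by breadth, then k-mer
  tc <- vapply(got, `[[`, numeric(1), "tissue_count")
  expect_true(all(diff(tc) <= 0))

  # shuffling samples does not change the outcome
  perm <- sample(ncol(counts))
  tab2 <- fixture_table(counts[, perm], samples[perm, ])
  got2 <- filter_candidates(tab2, threshold = 500)
  expect_equal(names(got2), names(got))
  for (km in names(got))
    expect_equal(got2[[km]]$ratios[names(got[[km]]$ratios)], got[[km]]$ratios)

  # nothing above threshold -> empty result
  tab_lo <- five_tissue_fixture(30, c(20, 20, 20, 20, 20))
  expect_length(filter_candidates(tab_lo), 0)
})

test_that("imputation keeps every ratio finite", {
  # k-mer absent from all normals: denominator is the imputation floor
  tab <- five_tissue_fixture(1e7, rep(NA_real_, 5))
  prof <- overabundance_profile(fixture_kmers(1), tab)
  expect_true(all(is.finite(prof$ratios)))
  expect_equal(unname(prof$ratios[["tissue1"]]), 1e7 / 10)
})

test_that("display truncation truncates toward zero at two decimals", {
  expect_equal(truncate_ratio(0.16896), 0.16)
  expect_equal(truncate_ratio(c(0.999, 1234.5678)), c(0.99, 1234.56))
})

test_that("sample sheets validate cohort and tissue labels", {
  p <- tempfile()
  writeLines(c("sample_id\tcohort\ttissue",
               "t1\ttumor\t", "n1\tnormal\tliver"), p)
  sheet <- read_sample_sheet(p)
  expect_equal(nrow(sheet), 2)
  expect_true(is.na(sheet$total_bp[1]))
  writeLines(c("sample_id\tcohort\ttissue", "n1\tnormal\t"), p)
  expect_error(read_sample_sheet(p), "without tissue")
  writeLines(c("sample_id\tcohort\ttissue", "x\tweird\tliver"), p)
  expect_error(read_sample_sheet(p), "cohort")
})
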