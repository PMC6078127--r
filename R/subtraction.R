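#' Normalize a raw k-mer count to sequencing effort
#'
#' Converts a raw count into an abundance per 10^9 bp of sequencing effort
#' (count-per-billion-bp), making libraries of different depth comparable.
#'
#' @param count non-negative raw count (vectorized).
#' @param total_bp sequencing effort in base pairs (> 0).
#' @return abundance, `count * 1e9 / total_bp`.
#' @examples
#' normalize_abundance(100, 2e9)  # 50
#' @export
normalize_abundance <- function(count, total_bp) {
  if (any(total_bp <= 0)) stop("total_bp must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  count * 1e9 / total_bp
}

#' Build the normalized tumor/normal abundance table
#'
#' Takes the union of k-mers over all per-sample catalogs; k-mers counted in
#' no sample never appear. Missing entries are imputed asymmetrically at the
#' raw-count level before normalization: 0 for tumor samples (conservative
#' for targeting) and `min_count` for normal samples (the counting threshold
#' means absence only bounds the count from above), then every raw count is
#' normalized per sample with [normalize_abundance()]. The normal-sample
#' floor therefore guarantees strictly positive denominators for every
#' downstream ratio.
#'
#' @param catalogs list of `sample_catalog` objects sharing k and min_count;
#'   at least one tumor and one normal sample.
#' @return an `abundance_table`: numeric matrix (k-mers x samples) plus a
#'   samples data frame (sample_id, cohort, tissue, total_bp).
#' @export
build_abundance_table <- function(catalogs) {
  stopifnot(length(catalogs) >= 2L,
            all(vapply(catalogs, inherits, logical(1), "sample_catalog")))
  ks <- unique(vapply(catalogs, `[[`, integer(1), "k"))
  if (length(ks) != 1L) stop("catalogs mix different k: ", paste(ks, collapse = ", "))
  mc <- unique(vapply(catalogs, `[[`, integer(1), "min_count"))
  if (length(mc) != 1L) stop("catalogs mix different min_count thresholds")
  ids <- vapply(catalogs, function(cat) cat$meta$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample_id: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cohorts <- vapply(catalogs, function(cat) cat$meta$cohort, character(1))
  if (!any(cohorts == "tumor") || !any(cohorts == "normal"))
    stop("need at least one tumor and one normal sample")
  tissues <- vapply(catalogs, function(cat) cat$meta$tissue, character(1))
  total_bp <- vapply(catalogs, function(cat) cat$meta$total_bp, numeric(1))
  if (anyNA(total_bp) || any(total_bp <= 0))
    stop("every counted sample must have total_bp > 0")

  kmers <- sort(unique(unlist(lapply(catalogs, function(cat) names(cat$counts)),
                              use.names = FALSE)),
                method = "radix")
  raw <- matrix(0, nrow = length(kmers), ncol = length(catalogs),
                dimnames = list(kmers, ids))
  for (j in seq_along(catalogs)) {
    if (cohorts[j] == "normal") raw[, j] <- mc
    cts <- catalogs[[j]]$counts
    if (length(cts)) raw[match(names(cts), kmers), j] <- cts
  }
  ab <- sweep(raw, 2, 1e9 / total_bp, `*`)
  structure(list(abundance = ab,
                 samples = data.frame(sample_id = ids, cohort = cohorts,
                                      tissue = tissues, total_bp = total_bp,
                                      stringsAsFactors = FALSE),
                 k = ks, min_count = mc, imputation_floor = mc),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("Abundance table: %d k-mers (k = %d) x %d samples (%d tumor, %d normal; %d tissues)\n",
              nrow(x$abundance), x$k, nrow(x$samples),
              sum(x$samples$cohort == "tumor"),
              sum(x$samples$cohort == "normal"),
              length(unique(x$samples$tissue[x$samples$cohort == "normal"]))))
  invisible(x)
}

table_tissues <- function(table) {
  unique(table$samples$tissue[table$samples$cohort == "normal"])
}

#' Per-tissue tumor:normal abundance ratio
#'
#' The subtraction statistic: the minimum k-mer abundance over tumor samples
#' divided by the maximum abundance over the given tissue's normal samples.
#' Both extremes make the ratio conservative — every tumor sample must carry
#' the k-mer highly, and no normal sample of the tissue may. Full precision
#' is returned; see [truncate_ratio()] for the two-decimal display form.
#'
#' @param kmer k-mer string present in `table`.
#' @param table an `abundance_table`.
#' @param tissue tissue label with at least one normal sample.
#' @return non-negative ratio (finite, since normal-side imputation keeps
#'   denominators positive).
#' @export
tissue_ratio <- function(kmer, table, tissue) {
  stopifnot(inherits(table, "abundance_table"))
  if (!tissue %in% table_tissues(table)) stop("unknown tissue: ", tissue)
  if (!kmer %in% rownames(table$abundance)) stop("k-mer not in table: ", kmer)
  tum <- table$abundance[kmer, table$samples$cohort == "tumor"]
  nrm <- table$abundance[kmer, table$samples$cohort == "normal" &
                                 table$samples$tissue == tissue]
  min(tum) / max(nrm)
}

# Ratio matrix for all k-mers x tissues at once (same statistic as
# tissue_ratio, vectorized).
ratio_matrix <- function(table) {
  tum <- table$abundance[, table$samples$cohort == "tumor", drop = FALSE]
  tmin <- do.call(pmin, as.data.frame(tum))
  tissues <- table_tissues(table)
  out <- matrix(NA_real_, nrow = nrow(table$abundance), ncol = length(tissues),
                dimnames = list(rownames(table$abundance), tissues))
  for (ts in tissues) {
    nrm <- table$abundance[, table$samples$cohort == "normal" &
                               table$samples$tissue == ts, drop = FALSE]
    out[, ts] <- tmin / do.call(pmax, as.data.frame(nrm))
  }
  out
}

new_ratio_profile <- function(kmer, ratios, threshold) {
  flags <- ratios > threshold
  structure(list(kmer = kmer, ratios = ratios, overabundant = flags,
                 threshold = threshold, tissue_count = sum(flags)),
            class = "tissue_ratio_profile")
}

#' @export
print.tissue_ratio_profile <- function(x, ...) {
  cat(sprintf("k-mer %s: over-abundant (ratio > %g) in %d of %d tissues\n",
              x$kmer, x$threshold, x$tissue_count, length(x$ratios)))
  invisible(x)
}

#' Over-abundance profile of one k-mer across tissues
#'
#' Computes the per-tissue tumor:normal ratio for one k-mer and flags the
#' tissues where the ratio strictly exceeds `threshold` ("over-abundant").
#' A ratio exactly at the threshold is not flagged.
#'
#' @param kmer k-mer string.
#' @param table an `abundance_table`.
#' @param threshold over-abundance ratio threshold (default 500).
#' @return a `tissue_ratio_profile` with per-tissue ratios, flags, and the
#'   flagged-tissue count.
#' @export
overabundance_profile <- function(kmer, table, threshold = 500) {
  if (threshold <= 0) stop("threshold must be positive")
  tissues <- table_tissues(table)
  if (length(tissues) == 0L) stop("table has no tissues")
  ratios <- vapply(tissues, function(ts) tissue_ratio(kmer, table, ts),
                   numeric(1))
  new_ratio_profile(kmer, ratios, threshold)
}

#' Filter candidate k-mers by over-abundance
#'
#' Retains every k-mer that is over-abundant (ratio strictly > `threshold`)
#' in at least one tissue; breadth across tissues is rewarded later at the
#' ranking stage. Output is sorted by flagged-tissue count (descending),
#' ties by k-mer code ascending, so results are deterministic and invariant
#' to sample ordering.
#'
#' @param table an `abundance_table`.
#' @param threshold over-abundance ratio threshold (default 500).
#' @return named list of `tissue_ratio_profile` objects (possibly empty).
#' @export
filter_candidates <- function(table, threshold = 500) {
  if (threshold <= 0) stop("threshold must be positive")
  rm_ <- ratio_matrix(table)
  counts <- rowSums(rm_ > threshold)
  keep <- names(counts)[counts > 0]
  keep <- keep[order(-counts[keep], keep, method = "radix")]
  profiles <- lapply(keep, function(km)
    new_ratio_profile(km, rm_[km, ], threshold))
  stats::setNames(profiles, keep)
}

#' Truncate a ratio for display
#'
#' Truncates toward zero at two decimals (0.16896 -> 0.16). Files always
#' carry full precision; this is a formatting concern only.
#'
#' @param x numeric vector.
#' @param digits decimals kept (default 2).
#' @return truncated numeric vector.
#' @export
truncate_ratio <- function(x, digits = 2) {
  trunc(x * 10^digits) / 10^digits
}

#' Read a sample sheet TSV
#'
#' Columns: sample_id, cohort (tumor|normal), tissue, and optional total_bp
#' override.
#'
#' @param path TSV path.
#' @return data frame with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "cohort", "tissue")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  if (!all(df$cohort %in% c("tumor", "normal")))
    stop("cohort must be 'tumor' or 'normal'")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet")
  bad <- df$cohort == "normal" & !nzchar(df$tissue)
  if (any(bad))
    stop("normal sample(s) without tissue label: ",
         paste(df$sample_id[bad], collapse = ", "))
  df$total_bp <- if ("total_bp" %in% names(df))
    suppressWarnings(as.numeric(df$total_bp)) else NA_real_
  df
}

#' Write the abundance table and ratio profiles as TSV
#'
#' @param table an `abundance_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  df <- data.frame(kmer = rownames(table$abundance),
                   table$abundance, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_table
#' @param profiles list of `tissue_ratio_profile` objects.
#' @export
write_ratio_profiles <- function(profiles, path) {
  if (length(profiles) == 0L) {
    writeLines("kmer\ttissue_count", path)
    return(invisible(path))
  }
  tissues <- names(profiles[[1]]$ratios)
  rows <- vapply(profiles, function(p)
    paste(c(p$kmer, format(p$ratios[tissues], digits = 15, trim = TRUE),
            p$tissue_count), collapse = "\t"),
    character(1))
  writeLines(c(paste(c("kmer", tissues, "tissue_count"), collapse = "\t"),
               rows), path)
  invisible(path)
}
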