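#' Configuration for a synthetic tumor/normal cohort
#'
#' Defaults emulate the structure of the cohort the subtraction screen is
#' designed for: 26 normal tissues with 6-26 samples each, 3 tumor samples,
#' ~100 bp reads, and a small set of planted tumor-specific transcripts
#' expressed in no normal sample. Planted transcripts are short (on the
#' order of a read length) and strongly expressed in tumor samples, so that
#' at desk-scale sequencing effort their k-mers clear the >500:1
#' over-abundance filter against the normal-side imputation floor; see the
#' methods vignette for the arithmetic behind these defaults.
#'
#' @param n_tissues number of normal tissues (default 26).
#' @param samples_per_tissue inclusive range of samples per tissue
#'   (default c(6, 26); drawn uniformly per tissue).
#' @param n_tumor_samples number of tumor samples (default 3).
#' @param n_shared_transcripts transcripts expressed in every sample
#'   (default 30).
#' @param n_tumor_specific planted tumor-only transcripts (default 2).
#' @param shared_length_range length range of shared transcripts (bp).
#' @param tumor_specific_length_range length range of planted transcripts.
#' @param fold_excess tumor expression weight of each planted transcript
#'   relative to the unit shared-transcript scale (> 1; default 1000).
#' @param read_length read length in bp (default 100).
#' @param reads_per_sample reads drawn per sample (default 30000).
#' @param error_rate per-base substitution error rate (default 0.001).
#' @param seed integer seed; every simulator output is reproducible given
#'   the config.
#' @return a `cohort_config`.
#' @export
cohort_config <- function(n_tissues = 26, samples_per_tissue = c(6, 26),
                          n_tumor_samples = 3, n_shared_transcripts = 30,
                          n_tumor_specific = 2,
                          shared_length_range = c(200, 400),
                          tumor_specific_length_range = c(100, 130),
                          fold_excess = 1000, read_length = 100,
                          reads_per_sample = 30000, error_rate = 0.001,
                          seed = 1) {
  cfg <- list(n_tissues = n_tissues, samples_per_tissue = samples_per_tissue,
              n_tumor_samples = n_tumor_samples,
              n_shared_transcripts = n_shared_transcripts,
              n_tumor_specific = n_tumor_specific,
              shared_length_range = shared_length_range,
              tumor_specific_length_range = tumor_specific_length_range,
              fold_excess = fold_excess, read_length = read_length,
              reads_per_sample = reads_per_sample, error_rate = error_rate,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_tissues >= 1, n_tumor_samples >= 1,
              n_shared_transcripts >= 1, n_tumor_specific >= 1,
              length(samples_per_tissue) == 2,
              samples_per_tissue[1] >= 1,
              samples_per_tissue[2] >= samples_per_tissue[1],
              read_length >= 1, reads_per_sample >= 1, error_rate >= 0,
              error_rate < 1)
    if (fold_excess <= 1) stop("fold_excess must exceed 1")
    if (read_length > min(shared_length_range[1],
                          tumor_specific_length_range[1]))
      stop("read length exceeds the minimum transcript length; reads could ",
           "not be drawn")
  })
  class(cfg) <- "cohort_config"
  cfg
}

#' Desk-scale cohort preset
#'
#' A small 10-tissue, 2-samples-per-tissue, 24-transcript preset for fast
#' end-to-end tests; same generative model as the full default.
#'
#' @param ... overrides passed to [cohort_config()].
#' @return a `cohort_config`.
#' @export
toy_cohort_config <- function(...) {
  defaults <- list(n_tissues = 10, samples_per_tissue = c(2, 2),
                   n_tumor_samples = 3, n_shared_transcripts = 22,
                   n_tumor_specific = 2, reads_per_sample = 30000)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sample() treats a length-1 numeric as 1:x; draw from an explicit range
sample_range <- function(range, n) {
  range[1] + sample.int(range[2] - range[1] + 1L, n, replace = TRUE) - 1L
}

# Deterministic cohort blueprint: transcripts, per-sample metadata, weights
# and per-sample RNG seeds. Both the file-emitting and the streaming
# counting paths are built on this, so they see identical reads.
cohort_plan <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_shared <- config$n_shared_transcripts
  n_planted <- config$n_tumor_specific
  shared_len <- sample_range(config$shared_length_range, n_shared)
  planted_len <- sample_range(config$tumor_specific_length_range, n_planted)
  ids <- c(sprintf("shared_%02d", seq_len(n_shared)),
           sprintf("tumoronly_%02d", seq_len(n_planted)))
  seqs <- vapply(c(shared_len, planted_len), random_dna, character(1))
  names(seqs) <- ids
  planted <- startsWith(ids, "tumoronly_")

  # expression weights: heavy-tailed lognormal for shared transcripts,
  # fold_excess for planted ones in tumor samples, zero in normals
  w_shared <- stats::rlnorm(n_shared, meanlog = 0, sdlog = 1)
  w_normal <- c(w_shared, rep(0, n_planted))
  w_tumor <- c(w_shared, rep(config$fold_excess, n_planted))

  n_per_tissue <- sample_range(config$samples_per_tissue, config$n_tissues)
  tissue_names <- sprintf("tissue_%02d", seq_len(config$n_tissues))
  samples <- rbind(
    data.frame(sample_id = sprintf("tumor_%02d", seq_len(config$n_tumor_samples)),
               cohort = "tumor", tissue = "", stringsAsFactors = FALSE),
    data.frame(sample_id = unlist(lapply(seq_len(config$n_tissues), function(i)
                 sprintf("%s_s%02d", tissue_names[i], seq_len(n_per_tissue[i])))),
               cohort = "normal",
               tissue = rep(tissue_names, n_per_tissue),
               stringsAsFactors = FALSE))
  samples$total_bp <- config$reads_per_sample * config$read_length
  samples$seed <- sample.int(.Machine$integer.max - 1L, nrow(samples))

  list(config = config, transcripts = seqs, planted = planted,
       weights_normal = w_normal, weights_tumor = w_tumor, samples = samples)
}

plan_truth <- function(plan) {
  data.frame(transcript_id = names(plan$transcripts),
             length = nchar(plan$transcripts),
             planted = plan$planted,
             weight_tumor = plan$weights_tumor,
             weight_normal = plan$weights_normal,
             stringsAsFactors = FALSE)
}

#' Simulate a tumor/normal RNA-seq cohort to disk
#'
#' Writes a transcriptome FASTA, one FASTQ per sample, a sample sheet TSV
#' and a ground-truth TSV. Shared transcripts are expressed in all samples
#' with lognormal weights; planted transcripts only in tumor samples at the
#' configured fold-excess. Reads are drawn from transcripts proportionally
#' to weight with substitution errors, and everything is deterministic given
#' the config (including its seed).
#'
#' @param config a [cohort_config()].
#' @param dir output directory (created if needed).
#' @param gzip write FASTQ gzip-compressed.
#' @return invisibly, a list with the output paths and the ground truth.
#' @export
simulate_cohort <- function(config, dir, gzip = FALSE) {
  plan <- cohort_plan(config)
  dir.create(file.path(dir, "reads"), recursive = TRUE, showWarnings = FALSE)
  fa_path <- file.path(dir, "transcripts.fa")
  writeLines(as.vector(rbind(paste0(">", names(plan$transcripts)),
                             plan$transcripts)), fa_path)
  qual <- strrep("I", config$read_length)
  read_paths <- character(nrow(plan$samples))
  for (i in seq_len(nrow(plan$samples))) {
    s <- plan$samples[i, ]
    w <- if (s$cohort == "tumor") plan$weights_tumor else plan$weights_normal
    set.seed(s$seed)
    reads <- cpp_simulate_reads(plan$transcripts, w, config$reads_per_sample,
                                config$read_length, config$error_rate)
    path <- file.path(dir, "reads",
                      paste0(s$sample_id, ".fastq", if (gzip) ".gz" else ""))
    con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
    writeLines(as.vector(rbind(paste0("@", s$sample_id, "_r", seq_along(reads)),
                               reads, "+", qual)), con)
    close(con)
    read_paths[i] <- path
  }
  sheet <- plan$samples[, c("sample_id", "cohort", "tissue", "total_bp")]
  sheet_path <- file.path(dir, "samples.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- plan_truth(plan)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(transcripts = fa_path, reads = read_paths,
                 sample_sheet = sheet_path, truth_file = truth_path,
                 truth = truth))
}

#' Simulate and count a cohort without materializing read files
#'
#' Streams the same reads as [simulate_cohort()] (identical RNG draws per
#' sample) directly into per-sample k-mer catalogs, which makes repeated
#' whole-cohort recovery experiments cheap.
#'
#' @param config a [cohort_config()].
#' @param k word length (default 25).
#' @param min_count per-sample occurrence threshold (default 10).
#' @return list with `catalogs` (list of `sample_catalog`), `transcripts`
#'   (named character) and `truth` (data frame).
#' @export
simulate_cohort_catalogs <- function(config, k = 25, min_count = 10) {
  plan <- cohort_plan(config)
  catalogs <- vector("list", nrow(plan$samples))
  for (i in seq_len(nrow(plan$samples))) {
    s <- plan$samples[i, ]
    w <- if (s$cohort == "tumor") plan$weights_tumor else plan$weights_normal
    set.seed(s$seed)
    res <- cpp_simulate_count(plan$transcripts, w, config$reads_per_sample,
                              config$read_length, config$error_rate,
                              as.integer(k), as.integer(min_count))
    meta <- sample_meta(s$sample_id, s$cohort, s$tissue, res$total_bp)
    catalogs[[i]] <- new_sample_catalog(meta,
                                        stats::setNames(res$count, res$kmer),
                                        k, min_count)
  }
  list(catalogs = catalogs, transcripts = plan$transcripts,
       truth = plan_truth(plan), samples = plan$samples)
}

#' Simulate a viability plate from a median-effect ground truth
#'
#' True fraction affected follows the median-effect model
#' `FA(D) = (D/Dm)^m / (1 + (D/Dm)^m)`; well fluorescence is
#' `control_signal * (1 - FA) * (1 + e)` with Gaussian noise e. The plate
#' includes untreated vehicle wells and scramble-control wells with a small
#' sequence-independent toxicity.
#'
#' @param m true median-effect slope.
#' @param Dm true median-effect dose, µM.
#' @param doses dose series in µM (all > 0).
#' @param replicates wells per dose (default 6).
#' @param noise_sd standard deviation of the multiplicative Gaussian noise
#'   (default 0.05; 0 gives a noise-free plate).
#' @param treatment treatment label (default "oligo").
#' @param control_signal mean untreated fluorescence (default 1000).
#' @param scramble_fa true fraction affected of the scramble control
#'   (default 0.03).
#' @param seed optional integer seed.
#' @return data frame of plate records (well, treatment, dose_uM,
#'   fluorescence).
#' @export
simulate_viability <- function(m, Dm, doses = c(0.03, 0.1, 0.3, 1, 3),
                               replicates = 6, noise_sd = 0.05,
                               treatment = "oligo", control_signal = 1000,
                               scramble_fa = 0.03, seed = NULL) {
  if (any(doses <= 0)) stop("doses must be positive")
  if (replicates < 1) stop("replicates must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  true_fa <- function(D) { r <- (D / Dm)^m; r / (1 + r) }
  wells <- expand.grid(rep = seq_len(replicates), dose_uM = doses,
                       KEEP.OUT.ATTRS = FALSE)
  noise <- function(n) if (noise_sd > 0) 1 + stats::rnorm(n, 0, noise_sd) else 1
  treated <- data.frame(
    well = sprintf("T%03d", seq_len(nrow(wells))),
    treatment = treatment, dose_uM = wells$dose_uM,
    fluorescence = control_signal * (1 - true_fa(wells$dose_uM)) *
      noise(nrow(wells)),
    stringsAsFactors = FALSE)
  vehicle <- data.frame(
    well = sprintf("V%03d", seq_len(replicates)),
    treatment = "vehicle", dose_uM = 0,
    fluorescence = control_signal * noise(replicates),
    stringsAsFactors = FALSE)
  scramble <- data.frame(
    well = sprintf("S%03d", seq_len(replicates)),
    treatment = "scramble", dose_uM = max(doses),
    fluorescence = control_signal * (1 - scramble_fa) * noise(replicates),
    stringsAsFactors = FALSE)
  out <- rbind(vehicle, scramble, treated)
  out$fluorescence <- pmax(out$fluorescence, 0)
  rownames(out) <- NULL
  out
}
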