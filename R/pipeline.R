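#' Pipeline run configuration
#'
#' Bundles every tunable of the subtraction funnel with its default:
#' k = 25, per-sample count threshold 10, over-abundance ratio threshold
#' 500, target-selection threshold 10,000, top 400 transcripts, CI effect
#' level 0.5 and additive band [0.9, 1.1].
#'
#' @param k word length.
#' @param min_count per-sample occurrence threshold.
#' @param ratio_threshold over-abundance ratio threshold.
#' @param target_threshold target-selection ratio threshold.
#' @param top_n transcripts kept at ranking.
#' @param fa effect level for combination-index evaluation.
#' @param additive_band closed CI interval labeled additive.
#' @param canonical count canonical (strand-collapsed) k-mers.
#' @param adjust_scramble subtract scramble FA when summarizing plates.
#' @param seed integer seed for any stochastic stage.
#' @return a `run_config` (validated, serializable with
#'   [write_run_config()]).
#' @export
run_config <- function(k = 25, min_count = 10, ratio_threshold = 500,
                       target_threshold = 10000, top_n = 400, fa = 0.5,
                       additive_band = c(0.9, 1.1), canonical = FALSE,
                       adjust_scramble = FALSE, seed = 1) {
  cfg <- list(k = as.integer(k), min_count = as.integer(min_count),
              ratio_threshold = ratio_threshold,
              target_threshold = target_threshold,
              top_n = as.integer(top_n), fa = fa,
              additive_band = additive_band,
              canonical = isTRUE(canonical),
              adjust_scramble = isTRUE(adjust_scramble),
              seed = as.integer(seed))
  if (cfg$k < 1 || cfg$min_count < 1 || cfg$ratio_threshold <= 0 ||
      cfg$target_threshold <= 0 || cfg$top_n < 1)
    stop("thresholds and sizes must be positive")
  if (cfg$fa <= 0 || cfg$fa >= 1) stop("fa must lie strictly in (0, 1)")
  class(cfg) <- "run_config"
  cfg
}

#' Serialize / load a run configuration
#'
#' Flat `key=value` text document; every run artifact directory embeds the
#' resolved configuration so runs are reconstructible.
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `path` invisibly / a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  vals <- vapply(unclass(config), function(v)
    paste(format(v, scientific = FALSE, trim = TRUE), collapse = ","),
    character(1))
  writeLines(paste0(names(vals), "=", vals), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  num <- function(x) as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])
  run_config(k = num(vals[["k"]]), min_count = num(vals[["min_count"]]),
             ratio_threshold = num(vals[["ratio_threshold"]]),
             target_threshold = num(vals[["target_threshold"]]),
             top_n = num(vals[["top_n"]]), fa = num(vals[["fa"]]),
             additive_band = num(vals[["additive_band"]]),
             canonical = vals[["canonical"]] == "TRUE",
             adjust_scramble = vals[["adjust_scramble"]] == "TRUE",
             seed = num(vals[["seed"]]))
}

pipeline_log <- function(quiet, ...) {
  if (!quiet) message("[kmerscreen] ", sprintf(...))
  invisible(NULL)
}

#' Run the subtraction funnel end to end
#'
#' Orchestrates counting, subtraction, annotation, ranking, target selection
#' and oligo design over a cohort on disk, writing deterministic artifacts
#' (catalog TSVs, candidate profiles, ranking, heat-map matrix, target list,
#' oligo FASTA) plus a machine-readable run summary that records the funnel
#' counts at each stage: k-mers cataloged, candidates after the
#' over-abundance filter, transcripts carrying a candidate, transcripts
#' ranked, and targets selected.
#'
#' @param config a [run_config()].
#' @param sample_sheet path to the sample sheet TSV (sample_id, cohort,
#'   tissue, optional total_bp override).
#' @param reads_dir directory holding `<sample_id>.fastq[.gz]` /
#'   `<sample_id>.fasta[.gz]` read files.
#' @param transcripts path to the reference transcriptome FASTA.
#' @param out_dir artifact directory (created if needed).
#' @param target_floor keep only targets qualifying in at least this many
#'   tissues (default 1).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the funnel counts, artifact paths,
#'   ranking, targets and profiles.
#' @export
run_pipeline <- function(config, sample_sheet, reads_dir, transcripts,
                         out_dir, target_floor = 1, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(sample_sheet, reads_dir, transcripts))
    if (!file.exists(p)) stop("missing input: ", p)
  sheet <- read_sample_sheet(sample_sheet)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(out_dir, "run_config.txt"))

  pipeline_log(quiet, "counting %d samples (k = %d, min_count = %d)",
               nrow(sheet), config$k, config$min_count)
  catalogs <- lapply(seq_len(nrow(sheet)), function(i) {
    s <- sheet[i, ]
    hits <- list.files(reads_dir, full.names = TRUE,
                       pattern = paste0("^", s$sample_id,
                                        "\\.(fastq|fasta|fa|fq)(\\.gz)?$"))
    if (length(hits) != 1L)
      stop("expected exactly one read file for sample '", s$sample_id,
           "' in ", reads_dir, " (found ", length(hits), ")")
    meta <- sample_meta(s$sample_id, s$cohort, s$tissue, s$total_bp)
    count_sample(hits, meta, k = config$k, min_count = config$min_count,
                 canonical = config$canonical)
  })
  cat_dir <- file.path(out_dir, "catalogs")
  dir.create(cat_dir, showWarnings = FALSE)
  for (cat_ in catalogs)
    write_catalog(cat_, file.path(cat_dir,
                                  paste0(cat_$meta$sample_id, ".catalog.tsv")))

  table <- build_abundance_table(catalogs)
  n_cataloged <- nrow(table$abundance)
  pipeline_log(quiet, "cataloged %d distinct k-mers", n_cataloged)

  profiles <- filter_candidates(table, threshold = config$ratio_threshold)
  n_candidates <- length(profiles)
  pipeline_log(quiet, "%d candidate k-mers over-abundant (> %g) in >= 1 tissue",
               n_candidates, config$ratio_threshold)
  write_ratio_profiles(profiles, file.path(out_dir, "candidates.tsv"))

  index <- index_transcriptome(transcripts, k = config$k)
  scores <- score_transcripts(index, profiles)
  n_with_candidate <- sum(scores$tissue_count > 0)
  ranking <- rank_transcripts(scores[scores$tissue_count > 0, , drop = FALSE],
                              top_n = config$top_n)
  pipeline_log(quiet, "%d transcripts carry a candidate k-mer; %d ranked",
               n_with_candidate, nrow(ranking))
  utils::write.table(ranking, file.path(out_dir, "ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  artifacts <- list(run_config = file.path(out_dir, "run_config.txt"),
                    candidates = file.path(out_dir, "candidates.tsv"),
                    ranking = file.path(out_dir, "ranking.tsv"))
  targets <- NULL
  if (nrow(ranking) > 0) {
    hm <- heatmap_matrix(ranking, profiles)
    write_heatmap(hm, file.path(out_dir, "heatmap.tsv"))
    artifacts$heatmap <- file.path(out_dir, "heatmap.tsv")
    targets <- select_targets(ranking, profiles,
                              target_threshold = config$target_threshold)
    targets <- targets[targets$qualifying_tissues >= target_floor, ,
                       drop = FALSE]
    utils::write.table(targets, file.path(out_dir, "targets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts$targets <- file.path(out_dir, "targets.tsv")
    if (nrow(targets) > 0) {
      seqs <- vapply(seq_len(nrow(targets)), function(i)
        design_antisense(index$transcripts[[targets$transcript_id[i]]],
                         targets$hit_offset[i], config$k), character(1))
      oligos <- stats::setNames(seqs, paste0(targets$transcript_id, "_aso"))
      write_oligos(oligos, file.path(out_dir, "oligos.fa"))
      artifacts$oligos <- file.path(out_dir, "oligos.fa")
    }
  }
  n_targets <- if (is.null(targets)) 0L else nrow(targets)
  pipeline_log(quiet, "%d targets selected (ratio > %g in >= %d tissues)",
               n_targets, config$target_threshold, target_floor)

  funnel <- c(kmers_cataloged = n_cataloged,
              candidates_filtered = n_candidates,
              transcripts_with_candidate = n_with_candidate,
              transcripts_ranked = nrow(ranking),
              targets_selected = n_targets)
  summary_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(list(funnel = as.list(funnel),
                            config = unclass(config),
                            artifacts = artifacts),
                       summary_path, auto_unbox = TRUE, pretty = TRUE)
  artifacts$run_summary <- summary_path
  invisible(list(funnel = funnel, artifacts = artifacts, ranking = ranking,
                 targets = targets, profiles = profiles, table = table))
}
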