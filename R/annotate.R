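#' Index every k-mer of a reference transcriptome
#'
#' Catalogs all valid k-length windows of every transcript together with
#' their 0-based offsets, so that any candidate k-mer can be mapped back to
#' the transcripts (and positions) containing it. Ambiguous-base windows are
#' skipped as in [extract_kmers()]. A k-mer shared by several transcripts
#' (e.g. splice variants) is credited to every one of them.
#'
#' @param transcripts named character vector of transcript sequences, or a
#'   path to a transcriptome FASTA. Ids are taken from FASTA headers up to
#'   the first whitespace and must be unique.
#' @param k word length (default 25).
#' @return a `transcriptome_index`: transcript sequences plus a hits table
#'   (kmer, transcript_id, offset).
#' @export
index_transcriptome <- function(transcripts, k = 25) {
  if (length(transcripts) == 1L && is.character(transcripts) &&
      file.exists(transcripts))
    transcripts <- read_sequences(transcripts)
  if (length(transcripts) == 0L) stop("no transcript records")
  ids <- sub("\\s.*$", "", names(transcripts))
  if (is.null(ids) || any(!nzchar(ids))) stop("transcripts must be named")
  if (anyDuplicated(ids))
    stop("duplicate transcript id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(transcripts) <- ids
  empty <- !nzchar(transcripts)
  if (any(empty)) {
    warning("skipping empty transcript(s): ", paste(ids[empty], collapse = ", "))
    transcripts <- transcripts[!empty]
    ids <- ids[!empty]
  }
  hit_list <- lapply(ids, function(id) {
    kms <- extract_kmers(transcripts[[id]], k)
    if (length(kms) == 0L) return(NULL)
    # offsets of valid windows: re-derive by position since ambiguous
    # windows are skipped
    n <- nchar(transcripts[[id]])
    starts <- seq_len(n - k + 1L)
    s <- chartr("acgtuU", "ACGTTT", transcripts[[id]])
    flag <- !strsplit(s, "", fixed = TRUE)[[1]] %in% c("A", "C", "G", "T")
    cs <- c(0L, cumsum(flag))
    ok <- (cs[starts + k] - cs[starts]) == 0L
    data.frame(kmer = kms, transcript_id = id, offset = starts[ok] - 1L,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hit_list)
  if (is.null(hits))
    hits <- data.frame(kmer = character(0), transcript_id = character(0),
                       offset = integer(0), stringsAsFactors = FALSE)
  structure(list(transcripts = transcripts, hits = hits, k = as.integer(k)),
            class = "transcriptome_index")
}

#' @export
print.transcriptome_index <- function(x, ...) {
  cat(sprintf("Transcriptome index: %d transcripts, %d k-mer hits (k = %d)\n",
              length(x$transcripts), nrow(x$hits), x$k))
  invisible(x)
}

#' Score transcripts by the over-abundance breadth of their k-mers
#'
#' For each transcript, selects among its contained candidate k-mers the one
#' over-abundant in the maximum number of tissues, and associates that
#' maximum over-abundance tissue count (and the achieving k-mer) with the
#' transcript. Ties are broken by the larger minimum per-tissue ratio
#' (favoring uniformly extreme k-mers), then by the smaller k-mer code, so
#' scoring is deterministic. Transcripts containing no candidate k-mer score
#' 0 with no selected k-mer.
#'
#' @param index a `transcriptome_index`.
#' @param profiles named list of `tissue_ratio_profile` objects (from
#'   [filter_candidates()]).
#' @return data frame of class `transcript_scores`: transcript_id,
#'   selected_kmer, hit_offset, tissue_count, min_ratio.
#' @export
score_transcripts <- function(index, profiles) {
  stopifnot(inherits(index, "transcriptome_index"))
  ids <- names(index$transcripts)
  cand <- index$hits[index$hits$kmer %in% names(profiles), , drop = FALSE]
  counts <- vapply(profiles, `[[`, numeric(1), "tissue_count")
  minr <- vapply(profiles, function(p) min(p$ratios), numeric(1))
  rows <- lapply(ids, function(id) {
    h <- cand[cand$transcript_id == id, , drop = FALSE]
    if (nrow(h) == 0L)
      return(data.frame(transcript_id = id, selected_kmer = NA_character_,
                        hit_offset = NA_integer_, tissue_count = 0L,
                        min_ratio = NA_real_, stringsAsFactors = FALSE))
    h <- h[!duplicated(h$kmer), , drop = FALSE]  # first (leftmost) offset
    ord <- order(-counts[h$kmer], -minr[h$kmer], h$kmer, method = "radix")
    best <- h[ord[1], ]
    data.frame(transcript_id = id, selected_kmer = best$kmer,
               hit_offset = best$offset,
               tissue_count = as.integer(counts[best$kmer]),
               min_ratio = minr[best$kmer], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("transcript_scores", "data.frame")
  out
}

#' Rank transcripts and keep the top set
#'
#' Orders by tissue count (descending), then by the selected k-mer's minimum
#' per-tissue ratio (descending), then by transcript id (ascending), and
#' truncates to `top_n`. The order is total and deterministic: shuffled
#' input yields identical output.
#'
#' @param scores a `transcript_scores` data frame.
#' @param top_n maximum transcripts kept (default 400).
#' @return the ranked, truncated `transcript_scores` data frame with a
#'   `rank` column prepended.
#' @export
rank_transcripts <- function(scores, top_n = 400) {
  if (top_n < 1) stop("top_n must be >= 1")
  mr <- ifelse(is.na(scores$min_ratio), -Inf, scores$min_ratio)
  ord <- order(-scores$tissue_count, -mr, scores$transcript_id,
               method = "radix")
  out <- scores[ord, , drop = FALSE]
  out <- utils::head(out, top_n)
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("transcript_scores", "data.frame")
  out
}

#' Per-tissue ratio matrix for ranked transcripts
#'
#' Rows are ranked transcripts (rank order), columns are tissues (input
#' order), cells are the selected k-mer's tumor:normal ratio — the matrix
#' behind the tissue/transcript heat map. Transcripts without a selected
#' k-mer are dropped.
#'
#' @param ranking output of [rank_transcripts()].
#' @param profiles named list of `tissue_ratio_profile` objects covering
#'   every selected k-mer.
#' @param tissues tissue order for the columns; defaults to the order in the
#'   first profile.
#' @return numeric matrix (transcripts x tissues).
#' @export
heatmap_matrix <- function(ranking, profiles, tissues = NULL) {
  keep <- !is.na(ranking$selected_kmer)
  ranking <- ranking[keep, , drop = FALSE]
  if (nrow(ranking) == 0L) stop("ranking contains no scored transcripts")
  missing <- setdiff(ranking$selected_kmer, names(profiles))
  if (length(missing))
    stop("no ratio profile for selected k-mer(s): ",
         paste(missing, collapse = ", "))
  if (is.null(tissues)) tissues <- names(profiles[[1]]$ratios)
  m <- t(vapply(ranking$selected_kmer,
                function(km) profiles[[km]]$ratios[tissues], numeric(length(tissues))))
  dimnames(m) <- list(ranking$transcript_id, tissues)
  m
}

#' Write / render the heat-map matrix
#'
#' @param m matrix from [heatmap_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(m, path) {
  df <- data.frame(transcript_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_heatmap
#' @param png_path optional output PNG; cells are rendered on a log10 scale
#'   (monotone in the ratio).
#' @export
render_heatmap <- function(m, png_path) {
  grDevices::png(png_path, width = 900, height = 600)
  on.exit(grDevices::dev.off())
  lm_ <- log10(pmax(m, .Machine$double.xmin))
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(lm_),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "tissue", ylab = "transcript (rank order)",
                  axes = FALSE, main = "log10 tumor:normal abundance ratio")
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.6)
  graphics::box()
  invisible(png_path)
}

#' Select therapeutic targets from a ranking
#'
#' For each ranked transcript, counts the tissues in which its selected
#' k-mer's ratio strictly exceeds `target_threshold` (default 10,000:1).
#' Output is sorted by that qualifying-tissue count, descending; the caller
#' applies a floor (e.g. all tissues) to shortlist.
#'
#' @param ranking output of [rank_transcripts()].
#' @param profiles named list of `tissue_ratio_profile` objects.
#' @param target_threshold ratio threshold for a tissue to qualify.
#' @return data frame of class `target_calls`: transcript_id, selected_kmer,
#'   hit_offset, qualifying_tissues, target_threshold.
#' @export
select_targets <- function(ranking, profiles, target_threshold = 10000) {
  if (target_threshold <= 0) stop("target_threshold must be positive")
  keep <- !is.na(ranking$selected_kmer)
  ranking <- ranking[keep, , drop = FALSE]
  if (nrow(ranking) == 0L) {
    out <- data.frame(transcript_id = character(0), selected_kmer = character(0),
                      hit_offset = integer(0), qualifying_tissues = integer(0),
                      target_threshold = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("target_calls", "data.frame")
    return(out)
  }
  qual <- vapply(ranking$selected_kmer, function(km)
    sum(profiles[[km]]$ratios > target_threshold), integer(1))
  out <- data.frame(transcript_id = ranking$transcript_id,
                    selected_kmer = ranking$selected_kmer,
                    hit_offset = ranking$hit_offset,
                    qualifying_tissues = as.integer(qual),
                    target_threshold = target_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$qualifying_tissues), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_calls", "data.frame")
  out
}

#' Design an antisense oligomer against a transcript window
#'
#' Returns the reverse complement of the target window, written 5'->3' in
#' the DNA alphabet — the sequence an antisense oligomer needs to hybridize
#' to that stretch of the transcript. Typical antisense oligomers are 15-30
#' bases; a warning is issued outside that range.
#'
#' @param sequence transcript sequence.
#' @param start 0-based offset of the target window.
#' @param length window length.
#' @return oligo sequence (character).
#' @examples
#' design_antisense("GGAACCTT", 2, 4)  # "GGTT"
#' @export
design_antisense <- function(sequence, start, length) {
  n <- nchar(sequence)
  if (start < 0 || start + length > n)
    stop("window [", start, ", ", start + length, ") out of bounds for a ",
         n, " nt transcript")
  if (length < 15 || length > 30)
    warning("oligo length ", length, " is outside the usual 15-30 nt range")
  window <- substr(sequence, start + 1, start + length)
  reverse_complement(window)
}

#' Write oligo sequences as FASTA
#'
#' @param oligos named character vector of oligo sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_oligos <- function(oligos, path) {
  writeLines(as.vector(rbind(paste0(">", names(oligos)), oligos)), path)
  invisible(path)
}
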