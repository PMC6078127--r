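#' Extract all k-length windows of a nucleotide sequence
#'
#' Slides a window of length k left to right over `sequence`. Windows that
#' contain any symbol outside \{A,C,G,T,U\} are skipped entirely; U is
#' treated as T. No reverse-complement canonicalization is applied:
#' transcript sequences are stranded, so a k-mer and its reverse complement
#' are distinct observations.
#'
#' @param sequence a single nucleotide string.
#' @param k window length (>= 1).
#' @return character vector of k-mers in window order; empty when the
#'   sequence is shorter than k.
#' @examples
#' extract_kmers("ACGTA", 3)
#' extract_kmers("ACGNACG", 3)  # windows covering N are skipped
#' @export
extract_kmers <- function(sequence, k) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  cpp_extract_kmers(sequence, k)
}

#' Sample metadata for one sequencing library
#'
#' @param sample_id sample identifier.
#' @param cohort either "tumor" or "normal".
#' @param tissue tissue label; required non-empty for normal samples and
#'   empty for tumor samples.
#' @param total_bp total sequencing effort in base pairs; NA means "derive
#'   from the reads at counting time".
#' @return an object of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, cohort = c("tumor", "normal"),
                        tissue = "", total_bp = NA_real_) {
  cohort <- match.arg(cohort)
  if (cohort == "normal" && (!nzchar(tissue) || is.na(tissue)))
    stop("normal samples must carry a non-empty tissue label")
  if (cohort == "tumor") tissue <- ""
  if (!is.na(total_bp) && total_bp <= 0)
    stop("total_bp must be positive")
  structure(list(sample_id = as.character(sample_id), cohort = cohort,
                 tissue = as.character(tissue),
                 total_bp = as.numeric(total_bp)),
            class = "sample_meta")
}

new_sample_catalog <- function(meta, counts, k, min_count) {
  structure(list(meta = meta, counts = counts, k = as.integer(k),
                 min_count = as.integer(min_count)),
            class = "sample_catalog")
}

#' Count thresholded k-mers in one sample
#'
#' Accumulates k-mer counts over all reads (see [extract_kmers()] for the
#' window rules) and drops every k-mer seen fewer than `min_count` times in
#' the sample — the occurrence threshold is strict, so a k-mer seen exactly
#' `min_count` times is kept. Unless `meta` carries a `total_bp` override,
#' sequencing effort is recorded as the sum of read lengths.
#'
#' @param reads character vector of reads, or a path to a FASTA/FASTQ file
#'   (optionally gzip-compressed).
#' @param meta a [sample_meta()] object.
#' @param k word length (default 25).
#' @param min_count per-sample occurrence threshold (default 10).
#' @param canonical count each window as the lexicographic minimum of the
#'   k-mer and its reverse complement. Off by default: matching k-mers to
#'   stranded transcript sequences later would create false joins.
#' @return a `sample_catalog`: metadata plus a named integer count vector in
#'   lexicographic k-mer order.
#' @export
count_sample <- function(reads, meta, k = 25, min_count = 10,
                         canonical = FALSE) {
  stopifnot(inherits(meta, "sample_meta"))
  if (min_count < 1) stop("min_count must be >= 1")
  k <- as.integer(k)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_sequences(reads)
  if (length(reads) == 0L) stop("reads must be non-empty")
  if (!is.character(reads)) stop("reads must be a character vector or file path")
  tallied <- cpp_count_reads(reads, k, as.integer(min_count), canonical)
  counts <- stats::setNames(tallied$count, tallied$kmer)
  if (all(nchar(reads) < k))
    warning("k = ", k, " exceeds every read length; catalog is empty")
  if (is.na(meta$total_bp)) meta$total_bp <- sum(as.numeric(nchar(reads)))
  new_sample_catalog(meta, counts, k, min_count)
}

#' @export
print.sample_catalog <- function(x, ...) {
  cat(sprintf("Sample catalog '%s' (%s%s): %d k-mers (k = %d, min_count = %d, total_bp = %s)\n",
              x$meta$sample_id, x$meta$cohort,
              if (nzchar(x$meta$tissue)) paste0(", ", x$meta$tissue) else "",
              length(x$counts), x$k, x$min_count,
              format(x$meta$total_bp, big.mark = ",")))
  invisible(x)
}

#' Read sequences from FASTA or FASTQ (optionally gzipped)
#'
#' Format is sniffed from the first non-empty character (`>` FASTA,
#' `@` FASTQ), so compressed files and arbitrary extensions work.
#'
#' @param path file path.
#' @return character vector of sequences (names kept from record ids).
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0L) return(character(0))
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  seqs <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as.character(seqs), names(seqs))
}

#' Parse an external k-mer dump
#'
#' Reads the two dump dialects produced by stand-alone k-mer counters:
#' columnar (`KMER COUNT` per line) and FASTA-style (`>COUNT` header
#' followed by the k-mer). Counts are returned raw; apply the per-sample
#' threshold afterwards.
#'
#' @param input path to a dump file or a character vector of lines.
#' @param k expected word length; each record is validated against it.
#' @return named integer vector of raw counts.
#' @export
parse_kmer_dump <- function(input, k = 25) {
  lines <- if (length(input) == 1L && file.exists(input))
    readLines(input) else input
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0L)
    return(stats::setNames(integer(0), character(0)))
  fasta <- startsWith(trimws(lines[lines_keep[1]]), ">")
  kmers <- character(0)
  counts <- integer(0)
  if (fasta) {
    i <- 1
    while (i <= length(lines_keep)) {
      ln <- lines_keep[i]
      hdr <- trimws(lines[ln])
      if (!startsWith(hdr, ">"))
        stop("mixed dump dialects at line ", ln,
             ": expected a '>' header in FASTA dialect")
      cnt <- suppressWarnings(as.integer(sub("^>", "", hdr)))
      if (is.na(cnt))
        stop("malformed count header at line ", ln, ": '", hdr, "'")
      if (i + 1 > length(lines_keep))
        stop("truncated record: header at line ", ln, " has no k-mer line")
      ln2 <- lines_keep[i + 1]
      km <- trimws(lines[ln2])
      validate_dump_kmer(km, k, ln2)
      kmers <- c(kmers, km)
      counts <- c(counts, cnt)
      i <- i + 2
    }
  } else {
    for (ln in lines_keep) {
      txt <- trimws(lines[ln])
      if (startsWith(txt, ">"))
        stop("mixed dump dialects at line ", ln,
             ": '>' header inside columnar dialect")
      parts <- strsplit(txt, "[ \t]+")[[1]]
      if (length(parts) != 2L)
        stop("expected 'KMER COUNT' at line ", ln, ": '", txt, "'")
      validate_dump_kmer(parts[1], k, ln)
      cnt <- suppressWarnings(as.integer(parts[2]))
      if (is.na(cnt)) stop("malformed count at line ", ln, ": '", txt, "'")
      kmers <- c(kmers, parts[1])
      counts <- c(counts, cnt)
    }
  }
  out <- tapply(counts, kmers, sum)
  codes <- sort(names(out), method = "radix")
  stats::setNames(as.integer(out[codes]), codes)
}

validate_dump_kmer <- function(km, k, line) {
  if (nchar(km) != k)
    stop("k-mer of length ", nchar(km), " at line ", line,
         " (expected k = ", k, ")")
  if (grepl("[^ACGTacgt]", km))
    stop("non-ACGT symbol in k-mer at line ", line)
  invisible(TRUE)
}

catalog_header_fields <- c("sample_id", "cohort", "tissue", "total_bp",
                           "k", "min_count")

#' Write a sample catalog as TSV
#'
#' The file carries a commented header (sample_id, cohort, tissue, total_bp,
#' k, min_count) followed by `kmer<TAB>count` rows in lexicographic k-mer
#' order, so serialization is deterministic and diffable.
#'
#' @param catalog a `sample_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "sample_catalog"))
  m <- catalog$meta
  hdr <- c(paste0("# sample_id=", m$sample_id),
           paste0("# cohort=", m$cohort),
           paste0("# tissue=", m$tissue),
           paste0("# total_bp=", format(m$total_bp, scientific = FALSE)),
           paste0("# k=", catalog$k),
           paste0("# min_count=", catalog$min_count),
           "kmer\tcount")
  ord <- sort(names(catalog$counts), method = "radix")
  rows <- if (length(ord)) paste0(ord, "\t", catalog$counts[ord]) else character(0)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a sample catalog written by [write_catalog()]
#'
#' @param path catalog TSV path.
#' @return a `sample_catalog`.
#' @export
read_catalog <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^# ", lines, value = TRUE)
  kv <- sub("^# ([^=]+)=(.*)$", "\\1\r\\2", hdr_lines)
  kv <- strsplit(kv, "\r", fixed = TRUE)
  fields <- stats::setNames(vapply(kv, function(x) if (length(x) > 1) x[2] else "",
                                   character(1)),
                            vapply(kv, `[`, character(1), 1))
  missing <- setdiff(catalog_header_fields, names(fields))
  if (length(missing))
    stop("catalog header is missing field(s): ", paste(missing, collapse = ", "))
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) == 0L || body[1] != "kmer\tcount")
    stop("catalog body must start with a 'kmer\\tcount' header row")
  body <- body[-1]
  counts <- integer(0)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    counts <- stats::setNames(as.integer(vapply(parts, `[`, character(1), 2)),
                              vapply(parts, `[`, character(1), 1))
  } else {
    counts <- stats::setNames(integer(0), character(0))
  }
  meta <- sample_meta(fields[["sample_id"]], fields[["cohort"]],
                      fields[["tissue"]],
                      as.numeric(fields[["total_bp"]]))
  new_sample_catalog(meta, counts, as.integer(fields[["k"]]),
                     as.integer(fields[["min_count"]]))
}
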