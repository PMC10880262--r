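# External formats. All coordinates inside the package are 0-based
# half-open; 1-based inclusive appears only at the BLAST-tabular and
# RepeatMasker boundaries.

#' Import BLAST tabular (outfmt 6) hits
#'
#' Reads the 12-column tab-separated BLAST dialect
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`) produced by searching long reads against a satellite
#' library, as an alternative to the built-in [scan_read()] scanner. The
#' long read is the query: columns 7-8 hold 1-based inclusive read
#' coordinates, with `qstart > qend` signalling a minus-strand hit.
#'
#' @param path Tabular hits file.
#' @return Tibble of hit records: `read_id`, `ref_name`, `read_start`,
#'   `read_end` (0-based half-open, `read_start < read_end`), `strand`
#'   (`"+"`/`"-"`), `percent_identity`.
#' @export
parse_hits_tabular <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(read_id = character(), ref_name = character(),
                  read_start = integer(), read_end = integer(),
                  strand = character(), percent_identity = double()))
  }
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 12) {
      stopf("line %d: expected 12 tab-separated columns, found %d", i, length(f))
    }
    qstart <- suppressWarnings(as.integer(f[7]))
    qend <- suppressWarnings(as.integer(f[8]))
    pid <- suppressWarnings(as.numeric(f[3]))
    if (anyNA(c(qstart, qend, pid))) stopf("line %d: malformed numeric field", i)
    if (pid < 0 || pid > 100) stopf("line %d: percent identity %s out of range", i, f[3])
    strand <- if (qstart <= qend) "+" else "-"
    lo <- min(qstart, qend); hi <- max(qstart, qend)
    recs[[i]] <- tibble(read_id = f[1], ref_name = f[2],
                        read_start = lo - 1L, read_end = hi,
                        strand = strand, percent_identity = pid)
  }
  bind_rows(recs)
}

#' Write hits in BLAST tabular (outfmt 6) dialect
#'
#' Inverse of [parse_hits_tabular()] on the fields it preserves
#' (`read_id`, coordinates, strand, identity); alignment-statistic columns
#' are emitted as placeholders.
#'
#' @param hits Tibble as returned by [parse_hits_tabular()] or [scan_read()].
#' @param path Output path.
#' @export
write_hits_tabular <- function(hits, path) {
  span <- hits$read_end - hits$read_start
  qstart <- ifelse(hits$strand == "+", hits$read_start + 1L, hits$read_end)
  qend <- ifelse(hits$strand == "+", hits$read_end, hits$read_start + 1L)
  lines <- sprintf("%s\t%s\t%.2f\t%d\t0\t0\t%d\t%d\t1\t%d\t0.0\t0",
                   hits$read_id, hits$ref_name, hits$percent_identity,
                   span, qstart, qend, span)
  writeLines(lines, path)
  invisible(path)
}

#' Import a RepeatMasker ".out" annotation
#'
#' Parses the standard RepeatMasker output layout (three header lines, then
#' whitespace-separated fixed columns) and returns labeled intervals used to
#' annotate non-satellite blocks (transposable elements and other repeats).
#'
#' @param path RepeatMasker `.out` file.
#' @return Tibble: `read_id`, `start`, `end` (0-based half-open), `strand`,
#'   `family`, `repeat_class`.
#' @export
parse_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  head2 <- paste(lines[1:min(2, length(lines))], collapse = " ")
  if (length(lines) < 3 || !grepl("SW|score", head2, ignore.case = TRUE)) {
    stopf("'%s' does not start with a recognizable RepeatMasker header", path)
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) {
    return(tibble(read_id = character(), start = integer(), end = integer(),
                  strand = character(), family = character(),
                  repeat_class = character()))
  }
  recs <- map(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) < 11) stopf("body line %d: expected >= 11 columns, found %d", i, length(f))
    start1 <- suppressWarnings(as.integer(f[6]))
    end1 <- suppressWarnings(as.integer(f[7]))
    if (anyNA(c(start1, end1))) stopf("body line %d: malformed coordinates", i)
    if (end1 <= start1 - 1L) stopf("body line %d: interval end <= start", i)
    tibble(read_id = f[5], start = start1 - 1L, end = end1,
           strand = if (f[9] == "C") "-" else "+",
           family = f[10], repeat_class = f[11])
  })
  bind_rows(recs)
}

#' Write intervals as BED
#'
#' Emits 0-based half-open BED lines (`chrom start end name score strand`)
#' for any tibble carrying `read_id`, `start`, `end` and optionally `name`,
#' `score`, `strand`.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("read_id", "start", "end") %in% names(x)))
  if (any(x$end <= x$start)) stopf("BED intervals must satisfy start < end")
  name <- x[["name"]] %||% rep(".", nrow(x))
  score <- x[["score"]] %||% rep(0, nrow(x))
  strand <- x[["strand"]] %||% rep(".", nrow(x))
  readr::write_tsv(
    tibble(chrom = x$read_id, start = x$start, end = x$end,
           name = name, score = score, strand = strand),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Read a 6-column BED file
#'
#' @param path BED path as written by [write_bed()].
#' @return Tibble `read_id`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  readr::read_tsv(path,
                  col_names = c("read_id", "start", "end", "name", "score", "strand"),
                  col_types = "ciicdc", progress = FALSE)
}

#' Write a per-base coverage vector as bedGraph
#'
#' Run-length encodes the coverage so consecutive equal values collapse to
#' one interval; coordinates are 0-based half-open.
#'
#' @param coverage Numeric vector of per-base coverage.
#' @param ref Reference (read) identifier for column 1.
#' @param path Output path.
#' @export
write_bedgraph <- function(coverage, ref, path) {
  r <- rle(as.numeric(coverage))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  readr::write_tsv(tibble(ref = ref, start = starts, end = ends, value = r$values),
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a bedGraph back to a per-base coverage vector
#'
#' @param path bedGraph path (single reference).
#' @return Numeric coverage vector.
#' @export
read_bedgraph <- function(path) {
  x <- readr::read_tsv(path, col_names = c("ref", "start", "end", "value"),
                       col_types = "ciid", progress = FALSE)
  if (length(unique(x$ref)) > 1) stopf("read_bedgraph expects a single reference")
  cov <- numeric(max(x$end))
  for (i in seq_len(nrow(x))) cov[(x$start[i] + 1):x$end[i]] <- x$value[i]
  cov
}

#' Write reads to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output FASTA.
#' @export
write_reads_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read FASTA/FASTQ sequences as a named character vector
#'
#' @param path FASTA or FASTQ file (format detected from extension).
#' @return Named character vector of upper-case sequences.
#' @export
read_reads <- function(path) {
  fq <- grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
  x <- if (fq) Biostrings::readDNAStringSet(path, format = "fastq")
       else Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}
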