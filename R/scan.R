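# Satellite block discovery in long reads: deterministic seed-and-extend
# against each consensus on both strands, then chaining of hits into
# satellite / non-satellite blocks and array typing.

.edit_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    }
    m
  }
})

align_consensus <- function(cons, window, type = "global-local") {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(cons), Biostrings::DNAString(window),
    type = type, substitutionMatrix = .edit_matrix(),
    gapOpening = 4, gapExtension = 1
  )
}

# percent identity = matches / alignment columns (gap columns included),
# the BLAST convention
aln_identity <- function(aln) {
  ni <- Biostrings::nindel(aln)
  cols <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) +
    Biostrings::insertion(ni)[1, "WidthSum"] + Biostrings::deletion(ni)[1, "WidthSum"]
  as.numeric(100 * Biostrings::nmatch(aln) / cols)
}

#' Scan one read for satellite hits
#'
#' Deterministic seed-and-extend replacement for an external BLAST search:
#' exact `word_size`-mers shared between consensus and read vote for
#' candidate monomer placements (diagonals); each candidate is refined by a
#' semi-global alignment of the full consensus against the local read
#' window, on both strands, for every unit in the library. External BLAST
#' hits can be supplied instead via [parse_hits_tabular()].
#'
#' @param read DNA sequence (character) of the long read.
#' @param library A `consensus_library`.
#' @param identity_floor Minimum percent identity to keep a hit (default
#'   70, the screening threshold used for satellite discovery).
#' @param word_size Exact seed length (default 11; smaller values increase
#'   sensitivity on diverged arrays at some cost).
#' @param min_seeds Minimum seed votes for a candidate placement
#'   (default 3).
#' @param read_id Identifier recorded in the output.
#' @return Tibble of hits: `read_id`, `ref_name`, `sat_class`,
#'   `read_start`, `read_end` (0-based half-open), `strand`,
#'   `percent_identity`, `score`, `n_seeds`, sorted by `read_start`.
#' @export
scan_read <- function(read, library, identity_floor = 70, word_size = 11L,
                      min_seeds = 3L, read_id = "read") {
  read <- toupper(read)
  rlen <- nchar(read)
  empty <- tibble(read_id = character(), ref_name = character(),
                  sat_class = character(), read_start = integer(),
                  read_end = integer(), strand = character(),
                  percent_identity = double(), score = double(),
                  n_seeds = integer())
  if (rlen < word_size) return(empty)
  subject <- Biostrings::DNAString(read)
  hits <- list()
  for (i in seq_len(nrow(library$units))) {
    unit <- library$units[i, ]
    L <- unit$monomer_length
    if (rlen < L * 0.5) next
    for (strand in c("+", "-")) {
      cons <- if (strand == "+") unit$sequence else revcomp(unit$sequence)
      n_words <- L - word_size + 1L
      if (n_words < 1) next
      cache_key <- paste(unit$name, strand, word_size, sep = "|")
      cached <- library$cache[[cache_key]]
      if (is.null(cached)) {
        words <- substring(cons, seq_len(n_words), seq_len(n_words) + word_size - 1L)
        uw <- unique(words)
        cached <- list(
          word_pos = split(seq_len(n_words), factor(words, levels = uw)),
          pd = Biostrings::PDict(Biostrings::DNAStringSet(uw)),
          n_uw = length(uw)
        )
        library$cache[[cache_key]] <- cached
      }
      word_pos <- cached$word_pos
      pd <- cached$pd
      uw <- seq_len(cached$n_uw)
      m <- Biostrings::matchPDict(pd, subject)
      diags <- unlist(map(seq_along(uw), function(k) {
        st <- Biostrings::startIndex(m)[[k]]
        if (is.null(st) || length(st) == 0) return(integer())
        as.vector(outer(st, word_pos[[k]], "-"))
      }))
      if (length(diags) < min_seeds) next
      ds <- sort(diags)
      grp <- cumsum(c(1L, as.integer(diff(ds) > 6L)))
      cand <- tibble(diag = ds, grp = grp) |>
        group_by(.data$grp) |>
        summarise(diag = round(median(.data$diag)), n_seeds = n(), .groups = "drop") |>
        filter(.data$n_seeds >= min_seeds)
      if (nrow(cand) == 0) next
      # drop candidates within half a monomer of a stronger one
      cand <- arrange(cand, desc(.data$n_seeds), .data$diag)
      keep <- rep(TRUE, nrow(cand))
      for (a in seq_len(nrow(cand))) {
        if (!keep[a]) next
        close_by <- abs(cand$diag - cand$diag[a]) < 0.5 * L & seq_len(nrow(cand)) > a
        keep[close_by] <- FALSE
      }
      cand <- cand[keep, ]
      for (a in seq_len(nrow(cand))) {
        d <- cand$diag[a]                       # 0-based approximate start
        win_start <- max(0L, d - 12L)
        win_end <- min(rlen, d + L + 12L)
        if (win_end - win_start < 0.5 * L) next
        aln <- align_consensus(cons, substr(read, win_start + 1L, win_end))
        pid <- aln_identity(aln)
        if (pid < identity_floor) next
        s <- win_start + Biostrings::start(Biostrings::subject(aln)) - 1L
        e <- win_start + Biostrings::end(Biostrings::subject(aln))
        hits[[length(hits) + 1L]] <- tibble(
          read_id = read_id, ref_name = unit$name, sat_class = unit$sat_class,
          read_start = as.integer(s), read_end = as.integer(e), strand = strand,
          percent_identity = pid, score = Biostrings::score(aln),
          n_seeds = cand$n_seeds[a]
        )
      }
    }
  }
  if (length(hits) == 0) return(empty)
  out <- bind_rows(hits)
  # non-redundant within class/strand: best identity wins on >50% overlaps
  out <- out |>
    arrange(desc(.data$percent_identity), desc(.data$read_end - .data$read_start),
            .data$read_start)
  keep <- rep(TRUE, nrow(out))
  for (a in seq_len(nrow(out))) {
    if (!keep[a]) next
    later <- which(keep & seq_len(nrow(out)) > a &
                     out$sat_class == out$sat_class[a] & out$strand == out$strand[a])
    if (length(later) == 0) next
    ov <- pmin(out$read_end[later], out$read_end[a]) -
      pmax(out$read_start[later], out$read_start[a])
    shorter <- pmin(out$read_end[later] - out$read_start[later],
                    out$read_end[a] - out$read_start[a])
    keep[later[ov > 0.5 * shorter]] <- FALSE
  }
  arrange(out[keep, ], .data$read_start)
}

#' Segment scanned hits into blocks and type the array
#'
#' Chains adjacent same-class, same-strand hits into satellite blocks
#' (merging across gaps below half a monomer), labels internal unexplained
#' gaps of at least `gap_min` bp as non-satellite blocks (making the array
#' Type 2), and flags direction switches between consecutive same-class
#' blocks on opposite strands. Terminal unannotated margins never trigger
#' Type 2 (reads truncate arrays arbitrarily).
#'
#' @param read_id Read identifier.
#' @param hits Hit tibble from [scan_read()] or [parse_hits_tabular()]
#'   (must carry `sat_class`; join library names if importing).
#' @param read_length Read length in bp.
#' @param library A `consensus_library` (for monomer lengths).
#' @param gap_min Minimum internal gap (bp) labeled non-satellite
#'   (default 100).
#' @param gap_merge_frac Within-block merge tolerance as a fraction of the
#'   monomer length (default 0.5).
#' @param min_monomers Minimum hits per satellite block (default 2; one
#'   noisy hit is not an array).
#' @return Object of class `array_annotation`: ordered `blocks`,
#'   `array_type` (`"Type1"`/`"Type2"`), `direction_switch`, `composition`
#'   (per-label base fractions summing to 1) and `junction_classes`.
#' @export
segment_and_type <- function(read_id, hits, read_length, library,
                             gap_min = 100L, gap_merge_frac = 0.5,
                             min_monomers = 2L) {
  mono_len <- setNames(library$units$monomer_length, library$units$sat_class)
  blocks <- tibble(start = integer(), end = integer(), label = character(),
                   kind = character(), strand = character(),
                   n_hits = integer(), mean_identity = double())
  if (nrow(hits) > 0) {
    h <- arrange(hits, .data$read_start)
    gap_merge <- gap_merge_frac * unname(mono_len[h$sat_class])
    new_block <- c(TRUE, (h$sat_class[-1] != h$sat_class[-nrow(h)]) |
                     (h$strand[-1] != h$strand[-nrow(h)]) |
                     (h$read_start[-1] - h$read_end[-nrow(h)] >= gap_merge[-1]))
    h$block <- cumsum(new_block)
    blocks <- h |>
      group_by(.data$block) |>
      summarise(start = min(.data$read_start), end = max(.data$read_end),
                label = first(.data$sat_class), kind = "sat",
                strand = first(.data$strand), n_hits = n(),
                mean_identity = mean(.data$percent_identity), .groups = "drop") |>
      filter(.data$n_hits >= min_monomers) |>
      select(-"block") |>
      arrange(.data$start)
  }
  # internal gaps
  nonsat <- list()
  if (nrow(blocks) >= 2) {
    for (i in seq_len(nrow(blocks) - 1)) {
      gap <- blocks$start[i + 1] - blocks$end[i]
      if (gap >= gap_min) {
        nonsat[[length(nonsat) + 1L]] <- tibble(
          start = blocks$end[i], end = blocks$start[i + 1],
          label = "non_satellite", kind = "nonsat", strand = ".",
          n_hits = 0L, mean_identity = NA_real_
        )
      }
    }
  }
  all_blocks <- bind_rows(blocks, bind_rows(nonsat)) |> arrange(.data$start)
  sat_blocks <- filter(all_blocks, .data$kind == "sat")
  array_type <- if (nrow(sat_blocks) == 0) {
    NA_character_
  } else if (any(all_blocks$kind == "nonsat")) "Type2" else "Type1"
  direction_switch <- FALSE
  if (nrow(sat_blocks) >= 2) {
    for (cls in unique(sat_blocks$label)) {
      s <- filter(sat_blocks, .data$label == cls)
      if (nrow(s) >= 2 && any(s$strand[-1] != s$strand[-nrow(s)])) {
        direction_switch <- TRUE
      }
    }
  }
  covered <- sum(all_blocks$end - all_blocks$start)
  comp <- all_blocks |>
    group_by(.data$label) |>
    summarise(bases = sum(.data$end - .data$start), .groups = "drop")
  if (read_length - covered > 0) {
    comp <- bind_rows(comp, tibble(label = "unassigned",
                                   bases = read_length - covered))
  }
  comp <- mutate(comp, fraction = .data$bases / read_length)
  structure(
    list(read_id = read_id, read_length = read_length,
         blocks = mutate(all_blocks, read_id = read_id, .before = 1),
         array_type = array_type, direction_switch = direction_switch,
         composition = comp,
         junction_classes = sort(unique(sat_blocks$label))),
    class = "array_annotation"
  )
}

#' @export
print.array_annotation <- function(x, ...) {
  cat("<array_annotation> ", x$read_id, ": ", x$array_type %||% "unannotated",
      ", ", nrow(x$blocks), " block(s), direction_switch=", x$direction_switch,
      "\n", sep = "")
  invisible(x)
}

#' Scan and annotate one read
#'
#' Convenience wrapper: [scan_read()] followed by [segment_and_type()].
#'
#' @inheritParams scan_read
#' @inheritParams segment_and_type
#' @param ... Passed to [scan_read()].
#' @return An `array_annotation`.
#' @export
annotate_read <- function(read, library, read_id = "read", gap_min = 100L,
                          min_monomers = 2L, ...) {
  hits <- scan_read(read, library, read_id = read_id, ...)
  segment_and_type(read_id, hits, nchar(read), library, gap_min = gap_min,
                   min_monomers = min_monomers)
}

#' Annotate a cohort of reads
#'
#' @param reads Named character vector of read sequences.
#' @param library A `consensus_library`.
#' @param ... Passed to [annotate_read()].
#' @return List of `array_annotation` objects, named by read.
#' @export
annotate_cohort <- function(reads, library, ...) {
  ids <- names(reads) %||% sprintf("read_%03d", seq_along(reads))
  out <- map2(as.character(reads), ids,
              function(r, id) annotate_read(r, library, read_id = id, ...))
  setNames(out, ids)
}

#' Per-class base-composition summary over annotated reads
#'
#' Aggregates the fraction of bases per block label (satellite classes,
#' non-satellite, unassigned) over a cohort; fractions sum to 1.
#'
#' @param annotations List of `array_annotation` objects.
#' @return Tibble: `label`, `bases`, `fraction`.
#' @export
composition_summary <- function(annotations) {
  if (length(annotations) == 0) stopf("empty cohort")
  total <- sum(map_dbl(annotations, "read_length"))
  bind_rows(map(annotations, "composition")) |>
    group_by(.data$label) |>
    summarise(bases = sum(.data$bases), .groups = "drop") |>
    mutate(fraction = .data$bases / total) |>
    arrange(desc(.data$fraction))
}

#' Summary table over annotated reads
#'
#' @param annotations List of `array_annotation` objects.
#' @return Tibble: one row per read with `array_type`, `direction_switch`,
#'   block count and classes present.
#' @export
annotation_summary <- function(annotations) {
  bind_rows(map(annotations, function(a) {
    tibble(read_id = a$read_id, read_length = a$read_length,
           array_type = a$array_type, direction_switch = a$direction_switch,
           n_blocks = nrow(a$blocks),
           classes = paste(a$junction_classes, collapse = ","))
  }))
}

#' Read-length histogram
#'
#' Bins read lengths into fixed-width bins (default 500 bp, the
#' convention for long-read length distributions) and reports the mean.
#'
#' @param reads Character vector of sequences, or numeric lengths.
#' @param bin_bp Bin width in bp (> 0).
#' @return List: `histogram` tibble (`bin_start`, `bin_end`, `count`),
#'   `mean_length` (`NA` for empty input), `n`.
#' @export
read_length_histogram <- function(reads, bin_bp = 500L) {
  if (bin_bp <= 0) stopf("bin_bp must be > 0")
  lens <- if (is.character(reads)) nchar(reads) else as.numeric(reads)
  if (length(lens) == 0) {
    return(list(histogram = tibble(bin_start = integer(), bin_end = integer(),
                                   count = integer()),
                mean_length = NA_real_, n = 0L))
  }
  bin <- floor(lens / bin_bp)
  tab <- table(bin)
  list(
    histogram = tibble(bin_start = as.integer(names(tab)) * as.integer(bin_bp),
                       bin_end = (as.integer(names(tab)) + 1L) * as.integer(bin_bp),
                       count = as.integer(tab)),
    mean_length = mean(lens), n = length(lens)
  )
}
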