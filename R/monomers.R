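# Monomer decomposition and sequence-variation profiling: consensus-anchored
# tiling of an array block, per-position difference calls, repeat-period
# estimation and satellite class assignment.

# walk an alignment (pattern = consensus) and emit per-consensus-position
# difference calls; insertions are charged to the left-flank position
alignment_differences <- function(aln) {
  patt <- split_bases(as.character(Biostrings::alignedPattern(aln)))
  subj <- split_bases(as.character(Biostrings::alignedSubject(aln)))
  cons_pos <- 0L
  out_pos <- integer(); out_op <- character(); out_base <- character()
  for (k in seq_along(patt)) {
    if (patt[k] != "-") cons_pos <- cons_pos + 1L
    if (patt[k] == "-") {
      out_pos <- c(out_pos, max(cons_pos, 1L)); out_op <- c(out_op, "ins")
      out_base <- c(out_base, subj[k])
    } else if (subj[k] == "-") {
      out_pos <- c(out_pos, cons_pos); out_op <- c(out_op, "del")
      out_base <- c(out_base, NA_character_)
    } else if (patt[k] != subj[k]) {
      out_pos <- c(out_pos, cons_pos); out_op <- c(out_op, "sub")
      out_base <- c(out_base, subj[k])
    }
  }
  tibble(cons_pos = out_pos, op = out_op, base = out_base)
}

#' Decompose an array block into ordered monomers
#'
#' Consensus-anchored tiling: the class consensus is semi-globally aligned
#' (consensus global, block local) to successive windows of the block,
#' chaining non-overlapping placements left to right. Monomer lengths may
#' differ from the consensus through indels (capturing, e.g., 220-mer and
#' 250-mer major-satellite length variants). Placements whose divergence
#' exceeds `max_divergence` are rejected and left as gaps.
#'
#' @param sequence Block DNA sequence (forward orientation; see
#'   [decompose_block()] for strand handling).
#' @param unit One-row consensus tibble (see [library_unit()]).
#' @param max_divergence Maximum accepted divergence per monomer
#'   (default 0.40).
#' @return Tibble of monomer records: `ordinal`, `start`, `end` (0-based
#'   half-open within the block), `strand`, `sat_class`, `length`,
#'   `percent_identity` (matches / alignment columns), `n_sub`, `n_ins`,
#'   `n_del`, `score`, `partial`, `subunit_boundary` (bp offset of the
#'   dimer sub-unit junction, `NA` otherwise), `sequence` and
#'   `differences` (list-column of per-position calls).
#' @export
decompose_array <- function(sequence, unit, max_divergence = 0.40) {
  sequence <- toupper(sequence)
  slen <- nchar(sequence)
  L <- unit$monomer_length
  cons <- unit$sequence
  subunits <- unit$subunits[[1]]
  min_identity <- 100 * (1 - max_divergence)
  rows <- list()
  add_record <- function(aln, s, e, partial) {
    diffs <- alignment_differences(aln)
    sub_b <- if (!is.null(subunits)) {
      # observed offset of the consensus sub-unit junction inside the monomer
      ins_before <- sum(diffs$op == "ins" & diffs$cons_pos <= subunits[1])
      del_before <- sum(diffs$op == "del" & diffs$cons_pos <= subunits[1])
      as.integer(subunits[1] + ins_before - del_before)
    } else NA_integer_
    rows[[length(rows) + 1L]] <<- tibble(
      ordinal = length(rows) + 1L, start = as.integer(s), end = as.integer(e),
      strand = "+", sat_class = unit$sat_class, length = as.integer(e - s),
      percent_identity = aln_identity(aln),
      n_sub = sum(diffs$op == "sub"), n_ins = sum(diffs$op == "ins"),
      n_del = sum(diffs$op == "del"), score = Biostrings::score(aln),
      partial = partial, subunit_boundary = sub_b,
      sequence = substr(sequence, s + 1L, e), differences = list(diffs)
    )
  }
  empty <- tibble(ordinal = integer(), start = integer(), end = integer(),
                  strand = character(), sat_class = character(),
                  length = integer(), percent_identity = double(),
                  n_sub = integer(), n_ins = integer(), n_del = integer(),
                  score = double(), partial = logical(),
                  subunit_boundary = integer(), sequence = character(),
                  differences = list())
  if (slen < L) {
    # block shorter than one consensus copy: single partial record from a
    # local alignment (a global consensus placement cannot fit)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(cons), Biostrings::DNAString(sequence),
      type = "local", substitutionMatrix = .edit_matrix(),
      gapOpening = 4, gapExtension = 1)
    add_record(aln, Biostrings::start(Biostrings::subject(aln)) - 1L,
               Biostrings::end(Biostrings::subject(aln)), TRUE)
    return(bind_rows(rows))
  }
  pos <- 0L
  while (slen - pos >= 0.5 * L) {
    win_end <- min(slen, pos + ceiling(1.7 * L))
    aln <- align_consensus(cons, substr(sequence, pos + 1L, win_end))
    pid <- aln_identity(aln)
    if (pid < min_identity) {
      pos <- pos + L        # unresolvable stretch: leave a gap, move on
      next
    }
    s <- pos + Biostrings::start(Biostrings::subject(aln)) - 1L
    e <- pos + Biostrings::end(Biostrings::subject(aln))
    add_record(aln, s, e, FALSE)
    pos <- as.integer(e)
  }
  if (length(rows) == 0) return(empty)
  bind_rows(rows)
}

#' Decompose a (possibly reverse-strand) block
#'
#' Reverse-strand blocks are reverse-complemented before decomposition and
#' the resulting coordinates mirrored back into block space, so ordinals
#' run along the monomer orientation and identities are strand-invariant.
#'
#' @inheritParams decompose_array
#' @param strand `"+"` or `"-"`.
#' @return As [decompose_array()].
#' @export
decompose_block <- function(sequence, unit, strand = "+", max_divergence = 0.40) {
  if (strand == "+") return(decompose_array(sequence, unit, max_divergence))
  blen <- nchar(sequence)
  mono <- decompose_array(revcomp(sequence), unit, max_divergence)
  mutate(mono,
         tmp_start = blen - .data$end, end = blen - .data$start,
         start = .data$tmp_start, strand = "-") |>
    select(-"tmp_start")
}

#' Per-position variation profile
#'
#' Fraction of monomers whose aligned base differs from the consensus at
#' each consensus position (substitutions at the position; indels charged
#' to the left flank).
#'
#' @param monomers Monomer tibble from [decompose_array()] (>= 2 monomers).
#' @param unit The consensus unit the monomers were decomposed against.
#' @return Object of class `variation_profile`: `sat_class`, `n_monomers`,
#'   and `profile` tibble (`position`, `variant_fraction`).
#' @export
per_position_variation <- function(monomers, unit) {
  if (nrow(monomers) < 2) stopf("need >= 2 monomers for a variation profile")
  L <- unit$monomer_length
  counts <- numeric(L)
  for (i in seq_len(nrow(monomers))) {
    d <- monomers$differences[[i]]
    pos <- unique(d$cons_pos[d$cons_pos >= 1 & d$cons_pos <= L])
    counts[pos] <- counts[pos] + 1
  }
  structure(
    list(sat_class = unit$sat_class, n_monomers = nrow(monomers),
         profile = tibble(position = seq_len(L),
                          variant_fraction = counts / nrow(monomers))),
    class = "variation_profile"
  )
}

#' @export
print.variation_profile <- function(x, ...) {
  cat("<variation_profile> ", x$sat_class, ": ", nrow(x$profile),
      " positions over ", x$n_monomers, " monomers; mean variation ",
      sprintf("%.3f", mean(x$profile$variant_fraction)), "\n", sep = "")
  invisible(x)
}

#' Estimate the repeat period of a tandem array
#'
#' Shift-match autocorrelation: for each candidate lag, the fraction of
#' positions at which the sequence equals itself shifted by that lag. The
#' period is the smallest lag whose score is statistically
#' indistinguishable (within 3 standard errors) from the maximum, which
#' resolves harmonic lags (2L, 3L, ...) whose expected score equals that of
#' the true period under per-monomer mutation from a consensus. A
#' "no period" result is returned when no lag rises above the robust
#' background by `z_threshold` (default 5; the threshold is applied to a
#' median/MAD background over ~350 tested lags, so a multiplicity-aware
#' value is used rather than the classical 3).
#'
#' @param sequence Array DNA sequence (>= 5 expected periods recommended).
#' @param lag_min,lag_max Lag search window in bp (default 50-400,
#'   bracketing all mouse satellite monomer lengths).
#' @param z_threshold Robust z-score a peak must exceed to call a period.
#' @return Object of class `period_estimate`: `period` (bp, `NA` if no
#'   period), `peak_score`, `scores` tibble (`lag`, `score`).
#' @export
estimate_period <- function(sequence, lag_min = 50L, lag_max = 400L,
                            z_threshold = 5) {
  x <- utf8ToInt(toupper(sequence))
  n <- length(x)
  lags <- lag_min:min(lag_max, n - 50L)
  if (length(lags) == 0) stopf("sequence too short for the lag window")
  score <- map_dbl(lags, function(l) mean(x[1:(n - l)] == x[(l + 1):n]))
  bg_med <- median(score)
  bg_mad <- max(mad(score), 1e-6)
  peak <- max(score)
  tab <- tibble(lag = lags, score = score)
  if ((peak - bg_med) / bg_mad < z_threshold) {
    return(structure(list(period = NA_integer_, peak_score = peak,
                          scores = tab, background = bg_med),
                     class = "period_estimate"))
  }
  se <- sqrt(pmax(score * (1 - score), 1e-12) / (n - lags))
  cand <- lags[score >= peak - 3 * se]
  structure(list(period = as.integer(min(cand)), peak_score = peak,
                 scores = tab, background = bg_med),
            class = "period_estimate")
}

#' @export
print.period_estimate <- function(x, ...) {
  if (is.na(x$period)) {
    cat("<period_estimate> no period detected (peak score ",
        sprintf("%.3f", x$peak_score), ")\n", sep = "")
  } else {
    cat("<period_estimate> period ", x$period, " bp (score ",
        sprintf("%.3f", x$peak_score), ")\n", sep = "")
  }
  invisible(x)
}

#' Assign a satellite class to an array
#'
#' Decomposes the array against every candidate consensus and labels it by
#' the best-scoring class (summed alignment score over placed monomers).
#' Major-satellite arrays are split into homogeneous vs divergent by the
#' rule: divergent iff more than `divergent_min_monomers` monomers fall
#' below `divergent_identity` percent identity to the consensus.
#'
#' @param sequence Array DNA sequence.
#' @param library A `consensus_library`.
#' @param classes Candidate classes (default: all in the library).
#' @param identity_floor Minimum mean identity for any classification
#'   (default 70; below it the array is `unclassified`).
#' @param divergent_identity Identity threshold of the divergent-MaSat rule
#'   (default 75, gap-inclusive).
#' @param divergent_min_monomers Count threshold of the rule (default 10;
#'   strictly more than this many sub-threshold monomers are required).
#' @param max_divergence Passed to [decompose_array()].
#' @param screen_monomers Candidate classes are ranked on a prefix of this
#'   many monomer lengths (per-base summed alignment score); only the
#'   winner is decomposed in full (default 8).
#' @return Object of class `class_call`: `class` (e.g. `MiSat120`,
#'   `MaSat_divergent`, `unclassified`), `evidence` tibble (per-candidate
#'   statistics; prefix-based for non-winning candidates) and `monomers`
#'   (full decomposition under the winning consensus).
#' @export
assign_class <- function(sequence, library, classes = NULL,
                         identity_floor = 70, divergent_identity = 75,
                         divergent_min_monomers = 10L, max_divergence = 0.40,
                         screen_monomers = 8L) {
  classes <- classes %||% library$units$sat_class
  evidence <- list()
  for (cls in classes) {
    unit <- library_unit(library, cls)
    prefix <- substr(sequence, 1L,
                     min(nchar(sequence), screen_monomers * unit$monomer_length))
    dec <- decompose_array(prefix, unit, max_divergence)
    evidence[[cls]] <- tibble(
      sat_class = cls, n_monomers = nrow(dec),
      mean_identity = if (nrow(dec)) mean(dec$percent_identity) else NA_real_,
      total_score = if (nrow(dec)) sum(dec$score) / nchar(prefix) else -Inf
    )
  }
  ev <- bind_rows(evidence) |> arrange(desc(.data$total_score))
  best <- ev$sat_class[1]
  call_class <- "unclassified"
  monomers <- decompose_array(sequence, library_unit(library, best), max_divergence)
  ev$n_monomers[1] <- nrow(monomers)
  ev$mean_identity[1] <- if (nrow(monomers)) mean(monomers$percent_identity) else NA_real_
  if (nrow(monomers) > 0 && isTRUE(ev$mean_identity[1] >= identity_floor)) {
    call_class <- best
    if (best == "MaSat") {
      n_div <- sum(monomers$percent_identity < divergent_identity)
      call_class <- if (n_div > divergent_min_monomers) "MaSat_divergent"
                    else "MaSat_homogeneous"
    }
  }
  structure(list(class = call_class, evidence = ev, monomers = monomers),
            class = "class_call")
}

#' @export
print.class_call <- function(x, ...) {
  cat("<class_call> ", x$class, " (", nrow(x$monomers), " monomers, mean identity ",
      sprintf("%.1f", x$evidence$mean_identity[1]), "%)\n", sep = "")
  invisible(x)
}
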