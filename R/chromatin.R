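# ChIP/input fragment mapping, input-normalized fold enrichment, nucleosome
# phasing by coverage autocorrelation, and particle spacing.

coverage_from_fragments <- function(fr, ref_len) {
  tracks <- list()
  for (r in names(ref_len)) {
    x <- fr[fr$ref == r, ]
    len <- ref_len[[r]]
    if (nrow(x) == 0) { tracks[[r]] <- numeric(len); next }
    d <- tabulate(pmin(x$start, len - 1L) + 1L, len) -
      tabulate(pmin(x$end, len) + 1L, len)
    tracks[[r]] <- cumsum(d)
  }
  tracks
}

count_mismatch <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# built-in paired-end mapper: exact seed lookup + full-length verification,
# best single concordant placement per pair
map_pairs <- function(r1, r2, refs, insert_min, insert_max, seed_length,
                      max_mismatch) {
  spacer <- strrep("N", insert_max + 100L)
  offsets <- cumsum(c(0, head(nchar(refs$sequence) + nchar(spacer), -1)))
  names(offsets) <- refs$ref
  big <- paste(refs$sequence, collapse = spacer)
  big_dna <- Biostrings::DNAString(big)
  ref_of <- function(pos) {
    # pos is 1-based in concatenated space; returns 0-based local coordinate
    i <- findInterval(pos, offsets)
    list(ref = refs$ref[i], local = pos - 1L - offsets[i])
  }
  rc2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(r2)))
  seed_hits <- function(seqs) {
    seqs <- unname(seqs)
    ok <- nchar(seqs) >= seed_length
    seeds <- substr(seqs, 1L, seed_length)
    seeds[!ok] <- strrep("A", seed_length)
    m <- Biostrings::matchPDict(
      Biostrings::PDict(Biostrings::DNAStringSet(seeds)), big_dna)
    st <- Biostrings::startIndex(m)
    map(seq_along(seqs), function(i) {
      if (!ok[i]) return(integer())
      st[[i]] %||% integer()
    })
  }
  h1 <- seed_hits(r1)
  h2 <- seed_hits(rc2)
  n <- length(r1)
  out_ref <- character(n); out_start <- integer(n); out_end <- integer(n)
  status <- character(n)
  for (i in seq_len(n)) {
    cands <- list()
    for (p1 in h1[[i]]) {
      # search generously; the insert bound is enforced on the selected
      # placement so near-misses are counted as discarded, not unmapped
      mates <- h2[[i]][h2[[i]] >= p1 &
                         h2[[i]] + nchar(r2[i]) - p1 <= 3L * insert_max]
      for (p2 in mates) {
        frag_start <- p1 - 1L               # 0-based in concatenated space
        frag_end <- p2 - 1L + nchar(r2[i])
        insert <- frag_end - frag_start
        mm <- count_mismatch(substr(big, p1, p1 + nchar(r1[i]) - 1L), r1[i]) +
          count_mismatch(substr(big, p2, p2 + nchar(r2[i]) - 1L), rc2[i])
        if (mm > max_mismatch) next
        cands[[length(cands) + 1L]] <- list(start = frag_start, end = frag_end,
                                            insert = insert, mm = mm)
      }
    }
    if (length(cands) == 0) { status[i] <- "unmapped"; next }
    mm <- map_dbl(cands, "mm")
    starts <- map_dbl(cands, "start")
    best <- cands[[order(mm, starts)[1]]]   # best score, then leftmost
    if (best$insert < insert_min || best$insert > insert_max) {
      status[i] <- "discarded"; next
    }
    loc <- ref_of(best$start + 1L)
    status[i] <- "mapped"
    out_ref[i] <- loc$ref
    out_start[i] <- as.integer(loc$local)
    out_end[i] <- as.integer(loc$local + best$insert)
  }
  list(
    fragments = tibble(ref = out_ref[status == "mapped"],
                       start = out_start[status == "mapped"],
                       end = out_end[status == "mapped"]) |>
      mutate(mid = as.integer(round((.data$start + .data$end) / 2))),
    n_unmapped = sum(status == "unmapped"),
    n_discarded = sum(status == "discarded")
  )
}

#' Build fragment coverage tracks over array references
#'
#' Accepts either already-placed fragments (a `chip_fragments` object or a
#' tibble with `ref`, `start`, `end` — the imported-alignment path) or raw
#' paired reads (a tibble with `r1`, `r2`), which are placed by the
#' built-in mapper: exact-seed lookup plus full-length verification, best
#' single concordant placement per pair, insert length restricted to
#' `[insert_min, insert_max]`. Coverage is fragment-span (pair) coverage,
#' the biological unit for MNase data, not per-read coverage.
#'
#' @param x Fragments or paired reads (see Details).
#' @param refs Reference tibble (`ref`, `sequence`, `length`), e.g. from
#'   [array_refs()]; required for the mapping path and for track lengths.
#' @param insert_min,insert_max Concordant insert bounds in bp
#'   (default 10 and 700).
#' @param seed_length Exact seed length for the mapper (default 25).
#' @param max_mismatch Per-pair mismatch budget (default 4).
#' @param build_coverage If `FALSE`, skip per-base tracks (fragment counts
#'   only; sufficient for enrichment).
#' @return Object of class `coverage_tracks`: `tracks` (named list of
#'   per-base fragment coverage), `counts` (fragments per ref),
#'   `fragments`, `total_mapped`, `n_unmapped`, `n_discarded`.
#' @export
map_fragments <- function(x, refs = NULL, insert_min = 10L, insert_max = 700L,
                          seed_length = 25L, max_mismatch = 4L,
                          build_coverage = TRUE) {
  n_unmapped <- 0L; n_discarded <- 0L
  if (inherits(x, "chip_fragments")) {
    fr <- select(x$fragments, "ref", "start", "end", "mid")
    refs <- refs %||% x$refs
  } else if (is.data.frame(x) && all(c("ref", "start", "end") %in% names(x))) {
    fr <- as_tibble(x)
    if (!"mid" %in% names(fr)) {
      fr <- mutate(fr, mid = as.integer(round((.data$start + .data$end) / 2)))
    }
    if (is.null(refs)) stopf("refs required when passing a fragment table")
  } else if (is.data.frame(x) && all(c("r1", "r2") %in% names(x))) {
    if (is.null(refs) || is.null(refs$sequence)) {
      stopf("refs with sequences required for the mapping path")
    }
    m <- map_pairs(x$r1, x$r2, refs, insert_min, insert_max, seed_length,
                   max_mismatch)
    fr <- m$fragments
    n_unmapped <- m$n_unmapped
    n_discarded <- m$n_discarded
  } else {
    stopf("x must be chip_fragments, a fragment table, or a read-pair table")
  }
  if (nrow(refs) == 0) stopf("empty reference set")
  ref_len <- setNames(as.integer(refs$length), refs$ref)
  bad_insert <- fr$end - fr$start < insert_min | fr$end - fr$start > insert_max
  n_discarded <- n_discarded + sum(bad_insert)
  fr <- fr[!bad_insert, ]
  counts <- fr |> count(.data$ref, name = "n_fragments")
  counts <- left_join(tibble(ref = names(ref_len)), counts, by = "ref") |>
    mutate(n_fragments = ifelse(is.na(.data$n_fragments), 0L, .data$n_fragments))
  structure(
    list(tracks = if (build_coverage) coverage_from_fragments(fr, as.list(ref_len)) else NULL,
         counts = counts, fragments = fr, ref_len = ref_len,
         total_mapped = nrow(fr), n_unmapped = n_unmapped,
         n_discarded = n_discarded),
    class = "coverage_tracks"
  )
}

#' @export
print.coverage_tracks <- function(x, ...) {
  cat("<coverage_tracks> ", x$total_mapped, " fragments over ",
      nrow(x$counts), " reference(s); ", x$n_discarded, " discarded, ",
      x$n_unmapped, " unmapped\n", sep = "")
  invisible(x)
}

#' Input-normalized fold enrichment per satellite class
#'
#' `E_c = (ChIP fragments on class c / ChIP total) / (input fragments on
#' class c / input total)`, the fragment-count quotient; per-array folds
#' are also reported and averaged per class (the headline values average
#' three or more arrays per class).
#'
#' @param chip,input `coverage_tracks` for the ChIP mark and its input,
#'   over identical references.
#' @param class_map Tibble `ref`, `sat_class` assigning references to
#'   classes (`NA` or missing refs count as unassigned background).
#' @return Object of class `enrichment_table`: tibble with `sat_class`,
#'   `n_arrays`, `chip_fraction`, `input_fraction`, `fold` (pooled
#'   quotient; `NA` flagged when the input fraction is zero) and
#'   `mean_array_fold`; the per-array table is in `attr(, "per_array")`.
#' @export
fold_enrichment <- function(chip, input, class_map) {
  if (!setequal(chip$counts$ref, input$counts$ref)) {
    stopf("ChIP and input tracks must cover identical references")
  }
  joined <- chip$counts |>
    dplyr::rename(chip_n = "n_fragments") |>
    left_join(dplyr::rename(input$counts, input_n = "n_fragments"), by = "ref") |>
    left_join(class_map, by = "ref")
  chip_total <- sum(joined$chip_n)
  input_total <- sum(joined$input_n)
  per_array <- joined |>
    filter(!is.na(.data$sat_class)) |>
    mutate(chip_fraction = .data$chip_n / chip_total,
           input_fraction = .data$input_n / input_total,
           fold = ifelse(.data$input_fraction > 0,
                         .data$chip_fraction / .data$input_fraction, NA_real_))
  out <- per_array |>
    group_by(.data$sat_class) |>
    summarise(n_arrays = n(),
              chip_fraction = sum(.data$chip_n) / chip_total,
              input_fraction = sum(.data$input_n) / input_total,
              mean_array_fold = mean(.data$fold, na.rm = TRUE),
              .groups = "drop") |>
    mutate(fold = ifelse(.data$input_fraction > 0,
                         .data$chip_fraction / .data$input_fraction, NA_real_)) |>
    select("sat_class", "n_arrays", "chip_fraction", "input_fraction",
           "fold", "mean_array_fold")
  attr(out, "per_array") <- per_array
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Nucleosome phasing from a coverage track
#'
#' Mean-subtracted coverage autocorrelation over a lag window; the
#' dominant period is the best local maximum of the (lightly smoothed)
#' autocorrelation inside the window — a local maximum is required because
#' fragment-span coverage is intrinsically autocorrelated below the
#' fragment length, which would otherwise always win the argmax. The
#' phasing score is the peak height above the median window background,
#' normalized by the lag-0 autocorrelation: `S = (rho(T) - median) /
#' (1 - median)`, clipped to `[0, 1]`.
#'
#' @param track Numeric per-base fragment coverage vector.
#' @param lag_min,lag_max Lag window in bp (default 50-400).
#' @param score_threshold Minimum score to call the track phased
#'   (default 0.3).
#' @param smooth Width (odd, bp) of the running-mean smoother applied to
#'   the autocorrelation before peak finding (default 11).
#' @param monomer_length If given, the period is also expressed in monomer
#'   units.
#' @return Object of class `phasing_profile`: `period` (bp; `NA` when
#'   unphased), `score`, `phased`, `spacing_monomers`, and the `acf`
#'   tibble (`lag`, `rho`).
#' @export
phasing <- function(track, lag_min = 50L, lag_max = 400L,
                    score_threshold = 0.3, smooth = 11L,
                    monomer_length = NULL) {
  n <- length(track)
  if (n < lag_max + 50L) stopf("track too short for the lag window")
  x <- track - mean(track)
  denom <- sum(x^2)
  empty <- structure(list(period = NA_integer_, score = 0, phased = FALSE,
                          spacing_monomers = NA_real_,
                          acf = tibble(lag = integer(), rho = double())),
                     class = "phasing_profile")
  if (denom <= 0) return(empty)
  lags <- 1L:lag_max
  rho <- map_dbl(lags, function(l) sum(x[1:(n - l)] * x[(l + 1):n]) / denom)
  sm <- as.numeric(stats::filter(rho, rep(1 / smooth, smooth), sides = 2))
  sm[is.na(sm)] <- rho[is.na(sm)]
  win <- which(lags >= lag_min & lags <= lag_max)
  half <- max(smooth %/% 2, 3L)
  is_peak <- map_dbl(win, function(i) {
    lo <- max(1L, i - half); hi <- min(length(sm), i + half)
    as.numeric(sm[i] >= max(sm[lo:hi]) && sm[i] > sm[lo] && sm[i] > sm[hi])
  }) > 0
  acf_tab <- tibble(lag = lags, rho = rho)
  cand <- win[is_peak]
  if (length(cand) == 0) {
    out <- empty; out$acf <- acf_tab
    return(out)
  }
  bg <- median(rho[win])
  best_rho <- max(rho[cand])
  # among peaks within 5% of the best, prefer the smallest lag (harmonics)
  top <- cand[rho[cand] >= best_rho - 0.05 * abs(best_rho)]
  period <- lags[min(top)]
  s <- (rho[period] - bg) / (1 - bg)
  s <- min(max(s, 0), 1)
  phased <- s >= score_threshold
  structure(
    list(period = if (phased) as.integer(period) else NA_integer_,
         score = s, phased = phased,
         spacing_monomers = if (!is.null(monomer_length) && phased) {
           period / monomer_length
         } else NA_real_,
         acf = acf_tab),
    class = "phasing_profile"
  )
}

#' @export
print.phasing_profile <- function(x, ...) {
  if (x$phased) {
    cat("<phasing_profile> period ", x$period, " bp, score ",
        sprintf("%.2f", x$score), "\n", sep = "")
  } else {
    cat("<phasing_profile> unphased (score ", sprintf("%.2f", x$score), ")\n",
        sep = "")
  }
  invisible(x)
}

#' Modal chromatin-particle spacing in monomer units
#'
#' Calls coverage peaks (local maxima of the smoothed track above
#' median + k * MAD) and reports the most frequent inter-peak distance
#' rounded to whole monomer units.
#'
#' @param track Numeric per-base fragment coverage.
#' @param monomer_length Monomer length in bp.
#' @param k_mad Peak threshold in MAD units above the median (default 0.5;
#'   the threshold is additionally capped at the midpoint between median
#'   and maximum so that strongly phased, bimodal tracks keep their peaks).
#' @param smooth Running-mean smoother width in bp (default 31).
#' @return List: `spacing_monomers` (modal rounded spacing; `NA` when
#'   fewer than 3 peaks), `peaks` (0-based positions), `spacings_bp`.
#' @export
particle_spacing <- function(track, monomer_length, k_mad = 0.5, smooth = 31L) {
  n <- length(track)
  sm <- as.numeric(stats::filter(track, rep(1 / smooth, smooth), sides = 2))
  sm[is.na(sm)] <- track[is.na(sm)]
  thr <- min(median(sm) + k_mad * mad(sm), (median(sm) + max(sm)) / 2)
  w <- max(floor(monomer_length / 4), 5L)
  peaks <- integer()
  i <- w + 1L
  while (i <= n - w) {
    lo <- i - w; hi <- i + w
    if (sm[i] >= max(sm[lo:hi]) && sm[i] > thr) {
      peaks <- c(peaks, i - 1L)   # 0-based
      i <- i + w                  # skip the plateau
    }
    i <- i + 1L
  }
  if (length(peaks) < 3) {
    return(list(spacing_monomers = NA_real_, peaks = peaks,
                spacings_bp = diff(peaks)))
  }
  sp <- diff(peaks)
  units <- round(sp / monomer_length)
  units <- units[units >= 1]
  if (length(units) == 0) {
    return(list(spacing_monomers = NA_real_, peaks = peaks, spacings_bp = sp))
  }
  tab <- table(units)
  list(spacing_monomers = as.numeric(names(tab)[which.max(tab)]),
       peaks = peaks, spacings_bp = sp)
}

#' Per-side fold enrichment on junction arrays
#'
#' For reads carrying two or more satellite classes, computes the
#' input-normalized fold separately for each class side (fragments counted
#' by midpoint within the side's blocks), then summarizes per junction
#' type. Sides shorter than `min_monomers` monomer lengths are excluded;
#' sides with zero input coverage are flagged undefined.
#'
#' @param annotations List of `array_annotation` objects for junction
#'   reads (reference names must match the tracks).
#' @param chip,input `coverage_tracks` over the junction read references.
#' @param library A `consensus_library` (monomer lengths).
#' @param min_monomers Minimum side span in monomer units (default 2).
#' @return List: `per_side` tibble (`read_id`, `junction_type`,
#'   `sat_class`, `chip_fraction`, `input_fraction`, `fold`) and `summary`
#'   (mean fold per junction type and class side).
#' @export
junction_profile <- function(annotations, chip, input, library,
                             min_monomers = 2L) {
  mono_len <- setNames(library$units$monomer_length, library$units$sat_class)
  chip_total <- chip$total_mapped
  input_total <- input$total_mapped
  rows <- list()
  for (a in annotations) {
    sat_blocks <- filter(a$blocks, .data$kind == "sat")
    classes <- unique(sat_blocks$label)
    if (length(classes) < 2) next
    jtype <- paste(sort(classes), collapse = "-")
    for (cls in classes) {
      b <- filter(sat_blocks, .data$label == cls)
      span <- sum(b$end - b$start)
      if (span < min_monomers * unname(mono_len[cls])) next
      in_side <- function(tr) {
        fr <- tr$fragments[tr$fragments$ref == a$read_id, ]
        sum(map_int(seq_len(nrow(b)), function(k) {
          sum(fr$mid >= b$start[k] & fr$mid < b$end[k])
        }))
      }
      cf <- in_side(chip) / chip_total
      gf <- in_side(input) / input_total
      rows[[length(rows) + 1L]] <- tibble(
        read_id = a$read_id, junction_type = jtype, sat_class = cls,
        chip_fraction = cf, input_fraction = gf,
        fold = ifelse(gf > 0, cf / gf, NA_real_)
      )
    }
  }
  per_side <- bind_rows(rows)
  summary <- if (nrow(per_side)) {
    per_side |>
      group_by(.data$junction_type, .data$sat_class) |>
      summarise(n_sides = n(), mean_fold = mean(.data$fold, na.rm = TRUE),
                .groups = "drop")
  } else {
    tibble(junction_type = character(), sat_class = character(),
           n_sides = integer(), mean_fold = double())
  }
  list(per_side = per_side, summary = summary)
}
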