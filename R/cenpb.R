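# CENP-B box detection and classification in minor-satellite monomers.

#' Scan monomers for CENP-B boxes
#'
#' Places the 17 bp motif at the expected consensus offset +/- `slack` in
#' each monomer and keeps the best placement by IUPAC-aware mismatch count
#' (ties broken toward the expected offset, then leftmost). A box is
#' "intact" iff it has zero mismatches at the motif's non-degenerate
#' positions; any mismatch at an essential position (15-17 by default)
#' raises `essential_hit`.
#'
#' @param monomers Monomer tibble from [decompose_array()] (must carry
#'   `sequence`; MiSat-family monomers expected).
#' @param motif A [cenpb_motif()].
#' @param expected_offset 0-based box offset within the monomer (defaults
#'   to the library annotation carried by `unit`).
#' @param unit Optional consensus unit row supplying `expected_offset`.
#' @param slack Placement slack in bp around the expected offset
#'   (default 5, absorbing small indels).
#' @param max_mismatch Mismatch budget for "intact" (default 0, the
#'   strictest reading of intact vs variant).
#' @return Tibble of box calls: `ordinal`, `offset` (0-based within the
#'   monomer), `box_seq`, `n_mismatch`, `intact`, `essential_hit`,
#'   `mismatches` (list-column: `position`, `motif_symbol`, `observed`),
#'   `scannable` (`FALSE` when the monomer is too short).
#' @export
scan_boxes <- function(monomers, motif, expected_offset = NULL, unit = NULL,
                       slack = 5L, max_mismatch = 0L) {
  if (is.null(expected_offset)) {
    if (is.null(unit) || is.na(unit$box_offset)) {
      stopf("expected_offset not given and unit carries no box_offset annotation")
    }
    expected_offset <- unit$box_offset
  }
  ess <- motif$essential_positions
  rows <- map(seq_len(nrow(monomers)), function(i) {
    seq_i <- monomers$sequence[i]
    mlen <- nchar(seq_i)
    base_row <- tibble(ordinal = monomers$ordinal[i], offset = NA_integer_,
                       box_seq = NA_character_, n_mismatch = NA_integer_,
                       intact = NA, essential_hit = NA,
                       mismatches = list(tibble(position = integer(),
                                                motif_symbol = character(),
                                                observed = character())),
                       scannable = FALSE)
    if (mlen < 17) return(base_row)
    offs <- max(0L, expected_offset - slack):min(mlen - 17L, expected_offset + slack)
    if (length(offs) == 0) return(base_row)
    best <- NULL
    for (o in offs) {
      window <- split_bases(substr(seq_i, o + 1L, o + 17L))
      mm <- which(!iupac_match(motif$symbols, window))
      cand <- list(offset = o, mm = mm, window = window,
                   dist = abs(o - expected_offset))
      if (is.null(best) || length(mm) < length(best$mm) ||
          (length(mm) == length(best$mm) && cand$dist < best$dist)) {
        best <- cand
      }
    }
    mm_tbl <- tibble(position = best$mm,
                     motif_symbol = motif$symbols[best$mm],
                     observed = best$window[best$mm])
    tibble(ordinal = monomers$ordinal[i], offset = as.integer(best$offset),
           box_seq = paste(best$window, collapse = ""),
           n_mismatch = length(best$mm),
           intact = length(best$mm) <= max_mismatch,
           essential_hit = any(best$mm %in% ess),
           mismatches = list(mm_tbl), scannable = TRUE)
  })
  bind_rows(rows)
}

#' Fraction of intact CENP-B boxes
#'
#' @param calls Box-call tibble from [scan_boxes()] (optionally carrying an
#'   `array_id` column for per-array aggregation).
#' @return One row per array (plus an `overall` row when several arrays are
#'   present): `n_boxes`, `n_intact`, `intact_fraction`,
#'   `intact_percent`. Arrays with no scannable box are flagged with
#'   `NA` fractions.
#' @export
intact_density <- function(calls) {
  if (nrow(calls) == 0) stopf("no box calls")
  calls <- mutate(calls, array_id = calls[["array_id"]] %||% "array")
  per_array <- calls |>
    group_by(.data$array_id) |>
    summarise(n_boxes = sum(.data$scannable),
              n_intact = sum(.data$intact & .data$scannable, na.rm = TRUE),
              .groups = "drop") |>
    mutate(intact_fraction = ifelse(.data$n_boxes > 0,
                                    .data$n_intact / .data$n_boxes, NA_real_),
           intact_percent = 100 * .data$intact_fraction)
  if (length(unique(per_array$array_id)) > 1) {
    overall <- summarise(per_array, array_id = "overall",
                         n_boxes = sum(.data$n_boxes),
                         n_intact = sum(.data$n_intact)) |>
      mutate(intact_fraction = ifelse(.data$n_boxes > 0,
                                      .data$n_intact / .data$n_boxes, NA_real_),
             intact_percent = 100 * .data$intact_fraction)
    per_array <- bind_rows(per_array, overall)
  }
  per_array
}

#' Cluster observed box sequences at full identity
#'
#' Groups observed 17-mers exactly (identity 1.0 clustering collapses to
#' exact-sequence grouping) and counts occurrences.
#'
#' @param calls Box-call tibble from [scan_boxes()].
#' @return Tibble `box_seq`, `count`, `intact`, sorted by count
#'   (descending) then sequence.
#' @export
cluster_box_variants <- function(calls) {
  if (nrow(calls) == 0) stopf("no box calls")
  calls |>
    filter(.data$scannable) |>
    group_by(.data$box_seq) |>
    summarise(count = n(), intact = first(.data$intact), .groups = "drop") |>
    arrange(desc(.data$count), .data$box_seq)
}
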