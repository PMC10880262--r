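# Synthetic data generator: long reads with known block/monomer/box truth,
# and ChIP/input fragment sets with known per-class fold and phasing truth.

#' Specify a synthetic satellite array
#'
#' Describes one tandem satellite array for [simulate_array_read()]. The
#' per-monomer divergence is realized as an exact substitution count
#' `round(divergence * monomer_length)` at positions sampled without
#' replacement, so the recorded truth is the realized mismatch fraction.
#'
#' @param sat_class One of [sat_classes].
#' @param n_monomers Number of monomer copies (>= 1).
#' @param divergence Substitution fraction in `[0, 1]`; scalar or one value
#'   per monomer.
#' @param indel_rate Single-base indel fraction per monomer (default 0).
#' @param intact_box_fraction For MiSat-family classes, the fraction of
#'   monomers whose CENP-B box window is left untouched; the remaining
#'   monomers carry at least one substitution at a non-degenerate motif
#'   position. `NULL` (default) applies no box constraint.
#' @param cassettes Tibble of interspersed non-satellite inserts with
#'   columns `after_monomer`, `length`, `label` (e.g. a TE-like cassette).
#' @param direction_switch_at Monomer index after which the remainder of
#'   the array is inverted (reverse-complemented), or `NULL`.
#' @param junction_partner A second `array_spec` concatenated after this
#'   array to form a junction read, or `NULL`.
#' @param seed Integer seed; output is a deterministic function of the spec.
#' @return An object of class `array_spec`.
#' @export
array_spec <- function(sat_class, n_monomers, divergence = 0,
                       indel_rate = 0, intact_box_fraction = NULL,
                       cassettes = NULL, direction_switch_at = NULL,
                       junction_partner = NULL, seed = 1L) {
  if (!sat_class %in% sat_classes) stopf("unknown sat_class '%s'", sat_class)
  n_monomers <- as.integer(n_monomers)
  if (n_monomers < 1) stopf("n_monomers must be >= 1")
  check_fraction(divergence, "divergence")
  check_fraction(indel_rate, "indel_rate")
  if (!is.null(intact_box_fraction)) check_fraction(intact_box_fraction, "intact_box_fraction")
  if (!length(divergence) %in% c(1L, n_monomers)) {
    stopf("divergence must be scalar or length n_monomers")
  }
  if (!is.null(cassettes)) {
    cassettes <- as_tibble(cassettes)
    stopifnot(all(c("after_monomer", "length", "label") %in% names(cassettes)))
    if (any(cassettes$after_monomer > n_monomers) || any(cassettes$after_monomer < 0)) {
      stopf("cassette position beyond array (n_monomers = %d)", n_monomers)
    }
  }
  if (!is.null(junction_partner) && !inherits(junction_partner, "array_spec")) {
    stopf("junction_partner must be an array_spec")
  }
  structure(
    list(sat_class = sat_class, n_monomers = n_monomers,
         divergence = divergence, indel_rate = indel_rate,
         intact_box_fraction = intact_box_fraction, cassettes = cassettes,
         direction_switch_at = direction_switch_at,
         junction_partner = junction_partner, seed = as.integer(seed)),
    class = "array_spec"
  )
}

# mutate one monomer; returns list(seq, n_sub, n_ins, n_del, intact)
mutate_monomer <- function(cons, L, d, indel_rate, box_window, nondegen_box_pos,
                           intact) {
  bases <- split_bases(cons)
  n_sub <- round(d * L)
  forbidden <- if (isTRUE(intact)) box_window else integer()
  pool <- setdiff(seq_len(L), forbidden)
  sub_pos <- integer()
  if (isFALSE(intact)) {
    # guarantee a variant box: one substitution at a non-degenerate motif position
    forced <- sample(nondegen_box_pos, 1L)
    extra <- max(n_sub - 1L, 0L)
    sub_pos <- c(forced, sample(setdiff(pool, forced), min(extra, L - 1L)))
  } else if (n_sub > 0) {
    sub_pos <- sample(pool, min(n_sub, length(pool)))
  }
  if (length(sub_pos)) bases[sub_pos] <- mutate_base(bases[sub_pos])
  n_ins <- 0L; n_del <- 0L
  n_indel <- round(indel_rate * L)
  if (n_indel > 0) {
    for (k in seq_len(n_indel)) {
      pos <- sample(setdiff(seq_along(bases), forbidden), 1L)
      if (runif(1) < 0.5) {
        bases <- append(bases, sample(DNA_BASES, 1L), after = pos)
        n_ins <- n_ins + 1L
      } else {
        bases <- bases[-pos]
        n_del <- n_del + 1L
      }
    }
  }
  list(seq = paste(bases, collapse = ""), n_sub = length(sub_pos),
       n_ins = n_ins, n_del = n_del)
}

simulate_one_array <- function(spec, library, read_id) {
  unit <- library_unit(library, spec$sat_class)
  cons <- unit$sequence
  L <- unit$monomer_length
  n <- spec$n_monomers
  d <- rep(spec$divergence, length.out = n)
  set.seed(spec$seed)

  has_box <- !is.na(unit$box_offset) && !is.null(spec$intact_box_fraction)
  box_window <- if (!is.na(unit$box_offset)) (unit$box_offset + 1L):(unit$box_offset + 17L) else integer()
  nondegen_box_pos <- if (length(box_window)) {
    box_window[!library$motif$degenerate]
  } else integer()
  intact_flags <- rep(NA, n)
  if (has_box) {
    k <- round(spec$intact_box_fraction * n)
    intact_flags <- rep(FALSE, n)
    intact_flags[sample.int(n, k)] <- TRUE
  }

  pieces <- map(seq_len(n), function(i) {
    m <- mutate_monomer(cons, L, d[i], spec$indel_rate, box_window,
                        nondegen_box_pos, if (has_box) intact_flags[i] else NA)
    m$ordinal <- i
    m$strand <- "+"
    m
  })

  # inversion: the tail segment is reverse-complemented as a unit, so its
  # monomers appear reverse-complemented and in reversed order
  if (!is.null(spec$direction_switch_at)) {
    sw <- as.integer(spec$direction_switch_at)
    if (sw < 1 || sw >= n) stopf("direction_switch_at must lie in [1, n_monomers)")
    tail_idx <- (sw + 1):n
    tail_pieces <- rev(pieces[tail_idx])
    tail_pieces <- map(tail_pieces, function(p) {
      p$seq <- revcomp(p$seq); p$strand <- "-"; p
    })
    pieces <- c(pieces[1:sw], tail_pieces)
  }

  # interleave cassettes (positions count monomers in read order)
  elements <- list()
  cas <- spec$cassettes
  cas_after <- if (is.null(cas)) integer() else cas$after_monomer
  if (!is.null(cas) && any(cas_after == 0)) {
    for (j in which(cas_after == 0)) {
      elements[[length(elements) + 1L]] <-
        list(kind = "nonsat", seq = random_dna(cas$length[j]), label = cas$label[j])
    }
  }
  for (i in seq_len(n)) {
    p <- pieces[[i]]
    elements[[length(elements) + 1L]] <-
      list(kind = "sat", seq = p$seq, label = spec$sat_class, monomer = p)
    if (!is.null(cas)) {
      for (j in which(cas_after == i)) {
        elements[[length(elements) + 1L]] <-
          list(kind = "nonsat", seq = random_dna(cas$length[j]), label = cas$label[j])
      }
    }
  }

  # assemble and record truth covering every base exactly once
  seqs <- map_chr(elements, "seq")
  lens <- nchar(seqs)
  ends <- cumsum(lens)
  starts <- ends - lens
  monomers <- list(); blocks <- list()
  for (i in seq_along(elements)) {
    e <- elements[[i]]
    if (e$kind == "sat") {
      p <- e$monomer
      monomers[[length(monomers) + 1L]] <- tibble(
        read_id = read_id, ordinal = p$ordinal, start = starts[i], end = ends[i],
        strand = p$strand, sat_class = spec$sat_class,
        true_divergence = p$n_sub / L, n_sub = p$n_sub, n_ins = p$n_ins,
        n_del = p$n_del,
        intact_box = if (has_box) intact_flags[p$ordinal] else NA
      )
    }
    blocks[[length(blocks) + 1L]] <- tibble(
      read_id = read_id, start = starts[i], end = ends[i],
      label = e$label, kind = e$kind,
      strand = if (e$kind == "sat") e$monomer$strand else "."
    )
  }
  blocks <- bind_rows(blocks)
  # merge adjacent same-label same-strand truth blocks
  blocks <- blocks |>
    mutate(grp = cumsum(c(1, as.integer(
      .data$label[-1] != .data$label[-n()] | .data$strand[-1] != .data$strand[-n()]
    )))) |>
    group_by(.data$grp) |>
    summarise(read_id = first(.data$read_id), start = min(.data$start),
              end = max(.data$end), label = first(.data$label),
              kind = first(.data$kind), strand = first(.data$strand),
              .groups = "drop") |>
    select(-"grp") |>
    arrange(.data$start)

  list(sequence = paste(seqs, collapse = ""), blocks = blocks,
       monomers = bind_rows(monomers))
}

#' Simulate one long read carrying a satellite array
#'
#' Builds the read as an ordered concatenation of mutated monomer copies,
#' with optional interspersed non-satellite cassettes, a direction switch
#' (inversion of the array tail) and a junction partner array appended at
#' the end. Ground truth covers every emitted base exactly once.
#'
#' @param spec An [array_spec()].
#' @param library A `consensus_library`.
#' @param read_id Identifier for the emitted read.
#' @return List of class `sat_read` with elements `read_id`, `sequence`,
#'   `blocks` (truth block tibble: `start`, `end`, `label`, `kind`,
#'   `strand`) and `monomers` (per-monomer truth: ordinal, coordinates,
#'   strand, realized divergence, indel counts, intact-box flag).
#' @export
simulate_array_read <- function(spec, library, read_id = "synthetic_read") {
  res <- simulate_one_array(spec, library, read_id)
  if (!is.null(spec$junction_partner)) {
    part <- simulate_one_array(spec$junction_partner, library, read_id)
    off <- nchar(res$sequence)
    part$blocks <- mutate(part$blocks, start = .data$start + off, end = .data$end + off)
    part$monomers <- mutate(part$monomers, start = .data$start + off,
                            end = .data$end + off,
                            ordinal = .data$ordinal + max(res$monomers$ordinal %||% 0L))
    res$sequence <- paste0(res$sequence, part$sequence)
    res$blocks <- bind_rows(res$blocks, part$blocks)
    res$monomers <- bind_rows(res$monomers, part$monomers)
  }
  structure(list(read_id = read_id, sequence = res$sequence,
                 blocks = res$blocks, monomers = res$monomers),
            class = "sat_read")
}

#' @export
print.sat_read <- function(x, ...) {
  cat("<sat_read> ", x$read_id, ": ", nchar(x$sequence), " bp, ",
      nrow(x$monomers), " monomers, ", nrow(x$blocks), " truth blocks\n", sep = "")
  invisible(x)
}

#' Simulate a cohort of satellite reads
#'
#' @param specs List of [array_spec()] objects (seeds should differ).
#' @param library A `consensus_library`.
#' @param ids Read identifiers (default `read_001`, ...).
#' @return List with `reads` (named character vector), `blocks` and
#'   `monomers` (combined truth tibbles), and `sat_reads` (the individual
#'   [simulate_array_read()] results).
#' @export
simulate_cohort <- function(specs, library, ids = NULL) {
  ids <- ids %||% sprintf("read_%03d", seq_along(specs))
  out <- map2(specs, ids, function(s, id) simulate_array_read(s, library, id))
  list(
    reads = setNames(map_chr(out, "sequence"), ids),
    blocks = bind_rows(map(out, "blocks")),
    monomers = bind_rows(map(out, "monomers")),
    sat_reads = out
  )
}

#' Specify a synthetic ChIP or input sample
#'
#' @param mark One of `"CENP-A"`, `"H3K9me3"`, `"H3K27me3"`, `"input"`.
#' @param fold_by_class Named numeric vector mapping satellite classes to
#'   fold enrichment (>= 0); ignored for `mark = "input"`.
#' @param phased If `TRUE`, ChIP fragment midpoints on satellite blocks are
#'   drawn from Gaussians centered once per nucleosome period.
#' @param nucleosome_period_bp Phasing period in bp; alternatively give
#'   `particle_spacing_monomers` and the period is that many monomer
#'   lengths.
#' @param particle_spacing_monomers Nucleosome spacing in monomer units.
#' @param phasing_sd Gaussian SD (bp) of midpoints around nucleosome
#'   centers (default 15).
#' @param fragment_length_mean,fragment_length_sd MNase fragment length
#'   model, default 150 +/- 15 bp (mononucleosomes).
#' @param read_length Read length for emitted pairs (default 75 bp).
#' @param depth Target mean input fragment coverage over the satellite
#'   references (default 50).
#' @param seed Integer seed.
#' @return An object of class `chip_spec`.
#' @export
chip_spec <- function(mark, fold_by_class = NULL, phased = FALSE,
                      nucleosome_period_bp = NULL,
                      particle_spacing_monomers = NULL, phasing_sd = 15,
                      fragment_length_mean = 150, fragment_length_sd = 15,
                      read_length = 75, depth = 50, seed = 1L) {
  marks <- c("CENP-A", "H3K9me3", "H3K27me3", "input")
  if (!mark %in% marks) stopf("mark must be one of %s", paste(marks, collapse = ", "))
  if (mark != "input") {
    if (is.null(fold_by_class) || is.null(names(fold_by_class))) {
      stopf("fold_by_class must be a named numeric vector for ChIP marks")
    }
    if (any(fold_by_class < 0)) stopf("fold_by_class values must be >= 0")
  }
  if (depth <= 0) stopf("depth must be > 0")
  structure(
    list(mark = mark, fold_by_class = fold_by_class, phased = phased,
         nucleosome_period_bp = nucleosome_period_bp,
         particle_spacing_monomers = particle_spacing_monomers,
         phasing_sd = phasing_sd,
         fragment_length_mean = fragment_length_mean,
         fragment_length_sd = fragment_length_sd,
         read_length = read_length, depth = depth, seed = as.integer(seed)),
    class = "chip_spec"
  )
}

#' Build an array-reference table from simulated reads
#'
#' Converts [simulate_array_read()] outputs into the reference table used by
#' [simulate_chip_fragments()] and [map_fragments()]: one row per reference
#' with its satellite block annotation (non-satellite truth blocks are kept
#' with their own labels).
#'
#' @param sat_reads List of `sat_read` objects.
#' @param library A `consensus_library` (for monomer lengths).
#' @return Tibble: `ref`, `sequence`, `length`, `blocks` (list-column of
#'   block tibbles with `start`, `end`, `sat_class`, `monomer_length`).
#' @export
array_refs <- function(sat_reads, library) {
  rows <- map(sat_reads, function(sr) {
    blocks <- sr$blocks |>
      mutate(sat_class = ifelse(.data$kind == "sat", .data$label, NA_character_),
             monomer_length = map_int(.data$label, function(lb) {
               if (lb %in% library$units$sat_class) {
                 as.integer(library_unit(library, lb)$monomer_length)
               } else NA_integer_
             })) |>
      select("start", "end", "sat_class", "monomer_length")
    tibble(ref = sr$read_id, sequence = sr$sequence,
           length = nchar(sr$sequence), blocks = list(blocks))
  })
  bind_rows(rows)
}

#' Background decoy length for a ChIP experiment
#'
#' The smallest background reference (with 10% headroom) under which the
#' ChIP fragment-mass balance `sum(fold_c * g_c) <= 1` is feasible for the
#' given folds. A ChIP sample and its matched input must be simulated over
#' the same background length for the input-normalized quotient to be
#' meaningful; compute it once from the largest folds in the experiment
#' and pass it to every [simulate_chip_fragments()] call.
#'
#' @param refs Reference table from [array_refs()].
#' @param fold_by_class Named fold vector (use the largest fold per class
#'   across all marks in the experiment).
#' @return Background length in bp.
#' @export
chip_background_length <- function(refs, fold_by_class) {
  blocks <- bind_rows(refs$blocks) |>
    filter(!is.na(.data$sat_class)) |>
    mutate(len = .data$end - .data$start)
  per_class <- blocks |>
    group_by(.data$sat_class) |>
    summarise(len = sum(.data$len), .groups = "drop")
  folds <- map_dbl(per_class$sat_class, function(cls) {
    f <- fold_by_class[cls]
    if (is.na(f)) 1 else unname(f)
  })
  max(as.integer(ceiling(1.1 * sum(folds * per_class$len))), 1000L)
}

#' Simulate ChIP or input fragments over array references
#'
#' Input fragments are placed uniformly over the references plus a
#' background decoy reference. ChIP fragments are placed so that the
#' expected fragment mass on a satellite class equals `fold * input mass`,
#' with the background absorbing the remainder; the input-normalized fold
#' estimator therefore recovers the spec fold exactly in expectation. When
#' `phased`, ChIP midpoints on satellite blocks are Gaussian around centers
#' spaced one nucleosome period apart.
#'
#' @param refs Reference table from [array_refs()].
#' @param spec A [chip_spec()].
#' @param background_length Length (bp) of the unannotated background
#'   reference; defaults to [chip_background_length()] under this spec's
#'   folds. A ChIP sample and its matched input must share this value
#'   (compute it once via [chip_background_length()]); an error is raised
#'   if `sum(fold_c * g_c) > 1`.
#' @param emit_reads If `TRUE`, attach paired-end read sequences
#'   (`r1`, `r2`) cut from the reference sequences.
#' @return Object of class `chip_fragments`: `fragments` tibble
#'   (`ref`, `start`, `end`, `mid`), `refs` (including `.background`),
#'   `blocks`, and the generating `spec`.
#' @export
simulate_chip_fragments <- function(refs, spec, background_length = NULL,
                                    emit_reads = FALSE) {
  if (nrow(refs) == 0) stopf("empty reference set")
  set.seed(spec$seed)
  blocks <- bind_rows(map(seq_len(nrow(refs)), function(i) {
    mutate(refs$blocks[[i]], ref = refs$ref[i])
  })) |>
    mutate(len = .data$end - .data$start)
  sat_len_by_class <- blocks |>
    filter(!is.na(.data$sat_class)) |>
    group_by(.data$sat_class) |>
    summarise(len = sum(.data$len), .groups = "drop")

  is_input <- spec$mark == "input"
  fold_of <- function(cls) {
    if (is_input || is.na(cls)) return(1)
    f <- spec$fold_by_class[cls]
    if (is.na(f)) stopf("fold_by_class missing class '%s'", cls)
    unname(f)
  }
  if (is.null(background_length)) {
    background_length <- chip_background_length(
      refs, if (is_input) setNames(numeric(0), character(0)) else spec$fold_by_class)
  }
  background_length <- max(as.integer(background_length), 1000L)

  all_blocks <- bind_rows(
    select(blocks, "ref", "start", "end", "sat_class", "monomer_length", "len"),
    tibble(ref = ".background", start = 0L, end = background_length,
           sat_class = NA_character_, monomer_length = NA_integer_,
           len = background_length)
  )
  total_len <- sum(all_blocks$len)
  g <- all_blocks$len / total_len                    # input mass per block
  if (is_input) {
    w <- g
  } else {
    w <- map_dbl(seq_len(nrow(all_blocks)), function(i) {
      if (all_blocks$ref[i] == ".background") return(NA_real_)
      fold_of(all_blocks$sat_class[i]) * g[i]
    })
    rem <- 1 - sum(w, na.rm = TRUE)
    if (rem < 0) {
      stopf("fold_by_class infeasible: sum(fold * input fraction) = %.3f > 1; increase background_length",
            1 - rem)
    }
    w[is.na(w)] <- rem
  }

  sat_total <- sum(blocks$len)
  g_sat <- sat_total / total_len
  n_frag <- max(1000L, round(spec$depth * sat_total / spec$fragment_length_mean / g_sat))

  idx <- sample.int(nrow(all_blocks), n_frag, replace = TRUE, prob = w)
  b_start <- all_blocks$start[idx]
  b_len <- all_blocks$len[idx]
  phased_here <- (!is_input) && isTRUE(spec$phased) & !is.na(all_blocks$sat_class[idx])
  period <- spec$nucleosome_period_bp
  if (is.null(period) && !is.null(spec$particle_spacing_monomers)) {
    period_by_block <- spec$particle_spacing_monomers * all_blocks$monomer_length[idx]
  } else {
    period_by_block <- rep(period %||% NA_real_, n_frag)
  }
  mid <- b_start + runif(n_frag) * b_len
  if (any(phased_here)) {
    ph <- which(phased_here & !is.na(period_by_block))
    Tb <- period_by_block[ph]
    n_centers <- pmax(floor(b_len[ph] / Tb), 1)
    center_k <- floor(runif(length(ph)) * n_centers)
    centers <- b_start[ph] + center_k * Tb + Tb / 2
    mid[ph] <- rnorm(length(ph), mean = centers, sd = spec$phasing_sd)
  }
  flen <- pmax(round(rnorm(n_frag, spec$fragment_length_mean, spec$fragment_length_sd)), 20L)
  ref_len <- setNames(c(refs$length, background_length), c(refs$ref, ".background"))
  frag_ref <- all_blocks$ref[idx]
  rl <- unname(ref_len[frag_ref])
  start <- pmin(pmax(round(mid - flen / 2), 0L), pmax(rl - flen, 0L))
  end <- pmin(start + flen, rl)
  fragments <- tibble(ref = frag_ref, start = as.integer(start),
                      end = as.integer(end),
                      mid = as.integer(round((start + end) / 2)))

  out_refs <- bind_rows(
    select(refs, "ref", "length"),
    tibble(ref = ".background", length = background_length)
  )
  if (emit_reads) {
    seqs <- c(setNames(refs$sequence, refs$ref),
              setNames(random_dna(background_length), ".background"))
    rlb <- spec$read_length
    fragments <- fragments |>
      mutate(
        r1 = unname(substr(seqs[.data$ref], .data$start + 1L,
                           pmin(.data$start + rlb, .data$end))),
        r2 = unname(map_chr(substr(seqs[.data$ref],
                                   pmax(.data$end - rlb + 1L, .data$start + 1L),
                                   .data$end), revcomp))
      )
    attr(fragments, "ref_seqs") <- seqs
  }
  structure(list(fragments = fragments, refs = out_refs,
                 blocks = select(all_blocks, -"len"), spec = spec),
            class = "chip_fragments")
}

#' @export
print.chip_fragments <- function(x, ...) {
  cat("<chip_fragments> mark ", x$spec$mark, ": ", nrow(x$fragments),
      " fragments over ", nrow(x$refs), " reference(s)\n", sep = "")
  invisible(x)
}

#' Write simulated paired-end reads as FASTQ
#'
#' @param fragments `chip_fragments` produced with `emit_reads = TRUE`.
#' @param path_r1,path_r2 Output FASTQ paths for the two mates.
#' @export
write_fastq_pair <- function(fragments, path_r1, path_r2) {
  fr <- fragments$fragments
  if (is.null(fr[["r1"]])) stopf("fragments were simulated without emit_reads = TRUE")
  ids <- sprintf("frag_%06d", seq_len(nrow(fr)))
  wr <- function(seqs, path) {
    q <- strrep("I", nchar(seqs))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", q), path)
  }
  wr(fr$r1, path_r1)
  wr(fr$r2, path_r2)
  invisible(c(path_r1, path_r2))
}
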