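# Fragment mapping, enrichment, phasing, particle spacing, junctions.

three_arrays <- function(sat_class, n, seed0) {
  srs <- lapply(1:3, function(i) {
    simulate_array_read(
      array_spec(sat_class, n, divergence = 0.05, seed = seed0 + i),
      test_lib, read_id = sprintf("%s_arr%d", sat_class, i))
  })
  array_refs(srs, test_lib)
}

test_that("one placed pair increments fragment coverage over its span", {
  refs <- tibble::tibble(ref = "r", sequence = strrep("ACGT", 100), length = 400L)
  fr <- tibble::tibble(ref = "r", start = 100L, end = 250L)
  tr <- map_fragments(fr, refs)
  expect_equal(sum(tr$tracks$r), 150)
  expect_equal(tr$tracks$r[101], 1)
  expect_equal(tr$tracks$r[250], 1)
  expect_equal(tr$tracks$r[100], 0)
  expect_equal(tr$tracks$r[251], 0)
})

test_that("the built-in mapper recovers exact placements and discards discordant pairs", {
  sr <- make_read("MiSat120", 20, divergence = 0.05, seed = 120)
  refs <- array_refs(list(sr), test_lib)[, c("ref", "sequence", "length")]
  ch <- simulate_chip_fragments(array_refs(list(sr), test_lib),
                                chip_spec("input", depth = 2, seed = 121),
                                background_length = 2000, emit_reads = TRUE)
  seqs <- attr(ch$fragments, "ref_seqs")
  refs <- dplyr::bind_rows(refs, tibble::tibble(ref = ".background",
                                                sequence = unname(seqs[".background"]),
                                                length = 2000L))
  mt <- map_fragments(ch$fragments[, c("r1", "r2")], refs)
  expect_equal(mt$total_mapped, nrow(ch$fragments))
  expect_equal(mt$fragments$ref, ch$fragments$ref)
  expect_equal(mt$fragments$start, ch$fragments$start)
  expect_equal(mt$fragments$end, ch$fragments$end)
  # discordant pair: insert 900 > 700
  bad <- tibble::tibble(r1 = substr(sr$sequence, 1, 75),
                        r2 = centrosat:::revcomp(substr(sr$sequence, 826, 900)))
  mb <- map_fragments(bad, refs)
  expect_equal(mb$n_discarded, 1L)
  expect_equal(mb$total_mapped, 0L)
})

test_that("simulated depth is recovered as mean coverage", {
  sr <- make_read("MiSat120", 50, divergence = 0.05, seed = 122)
  refs <- array_refs(list(sr), test_lib)
  ch <- simulate_chip_fragments(refs, chip_spec("input", depth = 50, seed = 123),
                                background_length = 20000)
  tr <- map_fragments(ch)
  expect_equal(mean(tr$tracks[[sr$read_id]]), 50, tolerance = 0.05)
})

test_that("fold enrichment is the fraction quotient with flagged zeros", {
  counts <- function(ns) {
    tibble::tibble(ref = names(ns), n_fragments = unname(as.integer(ns)))
  }
  mk_tracks <- function(ns) {
    structure(list(counts = counts(ns), total_mapped = sum(ns),
                   fragments = NULL), class = "coverage_tracks")
  }
  chip <- mk_tracks(c(a = 500, bg = 500))
  input <- mk_tracks(c(a = 250, bg = 750))
  e <- fold_enrichment(chip, input, tibble::tibble(ref = "a", sat_class = "X"))
  expect_equal(e$fold, 2)
  null <- fold_enrichment(input, input, tibble::tibble(ref = "a", sat_class = "X"))
  expect_equal(null$fold, 1)
  zero <- fold_enrichment(chip, mk_tracks(c(a = 0, bg = 1000)),
                          tibble::tibble(ref = "a", sat_class = "X"))
  expect_true(is.na(zero$fold))
})

test_that("fragment counts are conserved across class assignment", {
  refs <- three_arrays("MaSat", 30, 130)
  bg <- chip_background_length(refs, c(MaSat = 3.5))
  chip <- map_fragments(simulate_chip_fragments(
    refs, chip_spec("H3K9me3", c(MaSat = 3.5), depth = 30, seed = 131),
    background_length = bg), build_coverage = FALSE)
  expect_equal(sum(chip$counts$n_fragments), chip$total_mapped)
})

test_that("generator folds are recovered within 10% at depth 50", {
  refs <- three_arrays("MaSat", 40, 140)
  bg <- chip_background_length(refs, c(MaSat = 3.5))
  cmap <- tibble::tibble(ref = refs$ref, sat_class = "MaSat")
  chip <- map_fragments(simulate_chip_fragments(
    refs, chip_spec("H3K9me3", c(MaSat = 3.5), depth = 50, seed = 141),
    background_length = bg), build_coverage = FALSE)
  input <- map_fragments(simulate_chip_fragments(
    refs, chip_spec("input", depth = 50, seed = 142),
    background_length = bg), build_coverage = FALSE)
  e <- fold_enrichment(chip, input, cmap)
  expect_equal(e$fold, 3.5, tolerance = 0.1)
  expect_equal(e$n_arrays, 3L)
})

test_that("enrichment is invariant to ChIP sequencing depth", {
  refs <- three_arrays("MiSat120", 40, 150)
  bg <- chip_background_length(refs, c(MiSat120 = 5))
  cmap <- tibble::tibble(ref = refs$ref, sat_class = "MiSat120")
  input <- map_fragments(simulate_chip_fragments(
    refs, chip_spec("input", depth = 50, seed = 151),
    background_length = bg), build_coverage = FALSE)
  folds <- vapply(c(25, 50), function(d) {
    chip <- map_fragments(simulate_chip_fragments(
      refs, chip_spec("CENP-A", c(MiSat120 = 5), depth = d, seed = 152),
      background_length = bg), build_coverage = FALSE)
    fold_enrichment(chip, input, cmap)$fold
  }, numeric(1))
  expect_equal(folds[1], folds[2], tolerance = 0.05)
})

test_that("an ideal coverage comb phases at its period with a high score", {
  cov <- rep(0, 234 * 40)
  centers <- seq(117, length(cov) - 117, by = 234)
  for (c0 in centers) cov[(c0 - 60):(c0 + 60)] <- 1
  ph <- phasing(cov, monomer_length = 234)
  expect_equal(ph$period, 234L)
  expect_gt(ph$score, 0.8)
  expect_equal(ph$spacing_monomers, 1)
})

test_that("uniform noisy coverage is unphased and flat tracks score zero", {
  set.seed(160)
  ph <- phasing(rpois(8000, 30))
  expect_false(ph$phased)
  expect_true(is.na(ph$period))
  flat <- phasing(rep(5, 8000))
  expect_equal(flat$score, 0)
  expect_false(flat$phased)
})

test_that("phased and unphased simulations separate across seeds", {
  sr <- make_read("MaSat", 60, divergence = 0.03, seed = 161)
  refs <- array_refs(list(sr), test_lib)
  for (seed in c(1, 2, 3)) {
    phd <- simulate_chip_fragments(
      refs, chip_spec("H3K9me3", c(MaSat = 3.5), phased = TRUE,
                      nucleosome_period_bp = 234, depth = 50, seed = 162 + seed),
      background_length = 60000)
    s_ph <- phasing(map_fragments(phd)$tracks[[sr$read_id]])
    expect_gt(s_ph$score, 0.5)
    expect_equal(s_ph$period, 234L)
    unp <- simulate_chip_fragments(
      refs, chip_spec("CENP-A", c(MaSat = 3.5), phased = FALSE, depth = 50,
                      seed = 170 + seed),
      background_length = 60000)
    s_un <- phasing(map_fragments(unp)$tracks[[sr$read_id]])
    expect_lt(s_un$score, 0.3)
    expect_false(s_un$phased)
  }
})

test_that("particle spacing reports the modal monomer-unit distance", {
  cov <- rep(0, 120 * 60)
  for (c0 in seq(120, length(cov) - 120, by = 240)) {
    cov[(c0 - 40):(c0 + 40)] <- cov[(c0 - 40):(c0 + 40)] + 1
  }
  expect_equal(particle_spacing(cov, 120)$spacing_monomers, 2)
  cov1 <- rep(0, 120 * 60)
  for (c0 in seq(60, length(cov1) - 60, by = 120)) {
    cov1[(c0 - 30):(c0 + 30)] <- 1
  }
  expect_equal(particle_spacing(cov1, 120)$spacing_monomers, 1)
  expect_true(is.na(particle_spacing(rep(0, 1000), 120)$spacing_monomers))
})

test_that("noisy two-monomer CENP-A particles give modal spacing 2", {
  sr <- make_read("MiSat120", 80, divergence = 0.03, seed = 180)
  refs <- array_refs(list(sr), test_lib)
  ch <- simulate_chip_fragments(
    refs, chip_spec("CENP-A", c(MiSat120 = 20), phased = TRUE,
                    particle_spacing_monomers = 2, depth = 60, seed = 181),
    background_length = 250000)
  ps <- particle_spacing(map_fragments(ch)$tracks[[sr$read_id]], 120)
  expect_equal(ps$spacing_monomers, 2)
})

test_that("junction sides recover their separate folds", {
  srs <- lapply(1:3, function(i) {
    simulate_array_read(
      array_spec("MiSat120", 25, divergence = 0.05, seed = 190 + i,
                 junction_partner = array_spec("MaSat", 15, divergence = 0.05,
                                               seed = 195 + i)),
      test_lib, read_id = sprintf("jx%d", i))
  })
  refs <- array_refs(srs, test_lib)
  folds <- c(MiSat120 = 44, MaSat = 2.7)
  bg <- chip_background_length(refs, folds)
  chip <- map_fragments(simulate_chip_fragments(
    refs, chip_spec("CENP-A", folds, depth = 60, seed = 200),
    background_length = bg))
  input <- map_fragments(simulate_chip_fragments(
    refs, chip_spec("input", depth = 60, seed = 201),
    background_length = bg))
  anns <- lapply(srs, function(sr) {
    segment_and_type(sr$read_id,
                     scan_read(sr$sequence, test_lib, read_id = sr$read_id),
                     nchar(sr$sequence), test_lib)
  })
  jp <- junction_profile(anns, chip, input, test_lib)
  s <- jp$summary
  expect_equal(s$junction_type, rep("MaSat-MiSat120", 2))
  expect_equal(s$mean_fold[s$sat_class == "MiSat120"], 44, tolerance = 0.15)
  expect_equal(s$mean_fold[s$sat_class == "MaSat"], 2.7, tolerance = 0.15)
  # input vs itself: all sides at fold 1
  jp0 <- junction_profile(anns, input, input, test_lib)
  expect_true(all(abs(jp0$per_side$fold - 1) < 1e-9))
})
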