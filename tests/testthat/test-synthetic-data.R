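# Generator ground truth: construction, determinism, conservation.

test_that("exact arrays are verbatim consensus concatenations", {
  sr <- make_read("MiSat120", 3, divergence = 0, seed = 2)
  expect_equal(sr$sequence, strrep(mi120$sequence, 3))
  expect_equal(nrow(sr$monomers), 3L)
  expect_equal(sr$monomers$true_divergence, rep(0, 3))
})

test_that("cassettes add their length and a non-satellite truth block", {
  sr <- simulate_array_read(
    array_spec("MiSat120", 20, divergence = 0,
               cassettes = tibble::tibble(after_monomer = 10, length = 500,
                                          label = "TE_like"),
               seed = 3),
    test_lib)
  expect_equal(nchar(sr$sequence), 20L * 120L + 500L)
  nonsat <- dplyr::filter(sr$blocks, kind == "nonsat")
  expect_equal(nrow(nonsat), 1L)
  expect_equal(nonsat$end - nonsat$start, 500L)
  expect_equal(nonsat$start, 10L * 120L)
  expect_error(
    simulate_array_read(
      array_spec("MiSat120", 5,
                 cassettes = tibble::tibble(after_monomer = 9, length = 10,
                                            label = "x")),
      test_lib),
    "beyond")
})

test_that("truth covers every base exactly once", {
  specs <- list(
    array_spec("MiSat120", 10, divergence = 0.05, seed = 4,
               cassettes = tibble::tibble(after_monomer = 5, length = 300,
                                          label = "TE")),
    array_spec("MaSat", 8, divergence = 0.1, direction_switch_at = 4, seed = 5),
    array_spec("MiSat120", 6, divergence = 0.05, seed = 6,
               junction_partner = array_spec("MaSat", 6, divergence = 0.05, seed = 7))
  )
  for (sp in specs) {
    sr <- simulate_array_read(sp, test_lib)
    b <- dplyr::arrange(sr$blocks, start)
    expect_equal(b$start[1], 0L)
    expect_equal(b$end[nrow(b)], nchar(sr$sequence))
    if (nrow(b) > 1) expect_equal(b$start[-1], b$end[-nrow(b)])
  }
})

test_that("intact-box count is exactly round(fraction * n)", {
  for (f in c(0.67, 0.20)) {
    sr <- simulate_array_read(
      array_spec("MiSat120", 100, divergence = 0.05, intact_box_fraction = f,
                 seed = 8),
      test_lib)
    expect_equal(sum(sr$monomers$intact_box), round(f * 100))
  }
})

test_that("identical spec and seed give identical output", {
  a <- simulate_array_read(array_spec("MaSat", 10, divergence = 0.1, seed = 11),
                           test_lib)
  b <- simulate_array_read(array_spec("MaSat", 10, divergence = 0.1, seed = 11),
                           test_lib)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$monomers, b$monomers)
  c <- simulate_array_read(array_spec("MaSat", 10, divergence = 0.1, seed = 12),
                           test_lib)
  expect_false(identical(a$sequence, c$sequence))
})

test_that("realized divergence equals the recorded truth (conservation)", {
  sr <- make_read("MaSat", 20, divergence = 0.15, seed = 13)
  mono <- decompose_array(sr$sequence, masat)
  # alignment-recovered mismatch fraction equals generator truth per monomer
  expect_equal(mono$n_sub / 234, sr$monomers$true_divergence, tolerance = 1e-9)
})

test_that("chip fragment sets are deterministic and class-balanced", {
  sr <- make_read("MiSat120", 30, divergence = 0.05, seed = 14)
  refs <- array_refs(list(sr), test_lib)
  sp <- chip_spec("CENP-A", c(MiSat120 = 2), depth = 20, seed = 15)
  a <- simulate_chip_fragments(refs, sp, background_length = 20000)
  b <- simulate_chip_fragments(refs, sp, background_length = 20000)
  expect_identical(a$fragments, b$fragments)
  expect_error(simulate_chip_fragments(refs[0, ], sp), "empty")
  # infeasible fold/background combination is rejected, never silently rescaled
  expect_error(
    simulate_chip_fragments(refs, chip_spec("CENP-A", c(MiSat120 = 50),
                                            depth = 20, seed = 1),
                            background_length = 5000),
    "infeasible")
})

test_that("null ChIP (fold 1, unphased) matches input in expectation", {
  sr <- make_read("MiSat120", 30, divergence = 0.05, seed = 16)
  refs <- array_refs(list(sr), test_lib)
  bg <- 30000L
  chip <- simulate_chip_fragments(
    refs, chip_spec("CENP-A", c(MiSat120 = 1), depth = 60, seed = 17),
    background_length = bg)
  inp <- simulate_chip_fragments(
    refs, chip_spec("input", depth = 60, seed = 18), background_length = bg)
  f <- mean(chip$fragments$ref != ".background")
  g <- mean(inp$fragments$ref != ".background")
  expect_equal(f / g, 1, tolerance = 0.1)
})

test_that("phased midpoint placement produces the requested period", {
  sr <- make_read("MaSat", 60, divergence = 0.02, seed = 19)
  refs <- array_refs(list(sr), test_lib)
  ch <- simulate_chip_fragments(
    refs, chip_spec("H3K9me3", c(MaSat = 3), phased = TRUE,
                    nucleosome_period_bp = 234, depth = 50, seed = 20),
    background_length = 60000)
  mids <- ch$fragments$mid[ch$fragments$ref == sr$read_id]
  phase <- mids %% 234
  # midpoints concentrate around the nucleosome center (117) within each monomer
  expect_lt(mean(pmin(abs(phase - 117), 234 - abs(phase - 117))), 30)
})

test_that("paired reads are cut from the reference sequences", {
  sr <- make_read("MiSat120", 10, divergence = 0.05, seed = 21)
  refs <- array_refs(list(sr), test_lib)
  ch <- simulate_chip_fragments(
    refs, chip_spec("input", depth = 5, seed = 22),
    background_length = 5000, emit_reads = TRUE)
  fr <- ch$fragments
  on_array <- which(fr$ref == sr$read_id)[1:10]
  for (i in on_array) {
    expect_equal(fr$r1[i],
                 substr(sr$sequence, fr$start[i] + 1, fr$start[i] + nchar(fr$r1[i])))
  }
  p1 <- withr::local_tempfile(fileext = ".fq")
  p2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq_pair(ch, p1, p2)
  r1 <- read_reads(p1)
  expect_equal(length(r1), nrow(fr))
  expect_equal(unname(r1[1]), fr$r1[1])
})
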