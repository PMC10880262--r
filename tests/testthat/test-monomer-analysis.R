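# Monomer decomposition, identity, per-position variation, period, class.

test_that("exact concatenated monomers decompose at 100% identity", {
  dec <- decompose_array(strrep(mi120$sequence, 5), mi120)
  expect_equal(nrow(dec), 5L)
  expect_equal(dec$percent_identity, rep(100, 5))
  expect_equal(dec$start, seq(0L, 480L, by = 120L))
  expect_equal(dec$length, rep(120L, 5))
})

test_that("six substitutions in a 120-mer give identity 95.0", {
  bases <- strsplit(mi120$sequence, "")[[1]]
  pos <- c(5, 20, 41, 77, 99, 110)
  for (p in pos) bases[p] <- setdiff(c("A", "C", "G", "T"), bases[p])[1]
  mutated <- paste(bases, collapse = "")
  dec <- decompose_array(paste0(mi120$sequence, mutated, mi120$sequence), mi120)
  expect_equal(dec$percent_identity[2], 100 * 114 / 120)
  expect_equal(dec$n_sub[2], 6L)
})

test_that("a 14 bp deletion yields a 220-mer monomer with the deletion recorded", {
  m3 <- paste0(substr(masat$sequence, 1, 100), substr(masat$sequence, 115, 234))
  arr <- paste0(strrep(masat$sequence, 2), m3, strrep(masat$sequence, 2))
  dec <- decompose_array(arr, masat)
  expect_equal(nrow(dec), 5L)
  expect_equal(dec$length[3], 220L)
  expect_equal(dec$n_del[3], 14L)
  d <- dec$differences[[3]]
  expect_equal(sum(d$op == "del"), 14L)
})

test_that("recovered identity matches generator truth across the divergence grid", {
  for (d in c(0, 0.05, 0.10, 0.203)) {
    sr <- make_read("MiSat120", 30, divergence = d, seed = round(100 * d) + 50)
    dec <- decompose_array(sr$sequence, mi120)
    expect_equal(nrow(dec), 30L)
    expect_equal(mean(dec$percent_identity), 100 * (1 - d), tolerance = 0.011)
  }
})

test_that("decomposition mirrors under reverse complementation", {
  sr <- make_read("MiSat120", 10, divergence = 0.08, seed = 52)
  fwd <- decompose_array(sr$sequence, mi120)
  rev <- decompose_block(centrosat:::revcomp(sr$sequence), mi120, strand = "-")
  expect_equal(sort(rev$percent_identity), sort(fwd$percent_identity))
  n <- nchar(sr$sequence)
  expect_equal(sort(rev$start), sort(n - fwd$end))
  expect_true(all(rev$strand == "-"))
})

test_that("a block shorter than the consensus yields one flagged partial record", {
  dec <- decompose_array(substr(mi120$sequence, 1, 80), mi120)
  expect_equal(nrow(dec), 1L)
  expect_true(dec$partial[1])
})

test_that("per-position variation localizes substitutions", {
  # 10 copies, 5 of them substituted at consensus position 7
  bases <- strsplit(mi120$sequence, "")[[1]]
  bases[7] <- setdiff(c("A", "C", "G", "T"), bases[7])[1]
  mut <- paste(bases, collapse = "")
  arr <- paste0(strrep(mi120$sequence, 5), strrep(mut, 5))
  dec <- decompose_array(arr, mi120)
  vp <- per_position_variation(dec, mi120)
  expect_equal(vp$profile$variant_fraction[7], 0.5)
  expect_equal(sum(vp$profile$variant_fraction[-7]), 0)
  # all identical -> all-zero profile
  vp0 <- per_position_variation(decompose_array(strrep(mi120$sequence, 4), mi120),
                                mi120)
  expect_equal(sum(vp0$profile$variant_fraction), 0)
  expect_error(per_position_variation(dec[1, ], mi120), ">= 2")
})

test_that("mean profile variation agrees with mean identity", {
  sr <- make_read("MaSat", 25, divergence = 0.1, seed = 53)
  dec <- decompose_array(sr$sequence, masat)
  vp <- per_position_variation(dec, masat)
  expect_equal(mean(vp$profile$variant_fraction),
               1 - mean(dec$percent_identity) / 100, tolerance = 0.005)
  g <- glance(vp)
  expect_equal(g$n_monomers, 25L)
})

test_that("box-window mutations dominate the variation profile", {
  sr <- simulate_array_read(
    array_spec("MiSat120", 50, divergence = 0.02, intact_box_fraction = 0.2,
               seed = 54),
    test_lib)
  dec <- decompose_array(sr$sequence, mi120)
  vp <- per_position_variation(dec, mi120)
  box_win <- (mi120$box_offset + 1):(mi120$box_offset + 17)
  nd <- box_win[!test_lib$motif$degenerate]
  expect_gt(mean(vp$profile$variant_fraction[nd]),
            3 * mean(vp$profile$variant_fraction[-box_win]))
})

test_that("period estimation is exact on tandem arrays and null on noise", {
  expect_equal(estimate_period(strrep(mi120$sequence, 50))$period, 120L)
  for (seed in 1:5) {
    sr120 <- make_read("MiSat120", 50, divergence = 0.02, seed = 60 + seed)
    expect_equal(estimate_period(sr120$sequence)$period, 120L)
    sr234 <- make_read("MaSat", 50, divergence = 0.02, seed = 70 + seed)
    expect_equal(estimate_period(sr234$sequence)$period, 234L)
  }
  for (seed in 1:5) {
    expect_true(is.na(estimate_period(random_read(6000, 80 + seed))$period))
  }
})

test_that("class assignment separates the MiSat length variants", {
  expect_equal(assign_class(make_read("MiSat120", 15, 0.04, seed = 90)$sequence,
                            test_lib)$class, "MiSat120")
  expect_equal(assign_class(make_read("MiSat112", 15, 0.04, seed = 91)$sequence,
                            test_lib)$class, "MiSat112")
  expect_equal(assign_class(make_read("MiSat112_64", 15, 0.04, seed = 92)$sequence,
                            test_lib)$class, "MiSat112_64")
})

test_that("the divergent-MaSat rule requires more than 10 sub-threshold monomers", {
  div <- assign_class(
    simulate_array_read(
      array_spec("MaSat", 30, divergence = c(rep(0.3, 12), rep(0.05, 18)),
                 seed = 93), test_lib)$sequence,
    test_lib)
  expect_equal(div$class, "MaSat_divergent")
  edge <- assign_class(
    simulate_array_read(
      array_spec("MaSat", 30, divergence = c(rep(0.3, 5), rep(0.05, 25)),
                 seed = 94), test_lib)$sequence,
    test_lib)
  expect_equal(edge$class, "MaSat_homogeneous")
})

test_that("unclassifiable sequence is flagged", {
  cc <- assign_class(random_read(1500, 95), test_lib)
  expect_equal(cc$class, "unclassified")
  expect_s3_class(tidy(cc), "tbl_df")
})

test_that("dimer decomposition records the sub-unit boundary", {
  unit <- library_unit(test_lib, "MiSat112_64")
  dec <- decompose_array(strrep(unit$sequence, 4), unit)
  expect_equal(dec$subunit_boundary, rep(112L, 4))
})
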