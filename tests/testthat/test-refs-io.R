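# Consensus library loading and the external format boundary.

test_that("consensus library round-trips through FASTA with header tags", {
  path <- withr::local_tempfile(fileext = ".fasta")
  write_consensus_library(test_lib, path)
  lib2 <- load_consensus_library(path, test_lib$motif)
  expect_equal(lib2$units$sequence, test_lib$units$sequence)
  expect_equal(lib2$units$sat_class, test_lib$units$sat_class)
  expect_equal(lib2$units$box_offset, test_lib$units$box_offset)
  expect_equal(lib2$units$subunits, test_lib$units$subunits)
})

test_that("library loader validates records", {
  path <- withr::local_tempfile(fileext = ".fasta")
  # lowercase bases are upper-cased
  writeLines(c(">u class=MaSat", tolower(masat$sequence)), path)
  lib2 <- load_consensus_library(path, test_lib$motif)
  expect_equal(lib2$units$sequence[1], masat$sequence)
  expect_equal(lib2$units$monomer_length[1], 234L)
  # missing class tag
  writeLines(c(">u", masat$sequence), path)
  expect_error(load_consensus_library(path, test_lib$motif), "class")
  # unknown class tag names the record
  writeLines(c(">badrec class=FooSat", masat$sequence), path)
  expect_error(load_consensus_library(path, test_lib$motif), "badrec")
  # wrong length under strict checking
  writeLines(c(">short class=MiSat120", substr(mi120$sequence, 1, 119)), path)
  expect_error(load_consensus_library(path, test_lib$motif), "119")
  expect_silent(load_consensus_library(path, test_lib$motif, strict_length = FALSE))
  # empty file
  writeLines(character(), path)
  expect_error(load_consensus_library(path, test_lib$motif), "no records")
})

test_that("CENP-B motif construction enforces its invariants", {
  m <- cenpb_motif("NTTCGNNNNANNCGGGN")
  expect_equal(nchar(m$sequence), 17L)
  expect_true(all(c(15L, 16L, 17L) %in% m$essential_positions))
  expect_error(cenpb_motif("ACGT"), "17")
  expect_error(cenpb_motif("NTTCGNNNNANNCGGGN", essential_positions = c(1, 2)),
               "15, 16, 17")
  expect_error(cenpb_motif("NTTCGNNNNANNCGGG?"), "IUPAC")
})

test_that("BLAST tabular import applies the coordinate and strand conventions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("r1", "misat", "100.00", "120", "0", "0", "1", "120", "1", "120",
            "1e-50", "222"), collapse = "\t"),
    paste(c("r1", "misat", "95.00", "120", "6", "0", "240", "121", "1", "120",
            "1e-40", "200"), collapse = "\t")
  ), path)
  h <- parse_hits_tabular(path)
  # 1-based inclusive -> 0-based half-open
  expect_equal(h$read_start[1], 0L)
  expect_equal(h$read_end[1], 120L)
  expect_equal(h$strand[1], "+")
  # reversed coordinates normalize to read_start < read_end on the minus strand
  expect_equal(h$read_start[2], 120L)
  expect_equal(h$read_end[2], 240L)
  expect_equal(h$strand[2], "-")
  expect_equal(h$percent_identity, c(100, 95))
})

test_that("malformed BLAST tabular lines error with the line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c("r1", "misat", "100.00", "120", "0", "0", "1", "120", "1", "120",
            "1e-50", "222"), collapse = "\t"),
    paste(rep("y", 11), collapse = "\t")
  ), path)
  expect_error(parse_hits_tabular(path), "line 2")
  writeLines(paste(rep("x", 12), collapse = "\t"), path)
  expect_error(parse_hits_tabular(path), "line 1")
})

test_that("hit import/export is the identity on coordinates and strand", {
  sr <- make_read("MiSat120", 8, divergence = 0.05, seed = 5)
  hits <- scan_read(sr$sequence, test_lib, read_id = "r1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tabular(hits, path)
  back <- parse_hits_tabular(path)
  expect_equal(back$read_start, hits$read_start)
  expect_equal(back$read_end, hits$read_end)
  expect_equal(back$strand, hits$strand)
  expect_equal(back$read_id, hits$read_id)
})

test_that("RepeatMasker importer labels intervals and rejects bad input", {
  path <- system.file("extdata", "example_repeatmasker.out", package = "centrosat")
  rm <- parse_repeatmasker_out(path)
  expect_equal(nrow(rm), 2L)
  expect_equal(rm$family[1], "IAPEz-int")
  expect_equal(rm$repeat_class[1], "LTR/ERV2")
  expect_equal(rm$start[1], 1200L)   # 0-based half-open
  expect_equal(rm$end[1], 1700L)
  expect_equal(rm$strand[2], "-")
  # empty body after headers
  p2 <- withr::local_tempfile()
  writeLines(readLines(path)[1:3], p2)
  expect_equal(nrow(parse_repeatmasker_out(p2)), 0L)
  # end <= start
  bad <- readLines(path)
  bad[4] <- sub("1201  1700", "1700  1200", bad[4])
  writeLines(bad, p2)
  expect_error(parse_repeatmasker_out(p2), "end <= start")
  # unreadable header
  writeLines(c("nonsense", "x", "y"), p2)
  expect_error(parse_repeatmasker_out(p2), "header")
})

test_that("bedGraph writer run-length encodes and round-trips", {
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(c(0, 0, 3, 3), "r1", path)
  expect_equal(readLines(path), c("r1\t0\t2\t0", "r1\t2\t4\t3"))
  expect_equal(read_bedgraph(path), c(0, 0, 3, 3))
  cov <- c(rep(1, 5), rep(0, 3), 2)
  write_bedgraph(cov, "x", path)
  expect_equal(read_bedgraph(path), cov)
})

test_that("BED writer emits 0-based half-open lines and round-trips", {
  path <- withr::local_tempfile(fileext = ".bed")
  x <- tibble::tibble(read_id = "r1", start = 0L, end = 120L,
                      name = "MiSat120", strand = "+")
  write_bed(x, path)
  b <- read_bed(path)
  expect_equal(b$start, 0L)
  expect_equal(b$end, 120L)
  expect_equal(b$name, "MiSat120")
  expect_error(write_bed(tibble::tibble(read_id = "r", start = 5L, end = 5L), path),
               "start < end")
})

test_that("monomer tables survive a TSV round trip", {
  sr <- make_read("MiSat120", 5, divergence = 0.05, seed = 6)
  mono <- decompose_array(sr$sequence, mi120)
  tab <- mono[, c("ordinal", "start", "end", "strand", "sat_class",
                  "percent_identity", "length")]
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tab, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})
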