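#' Satellite classes known to the package
#'
#' Class labels for the mouse centromeric/pericentromeric repeat families:
#' 120-mer minor satellite (`MiSat120`), its 112-mer and 112-64-dimer length
#' variants, 234-mer major satellite (`MaSat`), the telocentric TLC satellite
#' (145-146 bp) and the telomeric `(TTAGGG)n` repeat (represented by a
#' multi-copy consensus unit).
#'
#' @export
sat_classes <- c("MiSat120", "MiSat112", "MiSat112_64", "MaSat", "TLC", "Telomere")

# expected monomer lengths per class used by the strict-length check;
# NA entries are validated by a predicate instead
.class_lengths <- list(
  MiSat120 = 120L, MiSat112 = 112L, MiSat112_64 = 176L, MaSat = 234L,
  TLC = c(145L, 146L), Telomere = NA_integer_
)

#' Construct a CENP-B box motif
#'
#' The CENP-B box is a 17 bp motif within minor-satellite monomers bound by
#' the CENP-B protein. The motif is supplied as an IUPAC-degenerate string;
#' positions 15-17 are conserved in functional boxes and are always part of
#' the essential set.
#'
#' @param sequence 17-symbol IUPAC DNA string.
#' @param essential_positions Integer vector of 1-based motif positions whose
#'   disruption is flagged as an essential hit. Must include 15, 16, 17.
#' @return An object of class `cenpb_motif`.
#' @export
cenpb_motif <- function(sequence, essential_positions = c(15L, 16L, 17L)) {
  sequence <- toupper(sequence)
  if (nchar(sequence) != 17) stopf("CENP-B box motif must be 17 symbols, got %d", nchar(sequence))
  sym <- split_bases(sequence)
  bad <- setdiff(sym, names(IUPAC_SETS))
  if (length(bad)) stopf("invalid IUPAC symbol(s) in motif: %s", paste(bad, collapse = ", "))
  essential_positions <- sort(unique(as.integer(essential_positions)))
  if (!all(essential_positions %in% 1:17)) stopf("essential positions must lie in 1..17")
  if (!all(c(15L, 16L, 17L) %in% essential_positions)) {
    stopf("essential positions must include 15, 16, 17")
  }
  structure(
    list(sequence = sequence, symbols = sym,
         essential_positions = essential_positions,
         degenerate = is_degenerate(sym)),
    class = "cenpb_motif"
  )
}

#' @export
print.cenpb_motif <- function(x, ...) {
  cat("<cenpb_motif> ", x$sequence, "\n  essential positions: ",
      paste(x$essential_positions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

new_consensus_library <- function(units, motif) {
  # per-library scratch cache (seed dictionaries for the scanner)
  structure(list(units = units, motif = motif, cache = new.env(parent = emptyenv())),
            class = "consensus_library")
}

#' @export
print.consensus_library <- function(x, ...) {
  cat("<consensus_library> ", nrow(x$units), " unit(s)\n", sep = "")
  print(select(x$units, "name", "sat_class", "monomer_length", "box_offset"))
  invisible(x)
}

validate_unit_length <- function(name, sat_class, len, subunit_lengths) {
  expected <- .class_lengths[[sat_class]]
  if (sat_class == "Telomere") {
    if (len %% 6 != 0) stopf("record '%s': Telomere unit length %d is not a multiple of 6", name, len)
    return(invisible(TRUE))
  }
  if (sat_class == "MiSat112_64") {
    if (!is.null(subunit_lengths) && sum(subunit_lengths) != len) {
      stopf("record '%s': subunit lengths %s do not sum to sequence length %d",
            name, paste(subunit_lengths, collapse = "+"), len)
    }
  }
  if (!len %in% expected) {
    stopf("record '%s': length %d does not match expected %s for class %s",
          name, len, paste(expected, collapse = "/"), sat_class)
  }
  invisible(TRUE)
}

#' Load a satellite consensus library from FASTA
#'
#' FASTA headers carry the class annotation as whitespace-separated
#' `key=value` tags after the record name, e.g.
#' `>misat_cons class=MiSat120 box_offset=60`. Recognized tags:
#' `class` (required, one of [sat_classes]), `box_offset` (0-based offset of
#' the CENP-B box within the monomer; MiSat-family classes), `subunits`
#' (e.g. `112+64` for the dimer class). Sequences are upper-cased.
#'
#' @param path FASTA file.
#' @param motif A [cenpb_motif] for downstream box scanning (the canonical
#'   motif is configuration, not a package constant).
#' @param strict_length If `TRUE` (default) record lengths must match the
#'   canonical monomer length of their class.
#' @return A `consensus_library`: `$units` tibble
#'   (name, sat_class, sequence, monomer_length, box_offset, subunits) and
#'   `$motif`.
#' @export
load_consensus_library <- function(path, motif, strict_length = TRUE) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stopf("consensus FASTA '%s' contains no records", path)
  headers <- names(seqs)
  units <- map(seq_along(seqs), function(i) {
    toks <- strsplit(trimws(headers[i]), "\\s+")[[1]]
    name <- toks[1]
    tags <- toks[-1]
    kv <- strsplit(tags, "=", fixed = TRUE)
    keys <- map_chr(kv, 1)
    vals <- map_chr(kv, function(x) if (length(x) > 1) x[2] else NA_character_)
    tagmap <- setNames(vals, keys)
    if (!"class" %in% keys) stopf("record '%s': missing class= tag in FASTA header", name)
    sat_class <- tagmap[["class"]]
    if (!sat_class %in% sat_classes) {
      stopf("record '%s': unknown satellite class '%s'", name, sat_class)
    }
    sequence <- toupper(as.character(seqs[[i]]))
    bad <- setdiff(unique(split_bases(sequence)), c(DNA_BASES, "N"))
    if (length(bad)) stopf("record '%s': invalid base(s) %s", name, paste(bad, collapse = ","))
    subunits <- if (!is.na(tagmap["subunits"] %||% NA)) {
      as.integer(strsplit(tagmap[["subunits"]], "+", fixed = TRUE)[[1]])
    } else NULL
    if (strict_length) validate_unit_length(name, sat_class, nchar(sequence), subunits)
    tibble(
      name = name, sat_class = sat_class, sequence = sequence,
      monomer_length = nchar(sequence),
      box_offset = as.integer(tagmap["box_offset"] %||% NA),
      subunits = list(subunits)
    )
  })
  new_consensus_library(bind_rows(units), motif)
}

#' Write a consensus library to FASTA
#'
#' Inverse of [load_consensus_library()]; headers round-trip losslessly.
#'
#' @param library A `consensus_library`.
#' @param path Output FASTA path.
#' @export
write_consensus_library <- function(library, path) {
  u <- library$units
  headers <- map_chr(seq_len(nrow(u)), function(i) {
    h <- paste0(u$name[i], " class=", u$sat_class[i])
    if (!is.na(u$box_offset[i])) h <- paste0(h, " box_offset=", u$box_offset[i])
    su <- u$subunits[[i]]
    if (!is.null(su)) h <- paste0(h, " subunits=", paste(su, collapse = "+"))
    h
  })
  x <- Biostrings::DNAStringSet(u$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Seeded synthetic stand-in consensus library
#'
#' The consensus sequences the mouse satellite literature uses are cited to
#' external references and are not bundled here; this builder generates a
#' synthetic stand-in library with the correct monomer lengths (120, 112,
#' 112+64, 234, 146 bp, and a 20-copy telomeric `TTAGGG` unit) and a CENP-B
#' box instance embedded at a fixed offset in the MiSat-family units. It is
#' intended for simulation, testing and examples; analyses of real reads
#' should load the published consensi via [load_consensus_library()].
#'
#' @param seed Integer seed; the library is a deterministic function of it.
#' @param motif The degenerate CENP-B box motif; the default is the published
#'   degenerate consensus `NTTCGNNNNANNCGGGN`.
#' @param box_instance Concrete 17-mer embedded in MiSat-family consensi;
#'   must match `motif` at all non-degenerate positions.
#' @return A `consensus_library`.
#' @export
synthetic_consensus_library <- function(seed = 101L,
                                        motif = cenpb_motif("NTTCGNNNNANNCGGGN"),
                                        box_instance = "CTTCGTTGGAAACGGGA") {
  if (nchar(box_instance) != 17) stopf("box_instance must be 17 bp")
  if (!all(iupac_match(motif$symbols, split_bases(box_instance)))) {
    stopf("box_instance is not compatible with the motif")
  }
  set.seed(as.integer(seed))
  embed_box <- function(seq, offset) {
    # offset is 0-based
    paste0(substr(seq, 1, offset), box_instance, substr(seq, offset + 18, nchar(seq)))
  }
  mi120 <- embed_box(random_dna(120), 60L)
  mi112 <- embed_box(random_dna(112), 50L)
  dimer <- paste0(embed_box(random_dna(112), 50L), random_dna(64))
  masat <- random_dna(234)
  tlc <- random_dna(146)
  telo <- paste(rep("TTAGGG", 20), collapse = "")
  units <- tibble(
    name = c("synthetic_MiSat120", "synthetic_MiSat112", "synthetic_MiSat112_64",
             "synthetic_MaSat", "synthetic_TLC", "synthetic_Telomere"),
    sat_class = sat_classes,
    sequence = c(mi120, mi112, dimer, masat, tlc, telo),
    monomer_length = nchar(c(mi120, mi112, dimer, masat, tlc, telo)),
    box_offset = c(60L, 50L, 50L, NA, NA, NA),
    subunits = list(NULL, NULL, c(112L, 64L), NULL, NULL, NULL)
  )
  new_consensus_library(units, motif)
}

#' Fetch one consensus unit by class
#'
#' @param library A `consensus_library`.
#' @param sat_class One of [sat_classes].
#' @return One-row tibble for the first unit of that class.
#' @export
library_unit <- function(library, sat_class) {
  u <- filter(library$units, .data$sat_class == !!sat_class)
  if (nrow(u) == 0) stopf("no consensus unit of class '%s' in library", sat_class)
  u[1, ]
}
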