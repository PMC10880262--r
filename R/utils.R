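# Internal helpers shared across modules.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
split_bases <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @noRd
random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# TRUE where observed base is compatible with the (possibly degenerate)
# motif symbol at that position; both inputs are character vectors of symbols
#' @noRd
iupac_match <- function(motif_sym, base) {
  mapply(function(m, b) b %in% (IUPAC_SETS[[m]] %||% character()),
         motif_sym, base, USE.NAMES = FALSE)
}

#' @noRd
is_degenerate <- function(motif_sym) {
  vapply(motif_sym, function(m) length(IUPAC_SETS[[m]] %||% "") > 1, logical(1))
}

# substitute a base with one of the three alternatives, uniformly
#' @noRd
mutate_base <- function(base) {
  vapply(base, function(b) sample(setdiff(DNA_BASES, b), 1), character(1),
         USE.NAMES = FALSE)
}

#' @noRd
stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

#' @noRd
check_fraction <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stopf("`%s` must lie in [0, 1]", name)
  }
  invisible(x)
}

# deterministic child seed so that independent stages under one master seed
# do not share RNG streams; kept below 2^31
#' @noRd
child_seed <- function(seed, tag) {
  (as.integer(seed) + sum(utf8ToInt(tag)) * 1009L) %% 2147483587L
}
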