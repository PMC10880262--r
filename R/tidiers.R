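# broom-style accessors for the fitted result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a phasing profile
#'
#' @param x A `phasing_profile`.
#' @param ... Ignored.
#' @return The autocorrelation tibble (`lag`, `rho`).
#' @export
tidy.phasing_profile <- function(x, ...) x$acf

#' One-row summary of a phasing profile
#'
#' @param x A `phasing_profile`.
#' @param ... Ignored.
#' @return Tibble with `period`, `score`, `phased`, `spacing_monomers`.
#' @export
glance.phasing_profile <- function(x, ...) {
  tibble(period = x$period, score = x$score, phased = x$phased,
         spacing_monomers = x$spacing_monomers)
}

#' Tidy a variation profile
#'
#' @param x A `variation_profile`.
#' @param ... Ignored.
#' @return The per-position tibble.
#' @export
tidy.variation_profile <- function(x, ...) x$profile

#' One-row summary of a variation profile
#'
#' @param x A `variation_profile`.
#' @param ... Ignored.
#' @return Tibble with `sat_class`, `n_monomers`, `mean_variation`,
#'   `max_variation`.
#' @export
glance.variation_profile <- function(x, ...) {
  tibble(sat_class = x$sat_class, n_monomers = x$n_monomers,
         mean_variation = mean(x$profile$variant_fraction),
         max_variation = max(x$profile$variant_fraction))
}

#' Tidy an array annotation
#'
#' @param x An `array_annotation`.
#' @param ... Ignored.
#' @return The ordered block tibble.
#' @export
tidy.array_annotation <- function(x, ...) x$blocks

#' One-row summary of an array annotation
#'
#' @param x An `array_annotation`.
#' @param ... Ignored.
#' @return Tibble with type, direction switch, block count and classes.
#' @export
glance.array_annotation <- function(x, ...) {
  tibble(read_id = x$read_id, read_length = x$read_length,
         array_type = x$array_type, direction_switch = x$direction_switch,
         n_blocks = nrow(x$blocks),
         classes = paste(x$junction_classes, collapse = ","))
}

#' Tidy a class call
#'
#' @param x A `class_call`.
#' @param ... Ignored.
#' @return The per-candidate evidence tibble.
#' @export
tidy.class_call <- function(x, ...) x$evidence

#' One-row summary of a class call
#'
#' @param x A `class_call`.
#' @param ... Ignored.
#' @return Tibble with the assigned class and supporting statistics.
#' @export
glance.class_call <- function(x, ...) {
  tibble(class = x$class, n_monomers = nrow(x$monomers),
         mean_identity = x$evidence$mean_identity[1])
}
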