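#' Storage element specification
#'
#' Describes the on-disk value type of a binary track: unsigned integers of
#' 1, 2, 4 or 8 bytes, or IEEE floating point of 4 or 8 bytes. The default
#' (2-byte unsigned) represents 2^16 = 65536 distinct count states per base;
#' pileup values exceeding the element maximum are saturated at
#' `2^(8 * width) - 1` and tallied as truncated positions in the build
#' statistics. Floating-point elements never saturate and allow fractional
#' signal such as microarray or mappability tracks.
#'
#' @param kind `"uint"` (unsigned integer, the default) or `"float"`.
#' @param width Bytes per element: 1, 2, 4 or 8 for `"uint"`; 4 or 8 for
#'   `"float"`. Default 2.
#' @return An object of class `element_spec` with fields `kind` and `width`.
#' @examples
#' element_spec()              # 2-byte unsigned, 65536 states
#' element_spec("float", 8)    # double-precision signal
#' @export
element_spec <- function(kind = c("uint", "float"), width = 2L) {
  kind <- match.arg(kind)
  width <- as.integer(width)
  if (length(width) != 1L || is.na(width) || !width %in% c(1L, 2L, 4L, 8L))
    usage_error("element width must be 1, 2, 4 or 8 bytes")
  if (kind == "float" && !width %in% c(4L, 8L))
    usage_error("floating-point elements must be 4 or 8 bytes wide")
  structure(list(kind = kind, width = width), class = "element_spec")
}

#' @export
print.element_spec <- function(x, ...) {
  cat(sprintf("<element_spec: %s, %d byte(s), %s states>\n", x$kind, x$width,
              if (x$kind == "uint") format(element_states(x), big.mark = ",")
              else "unbounded"))
  invisible(x)
}

#' Number of representable count states of an element
#'
#' For an unsigned integer element of `width` bytes this is
#' `2^(8 * width)` (65536 for the default); the largest storable value is
#' one less. Floating-point elements are unbounded (`Inf`).
#'
#' @param element An [element_spec()].
#' @return A number (possibly `Inf`).
#' @export
element_states <- function(element = element_spec()) {
  stopifnot(inherits(element, "element_spec"))
  if (element$kind == "uint") 2^(8 * element$width) else Inf
}

# Largest storable value (saturation bound).
element_max <- function(element) {
  if (element$kind == "uint") 2^(8 * element$width) - 1 else Inf
}

#' Payload size of a dense track
#'
#' Bytes needed to store one value per base over a genomic span, excluding
#' the fixed-size file header. A 250 Mb chromosome at the default 2 bytes
#' per base needs 500,000,000 bytes (~0.5 GB) per stratum, hence ~1.5 GB for
#' the three strata (forward, reverse, combined).
#'
#' @param span Number of bases covered (non-negative).
#' @param element An [element_spec()].
#' @return Payload size in bytes.
#' @examples
#' payload_size(250e6)                     # 5e8 bytes, one stratum
#' 3 * payload_size(250e6)                 # ~1.5 GB for three strata
#' @export
payload_size <- function(span, element = element_spec()) {
  stopifnot(inherits(element, "element_spec"))
  if (any(span < 0)) usage_error("span must be non-negative")
  span * element$width
}
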