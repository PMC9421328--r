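#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(
    class = c("inkaflow_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_input <- function(...) {
  stop(structure(
    class = c("inkaflow_input_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_format <- function(...) {
  stop(structure(
    class = c("inkaflow_format_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

## scalar checks used by config validators
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Site keys: the canonical row identity used throughout
## ("<protein>_<position><residue>", optionally "_M<multiplicity>").
make_site_key <- function(protein, position, residue, multiplicity = NULL) {
  if (length(protein) == 0L) return(character(0))  # paste0 drops 0-length args
  key <- paste0(protein, "_", position, residue)
  if (!is.null(multiplicity)) key <- paste0(key, "_M", multiplicity)
  key
}

#' Flanking-sequence site key
#'
#' Canonical site key used by phosphosite signature databases: the 15-mer
#' sequence window with the phosphoresidue (position 8) in lower case and
#' the flanks in upper case.
#'
#' @param window character vector of 15-mer sequence windows.
#' @return Character vector of normalized keys.
#' @export
flanking_key <- function(window) {
  stopifnot(all(nchar(window) == 15L))
  paste0(
    toupper(substr(window, 1L, 7L)),
    tolower(substr(window, 8L, 8L)),
    toupper(substr(window, 9L, 15L))
  )
}
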