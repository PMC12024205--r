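`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a classed hafes error
#'
#' All package errors carry a subclass of `hafes_error` so that callers (and
#' the CLI exit-code mapper) can dispatch on the failure kind:
#' `hafes_format_error` (unparseable KB file), `hafes_validation_error`
#' (invariant violations, bad codes), `hafes_screening_error` (logically
#' inconsistent complaint), `hafes_constraint_error` (empty or violated
#' device constraint), `hafes_usage_error` (bad CLI invocation),
#' `hafes_ordering_error` (workflow step out of order).
#'
#' @param message error text.
#' @param class subclass name.
#' @param ... extra condition fields (e.g. a `report`).
#' @noRd
hafes_abort <- function(message, class = "hafes_error", ...) {
  cond <- structure(
    class = unique(c(class, "hafes_error", "error", "condition")),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

# Recursively sort named list components so serialization is canonical.
# Unnamed lists (guide rows, solutions) keep their order: order is meaning.
canonical_sort <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm) && all(nzchar(nm))) {
    x <- x[order(nm, method = "radix")]
  }
  lapply(x, canonical_sort)
}

# Canonical JSON text: key-sorted, fixed formatting, full precision.
# Two serializations of structurally equal objects are byte-identical.
canonical_json <- function(x) {
  jsonlite::toJSON(canonical_sort(x), auto_unbox = TRUE, digits = NA,
                   pretty = 2, null = "null")
}

write_canonical_json <- function(x, path) {
  txt <- enc2utf8(as.character(canonical_json(x)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con = con, useBytes = TRUE)
  invisible(path)
}

# scalar coercion helpers used by the constructors
as_scalar_chr <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (length(x) != 1L || !is.character(x) && !is.factor(x))
    hafes_abort(sprintf("%s must be a single string", what),
                "hafes_validation_error")
  as.character(x)
}

as_scalar_num <- function(x, what) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    hafes_abort(sprintf("%s must be a single number", what),
                "hafes_validation_error")
  as.numeric(x)
}

as_scalar_int <- function(x, what) {
  v <- as_scalar_num(x, what)
  if (v != round(v))
    hafes_abort(sprintf("%s must be an integer", what),
                "hafes_validation_error")
  as.integer(v)
}
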