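#' The six-question self-assessment questionnaire
#'
#' Returns the packaged questionnaire schema: three sections (nature of the
#' complaint, listening context, impact assessment) each holding two of the
#' six complaint dimensions, with item labels resolved in the requested
#' locale. Item codes are 0-based integers in catalog order and never depend
#' on locale, so encoded responses are language-independent.
#'
#' @param locale language tag, `"en"` or `"fr"`. Any other tag falls back to
#'   English with a warning.
#' @return An object of class `hafes_questionnaire`: a list with `locale`,
#'   `sections` (dimension names per section), `dimensions` (per dimension a
#'   data frame of `code` and `label`), `sizes` (named integer vector of
#'   catalog sizes) and `ordinal` (names of the ordinal dimensions).
#' @examples
#' q <- get_questionnaire("fr")
#' q$sizes
#' head(q$dimensions$cause)
#' @export
get_questionnaire <- function(locale = "en") {
  locale <- as_scalar_chr(locale, "locale")
  if (!locale %in% .hafes_locales) {
    warning(sprintf("locale '%s' is not available; falling back to 'en'",
                    locale), call. = FALSE)
    locale <- "en"
  }
  dims <- lapply(names(.hafes_catalogs), function(d) {
    labels <- .hafes_catalogs[[d]][[locale]]
    data.frame(code = seq_along(labels) - 1L, label = labels,
               stringsAsFactors = FALSE)
  })
  names(dims) <- names(.hafes_catalogs)
  structure(
    list(locale = locale,
         sections = .hafes_sections,
         dimensions = dims,
         sizes = catalog_sizes(),
         ordinal = .hafes_ordinal_dimensions),
    class = "hafes_questionnaire"
  )
}

#' @export
print.hafes_questionnaire <- function(x, ...) {
  cat(sprintf("Self-assessment questionnaire (%s): %d dimensions\n",
              x$locale, length(x$dimensions)))
  for (sec in names(x$sections)) {
    cat(sprintf("  %s: %s\n", sec,
                paste(sprintf("%s (%d items)", x$sections[[sec]],
                              x$sizes[x$sections[[sec]]]), collapse = ", ")))
  }
  invisible(x)
}

#' Construct a complaint descriptor
#'
#' A complaint is six categorical codes, one per questionnaire dimension.
#' Codes are validated against the packaged catalog sizes.
#'
#' @param cause,specificity,environment,activity,frequency,discomfort
#'   integer item codes (0-based).
#' @return An object of class `hafes_complaint`: a named integer vector of
#'   length six.
#' @examples
#' complaint_descriptor(3, 0, 1, 0, 4, 1)  # whistling, quiet environment
#' @export
complaint_descriptor <- function(cause, specificity, environment, activity,
                                 frequency, discomfort) {
  codes <- c(cause = as_scalar_int(cause, "cause"),
             specificity = as_scalar_int(specificity, "specificity"),
             environment = as_scalar_int(environment, "environment"),
             activity = as_scalar_int(activity, "activity"),
             frequency = as_scalar_int(frequency, "frequency"),
             discomfort = as_scalar_int(discomfort, "discomfort"))
  sizes <- catalog_sizes()
  bad <- names(codes)[codes < 0L | codes >= sizes[names(codes)]]
  if (length(bad))
    hafes_abort(
      sprintf("complaint code out of catalog bounds for: %s",
              paste(bad, collapse = ", ")),
      "hafes_validation_error", dimensions = bad)
  structure(codes, class = "hafes_complaint")
}

as_complaint <- function(x) {
  if (inherits(x, "hafes_complaint")) return(x)
  x <- unlist(x)
  if (length(x) != 6L)
    hafes_abort("a complaint needs exactly six codes",
                "hafes_validation_error")
  if (is.null(names(x)) || !all(.hafes_dimensions %in% names(x)))
    names(x) <- .hafes_dimensions
  do.call(complaint_descriptor, as.list(x[.hafes_dimensions]))
}

#' @export
print.hafes_complaint <- function(x, ...) {
  cat("Complaint:", paste(sprintf("%s=%d", names(x), unclass(x)),
                          collapse = " "), "\n")
  invisible(x)
}

#' Encode questionnaire answers as a complaint descriptor
#'
#' Maps one selected item per dimension to its numeric code. Selections may
#' be given as item labels in the schema's locale or directly as integer
#' codes; the resulting codes are locale-invariant.
#'
#' @param answers named list or vector with one entry per dimension
#'   (`cause`, `specificity`, `environment`, `activity`, `frequency`,
#'   `discomfort`), each an item label or 0-based code.
#' @param schema a `hafes_questionnaire`, default the English schema.
#' @return A [complaint_descriptor()].
#' @examples
#' q <- get_questionnaire("en")
#' encode_complaint(list(cause = "The hearing aid whistles",
#'                       specificity = 0, environment = 1, activity = 0,
#'                       frequency = 4, discomfort = 1), q)
#' @export
encode_complaint <- function(answers, schema = get_questionnaire()) {
  stopifnot(inherits(schema, "hafes_questionnaire"))
  missing_dims <- setdiff(.hafes_dimensions, names(answers))
  if (length(missing_dims))
    hafes_abort(
      sprintf("incomplete response: missing %s",
              paste(missing_dims, collapse = ", ")),
      "hafes_validation_error", dimensions = missing_dims)
  codes <- lapply(.hafes_dimensions, function(d) {
    sel <- answers[[d]]
    cat_df <- schema$dimensions[[d]]
    if (is.character(sel)) {
      hit <- match(sel, cat_df$label)
      if (is.na(hit))
        hafes_abort(
          sprintf("unknown %s item: '%s' (locale %s)", d, sel, schema$locale),
          "hafes_validation_error", dimensions = d)
      cat_df$code[hit]
    } else {
      as_scalar_int(sel, d)
    }
  })
  names(codes) <- .hafes_dimensions
  do.call(complaint_descriptor, codes)
}

#' Decode a complaint descriptor into human-readable phrases
#'
#' The inverse of [encode_complaint()]: renders one phrase per dimension in
#' the requested locale. Re-encoding the decoded labels yields the original
#' descriptor in any locale.
#'
#' @param complaint a `hafes_complaint` (or coercible six-code vector).
#' @param locale `"en"` or `"fr"`.
#' @return Named character vector of six phrases.
#' @examples
#' decode_complaint(complaint_descriptor(3, 0, 1, 0, 4, 1), "fr")
#' @export
decode_complaint <- function(complaint, locale = "en") {
  complaint <- as_complaint(complaint)
  schema <- get_questionnaire(locale)
  out <- vapply(.hafes_dimensions, function(d) {
    schema$dimensions[[d]]$label[complaint[[d]] + 1L]
  }, character(1))
  out
}

#' Classify a sound level into an environment band
#'
#' Maps a dB SPL level onto the questionnaire's environment categories:
#' very quiet \[0, 20\], quiet (20, 60\], noisy (60, 80\], very noisy
#' (80, Inf). The four bands follow the printed anchor ranges 0-20, 25-60,
#' 65-80 and 90-140 dB, with each band extended up to the next band's lower
#' anchor so the classifier is total on non-negative levels; anything above
#' 140 dB is still "very noisy". The fifth environment catalog item
#' ("varies/unspecified") is never produced.
#'
#' @param level sound level in dB SPL, `>= 0`.
#' @return The environment item code (0-3), named with the band.
#' @examples
#' classify_environment(10)  # very_quiet
#' classify_environment(70)  # noisy
#' @export
classify_environment <- function(level) {
  level <- as_scalar_num(level, "level")
  if (level < 0)
    hafes_abort("sound level must be non-negative dB SPL",
                "hafes_validation_error")
  b <- .hafes_env_bands
  # intervals are (lower, upper]; level 0 belongs to the first band
  i <- max(findInterval(level, b$lower, left.open = TRUE), 1L)
  setNames(b$code[i], b$name[i])
}

#' Screen a complaint for logical consistency
#'
#' A consistency rule names a forbidden combination of item codes over two or
#' more dimensions (e.g. an own-voice complaint while listening to the radio
#' in a quiet room). Screening flags matching complaints; it never drops
#' them, so the audit trail is preserved and screening can be explicitly
#' overridden downstream.
#'
#' @param complaint a `hafes_complaint`.
#' @param rules list of consistency rules (see [consistency_rule()]),
#'   typically `kb$consistency_rules`.
#' @param locale locale for violation messages.
#' @return An object of class `hafes_consistency_report`: list with
#'   `consistent` (flag) and `violations` (data frame of `rule_id`,
#'   `message`).
#' @export
check_consistency <- function(complaint, rules, locale = "en") {
  complaint <- as_complaint(complaint)
  hits <- Filter(function(r) pattern_matches(r$pattern, complaint), rules)
  violations <- data.frame(
    rule_id = vapply(hits, function(r) r$id, character(1)),
    message = vapply(hits, function(r) {
      msg <- r$message
      if (is.list(msg)) (msg[[locale]] %||% msg[["en"]] %||% "") else msg
    }, character(1)),
    stringsAsFactors = FALSE
  )
  structure(list(consistent = nrow(violations) == 0L,
                 violations = violations),
            class = "hafes_consistency_report")
}

#' @export
print.hafes_consistency_report <- function(x, ...) {
  if (x$consistent) {
    cat("Complaint is logically consistent.\n")
  } else {
    cat("Inconsistent complaint;", nrow(x$violations), "rule(s) violated:\n")
    for (i in seq_len(nrow(x$violations)))
      cat(sprintf("  [%s] %s\n", x$violations$rule_id[i],
                  x$violations$message[i]))
  }
  invisible(x)
}

#' Size of the complaint description space
#'
#' The number of distinct complaints expressible with the questionnaire: the
#' product of the catalog sizes over the four nature/context dimensions
#' (cause, specificity, environment, activity), optionally multiplied by the
#' two impact dimensions (frequency, discomfort). With the packaged catalogs
#' the four-dimension space holds 18 x 7 x 5 x 8 = 5040 complaints and the
#' full six-dimension space 5040 x 7 x 3 = 105,840.
#'
#' @param schema a `hafes_questionnaire`.
#' @param include_impact include frequency and discomfort in the product?
#' @return Integer count.
#' @seealso [complaint_space()] for the explicit enumeration.
#' @examples
#' enumerate_complaint_space(get_questionnaire())          # 5040
#' enumerate_complaint_space(include_impact = TRUE)        # 105840
#' @export
enumerate_complaint_space <- function(schema = get_questionnaire(),
                                      include_impact = FALSE) {
  stopifnot(inherits(schema, "hafes_questionnaire"))
  dims <- c("cause", "specificity", "environment", "activity")
  if (include_impact) dims <- c(dims, "frequency", "discomfort")
  as.integer(prod(schema$sizes[dims]))
}

#' Enumerate the nature/context complaint space
#'
#' Explicit Cartesian enumeration of the cause x specificity x environment x
#' activity space (5040 rows with the packaged catalogs). Impact codes are
#' fixed at frequency 0, discomfort 0, which do not take part in guide
#' matching.
#'
#' @param schema a `hafes_questionnaire`.
#' @return Data frame with the six code columns, one row per complaint.
#' @export
complaint_space <- function(schema = get_questionnaire()) {
  sz <- schema$sizes
  grid <- expand.grid(cause = 0:(sz[["cause"]] - 1L),
                      specificity = 0:(sz[["specificity"]] - 1L),
                      environment = 0:(sz[["environment"]] - 1L),
                      activity = 0:(sz[["activity"]] - 1L),
                      KEEP.OUT.ATTRS = FALSE)
  grid$frequency <- 0L
  grid$discomfort <- 0L
  grid
}

# does a partial pattern (named list of allowed code sets; absent/NULL =
# wildcard) accept this complaint?
pattern_matches <- function(pattern, complaint) {
  for (d in names(pattern)) {
    allowed <- pattern[[d]]
    if (is.null(allowed)) next
    if (!complaint[[d]] %in% allowed) return(FALSE)
  }
  TRUE
}
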