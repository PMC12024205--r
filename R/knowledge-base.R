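# Knowledge-base data model: solution categories, commands, parameter
# specifications, device profiles, fitting-guide entries, consistency rules
# and the adjustment policy, plus the canonical JSON on-disk format.

# the six solution categories; "AE" is accepted as an input alias for "EA"
.hafes_categories <- data.frame(
  code = c("R", "AP", "EA", "T", "C", "AC"),
  label = c("Recommendation", "Physical adjustment",
            "Electroacoustic adjustment", "Therapy", "Consultation",
            "Accommodation"),
  stringsAsFactors = FALSE
)

#' The six solution categories
#'
#' Fitting solutions are classified as Recommendation (R, something the
#' wearer can do), Physical adjustment (AP, tube/earpiece/placement),
#' Electroacoustic adjustment (EA, a parameter change on the device),
#' Therapy (T), Consultation (C) and Accommodation (AC, adaptation period).
#'
#' @return Data frame with columns `code` and `label`.
#' @export
solution_categories <- function() .hafes_categories

canon_category <- function(code) {
  code <- as_scalar_chr(code, "solution category")
  if (identical(code, "AE")) code <- "EA"  # prose alias for the table code
  if (!code %in% .hafes_categories$code)
    hafes_abort(sprintf("unknown solution category '%s'", code),
                "hafes_validation_error")
  code
}

#' Fitting command
#'
#' An electroacoustic operation: a direction (increase/decrease) and a level,
#' the count of `+`/`-` symbols in the guide notation (`decrease--` is
#' direction decrease, level 2). The effective change is
#' `sign * level * step_unit` of the target parameter.
#'
#' @param direction `"increase"` or `"decrease"`.
#' @param level integer `>= 1` symbol count (packaged guide uses 1-4).
#' @return Object of class `hafes_command`.
#' @examples
#' command("decrease", 2)
#' @export
command <- function(direction, level = 1L) {
  direction <- match.arg(direction, c("increase", "decrease"))
  level <- as_scalar_int(level, "command level")
  if (level < 1L)
    hafes_abort("command level must be >= 1", "hafes_validation_error")
  structure(list(direction = direction, level = level),
            class = "hafes_command")
}

command_sign <- function(cmd) if (cmd$direction == "increase") 1 else -1

as_command <- function(x) {
  if (inherits(x, "hafes_command")) x
  else command(x$direction, x$level %||% 1L)
}

#' @export
format.hafes_command <- function(x, ...) {
  paste0(x$direction, strrep(if (x$direction == "increase") "+" else "-",
                             x$level))
}

#' @export
print.hafes_command <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Electroacoustic parameter specification
#'
#' @param name canonical identifier (e.g. `"MCL"`, `"UCL"`, `"nb_vol"`,
#'   `"enerFaibl"`).
#' @param group parameter group (e.g. `"dynamic"`, `"volume"`, `"silence"`).
#' @param unit `"dB"` or `""` (dimensionless).
#' @param typical_range numeric `c(min, max)` of the generic device family.
#' @param default_value factory default; must lie in `typical_range`.
#' @param step_unit magnitude of a level-1 command, `> 0`.
#' @param manufacturer_alias optional manufacturer name (e.g. `"min_dyn"`).
#' @return Object of class `hafes_parameter`.
#' @export
parameter_spec <- function(name, group, unit, typical_range, default_value,
                           step_unit, manufacturer_alias = NULL) {
  name <- as_scalar_chr(name, "parameter name")
  typical_range <- as.numeric(typical_range)
  if (length(typical_range) != 2L || typical_range[1] > typical_range[2])
    hafes_abort(sprintf("parameter %s: typical_range must be [min, max]",
                        name), "hafes_validation_error")
  default_value <- as_scalar_num(default_value, "default_value")
  step_unit <- as_scalar_num(step_unit, "step_unit")
  if (step_unit <= 0)
    hafes_abort(sprintf("parameter %s: step_unit must be > 0", name),
                "hafes_validation_error")
  if (default_value < typical_range[1] || default_value > typical_range[2])
    hafes_abort(sprintf("parameter %s: default %g outside typical range",
                        name, default_value), "hafes_validation_error")
  structure(list(name = name,
                 manufacturer_alias = as_scalar_chr(manufacturer_alias,
                                                    "manufacturer_alias"),
                 group = as_scalar_chr(group, "group"),
                 unit = as_scalar_chr(unit, "unit"),
                 typical_range = typical_range,
                 default_value = default_value,
                 step_unit = step_unit),
            class = "hafes_parameter")
}

#' Device constraint profile
#'
#' Per-model overrides of parameter ranges; the effective range used for
#' clamping is the intersection of the parameter's typical range and the
#' device override.
#'
#' @param model device model name.
#' @param form_factor `"BTE"`, `"body"` or `"other"`.
#' @param overrides named list, parameter name -> numeric `c(min, max)`.
#' @return Object of class `hafes_device`.
#' @export
device_profile <- function(model, form_factor = "other", overrides = list()) {
  form_factor <- match.arg(form_factor, c("BTE", "body", "other"))
  overrides <- lapply(overrides, function(r) {
    r <- as.numeric(r)
    if (length(r) != 2L || r[1] > r[2])
      hafes_abort("device override must be [min, max]",
                  "hafes_validation_error")
    r
  })
  structure(list(model = as_scalar_chr(model, "model"),
                 form_factor = form_factor,
                 overrides = overrides),
            class = "hafes_device")
}

#' Fitting solution
#'
#' One step of a guide entry's prioritized plan. Electroacoustic (EA)
#' solutions must carry the parameter to modify and the command to apply;
#' other categories must not.
#'
#' @param category one of `R`, `AP`, `EA`, `T`, `C`, `AC` (`AE` accepted as
#'   alias for `EA`).
#' @param parameter canonical parameter name (EA only).
#' @param command a [command()] (EA only).
#' @param advice optional per-locale advice text (named list `en`/`fr` or a
#'   single string).
#' @param provenance `"expert"`, `"manufacturer"` or `"research"`.
#' @param target_value optional explicit target value for an EA step, used
#'   by audiologist-modified plans; checked against the device constraints
#'   at review time.
#' @return Object of class `hafes_solution`.
#' @export
solution <- function(category, parameter = NULL, command = NULL,
                     advice = NULL, provenance = "expert",
                     target_value = NULL) {
  category <- canon_category(category)
  provenance <- match.arg(provenance,
                          c("expert", "manufacturer", "research"))
  if (category == "EA") {
    if (is.null(parameter) || is.null(command))
      hafes_abort("EA solutions require both a parameter and a command",
                  "hafes_validation_error")
  } else if (!is.null(parameter) || !is.null(command)) {
    hafes_abort(sprintf(
      "solution category %s must not carry a parameter or command",
      category), "hafes_validation_error")
  }
  if (!is.null(command)) command <- as_command(command)
  structure(list(category = category,
                 parameter = as_scalar_chr(parameter, "parameter"),
                 command = command,
                 advice = advice,
                 provenance = provenance,
                 target_value = if (!is.null(target_value))
                   as_scalar_num(target_value, "target_value")),
            class = "hafes_solution")
}

#' Fitting-guide entry
#'
#' One complaint class: a per-dimension pattern over cause, specificity,
#' environment and activity (each a set of allowed codes, or absent for a
#' wildcard) with an ordered solution plan. The impact dimensions (frequency,
#' discomfort) never select the class; they travel with the recommendation
#' as urgency metadata.
#'
#' @param id integer entry id (guide row number).
#' @param pattern named list over a subset of
#'   `cause`/`specificity`/`environment`/`activity`; each element an integer
#'   vector of allowed codes. Optional demographic guard fields `age_range`
#'   (numeric `c(min, max)` years) and `comorbidities` (character tags) are
#'   evaluated as extra dimensions when demographics are supplied.
#' @param solutions non-empty list of [solution()]s in priority order.
#' @param recommendation_text per-locale advisory text shown to the wearer
#'   (named list `en`/`fr`), or `NULL`.
#' @param source `"printed"` for entries transcribed from the published
#'   guide, `"synthetic_placeholder"` for stand-ins.
#' @param alternative optional annotation recording a documented variant of
#'   the entry (kept for audit, never executed).
#' @return Object of class `hafes_guide_entry`.
#' @export
guide_entry <- function(id, pattern, solutions, recommendation_text = NULL,
                        source = "printed", alternative = NULL) {
  id <- as_scalar_int(id, "guide entry id")
  if (!length(solutions))
    hafes_abort(sprintf("guide entry %d: solutions must be non-empty", id),
                "hafes_validation_error")
  solutions <- lapply(solutions, function(s) {
    if (inherits(s, "hafes_solution")) s else do.call(solution, s)
  })
  match_dims <- c("cause", "specificity", "environment", "activity")
  extra <- setdiff(names(pattern),
                   c(match_dims, "age_range", "comorbidities"))
  if (length(extra))
    hafes_abort(sprintf("guide entry %d: unknown pattern dimension(s) %s",
                        id, paste(extra, collapse = ", ")),
                "hafes_validation_error")
  pattern[match_dims] <- lapply(pattern[match_dims], function(v)
    if (is.null(v)) NULL else as.integer(v))
  pattern <- Filter(Negate(is.null), pattern)
  structure(list(id = id,
                 pattern = pattern,
                 solutions = solutions,
                 recommendation_text = recommendation_text,
                 source = match.arg(source,
                                    c("printed", "synthetic_placeholder")),
                 alternative = alternative),
            class = "hafes_guide_entry")
}

#' Consistency rule
#'
#' A forbidden combination of item codes covering at least two dimensions.
#'
#' @param id rule identifier.
#' @param pattern named list (dimension -> allowed code set) over `>= 2` of
#'   the six dimensions; a complaint matching every listed set violates the
#'   rule.
#' @param message per-locale explanation (named list `en`/`fr`).
#' @return Object of class `hafes_consistency_rule`.
#' @export
consistency_rule <- function(id, pattern, message) {
  if (length(pattern) < 2L)
    hafes_abort("a consistency rule must cover at least two dimensions",
                "hafes_validation_error")
  bad <- setdiff(names(pattern), .hafes_dimensions)
  if (length(bad))
    hafes_abort(sprintf("consistency rule %s: unknown dimension(s) %s", id,
                        paste(bad, collapse = ", ")),
                "hafes_validation_error")
  structure(list(id = as_scalar_chr(id, "rule id"),
                 pattern = lapply(pattern, as.integer),
                 message = message),
            class = "hafes_consistency_rule")
}

#' Adjustment policy
#'
#' Policy constants for electroacoustic changes: the range of gain changes
#' noticeable to the wearer (4-12 dB for frequency gain) and the default
#' level-1 step for dB gain parameters (6 dB, so a level-2 command moves
#' 12 dB, the top of the noticeable range).
#'
#' @param noticeable_gain_range numeric `c(min_dB, max_dB)`.
#' @param default_gain_step_unit dB magnitude of one command level.
#' @return Object of class `hafes_policy`.
#' @export
adjustment_policy <- function(noticeable_gain_range = c(4, 12),
                              default_gain_step_unit = 6) {
  noticeable_gain_range <- as.numeric(noticeable_gain_range)
  step <- as_scalar_num(default_gain_step_unit, "default_gain_step_unit")
  if (length(noticeable_gain_range) != 2L ||
      noticeable_gain_range[1] > noticeable_gain_range[2])
    hafes_abort("noticeable_gain_range must be [min, max]",
                "hafes_validation_error")
  if (step <= 0)
    hafes_abort("default_gain_step_unit must be > 0",
                "hafes_validation_error")
  structure(list(noticeable_gain_range = noticeable_gain_range,
                 default_gain_step_unit = step),
            class = "hafes_policy")
}

#' Assemble a knowledge base
#'
#' @param version schema version string.
#' @param parameters list of [parameter_spec()]s.
#' @param devices list of [device_profile()]s.
#' @param guide list of [guide_entry()]s.
#' @param consistency_rules list of [consistency_rule()]s.
#' @param policy an [adjustment_policy()].
#' @return Object of class `hafes_kb`.
#' @export
knowledge_base <- function(version = "1.0", parameters = list(),
                           devices = list(), guide = list(),
                           consistency_rules = list(),
                           policy = adjustment_policy()) {
  structure(list(version = as_scalar_chr(version, "version"),
                 parameters = parameters,
                 devices = devices,
                 guide = guide,
                 consistency_rules = consistency_rules,
                 policy = policy),
            class = "hafes_kb")
}

#' @export
print.hafes_kb <- function(x, ...) {
  cat(sprintf(
    "Hearing-aid fitting knowledge base v%s: %d parameters, %d devices, %d guide entries, %d consistency rules\n",
    x$version, length(x$parameters), length(x$devices), length(x$guide),
    length(x$consistency_rules)))
  invisible(x)
}

kb_parameter <- function(kb, name, error = TRUE) {
  for (p in kb$parameters) if (identical(p$name, name)) return(p)
  if (error)
    hafes_abort(sprintf("parameter '%s' is not declared in the knowledge base",
                        name), "hafes_validation_error")
  NULL
}

kb_device <- function(kb, model, error = TRUE) {
  if (is.null(model)) return(NULL)
  if (inherits(model, "hafes_device")) return(model)
  for (d in kb$devices) if (identical(d$model, model)) return(d)
  if (error)
    hafes_abort(sprintf("device '%s' is not declared in the knowledge base",
                        model), "hafes_validation_error")
  NULL
}

#' Effective constraint interval and clamping
#'
#' The effective range of a parameter on a device is the intersection of the
#' parameter's typical range and the device's override, if any (a BTE
#' profile may limit MCL to 70 dB although the typical range runs to
#' 120 dB). `clamp_to_constraints()` projects a value onto that interval.
#'
#' @param value number to clamp.
#' @param parameter a [parameter_spec()].
#' @param device optional [device_profile()].
#' @return List with `value` (clamped), `was_clamped` (flag) and `range`
#'   (the effective `c(min, max)`).
#' @examples
#' mcl <- parameter_spec("MCL", "dynamic", "dB", c(0, 120), 50, 6, "min_dyn")
#' bte <- device_profile("BalafonBTE", "BTE", list(MCL = c(0, 70)))
#' clamp_to_constraints(75, mcl, bte)  # 70, clamped
#' @export
clamp_to_constraints <- function(value, parameter, device = NULL) {
  value <- as_scalar_num(value, "value")
  rng <- effective_range(parameter, device)
  clamped <- min(max(value, rng[1]), rng[2])
  list(value = clamped, was_clamped = clamped != value, range = rng)
}

#' @rdname clamp_to_constraints
#' @export
effective_range <- function(parameter, device = NULL) {
  rng <- parameter$typical_range
  if (!is.null(device)) {
    ov <- device$overrides[[parameter$name]]
    if (!is.null(ov)) rng <- c(max(rng[1], ov[1]), min(rng[2], ov[2]))
  }
  if (rng[1] > rng[2])
    hafes_abort(sprintf(
      "empty constraint intersection for parameter %s on device %s",
      parameter$name, if (is.null(device)) "<none>" else device$model),
      "hafes_constraint_error",
      parameter = parameter$name,
      device = if (is.null(device)) NULL else device$model)
  rng
}

#' Validate a knowledge base
#'
#' Checks every structural invariant of the model: unique parameter names
#' and guide ids, ranges ordered and defaults in range, device overrides
#' resolving to declared parameters with non-empty effective intersections,
#' EA solutions carrying exactly a parameter and a command (and only EA
#' doing so), pattern codes within the questionnaire catalog bounds, command
#' levels within the guide notation, policy step law inside the noticeable
#' range, and consistency rules covering at least two dimensions. Warnings
#' flag guide entries unreachable by any encodable complaint (exhaustive
#' scan of the nature/context space) and synthetic placeholder entries.
#'
#' @param kb a `hafes_kb`.
#' @param check_reachability run the exhaustive reachability scan?
#' @return Object of class `hafes_validation`: list with `valid`, `errors`,
#'   `warnings`.
#' @export
validate_knowledge_base <- function(kb, check_reachability = TRUE) {
  errors <- character()
  warnings <- character()
  err <- function(fmt, ...) errors <<- c(errors, sprintf(fmt, ...))
  wrn <- function(fmt, ...) warnings <<- c(warnings, sprintf(fmt, ...))

  pnames <- vapply(kb$parameters, function(p) p$name, character(1))
  if (anyDuplicated(pnames))
    err("duplicate parameter names: %s",
        paste(unique(pnames[duplicated(pnames)]), collapse = ", "))
  for (p in kb$parameters) {
    if (p$typical_range[1] > p$typical_range[2])
      err("parameter %s: typical_range is not ordered", p$name)
    if (p$default_value < p$typical_range[1] ||
        p$default_value > p$typical_range[2])
      err("parameter %s: default value outside typical range", p$name)
    if (p$step_unit <= 0) err("parameter %s: step_unit must be > 0", p$name)
  }

  for (d in kb$devices) {
    for (nm in names(d$overrides)) {
      if (!nm %in% pnames) {
        err("device %s: override references undeclared parameter %s",
            d$model, nm)
        next
      }
      p <- kb_parameter(kb, nm)
      ov <- d$overrides[[nm]]
      if (max(p$typical_range[1], ov[1]) > min(p$typical_range[2], ov[2]))
        err("device %s: empty effective range for parameter %s", d$model, nm)
    }
  }

  sizes <- catalog_sizes()
  ids <- vapply(kb$guide, function(g) g$id, integer(1))
  if (anyDuplicated(ids))
    err("duplicate guide entry ids: %s",
        paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (g in kb$guide) {
    if (!length(g$solutions))
      err("guide entry %d: empty solution plan", g$id)
    for (s in g$solutions) {
      if (s$category == "EA") {
        if (is.null(s$parameter) || is.null(s$command)) {
          err("guide entry %d: EA solution missing parameter or command",
              g$id)
        } else {
          if (!s$parameter %in% pnames)
            err("guide entry %d: EA solution references undeclared parameter %s",
                g$id, s$parameter)
          if (s$command$level > 4L)
            wrn("guide entry %d: command level %d exceeds the guide notation (1-4)",
                g$id, s$command$level)
        }
      } else if (!is.null(s$parameter) || !is.null(s$command)) {
        err("guide entry %d: non-EA solution carries a parameter or command",
            g$id)
      }
    }
    for (d in intersect(names(g$pattern),
                        c("cause", "specificity", "environment", "activity"))) {
      codes <- g$pattern[[d]]
      if (any(codes < 0L | codes >= sizes[[d]]))
        err("guide entry %d: pattern cites out-of-bounds %s code(s) %s",
            g$id, d,
            paste(codes[codes < 0L | codes >= sizes[[d]]], collapse = ", "))
    }
    if (identical(g$source, "synthetic_placeholder"))
      wrn("guide entry %d is a synthetic placeholder (untranscribed source row)",
          g$id)
  }

  for (r in kb$consistency_rules) {
    if (length(r$pattern) < 2L)
      err("consistency rule %s covers fewer than two dimensions", r$id)
    for (d in names(r$pattern)) {
      if (!d %in% .hafes_dimensions) {
        err("consistency rule %s: unknown dimension %s", r$id, d)
      } else if (any(r$pattern[[d]] < 0L | r$pattern[[d]] >= sizes[[d]])) {
        err("consistency rule %s: out-of-bounds %s code(s)", r$id, d)
      }
    }
  }

  pol <- kb$policy
  if (pol$noticeable_gain_range[1] > pol$default_gain_step_unit ||
      2 * pol$default_gain_step_unit > pol$noticeable_gain_range[2])
    err("policy: step law (1x, 2x step unit) falls outside the noticeable gain range")

  if (check_reachability && length(kb$guide) && !length(errors)) {
    hits <- coverage_counts(kb, complaint_space())
    unreachable <- ids[!ids %in% names(hits)[hits > 0L]]
    for (id in unreachable)
      wrn("guide entry %d is unreachable by any encodable complaint", id)
  }

  structure(list(valid = length(errors) == 0L, errors = errors,
                 warnings = warnings),
            class = "hafes_validation")
}

#' @export
print.hafes_validation <- function(x, ...) {
  cat(sprintf("Knowledge base validation: %s (%d error(s), %d warning(s))\n",
              if (x$valid) "OK" else "INVALID",
              length(x$errors), length(x$warnings)))
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
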