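# On-disk knowledge-base format: a schema-versioned JSON document with
# top-level keys version/parameters/devices/guide/consistency_rules/policy.
# Serialization is canonical (recursively key-sorted objects, fixed number
# formatting) so that repeated saves of the same knowledge base are
# byte-identical and the save->load round trip is the identity.

drop_null <- function(x) Filter(Negate(is.null), x)

kb_to_list <- function(kb) {
  list(
    version = kb$version,
    policy = list(
      noticeable_gain_range = kb$policy$noticeable_gain_range,
      default_gain_step_unit = kb$policy$default_gain_step_unit
    ),
    parameters = lapply(kb$parameters, function(p) drop_null(list(
      name = p$name,
      manufacturer_alias = p$manufacturer_alias,
      group = p$group,
      unit = p$unit,
      typical_range = p$typical_range,
      default_value = p$default_value,
      step_unit = p$step_unit
    ))),
    devices = lapply(kb$devices, function(d) list(
      model = d$model,
      form_factor = d$form_factor,
      overrides = d$overrides
    )),
    guide = lapply(kb$guide, function(g) drop_null(list(
      id = g$id,
      pattern = g$pattern,
      solutions = lapply(g$solutions, function(s) drop_null(list(
        category = s$category,
        parameter = s$parameter,
        command = if (!is.null(s$command))
          list(direction = s$command$direction, level = s$command$level),
        advice = s$advice,
        provenance = s$provenance
      ))),
      recommendation_text = g$recommendation_text,
      source = g$source,
      alternative = g$alternative
    ))),
    consistency_rules = lapply(kb$consistency_rules, function(r) list(
      id = r$id,
      pattern = r$pattern,
      message = r$message
    ))
  )
}

as_int_vec <- function(x) as.integer(unlist(x))
as_num_vec <- function(x) as.numeric(unlist(x))
as_chr_list <- function(x) if (is.null(x)) NULL else lapply(x, as.character)

list_to_kb <- function(raw) {
  knowledge_base(
    version = raw$version %||% "1.0",
    policy = adjustment_policy(
      noticeable_gain_range =
        as_num_vec(raw$policy$noticeable_gain_range %||% c(4, 12)),
      default_gain_step_unit = raw$policy$default_gain_step_unit %||% 6
    ),
    parameters = lapply(raw$parameters %||% list(), function(p)
      parameter_spec(name = p$name,
                     group = p$group,
                     unit = p$unit %||% "",
                     typical_range = as_num_vec(p$typical_range),
                     default_value = p$default_value,
                     step_unit = p$step_unit,
                     manufacturer_alias = p$manufacturer_alias)),
    devices = lapply(raw$devices %||% list(), function(d)
      device_profile(model = d$model,
                     form_factor = d$form_factor %||% "other",
                     overrides = lapply(d$overrides %||% list(), as_num_vec))),
    guide = lapply(raw$guide %||% list(), function(g)
      guide_entry(id = g$id,
                  pattern = lapply(g$pattern %||% list(), as_int_vec),
                  solutions = lapply(g$solutions, function(s)
                    solution(category = s$category,
                             parameter = s$parameter,
                             command = if (!is.null(s$command))
                               command(s$command$direction, s$command$level),
                             advice = as_chr_list(s$advice),
                             provenance = s$provenance %||% "expert")),
                  recommendation_text = as_chr_list(g$recommendation_text),
                  source = g$source %||% "printed",
                  alternative = g$alternative)),
    consistency_rules = lapply(raw$consistency_rules %||% list(), function(r)
      consistency_rule(id = r$id,
                       pattern = lapply(r$pattern, as_int_vec),
                       message = as_chr_list(r$message)))
  )
}

#' Load a knowledge base from its JSON file
#'
#' Parses the schema-versioned JSON dialect written by
#' [save_knowledge_base()], links every cross-reference (guide entries to
#' parameters, device overrides to parameters) and validates the result;
#' loading fails if validation reports any error.
#'
#' @param path path to a knowledge-base JSON file.
#' @return A validated `hafes_kb`.
#' @examples
#' path <- system.file("extdata", "balafon_kb.json", package = "hafes")
#' kb <- load_knowledge_base(path)
#' kb
#' @export
load_knowledge_base <- function(path) {
  if (!file.exists(path))
    hafes_abort(sprintf("knowledge-base file not found: %s", path),
                "hafes_format_error")
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) hafes_abort(
      sprintf("cannot parse knowledge-base file %s: %s", path,
              conditionMessage(e)),
      "hafes_format_error")
  )
  kb <- list_to_kb(raw)
  report <- validate_knowledge_base(kb, check_reachability = FALSE)
  if (!report$valid)
    hafes_abort(
      sprintf("knowledge base %s is invalid:\n%s", path,
              paste(" -", report$errors, collapse = "\n")),
      "hafes_validation_error", report = report)
  kb
}

#' Save a knowledge base to its JSON file
#'
#' Writes the canonical serialization: keys recursively sorted, numbers at
#' full precision, two-space indentation, UTF-8. Saving the same knowledge
#' base twice produces byte-identical files, and
#' `load_knowledge_base(save_knowledge_base(kb))` is structurally the
#' identity.
#'
#' @param kb a valid `hafes_kb`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
save_knowledge_base <- function(kb, path) {
  stopifnot(inherits(kb, "hafes_kb"))
  report <- validate_knowledge_base(kb, check_reachability = FALSE)
  if (!report$valid)
    hafes_abort(
      paste("refusing to save an invalid knowledge base:\n",
            paste(" -", report$errors, collapse = "\n")),
      "hafes_validation_error", report = report)
  write_canonical_json(kb_to_list(kb), path)
  invisible(path)
}
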