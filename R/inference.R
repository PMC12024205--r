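# Inference engine: maps an encoded complaint to its most specific guide
# entry, derives the ordered solution plan, computes constraint-clamped
# electroacoustic adjustments, and records an explanation trace. This is an
# explicit forward evaluator over the fitting guide; conflict resolution is
# maximal specificity (count of non-wildcard dimensions matched), ties
# broken by lowest entry id, and a total consultation fallback.

.match_dims <- c("cause", "specificity", "environment", "activity")

# score an entry against one complaint; NA if it does not match.
# demographics (age, comorbidities) are extra pattern dimensions: a guard
# present on the entry must be satisfied when demographics are supplied and
# then contributes to the score; an unguarded entry ignores demographics.
entry_score <- function(entry, complaint, demographics = NULL) {
  score <- 0L
  matched <- character()
  for (d in .match_dims) {
    allowed <- entry$pattern[[d]]
    if (is.null(allowed)) next
    if (!complaint[[d]] %in% allowed) return(list(score = NA_integer_))
    score <- score + 1L
    matched <- c(matched, d)
  }
  if (!is.null(entry$pattern$age_range)) {
    age <- demographics$age
    if (is.null(age)) return(list(score = NA_integer_))
    rng <- entry$pattern$age_range
    if (age < rng[1] || age > rng[2]) return(list(score = NA_integer_))
    score <- score + 1L
    matched <- c(matched, "age")
  }
  if (!is.null(entry$pattern$comorbidities)) {
    tags <- demographics$comorbidities
    if (is.null(tags) || !all(entry$pattern$comorbidities %in% tags))
      return(list(score = NA_integer_))
    score <- score + 1L
    matched <- c(matched, "comorbidities")
  }
  list(score = score, matched = matched)
}

#' Match a complaint to its complaint class
#'
#' Evaluates every fitting-guide entry against the complaint and returns the
#' entry matching with maximal specificity (the count of non-wildcard
#' pattern dimensions it pins down); ties are broken by lowest entry id, so
#' "whistling in a quiet environment" beats the generic "whistling" entry.
#' When no entry matches, the total consultation fallback is returned.
#'
#' @param complaint a `hafes_complaint`.
#' @param kb a `hafes_kb`.
#' @param demographics optional list with `age` (years) and `comorbidities`
#'   (character tags), evaluated against entry guard fields when present.
#' @return Object of class `hafes_match`: list with `entry_id` (integer, or
#'   `NA` for the fallback), `fallback` flag, `specificity_score` and
#'   `bound_dimensions`.
#' @export
match_complaint <- function(complaint, kb, demographics = NULL) {
  complaint <- as_complaint(complaint)
  best <- list(entry_id = NA_integer_, fallback = TRUE,
               specificity_score = 0L, bound_dimensions = character())
  best_score <- -1L
  ord <- order(vapply(kb$guide, function(g) g$id, integer(1)))
  for (g in kb$guide[ord]) {
    sc <- entry_score(g, complaint, demographics)
    if (!is.na(sc$score) && sc$score > best_score) {
      best_score <- sc$score
      best <- list(entry_id = g$id, fallback = FALSE,
                   specificity_score = sc$score,
                   bound_dimensions = sc$matched)
    }
  }
  structure(best, class = "hafes_match")
}

#' @export
print.hafes_match <- function(x, ...) {
  if (x$fallback) {
    cat("No complaint class matched: consultation fallback.\n")
  } else {
    cat(sprintf("Matched guide entry %d (specificity %d: %s)\n",
                x$entry_id, x$specificity_score,
                paste(x$bound_dimensions, collapse = ", ")))
  }
  invisible(x)
}

# vectorized matcher over a complaint data frame; returns integer entry ids
# (NA = fallback). Used by coverage and reachability scans.
match_space <- function(kb, complaints) {
  n <- nrow(complaints)
  best_score <- rep(-1L, n)
  best_id <- rep(NA_integer_, n)
  ord <- order(vapply(kb$guide, function(g) g$id, integer(1)))
  for (g in kb$guide[ord]) {
    if (!is.null(g$pattern$age_range) || !is.null(g$pattern$comorbidities))
      next  # demographic-guarded entries never fire without demographics
    ok <- rep(TRUE, n)
    score <- 0L
    for (d in .match_dims) {
      allowed <- g$pattern[[d]]
      if (is.null(allowed)) next
      ok <- ok & complaints[[d]] %in% allowed
      score <- score + 1L
    }
    upd <- ok & score > best_score
    best_score[upd] <- score
    best_id[upd] <- g$id
  }
  best_id
}

kb_entry <- function(kb, id) {
  for (g in kb$guide) if (g$id == id) return(g)
  hafes_abort(sprintf("no guide entry with id %d", id),
              "hafes_validation_error")
}

#' Compute one constraint-clamped electroacoustic adjustment
#'
#' Applies the step law: the requested change is
#' `sign(command) * level(command) * step_unit` of the parameter, and the
#' proposed value is the requested value clamped to the effective constraint
#' interval (typical range intersected with the device override). The
#' level-1 step for dB gain parameters is 6 dB, so a `decrease-` on MCL
#' moves it down 6 dB and a level-2 command moves 12 dB, the top of the
#' 4-12 dB noticeable-gain range.
#'
#' @param cmd a [command()].
#' @param parameter a [parameter_spec()].
#' @param device optional [device_profile()].
#' @param current_value current fitting value; values outside the effective
#'   range are pre-clamped with a note.
#' @param policy an [adjustment_policy()] (carried for the trace; the step
#'   magnitude itself comes from the parameter's `step_unit`).
#' @return Object of class `hafes_adjustment`: `parameter`,
#'   `previous_value`, `requested_value`, `proposed_value`, `delta`
#'   (`proposed - previous`), `was_clamped`, `command`, `notes`.
#' @examples
#' mcl <- parameter_spec("MCL", "dynamic", "dB", c(0, 120), 50, 6, "min_dyn")
#' compute_adjustment(command("decrease", 1), mcl, current_value = 60)
#' @export
compute_adjustment <- function(cmd, parameter, device = NULL,
                               current_value = NULL,
                               policy = adjustment_policy()) {
  stopifnot(inherits(cmd, "hafes_command"),
            inherits(parameter, "hafes_parameter"))
  notes <- character()
  current_value <- current_value %||% parameter$default_value
  current_value <- as_scalar_num(current_value, "current_value")
  pre <- clamp_to_constraints(current_value, parameter, device)
  if (pre$was_clamped) {
    notes <- c(notes, sprintf(
      "current value %g outside effective range [%g, %g]; pre-clamped to %g",
      current_value, pre$range[1], pre$range[2], pre$value))
    current_value <- pre$value
  }
  raw_delta <- command_sign(cmd) * cmd$level * parameter$step_unit
  requested <- current_value + raw_delta
  post <- clamp_to_constraints(requested, parameter, device)
  structure(list(parameter = parameter$name,
                 previous_value = current_value,
                 requested_value = requested,
                 proposed_value = post$value,
                 delta = post$value - current_value,
                 was_clamped = post$was_clamped,
                 range = post$range,
                 command = cmd,
                 notes = notes),
            class = "hafes_adjustment")
}

#' @export
print.hafes_adjustment <- function(x, ...) {
  cat(sprintf("%s: %g -> %g (%s%s)\n", x$parameter, x$previous_value,
              x$proposed_value, format(x$command),
              if (x$was_clamped)
                sprintf("; requested %g clamped to [%g, %g]",
                        x$requested_value, x$range[1], x$range[2]) else ""))
  invisible(x)
}

fallback_solution <- function() {
  solution("C", advice = list(
    en = "No complaint class matched. Please consult a hearing care professional.",
    fr = "Aucune classe de plainte ne correspond. Veuillez consulter un professionnel de l'audition."
  ))
}

#' Generate a fitting recommendation for a complaint
#'
#' The full inference pass: the complaint is screened against the
#' knowledge base's consistency rules (screening can be explicitly
#' overridden), matched to its most specific complaint class, and the
#' class's ordered solution plan is instantiated — one constraint-clamped
#' [compute_adjustment()] per electroacoustic step, evaluated against the
#' supplied fitting state (parameter defaults when absent). Every decision
#' is recorded in the explanation trace; the whole function is a pure,
#' deterministic function of its inputs.
#'
#' @param complaint a `hafes_complaint`.
#' @param kb a `hafes_kb`.
#' @param device a [device_profile()] or a model name declared in `kb`, or
#'   `NULL`.
#' @param fitting optional named numeric vector/list of current parameter
#'   values.
#' @param locale `"en"` or `"fr"` for the advisory texts.
#' @param override_screening proceed despite a failed consistency screen?
#' @param demographics optional demographics for guarded entries.
#' @return Object of class `hafes_recommendation`: `complaint`, `match`,
#'   `plan` (ordered solutions), `adjustments` (one per EA step),
#'   `advice_text`, `urgency` (ordinal frequency/discomfort codes) and
#'   `trace`.
#' @export
recommend <- function(complaint, kb, device = NULL, fitting = NULL,
                      locale = "en", override_screening = FALSE,
                      demographics = NULL) {
  complaint <- as_complaint(complaint)
  device <- kb_device(kb, device)
  trace <- list()
  push <- function(ev) trace[[length(trace) + 1L]] <<- ev

  screen <- check_consistency(complaint, kb$consistency_rules, locale)
  push(list(type = "screening", consistent = screen$consistent,
            violated_rules = screen$violations$rule_id,
            overridden = !screen$consistent && override_screening))
  if (!screen$consistent && !override_screening)
    hafes_abort(
      paste("complaint failed consistency screening:",
            paste(screen$violations$rule_id, collapse = ", ")),
      "hafes_screening_error", report = screen)

  m <- match_complaint(complaint, kb, demographics)
  if (m$fallback) {
    push(list(type = "fallback",
              reason = "no guide entry matches the complaint"))
    plan <- list(fallback_solution())
    advice <- plan[[1]]$advice[[locale]] %||% plan[[1]]$advice[["en"]]
  } else {
    entry <- kb_entry(kb, m$entry_id)
    push(list(type = "rule_fired", entry_id = entry$id,
              specificity_score = m$specificity_score,
              bound_dimensions = m$bound_dimensions,
              matched_pattern = entry$pattern,
              source = entry$source))
    plan <- entry$solutions
    advice <- if (!is.null(entry$recommendation_text))
      entry$recommendation_text[[locale]] %||%
        entry$recommendation_text[["en"]]
  }

  adjustments <- list()
  for (s in plan) {
    push(list(type = "provenance", category = s$category,
              provenance = s$provenance))
    if (s$category != "EA") next
    p <- kb_parameter(kb, s$parameter)
    current <- fitting[[p$name]] %||% p$default_value
    adj <- compute_adjustment(s$command, p, device, current, kb$policy)
    push(list(type = "policy_applied", parameter = p$name,
              command = format(s$command), step_unit = p$step_unit,
              raw_delta = command_sign(s$command) * s$command$level *
                p$step_unit,
              noticeable_gain_range = kb$policy$noticeable_gain_range))
    if (adj$was_clamped || length(adj$notes))
      push(list(type = "constraint_applied", parameter = p$name,
                device = if (is.null(device)) NULL else device$model,
                requested_value = adj$requested_value,
                applied_value = adj$proposed_value,
                range = adj$range, notes = adj$notes))
    adjustments[[length(adjustments) + 1L]] <- adj
  }

  structure(list(complaint = complaint,
                 match = m,
                 plan = plan,
                 adjustments = adjustments,
                 advice_text = advice,
                 urgency = c(frequency = complaint[["frequency"]],
                             discomfort = complaint[["discomfort"]]),
                 locale = locale,
                 device = if (is.null(device)) NULL else device$model,
                 trace = trace),
            class = "hafes_recommendation")
}

#' @export
print.hafes_recommendation <- function(x, ...) {
  cat(explain(x, x$locale), sep = "\n")
  invisible(x)
}

#' Render a recommendation's explanation trace
#'
#' Formats the trace events in order: consistency screening, the rule fired
#' (entry id and matched dimensions) or the consultation fallback, the step
#' law applied to each electroacoustic adjustment, every constraint clamp
#' (requested vs applied value), and the provenance of each plan step. The
#' text reconstructs the decision path without re-running inference.
#'
#' @param recommendation a `hafes_recommendation`.
#' @param locale `"en"` or `"fr"` (section labels are English; advisory
#'   texts follow the recommendation's locale).
#' @return Character vector of lines.
#' @export
explain <- function(recommendation, locale = "en") {
  r <- recommendation
  out <- character()
  emit <- function(...) out <<- c(out, sprintf(...))
  emit("Complaint codes: %s",
       paste(sprintf("%s=%d", names(r$complaint), unclass(r$complaint)),
             collapse = " "))
  for (ev in r$trace) {
    switch(ev$type,
      screening = {
        if (ev$consistent) emit("Screening: complaint is logically consistent.")
        else emit("Screening: INCONSISTENT (rules %s)%s",
                  paste(ev$violated_rules, collapse = ", "),
                  if (isTRUE(ev$overridden)) "; overridden by caller" else "")
      },
      rule_fired = emit(
        "Rule fired: guide entry %d (matched %s; specificity %d)%s",
        ev$entry_id, paste(ev$bound_dimensions, collapse = ", "),
        ev$specificity_score,
        if (identical(ev$source, "synthetic_placeholder"))
          " [synthetic placeholder entry]" else ""),
      fallback = emit(
        "No complaint class matched; consultation fallback advised."),
      policy_applied = emit(
        "Step law on %s: %s at %g per level -> requested change %+g",
        ev$parameter, ev$command, ev$step_unit, ev$raw_delta),
      constraint_applied = emit(
        "Constraint on %s%s: requested %g, applied %g (range [%g, %g])",
        ev$parameter,
        if (!is.null(ev$device)) paste0(" (", ev$device, ")") else "",
        ev$requested_value, ev$applied_value, ev$range[1], ev$range[2]),
      provenance = emit("Plan step (%s), provenance: %s",
                        ev$category, ev$provenance)
    )
  }
  for (a in r$adjustments)
    emit("Adjustment: %s %g -> %g (delta %+g)%s", a$parameter,
         a$previous_value, a$proposed_value, a$delta,
         if (a$was_clamped) " [clamped]" else "")
  if (!is.null(r$advice_text)) emit("Advice: %s", r$advice_text)
  out
}
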