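# Four-phase session workflow: complaint intake -> inference -> audiologist
# review (approve / modify / reject / refer / request more information) ->
# patient satisfaction feedback with plan-cursor advancement, plus
# per-class resolution statistics. Every transition appends an immutable
# event; replaying the event log reconstructs the session, and no
# electroacoustic change is considered applied without an approving review.

next_session_id <- function() {
  .hafes_state$session_counter <- .hafes_state$session_counter + 1L
  sprintf("S%06d-%s", .hafes_state$session_counter,
          format(Sys.time(), "%Y%m%d%H%M%S"))
}

append_event <- function(session, action, payload = list()) {
  session$events[[length(session$events) + 1L]] <-
    list(seq = length(session$events) + 1L, action = action,
         payload = payload)
  session
}

#' Open a fitting session
#'
#' Runs inference on the complaint and opens a session in the
#' review-pending state with the plan cursor on the first solution.
#'
#' @param complaint a `hafes_complaint`.
#' @param kb a `hafes_kb`.
#' @param device device model name declared in `kb`, or `NULL`.
#' @param fitting optional named current parameter values.
#' @param locale advisory-text locale.
#' @param override_screening proceed despite failed consistency screening?
#' @return Object of class `hafes_session`.
#' @export
open_session <- function(complaint, kb, device = NULL, fitting = NULL,
                         locale = "en", override_screening = FALSE) {
  rec <- recommend(complaint, kb, device = device, fitting = fitting,
                   locale = locale,
                   override_screening = override_screening)
  session <- structure(list(
    session_id = next_session_id(),
    complaint = as_complaint(complaint),
    device = if (is.null(device)) NULL
             else kb_device(kb, device)$model,
    recommendation = rec,
    review = "pending",
    modified_plan = NULL,
    feedback = list(),
    followup_questions = NULL,
    plan_cursor = 1L,
    status = "open",
    events = list()
  ), class = "hafes_session")
  append_event(session, "opened", list(
    session_id = session$session_id,
    complaint = as.list(unclass(session$complaint)),
    device = session$device,
    fitting = fitting,
    locale = locale,
    override_screening = override_screening,
    recommendation = rec
  ))
}

active_plan <- function(session) {
  session$modified_plan %||% session$recommendation$plan
}

#' Record the audiologist's review decision
#'
#' A pending session can be approved, modified (the modified plan is
#' re-validated against the device constraints before acceptance), rejected,
#' referred for clinical consultation, or sent back for more information
#' (the session stays pending, with targeted follow-up questions drawn from
#' the complaint dimensions the matched entry left unspecified).
#'
#' @param session a pending `hafes_session`.
#' @param decision one of `"approve"`, `"modify"`, `"reject"`, `"refer"`,
#'   `"request_info"`.
#' @param modified_plan for `"modify"`: list of [solution()]s replacing the
#'   plan; EA steps may carry a `target_value`, checked against the
#'   effective device constraints (a violating target rejects the
#'   modification with a clamp report).
#' @param kb the knowledge base (needed to re-validate a modified plan).
#' @param questions for `"request_info"`: explicit follow-up question text.
#' @return The updated session.
#' @export
review_session <- function(session, decision, modified_plan = NULL,
                           kb = NULL, questions = NULL) {
  stopifnot(inherits(session, "hafes_session"))
  if (session$review != "pending")
    hafes_abort(sprintf("session %s has already been reviewed (%s)",
                        session$session_id, session$review),
                "hafes_ordering_error")
  decision <- match.arg(decision, c("approve", "modify", "reject", "refer",
                                    "request_info"))
  if (decision == "modify") {
    if (is.null(modified_plan) || !length(modified_plan))
      hafes_abort("a modification needs a non-empty modified plan",
                  "hafes_usage_error")
    if (is.null(kb))
      hafes_abort("re-validating a modified plan requires the knowledge base",
                  "hafes_usage_error")
    device <- kb_device(kb, session$device)
    for (s in modified_plan) {
      if (!inherits(s, "hafes_solution"))
        hafes_abort("modified plan items must be solutions",
                    "hafes_usage_error")
      if (s$category != "EA" || is.null(s$target_value)) next
      p <- kb_parameter(kb, s$parameter)
      cl <- clamp_to_constraints(s$target_value, p, device)
      if (cl$was_clamped)
        hafes_abort(sprintf(
          "modified plan rejected: %s target %g violates the effective range [%g, %g]%s",
          s$parameter, s$target_value, cl$range[1], cl$range[2],
          if (!is.null(device)) sprintf(" on %s", device$model) else ""),
          "hafes_constraint_error",
          clamp_report = list(parameter = s$parameter,
                              requested = s$target_value,
                              applied = cl$value, range = cl$range))
    }
    session$modified_plan <- modified_plan
  }
  session$review <- switch(decision,
    approve = "approved", modify = "modified", reject = "rejected",
    refer = "referred", request_info = "pending")
  if (decision %in% c("reject", "refer")) session$status <- "closed"
  if (decision == "request_info") {
    session$followup_questions <- questions %||%
      followup_questions(session)
  }
  append_event(session, "reviewed",
               list(decision = decision,
                    modified_plan = modified_plan,
                    questions = session$followup_questions))
}

# follow-up questions target the dimensions the matched entry did not pin
# down (all four nature/context dimensions for a fallback)
followup_questions <- function(session) {
  bound <- session$recommendation$match$bound_dimensions
  open_dims <- setdiff(.match_dims, bound)
  sprintf("Please specify the %s of the complaint.", open_dims)
}

#' Record patient satisfaction feedback
#'
#' Feedback is only accepted after an approving (or modifying) review — the
#' clinical-oversight contract: no adjustment is applied, hence none can be
#' rated, without review. A satisfied patient closes the session as
#' resolved. An unsatisfied patient advances the plan cursor to the next
#' solution of the prioritized plan; when the plan is exhausted the session
#' closes as unresolved consultation.
#'
#' @param session a reviewed `hafes_session`.
#' @param satisfied logical flag.
#' @param rating optional ordinal satisfaction detail, 1 (very unsatisfied)
#'   to 5 (very satisfied).
#' @return The updated session.
#' @export
record_feedback <- function(session, satisfied, rating = NULL) {
  stopifnot(inherits(session, "hafes_session"))
  if (!session$review %in% c("approved", "modified"))
    hafes_abort(sprintf(
      "feedback requires an approved or modified review (session %s is %s)",
      session$session_id, session$review), "hafes_ordering_error")
  if (session$status %in% c("resolved", "unresolved_consultation"))
    hafes_abort("session is already closed", "hafes_ordering_error")
  satisfied <- isTRUE(satisfied)
  if (!is.null(rating)) {
    rating <- as_scalar_int(rating, "rating")
    if (rating < 1L || rating > 5L)
      hafes_abort("rating must be on the 1-5 ordinal scale",
                  "hafes_validation_error")
  }
  session$feedback[[length(session$feedback) + 1L]] <-
    list(cursor = session$plan_cursor, satisfied = satisfied,
         rating = rating)
  if (satisfied) {
    session$status <- "resolved"
  } else if (session$plan_cursor < length(active_plan(session))) {
    session$plan_cursor <- session$plan_cursor + 1L
  } else {
    session$status <- "unresolved_consultation"
  }
  append_event(session, "feedback",
               list(satisfied = satisfied, rating = rating,
                    cursor = session$plan_cursor,
                    status = session$status))
}

#' Reconstruct a session from its event log
#'
#' Sessions are event-sourced: each transition appends an immutable event
#' carrying everything needed to replay it. `replay_session()` folds the
#' log back into a session equal to the original.
#'
#' @param events a session's `events` list.
#' @param kb the knowledge base (to re-validate replayed modifications).
#' @return A `hafes_session`.
#' @export
replay_session <- function(events, kb = NULL) {
  if (!length(events) || events[[1]]$action != "opened")
    hafes_abort("event log must start with an 'opened' event",
                "hafes_validation_error")
  p <- events[[1]]$payload
  session <- structure(list(
    session_id = p$session_id,
    complaint = as_complaint(p$complaint),
    device = p$device,
    recommendation = p$recommendation,
    review = "pending",
    modified_plan = NULL,
    feedback = list(),
    followup_questions = NULL,
    plan_cursor = 1L,
    status = "open",
    events = list(events[[1]])
  ), class = "hafes_session")
  for (ev in events[-1]) {
    session <- switch(ev$action,
      reviewed = review_session(session, ev$payload$decision,
                                modified_plan = ev$payload$modified_plan,
                                kb = kb,
                                questions = ev$payload$questions),
      feedback = record_feedback(session, ev$payload$satisfied,
                                 ev$payload$rating),
      hafes_abort(sprintf("unknown event action '%s'", ev$action),
                  "hafes_validation_error"))
  }
  session
}

#' @export
print.hafes_session <- function(x, ...) {
  cat(sprintf("Session %s [%s/%s] cursor %d/%d, %d event(s)\n",
              x$session_id, x$status, x$review, x$plan_cursor,
              length(active_plan(x)), length(x$events)))
  invisible(x)
}

#' Per-class resolution statistics
#'
#' Counts, per complaint class (guide entry id, with consultation fallbacks
#' pooled under `"fallback"`), the session attempts, resolutions and
#' resolution rate, and flags classes whose rate falls below a threshold
#' for knowledge-base review.
#'
#' @param sessions list of `hafes_session`s.
#' @param flag_threshold classes with resolution rate strictly below this
#'   are flagged.
#' @return Object of class `hafes_resolution_stats`: list with `stats`
#'   (data frame of `class`, `attempts`, `resolved`, `rate`,
#'   `fallback_count`) and `flagged` (class labels below threshold).
#' @export
resolution_stats <- function(sessions, flag_threshold = 0.5) {
  if (!length(sessions))
    return(structure(list(
      stats = data.frame(class = character(), attempts = integer(),
                         resolved = integer(), rate = numeric(),
                         fallback_count = integer(),
                         stringsAsFactors = FALSE),
      flagged = character()), class = "hafes_resolution_stats"))
  cls <- vapply(sessions, function(s) {
    m <- s$recommendation$match
    if (m$fallback) "fallback" else as.character(m$entry_id)
  }, character(1))
  resolved <- vapply(sessions, function(s)
    identical(s$status, "resolved"), logical(1))
  fallback <- cls == "fallback"
  agg <- lapply(split(seq_along(sessions), cls), function(idx) {
    data.frame(attempts = length(idx),
               resolved = sum(resolved[idx]),
               rate = sum(resolved[idx]) / length(idx),
               fallback_count = sum(fallback[idx]),
               stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, agg)
  stats <- cbind(data.frame(class = names(agg), stringsAsFactors = FALSE),
                 stats)
  rownames(stats) <- NULL
  structure(list(stats = stats,
                 flagged = stats$class[stats$rate < flag_threshold]),
            class = "hafes_resolution_stats")
}

#' @export
print.hafes_resolution_stats <- function(x, ...) {
  cat("Resolution statistics per complaint class:\n")
  print(x$stats, row.names = FALSE)
  if (length(x$flagged))
    cat("Flagged for knowledge-base review:",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
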