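test_that("opening a session runs inference and starts review-pending at the first plan step", {
  s <- open_session(cpl(3, env = 1), balafon, "BalafonBTE")
  expect_equal(s$review, "pending")
  expect_equal(s$plan_cursor, 1L)
  expect_equal(s$status, "open")
  expect_equal(s$recommendation$plan[[1]]$category, "AP")
  # fallback complaint opens a consultation-flagged session
  sf <- open_session(cpl(12, env = 2), balafon)
  expect_true(sf$recommendation$match$fallback)
  expect_equal(sf$recommendation$plan[[1]]$category, "C")
  # identical inputs: identical recommendations, distinct session ids
  s2 <- open_session(cpl(3, env = 1), balafon, "BalafonBTE")
  expect_identical(s$recommendation, s2$recommendation)
  expect_false(identical(s$session_id, s2$session_id))
})

test_that("review decisions transition the session and validate modified plans against constraints", {
  s <- open_session(cpl(9, env = 1), balafon, "BalafonBTE")
  a <- review_session(s, "approve")
  expect_equal(a$review, "approved")
  expect_identical(hafes:::active_plan(a), a$recommendation$plan)
  # an MCL target of 80 dB violates the BTE's 70 dB ceiling
  bad_plan <- list(solution("EA", parameter = "MCL",
                            command = command("increase", 1),
                            target_value = 80))
  err <- expect_error(
    review_session(s, "modify", modified_plan = bad_plan, kb = balafon),
    class = "hafes_constraint_error")
  expect_equal(err$clamp_report$range, c(0, 70))
  expect_match(conditionMessage(err), "70")
  # a compliant modification is accepted
  ok_plan <- list(solution("EA", parameter = "MCL",
                           command = command("increase", 1),
                           target_value = 65))
  m <- review_session(s, "modify", modified_plan = ok_plan, kb = balafon)
  expect_equal(m$review, "modified")
  # referral freezes the plan and closes the session
  r <- review_session(s, "refer")
  expect_equal(r$review, "referred")
  expect_equal(r$status, "closed")
  # double review is an ordering error
  expect_error(review_session(a, "approve"),
               class = "hafes_ordering_error")
})

test_that("requesting more information keeps the session pending with targeted follow-ups", {
  s <- open_session(cpl(3, env = 4), balafon)  # generic whistling, row 5
  q <- review_session(s, "request_info")
  expect_equal(q$review, "pending")
  # row 5 pins down only the cause; the open dimensions are queried
  expect_match(q$followup_questions, "specificity", all = FALSE)
  expect_match(q$followup_questions, "environment", all = FALSE)
  expect_false(any(grepl("\\bcause\\b", q$followup_questions)))
})

test_that("feedback advances the plan cursor and closes sessions by the exhaustion rule", {
  # a two-solution plan: physical check first, then an EA step
  kb <- balafon
  kb$guide[[3]]$solutions <- list(
    solution("AP"),
    solution("EA", parameter = "MCL", command = command("decrease", 1)))
  s <- open_session(cpl(3, env = 1), kb, "BalafonBTE")
  s <- review_session(s, "approve")
  # unsatisfied after the AP step: cursor moves to the EA step
  s <- record_feedback(s, FALSE)
  expect_equal(s$plan_cursor, 2L)
  expect_equal(s$status, "open")
  # unsatisfied at the last step: unresolved-consultation closure
  s <- record_feedback(s, FALSE, rating = 2)
  expect_equal(s$status, "unresolved_consultation")
  # satisfied at step 0 resolves immediately
  s2 <- record_feedback(review_session(
    open_session(cpl(3, env = 1), kb, "BalafonBTE"), "approve"), TRUE)
  expect_equal(s2$status, "resolved")
})

test_that("feedback before review violates the clinical-oversight ordering", {
  s <- open_session(cpl(3, env = 1), balafon)
  expect_error(record_feedback(s, TRUE), class = "hafes_ordering_error")
  rejected <- review_session(s, "reject")
  expect_error(record_feedback(rejected, TRUE),
               class = "hafes_ordering_error")
})

test_that("the plan cursor never decreases and events accumulate append-only", {
  kb <- balafon
  kb$guide[[3]]$solutions <- list(solution("AP"), solution("AC"),
                                  solution("C"))
  s <- review_session(open_session(cpl(3, env = 1), kb), "approve")
  cursors <- s$plan_cursor
  n_events <- length(s$events)
  while (s$status == "open") {
    s <- record_feedback(s, FALSE)
    cursors <- c(cursors, s$plan_cursor)
    expect_gt(length(s$events), n_events)
    n_events <- length(s$events)
  }
  expect_true(all(diff(cursors) >= 0))
})

test_that("replaying the event log reconstructs the session exactly", {
  s <- open_session(cpl(9, env = 3), balafon, "BalafonBTE",
                    fitting = list(enerFaibl = 7))
  s <- review_session(s, "approve")
  s <- record_feedback(s, FALSE)
  expect_identical(replay_session(s$events), s)
  # replay also re-validates modifications
  s2 <- open_session(cpl(9, env = 3), balafon, "BalafonBTE")
  s2 <- review_session(s2, "modify", modified_plan = list(
    solution("EA", parameter = "enerFaibl", command = command("decrease", 2),
             target_value = 3)), kb = balafon)
  expect_identical(replay_session(s2$events, kb = balafon), s2)
})

test_that("resolution statistics match a naive recount oracle and flag weak classes", {
  kb <- balafon
  sessions <- list()
  finish <- function(c0, satisfied) {
    s <- review_session(open_session(c0, kb, override_screening = TRUE),
                        "approve")
    record_feedback(s, satisfied)
  }
  # 10 sessions of the whistling-in-quiet class, 7 resolved
  for (i in 1:10) sessions <- c(sessions, list(finish(cpl(3, env = 1),
                                                      i <= 7)))
  # 4 fallback sessions, 1 resolved
  for (i in 1:4) sessions <- c(sessions, list(finish(cpl(12, env = 2),
                                                     i == 1)))
  st <- resolution_stats(sessions, flag_threshold = 0.5)
  row3 <- st$stats[st$stats$class == "3", ]
  expect_equal(row3$attempts, 10L)
  expect_equal(row3$resolved, 7L)
  expect_equal(row3$rate, 0.7)
  rowf <- st$stats[st$stats$class == "fallback", ]
  expect_equal(rowf$attempts, 4L)
  expect_equal(rowf$fallback_count, 4L)
  expect_true("fallback" %in% st$flagged)
  expect_false("3" %in% st$flagged)
  # naive recount oracle over the session list
  expect_equal(sum(st$stats$attempts), length(sessions))
  expect_equal(sum(st$stats$resolved),
               sum(vapply(sessions, function(s)
                 identical(s$status, "resolved"), logical(1))))
  # empty log gives empty stats
  empty <- resolution_stats(list())
  expect_equal(nrow(empty$stats), 0L)
})
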