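# cause codes used below: 1 too loud, 2 too soft, 3 whistling, 9 sound
# cutting; environment codes: 0/1 quiet, 2/3 noisy, 4 unspecified.

test_that("matching picks the most specific entry, with generic entries as fallback tiers", {
  # whistling in a quiet environment -> the specific AP entry (row 3)
  m3 <- match_complaint(cpl(3, env = 1), balafon)
  expect_equal(m3$entry_id, 3L)
  expect_setequal(m3$bound_dimensions, c("cause", "environment"))
  expect_equal(m3$specificity_score, 2L)
  # whistling with environment unspecified -> the generic EA entry (row 5)
  m5 <- match_complaint(cpl(3, env = 4), balafon)
  expect_equal(m5$entry_id, 5L)
  expect_equal(m5$specificity_score, 1L)
  # a combination no entry covers -> consultation fallback with score 0
  mf <- match_complaint(cpl(12, env = 2), balafon)
  expect_true(mf$fallback)
  expect_true(is.na(mf$entry_id))
  expect_equal(mf$specificity_score, 0L)
})

test_that("matching equals the brute-force maximal-specificity oracle over the full complaint space", {
  space <- complaint_space()
  fast <- hafes:::match_space(balafon, space)
  oracle <- vapply(seq_len(nrow(space)), function(i) {
    c0 <- as.integer(space[i, 1:6])
    names(c0) <- names(space)[1:6]
    oracle_match_id(c0, balafon)
  }, integer(1))
  expect_identical(fast, oracle)
  # the single-complaint matcher agrees with the vectorized path on a
  # seeded subsample
  set.seed(3)
  for (i in sample.int(nrow(space), 150)) {
    m <- match_complaint(complaint_descriptor(
      space$cause[i], space$specificity[i], space$environment[i],
      space$activity[i], 0, 0), balafon)
    expect_identical(m$entry_id, fast[i])
  }
})

test_that("adding a satisfied constraint to a pattern never decreases the specificity score", {
  set.seed(21)
  sizes <- get_questionnaire()$sizes
  dims <- c("cause", "specificity", "environment", "activity")
  for (i in 1:50) {
    codes <- vapply(sizes, function(n) sample.int(n, 1) - 1L, integer(1))
    c0 <- do.call(complaint_descriptor, as.list(codes))
    picked <- sample(dims, sample.int(3, 1))
    pattern <- setNames(lapply(picked, function(d) c0[[d]]), picked)
    e1 <- guide_entry(1, pattern, list(solution("C")))
    s1 <- hafes:::entry_score(e1, c0)$score
    extra <- setdiff(dims, picked)[1]
    pattern2 <- c(pattern, setNames(list(c0[[extra]]), extra))
    e2 <- guide_entry(1, pattern2, list(solution("C")))
    s2 <- hafes:::entry_score(e2, c0)$score
    expect_gte(s2, s1)
  }
})

test_that("the step law computes sign * level * step_unit, then clamps", {
  mcl <- Filter(function(p) p$name == "MCL", balafon$parameters)[[1]]
  bte <- Filter(function(d) d$model == "BalafonBTE", balafon$devices)[[1]]
  # single-step decrease from 60 dB: exactly 6 dB down
  a1 <- compute_adjustment(command("decrease", 1), mcl, current_value = 60)
  expect_equal(a1$proposed_value, 54)
  expect_equal(a1$delta, -6)
  expect_false(a1$was_clamped)
  # double-step increase from 62 dB on the BTE: 74 requested, 70 applied
  a2 <- compute_adjustment(command("increase", 2), mcl, bte,
                           current_value = 62)
  expect_equal(a2$requested_value, 74)
  expect_equal(a2$proposed_value, 70)
  expect_true(a2$was_clamped)
  # saturation: already at the ceiling
  a3 <- compute_adjustment(command("increase", 1), mcl, bte,
                           current_value = 70)
  expect_equal(a3$proposed_value, 70)
  expect_equal(a3$delta, 0)
  expect_true(a3$was_clamped)
  # out-of-range current value is pre-clamped with a note
  a4 <- compute_adjustment(command("decrease", 1), mcl, bte,
                           current_value = 90)
  expect_equal(a4$previous_value, 70)
  expect_equal(a4$proposed_value, 64)
  expect_match(a4$notes, "pre-clamped", all = FALSE)
})

test_that("recommendations reproduce the printed guide rows", {
  # "not hearing sounds": consultation with the standby/battery advisory
  r1 <- recommend(cpl(0), balafon)
  expect_equal(r1$match$entry_id, 1L)
  expect_equal(r1$plan[[1]]$category, "C")
  expect_match(r1$advice_text, "standby")
  # "sound cutting in noisy environment": enerFaibl decrease level 4
  r24 <- recommend(cpl(9, env = 3), balafon, device = "BalafonBTE")
  expect_equal(r24$match$entry_id, 24L)
  s <- r24$plan[[1]]
  expect_equal(s$category, "EA")
  expect_equal(s$parameter, "enerFaibl")
  expect_equal(s$command$direction, "decrease")
  expect_equal(s$command$level, 4L)
  expect_length(r24$adjustments, 1)
  expect_equal(r24$adjustments[[1]]$delta, -4)  # 1-unit step, level 4
})

test_that("recommend is pure and deterministic with a bit-stable serialized trace", {
  args <- list(cpl(2, spec = 1, env = 1), balafon, device = "BalafonBTE",
               fitting = list(UCL = 80))
  r1 <- do.call(recommend, args)
  r2 <- do.call(recommend, args)
  expect_identical(r1, r2)
  expect_identical(hafes:::canonical_json(r1$trace),
                   hafes:::canonical_json(r2$trace))
  # French advisory text for the same class
  rf <- recommend(cpl(2, spec = 1, env = 1), balafon, locale = "fr")
  expect_match(rf$advice_text, "Augmentez")
})

test_that("no adjustment ever leaves the effective constraint interval (post-hoc clamp oracle)", {
  set.seed(17)
  space <- complaint_space()
  bte <- Filter(function(d) d$model == "BalafonBTE", balafon$devices)[[1]]
  for (i in sample.int(nrow(space), 120)) {
    c0 <- complaint_descriptor(space$cause[i], space$specificity[i],
                               space$environment[i], space$activity[i],
                               sample(0:6, 1), sample(0:2, 1))
    fitting <- list(MCL = runif(1, 0, 120), UCL = runif(1, 0, 140),
                    nb_vol = runif(1, 1, 10), enerFaibl = runif(1, 0, 10))
    r <- tryCatch(
      recommend(c0, balafon, device = "BalafonBTE", fitting = fitting),
      hafes_screening_error = function(e) NULL)
    if (is.null(r)) next  # flagged inconsistent; totality tested below
    for (a in r$adjustments) {
      p <- Filter(function(p) p$name == a$parameter, balafon$parameters)[[1]]
      rng <- effective_range(p, bte)
      expect_gte(a$proposed_value, rng[1])
      expect_lte(a$proposed_value, rng[2])
      expect_equal(a$delta, a$proposed_value - a$previous_value)
    }
  }
})

test_that("every valid complaint yields a recommendation once screening passes or is overridden", {
  set.seed(29)
  space <- complaint_space()
  for (i in sample.int(nrow(space), 100)) {
    c0 <- complaint_descriptor(space$cause[i], space$specificity[i],
                               space$environment[i], space$activity[i], 0, 0)
    r <- recommend(c0, balafon, override_screening = TRUE)
    expect_s3_class(r, "hafes_recommendation")
    expect_gte(length(r$plan), 1)
    expect_gte(length(r$trace), 1)
  }
})

test_that("inconsistent complaints are refused unless explicitly overridden", {
  bad <- complaint_descriptor(6, 4, 1, 4, 3, 1)
  err <- expect_error(recommend(bad, balafon),
                      class = "hafes_screening_error")
  expect_s3_class(err$report, "hafes_consistency_report")
  r <- recommend(bad, balafon, override_screening = TRUE)
  expect_true(any(vapply(r$trace, function(ev)
    identical(ev$type, "screening") && isTRUE(ev$overridden), logical(1))))
})

test_that("explanations name the entry, matched dimensions, step law and clamps", {
  txt3 <- explain(recommend(cpl(3, env = 1), balafon))
  expect_match(txt3, "guide entry 3", all = FALSE)
  expect_match(txt3, "cause, environment", all = FALSE)
  # fallback explanation advises consultation
  txtf <- explain(recommend(cpl(12, env = 2), balafon))
  expect_match(txtf, "No complaint class matched", all = FALSE)
  expect_match(txtf, "consult", ignore.case = TRUE, all = FALSE)
  # clamped MCL case reports requested 74, applied 70
  rc <- recommend(cpl(2, env = 1), balafon, device = "BalafonBTE",
                  fitting = list(MCL = 62))
  txtc <- explain(rc)
  expect_match(txtc, "requested 74, applied 70", all = FALSE)
})

test_that("demographic guard fields act as extra pattern dimensions", {
  kb <- balafon
  kb$guide[[length(kb$guide) + 1L]] <- guide_entry(
    99, list(cause = 3L, environment = c(0L, 1L), age_range = c(65, 120)),
    list(solution("C")))
  young <- match_complaint(cpl(3, env = 1), kb,
                           demographics = list(age = 30))
  old <- match_complaint(cpl(3, env = 1), kb,
                         demographics = list(age = 72))
  expect_equal(young$entry_id, 3L)   # guard not satisfied
  expect_equal(old$entry_id, 99L)    # guard adds specificity
  expect_equal(old$specificity_score, 3L)
  # without demographics the guarded entry never fires
  expect_equal(match_complaint(cpl(3, env = 1), kb)$entry_id, 3L)
})
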