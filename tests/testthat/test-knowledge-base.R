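test_that("the packaged Balafon fixture validates cleanly and has the expected structure", {
  report <- validate_knowledge_base(balafon)
  expect_true(report$valid)
  expect_length(report$errors, 0)
  pnames <- vapply(balafon$parameters, `[[`, character(1), "name")
  expect_setequal(pnames, c("MCL", "UCL", "nb_vol", "enerFaibl"))
  ef <- Filter(function(p) p$name == "enerFaibl", balafon$parameters)[[1]]
  expect_equal(ef$group, "silence")
  aliases <- vapply(balafon$parameters, function(p)
    p$manufacturer_alias %||% "", character(1))
  expect_true(all(c("min_dyn", "max_dyn") %in% aliases))
  bte <- Filter(function(d) d$form_factor == "BTE", balafon$devices)[[1]]
  expect_equal(bte$overrides$MCL, c(0, 70))
})

test_that("the packaged fixture file loads and equals the in-code builder", {
  path <- system.file("extdata", "balafon_kb.json", package = "hafes")
  skip_if(path == "", "fixture not installed")
  kb <- load_knowledge_base(path)
  tf1 <- withr::local_tempfile(fileext = ".json")
  tf2 <- withr::local_tempfile(fileext = ".json")
  save_knowledge_base(kb, tf1)
  save_knowledge_base(balafon, tf2)
  expect_identical(readLines(tf1, encoding = "UTF-8"),
                   readLines(tf2, encoding = "UTF-8"))
})

test_that("a minimal knowledge base loads with empty overrides", {
  tf <- withr::local_tempfile(fileext = ".json")
  save_knowledge_base(minimal_kb(), tf)
  kb <- load_knowledge_base(tf)
  expect_length(kb$devices, 0)
  expect_length(kb$guide, 1)
  expect_equal(kb$parameters[[1]]$name, "MCL")
})

test_that("save-then-load is the identity and repeated saves are byte-identical", {
  tf1 <- withr::local_tempfile(fileext = ".json")
  tf2 <- withr::local_tempfile(fileext = ".json")
  tf3 <- withr::local_tempfile(fileext = ".json")
  save_knowledge_base(balafon, tf1)
  kb2 <- load_knowledge_base(tf1)
  save_knowledge_base(kb2, tf2)
  expect_identical(readBin(tf1, "raw", file.size(tf1)),
                   readBin(tf2, "raw", file.size(tf2)))
  # structural round trip: the reloaded KB behaves identically
  expect_equal(length(kb2$guide), length(balafon$guide))
  expect_identical(match_complaint(cpl(9, env = 2), kb2)$entry_id,
                   match_complaint(cpl(9, env = 2), balafon)$entry_id)
  # two saves of the same object are byte-identical
  save_knowledge_base(balafon, tf3)
  expect_identical(readBin(tf1, "raw", file.size(tf1)),
                   readBin(tf3, "raw", file.size(tf3)))
})

test_that("unicode French labels survive the round trip", {
  tf <- withr::local_tempfile(fileext = ".json")
  save_knowledge_base(balafon, tf)
  kb <- load_knowledge_base(tf)
  e8 <- Filter(function(g) g$id == 8L, kb$guide)[[1]]
  expect_match(e8$recommendation_text$fr, "thérapie")
})

test_that("parse failures and dangling references are reported as classed errors", {
  tf <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json", tf)
  expect_error(load_knowledge_base(tf), class = "hafes_format_error")
  expect_error(load_knowledge_base(file.path(tempdir(), "no_such_kb.json")),
               class = "hafes_format_error")
  # EA solution referencing an undeclared parameter
  kb <- minimal_kb()
  kb$guide[[1]] <- guide_entry(1, list(cause = 0L), list(
    solution("EA", parameter = "ghost", command = command("decrease", 1))))
  save_knowledge_base_raw <- function(kb, path)
    hafes:::write_canonical_json(hafes:::kb_to_list(kb), path)
  save_knowledge_base_raw(kb, tf)
  err <- expect_error(load_knowledge_base(tf),
                      class = "hafes_validation_error")
  expect_match(conditionMessage(err), "ghost")
})

test_that("validation catches broken invariants and names the offending entry", {
  kb <- minimal_kb()
  # EA without parameter/command is rejected by the constructor itself
  expect_error(solution("EA"), class = "hafes_validation_error")
  # AE accepted as an alias for EA
  s <- solution("AE", parameter = "MCL", command = command("increase", 1))
  expect_equal(s$category, "EA")
  # bypass the constructor to exercise the validator on a corrupted entry
  kb$guide[[1]]$solutions[[1]] <- structure(
    list(category = "EA", parameter = NULL, command = NULL,
         advice = NULL, provenance = "expert"),
    class = "hafes_solution")
  rep1 <- validate_knowledge_base(kb, check_reachability = FALSE)
  expect_false(rep1$valid)
  expect_match(rep1$errors, "entry 1", all = FALSE)

  # pattern citing an out-of-bounds cause code (catalog is 0-17)
  kb2 <- minimal_kb()
  kb2$guide[[1]]$pattern$cause <- 18L
  rep2 <- validate_knowledge_base(kb2, check_reachability = FALSE)
  expect_false(rep2$valid)
  expect_match(rep2$errors, "out-of-bounds cause", all = FALSE)

  # unreachable entries produce warnings, not errors: a duplicate of the
  # first entry's pattern is shadowed everywhere by the lower id
  kb3 <- minimal_kb()
  kb3$guide[[2]] <- guide_entry(2, list(cause = 0L),
                                list(solution("C")))
  rep3 <- validate_knowledge_base(kb3)
  expect_true(rep3$valid)
  expect_match(rep3$warnings, "unreachable", all = FALSE)
})

test_that("constructor invariants hold for parameters, commands and policy", {
  expect_error(parameter_spec("X", "dynamic", "dB", c(10, 0), 5, 1),
               class = "hafes_validation_error")
  expect_error(parameter_spec("X", "dynamic", "dB", c(0, 10), 50, 1),
               class = "hafes_validation_error")
  expect_error(parameter_spec("X", "dynamic", "dB", c(0, 10), 5, 0),
               class = "hafes_validation_error")
  expect_error(command("decrease", 0), class = "hafes_validation_error")
  expect_equal(format(command("decrease", 2)), "decrease--")
  expect_equal(format(command("increase", 1)), "increase+")
  expect_error(adjustment_policy(c(12, 4), 6),
               class = "hafes_validation_error")
  expect_error(consistency_rule("r", list(cause = 0L), "msg"),
               class = "hafes_validation_error")
})

test_that("clamping uses the intersection of typical range and device override", {
  mcl <- Filter(function(p) p$name == "MCL", balafon$parameters)[[1]]
  bte <- Filter(function(d) d$model == "BalafonBTE", balafon$devices)[[1]]
  r1 <- clamp_to_constraints(75, mcl, bte)
  expect_equal(r1$value, 70)
  expect_true(r1$was_clamped)
  r2 <- clamp_to_constraints(35, mcl, bte)
  expect_equal(r2$value, 35)
  expect_false(r2$was_clamped)
  r3 <- clamp_to_constraints(-5, mcl)
  expect_equal(r3$value, 0)
  expect_true(r3$was_clamped)
  # without the device, the full typical range applies
  expect_equal(clamp_to_constraints(110, mcl)$value, 110)
  expect_equal(clamp_to_constraints(110, mcl, bte)$value, 70)
  # empty intersection is a configuration error naming the parameter
  bad <- device_profile("broken", "BTE", list(MCL = c(-10, -5)))
  err <- expect_error(clamp_to_constraints(50, mcl, bad),
                      class = "hafes_constraint_error")
  expect_match(conditionMessage(err), "MCL")
  expect_match(conditionMessage(err), "broken")
})

test_that("clamping is idempotent, bounded and monotone over randomized inputs", {
  set.seed(7)
  mcl <- Filter(function(p) p$name == "MCL", balafon$parameters)[[1]]
  devices <- c(balafon$devices, list(NULL))
  for (i in 1:50) {
    dev <- devices[[sample.int(length(devices), 1)]]
    v <- runif(1, -50, 200)
    r <- clamp_to_constraints(v, mcl, dev)
    expect_equal(clamp_to_constraints(r$value, mcl, dev)$value, r$value)
    expect_gte(r$value, r$range[1])
    expect_lte(r$value, r$range[2])
    # monotone non-decreasing in the input
    r2 <- clamp_to_constraints(v + runif(1, 0, 30), mcl, dev)
    expect_gte(r2$value, r$value)
  }
})
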